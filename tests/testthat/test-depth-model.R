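test_that("drainage classes map onto the published aeration depths", {
  expect_equal(aeration_depth(1:7), c(10, 40, 75, 115, 160, 210, 265))
  expect_true(all(diff(aeration_depth(1:7)) > 0))
  expect_error(aeration_depth(0), "1-7")
  expect_error(aeration_depth(8), "1-7")
  expect_error(aeration_depth(2.5), "1-7")
  expect_true(is.na(aeration_depth(NA)))
})

test_that("bedrock is the shallower of the record and a >90 v% layer", {
  a <- benign_layers("a"); a$depth_to_bedrock <- 80
  expect_equal(bedrock_depth(a)$bedrock_depth, 80)
  b <- benign_layers("b"); b$cf[5] <- 95  # layer 60-100
  expect_equal(bedrock_depth(b)$bedrock_depth, 60)
  c_ <- benign_layers("c"); c_$depth_to_bedrock <- 80; c_$cf[4] <- 95
  expect_equal(bedrock_depth(c_)$bedrock_depth, 30)
  d <- benign_layers("d"); d$cf[4] <- 90  # exactly 90 does not count
  expect_true(is.na(bedrock_depth(d)$bedrock_depth))
})

test_that("rootable depth is the minimum candidate with correct attribution", {
  no_restr <- tibble::tibble(profile_id = character(), factor = character(),
                             restriction_depth = numeric())
  # nothing restricts: crop maximum
  e1 <- rzd(benign_layers("p", drainage_class = NA), no_restr)
  expect_equal(e1$rzd, 150)
  expect_equal(e1$limiting_factor, "depth max")
  # drainage class 3 alone
  e2 <- rzd(benign_layers("p", drainage_class = 3), no_restr)
  expect_equal(e2$rzd, 75)
  expect_equal(e2$limiting_factor, "depth aeration")
  # bedrock 60 beats aeration 115
  x <- benign_layers("p", drainage_class = 4)
  x$depth_to_bedrock <- 60
  e3 <- rzd(x, no_restr)
  expect_equal(e3$rzd, 60)
  expect_equal(e3$limiting_factor, "depth soil")
  # a layer factor shallower than everything else
  restr <- tibble::tibble(profile_id = "p", factor = "sodicity_exch_na",
                          restriction_depth = 40)
  e4 <- rzd(x, restr)
  expect_equal(e4$rzd, 40)
  expect_equal(e4$limiting_factor, "sodicity_exch_na")
})

test_that("ties go to the fixed precedence and aeration beyond the crop
           depth never limits", {
  no_restr <- tibble::tibble(profile_id = character(), factor = character(),
                             restriction_depth = numeric())
  # bedrock and aeration both at 75: bedrock wins
  x <- benign_layers("p", drainage_class = 3)
  x$depth_to_bedrock <- 75
  e <- rzd(x, no_restr)
  expect_equal(e$limiting_factor, "depth soil")
  # bedrock at exactly 150 ties with the crop maximum: crop maximum wins
  y <- benign_layers("p", drainage_class = NA)
  y$depth_to_bedrock <- 150
  expect_equal(rzd(y, no_restr)$limiting_factor, "depth max")
  # classes 5-7 aerate beyond 150 cm and cannot limit
  for (dc in 5:7) {
    ez <- rzd(benign_layers("p", drainage_class = dc), no_restr)
    expect_equal(ez$limiting_factor, "depth max")
    expect_equal(ez$rzd, 150)
  }
})

test_that("rootable depth never exceeds any candidate on synthetic data", {
  prof <- generate_profiles("mixed", n = 120, seed = 17)
  ev <- evaluate_profiles(prof, quiet = TRUE)
  de <- ev$depth_eval
  expect_true(all(de$rzd <= de$max_crop_depth))
  expect_true(all(de$rzd >= 0))
  expect_true(all(is.na(de$bedrock_depth) | de$rzd <= de$bedrock_depth))
  expect_true(all(is.na(de$aeration_depth) | de$rzd <= de$aeration_depth))
  expect_true(all(is.na(de$layer_restriction) |
                    de$rzd <= de$layer_restriction))
  attained <- purrr::pmap_lgl(de, function(...) {
    r <- list(...)
    isTRUE(all.equal(r$rzd, min(r$max_crop_depth, r$bedrock_depth,
                                r$aeration_depth, r$layer_restriction,
                                na.rm = TRUE)))
  })
  expect_true(all(attained))
})

test_that("limiting-factor summary conserves area and restricted volume", {
  prof <- generate_profiles("mixed", n = 100, seed = 23)
  ev <- evaluate_profiles(prof, quiet = TRUE)
  sm <- summarize_limiting_factors(ev$depth_eval, area_km2 = 1)
  expect_equal(sum(sm$area_km2), 100)  # extents partition the area
  expect_equal(sum(sm$restricted_volume_km3),
               sum((150 - ev$depth_eval$rzd) * 1e-5))
  # single cells: worked volume arithmetic
  one <- ev$depth_eval[1, ]
  one$rzd <- 50; one$limiting_factor <- "depth soil"
  expect_equal(summarize_limiting_factors(one)$restricted_volume_km3, 1e-3)
  one$rzd <- 150; one$limiting_factor <- "depth max"
  expect_equal(summarize_limiting_factors(one)$restricted_volume_km3, 0)
})
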
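test_that("uniform 10 v% capacity over 150 cm gives exactly 150 mm", {
  ev <- evaluate_profiles(pinned_retention_layers(), quiet = TRUE)
  expect_equal(ev$depth_eval$rzd, 150)
  expect_equal(ev$water$rz_pawhc_mm, 150)
  expect_equal(ev$water$mm_unlimited, 150)
  expect_equal(ev$water$pawhc_weighted_v, 10)
  expect_equal(ev$water$sfef_weighted, 1)
})

test_that("per-interval contributions are pro-rata overlaps with the root
           zone", {
  x <- layer_retention(pinned_retention_layers(pawhc_v = 8, cf = 10))
  de <- tibble::tibble(profile_id = "flat", rzd = 100, max_crop_depth = 150)
  w <- rz_pawhc(x, de)
  expect_equal(w$rz_pawhc_mm, 8 / 10 * 0.9 * 100)  # 72 mm
  detail <- rz_pawhc(x, de, detail = TRUE)
  expect_equal(detail$thickness_root_zone, c(5, 10, 15, 30, 40, 0))
  expect_equal(sum(detail$water_mm), w$rz_pawhc_mm)
  # a zero rootable depth is a valid 0 mm result
  de0 <- dplyr::mutate(de, rzd = 0)
  expect_equal(rz_pawhc(x, de0)$rz_pawhc_mm, 0)
})

test_that("the 100-200 cm interval contributes only up to the crop depth", {
  x <- layer_retention(pinned_retention_layers(pawhc_v = 10, cf = 0))
  de <- tibble::tibble(profile_id = "flat", rzd = 150, max_crop_depth = 150)
  detail <- rz_pawhc(x, de, detail = TRUE)
  expect_equal(detail$thickness_root_zone[6], 50)  # not 100
})

test_that("capacity is monotone in rootable depth and truncation is
           additive", {
  prof <- generate_profiles("mixed", n = 40, seed = 31)
  ret <- layer_retention(prof)
  ev <- evaluate_profiles(prof, quiet = TRUE)
  de <- ev$depth_eval
  # monotone: deepen every root zone by 10 cm (capped at 150)
  deeper <- dplyr::mutate(de, rzd = pmin(rzd + 10, 150))
  w0 <- rz_pawhc(ret, de)
  w1 <- rz_pawhc(ret, deeper)
  expect_true(all(w1$rz_pawhc_mm >= w0$rz_pawhc_mm - 1e-12))
  # additive: shortening the crop depth equals truncating contributions
  de100 <- dplyr::mutate(de, rzd = pmin(rzd, 100), max_crop_depth = 100)
  w100 <- rz_pawhc(ret, de100, max_crop_depth = 100)
  detail <- rz_pawhc(ret, de, detail = TRUE) |>
    dplyr::inner_join(de100[c("profile_id", "rzd")], by = "profile_id",
                      suffix = c("", "_short")) |>
    dplyr::mutate(w = pmax(pmin(bottom, rzd_short) - pmin(top, rzd_short),
                           0) * pawhc / 10 * sfef) |>
    dplyr::group_by(profile_id) |>
    dplyr::summarise(mm = sum(w))
  expect_equal(w100$rz_pawhc_mm, detail$mm)
})

test_that("the limitation decomposition is nested where it must be", {
  prof <- generate_profiles("mixed", n = 60, seed = 37)
  ev <- evaluate_profiles(prof, quiet = TRUE)
  w <- ev$water
  expect_true(all(w$mm_pawhc_sfef <= w$mm_pawhc + 1e-9))
  expect_true(all(w$mm_full <= w$mm_pawhc_sfef + 1e-9))
  expect_equal(w$mm_full, w$rz_pawhc_mm)
  expect_true(all(w$mm_unlimited == 150))
})

test_that("profile reports carry every intermediate and round-trip as JSON", {
  prof <- generate_profiles("sodic_lowland", n = 2, seed = 3)
  ev <- evaluate_profiles(prof, quiet = TRUE)
  id <- ev$depth_eval$profile_id[1]
  rep1 <- profile_report(ev, id)
  expect_equal(rep1$depth_evaluation$limiting_factor, "sodicity_exch_na")
  expect_true(rep1$restriction_depths$restriction_depth[
    rep1$restriction_depths$factor == "sodicity_exch_na"] < 150)
  expect_setequal(names(rep1),
                  c("profile_id", "layers", "factor_ri",
                    "restriction_depths", "depth_evaluation", "water",
                    "intervals"))
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_report(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$depth_evaluation$rzd, rep1$depth_evaluation$rzd)
  expect_equal(back$water$rz_pawhc_mm, rep1$water$rz_pawhc_mm)
  expect_equal(unlist(back$factor_ri$ri), rep1$factor_ri$ri)
  expect_error(profile_report(ev, "nope"), "unknown profile")
})

test_that("an unconstrained profile reports no restriction anywhere", {
  prof <- generate_profiles("unconstrained", n = 1, seed = 8)
  ev <- evaluate_profiles(prof, quiet = TRUE)
  rep1 <- profile_report(ev, prof$profile_id[1])
  expect_true(all(rep1$factor_ri$ri >= 20))
  expect_equal(rep1$depth_evaluation$rzd, 150)
  expect_true(all(is.na(rep1$restriction_depths$restriction_depth)))
})
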
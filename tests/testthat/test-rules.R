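test_that("the packaged rule set reproduces every published breakpoint", {
  rules <- default_rules()
  ref <- table4_reference()
  expect_setequal(unique(rules$factor), names(ref))
  for (f in names(ref)) {
    vals <- ref[[f]][, 1]
    ris <- ref[[f]][, 2]
    expect_identical(eval_rule(rules, vals, factor = f), ris,
                     label = paste("breakpoints of", f))
  }
})

test_that("rule evaluation interpolates linearly and clamps outside", {
  rules <- default_rules()
  expect_equal(eval_rule(rules, 4.0, "acidity_ph"), 20)
  # halfway up the graded limb of the acidity rule
  expect_equal(eval_rule(rules, 4.75, "acidity_ph"), 60)
  expect_equal(eval_rule(rules, 4.5, "acidity_ph"),
               20 + (4.5 - 4) / 1.5 * 80)
  expect_equal(eval_rule(rules, 30, "porosity_vmc_sat"), 20)
  # constant beyond the outer breakpoints
  expect_equal(eval_rule(rules, 0.5, "acidity_ph"), 0)
  expect_equal(eval_rule(rules, 13.9, "acidity_ph"), 100)
  expect_equal(eval_rule(rules, -5, "texture_f_sand"), 100)
  expect_true(is.na(eval_rule(rules, NA_real_, "acidity_ph")))
})

test_that("rule output stays in [0, 100] and is monotone between breakpoints", {
  rules <- default_rules()
  for (f in unique(rules$factor)) {
    rule <- rules[rules$factor == f, ]
    grid <- seq(min(rule$value) - 1, max(rule$value) + 1, length.out = 400)
    ri <- eval_rule(rule, grid)
    expect_true(all(ri >= 0 & ri <= 100), label = f)
    for (i in seq_len(nrow(rule) - 1)) {
      seg <- seq(rule$value[i], rule$value[i + 1], length.out = 20)
      ri_seg <- eval_rule(rule, seg)
      expect_true(all(diff(ri_seg) >= -1e-9) || all(diff(ri_seg) <= 1e-9),
                  label = paste(f, "segment", i))
    }
  }
})

test_that("inverting the acidity rule reads off stricter pH thresholds", {
  rules <- default_rules()
  ph30 <- invert_rule(rules, 30, factor = "acidity_ph")
  expect_equal(ph30, 4 + (30 - 20) / (100 - 20) * 1.5)  # 4.1875
  expect_equal(round(ph30, 1), 4.2)
  expect_equal(invert_rule(rules, 20, factor = "acidity_ph"), 4)
  expect_equal(invert_rule(rules, 100, factor = "sodicity_exch_na"), 1)
})

test_that("clay-corrected bulk density matches its critical densities", {
  expect_equal(f_bd(1.25, 100), 0)
  expect_equal(f_bd(1.60, 0), 0)
  expect_equal(f_bd(1.90, 0), 0.30)
  expect_equal(eval_rule(default_rules(), f_bd(1.90, 0), "porosity_f_bd"), 0)
  expect_error(f_bd(1.4, 120), "clay")
  expect_error(f_bd(-1, 30), "bd")
})

test_that("aluminium saturation is a CEC percentage, skipped when undefined", {
  rules <- default_rules()
  expect_equal(f_exch_al(3, 10), 30)
  expect_equal(eval_rule(rules, f_exch_al(3, 10), "toxicity_f_exch_al"), 100)
  expect_equal(f_exch_al(0, 10), 0)
  expect_equal(f_exch_al(7.5, 10), 75)
  expect_equal(eval_rule(rules, f_exch_al(7.5, 10), "toxicity_f_exch_al"), 20)
  expect_equal(f_exch_al(30, 10), 100)  # clamped
  expect_warning(out <- f_exch_al(3, 0), "undefined")
  expect_true(is.na(out))
})

test_that("texture change is the increase assigned to the deeper interval", {
  x <- benign_layers()
  x$sand <- c(40, 40, 40, 95, 95, 95)
  x$silt <- c(30, 30, 30, 3, 3, 3)
  x$clay <- c(30, 30, 30, 2, 2, 2)
  tc <- texture_change(x)
  expect_equal(tc$d_sand, c(0, 0, 0, 55, 0, 0))
  expect_equal(eval_rule(default_rules(), 55, "texture_f_sand"), 0)
  # clay increase of exactly 30 is still fully adequate
  y <- benign_layers()
  y$clay <- c(10, 10, 10, 40, 40, 40)
  y$sand <- 100 - y$clay - y$silt
  tcy <- texture_change(y)
  expect_equal(tcy$d_clay[4], 30)
  expect_equal(eval_rule(default_rules(), 30, "texture_f_clay"), 100)
  # uniform texture: no change anywhere
  expect_true(all(texture_change(benign_layers())$d_sand == 0))
  # single-layer profile
  one <- benign_layers()[1, ]
  expect_equal(texture_change(one)$d_sand, 0)
})

test_that("rules files round-trip through CSV with custom thresholds", {
  rules <- default_rules()
  stricter <- dplyr::mutate(rules, value = ifelse(
    factor == "acidity_ph" & ri == 20, 4.2, value))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(stricter, path, progress = FALSE)
  back <- read_rules(path)
  expect_equal(eval_rule(back, 4.2, "acidity_ph"), 20)
  # malformed rules are rejected
  broken <- rules[rules$ri != 20, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2, progress = FALSE)
  expect_error(read_rules(path2), "malformed")
})
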
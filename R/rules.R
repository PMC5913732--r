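#' Rootability-index rules
#'
#' Loads a rule table in long format: one row per breakpoint with columns
#' `factor`, `variable`, `unit`, `value`, `ri`. Between breakpoints the
#' rootability index (RI, % adequacy for root growth) is linearly
#' interpolated; beyond the outer breakpoints it is constant. The packaged
#' default transcribes the published maize rule set: porosity (saturated
#' moisture content and clay-corrected bulk density), soil volume (coarse
#' fragments), texture (sand content, abrupt sand/clay increases), induration
#' (carbonates, gypsum), acidity and alkalinity (pH-H2O), salinity (EC),
#' sodicity (exchangeable Na) and aluminium toxicity (exchangeable Al and its
#' CEC saturation).
#'
#' @param path Rules CSV (or YAML with the same fields); default the packaged
#'   rule set.
#' @return Tibble of breakpoints, ordered by factor and value.
#' @export
read_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rootability_rules.csv",
                        package = "rzpawhc")
  }
  rules <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    purrr::map_dfr(yaml::read_yaml(path), tibble::as_tibble)
  } else {
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  }
  need <- c("factor", "variable", "unit", "value", "ri")
  if (!all(need %in% names(rules))) {
    stop("rules file lacks column(s): ",
         paste(setdiff(need, names(rules)), collapse = ", "), call. = FALSE)
  }
  # keep the file's factor order (it fixes tie-break precedence downstream),
  # sort breakpoints by value within each factor
  rules <- dplyr::arrange(rules, match(.data$factor, unique(.data$factor)),
                          .data$value)
  chk <- rules |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      mono = all(diff(.data$value) > 0),
      has_threshold = any(.data$ri == 20),
      ri_ok = all(.data$ri >= 0 & .data$ri <= 100),
      .groups = "drop"
    )
  bad <- chk$factor[!(chk$mono & chk$has_threshold & chk$ri_ok)]
  if (length(bad) > 0) {
    stop("malformed rule(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rules
}

#' @rdname read_rules
#' @export
default_rules <- function() read_rules()

#' Evaluate a rootability rule
#'
#' Piecewise-linear interpolation of the rootability index at `value`, exact
#' at the breakpoints and constant beyond the outer ones.
#'
#' @param rule Breakpoints of one factor: a tibble with `value` and `ri`
#'   columns, or a full rules table plus `factor` to select from it.
#' @param value Numeric vector of soil-property values.
#' @param factor Factor name, required when `rule` covers several factors.
#' @return Rootability index in 0-100 (%), NA where `value` is NA.
#' @export
eval_rule <- function(rule, value, factor = NULL) {
  if (!is.null(factor)) rule <- rule[rule$factor == factor, ]
  if (nrow(rule) < 2) stop("rule needs at least 2 breakpoints", call. = FALSE)
  out <- rep(NA_real_, length(value))
  ok <- !is.na(value)
  if (any(ok)) {
    out[ok] <- stats::approx(rule$value, rule$ri, xout = value[ok],
                             rule = 2, ties = "ordered")$y
  }
  out
}

#' Invert a rootability rule on its graded limb
#'
#' Returns the soil-property value at which the rule's rootability index
#' equals `ri`, searched over the breakpoint segments (shallowest matching
#' segment first). Used, e.g., to read off the stricter pH threshold implied
#' by raising the threshold index.
#'
#' @inheritParams eval_rule
#' @param ri Target rootability index (scalar, 0-100).
#' @return Soil-property value (in the rule's unit).
#' @export
invert_rule <- function(rule, ri, factor = NULL) {
  if (!is.null(factor)) rule <- rule[rule$factor == factor, ]
  stopifnot(length(ri) == 1, ri >= 0, ri <= 100)
  v <- rule$value
  r <- rule$ri
  for (i in seq_len(nrow(rule) - 1)) {
    lo <- min(r[i], r[i + 1]); hi <- max(r[i], r[i + 1])
    if (ri >= lo && ri <= hi && r[i] != r[i + 1]) {
      return(v[i] + (ri - r[i]) / (r[i + 1] - r[i]) * (v[i + 1] - v[i]))
    }
  }
  stop("rootability index ", ri, " not attained on any graded segment",
       call. = FALSE)
}

#' Clay-corrected bulk density excess
#'
#' Bulk density relative to a critical, texture-dependent bulk density:
#' `f_bd = bd - (1.6 - 0.0035 * clay)`, so the critical density runs from
#' 1.60 kg/dm3 for pure sand to 1.25 kg/dm3 for pure clay. Positive values
#' mean denser-than-critical soil.
#'
#' @param bd Bulk density of the fine earth, kg/dm3.
#' @param clay Clay content, g/100 g.
#' @return f.BD in kg/dm3.
#' @export
f_bd <- function(bd, clay) {
  if (any(!is.na(clay) & (clay < 0 | clay > 100))) {
    stop("clay must be in [0, 100]", call. = FALSE)
  }
  if (any(!is.na(bd) & bd <= 0)) stop("bd must be > 0", call. = FALSE)
  bd - (1.6 - 0.0035 * clay)
}

#' Exchangeable aluminium saturation
#'
#' `f_exch_al = 100 * exch_al / cec`, clamped at 100%. A zero or missing CEC
#' leaves the saturation undefined (NA with a warning), so the factor is
#' skipped rather than divided by zero.
#'
#' @param exch_al Exchangeable aluminium, cmolc/kg.
#' @param cec Cation exchange capacity, cmolc/kg.
#' @return Aluminium saturation, % of CEC, in 0-100.
#' @export
f_exch_al <- function(exch_al, cec) {
  if (any(!is.na(exch_al) & exch_al < 0)) {
    stop("exch_al must be >= 0", call. = FALSE)
  }
  undef <- !is.na(exch_al) & (is.na(cec) | cec <= 0)
  if (any(undef)) {
    warning("aluminium saturation undefined (CEC <= 0 or missing) for ",
            sum(undef), " layer(s); factor skipped there", call. = FALSE)
  }
  out <- ifelse(undef, NA_real_, pmin(100 * exch_al / cec, 100))
  out
}

#' Abrupt texture change between consecutive depth intervals
#'
#' The increase of sand (`d_sand`) and clay (`d_clay`) content from each
#' interval to the next deeper one, assigned to the deeper interval; the
#' surface interval gets 0. Decreases count as 0 change for the rules, but
#' the signed difference is returned so it can be inspected.
#'
#' @param x Layer table with `profile_id`, `top`, `sand`, `clay`.
#' @return `x` with `d_sand` and `d_clay` columns added.
#' @export
texture_change <- function(x) {
  x |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$profile_id, .data$top) |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::mutate(
      d_sand = dplyr::coalesce(.data$sand - dplyr::lag(.data$sand), 0),
      d_clay = dplyr::coalesce(.data$clay - dplyr::lag(.data$clay), 0)
    ) |>
    dplyr::ungroup()
}
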
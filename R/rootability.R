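#' Rootability indices of every soil factor for every layer
#'
#' Evaluates each rule of the rule table on every depth interval. Derived
#' variables (`f_bd`, `d_sand`, `d_clay`, `f_exch_al`) are computed first;
#' the porosity rule on saturated moisture content uses the `vmc_sat` column,
#' so retention must have been computed (see [layer_retention()]). Factors
#' whose input property is missing for a layer are skipped there (no RI row):
#' an unmeasured property is never treated as adverse. Skipped factors are
#' reported via a message unless `quiet = TRUE`.
#'
#' @param x Layer table with retention columns (from [layer_retention()]).
#' @param rules Rule table, see [read_rules()].
#' @param threshold Threshold rootability index (%), default 20. A layer is
#'   adequate iff the minimum RI over its evaluated factors is >= threshold
#'   (restriction requires RI strictly below it).
#' @param quiet Suppress the skipped-factor message.
#' @return Long tibble: `profile_id`, `top`, `bottom`, `factor`, `value`,
#'   `ri`, plus a logical `adequate` per layer repeated on each row.
#' @export
evaluate_layers <- function(x, rules = default_rules(), threshold = 20,
                            quiet = FALSE) {
  stopifnot(is.data.frame(x), "vmc_sat" %in% names(x))
  x <- texture_change(x)
  x$f_bd <- f_bd(x$bd, x$clay)
  x$f_exch_al <- suppressWarnings(f_exch_al(x$exch_al, x$cec))
  for (nm in setdiff(unique(rules$variable), names(x))) x[[nm]] <- NA_real_

  per_factor <- rules |>
    dplyr::group_by(.data$factor) |>
    dplyr::group_map(function(rule, key) {
      var <- rule$variable[1]
      tibble::tibble(
        profile_id = x$profile_id, top = x$top, bottom = x$bottom,
        factor = key$factor, variable = var, value = x[[var]],
        ri = eval_rule(rule, x[[var]])
      )
    })
  ri_long <- dplyr::bind_rows(per_factor)

  skipped <- ri_long |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(n_skipped = sum(is.na(.data$ri)), .groups = "drop") |>
    dplyr::filter(.data$n_skipped > 0)
  if (!quiet && nrow(skipped) > 0) {
    message("factor(s) skipped where input is missing: ",
            paste0(skipped$factor, " (", skipped$n_skipped, " layers)",
                   collapse = ", "))
  }
  ri_long <- dplyr::filter(ri_long, !is.na(.data$ri))

  adequacy <- ri_long |>
    dplyr::group_by(.data$profile_id, .data$top, .data$bottom) |>
    dplyr::summarise(adequate = min(.data$ri) >= threshold, .groups = "drop")
  dplyr::left_join(ri_long, adequacy,
                   by = c("profile_id", "top", "bottom")) |>
    dplyr::arrange(.data$profile_id, .data$factor, .data$top)
}

# Depth-continuous RI for one factor of one profile: piecewise-linear through
# the interval midpoints, constant above the first and below the last.
interp_ri <- function(depth, mid, ri) {
  stats::approx(mid, ri, xout = depth, rule = 2, ties = "ordered")$y
}

restriction_depth_one <- function(mid, ri, threshold) {
  if (ri[1] < threshold) return(0)
  if (length(mid) == 1) return(NA_real_)
  for (i in seq_len(length(mid) - 1)) {
    if (ri[i] >= threshold && ri[i + 1] < threshold) {
      return(mid[i] + (ri[i] - threshold) / (ri[i] - ri[i + 1]) *
               (mid[i + 1] - mid[i]))
    }
  }
  NA_real_
}

#' Shallowest restricted depth per soil factor
#'
#' The per-interval rootability indices are made depth-continuous by linear
#' interpolation through the interval midpoints (constant above the first and
#' below the last midpoint), and each factor is scanned downward for the
#' shallowest depth at which its RI falls below the threshold index. At the
#' crossing itself (RI exactly equal to the threshold) soil is still adequate;
#' the reported depth is the infimum of the restricted zone. A factor whose RI
#' never drops below the threshold contributes no restriction (NA).
#'
#' @param ri_long Long RI table from [evaluate_layers()].
#' @param threshold Threshold rootability index (%), default 20.
#' @return Tibble: `profile_id`, `factor`, `restriction_depth` (cm, NA if
#'   unrestricted).
#' @export
restriction_depth <- function(ri_long, threshold = 20) {
  ri_long |>
    dplyr::mutate(mid = (.data$top + .data$bottom) / 2) |>
    dplyr::arrange(.data$profile_id, .data$factor, .data$mid) |>
    dplyr::group_by(.data$profile_id, .data$factor) |>
    dplyr::summarise(
      restriction_depth = restriction_depth_one(.data$mid, .data$ri,
                                                threshold),
      .groups = "drop"
    )
}
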
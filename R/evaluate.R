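#' Evaluation configuration
#'
#' Bundles the tunable parameters of the evaluation. The defaults are the
#' published configuration for maize: field capacity at pF 2.3, threshold
#' rootability index 20%, maximum crop rooting depth 150 cm, reference PAWHC
#' of 10 v% for the unlimited decomposition member, the packaged rule set and
#' the tropical-soil PTF coefficients.
#'
#' @param fc_pf Field-capacity pF: 2.0, 2.3 (default) or 2.5.
#' @param threshold_index Threshold rootability index, % in (0, 100).
#' @param max_crop_depth Maximum crop rooting depth, cm.
#' @param default_pawhc Reference PAWHC for the decomposition, v%.
#' @param rules Rule table ([read_rules()]) or path to a rules file.
#' @param ptf_coefficients PTF coefficients ([read_ptf_coefficients()]) or
#'   path to a coefficients file.
#' @return A list of class `rz_config`.
#' @export
rz_config <- function(fc_pf = 2.3, threshold_index = 20, max_crop_depth = 150,
                      default_pawhc = 10, rules = NULL,
                      ptf_coefficients = NULL) {
  fc_suction_cm(fc_pf)  # validates
  stopifnot(threshold_index > 0, threshold_index < 100, max_crop_depth > 0,
            default_pawhc >= 0)
  if (is.null(rules)) rules <- read_rules()
  if (is.character(rules)) rules <- read_rules(rules)
  if (is.null(ptf_coefficients)) ptf_coefficients <- read_ptf_coefficients()
  if (is.character(ptf_coefficients)) {
    ptf_coefficients <- read_ptf_coefficients(ptf_coefficients)
  }
  structure(list(fc_pf = fc_pf, threshold_index = threshold_index,
                 max_crop_depth = max_crop_depth,
                 default_pawhc = default_pawhc, rules = rules,
                 ptf_coefficients = ptf_coefficients),
            class = "rz_config")
}

#' Evaluate soil profiles for rootable depth and root zone water capacity
#'
#' Runs the full evaluation chain on a layer table: validation, pedotransfer
#' water retention per depth interval, rootability indices for every soil
#' factor, per-factor restriction depths, the profile-level depth limits
#' (aeration from drainage class, bedrock, crop maximum), the rootable depth
#' with its limiting factor, and the aggregation of plant-available water
#' over the root zone.
#'
#' @param x Layer table (see [profile_columns()]); validated internally.
#' @param config An [rz_config()].
#' @param quiet Suppress skipped-factor messages.
#' @return An object of class `rz_evaluation`: a list with tibbles
#'   `retention` (layers plus van Genuchten parameters and VMC summaries),
#'   `factor_ri` (long per-layer rootability indices), `restrictions`
#'   (per-factor restriction depths), `depth_eval` (per-profile candidate
#'   depths, rootable depth, limiting factor), `water` (per-profile water
#'   capacity and decomposition), `intervals` (per-interval contributions)
#'   and the `config`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' profiles <- generate_profiles("mixed", n = 8, seed = 1)
#' ev <- evaluate_profiles(profiles)
#' tidy(ev)
#' glance(ev)
#' @export
evaluate_profiles <- function(x, config = rz_config(), quiet = FALSE) {
  stopifnot(inherits(config, "rz_config"))
  x <- validate_profiles(x)
  retention <- layer_retention(x, fc_pf = config$fc_pf,
                               coef = config$ptf_coefficients)
  factor_ri <- evaluate_layers(retention, rules = config$rules,
                               threshold = config$threshold_index,
                               quiet = quiet)
  restrictions <- restriction_depth(factor_ri,
                                    threshold = config$threshold_index)
  depth_eval <- rzd(x, restrictions,
                    max_crop_depth = config$max_crop_depth,
                    factor_order = unique(config$rules$factor))
  water <- rz_pawhc(retention, depth_eval,
                    max_crop_depth = config$max_crop_depth,
                    default_pawhc = config$default_pawhc)
  intervals <- rz_pawhc(retention, depth_eval,
                        max_crop_depth = config$max_crop_depth,
                        default_pawhc = config$default_pawhc, detail = TRUE)
  structure(list(retention = retention, factor_ri = factor_ri,
                 restrictions = restrictions, depth_eval = depth_eval,
                 water = water, intervals = intervals, config = config),
            class = "rz_evaluation")
}

#' @export
print.rz_evaluation <- function(x, ...) {
  n <- nrow(x$depth_eval)
  cat("Root zone evaluation of", n, "profile(s)\n")
  cat(sprintf("  fc at pF %.1f, threshold RI %g%%, max crop depth %g cm\n",
              x$config$fc_pf, x$config$threshold_index,
              x$config$max_crop_depth))
  s <- glance(x)
  cat(sprintf("  mean RZD %.1f cm, mean RZ-PAWHC %.1f mm\n",
              s$mean_rzd, s$mean_rz_pawhc_mm))
  invisible(x)
}

#' @export
print.rz_config <- function(x, ...) {
  cat(sprintf(paste0("rz_config: fc_pf %.1f, threshold RI %g%%, max crop ",
                     "depth %g cm, default PAWHC %g v%%\n"),
              x$fc_pf, x$threshold_index, x$max_crop_depth, x$default_pawhc))
  invisible(x)
}

#' Tidy a root zone evaluation into one row per profile
#'
#' @param x An `rz_evaluation`.
#' @param ... Unused.
#' @return Tibble: `profile_id`, `rzd`, `limiting_factor`, `rz_pawhc_mm`,
#'   `pawhc_weighted_v`, `sfef_weighted` and the `mm_*` decomposition.
#' @export
tidy.rz_evaluation <- function(x, ...) {
  x$depth_eval[c("profile_id", "rzd", "limiting_factor")] |>
    dplyr::left_join(dplyr::select(x$water, -"rzd"), by = "profile_id")
}

#' One-row summary of a root zone evaluation
#'
#' @param x An `rz_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with profile count and means/sds of rootable depth
#'   and water capacity.
#' @export
glance.rz_evaluation <- function(x, ...) {
  tibble::tibble(
    n_profiles = nrow(x$depth_eval),
    mean_rzd = mean(x$depth_eval$rzd),
    sd_rzd = stats::sd(x$depth_eval$rzd),
    mean_rz_pawhc_mm = mean(x$water$rz_pawhc_mm),
    sd_rz_pawhc_mm = stats::sd(x$water$rz_pawhc_mm),
    mean_pawhc_v = mean(x$water$pawhc_weighted_v, na.rm = TRUE),
    mean_sfef = mean(x$water$sfef_weighted, na.rm = TRUE),
    prop_unrestricted = mean(x$depth_eval$limiting_factor == "depth max")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
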
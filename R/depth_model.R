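#' Depth of aerated soil from drainage class
#'
#' Interprets the ordinal drainage class (1 = very poorly drained ... 7 =
#' excessively drained) as a depth of aerated soil via the quadratic
#' `2.5 x^2 + 22.5 x - 15`, which reproduces the series 10, 40, 75, 115, 160,
#' 210, 265 cm for classes 1-7. Missing classes return NA (treated downstream
#' as non-limiting).
#'
#' @param drainage_class Integer-valued vector in 1-7 (NA allowed).
#' @return Depth of aerated soil, cm.
#' @export
aeration_depth <- function(drainage_class) {
  ok <- is.na(drainage_class) |
    (drainage_class >= 1 & drainage_class <= 7 &
       drainage_class == round(drainage_class))
  if (!all(ok)) {
    stop("drainage_class must be an integer in 1-7", call. = FALSE)
  }
  2.5 * drainage_class^2 + 22.5 * drainage_class - 15
}

#' Depth of soil to bedrock
#'
#' Per profile, the shallower of the recorded depth to bedrock and the top of
#' the shallowest layer whose coarse fragments content exceeds 90 v% (such
#' layers are treated as bedrock). NA when neither applies.
#'
#' @param x Layer table with `profile_id`, `top`, `cf` and optionally
#'   `depth_to_bedrock`.
#' @return Tibble: `profile_id`, `bedrock_depth` (cm, NA if none).
#' @export
bedrock_depth <- function(x) {
  if (!"depth_to_bedrock" %in% names(x)) x$depth_to_bedrock <- NA_real_
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::summarise(
      bedrock_depth = suppressWarnings(min(
        .data$depth_to_bedrock[1],
        .data$top[!is.na(.data$cf) & .data$cf > 90],
        na.rm = TRUE
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(bedrock_depth = ifelse(is.infinite(.data$bedrock_depth),
                                         NA_real_, .data$bedrock_depth))
}

# Candidate precedence for ties: profile-wide limits before layer factors,
# so attribution is deterministic when several candidates share the minimum.
candidate_order <- function(factors) {
  c("depth max", "depth soil", "depth aeration", factors)
}

#' Rootable depth and limiting factor
#'
#' The root zone depth (RZD) of each profile is the shallowest of (a) the
#' per-factor layer restriction depths, (b) the depth to bedrock, (c) the
#' depth of aerated soil and (d) the crop's genetic maximum rooting depth
#' (150 cm for maize). The factor attaining the minimum is recorded as the
#' limiting factor; ties are broken by the fixed precedence crop maximum
#' ("depth max") < bedrock ("depth soil") < aeration ("depth aeration") <
#' layer factors in rule order. Missing bedrock or drainage information makes
#' that candidate non-limiting.
#'
#' @param x Layer table (profile-level columns `drainage_class`,
#'   `depth_to_bedrock` are read from it).
#' @param restrictions Per-factor restriction depths from
#'   [restriction_depth()].
#' @param max_crop_depth Genetic maximum rooting depth, cm (default 150).
#' @param factor_order Optional character vector giving the tie-break
#'   precedence among layer factors (default: the order they appear in
#'   `restrictions`, i.e. alphabetical; the pipeline passes rule-file order).
#' @return Tibble, one row per profile: `profile_id`, `layer_restriction`,
#'   `layer_factor`, `aeration_depth`, `bedrock_depth`, `max_crop_depth`,
#'   `rzd`, `limiting_factor`.
#' @export
rzd <- function(x, restrictions, max_crop_depth = 150, factor_order = NULL) {
  if (!is.null(factor_order)) {
    restrictions <- dplyr::arrange(restrictions,
                                   match(.data$factor, factor_order))
  }
  prof <- x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::summarise(
      drainage_class = .data$drainage_class[1],
      .groups = "drop"
    ) |>
    dplyr::left_join(bedrock_depth(x), by = "profile_id") |>
    dplyr::mutate(aeration_depth = aeration_depth(.data$drainage_class))

  layer_min <- restrictions |>
    dplyr::filter(!is.na(.data$restriction_depth)) |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::slice_min(.data$restriction_depth, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("profile_id", layer_restriction = "restriction_depth",
                  layer_factor = "factor")

  prof |>
    dplyr::left_join(layer_min, by = "profile_id") |>
    dplyr::mutate(max_crop_depth = max_crop_depth) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rzd = min(.data$max_crop_depth, .data$bedrock_depth,
                .data$aeration_depth, .data$layer_restriction, na.rm = TRUE),
      limiting_factor = {
        cand <- c("depth max" = .data$max_crop_depth,
                  "depth soil" = .data$bedrock_depth,
                  "depth aeration" = .data$aeration_depth)
        if (!is.na(.data$layer_restriction)) {
          cand <- c(cand,
                    rlang::set_names(.data$layer_restriction,
                                     .data$layer_factor))
        }
        names(cand)[which(!is.na(cand) & cand == .data$rzd)[1]]
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("profile_id", "layer_restriction", "layer_factor",
                  "aeration_depth", "bedrock_depth", "max_crop_depth",
                  "rzd", "limiting_factor")
}

#' Extent, degree and severity of the limiting factors
#'
#' Summarises a set of profile evaluations by limiting factor: the extent
#' (area, km2), the degree (mean and sd of the restricted rootable depth, cm)
#' and the severity (restricted soil volume, km3, computed as
#' `area x (max_crop_depth - rzd) x 1e-5`). The extents partition the total
#' area and the factor volumes sum to the total restricted volume.
#'
#' @param depth_eval Per-profile depth evaluation from [rzd()].
#' @param area_km2 Area weight per profile (scalar or vector), km2; default 1.
#' @return Tibble per limiting factor: `limiting_factor`, `n`, `area_km2`,
#'   `mean_rzd`, `sd_rzd`, `restricted_volume_km3`.
#' @export
summarize_limiting_factors <- function(depth_eval, area_km2 = 1) {
  stopifnot(nrow(depth_eval) >= 1)
  depth_eval |>
    dplyr::mutate(.area_w = area_km2) |>
    dplyr::group_by(.data$limiting_factor) |>
    dplyr::summarise(
      n = dplyr::n(),
      area_km2 = sum(.data$.area_w),
      mean_rzd = mean(.data$rzd),
      sd_rzd = stats::sd(.data$rzd),
      restricted_volume_km3 = sum(.data$.area_w *
                                    (.data$max_crop_depth - .data$rzd) * 1e-5),
      .groups = "drop"
    )
}
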
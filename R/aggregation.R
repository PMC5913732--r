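#' Root zone plant-available water holding capacity
#'
#' Combines the per-interval plant-available water holding capacity of the
#' fine earth (v%), the soil fine earth fraction and the rootable depth into a
#' single capacity in mm per profile. Each interval contributes its overlap
#' with `[0, rzd]` (cm) times `pawhc / 10` (1 cm of soil at 1 v% holds 0.1 mm
#' of water) times the fine earth fraction; intervals cut by the rootable
#' depth contribute pro rata. A nested decomposition is reported alongside:
#' `mm_unlimited` (default PAWHC of 10 v% over the full crop depth, 150 mm for
#' maize), `mm_pawhc` (actual PAWHC, no other limits), `mm_pawhc_sfef`
#' (plus coarse-fragment correction) and `mm_full` (plus truncation at the
#' rootable depth, equal to `rz_pawhc_mm`).
#'
#' @param x Layer table with retention columns (from [layer_retention()]) and
#'   `cf`.
#' @param depth_eval Per-profile depth evaluation from [rzd()].
#' @param max_crop_depth Genetic maximum rooting depth, cm.
#' @param default_pawhc Reference PAWHC (v%) for the unlimited member of the
#'   decomposition, default 10.
#' @param detail If TRUE, return the per-interval contribution table instead
#'   of the per-profile summary.
#' @return Per-profile tibble: `profile_id`, `rz_pawhc_mm`,
#'   `pawhc_weighted_v` (thickness-weighted mean PAWHC over the root zone,
#'   v%), `sfef_weighted` (likewise for the fine earth fraction), and the
#'   `mm_*` decomposition; or the per-interval table when `detail = TRUE`.
#' @export
rz_pawhc <- function(x, depth_eval, max_crop_depth = 150, default_pawhc = 10,
                     detail = FALSE) {
  stopifnot(all(c("pawhc", "cf") %in% names(x)))
  overlap <- function(top, bottom, d) pmax(pmin(bottom, d) - pmin(top, d), 0)
  per_interval <- x |>
    tibble::as_tibble() |>
    dplyr::inner_join(depth_eval[c("profile_id", "rzd")], by = "profile_id") |>
    dplyr::mutate(
      sfef = sfef(.data$cf),
      thickness_root_zone = overlap(.data$top, .data$bottom, .data$rzd),
      thickness_crop = overlap(.data$top, .data$bottom, max_crop_depth),
      water_mm = .data$thickness_root_zone * .data$pawhc / 10 * .data$sfef
    )
  if (detail) {
    return(per_interval[c("profile_id", "top", "bottom", "rzd", "pawhc",
                          "sfef", "thickness_root_zone", "water_mm")])
  }
  per_interval |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::summarise(
      rzd = .data$rzd[1],
      rz_pawhc_mm = sum(.data$water_mm),
      pawhc_weighted_v = ifelse(
        sum(.data$thickness_root_zone) > 0,
        sum(.data$pawhc * .data$thickness_root_zone) /
          sum(.data$thickness_root_zone), NA_real_),
      sfef_weighted = ifelse(
        sum(.data$thickness_root_zone) > 0,
        sum(.data$sfef * .data$thickness_root_zone) /
          sum(.data$thickness_root_zone), NA_real_),
      mm_unlimited = max_crop_depth * default_pawhc / 10,
      mm_pawhc = sum(.data$thickness_crop * .data$pawhc / 10),
      mm_pawhc_sfef = sum(.data$thickness_crop * .data$pawhc / 10 *
                            .data$sfef),
      mm_full = sum(.data$water_mm),
      .groups = "drop"
    )
}

#' Full diagnostic record for one profile
#'
#' Gathers every intermediate of the evaluation of a single profile —
#' layer properties, retention summaries, factor rootability indices,
#' per-factor restriction depths, candidate depths, limiting factor and
#' per-interval water contributions — into one nested list that serialises
#' losslessly to JSON (see [write_profile_report()]).
#'
#' @param ev An `rz_evaluation` from [evaluate_profiles()].
#' @param profile_id Profile identifier present in the evaluation.
#' @return Nested list of tibble-backed records.
#' @export
profile_report <- function(ev, profile_id) {
  stopifnot(inherits(ev, "rz_evaluation"))
  pick <- function(tbl) as.data.frame(tbl[tbl$profile_id == profile_id, ])
  if (nrow(pick(ev$depth_eval)) == 0) {
    stop("unknown profile_id: ", profile_id, call. = FALSE)
  }
  list(
    profile_id = profile_id,
    layers = pick(ev$retention),
    factor_ri = pick(ev$factor_ri),
    restriction_depths = pick(ev$restrictions),
    depth_evaluation = pick(ev$depth_eval),
    water = pick(ev$water),
    intervals = pick(ev$intervals)
  )
}

#' @rdname profile_report
#' @param report A report from [profile_report()].
#' @param path Output JSON path.
#' @export
write_profile_report <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write reports", call. = FALSE)
  }
  jsonlite::write_json(report, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
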
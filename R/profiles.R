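#' Canonical soil-profile layer columns
#'
#' A profile layer table holds one row per profile x depth interval. Depths are
#' in cm, intervals are half-open `[top, bottom)` with the surface at 0 and,
#' within a profile, ordered, non-overlapping and contiguous from 0.
#'
#' Required per-layer columns: `profile_id`, `top`, `bottom`, `sand`, `silt`,
#' `clay` (g/100 g), `oc` (g/kg), `bd` (kg/dm3, fine earth), `cec` (cmolc/kg),
#' `ph` (pH-H2O), `cf` (coarse fragments, v%). Optional per-layer columns:
#' `ec` (dS/m), `exch_na`, `exch_al` (cmolc/kg), `caco3`, `caso4` (g/kg).
#' Optional profile-level columns (repeated on every layer row):
#' `drainage_class` (ordinal 1-7), `depth_to_bedrock` (cm), `lon`, `lat`.
#'
#' @return Character vector of canonical column names.
#' @export
profile_columns <- function() {
  c("profile_id", "top", "bottom",
    "sand", "silt", "clay", "oc", "bd", "cec", "ph", "cf",
    "ec", "exch_na", "exch_al", "caco3", "caso4",
    "drainage_class", "depth_to_bedrock", "lon", "lat")
}

required_layer_columns <- function() {
  c("profile_id", "top", "bottom",
    "sand", "silt", "clay", "oc", "bd", "cec", "ph", "cf")
}

optional_layer_columns <- function() {
  c("ec", "exch_na", "exch_al", "caco3", "caso4",
    "drainage_class", "depth_to_bedrock", "lon", "lat")
}

#' The six standard reporting depth intervals
#'
#' The GlobalSoilMap convention: 0-5, 5-15, 15-30, 30-60, 60-100 and
#' 100-200 cm.
#'
#' @return A tibble with columns `top` and `bottom` (cm).
#' @export
standard_intervals <- function() {
  tibble::tibble(top    = c(0, 5, 15, 30, 60, 100),
                 bottom = c(5, 15, 30, 60, 100, 200))
}

#' Validate a profile layer table
#'
#' Checks the layer-table invariants: required columns present, depth intervals
#' ordered, non-overlapping and contiguous from the surface within each
#' profile, texture fractions summing to 100 (within 1 g/100 g) where all three
#' are present, and physical ranges (fractions in 0-100, bulk density in
#' (0, 2.65], pH in 1-14, non-negative chemistry, drainage class in 1-7).
#' Layers are re-sorted by `top` within profile before checking, so input
#' ordering does not matter.
#'
#' @param x Data frame of profile layers (see [profile_columns()]).
#' @return The validated, sorted layer table as a tibble (invisibly usable in
#'   a pipe); errors name the offending profile.
#' @export
validate_profiles <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(required_layer_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  for (col in setdiff(optional_layer_columns(), names(x))) {
    x[[col]] <- NA_real_
  }
  # all-NA columns read back from file arrive as logical; keep them numeric
  numeric_cols <- setdiff(profile_columns(), "profile_id")
  for (col in intersect(numeric_cols, names(x))) {
    if (!is.numeric(x[[col]])) x[[col]] <- as.numeric(x[[col]])
  }
  x <- dplyr::arrange(x, .data$profile_id, .data$top)

  bad_interval <- x$bottom <= x$top | x$top < 0
  if (any(bad_interval)) {
    stop("invalid depth interval(s) in profile(s): ",
         paste(unique(x$profile_id[bad_interval]), collapse = ", "),
         call. = FALSE)
  }
  chk <- x |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::summarise(
      starts_at_0 = .data$top[1] == 0,
      contiguous  = all(.data$top[-1] == .data$bottom[-dplyr::n()]) ||
        dplyr::n() == 1,
      .groups = "drop"
    )
  bad <- chk$profile_id[!(chk$starts_at_0 & chk$contiguous)]
  if (length(bad) > 0) {
    stop("depth intervals not contiguous from 0 in profile(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  tex <- rowSums(cbind(x$sand, x$silt, x$clay))
  tex_ok <- is.na(tex) | abs(tex - 100) <= 1
  if (!all(tex_ok)) {
    stop("sand+silt+clay outside 100 +/- 1 in profile(s): ",
         paste(unique(x$profile_id[!tex_ok]), collapse = ", "), call. = FALSE)
  }
  range_check <- function(v, lo, hi, nm) {
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad)) {
      stop(nm, " outside [", lo, ", ", hi, "] in profile(s): ",
           paste(unique(x$profile_id[bad]), collapse = ", "), call. = FALSE)
    }
  }
  range_check(x$sand, 0, 100, "sand")
  range_check(x$silt, 0, 100, "silt")
  range_check(x$clay, 0, 100, "clay")
  range_check(x$cf, 0, 100, "cf")
  range_check(x$bd, 1e-9, 2.65, "bd")
  range_check(x$ph, 1, 14, "ph")
  range_check(x$drainage_class, 1, 7, "drainage_class")
  for (nm in c("oc", "cec", "ec", "exch_na", "exch_al", "caco3", "caso4",
               "depth_to_bedrock")) {
    range_check(x[[nm]], 0, Inf, nm)
  }
  x
}

#' Read soil profiles from a delimited file
#'
#' Reads a CSV/TSV of per-layer soil properties into the canonical layer
#' table. Column names can be mapped from the file's own header via `schema`,
#' either a named character vector (`c(canonical = "file_column")`) or the
#' path to a YAML file holding such a mapping.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from extension).
#' @param schema Optional column mapping, named vector or YAML file path.
#' @return Validated tibble of profile layers, sorted by profile and depth.
#' @export
read_profiles <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
      schema <- unlist(yaml::read_yaml(schema))
    }
    absent <- setdiff(schema, names(raw))
    if (length(absent) > 0) {
      stop("schema maps to column(s) absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    raw <- dplyr::rename(raw, dplyr::all_of(schema))
  }
  keep <- intersect(profile_columns(), names(raw))
  validate_profiles(raw[keep])
}

#' Write per-profile evaluation results
#'
#' Writes one row per profile with the rootable depth, the limiting factor and
#' the root zone plant-available water capacity; optionally a companion
#' per-interval detail table.
#'
#' @param results Per-profile results with columns `profile_id`, `rzd`,
#'   `limiting_factor`, `rz_pawhc_mm` (as produced by [evaluate_profiles()]
#'   and [tidy()]).
#' @param path Output CSV path.
#' @param details Optional per-interval tibble written next to `path` with a
#'   `_intervals` suffix.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, details = NULL) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) stop("no results to write", call. = FALSE)
  need <- c("profile_id", "rzd", "limiting_factor", "rz_pawhc_mm")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols) > 0) {
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(results[union(need, names(results))], path, progress = FALSE)
  if (!is.null(details)) {
    dpath <- sub("(\\.[^.]+)$", "_intervals\\1", path)
    readr::write_csv(details, dpath, progress = FALSE)
  }
  invisible(path)
}
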
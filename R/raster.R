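# Minimal ESRI ASCII grid (.asc) I/O. The format is plain text: a six-line
# header (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) and
# then nrows lines of ncols values, northernmost row first. No raster
# package is required for this.

#' Read / write an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return `read_asc`: a list with `values` (numeric matrix, nodata as NA,
#'   row 1 = northernmost) and the header fields `xllcorner`, `yllcorner`,
#'   `cellsize`, `nodata`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed .asc header in ", path, call. = FALSE)
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = lines[-seq_len(n_hdr)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("value count does not match header in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' @rdname read_asc
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param xllcorner,yllcorner,cellsize Grid registration.
#' @param nodata Value written for NA cells.
#' @export
write_asc <- function(values, path, xllcorner = 0, yllcorner = 0,
                      cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(values))
  vals <- values
  vals[is.na(vals)] <- nodata
  hdr <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
           paste("xllcorner", format(xllcorner, digits = 15)),
           paste("yllcorner", format(yllcorner, digits = 15)),
           paste("cellsize", format(cellsize, digits = 15)),
           paste("NODATA_value", nodata))
  body <- apply(vals, 1, function(r) {
    paste(formatC(r, format = "g", digits = 15), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xllcorner, a$yllcorner, a$cellsize),
                     c(b$xllcorner, b$yllcorner, b$cellsize)))
}

#' Read a per-depth-interval raster stack into a layer table
#'
#' Expects a directory of `.asc` grids named `<property>_<top>_<bottom>.asc`
#' for per-layer properties (e.g. `clay_0_5.asc`) and `<property>.asc` for
#' profile-level properties (`drainage_class`, `depth_to_bedrock`). All grids
#' must share registration (dimensions, corner, cell size); a mismatch is an
#' alignment error. Each grid cell becomes one profile with id
#' `cell_<row>_<col>` and coordinates at the cell centre; nodata becomes NA
#' ("missing"), never zero.
#'
#' @param dir Directory containing the `.asc` stack.
#' @return Layer table (unvalidated cells may carry NA for missing
#'   properties; see [evaluate_raster_stack()]).
#' @export
read_raster_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (length(files) == 0) stop("no .asc files in ", dir, call. = FALSE)
  info <- tibble::tibble(path = files,
                         base = sub("\\.asc$", "", basename(files)))
  m <- regmatches(info$base,
                  regexec("^(.*)_([0-9]+)_([0-9]+)$", info$base))
  info$property <- purrr::map2_chr(m, info$base,
                                   ~ if (length(.x) == 4) .x[2] else .y)
  info$top <- purrr::map_dbl(m, ~ if (length(.x) == 4) as.numeric(.x[3])
                             else NA_real_)
  info$bottom <- purrr::map_dbl(m, ~ if (length(.x) == 4) as.numeric(.x[4])
                                else NA_real_)
  grids <- purrr::map(info$path, read_asc)
  ref <- grids[[1]]
  aligned <- purrr::map_lgl(grids, same_grid, b = ref)
  if (!all(aligned)) {
    stop("raster grid mismatch: ",
         paste(basename(info$path[!aligned]), collapse = ", "), call. = FALSE)
  }
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  cells <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  cells$profile_id <- sprintf("cell_%03d_%03d", cells$row, cells$col)
  # row 1 is the northernmost row
  cells$lon <- ref$xllcorner + (cells$col - 0.5) * ref$cellsize
  cells$lat <- ref$yllcorner + (nr - cells$row + 0.5) * ref$cellsize

  layer_info <- info[!is.na(info$top), ]
  intervals <- dplyr::distinct(layer_info[c("top", "bottom")]) |>
    dplyr::arrange(.data$top)
  out <- tidyr::expand_grid(cells, intervals)
  for (k in seq_len(nrow(info))) {
    v <- grids[[k]]$values[cbind(out$row, out$col)]
    if (is.na(info$top[k])) {
      out[[info$property[k]]] <- v
    } else {
      sel <- out$top == info$top[k] & out$bottom == info$bottom[k]
      if (!info$property[k] %in% names(out)) {
        out[[info$property[k]]] <- NA_real_
      }
      out[[info$property[k]]][sel] <- v[sel]
    }
  }
  dplyr::select(out, -"row", -"col") |>
    dplyr::relocate("profile_id", "top", "bottom") |>
    dplyr::arrange(.data$profile_id, .data$top)
}

#' Evaluate a raster stack cell by cell
#'
#' Reads the stack with [read_raster_stack()], sets aside cells missing any
#' required property (they appear in the result with NA depth and capacity
#' and the missing property named), and evaluates the remaining cells exactly
#' as the tabular path does.
#'
#' @param dir Directory containing the `.asc` stack.
#' @param config An [rz_config()].
#' @param quiet Suppress messages.
#' @return Tidy per-cell results (see [tidy.rz_evaluation()]) with an extra
#'   `missing` column naming absent required properties (NA when complete).
#' @export
evaluate_raster_stack <- function(dir, config = rz_config(), quiet = TRUE) {
  layers <- read_raster_stack(dir)
  req <- setdiff(required_layer_columns(), c("profile_id", "top", "bottom"))
  miss_flags <- layers |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(req), ~ any(is.na(.x))),
                     .groups = "drop")
  miss <- tibble::tibble(
    profile_id = miss_flags$profile_id,
    missing = apply(miss_flags[req], 1,
                    function(r) paste(req[r], collapse = ","))
  ) |>
    dplyr::mutate(missing = dplyr::na_if(.data$missing, ""))
  incomplete <- miss$profile_id[!is.na(miss$missing)]
  if (length(incomplete) > 0 && !quiet) {
    message(length(incomplete), " cell(s) set aside with missing inputs")
  }
  ok <- dplyr::filter(layers, !.data$profile_id %in% incomplete)
  res <- if (nrow(ok) > 0) {
    tidy(evaluate_profiles(ok, config = config, quiet = quiet))
  } else {
    tibble::tibble(profile_id = character())
  }
  miss |>
    dplyr::left_join(res, by = "profile_id") |>
    dplyr::relocate("missing", .after = dplyr::last_col())
}

#' Write a synthetic raster fixture
#'
#' Generates `nrow x ncol` synthetic profiles (see [generate_profiles()]),
#' assigns them to grid cells row-major, and writes one `.asc` grid per
#' property per depth interval plus `drainage_class.asc` and, when present,
#' `depth_to_bedrock.asc`. The returned (invisible) layer table carries the
#' cell ids, so tabular and raster evaluation of the same fixture can be
#' compared directly.
#'
#' @param dir Output directory (created if needed).
#' @param scenario,seed Passed to [generate_profiles()].
#' @param nrow,ncol Grid size (kept small; fixtures are for tests).
#' @param cellsize,xllcorner,yllcorner Grid registration.
#' @return The cell-indexed layer table, invisibly.
#' @export
generate_raster_fixture <- function(dir, scenario = "mixed", nrow = 4,
                                    ncol = 4, seed = 1, cellsize = 1,
                                    xllcorner = 0, yllcorner = 0) {
  stopifnot(nrow >= 1, ncol >= 1, nrow * ncol <= 10000)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- generate_profiles(scenario, n = nrow * ncol, seed = seed)
  ids <- unique(prof$profile_id)
  cells <- tidyr::expand_grid(row = seq_len(nrow), col = seq_len(ncol))
  map <- tibble::tibble(
    profile_id = ids,
    cell_id = sprintf("cell_%03d_%03d", cells$row, cells$col),
    row = cells$row, col = cells$col
  )
  prof <- dplyr::left_join(prof, map, by = "profile_id") |>
    dplyr::mutate(profile_id = .data$cell_id,
                  lon = xllcorner + (.data$col - 0.5) * cellsize,
                  lat = yllcorner + (nrow - .data$row + 0.5) * cellsize)

  layer_vars <- c("sand", "silt", "clay", "oc", "bd", "cec", "ph", "cf",
                  "ec", "exch_na", "exch_al", "caco3", "caso4")
  iv <- dplyr::distinct(prof[c("top", "bottom")])
  for (v in layer_vars) {
    if (all(is.na(prof[[v]]))) next
    for (j in seq_len(base::nrow(iv))) {
      sub <- prof[prof$top == iv$top[j], ]
      m <- matrix(NA_real_, nrow, ncol)
      m[cbind(sub$row, sub$col)] <- sub[[v]]
      write_asc(m, file.path(dir, sprintf("%s_%g_%g.asc", v, iv$top[j],
                                          iv$bottom[j])),
                xllcorner = xllcorner, yllcorner = yllcorner,
                cellsize = cellsize)
    }
  }
  for (v in c("drainage_class", "depth_to_bedrock")) {
    sub <- prof[prof$top == 0, ]
    if (all(is.na(sub[[v]]))) next
    m <- matrix(NA_real_, nrow, ncol)
    m[cbind(sub$row, sub$col)] <- sub[[v]]
    write_asc(m, file.path(dir, paste0(v, ".asc")), xllcorner = xllcorner,
              yllcorner = yllcorner, cellsize = cellsize)
  }
  invisible(dplyr::select(prof, -"cell_id", -"row", -"col"))
}
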
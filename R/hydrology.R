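# 1 cm of water column = 0.0980665 kPa; used to convert suction heads in cm
# to the kPa convention of the pedotransfer coefficients.
KPA_PER_CM <- 0.0980665

#' Suction heads for the field-capacity and wilting-point conventions
#'
#' Field capacity may be defined at pF 2.0, 2.3 or 2.5; these correspond to
#' suction heads of 100, 200 and 300 cm of water. The permanent wilting point
#' for maize is pF 4.2, taken as a suction of 15,000 cm. The mapping uses
#' these conventional equivalences, not `10^pF`.
#'
#' @param fc_pf Field-capacity pF, one of 2.0, 2.3, 2.5.
#' @return Suction head in cm of water.
#' @export
fc_suction_cm <- function(fc_pf) {
  map <- c("2" = 100, "2.3" = 200, "2.5" = 300)
  key <- as.character(fc_pf)
  if (!key %in% names(map)) {
    stop("fc_pf must be one of 2.0, 2.3, 2.5", call. = FALSE)
  }
  unname(map[key])
}

#' @rdname fc_suction_cm
#' @export
pwp_suction_cm <- function() 15000

#' van Genuchten water retention
#'
#' Volumetric moisture content at suction head `h`:
#' `theta(h) = theta_r + (theta_s - theta_r) / (1 + (alpha h)^n)^(1 - 1/n)`.
#' All arguments are vectorised and recycled.
#'
#' @param h Suction head, cm of water, >= 0.
#' @param theta_r,theta_s Residual and saturated volumetric moisture content
#'   (cm3/cm3), `0 <= theta_r < theta_s <= 1`.
#' @param alpha Inverse suction scale (1/cm), > 0.
#' @param n Shape parameter, > 1.
#' @return Volumetric moisture content (cm3/cm3).
#' @export
vg_theta <- function(h, theta_r, theta_s, alpha, n) {
  if (any(h < 0, na.rm = TRUE)) stop("suction h must be >= 0", call. = FALSE)
  ok <- theta_r >= 0 & theta_r < theta_s & theta_s <= 1 & alpha > 0 & n > 1
  if (any(!ok, na.rm = TRUE)) {
    stop("invalid van Genuchten parameters", call. = FALSE)
  }
  m <- 1 - 1 / n
  theta_r + (theta_s - theta_r) / (1 + (alpha * h)^n)^m
}

#' Pedotransfer coefficients for the tropical-soil van Genuchten PTF
#'
#' Reads a coefficients table (see `inst/extdata/ptf_tropical_vg.csv`, the
#' default, for format and provenance). The file is plain CSV with a `#`
#' provenance header; rows are regression terms, columns the four van
#' Genuchten targets.
#'
#' @param path Path to a coefficients CSV; default the packaged file.
#' @return Tibble with columns `term`, `ln_alpha`, `ln_n`, `theta_s`,
#'   `theta_r`.
#' @export
read_ptf_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ptf_tropical_vg.csv", package = "rzpawhc")
  }
  coef <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  need <- c("term", "ln_alpha", "ln_n", "theta_s", "theta_r")
  if (!all(need %in% names(coef))) {
    stop("PTF coefficients file lacks column(s): ",
         paste(setdiff(need, names(coef)), collapse = ", "), call. = FALSE)
  }
  terms <- c("intercept", "sand", "silt", "clay", "oc", "bd", "cec", "ph",
             "silt2", "clay2", "sand_silt", "sand_clay")
  if (!setequal(coef$term, terms)) {
    stop("PTF coefficients file must define exactly the terms: ",
         paste(terms, collapse = ", "), call. = FALSE)
  }
  coef[match(terms, coef$term), ]
}

#' van Genuchten parameters from routine soil properties
#'
#' Applies the tropical-soil pedotransfer regression to each layer, yielding
#' the water-retention parameters. Regressors are sand, silt and clay
#' (g/100 g), organic carbon (converted from g/kg to g/100 g), bulk density of
#' the fine earth (kg/dm3), CEC (cmolc/kg) and pH-H2O; CEC and pH act as
#' mineralogy proxies for highly leached soils. The fitted `alpha` is in 1/kPa
#' and is converted to 1/cm so that all suction heads in the package are in cm
#' of water. A regression can return a small negative residual moisture; such
#' `theta_r` is clamped to 0 with a warning.
#'
#' @param x Layer table with columns `sand`, `silt`, `clay`, `oc`, `bd`,
#'   `cec`, `ph` (see [profile_columns()]).
#' @param coef Coefficients tibble from [read_ptf_coefficients()].
#' @return `x` with columns `theta_r`, `theta_s`, `alpha` (1/cm), `n` added.
#' @export
ptf_params <- function(x, coef = read_ptf_coefficients()) {
  stopifnot(is.data.frame(x))
  need <- c("sand", "silt", "clay", "oc", "bd", "cec", "ph")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("PTF input column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in need) {
    if (any(is.na(x[[nm]]))) {
      stop("PTF input '", nm, "' is missing (NA) for ",
           sum(is.na(x[[nm]])), " layer(s)", call. = FALSE)
    }
  }
  X <- cbind(intercept = 1, sand = x$sand, silt = x$silt, clay = x$clay,
             oc = x$oc / 10, bd = x$bd, cec = x$cec, ph = x$ph,
             silt2 = x$silt^2, clay2 = x$clay^2,
             sand_silt = x$sand * x$silt, sand_clay = x$sand * x$clay)
  lin <- function(target) drop(X %*% coef[[target]]) / 100
  theta_r <- lin("theta_r")
  theta_s <- lin("theta_s")
  alpha <- exp(lin("ln_alpha")) * KPA_PER_CM  # 1/kPa -> 1/cm
  n <- exp(lin("ln_n"))
  if (any(theta_r < 0)) {
    warning("negative fitted theta_r clamped to 0 for ",
            sum(theta_r < 0), " layer(s)", call. = FALSE)
    theta_r <- pmax(theta_r, 0)
  }
  if (any(theta_r >= theta_s)) {
    warning("fitted theta_r >= theta_s clamped for ",
            sum(theta_r >= theta_s), " layer(s)", call. = FALSE)
    theta_r <- pmin(theta_r, theta_s - 1e-6)
  }
  dplyr::mutate(tibble::as_tibble(x), theta_r = theta_r, theta_s = theta_s,
                alpha = alpha, n = n)
}

#' Water retention summary per layer
#'
#' Computes the volumetric moisture content of the soil fine earth at
#' saturation (pF 0), field capacity and permanent wilting point, and the
#' plant-available water holding capacity `pawhc = vmc_fc - vmc_pwp`, all in
#' v%. Parameters come from the pedotransfer function unless the table already
#' carries `theta_r`, `theta_s`, `alpha`, `n` columns (retention from directly
#' fitted curves) or `vmc_sat`, `vmc_fc`, `vmc_pwp` columns (directly measured
#' retention, used as given; only `pawhc` is recomputed).
#'
#' @param x Layer table; see [ptf_params()].
#' @param fc_pf Field-capacity definition, one of 2.0, 2.3 (default), 2.5.
#' @param coef PTF coefficients, see [read_ptf_coefficients()].
#' @return `x` with `vmc_sat`, `vmc_fc`, `vmc_pwp`, `pawhc` (v%) added.
#' @export
layer_retention <- function(x, fc_pf = 2.3, coef = read_ptf_coefficients()) {
  vmc_cols <- c("vmc_sat", "vmc_fc", "vmc_pwp")
  if (all(vmc_cols %in% names(x))) {
    out <- dplyr::mutate(tibble::as_tibble(x),
                         pawhc = .data$vmc_fc - .data$vmc_pwp)
    stopifnot(all(out$vmc_sat >= out$vmc_fc - 1e-9),
              all(out$vmc_fc >= out$vmc_pwp - 1e-9))
    return(out)
  }
  vg_cols <- c("theta_r", "theta_s", "alpha", "n")
  if (!all(vg_cols %in% names(x))) {
    x <- ptf_params(x, coef = coef)
  }
  h_fc <- fc_suction_cm(fc_pf)
  out <- dplyr::mutate(
    tibble::as_tibble(x),
    vmc_sat = 100 * vg_theta(0, .data$theta_r, .data$theta_s,
                             .data$alpha, .data$n),
    vmc_fc  = 100 * vg_theta(h_fc, .data$theta_r, .data$theta_s,
                             .data$alpha, .data$n),
    vmc_pwp = 100 * vg_theta(pwp_suction_cm(), .data$theta_r, .data$theta_s,
                             .data$alpha, .data$n),
    pawhc   = .data$vmc_fc - .data$vmc_pwp
  )
  stopifnot(all(out$vmc_sat >= out$vmc_fc - 1e-9),
            all(out$vmc_fc >= out$vmc_pwp - 1e-9))
  out
}

#' Soil fine earth fraction
#'
#' The volume fraction of soil that roots can exploit: coarse fragments (v%)
#' deducted from 100%.
#'
#' @param cf Coarse fragments content, v%, in 0-100.
#' @return Fraction in 0-1.
#' @export
sfef <- function(cf) {
  if (any(!is.na(cf) & (cf < 0 | cf > 100))) {
    stop("coarse fragments content must be in [0, 100] v%", call. = FALSE)
  }
  (100 - cf) / 100
}
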
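# Shared fixtures and independent oracles.

# A hand-written benign profile on the six standard intervals: every
# rootability factor comfortably adequate, well drained, no bedrock.
benign_layers <- function(profile_id = "p1", drainage_class = 6) {
  iv <- standard_intervals()
  tibble::tibble(
    profile_id = profile_id, top = iv$top, bottom = iv$bottom,
    sand = 40, silt = 30, clay = 30, oc = 10, bd = 1.3, cec = 15, ph = 6,
    cf = 2, ec = 0.1, exch_na = 0.1, exch_al = 0.1, caco3 = 10, caso4 = 5,
    drainage_class = drainage_class, depth_to_bedrock = NA_real_
  )
}

# Profile with retention pinned directly: PAWHC exactly `pawhc_v` v% in every
# interval, porosity ample, everything else benign.
pinned_retention_layers <- function(profile_id = "flat", pawhc_v = 10,
                                    cf = 0, drainage_class = 5) {
  x <- benign_layers(profile_id, drainage_class)
  x$cf <- cf
  x$vmc_sat <- 45
  x$vmc_fc <- 15 + pawhc_v
  x$vmc_pwp <- 15
  x
}

# Brute-force 1 cm scan of the depth-continuous (midpoint-interpolated)
# rootability index: first scanned depth strictly below the threshold.
scan_restriction <- function(mid, ri, threshold = 20, step = 1,
                             max_depth = 250) {
  d <- seq(0, max_depth, by = step)
  riv <- stats::approx(mid, ri, xout = d, rule = 2)$y
  i <- which(riv < threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(0)
  d[i]
}

# The published rule breakpoints, written out independently of the packaged
# rules file (value, ri), adequacy columns RI100 | RI100 | RI20 | RI0 | RI0.
table4_reference <- function() {
  list(
    porosity_vmc_sat   = cbind(c(0, 27.5, 30, 40, 100), c(0, 0, 20, 100, 100)),
    porosity_f_bd      = cbind(c(0, 0.24, 0.3), c(100, 20, 0)),
    volume_crsvol      = cbind(c(0, 80, 88, 90, 100), c(100, 100, 20, 0, 0)),
    texture_sand       = cbind(c(0, 95, 99, 100), c(100, 100, 20, 0)),
    texture_f_sand     = cbind(c(0, 30, 50, 55, 100), c(100, 100, 20, 0, 0)),
    texture_f_clay     = cbind(c(0, 30, 50, 55, 100), c(100, 100, 20, 0, 0)),
    induration_caco3   = cbind(c(0, 150, 400, 450, 1000),
                               c(100, 100, 20, 0, 0)),
    induration_caso4   = cbind(c(0, 50, 300, 350, 1000),
                               c(100, 100, 20, 0, 0)),
    acidity_ph         = cbind(c(1, 3.63, 4, 5.5, 12), c(0, 0, 20, 100, 100)),
    alkalinity_ph      = cbind(c(1, 7.8, 8.8, 9.05, 12),
                               c(100, 100, 20, 0, 0)),
    salinity_ec        = cbind(c(0, 1.5, 5.7, 6.75), c(100, 100, 20, 0)),
    sodicity_exch_na   = cbind(c(0, 1, 4.2, 5), c(100, 100, 20, 0)),
    toxicity_exch_al   = cbind(c(0, 2.5, 5.7, 6.5), c(100, 100, 20, 0)),
    toxicity_f_exch_al = cbind(c(0, 35, 75, 85, 100), c(100, 100, 20, 0, 0))
  )
}
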
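# Truncated-normal draw via inverse CDF, so every draw consumes exactly one
# uniform from the RNG stream.
rtnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

# Log-normal capped draw for the highly skewed properties (coarse fragments,
# EC, exchangeable Na).
rlnorm_cap <- function(n, meanlog, sdlog, hi) {
  pmin(stats::rlnorm(n, meanlog, sdlog), hi)
}

#' Scenario names understood by the synthetic-profile generator
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() {
  c("unconstrained", "sodic_lowland", "shallow_bedrock", "poorly_drained",
    "acid_toxic", "gravelly", "saline", "mixed")
}

# One benign profile on the six standard intervals: all rootability factors
# comfortably adequate, drainage class 5-7 (aerated beyond 150 cm), no
# bedrock. Property marginals sit inside the observed ranges of the source
# soil-profile compilation; clay mildly increases and organic carbon
# decreases with depth.
benign_profile <- function(profile_id) {
  iv <- standard_intervals()
  k <- nrow(iv)
  mid <- (iv$top + iv$bottom) / 2
  clay0 <- rtnorm(1, 25, 8, 8, 40)
  clay <- pmin(clay0 + cumsum(c(0, stats::runif(k - 1, 0, 4))), 60)
  silt <- rtnorm(1, 16, 6, 4, 30) + stats::runif(k, -1, 1)
  silt <- pmax(silt, 2)
  over <- clay + silt > 95
  silt[over] <- 95 - clay[over]
  sand <- 100 - clay - silt
  oc0 <- rlnorm_cap(1, log(15), 0.4, 50)
  tibble::tibble(
    profile_id = profile_id,
    top = iv$top, bottom = iv$bottom,
    sand = sand, silt = silt, clay = clay,
    oc = pmax(oc0 * exp(-mid / 60), 1),
    bd = rtnorm(1, 1.3, 0.1, 1.05, 1.5) + 0.03 * (seq_len(k) - 1) / k,
    cec = rtnorm(1, 14, 5, 4, 35) + stats::runif(k, -1, 1),
    ph = rtnorm(1, 6.0, 0.5, 4.8, 7.4) + stats::runif(k, -0.1, 0.1),
    cf = rlnorm_cap(k, log(2), 0.8, 12),
    ec = rlnorm_cap(k, log(0.08), 1, 1.2),
    exch_na = rlnorm_cap(k, log(0.1), 1, 0.9),
    exch_al = stats::runif(k, 0, 0.4),
    caco3 = stats::runif(1, 0, 80) + stats::runif(k, 0, 10),
    caso4 = stats::runif(1, 0, 20) + stats::runif(k, 0, 5),
    drainage_class = sample(5:7, 1),
    depth_to_bedrock = NA_real_,
    lon = stats::runif(1, -17, 48), lat = stats::runif(1, -34, 17)
  )
}

# Adverse-property injections. Each targets one limiting factor and edits the
# layers below `below` cm (default 30, i.e. the 30-60, 60-100 and 100-200 cm
# intervals) so the restriction depth falls between the adjacent interval
# midpoints.
inject <- function(p, target, below = 30) {
  i <- p$top >= below
  switch(
    target,
    porosity_vmc_sat = {
      # dense low-porosity subsoil: saturated VMC drops below 27.5 v%
      p$bd[i] <- stats::runif(1, 1.97, 2.1)
      p$clay[i] <- 18; p$silt[i] <- 16; p$sand[i] <- 66
      p$cec[i] <- 5; p$ph[i] <- 5.2
    },
    porosity_f_bd = {
      # denser than the texture-critical bulk density, porosity itself ok
      p$clay[i] <- 45; p$silt[i] <- 16; p$sand[i] <- 39
      p$bd[i] <- 1.6 - 0.0035 * 45 + stats::runif(1, 0.31, 0.35)
      p$cec[i] <- 20; p$ph[i] <- 6.5
    },
    volume_crsvol = p$cf[i] <- stats::runif(sum(i), 88.5, 90),
    texture_sand = {
      p$sand[!i] <- 85; p$silt[!i] <- 7; p$clay[!i] <- 8
      s <- stats::runif(1, 99.2, 99.8)
      p$sand[i] <- s; p$clay[i] <- 0.1; p$silt[i] <- 100 - s - 0.1
      p$oc[i] <- 2; p$cec[i] <- 3
    },
    texture_f_sand = {
      p$sand[!i] <- 35; p$clay[!i] <- 40; p$silt[!i] <- 25
      p$sand[i] <- 35 + stats::runif(1, 52, 54)
      p$clay[i] <- 6; p$silt[i] <- 100 - p$sand[i] - 6
    },
    texture_f_clay = {
      p$clay[!i] <- 10; p$sand[!i] <- 74; p$silt[!i] <- 16
      p$clay[i] <- 10 + stats::runif(1, 52, 54)
      p$sand[i] <- 100 - p$clay[i] - 16; p$silt[i] <- 16
    },
    induration_caco3 = p$caco3[i] <- stats::runif(1, 420, 600),
    induration_caso4 = p$caso4[i] <- stats::runif(1, 320, 500),
    acidity_ph = { p$ph[i] <- stats::runif(1, 3.66, 3.85); p$exch_al[i] <- 0 },
    alkalinity_ph = p$ph[i] <- stats::runif(1, 9.1, 9.5),
    salinity_ec = p$ec[i] <- stats::runif(1, 6.9, 15),
    sodicity_exch_na = p$exch_na[i] <- stats::runif(1, 5.5, 9),
    toxicity_exch_al = {
      p$exch_al[i] <- stats::runif(1, 6.6, 8)
      p$cec[i] <- 30; p$ph[i] <- 4.9
    },
    toxicity_f_exch_al = {
      p$exch_al[i] <- stats::runif(1, 3.0, 3.3)
      p$cec[i] <- 3.5; p$ph[i] <- 4.9
    },
    depth_soil = p$depth_to_bedrock <- stats::runif(1, 20, 120),
    depth_aeration = p$drainage_class <- sample(1:4, 1),
    depth_max = NULL,
    stop("unknown injection target: ", target, call. = FALSE)
  )
  p
}

mixed_targets <- function() {
  c("porosity_vmc_sat", "porosity_f_bd", "volume_crsvol", "texture_sand",
    "texture_f_sand", "texture_f_clay", "induration_caco3",
    "induration_caso4", "acidity_ph", "alkalinity_ph", "salinity_ec",
    "sodicity_exch_na", "toxicity_exch_al", "toxicity_f_exch_al",
    "depth_soil", "depth_aeration", "depth_max")
}

#' Generate synthetic soil profiles
#'
#' Seeded generator of soil profiles on the six standard depth intervals,
#' with property marginals anchored to the observed ranges of a continental
#' soil-profile compilation (skewed properties drawn log-normal, clay
#' increasing and organic carbon decreasing with depth). Scenarios inject
#' documented adverse conditions: `unconstrained` profiles evaluate to the
#' full crop depth; `sodic_lowland` raises exchangeable Na above its
#' threshold below 30 cm; `shallow_bedrock` records bedrock between 20 and
#' 120 cm; `poorly_drained` draws drainage classes 1-3; `acid_toxic` gives
#' strongly acid, aluminium-toxic subsoil; `gravelly` fills the subsoil with
#' 88-90 v% coarse fragments; `saline` raises EC beyond its threshold;
#' `mixed` cycles deterministically through targeted injections so every
#' rootability factor and every profile-level limit occurs as the limiting
#' factor.
#'
#' One `set.seed(seed)` governs the whole run; profiles are drawn
#' sequentially from that stream, so a prefix of a larger run equals a
#' smaller run with the same seed.
#'
#' @param scenario One of [scenario_names()].
#' @param n Number of profiles, >= 1.
#' @param seed Integer seed.
#' @return Validated layer table, `n` profiles x 6 intervals.
#' @export
generate_profiles <- function(scenario = "mixed", n = 10, seed = 1) {
  if (!scenario %in% scenario_names()) {
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(scenario_names(), collapse = ", "), call. = FALSE)
  }
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  targets <- mixed_targets()
  make_one <- function(i) {
    p <- benign_profile(sprintf("%s_%04d", scenario, i))
    switch(scenario,
      unconstrained = p,
      sodic_lowland = inject(p, "sodicity_exch_na"),
      shallow_bedrock = inject(p, "depth_soil"),
      poorly_drained = inject(p, "depth_aeration"),
      acid_toxic = inject(inject(p, "acidity_ph"), "toxicity_exch_al",
                          below = 60),
      gravelly = inject(p, "volume_crsvol"),
      saline = inject(p, "salinity_ec"),
      mixed = inject(p, targets[(i - 1) %% length(targets) + 1])
    )
  }
  validate_profiles(purrr::map_dfr(seq_len(n), make_one))
}
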
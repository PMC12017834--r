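# Seeded synthetic-data generators. Each generator reproduces the
# statistical structure the corresponding analysis stage assumes, so the
# whole chain is testable without the (undeposited) raw measurements.
# Defaults emulate the study conditions: 17 trait species, slope 1.4 /
# intercept -1.82 allometry, 40- and 27-grain De regimes with 3-30%
# overdispersion, 210-280 ka enamel transects, volt-scale beam intensities
# with Kr/Rb contamination, and the 11-unit vegetation baseline.
# Every generator is deterministic given (arguments, seed) and its output
# passes the consuming function's input validation.

#' Simulate a phylogeny and allometric trait table
#'
#' Draws a coalescent tree (rescaled to unit height), evolves log10 body
#' mass by Brownian motion, and sets log10 home range to
#' `intercept + slope * log10(mass)` plus Brownian phylogenetic noise.
#' With `noise_sd = 0` the traits are perfectly collinear (R^2 = 1); with
#' `star = TRUE` the tree is a star phylogeny, under which the PGLS fit
#' equals OLS.
#'
#' @param n_tips number of species (default 17, the extant trait panel size).
#' @param slope,intercept allometry on the log10-log10 scale (defaults 1.4
#'   and -1.82).
#' @param mass_log10_mean,mass_log10_sd location/spread of log10 body mass.
#' @param noise_sd SD of the Brownian residual in log10 home range at the
#'   tips (default 1.2, which puts the mass effect at roughly a third of the
#'   home-range variance, the regime observed in extant macropodids).
#' @param star use a star phylogeny instead of a coalescent tree.
#' @param seed RNG seed.
#' @return List with `tree` (phylo) and `traits` (wide-form data frame).
#' @export
gen_traits <- function(n_tips = 17, slope = 1.4, intercept = -1.82,
                       mass_log10_mean = 0.8, mass_log10_sd = 0.6,
                       noise_sd = 1.2, star = FALSE, seed = 1) {
  stop_if(n_tips < 3, "need n_tips >= 3")
  stop_if(noise_sd < 0 || mass_log10_sd < 0, "invalid sigma")
  set.seed(seed)
  if (star) {
    tree <- ape::stree(n_tips, type = "star")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree <- ape::rcoal(n_tips)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  C <- bm_covariance(tree)
  L <- chol(C + diag(1e-12, n_tips))
  bm_draw <- function(sd) drop(crossprod(L, rnorm(n_tips))) * sd
  logm <- mass_log10_mean + bm_draw(mass_log10_sd)
  logh <- intercept + slope * logm + bm_draw(noise_sd)
  traits <- data.frame(species = tree$tip.label,
                       body_mass_kg = 10^logm, home_range_km2 = 10^logh)
  list(tree = tree, traits = traits)
}

#' Simulate a single-grain De distribution
#'
#' True log doses are drawn from the (possibly multi-component) log-normal
#' dispersion model, then blurred with relative measurement error:
#' `log De_obs = log De_true + rel_se * e`, `se = rel_se * De_obs`.
#'
#' @param n number of accepted grains.
#' @param central_gy central dose(s) in Gy; a vector together with `props`
#'   gives a discrete mixture (e.g. `c(100, 300)` with `props = c(0.7, 0.3)`).
#' @param od overdispersion (relative SD of true log doses around each
#'   component).
#' @param rel_se relative measurement error per grain (default 0.30, the
#'   single-grain extended-range regime).
#' @param props mixture proportions (recycled/normalised).
#' @param sample sample label.
#' @param seed RNG seed.
#' @return A [dose_distribution()].
#' @export
gen_grains <- function(n = 40, central_gy = 277, od = 0.30, rel_se = 0.30,
                       props = 1, sample = "synthetic", seed = 1) {
  stop_if(od < 0 || rel_se <= 0, "invalid dispersion parameters")
  set.seed(seed)
  props <- rep_len(props, length(central_gy))
  props <- props / sum(props)
  comp <- sample.int(length(central_gy), n, replace = TRUE, prob = props)
  z_true <- log(central_gy[comp]) + od * rnorm(n)
  z_obs <- z_true + rel_se * rnorm(n)
  de <- exp(z_obs)
  dose_distribution(de = de, se = rel_se * de, sample = sample)
}

#' Simulate an enamel U-series transect
#'
#' Runs the forward diffusion-adsorption-decay model at the requested age
#' and boundary 234U/238U, then adds independent Gaussian noise at the
#' stated 2-sigma levels (the scale of the published transect tables).
#'
#' @param age_ka true burial age (ka).
#' @param a234_init boundary (water) 234U/238U activity ratio.
#' @param n_spots number of laser spots along the transect.
#' @param noise_2sd named vector `c(a234 = ..., a230 = ...)` of 2-sigma
#'   noise; set both to 0 for a noise-free profile.
#' @param kappa diffusion parameter, as in [idad_forward()].
#' @param seed RNG seed.
#' @return Profile data frame in the [idad_age()] input layout.
#' @export
gen_useries_profile <- function(age_ka = 250, a234_init = 1.25, n_spots = 20,
                                noise_2sd = c(a234 = 0.012, a230 = 0.06),
                                kappa = 0.002, seed = 1) {
  set.seed(seed)
  pos <- seq(0.04, 0.96, length.out = n_spots)
  f <- idad_forward(age_ka, a234_init, pos, kappa = kappa)
  s34 <- noise_2sd[["a234"]] / 2
  s30 <- noise_2sd[["a230"]] / 2
  data.frame(position_rel = pos,
             a234_238 = f$a234_238 + rnorm(n_spots, 0, s34),
             a234_238_2sd = rep(max(noise_2sd[["a234"]], 1e-6), n_spots),
             a230_238 = f$a230_238 + rnorm(n_spots, 0, s30),
             a230_238_2sd = rep(max(noise_2sd[["a230"]], 1e-6), n_spots))
}

#' Simulate a laser-ablation Sr session of beam cycles
#'
#' Builds a bracketed session (standard block, samples, standard block) of
#' per-cycle Faraday intensities for masses 82-88 with known truth:
#' exponential-law mass bias (optionally drifting), Kr gas blank at natural
#' abundances, Rb contamination fractionated like Sr, a constant additive
#' baseline, a slow multiplicative gain drift on the mass-87 channel (what
#' the bracketing correction removes), and Gaussian beam noise scaling with
#' sqrt(intensity).
#'
#' @param truth true 87Sr/86Sr of the sample spots.
#' @param n_samples number of sample spots.
#' @param beta true mass-bias exponent (drifts linearly by `beta_drift`
#'   across the session).
#' @param beta_drift total linear change in beta over the session.
#' @param kr82_v,rb85_v 82Kr and 85Rb beam intensities (V) in the ablation
#'   window.
#' @param sr86_v 86Sr ablation intensity (V).
#' @param baseline_v additive baseline on every mass (V).
#' @param drift87 total fractional gain drift of the mass-87 channel across
#'   the session.
#' @param noise_v beam noise SD (V) at 1 V intensity; 0 for a noiseless
#'   session.
#' @param n_baseline,n_ablation cycles per window.
#' @param seed RNG seed.
#' @return List with `cycles` (session data frame for [reduce_session()]),
#'   `truth`, and the per-spot layout.
#' @export
gen_beams <- function(truth = 0.708500, n_samples = 2, beta = 1.8,
                      beta_drift = 0, kr82_v = 5e-4, rb85_v = 1e-3,
                      sr86_v = 3, baseline_v = 0.01, drift87 = 0,
                      noise_v = 5e-4, n_baseline = 10, n_ablation = 50,
                      seed = 1) {
  set.seed(seed)
  cst <- sr_constants()
  m <- cst$mass
  spots <- data.frame(
    spot = c(sprintf("clam_pre_%d", 1:3), sprintf("seal_pre_%d", 1:3),
             sprintf("sample_%d", seq_len(n_samples)),
             sprintf("seal_post_%d", 1:3), sprintf("clam_post_%d", 1:3)),
    role = c(rep("bracketing standard", 3), rep("accuracy standard", 3),
             rep("sample", n_samples),
             rep("accuracy standard", 3), rep("bracketing standard", 3)),
    r87_86 = c(rep(cst$seawater_87_86, 6), rep(truth, n_samples),
               rep(cst$seawater_87_86, 6))
  )
  n_spots <- nrow(spots)
  cyc_per_spot <- n_baseline + n_ablation
  t_total <- n_spots * cyc_per_spot

  out <- vector("list", n_spots)
  for (i in seq_len(n_spots)) {
    t_s <- ((i - 1) * cyc_per_spot + seq_len(cyc_per_spot)) * 1.0
    frac <- mean(t_s) / t_total
    b_i <- beta + beta_drift * frac
    g87 <- 1 + drift87 * frac
    ab <- c(rep(0, n_baseline), rep(1, n_ablation))  # ablation on/off

    bias <- function(r_true, mx) r_true * (m[[mx]] / m[["m86"]])^(-b_i)
    m86 <- sr86_v * ab
    m88 <- bias(cst$r88_86_canonical, "m88") * m86
    m87sr <- bias(spots$r87_86[i], "m87") * m86 * g87
    m84sr <- bias(cst$r84_86_natural, "m84") * m86
    m85 <- rb85_v * ab
    m87rb <- m85 * cst$rb87_85 * (m[["m87"]] / m[["m85"]])^(-b_i) * g87
    m82 <- rep(kr82_v, cyc_per_spot)           # gas blank: always present
    m83 <- m82 * 0.11500 / 0.11593
    m84kr <- m82 * cst$kr84_82
    m86kr <- m82 * cst$kr86_82

    raw <- data.frame(
      spot = spots$spot[i], role = spots$role[i],
      cycle = seq_len(cyc_per_spot), t_s = t_s,
      m82 = m82, m83 = m83, m84 = m84sr + m84kr, m85 = m85,
      m86 = m86 + m86kr, m87 = m87sr + m87rb, m88 = m88)
    for (mx in beam_cols) {
      raw[[mx]] <- raw[[mx]] + baseline_v
      if (noise_v > 0)
        raw[[mx]] <- raw[[mx]] + rnorm(cyc_per_spot, 0,
                                       noise_v * sqrt(pmax(raw[[mx]], 0.05)))
    }
    out[[i]] <- raw
  }
  list(cycles = do.call(rbind, out), truth = truth, spots = spots,
       n_baseline = n_baseline)
}

#' Generate a baseline-and-specimen scenario
#'
#' `scenario = "mt_etna"` reconstructs per-unit plant samples whose means
#' and 2SE round-trip exactly to the published Mt Etna baseline (via a
#' deterministic symmetric spread), together with the published specimen
#' summaries. `scenario = "random"` draws unit means uniformly from
#' `ratio_range` and specimens from randomly chosen units.
#'
#' @param scenario `"mt_etna"` or `"random"`.
#' @param n_units,samples_per_unit,ratio_range,unit_2se random-scenario
#'   parameters.
#' @param seed RNG seed (random scenario only).
#' @return List with `plants` (unit, sample_id, sr87_86), `baseline` (the
#'   per-unit summary) and `specimens`.
#' @export
gen_baseline_and_teeth <- function(scenario = c("mt_etna", "random"),
                                   n_units = 8, samples_per_unit = 3,
                                   ratio_range = c(0.705, 0.710),
                                   unit_2se = 3e-4, seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "mt_etna") {
    b <- mt_etna_sr_baseline()
    plants <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
      n <- b$n[i]
      v <- if (n == 1) b$mean_87_86[i] else {
        z <- seq(-1, 1, length.out = n)
        sdv <- b$two_se[i] * sqrt(n) / 2
        b$mean_87_86[i] + sdv * (z - mean(z)) / sd(z)
      }
      data.frame(unit = b$unit[i], sample_id = sprintf("%s_%d", b$unit[i], seq_len(n)),
                 sr87_86 = v)
    }))
    return(list(plants = plants, baseline = b, specimens = mt_etna_specimens()))
  }
  set.seed(seed)
  units <- sprintf("unit_%02d", seq_len(n_units))
  mu <- runif(n_units, ratio_range[1], ratio_range[2])
  sdv <- unit_2se * sqrt(samples_per_unit) / 2
  plants <- do.call(rbind, lapply(seq_len(n_units), function(i) {
    data.frame(unit = units[i],
               sample_id = sprintf("%s_%d", units[i], seq_len(samples_per_unit)),
               sr87_86 = rnorm(samples_per_unit, mu[i], sdv))
  }))
  baseline <- build_baseline(plants, local_units = units[1])
  specimens <- data.frame(tooth = sprintf("tooth_%d", 1:3),
                          unit = sample(units, 3, replace = TRUE))
  specimens$mean_87_86 <- mu[match(specimens$unit, units)] +
    rnorm(3, 0, unit_2se / 2)
  specimens$two_se <- unit_2se / 2
  list(plants = plants, baseline = baseline, specimens = specimens)
}
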
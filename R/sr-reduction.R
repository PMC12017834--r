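# Reduction of raw multi-collector beam intensities (masses 82-88, volts) to
# corrected 87Sr/86Sr per ablation spot: baseline subtraction, Kr and Rb
# isobaric-interference removal, exponential-law mass bias from 88Sr/86Sr,
# and standard-sample-standard bracketing against a carbonate standard of
# known (modern seawater) composition.

#' Isotope constants for Sr reduction
#'
#' Canonical 88Sr/86Sr used for internal normalisation, natural Kr and Rb
#' isotope abundance ratios used for interference stripping, the natural
#' 84Sr/86Sr used as a quality flag, and exact isotope masses for the
#' exponential mass-fractionation law.
#'
#' @return Named list of constants; fixed per reduction run.
#' @export
sr_constants <- function() {
  list(
    r88_86_canonical = 8.375209,   # i.e. 86Sr/88Sr = 0.1194
    r84_86_natural = 0.0565,       # quality-control target after correction
    kr84_82 = 0.56987 / 0.11593,   # natural Kr abundances
    kr86_82 = 0.17279 / 0.11593,
    kr84_83 = 0.56987 / 0.11500,
    kr86_83 = 0.17279 / 0.11500,
    rb87_85 = 0.27830 / 0.72170,   # natural 87Rb/85Rb
    mass = c(m82 = 81.913481, m83 = 82.914127, m84 = 83.913419,
             m85 = 84.911790, m86 = 85.909261, m87 = 86.908877,
             m88 = 87.905612),
    seawater_87_86 = 0.709182
  )
}

beam_cols <- c("m82", "m83", "m84", "m85", "m86", "m87", "m88")

#' Baseline subtraction for one spot
#'
#' Subtracts the per-mass mean of the baseline (gas-blank) cycles from every
#' ablation cycle. `method = "linear"` instead fits a straight line through
#' the baseline cycles versus time and subtracts its prediction at each
#' ablation time, which removes a drifting baseline.
#'
#' @param cycles data frame of beam cycles with columns `t_s` and
#'   `m82 ... m88`.
#' @param baseline logical or integer index of the baseline cycles (>= 3).
#' @param ablation logical or integer index of the ablation cycles (disjoint
#'   from `baseline`).
#' @param method `"mean"` or `"linear"`.
#' @return The ablation cycles with baseline-corrected intensities (negative
#'   values are permitted and flagged downstream).
#' @export
baseline_subtract <- function(cycles, baseline, ablation, method = c("mean", "linear")) {
  method <- match.arg(method)
  stop_if(!all(beam_cols %in% names(cycles)),
          "cycles need columns: ", paste(beam_cols, collapse = ", "))
  bl <- cycles[baseline, , drop = FALSE]
  ab <- cycles[ablation, , drop = FALSE]
  stop_if(nrow(bl) < 3, "baseline window needs at least 3 cycles")
  stop_if(nrow(ab) < 1, "ablation window is empty")
  idx <- seq_len(nrow(cycles))
  stop_if(length(intersect(idx[baseline], idx[ablation])) > 0,
          "baseline and ablation windows must be disjoint")
  for (m in beam_cols) {
    if (method == "mean") {
      ab[[m]] <- ab[[m]] - mean(bl[[m]])
    } else {
      fit <- lm(bl[[m]] ~ bl$t_s)
      ab[[m]] <- ab[[m]] - (coef(fit)[1] + coef(fit)[2] * ab$t_s)
    }
  }
  ab
}

#' Krypton interference correction
#'
#' Estimates the 84Kr and 86Kr beams from the interference-free 82Kr monitor
#' (optionally averaged with the 83Kr prediction) using natural Kr abundance
#' ratios, and subtracts them from the mass-84 and mass-86 beams.
#'
#' @param net baseline-subtracted cycles.
#' @param c isotope constants from [sr_constants()].
#' @param monitor `"kr82"` (default, as reduction schemes for these
#'   collectors state) or `"mean"` to average the 82Kr- and 83Kr-based
#'   predictions.
#' @return Cycles with Kr removed from `m84` and `m86`; attribute
#'   `negative_flag` marks cycles driven negative.
#' @export
kr_correct <- function(net, c = sr_constants(), monitor = c("kr82", "mean")) {
  monitor <- match.arg(monitor)
  if (monitor == "kr82") {
    kr84 <- net$m82 * c$kr84_82
    kr86 <- net$m82 * c$kr86_82
  } else {
    kr84 <- (net$m82 * c$kr84_82 + net$m83 * c$kr84_83) / 2
    kr86 <- (net$m82 * c$kr86_82 + net$m83 * c$kr86_83) / 2
  }
  net$m84 <- net$m84 - kr84
  net$m86 <- net$m86 - kr86
  attr(net, "negative_flag") <- any(net$m84 < 0 | net$m86 < 0)
  net
}

#' Exponential-law mass bias from the 88Sr/86Sr ratio
#'
#' `beta = ln(R_canonical / R_measured) / ln(m88 / m86)` per cycle, on the
#' Kr-corrected beams. The cycle-wise betas are summarised by their median
#' to stabilise low beams.
#'
#' @param net Kr-corrected cycles.
#' @param c isotope constants.
#' @return List with `beta` (median) and `beta_cycles`.
#' @export
mass_bias <- function(net, c = sr_constants()) {
  stop_if(any(net$m86 <= 0) || any(net$m88 <= 0),
          "non-positive 86Sr/88Sr beams: cannot compute mass bias")
  r_meas <- net$m88 / net$m86
  b <- log(c$r88_86_canonical / r_meas) / log(c$mass["m88"] / c$mass["m86"])
  list(beta = median(b), beta_cycles = unname(b))
}

#' Rubidium interference correction on mass 87
#'
#' Estimates the *measured* 87Rb beam from the 85Rb monitor: the natural
#' 87Rb/85Rb ratio fractionates in the plasma by the same exponential law as
#' Sr, so the beam arriving at mass 87 is
#' `m85 * (87Rb/85Rb)_nat * (m87/m85)^(-beta)` (with `beta` the exponent
#' that corrects measured ratios back to true values). That beam is
#' subtracted from the mass-87 channel.
#'
#' @param net Kr-corrected cycles.
#' @param beta mass-bias exponent from [mass_bias()].
#' @param c isotope constants.
#' @return Cycles with `m87` replaced by the Rb-stripped 87Sr beam;
#'   attribute `overcorrected` flags negative results.
#' @export
rb_correct <- function(net, beta, c = sr_constants()) {
  rb87 <- net$m85 * c$rb87_85 * (c$mass["m87"] / c$mass["m85"])^(-beta)
  net$m87 <- net$m87 - rb87
  attr(net, "overcorrected") <- any(net$m87 < 0)
  net
}

# internally corrected ratios for one spot's net cycles
spot_ratios <- function(net, c = sr_constants()) {
  mb <- mass_bias(net, c)
  net2 <- rb_correct(net, mb$beta, c)
  m <- c$mass
  r87 <- net2$m87 / net2$m86 * (m["m87"] / m["m86"])^mb$beta
  r84 <- net2$m84 / net2$m86 * (m["m84"] / m["m86"])^mb$beta
  rb86 <- (net$m85 * c$rb87_85 * (m["m87"] / m["m85"])^mb$beta) / net2$m86 *
    (m["m87"] / m["m86"])^mb$beta
  n <- length(r87)
  list(r87_86 = mean(r87), r87_86_se = if (n > 1) sd(r87) / sqrt(n) else 0,
       r84_86 = mean(r84), rb87_86 = mean(rb86), beta = mb$beta,
       n_cycles = n, overcorrected = isTRUE(attr(net2, "overcorrected")))
}

#' Reduce a full laser-ablation Sr session
#'
#' Runs the complete correction chain for every spot (baseline subtraction,
#' Kr and Rb stripping, mass-bias normalisation), then applies
#' standard-sample-standard bracketing: the internally corrected ratio of
#' the bracketing standard, interpolated linearly in time between the
#' standard blocks before and after each sample, is pinned to its accepted
#' value and the resulting factor applied to the samples.
#'
#' @param cycles data frame with columns
#'   `spot, role, cycle, t_s, m82, m83, m84, m85, m86, m87, m88`; `role` is
#'   one of `sample`, `bracketing standard`, `accuracy standard`.
#' @param baseline_cycles number of leading cycles per spot treated as
#'   baseline (the rest are ablation).
#' @param accepted accepted 87Sr/86Sr of the bracketing standard (default
#'   modern seawater, 0.709182).
#' @param c isotope constants.
#' @param baseline_method passed to [baseline_subtract()].
#' @param kr_monitor passed to [kr_correct()].
#' @return Data frame of class `"reduced_spots"`: one row per spot with
#'   internally corrected and bracketed ratios, internal 2SE, beta, and
#'   quality flags (`r84_86` near its natural value is the quality check).
#' @export
reduce_session <- function(cycles, baseline_cycles = 10,
                           accepted = sr_constants()$seawater_87_86,
                           c = sr_constants(), baseline_method = "mean",
                           kr_monitor = "kr82") {
  need <- c("spot", "role", "t_s", beam_cols)
  stop_if(!all(need %in% names(cycles)), "cycles need columns: ",
          paste(need, collapse = ", "))
  spots <- unique(cycles$spot)
  rows <- lapply(spots, function(sp) {
    cs <- cycles[cycles$spot == sp, , drop = FALSE]
    cs <- cs[order(cs$t_s), , drop = FALSE]
    nb <- min(baseline_cycles, nrow(cs) - 1L)
    net <- baseline_subtract(cs, seq_len(nb), (nb + 1):nrow(cs),
                             method = baseline_method)
    net <- kr_correct(net, c, monitor = kr_monitor)
    r <- spot_ratios(net, c)
    data.frame(spot = sp, role = cs$role[1], t_s = mean(net$t_s),
               r87_86_internal = r$r87_86, r87_86_se = r$r87_86_se,
               r84_86 = r$r84_86, rb87_86 = r$rb87_86, beta = r$beta,
               n_cycles = r$n_cycles, overcorrected = r$overcorrected)
  })
  out <- do.call(rbind, rows)

  std <- out[out$role == "bracketing standard", , drop = FALSE]
  stop_if(nrow(std) == 0, "no bracketing standards in session")
  if (nrow(std) == 1) {
    std_at <- function(t) rep(std$r87_86_internal, length(t))
  } else {
    std_at <- function(t) stats::approx(std$t_s, std$r87_86_internal,
                                        xout = t, rule = 2)$y
  }
  out$bracket_factor <- accepted / std_at(out$t_s)
  out$r87_86 <- out$r87_86_internal * out$bracket_factor
  out$two_se <- 2 * out$r87_86_se * out$bracket_factor
  out$r84_86_ok <- abs(out$r84_86 - c$r84_86_natural) < 0.002
  class(out) <- c("reduced_spots", "data.frame")
  out
}

#' Summarise reduced spots per tooth/transect
#'
#' Mean 87Sr/86Sr and `2 * sd/sqrt(n)` per group; a single-spot group falls
#' back to twice the spot's internal SE.
#'
#' @param spots data frame with columns `tooth`, `transect`, `r87_86` and
#'   (for the single-spot fallback) `r87_86_se`.
#' @return Data frame `tooth, transect, mean_87_86, two_se, n_spots`.
#' @export
transect_summary <- function(spots) {
  need <- c("tooth", "transect", "r87_86")
  stop_if(!all(need %in% names(spots)), "spots need columns: ",
          paste(need, collapse = ", "))
  groups <- unique(spots[, c("tooth", "transect")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- spots[spots$tooth == groups$tooth[i] & spots$transect == groups$transect[i], ]
    n <- nrow(g)
    two_se <- if (n > 1) 2 * sd(g$r87_86) / sqrt(n)
              else if ("r87_86_se" %in% names(g)) 2 * g$r87_86_se else 0
    data.frame(tooth = groups$tooth[i], transect = groups$transect[i],
               mean_87_86 = mean(g$r87_86), two_se = two_se, n_spots = n)
  })
  do.call(rbind, rows)
}

#' Welch two-sample t test
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return List `t, df, p`.
#' @export
welch_t <- function(a, b) {
  stop_if(length(a) < 2 || length(b) < 2, "each group needs n >= 2")
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test()])
#' followed by Dunn's pairwise z tests on mean ranks, with Holm adjustment
#' by default (raw and Bonferroni p values are also returned).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return List `H, df, p, pairwise` (data frame with z, p_raw, p_holm,
#'   p_bonferroni).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.factor(groups)
  stop_if(nlevels(groups) < 2, "need at least 2 groups")
  if (length(unique(values)) == 1) {
    lv <- levels(groups)
    pw <- t(utils::combn(lv, 2))
    pairwise <- data.frame(group_a = pw[, 1], group_b = pw[, 2], z = 0,
                           p_raw = 1, p_holm = 1, p_bonferroni = 1)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1, pairwise = pairwise))
  }
  kt <- kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  pw <- t(utils::combn(lv, 2))
  z <- p_raw <- numeric(nrow(pw))
  for (i in seq_len(nrow(pw))) {
    a <- pw[i, 1]; b <- pw[i, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[i] <- 2 * pnorm(-abs(z[i]))
  }
  pairwise <- data.frame(group_a = pw[, 1], group_b = pw[, 2], z = z,
                         p_raw = p_raw,
                         p_holm = stats::p.adjust(p_raw, "holm"),
                         p_bonferroni = stats::p.adjust(p_raw, "bonferroni"))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       pairwise = pairwise)
}
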
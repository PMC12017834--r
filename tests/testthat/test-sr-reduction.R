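# n cycles: the first n_bl are gas blank (baseline level only), the rest
# carry the ablation signal on top of the baseline level
make_cycles <- function(n = 20, n_bl = 5, base = 0) {
  ab <- c(rep(0, n_bl), rep(1, n - n_bl))
  data.frame(t_s = seq_len(n),
             m82 = base, m83 = base, m84 = base + 0.1 * ab, m85 = base,
             m86 = base + 2 * ab, m87 = base + 1.4 * ab, m88 = base + 16 * ab)
}

test_that("baseline subtraction removes constant and drifting baselines", {
  cyc <- make_cycles(20, base = 0.05)
  net <- baseline_subtract(cyc, 1:5, 6:20, method = "mean")
  expect_equal(net$m86, rep(2, 15))
  expect_equal(net$m82, rep(0, 15))
  # zero baseline -> identity
  cyc0 <- make_cycles(20, base = 0)
  net0 <- baseline_subtract(cyc0, 1:5, 6:20)
  expect_equal(net0$m87, cyc0$m87[6:20])
  # linearly drifting baseline removed exactly by the linear option
  cycd <- make_cycles(20)
  drift <- 0.01 * cycd$t_s
  for (m in c("m82", "m86", "m87")) cycd[[m]] <- cycd[[m]] + drift
  netd <- baseline_subtract(cycd, 1:5, 6:20, method = "linear")
  expect_equal(netd$m86, rep(2, 15), tolerance = 1e-10)
  expect_error(baseline_subtract(cyc, 1:2, 3:20), "at least 3")
  expect_error(baseline_subtract(cyc, 1:5, 5:20), "disjoint")
})

test_that("Kr correction strips the gas interference from masses 84 and 86", {
  cst <- sr_constants()
  net <- make_cycles(5, n_bl = 0)[, -1]
  net$t_s <- 1:5
  # no Kr -> identity
  out <- kr_correct(net, cst)
  expect_equal(out$m84, net$m84)
  expect_equal(out$m86, net$m86)
  # pure Kr blank constructed from natural abundances reduces to ~0
  blank <- net
  blank$m82 <- 0.001
  blank$m83 <- 0.001 * 0.11500 / 0.11593
  blank$m84 <- 0.001 * cst$kr84_82
  blank$m86 <- 0.001 * cst$kr86_82
  outb <- kr_correct(blank, cst)
  expect_equal(outb$m84, rep(0, 5), tolerance = 1e-12)
  expect_equal(outb$m86, rep(0, 5), tolerance = 1e-12)
  # averaged 82/83 monitor gives the same answer for consistent Kr
  outm <- kr_correct(blank, cst, monitor = "mean")
  expect_equal(outm$m84, rep(0, 5), tolerance = 1e-12)
})

test_that("mass bias follows the exponential law algebra", {
  cst <- sr_constants()
  net <- make_cycles(5, n_bl = 0)[, -1]
  net$m86 <- 1
  net$m88 <- cst$r88_86_canonical
  expect_equal(mass_bias(net, cst)$beta, 0)
  # measured = canonical * (m88/m86)^0.5 -> beta = -0.5
  net$m88 <- cst$r88_86_canonical * (cst$mass["m88"] / cst$mass["m86"])^0.5
  expect_equal(mass_bias(net, cst)$beta, -0.5, tolerance = 1e-12)
  # round trip at an arbitrary beta
  b_true <- 1.8
  net$m88 <- cst$r88_86_canonical * (cst$mass["m88"] / cst$mass["m86"])^(-b_true)
  expect_equal(mass_bias(net, cst)$beta, b_true, tolerance = 1e-12)
})

test_that("Rb correction removes the fractionated 87Rb beam", {
  cst <- sr_constants()
  net <- make_cycles(5, n_bl = 0)[, -1]
  # no Rb -> identity
  out <- rb_correct(net, beta = 1.5, cst)
  expect_equal(out$m87, net$m87)
  # beta = 0 reduces to plain natural-ratio subtraction
  net$m85 <- 0.01
  out0 <- rb_correct(net, beta = 0, cst)
  expect_equal(out0$m87, net$m87 - 0.01 * cst$rb87_85)
  # a known doped beam is removed exactly
  b <- 1.8
  doped <- net
  doped$m87 <- net$m87 + 0.01 * cst$rb87_85 *
    (cst$mass["m87"] / cst$mass["m85"])^(-b)
  outd <- rb_correct(doped, beta = b, cst)
  expect_equal(outd$m87, net$m87, tolerance = 1e-12)
})

test_that("the full reduction chain recovers a known truth", {
  # zero noise: exact to well within 5e-5
  s <- gen_beams(truth = 0.708500, beta = 1.8, beta_drift = 0.1,
                 drift87 = 5e-5, noise_v = 0, seed = 2)
  red <- reduce_session(s$cycles, baseline_cycles = s$n_baseline)
  samp <- red[red$role == "sample", ]
  expect_lt(max(abs(samp$r87_86 - 0.708500)), 5e-5)
  # quality flag: corrected 84Sr/86Sr near its natural value
  expect_true(all(samp$r84_86_ok))
  expect_equal(samp$r84_86, rep(0.0565, nrow(samp)), tolerance = 1e-4)
  # accuracy standard lands on the seawater value (the session check)
  seal <- red[red$role == "accuracy standard", ]
  expect_lt(max(abs(seal$r87_86 - 0.709182)), 5e-5)
})

test_that("the corrected ratio is invariant to uniform beam scaling", {
  s <- gen_beams(truth = 0.7085, beta = 1.8, noise_v = 0, seed = 3)
  cyc2 <- s$cycles
  for (m in c("m82", "m83", "m84", "m85", "m86", "m87", "m88"))
    cyc2[[m]] <- cyc2[[m]] * 3.7
  r1 <- reduce_session(s$cycles, baseline_cycles = s$n_baseline)
  r2 <- reduce_session(cyc2, baseline_cycles = s$n_baseline)
  expect_equal(r2$r87_86, r1$r87_86, tolerance = 1e-12)
})

test_that("bracketing with an on-value standard is idempotent and removes drift", {
  # standard measuring exactly the accepted value -> factor 1
  s <- gen_beams(truth = 0.7085, beta = 1.8, noise_v = 0, seed = 4)
  red <- reduce_session(s$cycles, baseline_cycles = s$n_baseline)
  expect_equal(red$bracket_factor, rep(1, nrow(red)), tolerance = 1e-10)
  # linear drift on the 87 channel is removed by interpolation
  sd_ <- gen_beams(truth = 0.7085, beta = 1.8, drift87 = 2e-4, noise_v = 0,
                   seed = 5)
  redd <- reduce_session(sd_$cycles, baseline_cycles = sd_$n_baseline)
  samp <- redd[redd$role == "sample", ]
  expect_lt(max(abs(samp$r87_86 - 0.7085)), 1.5e-5)
  # without bracketing the drift would bias by ~ truth * drift/2 ~ 7e-5
  expect_gt(max(abs(samp$r87_86_internal - 0.7085)), 3e-5)
})

test_that("transect summaries use 2 * sd/sqrt(n) with a single-spot fallback", {
  spots <- data.frame(tooth = c("t1", "t1", "t1", "t2"),
                      transect = c(1, 1, 1, 1),
                      r87_86 = c(0.708, 0.7081, 0.7082, 0.709),
                      r87_86_se = c(1e-5, 1e-5, 1e-5, 3e-5))
  ts <- transect_summary(spots)
  r1 <- ts[ts$tooth == "t1", ]
  expect_equal(r1$mean_87_86, 0.7081)
  expect_equal(r1$two_se, 2 * sd(c(0.708, 0.7081, 0.7082)) / sqrt(3))
  r2 <- ts[ts$tooth == "t2", ]
  expect_equal(r2$two_se, 6e-5)  # single spot: 2 * internal SE
  # two equal spots -> zero scatter
  eq <- transect_summary(data.frame(tooth = "t", transect = 1,
                                    r87_86 = c(0.708, 0.708)))
  expect_equal(eq$two_se, 0)
})

test_that("Welch t test matches the hand-computed statistic", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.8)
  w <- welch_t(a, b)
  se <- sqrt(var(a) / 12 + var(b) / 12)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 12)^2 / 11 + (var(b) / 12)^2 / 11)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  # identical groups -> p = 1
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("crown-base contrast at the published scale is highly significant", {
  set.seed(14)
  crown <- rnorm(12, 0.708804, 0.000216 * sqrt(12) / 2)
  base <- rnorm(16, 0.707706, 0.000086 * sqrt(16) / 2)
  expect_lt(welch_t(crown, base)$p, 0.001)
})

test_that("Kruskal-Wallis + Dunn agrees with a permutation oracle", {
  set.seed(10)
  groups <- rep(c("a", "b", "c"), each = 5)
  values <- c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 2.5))
  kd <- kruskal_dunn(values, groups)
  # permutation null for H
  H_obs <- kd$H
  perm <- replicate(2000, {
    kruskal.test(values, sample(groups))$statistic
  })
  p_perm <- mean(perm >= H_obs - 1e-12)
  expect_lt(abs(p_perm - kd$p), 0.05)
  # the shifted group drives the significant pairwise contrasts
  pw <- kd$pairwise
  with_c <- pw$group_a == "c" | pw$group_b == "c"
  expect_true(all(pw$p_holm[with_c] < 0.05))
  expect_true(all(pw$p_holm[!with_c] > 0.05))
  # identical groups -> H = 0, p = 1
  kd0 <- kruskal_dunn(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(kd0$H, 0)
  expect_equal(kd0$p, 1)
})
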
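test_that("CAM degenerates correctly on identical grains", {
  d <- dose_distribution(de = rep(150, 10), se = rep(15, 10))
  fit <- central_age_model(d)
  expect_equal(fit$burial_dose, 150, tolerance = 1e-6)
  expect_lt(fit$overdispersion, 1e-4)
})

test_that("CAM estimate satisfies the weighted-mean stationarity condition", {
  d <- gen_grains(n = 50, central_gy = 200, od = 0.2, rel_se = 0.15, seed = 4)
  fit <- central_age_model(d)
  g <- d$grains
  z <- log(g$de); s <- g$se / g$de
  w <- 1 / (fit$overdispersion^2 + s^2)
  expect_equal(log(fit$burial_dose), sum(w * z) / sum(w), tolerance = 1e-7)
  # central dose lies within the span of accepted doses
  expect_gt(fit$burial_dose, min(g$de))
  expect_lt(fit$burial_dose, max(g$de))
})

test_that("CAM recovers simulated central dose and overdispersion", {
  d <- gen_grains(n = 300, central_gy = 280, od = 0.25, rel_se = 0.10, seed = 7)
  fit <- central_age_model(d)
  expect_lt(abs(fit$burial_dose - 280), 2 * fit$burial_dose_se)
  expect_lt(abs(fit$overdispersion - 0.25), 2 * fit$overdispersion_se)
})

test_that("CAM maximum matches a profile-likelihood grid oracle", {
  d <- gen_grains(n = 20, central_gy = 120, od = 0.2, rel_se = 0.12, seed = 9)
  fit <- central_age_model(d)
  g <- d$grains
  z <- log(g$de); s <- g$se / g$de
  oracle <- grid_maximise(function(a, b) pr_cam_loglik(a, b, z, s),
                          lo = c(min(z), 0), hi = c(max(z), 2 * sd(z)))
  expect_equal(fit$max_log_likelihood, oracle, tolerance = 1e-6)
  expect_gte(fit$max_log_likelihood, oracle - 1e-6)
})

test_that("CAM rejects non-positive doses with a helpful message", {
  d <- dose_distribution(de = c(-1, 5, 10), se = c(1, 1, 1))
  expect_error(central_age_model(d), "unlogged")
})

test_that("MAM-3 matches CAM on unmixed data and finds the low component in mixtures", {
  # unmixed: minimum dose ~ central dose, p near 1
  d <- gen_grains(n = 80, central_gy = 200, od = 0.15, rel_se = 0.10, seed = 21)
  cam <- central_age_model(d)
  mam <- minimum_age_model(d, 3, sigma_b = 0.1)
  expect_lt(abs(mam$burial_dose - cam$burial_dose),
            2 * sqrt(cam$burial_dose_se^2 + mam$burial_dose_se^2))
  # MAM minimum never exceeds the CAM central dose (optimizer tolerance)
  expect_lte(mam$burial_dose, cam$burial_dose * (1 + 1e-4))
  # mixture: 70% at 100 Gy, 30% at 300 Gy
  dm <- gen_grains(n = 100, central_gy = c(100, 300), od = 0.10, rel_se = 0.10,
                   props = c(0.7, 0.3), seed = 3)
  fm <- minimum_age_model(dm, 3, sigma_b = 0.1)
  expect_lt(abs(fm$burial_dose - 100), 2 * fm$burial_dose_se)
  camm <- central_age_model(dm)
  expect_lt(fm$burial_dose, camm$burial_dose)
})

test_that("MAM-3 optimum matches a 3-parameter grid oracle", {
  d <- gen_grains(n = 15, central_gy = c(100, 250), od = 0.1, rel_se = 0.1,
                  props = c(0.6, 0.4), seed = 5)
  fit <- minimum_age_model(d, 3, sigma_b = 0.1)
  g <- d$grains
  z <- log(g$de); s <- sqrt((g$se / g$de)^2 + 0.1^2)
  oracle <- grid_maximise3(
    function(gam, p, sig) {
      if (p <= 0 || p >= 1 || sig <= 0) return(-Inf)
      pr_mam_loglik(gam, p, gam, sig, z, s)
    },
    lo = c(min(z) - 0.2, 0.01, 0.01), hi = c(max(z), 0.99, 1.5))
  expect_equal(fit$max_log_likelihood, oracle, tolerance = 1e-4)
})

test_that("MAM-4 nests MAM-3 and fits with a free mean", {
  d <- gen_grains(n = 60, central_gy = c(100, 300), od = 0.1, rel_se = 0.1,
                  props = c(0.6, 0.4), seed = 13)
  m3 <- minimum_age_model(d, 3, sigma_b = 0.1)
  m4 <- minimum_age_model(d, 4, sigma_b = 0.1)
  expect_gte(m4$max_log_likelihood, m3$max_log_likelihood - 1e-4)
  expect_equal(m4$n_parameters, 4)
})

test_that("Lmax selection prefers CAM on unmixed data, MAM on mixtures", {
  d <- gen_grains(n = 80, central_gy = 250, od = 0.15, rel_se = 0.10, seed = 31)
  cam <- central_age_model(d)
  m3 <- minimum_age_model(d, 3, sigma_b = 0)
  m4 <- minimum_age_model(d, 4, sigma_b = 0)
  sel <- select_age_model(cam, m3, m4)
  expect_equal(sel$chosen, "CAM")

  dm <- gen_grains(n = 120, central_gy = c(80, 400), od = 0.05, rel_se = 0.08,
                   props = c(0.5, 0.5), seed = 32)
  sel2 <- select_age_model(central_age_model(dm),
                           minimum_age_model(dm, 3, sigma_b = 0),
                           minimum_age_model(dm, 4, sigma_b = 0))
  expect_true(sel2$chosen %in% c("MAM3", "MAM4"))

  # identical likelihoods -> parsimony tie-break to CAM
  fake <- function(model, k) paleorange:::new_dose_model(
    model, 100, 5, 0.1, 0.02, max_log_likelihood = -10, n_parameters = k,
    n_grains = 40, sigma_b = 0, parameters = c())
  sel3 <- select_age_model(fake("CAM", 2), fake("MAM3", 3), fake("MAM4", 4),
                           criterion = "raw")
  expect_equal(sel3$chosen, "CAM")
  expect_error(select_age_model(cam, minimum_age_model(dm, 3, sigma_b = 0)),
               "different grain sets")
})

test_that("weighted skewness test flags heavy upper tails only", {
  # symmetric distribution: not significant
  set.seed(8)
  de <- exp(rnorm(60, log(100), 0.2))
  d <- dose_distribution(de, 0.1 * de)
  ws <- weighted_skewness_test(d)
  expect_false(ws$significant)
  # strong positive skew in log space
  z <- c(rnorm(50, log(100), 0.05), log(100) + abs(rnorm(25, 0, 1.2)) + 0.5)
  de2 <- exp(z)
  ws2 <- weighted_skewness_test(dose_distribution(de2, 0.05 * de2))
  expect_true(ws2$significant)
  # n = 6 equal weights: bound = c * 1
  d6 <- dose_distribution(exp(rnorm(6, 5, 0.3)), se = exp(rnorm(6, 5, 0.3)) * 0.1)
  d6$grains$se <- d6$grains$de * 0.1
  expect_equal(weighted_skewness_test(d6, c_crit = 2)$critical_value, 2)
})

test_that("radial-plot coordinates standardise against the reference dose", {
  d <- dose_distribution(de = c(100, 110, 90), se = c(10, 11, 9))
  rc <- radial_plot_coords(d, reference = 100)
  expect_equal(rc$std_estimate[1], 0)
  expect_equal(rc$precision, rep(10, 3))
  # with no overdispersion ~95% of grains sit within the 2-sigma band
  big <- gen_grains(n = 2000, central_gy = 100, od = 0, rel_se = 0.1, seed = 6)
  rcb <- radial_plot_coords(big, reference = 100)
  expect_gt(mean(rcb$within_2sigma), 0.93)
  expect_lt(mean(rcb$within_2sigma), 0.97)
})

test_that("grain CSV round-trips through read_grains", {
  tmp <- tempfile(fileext = ".csv")
  d <- gen_grains(n = 12, seed = 2)
  df <- cbind(sample = "s1", d$grains)
  names(df) <- c("sample", "grain_id", "de_gy", "se_gy", "accepted")
  write.csv(df, tmp, row.names = FALSE)
  d2 <- read_grains(tmp, sample = "s1")
  expect_equal(d2$grains$de, d$grains$de)
  expect_equal(d2$n_accepted, d$n_accepted)
  unlink(tmp)
})
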
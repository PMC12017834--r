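test_that("weighted trait averaging follows inverse-variance weights", {
  expect_equal(weighted_trait_average(5, 1), 5)
  expect_equal(weighted_trait_average(c(2, 4), c(1, 1)), 3)
  # hand computation: w = (1, 1/4), (2 + 1)/(1.25) = 2.4
  expect_equal(weighted_trait_average(c(2, 4), c(1, 2)), 2.4)
  # 1/e weighting option
  expect_equal(weighted_trait_average(c(2, 4), c(1, 2), "inverse_error"),
               (2 + 2) / 1.5)
  expect_error(weighted_trait_average(numeric(0), numeric(0)), "at least one")
  expect_error(weighted_trait_average(c(1, 2), c(1, 0)), "> 0")
})

test_that("tree pruning preserves root-to-tip path lengths", {
  set.seed(42)
  tree <- ape::rtree(20)
  keep <- sample(tree$tip.label, 10)
  pruned <- prune_tree(tree, keep)
  expect_setequal(pruned$tip.label, keep)
  d_full <- ape::cophenetic.phylo(tree)[keep, keep]
  d_sub <- ape::cophenetic.phylo(pruned)[keep, keep]
  expect_equal(d_sub, d_full)
  expect_error(prune_tree(tree, c(keep[1], "nope")), "nope")
  # keeping everything returns an equivalent tree
  all_kept <- prune_tree(tree, tree$tip.label)
  expect_equal(ape::cophenetic.phylo(all_kept), ape::cophenetic.phylo(tree))
})

test_that("BM covariance equals brute-force shared path lengths", {
  # star tree -> identity
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, 5)
  expect_equal(unname(bm_covariance(star)), diag(5))
  # two sisters joined at depth 0.6 of total 1.0
  sisters <- ape::read.tree(text = "(a:0.4,b:0.4):0.6;")
  # read as unrooted 2-tip; build via 3-tip tree instead
  tr <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1.0);")
  C <- bm_covariance(tr)
  expect_equal(C["a", "b"], 0.6)
  expect_equal(C["a", "a"], 1.0)
  # arbitrary tree vs oracle
  set.seed(7)
  tree <- ape::rtree(8)
  expect_equal(bm_covariance(tree), brute_force_bm_cov(tree), tolerance = 1e-12)
})

make_fixture_traits <- function(seed = 11, n = 17) {
  gen_traits(n_tips = n, seed = seed)
}

test_that("PGLS with identity covariance reproduces OLS exactly", {
  g <- make_fixture_traits()
  fit <- pgls_allometry(g$traits, C = diag(nrow(g$traits)))
  ols <- lm(log10(home_range_km2) ~ log10(body_mass_kg), data = g$traits)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$r.squared, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("PGLS matches an independent GLS implementation under BM", {
  skip_if_not_installed("nlme")
  g <- make_fixture_traits(seed = 3)
  fit <- pgls_allometry(g$traits, g$tree)
  df <- data.frame(y = log10(g$traits$home_range_km2),
                   x = log10(g$traits$body_mass_kg),
                   species = g$traits$species)
  rownames(df) <- df$species
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, g$tree, form = ~species))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("PGLS recovers the generating slope across seeded replicates", {
  fits <- lapply(1:200, function(i) {
    g <- gen_traits(n_tips = 50, seed = 2000 + i)
    pgls_allometry(g$traits, g$tree)
  })
  slopes <- vapply(fits, function(f) unname(coef(f)[2]), numeric(1))
  expect_lt(abs(mean(slopes) - 1.4), 0.05)
  # 95% coefficient intervals cover the truth in >= 90% of replicates
  crit <- qt(0.975, 48)
  cover <- vapply(fits, function(f)
    abs(coef(f)[2] - 1.4) <= crit * sqrt(f$vcov[2, 2]), logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("R^2 is invariant under uniform branch-length rescaling", {
  g <- make_fixture_traits(seed = 5)
  f1 <- pgls_allometry(g$traits, g$tree)
  tree2 <- g$tree
  tree2$edge.length <- tree2$edge.length * 37.5
  f2 <- pgls_allometry(g$traits, tree2)
  expect_equal(f1$r.squared, f2$r.squared, tolerance = 1e-10)
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-10)
})

test_that("home-range prediction follows the fitted power law", {
  fit <- structure(list(coefficients = c(`(Intercept)` = -1.82,
                                         `log10(body_mass_kg)` = 1.4),
                        vcov = diag(c(0.04, 0.02))),
                   class = "pgls_allometry")
  p <- predict(fit, 50)
  expect_equal(p$fit_km2, 10^(1.4 * log10(50) - 1.82))
  expect_true(p$lwr_km2 <= p$fit_km2 && p$fit_km2 <= p$upr_km2)
  # slope 0, intercept 0 -> 1 km^2 everywhere
  flat <- structure(list(coefficients = c(0, 0), vcov = diag(2) * 0),
                    class = "pgls_allometry")
  expect_equal(predict(flat, c(1, 50, 170))$fit_km2, rep(1, 3))
  # strictly monotone in mass for positive slope
  masses <- seq(10, 200, by = 5)
  expect_true(all(diff(predict(fit, masses)$fit_km2) > 0))
  expect_error(predict(fit, -1), "> 0")
})

test_that("long-form trait tables collapse through the weighted average", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    species = c("a", "a", "a", "b", "b"),
    trait = c("body_mass_kg", "body_mass_kg", "home_range_km2",
              "body_mass_kg", "home_range_km2"),
    value = c(2, 4, 1, 10, 3), error = c(1, 2, 0.5, 1, 1),
    source = "x"), tmp, row.names = FALSE)
  tr <- read_traits(tmp)
  expect_equal(tr$body_mass_kg[tr$species == "a"], 2.4)
  expect_equal(tr$home_range_km2[tr$species == "b"], 3)
  unlink(tmp)
})
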
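#' Inverse-variance weighted average of published trait estimates
#'
#' Collapses multiple published estimates of a trait (each with its own
#' reported error) into a single value, weighting each estimate in proportion
#' to its precision. The default weights are `1/error^2` (inverse variance);
#' `weighting = "inverse_error"` uses `1/error` instead.
#'
#' @param values numeric vector of published estimates.
#' @param errors numeric vector of positive errors, one per estimate.
#' @param weighting `"inverse_variance"` (default) or `"inverse_error"`.
#' @return The weighted mean, a length-one numeric.
#' @examples
#' weighted_trait_average(c(2, 4), c(1, 2))  # 2.4
#' @export
weighted_trait_average <- function(values, errors,
                                   weighting = c("inverse_variance", "inverse_error")) {
  weighting <- match.arg(weighting)
  stop_if(length(values) < 1L, "need at least one estimate")
  stop_if(length(values) != length(errors), "`values` and `errors` lengths differ")
  stop_if(any(!is.finite(values)) || any(!is.finite(errors)),
          "estimates and errors must be finite")
  stop_if(any(errors <= 0), "all errors must be > 0")
  w <- if (weighting == "inverse_variance") 1 / errors^2 else 1 / errors
  sum(w * values) / sum(w)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep`, collapsing the resulting degree-2 internal
#' nodes so that root-to-tip path lengths of the retained taxa are preserved.
#' Thin wrapper around [ape::keep.tip()] with explicit error reporting for
#' unknown taxa.
#'
#' @param tree an [ape::phylo] object (rooted, with branch lengths).
#' @param keep character vector of tip labels to retain.
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  stop_if(!inherits(tree, "phylo"), "`tree` must be an ape \"phylo\" object")
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  stop_if(length(missing) > 0,
          "taxa not in tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, keep)
}

#' Brownian-motion trait covariance implied by a phylogeny
#'
#' Expected covariance of a trait evolving by Brownian motion: `C[i, j]` is
#' the shared branch length from the root to the most recent common ancestor
#' of tips i and j, and `C[i, i]` the root-to-tip distance.
#'
#' @param tree an [ape::phylo] object with non-negative branch lengths.
#' @return Symmetric n x n matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  stop_if(!inherits(tree, "phylo"), "`tree` must be an ape \"phylo\" object")
  stop_if(is.null(tree$edge.length), "tree has no branch lengths")
  stop_if(any(tree$edge.length < 0), "negative branch length in tree")
  ape::vcv.phylo(tree)
}

#' Phylogenetic generalised least squares allometry
#'
#' Fits the power law `home_range = 10^intercept * body_mass^slope` as a
#' linear regression of log10 home range on log10 body mass, with residuals
#' correlated according to a Brownian-motion phylogenetic covariance
#' (optionally scaled by Pagel's lambda). With `C = diag(n)` the fit reduces
#' exactly to ordinary least squares.
#'
#' The GLS coefficient of determination is computed against the GLS-weighted
#' intercept-only model, and the overall F statistic is
#' `(n - 2) R^2 / (1 - R^2)` on (1, n - 2) degrees of freedom.
#'
#' @param traits data frame with columns `species`, `body_mass_kg`,
#'   `home_range_km2` (see [read_traits()] for the long form).
#' @param tree phylogeny covering all species in `traits` (extra tips are
#'   pruned), or `NULL` together with `C`.
#' @param C optional covariance matrix to use directly instead of `tree`
#'   (rows/columns matched to `traits$species` by name when named).
#' @param lambda Pagel's lambda: a number in \[0, 1\] scaling off-diagonal
#'   covariances (1 = pure Brownian motion, 0 = star phylogeny/OLS), or
#'   `"ML"` to profile it by maximum likelihood.
#' @return An object of class `"pgls_allometry"` with components `coefficients`
#'   (intercept, slope on the log10 scale), `vcov`, `sigma2`, `r.squared`,
#'   `fstatistic` (value, df1, df2), `p.value`, `lambda`, `n`, `logLik`, and
#'   the model frame.
#' @seealso [predict.pgls_allometry()], [simulate.pgls_allometry()]
#' @export
pgls_allometry <- function(traits, tree = NULL, C = NULL, lambda = 1) {
  stop_if(!is.data.frame(traits), "`traits` must be a data frame")
  need <- c("species", "body_mass_kg", "home_range_km2")
  stop_if(!all(need %in% names(traits)),
          "`traits` needs columns: ", paste(need, collapse = ", "))
  traits <- traits[complete.cases(traits[, need]), , drop = FALSE]
  n <- nrow(traits)
  stop_if(n < 3, "need at least 3 species")
  stop_if(any(traits$body_mass_kg <= 0), "body masses must be > 0")
  stop_if(any(traits$home_range_km2 <= 0), "home ranges must be > 0")
  sp <- as.character(traits$species)
  stop_if(anyDuplicated(sp) > 0, "duplicated species in `traits`")

  if (is.null(C)) {
    stop_if(is.null(tree), "supply either `tree` or `C`")
    tree <- prune_tree(tree, sp)
    C <- bm_covariance(tree)
    C <- C[sp, sp]
  } else {
    stop_if(nrow(C) != n || ncol(C) != n, "`C` has wrong dimensions")
    if (!is.null(rownames(C))) C <- C[sp, sp]
  }

  x <- log10(traits$body_mass_kg)
  y <- log10(traits$home_range_km2)
  X <- cbind("(Intercept)" = 1, "log10(body_mass_kg)" = x)

  scale_lambda <- function(C, lam) {
    Cl <- C * lam
    diag(Cl) <- diag(C)
    Cl
  }

  if (identical(lambda, "ML")) {
    nll <- function(lam) -gls_core(X, y, scale_lambda(C, lam))$logLik
    opt <- stats::optimize(nll, c(0, 1))
    lambda <- opt$minimum
  }
  assert_scalar(lambda, "lambda", nonneg = TRUE)
  stop_if(lambda > 1, "`lambda` must be in [0, 1]")
  Cl <- scale_lambda(C, lambda)
  fit <- gls_core(X, y, Cl)

  # GLS R^2 against the GLS-weighted intercept-only model
  fit0 <- gls_core(X[, 1, drop = FALSE], y, Cl)
  r2 <- 1 - fit$rss / fit0$rss
  f <- (n - 2) * r2 / (1 - r2)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)

  structure(list(
    coefficients = fit$beta,
    vcov = fit$vcov,
    sigma2 = fit$sigma2,
    r.squared = r2,
    fstatistic = c(value = f, df1 = 1, df2 = n - 2),
    p.value = p,
    lambda = lambda,
    n = n,
    logLik = fit$logLik,
    residuals = setNames(fit$resid, sp),
    fitted = setNames(fit$fitted, sp),
    model = data.frame(species = sp, log10_mass = x, log10_range = y),
    C = Cl
  ), class = "pgls_allometry")
}

# GLS workhorse: beta = (X' C^-1 X)^-1 X' C^-1 y via the Cholesky root of C.
gls_core <- function(X, y, C) {
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  # whiten: solve L' u = v  => u = L'^-1 v, so u'u = v' C^-1 v
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qrX <- qr(Xw)
  beta <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  n <- length(y); p <- ncol(X)
  sigma2 <- rss / (n - p)
  XtX <- crossprod(Xw)
  vcov <- sigma2 * chol2inv(chol(XtX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% beta)
  # ML log-likelihood (sigma2_ML = rss/n), used for lambda profiling
  logdetC <- 2 * sum(log(diag(L)))
  logLik <- -0.5 * (n * log(2 * pi * rss / n) + n + logdetC)
  list(beta = beta, vcov = vcov, sigma2 = sigma2, rss = rss,
       resid = drop(y - fitted), fitted = fitted, logLik = logLik)
}

#' @export
print.pgls_allometry <- function(x, ...) {
  cat("Phylogenetic GLS allometry (log10-log10)\n")
  cat(sprintf("  log10(home range) = %.3f + %.3f * log10(body mass)\n",
              x$coefficients[1], x$coefficients[2]))
  cat(sprintf("  n = %d, lambda = %.3g, R^2 = %.3f, F(%d, %d) = %.3f, p = %.4g\n",
              x$n, x$lambda, x$r.squared, x$fstatistic["df1"],
              x$fstatistic["df2"], x$fstatistic["value"], x$p.value))
  invisible(x)
}

#' @export
summary.pgls_allometry <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `t value` = tval,
                 `Pr(>|t|)` = 2 * stats::pt(abs(tval), object$n - 2, lower.tail = FALSE))
  out <- list(coefficients = coefs, r.squared = object$r.squared,
              fstatistic = object$fstatistic, p.value = object$p.value,
              lambda = object$lambda, n = object$n, sigma2 = object$sigma2)
  class(out) <- "summary.pgls_allometry"
  out
}

#' @export
print.summary.pgls_allometry <- function(x, ...) {
  cat("Phylogenetic GLS allometry\n\nCoefficients (log10 scale):\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nR^2 = %.3f, F(%d, %d) = %.3f, p = %.4g, lambda = %.3g, n = %d\n",
              x$r.squared, x$fstatistic["df1"], x$fstatistic["df2"],
              x$fstatistic["value"], x$p.value, x$lambda, x$n))
  invisible(x)
}

#' @export
coef.pgls_allometry <- function(object, ...) object$coefficients

#' @export
vcov.pgls_allometry <- function(object, ...) object$vcov

#' @export
residuals.pgls_allometry <- function(object, ...) object$residuals

#' @export
fitted.pgls_allometry <- function(object, ...) object$fitted

#' Predict home range for new body masses
#'
#' Evaluates the fitted power law at the supplied masses and propagates the
#' coefficient covariance in log10 space; the interval is
#' `10^(fit +/- crit * se)`. The default `crit = 2` reports a "+/- 2 SE"
#' interval (approximately 95% coverage).
#'
#' @param object a [pgls_allometry()] fit.
#' @param mass body masses in kg (vector allowed).
#' @param crit critical multiplier on the log-scale standard error.
#' @param ... unused.
#' @return Data frame with columns `mass_kg`, `fit_km2`, `lwr_km2`, `upr_km2`,
#'   `se_log10`.
#' @export
predict.pgls_allometry <- function(object, mass, crit = 2, ...) {
  stop_if(missing(mass), "`mass` is required")
  stop_if(any(!is.finite(mass)) || any(mass <= 0), "masses must be finite and > 0")
  Xn <- cbind(1, log10(mass))
  log_fit <- drop(Xn %*% object$coefficients)
  se <- sqrt(rowSums((Xn %*% object$vcov) * Xn))
  data.frame(mass_kg = mass,
             fit_km2 = 10^log_fit,
             lwr_km2 = 10^(log_fit - crit * se),
             upr_km2 = 10^(log_fit + crit * se),
             se_log10 = se)
}

#' Simulate trait data from a fitted allometry
#'
#' Draws new log10 home ranges at the observed masses under the fitted model:
#' mean from the regression line, covariance `sigma2 * C` (the phylogenetic
#' residual covariance). Useful for parametric-bootstrap recovery checks.
#'
#' @param object a [pgls_allometry()] fit.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list of `nsim` data frames shaped like the original `traits`.
#' @export
simulate.pgls_allometry <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  L <- chol(object$sigma2 * object$C)
  n <- object$n
  lapply(seq_len(nsim), function(i) {
    y <- mu + drop(crossprod(L, rnorm(n)))
    data.frame(species = object$model$species,
               body_mass_kg = 10^object$model$log10_mass,
               home_range_km2 = 10^y)
  })
}

#' @export
plot.pgls_allometry <- function(x, ...) {
  plot(x$model$log10_mass, x$model$log10_range,
       xlab = "log10 body mass (kg)", ylab = "log10 home range (km2)",
       main = "Home range allometry", ...)
  graphics::abline(x$coefficients[1], x$coefficients[2])
  invisible(x)
}

#' Mean predicted home range over a set of body masses
#'
#' Averages point predictions over a vector of candidate body masses and
#' reports the spread as twice the standard error of that mean — the
#' convention used for summarising a genus-level range prediction when several
#' body-mass estimates are in play.
#'
#' @param object a [pgls_allometry()] fit.
#' @param masses body masses (kg) to average over.
#' @return List with `mean_km2`, `two_se_km2` and the per-mass predictions.
#' @export
mean_home_range <- function(object, masses) {
  pred <- predict(object, masses)
  m <- mean(pred$fit_km2)
  se <- if (length(masses) > 1) sd(pred$fit_km2) / sqrt(length(masses)) else pred$se_log10 * m * log(10)
  list(mean_km2 = m, two_se_km2 = 2 * se, predictions = pred)
}

#' Read a trait table (wide or long form)
#'
#' Wide form: columns `species,body_mass_kg,home_range_km2`. Long form:
#' columns `species,trait,value,error,source` with `trait` in
#' `{body_mass_kg, home_range_km2}`; per-source estimates are collapsed with
#' [weighted_trait_average()].
#'
#' @param path CSV file path.
#' @param weighting passed to [weighted_trait_average()] for the long form.
#' @return Wide-form data frame `species,body_mass_kg,home_range_km2`.
#' @export
read_traits <- function(path, weighting = "inverse_variance") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("body_mass_kg", "home_range_km2") %in% names(d))) return(d)
  need <- c("species", "trait", "value", "error")
  stop_if(!all(need %in% names(d)),
          "long-form trait CSV needs columns: ", paste(need, collapse = ", "))
  sp <- unique(d$species)
  out <- lapply(sp, function(s) {
    ds <- d[d$species == s, ]
    vals <- vapply(c("body_mass_kg", "home_range_km2"), function(tr) {
      dt <- ds[ds$trait == tr, ]
      stop_if(nrow(dt) == 0, "species ", s, " lacks trait ", tr)
      weighted_trait_average(dt$value, dt$error, weighting)
    }, numeric(1))
    data.frame(species = s, body_mass_kg = vals[1], home_range_km2 = vals[2])
  })
  do.call(rbind, out)
}
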
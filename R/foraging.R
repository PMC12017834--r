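# Bioavailable-Sr baseline construction and local/extra-local classification
# of specimens against the geological units around a fossil site.

#' Build a per-unit bioavailable Sr baseline from plant samples
#'
#' @param samples data frame with columns `unit` and `sr87_86` (one row per
#'   plant sample).
#' @param local_units character vector naming the units considered "local"
#'   to the fossil site.
#' @return Data frame `unit, mean_87_86, two_se, n, local`; single-sample
#'   units carry `two_se = 0` and are flagged `range_unknown`.
#' @export
build_baseline <- function(samples, local_units = character()) {
  stop_if(!all(c("unit", "sr87_86") %in% names(samples)),
          "samples need columns `unit` and `sr87_86`")
  samples <- samples[!is.na(samples$sr87_86), , drop = FALSE]
  units <- unique(samples$unit)
  rows <- lapply(units, function(u) {
    v <- samples$sr87_86[samples$unit == u]
    if (length(v) == 0) {
      warning("unit ", u, " has no samples; skipped")
      return(NULL)
    }
    data.frame(unit = u, mean_87_86 = mean(v),
               two_se = if (length(v) > 1) 2 * sd(v) / sqrt(length(v)) else 0,
               n = length(v), local = u %in% local_units,
               range_unknown = length(v) == 1)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Interval comparison of two mean +/- 2SE summaries
#'
#' @param a,b numeric length-2 vectors `c(mean, two_se)`.
#' @param mode `"containment"`: a's interval lies entirely within b's;
#'   `"overlap"`: the intervals intersect.
#' @return Logical.
#' @export
interval_overlap <- function(a, b, mode = c("containment", "overlap")) {
  mode <- match.arg(mode)
  ai <- c(a[1] - a[2], a[1] + a[2])
  bi <- c(b[1] - b[2], b[1] + b[2])
  if (mode == "containment") ai[1] >= bi[1] && ai[2] <= bi[2]
  else ai[1] <= bi[2] && bi[1] <= ai[2]
}

#' Classify a specimen as local or extra-local
#'
#' Tests the specimen's mean +/- 2SE against the local baseline units in
#' priority order (by default the host limestone first, then the broader
#' formation). The default mode asks whether the specimen interval falls
#' within the unit's interval ("containment", the reading of a specimen
#' lying within the range of values measured on a unit); `"overlap"` only
#' requires intersection. Units sampled once (2SE = 0) are instead compared
#' by absolute distance against `n1_tol`. If no local unit matches, the
#' verdict is `extra-local` and all units are ranked by |specimen - unit|.
#'
#' @param mean_87_86,two_se specimen summary.
#' @param baseline a [build_baseline()] table (or same columns).
#' @param local_units ordered character vector of local units; defaults to
#'   the units flagged `local` in `baseline`, in their table order.
#' @param mode `"containment"` (default) or `"overlap"`.
#' @param n1_tol absolute tolerance for single-sample units (default 3e-4,
#'   the scale of observed baseline 2SEs).
#' @return Object of class `"mobility_classification"`: `verdict` (one of
#'   `local-<unit>` for the matched local unit, or `"extra-local"`),
#'   `candidates` (all units ranked by distance, with match flags), and the
#'   inputs.
#' @export
classify_specimen <- function(mean_87_86, two_se, baseline,
                              local_units = NULL,
                              mode = c("containment", "overlap"),
                              n1_tol = 3e-4) {
  mode <- match.arg(mode)
  stop_if(nrow(baseline) == 0, "empty baseline")
  if (is.null(local_units)) local_units <- baseline$unit[baseline$local]
  stop_if(!all(local_units %in% baseline$unit),
          "local units missing from baseline")

  matches <- function(u) {
    b <- baseline[baseline$unit == u, ]
    if (b$two_se == 0) abs(mean_87_86 - b$mean_87_86) <= n1_tol
    else interval_overlap(c(mean_87_86, two_se), c(b$mean_87_86, b$two_se), mode)
  }
  cand <- baseline[order(abs(baseline$mean_87_86 - mean_87_86)), ]
  cand$delta <- abs(cand$mean_87_86 - mean_87_86)
  cand$match <- vapply(cand$unit, matches, logical(1))

  verdict <- "extra-local"
  for (u in local_units) if (matches(u)) { verdict <- paste0("local-", u); break }

  structure(list(verdict = verdict, candidates = cand,
                 specimen = c(mean = mean_87_86, two_se = two_se),
                 mode = mode, local_units = local_units),
            class = "mobility_classification")
}

#' @export
print.mobility_classification <- function(x, ...) {
  cat(sprintf("Specimen %.6f +/- %.6f: %s (%s mode)\n",
              x$specimen["mean"], x$specimen["two_se"], x$verdict, x$mode))
  top <- head(x$candidates[, c("unit", "mean_87_86", "delta", "match")], 3)
  cat("Nearest units:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way decomposition (via [stats::aov()]); used
#' e.g. on per-tooth mean U-Th ages grouped by stratigraphic unit.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return List `F, df1, df2, p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  stop_if(nlevels(groups) < 2, "need at least 2 groups")
  stop_if(length(values) - nlevels(groups) < 1, "not enough residual degrees of freedom")
  tab <- summary(aov(values ~ groups))[[1]]
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"])
}

#' Radius of the circle with a given area
#'
#' Converts a home-range area to the radius of the equivalent circle,
#' `sqrt(area / pi)`, for map comparison.
#'
#' @param area area in km^2 (> 0).
#' @return Radius in km.
#' @export
range_geometry <- function(area) {
  stop_if(any(!is.finite(area)) || any(area <= 0), "area must be > 0")
  sqrt(area / pi)
}
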
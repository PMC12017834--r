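# Independent oracles used to validate the package's own estimators. These
# deliberately avoid the code paths they check: brute-force traversals and
# nested grid refinement only.

# Shared root-to-MRCA path length for every tip pair, computed by explicit
# edge-path intersection (oracle for bm_covariance / ape::vcv.phylo).
brute_force_bm_cov <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      out <- c(out, node)  # identify edge by its child node
      node <- parent[node]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(elen[shared])
  }
  C
}

# Nested grid refinement maximising a 2-parameter log-likelihood; returns the
# best log-likelihood found. Independent of stats::optim/optimize.
grid_maximise <- function(loglik, lo, hi, n_grid = 15, n_zoom = 8) {
  for (z in seq_len(n_zoom)) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    vals <- outer(g1, g2, Vectorize(function(a, b) loglik(a, b)))
    idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    s1 <- diff(range(g1)) / (n_grid - 1)
    s2 <- diff(range(g2)) / (n_grid - 1)
    lo <- c(max(lo[1], g1[idx[1]] - s1), max(lo[2], g2[idx[2]] - s2))
    hi <- c(min(hi[1], g1[idx[1]] + s1), min(hi[2], g2[idx[2]] + s2))
  }
  max(vals)
}

# Same idea in three parameters (for the MAM-3 likelihood surface).
grid_maximise3 <- function(loglik, lo, hi, n_grid = 9, n_zoom = 8) {
  for (z in seq_len(n_zoom)) {
    gs <- lapply(1:3, function(k) seq(lo[k], hi[k], length.out = n_grid))
    best <- -Inf; best_at <- NULL
    for (a in gs[[1]]) for (b in gs[[2]]) for (cc in gs[[3]]) {
      v <- loglik(a, b, cc)
      if (is.finite(v) && v > best) { best <- v; best_at <- c(a, b, cc) }
    }
    step <- vapply(1:3, function(k) diff(range(gs[[k]])) / (n_grid - 1), numeric(1))
    lo <- pmax(lo, best_at - step)
    hi <- pmin(hi, best_at + step)
  }
  best
}

# access to internal likelihoods for oracle comparisons
pr_cam_loglik <- function(delta, sigma, z, s)
  paleorange:::cam_loglik(delta, sigma, z, s)
pr_mam_loglik <- function(gamma, p, mu, sigma, z, s)
  paleorange:::mam_loglik(gamma, p, mu, sigma, z, s)
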
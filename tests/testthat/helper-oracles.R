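# Independent oracles used across tests. Each reimplements the checked
# quantity by a different route than the package code (full-matrix scans,
# exhaustive enumeration, closed forms).

# Greedy globally-nearest one-to-one odd->even matching, computed by repeated
# scans of the full distance matrix (reference for pair_displacements).
oracle_greedy_match <- function(records, r_max_nm) {
  out <- NULL
  for (f in sort(unique(records$frame[records$frame %% 2 == 1]))) {
    oi <- which(records$frame == f)
    ei <- which(records$frame == f + 1)
    if (length(oi) == 0 || length(ei) == 0) next
    D <- outer(seq_along(oi), seq_along(ei), function(a, b) {
      sqrt((records$x[oi[a]] - records$x[ei[b]])^2 +
             (records$y[oi[a]] - records$y[ei[b]])^2)
    })
    D[D > r_max_nm] <- NA
    while (any(!is.na(D))) {
      dmin <- min(D, na.rm = TRUE)
      hits <- which(D == dmin, arr.ind = TRUE)
      # tie-break: lowest odd record index, then lowest even record index
      hits <- hits[order(oi[hits[, 1]], ei[hits[, 2]]), , drop = FALSE]
      a <- hits[1, 1]; b <- hits[1, 2]
      out <- rbind(out, c(oi[a], ei[b]))
      D[a, ] <- NA; D[, b] <- NA
    }
  }
  out
}

# Connected components of the point set under a fixed distance threshold
# (reference segmentation for cluster_cells on well-separated clouds);
# brute-force full distance matrix, so apply it to modest point counts only.
oracle_threshold_components <- function(x, y, threshold) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  hits <- which(D <= threshold & upper.tri(D), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(hits)) g <- igraph::add_edges(g, t(hits))
  igraph::components(g)$membership
}

# Exhaustive two-sided Fisher p: enumerate every table with the observed
# margins, computing table probabilities from binomial coefficients.
oracle_fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(r1 + r2, c1)
  p <- exp(logp)
  obs <- p[match(tab[1, 1], support)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Closed-form Rayleigh MLE (no truncation, no background).
oracle_rayleigh_mle <- function(r, dt_s) sum(r^2) / (4 * length(r) * dt_s) / 1e6

make_cloud <- function(n, x0, x1, y0, y1) {
  tibble::tibble(x = runif(n, x0, x1), y = runif(n, y0, y1))
}
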
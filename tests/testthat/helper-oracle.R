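# Independent O(n^2) pairwise-distance implementation of the density-scan
# core/border rules, used as the oracle for detect_clusters().
brute_force_clusters <- function(mask, eps, v_min, metric = "euclidean") {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(list())
  d <- as.matrix(stats::dist(pts,
    method = if (metric == "chebyshev") "maximum" else metric))
  nb <- d <= eps + 1e-12
  diag(nb) <- FALSE
  core <- rowSums(nb) > v_min
  if (!any(core)) return(list())
  ci <- which(core)
  lab <- seq_along(ci)
  repeat {
    changed <- FALSE
    for (a in seq_along(ci)) {
      for (b in seq_along(ci)) {
        if (nb[ci[a], ci[b]] && lab[a] != lab[b]) {
          l <- min(lab[a], lab[b])
          lab[lab == max(lab[a], lab[b])] <- l
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  assign_of <- integer(n)
  assign_of[ci] <- lab
  for (i in which(!core)) {
    cand <- ci[nb[i, ci]]
    if (length(cand) == 0) next
    dm <- d[i, cand]
    best <- cand[dm == min(dm)]
    key <- pts[best, 1] * 1e6 + pts[best, 2]   # lexicographic (x, y)
    assign_of[i] <- assign_of[best[which.min(key)]]
  }
  sets <- split(seq_len(n), assign_of)
  sets <- sets[names(sets) != "0"]
  lapply(unname(sets), function(ix) {
    m <- pts[ix, , drop = FALSE]
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
}

# canonical form of a cluster partition (order-free comparison)
canonical_partition <- function(voxel_sets) {
  sort(unname(vapply(voxel_sets, function(m) {
    paste(m[, 1], m[, 2], sep = ",", collapse = ";")
  }, character(1))))
}
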
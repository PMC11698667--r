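# Independent dense-matrix oracles and instance helpers used across the
# suite. These deliberately avoid the package's implicit-operator code paths
# so that agreement between the two is a genuine cross-check.

# Dense incidence matrix in the package's width-major slot order.
dense_Q <- function(n) {
  sp <- expand_pairs(n)
  Q <- matrix(0, nrow(sp), n)
  for (k in seq_len(nrow(sp))) {
    Q[k, sp$i[k]] <- -1
    Q[k, sp$j[k]] <- 1
  }
  Q
}

expand_pairs <- function(n) {
  out <- NULL
  for (w in seq_len(n - 1)) {
    for (i in seq_len(n - w)) out <- rbind(out, c(i, i + w))
  }
  data.frame(i = out[, 1], j = out[, 2])
}

# Explicit sort-permute-multiply: sort the pairwise differences (ties broken
# lexicographically on (i, j)), give the t-th smallest interval the t-th
# smallest distance, and accumulate through the dense transpose.
explicit_match_apply <- function(D, z) {
  n <- length(z)
  Q <- dense_Q(n)
  sp <- expand_pairs(n)
  lens <- as.vector(Q %*% z)
  ord <- order(lens, sp$i, sp$j)
  dslot <- numeric(length(D))
  dslot[ord] <- sort(D)
  list(z = as.vector(t(Q) %*% dslot),
       i = sp$i[ord], j = sp$j[ord])
}

# A random noisy instance at unit scale.
rand_instance <- function(n, noise_sd = 0, seed = 1) {
  z <- sample_points("uniform", n, seed = seed)
  D <- make_noisy_instance(z, noise_spec(if (noise_sd > 0) "gaussian" else "none",
                                         noise_sd, seed = seed + 1L))
  list(z = z, D = D)
}

# All order-preserving injections of k elements into 1..m (for certifying the
# monotone matching DP by enumeration).
brute_monotone_cost <- function(D, E) {
  k <- length(E)
  if (k == 0) return(0)
  combos <- utils::combn(length(D), k)
  best <- Inf
  for (c in seq_len(ncol(combos))) {
    best <- min(best, sum(abs(D[combos[, c]] - E)))
  }
  best
}
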
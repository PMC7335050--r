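# Independent oracles used to cross-check the implementation paths.

# Best-fit RMSD via the quaternion eigenvalue method: the optimal proper
# rotation corresponds to the largest eigenvalue of the 4x4 key matrix
# built from the correlation matrix of the centered coordinate sets.
# Entirely independent of the SVD/Kabsch route in the package.
quat_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  R <- crossprod(Xc, Yc)
  F <- matrix(0, 4, 4)
  F[1, 1] <- R[1, 1] + R[2, 2] + R[3, 3]
  F[1, 2] <- F[2, 1] <- R[2, 3] - R[3, 2]
  F[1, 3] <- F[3, 1] <- R[3, 1] - R[1, 3]
  F[1, 4] <- F[4, 1] <- R[1, 2] - R[2, 1]
  F[2, 2] <- R[1, 1] - R[2, 2] - R[3, 3]
  F[2, 3] <- F[3, 2] <- R[1, 2] + R[2, 1]
  F[2, 4] <- F[4, 2] <- R[1, 3] + R[3, 1]
  F[3, 3] <- -R[1, 1] + R[2, 2] - R[3, 3]
  F[3, 4] <- F[4, 3] <- R[2, 3] + R[3, 2]
  F[4, 4] <- -R[1, 1] - R[2, 2] + R[3, 3]
  lambda <- max(eigen(F, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lambda) / nrow(X)
  sqrt(max(0, msd))
}

# Naive average-linkage reference: at every step, recompute every
# inter-cluster average distance from scratch off the original matrix
# (indicator aggregation; no incremental update is shared with the
# implementation), merge the closest pair while the minimum average is
# <= eps, ties resolved toward the lowest (i, j) pair of clusters ordered
# by smallest member index.  Returns, per frame, the smallest member index
# of its final cluster (a canonical partition label).
naive_avg_linkage <- function(D, eps) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
    M <- matrix(0, n, k)
    for (j in seq_len(k)) M[clusters[[j]], j] <- 1
    sizes <- colSums(M)
    avg <- (t(M) %*% D %*% M) / outer(sizes, sizes)
    avg[!upper.tri(avg)] <- Inf
    bestd <- min(avg)
    if (bestd > eps) break
    w <- which(avg == bestd, arr.ind = TRUE)
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
    clusters[[w[1L]]] <- sort(c(clusters[[w[1L]]], clusters[[w[2L]]]))
    clusters[[w[2L]]] <- NULL
  }
  labels <- integer(n)
  for (cl in clusters) labels[cl] <- min(cl)
  labels
}

# Canonical partition labels (smallest member index per cluster) from a
# gm_clusters result, for comparison against naive_avg_linkage().
partition_signature <- function(labels) {
  vapply(labels, function(l) min(which(labels == l)), integer(1))
}

# Exhaustive enrichment null on small toys: the permutation null is the
# hypergeometric law of the in-groove count when k of n assigned residues
# are drawn without replacement.
hyper_tail_p <- function(obs, groove_size, n_assigned, k) {
  sum(dhyper(obs:min(k, groove_size), groove_size,
             n_assigned - groove_size, k))
}

# Random symmetric distance matrix with zero diagonal.
random_dist_matrix <- function(n, dmax = 10) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, dmax)
  m + t(m)
}
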
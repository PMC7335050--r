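# Superposition, pairwise RMSD, epsilon-terminated average linkage (checked
# against a naive reference), populations and site comparison.

test_that("read_ensemble round-trips a multi-model PDB under a mask", {
  frames <- array(rnorm(10 * 3 * 3, sd = 5), c(10, 3, 3))
  d <- withr::local_tempdir()
  p <- file.path(d, "ens.pdb")
  write_multimodel_pdb(frames, p, residue_ids = 1:10, chain = "A")
  e <- read_ensemble(p, atom_mask("1-10"), receptor_chain = "A")
  expect_equal(dim(e$frames), c(10L, 3L, 3L))
  expect_equal(e$frames, frames, tolerance = 1e-3)
  expect_identical(read_ensemble(p, atom_mask("1-10"))$frames, e$frames)

  # masked residue missing from one model: error names frame and residue
  expect_error(read_ensemble(p, atom_mask("1-11")),
               "frame 1.*residue.*11")
})

test_that("read_ensemble accepts plain coordinate tables", {
  d <- withr::local_tempdir()
  p <- file.path(d, "frames.txt")
  tab <- expand.grid(atom = 1:5, frame = 1:4)
  tab$x <- rnorm(20); tab$y <- rnorm(20); tab$z <- rnorm(20)
  write.table(tab, p, row.names = FALSE)
  e <- read_ensemble(p, format = "table")
  expect_equal(dim(e$frames), c(5L, 3L, 4L))
  expect_equal(e$frames[2, 1, 3], tab$x[tab$frame == 3 & tab$atom == 2])
})

test_that("kabsch_superpose recovers rigid transforms and is symmetric", {
  set.seed(101)
  X <- matrix(rnorm(36), 12, 3)
  R <- with(list(th = 1.1), matrix(c(cos(th), -sin(th), 0,
                                     sin(th), cos(th), 0, 0, 0, 1),
                                   3, 3, byrow = TRUE))
  Y <- X %*% t(R) + matrix(rep(c(3, -2, 7), each = 12), 12, 3)
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(sweep(X %*% t(fit$rotation), 2, fit$translation, `+`), Y,
               tolerance = 1e-8)
  for (i in 1:20) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
                 tolerance = 1e-10)
  }
  # degenerate input: collinear points
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "3 atoms")
})

test_that("kabsch agrees with the quaternion-eigenvalue oracle", {
  set.seed(7)
  for (i in 1:50) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, quat_rmsd(X, Y),
                 tolerance = 1e-10)
  }
})

test_that("pairwise_rmsd matches per-pair superposition and its contracts", {
  set.seed(8)
  frames <- array(rnorm(8 * 3 * 6, sd = 3), c(8, 3, 6))
  frames[, , 4] <- frames[, , 2]  # duplicated frame
  D <- pairwise_rmsd(frames)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 6))
  expect_equal(D[2, 4], 0)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j],
                 kabsch_superpose(frames[, , i], frames[, , j])$rmsd,
                 tolerance = 1e-9)
  }
  expect_lte(triangle_violations(D), 0.10)

  # jitter-free two-center ensemble: exactly two distinct off-diagonal
  # values (zero within clusters, one between)
  cen <- gen_conformer_centers(10, 2, separation = 4, seed = 3)
  e <- gen_ensemble(cen, c(0.5, 0.5), 12, jitter_sd = 0, seed = 5)
  D2 <- round(pairwise_rmsd(e), 9)
  expect_equal(length(unique(D2[upper.tri(D2)])), 2L)
})

test_that("average linkage honours the epsilon termination limits", {
  set.seed(11)
  D <- random_dist_matrix(12)
  one <- average_linkage_cluster(D, epsilon = max(D) * 2)
  expect_equal(one$populations, 1)
  expect_equal(length(unique(one$labels)), 1L)
  expect_equal(top_population(one)$population, 1.0)

  allsing <- average_linkage_cluster(D, epsilon = min(D[D > 0]) / 2)
  expect_equal(length(unique(allsing$labels)), 12L)
  expect_equal(allsing$populations, rep(1 / 12, 12))

  expect_error(average_linkage_cluster(D, epsilon = 0), "positive")
  D2 <- D; D2[1, 2] <- D2[1, 2] + 1
  expect_error(average_linkage_cluster(D2, 1), "symmetric")
})

test_that("partitions match the naive average-linkage reference", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    D <- random_dist_matrix(n)
    eps <- quantile(D[upper.tri(D)], runif(1, 0.1, 0.9))
    got <- average_linkage_cluster(D, eps)
    expect_identical(partition_signature(got$labels),
                     naive_avg_linkage(D, eps))
  }
})

test_that("cluster count is non-increasing in epsilon", {
  set.seed(13)
  D <- random_dist_matrix(25)
  epss <- sort(runif(8, 0, 12))
  ks <- vapply(epss, function(e)
    length(average_linkage_cluster(D, e)$populations), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("the pipeline is invariant to one global rigid motion", {
  cen <- gen_conformer_centers(10, 2, separation = 5, seed = 4)
  e <- gen_ensemble(cen, c(0.6, 0.4), 40, jitter_sd = 0.3, seed = 6)
  D <- pairwise_rmsd(e)
  th <- 0.8
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- e
  for (i in 1:40) {
    moved$frames[, , i] <- moved$frames[, , i] %*% t(R) +
      matrix(rep(c(10, -4, 2), each = 10), 10, 3)
  }
  Dm <- pairwise_rmsd(moved)
  expect_equal(Dm, D, tolerance = 1e-8)
  expect_identical(average_linkage_cluster(round(Dm, 8), 2)$labels,
                   average_linkage_cluster(round(D, 8), 2)$labels)
})

test_that("medoid representative minimises within-cluster distance", {
  set.seed(14)
  D <- random_dist_matrix(10)
  cl <- average_linkage_cluster(D, quantile(D[upper.tri(D)], 0.5))
  for (k in seq_along(cl$populations)) {
    members <- which(cl$labels == k)
    med <- cl$representative_frames[k]
    sums <- rowSums(D[members, members, drop = FALSE])
    expect_equal(sums[which(members == med)], min(sums))
  }
})

test_that("compare_sites ranks sites and flags inconclusive ties", {
  cen <- gen_conformer_centers(10, 3, separation = 5, seed = 15)
  hi <- gen_ensemble(cen[1:2], c(0.75, 0.25), 300, jitter_sd = 0.2,
                     seed = 16)
  lo <- gen_ensemble(cen, c(0.35, 0.33, 0.32), 300, jitter_sd = 0.2,
                     seed = 17)
  cmp <- compare_sites(list(canonical = hi, noncanonical = lo),
                       epsilon = 2, seed = 18)
  expect_equal(cmp$ranking$site, c("canonical", "noncanonical"))
  expect_true(cmp$conclusive)
  expect_gt(cmp$ranking$lower[1], cmp$ranking$upper[2])

  same <- compare_sites(list(a = hi, b = hi), epsilon = 2, seed = 19)
  expect_false(same$conclusive)

  again <- compare_sites(list(canonical = hi, noncanonical = lo),
                         epsilon = 2, seed = 18)
  expect_identical(cmp$ranking, again$ranking)
})
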
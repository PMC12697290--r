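# Superposition, RMSD matrices, clustering and representative picking.

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(11)
  a <- matrix(rnorm(36), 12, 3)
  k0 <- kabsch_superpose(a, a)
  expect_equal(k0$rmsd, 0, tolerance = 1e-12)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  b <- rigid_move(a, theta = pi / 2, shift = c(4, -1, 2))
  k1 <- kabsch_superpose(a, b)
  expect_lt(k1$rmsd, 1e-9)
  expect_equal(det(k1$rotation), 1, tolerance = 1e-9)
  # fit formula maps b onto a
  fitted <- b %*% t(k1$rotation) +
    matrix(k1$translation, nrow(b), 3, byrow = TRUE)
  expect_equal(fitted, a, tolerance = 1e-9)
  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch RMSD is the global minimum (rotation-grid oracle)", {
  # two 4-point sets; brute-force search over a dense rotation grid can
  # only do as well as the analytic optimum, and approaches it
  set.seed(2)
  a <- matrix(rnorm(12), 4, 3)
  b <- a + matrix(rnorm(12, sd = 0.3), 4, 3)
  opt <- kabsch_superpose(a, b)$rmsd
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  euler_rmsd <- function(al, be, ga) {
    rz1 <- matrix(c(cos(al), -sin(al), 0, sin(al), cos(al), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    ry <- matrix(c(cos(be), 0, sin(be), 0, 1, 0, -sin(be), 0, cos(be)), 3,
                 byrow = TRUE)
    rz2 <- matrix(c(cos(ga), -sin(ga), 0, sin(ga), cos(ga), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    sqrt(mean(rowSums((bc %*% t(rz1 %*% ry %*% rz2) - ac)^2)))
  }
  # coarse Euler-angle sweep: no rotation among 8000+ beats the analytic
  # optimum, and the grid lands close to it
  best <- Inf
  for (al in seq(0, 2 * pi, length.out = 25))
    for (be in seq(0, pi, length.out = 13))
      for (ga in seq(0, 2 * pi, length.out = 25)) {
        v <- euler_rmsd(al, be, ga)
        if (v < best) best <- v
      }
  expect_gte(best, opt - 1e-9)   # the analytic optimum is a lower bound
  expect_close(best, opt, 0.05)  # grid resolution ~0.26 rad gets this close
  # and no perturbation of the analytic rotation improves on it
  r_opt <- kabsch_superpose(a, b)$rotation
  set.seed(3)
  for (k in 1:300) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 1e-4, 0.3)
    kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                 3, byrow = TRUE)
    r_pert <- (diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx) %*% r_opt
    v <- sqrt(mean(rowSums((bc %*% t(r_pert) - ac)^2)))
    expect_gte(v, opt - 1e-12)
  }
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and matches per-pair calls", {
  ens <- gen_toy_ensemble(ensemble_sim_spec(n_clusters = 2,
                                            members_per_cluster = 3,
                                            n_atoms = 25, seed = 5))
  D <- pairwise_rmsd_matrix(ens)
  expect_equal(D$d, t(D$d))
  expect_equal(diag(D$d), rep(0, 6), ignore_attr = TRUE)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D$d[i, j],
                 kabsch_superpose(ens[[i]]$ca_coords,
                                  ens[[j]]$ca_coords)$rmsd,
                 tolerance = 1e-9)
  }
  # identical structures -> all-zero matrix; duplicates give d = 0 and
  # equal rows
  same <- list(ens[[1]], ens[[1]], ens[[2]])
  same[[2]]$id <- "copy"
  D2 <- pairwise_rmsd_matrix(same)
  expect_equal(D2$d[1, 2], 0, tolerance = 1e-9)
  expect_equal(D2$d[1, 3], D2$d[2, 3], tolerance = 1e-9)
})

test_that("RMSD matrix is invariant under rigid motion of any structure", {
  ens <- gen_toy_ensemble(ensemble_sim_spec(n_clusters = 2,
                                            members_per_cluster = 2,
                                            n_atoms = 20, seed = 9))
  D <- pairwise_rmsd_matrix(ens)
  ens[[3]]$ca_coords <- rigid_move(ens[[3]]$ca_coords, 1.2, c(-5, 8, 1))
  D2 <- pairwise_rmsd_matrix(ens)
  expect_equal(D$d, D2$d, tolerance = 1e-8)
})

test_that("silhouette matches the naive per-point formula and its oracle", {
  set.seed(13)
  n <- 12
  pts <- rbind(matrix(rnorm(18, 0), 6, 3), matrix(rnorm(18, 8), 6, 3))
  d <- as.matrix(dist(pts))
  D <- distance_matrix(sprintf("s%02d", 1:n), d)
  labels <- rep(1:2, each = 6)
  got <- silhouette_score(D, labels)
  # naive double loop
  s <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(d[i, own])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl])))
    s[i] <- (b - a) / max(a, b)
  }
  expect_equal(got, mean(s), tolerance = 1e-12)
  # independent implementation (cluster package)
  sil <- cluster::silhouette(labels, dmatrix = d)
  expect_equal(got, mean(sil[, "sil_width"]), tolerance = 1e-9)
  # two far blobs -> near 1; random labels on noise -> near 0
  expect_gt(got, 0.8)
  set.seed(31)
  u <- matrix(runif(60 * 60), 60)
  u <- (u + t(u)) / 2; diag(u) <- 0
  Du <- distance_matrix(sprintf("u%02d", 1:60), u)
  expect_lt(abs(silhouette_score(Du, sample(1:3, 60, TRUE))), 0.1)
  expect_error(silhouette_score(D, rep(1, n)), "at least 2")
})

test_that("clustering recovers planted partitions and matches k-medoids cost", {
  ens <- gen_toy_ensemble(ensemble_sim_spec(n_clusters = 2,
                                            members_per_cluster = 5,
                                            n_atoms = 30, within_sd = 0.2,
                                            between_sd = 6, seed = 17))
  D <- pairwise_rmsd_matrix(ens)
  res <- cluster_distance_matrix(D, 2, seed = 1)
  truth <- rep(1:2, each = 5)
  expect_equal(length(unique(paste(res$labels, truth))), 2)  # same partition
  expect_gt(res$silhouette, 0.7)
  # boundary k = n - 1: every cluster non-empty, silhouette defined
  res2 <- cluster_distance_matrix(D, 9, seed = 1)
  expect_equal(length(unique(res2$labels)), 9)
  expect_true(res2$silhouette >= -1 && res2$silhouette <= 1)
  expect_error(cluster_distance_matrix(D, 1), "k must be")
  # cost within 1% of exhaustive k-medoids on small n
  small <- gen_toy_ensemble(ensemble_sim_spec(n_clusters = 3,
                                              members_per_cluster = 3,
                                              n_atoms = 20, seed = 23))
  Ds <- pairwise_rmsd_matrix(small)
  r3 <- cluster_distance_matrix(Ds, 3, seed = 2)
  cost <- sum(vapply(1:3, function(cl) {
    members <- which(r3$labels == cl)
    med <- which(names(r3$labels) %in% r3$representatives[as.character(cl)])
    sum(Ds$d[members, med])
  }, 0))
  expect_lte(cost, brute_kmedoids_cost(Ds$d, 3) * 1.01)
})

test_that("select_k finds the planted K and warns on structureless input", {
  ens <- gen_toy_ensemble(ensemble_sim_spec(n_clusters = 2,
                                            members_per_cluster = 6,
                                            n_atoms = 25, seed = 3))
  D <- pairwise_rmsd_matrix(ens)
  expect_equal(select_k(D, 2, 6, seed = 1)$k, 2L)
  ens10 <- gen_toy_ensemble(ensemble_sim_spec(seed = 4))  # 10 x 7 default
  expect_equal(select_k(pairwise_rmsd_matrix(ens10), seed = 1)$k, 10L)
  # uniform random matrix: a result with a warning, not an error
  set.seed(5)
  u <- matrix(runif(30 * 30, 1, 1.2), 30)
  u <- (u + t(u)) / 2; diag(u) <- 0
  expect_warning(res <- select_k(distance_matrix(sprintf("r%02d", 1:30), u),
                                 2, 6, seed = 1), "weak cluster")
  expect_lt(abs(res$silhouette), 0.2)
})

test_that("representatives are medoids, tie-broken lexicographically, order-invariant", {
  # 3-member cluster with distances 1,1,2: the middle member wins
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 1; d[2, 3] <- d[3, 2] <- 1; d[1, 3] <- d[3, 1] <- 2
  d[4, 1:3] <- d[1:3, 4] <- 9
  D <- distance_matrix(c("a", "b", "c", "z"), d)
  reps <- pick_representatives(D, c(1, 1, 1, 2))
  expect_equal(unname(reps), c("b", "z"))       # medoid + singleton
  # exhaustive argmin oracle on a random matrix
  set.seed(19)
  m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 0
  Dm <- distance_matrix(sprintf("s%d", 1:8), m)
  labels <- c(1, 1, 1, 1, 2, 2, 2, 2)
  reps2 <- pick_representatives(Dm, labels)
  for (cl in 1:2) {
    members <- which(labels == cl)
    costs <- vapply(members, function(i) mean(m[i, setdiff(members, i)]), 0)
    expect_equal(reps2[[as.character(cl)]],
                 Dm$ids[members[which.min(costs)]])
  }
  # input order invariance (up to the stated tie rule)
  perm <- c(5, 3, 8, 1, 7, 2, 4, 6)
  Dp <- distance_matrix(Dm$ids[perm], m[perm, perm])
  repsp <- pick_representatives(Dp, labels[perm])
  expect_setequal(unname(repsp), unname(reps2))
})
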
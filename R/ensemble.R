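# Crystal-ensemble analysis: optimal rigid superposition, pairwise
# C-alpha RMSD matrices, K-means clustering on a classical MDS embedding,
# silhouette-guided choice of K, and medoid representatives.

#' Optimal rigid-body superposition of two point sets
#'
#' Kabsch algorithm: returns the proper rotation and translation mapping
#' \code{b} onto \code{a} with the globally minimal RMSD over rigid
#' motions, computed via the SVD of the cross-covariance matrix with the
#' reflection-correcting determinant sign.
#'
#' @param a,b numeric n x 3 matrices (n >= 3) in correspondence.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3; the fit is \code{b \%*\% t(rotation) + translation}) and
#'   \code{rmsd} (Angstrom).
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("coordinate sets must be matching n x 3 matrices")
  if (nrow(a) < 3L) stop("need at least 3 points for superposition")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite coordinates")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  for (m in list(ac, bc)) {
    sv <- svd(m, nu = 0, nv = 0)$d
    if (sv[2] < 1e-8) stop("degenerate (collinear) coordinates")
  }
  h <- crossprod(bc, ac)           # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- bc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - ac)^2)))
  list(rotation = rot, translation = as.numeric(ca - cb %*% t(rot)),
       rmsd = rmsd)
}

#' Pairwise superposed C-alpha RMSD matrix of an ensemble
#'
#' Structures are put in residue correspondence by the intersection of
#' their (chain, residue number) labels; each entry is the Kabsch-optimal
#' RMSD for that pair.
#'
#' @param ensemble list of \code{StructureModel}.
#' @return object of class \code{DistanceMatrix}: list with \code{ids}
#'   and the symmetric matrix \code{d}.
#' @export
pairwise_rmsd_matrix <- function(ensemble) {
  stopifnot(length(ensemble) >= 2L)
  ids <- vapply(ensemble, function(s) s$id, "")
  keys <- lapply(ensemble, function(s)
    paste(s$residue_labels$chain, s$residue_labels$resno, sep = ":"))
  common <- Reduce(intersect, keys)
  if (length(common) < 3L)
    stop("fewer than 3 common residues across the ensemble (",
         length(common), " shared)")
  coords <- lapply(seq_along(ensemble), function(k)
    ensemble[[k]]$ca_coords[match(common, keys[[k]]), , drop = FALSE])
  n <- length(ensemble)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    r <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    d[i, j] <- r; d[j, i] <- r
  }
  distance_matrix(ids, d)
}

#' Construct a DistanceMatrix object
#' @param ids structure identifiers.
#' @param d symmetric non-negative matrix with zero diagonal.
#' @return object of class \code{DistanceMatrix}.
#' @export
distance_matrix <- function(ids, d) {
  d <- as.matrix(d)
  stopifnot(length(ids) == nrow(d), nrow(d) == ncol(d))
  if (any(d < 0)) stop("negative distances in matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("asymmetric distance matrix")
  if (any(abs(diag(d)) > 1e-8)) stop("nonzero diagonal in distance matrix")
  dimnames(d) <- list(ids, ids)
  structure(list(ids = as.character(ids), d = d), class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("<DistanceMatrix> ", length(x$ids), " structures, RMSD range [",
      sprintf("%.3f", min(x$d[upper.tri(x$d)])), ", ",
      sprintf("%.3f", max(x$d)), "] A\n", sep = "")
  invisible(x)
}

# classical MDS embedding of a distance matrix: top positive-eigenvalue
# coordinates, at most min(n-1, 10) of them
.mds_embed <- function(D, max_dim = 10L) {
  n <- length(D$ids)
  k <- min(n - 1L, max_dim)
  mds <- suppressWarnings(stats::cmdscale(D$d, k = k, eig = TRUE))
  pts <- mds$points
  if (is.null(dim(pts)) || ncol(pts) == 0L)
    pts <- matrix(0, n, 1)
  pts
}

#' Cluster a distance matrix into k groups
#'
#' Embeds the matrix by classical multidimensional scaling (top
#' min(n-1, 10) coordinates) and runs K-means with 20 restarts; this
#' honours a K-means protocol while operating on RMSD input. Labels are
#' deterministic for a given seed.
#'
#' @param D a \code{DistanceMatrix}.
#' @param k number of clusters, 2 <= k <= n-1.
#' @param seed integer RNG seed for the restarts.
#' @param n_restarts K-means restarts (default 20).
#' @return object of class \code{ClusterResult}: list with \code{k},
#'   \code{labels} (named integer vector), \code{silhouette},
#'   \code{representatives} (one id per cluster), \code{seed}.
#' @export
cluster_distance_matrix <- function(D, k, seed = 1L, n_restarts = 20L) {
  stopifnot(inherits(D, "DistanceMatrix"))
  n <- length(D$ids)
  if (k < 2L || k > n - 1L) stop("k must be in [2, n-1], got ", k)
  pts <- .mds_embed(D)
  # hierarchical (Ward) centroids give a strong deterministic start; the
  # seeded random restarts guard against the rare case where it is poor
  hc_labels <- stats::cutree(stats::hclust(stats::dist(pts), "ward.D2"), k)
  centers0 <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(pts[hc_labels == cl, , drop = FALSE])))
  km_hc <- tryCatch(stats::kmeans(pts, centers = centers0, iter.max = 100L),
                    error = function(e) NULL)
  km_rand <- NULL
  for (attempt in 0:4) {
    km_rand <- tryCatch({
      set.seed(seed + attempt)
      stats::kmeans(pts, centers = k, nstart = n_restarts, iter.max = 100L)
    }, error = function(e) NULL)
    if (!is.null(km_rand)) break
  }
  cands <- Filter(Negate(is.null), list(km_hc, km_rand))
  if (!length(cands)) stop("k-means failed for k = ", k)
  best_km <- cands[[which.min(vapply(cands, function(x) x$tot.withinss, 0))]]
  labels <- best_km$cluster
  names(labels) <- D$ids
  sil <- silhouette_score(D, labels)
  reps <- pick_representatives(D, labels)
  structure(list(k = as.integer(k), labels = labels, silhouette = sil,
                 representatives = reps, seed = as.integer(seed)),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("<ClusterResult> k = ", x$k, ", silhouette = ",
      sprintf("%.3f", x$silhouette), "\n", sep = "")
  cat("  sizes:", paste(table(x$labels), collapse = " "), "\n")
  cat("  representatives:", paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette width of a labelled distance matrix
#'
#' For each point, \eqn{s = (b - a) / max(a, b)} with \eqn{a} the mean
#' distance to co-members and \eqn{b} the smallest mean distance to
#' another cluster; members of singleton clusters contribute 0 (the
#' standard convention). Returns the mean over points, in [-1, 1].
#'
#' @param D a \code{DistanceMatrix}.
#' @param labels integer cluster labels, one per structure.
#' @return mean silhouette width.
#' @export
silhouette_score <- function(D, labels) {
  stopifnot(inherits(D, "DistanceMatrix"))
  labels <- as.integer(labels)
  n <- length(D$ids)
  stopifnot(length(labels) == n)
  uniq <- sort(unique(labels))
  if (length(uniq) < 2L) stop("silhouette needs at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D$d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(uniq, labels[i]), function(cl)
      mean(D$d[i, labels == cl]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Select the number of clusters by silhouette over a K grid
#'
#' Clusters the matrix for each K in \code{kmin:kmax} and returns the
#' clustering with the highest silhouette, ties broken toward smaller K.
#' When even the best silhouette is weak (< 0.1) the result is still
#' returned, with a warning that the matrix shows little cluster
#' structure.
#'
#' @param D a \code{DistanceMatrix}.
#' @param kmin,kmax K grid bounds (defaults 2 and 14; kmax is clipped to
#'   n-1).
#' @param seed RNG seed passed to each clustering.
#' @return the best \code{ClusterResult}; its \code{silhouette_by_k}
#'   field records the full profile.
#' @export
select_k <- function(D, kmin = 2L, kmax = 14L, seed = 1L) {
  stopifnot(inherits(D, "DistanceMatrix"))
  n <- length(D$ids)
  kmax <- min(kmax, n - 1L)
  if (kmin > kmax) stop("empty K grid")
  grid <- seq.int(kmin, kmax)
  results <- lapply(grid, function(k) cluster_distance_matrix(D, k, seed = seed))
  sils <- vapply(results, function(r) r$silhouette, 0)
  best <- which.max(sils)  # which.max takes the first (smallest K) on ties
  out <- results[[best]]
  out$silhouette_by_k <- stats::setNames(sils, grid)
  if (out$silhouette < 0.1)
    warning("weak cluster structure: best silhouette ",
            sprintf("%.3f", out$silhouette), " at K = ", out$k)
  out
}

#' Medoid representative of each cluster
#'
#' Per cluster, the member minimising the mean RMSD to its co-members
#' (the structure closest to the cluster centre in distance-matrix
#' terms); ties break to the lexicographically smallest id. A singleton
#' cluster is represented by its only member.
#'
#' @param D a \code{DistanceMatrix}.
#' @param labels integer cluster labels.
#' @return character vector of representative ids, named by cluster.
#' @export
pick_representatives <- function(D, labels) {
  stopifnot(inherits(D, "DistanceMatrix"))
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(D$ids))
  uniq <- sort(unique(labels))
  reps <- vapply(uniq, function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1L) return(D$ids[members])
    cost <- vapply(members, function(i)
      mean(D$d[i, setdiff(members, i)]), 0)
    cand <- members[cost <= min(cost) + 1e-12]
    sort(D$ids[cand])[1]
  }, "")
  stats::setNames(reps, uniq)
}

#' Write a cluster result to JSON
#' @param result a \code{ClusterResult}.
#' @param path output path.
#' @return \code{path} invisibly.
#' @export
write_cluster_json <- function(result, path) {
  stopifnot(inherits(result, "ClusterResult"))
  jsonlite::write_json(
    list(k = result$k,
         labels = as.list(stats::setNames(unname(result$labels),
                                          names(result$labels))),
         silhouette = result$silhouette,
         silhouette_by_k = as.list(result$silhouette_by_k),
         representatives = unname(result$representatives),
         seed = result$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a distance matrix as CSV with an id header
#' @param D a \code{DistanceMatrix}.
#' @param path CSV path.
#' @return \code{path} invisibly (write) or a \code{DistanceMatrix} (read).
#' @export
write_distance_csv <- function(D, path) {
  stopifnot(inherits(D, "DistanceMatrix"))
  utils::write.csv(as.data.frame(D$d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  distance_matrix(rownames(m), as.matrix(m))
}
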
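# Synthetic fixtures: toy structure ensembles with planted clusters, toy
# ligand libraries from a template grammar, docking-score tables with
# stated class-conditional Gaussians, and FitValue tables with stated
# failure rates. All generators are deterministic given a seed and write
# the same formats the real pipeline consumes.

#' Specification for a planted-cluster structure ensemble
#'
#' @param n_clusters number of planted conformational clusters.
#' @param members_per_cluster structures per cluster.
#' @param n_atoms residues per structure (>= 4).
#' @param within_sd per-coordinate Gaussian displacement SD within a
#'   cluster (Angstrom).
#' @param between_sd per-coordinate SD of the cluster-base displacement
#'   (Angstrom); must be >= within_sd.
#' @param seed RNG seed.
#' @return list of class \code{EnsembleSimSpec}.
#' @export
ensemble_sim_spec <- function(n_clusters = 10L, members_per_cluster = 7L,
                              n_atoms = 40L, within_sd = 0.3,
                              between_sd = 5.0, seed = 1L) {
  stopifnot(n_clusters >= 1L, members_per_cluster >= 1L, n_atoms >= 4L,
            within_sd > 0, between_sd >= within_sd)
  structure(list(n_clusters = as.integer(n_clusters),
                 members_per_cluster = as.integer(members_per_cluster),
                 n_atoms = as.integer(n_atoms), within_sd = within_sd,
                 between_sd = between_sd, seed = as.integer(seed)),
            class = "EnsembleSimSpec")
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a toy structure ensemble with planted clusters
#'
#' A shared random-coil C-alpha trace is displaced per cluster by iid
#' Gaussians (SD \code{between_sd}) to form cluster bases; members add
#' iid within-cluster displacement (SD \code{within_sd}) plus a random
#' rigid motion, which superposition removes. With
#' \code{between_sd / within_sd >= 10} the planted partition is
#' recoverable by silhouette-guided clustering.
#'
#' @param spec an \code{EnsembleSimSpec}.
#' @return list of \code{StructureModel} (ids "C<k>M<m>").
#' @export
gen_toy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSimSpec"))
  set.seed(spec$seed)
  n <- spec$n_atoms
  # random coil: unit steps of 3.8 A (approximate CA-CA distance)
  steps <- matrix(stats::rnorm(3 * n), n, 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  base <- apply(steps, 2, cumsum)
  out <- list()
  for (k in seq_len(spec$n_clusters)) {
    cluster_base <- base + matrix(stats::rnorm(3 * n, sd = spec$between_sd), n, 3)
    for (m in seq_len(spec$members_per_cluster)) {
      coords <- cluster_base +
        matrix(stats::rnorm(3 * n, sd = spec$within_sd), n, 3)
      rot <- .random_rotation()
      shift <- stats::rnorm(3, sd = 20)
      coords <- coords %*% rot + matrix(shift, n, 3, byrow = TRUE)
      out[[length(out) + 1L]] <- structure_model(
        sprintf("C%02dM%02d", k, m), coords)
    }
  }
  out
}

#' Specification for a synthetic docking-score table
#'
#' Scores are on the docking-energy scale: lower = better, actives drawn
#' below decoys.
#'
#' @param n_active,n_decoy class sizes.
#' @param feature_ids names of the score features (structures).
#' @param active_mean,decoy_mean per-feature class means (recycled).
#' @param sd per-feature SD (recycled, > 0).
#' @param rho equicorrelation between features within a ligand, in [0, 1).
#' @param fail_prob length-2 vector of failure probabilities
#'   c(active, decoy), each in [0, 1).
#' @param seed RNG seed.
#' @return list of class \code{ScoreSimSpec}.
#' @export
score_sim_spec <- function(n_active = 100L, n_decoy = 5000L,
                           feature_ids = c("S1", "S2"),
                           active_mean = -9, decoy_mean = -7, sd = 1,
                           rho = 0, fail_prob = c(0, 0), seed = 1L) {
  stopifnot(n_active >= 1L, n_decoy >= 1L, length(feature_ids) >= 1L,
            all(sd > 0), rho >= 0, rho < 1,
            length(fail_prob) == 2L, all(fail_prob >= 0), all(fail_prob < 1))
  m <- length(feature_ids)
  structure(list(n_active = as.integer(n_active),
                 n_decoy = as.integer(n_decoy),
                 feature_ids = as.character(feature_ids),
                 active_mean = rep_len(active_mean, m),
                 decoy_mean = rep_len(decoy_mean, m),
                 sd = rep_len(sd, m), rho = rho,
                 fail_prob = fail_prob, seed = as.integer(seed)),
            class = "ScoreSimSpec")
}

#' Generate a synthetic docking-score table
#'
#' Per class, scores are multivariate normal with equicorrelation
#' \code{rho} across features; entries fail (become the sentinel)
#' independently with the class failure probability. Labels are attached
#' (1 active / 0 decoy).
#'
#' @param spec a \code{ScoreSimSpec}.
#' @param sentinel failure sentinel (default -10).
#' @return a labelled \code{ScoreTable}.
#' @export
gen_score_table <- function(spec, sentinel = FIT_SENTINEL) {
  stopifnot(inherits(spec, "ScoreSimSpec"))
  set.seed(spec$seed)
  m <- length(spec$feature_ids)
  draw <- function(nn, means) {
    shared <- stats::rnorm(nn)
    e <- matrix(stats::rnorm(nn * m), nn, m)
    z <- sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * e
    sweep(z, 2, spec$sd, `*`) + matrix(means, nn, m, byrow = TRUE)
  }
  va <- draw(spec$n_active, spec$active_mean)
  vd <- draw(spec$n_decoy, spec$decoy_mean)
  vals <- rbind(va, vd)
  labels <- c(rep(1L, spec$n_active), rep(0L, spec$n_decoy))
  fp <- ifelse(labels == 1L, spec$fail_prob[1], spec$fail_prob[2])
  fail <- matrix(stats::runif(nrow(vals) * m), nrow(vals), m) <
    matrix(fp, nrow(vals), m)
  vals[fail] <- sentinel
  ids <- c(sprintf("A%05d", seq_len(spec$n_active)),
           sprintf("D%05d", seq_len(spec$n_decoy)))
  score_table(ids, spec$feature_ids, vals, labels, sentinel = sentinel)
}

# ---- template grammar for toy ligand libraries -------------------------

# substituent fragments: atoms placed along the outward radial direction,
# 1.4 A apart with a small out-of-plane kink
.substituents <- list(
  none     = NULL,
  methyl   = list(el = "C",  ch = 0L),
  ethyl    = list(el = c("C", "C"), ch = c(0L, 0L), bonds = rbind(c(1, 2, 1))),
  propyl   = list(el = c("C", "C", "C"), ch = c(0L, 0L, 0L),
                  bonds = rbind(c(1, 2, 1), c(2, 3, 1))),
  hydroxyl = list(el = "O",  ch = 0L),
  amine    = list(el = "N",  ch = 0L),
  chloro   = list(el = "Cl", ch = 0L),
  fluoro   = list(el = "F",  ch = 0L),
  methoxy  = list(el = c("O", "C"), ch = c(0L, 0L), bonds = rbind(c(1, 2, 1))),
  carboxyl = list(el = c("C", "O", "O"), ch = c(0L, 0L, 0L),
                  bonds = rbind(c(1, 2, 2), c(1, 3, 1))),
  carboxylate = list(el = c("C", "O", "O"), ch = c(0L, 0L, -1L),
                     bonds = rbind(c(1, 2, 2), c(1, 3, 1))),
  cyano    = list(el = c("C", "N"), ch = c(0L, 0L), bonds = rbind(c(1, 2, 3))),
  acetyl   = list(el = c("C", "O", "C"), ch = c(0L, 0L, 0L),
                  bonds = rbind(c(1, 2, 2), c(1, 3, 1))),
  hydroxymethyl = list(el = c("C", "O"), ch = c(0L, 0L),
                       bonds = rbind(c(1, 2, 1))),
  dimethylamino = list(el = c("N", "C", "C"), ch = c(0L, 0L, 0L),
                       bonds = rbind(c(1, 2, 1), c(1, 3, 1))),
  carboxamide = list(el = c("C", "O", "N"), ch = c(0L, 0L, 0L),
                     bonds = rbind(c(1, 2, 2), c(1, 3, 1))),
  trifluoromethyl = list(el = c("C", "F", "F", "F"), ch = rep(0L, 4),
                         bonds = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)))
)

.scaffolds <- list(
  benzene = list(el = rep("C", 6), arom = TRUE, sites = c(1L, 3L, 5L)),
  pyridine = list(el = c("N", rep("C", 5)), arom = TRUE, sites = c(2L, 4L, 6L)),
  pyrimidine = list(el = c("N", "C", "N", "C", "C", "C"), arom = TRUE,
                    sites = c(2L, 4L, 6L)),
  cyclohexane = list(el = rep("C", 6), arom = FALSE, sites = c(1L, 3L, 5L)),
  piperidine = list(el = c("N", rep("C", 5)), arom = FALSE,
                    sites = c(2L, 4L, 6L)),
  furan = list(el = c("O", "C", "C", "C", "C"), arom = TRUE,
               sites = c(2L, 3L, 5L)),
  thiophene = list(el = c("S", "C", "C", "C", "C"), arom = TRUE,
                   sites = c(2L, 3L, 5L))
)

# assemble one molecule: scaffold hexagon + substituents at ring sites
.build_template_molecule <- function(id, scaffold_name, sub_names) {
  sc <- .scaffolds[[scaffold_name]]
  nring <- length(sc$el)
  ang <- 2 * pi * (seq_len(nring) - 1) / nring
  r_ring <- 1.39
  el <- sc$el; ch <- rep(0L, nring); arom <- rep(sc$arom, nring)
  xyz <- cbind(r_ring * cos(ang), r_ring * sin(ang), 0)
  ord <- if (sc$arom) 4L else 1L
  bonds <- cbind(seq_len(nring), c(seq_len(nring)[-1], 1L), ord)
  for (s in seq_along(sub_names)) {
    frag <- .substituents[[sub_names[s]]]
    if (is.null(frag)) next
    site <- sc$sites[s]
    dir <- c(cos(ang[site]), sin(ang[site]), 0)
    base <- length(el)
    nfr <- length(frag$el)
    el <- c(el, frag$el); ch <- c(ch, frag$ch); arom <- c(arom, rep(FALSE, nfr))
    # place fragment atoms outward with a z kink so chains are not collinear
    fx <- t(vapply(seq_len(nfr), function(k)
      xyz[site, ] + dir * (1.4 * k) + c(0, 0, 0.3 * ((k - 1) %% 2)),
      numeric(3)))
    # branch atoms of carboxyl-type fragments spread sideways
    if (nfr == 3L && frag$el[1] == "C" && all(frag$el[2:3] == "O")) {
      side <- c(-dir[2], dir[1], 0)
      fx[2, ] <- fx[1, ] + 1.25 * (dir * 0.5 + side * 0.866)
      fx[3, ] <- fx[1, ] + 1.25 * (dir * 0.5 - side * 0.866)
    }
    xyz <- rbind(xyz, fx)
    bonds <- rbind(bonds, c(site, base + 1L, 1L))
    if (!is.null(frag$bonds))
      bonds <- rbind(bonds, cbind(base + frag$bonds[, 1],
                                  base + frag$bonds[, 2], frag$bonds[, 3]))
  }
  mol <- molecule(id,
                  data.frame(element = el, charge = ch, aromatic = arom),
                  data.frame(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3]),
                  conformers = list(xyz))
  mol$smiles <- write_smiles(mol)
  mol
}

#' Generate a toy ligand library from a template grammar
#'
#' Molecules are assembled from ring scaffolds (benzene, pyridine,
#' pyrimidine, cyclohexane, piperidine, furan, thiophene) with up to
#' three substituents drawn from a 17-fragment set spanning MW, logP,
#' donor/acceptor and charge ranges; each molecule
#' carries one clean template-geometry conformer and a SMILES string.
#' Ids are unique ("L00001", ...) and the output is bit-reproducible for
#' a seed.
#'
#' @param n number of molecules (>= 1).
#' @param seed RNG seed.
#' @return list of \code{Molecule}.
#' @export
gen_toy_library <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  scaff <- names(.scaffolds)
  subs <- names(.substituents)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sname <- sample(scaff, 1)
    snames <- sample(subs, 3, replace = TRUE)
    out[[i]] <- .build_template_molecule(sprintf("L%05d", i), sname, snames)
  }
  out
}

#' Generate a synthetic FitValue table with stated failure rates
#'
#' Non-failed FitValues are Gaussian per class; failed entries are
#' exactly the -10 sentinel ("ligands that failed to fit").
#'
#' @param n_active,n_decoy class sizes.
#' @param active_fail_prob,decoy_fail_prob failure probabilities in
#'   [0, 1).
#' @param means length-2 c(active, decoy) FitValue means (default 4, 2).
#' @param sds length-2 SDs (default 1, 1).
#' @param seed RNG seed.
#' @return a labelled single-feature \code{ScoreTable} ("FitValue").
#' @export
gen_fit_values <- function(n_active, n_decoy, active_fail_prob = 0,
                           decoy_fail_prob = 0, means = c(4, 2),
                           sds = c(1, 1), seed = 1L) {
  stopifnot(active_fail_prob >= 0, active_fail_prob <= 1,
            decoy_fail_prob >= 0, decoy_fail_prob <= 1, all(sds > 0))
  set.seed(seed)
  va <- stats::rnorm(n_active, means[1], sds[1])
  vd <- stats::rnorm(n_decoy, means[2], sds[2])
  fa <- stats::runif(n_active) < active_fail_prob
  fd <- stats::runif(n_decoy) < decoy_fail_prob
  va[fa] <- FIT_SENTINEL; vd[fd] <- FIT_SENTINEL
  score_table(c(sprintf("A%05d", seq_len(n_active)),
                sprintf("D%05d", seq_len(n_decoy))),
              "FitValue", matrix(c(va, vd), ncol = 1),
              c(rep(1L, n_active), rep(0L, n_decoy)))
}
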
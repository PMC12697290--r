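# End-to-end screen orchestration: pharmacophore filter -> naive Bayes
# consensus ranking -> top-N -> fingerprint clustering -> per-cluster
# representatives; plus the selectivity-index assay arithmetic.

#' Configuration for an end-to-end virtual screen
#'
#' @param pharmacophore a \code{PharmacophoreModel} (or JSON path).
#' @param scores a \code{ScoreTable} covering the pharmacophore
#'   survivors (or CSV path), or NULL when \code{mock_scorer} is given.
#' @param nbc_model a prefitted \code{nbc_model}; alternatively supply
#'   \code{training_scores} (a labelled \code{ScoreTable}) to fit one.
#' @param training_scores labelled \code{ScoreTable} used to fit the
#'   consensus model when \code{nbc_model} is NULL.
#' @param nbc_features feature ids used by the consensus model (default:
#'   all features of the score source).
#' @param mock_scorer optional function(ids, feature_ids, seed) returning
#'   a \code{ScoreTable}; stands in for a docking engine in tests.
#' @param keep_fraction pharmacophore survivor fraction (default 0.01).
#' @param top_n compounds kept after consensus ranking (default 100).
#' @param n_clusters fingerprint clusters among the top compounds
#'   (default 10; FCFP-style functional-class diameter-6 fingerprints).
#' @param fingerprint_diameter,fingerprint_scheme fingerprint settings.
#' @param seed master seed for the stochastic stages.
#' @return list of class \code{ScreenConfig}.
#' @export
screen_config <- function(pharmacophore, scores = NULL, nbc_model = NULL,
                          training_scores = NULL, nbc_features = NULL,
                          mock_scorer = NULL, keep_fraction = 0.01,
                          top_n = 100L, n_clusters = 10L,
                          fingerprint_diameter = 6L,
                          fingerprint_scheme = "functional-class",
                          seed = 1L) {
  if (is.character(pharmacophore))
    pharmacophore <- read_pharmacophore_json(pharmacophore)
  stopifnot(inherits(pharmacophore, "PharmacophoreModel"))
  if (is.character(scores)) scores <- read_score_csv(scores)
  if (is.null(scores) && is.null(mock_scorer))
    stop("either scores or a mock_scorer must be supplied")
  if (is.null(nbc_model) && is.null(training_scores))
    stop("either a fitted nbc_model or training_scores must be supplied")
  stopifnot(keep_fraction > 0, keep_fraction <= 1,
            top_n >= n_clusters, n_clusters >= 1L)
  structure(list(pharmacophore = pharmacophore, scores = scores,
                 nbc_model = nbc_model, training_scores = training_scores,
                 nbc_features = nbc_features, mock_scorer = mock_scorer,
                 keep_fraction = keep_fraction, top_n = as.integer(top_n),
                 n_clusters = as.integer(n_clusters),
                 fingerprint_diameter = as.integer(fingerprint_diameter),
                 fingerprint_scheme = fingerprint_scheme,
                 seed = as.integer(seed)),
            class = "ScreenConfig")
}

#' Run the full virtual screen
#'
#' Stages, in order: (1) pharmacophore screening keeps
#' \code{ceiling(keep_fraction * n)} matched ligands; (2) the naive
#' Bayes consensus model scores the survivors from the ensemble score
#' table and the top \code{top_n} by log-odds are kept (FitValue breaks
#' ties); (3) survivors are clustered by functional-class fingerprint
#' into \code{n_clusters} groups (reduced with a warning when there are
#' fewer survivors); (4) the highest log-odds member of each cluster is
#' flagged as its representative. Deterministic given the config seed.
#'
#' @param config a \code{ScreenConfig}.
#' @param library list of \code{Molecule}.
#' @return object of class \code{HitList}: data.frame (id, fit_value,
#'   log_odds, cluster, representative) ranked by log-odds, with the
#'   per-stage counts in attribute \code{"stage_log"}.
#' @export
run_screen <- function(config, library) {
  stopifnot(inherits(config, "ScreenConfig"), length(library) >= 1L)
  log_rows <- list()
  note <- function(stage, n_in, n_out)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, seed = config$seed)
  ## stage 1: pharmacophore filter
  kept <- screen_library(library, config$pharmacophore,
                         keep_fraction = config$keep_fraction)
  note("pharmacophore", length(library), nrow(kept))
  if (!nrow(kept)) {
    out <- data.frame(id = character(0), fit_value = numeric(0),
                      log_odds = numeric(0), cluster = integer(0),
                      representative = logical(0))
    attr(out, "stage_log") <- do.call(rbind, log_rows)
    class(out) <- c("HitList", class(out))
    return(out)
  }
  ## stage 2: consensus scoring
  scores <- config$scores
  model <- config$nbc_model
  if (is.null(model))
    model <- fit_nbc(config$training_scores, features = config$nbc_features)
  feats <- names(model$features)
  if (is.null(scores)) {
    scores <- config$mock_scorer(kept$id, feats, config$seed)
  }
  missing_ids <- setdiff(kept$id, scores$ligand_ids)
  if (length(missing_ids))
    stop("score table does not cover survivor(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  rows <- match(kept$id, scores$ligand_ids)
  lo <- vapply(rows, function(r)
    predict_log_odds(model, stats::setNames(scores$values[r, ],
                                            scores$feature_ids)), 0)
  tab <- data.frame(id = kept$id, fit_value = kept$fit_value, log_odds = lo)
  tab <- tab[order(-tab$log_odds, -tab$fit_value, tab$id), , drop = FALSE]
  n_before <- nrow(tab)
  tab <- utils::head(tab, config$top_n)
  note("consensus_topN", n_before, nrow(tab))
  ## stage 3: fingerprint clustering
  k <- config$n_clusters
  if (nrow(tab) < k) {
    warning("only ", nrow(tab), " survivors; reducing clusters from ", k)
    k <- nrow(tab)
  }
  mols <- library[match(tab$id, vapply(library, function(m) m$id, ""))]
  fps <- lapply(mols, circular_fingerprint,
                diameter = config$fingerprint_diameter,
                scheme = config$fingerprint_scheme)
  tab$cluster <- cluster_hits(fps, k, seed = config$seed)
  note("fingerprint_clustering", nrow(tab), k)
  ## stage 4: per-cluster representative = best log-odds
  tab$representative <- FALSE
  for (cl in unique(tab$cluster)) {
    members <- which(tab$cluster == cl)
    tab$representative[members[1]] <- TRUE  # tab is sorted by log-odds
  }
  note("representatives", k, sum(tab$representative))
  rownames(tab) <- NULL
  attr(tab, "stage_log") <- do.call(rbind, log_rows)
  class(tab) <- c("HitList", class(tab))
  tab
}

#' @export
print.HitList <- function(x, ...) {
  cat("<HitList> ", nrow(x), " hits, ",
      length(unique(x$cluster)), " clusters, ",
      sum(x$representative), " representatives\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Cluster fingerprints by k-medoids on Tanimoto distance
#'
#' Partitions around medoids (PAM) on the 1 - Tanimoto distance matrix.
#' PAM's BUILD + SWAP search is deterministic; the seed argument is kept
#' for interface stability and recorded in the result attributes.
#'
#' @param fps list of \code{Fingerprint}.
#' @param n_clusters number of clusters (<= length(fps)).
#' @param seed recorded seed.
#' @return integer cluster labels.
#' @export
cluster_hits <- function(fps, n_clusters, seed = 1L) {
  n <- length(fps)
  if (n_clusters > n) stop("n_clusters (", n_clusters,
                           ") exceeds number of fingerprints (", n, ")")
  if (n_clusters == n) return(seq_len(n))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    s <- suppressMessages(tanimoto(fps[[i]], fps[[j]]))
    d[i, j] <- 1 - s; d[j, i] <- 1 - s
  }
  pm <- cluster::pam(stats::as.dist(d), k = n_clusters, diss = TRUE)
  labels <- as.integer(pm$clustering)
  attr(labels, "medoids") <- pm$id.med
  attr(labels, "seed") <- seed
  labels
}

#' Selectivity index from two IC50 values
#'
#' \code{IC50(off-target) / IC50(target)}, rounded half-up to one
#' decimal: the fold-selectivity of an inhibitor for its primary target
#' over a counter-screen enzyme.
#'
#' @param ic50_off_target off-target IC50 (uM), > 0.
#' @param ic50_target on-target IC50 (uM), > 0.
#' @return the index, one decimal.
#' @export
selectivity_index <- function(ic50_off_target, ic50_target) {
  if (!is.finite(ic50_off_target) || !is.finite(ic50_target) ||
      ic50_off_target <= 0 || ic50_target <= 0)
    stop("IC50 values must be positive")
  floor(ic50_off_target / ic50_target * 10 + 0.5) / 10
}

#' Write a hit list as CSV
#' @param hits a \code{HitList}.
#' @param path CSV path.
#' @return \code{path} invisibly.
#' @export
write_hitlist_csv <- function(hits, path) {
  utils::write.csv(as.data.frame(hits), path, row.names = FALSE)
  invisible(path)
}
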
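# Naive Bayes consensus classification over continuous score features
# (docking scores, FitValues) with sentinel handling, ROC/AUC, stratified
# cross-validation, and multi-conformation combination models.

#' Construct a ligand-by-feature score table
#'
#' The container feeding the naive Bayes stage: one row per ligand, one
#' column per feature (crystal structure / conformation / FitValue).
#' Entries equal to \code{sentinel} mark fit or docking failures and are
#' never treated as ordinary numbers.
#'
#' @param ligand_ids character vector of unique ligand ids.
#' @param feature_ids character vector of unique feature (structure) ids.
#' @param values numeric matrix, length(ligand_ids) x length(feature_ids).
#' @param labels optional binary vector (1 active / 0 decoy).
#' @param sentinel reserved failure value (default -10).
#' @return object of class \code{ScoreTable}.
#' @export
score_table <- function(ligand_ids, feature_ids, values, labels = NULL,
                        sentinel = FIT_SENTINEL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(ligand_ids),
            ncol(values) == length(feature_ids))
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique")
  if (anyDuplicated(ligand_ids)) stop("ligand ids must be unique")
  if (any(!is.finite(values))) stop("score values must be finite (use the sentinel for failures)")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == length(ligand_ids), all(labels %in% 0:1))
  }
  dimnames(values) <- list(ligand_ids, feature_ids)
  structure(list(ligand_ids = as.character(ligand_ids),
                 feature_ids = as.character(feature_ids),
                 values = values, labels = labels, sentinel = sentinel),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  nfail <- sum(x$values == x$sentinel)
  cat("<ScoreTable> ", nrow(x$values), " ligands x ", ncol(x$values),
      " features, ", nfail, " sentinel entries",
      if (!is.null(x$labels)) paste0(", ", sum(x$labels == 1L), " actives / ",
                                     sum(x$labels == 0L), " decoys"),
      "\n", sep = "")
  invisible(x)
}

#' Fit a binned naive Bayes classifier on a score table
#'
#' Per feature, bin edges are learned by equal-frequency binning of the
#' pooled non-sentinel training values (default 16 bins); sentinel
#' entries occupy a dedicated extra bin. Class-conditional bin
#' probabilities are Laplace-smoothed with \code{alpha}, so every bin has
#' positive probability in both classes and an all-sentinel feature is
#' still valid.
#'
#' @param table a labelled \code{ScoreTable}.
#' @param features feature ids to use (default: all).
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @param n_bins number of value bins per feature (default 16).
#' @return object of class \code{nbc_model} with priors and per-feature
#'   bin edges and class-conditional log-likelihoods.
#' @export
fit_nbc <- function(table, features = NULL, alpha = 1, n_bins = 16L) {
  stopifnot(inherits(table, "ScoreTable"))
  if (is.null(table$labels)) stop("score table has no labels")
  if (is.null(features)) features <- table$feature_ids
  features <- unique(as.character(features))
  if (!length(features)) stop("no features selected")
  missing_f <- setdiff(features, table$feature_ids)
  if (length(missing_f))
    stop("features not in table: ", paste(missing_f, collapse = ", "))
  y <- table$labels
  if (!all(0:1 %in% y)) stop("both classes must be present")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  feats <- lapply(features, function(f) {
    v <- table$values[, f]
    ok <- v != table$sentinel
    edges <- if (any(ok)) {
      qs <- stats::quantile(v[ok], probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7)
      unique(qs[-c(1, length(qs))])
    } else numeric(0)
    # bin index: 1..(length(edges)+1) for values, 0 for sentinel
    bin_of <- function(x, sent) {
      b <- findInterval(x, edges) + 1L
      b[sent] <- 0L
      b
    }
    b <- bin_of(v, !ok)
    k <- length(edges) + 2L   # value bins + sentinel bin
    count <- function(cls) {
      tab <- tabulate(b[y == cls] + 1L, nbins = k)  # index 1 = sentinel
      tab
    }
    c1 <- count(1L); c0 <- count(0L)
    loglik1 <- log((c1 + alpha) / (n1 + alpha * k))
    loglik0 <- log((c0 + alpha) / (n0 + alpha * k))
    list(feature = f, edges = edges, loglik1 = loglik1, loglik0 = loglik0)
  })
  names(feats) <- features
  structure(list(priors = c(p1 = n1 / (n1 + n0), p0 = n0 / (n1 + n0)),
                 features = feats, alpha = alpha, n_bins = as.integer(n_bins),
                 sentinel = table$sentinel),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("Binned naive Bayes classifier\n")
  cat("  features: ", paste(names(x$features), collapse = ", "), "\n", sep = "")
  cat(sprintf("  priors: P(active) = %.3f, P(decoy) = %.3f\n",
              x$priors["p1"], x$priors["p0"]))
  cat("  bins per feature: up to ", x$n_bins, " + sentinel bin; alpha = ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

#' Posterior log-odds of activity for one feature row
#'
#' \deqn{\log \frac{\pi_1}{\pi_0} + \sum_f \log \frac{P(bin_f | 1)}{P(bin_f | 0)}}
#' Sentinel values fall into the dedicated sentinel bin; every bin is
#' smoothed, so the result is always finite.
#'
#' @param model an \code{nbc_model}.
#' @param row named numeric vector providing a value (sentinel allowed)
#'   for every model feature.
#' @return log-odds (scalar).
#' @export
predict_log_odds <- function(model, row) {
  stopifnot(inherits(model, "nbc_model"))
  fnames <- names(model$features)
  if (!all(fnames %in% names(row)))
    stop("row is missing feature(s): ",
         paste(setdiff(fnames, names(row)), collapse = ", "))
  lo <- log(model$priors[["p1"]] / model$priors[["p0"]])
  for (f in fnames) {
    ft <- model$features[[f]]
    v <- row[[f]]
    idx <- if (v == model$sentinel) 1L else findInterval(v, ft$edges) + 2L
    lo <- lo + ft$loglik1[idx] - ft$loglik0[idx]
  }
  unname(lo)
}

#' @describeIn fit_nbc predict log-odds for all rows of a score table
#'   (or a plain matrix with matching feature columns).
#' @param object an \code{nbc_model}.
#' @param newdata a \code{ScoreTable} or numeric matrix with feature
#'   columns.
#' @param ... unused.
#' @export
predict.nbc_model <- function(object, newdata, ...) {
  vals <- if (inherits(newdata, "ScoreTable")) newdata$values else as.matrix(newdata)
  vapply(seq_len(nrow(vals)), function(i)
    predict_log_odds(object, stats::setNames(vals[i, ], colnames(vals))), 0)
}

#' ROC curve and AUC of a score against binary labels
#'
#' Rank-based (midrank-tie) AUC, identical to the Mann-Whitney
#' U-statistic scaled by \eqn{n_1 n_0}; the curve sweeps thresholds over
#' the unique score values. \code{direction = "lower"} treats lower
#' scores as more active (docking energies); \code{"higher"} the reverse
#' (FitValues, log-odds).
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 active / 0 decoy).
#' @param direction "higher" or "lower" = which scores rank as active.
#' @return object of class \code{ROCResult}: list with \code{auc},
#'   \code{thresholds}, \code{tpr}, \code{fpr}.
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (!all(0:1 %in% labels)) stop("both classes must be present")
  s <- if (direction == "lower") -scores else scores
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # cumulative counts of predictions >= threshold, one point per unique score
  ord <- order(-s)
  ss <- s[ord]; yy <- labels[ord]
  cum1 <- cumsum(yy == 1L); cum0 <- cumsum(yy == 0L)
  idx <- which(c(diff(ss) != 0, TRUE))
  thr <- ss[idx]
  tpr <- c(0, cum1[idx] / n1)
  fpr <- c(0, cum0[idx] / n0)
  structure(list(auc = auc, thresholds = c(Inf, thr), tpr = tpr, fpr = fpr,
                 direction = direction),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat("<ROCResult> AUC = ", sprintf("%.4f", x$auc), " (", x$direction,
      " scores rank active), ", length(x$thresholds), " thresholds\n",
      sep = "")
  invisible(x)
}

#' @export
plot.ROCResult <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

# stratified fold assignment, deterministic per seed
.stratified_folds <- function(labels, folds, seed) {
  if (min(table(labels)) < folds)
    stop("each class needs at least ", folds, " members for ", folds,
         "-fold stratification")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated AUC of a naive Bayes model
#'
#' Stratified k-fold cross-validation: the model is refitted on each
#' training split, out-of-fold log-odds are pooled, and a single AUC is
#' computed on the pooled predictions. Deterministic for a given seed.
#'
#' @param table a labelled \code{ScoreTable}.
#' @param features feature ids to use (default all).
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param alpha,n_bins passed to \code{\link{fit_nbc}}.
#' @return pooled out-of-fold AUC (scalar).
#' @export
cv_auc <- function(table, features = NULL, folds = 5L, seed = 1L,
                   alpha = 1, n_bins = 16L) {
  stopifnot(inherits(table, "ScoreTable"))
  if (is.null(table$labels)) stop("score table has no labels")
  if (is.null(features)) features <- table$feature_ids
  y <- table$labels
  fold <- .stratified_folds(y, folds, seed)
  preds <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    sub <- score_table(table$ligand_ids[tr], table$feature_ids,
                       table$values[tr, , drop = FALSE], y[tr],
                       sentinel = table$sentinel)
    m <- fit_nbc(sub, features = features, alpha = alpha, n_bins = n_bins)
    te <- which(!tr)
    preds[te] <- vapply(te, function(i)
      predict_log_odds(m, stats::setNames(table$values[i, ],
                                          table$feature_ids)), 0)
  }
  roc_auc(preds, y, direction = "higher")$auc
}

#' Cross-validated AUC for a set of feature combinations
#'
#' Evaluates \code{\link{cv_auc}} for each feature subset using the same
#' fold assignment throughout, so combinations are compared paired.
#' Duplicate features within a combination are collapsed.
#'
#' @param table a labelled \code{ScoreTable}.
#' @param combos list of character vectors of feature ids.
#' @param folds,seed,alpha,n_bins as in \code{\link{cv_auc}}.
#' @return data.frame (combo, n_features, cv_auc) in input order.
#' @export
enumerate_combo_models <- function(table, combos, folds = 5L, seed = 1L,
                                   alpha = 1, n_bins = 16L) {
  stopifnot(inherits(table, "ScoreTable"), length(combos) >= 1L)
  res <- lapply(combos, function(fs) {
    fs <- unique(as.character(fs))
    if (!length(fs)) stop("empty feature combination")
    auc <- cv_auc(table, features = fs, folds = folds, seed = seed,
                  alpha = alpha, n_bins = n_bins)
    data.frame(combo = paste(fs, collapse = "+"),
               n_features = length(fs), cv_auc = auc)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' All 2..m-subset combination models of a feature set
#'
#' Convenience enumerator for the standard design: every subset of size
#' 2 or more of \code{features} (4 features give the 11 classical
#' combination models).
#'
#' @param features character vector of feature ids.
#' @return list of character vectors.
#' @export
all_feature_combos <- function(features) {
  features <- unique(as.character(features))
  out <- list()
  for (m in 2:length(features))
    out <- c(out, utils::combn(features, m, simplify = FALSE))
  out
}

#' Read/write a score table as CSV
#'
#' Layout: columns \code{ligand_id}, optional \code{label}, then one
#' column per feature. Sentinel cells may be written as the literal
#' \code{FAIL} or the numeric sentinel.
#'
#' @param table a \code{ScoreTable}.
#' @param path CSV path.
#' @param fail_literal write sentinel entries as "FAIL" (default TRUE).
#' @param sentinel sentinel value used when reading (default -10).
#' @return \code{path} invisibly (write) or a \code{ScoreTable} (read).
#' @export
write_score_csv <- function(table, path, fail_literal = TRUE) {
  stopifnot(inherits(table, "ScoreTable"))
  vals <- as.data.frame(table$values)
  if (fail_literal) vals[table$values == table$sentinel] <- "FAIL"
  df <- cbind(data.frame(ligand_id = table$ligand_ids), vals)
  if (!is.null(table$labels)) df <- cbind(df[1], label = table$labels, df[-1])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_score_csv
#' @export
read_score_csv <- function(path, sentinel = FIT_SENTINEL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("ligand_id" %in% names(df))
  labels <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  fcols <- setdiff(names(df), c("ligand_id", "label"))
  vals <- as.matrix(as.data.frame(lapply(df[fcols], function(col) {
    col[col == "FAIL"] <- sentinel
    as.numeric(col)
  }), check.names = FALSE))
  score_table(df$ligand_id, fcols, vals, labels, sentinel = sentinel)
}
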
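# Active/decoy benchmark assembly: activity filtering, property-matched
# decoy selection, stratified train/test splitting, and descriptor-space
# PCA.

#' Construct a labelled active/decoy library
#'
#' @param molecules list of \code{Molecule} with unique ids.
#' @param label binary vector (1 active / 0 decoy), one per molecule.
#' @param source character vector of source tags (recycled).
#' @param split optional character vector of "train"/"test" assignments.
#' @return object of class \code{LabeledLibrary}.
#' @export
labeled_library <- function(molecules, label, source = "user", split = NULL) {
  ids <- vapply(molecules, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  label <- as.integer(label)
  stopifnot(length(label) == length(molecules), all(label %in% 0:1))
  meta <- data.frame(id = ids, label = label,
                     source = rep_len(source, length(ids)),
                     stringsAsFactors = FALSE)
  if (!is.null(split)) {
    stopifnot(length(split) == length(ids), all(split %in% c("train", "test")))
    meta$split <- split
  }
  structure(list(molecules = molecules, meta = meta),
            class = "LabeledLibrary")
}

#' @export
print.LabeledLibrary <- function(x, ...) {
  cat("<LabeledLibrary> ", nrow(x$meta), " molecules: ",
      sum(x$meta$label == 1L), " actives, ", sum(x$meta$label == 0L),
      " decoys", sep = "")
  if (!is.null(x$meta$split))
    cat(" (train ", sum(x$meta$split == "train"), " / test ",
        sum(x$meta$split == "test"), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Filter activity records down to qualifying actives
#'
#' Keeps orthosteric compounds with Ki strictly below \code{ki_max}
#' (10 uM by default); records without a Ki are dropped with a message,
#' allosteric ones silently excluded. Filtering never throws on content.
#'
#' @param molecules list of \code{Molecule}.
#' @param ki numeric Ki in uM (NA = not measured).
#' @param allosteric logical flag per record.
#' @param ki_max strict upper Ki bound in uM (default 10).
#' @return list of retained \code{Molecule}.
#' @export
filter_actives <- function(molecules, ki, allosteric = FALSE, ki_max = 10) {
  stopifnot(length(molecules) == length(ki))
  allosteric <- rep_len(as.logical(allosteric), length(molecules))
  if (any(ki < 0, na.rm = TRUE)) stop("negative Ki value")
  no_ki <- is.na(ki)
  if (any(no_ki))
    message("filter_actives: dropping ", sum(no_ki), " record(s) without Ki")
  keep <- !no_ki & ki < ki_max & !allosteric
  molecules[keep]
}

# default DUD-E-style property windows
.decoy_windows <- list(mw = 25, alogp = 1.0, n_hbd = 1, n_hba = 2,
                       n_rotb = 2)

#' Select property-matched decoys for a set of actives
#'
#' For each active, pool members inside the property windows (MW, ALogP,
#' HBD, HBA, rotatable bonds; net formal charge matched exactly) and with
#' element-scheme Tanimoto at most \code{max_tanimoto} to \emph{every}
#' active are ranked by window-normalised L1 descriptor distance, and the
#' closest \code{ratio} unused members are taken. A pool member serves
#' more than one active only when the unused pool is exhausted (noted via
#' a message); too few eligible members for some active is an error
#' stating the deficit.
#'
#' @param actives list of active \code{Molecule}.
#' @param pool list of candidate decoy \code{Molecule} (ids disjoint from
#'   the actives).
#' @param ratio decoys per active (default 50).
#' @param windows named list overriding the default property windows.
#' @param max_tanimoto topological-similarity ceiling versus all actives
#'   (default 0.35).
#' @return a \code{LabeledLibrary} of actives (label 1) and matched
#'   decoys (label 0).
#' @export
match_decoys <- function(actives, pool, ratio = 50L, windows = list(),
                         max_tanimoto = 0.35) {
  stopifnot(length(actives) >= 1L, length(pool) >= 1L, ratio >= 1L)
  act_ids <- vapply(actives, function(m) m$id, "")
  pool_ids <- vapply(pool, function(m) m$id, "")
  if (length(intersect(act_ids, pool_ids)))
    stop("pool ids overlap the actives")
  w <- utils::modifyList(.decoy_windows, windows)
  da <- descriptor_matrix(actives); dp <- descriptor_matrix(pool)
  ca <- vapply(actives, net_charge, 0L); cp <- vapply(pool, net_charge, 0L)
  props <- c("mw", "alogp", "n_hbd", "n_hba", "n_rotb")
  dam <- as.matrix(da[, props]); dpm <- as.matrix(dp[, props])
  wvec <- unlist(w[props])
  # pool members outside every active's windows can never be selected, so
  # only the remainder needs fingerprints for the similarity ceiling
  candidate <- rep(FALSE, length(pool))
  for (a in seq_along(actives)) {
    dev <- abs(dpm - matrix(dam[a, ], nrow(dpm), length(props), byrow = TRUE))
    candidate <- candidate |
      (rowSums(dev <= matrix(wvec, nrow(dpm), length(props),
                             byrow = TRUE)) == length(props) & cp == ca[a])
  }
  fpa <- lapply(actives, circular_fingerprint, diameter = 4L, scheme = "element")
  # dense bit matrices so the all-pairs Tanimoto reduces to one crossprod
  as_bits <- function(fps) {
    m <- matrix(0, length(fps), fps[[1]]$nbits)
    for (i in seq_along(fps)) m[i, fps[[i]]$bits] <- 1
    m
  }
  ba <- as_bits(fpa)
  sim_ok <- rep(FALSE, length(pool))
  cand_idx <- which(candidate)
  if (length(cand_idx)) {
    fpp <- lapply(pool[cand_idx], circular_fingerprint, diameter = 4L,
                  scheme = "element")
    bp <- as_bits(fpp)
    inter <- bp %*% t(ba)
    uni <- outer(rowSums(bp), rowSums(ba), `+`) - inter
    sim <- inter / pmax(uni, 1)
    sim_ok[cand_idx] <- apply(sim, 1, max) <= max_tanimoto
  }
  used <- logical(length(pool))
  chosen <- integer(0)
  reused <- 0L
  for (a in seq_along(actives)) {
    dev <- abs(dpm - matrix(dam[a, ], nrow(dpm), length(props), byrow = TRUE))
    inwin <- rowSums(dev <= matrix(wvec, nrow(dpm), length(props),
                                   byrow = TRUE)) == length(props)
    elig <- which(inwin & cp == ca[a] & sim_ok)
    if (length(elig) < ratio)
      stop("pool too small for active '", act_ids[a], "': ", length(elig),
           " eligible decoys, need ", ratio,
           " (deficit ", ratio - length(elig), ")")
    l1 <- rowSums(dev[elig, , drop = FALSE] /
                    matrix(wvec, length(elig), length(props), byrow = TRUE))
    ord <- elig[order(l1, pool_ids[elig])]
    fresh <- ord[!used[ord]]
    take <- utils::head(fresh, ratio)
    if (length(take) < ratio) {
      extra <- utils::head(setdiff(ord, take), ratio - length(take))
      reused <- reused + length(extra)
      take <- c(take, extra)
    }
    used[take] <- TRUE
    chosen <- c(chosen, take)
  }
  if (reused > 0L)
    message("match_decoys: pool exhausted; ", reused,
            " decoy assignment(s) reuse pool members")
  decoys <- pool[chosen]
  # reused members appear once in the library
  dec_ids <- vapply(decoys, function(m) m$id, "")
  decoys <- decoys[!duplicated(dec_ids)]
  labeled_library(c(actives, decoys),
                  c(rep(1L, length(actives)), rep(0L, length(decoys))),
                  source = c(rep("active", length(actives)),
                             rep("decoy", length(decoys))))
}

#' Stratified train/test split of a labelled library
#'
#' Splits each class independently at the configured ratio (default 4:1)
#' after a seeded shuffle, so train:test sizes are within one of the
#' exact ratio per class and the split is reproducible.
#'
#' @param lib a \code{LabeledLibrary}.
#' @param ratio length-2 integer vector c(train, test) (default 4:1).
#' @param seed shuffle seed.
#' @return the library with a \code{split} column added.
#' @export
split_train_test <- function(lib, ratio = c(4L, 1L), seed = 1L) {
  stopifnot(inherits(lib, "LabeledLibrary"), length(ratio) == 2L,
            all(ratio >= 1L))
  y <- lib$meta$label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  need <- sum(ratio)
  if (min(table(y)) < need)
    stop("a class has fewer than ", need, " members; cannot split ",
         ratio[1], ":", ratio[2])
  set.seed(seed)
  split <- character(nrow(lib$meta))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    ntr <- round(length(idx) * ratio[1] / need)
    split[idx[seq_len(ntr)]] <- "train"
    split[idx[-seq_len(ntr)]] <- "test"
  }
  lib$meta$split <- split
  lib
}

#' PCA of the benchmark's descriptor space
#'
#' Computes the eight descriptors for every library member, z-scores
#' them (zero-variance descriptors are dropped with a warning), and
#' eigendecomposes the covariance. Loading signs follow the
#' largest-absolute-loading-positive convention so results are
#' reproducible across platforms.
#'
#' @param lib a \code{LabeledLibrary} (or plain list of \code{Molecule}).
#' @return object of class \code{PCAResult}: \code{loadings} (p x p),
#'   \code{scores} (n x p), \code{explained_variance_ratio} (length p,
#'   non-increasing, summing to 1), \code{descriptors} (the z-scored
#'   matrix), \code{meta}.
#' @export
pca_chemspace <- function(lib) {
  mols <- if (inherits(lib, "LabeledLibrary")) lib$molecules else lib
  if (length(mols) < 2L) stop("need at least 2 molecules for PCA")
  dm <- descriptor_matrix(mols)
  vars <- vapply(dm, stats::var, 0)
  if (any(vars == 0)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(names(dm)[vars == 0], collapse = ", "))
    dm <- dm[, vars > 0, drop = FALSE]
  }
  z <- scale(as.matrix(dm))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  # sign convention: the largest-|loading| entry of each component is
  # positive
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained_variance_ratio = evr, descriptors = z,
                 meta = if (inherits(lib, "LabeledLibrary")) lib$meta else NULL),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("<PCAResult> ", nrow(x$scores), " molecules, ", ncol(x$loadings),
      " components\n  variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio[
        seq_len(min(3, length(x$explained_variance_ratio)))]),
        collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Read/write a labelled library as CSV (id, smiles, label, source, split)
#' @param lib a \code{LabeledLibrary}.
#' @param path CSV path.
#' @return \code{path} invisibly (write) or a \code{LabeledLibrary}
#'   (read; molecules rebuilt from SMILES, 2D only).
#' @export
write_library_csv <- function(lib, path) {
  stopifnot(inherits(lib, "LabeledLibrary"))
  sm <- vapply(lib$molecules, function(m)
    if (!is.null(m$smiles)) m$smiles else write_smiles(m), "")
  df <- cbind(lib$meta[, "id", drop = FALSE], smiles = sm,
              lib$meta[, setdiff(names(lib$meta), "id"), drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "smiles", "label") %in% names(df)))
  mols <- lapply(seq_len(nrow(df)), function(i)
    parse_smiles(df$smiles[i], id = df$id[i]))
  labeled_library(mols, df$label,
                  source = if ("source" %in% names(df)) df$source else "csv",
                  split = if ("split" %in% names(df)) df$split else NULL)
}
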
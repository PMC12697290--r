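# Pharmacophore models: typed tolerance spheres fitted to ligand feature
# points with a Catalyst-style geometric FitValue and a fixed -10
# sentinel for ligands that fail to map.

.feature_kinds <- c("A", "D", "H", "R", "N", "P")

#' Fail sentinel for pharmacophore fitting
#'
#' Ligands with no valid feature mapping receive this FitValue so they
#' sort below every matched ligand and can be recognised downstream
#' (the naive Bayes stage gives the sentinel its own bin).
#' @export
FIT_SENTINEL <- -10

#' Construct a pharmacophore model
#'
#' @param id model identifier.
#' @param features data.frame with columns \code{kind} (one of A, D, H,
#'   R, N, P: acceptor, donor, hydrophobic, aromatic ring, negative
#'   ionizable, positive ionizable), \code{x}, \code{y}, \code{z}
#'   (Angstrom), and optionally \code{tolerance} (default 1.6 A) and
#'   \code{weight} (default 1).
#' @param exclusion optional data.frame of steric exclusion spheres with
#'   columns \code{x}, \code{y}, \code{z}, \code{radius}.
#' @param min_features_to_match minimum number of features a ligand must
#'   map (default: all of them).
#' @return object of class \code{PharmacophoreModel}.
#' @export
pharmacophore_model <- function(id, features, exclusion = NULL,
                                min_features_to_match = NULL) {
  features <- as.data.frame(features)
  stopifnot(all(c("kind", "x", "y", "z") %in% names(features)))
  if (!all(features$kind %in% .feature_kinds))
    stop("unknown feature kind(s): ",
         paste(setdiff(features$kind, .feature_kinds), collapse = ", "))
  if (is.null(features$tolerance)) features$tolerance <- 1.6
  if (is.null(features$weight)) features$weight <- 1
  if (any(features$tolerance <= 0)) stop("tolerances must be positive")
  if (is.null(exclusion))
    exclusion <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            radius = numeric(0))
  exclusion <- as.data.frame(exclusion)
  if (is.null(min_features_to_match)) min_features_to_match <- nrow(features)
  if (min_features_to_match > nrow(features))
    stop("min_features_to_match exceeds the feature count")
  structure(list(id = id, features = features, exclusion = exclusion,
                 min_features_to_match = as.integer(min_features_to_match)),
            class = "PharmacophoreModel")
}

#' @export
print.PharmacophoreModel <- function(x, ...) {
  code <- paste(sort(x$features$kind), collapse = "")
  cat("<PharmacophoreModel> ", x$id, ": ", nrow(x$features), " features (",
      code, "), ", nrow(x$exclusion), " exclusion sphere(s), match >= ",
      x$min_features_to_match, "\n", sep = "")
  invisible(x)
}

#' Parse a pharmacophore feature code into kind counts
#'
#' Feature-set codes such as "AANNR" (two acceptors, two negative
#' ionizable groups, one aromatic ring) are multisets over the six-letter
#' alphabet A, D, H, R, N, P.
#'
#' @param code character string over the feature alphabet (may be empty).
#' @return named integer vector of counts for the letters present.
#' @export
parse_feature_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!nzchar(code)) return(stats::setNames(integer(0), character(0)))
  letters_ <- strsplit(code, "")[[1]]
  bad <- setdiff(letters_, .feature_kinds)
  if (length(bad))
    stop("unknown feature letter(s): ", paste(unique(bad), collapse = ", "))
  tab <- table(factor(letters_, levels = .feature_kinds))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0L]
}

#' Perceive pharmacophoric feature points of a ligand conformer
#'
#' Acceptors and donors sit on their heteroatoms, aromatic-ring features
#' at ring centroids, hydrophobic features at the centroid of each
#' connected fragment of three or more non-polar carbons, ionizable
#' features at charged-group centroids.
#'
#' @param mol a \code{Molecule} with at least one conformer.
#' @param conformer_index conformer to use (default 1).
#' @return data.frame with columns \code{kind}, \code{x}, \code{y},
#'   \code{z}, \code{atoms} (list of contributing atom indices).
#' @export
perceive_ligand_features <- function(mol, conformer_index = 1L) {
  stopifnot(inherits(mol, "Molecule"))
  if (conformer_index > length(mol$conformers))
    stop("molecule '", mol$id, "' has no conformer ", conformer_index)
  xyz <- mol$conformers[[conformer_index]]
  fl <- .atom_flags(mol)
  rows <- list()
  add <- function(kind, atoms) {
    ctr <- colMeans(xyz[atoms, , drop = FALSE])
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
      atoms = I(list(sort(atoms))))
  }
  for (v in which(fl$acceptor)) add("A", v)
  for (v in which(fl$donor)) add("D", v)
  for (ring in aromatic_rings(mol)) add("R", ring)
  for (frag in .hydrophobic_fragments(mol)) add("H", frag)
  neg <- .neg_ionizable_groups(mol)
  for (grp in neg) add("N", grp)
  neg_atoms <- unlist(neg)
  for (v in which(mol$atoms$charge < 0L))
    if (!v %in% neg_atoms) add("N", v)
  pos <- .pos_ionizable_groups(mol)
  for (grp in pos) add("P", grp)
  if (!length(rows))
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), atoms = I(list())))
  do.call(rbind, rows)
}

# all injective kind-respecting assignments of model-feature subsets of
# size >= min_size to ligand feature points; returns list of integer
# vectors of length n_features with NA for unmatched features
.enumerate_assignments <- function(model_kinds, point_kinds, min_size, cap = 1e5) {
  nf <- length(model_kinds)
  count <- 0
  assignments <- list()
  subsets_of_size <- function(m) utils::combn(nf, m, simplify = FALSE)
  lo <- max(min_size, 3L)
  if (lo > nf) return(assignments)
  for (m in seq(nf, lo)) {
    for (S in subsets_of_size(m)) {
      # per kind, arrangements of ligand points for that kind's features
      kinds_in_S <- model_kinds[S]
      per_kind <- list()
      ok <- TRUE
      for (kd in unique(kinds_in_S)) {
        fidx <- S[kinds_in_S == kd]
        pts <- which(point_kinds == kd)
        if (length(pts) < length(fidx)) { ok <- FALSE; break }
        arr <- .arrangements(pts, length(fidx))
        per_kind[[kd]] <- list(fidx = fidx, arr = arr)
      }
      if (!ok) next
      combos <- prod(vapply(per_kind, function(p) nrow(p$arr), 0))
      if (count + combos > cap) return(NULL)  # cap exceeded
      count <- count + combos
      # cartesian product over kinds
      idx_grid <- expand.grid(lapply(per_kind, function(p) seq_len(nrow(p$arr))))
      for (r in seq_len(nrow(idx_grid))) {
        asg <- rep(NA_integer_, nf)
        for (ci in seq_along(per_kind)) {
          p <- per_kind[[ci]]
          asg[p$fidx] <- p$arr[idx_grid[r, ci], ]
        }
        assignments[[length(assignments) + 1L]] <- asg
      }
    }
  }
  assignments
}

# ordered arrangements (permutations of size k) of a vector
.arrangements <- function(v, k) {
  if (k == 0L) return(matrix(integer(0), 1, 0))
  if (k == 1L) return(matrix(v, ncol = 1))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), v)
  do.call(rbind, out)
}

# score one assignment on one conformer; returns fit value or NA if the
# alignment is degenerate or an exclusion sphere is violated
.score_assignment <- function(asg, model, points, xyz) {
  matched <- which(!is.na(asg))
  mc <- as.matrix(model$features[matched, c("x", "y", "z")])
  lp <- as.matrix(points[asg[matched], c("x", "y", "z")])
  fit <- tryCatch(kabsch_superpose(mc, lp), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  moved <- xyz %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
  if (nrow(model$exclusion)) {
    for (e in seq_len(nrow(model$exclusion))) {
      ctr <- as.numeric(model$exclusion[e, c("x", "y", "z")])
      dd <- sqrt(rowSums(sweep(moved, 2, ctr)^2))
      if (any(dd < model$exclusion$radius[e])) return(NA_real_)
    }
  }
  pts_moved <- lp %*% t(fit$rotation) +
    matrix(fit$translation, nrow(lp), 3, byrow = TRUE)
  d <- sqrt(rowSums((pts_moved - mc)^2))
  tol <- model$features$tolerance[matched]
  w <- model$features$weight[matched]
  sum(w * pmax(0, 1 - (d / tol)^2))
}

#' Fit a ligand to a pharmacophore model
#'
#' Over all conformers and all injective kind-respecting assignments of
#' model features to ligand feature points (of size at least
#' \code{min_features_to_match}), rigid-aligns the assigned points by
#' Kabsch superposition, rejects placements that push any heavy atom into
#' an exclusion sphere, and scores
#' \deqn{FitValue = \sum_f w_f \max(0, 1 - (d_f / tol_f)^2)}
#' with \eqn{d_f} the post-alignment centre distance. The best value over
#' all placements is returned; a ligand with no valid placement gets the
#' \code{-10} sentinel. Assignment enumeration is exact up to \code{cap}
#' assignments per conformer, beyond which a greedy search with 2-swap
#' refinement is used (and noted via a message).
#'
#' @param mol a \code{Molecule} with at least one conformer.
#' @param model a \code{PharmacophoreModel} with at least 3 features.
#' @param cap maximum number of exactly enumerated assignments.
#' @return list of class \code{FitResult}: \code{matched},
#'   \code{fit_value}, \code{mapping} (feature index -> ligand feature
#'   point index), \code{conformer_index}.
#' @export
fit_to_model <- function(mol, model, cap = 1e5) {
  stopifnot(inherits(mol, "Molecule"), inherits(model, "PharmacophoreModel"))
  if (nrow(model$features) < 3L)
    stop("model must have at least 3 features for a defined alignment")
  if (!length(mol$conformers))
    stop("molecule '", mol$id, "' has no conformer")
  min_size <- max(3L, model$min_features_to_match)
  best <- list(matched = FALSE, fit_value = FIT_SENTINEL,
               mapping = NULL, conformer_index = NA_integer_)
  for (ci in seq_along(mol$conformers)) {
    points <- perceive_ligand_features(mol, ci)
    if (!nrow(points)) next
    asgs <- .enumerate_assignments(model$features$kind, points$kind,
                                   min_size, cap = cap)
    if (is.null(asgs)) {
      message("fit_to_model: assignment cap exceeded for '", mol$id,
              "', using greedy search with 2-swap refinement")
      asgs <- .greedy_assignments(model, points, min_size)
    }
    xyz <- mol$conformers[[ci]]
    for (asg in asgs) {
      val <- .score_assignment(asg, model, points, xyz)
      if (!is.na(val) && val > best$fit_value) {
        best <- list(matched = TRUE, fit_value = val, mapping = asg,
                     conformer_index = ci)
      }
    }
  }
  class(best) <- "FitResult"
  best
}

#' @export
print.FitResult <- function(x, ...) {
  if (x$matched)
    cat("<FitResult> matched, FitValue = ", sprintf("%.3f", x$fit_value),
        " (conformer ", x$conformer_index, ")\n", sep = "")
  else
    cat("<FitResult> unmatched, FitValue sentinel =", x$fit_value, "\n")
  invisible(x)
}

# greedy full-size assignment by internal-distance compatibility plus
# 2-swap refinement on the true fit value; returns a small list of
# candidate assignments
.greedy_assignments <- function(model, points, min_size) {
  mk <- model$features$kind
  nf <- length(mk)
  mc <- as.matrix(model$features[, c("x", "y", "z")])
  pc <- as.matrix(points[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(mc))
  dp <- as.matrix(stats::dist(pc))
  asg <- rep(NA_integer_, nf)
  used <- logical(nrow(points))
  ord <- order(vapply(seq_len(nf), function(f)
    -sum(points$kind == mk[f]), 0))  # scarcest kinds first
  for (f in ord) {
    cand <- which(points$kind == mk[f] & !used)
    if (!length(cand)) next
    placed <- which(!is.na(asg))
    if (!length(placed)) { asg[f] <- cand[1]; used[cand[1]] <- TRUE; next }
    cost <- vapply(cand, function(p)
      sum(abs(dm[f, placed] - dp[p, asg[placed]])), 0)
    pick <- cand[which.min(cost)]
    asg[f] <- pick; used[pick] <- TRUE
  }
  if (sum(!is.na(asg)) < min_size) return(list())
  out <- list(asg)
  # 2-swap refinement among same-kind placements
  for (f1 in seq_len(nf - 1L)) for (f2 in seq(f1 + 1L, nf)) {
    if (mk[f1] != mk[f2]) next
    if (is.na(asg[f1]) || is.na(asg[f2])) next
    sw <- asg; sw[c(f1, f2)] <- sw[c(f2, f1)]
    out[[length(out) + 1L]] <- sw
  }
  out
}

#' Screen a ligand library through a pharmacophore model
#'
#' Fits every library member, ranks by FitValue (descending) and keeps
#' the top \code{ceiling(keep_fraction * n)}. Sentinel (-10) entries are
#' never kept unless \code{keep_fraction = 1}.
#'
#' @param library list of \code{Molecule}.
#' @param model a \code{PharmacophoreModel}.
#' @param keep_fraction fraction of the library to keep (default 0.01,
#'   the "around 1 percent" screening regime).
#' @param cap passed to \code{\link{fit_to_model}}.
#' @return data.frame (id, fit_value, matched, conformer_index) of the
#'   kept ligands, sorted by fit_value descending; the full table is
#'   attached as attribute \code{"all"}.
#' @export
screen_library <- function(library, model, keep_fraction = 0.01, cap = 1e5) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (!length(library)) {
    warning("empty ligand library")
    return(data.frame(id = character(0), fit_value = numeric(0),
                      matched = logical(0), conformer_index = integer(0)))
  }
  fits <- lapply(library, fit_to_model, model = model, cap = cap)
  tab <- data.frame(
    id = vapply(library, function(m) m$id, ""),
    fit_value = vapply(fits, function(f) f$fit_value, 0),
    matched = vapply(fits, function(f) f$matched, TRUE),
    conformer_index = vapply(fits, function(f)
      as.integer(f$conformer_index), 1L))
  ord <- order(-tab$fit_value, tab$id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  m <- ceiling(keep_fraction * nrow(tab))
  kept <- tab[seq_len(m), , drop = FALSE]
  if (keep_fraction < 1) kept <- kept[kept$matched, , drop = FALSE]
  if (!nrow(kept)) warning("no ligand matched the pharmacophore")
  attr(kept, "all") <- tab
  kept
}

#' Derive a pharmacophore model from a receptor-ligand complex
#'
#' A simplified, geometry-only stand-in for hypothesis generation from a
#' complex: ligand feature points are retained only where the protein
#' provides a complementary contact (donor/acceptor: a polar protein atom
#' within 3.5 A; hydrophobic: at least 3 apolar protein atoms within
#' 4.5 A; negative ionizable: a basic-residue nitrogen within 4.0 A;
#' positive ionizable: an acidic-residue oxygen within 4.0 A; ring: an
#' aromatic-residue side-chain atom within 5.0 A), then capped to at most
#' 6 features by descending protein-contact count.
#'
#' @param structure a \code{StructureModel} with a bound ligand and
#'   protein atoms.
#' @param tolerance feature sphere radius (default 1.6 A).
#' @return a \code{PharmacophoreModel}.
#' @export
derive_model_from_complex <- function(structure, tolerance = 1.6) {
  stopifnot(inherits(structure, "StructureModel"))
  if (is.null(structure$ligand) || !length(structure$ligand$conformers))
    stop("structure '", structure$id, "' has no ligand with coordinates")
  if (is.null(structure$protein_atoms))
    stop("structure '", structure$id, "' has no protein atoms")
  pts <- perceive_ligand_features(structure$ligand, 1L)
  if (!nrow(pts)) stop("no ligand feature points perceived")
  pa <- structure$protein_atoms
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  basic_n <- pa$element == "N" & pa$resid %in% c("ARG", "LYS", "HIS")
  acidic_o <- pa$element == "O" & pa$resid %in% c("ASP", "GLU")
  ring_res <- pa$resid %in% c("PHE", "TYR", "TRP", "HIS") &
    !(pa$elety %in% c("N", "CA", "C", "O"))
  polar <- pa$element %in% c("N", "O")
  apolar <- pa$element %in% c("C", "S")
  contacts <- integer(nrow(pts))
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ctr <- as.numeric(pts[i, c("x", "y", "z")])
    dd <- sqrt(rowSums(sweep(pxyz, 2, ctr)^2))
    kind <- pts$kind[i]
    hit <- switch(kind,
      A = , D = which(polar & dd <= 3.5),
      H = which(apolar & dd <= 4.5),
      N = which(basic_n & dd <= 4.0),
      P = which(acidic_o & dd <= 4.0),
      R = which(ring_res & dd <= 5.0))
    ok <- if (kind == "H") length(hit) >= 3L else length(hit) >= 1L
    keep[i] <- ok
    contacts[i] <- length(hit)
  }
  sel <- which(keep)
  if (!length(sel)) stop("no ligand feature has complementary protein context")
  sel <- sel[order(-contacts[sel], pts$kind[sel], sel)]
  if (length(sel) > 6L) sel <- sel[1:6]
  feats <- pts[sort(sel), c("kind", "x", "y", "z")]
  feats$tolerance <- tolerance
  feats$weight <- 1
  pharmacophore_model(structure$id, feats)
}

#' Cross-validated AUC of a pharmacophore as a one-feature classifier
#'
#' Fits every labelled library member to the model (failed fits keep the
#' -10 sentinel), then feeds the FitValue column to the naive Bayes
#' classifier under stratified k-fold cross-validation and returns the
#' pooled out-of-fold AUC.
#'
#' @param model a \code{PharmacophoreModel}.
#' @param library list of \code{Molecule}.
#' @param labels binary vector (1 = active, 0 = decoy), one per molecule.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param cap passed to \code{\link{fit_to_model}}.
#' @return cross-validated AUC (scalar).
#' @export
validate_model <- function(model, library, labels, folds = 5L, seed = 1L,
                           cap = 1e5) {
  stopifnot(length(library) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  fv <- vapply(library, function(m)
    fit_to_model(m, model, cap = cap)$fit_value, 0)
  tab <- score_table(ligand_ids = vapply(library, function(m) m$id, ""),
                     feature_ids = "FitValue",
                     values = matrix(fv, ncol = 1),
                     labels = labels, sentinel = FIT_SENTINEL)
  cv_auc(tab, features = "FitValue", folds = folds, seed = seed)
}

#' Read/write a pharmacophore model as JSON
#' @param model a \code{PharmacophoreModel}.
#' @param path JSON file path.
#' @return \code{path} invisibly (write) or a model (read).
#' @export
write_pharmacophore_json <- function(model, path) {
  stopifnot(inherits(model, "PharmacophoreModel"))
  feats <- lapply(seq_len(nrow(model$features)), function(i) {
    f <- model$features[i, ]
    list(kind = f$kind, center = c(f$x, f$y, f$z),
         tolerance = f$tolerance, weight = f$weight)
  })
  excl <- lapply(seq_len(nrow(model$exclusion)), function(i) {
    e <- model$exclusion[i, ]
    list(center = c(e$x, e$y, e$z), radius = e$radius)
  })
  jsonlite::write_json(
    list(id = model$id, features = feats, exclusion = excl,
         min_features_to_match = model$min_features_to_match),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pharmacophore_json
#' @export
read_pharmacophore_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- do.call(rbind, lapply(j$features, function(f)
    data.frame(kind = f$kind, x = f$center[[1]], y = f$center[[2]],
               z = f$center[[3]], tolerance = f$tolerance,
               weight = f$weight)))
  excl <- if (length(j$exclusion))
    do.call(rbind, lapply(j$exclusion, function(e)
      data.frame(x = e$center[[1]], y = e$center[[2]], z = e$center[[3]],
                 radius = e$radius)))
  else NULL
  pharmacophore_model(j$id, feats, excl, j$min_features_to_match)
}
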
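# Docking evaluation: symmetry-corrected ligand pose RMSD, top-scored
# versus best pose bookkeeping with the 2 Angstrom success rule, and the
# Mann-Whitney U test for active/decoy score separation.

# all automorphisms of the heavy-atom graph preserving element and bond
# order, via VF2 (igraph); returns a list of permutation vectors, or just
# the identity (with a warning) when the count exceeds `cap`
.graph_automorphisms <- function(mol, cap = 1e4) {
  n <- n_atoms(mol)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  vcol <- as.integer(factor(paste(mol$atoms$element, mol$atoms$charge)))
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
    ecol <- as.integer(mol$bonds$order)
  } else ecol <- integer(0)
  cnt <- igraph::count_isomorphisms(g, g, method = "vf2",
                                    vertex.color1 = vcol, vertex.color2 = vcol,
                                    edge.color1 = ecol, edge.color2 = ecol)
  if (cnt > cap) {
    warning("automorphism count ", cnt, " exceeds cap ", cap,
            "; falling back to identity-only RMSD")
    return(list(seq_len(n)))
  }
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = vcol, vertex.color2 = vcol,
                               edge.color1 = ecol, edge.color2 = ecol)
  lapply(maps, as.integer)
}

#' Symmetry-corrected in-place RMSD between two poses of one ligand
#'
#' Minimum heavy-atom RMSD over the automorphisms of the molecular graph
#' (element- and bond-order-preserving), so topologically equivalent
#' atoms (e.g. the two ortho carbons of a phenyl ring) do not inflate the
#' RMSD. By default no re-superposition is applied (the standard
#' convention for redocking, where both poses live in the receptor
#' frame); \code{superpose = TRUE} optimally aligns first.
#'
#' @param mol the \code{Molecule} (defines the graph).
#' @param coords_a,coords_b n_heavy x 3 coordinate matrices.
#' @param superpose rigid-align before computing the RMSD (default FALSE).
#' @param cap automorphism-count cap (default 1e4).
#' @return RMSD in Angstrom.
#' @export
symmetry_corrected_rmsd <- function(mol, coords_a, coords_b,
                                    superpose = FALSE, cap = 1e4) {
  stopifnot(inherits(mol, "Molecule"))
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  n <- n_atoms(mol)
  if (nrow(a) != n || nrow(b) != n)
    stop("coordinate rows (", nrow(a), ", ", nrow(b),
         ") must equal the heavy-atom count (", n, ")")
  perms <- .graph_automorphisms(mol, cap = cap)
  best <- Inf
  for (p in perms) {
    bp <- b[p, , drop = FALSE]
    r <- if (superpose) kabsch_superpose(a, bp)$rmsd
         else sqrt(mean(rowSums((a - bp)^2)))
    if (r < best) best <- r
  }
  best
}

#' Bundle docked poses of one ligand with its native conformation
#'
#' @param ligand a \code{Molecule} (heavy-atom graph of the ligand).
#' @param native_conformer n_heavy x 3 matrix, the crystal pose.
#' @param docked data.frame-like with one row per pose: columns
#'   \code{program}, \code{structure}, \code{score}, plus a parallel list
#'   \code{coords} of n_heavy x 3 matrices.
#' @param coords list of pose coordinate matrices, parallel to
#'   \code{docked} rows.
#' @return object of class \code{PoseSet}.
#' @export
pose_set <- function(ligand, native_conformer, docked, coords) {
  stopifnot(inherits(ligand, "Molecule"))
  native_conformer <- as.matrix(native_conformer)
  stopifnot(nrow(native_conformer) == n_atoms(ligand))
  docked <- as.data.frame(docked)
  stopifnot(all(c("program", "structure", "score") %in% names(docked)),
            length(coords) == nrow(docked), all(is.finite(docked$score)))
  for (m in coords) stopifnot(nrow(as.matrix(m)) == n_atoms(ligand))
  structure(list(ligand = ligand, native_conformer = native_conformer,
                 docked = docked, coords = coords),
            class = "PoseSet")
}

#' Redocking report: top-scored and best pose RMSD per program/structure
#'
#' For each (program, structure) group: the top-scored pose is the one
#' with the best docking score (lower is better by default, ties to the
#' first in input order), the best pose is the one with the lowest
#' symmetry-corrected RMSD to the native conformation, and the redock
#' succeeds when the top-scored pose RMSD is within \code{threshold}
#' (2 Angstrom, the standard cutoff; above it the prediction is counted
#' as failed).
#'
#' @param poses a \code{PoseSet}.
#' @param threshold success cutoff in Angstrom (default 2.0).
#' @param score_direction "lower" (docking energies, default) or
#'   "higher" = better score.
#' @return data.frame of class \code{RedockReport}: program, structure,
#'   top_scored_rmsd, best_rmsd, success.
#' @export
redock_report <- function(poses, threshold = 2.0,
                          score_direction = c("lower", "higher")) {
  stopifnot(inherits(poses, "PoseSet"))
  score_direction <- match.arg(score_direction)
  if (!nrow(poses$docked)) stop("empty docked pose list")
  rmsds <- vapply(seq_along(poses$coords), function(k)
    symmetry_corrected_rmsd(poses$ligand, poses$native_conformer,
                            poses$coords[[k]]), 0)
  grp <- interaction(poses$docked$program, poses$docked$structure, drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    sc <- poses$docked$score[idx]
    eff <- if (score_direction == "lower") sc else -sc
    top <- idx[which.min(eff)]        # first occurrence wins ties
    data.frame(program = poses$docked$program[top],
               structure = poses$docked$structure[top],
               top_scored_rmsd = rmsds[top],
               best_rmsd = min(rmsds[idx]),
               success = rmsds[top] <= threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("RedockReport", class(out))
  out
}

#' Mann-Whitney U test for two score samples
#'
#' Midrank U statistic with tie correction. The U reported counts pairs
#' where an \code{x} value exceeds a \code{y} value (ties count 1/2), so
#' \eqn{U / (n_x n_y)} equals the rank AUC of \code{x} over \code{y}.
#' The two-sided p-value is computed by exact enumeration of all label
#' assignments when \eqn{n_x + n_y \le} \code{exact_limit} (ties
#' included), and by the normal approximation with continuity and tie
#' correction otherwise. When every value in both samples is identical
#' the test is uninformative and p = 1 is returned with a warning.
#'
#' @param x,y numeric score vectors (each non-empty).
#' @param exact_limit pooled-size bound for the exact test (default 12).
#' @return list with \code{U} and \code{p_two_sided}.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(U = n1 * n2 / 2, p_two_sided = 1))
  }
  ustat <- function(is_x) {
    r <- rank(pooled, ties.method = "average")
    sum(r[is_x]) - n1 * (n1 + 1) / 2
  }
  u_of <- function(sel) {
    r <- rank(pooled, ties.method = "average")
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    sels <- utils::combn(n, n1, simplify = FALSE)
    us <- vapply(sels, u_of, 0)
    p <- mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
  } else {
    # normal approximation with tie correction and continuity correction
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- (abs(obs - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
    p <- min(1, p)
  }
  list(U = obs, p_two_sided = p)
}
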
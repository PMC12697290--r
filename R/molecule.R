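#' Molecular graph with optional 3D conformers
#'
#' Constructs the light-weight molecule container used throughout the
#' package: an H-suppressed atom/bond graph plus zero or more conformer
#' coordinate sets. Atom indices are 0-free: everything in R is 1-based;
#' conversion to the 1-based SDF convention happens only at the file
#' boundary.
#'
#' @param id character scalar, molecule identifier.
#' @param atoms data.frame with columns \code{element} (symbol),
#'   \code{charge} (integer formal charge), \code{aromatic} (logical).
#'   An optional \code{hcount} column gives implicit hydrogen counts;
#'   when absent they are filled in from default valences.
#' @param bonds data.frame with columns \code{i}, \code{j} (atom indices)
#'   and \code{order} (1, 2, 3, or 4 for aromatic).
#' @param conformers list of numeric matrices, each n_atoms x 3 (Angstrom).
#' @param smiles optional SMILES string carried as metadata.
#' @return object of class \code{Molecule}.
#' @export
molecule <- function(id, atoms, bonds = NULL, conformers = list(), smiles = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$aromatic <- as.logical(atoms$aromatic)
  n <- nrow(atoms)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  bonds <- as.data.frame(bonds)
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  if (nrow(bonds)) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond atom index out of range for molecule '", id, "'")
    if (any(bonds$i == bonds$j))
      stop("self-loop bond in molecule '", id, "'")
    if (!all(bonds$order %in% 1:4))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  conformers <- lapply(conformers, function(xyz) {
    xyz <- as.matrix(xyz)
    storage.mode(xyz) <- "double"
    if (nrow(xyz) != n || ncol(xyz) != 3L)
      stop("conformer must be n_atoms x 3 for molecule '", id, "'")
    unname(xyz)
  })
  if (is.null(atoms$hcount)) {
    atoms$hcount <- implicit_h_counts(atoms, bonds)
  } else {
    atoms$hcount <- as.integer(atoms$hcount)
    if (any(atoms$hcount < 0L)) stop("negative hcount")
  }
  mol <- structure(
    list(id = id, atoms = atoms, bonds = bonds, conformers = conformers,
         smiles = smiles),
    class = "Molecule")
  mol$adj <- .build_adjacency(nrow(atoms), bonds)
  mol
}

#' @export
print.Molecule <- function(x, ...) {
  cat("<Molecule> ", x$id, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", length(x$conformers), " conformer(s)\n",
      sep = "")
  if (!is.null(x$smiles)) cat("  smiles: ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms of a molecule
#' @param mol a \code{Molecule}.
#' @return integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# default valences used for implicit-H completion; aromatic bonds count 1.5
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)

# bond-order sum per atom (aromatic bond = 1.5, rounded down at the end
# so an aromatic carbon with two ring bonds and one substituent sums to 4)
.bond_order_sum <- function(atoms, bonds) {
  n <- nrow(atoms)
  s <- numeric(n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      s[bonds$i[k]] <- s[bonds$i[k]] + ord[k]
      s[bonds$j[k]] <- s[bonds$j[k]] + ord[k]
    }
  }
  s
}

implicit_h_counts <- function(atoms, bonds) {
  val <- .default_valence[atoms$element]
  if (anyNA(val)) {
    bad <- unique(atoms$element[is.na(val)])
    stop("no default valence for element(s): ", paste(bad, collapse = ", "))
  }
  # charge shifts effective valence for N (+1 -> 4) and O/N anions
  eff <- unname(val) + ifelse(atoms$element %in% c("N", "P"), atoms$charge,
                       ifelse(atoms$element %in% c("O", "S"), atoms$charge, 0L))
  h <- floor(eff - .bond_order_sum(atoms, bonds) + 1e-9)
  pmax(as.integer(h), 0L)
}

# adjacency list: for each atom, matrix of (nbr, order); cached on the
# molecule at construction
.adjacency <- function(mol) {
  if (!is.null(mol$adj)) return(mol$adj)
  .build_adjacency(n_atoms(mol), mol$bonds)
}

.build_adjacency <- function(n, b) {
  src <- c(b$i, b$j); dst <- c(b$j, b$i); ord <- c(b$order, b$order)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("nbr", "order")))
  adj <- rep(list(empty), n)
  if (length(src)) {
    o <- order(src)
    src <- src[o]; dst <- dst[o]; ord <- ord[o]
    runs <- split(seq_along(src), src)
    for (nm in names(runs)) {
      idx <- runs[[nm]]
      adj[[as.integer(nm)]] <- matrix(c(dst[idx], ord[idx]), ncol = 2,
                                      dimnames = list(NULL, c("nbr", "order")))
    }
  }
  adj
}

# heavy-atom degree vector
.degree <- function(mol) {
  n <- n_atoms(mol)
  tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
}

# connected components of the heavy-atom graph (restricted to `keep` atoms
# when given); returns a list of atom-index vectors
.components <- function(mol, keep = NULL) {
  n <- n_atoms(mol)
  if (is.null(keep)) keep <- seq_len(n)
  inset <- logical(n); inset[keep] <- TRUE
  adj <- .adjacency(mol)
  seen <- logical(n)
  comps <- list()
  for (s in keep) {
    if (seen[s]) next
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]][, "nbr"]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# TRUE for each bond that lies on a cycle; a bond is acyclic exactly when
# it is a bridge, found in one DFS pass (Tarjan low-link)
.ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  n <- n_atoms(mol)
  adj_n <- vector("list", n)   # neighbor atoms
  adj_e <- vector("list", n)   # bond indices
  for (k in seq_len(nb)) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj_n[[i]] <- c(adj_n[[i]], j); adj_e[[i]] <- c(adj_e[[i]], k)
    adj_n[[j]] <- c(adj_n[[j]], i); adj_e[[j]] <- c(adj_e[[j]], k)
  }
  disc <- integer(n); low <- integer(n)
  bridge <- logical(nb)
  timer <- 0L
  # iterative DFS with flat integer stacks (recursion-free, low overhead)
  sv <- integer(n + 1L); se <- integer(n + 1L); sp <- integer(n + 1L)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    depth <- 1L
    sv[1] <- root; se[1] <- 0L; sp[1] <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (depth > 0L) {
      v <- sv[depth]
      p <- sp[depth]
      if (p <= length(adj_n[[v]])) {
        w <- adj_n[[v]][p]; e <- adj_e[[v]][p]
        sp[depth] <- p + 1L
        if (e == se[depth]) next
        if (disc[w] != 0L) {
          if (disc[w] < low[v]) low[v] <- disc[w]
        } else {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          depth <- depth + 1L
          sv[depth] <- w; se[depth] <- e; sp[depth] <- 1L
        }
      } else {
        depth <- depth - 1L
        if (depth > 0L) {
          u <- sv[depth]
          if (low[v] < low[u]) low[u] <- low[v]
          if (low[v] > disc[u]) bridge[se[depth + 1L]] <- TRUE
        }
      }
    }
  }
  !bridge
}

# chordless cycles of length 3..maxlen restricted to the given bonds;
# used for aromatic-ring perception. Returns list of atom-index vectors.
.small_rings <- function(mol, bond_mask = NULL, maxlen = 7L) {
  bonds <- mol$bonds
  if (!is.null(bond_mask)) bonds <- bonds[bond_mask, , drop = FALSE]
  if (!nrow(bonds)) return(list())
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  has_edge <- function(a, b) b %in% adj[[a]]
  rings <- list()
  keys <- character(0)
  # DFS for simple cycles anchored at their smallest vertex
  path_search <- function(start, path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        # chordless check: no edge between non-consecutive path members
        ok <- TRUE
        L <- length(path)
        for (a in seq_len(L - 2L)) {
          for (b in seq(a + 2L, L)) {
            if (a == 1L && b == L) next
            if (has_edge(path[a], path[b])) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% keys) {
            keys[[length(keys) + 1L]] <<- key
            rings[[length(rings) + 1L]] <<- path
          }
        }
      } else if (!(w %in% path) && w > start && length(path) < maxlen) {
        path_search(start, c(path, w))
      }
    }
  }
  verts <- sort(unique(c(bonds$i, bonds$j)))
  for (s in verts) path_search(s, s)
  rings
}

# aromatic rings (atom-index vectors) from the aromatic-bond subgraph
aromatic_rings <- function(mol) {
  if (!nrow(mol$bonds)) return(list())
  .small_rings(mol, bond_mask = mol$bonds$order == 4L, maxlen = 7L)
}

#' Validate a molecule's internal consistency
#'
#' Checks bond index ranges, conformer shapes and valence plausibility.
#' Called by readers and generators; exposed for user data.
#'
#' @param mol a \code{Molecule}.
#' @return \code{TRUE} invisibly; stops with a message otherwise.
#' @export
validate_molecule <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  n <- n_atoms(mol)
  if (nrow(mol$bonds)) {
    stopifnot(all(mol$bonds$i >= 1L), all(mol$bonds$j <= n),
              all(mol$bonds$i != mol$bonds$j))
  }
  for (xyz in mol$conformers) {
    stopifnot(nrow(xyz) == n, ncol(xyz) == 3L, all(is.finite(xyz)))
  }
  val <- .default_valence[mol$atoms$element]
  if (anyNA(val))
    stop("unknown element in molecule '", mol$id, "': ",
         paste(unique(mol$atoms$element[is.na(val)]), collapse = ", "))
  invisible(TRUE)
}
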
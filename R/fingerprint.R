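# Circular (Morgan-style) fingerprints with element-based (ECFP-like) or
# functional-class (FCFP-like) atom invariants, hashed with 32-bit FNV-1a
# so bit positions are reproducible across platforms.

.fnv_offset <- 2166136261
.fnv_prime <- 16777619

# (h * prime) mod 2^32 using 16-bit limbs to stay inside double precision
.mulmod32 <- function(h) {
  h1 <- floor(h / 65536)
  h0 <- h - h1 * 65536
  (h0 * .fnv_prime + ((h1 * .fnv_prime) %% 65536) * 65536) %% 4294967296
}

# FNV-1a over a vector of non-negative 32-bit values, one xor/multiply
# round per value (32-bit units instead of bytes, for speed; fixed here
# so bit positions are reproducible across runs and platforms). The
# 16-bit limb arithmetic keeps every intermediate inside exact double
# precision.
.fnv1a <- function(values) .fnv1a_raw(values)

.fnv1a_raw <- function(values) {
  .fnv1a_vec(matrix(values, nrow = 1))
}

# vectorised variant: one FNV-1a hash per row of a tuple matrix
.fnv1a_vec <- function(m) {
  h <- rep(2166136261, nrow(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    a1 <- h %/% 65536; b1 <- v %/% 65536
    x <- bitwXor(as.integer(a1), as.integer(b1)) * 65536 +
      bitwXor(as.integer(h - a1 * 65536), as.integer(v - b1 * 65536))
    x1 <- x %/% 65536
    h <- ((x - x1 * 65536) * 16777619 +
            ((x1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

# initial per-atom invariants for the two schemes
.initial_invariants <- function(mol, scheme) {
  atoms <- mol$atoms
  deg <- .degree(mol)
  if (scheme == "element") {
    .fnv1a_vec(cbind(.atomic_number[atoms$element], atoms$charge + 16,
                     as.integer(atoms$aromatic), deg, atoms$hcount))
  } else {
    fl <- .atom_flags(mol)
    code <- fl$donor + 2 * fl$acceptor + 4 * fl$pos + 8 * fl$neg +
      16 * fl$aromatic + 32 * fl$halogen
    .fnv1a_vec(matrix(code, ncol = 1))
  }
}

#' Circular fingerprint of a molecule
#'
#' Morgan-style iterative neighbourhood hashing up to the given bond
#' diameter. The element scheme hashes (atomic number, charge, aromatic
#' flag, degree, H count); the functional-class scheme (the FCFP analogue)
#' hashes the six pharmacophoric flags donor/acceptor/positively
#' ionizable/negatively ionizable/aromatic/halogen. Each environment hash
#' is folded modulo \code{nbits} into a bit vector. Deterministic for a
#' fixed molecule, invariant under atom reordering.
#'
#' @param mol a \code{Molecule}.
#' @param diameter even non-negative bond diameter (FCFP_6 = 6).
#' @param scheme "element" or "functional-class".
#' @param nbits fingerprint length, a power of two.
#' @return object of class \code{Fingerprint}: list with \code{bits}
#'   (sorted 1-based positions of set bits), \code{nbits}, \code{scheme},
#'   \code{diameter}.
#' @export
circular_fingerprint <- function(mol, diameter = 6L,
                                 scheme = c("functional-class", "element"),
                                 nbits = 2048L) {
  scheme <- scheme[1]
  if (!scheme %in% c("functional-class", "element"))
    stop("unknown fingerprint scheme: ", scheme)
  stopifnot(diameter >= 0L, diameter %% 2L == 0L)
  if (nbits < 1L || bitwAnd(as.integer(nbits), as.integer(nbits) - 1L) != 0L)
    stop("nbits must be a power of two, got ", nbits)
  inv <- .initial_invariants(mol, scheme)
  adj <- .adjacency(mol)
  all_hashes <- inv
  n_iter <- diameter %/% 2L
  deg <- .degree(mol)
  if (n_iter > 0L) for (r in seq_len(n_iter)) {
    new_inv <- numeric(n_atoms(mol))
    # atoms with equal degree share a tuple length: hash them as a block
    for (d in unique(deg)) {
      vs <- which(deg == d)
      if (d == 0L) {
        new_inv[vs] <- .fnv1a_vec(cbind(r, inv[vs]))
        next
      }
      tuples <- t(vapply(vs, function(v) {
        nb <- adj[[v]]
        ords <- nb[, "order"]; nin <- inv[nb[, "nbr"]]
        # sort neighbour (order, invariant) pairs by a single exact key
        o <- order(nin * 8 + ords)
        c(r, inv[v], as.vector(rbind(ords[o], nin[o])))
      }, numeric(2 + 2 * d)))
      new_inv[vs] <- .fnv1a_vec(tuples)
    }
    inv <- new_inv
    all_hashes <- c(all_hashes, inv)
  }
  bits <- sort(unique(all_hashes %% nbits)) + 1L
  structure(list(bits = as.integer(bits), nbits = as.integer(nbits),
                 scheme = scheme, diameter = as.integer(diameter)),
            class = "Fingerprint")
}

#' @export
print.Fingerprint <- function(x, ...) {
  cat("<Fingerprint> ", x$scheme, " diameter ", x$diameter, ", ",
      length(x$bits), "/", x$nbits, " bits set\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over set bits. Two all-zero fingerprints
#' compare as 1 by convention (a message notes it).
#'
#' @param a,b \code{Fingerprint} objects of equal length and scheme.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "Fingerprint"), inherits(b, "Fingerprint"))
  if (a$nbits != b$nbits || a$scheme != b$scheme)
    stop("fingerprints differ in length or scheme")
  if (!length(a$bits) && !length(b$bits)) {
    message("tanimoto: both fingerprints empty; returning 1 by convention")
    return(1)
  }
  inter <- length(intersect(a$bits, b$bits))
  inter / (length(a$bits) + length(b$bits) - inter)
}
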
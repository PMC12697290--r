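# The eight physicochemical descriptors used for chemical-space analysis
# and decoy property matching: ALogP, MW, HBD, HBA, rotatable bonds, ring
# count, aromatic ring count, fractional polar surface area.

.atomic_mass <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.086, P = 30.974, S = 32.06,
                  Cl = 35.453, Br = 79.904, I = 126.904)

# atom-contribution logP, Crippen-style coarse classes (published
# contribution magnitudes, collapsed to a compact class table)
.logp_contrib <- function(atoms, bonds, adj) {
  n <- nrow(atoms)
  out <- numeric(n)
  for (v in seq_len(n)) {
    el <- atoms$element[v]
    nb <- adj[[v]]
    nbr_el <- if (nrow(nb)) atoms$element[nb[, "nbr"]] else character(0)
    het_nbr <- any(!nbr_el %in% c("C", "H"))
    out[v] <- switch(el,
      C = if (atoms$aromatic[v]) 0.2955
          else if (het_nbr) -0.2035 else 0.1441,
      N = if (atoms$aromatic[v]) -0.3239
          else if (atoms$charge[v] > 0L) -1.95 else -1.0190,
      O = if (atoms$aromatic[v]) 0.0335
          else if (atoms$charge[v] < 0L) -1.326
          else if (any(nb[, "order"] >= 2L)) -0.1526 else -0.2893,
      S = 0.6482, P = 0.8612,
      F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
      B = 0.05, Si = 0.1,
      0)
    # implicit hydrogens: H on carbon adds, H on heteroatom subtracts
    hpar <- if (el == "C") 0.1230 else -0.2677
    out[v] <- out[v] + atoms$hcount[v] * hpar
  }
  sum(out)
}

# Ertl-style topological polar surface area contributions (A^2),
# keyed on element / aromaticity / H count / charge / max bond order
.tpsa_contrib <- function(atoms, bonds, adj) {
  n <- nrow(atoms)
  total <- 0
  for (v in seq_len(n)) {
    el <- atoms$element[v]
    if (!el %in% c("N", "O", "S", "P")) next
    nb <- adj[[v]]
    maxord <- if (nrow(nb)) max(nb[, "order"]) else 0L
    h <- atoms$hcount[v]; chg <- atoms$charge[v]; arom <- atoms$aromatic[v]
    contrib <- if (el == "N") {
      if (arom) { if (h >= 1L) 15.79 else 12.89 }
      else if (chg > 0L) { if (h >= 3L) 27.64 else if (h == 2L) 16.61 else 4.44 }
      else if (h >= 2L) 26.02
      else if (h == 1L) 12.03
      else if (maxord >= 2L) 12.36
      else 3.24
    } else if (el == "O") {
      if (arom) 13.14
      else if (chg < 0L) 23.06
      else if (h >= 1L) 20.23
      else if (maxord >= 2L) 17.07
      else 9.23
    } else if (el == "S") {
      if (arom) 28.24 else if (h >= 1L) 38.80
      else if (maxord >= 2L) 32.09 else 25.30
    } else { # P
      13.59
    }
    total <- total + contrib
  }
  total
}

# element surface increments for the fractional-PSA denominator: a
# deterministic atom-count-weighted estimate of total topological surface
.surface_increment <- c(C = 12, N = 11, O = 10, S = 16, P = 16,
                        F = 9, Cl = 15, Br = 18, I = 21, B = 13, Si = 17)

.is_amide_n <- function(v, atoms, adj) {
  if (atoms$element[v] != "N" || atoms$aromatic[v]) return(FALSE)
  nb <- adj[[v]]
  if (!nrow(nb)) return(FALSE)
  for (k in seq_len(nrow(nb))) {
    if (nb[k, "order"] != 1L) next
    c_at <- nb[k, "nbr"]
    if (atoms$element[c_at] != "C") next
    cnb <- adj[[c_at]]
    if (any(cnb[, "order"] == 2L & atoms$element[cnb[, "nbr"]] == "O"))
      return(TRUE)
  }
  FALSE
}

#' Compute the eight-descriptor vector of a molecule
#'
#' Returns ALogP (atom-contribution log partition coefficient), molecular
#' weight (implicit hydrogens included), hydrogen-bond donor and acceptor
#' counts, rotatable-bond count (single, acyclic, non-terminal, non-amide),
#' ring count (cyclomatic), aromatic ring count, and fractional polar
#' surface area (topological PSA over an element-increment total-surface
#' estimate, capped at 1).
#'
#' @param mol a \code{Molecule}.
#' @return a one-row data.frame of class \code{DescriptorVector} with
#'   columns alogp, mw, n_hbd, n_hba, n_rotb, n_rings, n_arom_rings, fpsa.
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  out <- as.data.frame(as.list(.descriptor_values(mol)))
  out$n_hbd <- as.integer(out$n_hbd); out$n_hba <- as.integer(out$n_hba)
  out$n_rotb <- as.integer(out$n_rotb)
  out$n_rings <- as.integer(out$n_rings)
  out$n_arom_rings <- as.integer(out$n_arom_rings)
  class(out) <- c("DescriptorVector", class(out))
  out
}

.descriptor_values <- function(mol) {
  atoms <- mol$atoms; bonds <- mol$bonds
  el <- atoms$element; chg <- atoms$charge; arom <- atoms$aromatic
  hc <- atoms$hcount
  n <- length(el)
  badel <- setdiff(unique(el), names(.atomic_mass))
  if (length(badel))
    stop("unknown element(s) in molecule '", mol$id, "': ",
         paste(badel, collapse = ", "))
  bi <- bonds$i; bj <- bonds$j; bo <- bonds$order
  deg <- tabulate(c(bi, bj), nbins = n)
  # per-atom bond aggregates
  maxord <- integer(n)
  nbr_not_c <- logical(n)
  if (length(bi)) {
    for (k in seq_along(bi)) {
      if (bo[k] > maxord[bi[k]]) maxord[bi[k]] <- bo[k]
      if (bo[k] > maxord[bj[k]]) maxord[bj[k]] <- bo[k]
    }
    nc <- el != "C"
    nbr_not_c[bi[nc[bj]]] <- TRUE
    nbr_not_c[bj[nc[bi]]] <- TRUE
  }
  # carbonyl carbons and amide nitrogens, from the bond list
  dbl_o <- logical(n)   # atom has a double bond to O
  if (length(bi)) {
    sel <- bo == 2L & el[bj] == "O"; dbl_o[bi[sel]] <- TRUE
    sel <- bo == 2L & el[bi] == "O"; dbl_o[bj[sel]] <- TRUE
  }
  carbonyl_c <- el == "C" & dbl_o
  amide_n <- logical(n)
  if (length(bi)) {
    sel <- bo == 1L & el[bi] == "N" & !arom[bi] & carbonyl_c[bj]
    amide_n[bi[sel]] <- TRUE
    sel <- bo == 1L & el[bj] == "N" & !arom[bj] & carbonyl_c[bi]
    amide_n[bj[sel]] <- TRUE
  }
  mw <- sum(.atomic_mass[el]) + sum(hc) * 1.008
  # ALogP: vectorised atom-class contributions
  lp <- numeric(n)
  isC <- el == "C"; isN <- el == "N"; isO <- el == "O"
  lp[isC] <- ifelse(arom[isC], 0.2955,
                    ifelse(nbr_not_c[isC], -0.2035, 0.1441))
  lp[isN] <- ifelse(arom[isN], -0.3239,
                    ifelse(chg[isN] > 0L, -1.95, -1.0190))
  lp[isO] <- ifelse(arom[isO], 0.0335,
                    ifelse(chg[isO] < 0L, -1.326,
                           ifelse(maxord[isO] >= 2L, -0.1526, -0.2893)))
  other <- c(S = 0.6482, P = 0.8612, F = 0.4202, Cl = 0.6895,
             Br = 0.8456, I = 0.8857, B = 0.05, Si = 0.1)
  rest <- !(isC | isN | isO)
  lp[rest] <- other[el[rest]]
  alogp <- sum(lp) + sum(hc * ifelse(isC, 0.1230, -0.2677))
  # TPSA: vectorised Ertl-style contributions for N/O/S/P
  tp <- numeric(n)
  tp[isN] <- ifelse(arom[isN], ifelse(hc[isN] >= 1L, 15.79, 12.89),
             ifelse(chg[isN] > 0L,
                    ifelse(hc[isN] >= 3L, 27.64,
                           ifelse(hc[isN] == 2L, 16.61, 4.44)),
             ifelse(hc[isN] >= 2L, 26.02,
             ifelse(hc[isN] == 1L, 12.03,
                    ifelse(maxord[isN] >= 2L, 12.36, 3.24)))))
  tp[isO] <- ifelse(arom[isO], 13.14,
             ifelse(chg[isO] < 0L, 23.06,
             ifelse(hc[isO] >= 1L, 20.23,
                    ifelse(maxord[isO] >= 2L, 17.07, 9.23))))
  isS <- el == "S"
  tp[isS] <- ifelse(arom[isS], 28.24,
             ifelse(hc[isS] >= 1L, 38.80,
                    ifelse(maxord[isS] >= 2L, 32.09, 25.30)))
  tp[el == "P"] <- 13.59
  tpsa <- sum(tp)
  surf <- sum(.surface_increment[el]) + 6 * sum(hc)
  fpsa <- min(1, tpsa / surf)
  is_no <- isN | isO
  n_hbd <- sum(is_no & hc >= 1L & chg >= 0L)
  pyrrole_n <- isN & arom & hc >= 1L
  n_hba <- sum(isO | (isN & !amide_n & !pyrrole_n & chg <= 0L))
  # rotatable: single, acyclic, both ends heavy-degree >= 2, not amide C-N
  n_rotb <- 0L
  if (length(bi)) {
    ring <- .ring_bonds(mol)
    amide_bond <- (amide_n[bi] & carbonyl_c[bj]) |
                  (amide_n[bj] & carbonyl_c[bi])
    n_rotb <- sum(bo == 1L & !ring & deg[bi] >= 2L & deg[bj] >= 2L &
                    !amide_bond)
  }
  ncomp <- length(.components(mol))
  n_rings <- length(bi) - n + ncomp
  ar_mask <- bo == 4L
  if (any(ar_mask)) {
    # cyclomatic count of the aromatic-bond subgraph only
    abi <- bi[ar_mask]; abj <- bj[ar_mask]
    ar_atoms <- sort(unique(c(abi, abj)))
    aadj <- vector("list", n)
    for (k in seq_along(abi)) {
      aadj[[abi[k]]] <- c(aadj[[abi[k]]], abj[k])
      aadj[[abj[k]]] <- c(aadj[[abj[k]]], abi[k])
    }
    seen <- logical(n); ar_comp <- 0L
    for (s in ar_atoms) {
      if (seen[s]) next
      ar_comp <- ar_comp + 1L
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        new <- aadj[[v]][!seen[aadj[[v]]]]
        seen[new] <- TRUE; queue <- c(queue, new)
      }
    }
    n_arom_rings <- sum(ar_mask) - length(ar_atoms) + ar_comp
  } else n_arom_rings <- 0L
  c(alogp = alogp, mw = unname(mw), n_hbd = n_hbd, n_hba = n_hba,
    n_rotb = as.integer(n_rotb), n_rings = n_rings,
    n_arom_rings = n_arom_rings, fpsa = unname(fpsa))
}

#' Descriptor matrix for a list of molecules
#' @param mols list of \code{Molecule}.
#' @return data.frame, one row per molecule, rownames = molecule ids.
#' @export
descriptor_matrix <- function(mols) {
  m <- t(vapply(mols, .descriptor_values, numeric(8)))
  out <- as.data.frame(m)
  rownames(out) <- vapply(mols, function(mm) mm$id, "")
  out
}

# net formal charge, used for decoy charge matching
net_charge <- function(mol) sum(mol$atoms$charge)
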
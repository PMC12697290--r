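# Chemical feature perception shared by the functional-class fingerprint
# and the pharmacophore module: donors, acceptors, ionizable groups,
# hydrophobic fragments, aromatic rings.

# per-atom logical flags
.atom_flags <- function(mol, adj = .adjacency(mol)) {
  atoms <- mol$atoms
  n <- nrow(atoms)
  amide_n <- vapply(seq_len(n), .is_amide_n, TRUE, atoms = atoms, adj = adj)
  donor <- atoms$element %in% c("N", "O") & atoms$hcount >= 1L & atoms$charge >= 0L
  pyrrole_n <- atoms$element == "N" & atoms$aromatic & atoms$hcount >= 1L
  acceptor <- (atoms$element == "O" & atoms$charge <= 0L) |
    (atoms$element == "N" & !amide_n & !pyrrole_n & atoms$charge <= 0L)
  halogen <- atoms$element %in% c("F", "Cl", "Br", "I")
  neg_atoms <- unique(unlist(.neg_ionizable_groups(mol, adj)))
  pos_atoms <- unique(unlist(.pos_ionizable_groups(mol, adj)))
  neg <- seq_len(n) %in% neg_atoms | atoms$charge < 0L
  pos <- seq_len(n) %in% pos_atoms | atoms$charge > 0L
  list(donor = donor, acceptor = acceptor, pos = pos, neg = neg,
       aromatic = atoms$aromatic, halogen = halogen)
}

# negative-ionizable groups: carboxylate/carboxylic acid, sulfonate,
# phosphate/phosphonate. Returns list of atom-index vectors.
.neg_ionizable_groups <- function(mol, adj = .adjacency(mol)) {
  atoms <- mol$atoms
  groups <- list()
  for (v in seq_len(nrow(atoms))) {
    el <- atoms$element[v]
    if (!el %in% c("C", "S", "P")) next
    nb <- adj[[v]]
    if (!nrow(nb)) next
    o_dbl <- nb[nb[, "order"] == 2L &
                  atoms$element[nb[, "nbr"]] == "O", "nbr"]
    o_sng <- nb[nb[, "order"] == 1L &
                  atoms$element[nb[, "nbr"]] == "O", "nbr"]
    # terminal single-bonded O (charged or protonated hydroxyl)
    o_sng <- o_sng[.degree(mol)[o_sng] == 1L]
    ok <- (el == "C" && length(o_dbl) >= 1L && length(o_sng) >= 1L) ||
          (el == "S" && length(o_dbl) >= 2L && length(o_sng) >= 1L) ||
          (el == "P" && length(o_dbl) >= 1L && length(o_sng) >= 1L)
    if (ok) groups[[length(groups) + 1L]] <- sort(c(v, o_dbl, o_sng))
  }
  groups
}

# positive-ionizable groups: aliphatic amines (primary/secondary/tertiary,
# not amide, not aromatic), amidine/guanidine carbons with their nitrogens,
# and any formally positive nitrogen.
.pos_ionizable_groups <- function(mol, adj = .adjacency(mol)) {
  atoms <- mol$atoms
  groups <- list()
  claimed <- logical(nrow(atoms))
  for (v in seq_len(nrow(atoms))) {
    if (atoms$element[v] != "C") next
    nb <- adj[[v]]
    if (!nrow(nb)) next
    n_dbl <- nb[nb[, "order"] == 2L & atoms$element[nb[, "nbr"]] == "N", "nbr"]
    n_sng <- nb[nb[, "order"] == 1L & atoms$element[nb[, "nbr"]] == "N", "nbr"]
    if (length(n_dbl) >= 1L && length(n_sng) >= 1L) {
      grp <- sort(c(v, n_dbl, n_sng))
      groups[[length(groups) + 1L]] <- grp
      claimed[grp] <- TRUE
    }
  }
  for (v in seq_len(nrow(atoms))) {
    if (claimed[v]) next
    if (atoms$element[v] != "N") next
    if (atoms$charge[v] > 0L) {
      groups[[length(groups) + 1L]] <- v
      next
    }
    if (atoms$aromatic[v]) next
    nb <- adj[[v]]
    if (nrow(nb) && any(nb[, "order"] > 1L)) next
    if (.is_amide_n(v, atoms, adj)) next
    # basic aliphatic amine: all neighbors sp3-like carbons
    nbr <- nb[, "nbr"]
    if (length(nbr) && all(atoms$element[nbr] == "C" & !atoms$aromatic[nbr]))
      groups[[length(groups) + 1L]] <- v
  }
  groups
}

# hydrophobic fragments: connected sets of >=3 non-aromatic carbons none
# of which touches a heteroatom (the package's rule; purely aromatic
# carbons belong to ring features instead)
.hydrophobic_fragments <- function(mol) {
  atoms <- mol$atoms
  adj <- .adjacency(mol)
  cand <- which(atoms$element == "C" & !atoms$aromatic)
  cand <- cand[vapply(cand, function(v) {
    nb <- adj[[v]]
    !nrow(nb) || all(atoms$element[nb[, "nbr"]] %in% c("C"))
  }, TRUE)]
  comps <- .components(mol, keep = cand)
  comps[vapply(comps, length, 1L) >= 3L]
}
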
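# Shared fixture builders: all fixtures are constructed in code.

# regular hexagon coordinates (benzene-like ring), radius 1.39 A
hexagon_coords <- function(radius = 1.39) {
  ang <- 2 * pi * (0:5) / 6
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

benzene_mol <- function(id = "benzene") {
  m <- parse_smiles("c1ccccc1", id)
  m$conformers <- list(hexagon_coords())
  m
}

# apply a rigid motion (rotation about z by theta + shift)
rigid_move <- function(xyz, theta = 0.7, shift = c(3, -2, 5)) {
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, byrow = TRUE)
  xyz %*% t(rot) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}

# atom-permuted deep copy of a molecule (perm[new] = old index)
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  bonds <- mol$bonds
  bonds$i <- inv[bonds$i]; bonds$j <- inv[bonds$j]
  confs <- lapply(mol$conformers, function(x) x[perm, , drop = FALSE])
  molecule(paste0(mol$id, "_perm"), atoms, bonds, confs)
}

# synthetic PDB text: n CA atoms on a helix-like curve, optional ligand
write_helix_pdb <- function(path, n = 10, ligand_atoms = 0, altloc = FALSE) {
  lines <- character(0)
  serial <- 0
  ca_line <- function(serial, resno, alt, x, y, z) sprintf(
    "ATOM  %5d  CA %s%s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    serial, alt, "ALA", resno, x, y, z)
  for (i in seq_len(n)) {
    serial <- serial + 1
    if (altloc && i == 2) {
      # residue with A/B alternates: only A must be retained
      lines <- c(lines, ca_line(serial, i, "A", 2.3 * cos(i), 2.3 * sin(i),
                                1.5 * i))
      serial <- serial + 1
      lines <- c(lines, ca_line(serial, i, "B", 99, 99, 99))
    } else {
      lines <- c(lines, ca_line(serial, i, " ", 2.3 * cos(i), 2.3 * sin(i),
                                1.5 * i))
    }
  }
  lines <- c(lines, "TER")
  for (j in seq_len(ligand_atoms)) {
    serial <- serial + 1
    lines <- c(lines, sprintf(
      "HETATM%5d  C%-2d LIG A 900    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, j, 1.0 * j, 0.5 * j, 0.0))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

# tiny labelled score-table fixture
toy_score_table <- function(n1 = 30, n0 = 70, delta = 2, seed = 1) {
  gen_score_table(score_sim_spec(n_active = n1, n_decoy = n0,
                                 feature_ids = "S1", active_mean = -7 - delta,
                                 decoy_mean = -7, sd = 1, rho = 0,
                                 seed = seed))
}

# brute-force k-medoids: exhaustive over all k-subsets of medoids
brute_kmedoids_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
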
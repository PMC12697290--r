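# File I/O: SDF (through ChemmineR), PDB (through bio3d), plus the
# StructureModel container for protein conformations.

.charge_from_code <- function(code) {
  # V2000 atom-block charge codes
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

.code_from_charge <- function(charge) {
  map <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
           `-1` = 5L, `-2` = 6L, `-3` = 7L)
  out <- map[as.character(charge)]
  out[is.na(out)] <- 0L
  unname(out)
}

# one ChemmineR SDF record -> Molecule pieces (pre H-folding)
.sdf_record_to_molecule <- function(sdf, fold_hydrogens = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  xyz <- unname(ab[, 1:3, drop = FALSE])
  chg_codes <- if ("C6" %in% colnames(ab)) ab[, "C6"]
               else if (ncol(ab) >= 5) ab[, 5] else rep(0, nrow(ab))
  chg <- .charge_from_code(chg_codes)
  if (is.null(dim(bb)) && length(bb)) bb <- matrix(bb, nrow = 1)
  if (is.null(bb) || !length(bb)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  aromatic <- logical(length(el))
  if (nrow(bonds)) {
    ar_atoms <- unique(c(bonds$i[bonds$order == 4L], bonds$j[bonds$order == 4L]))
    aromatic[ar_atoms] <- TRUE
  }
  if (fold_hydrogens && any(el == "H")) {
    hidx <- which(el == "H")
    hcount <- integer(length(el))
    for (k in seq_len(nrow(bonds))) {
      if (el[bonds$i[k]] == "H" && el[bonds$j[k]] != "H")
        hcount[bonds$j[k]] <- hcount[bonds$j[k]] + 1L
      if (el[bonds$j[k]] == "H" && el[bonds$i[k]] != "H")
        hcount[bonds$i[k]] <- hcount[bonds$i[k]] + 1L
    }
    keep <- setdiff(seq_along(el), hidx)
    remap <- match(seq_along(el), keep)
    bonds <- bonds[!(bonds$i %in% hidx) & !(bonds$j %in% hidx), , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- data.frame(element = el[keep], charge = chg[keep],
                        aromatic = aromatic[keep])
    # explicit H folded in on top of the valence-implied count
    atoms$hcount <- implicit_h_counts(atoms, bonds)
    expl <- hcount[keep]
    atoms$hcount <- pmax(atoms$hcount, expl)
    xyz <- xyz[keep, , drop = FALSE]
  } else {
    atoms <- data.frame(element = el, charge = chg, aromatic = aromatic)
  }
  props <- tryCatch(ChemmineR::datablock(sdf), error = function(e) character(0))
  list(atoms = atoms, bonds = bonds, xyz = xyz, props = props)
}

#' Read an SDF file into molecules
#'
#' Parses a V2000 SD file via ChemmineR. Consecutive or non-consecutive
#' records sharing a molecule title are merged into one \code{Molecule}
#' with one conformer per record; record-level data fields are kept in
#' \code{$props} (a list parallel to the conformer list). Explicit
#' hydrogens are folded into implicit counts by default.
#'
#' @param path SDF file path.
#' @param fold_hydrogens fold explicit H atoms into heavy-atom counts.
#' @return list of \code{Molecule}; empty list for an empty file.
#' @export
read_sdf <- function(path, fold_hydrogens = TRUE) {
  stopifnot(file.exists(path))
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || all(!nzchar(trimws(txt)))) return(list())
  sdfset <- ChemmineR::read.SDFset(path)
  ids <- vapply(seq_along(ChemmineR::cid(sdfset)), function(k) {
    h <- ChemmineR::header(sdfset[[k]])
    nm <- trimws(h[["Molecule_Name"]])
    if (!nzchar(nm)) paste0("record_", k) else nm
  }, "")
  out <- list()
  for (k in seq_along(ids)) {
    rec <- tryCatch(
      .sdf_record_to_molecule(sdfset[[k]], fold_hydrogens = fold_hydrogens),
      error = function(e) stop("malformed SDF record ", k, " ('", ids[k],
                               "'): ", conditionMessage(e)))
    id <- ids[k]
    if (is.null(out[[id]])) {
      mol <- molecule(id, rec$atoms, rec$bonds,
                      conformers = list(rec$xyz))
      mol$props <- list(rec$props)
      out[[id]] <- mol
    } else {
      if (nrow(rec$atoms) != n_atoms(out[[id]]))
        stop("malformed SDF record ", k, " ('", id,
             "'): atom count differs from earlier record with the same id")
      out[[id]]$conformers <- c(out[[id]]$conformers, list(rec$xyz))
      out[[id]]$props <- c(out[[id]]$props, list(rec$props))
    }
  }
  unname(out)
}

.molecule_to_sdf_records <- function(mol) {
  n <- n_atoms(mol)
  confs <- mol$conformers
  if (!length(confs)) confs <- list(matrix(0, n, 3))
  lapply(seq_along(confs), function(ci) {
    ab <- matrix(0, n, 15,
                 dimnames = list(paste(mol$atoms$element, seq_len(n), sep = "_"),
                                 c("C1", "C2", "C3", paste0("C", 5:16))))
    # 4-decimal rounding matches the V2000 coordinate precision and keeps
    # the writer in fixed (non-scientific) notation
    ab[, 1:3] <- round(confs[[ci]], 4)
    ab[, "C6"] <- .code_from_charge(mol$atoms$charge)
    nb <- nrow(mol$bonds)
    bb <- matrix(0L, nb, 3, dimnames = list(NULL, c("C1", "C2", "C3")))
    if (nb) bb[] <- cbind(mol$bonds$i, mol$bonds$j, mol$bonds$order)
    db <- character(0)
    if (!is.null(mol$props) && length(mol$props) >= ci && length(mol$props[[ci]]))
      db <- mol$props[[ci]]
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
    methods::new("SDF",
                 header = c(Molecule_Name = mol$id, Source = "evscreen",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
}

#' Write molecules to an SDF file
#'
#' One record per conformer (molecules without conformers get a single
#' zero-coordinate record). Coordinates are written at 4 decimals, the
#' V2000 standard, so a write/read round trip preserves them exactly at
#' that precision.
#'
#' @param mols list of \code{Molecule} (or a single one).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  recs <- unlist(lapply(mols, .molecule_to_sdf_records))
  sdfset <- ChemmineR::SDFset(SDFlist = recs)
  ChemmineR::cid(sdfset) <- make.unique(vapply(recs, function(r)
    ChemmineR::header(r)[["Molecule_Name"]], ""))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Protein conformation container
#'
#' Holds one crystal-structure conformation: C-alpha trace, residue
#' labels, optionally the bound active-site ligand and the protein heavy
#' atoms (used for complex-based pharmacophore derivation).
#'
#' @param id structure identifier (e.g. a PDB entry code).
#' @param ca_coords numeric n_residues x 3 matrix of C-alpha coordinates.
#' @param residue_labels data.frame with columns \code{chain},
#'   \code{resno}, one row per residue.
#' @param ligand optional \code{Molecule} bound at the active site.
#' @param protein_atoms optional data.frame of protein heavy atoms
#'   (columns element, x, y, z, resid, elety).
#' @return object of class \code{StructureModel}.
#' @export
structure_model <- function(id, ca_coords, residue_labels = NULL,
                            ligand = NULL, protein_atoms = NULL) {
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  stopifnot(ncol(ca_coords) == 3L, all(is.finite(ca_coords)))
  n <- nrow(ca_coords)
  if (is.null(residue_labels))
    residue_labels <- data.frame(chain = rep("A", n), resno = seq_len(n))
  stopifnot(nrow(residue_labels) == n)
  structure(list(id = id, ca_coords = unname(ca_coords),
                 residue_labels = residue_labels, ligand = ligand,
                 protein_atoms = protein_atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("<StructureModel> ", x$id, ": ", nrow(x$ca_coords), " residues",
      if (!is.null(x$ligand)) paste0(", ligand '", x$ligand$id, "' (",
                                     n_atoms(x$ligand), " atoms)"),
      "\n", sep = "")
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses coordinate records via bio3d, keeping the first model and first
#' alternate location. The C-alpha trace defines the conformation; when
#' \code{ligand_resname} is given, matching HETATM heavy atoms become the
#' bound-ligand \code{Molecule} (connectivity-free: PDB carries no bond
#' block in scope here).
#'
#' @param path PDB file path.
#' @param ligand_resname residue name of the bound ligand, or NULL.
#' @return a \code{StructureModel}.
#' @export
read_pdb_structure <- function(path, ligand_resname = NULL) {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  # bio3d with rm.alt=TRUE already keeps first altLoc; be explicit anyway
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no C-alpha atoms in ", path)
  prot <- at[at$type == "ATOM" & (is.na(at$elesy) | at$elesy != "H"), ,
             drop = FALSE]
  protein_atoms <- data.frame(element = ifelse(is.na(prot$elesy) | !nzchar(prot$elesy),
                                               substr(trimws(prot$elety), 1, 1),
                                               prot$elesy),
                              x = prot$x, y = prot$y, z = prot$z,
                              resid = prot$resid, elety = prot$elety)
  ligand <- NULL
  if (!is.null(ligand_resname)) {
    lig <- at[at$type == "HETATM" & at$resid == ligand_resname, , drop = FALSE]
    lig <- lig[is.na(lig$elesy) | lig$elesy != "H", , drop = FALSE]
    if (nrow(lig)) {
      el <- ifelse(is.na(lig$elesy) | !nzchar(lig$elesy),
                   substr(trimws(lig$elety), 1, 1), lig$elesy)
      ligand <- molecule(ligand_resname,
                         data.frame(element = el, charge = 0L,
                                    aromatic = FALSE, hcount = 0L),
                         conformers = list(cbind(lig$x, lig$y, lig$z)))
    }
  }
  id <- sub("\\.pdb$", "", basename(path))
  structure_model(id, cbind(ca$x, ca$y, ca$z),
                  data.frame(chain = ca$chain, resno = ca$resno),
                  ligand = ligand, protein_atoms = protein_atoms)
}
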
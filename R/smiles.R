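# SMILES subset reader/writer.
#
# Supported: organic-subset atoms (B C N O P S F Cl Br I), aromatic
# lowercase (b c n o p s), bracket atoms with explicit H count and formal
# charge, bond symbols - = # :, branches, ring-bond closures (digits and
# %nn). Not supported (out of scope): stereochemistry, isotopes,
# multi-component dots.

.organic_elements <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")

#' Parse a SMILES string into a Molecule
#'
#' Covers the connectivity subset used by the package's CSV interfaces:
#' rings, branches, charges and aromaticity. Molecules built from SMILES
#' carry no conformer and support 2D operations only (descriptors,
#' fingerprints, benchmark assembly).
#'
#' @param smiles SMILES string.
#' @param id identifier for the resulting molecule (default the string).
#' @return a \code{Molecule} with zero conformers.
#' @export
parse_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  el <- character(0); ar <- logical(0); ch <- integer(0); hc <- integer(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  prev_stack <- integer(0)   # branch stack
  prev <- 0L                 # last atom index, 0 = none
  pending_bond <- NA_integer_
  ring_open <- list()        # label -> c(atom, order)
  pos <- 1L
  add_atom <- function(sym, aromatic, charge, hcount) {
    el[length(el) + 1L] <<- sym
    ar[length(ar) + 1L] <<- aromatic
    ch[length(ch) + 1L] <<- charge
    hc[length(hc) + 1L] <<- hcount
    idx <- length(el)
    if (prev > 0L) {
      ord <- pending_bond
      if (is.na(ord)) ord <- if (ar[prev] && aromatic) 4L else 1L
      bi[length(bi) + 1L] <<- prev; bj[length(bj) + 1L] <<- idx
      bo[length(bo) + 1L] <<- ord
    }
    pending_bond <<- NA_integer_
    prev <<- idx
    idx
  }
  close_ring <- function(label) {
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      ord <- pending_bond
      if (is.na(ord)) ord <- op[2]
      if (is.na(ord)) ord <- if (ar[op[1]] && ar[prev]) 4L else 1L
      bi[length(bi) + 1L] <<- op[1]; bj[length(bj) + 1L] <<- prev
      bo[length(bo) + 1L] <<- as.integer(ord)
      ring_open[[label]] <<- NULL
    } else {
      ring_open[[label]] <<- c(prev, pending_bond)
    }
    pending_bond <<- NA_integer_
  }
  while (pos <= n) {
    c1 <- chars[pos]
    two <- if (pos < n) paste0(c1, chars[pos + 1L]) else ""
    if (c1 == "(") {
      prev_stack <- c(prev_stack, prev); pos <- pos + 1L
    } else if (c1 == ")") {
      if (!length(prev_stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      pos <- pos + 1L
    } else if (c1 == "-") { pending_bond <- 1L; pos <- pos + 1L
    } else if (c1 == "=") { pending_bond <- 2L; pos <- pos + 1L
    } else if (c1 == "#") { pending_bond <- 3L; pos <- pos + 1L
    } else if (c1 == ":") { pending_bond <- 4L; pos <- pos + 1L
    } else if (grepl("[0-9]", c1)) {
      close_ring(c1); pos <- pos + 1L
    } else if (c1 == "%") {
      if (pos + 2L > n) stop("truncated %nn ring label in SMILES: ", smiles)
      close_ring(paste0(chars[pos + 1L], chars[pos + 2L])); pos <- pos + 3L
    } else if (c1 == "[") {
      close_pos <- pos
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > n) stop("unclosed '[' in SMILES: ", smiles)
      body <- substr(smiles, pos + 1L, close_pos - 1L)
      m <- regmatches(body,
        regexec("^([A-Za-z][a-z]?)(H([0-9]?))?([+-]+[0-9]*|[+-][0-9]*)?$", body))[[1]]
      if (!length(m)) stop("unsupported bracket atom [", body, "] in: ", smiles)
      sym <- m[2]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      if (aromatic) sym <- toupper(sym)
      hcount <- if (nzchar(m[3])) { if (nzchar(m[4])) as.integer(m[4]) else 1L } else 0L
      charge <- 0L
      if (nzchar(m[5])) {
        cs <- m[5]
        sgn <- if (substr(cs, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", cs)
        charge <- if (nzchar(digits)) sgn * as.integer(digits)
                  else sgn * nchar(gsub("[^+-]", "", cs))
      }
      add_atom(sym, aromatic, charge, hcount)
      pos <- close_pos + 1L
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE, 0L, NA_integer_); pos <- pos + 2L
    } else if (c1 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(c1, FALSE, 0L, NA_integer_); pos <- pos + 1L
    } else if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(c1), TRUE, 0L, NA_integer_); pos <- pos + 1L
    } else {
      stop("unsupported SMILES token '", c1, "' at position ", pos, " in: ", smiles)
    }
  }
  if (length(prev_stack)) stop("unbalanced '(' in SMILES: ", smiles)
  open_labels <- names(ring_open)[!vapply(ring_open, is.null, TRUE)]
  if (length(open_labels)) stop("unclosed ring bond(s) in SMILES: ", smiles)
  atoms <- data.frame(element = el, charge = ch, aromatic = ar, hcount = hc)
  bonds <- data.frame(i = bi, j = bj, order = bo)
  # fill implicit H where not given by a bracket atom
  miss <- is.na(atoms$hcount)
  if (any(miss)) {
    auto <- implicit_h_counts(atoms, bonds)
    atoms$hcount[miss] <- auto[miss]
  }
  molecule(id, atoms, bonds, smiles = smiles)
}

#' Write a Molecule as a SMILES string
#'
#' Generic depth-first writer with numeric ring-closure labels; aromatic
#' atoms are emitted lowercase with aromatic ring bonds implicit. No
#' stereochemistry is emitted.
#'
#' @param mol a \code{Molecule}.
#' @return SMILES string.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "Molecule"))
  n <- n_atoms(mol)
  if (n == 0L) stop("empty molecule")
  adj <- .adjacency(mol)
  visited <- logical(n)
  ring_label <- 0L
  closures <- vector("list", n)  # atom -> list of c(label, order)
  bond_used <- new.env(hash = TRUE)
  bkey <- function(a, b) paste(min(a, b), max(a, b))
  atom_token <- function(v) {
    a <- mol$atoms[v, ]
    needs_bracket <- a$charge != 0L ||
      (!a$element %in% .organic_elements)
    sym <- a$element
    if (a$aromatic) sym <- tolower(sym)
    if (!needs_bracket) return(sym)
    hstr <- if (a$hcount == 0L) "" else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
    cstr <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else
            if (a$charge == -1L) "-" else sprintf("%+d", a$charge)
    paste0("[", sym, hstr, cstr, "]")
  }
  bond_token <- function(order, a, b) {
    if (order == 1L) {
      if (mol$atoms$aromatic[a] && mol$atoms$aromatic[b]) "-" else ""
    } else if (order == 2L) "="
    else if (order == 3L) "#"
    else if (mol$atoms$aromatic[a] && mol$atoms$aromatic[b]) "" else ":"
  }
  # ring-closure tokens must be emitted on both atoms; closures[[w]] is
  # appended after w has already been printed when w precedes v in DFS, so
  # run a two-pass scheme: first DFS records closures, second prints.
  pass1_closures <- function() {
    visited <<- logical(n)
    closures <<- vector("list", n)
    bond_used2 <- new.env(hash = TRUE)
    lab <- 0L
    rec <- function(v) {
      visited[v] <<- TRUE
      nb <- adj[[v]]
      if (nrow(nb)) for (k in seq_len(nrow(nb))) {
        w <- nb[k, "nbr"]; o <- nb[k, "order"]
        key <- bkey(v, w)
        if (!is.null(bond_used2[[key]])) next
        if (visited[w]) {
          bond_used2[[key]] <- TRUE
          lab <<- lab + 1L
          labs <- if (lab < 10L) as.character(lab) else paste0("%", sprintf("%02d", lab))
          tok <- paste0(bond_token(o, v, w), labs)
          closures[[w]] <<- c(closures[[w]], list(tok))
          closures[[v]] <<- c(closures[[v]], list(tok))
          assign(key, "ring", envir = bond_used)
        } else {
          bond_used2[[key]] <- TRUE
          rec(w)
        }
      }
    }
    rec(1L)
  }
  pass1_closures()
  # second pass: print, skipping ring bonds found in pass 1
  visited <- logical(n)
  emit2 <- function(v) {
    visited[v] <<- TRUE
    out <- atom_token(v)
    for (cl in closures[[v]]) out <- paste0(out, cl)
    nb <- adj[[v]]
    branches <- character(0)
    if (nrow(nb)) for (k in seq_len(nrow(nb))) {
      w <- nb[k, "nbr"]; o <- nb[k, "order"]
      key <- bkey(v, w)
      if (identical(bond_used[[key]], "ring")) next
      if (visited[w]) next
      branches <- c(branches, paste0(bond_token(o, v, w), emit2(w)))
    }
    if (length(branches) > 1L) {
      out <- paste0(out,
        paste0(vapply(branches[-length(branches)],
                      function(b) paste0("(", b, ")"), ""), collapse = ""),
        branches[length(branches)])
    } else if (length(branches) == 1L) {
      out <- paste0(out, branches)
    }
    out
  }
  emit2(1L)
}
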
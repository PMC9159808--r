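# SMILES parsing onto a heavy-atom molecular graph.
#
# Supports the organic subset (B C N O P S F Cl Br I and aromatic
# b c n o p s), bracket atoms with charge and explicit hydrogen count,
# branches, ring-bond closures (incl. %nn), bond symbols - = # : / \
# (directional bonds read as single; stereo is out of scope), and
# dot-disconnected components. Isotope and chirality marks are parsed
# and discarded.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

# allowed valence sets used for implicit-hydrogen assignment
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6), As = c(3, 5)
)

#' Parse a SMILES string into a molecular graph
#'
#' Produces the raw (possibly multi-component) heavy-atom graph. Most users
#' want [standardize_molecule()] or [load_molecules()], which also strip
#' counterions and compute the canonical serialization.
#'
#' @param smiles a single SMILES string.
#' @return a list with `atoms` (data.frame: `element`, `charge`, `aromatic`,
#'   `nH`, `degree`) and `bonds` (data.frame: `a1`, `a2`, `order`,
#'   `aromatic`); `order` is 1, 2 or 3, with aromatic bonds carried on the
#'   `aromatic` flag.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  elements <- character(0)
  charges <- integer(0)
  aromatic <- logical(0)
  bracket_h <- integer(0)  # NA for organic-subset atoms
  b_a1 <- integer(0); b_a2 <- integer(0); b_sym <- character(0)

  prev_stack <- integer(0)
  prev <- NA_integer_
  pending <- NA_character_
  ring_open <- list()  # digit -> list(atom, sym)

  add_atom <- function(el, chg, arom, hcount) {
    elements[length(elements) + 1L] <<- el
    charges[length(charges) + 1L] <<- chg
    aromatic[length(aromatic) + 1L] <<- arom
    bracket_h[length(bracket_h) + 1L] <<- hcount
    idx <- length(elements)
    if (!is.na(prev)) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- idx
      b_sym[length(b_sym) + 1L] <<- if (is.na(pending)) "" else pending
    }
    prev <<- idx
    pending <<- NA_character_
    idx
  }

  close_ring <- function(digit) {
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      sym <- if (!is.na(pending)) pending else op$sym
      if (op$atom == prev) stop("ring bond to self in SMILES: ", smiles)
      b_a1[length(b_a1) + 1L] <<- op$atom
      b_a2[length(b_a2) + 1L] <<- prev
      b_sym[length(b_sym) + 1L] <<- if (is.na(sym)) "" else sym
    } else {
      if (is.na(prev)) stop("ring-bond digit before any atom in: ", smiles)
      ring_open[[key]] <<- list(atom = prev,
                                sym = if (is.na(pending)) NA_character_ else pending)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(tok, smiles)
      add_atom(at$element, at$charge, at$aromatic, at$nH)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), 0L, FALSE, NA_integer_)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, 0L, FALSE, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), 0L, TRUE, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "$")) {
      pending <- switch(ch, "/" = "-", "\\" = "-", ch)
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES: ", smiles)
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring bond in SMILES: ", smiles)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      break
    } else {
      stop("unsupported SMILES character '", ch, "' in: ", smiles)
    }
  }
  if (length(ring_open) > 0L) stop("unmatched ring bond in SMILES: ", smiles)
  if (length(prev_stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(elements) == 0L) stop("SMILES contains no atoms: ", smiles)

  atoms <- data.frame(element = elements, charge = charges,
                      aromatic = aromatic, stringsAsFactors = FALSE)
  bonds <- .resolve_bonds(atoms, b_a1, b_a2, b_sym)
  atoms$nH <- .implicit_hydrogens(atoms, bonds, bracket_h)
  atoms$degree <- .heavy_degrees(nrow(atoms), bonds)
  list(atoms = atoms, bonds = bonds)
}

.parse_bracket_atom <- function(tok, smiles) {
  m <- regmatches(tok, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)((?:@{1,2})?)(H[0-9]*)?(\\+{1,}|-{1,}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
    tok))[[1]]
  if (length(m) == 0L) stop("cannot parse bracket atom [", tok, "] in: ", smiles)
  sym <- m[3]
  arom <- sym == tolower(sym) && substr(sym, 1, 1) %in% c("b","c","n","o","p","s")
  el <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  if (arom && !(el %in% .AROMATIC_OK))
    stop("aromatic flag not supported for element ", el, " in: ", smiles)
  hc <- m[5]
  nH <- if (is.na(hc) || hc == "") 0L
        else if (hc == "H") 1L
        else as.integer(substring(hc, 2))
  cs <- m[6]
  charge <- if (is.na(cs) || cs == "") 0L
            else if (grepl("^\\++$", cs)) nchar(cs)
            else if (grepl("^-+$", cs)) -nchar(cs)
            else as.integer(sub("\\+", "", cs))
  list(element = el, charge = as.integer(charge), aromatic = arom, nH = nH)
}

# Decide bond orders/aromaticity. Unspecified bonds between two aromatic
# atoms are aromatic only when the bond lies in a ring (so the biphenyl
# linker written without '-' stays single); ':' forces aromatic.
.resolve_bonds <- function(atoms, a1, a2, sym) {
  m <- length(a1)
  order <- rep(1L, m)
  arom <- rep(FALSE, m)
  if (m > 0) {
    for (e in seq_len(m)) {
      s <- sym[e]
      if (s == "=") order[e] <- 2L
      else if (s == "#" || s == "$") order[e] <- 3L
      else if (s == ":") arom[e] <- TRUE
      else if (s == "") {
        if (atoms$aromatic[a1[e]] && atoms$aromatic[a2[e]] &&
            .bond_in_ring(length(atoms$element), a1, a2, e))
          arom[e] <- TRUE
      }
    }
  }
  data.frame(a1 = a1, a2 = a2, order = order, aromatic = arom)
}

# is bond e part of a cycle? (endpoints still connected without it)
.bond_in_ring <- function(n_atoms, a1, a2, e) {
  src <- a1[e]; dst <- a2[e]
  adj <- vector("list", n_atoms)
  for (k in seq_along(a1)) {
    if (k == e) next
    adj[[a1[k]]] <- c(adj[[a1[k]]], a2[k])
    adj[[a2[k]]] <- c(adj[[a2[k]]], a1[k])
  }
  seen <- logical(n_atoms)
  queue <- src
  seen[src] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (w == dst) return(TRUE)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  FALSE
}

# Implicit hydrogen counts. Bracket atoms carry their explicit count;
# organic-subset atoms get the smallest allowed valence covering the bond
# sum (aromatic atoms reserve one unit for the ring pi system).
.implicit_hydrogens <- function(atoms, bonds, bracket_h) {
  n <- nrow(atoms)
  nH <- integer(n)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    contrib <- ifelse(bonds$aromatic, 1, bonds$order)
    for (e in seq_len(nrow(bonds))) {
      bsum[bonds$a1[e]] <- bsum[bonds$a1[e]] + contrib[e]
      bsum[bonds$a2[e]] <- bsum[bonds$a2[e]] + contrib[e]
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(bracket_h[i])) { nH[i] <- bracket_h[i]; next }
    vals <- .VALENCES[[atoms$element[i]]]
    if (is.null(vals)) { nH[i] <- 0L; next }
    need <- bsum[i] + if (atoms$aromatic[i]) 1 else 0
    v <- vals[vals >= need]
    nH[i] <- if (length(v) == 0L) 0L else as.integer(v[1] - need)
  }
  nH
}

.heavy_degrees <- function(n_atoms, bonds) {
  deg <- integer(n_atoms)
  if (nrow(bonds) > 0) {
    t1 <- tabulate(bonds$a1, nbins = n_atoms)
    t2 <- tabulate(bonds$a2, nbins = n_atoms)
    deg <- t1 + t2
  }
  deg
}

# connected components of the heavy-atom graph; returns membership vector
.graph_components <- function(n_atoms, bonds) {
  comp <- integer(n_atoms)
  adj <- vector("list", n_atoms)
  if (nrow(bonds) > 0) {
    for (e in seq_len(nrow(bonds))) {
      adj[[bonds$a1[e]]] <- c(adj[[bonds$a1[e]]], bonds$a2[e])
      adj[[bonds$a2[e]]] <- c(adj[[bonds$a2[e]]], bonds$a1[e])
    }
  }
  cur <- 0L
  for (s in seq_len(n_atoms)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# induce the subgraph on a set of atom indices (renumbered 1..k)
.induce_subgraph <- function(mol, keep) {
  keep <- sort(keep)
  map <- match(seq_along(mol$atoms$element), keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  bonds <- mol$bonds[bsel, , drop = FALSE]
  if (nrow(bonds) > 0) {
    bonds$a1 <- map[bonds$a1]
    bonds$a2 <- map[bonds$a2]
  }
  rownames(bonds) <- NULL
  atoms$degree <- .heavy_degrees(nrow(atoms), bonds)
  list(atoms = atoms, bonds = bonds)
}
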
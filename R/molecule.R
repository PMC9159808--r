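# Standardized molecules: salt stripping, canonical serialization,
# canonical SMILES output, and SMILES/SDF readers.

#' Standardize a parsed molecule
#'
#' Keeps the largest covalent fragment (counterion removal), assigns
#' hydrogen-bond donor/acceptor flags, and computes a canonical
#' serialization plus a canonical SMILES. Ties on fragment size are broken
#' by the lexicographically smallest canonical serialization.
#'
#' @param mol result of [parse_smiles()] (or an SDF record graph).
#' @param id identifier carried through the pipeline.
#' @return an object of class `std_mol`: list with `id`, `atoms`
#'   (element, charge, aromatic, nH, degree, donor, acceptor), `bonds`
#'   (a1, a2, order, aromatic), `canonical_smiles` and `mol_key` (the
#'   canonical serialization used for identity tests).
#' @export
standardize_molecule <- function(mol, id = "mol") {
  n <- nrow(mol$atoms)
  if (n == 0L) stop("molecule has no heavy atoms")
  comp <- .graph_components(n, mol$bonds)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      keys <- vapply(best, function(ci) {
        .molecule_key(.induce_subgraph(mol, which(comp == ci)))
      }, character(1))
      best <- best[order(keys)][1]
    } else best <- best[1]
    mol <- .induce_subgraph(mol, which(comp == best))
  }
  if (nrow(mol$atoms) == 0L) stop("empty molecule after salt stripping")
  atoms <- mol$atoms
  atoms$donor <- atoms$element %in% c("N", "O") & atoms$nH > 0L
  atoms$acceptor <- atoms$element %in% c("N", "O")
  out <- list(id = id, atoms = atoms, bonds = mol$bonds)
  out$mol_key <- .molecule_key(out)
  out$canonical_smiles <- .write_canonical_smiles(out)
  class(out) <- "std_mol"
  out
}

#' Parse and standardize a single SMILES
#'
#' Convenience wrapper: [parse_smiles()] then [standardize_molecule()].
#'
#' @inheritParams parse_smiles
#' @inheritParams standardize_molecule
#' @return a `std_mol` object.
#' @export
smiles_to_molecule <- function(smiles, id = "mol") {
  standardize_molecule(parse_smiles(smiles), id = id)
}

#' @export
print.std_mol <- function(x, ...) {
  cat(sprintf("<std_mol %s: %d heavy atoms, %d bonds, %s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$canonical_smiles))
  invisible(x)
}

# full atom label used for molecule identity and fragment keys (base part)
.atom_full_labels <- function(atoms) {
  paste0(atoms$element,
         ifelse(atoms$charge != 0L, sprintf("%+d", atoms$charge), ""),
         ifelse(atoms$aromatic, ":ar", ""),
         ":H", atoms$nH)
}

.bond_labels <- function(bonds) {
  if (nrow(bonds) == 0L) return(character(0))
  ifelse(bonds$aromatic, "a", as.character(bonds$order))
}

# Weisfeiler-Lehman colour refinement: stable across atom relabelings,
# used only to seed the canonical-order search so symmetric molecules do
# not blow up the backtracking.
.wl_refine <- function(labels, bonds, rounds = 3L) {
  n <- length(labels)
  lab <- labels
  if (nrow(bonds) > 0L) {
    blab <- .bond_labels(bonds)
    adj <- vector("list", n)
    for (e in seq_len(nrow(bonds))) {
      adj[[bonds$a1[e]]] <- c(adj[[bonds$a1[e]]], list(c(blab[e], bonds$a2[e])))
      adj[[bonds$a2[e]]] <- c(adj[[bonds$a2[e]]], list(c(blab[e], bonds$a1[e])))
    }
    for (r in seq_len(rounds)) {
      lab <- vapply(seq_len(n), function(v) {
        nb <- vapply(adj[[v]], function(p) paste0(p[1], "~", lab[as.integer(p[2])]),
                     character(1))
        paste0(lab[v], "{", paste(sort(nb), collapse = ","), "}")
      }, character(1))
    }
  }
  lab
}

# canonical atom order (positions -> original indices)
.canonical_atom_order <- function(mol) {
  n <- nrow(mol$atoms)
  base <- .atom_full_labels(mol$atoms)
  ref <- .wl_refine(base, mol$bonds)
  lab_codes <- match(ref, sort(unique(ref))) - 1L
  blab <- .bond_labels(mol$bonds)
  elab_codes <- if (length(blab)) match(blab, sort(unique(blab))) - 1L else integer(0)
  edges <- if (nrow(mol$bonds) > 0L)
    cbind(mol$bonds$a1 - 1L, mol$bonds$a2 - 1L) else matrix(0L, 0, 2)
  storage.mode(edges) <- "integer"
  cpp_canonical_order(n, edges, lab_codes, elab_codes)
}

# canonical serialization (identity key) of a connected or multi-component
# raw graph; invariant to atom relabeling
.molecule_key <- function(mol) {
  n <- nrow(mol$atoms)
  ord <- .canonical_atom_order(mol)
  pos <- integer(n); pos[ord] <- seq_len(n)
  labs <- .atom_full_labels(mol$atoms)[ord]
  key <- paste(labs, collapse = "|")
  if (nrow(mol$bonds) > 0L) {
    blab <- .bond_labels(mol$bonds)
    a <- pmin(pos[mol$bonds$a1], pos[mol$bonds$a2])
    b <- pmax(pos[mol$bonds$a1], pos[mol$bonds$a2])
    ed <- sort(paste0(a, "-", b, ":", blab))
    key <- paste0(key, "||", paste(ed, collapse = ","))
  }
  key
}

# ---------------------------------------------------------------------------
# canonical SMILES writer
# ---------------------------------------------------------------------------

.atom_token <- function(atoms, v, bonds) {
  el <- atoms$element[v]
  arom <- atoms$aromatic[v]
  sym <- if (arom) tolower(el) else el
  # would the parser infer the stored hydrogen count without a bracket?
  plain_ok <- el %in% .ORGANIC_SUBSET && atoms$charge[v] == 0L
  if (plain_ok) {
    inc <- bonds$a1 == v | bonds$a2 == v
    bsum <- sum(ifelse(bonds$aromatic[inc], 1, bonds$order[inc]))
    vals <- .VALENCES[[el]]
    need <- bsum + if (arom) 1 else 0
    vv <- vals[vals >= need]
    implied <- if (length(vv) == 0L) 0L else as.integer(vv[1] - need)
    plain_ok <- implied == atoms$nH[v]
  }
  if (plain_ok) return(sym)
  h <- atoms$nH[v]
  hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- atoms$charge[v]
  cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
        else sprintf("%+d", ch)
  paste0("[", sym, hs, cs, "]")
}

.bond_token <- function(bonds, e, atoms) {
  if (bonds$aromatic[e]) return("")
  o <- bonds$order[e]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl linker)
  if (atoms$aromatic[bonds$a1[e]] && atoms$aromatic[bonds$a2[e]]) return("-")
  ""
}

.write_canonical_smiles <- function(mol) {
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms)
  ord <- .canonical_atom_order(mol)
  rank <- integer(n); rank[ord] <- seq_len(n)
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (e in seq_len(nrow(bonds))) {
      adj[[bonds$a1[e]]] <- rbind(adj[[bonds$a1[e]]], c(bonds$a2[e], e))
      adj[[bonds$a2[e]]] <- rbind(adj[[bonds$a2[e]]], c(bonds$a1[e], e))
    }
  }
  visited <- logical(n)
  edge_used <- logical(nrow(bonds))
  ring_digit <- 0L
  # per-atom ring-closure annotations: list of c(digit, bond_sym_at_open)
  closures <- vector("list", n)
  tree_children <- vector("list", n)  # each: rbind(c(child, edge))
  root <- ord[1]
  # iterative DFS to collect tree and ring closures in canonical order
  stack <- list(list(v = root, parent = 0L))
  visited[root] <- TRUE
  dfs_collect <- function(v) {
    nbrs <- adj[[v]]
    if (is.null(nbrs)) return(invisible(NULL))
    nbrs <- nbrs[order(rank[nbrs[, 1]]), , drop = FALSE]
    for (k in seq_len(nrow(nbrs))) {
      w <- nbrs[k, 1]; e <- nbrs[k, 2]
      if (edge_used[e]) next
      if (!visited[w]) {
        edge_used[e] <<- TRUE
        visited[w] <<- TRUE
        tree_children[[v]] <<- rbind(tree_children[[v]], c(w, e))
        dfs_collect(w)
      } else {
        edge_used[e] <<- TRUE
        ring_digit <<- ring_digit + 1L
        d <- ring_digit
        sym <- .bond_token(bonds, e, atoms)
        closures[[w]] <<- c(closures[[w]], list(c(d, sym)))
        closures[[v]] <<- c(closures[[v]], list(c(d, "")))
      }
    }
  }
  dfs_collect(root)
  digit_str <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
  emit <- function(v) {
    out <- .atom_token(atoms, v, bonds)
    for (cl in closures[[v]])
      out <- paste0(out, cl[2], digit_str(as.integer(cl[1])))
    ch <- tree_children[[v]]
    if (!is.null(ch)) {
      for (k in seq_len(nrow(ch))) {
        w <- ch[k, 1]; e <- ch[k, 2]
        piece <- paste0(.bond_token(bonds, e, atoms), emit(w))
        out <- if (k < nrow(ch)) paste0(out, "(", piece, ")")
               else paste0(out, piece)
      }
    }
    out
  }
  emit(root)
}

# ---------------------------------------------------------------------------
# file readers
# ---------------------------------------------------------------------------

#' Load and standardize molecules from a SMILES or SDF file
#'
#' SMILES files carry one record per line: `SMILES identifier`, whitespace
#' separated (identifier optional; falls back to `mol<line>`). SDF input is
#' parsed from the V2000 connection table (`M  CHG` honoured, bond type 4
#' read as aromatic). Unparsable records are collected in a rejects report
#' attached as the `"rejects"` attribute (data.frame `id`, `line_no`,
#' `reason`) and reported with a warning -- they are never silently dropped.
#'
#' @param path file to read.
#' @param format `"smi"` or `"sdf"`; default guessed from the extension.
#' @return list of `std_mol`, input order preserved, with attribute
#'   `"rejects"`.
#' @export
load_molecules <- function(path, format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) "sdf" else "smi"
  }
  if (format == "smi") .load_smi(path) else .load_sdf(path)
}

.load_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  rej <- data.frame(id = character(0), line_no = integer(0),
                    reason = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2) parts[2] else paste0("mol", i)
    m <- tryCatch(smiles_to_molecule(smi, id = id), error = function(e) e)
    if (inherits(m, "error")) {
      rej <- rbind(rej, data.frame(id = id, line_no = i,
                                   reason = conditionMessage(m),
                                   stringsAsFactors = FALSE))
    } else {
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (nrow(rej) > 0)
    warning(nrow(rej), " record(s) rejected while reading ", path)
  attr(mols, "rejects") <- rej
  mols
}

.load_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty SDF file: ", path)
  # split into records on $$$$
  recs <- split(lines, cumsum(c(0, utils::head(grepl("^\\${4}", lines), -1))))
  mols <- list()
  rej <- data.frame(id = character(0), line_no = integer(0),
                    reason = character(0), stringsAsFactors = FALSE)
  offset <- 0L
  for (r in recs) {
    first <- offset + 1L
    offset <- offset + length(r)
    r <- r[!grepl("^\\${4}", r)]
    if (all(!nzchar(trimws(r)))) next
    id <- trimws(r[1])
    if (!nzchar(id)) id <- paste0("mol_line", first)
    m <- tryCatch(.parse_sdf_record(r), error = function(e) e)
    if (inherits(m, "error")) {
      rej <- rbind(rej, data.frame(id = id, line_no = first,
                                   reason = conditionMessage(m),
                                   stringsAsFactors = FALSE))
    } else {
      mols[[length(mols) + 1L]] <- standardize_molecule(m, id = id)
    }
  }
  if (nrow(rej) > 0)
    warning(nrow(rej), " record(s) rejected while reading ", path)
  attr(mols, "rejects") <- rej
  mols
}

.parse_sdf_record <- function(r) {
  if (length(r) < 4L) stop("truncated SDF record")
  counts <- r[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("bad counts line in SDF record")
  if (length(r) < 4L + na + nb) stop("truncated SDF connection table")
  el <- character(na)
  for (i in seq_len(na)) {
    ln <- r[4L + i]
    el[i] <- trimws(substr(ln, 32, 34))
    if (!nzchar(el[i])) el[i] <- trimws(strsplit(trimws(ln), "[ \t]+")[[1]][4])
  }
  heavy <- el != "H"
  a1 <- integer(nb); a2 <- integer(nb); bt <- integer(nb)
  for (i in seq_len(nb)) {
    ln <- r[4L + na + i]
    a1[i] <- as.integer(substr(ln, 1, 3))
    a2[i] <- as.integer(substr(ln, 4, 6))
    bt[i] <- as.integer(substr(ln, 7, 9))
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", r, value = TRUE)) {
    flds <- strsplit(trimws(sub("^M  CHG", "", ln)), "[ \t]+")[[1]]
    k <- as.integer(flds[1])
    for (j in seq_len(k)) {
      charge[as.integer(flds[2 * j])] <- as.integer(flds[2 * j + 1])
    }
  }
  # count explicit hydrogens per heavy atom, then drop them
  explH <- integer(na)
  for (i in seq_len(nb)) {
    if (el[a1[i]] == "H" && heavy[a2[i]]) explH[a2[i]] <- explH[a2[i]] + 1L
    if (el[a2[i]] == "H" && heavy[a1[i]]) explH[a1[i]] <- explH[a1[i]] + 1L
  }
  keep <- which(heavy)
  map <- match(seq_len(na), keep)
  bsel <- heavy[a1] & heavy[a2]
  arom <- bt == 4L
  atoms <- data.frame(element = el[keep], charge = charge[keep],
                      aromatic = FALSE, stringsAsFactors = FALSE)
  # atom is aromatic if it takes part in an aromatic bond
  for (i in which(bsel & arom)) {
    atoms$aromatic[map[a1[i]]] <- TRUE
    atoms$aromatic[map[a2[i]]] <- TRUE
  }
  bonds <- data.frame(a1 = map[a1[bsel]], a2 = map[a2[bsel]],
                      order = ifelse(arom[bsel], 1L, bt[bsel]),
                      aromatic = arom[bsel])
  bracket_h <- rep(NA_integer_, nrow(atoms))
  # explicit hydrogens in the ctab are kept as part of the hydrogen count
  has_expl <- explH[keep] > 0L
  nH_impl <- .implicit_hydrogens(atoms, bonds, bracket_h)
  atoms$nH <- ifelse(has_expl, explH[keep], nH_impl)
  atoms$degree <- .heavy_degrees(nrow(atoms), bonds)
  list(atoms = atoms, bonds = bonds)
}

#' Write a rejects report CSV
#'
#' @param mols result of [load_molecules()].
#' @param path output CSV (columns `id`, `line_no`, `reason`).
#' @return the rejects data.frame, invisibly.
#' @export
write_rejects_report <- function(mols, path) {
  rej <- attr(mols, "rejects")
  if (is.null(rej)) rej <- data.frame(id = character(0), line_no = integer(0),
                                      reason = character(0))
  utils::write.csv(rej, path, row.names = FALSE)
  invisible(rej)
}
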
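# Independent oracles used to freeze expected values and to cross-check the
# package implementation. Everything here deliberately avoids the package's
# own enumeration/canonicalization code paths.

# ---- naive connected-induced-subgraph enumeration (combn + BFS) -----------

oracle_connected <- function(sub, edges) {
  k <- length(sub)
  if (k == 1L) return(TRUE)
  adj <- lapply(sub, function(v) {
    nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
    intersect(nb, sub)
  })
  names(adj) <- as.character(sub)
  seen <- sub[1]
  queue <- sub[1]
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[as.character(v)]]) {
      if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
  }
  length(seen) == k
}

# all connected vertex-induced subgraphs with size in [min_size, max_size];
# returns a list of sorted atom-index vectors
oracle_subgraphs <- function(n, edges, min_size, max_size) {
  out <- list()
  if (min_size > n) return(out)
  for (k in seq(min_size, min(max_size, n))) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (sub in combos) {
      if (oracle_connected(sub, edges)) out[[length(out) + 1L]] <- sub
    }
  }
  out
}

# ---- distinction labels recomputed independently of the package ----------

oracle_atom_labels <- function(mol, distinctions) {
  a <- mol$atoms
  lab <- paste0(a$element, "|", a$charge)
  if ("A" %in% distinctions) lab <- paste0(lab, "|ar", as.integer(a$aromatic))
  if ("C" %in% distinctions) lab <- paste0(lab, "|deg", a$degree)
  if ("D" %in% distinctions)
    lab <- paste0(lab, "|d", as.integer(a$donor), "a", as.integer(a$acceptor))
  lab
}

oracle_bond_labels <- function(mol, distinctions) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(character(0))
  if ("B" %in% distinctions) ifelse(b$aromatic, "arom", as.character(b$order))
  else rep("e", nrow(b))
}

# ---- igraph(BLISS)-based canonical form of a labelled fragment -----------
# Edge labels are handled by subdividing each edge into a coloured vertex,
# so only vertex-coloured canonicalization is needed.

oracle_fragment_key <- function(mol, sub, distinctions) {
  sub <- sort(sub)
  vlab <- oracle_atom_labels(mol, distinctions)[sub]
  bsel <- which(mol$bonds$a1 %in% sub & mol$bonds$a2 %in% sub)
  elab <- oracle_bond_labels(mol, distinctions)[bsel]
  e1 <- match(mol$bonds$a1[bsel], sub)
  e2 <- match(mol$bonds$a2[bsel], sub)
  k <- length(sub)
  # subdivide: edge i becomes vertex k + i
  nv <- k + length(bsel)
  edges <- integer(0)
  for (i in seq_along(bsel)) {
    edges <- c(edges, e1[i], k + i, k + i, e2[i])
  }
  edge_lab <- if (length(elab)) paste0("EDGE::", elab) else character(0)
  all_lab <- c(vlab, edge_lab)
  colors <- match(all_lab, sort(unique(all_lab)))
  if (nv == 1L) return(all_lab)
  g <- igraph::make_graph(edges = edges, n = nv, directed = FALSE)
  cp <- igraph::canonical_permutation(g, colors = colors)
  gp <- igraph::permute(g, cp$labeling)
  new_lab <- character(nv)
  new_lab[cp$labeling] <- all_lab
  el <- igraph::as_edgelist(gp)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(paste(new_lab, collapse = ";"), "//",
         paste(paste0(el[, 1], "-", el[, 2]), collapse = ","))
}

# Full oracle check: the implementation enumerates exactly the oracle's
# subgraph set, and its key grouping induces a bijection with the oracle's
# isomorphism classes.
expect_oracle_equivalent <- function(mol, config) {
  impl <- enumerate_fragments(mol, config)
  edges <- cbind(mol$bonds$a1, mol$bonds$a2)
  subs <- oracle_subgraphs(nrow(mol$atoms), edges,
                           config$min_atoms, config$max_atoms)
  impl_sets <- vapply(attr(impl, "atoms"),
                      function(a) paste(sort(a), collapse = ","), character(1))
  oracle_sets <- vapply(subs, function(s) paste(s, collapse = ","), character(1))
  expect_identical(sort(impl_sets), sort(oracle_sets))
  okeys <- vapply(subs, oracle_fragment_key, character(1),
                  mol = mol, distinctions = config$distinctions)
  ikeys <- impl$key[match(oracle_sets, impl_sets)]
  tab <- table(ikeys, okeys)
  # bijection: every implementation key maps to exactly one oracle class
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  invisible(TRUE)
}

# ---- bitwise CRC-32 oracle (reflected, IEEE polynomial) -------------------
# double-arithmetic implementation; slow but independent of the C++ table.

oracle_xor32 <- function(a, b) {
  bits_a <- floor(a / 2^(0:31)) %% 2
  bits_b <- floor(b / 2^(0:31)) %% 2
  sum(((bits_a + bits_b) %% 2) * 2^(0:31))
}

oracle_crc32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  crc <- 4294967295
  for (byte in bytes) {
    crc <- oracle_xor32(crc, byte)
    for (k in 1:8) {
      odd <- crc %% 2 == 1
      crc <- floor(crc / 2)
      if (odd) crc <- oracle_xor32(crc, 3988292384)
    }
  }
  oracle_xor32(crc, 4294967295)
}

# ---- misc helpers ---------------------------------------------------------

# deterministically shuffle the atoms of a parsed molecule (relabeling test)
permute_molecule <- function(raw, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  atoms <- raw$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- raw$bonds
  bonds$a1 <- inv[bonds$a1]
  bonds$a2 <- inv[bonds$a2]
  list(atoms = atoms, bonds = bonds)
}

# small diverse molecule set (<= 12 heavy atoms) for oracle cross-checks
oracle_molecule_smiles <- function() {
  c("c1ccccc1", "c1ccncc1", "c1ccc2ncccc2c1", "C1CCCCC1", "O1CCNCC1",
    "CCO", "CC(=O)O", "CC(C)C", "CCCCCC", "CC(N)C(=O)O",
    "c1ccc(O)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1", "CC(=O)[O-]",
    "C[N+](C)(C)C", "CC#N", "C=CC=C", "CC=O", "CNC", "COC",
    "c1cocc1", "c1cscc1", "c1cc[nH]c1", "CC(C)(C)C", "ClCCCl",
    "FC(F)F", "OCC(O)CO", "N#Cc1ccccc1", "CSC", "O=C1CCCCC1",
    "c1ccc(-c2ccccc2)cc1", "C1Oc2ccccc2C=C1")
}
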
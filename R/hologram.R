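# Molecular holograms: exhaustive connected-fragment enumeration,
# canonical fragment keys under configurable distinction flags, CRC-32
# hashing into L bins, and the n x L hologram matrix.

.ALLOWED_L <- c(53L, 59L, 61L, 71L, 83L, 97L, 151L, 199L, 257L, 307L, 353L,
                401L)

#' Hologram configuration
#'
#' Controls fragment enumeration and hashing. Distinction flags follow the
#' HQSAR convention: `A` adds the aromatic flag to atom identity, `B` adds
#' bond orders to edges, `C` adds each atom's heavy-atom degree in the
#' parent molecule, `D` adds hydrogen-bond donor/acceptor classification,
#' and `H` includes hydrogens as explicit fragment atoms. Element and formal
#' charge are always part of atom identity. The default (fragment size 5-8,
#' distinctions A/C, 353 bins) is the best-performing configuration of the
#' underlying study.
#'
#' @param min_atoms,max_atoms fragment size window, `1 <= min <= max <= 11`.
#' @param distinctions character subset of `c("A","B","C","D","H")`.
#' @param length_L number of hash bins; one of 53, 59, 61, 71, 83, 97, 151,
#'   199, 257, 307, 353, 401.
#' @param cap abort enumeration beyond this many fragment occurrences per
#'   molecule (guards pathological inputs).
#' @return object of class `hologram_config`.
#' @export
hologram_config <- function(min_atoms = 5L, max_atoms = 8L,
                            distinctions = c("A", "C"), length_L = 353L,
                            cap = 2e6) {
  min_atoms <- as.integer(min_atoms); max_atoms <- as.integer(max_atoms)
  length_L <- as.integer(length_L)
  if (!(min_atoms >= 1L && min_atoms <= max_atoms && max_atoms <= 11L))
    stop("fragment size window must satisfy 1 <= min_atoms <= max_atoms <= 11")
  distinctions <- unique(as.character(distinctions))
  bad <- setdiff(distinctions, c("A", "B", "C", "D", "H"))
  if (length(bad) > 0) stop("unknown distinction flag(s): ", paste(bad, collapse = ", "))
  if (!(length_L %in% .ALLOWED_L))
    stop("length_L must be one of ", paste(.ALLOWED_L, collapse = ", "))
  structure(list(min_atoms = min_atoms, max_atoms = max_atoms,
                 distinctions = sort(distinctions), length_L = length_L,
                 cap = cap),
            class = "hologram_config")
}

#' @export
print.hologram_config <- function(x, ...) {
  cat(sprintf("<hologram_config: size %d-%d, distinctions {%s}, L=%d>\n",
              x$min_atoms, x$max_atoms, paste(x$distinctions, collapse = ","),
              x$length_L))
  invisible(x)
}

# Build the (possibly H-expanded) enumeration graph with distinction-
# resolved atom and edge label strings.
.fragment_graph <- function(mol, config) {
  atoms <- mol$atoms; bonds <- mol$bonds
  d <- config$distinctions
  lab <- paste0(atoms$element,
                ifelse(atoms$charge != 0L, sprintf("%+d", atoms$charge), ""))
  if ("A" %in% d) lab <- paste0(lab, ifelse(atoms$aromatic, "&ar", ""))
  if ("C" %in% d) lab <- paste0(lab, "&d", atoms$degree)
  if ("D" %in% d)
    lab <- paste0(lab,
                  ifelse(atoms$donor, "&don", ""),
                  ifelse(atoms$acceptor, "&acc", ""))
  edges <- if (nrow(bonds) > 0L) cbind(bonds$a1, bonds$a2) else matrix(0L, 0, 2)
  elab <- if ("B" %in% d) .bond_labels(bonds) else rep("", nrow(bonds))
  n_heavy <- nrow(atoms)
  hparent <- integer(0)  # heavy atom each explicit-H node hangs off
  if ("H" %in% d) {
    hl <- if ("C" %in% d) "H&d1" else "H"
    for (v in seq_len(n_heavy)) {
      nh <- atoms$nH[v]
      if (nh > 0L) {
        new_idx <- length(lab) + seq_len(nh)
        lab <- c(lab, rep(hl, nh))
        edges <- rbind(edges, cbind(rep(v, nh), new_idx))
        elab <- c(elab, rep(if ("B" %in% d) "1" else "", nh))
        hparent <- c(hparent, rep(v, nh))
      }
    }
  }
  list(n = length(lab), n_heavy = n_heavy, edges = edges,
       lab = lab, elab = elab, hparent = hparent)
}

#' Enumerate fragment occurrences of a molecule
#'
#' Every connected vertex-induced subgraph of the heavy-atom graph (of the
#' hydrogen-explicit graph when flag `H` is active) whose atom count lies in
#' the configured window yields one occurrence: linear, branched and cyclic
#' fragments alike. Each occurrence carries a canonical key string that is
#' invariant to atom relabeling; isomorphic fragments with identical
#' active-distinction labels share a key.
#'
#' @param mol a `std_mol`.
#' @param config a [hologram_config()].
#' @return object of class `fragment_set`: data.frame-like list with `key`
#'   (character, one per occurrence), `atom_count`, and attribute `atoms`
#'   (list of atom-index vectors into the enumeration graph; indices
#'   `<= n_heavy` are heavy atoms of `mol`).
#' @export
enumerate_fragments <- function(mol, config = hologram_config()) {
  stopifnot(inherits(mol, "std_mol"), inherits(config, "hologram_config"))
  if (nrow(mol$atoms) == 0L) stop("molecule has zero heavy atoms")
  g <- .fragment_graph(mol, config)
  lab_codes <- match(g$lab, sort(unique(g$lab))) - 1L
  elab_levels <- sort(unique(g$elab))
  elab_codes <- if (length(g$elab)) match(g$elab, elab_levels) - 1L
                else integer(0)
  edges <- g$edges
  if (nrow(edges) > 0) edges <- edges - 1L
  storage.mode(edges) <- "integer"
  res <- cpp_enumerate_fragments(g$n, edges, lab_codes, g$lab, elab_codes,
                                 elab_levels, config$min_atoms,
                                 config$max_atoms, config$cap)
  atoms <- res$atoms
  out <- list(key = as.character(res$keys),
              atom_count = vapply(atoms, length, integer(1)))
  attr(out, "atoms") <- atoms
  attr(out, "n_heavy") <- g$n_heavy
  attr(out, "hparent") <- g$hparent
  class(out) <- "fragment_set"
  out
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set: %d occurrences, %d unique keys>\n",
              length(x$key), length(unique(x$key))))
  invisible(x)
}

#' Canonical key of one fragment subgraph
#'
#' Exposed mostly for testing: computes the canonical key string of the
#' vertex-induced subgraph of `mol` on `atom_idx` under the distinction
#' flags of `config`.
#'
#' @param mol a `std_mol`.
#' @param atom_idx heavy-atom indices (1-based) of a connected subgraph.
#' @param config a [hologram_config()] (its size window is ignored here).
#' @return the canonical key string.
#' @export
canonical_fragment_key <- function(mol, atom_idx, config = hologram_config()) {
  g <- .fragment_graph(mol, config)
  atom_idx <- sort(unique(as.integer(atom_idx)))
  if (any(atom_idx < 1L | atom_idx > g$n))
    stop("atom_idx out of range")
  sel <- g$edges[, 1] %in% atom_idx & g$edges[, 2] %in% atom_idx
  edges <- g$edges[sel, , drop = FALSE]
  # connectivity check
  comp <- .graph_components(length(atom_idx),
                            data.frame(a1 = match(edges[, 1], atom_idx),
                                       a2 = match(edges[, 2], atom_idx)))
  if (length(atom_idx) > 1L && max(comp) > 1L)
    stop("atom_idx does not induce a connected subgraph")
  lab <- g$lab[atom_idx]
  elab <- g$elab[sel]
  ed <- cbind(match(edges[, 1], atom_idx), match(edges[, 2], atom_idx)) - 1L
  storage.mode(ed) <- "integer"
  lab_codes <- match(lab, sort(unique(lab))) - 1L
  elab_levels <- sort(unique(elab))
  elab_codes <- if (length(elab)) match(elab, elab_levels) - 1L else integer(0)
  as.character(cpp_canonical_key(length(atom_idx), ed, lab_codes, lab,
                                 elab_codes, elab_levels))
}

#' CRC-32 checksum (IEEE polynomial) of strings
#'
#' Platform-independent, matches zlib's `crc32`. Used to assign each unique
#' fragment its "specific large integer".
#'
#' @param x character vector.
#' @return numeric vector of unsigned 32-bit checksums.
#' @export
crc32 <- function(x) {
  cpp_crc32(as.character(x))
}

#' Hash a fragment key into a hologram bin
#'
#' `bin = (CRC32(key) mod L) + 1`, i.e. bins are 1..L.
#'
#' @param key character vector of fragment key strings.
#' @param L hologram length.
#' @return integer bin indices in `1..L`.
#' @export
hash_to_bin <- function(key, L) {
  if (any(!nzchar(key))) stop("empty fragment key")
  as.integer(cpp_crc32(as.character(key)) %% L) + 1L
}

#' Build a hologram from fragment occurrences
#'
#' @param fragments a `fragment_set` (or character vector of keys).
#' @param L hologram length (must be in the allowed set).
#' @return object of class `hologram`: list with `bins` (integer vector of
#'   length `L`) and `total_fragments`.
#' @export
build_hologram <- function(fragments, L = 353L) {
  L <- as.integer(L)
  if (!(L %in% .ALLOWED_L))
    stop("L must be one of ", paste(.ALLOWED_L, collapse = ", "))
  keys <- if (inherits(fragments, "fragment_set")) fragments$key
          else as.character(fragments)
  bins <- integer(L)
  if (length(keys) > 0) {
    b <- hash_to_bin(keys, L)
    tb <- tabulate(b, nbins = L)
    bins <- as.integer(tb)
  }
  structure(list(bins = bins, total_fragments = length(keys), L = L),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram: L=%d, %d fragment occurrences, %d occupied bins>\n",
              x$L, x$total_fragments, sum(x$bins > 0)))
  invisible(x)
}

#' Hologram matrix of a molecule collection
#'
#' @param mols list of `std_mol`.
#' @param config a [hologram_config()].
#' @param skip_errors if `TRUE`, molecules failing enumeration get a row of
#'   `NA` and a warning; otherwise the run aborts naming the molecule.
#' @return numeric matrix `n x L`, rownames = molecule ids, column `j` =
#'   bin `j`.
#' @export
hologram_matrix <- function(mols, config = hologram_config(),
                            skip_errors = FALSE) {
  if (length(mols) == 0L) stop("empty molecule list")
  ids <- vapply(mols, function(m) m$id, character(1))
  X <- matrix(NA_real_, nrow = length(mols), ncol = config$length_L,
              dimnames = list(ids, paste0("bin", seq_len(config$length_L))))
  for (i in seq_along(mols)) {
    h <- tryCatch(
      build_hologram(enumerate_fragments(mols[[i]], config), config$length_L),
      error = function(e) e)
    if (inherits(h, "error")) {
      if (!skip_errors)
        stop("hologram failed for molecule '", ids[i], "': ",
             conditionMessage(h))
      warning("hologram failed for molecule '", ids[i], "': ",
              conditionMessage(h), "; row set to NA")
    } else {
      X[i, ] <- h$bins
    }
  }
  X
}
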
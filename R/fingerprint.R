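# Hashed circular (Morgan-style, ECFP-like) fingerprints and MaxMin
# Tanimoto diversity selection.
#
# The atom-environment hashing is an internally consistent re-implementation
# of the ECFP idea (iterated neighbourhood hashing, CRC-32 based); it is not
# bit-compatible with any vendor ECFP_6, which matters only for absolute
# similarity values, not for the diversity-ranking role it plays here.

#' Hashed circular fingerprint of a standardized molecule
#'
#' Radius 3 corresponds to ECFP_6 (diameter 6). Environments of all radii
#' 0..radius are hashed (CRC-32 of the canonical environment string) and
#' folded modulo `n_bits`.
#'
#' @param mol a `std_mol`.
#' @param radius maximum environment radius (default 3).
#' @param n_bits fingerprint width (default 2048; must be >= 64).
#' @return object of class `circ_fp`: list with `id`, `on_bits` (sorted
#'   0-based integer indices), `radius`, `n_bits`.
#' @export
circular_fingerprint <- function(mol, radius = 3L, n_bits = 2048L) {
  stopifnot(inherits(mol, "std_mol"))
  if (n_bits < 64L) stop("n_bits must be >= 64")
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms)
  blab <- .bond_labels(bonds)
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (e in seq_len(nrow(bonds))) {
      adj[[bonds$a1[e]]] <- rbind(adj[[bonds$a1[e]]], c(bonds$a2[e], e))
      adj[[bonds$a2[e]]] <- rbind(adj[[bonds$a2[e]]], c(bonds$a1[e], e))
    }
  }
  lab <- paste0(atoms$element, ";", atoms$charge, ";",
                as.integer(atoms$aromatic), ";", atoms$degree, ";", atoms$nH)
  h <- cpp_crc32(lab)
  all_hashes <- h
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      nxt <- vapply(seq_len(n), function(v) {
        if (is.null(adj[[v]])) return(format(h[v], scientific = FALSE))
        nb <- sort(vapply(seq_len(nrow(adj[[v]])), function(k) {
          paste0(blab[adj[[v]][k, 2]], "~",
                 format(h[adj[[v]][k, 1]], scientific = FALSE))
        }, character(1)))
        paste0(format(h[v], scientific = FALSE), "(", paste(nb, collapse = ","), ")")
      }, character(1))
      h <- cpp_crc32(nxt)
      all_hashes <- c(all_hashes, h)
    }
  }
  bits <- sort(unique(as.integer(all_hashes %% n_bits)))
  structure(list(id = mol$id, on_bits = bits,
                 radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "circ_fp")
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |A intersect B| / |A union B|`. Two empty fingerprints are defined
#' identical (distance 0, with a message).
#'
#' @param a,b `circ_fp` objects with equal `n_bits`.
#' @return a number in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  stopifnot(inherits(a, "circ_fp"), inherits(b, "circ_fp"))
  if (a$n_bits != b$n_bits) stop("fingerprints have different n_bits")
  u <- length(union(a$on_bits, b$on_bits))
  if (u == 0L) {
    message("both fingerprints empty; distance defined as 0")
    return(0)
  }
  1 - length(intersect(a$on_bits, b$on_bits)) / u
}

#' Greedy MaxMin diversity selection
#'
#' Picks `n_select` fingerprints maximizing, at each step, the minimum
#' Tanimoto distance to the already selected set (the "Find Diverse
#' Molecules" idea). The first pick is a seeded-uniform draw from the
#' population; later ties break by input order.
#'
#' @param fps list of `circ_fp`.
#' @param n_select number to select (1..length(fps)).
#' @param seed integer seed controlling the first pick.
#' @return list with `selected_ids`, `remaining_ids`, `selected_idx`,
#'   `min_distance_trace` (NA for the first pick, then the achieved
#'   max-min distance at each step).
#' @export
maxmin_diverse_select <- function(fps, n_select, seed = 1L) {
  n <- length(fps)
  if (n_select < 1L || n_select > n)
    stop("n_select must be between 1 and the population size (", n, ")")
  ids <- vapply(fps, function(f) f$id, character(1))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  first <- sample.int(n, 1L)
  selected <- first
  trace <- NA_real_
  mind <- vapply(seq_len(n), function(i) tanimoto_distance(fps[[i]], fps[[first]]),
                 numeric(1))
  while (length(selected) < n_select) {
    mind[selected] <- -Inf
    best <- which(mind == max(mind))[1]  # ties -> input order
    trace <- c(trace, mind[best])
    selected <- c(selected, best)
    dnew <- vapply(seq_len(n), function(i) tanimoto_distance(fps[[i]], fps[[best]]),
                   numeric(1))
    mind <- pmin(mind, dnew)
  }
  remaining <- setdiff(seq_len(n), selected)
  list(selected_ids = ids[selected], remaining_ids = ids[remaining],
       selected_idx = selected, min_distance_trace = trace)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
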
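# Atomic contribution mapping: project hologram PLS coefficients back onto
# atoms. Each fragment occurrence donates its bin's coefficient divided by
# the fragment's atom count to every atom it contains; an atom's score is
# the sum over the occurrences containing it. Colliding fragments share a
# bin coefficient -- no de-collision is attempted, faithful to the hashed
# hologram.

#' Per-atom activity contributions of a molecule
#'
#' Coefficients are taken on the original (count) scale of the hologram
#' matrix (`coef_original`); bins dropped during auto-scaling contribute 0.
#'
#' @param mol a `std_mol`.
#' @param model a `plsda_model` trained on a hologram matrix built with
#'   exactly `config` (L must match the model's feature count; a mismatch
#'   is an error).
#' @param config the [hologram_config()] used in training.
#' @return object of class `atom_contributions`: list with `scores`
#'   (numeric, one per heavy atom), `total` (sum over fragment occurrences
#'   of their bin coefficients), `id`.
#' @export
atomic_contributions <- function(mol, model, config = hologram_config()) {
  stopifnot(inherits(mol, "std_mol"), inherits(model, "plsda_model"),
            inherits(config, "hologram_config"))
  if (model$n_features != config$length_L)
    stop("config/model mismatch: model has ", model$n_features,
         " features but config length_L is ", config$length_L)
  frags <- enumerate_fragments(mol, config)
  members <- attr(frags, "atoms")
  n_heavy <- attr(frags, "n_heavy")
  hparent <- attr(frags, "hparent")
  coef_full <- numeric(model$n_features)
  coef_full[model$kept_columns] <- model$coef_original
  scores <- numeric(nrow(mol$atoms))
  total <- 0
  if (length(frags$key) > 0) {
    bins <- hash_to_bin(frags$key, config$length_L)
    for (i in seq_along(bins)) {
      cf <- coef_full[bins[i]]
      total <- total + cf
      at <- members[[i]]
      # explicit-H nodes fold their share into the bonded heavy atom so the
      # per-molecule sum is conserved exactly
      over <- at > n_heavy
      if (any(over)) at[over] <- hparent[at[over] - n_heavy]
      share <- cf / length(members[[i]])
      for (a in at) scores[a] <- scores[a] + share
    }
  }
  structure(list(id = mol$id, scores = scores, total = total),
            class = "atom_contributions")
}

#' @export
print.atom_contributions <- function(x, ...) {
  cat(sprintf("<atom_contributions %s: %d atoms, total %.4g>\n",
              x$id, length(x$scores), x$total))
  invisible(x)
}

#' Annotate a molecule with per-atom contribution scores
#'
#' Produces a plain-text record: one row per heavy atom with its element,
#' canonical rank and score (full precision), suitable for downstream
#' colour-coding.
#'
#' @param mol a `std_mol`.
#' @param contributions an [atomic_contributions()] result for `mol`.
#' @return data.frame with `id`, `atom_index`, `element`, `score`.
#' @export
annotate_contributions <- function(mol, contributions) {
  stopifnot(inherits(mol, "std_mol"),
            inherits(contributions, "atom_contributions"))
  if (length(contributions$scores) != nrow(mol$atoms))
    stop("score vector length (", length(contributions$scores),
         ") does not match heavy-atom count (", nrow(mol$atoms), ")")
  data.frame(id = mol$id,
             atom_index = seq_len(nrow(mol$atoms)),
             element = mol$atoms$element,
             score = contributions$scores,
             stringsAsFactors = FALSE)
}

#' Write contribution annotations as CSV (round-trips at full precision)
#'
#' @param annotation result of [annotate_contributions()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(annotation, path) {
  dat <- annotation
  dat$score <- format(dat$score, digits = 17, trim = TRUE,
                      scientific = FALSE)
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
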
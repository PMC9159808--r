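# Seeded synthetic fixtures: labelled molecule sets with planted
# class-discriminating fragments, plus a surrogate scalar descriptor whose
# per-class distributions straddle the published decision threshold.
#
# Class 1 molecules are grown from aromatic biphenyl / quinoline / chromene
# scaffolds (the fragment families reported as high-contribution), class 0
# from aliphatic and small polar scaffolds. The surrogate descriptor is
# Normal(mu1, sigma) vs Normal(mu0, sigma) with defaults placing the Bayes
# boundary at -0.1, so the fixed published rule threshold is meaningful on
# synthetic data by construction (a design convenience, not a claim about
# real BV12-DRY values).

.POS_TEMPLATES <- c(
  biphenyl = "c1cc{R1}ccc1-c1ccc{R2}cc1",
  quinoline = "c1cc{R1}c2ncccc2c1",
  chromene = "C1Oc2cc{R1}ccc2C=C1"
)
.NEG_TEMPLATES <- c(
  cyclohexane = "C1CC{R1}CCC1",
  morpholine = "O1CC{R1}NCC1",
  hexane = "CCC{R1}CCC",
  ether = "CCOCC{R1}C"
)
.DECORATIONS <- c("C", "CC", "O", "N", "F", "Cl", "C(C)C", "CO", "C=O")

#' Specification of a synthetic fixture set
#'
#' @param n_per_class molecules per class (default 200).
#' @param positive_templates,negative_templates named character vectors of
#'   scaffold SMILES templates with `{R1}`, `{R2}`, ... substitution sites.
#' @param decorations substituent SMILES fragments.
#' @param decoration_rate probability a substitution site is decorated
#'   (default 0.5).
#' @param label_noise probability a label is flipped (default 0.05, so
#'   perfect scores cannot mask bugs).
#' @param mu1,mu0,sigma surrogate-descriptor class means and common SD
#'   (defaults 0.4, -0.6, 0.35: Bayes boundary at -0.1).
#' @param seed integer seed; all outputs are bytewise deterministic in it.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = 200L,
                         positive_templates = .POS_TEMPLATES,
                         negative_templates = .NEG_TEMPLATES,
                         decorations = .DECORATIONS,
                         decoration_rate = 0.5,
                         label_noise = 0.05,
                         mu1 = 0.4, mu0 = -0.6, sigma = 0.35,
                         seed = 17L) {
  stopifnot(n_per_class >= 0,
            decoration_rate >= 0, decoration_rate <= 1,
            label_noise >= 0, label_noise <= 1,
            sigma > 0)
  # validate scaffolds: every template must parse with empty and decorated sites
  for (tpl in c(positive_templates, negative_templates)) {
    smi <- gsub("\\{R[0-9]+\\}", "", tpl)
    ok <- tryCatch({ parse_smiles(smi); TRUE }, error = function(e) FALSE)
    if (!ok) stop("invalid scaffold template: ", tpl)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 positive_templates = positive_templates,
                 negative_templates = negative_templates,
                 decorations = decorations,
                 decoration_rate = decoration_rate,
                 label_noise = label_noise,
                 mu1 = mu1, mu0 = mu0, sigma = sigma,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.decorate_template <- function(tpl, decorations, rate) {
  sites <- gregexpr("\\{R[0-9]+\\}", tpl)[[1]]
  n_sites <- if (sites[1] == -1) 0L else length(sites)
  out <- tpl
  for (k in seq_len(n_sites)) {
    sub <- if (stats::runif(1) < rate)
      paste0("(", sample(decorations, 1L), ")") else ""
    out <- sub("\\{R[0-9]+\\}", sub, out)
  }
  out
}

#' Generate a labelled synthetic SMILES set
#'
#' Class-1 molecules from positive scaffolds with random decorations,
#' class-0 from negative scaffolds; labels then flipped independently with
#' probability `label_noise`. Fully deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with `id`, `smiles`, `label` (post-noise) and
#'   `true_class` (pre-noise scaffold class).
#' @export
generate_labeled_smiles <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_per_class
  rows <- list()
  for (cls in c(1L, 0L)) {
    tpls <- if (cls == 1L) spec$positive_templates else spec$negative_templates
    for (i in seq_len(n)) {
      tpl <- tpls[[sample.int(length(tpls), 1L)]]
      smi <- .decorate_template(tpl, spec$decorations, spec$decoration_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("syn_%d_%03d", cls, i), smiles = smi,
        true_class = cls, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      label = integer(0), true_class = integer(0)))
  out <- do.call(rbind, rows)
  flip <- stats::runif(nrow(out)) < spec$label_noise
  out$label <- ifelse(flip, 1L - out$true_class, out$true_class)
  rownames(out) <- NULL
  out[, c("id", "smiles", "label", "true_class")]
}

#' Generate the surrogate descriptor table
#'
#' `BV12_DRY_surrogate ~ N(mu1, sigma)` for class 1 and `N(mu0, sigma)` for
#' class 0 (post-noise labels are NOT used: the descriptor tracks the true
#' class, as a real physicochemical property would). `LogP_surrogate` is a
#' heavily overlapping nuisance column. Deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @param ids identifiers.
#' @param true_class 0/1 vector aligned with `ids`.
#' @return data.frame with `id`, `BV12_DRY_surrogate`, `LogP_surrogate`.
#' @export
generate_descriptor_table <- function(spec, ids, true_class) {
  stopifnot(inherits(spec, "fixture_spec"), length(ids) == length(true_class))
  if (!all(true_class %in% c(0, 1))) stop("true_class must be 0/1")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(spec$seed + 1L)
  mu <- ifelse(true_class == 1, spec$mu1, spec$mu0)
  bv <- stats::rnorm(length(ids), mean = mu, sd = spec$sigma)
  # nuisance: small class shift, large overlap
  lp <- stats::rnorm(length(ids), mean = 2 + 0.3 * (true_class == 1), sd = 1.5)
  data.frame(id = as.character(ids), BV12_DRY_surrogate = bv,
             LogP_surrogate = lp, stringsAsFactors = FALSE)
}

#' Write a complete fixture bundle to disk
#'
#' Emits `molecules.smi` (SMILES + id), `labels.csv` (`id,label`) and
#' `descriptors.csv` in the dialects the rest of the package consumes.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the three file paths and the generated
#'   data.
#' @export
write_fixture_files <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mols <- generate_labeled_smiles(spec)
  desc <- generate_descriptor_table(spec, mols$id, mols$true_class)
  smi_path <- file.path(dir, "molecules.smi")
  writeLines(paste(mols$smiles, mols$id), smi_path)
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(mols[, c("id", "label")], lab_path, row.names = FALSE,
                   quote = FALSE)
  desc_path <- file.path(dir, "descriptors.csv")
  dout <- desc
  dout$BV12_DRY_surrogate <- format(dout$BV12_DRY_surrogate, digits = 17,
                                    trim = TRUE, scientific = FALSE)
  dout$LogP_surrogate <- format(dout$LogP_surrogate, digits = 17,
                                trim = TRUE, scientific = FALSE)
  utils::write.csv(dout, desc_path, row.names = FALSE, quote = FALSE)
  invisible(list(smiles = smi_path, labels = lab_path,
                 descriptors = desc_path, molecules = mols,
                 descriptor_table = desc))
}
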
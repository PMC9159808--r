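# Single-descriptor threshold rule (the BV12-DRY > -0.1 rule) and the
# two-stage integrative classifier combining it with hologram PLS-DA.

#' Construct a threshold rule model
#'
#' The default is the published rule: a compound with `BV12-DRY > -0.1` is
#' classified as an inhibitor (strict inequality; equality classifies 0).
#'
#' @param descriptor_name column the rule reads.
#' @param threshold finite decision threshold.
#' @param direction `"greater_is_positive"` (default) or
#'   `"less_is_positive"`.
#' @return object of class `rule_model`.
#' @export
rule_model <- function(descriptor_name = "BV12-DRY", threshold = -0.1,
                       direction = c("greater_is_positive",
                                     "less_is_positive")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(list(descriptor_name = descriptor_name, threshold = threshold,
                 direction = direction), class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  op <- if (x$direction == "greater_is_positive") ">" else "<"
  cat(sprintf("<rule_model: class 1 iff %s %s %g>\n",
              x$descriptor_name, op, x$threshold))
  invisible(x)
}

#' Apply a threshold rule to descriptor values
#'
#' @param rule a `rule_model`.
#' @param values numeric vector (no missing values), or a data.frame
#'   containing the rule's descriptor column.
#' @return integer 0/1 labels (strict inequality: a value exactly at the
#'   threshold classifies as 0).
#' @export
apply_rule <- function(rule, values) {
  stopifnot(inherits(rule, "rule_model"))
  if (is.data.frame(values)) {
    if (!(rule$descriptor_name %in% names(values)))
      stop("descriptor column '", rule$descriptor_name, "' not found")
    values <- values[[rule$descriptor_name]]
  }
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing descriptor values")
  if (rule$direction == "greater_is_positive")
    as.integer(values > rule$threshold)
  else
    as.integer(values < rule$threshold)
}

#' Calibrate a threshold rule from labelled values
#'
#' Scans all midpoints between adjacent sorted unique values and picks the
#' threshold maximizing balanced accuracy (mean of SEN and SPE); ties break
#' towards the smallest threshold. The direction is whichever sign of the
#' rule scores higher (ties prefer `greater_is_positive`).
#'
#' @param values numeric descriptor values.
#' @param labels binary 0/1 labels; both classes must be present.
#' @param descriptor_name stored in the returned model.
#' @return a `rule_model` with attribute `"balanced_accuracy"`.
#' @export
calibrate_threshold <- function(values, labels,
                                descriptor_name = "descriptor") {
  values <- as.numeric(values); labels <- as.numeric(labels)
  stopifnot(length(values) == length(labels))
  if (anyNA(values) || anyNA(labels)) stop("missing values")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  u <- sort(unique(values))
  if (length(u) < 2L) stop("descriptor is constant; no threshold exists")
  mids <- (u[-1] + u[-length(u)]) / 2
  bal <- function(pred) {
    sen <- mean(pred[labels == 1] == 1)
    spe <- mean(pred[labels == 0] == 0)
    (sen + spe) / 2
  }
  ba_gt <- vapply(mids, function(th) bal(as.integer(values > th)), numeric(1))
  ba_lt <- vapply(mids, function(th) bal(as.integer(values < th)), numeric(1))
  best_gt <- max(ba_gt); best_lt <- max(ba_lt)
  if (best_gt >= best_lt) {
    th <- mids[which(ba_gt == best_gt)[1]]  # smallest threshold on ties
    out <- rule_model(descriptor_name, th, "greater_is_positive")
    attr(out, "balanced_accuracy") <- best_gt
  } else {
    th <- mids[which(ba_lt == best_lt)[1]]
    out <- rule_model(descriptor_name, th, "less_is_positive")
    attr(out, "balanced_accuracy") <- best_lt
  }
  out
}

#' Construct a two-stage integrative classifier
#'
#' Stage one is hologram PLS-DA; stage two re-assigns some compounds with
#' the threshold rule. Two modes exist because the published integration is
#' label-aware and cannot run at deployment:
#' \describe{
#'   \item{`deploy`}{label-blind: compounds whose continuous PLS-DA score
#'     falls inside the ambiguity band `[cutoff - delta, cutoff + delta]`
#'     are re-assigned by the rule; all others keep the PLS-DA label.}
#'   \item{`oracle_eval`}{evaluation-only, mirrors the source procedure:
#'     compounds the PLS-DA misclassifies (requires true labels) are
#'     re-evaluated by the rule. Output is flagged as label-aware.}
#' }
#'
#' @param pls a `plsda_model`.
#' @param rule a `rule_model`.
#' @param delta ambiguity half-band width, `>= 0` (default 0.15; only used
#'   in deploy mode).
#' @param mode `"deploy"` or `"oracle_eval"`.
#' @return object of class `integrative_model`.
#' @export
integrative_model <- function(pls, rule, delta = 0.15,
                              mode = c("deploy", "oracle_eval")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pls, "plsda_model"), inherits(rule, "rule_model"),
            delta >= 0)
  structure(list(pls = pls, rule = rule, delta = delta, mode = mode),
            class = "integrative_model")
}

#' Run the two-stage integrative classifier
#'
#' @param imodel an [integrative_model()].
#' @param X hologram matrix (same columns as the PLS training matrix).
#' @param descriptor_values numeric vector (or data.frame with the rule's
#'   column), aligned row-for-row with `X`.
#' @param labels true 0/1 labels; required in `oracle_eval` mode, ignored in
#'   `deploy` mode.
#' @return data.frame with `score` (PLS-DA continuous score), `label`
#'   (final 0/1 class) and `provenance` (`"pls"` or `"rule"`, exactly one
#'   per compound); attribute `"label_aware"` is `TRUE` in oracle mode.
#' @export
integrate_classify <- function(imodel, X, descriptor_values, labels = NULL) {
  stopifnot(inherits(imodel, "integrative_model"))
  pred <- predict(imodel$pls, X)
  rule_lab <- apply_rule(imodel$rule, descriptor_values)
  n <- length(pred$label)
  if (length(rule_lab) != n)
    stop("descriptor values and hologram matrix have different sizes")
  if (imodel$mode == "oracle_eval") {
    if (is.null(labels))
      stop("oracle_eval mode requires true labels")
    labels <- as.numeric(labels)
    use_rule <- pred$label != labels
  } else {
    cut <- imodel$pls$class_cutoff
    use_rule <- pred$score >= cut - imodel$delta &
                pred$score <= cut + imodel$delta
  }
  out <- data.frame(
    score = pred$score,
    label = ifelse(use_rule, rule_lab, pred$label),
    provenance = ifelse(use_rule, "rule", "pls"),
    stringsAsFactors = FALSE)
  attr(out, "label_aware") <- imodel$mode == "oracle_eval"
  out
}
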
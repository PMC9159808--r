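# Confusion-matrix metrics (ACC, SEN, SPE, MCC) and repeated random-split
# robustness evaluation. Positive class = 1 (inhibitor).

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth equal-length binary vectors (0/1).
#' @return object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN` (and `n`).
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- as.numeric(predicted); truth <- as.numeric(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth have different lengths")
  if (length(truth) < 1L) stop("empty label vectors")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be binary 0/1")
  structure(list(
    TP = sum(predicted == 1 & truth == 1),
    TN = sum(predicted == 0 & truth == 0),
    FP = sum(predicted == 1 & truth == 0),
    FN = sum(predicted == 0 & truth == 1),
    n = length(truth)), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/n, SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' MCC = (TP*TN - FN*FP) / sqrt((TN+FN)(FN+TP)(TP+FP)(FP+TN)).
#' An empty SEN or SPE denominator yields `NA` with a warning (never a
#' silently optimistic 0 or 1); an MCC denominator of zero yields MCC = 0
#' by convention, with a message.
#'
#' @param counts a `confusion_counts`, or TP/TN/FP/FN passed directly.
#' @param TN,FP,FN counts when `counts` is given as the TP scalar.
#' @return list with `ACC`, `SEN`, `SPE`, `MCC`.
#' @export
compute_metrics <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- structure(list(TP = counts, TN = TN, FP = FP, FN = FN,
                             n = counts + TN + FP + FN),
                        class = "confusion_counts")
  }
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  n <- tp + tn + fp + fn
  if (n <= 0) stop("confusion counts sum to zero")
  acc <- (tp + tn) / n
  sen <- if (tp + fn == 0) {
    warning("SEN undefined: no positive samples"); NA_real_
  } else tp / (tp + fn)
  spe <- if (tn + fp == 0) {
    warning("SPE undefined: no negative samples"); NA_real_
  } else tn / (tn + fp)
  denom <- (tn + fn) * (fn + tp) * (tp + fp) * (fp + tn)
  mcc <- if (denom == 0) {
    message("MCC denominator zero; MCC set to 0 by convention")
    0
  } else (tp * tn - fn * fp) / sqrt(denom)
  list(ACC = acc, SEN = sen, SPE = spe, MCC = mcc)
}

#' Round metrics half-up to 2 decimals for report display
#'
#' R's `round()` rounds half to even; printed reports use half-up.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Repeated random-split robustness evaluation
#'
#' For each repeat: a seeded random split into training/validation at
#' `train_fraction`, model fit on the training part, accuracy on both
#' parts. Splits that leave the training part single-class are resampled
#' (the count of resamples is reported). Deterministic given `seed`.
#'
#' @param X predictor matrix; `y` binary labels.
#' @param fit_fun `function(X, y)` returning a fitted model.
#' @param predict_fun `function(model, X)` returning 0/1 labels.
#' @param n_repeats number of repeats (default 1000).
#' @param train_fraction fraction used for training (default 2/3, i.e. the
#'   2:1 split of the source protocol).
#' @param seed integer seed.
#' @return list with `summary` (mean/sd of training and validation ACC),
#'   `records` (data.frame with one row per repeat) and `n_resampled`.
#' @export
repeated_split_eval <- function(X, y, fit_fun, predict_fun,
                                n_repeats = 1000L, train_fraction = 2 / 3,
                                seed = 1L) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  n_train <- round(n * train_fraction)
  if (n_train < 2L || n_train >= n) stop("degenerate train_fraction")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  acc_tr <- numeric(n_repeats); acc_va <- numeric(n_repeats)
  n_resampled <- 0L
  for (r in seq_len(n_repeats)) {
    repeat {
      idx <- sample.int(n, n_train)
      if (length(unique(y[idx])) == 2L &&
          length(unique(y[-idx])) >= 1L) break
      n_resampled <- n_resampled + 1L
    }
    model <- fit_fun(X[idx, , drop = FALSE], y[idx])
    acc_tr[r] <- mean(predict_fun(model, X[idx, , drop = FALSE]) == y[idx])
    acc_va[r] <- mean(predict_fun(model, X[-idx, , drop = FALSE]) == y[-idx])
  }
  list(summary = data.frame(
         set = c("training", "validation"),
         mean_acc = c(mean(acc_tr), mean(acc_va)),
         sd_acc = c(stats::sd(acc_tr), stats::sd(acc_va))),
       records = data.frame(repeat_no = seq_len(n_repeats),
                            train_acc = acc_tr, validation_acc = acc_va),
       n_resampled = n_resampled)
}
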
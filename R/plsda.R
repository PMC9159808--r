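# PLS-DA: auto-scaling, NIPALS PLS1 on a 0/1 response, cross-validated
# component selection, prediction, JSON serialization.

#' Fit auto-scaling parameters
#'
#' Per-column mean and standard deviation (ddof = 1). Zero-variance columns
#' are dropped and recorded; the transform is `(x - mean) / sd` over the
#' kept columns.
#'
#' @param X numeric matrix, `n >= 2` rows, no missing values.
#' @return list with `means`, `sds` (over kept columns), `kept_columns`
#'   (integer indices into the original columns) and `dropped_columns`.
#' @export
autoscale_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows")
  if (anyNA(X)) stop("X contains missing values")
  mu <- unname(colMeans(X))
  sd <- unname(apply(X, 2, stats::sd))  # ddof = 1
  kept <- which(sd > 0)
  if (length(kept) == 0L) stop("all columns have zero variance")
  list(means = mu[kept], sds = sd[kept], kept_columns = unname(kept),
       dropped_columns = setdiff(seq_len(ncol(X)), kept))
}

.autoscale_apply <- function(X, sc) {
  X <- as.matrix(X)[, sc$kept_columns, drop = FALSE]
  sweep(sweep(X, 2, sc$means, "-"), 2, sc$sds, "/")
}

#' NIPALS PLS1 on pre-scaled data
#'
#' Classic NIPALS for a single response: `w = X'y / ||X'y||`, `t = Xw`,
#' `p = X't / t't`, `q = y't / t't`, deflate `X <- X - t p'`. Regression
#' coefficients are reconstructed as `b = W (P'W)^{-1} q` so that
#' `yhat = X b` on the scaled data.
#'
#' @param X_scaled centred/scaled predictor matrix.
#' @param y_centered centred response vector.
#' @param k number of latent variables requested.
#' @return list with `W`, `P` (p x k), `q` (length k), `coefficients`
#'   (length p), `scores` (n x k) and `k` (achieved components; may be less
#'   than requested if deflation degenerates, with a warning).
#' @export
fit_pls_nipals <- function(X_scaled, y_centered, k) {
  X <- as.matrix(X_scaled)
  y <- as.numeric(y_centered)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, k >= 1L)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); q <- numeric(0)
  Tm <- matrix(0, n, 0)
  Xd <- X
  eps <- 1e-12
  for (a in seq_len(k)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < eps) {
      warning("NIPALS deflation degenerated at component ", a,
              "; returning ", a - 1L, " components")
      break
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < eps) {
      warning("NIPALS score collapsed at component ", a,
              "; returning ", a - 1L, " components")
      break
    }
    pv <- crossprod(Xd, t) / tt
    qa <- sum(y * t) / tt
    Xd <- Xd - t %*% t(pv)
    W <- cbind(W, w); P <- cbind(P, pv); q <- c(q, qa); Tm <- cbind(Tm, t)
  }
  k_got <- ncol(W)
  if (k_got == 0L) stop("no PLS components could be extracted")
  b <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, q = q, coefficients = as.numeric(b), scores = Tm,
       k = k_got)
}

.stratified_folds <- function(y, folds, seed) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Select the number of PLS components by stratified k-fold CV
#'
#' For each `k = 1..k_max`, fits on the training folds and scores held-out
#' accuracy at the class cutoff; returns the `k` maximizing CV accuracy
#' (ties broken towards the smallest k). Deterministic given `seed`.
#'
#' @param X predictor matrix; `y` binary 0/1 response.
#' @param k_max largest component count to try (capped at the scaled-data
#'   rank bound `min(n - 1, p_kept)`).
#' @param folds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param cutoff class cutoff on the continuous score (default 0.5).
#' @return list with `n_components` and `cv_trace` (CV accuracy for each k,
#'   length `k_max` after capping).
#' @export
select_components_cv <- function(X, y, k_max = 15L, folds = 10L, seed = 1L,
                                 cutoff = 0.5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (min(table(y)) < folds)
    stop("too few samples of one class for ", folds, "-fold stratification")
  sc <- autoscale_fit(X)
  k_cap <- max(1L, min(as.integer(k_max), n - n %/% folds - 1L,
                       length(sc$kept_columns)))
  fold_of <- .stratified_folds(y, folds, seed)
  acc <- matrix(NA_real_, nrow = folds, ncol = k_cap)
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    model <- tryCatch(
      plsda_fit(X[tr, , drop = FALSE], y[tr], n_components = k_cap,
                cutoff = cutoff, select = FALSE),
      error = function(e) NULL)
    if (is.null(model)) next
    for (k in seq_len(model$n_components)) {
      pred <- .plsda_predict_k(model, X[te, , drop = FALSE], k)
      acc[f, k] <- mean(as.integer(pred$score >= cutoff) == y[te])
    }
  }
  cv_trace <- colMeans(acc, na.rm = TRUE)
  n_components <- which.max(cv_trace)  # which.max takes the first (smallest k)
  list(n_components = as.integer(n_components), cv_trace = cv_trace)
}

#' Fit a PLS-DA classifier
#'
#' Auto-scales `X`, centres the 0/1 response, runs NIPALS, and (by default)
#' chooses the component count by stratified 10-fold cross-validated
#' accuracy.
#'
#' @param X numeric predictor matrix (e.g. a hologram matrix).
#' @param y binary response, 1 = inhibitor, 0 = non-inhibitor.
#' @param n_components components to fit; when `select = TRUE` this is the
#'   upper bound `k_max` for CV selection.
#' @param folds,seed CV settings (used when `select = TRUE`).
#' @param cutoff class cutoff in (0, 1); scores `>= cutoff` classify as 1.
#' @param select choose the component count by CV (default `TRUE`).
#' @return object of class `plsda_model` with scaling parameters, NIPALS
#'   `W`, `P`, `q`, scaled-space `coefficients`, `intercept` (mean of y),
#'   original-scale `coef_original`, `n_components`, `class_cutoff`,
#'   `cv_trace`, `n_features` (pre-drop column count).
#' @export
plsda_fit <- function(X, y, n_components = 15L, folds = 10L, seed = 1L,
                      cutoff = 0.5, select = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0,1)")
  cv_trace <- NULL
  if (select) {
    sel <- select_components_cv(X, y, k_max = n_components, folds = folds,
                                seed = seed, cutoff = cutoff)
    n_components <- sel$n_components
    cv_trace <- sel$cv_trace
  }
  sc <- autoscale_fit(X)
  Xs <- .autoscale_apply(X, sc)
  k_cap <- min(as.integer(n_components), nrow(Xs) - 1L, ncol(Xs))
  fit <- fit_pls_nipals(Xs, y - mean(y), k_cap)
  coef_orig <- fit$coefficients / sc$sds
  model <- list(
    means = sc$means, sds = sc$sds,
    kept_columns = sc$kept_columns, dropped_columns = sc$dropped_columns,
    n_features = ncol(X), feature_names = colnames(X),
    W = fit$W, P = fit$P, q = fit$q,
    coefficients = fit$coefficients,
    coef_original = as.numeric(coef_orig),
    intercept = mean(y),
    n_components = fit$k, class_cutoff = cutoff,
    cv_trace = cv_trace, seed = as.integer(seed))
  class(model) <- "plsda_model"
  model
}

# prediction with the first k components of a fitted model
.plsda_predict_k <- function(model, X_new, k) {
  sc <- list(means = model$means, sds = model$sds,
             kept_columns = model$kept_columns)
  Xs <- .autoscale_apply(X_new, sc)
  W <- model$W[, seq_len(k), drop = FALSE]
  P <- model$P[, seq_len(k), drop = FALSE]
  q <- model$q[seq_len(k)]
  b <- W %*% solve(crossprod(P, W), q)
  score <- as.numeric(Xs %*% b) + model$intercept
  list(score = score, label = as.integer(score >= model$class_cutoff))
}

#' Predict with a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param X_new matrix with the same columns as the training matrix
#'   (pre-drop); a mismatch is an error naming the offending columns.
#' @param ... unused.
#' @return list with `score` (continuous) and `label` (1 iff
#'   `score >= class_cutoff`; the boundary classifies as 1).
#' @export
predict.plsda_model <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$n_features) {
    stop("X_new has ", ncol(X_new), " columns; model was trained on ",
         object$n_features)
  }
  if (!is.null(object$feature_names) && !is.null(colnames(X_new)) &&
      !identical(colnames(X_new), object$feature_names)) {
    bad <- colnames(X_new)[colnames(X_new) != object$feature_names]
    stop("X_new column names do not match training columns: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  .plsda_predict_k(object, X_new, object$n_components)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model: %d components, %d/%d features kept, cutoff %.2f>\n",
              x$n_components, length(x$kept_columns), x$n_features,
              x$class_cutoff))
  invisible(x)
}

#' Serialize / restore a PLS-DA model as JSON
#'
#' Round-tripping reproduces predictions bit-for-bit on the same platform
#' (all numbers written at full precision).
#'
#' @param model a `plsda_model`.
#' @param path JSON file.
#' @return `plsda_save` returns `path` invisibly; `plsda_load` the model.
#' @export
plsda_save <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  obj <- unclass(model)
  obj$W <- as.numeric(obj$W); obj$P <- as.numeric(obj$P)
  obj$dim_k <- ncol(model$W)
  obj$dim_p <- nrow(model$W)
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly,
  # so a reloaded model reproduces predictions bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname plsda_save
#' @export
plsda_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$dim_k; p <- obj$dim_p
  obj$W <- matrix(obj$W, p, k); obj$P <- matrix(obj$P, p, k)
  obj$dim_k <- NULL; obj$dim_p <- NULL
  obj$kept_columns <- as.integer(obj$kept_columns)
  obj$n_components <- as.integer(obj$n_components)
  class(obj) <- "plsda_model"
  obj
}
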
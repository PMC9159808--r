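# Stepwise linear-regression feature selection over a scalar descriptor
# table. The response is the binary class regressed by ordinary least
# squares, exactly as in the protocol this reproduces (not "upgraded" to
# logistic regression): the selection statistic is the partial F-test.

#' Stepwise (forward/backward) linear-regression variable selection
#'
#' Forward step: among excluded variables, add the one with the smallest
#' partial-F p-value if that p-value is `<= p_enter`. Backward step: remove
#' any included variable whose partial-F p-value is `>= p_remove`. Steps
#' alternate to a fixed point. Ties break by column order, so the procedure
#' is deterministic. Entry stops (with a message) whenever the residual
#' degrees of freedom would fall to `n - p - 2 <= 0`.
#'
#' @param X numeric descriptor matrix with named columns, no missing values.
#' @param y numeric response (here: binary class labels 0/1).
#' @param p_enter entry threshold on the partial-F p-value (default 0.02).
#' @param p_remove removal threshold (default 0.10); must exceed `p_enter`.
#' @return list with `selected` (character vector, entry order) and `trace`,
#'   a data.frame with columns `step`, `action` (`enter`/`remove`),
#'   `variable`, `r_squared`, `adj_r_squared` describing the model after
#'   each action.
#' @export
stepwise_select <- function(X, y, p_enter = 0.02, p_remove = 0.10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (!(p_enter < p_remove)) stop("p_enter must be smaller than p_remove")

  vars <- colnames(X)
  included <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), r_squared = numeric(0),
                      adj_r_squared = numeric(0), stringsAsFactors = FALSE)
  step <- 0L

  rss <- function(cols) {
    if (length(cols) == 0L) return(sum((y - mean(y))^2))
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    sum(fit$residuals^2)
  }
  r2_of <- function(cols) {
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss(cols) / tss
    p <- length(cols)
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    c(r2, adj)
  }
  partial_f_p <- function(cols_small, cols_big) {
    # p-value for the one extra variable in cols_big
    rss0 <- rss(cols_small); rss1 <- rss(cols_big)
    df2 <- n - length(cols_big) - 1L
    if (df2 <= 0L) return(NA_real_)
    f <- (rss0 - rss1) / (rss1 / df2)
    if (!is.finite(f) || f < 0) f <- 0
    stats::pf(f, 1, df2, lower.tail = FALSE)
  }

  repeat {
    changed <- FALSE
    # forward
    excluded <- setdiff(vars, included)
    if (length(excluded) > 0L && n - length(included) - 2L > 0L) {
      pv <- vapply(excluded, function(v) partial_f_p(included, c(included, v)),
                   numeric(1))
      ok <- which(!is.na(pv))
      if (length(ok) > 0L) {
        best <- ok[which.min(pv[ok])]  # ties -> first in column order
        if (pv[best] <= p_enter) {
          included <- c(included, excluded[best])
          step <- step + 1L
          r2 <- r2_of(included)
          trace <- rbind(trace, data.frame(
            step = step, action = "enter", variable = excluded[best],
            r_squared = r2[1], adj_r_squared = r2[2],
            stringsAsFactors = FALSE))
          changed <- TRUE
        }
      }
    } else if (length(excluded) > 0L && n - length(included) - 2L <= 0L) {
      message("stepwise: refusing to enter further variables (n too small)")
    }
    # backward
    repeat {
      if (length(included) == 0L) break
      pv <- vapply(included, function(v)
        partial_f_p(setdiff(included, v), included), numeric(1))
      worst <- which.max(pv)
      if (!is.na(pv[worst]) && pv[worst] >= p_remove) {
        victim <- included[worst]
        included <- setdiff(included, victim)
        step <- step + 1L
        r2 <- r2_of(included)
        trace <- rbind(trace, data.frame(
          step = step, action = "remove", variable = victim,
          r_squared = r2[1], adj_r_squared = r2[2], stringsAsFactors = FALSE))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(selected = included, trace = trace)
}

#' Write a stepwise trace as CSV
#'
#' Mirrors the "Entered in Sequence / Removed / R2 / Adjusted R2" layout of
#' the tabular selection reports.
#'
#' @param result output of [stepwise_select()].
#' @param path CSV destination.
#' @return the trace data.frame, invisibly.
#' @export
write_stepwise_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(result$trace)
}
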
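# plsda: auto-scaling, NIPALS, CV component selection, prediction, JSON IO

test_that("auto-scaling drops constants and scales with ddof = 1", {
  X <- cbind(a = c(0, 2, 0, 2), b = rep(5, 4), c = rnorm(4))
  sc <- autoscale_fit(X)
  expect_identical(sc$dropped_columns, 2L)
  expect_identical(sc$kept_columns, c(1L, 3L))
  # column {0,2}: mean 1, sd(ddof=1) over {0,2,0,2} = 2/sqrt(3); check the
  # documented two-point convention on an n=2 matrix
  sc2 <- autoscale_fit(cbind(x = c(0, 2), y = c(1, 3)))
  Xs <- holopls:::.autoscale_apply(cbind(x = c(0, 2), y = c(1, 3)), sc2)
  expect_equal(Xs[, "x"], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # scaled columns have mean 0 and sd 1
  set.seed(4)
  M <- matrix(rnorm(60), 12, 5)
  scm <- autoscale_fit(M)
  Ms <- holopls:::.autoscale_apply(M, scm)
  expect_equal(unname(colMeans(Ms)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Ms, 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_error(autoscale_fit(matrix(1, 5, 3)), "zero variance")
  expect_error(autoscale_fit(matrix(NA_real_, 3, 2)), "missing")
})

test_that("NIPALS reproduces a perfect predictor and OLS at full rank", {
  # p = 1 predictor equal to the centred response
  y <- c(0, 1, 1, 0, 1, 0, 0, 1)
  X <- matrix(y - mean(y), ncol = 1)
  f <- fit_pls_nipals(scale(X), y - mean(y), 1)
  expect_lt(max(abs(scale(X) %*% f$coefficients - (y - mean(y)))), 1e-10)
  # full-component coefficients equal least squares (independent lm oracle)
  set.seed(31)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(50 * 5), 50, 5)
    yr <- rnorm(50)
    Xs <- scale(Xr)
    fr <- fit_pls_nipals(Xs, yr - mean(yr), 5)
    b_ols <- unname(coef(lm(I(yr - mean(yr)) ~ Xs - 1)))
    expect_lt(max(abs(fr$coefficients - b_ols)), 1e-8)
    # score orthogonality
    G <- crossprod(fr$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
  # degenerate deflation stops early with a warning
  X1 <- matrix(rnorm(20), 20, 1)
  expect_warning(fd <- fit_pls_nipals(scale(X1), rnorm(20), 3), "component")
  expect_equal(fd$k, 1)
})

test_that("CV component selection is stratified, seeded, and sane", {
  # perfectly separable single feature -> k = 1
  xs <- matrix(c(rnorm(50, -2), rnorm(50, 2)), ncol = 1)
  ys <- rep(c(0, 1), each = 50)
  s <- select_components_cv(xs, ys, k_max = 1, folds = 10, seed = 1)
  expect_equal(s$n_components, 1L)
  expect_gt(s$cv_trace[1], 0.9)
  # null data: permuted labels give near-chance CV accuracy
  set.seed(5)
  Xn <- matrix(rnorm(200 * 50), 200, 50)
  yn <- rep(c(0, 1), 100)
  sn <- select_components_cv(Xn, yn, k_max = 10, folds = 10, seed = 5)
  expect_gte(max(sn$cv_trace), 0.40)
  expect_lte(max(sn$cv_trace), 0.60)
  expect_length(sn$cv_trace, 10)
  # seeded reproducibility
  sn2 <- select_components_cv(Xn, yn, k_max = 10, folds = 10, seed = 5)
  expect_identical(sn, sn2)
  # stratification guard
  expect_error(select_components_cv(Xn[1:12, ], c(rep(0, 9), rep(1, 3)),
                                    folds = 10),
               "too few samples")
})

test_that("prediction respects the cutoff convention and input contracts", {
  set.seed(6)
  X <- rbind(matrix(rnorm(100, -1), 50, 2), matrix(rnorm(100, 1), 50, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(0, 1), each = 50)
  model <- plsda_fit(X, y, n_components = 2, select = FALSE, seed = 6)
  pred <- predict(model, X)
  expect_gt(mean(pred$label == y), 0.85)
  # duplicated row -> identical score
  X2 <- X[c(1, 1, 2), ]
  p2 <- predict(model, X2)
  expect_identical(p2$score[1], p2$score[2])
  # column mismatch errors name the problem
  expect_error(predict(model, X[, 1, drop = FALSE]), "columns")
  Xbad <- X; colnames(Xbad) <- c("f1", "zz")
  expect_error(predict(model, Xbad), "zz")
  # boundary: a score exactly at the cutoff classifies as 1
  toy <- structure(list(
    means = 0, sds = 1, kept_columns = 1L, dropped_columns = integer(0),
    n_features = 1L, feature_names = NULL,
    W = matrix(1), P = matrix(1), q = 1,
    coefficients = 1, coef_original = 1, intercept = 0.5,
    n_components = 1L, class_cutoff = 0.5, cv_trace = NULL, seed = 1L),
    class = "plsda_model")
  at_cut <- predict(toy, matrix(0, 1, 1))
  expect_equal(at_cut$score, 0.5)
  expect_equal(at_cut$label, 1L)
})

test_that("separable training data reaches training accuracy 1", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c(0, 1), each = 30)
  model <- plsda_fit(X, y, n_components = 2, folds = 5, seed = 8)
  expect_equal(mean(predict(model, X)$label == y), 1)
})

test_that("JSON round-trip reproduces predictions bit-for-bit", {
  set.seed(9)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c(0, 1), 20)
  model <- plsda_fit(X, y, n_components = 3, select = FALSE, seed = 9)
  path <- tempfile(fileext = ".json")
  plsda_save(model, path)
  back <- plsda_load(path)
  expect_identical(predict(back, X)$score, predict(model, X)$score)
  # and the file itself is deterministic
  path2 <- tempfile(fileext = ".json")
  plsda_save(model, path2)
  expect_identical(readLines(path), readLines(path2))
})
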
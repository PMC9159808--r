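# contribution_map: projecting PLS coefficients back onto atoms

# synthetic model whose original-scale coefficient is `value` for every bin
.unit_model <- function(L, value = 1) {
  structure(list(
    means = numeric(L), sds = rep(1, L), kept_columns = seq_len(L),
    dropped_columns = integer(0), n_features = L, feature_names = NULL,
    W = matrix(0, L, 1), P = matrix(0, L, 1), q = 0,
    coefficients = rep(value, L), coef_original = rep(value, L),
    intercept = 0.5, n_components = 1L, class_cutoff = 0.5,
    cv_trace = NULL, seed = 1L), class = "plsda_model")
}

test_that("a single-fragment molecule splits its coefficient evenly", {
  eth <- smiles_to_molecule("CC")
  cfg <- hologram_config(2, 2, "A", 53)
  ac <- atomic_contributions(eth, .unit_model(53, 3), cfg)
  expect_equal(ac$scores, c(1.5, 1.5))
  expect_equal(ac$total, 3)
})

test_that("contributions conserve the occurrence-coefficient sum", {
  set.seed(33)
  cfg <- hologram_config(1, 5, c("A", "C"), 53)
  model <- .unit_model(53)
  model$coef_original <- rnorm(53)
  for (smi in c("c1ccccc1", "c1ccc2ncccc2c1", "CC(N)C(=O)O",
                "C1Oc2ccccc2C=C1", "CCO")) {
    m <- smiles_to_molecule(smi)
    ac <- atomic_contributions(m, model, cfg)
    expect_equal(sum(ac$scores), ac$total, tolerance = 1e-12)
    # independent recomputation of the total from the fragment set
    f <- enumerate_fragments(m, cfg)
    expect_equal(ac$total,
                 sum(model$coef_original[hash_to_bin(f$key, 53)]),
                 tolerance = 1e-12)
  }
  # conservation also holds with explicit hydrogens in fragments
  cfg_h <- hologram_config(1, 4, c("A", "H"), 53)
  ach <- atomic_contributions(smiles_to_molecule("CCO"), model, cfg_h)
  expect_equal(sum(ach$scores), ach$total, tolerance = 1e-12)
})

test_that("symmetry-equivalent atoms score identically", {
  set.seed(34)
  model <- .unit_model(53)
  model$coef_original <- rnorm(53)
  cfg <- hologram_config(1, 4, c("A", "C"), 53)
  benz <- atomic_contributions(smiles_to_molecule("c1ccccc1"), model, cfg)
  expect_equal(max(benz$scores) - min(benz$scores), 0)
  # para-xylene: the two methyls equal, the four equivalent ring CH equal
  px <- atomic_contributions(smiles_to_molecule("Cc1ccc(C)cc1"), model, cfg)
  m <- smiles_to_molecule("Cc1ccc(C)cc1")
  methyls <- which(m$atoms$element == "C" & !m$atoms$aromatic)
  expect_equal(px$scores[methyls[1]], px$scores[methyls[2]])
  # isomorphic molecules: identical score multisets
  a <- atomic_contributions(smiles_to_molecule("NC(=O)c1ccccc1"), model, cfg)
  b <- atomic_contributions(smiles_to_molecule("c1ccccc1C(N)=O"), model, cfg)
  expect_equal(sort(a$scores), sort(b$scores), tolerance = 1e-12)
})

test_that("zero-coefficient models annotate zero everywhere, round-trip ok", {
  m <- smiles_to_molecule("CC(N)C(=O)O", "ala")
  cfg <- hologram_config(1, 4, "A", 53)
  ac <- atomic_contributions(m, .unit_model(53, 0), cfg)
  expect_true(all(ac$scores == 0))
  model <- .unit_model(53)
  set.seed(35)
  model$coef_original <- rnorm(53)
  ac2 <- atomic_contributions(m, model, cfg)
  ann <- annotate_contributions(m, ac2)
  expect_equal(nrow(ann), nrow(m$atoms))
  path <- tempfile(fileext = ".csv")
  write_contributions(ann, path)
  back <- utils::read.csv(path)
  expect_equal(back$score, ac2$scores, tolerance = 1e-15)
  # contract errors
  ac_bad <- ac2; ac_bad$scores <- ac_bad$scores[-1]
  expect_error(annotate_contributions(m, ac_bad), "length")
  expect_error(atomic_contributions(m, model, hologram_config(1, 4, "A", 353)),
               "mismatch")
})

test_that("a class-separating fragment earns the top positive scores", {
  # two-molecule training set where the pyridine ring separates the classes
  mols <- lapply(c(pos = "c1ccncc1CC", neg = "CCCCCC"), smiles_to_molecule)
  cfg <- hologram_config(2, 4, c("A", "C"), 53)
  X <- hologram_matrix(mols, cfg)
  # replicate rows so autoscaling/fitting has something to work with
  Xr <- X[rep(1:2, each = 5), ]
  yr <- rep(c(1, 0), each = 5)
  model <- plsda_fit(Xr, yr, n_components = 1, select = FALSE)
  ac <- atomic_contributions(mols[[1]], model, cfg)
  ring <- mols[[1]]$atoms$aromatic
  expect_gt(mean(ac$scores[ring]), mean(ac$scores[!ring]))
})
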
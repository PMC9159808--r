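# molecule_io: parsing, standardization, fingerprints, diversity selection

test_that("SMILES files load with order preserved and rejects reported", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene",
               "CCO ethanol",
               "CC(=O)[O-].[Na+] salt",
               "not_a_smiles)( broken"), smi)
  expect_warning(mols <- load_molecules(smi), "rejected")
  expect_length(mols, 3)
  expect_identical(vapply(mols, function(m) m$id, character(1)),
                   c("benzene", "ethanol", "salt"))
  # benzene: 6 aromatic carbons
  expect_equal(nrow(mols[[1]]$atoms), 6)
  expect_true(all(mols[[1]]$atoms$element == "C"))
  expect_true(all(mols[[1]]$atoms$aromatic))
  # ethanol: 3 heavy atoms, degrees 1,2,1
  expect_equal(nrow(mols[[2]]$atoms), 3)
  expect_identical(sort(mols[[2]]$atoms$degree), c(1L, 1L, 2L))
  # salt: counterion removed, acetate kept (4 heavy atoms)
  expect_equal(nrow(mols[[3]]$atoms), 4)
  expect_false("Na" %in% mols[[3]]$atoms$element)
  rej <- attr(mols, "rejects")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$line_no, 4L)
  expect_error(load_molecules(tempfile()), "cannot read")
})

test_that("standardization is canonical, idempotent, and breaks C.C ties", {
  forms <- c("c1ccccc1C(=O)N", "NC(=O)c1ccccc1", "C(N)(=O)c1ccccc1")
  mols <- lapply(forms, smiles_to_molecule)
  cs <- vapply(mols, function(m) m$canonical_smiles, character(1))
  expect_length(unique(cs), 1)
  keys <- vapply(mols, function(m) m$mol_key, character(1))
  expect_length(unique(keys), 1)
  # idempotence: re-standardizing the canonical form changes nothing
  again <- smiles_to_molecule(cs[1])
  expect_identical(again$canonical_smiles, cs[1])
  expect_identical(again$mol_key, keys[1])
  # degenerate tie: two single carbons -> one kept
  cc <- smiles_to_molecule("C.C")
  expect_equal(nrow(cc$atoms), 1)
  expect_identical(cc$atoms$element, "C")
  # quinoline: 10 heavy atoms, exactly one aromatic N
  q <- smiles_to_molecule("c1ccc2ncccc2c1")
  expect_equal(nrow(q$atoms), 10)
  expect_equal(sum(q$atoms$element == "N" & q$atoms$aromatic), 1)
  expect_error(smiles_to_molecule(""), "empty")
})

test_that("SDF records parse to the same standardized molecules", {
  sdf <- tempfile(fileext = ".sdf")
  writeLines(c(
    "ethanol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END",
    "$$$$",
    "benzene", "  test", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    paste0("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0",
           "  0  0  0  0  0  0")[rep(1, 6)],
    "  1  2  4  0  0  0  0",
    "  2  3  4  0  0  0  0",
    "  3  4  4  0  0  0  0",
    "  4  5  4  0  0  0  0",
    "  5  6  4  0  0  0  0",
    "  6  1  4  0  0  0  0",
    "M  END",
    "$$$$"), sdf)
  mols <- load_molecules(sdf, "sdf")
  expect_length(mols, 2)
  expect_identical(mols[[1]]$canonical_smiles,
                   smiles_to_molecule("CCO")$canonical_smiles)
  expect_identical(mols[[2]]$canonical_smiles,
                   smiles_to_molecule("c1ccccc1")$canonical_smiles)
})

test_that("circular fingerprints are order-invariant and discriminate", {
  f1 <- circular_fingerprint(smiles_to_molecule("c1ccccc1"))
  f2 <- circular_fingerprint(smiles_to_molecule("c1ccccc1"))
  expect_identical(f1$on_bits, f2$on_bits)
  # shuffled-input invariance across several molecules
  pairs <- list(c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"),
                c("OCCN", "NCCO"),
                c("c1ccc2ncccc2c1", "n1cccc2ccccc12"))
  for (p in pairs) {
    a <- circular_fingerprint(smiles_to_molecule(p[1]))
    b <- circular_fingerprint(smiles_to_molecule(p[2]))
    expect_identical(a$on_bits, b$on_bits)
  }
  cyc <- circular_fingerprint(smiles_to_molecule("C1CCCCC1"))
  expect_lt(1 - tanimoto_distance(f1, cyc), 1)
  ch4 <- circular_fingerprint(smiles_to_molecule("C"))
  expect_gte(length(ch4$on_bits), 1)
  expect_true(all(ch4$on_bits >= 0 & ch4$on_bits < ch4$n_bits))
  expect_error(circular_fingerprint(smiles_to_molecule("C"), n_bits = 32),
               ">= 64")
})

test_that("tanimoto distance follows the bit-set formula", {
  fp <- function(bits) structure(list(id = "x", on_bits = as.integer(bits),
                                      radius = 3L, n_bits = 2048L),
                                 class = "circ_fp")
  expect_equal(tanimoto_distance(fp(c(1, 5, 9)), fp(c(1, 5, 9))), 0)
  expect_equal(tanimoto_distance(fp(1:3), fp(4:6)), 1)
  expect_equal(tanimoto_distance(fp(1:3), fp(2:4)), 0.5)
  # symmetry
  expect_equal(tanimoto_distance(fp(1:4), fp(3:9)),
               tanimoto_distance(fp(3:9), fp(1:4)))
  expect_message(d <- tanimoto_distance(fp(integer(0)), fp(integer(0))),
                 "empty")
  expect_equal(d, 0)
  expect_error(tanimoto_distance(fp(1), structure(list(on_bits = 1L,
                                                       n_bits = 1024L),
                                                  class = "circ_fp")),
               "n_bits")
})

test_that("MaxMin selection is greedy, deterministic, and duplicate-aware", {
  smis <- c("c1ccccc1", "C1CCCCC1", "CCO", "CCCCCCCC", "c1ccncc1")
  fps <- lapply(seq_along(smis),
                function(i) circular_fingerprint(smiles_to_molecule(smis[i],
                                                                    paste0("m", i))))
  # n_select = population -> everything selected
  all_sel <- maxmin_diverse_select(fps, length(fps), seed = 3)
  expect_setequal(all_sel$selected_ids, paste0("m", 1:5))
  expect_length(all_sel$remaining_ids, 0)
  # determinism under a fixed seed
  s1 <- maxmin_diverse_select(fps, 3, seed = 11)
  s2 <- maxmin_diverse_select(fps, 3, seed = 11)
  expect_identical(s1, s2)
  # greedy oracle: replay the algorithm independently from the same start
  D <- outer(seq_along(fps), seq_along(fps),
             Vectorize(function(i, j) tanimoto_distance(fps[[i]], fps[[j]])))
  for (seed in 1:5) {
    got <- maxmin_diverse_select(fps, 3, seed = seed)
    sel <- got$selected_idx[1]
    while (length(sel) < 3) {
      mind <- apply(D[, sel, drop = FALSE], 1, min)
      mind[sel] <- -Inf
      sel <- c(sel, which.max(mind))
    }
    expect_identical(got$selected_idx, sel)
  }
  # duplicate pair: never both duplicates before a zero-distance pick forced
  dup_fps <- lapply(list("c1ccccc1", "c1ccccc1", "CCO", "CCCCO"),
                    function(s) circular_fingerprint(smiles_to_molecule(s, s)))
  for (seed in 1:8) {
    got <- maxmin_diverse_select(dup_fps, 3, seed = seed)
    first_two <- got$selected_idx[1:2]
    expect_false(all(c(1, 2) %in% first_two))
  }
  expect_error(maxmin_diverse_select(fps, 6, seed = 1), "between 1 and")
})
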
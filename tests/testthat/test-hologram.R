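# hologram: fragment enumeration, canonical keys, CRC hashing, matrices

test_that("config validation enforces window and length constraints", {
  expect_s3_class(hologram_config(), "hologram_config")
  expect_error(hologram_config(0, 4), "window")
  expect_error(hologram_config(5, 12), "window")
  expect_error(hologram_config(5, 4), "window")
  expect_error(hologram_config(1, 4, "A", 100), "length_L")
  expect_error(hologram_config(1, 4, "Z"), "distinction")
})

test_that("enumeration matches hand-derived counts on tiny molecules", {
  benz <- smiles_to_molecule("c1ccccc1")
  f <- enumerate_fragments(benz, hologram_config(1, 4, "A", 353))
  # 6 paths each of 1..4 aromatic carbons on the C6 cycle
  expect_length(f$key, 24)
  expect_length(unique(f$key), 4)
  expect_true(all(table(f$key) == 6))

  eth <- smiles_to_molecule("CCO")
  f2 <- enumerate_fragments(eth, hologram_config(1, 2, "A", 353))
  expect_length(f2$key, 5)        # C, C, O, C-C, C-O
  expect_length(unique(f2$key), 4)

  ch4 <- smiles_to_molecule("C")
  f3 <- enumerate_fragments(ch4, hologram_config(1, 4, "A", 353))
  expect_length(f3$key, 1)

  # H flag: methane's H-explicit star has 20 induced connected subgraphs
  # (C with any subset of 4 H's = 16, minus empty, plus 4 H singletons,
  # plus the C singleton counted in the 16)
  f4 <- enumerate_fragments(ch4, hologram_config(1, 5, c("A", "H"), 353))
  expect_length(f4$key, 20)
  expect_length(unique(f4$key), 6)  # H, C, CH, CH2, CH3, CH4
})

test_that("distinction flags change fragment identity as documented", {
  prop <- smiles_to_molecule("CCC")
  cfg_a <- hologram_config(1, 3, "A", 353)
  cfg_ac <- hologram_config(1, 3, c("A", "C"), 353)
  # terminal carbons identical under {A}
  expect_identical(canonical_fragment_key(prop, 1, cfg_a),
                   canonical_fragment_key(prop, 3, cfg_a))
  # terminal vs middle differ under {A,C} (parent degree 1 vs 2)
  expect_false(identical(canonical_fragment_key(prop, 1, cfg_ac),
                         canonical_fragment_key(prop, 2, cfg_ac)))
  # terminal vs terminal still identical under {A,C}
  expect_identical(canonical_fragment_key(prop, 1, cfg_ac),
                   canonical_fragment_key(prop, 3, cfg_ac))
  # non-isomorphic graphs: C-C-C path vs cyclopropane ring
  ring <- smiles_to_molecule("C1CC1")
  expect_false(identical(canonical_fragment_key(prop, 1:3, cfg_a),
                         canonical_fragment_key(ring, 1:3, cfg_a)))
  # bond orders only matter under B
  prpe <- smiles_to_molecule("C=CC")
  cfg_b <- hologram_config(1, 3, c("A", "B"), 353)
  expect_identical(canonical_fragment_key(prop, 1:3, cfg_a),
                   canonical_fragment_key(prpe, 1:3, cfg_a))
  expect_false(identical(canonical_fragment_key(prop, 1:3, cfg_b),
                         canonical_fragment_key(prpe, 1:3, cfg_b)))
  expect_error(canonical_fragment_key(prop, c(1, 3), cfg_a), "connected")
})

test_that("CRC hashing is deterministic, in range, and zlib-compatible", {
  # independent oracle values: R bitwise implementation + frozen zlib values
  expect_equal(crc32("abc"), oracle_crc32("abc"))
  expect_equal(crc32("abc"), 891568578)  # zlib.crc32(b"abc")
  benz <- smiles_to_molecule("c1ccccc1")
  key <- canonical_fragment_key(benz, 1:4, hologram_config(1, 4, "A", 353))
  expect_identical(key, "C&ar|C&ar|C&ar|C&ar||0-1:,0-2:,1-3:")
  expect_equal(crc32(key), 147803831)        # zlib.crc32 of the key string
  expect_equal(crc32(key), oracle_crc32(key))
  expect_equal(hash_to_bin(key, 353), 261L)  # 147803831 %% 353 + 1
  # range and determinism over many keys
  f <- enumerate_fragments(smiles_to_molecule("c1ccc2ncccc2c1"),
                           hologram_config(1, 6, c("A", "C"), 353))
  bins <- hash_to_bin(f$key, 53)
  expect_true(all(bins >= 1 & bins <= 53))
  expect_identical(bins, hash_to_bin(f$key, 53))
  expect_error(hash_to_bin("", 353), "empty")
})

test_that("holograms conserve occurrence counts", {
  benz <- smiles_to_molecule("c1ccccc1")
  h0 <- build_hologram(character(0), 353)
  expect_equal(h0$total_fragments, 0)
  expect_true(all(h0$bins == 0))
  f <- enumerate_fragments(benz, hologram_config(1, 4, "A", 353))
  h <- build_hologram(f, 353)
  expect_equal(sum(h$bins), 24)
  expect_equal(h$total_fragments, 24)
  # total conserved across hologram lengths (collisions only move counts)
  for (smi in c("c1ccc2ncccc2c1", "CC(N)C(=O)O", "C1Oc2ccccc2C=C1")) {
    fr <- enumerate_fragments(smiles_to_molecule(smi), hologram_config())
    expect_equal(sum(build_hologram(fr, 53)$bins),
                 sum(build_hologram(fr, 353)$bins))
  }
  expect_error(build_hologram(f, 100), "one of")
})

test_that("holograms are invariant under 20 random atom relabelings", {
  cfg <- hologram_config()
  smis <- c("c1ccc(-c2ccccc2)cc1", "C1Oc2ccccc2C=C1", "CC(N)C(=O)O",
            "c1cc(Cl)c2ncccc2c1")
  set.seed(99)
  for (smi in smis) {
    raw <- parse_smiles(smi)
    ref <- build_hologram(enumerate_fragments(standardize_molecule(raw), cfg),
                          cfg$length_L)
    for (i in 1:20) {
      perm <- sample.int(nrow(raw$atoms))
      m2 <- standardize_molecule(permute_molecule(raw, perm))
      h2 <- build_hologram(enumerate_fragments(m2, cfg), cfg$length_L)
      expect_identical(h2, ref)
    }
  }
})

test_that("widening the size window never decreases total fragments", {
  mols <- lapply(c("c1ccccc1", "CCCCO", "c1ccc2ncccc2c1"), smiles_to_molecule)
  for (m in mols) {
    totals <- vapply(1:8, function(mx) {
      length(enumerate_fragments(m, hologram_config(1, min(mx, 11), "A"))$key)
    }, numeric(1))
    expect_true(all(diff(totals) >= 0))
  }
})

test_that("hologram_matrix shapes, conservation, and error handling", {
  mols <- lapply(c("c1ccccc1", "c1ccccc1", "CCO"), smiles_to_molecule)
  mols <- lapply(seq_along(mols), function(i) { mols[[i]]$id <- paste0("m", i); mols[[i]] })
  cfg <- hologram_config(1, 4, "A", 53)
  X <- hologram_matrix(mols, cfg)
  expect_equal(dim(X), c(3, 53))
  expect_identical(X[1, ], X[2, ])  # identical molecules, identical rows
  expect_equal(unname(rowSums(X)),
               vapply(mols, function(m)
                 length(enumerate_fragments(m, cfg)$key), numeric(1)))
  # enumeration cap triggers the error path
  tight <- hologram_config(1, 4, "A", 53, cap = 3)
  expect_error(hologram_matrix(mols, tight), "m1")
  expect_warning(Xs <- hologram_matrix(mols, tight, skip_errors = TRUE),
                 "row set to NA")
  expect_true(all(is.na(Xs[1, ])))
  expect_error(hologram_matrix(list(), cfg), "empty")
})
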
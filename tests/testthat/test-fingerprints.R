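# fingerprint dialects and Tanimoto identities

test_that("Tanimoto identities hold", {
  f4 <- circular_fp(rec(VARIED_SMILES[1]), 4)
  expect_equal(tanimoto(f4, f4), 1)
  a <- screenrank:::new_fp("X", "binary", c(1, 2, 3))
  b <- screenrank:::new_fp("X", "binary", c(2, 3, 4))
  d <- screenrank:::new_fp("X", "binary", c(9, 10))
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(b, a), 0.5)
  expect_equal(tanimoto(a, d), 0)
  expect_error(tanimoto(a, screenrank:::new_fp("Y", "binary", 1)), "mismatch")
  e <- screenrank:::new_fp("X", "binary", numeric(0))
  expect_warning(z <- tanimoto(e, e), "empty")
  expect_equal(z, 0)
  # count form: sum(min)/sum(max)
  ca <- screenrank:::new_fp("C", "count", c(a = 2L, b = 1L))
  cb <- screenrank:::new_fp("C", "count", c(a = 1L, c = 3L))
  expect_equal(tanimoto(ca, cb), (1 + 0 + 0) / (2 + 1 + 3))
})

test_that("ECFP feature sets nest across diameters for every molecule", {
  for (smi in VARIED_SMILES) {
    r <- rec(smi)
    f2 <- circular_fp(r, 2)$features
    f4 <- circular_fp(r, 4)$features
    f6 <- circular_fp(r, 6)$features
    expect_true(all(f2 %in% f4))
    expect_true(all(f4 %in% f6))
  }
})

test_that("circular fingerprints reflect graph symmetry and atom order", {
  benzene <- circular_fp(rec("c1ccccc1"), 2)
  expect_lte(length(benzene$features), 2L)
  # same structure from different SMILES writings
  a <- circular_fp(rec("CC(=O)Oc1ccccc1C(=O)O"), 4)
  b <- circular_fp(rec("OC(=O)c1ccccc1OC(C)=O"), 4)
  expect_identical(a$features, b$features)
  # FCFP differs from ECFP but is itself order-invariant
  fa <- circular_fp(rec("CC(=O)Oc1ccccc1C(=O)O"), 4, functional_class = TRUE)
  fb <- circular_fp(rec("OC(=O)c1ccccc1OC(C)=O"), 4, functional_class = TRUE)
  expect_identical(fa$features, fb$features)
  expect_false(identical(a$features, fa$features))
})

test_that("structural keys are representation-invariant", {
  k1 <- structural_keys(rec("c1ccc2c(c1)cccn2"))
  k2 <- structural_keys(rec("C1=CC2=CC=CC=C2N=C1"))  # same molecule, kekulized
  expect_identical(k1$features, k2$features)
  expect_lte(length(structural_keys(rec("C"))$features), 2L)
  expect_gt(length(k1$features), 5L)
})

test_that("pharmacophore fingerprints encode typed distances", {
  expect_true(pharmacophore_fp(rec("C"), 2)$flagged)
  para <- pharmacophore_fp(rec("Nc1ccc(N)cc1"), 2)
  meta <- pharmacophore_fp(rec("Nc1cccc(N)c1"), 2)
  expect_false(identical(para$features, meta$features))
  # identical molecules: identical fingerprints in every dialect
  for (d in fingerprint_dialects()) {
    fa <- compute_fingerprint(rec(VARIED_SMILES[4]), d)
    fb <- compute_fingerprint(rec(VARIED_SMILES[4]), d)
    expect_identical(fa$features, fb$features)
  }
})

test_that("every dialect tag dispatches and tags its output", {
  r <- rec(VARIED_SMILES[1])
  for (d in fingerprint_dialects()) {
    fp <- compute_fingerprint(r, d)
    expect_s3_class(fp, "sr_fp")
    expect_equal(fp$dialect, d)
  }
  expect_error(compute_fingerprint(r, "ECFP_8"), "unknown")
})
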
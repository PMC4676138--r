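# salt stripping, classification, standardization, deduplication

test_that("largest_fragment strips recognized counter-ions only", {
  r <- rec("CCO")
  expect_identical(largest_fragment(r)$smiles, r$smiles)
  salt <- largest_fragment(rec("CC(=O)[O-].[Na+]"))
  expect_identical(salt$smiles, screenrank:::ob_canonical("CC(=O)[O-]"))
  expect_true("salt_stripped" %in% salt$flags)
  # equal-size organic fragments: untouched, mixture candidate
  mix <- largest_fragment(rec("OCCc1ccccc1.NCCc1ccccc1"))
  expect_true("mixture_candidate" %in% mix$flags)
  expect_length(screenrank:::sr_components(mix$mol), 2L)
})

test_that("classification order is inorganic, mixture, bad valence", {
  expect_equal(classify_record(rec("[Fe]")), "inorganic")
  expect_equal(classify_record(rec("[Na+].[Cl-]")), "inorganic")  # carbon-free
  expect_equal(classify_record(rec("CCO.OCC")), "mixture")
  expect_equal(classify_record(rec("CC(C)(C)(C)C")), "bad_valence")
  expect_equal(classify_record(rec("CCO")), "ok")
  expect_equal(classify_record(rec("O=[Si]=O")), "inorganic")  # disallowed element
})

test_that("standardization applies pH 7.4 rules and one tautomer", {
  expect_identical(standardize(rec("CC(=O)O"))$smiles,
                   screenrank:::ob_canonical("CC(=O)[O-]"))
  expect_identical(standardize(rec("c1ccccc1"))$smiles,
                   screenrank:::ob_canonical("c1ccccc1"))
  # keto and enol inputs converge on one canonical key
  keto <- standardize(rec("CC(=O)CC"))
  enol <- standardize(rec("C/C(O)=C/C"))
  expect_identical(keto$canonical_key, enol$canonical_key)
  # aliphatic amine protonated; aniline and amide are not
  expect_identical(standardize(rec("CCN"))$smiles, screenrank:::ob_canonical("CC[NH3+]"))
  expect_identical(standardize(rec("Nc1ccccc1"))$smiles,
                   screenrank:::ob_canonical("Nc1ccccc1"))
  expect_identical(standardize(rec("CC(=O)NC"))$smiles,
                   screenrank:::ob_canonical("CC(=O)NC"))
  # sulfonic acid deprotonated; guanidine protonated
  expect_identical(standardize(rec("CS(=O)(=O)O"))$smiles,
                   screenrank:::ob_canonical("CS(=O)(=O)[O-]"))
  expect_identical(standardize(rec("NC(=N)N"))$smiles,
                   screenrank:::ob_canonical("NC(=[NH2+])N"))
})

test_that("standardization is idempotent", {
  for (smi in c("CC(=O)O", "CCN", "NC(=N)N", "C/C(O)=C/C", "CS(=O)(=O)O",
                VARIED_SMILES)) {
    once <- standardize(rec(smi))
    twice <- standardize(once)
    expect_identical(twice$canonical_key, once$canonical_key)
  }
})

test_that("deduplication keeps first occurrences in input order", {
  rs <- lapply(c("CCO", "CCN", "CCC"), rec)
  expect_equal(deduplicate(rs)$n_duplicates, 0L)
  # free acid and sodium salt strip+standardize to the same key
  a <- standardize(largest_fragment(rec("CC(=O)Oc1ccccc1C(=O)O")))
  b <- standardize(largest_fragment(rec("CC(=O)Oc1ccccc1C(=O)[O-].[Na+]")))
  dd <- deduplicate(list(a, b))
  expect_equal(dd$n_duplicates, 1L)
  expect_identical(dd$kept[[1]]$record_id, a$record_id)
  same4 <- lapply(rep("c1ccccc1", 4), rec)
  expect_equal(deduplicate(same4)$n_duplicates, 3L)
})

test_that("curation report percentages are exact and partition removals", {
  fx <- generate_fixture_library(c(clean = 9, inorganic = 1), seed = 8)
  rep1 <- curate(fx$library)$report
  expect_equal(rep1$inorganic_pct, 10)
  expect_equal(rep1$total_out, 9L)

  fx2 <- generate_fixture_library(c(clean = 3, mixture = 1, duplicate_pair = 1), seed = 9)
  rep2 <- curate(fx2$library)$report
  expect_equal(rep2$total_in, 6L)
  expect_equal(rep2$total_removed_pct, 100 * 2 / 6, tolerance = 1e-12)
  expect_equal(rep2$total_in - rep2$total_out,
               rep2$inorganic + rep2$duplicate + rep2$mixture +
                 rep2$bad_valence + rep2$parse_failure)
})

test_that("curation is idempotent", {
  fx <- generate_fixture_library(
    c(clean = 6, salt = 2, inorganic = 1, mixture = 1, duplicate_pair = 1),
    seed = 10)
  first <- curate(fx$library)
  second <- curate(first$library)
  expect_equal(second$report$total_in, second$report$total_out)
  expect_identical(screenrank:::lib_keys(second$library),
                   screenrank:::lib_keys(first$library))
})
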
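# diversity, MaxMin, coverage, similarity ranking, enrichment, overlap

test_that("mean pairwise similarity matches direct computation", {
  lib2 <- lib_from_smiles(VARIED_SMILES[1:2])
  fps <- lib_fingerprints(lib2, "ECFP_2")
  expect_equal(as.numeric(mean_pairwise_similarity(lib2, "ECFP_2")),
               tanimoto(fps[[1]], fps[[2]]))
  lib_same <- lib_from_smiles(rep(VARIED_SMILES[1], 4))
  expect_equal(as.numeric(mean_pairwise_similarity(lib_same, "ECFP_2")), 1)
  expect_error(mean_pairwise_similarity(lib_from_smiles(VARIED_SMILES[1]), "ECFP_2"),
               "at least 2")
})

test_that("sampled mean pairwise similarity approximates the exhaustive mean", {
  pool <- screenrank:::CLEAN_POOL
  smiles <- rep(pool, length.out = 60)
  lib <- lib_from_smiles(smiles, "big")
  exact <- as.numeric(mean_pairwise_similarity(lib, "ECFP_2"))
  est <- mean_pairwise_similarity(lib, "ECFP_2", max_pairs = 600, seed = 5)
  expect_true(attr(est, "sampled"))
  expect_equal(attr(est, "n_pairs"), 600L)
  expect_lt(abs(as.numeric(est) - exact), 0.02)
})

test_that("MaxMin selection is greedy and deterministic", {
  lib <- lib_from_smiles(VARIED_SMILES)
  expect_length(maxmin_select(lib, "ECFP_2", length(VARIED_SMILES)), length(VARIED_SMILES))
  expect_error(maxmin_select(lib, "ECFP_2", 99), "k must be")
  # A, B identical, C distinct, first pick A -> picks C next
  labc <- lib_from_smiles(c(VARIED_SMILES[1], VARIED_SMILES[1], VARIED_SMILES[9]))
  expect_equal(maxmin_select(labc, "ECFP_2", 2, first_pick = 1), c(1L, 3L))
  # determinism
  s1 <- maxmin_select(lib, "ECFP_4", 5)
  s2 <- maxmin_select(lib, "ECFP_4", 5)
  expect_identical(s1, s2)
  # greedy property vs brute force: each successive pick maximizes its
  # min distance to the selected set (checked directly on <= 10 molecules)
  fps <- lib_fingerprints(lib, "ECFP_4")
  D <- outer(seq_along(fps), seq_along(fps),
             Vectorize(function(i, j) 1 - tanimoto(fps[[i]], fps[[j]])))
  sel <- maxmin_select(lib, "ECFP_4", 6)
  mind_seq <- numeric(0)
  for (step in 2:length(sel)) {
    prev <- sel[seq_len(step - 1)]
    cand_mind <- vapply(setdiff(seq_along(fps), prev),
                        function(j) min(D[j, prev]), 0)
    picked_mind <- min(D[sel[step], prev])
    expect_equal(picked_mind, max(cand_mind), tolerance = 1e-12)
    mind_seq <- c(mind_seq, picked_mind)
  }
  expect_true(all(diff(mind_seq) <= 1e-12))  # non-increasing over the run
})

test_that("coverage curves behave at the extremes and beat random selection", {
  # ten structurally distinct molecules, one label each
  lib <- lib_from_smiles(VARIED_SMILES)
  ls <- labeled_set(lib, paste0("target_", 1:10), min_members = 1L)
  cc <- coverage_curve(ls, "ECFP_4", sizes = c(3L, 10L))
  expect_equal(cc$coverage_pct[cc$size == 10], 100)
  # one label -> 100 % at any size
  ls1 <- labeled_set(lib, rep("only", 10), min_members = 1L)
  expect_true(all(coverage_curve(ls1, "ECFP_4", c(1L, 5L))$coverage_pct == 100))
  # clustered set: MaxMin covers all labels at k = n_labels, random does not
  clustered <- c("CCCCCCCC", "CCCCCCCCC", "c1ccccc1", "Cc1ccccc1",
                 "CCO", "CCCO", "CCN", "CCCN", "CC(=O)O", "CCC(=O)O")
  lsc <- labeled_set(lib_from_smiles(clustered),
                     rep(c("alkane", "arene", "alcohol", "amine", "acid"), each = 2))
  mm <- coverage_curve(lsc, "ECFP_4", sizes = 5L)
  rnd <- coverage_curve(lsc, "ECFP_4", sizes = 5L, random_baseline = TRUE,
                        seed = 3, n_reps = 50L)
  expect_equal(mm$coverage_pct, 100)
  expect_lt(rnd$coverage_pct, 100)
})

test_that("similarity ranking is stable, tie-aware and exact on a toy set", {
  lib <- lib_from_smiles(VARIED_SMILES)
  ref <- rec(VARIED_SMILES[4])
  rk <- rank_by_similarity(lib, ref, "ECFP_4")
  expect_equal(rk$record_id[1], screenrank:::lib_ids(lib)[4])
  expect_equal(rk$score[1], 1)
  # all-identical library: everything tied
  same <- rank_by_similarity(lib_from_smiles(rep(VARIED_SMILES[1], 3)),
                             rec(VARIED_SMILES[1]), "ECFP_4")
  expect_true(all(same$tied))
  # order agrees with brute-force scores
  fps <- lib_fingerprints(lib, "ECFP_4")
  ref_fp <- compute_fingerprint(ref, "ECFP_4")
  scores <- vapply(fps, tanimoto, 0, b = ref_fp)
  expect_equal(rk$score, sort(scores, decreasing = TRUE))
})

test_that("enrichment curves handle ties and bound the AUC", {
  # perfectly tied library: diagonal, AUC exactly 0.5
  tied <- data.frame(rank = 1:10, record_id = paste0("r", 1:10), score = 0.4)
  ec <- enrichment_curve(tied, paste0("r", c(2, 7)))
  expect_equal(ec$auc, 0.5)
  expect_equal(ec$points$pct_screened, c(0, 100))
  # all actives first: early saturation
  sep <- data.frame(rank = 1:10, record_id = paste0("r", 1:10),
                    score = seq(1, 0.1, length.out = 10))
  ec2 <- enrichment_curve(sep, paste0("r", 1:2))
  expect_equal(max(ec2$points$pct_actives[ec2$points$pct_screened <= 20]), 100)
  expect_equal(ec2$auc, 0.9)
  expect_error(enrichment_curve(sep, character(0)), "no active")
  # AUC(ranking) + AUC(reversed) = 1 for tie-free lists
  rev_sep <- transform(sep[10:1, ], rank = 1:10)
  ec3 <- enrichment_curve(rev_sep, paste0("r", 1:2))
  expect_equal(ec2$auc + ec3$auc, 1, tolerance = 1e-12)
  expect_true(all(diff(ec2$points$pct_actives) >= 0))
  expect_equal(utils::tail(ec2$points$pct_actives, 1), 100)
})

test_that("threshold search is inclusive and monotone in the threshold", {
  lib <- lib_from_smiles(VARIED_SMILES)
  ref <- rec(VARIED_SMILES[2])
  all_hits <- threshold_search(lib, ref, "ECFP_4", 0)
  expect_equal(nrow(all_hits), length(VARIED_SMILES))
  exact <- threshold_search(lib, ref, "ECFP_4", 1)
  expect_equal(exact$record_id, screenrank:::lib_ids(lib)[2])
  n_prev <- Inf
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    n <- nrow(threshold_search(lib, ref, "ECFP_4", thr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("planted analogues are recovered at threshold 0.7", {
  ref <- rec("CC(C)NCC(O)COc1ccccc1")
  analogues <- c("CC(C)NCC(O)COc1ccccc1", "CC(C)NCC(O)COc1ccc(C)cc1",
                 "CC(C)NCC(O)COc1ccc(F)cc1")
  decoys <- c("c1ccc2c(c1)cccn2", "CCCCCCCC", "Cc1nc2ccccc2s1",
              "O=C1NCCN1c1ccccc1", "C1CCCCC1")
  lib <- lib_from_smiles(c(analogues, decoys))
  hits <- threshold_search(lib, ref, "ECFP_4", 0.7)
  expect_setequal(hits$record_id, screenrank:::lib_ids(lib)[1:3])
})

test_that("substructure search supports variable atoms", {
  q <- expand_variable_query("c1ccc({X})cc1", c("N", "O"))
  expect_equal(q, c("c1ccc(N)cc1", "c1ccc(O)cc1"))
  lib <- lib_from_smiles(c("Nc1ccccc1", "Oc1ccccc1", "Cc1ccccc1"))
  hits <- substructure_search(lib, q)
  expect_setequal(hits$record_id, screenrank:::lib_ids(lib)[1:2])
  only_n <- substructure_search(lib, "c1ccc(N)cc1")
  expect_equal(only_n$record_id, screenrank:::lib_ids(lib)[1])
  expect_error(substructure_search(lib, "C1CC(("), "invalid")
  empty <- substructure_search(screenrank:::new_library("e", list()), "[#6]")
  expect_equal(nrow(empty), 0L)
})

test_that("library overlap is directional and exact on fixtures", {
  lib <- lib_from_smiles(VARIED_SMILES, "cand")
  expect_equal(compare_libraries(lib, lib)$percentage, 100)
  a <- lib_from_smiles(c("CCCCCCCC", "CCCCCCCCC"), "alkanes")
  b <- lib_from_smiles(c("c1ccc2c(c1)cccn2", "Cc1nc2ccccc2s1"), "heteroarenes")
  expect_equal(compare_libraries(a, b)$percentage, 0)
  # one planted analogue in a 10-compound candidate: 10.0 %
  cand <- lib_from_smiles(VARIED_SMILES, "cand")
  ih <- lib_from_smiles(VARIED_SMILES[1], "ih")
  cl <- compare_libraries(cand, ih)
  expect_equal(cl$count, 1L)
  expect_equal(cl$percentage, 10.0)
  # not symmetric
  expect_equal(compare_libraries(ih, cand)$percentage, 100)
})
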
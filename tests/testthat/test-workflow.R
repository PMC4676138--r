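# end-to-end workflow and the command-line surface

test_that("a dominating library gets final rank 1", {
  good <- generate_fixture_library(c(clean = 10), seed = 21, name = "goodlib")$library
  bad <- lib_from_smiles(DOMINATED_SMILES, "badlib")
  cfg <- workflow_config(libraries = list(goodlib = good, badlib = bad), seed = 7)
  res <- run_workflow(cfg)
  # the construction really is dominated, criterion by criterion
  g <- which(res$admet$library == "goodlib"); b <- which(res$admet$library == "badlib")
  expect_lt(res$admet$pct_fail_lipinski[g], res$admet$pct_fail_lipinski[b])
  expect_lt(res$admet$pct_fail_veber[g], res$admet$pct_fail_veber[b])
  expect_lt(res$admet$pct_logbb_neg[g], res$admet$pct_logbb_neg[b])
  expect_lt(res$promiscuity$promiscuous_pct[g], res$promiscuity$promiscuous_pct[b])
  for (cl in grep("mean_sim", names(res$diversity), value = TRUE)) {
    expect_lt(res$diversity[[cl]][g], res$diversity[[cl]][b])
  }
  expect_equal(res$best_library, "goodlib")
  expect_equal(unname(res$consensus$final_rank["goodlib"]), 1L)
})

test_that("identical libraries tie at final rank 1", {
  lib <- generate_fixture_library(c(clean = 8), seed = 33, name = "twin_a")$library
  twin <- screenrank:::new_library("twin_b", lib$records)
  cfg <- workflow_config(libraries = list(twin_a = lib, twin_b = twin), seed = 2)
  res <- run_workflow(cfg)
  expect_equal(unname(res$consensus$final_rank), c(1L, 1L))
})

test_that("workflow reruns are byte-identical and match offline consensus", {
  libs <- list(
    a = generate_fixture_library(c(clean = 6), seed = 41, name = "a")$library,
    b = generate_fixture_library(c(clean = 5, alert = 2), seed = 42, name = "b")$library
  )
  cfg <- workflow_config(libraries = libs, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_workflow(cfg, out_dir = d1)
  run_workflow(cfg, out_dir = d2)
  for (f in c("curation.csv", "admet.csv", "promiscuity.csv", "diversity.csv",
              "consensus.csv", "summary.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # consensus recomputed offline from the emitted CSVs agrees
  admet <- read_report(file.path(d1, "admet.csv"))
  prom <- read_report(file.path(d1, "promiscuity.csv"))
  div <- read_report(file.path(d1, "diversity.csv"))
  cons <- read_report(file.path(d1, "consensus.csv"))
  ct <- function(n, v, dir = "lower_better") criterion_table(n, setNames(v, admet$library), dir)
  blocks <- list(
    block_consensus(list(ct("l", admet$pct_fail_lipinski),
                         ct("v", admet$pct_fail_veber),
                         ct("b", admet$pct_logbb_neg)))$block_rank,
    dense_rank(setNames(prom$promiscuous_pct, prom$library)),
    block_consensus(lapply(grep("mean_sim", names(div), value = TRUE),
                           function(cl) ct(cl, div[[cl]])))$block_rank
  )
  offline <- total_consensus(blocks)
  expect_equal(unname(offline$final_rank[cons$library]), cons$final_rank)
})

test_that("the CLI returns documented exit codes", {
  expect_equal(as.integer(suppressMessages(sr_cli(character()))), 2L)
  expect_equal(as.integer(suppressMessages(sr_cli("no-such-command"))), 2L)
  lib <- generate_fixture_library(c(clean = 4), seed = 51, name = "clilib")$library
  smi <- withr::local_tempfile(fileext = ".smi")
  write_library(lib, smi, "smiles")
  out <- withr::local_tempdir()
  expect_equal(as.integer(sr_cli(c("curate", "--in", smi, "--format", "smiles",
                                   "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "curation.csv")))
  expect_equal(as.integer(suppressMessages(
    sr_cli(c("curate", "--in", "/does/not/exist.smi", "--format", "smiles",
             "--out", out)))), 1L)
  expect_equal(as.integer(suppressMessages(
    sr_cli(c("curate", "--in", smi)))), 2L)  # missing --out
  # rank with a single library is a data error
  cfgf <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("libraries:",
               "  - name: only",
               paste0("    path: ", smi),
               "    format: smiles"), cfgf)
  expect_equal(as.integer(suppressMessages(
    sr_cli(c("rank", "--config", cfgf, "--out", out)))), 1L)
})
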
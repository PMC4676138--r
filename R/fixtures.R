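#' Synthetic fixture libraries
#'
#' Generates small, fully deterministic toy libraries with planted curation
#' categories (salt forms, inorganics, mixtures, duplicate pairs) and alert
#' chemotypes, so that every downstream stage can be exercised without vendor
#' downloads.  The generator is a pure function of (spec, seed).
#'
#' @name fixtures
NULL

# Drug-like parent structures free of shipped alert chemotypes.
CLEAN_POOL <- c(
  "CCOC(=O)c1ccccc1N",
  "CC(C)NCC(O)COc1ccccc1",
  "c1ccc(cc1)S(=O)(=O)NC",
  "CN1CCN(CC1)c1ccccc1",
  "COc1ccc(cc1)C(=O)NCC",
  "Cc1ccc(cc1)NC(=O)C2CC2",
  "CCOc1ccc(cc1)CN1CCOCC1",
  "c1ccc2c(c1)cccn2",
  "CC(C)(C)OC(=O)N1CCC(CC1)N",
  "Fc1ccc(cc1)C(=O)N1CCCC1",
  "Clc1ccccc1NC(=O)C",
  "CCN(CC)C(=O)c1cccnc1",
  "CC1CCN(CC1)S(=O)(=O)c1ccccc1",
  "COc1cccc(c1)NC(=O)NC",
  "c1cnc2[nH]ccc2c1",
  "CC(=O)Nc1ccc(cc1)OCC",
  "CN(C)CCOC(c1ccccc1)c1ccccc1",
  "CCOC(=O)C1CCN(CC1)Cc1ccccc1",
  "Cc1nc2ccccc2s1",
  "O=C1NCCN1c1ccccc1",
  "CC(C)Oc1ccccc1C#N",
  "CCS(=O)(=O)N1CCC(CC1)C(=O)N",
  "c1ccc(cc1)CNC(=O)c1ccco1",
  "CN1C(=O)CC(c2ccccc2)C1=O",
  "CC(C)CN(C)C(=O)C1CCCO1",
  "Fc1cccc(F)c1C(=O)NC1CC1",
  "c1ccc(cc1)n1ccnc1",
  "CC1(C)CC(=O)N(C1=O)c1ccccc1",
  "COC(=O)c1csc(C)n1",
  "CCn1cc(cn1)C(=O)NC",
  "OCC1CCCN1Cc1ccccc1",
  "CC(O)c1ccc(Cl)cc1",
  "CN(C)S(=O)(=O)c1ccc(C)cc1",
  "C1Oc2ccccc2O1",
  "CCC(CC)C(=O)NCc1ccncc1",
  "Cc1ccc(cc1)N1CCC1=O",
  "COCCN1CCC(CC1)NC(=O)C",
  "c1ccc(cc1)Oc1ccccn1",
  "CC(C)c1nnc(o1)C1CCNC1",
  "COc1ccc(cc1)CCNC(=O)C1CC1"
)

# (parent, counter-ion) pairs; the parent survives salt stripping.
SALT_POOL <- list(
  c("CC(C)NCC(O)COc1ccccc1", "Cl"),
  c("CN1CCN(CC1)c1ccccc1", "Cl"),
  c("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "[Na+]"),
  c("CCCCNC(=O)c1ccc(O)cc1", "Cl"),
  c("CN(C)CCOC(c1ccccc1)c1ccccc1", "Cl"),
  c("OCC1CCCN1Cc1ccccc1", "CS(=O)(=O)O")
)

# Parents for duplicate pairs: each plants the free base plus its salt.
DUP_POOL <- list(
  c("CCN(CC)CCOC(=O)c1ccc(N)cc1", "Cl"),
  c("CN1CCC(CC1)OC(=O)c1ccccc1", "Cl"),
  c("CCCN1CCCC1C(=O)Nc1ccccc1", "Cl"),
  c("COc1ccc(cc1)CC(C)NC", "Cl")
)

INORGANIC_POOL <- c(
  "[Fe]",
  "[Na+].[Cl-]",
  "O=[Si]=O",
  "O[Al](O)O",
  "[Cu+2].[O-]S(=O)(=O)[O-]",
  "[Se]"
)

# Two organic fragments, each with > 6 heavy atoms (so never salt-stripped).
MIXTURE_POOL <- c(
  "OCCc1ccccc1.NCCc1ccccc1",
  "c1ccc2ccccc2c1.CCCCCCCO",
  "CCCCCCCCO.CCCCCCCCN",
  "COc1ccccc1CC(=O)N.CCCCOc1ccccc1"
)

# Structures hitting the shipped alert catalog.
ALERT_POOL <- c(
  "Oc1ccccc1O",
  "O=C1C=CC(=O)C=C1",
  "O=C1CSC(=S)N1",
  "C=CC(=O)c1ccccc1",
  "NC(=S)Nc1ccccc1",
  "O=[N+]([O-])c1ccc(N)cc1",
  "c1ccc(cc1)N=Nc1ccccc1",
  "BrCCc1ccccc1",
  "Oc1ccc(cc1)C=NNc1ccccc1",
  "O=C1C=CSN1C"
)

sample_pool <- function(pool, n) {
  if (n <= length(pool)) {
    pool[sample.int(length(pool), n)]
  } else {
    c(pool[sample.int(length(pool))], sample(pool, n - length(pool), replace = TRUE))
  }
}

#' Generate a synthetic fixture library
#'
#' @param spec named integer vector of planted-category counts; recognised
#'   names: `clean`, `salt`, `inorganic`, `mixture`, `duplicate_pair`,
#'   `alert`.  A `duplicate_pair` contributes two records (free base and salt
#'   form) of which curation removes one as a duplicate.
#' @param seed integer seed; the result is a pure function of (spec, seed).
#' @param name library name.
#' @return list with `library` (an `sr_library`) and `manifest` (data frame
#'   with `record_id`, `category`, `smiles` ground-truth labels).
#' @export
generate_fixture_library <- function(spec, seed = 1L, name = "fixture") {
  known <- c("clean", "salt", "inorganic", "mixture", "duplicate_pair", "alert")
  bad <- setdiff(names(spec), known)
  if (length(bad)) stop("unknown fixture categories: ", paste(bad, collapse = ", "))
  spec <- spec[names(spec) %in% known]
  if (any(spec < 0)) stop("fixture counts must be >= 0")
  if (length(spec) == 0L || sum(spec) == 0L) stop("fixture spec is empty")
  cnt <- function(k) if (k %in% names(spec)) as.integer(spec[[k]]) else 0L

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  smiles <- character()
  category <- character()
  add <- function(smi, cat) {
    smiles <<- c(smiles, smi)
    category <<- c(category, rep(cat, length(smi)))
  }
  if (cnt("clean") > 0) add(sample_pool(CLEAN_POOL, cnt("clean")), "clean")
  if (cnt("salt") > 0) {
    picks <- SALT_POOL[sample_pool(seq_along(SALT_POOL), cnt("salt"))]
    add(vapply(picks, function(p) paste(p[1], p[2], sep = "."), ""), "salt")
  }
  if (cnt("inorganic") > 0) add(sample_pool(INORGANIC_POOL, cnt("inorganic")), "inorganic")
  if (cnt("mixture") > 0) add(sample_pool(MIXTURE_POOL, cnt("mixture")), "mixture")
  if (cnt("duplicate_pair") > 0) {
    picks <- DUP_POOL[sample_pool(seq_along(DUP_POOL), cnt("duplicate_pair"))]
    for (p in picks) add(c(p[1], paste(p[1], p[2], sep = ".")), "duplicate_pair")
  }
  if (cnt("alert") > 0) add(sample_pool(ALERT_POOL, cnt("alert")), "alert")

  ord <- sample.int(length(smiles))
  smiles <- smiles[ord]; category <- category[ord]
  ids <- sprintf("%s_%03d", name, seq_along(smiles))
  records <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    rec <- new_record(ids[i], smiles[i], source = name)
    if (is.null(rec)) stop("fixture SMILES failed to parse: ", smiles[i])
    records[[i]] <- rec
  }
  list(
    library = new_library(name, records, provenance = sprintf("fixture(seed=%d)", seed)),
    manifest = data.frame(record_id = ids, category = category, smiles = smiles,
                          stringsAsFactors = FALSE)
  )
}
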
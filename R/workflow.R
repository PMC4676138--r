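#' Workflow orchestration
#'
#' Runs the full library-selection pipeline over a set of candidate
#' libraries: curation, ADME/T profiling, promiscuity alerts, internal
#' diversity, optional similarity to reference active compounds, optional
#' overlap with an in-house collection, and the two-level dense-rank
#' consensus that produces the final library ranking.
#'
#' @name workflow
NULL

#' Build a workflow configuration
#'
#' @param libraries either a named list of `sr_library` objects or a list of
#'   `list(name=, path=, format=)` entries to read from disk.
#' @param reference_actives optional character vector of SMILES; similarity
#'   criteria are skipped when empty.
#' @param in_house optional `sr_library` (or `list(path=, format=)`); overlap
#'   criterion skipped when NULL.
#' @param alert_catalog path to an alert catalog (NULL = shipped catalog).
#' @param diversity_dialects fingerprint dialects for internal diversity.
#' @param similarity_dialects fingerprint dialects for similarity criteria.
#' @param substructure_queries optional character vector of SMARTS patterns
#'   (e.g. from [expand_variable_query()]) for substructure similarity.
#' @param similarity_threshold Tanimoto cutoff counting a compound as
#'   similar to a reference active.
#' @param overlap_threshold Tanimoto cutoff for the in-house overlap.
#' @param max_pairs cap on pairs for mean pairwise similarity.
#' @param seed integer seed used for every stochastic step.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(libraries,
                            reference_actives = character(),
                            in_house = NULL,
                            alert_catalog = NULL,
                            diversity_dialects = c("ECFP_2", "MDL_keys", "PHRFC_2"),
                            similarity_dialects = c("ECFP_4", "ECFP_6", "MDL_keys", "PHFP_3"),
                            substructure_queries = character(),
                            similarity_threshold = 0.7,
                            overlap_threshold = 0.7,
                            max_pairs = 20000L,
                            seed = 1L) {
  structure(list(
    libraries = libraries,
    reference_actives = reference_actives,
    in_house = in_house,
    alert_catalog = alert_catalog,
    diversity_dialects = diversity_dialects,
    similarity_dialects = similarity_dialects,
    substructure_queries = substructure_queries,
    similarity_threshold = similarity_threshold,
    overlap_threshold = overlap_threshold,
    max_pairs = max_pairs,
    seed = as.integer(seed)
  ), class = "workflow_config")
}

#' Read a workflow configuration from YAML
#'
#' Keys mirror the arguments of [workflow_config()]; `libraries` entries are
#' `name` / `path` / `format` maps, `in_house` a `path` / `format` map.
#'
#' @param path YAML file.
#' @export
read_workflow_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$libraries) || length(y$libraries) == 0L) {
    stop("config must list at least one library")
  }
  args <- y[intersect(names(y), names(formals(workflow_config)))]
  do.call(workflow_config, args)
}

resolve_library <- function(entry, default_name = NULL) {
  if (inherits(entry, "sr_library")) return(entry)
  if (is.list(entry) && !is.null(entry$path)) {
    return(read_library(entry$path, format = entry$format %||% "sdf",
                        name = entry$name %||% default_name))
  }
  stop("cannot resolve library entry")
}

#' Run the library-selection workflow
#'
#' @param config a `workflow_config`.
#' @param out_dir optional directory; when given, every report table is
#'   written as CSV plus a `summary.txt` and a `run_log.txt` (seed,
#'   package version, per-stage timings).
#' @return a `workflow_result` list: `curation`, `admet`, `promiscuity`,
#'   `diversity`, `similarity` (NULL when no references), `overlap` (NULL
#'   when no in-house library), `consensus` (blocks, totals, final ranks)
#'   and `best_library`.
#' @export
run_workflow <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "workflow_config"))
  log_lines <- c(sprintf("screenrank %s", as.character(utils::packageVersion("screenrank"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  libs <- list()
  for (i in seq_along(config$libraries)) {
    nm <- names(config$libraries)[i]
    lib <- resolve_library(config$libraries[[i]], default_name = nm)
    libs[[lib$name]] <- lib
  }
  n_lib <- length(libs)
  catalog <- load_catalog(config$alert_catalog)

  curated <- list()
  curation_report <- NULL
  for (nm in names(libs)) {
    res <- curate(libs[[nm]])
    curated[[nm]] <- res$library
    curation_report <- rbind(curation_report, res$report)
  }
  log_lines <- c(log_lines, sprintf("curated %d libraries", n_lib))

  admet <- do.call(rbind, lapply(names(curated), function(nm) {
    admet_profile(curated[[nm]])$summary
  }))
  promiscuity <- do.call(rbind, lapply(names(curated), function(nm) {
    pf <- library_promiscuity_fraction(curated[[nm]], catalog)
    data.frame(library = nm, promiscuous_pct = pf$percentage,
               n_flagged = pf$n_flagged, stringsAsFactors = FALSE)
  }))

  diversity <- do.call(rbind, lapply(names(curated), function(nm) {
    row <- data.frame(library = nm, n = length(curated[[nm]]$records),
                      stringsAsFactors = FALSE)
    for (dia in config$diversity_dialects) {
      v <- mean_pairwise_similarity(curated[[nm]], dia,
                                    max_pairs = config$max_pairs,
                                    seed = config$seed)
      row[[paste0("mean_sim_", dia)]] <- as.numeric(v)
    }
    row
  }))

  similarity <- NULL
  if (length(config$reference_actives) > 0 || length(config$substructure_queries) > 0) {
    refs <- lapply(seq_along(config$reference_actives), function(i) {
      rec <- new_record(sprintf("ref_%02d", i), config$reference_actives[i])
      if (is.null(rec)) stop("reference active failed to parse: ",
                             config$reference_actives[i])
      standardize(rec)
    })
    similarity <- do.call(rbind, lapply(names(curated), function(nm) {
      row <- data.frame(library = nm, stringsAsFactors = FALSE)
      if (length(config$substructure_queries)) {
        row$substructure_count <-
          nrow(substructure_search(curated[[nm]], config$substructure_queries))
      }
      if (length(refs)) {
        for (dia in config$similarity_dialects) {
          cnt <- 0L
          for (ref in refs) {
            cnt <- cnt + nrow(threshold_search(curated[[nm]], ref, dia,
                                               config$similarity_threshold))
          }
          row[[paste0("similar_", dia)]] <- cnt
        }
      }
      row
    }))
  }

  overlap <- NULL
  if (!is.null(config$in_house)) {
    ih <- resolve_library(config$in_house, default_name = "in_house")
    ih <- curate(ih)$library
    overlap <- do.call(rbind, lapply(names(curated), function(nm) {
      cl <- compare_libraries(curated[[nm]], ih,
                              dialect = config$similarity_dialects[1],
                              threshold = config$overlap_threshold)
      data.frame(library = nm, similar_count = cl$count,
                 similar_pct = cl$percentage, stringsAsFactors = FALSE)
    }))
  }

  consensus <- NULL
  best <- NULL
  if (n_lib >= 2L) {
    nm <- admet$library
    ct <- function(name, v, dir = "lower_better") criterion_table(name, stats::setNames(v, nm), dir)
    adme_block <- block_consensus(list(
      ct("fail_lipinski", admet$pct_fail_lipinski),
      ct("fail_veber", admet$pct_fail_veber),
      ct("logbb_neg", admet$pct_logbb_neg)
    ))
    prom_rank <- dense_rank(stats::setNames(promiscuity$promiscuous_pct, nm), "lower_better")
    div_block <- block_consensus(lapply(config$diversity_dialects, function(dia) {
      ct(dia, diversity[[paste0("mean_sim_", dia)]])
    }))
    blocks <- list(admet = adme_block$block_rank, promiscuity = prom_rank,
                   diversity = div_block$block_rank)
    sim_block <- NULL
    if (!is.null(similarity)) {
      sim_cols <- setdiff(names(similarity), "library")
      sim_block <- block_consensus(lapply(sim_cols, function(cl) {
        ct(cl, similarity[[cl]], "higher_better")
      }))
      blocks$similarity <- sim_block$block_rank
    }
    core <- total_consensus(blocks)
    consensus <- list(blocks = blocks, adme_block = adme_block,
                      diversity_block = div_block, similarity_block = sim_block,
                      totals = core$totals, final_rank = core$final_rank)
    if (!is.null(overlap)) {
      ov <- stats::setNames(overlap$similar_pct, overlap$library)
      adj <- overlap_adjusted_rank(core$final_rank, ov)
      consensus$overlap_adjusted <- adj
      consensus$final_rank <- adj$final_rank
      consensus$totals <- adj$combined
    }
    best <- names(consensus$final_rank)[consensus$final_rank == 1]
  }

  result <- structure(list(
    curation = curation_report, admet = admet, promiscuity = promiscuity,
    diversity = diversity, similarity = similarity, overlap = overlap,
    consensus = consensus, best_library = best, seed = config$seed
  ), class = "workflow_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(curation_report, file.path(out_dir, "curation.csv"))
    write_report(admet, file.path(out_dir, "admet.csv"))
    write_report(promiscuity, file.path(out_dir, "promiscuity.csv"))
    write_report(diversity, file.path(out_dir, "diversity.csv"))
    if (!is.null(similarity)) write_report(similarity, file.path(out_dir, "similarity.csv"))
    if (!is.null(overlap)) write_report(overlap, file.path(out_dir, "overlap.csv"))
    if (!is.null(consensus)) {
      ranks <- data.frame(library = names(consensus$final_rank),
                          total = as.numeric(consensus$totals[names(consensus$final_rank)]),
                          final_rank = as.integer(consensus$final_rank),
                          stringsAsFactors = FALSE)
      for (bn in names(consensus$blocks)) {
        ranks[[paste0("rank_", bn)]] <-
          as.integer(consensus$blocks[[bn]][ranks$library])
      }
      write_report(ranks, file.path(out_dir, "consensus.csv"))
      writeLines(c(sprintf("best library: %s", paste(best, collapse = ", "))),
                 file.path(out_dir, "summary.txt"))
    }
    log_lines <- c(log_lines, sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("<workflow_result> ", nrow(x$curation), " libraries\n", sep = "")
  if (!is.null(x$consensus)) {
    fr <- x$consensus$final_rank
    for (nm in names(sort(fr))) {
      cat(sprintf("  %-35s total %-4g final rank %d\n", nm,
                  as.numeric(x$consensus$totals[nm]), fr[nm]))
    }
    cat("best library:", paste(x$best_library, collapse = ", "), "\n")
  }
  invisible(x)
}
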
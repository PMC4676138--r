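#' Diversity and similarity analysis
#'
#' Internal diversity (mean pairwise Tanimoto), greedy MaxMin diverse-subset
#' selection, label (target/indication) coverage curves, similarity ranking
#' against reference actives with enrichment curves, threshold and
#' substructure searches, and cross-library overlap.
#'
#' @name divsim
NULL

usable_fps <- function(fps) {
  !vapply(fps, function(f) isTRUE(f$flagged) || length(f$features) == 0L, TRUE)
}

#' Mean pairwise Tanimoto similarity of a library
#'
#' The average similarity over all unordered pairs; lower values mean higher
#' internal diversity.  For libraries whose pair count exceeds `max_pairs`,
#' an unbiased uniform sample of pairs is used.
#'
#' @param library an `sr_library`.
#' @param dialect fingerprint dialect tag.
#' @param max_pairs optional cap on the number of pairs evaluated.
#' @param seed RNG seed for pair sampling.
#' @return mean similarity, with attributes `n_pairs` (pairs evaluated),
#'   `sampled` (logical) and `n_excluded` (records without usable
#'   fingerprints).
#' @export
mean_pairwise_similarity <- function(library, dialect = "ECFP_2",
                                     max_pairs = NULL, seed = 1L) {
  fps <- lib_fingerprints(library, dialect)
  ok <- usable_fps(fps)
  fps <- fps[ok]
  n <- length(fps)
  if (n < 2L) stop("need at least 2 records with usable fingerprints")
  total <- n * (n - 1) / 2
  sampled <- !is.null(max_pairs) && total > max_pairs
  if (sampled) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    idx <- sample(total, max_pairs)
  } else {
    idx <- seq_len(total)
  }
  # pair index k (1-based, column-major over i<j)
  sims <- vapply(idx, function(k) {
    j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
    i <- k - (j - 1) * (j - 2) / 2
    tanimoto(fps[[i]], fps[[j]])
  }, 0)
  structure(mean(sims), n_pairs = length(idx), sampled = sampled,
            n_excluded = sum(!ok))
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
  else assign(".Random.seed", old, envir = globalenv())
}

#' Greedy MaxMin diverse subset selection
#'
#' Each pick maximizes its minimum Tanimoto distance (1 - similarity) to the
#' already-selected set; ties broken by input order.  The first pick defaults
#' to the record with maximal mean distance to all others; passing
#' `first_pick` overrides it.
#'
#' @param library an `sr_library` (records with unusable fingerprints are
#'   never selected unless k forces exhaustion of usable ones).
#' @param dialect dialect tag.
#' @param k subset size (1..n).
#' @param first_pick optional index of the first selected record.
#' @param fps optional precomputed fingerprint list (for repeated calls).
#' @return integer vector of selected record indices, in selection order.
#' @export
maxmin_select <- function(library, dialect = "ECFP_2", k, first_pick = NULL,
                          fps = NULL) {
  if (is.null(fps)) fps <- lib_fingerprints(library, dialect)
  n <- length(fps)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  ok <- usable_fps(fps)
  sim <- function(i, j) {
    if (!ok[i] || !ok[j]) return(0)
    tanimoto(fps[[i]], fps[[j]])
  }
  if (is.null(first_pick)) {
    meand <- vapply(seq_len(n), function(i) {
      mean(vapply(seq_len(n)[-i], function(j) 1 - sim(i, j), 0))
    }, 0)
    first_pick <- which.max(meand)  # ties: first index
  }
  selected <- first_pick
  mind <- vapply(seq_len(n), function(j) 1 - sim(first_pick, j), 0)
  mind[first_pick] <- -Inf
  while (length(selected) < k) {
    nxt <- which.max(mind)  # stable: first maximal index
    selected <- c(selected, nxt)
    d <- vapply(seq_len(n), function(j) 1 - sim(nxt, j), 0)
    mind <- pmin(mind, d)
    mind[nxt] <- -Inf
  }
  selected
}

# ---- labeled sets ------------------------------------------------------

#' Construct a labeled compound set
#'
#' Mirrors the preprocessing of benchmark target/indication sets: records
#' assigned to more than one label are dropped, then labels with fewer than
#' `min_members` records are dropped.
#'
#' @param library an `sr_library`.
#' @param labels character vector, one label per record (or named by
#'   record_id).
#' @param min_members minimum records per label (default 2).
#' @return object of class `sr_labeled_set`: list(library, labels).
#' @export
labeled_set <- function(library, labels, min_members = 2L) {
  ids <- lib_ids(library)
  if (!is.null(names(labels))) labels <- labels[ids]
  stopifnot(length(labels) == length(ids))
  multi <- ids[ave(as.integer(factor(labels)), ids,
                   FUN = function(x) length(unique(x))) > 1]
  keep <- !(ids %in% multi)
  tab <- table(labels[keep])
  keep <- keep & labels %in% names(tab)[tab >= min_members]
  structure(list(
    library = new_library(library$name, library$records[keep],
                          provenance = library$provenance),
    labels = labels[keep]
  ), class = "sr_labeled_set")
}

#' Read a labeled set from CSV (record_id, smiles, label)
#' @param path CSV path.
#' @param min_members minimum records per label.
#' @param name set name.
#' @export
read_labeled_set <- function(path, min_members = 2L, name = "labeled") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("record_id", "smiles", "label") %in% names(df)))
  records <- list()
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- new_record(df$record_id[i], df$smiles[i], source = name)
    if (!is.null(rec)) { records[[length(records) + 1L]] <- rec; keep[i] <- TRUE }
  }
  labeled_set(new_library(name, records, provenance = path),
              df$label[keep], min_members = min_members)
}

#' Label coverage as a function of MaxMin subset size
#'
#' For each size, a MaxMin subset is selected and the percentage of distinct
#' labels present in it is recorded.  With `random_baseline`, the curve is
#' instead averaged over `n_reps` random subsets per size.
#'
#' @param labeled an `sr_labeled_set`.
#' @param dialect dialect tag.
#' @param sizes strictly increasing subset sizes within 1..n.
#' @param seed seed for the random baseline.
#' @param random_baseline select at random instead of MaxMin.
#' @param n_reps random-baseline replicates (mean reported).
#' @return data frame `size`, `coverage_pct`.
#' @export
coverage_curve <- function(labeled, dialect = "ECFP_2", sizes, seed = 1L,
                           random_baseline = FALSE, n_reps = 10L) {
  lib <- labeled$library
  n <- length(lib$records)
  stopifnot(all(sizes >= 1), all(sizes <= n), !is.unsorted(sizes, strictly = TRUE))
  n_labels <- length(unique(labeled$labels))
  fps <- if (!random_baseline) lib_fingerprints(lib, dialect) else NULL
  cov <- vapply(sizes, function(k) {
    if (random_baseline) {
      old <- local_seed(seed + k)
      on.exit(restore_seed(old))
      mean(vapply(seq_len(n_reps), function(r) {
        sel <- sample(n, k)
        100 * length(unique(labeled$labels[sel])) / n_labels
      }, 0))
    } else {
      sel <- maxmin_select(lib, dialect, k, fps = fps)
      100 * length(unique(labeled$labels[sel])) / n_labels
    }
  }, 0)
  data.frame(size = sizes, coverage_pct = cov)
}

# ---- similarity ranking and enrichment ---------------------------------

#' Rank a library by similarity to a reference compound
#'
#' @param library an `sr_library`.
#' @param reference an `sr_record`.
#' @param dialect dialect tag.
#' @return data frame in descending similarity order (stable for ties):
#'   `rank`, `record_id`, `score`, `tied` (score shared with another record).
#' @export
rank_by_similarity <- function(library, reference, dialect = "ECFP_4") {
  ref_fp <- compute_fingerprint(reference, dialect)
  if (isTRUE(ref_fp$flagged) || length(ref_fp$features) == 0L) {
    stop("reference compound has an empty ", dialect, " fingerprint")
  }
  fps <- lib_fingerprints(library, dialect)
  scores <- vapply(fps, function(f) {
    if (isTRUE(f$flagged) || length(f$features) == 0L) 0 else tanimoto(ref_fp, f)
  }, 0)
  ord <- order(-scores)  # stable: preserves input order within ties
  out <- data.frame(
    rank = seq_along(ord),
    record_id = lib_ids(library)[ord],
    score = scores[ord],
    stringsAsFactors = FALSE
  )
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  out
}

#' Enrichment curve and averaged-coverage score
#'
#' Cumulative percentage of active compounds recovered versus percentage of
#' the ranked library screened.  Within a block of tied scores the curve is
#' the straight line between the block endpoints (tied compounds cannot be
#' ordered).  The scalar summary is the area under the curve on the unit
#' square (0.5 = random, 1 = ideal early recovery).
#'
#' @param ranked data frame from [rank_by_similarity()].
#' @param active logical vector named by record_id, or a character vector of
#'   active record_ids.
#' @return list with `points` (data frame `pct_screened`,
#'   `pct_actives`) and `auc`.
#' @export
enrichment_curve <- function(ranked, active) {
  if (is.character(active)) active <- setNames(ranked$record_id %in% active,
                                               ranked$record_id)
  act <- as.logical(active[ranked$record_id])
  act[is.na(act)] <- FALSE
  n <- nrow(ranked)
  n_act <- sum(act)
  if (n_act == 0L) stop("no active compounds in the ranked list")
  # tie blocks: runs of equal score
  ends <- cumsum(rle(ranked$score)$lengths)
  cum_act <- cumsum(act)
  x <- c(0, 100 * ends / n)
  y <- c(0, 100 * cum_act[ends] / n_act)
  auc <- sum(diff(x / 100) * (utils::head(y, -1) + utils::tail(y, -1)) / 200)
  list(points = data.frame(pct_screened = x, pct_actives = y), auc = auc)
}

#' Records at least `threshold`-similar to a reference
#'
#' @param library an `sr_library`.
#' @param reference an `sr_record`.
#' @param dialect dialect tag.
#' @param threshold Tanimoto threshold in [0, 1] (inclusive).
#' @return data frame `record_id`, `score` of matching records (input order).
#' @export
threshold_search <- function(library, reference, dialect = "ECFP_4",
                             threshold = 0.7) {
  stopifnot(threshold >= 0, threshold <= 1)
  ref_fp <- compute_fingerprint(reference, dialect)
  fps <- lib_fingerprints(library, dialect)
  scores <- vapply(fps, function(f) {
    if ((isTRUE(f$flagged) || length(f$features) == 0L) &&
        length(ref_fp$features) == 0L) 0
    else if (isTRUE(f$flagged) || length(f$features) == 0L) 0
    else tanimoto(ref_fp, f)
  }, 0)
  hit <- scores >= threshold
  data.frame(record_id = lib_ids(library)[hit], score = scores[hit],
             stringsAsFactors = FALSE)
}

#' Expand a variable-atom substructure template
#'
#' Replaces every occurrence of the placeholder `{X}` in a SMARTS template
#' with each alternative in turn (e.g. `c("N", "O", "S", "C", "c")` for a
#' variable ring position).
#'
#' @param template SMARTS with `{X}` placeholders.
#' @param alternatives character vector of SMARTS atom expressions.
#' @return character vector of concrete SMARTS patterns.
#' @export
expand_variable_query <- function(template, alternatives) {
  if (!grepl("{X}", template, fixed = TRUE)) return(template)
  vapply(alternatives, function(a) gsub("{X}", a, template, fixed = TRUE), "",
         USE.NAMES = FALSE)
}

#' Substructure search with optional variable atoms
#'
#' A record matches when any of the query patterns (e.g. the instantiations
#' of a variable-atom template) is a subgraph match.
#'
#' @param library an `sr_library`.
#' @param queries character vector of SMARTS (see
#'   [expand_variable_query()]); every pattern must compile.
#' @return data frame `record_id`, `pattern` (first matching pattern), input
#'   order.
#' @export
substructure_search <- function(library, queries) {
  for (q in queries) {
    if (!smarts_valid(q)) stop("invalid substructure query: ", q)
  }
  if (length(library$records) == 0L) {
    return(data.frame(record_id = character(), pattern = character()))
  }
  mols <- lib_obrefs(library)
  counts <- vapply(queries, function(q) {
    as.numeric(suppressWarnings(
      ChemmineOB::smartsSearch_OB(mols, q, uniqueMatches = TRUE)))
  }, numeric(length(library$records)))
  counts <- matrix(counts, nrow = length(library$records))
  hit <- rowSums(counts > 0) > 0
  first <- apply(counts, 1, function(r) if (any(r > 0)) queries[which(r > 0)[1]] else NA)
  data.frame(record_id = lib_ids(library)[hit], pattern = first[hit],
             stringsAsFactors = FALSE)
}

#' Overlap of a candidate library with an in-house collection
#'
#' Counts candidate records whose maximum Tanimoto similarity to any
#' in-house record reaches the threshold.  Not symmetric: swap the arguments
#' for the reverse direction.
#'
#' @param candidate,in_house `sr_library` objects.
#' @param dialect dialect tag (default the similarity workhorse ECFP_4).
#' @param threshold Tanimoto cutoff (default 0.7).
#' @return list with `count`, `percentage` (of candidate size, rounded to
#'   one decimal) and `percentage_raw`.
#' @export
compare_libraries <- function(candidate, in_house, dialect = "ECFP_4",
                              threshold = 0.7) {
  if (length(candidate$records) == 0L || length(in_house$records) == 0L) {
    stop("both libraries must be non-empty")
  }
  cfp <- lib_fingerprints(candidate, dialect)
  hfp <- lib_fingerprints(in_house, dialect)
  hok <- which(usable_fps(hfp))
  hit <- vapply(seq_along(cfp), function(i) {
    f <- cfp[[i]]
    if (isTRUE(f$flagged) || length(f$features) == 0L) return(FALSE)
    for (j in hok) {
      if (tanimoto(f, hfp[[j]]) >= threshold) return(TRUE)
    }
    FALSE
  }, TRUE)
  pct <- 100 * sum(hit) / length(cfp)
  list(count = sum(hit), percentage = round(pct, 1), percentage_raw = pct)
}
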
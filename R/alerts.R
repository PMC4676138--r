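#' Promiscuous-binder / frequent-hitter alerts
#'
#' Flags compounds matching a named catalog of SMARTS substructure alerts
#' (PAINS-style chemotype families and common HTS frequent hitters).  The
#' library-level statistic is the percentage of compounds with at least one
#' alert; compounds are flagged, never removed, because the workflow scores
#' libraries rather than editing them.
#'
#' @name alerts
NULL

smarts_valid <- function(smarts) {
  probe <- ChemmineOB::forEachMol("SMILES", "CCO", identity)
  tryCatch({
    suppressWarnings(ChemmineOB::smartsSearch_OB(probe, smarts, uniqueMatches = FALSE))
    TRUE
  }, error = function(e) FALSE)
}

#' Load an alert catalog
#'
#' File format: `name<TAB>SMARTS`, one per line, `#` comments.  Names must be
#' unique and every pattern must compile; violations are fatal with the line
#' number.
#'
#' @param path catalog file; default: the shipped PAINS/HTS-style catalog.
#' @return object of class `alert_catalog` (data frame `name`, `smarts`).
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) path <- sr_extdata("alerts_hts.txt")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  entries <- data.frame(name = character(), smarts = character(), line = integer())
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\t")[[1]]
    if (length(f) < 2L) stop("line ", i, ": expected name<TAB>SMARTS")
    entries <- rbind(entries, data.frame(name = f[1], smarts = f[2], line = i))
  }
  if (nrow(entries) == 0L) stop("alert catalog is empty: ", path)
  dup <- entries$name[duplicated(entries$name)]
  if (length(dup)) stop("duplicate alert name(s): ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(entries))) {
    if (!smarts_valid(entries$smarts[i])) {
      stop("line ", entries$line[i], ": SMARTS does not compile: ", entries$smarts[i])
    }
  }
  structure(entries[, c("name", "smarts")], class = c("alert_catalog", "data.frame"))
}

# match-count matrix (records x alerts) for a whole library in one pass
alert_matrix <- function(library, catalog) {
  mols <- lib_obrefs(library)
  m <- vapply(catalog$smarts, function(pat) {
    as.numeric(suppressWarnings(
      ChemmineOB::smartsSearch_OB(mols, pat, uniqueMatches = TRUE)))
  }, numeric(length(library$records)))
  m <- matrix(m, nrow = length(library$records),
              dimnames = list(lib_ids(library), catalog$name))
  m
}

#' Alert names matched by one record
#'
#' @param record an `sr_record`.
#' @param catalog an `alert_catalog`.
#' @return character vector of all matching alert names, in catalog order.
#' @export
flag_promiscuous <- function(record, catalog = load_catalog()) {
  lib1 <- new_library("tmp", list(record))
  m <- alert_matrix(lib1, catalog)
  catalog$name[m[1, ] > 0]
}

#' Percentage of a library flagged promiscuous
#'
#' A record counts once however many alerts it matches.
#'
#' @param library an `sr_library`.
#' @param catalog an `alert_catalog`.
#' @return list with `percentage`, `n_flagged`, and per-record `flags`
#'   (data frame `record_id`, `n_alerts`, `alerts`).
#' @export
library_promiscuity_fraction <- function(library, catalog = load_catalog()) {
  if (length(library$records) == 0L) stop("empty library")
  m <- alert_matrix(library, catalog)
  hit <- rowSums(m > 0) > 0
  flags <- data.frame(
    record_id = lib_ids(library),
    n_alerts = rowSums(m > 0),
    alerts = apply(m, 1, function(r) paste(colnames(m)[r > 0], collapse = ";")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(percentage = 100 * sum(hit) / length(hit),
       n_flagged = sum(hit),
       flags = flags)
}
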
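#' Molecule records and library I/O
#'
#' A library is an ordered collection of molecule records read from an SDF
#' (V2000) or SMILES file.  Each record keeps its source identifier, the
#' canonical SMILES of the structure as read, and a parsed molecular graph.
#' Entries that fail to parse are counted and reported, never fatal, because
#' vendor files routinely contain occasional junk and removal itself is a
#' statistic of interest downstream.
#'
#' @name chemio
NULL

new_record <- function(record_id, smiles, source = "", mol = NULL) {
  if (is.null(mol)) mol <- sr_mol_from_smiles(smiles)
  if (is.null(mol)) return(NULL)
  structure(list(
    record_id = record_id,
    source = source,
    smiles = mol$smiles,
    canonical_key = mol$smiles,
    mol = mol,
    flags = character()
  ), class = "sr_record")
}

#' @export
print.sr_record <- function(x, ...) {
  cat("<record ", x$record_id, "> ", x$smiles, "\n", sep = "")
  invisible(x)
}

new_library <- function(name, records, provenance = "", n_failed = 0L) {
  stopifnot(nzchar(name))
  structure(list(name = name, records = records, provenance = provenance,
                 n_parse_failed = as.integer(n_failed)),
            class = "sr_library")
}

#' @export
print.sr_library <- function(x, ...) {
  cat("<library ", x$name, "> ", length(x$records), " records",
      if (x$n_parse_failed > 0) paste0(" (", x$n_parse_failed, " parse failures)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.sr_library <- function(x) length(x$records)

lib_smiles <- function(lib) vapply(lib$records, function(r) r$smiles, "")
lib_ids <- function(lib) vapply(lib$records, function(r) r$record_id, "")
lib_keys <- function(lib) vapply(lib$records, function(r) r$canonical_key, "")

#' Read a compound library from file
#'
#' @param path path to an SDF (V2000) or SMILES file.  SMILES files hold one
#'   molecule per line with an optional whitespace/tab-separated identifier;
#'   blank lines and `#` comments are skipped.
#' @param format `"sdf"` or `"smiles"`.
#' @param name library name; defaults to the file name without extension.
#' @return an `sr_library`.  Unparseable entries are counted in
#'   `$n_parse_failed` and reported with [message()]; a file with zero
#'   parseable records is an error.
#' @export
read_library <- function(path, format = c("sdf", "smiles"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  records <- list()
  n_failed <- 0L
  if (format == "sdf") {
    txt <- readLines(path, warn = FALSE)
    ends <- grep("^\\${4}", txt)
    if (length(ends) == 0L && length(txt) > 0L) ends <- length(txt)
    start <- 1L
    entry_no <- 0L
    for (e in ends) {
      block <- txt[start:min(e, length(txt))]
      start <- e + 1L
      block <- block[!grepl("^\\${4}", block)]
      if (!any(nzchar(trimws(block)))) next
      entry_no <- entry_no + 1L
      id <- trimws(block[1])
      if (!nzchar(id)) id <- sprintf("%s_%04d", name, entry_no)
      smi <- ob_canonical_block(paste(c(block, "$$$$"), collapse = "\n"))
      rec <- if (nzchar(smi)) new_record(id, smi, source = name) else NULL
      if (is.null(rec)) {
        n_failed <- n_failed + 1L
        message("read_library: entry ", entry_no, " (", id, ") failed to parse")
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    entry_no <- 0L
    for (ln in lines) {
      ln <- trimws(ln)
      if (!nzchar(ln) || startsWith(ln, "#")) next
      entry_no <- entry_no + 1L
      fields <- strsplit(ln, "[\t ]+")[[1]]
      id <- if (length(fields) >= 2) fields[2] else sprintf("%s_%04d", name, entry_no)
      rec <- new_record(id, fields[1], source = name)
      if (is.null(rec)) {
        n_failed <- n_failed + 1L
        message("read_library: line entry ", entry_no, " ('", fields[1],
                "') failed to parse")
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  if (length(records) == 0L) {
    stop("no parseable records in ", path)
  }
  new_library(name, records, provenance = path, n_failed = n_failed)
}

# Canonical SMILES of one SDF entry; "" on failure.
ob_canonical_block <- function(sdf_text) {
  out <- ob_convert("SDF", "CAN", sdf_text)
  out <- strsplit(out, "[\t\n ]")[[1]]
  if (length(out) == 0L || !nzchar(out[1])) "" else out[1]
}

#' Write a library to file
#'
#' @param lib an `sr_library`.
#' @param path output path.
#' @param format `"smiles"` (canonical SMILES + id per line) or `"sdf"`.
#' @export
write_library <- function(lib, path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    writeLines(paste(lib_smiles(lib), lib_ids(lib), sep = "\t"), path)
  } else {
    blocks <- vapply(lib$records, function(r) {
      sdf <- ob_convert("SMI", "SDF", r$smiles)
      sub("^[^\n]*", r$record_id, sdf)  # title line = record id
    }, "")
    writeLines(paste(blocks, collapse = ""), sep = "", con = path)
  }
  invisible(path)
}

#' Write a tabular report as CSV
#'
#' Numeric cells are written with enough digits to round-trip exactly through
#' [read_report()].
#'
#' @param table a data frame with unique column names.
#' @param path output path.
#' @export
write_report <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop("column names must be unique")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- formatC(out[[j]], digits = 15, format = "g")
      bad <- !is.na(out[[j]]) & (as.numeric(s) != out[[j]])
      s[bad] <- formatC(out[[j]][bad], digits = 17, format = "g")
      out[[j]] <- trimws(s)
      out[[j]][is.na(table[[j]])] <- NA
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path)
  invisible(path)
}

#' Read back a CSV report written by [write_report()]
#' @param path CSV path.
#' @export
read_report <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
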
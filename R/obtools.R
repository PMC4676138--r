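# Thin wrappers around OpenBabel (via ChemmineOB) used by the molecule layer.
# All conversions are per-record so that a single bad structure never aborts a
# whole-library read.

ob_opts <- function(...) {
  nm <- c(...)
  if (length(nm) == 0L) return(NULL)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

#' @noRd
ob_convert <- function(from, to, source, options = NULL) {
  out <- tryCatch(
    suppressWarnings(
      if (is.null(options)) ChemmineOB::convertFormat(from, to, source)
      else ChemmineOB::convertFormat(from, to, source, options = options)
    ),
    error = function(e) ""
  )
  if (is.null(out) || length(out) == 0L) "" else out
}

# Canonical SMILES of a SMILES string; "" on parse failure.
ob_canonical <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  out <- strsplit(out, "[\t\n ]")[[1]]
  if (length(out) == 0L || !nzchar(out[1])) "" else out[1]
}

# Parse a TRIPOS MOL2 block into atom/bond tables.  Columns: element, type,
# x, y, z, pcharge (Gasteiger); bonds: a1, a2, type ("1","2","3","am","ar").
parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ai <- which(lines == "@<TRIPOS>ATOM")
  bi <- which(lines == "@<TRIPOS>BOND")
  if (length(ai) == 0L || length(bi) == 0L) return(NULL)
  end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  a_end <- min(end[end > ai[1]]) - 1L
  b_end <- min(end[end > bi[1]]) - 1L
  atom_lines <- lines[seq(ai[1] + 1L, a_end)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  bond_lines <- if (b_end > bi[1]) lines[seq(bi[1] + 1L, b_end)] else character()
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  af <- do.call(rbind, strsplit(trimws(atom_lines), "[[:space:]]+"))
  atoms <- data.frame(
    type = af[, 6],
    x = as.numeric(af[, 3]), y = as.numeric(af[, 4]), z = as.numeric(af[, 5]),
    pcharge = if (ncol(af) >= 9) as.numeric(af[, 9]) else NA_real_,
    stringsAsFactors = FALSE
  )
  atoms$element <- vapply(strsplit(atoms$type, ".", fixed = TRUE), `[`, "", 1L)
  atoms$aromatic <- grepl("\\.ar$", atoms$type)
  bonds <- if (length(bond_lines)) {
    bf <- do.call(rbind, strsplit(trimws(bond_lines), "[[:space:]]+"))
    data.frame(a1 = as.integer(bf[, 2]), a2 = as.integer(bf[, 3]),
               type = bf[, 4], stringsAsFactors = FALSE)
  } else {
    data.frame(a1 = integer(), a2 = integer(), type = character())
  }
  list(atoms = atoms, bonds = bonds)
}

# Parse a V2000 SDF/MOL block: elements, bond orders, formal charges.
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) return(NULL)
  if (length(lines) < 4L + na + nb) return(NULL)
  atom_lines <- lines[seq_len(na) + 4L]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(na)
  bond_lines <- if (nb > 0) lines[seq_len(nb) + 4L + na] else character()
  bonds <- if (nb > 0) {
    data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- strsplit(trimws(sub("^M  CHG", "", l)), "[[:space:]]+")[[1]]
    n <- as.integer(f[1])
    for (k in seq_len(n)) {
      charge[as.integer(f[2 * k])] <- as.integer(f[2 * k + 1])
    }
  }
  list(element = element, charge = charge, bonds = bonds)
}
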
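#' Library curation
#'
#' Implements the curation stage of the library-selection workflow: salt
#' stripping to the parent structure, removal of inorganics, mixtures and
#' bad-valence structures, rule-based protonation at physiological pH (7.4),
#' selection of a single canonical tautomer, and duplicate removal by
#' canonical SMILES of the standardized parent.  Removals are reported per
#' category as counts and percentages of the input size.
#'
#' @name curation
NULL

ORGANIC_ELEMENTS <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Se")

.sr_env <- new.env(parent = emptyenv())

sr_extdata <- function(file) {
  system.file("extdata", file, package = "screenrank", mustWork = TRUE)
}

#' Load the counter-ion list
#'
#' @param path optional path to a SMILES file (one counter-ion per line,
#'   optional name, `#` comments); defaults to the shipped list.
#' @return character vector of canonical SMILES.
#' @export
load_counterions <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sr_env$counterions)) return(.sr_env$counterions)
    path <- sr_extdata("counterions.smi")
    cache <- TRUE
  } else cache <- FALSE
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  smi <- vapply(strsplit(lines, "[\t ]+"), `[`, "", 1L)
  can <- vapply(smi, ob_canonical, "", USE.NAMES = FALSE)
  if (any(!nzchar(can))) stop("invalid counter-ion SMILES: ",
                              paste(smi[!nzchar(can)], collapse = ", "))
  can <- unique(can)
  if (cache) .sr_env$counterions <- can
  can
}

# per-atom neighbor table: list of data.frames (nbr, order, aromatic)
sr_nbrs <- function(mol) {
  out <- vector("list", mol$n)
  for (i in seq_len(mol$n)) out[[i]] <- data.frame(nbr = integer(), order = integer(), aromatic = logical())
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
      o <- mol$bonds$order[b]; a <- mol$bonds$aromatic[b]
      out[[i]] <- rbind(out[[i]], data.frame(nbr = j, order = o, aromatic = a))
      out[[j]] <- rbind(out[[j]], data.frame(nbr = i, order = o, aromatic = a))
    }
  }
  out
}

frag_charge <- function(mol, atoms) sum(mol$charge[atoms])

#' Reduce a record to its largest fragment (salt stripping)
#'
#' Multi-fragment records are reduced to the largest fragment when every
#' discarded fragment is a recognized counter-ion or a small (<= 6 heavy
#' atoms) fragment of opposite or zero net charge relative to the parent.
#' Equal-size largest fragments, or unrecognized partners, leave the record
#' unchanged (mixture handling belongs to [classify_record()]).
#'
#' @param record an `sr_record`.
#' @param counterions canonical SMILES of counter-ions (see
#'   [load_counterions()]).
#' @export
largest_fragment <- function(record, counterions = load_counterions()) {
  mol <- record$mol
  comps <- sr_components(mol)
  if (length(comps) <= 1L) return(record)
  sizes <- lengths(comps)
  imax <- which.max(sizes)
  if (sum(sizes == sizes[imax]) > 1L) {
    record$flags <- union(record$flags, "mixture_candidate")
    return(record)
  }
  qp <- frag_charge(mol, comps[[imax]])
  for (k in seq_along(comps)) {
    if (k == imax) next
    frag_smi <- ob_canonical(sr_write_smiles(mol, comps[[k]]))
    qf <- frag_charge(mol, comps[[k]])
    ok <- frag_smi %in% counterions ||
      (length(comps[[k]]) <= 6L && qf * qp <= 0)
    if (!ok) {
      record$flags <- union(record$flags, "mixture_candidate")
      return(record)
    }
  }
  newmol <- sr_mol_from_smiles(sr_write_smiles(mol, comps[[imax]]))
  if (is.null(newmol)) return(record)
  record$mol <- newmol
  record$smiles <- newmol$smiles
  record$canonical_key <- newmol$smiles
  record$flags <- union(record$flags, "salt_stripped")
  record
}

# standard valence table; NULL entry means "no constraint checked"
allowed_valence <- function(element, charge) {
  key <- paste0(element, ":", charge)
  tab <- list(
    "C:0" = 4, "C:1" = 3, "C:-1" = 3,
    "N:0" = 3, "N:1" = 4, "N:-1" = 2,
    "O:0" = 2, "O:1" = 3, "O:-1" = 1,
    "S:0" = c(2, 4, 6), "S:1" = c(3, 5), "S:-1" = 1,
    "P:0" = c(3, 5), "P:1" = 4,
    "F:0" = 1, "Cl:0" = 1, "Br:0" = 1, "I:0" = 1,
    "F:-1" = 0, "Cl:-1" = 0, "Br:-1" = 0, "I:-1" = 0,
    "B:0" = 3, "B:-1" = 4,
    "Se:0" = c(2, 4, 6)
  )
  tab[[key]]
}

#' Classify a record as ok / inorganic / mixture / bad_valence
#'
#' Categories are checked in the order inorganic, mixture, bad valence; the
#' first match wins.  Inorganic means the parent (largest) fragment has no
#' carbon or contains an element outside the allowed organic set.
#'
#' @param record an `sr_record` (salt stripping already applied).
#' @return one of `"ok"`, `"inorganic"`, `"mixture"`, `"bad_valence"`.
#' @export
classify_record <- function(record) {
  mol <- record$mol
  comps <- sr_components(mol)
  parent <- comps[[which.max(lengths(comps))]]
  el <- mol$element[parent]
  if (!any(el == "C") || any(!(el %in% ORGANIC_ELEMENTS))) return("inorganic")
  if (length(comps) > 1L) return("mixture")
  vsum <- integer(mol$n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      vsum[mol$bonds$a1[b]] <- vsum[mol$bonds$a1[b]] + mol$bonds$order[b]
      vsum[mol$bonds$a2[b]] <- vsum[mol$bonds$a2[b]] + mol$bonds$order[b]
    }
  }
  vsum <- vsum + mol$nH
  for (i in seq_len(mol$n)) {
    av <- allowed_valence(mol$element[i], mol$charge[i])
    if (!is.null(av) && !(vsum[i] %in% av) && vsum[i] > max(av)) return("bad_valence")
  }
  "ok"
}

# ---- standardization: tautomer + pH 7.4 protonation rules --------------

# Each rule scans the graph and, if it fires, edits charges / H counts /
# bond orders in place and returns TRUE.  Rules are written so that their
# products no longer match (idempotence).

rule_enol_to_keto <- function(mol) {
  nb <- sr_nbrs(mol)
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != 2L || mol$bonds$aromatic[b]) next
    for (sw in list(c(mol$bonds$a1[b], mol$bonds$a2[b]),
                    c(mol$bonds$a2[b], mol$bonds$a1[b]))) {
      ca <- sw[1]; cb <- sw[2]
      if (mol$element[ca] != "C" || mol$element[cb] != "C") next
      if (mol$aromatic[ca] || mol$aromatic[cb]) next
      oxy <- nb[[ca]]$nbr[nb[[ca]]$order == 1L & !nb[[ca]]$aromatic &
                            mol$element[nb[[ca]]$nbr] == "O"]
      oxy <- oxy[mol$charge[oxy] == 0L & mol$nH[oxy] >= 1L & sr_degree(mol)[oxy] == 1L]
      if (length(oxy) == 0L) next
      o <- oxy[1]
      ob <- which((mol$bonds$a1 == ca & mol$bonds$a2 == o) |
                    (mol$bonds$a2 == ca & mol$bonds$a1 == o))[1]
      mol$bonds$order[ob] <- 2L
      mol$bonds$order[b] <- 1L
      mol$nH[o] <- mol$nH[o] - 1L
      mol$nH[cb] <- mol$nH[cb] + 1L
      return(list(mol = mol, fired = TRUE))
    }
  }
  list(mol = mol, fired = FALSE)
}

rule_iminol_to_amide <- function(mol) {
  nb <- sr_nbrs(mol)
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != 2L || mol$bonds$aromatic[b]) next
    for (sw in list(c(mol$bonds$a1[b], mol$bonds$a2[b]),
                    c(mol$bonds$a2[b], mol$bonds$a1[b]))) {
      c_at <- sw[1]; n_at <- sw[2]
      if (mol$element[c_at] != "C" || mol$element[n_at] != "N") next
      if (mol$aromatic[c_at] || mol$aromatic[n_at]) next
      if (mol$charge[n_at] != 0L) next
      oxy <- nb[[c_at]]$nbr[nb[[c_at]]$order == 1L &
                              mol$element[nb[[c_at]]$nbr] == "O"]
      oxy <- oxy[mol$charge[oxy] == 0L & mol$nH[oxy] >= 1L & sr_degree(mol)[oxy] == 1L]
      if (length(oxy) == 0L) next
      o <- oxy[1]
      ob <- which((mol$bonds$a1 == c_at & mol$bonds$a2 == o) |
                    (mol$bonds$a2 == c_at & mol$bonds$a1 == o))[1]
      mol$bonds$order[ob] <- 2L
      mol$bonds$order[b] <- 1L
      mol$nH[o] <- mol$nH[o] - 1L
      mol$nH[n_at] <- mol$nH[n_at] + 1L
      return(list(mol = mol, fired = TRUE))
    }
  }
  list(mol = mol, fired = FALSE)
}

# acidic OH on C(=O), S(=O)(=O), P(=O): deprotonated at pH 7.4
rule_deprotonate_acids <- function(mol) {
  nb <- sr_nbrs(mol)
  for (i in seq_len(mol$n)) {
    el <- mol$element[i]
    if (!(el %in% c("C", "S", "P"))) next
    dbl_o <- sum(nb[[i]]$order == 2L & mol$element[nb[[i]]$nbr] == "O")
    if (el == "C" && dbl_o < 1L) next
    if (el == "S" && dbl_o < 2L) next
    if (el == "P" && dbl_o < 1L) next
    oh <- nb[[i]]$nbr[nb[[i]]$order == 1L & mol$element[nb[[i]]$nbr] == "O"]
    oh <- oh[mol$charge[oh] == 0L & mol$nH[oh] >= 1L & sr_degree(mol)[oh] == 1L]
    if (length(oh) == 0L) next
    # carboxylic & sulfonic: all acidic protons; phosphate: first only (pKa2 ~ 7)
    take <- if (el == "P") oh[1] else oh
    mol$charge[take] <- -1L
    mol$nH[take] <- mol$nH[take] - 1L
    return(list(mol = mol, fired = TRUE))
  }
  list(mol = mol, fired = FALSE)
}

# aliphatic amines and amidine/guanidine sp2 N: protonated at pH 7.4
rule_protonate_bases <- function(mol) {
  nb <- sr_nbrs(mol)
  deg <- sr_degree(mol)
  # amidine / guanidine: C(=N)(N)
  for (i in seq_len(mol$n)) {
    if (mol$element[i] != "C" || mol$aromatic[i]) next
    ns_dbl <- nb[[i]]$nbr[nb[[i]]$order == 2L & mol$element[nb[[i]]$nbr] == "N" &
                            !nb[[i]]$aromatic]
    ns_sgl <- nb[[i]]$nbr[nb[[i]]$order == 1L & mol$element[nb[[i]]$nbr] == "N"]
    het_dbl <- any(nb[[i]]$order == 2L & mol$element[nb[[i]]$nbr] %in% c("O", "S"))
    if (length(ns_dbl) == 1L && length(ns_sgl) >= 1L && !het_dbl &&
        mol$charge[ns_dbl] == 0L && !mol$aromatic[ns_dbl]) {
      mol$charge[ns_dbl] <- 1L
      mol$nH[ns_dbl] <- mol$nH[ns_dbl] + 1L
      return(list(mol = mol, fired = TRUE))
    }
  }
  # aliphatic amine
  for (i in seq_len(mol$n)) {
    if (mol$element[i] != "N" || mol$aromatic[i] || mol$charge[i] != 0L) next
    if (any(nb[[i]]$order > 1L) || any(nb[[i]]$aromatic)) next
    if (deg[i] > 3L) next
    neigh <- nb[[i]]$nbr
    if (any(mol$element[neigh] != "C")) next           # N-N, N-O, N-S: not basic
    if (any(mol$aromatic[neigh])) next                 # anilines: not basic
    carbonyl_like <- vapply(neigh, function(j) {
      nbj <- nb[[j]]
      any(nbj$order >= 2L & mol$element[nbj$nbr] %in% c("O", "N", "S"))
    }, TRUE)
    if (any(carbonyl_like)) next                       # amides, sulfonamides, enamines
    mol$charge[i] <- 1L
    mol$nH[i] <- mol$nH[i] + 1L
    return(list(mol = mol, fired = TRUE))
  }
  list(mol = mol, fired = FALSE)
}

#' Standardize a record (single tautomer, pH 7.4 protonation)
#'
#' Applies a deterministic, auditable rule set: enol-to-keto and
#' iminol-to-amide tautomer normalization, deprotonation of carboxylic,
#' sulfonic/sulfuric and (singly) phosphoric OH groups, and protonation of
#' aliphatic amines and amidine/guanidine groups.  Idempotent: products of a
#' rule no longer match it.
#'
#' @param record an `sr_record` classified `"ok"`.
#' @export
standardize <- function(record) {
  mol <- record$mol
  for (pass in 1:25) {
    fired <- FALSE
    for (rule in list(rule_enol_to_keto, rule_iminol_to_amide,
                      rule_deprotonate_acids, rule_protonate_bases)) {
      res <- rule(mol)
      mol <- res$mol
      if (res$fired) { fired <- TRUE; break }
    }
    if (!fired) break
  }
  newmol <- sr_reparse(mol)
  if (is.null(newmol)) return(record)  # keep original rather than lose the record
  record$mol <- newmol
  record$smiles <- newmol$smiles
  record$canonical_key <- newmol$smiles
  record
}

#' Remove duplicate records by canonical key
#'
#' @param records list of standardized `sr_record`s.
#' @return list with `kept` (first occurrence of each canonical key, input
#'   order) and `n_duplicates`.
#' @export
deduplicate <- function(records) {
  keys <- vapply(records, function(r) r$canonical_key, "")
  keep <- !duplicated(keys)
  list(kept = records[keep], n_duplicates = sum(!keep))
}

#' Curate a library
#'
#' Applies salt stripping, classification (removing inorganics, mixtures and
#' bad-valence structures), standardization and duplicate removal, and
#' reports per-category removal counts and percentages relative to the input
#' size (parse failures recorded at read time are included).
#'
#' @param library an `sr_library`.
#' @param counterions counter-ion canonical SMILES.
#' @return list with `library` (curated) and `report` (one-row data frame).
#' @export
curate <- function(library, counterions = load_counterions()) {
  n_parse <- library$n_parse_failed
  total_in <- length(library$records) + n_parse
  counts <- c(inorganic = 0L, duplicate = 0L, mixture = 0L, bad_valence = 0L,
              parse_failure = n_parse)
  kept <- list()
  for (rec in library$records) {
    rec <- largest_fragment(rec, counterions)
    cls <- classify_record(rec)
    if (cls != "ok") {
      counts[[if (cls == "inorganic") "inorganic" else if (cls == "mixture") "mixture" else "bad_valence"]] <-
        counts[[if (cls == "inorganic") "inorganic" else if (cls == "mixture") "mixture" else "bad_valence"]] + 1L
      next
    }
    kept[[length(kept) + 1L]] <- standardize(rec)
  }
  dd <- deduplicate(kept)
  counts[["duplicate"]] <- dd$n_duplicates
  out <- new_library(library$name, dd$kept, provenance = library$provenance)
  if (length(out$records) == 0L) warning("curation removed every record of ", library$name)
  pct <- if (total_in > 0) 100 * counts / total_in else counts * 0
  report <- data.frame(
    library = library$name,
    total_in = total_in,
    inorganic = counts[["inorganic"]], inorganic_pct = pct[["inorganic"]],
    duplicate = counts[["duplicate"]], duplicate_pct = pct[["duplicate"]],
    mixture = counts[["mixture"]], mixture_pct = pct[["mixture"]],
    bad_valence = counts[["bad_valence"]], bad_valence_pct = pct[["bad_valence"]],
    parse_failure = counts[["parse_failure"]], parse_failure_pct = pct[["parse_failure"]],
    total_out = length(out$records),
    total_removed_pct = if (total_in > 0) 100 * sum(counts) / total_in else 0,
    stringsAsFactors = FALSE
  )
  list(library = out, report = report)
}
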
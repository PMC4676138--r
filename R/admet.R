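#' ADME/T profiling
#'
#' Lipinski rule-of-five and Veber filters plus a blood-brain barrier
#' permeation (logBB) model expressed as linear plus truncated-power spline
#' terms over five descriptors: an atom-contribution log partition
#' coefficient (alogp98), the difference between positive and negative
#' partial-charge solvent-accessible surface area (dpsa1), the hydrogen-bond
#' acceptor count, and the E-state sums over trisubstituted amine nitrogens
#' (s_sssN) and methylene carbons (s_ssCH2).  Compounds with predicted
#' logBB >= 0 are classed permeable; logBB < 0 impermeable.
#'
#' @name admet
NULL

# OpenBabel molecule references for a whole library in one parse
lib_obrefs <- function(lib) {
  ChemmineOB::forEachMol("SMILES", paste(lib_smiles(lib), collapse = "\n"),
                         identity)
}

# rotatable bond: single, acyclic, non-amide bond between two heavy atoms
# each bound to at least one further heavy atom
count_rotatable <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(0L)
  deg <- sr_degree(mol)
  nb <- sr_nbrs(mol)
  is_amide_cn <- function(i, j) {
    for (sw in list(c(i, j), c(j, i))) {
      c_at <- sw[1]; n_at <- sw[2]
      if (mol$element[c_at] == "C" && mol$element[n_at] == "N" &&
          any(nb[[c_at]]$order == 2L & mol$element[nb[[c_at]]$nbr] == "O"))
        return(TRUE)
    }
    FALSE
  }
  n <- 0L
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != 1L || mol$bonds$aromatic[b] || mol$ring_bond[b]) next
    i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
    if (deg[i] < 2L || deg[j] < 2L) next
    if (is_amide_cn(i, j)) next
    # terminal symmetric tops (e.g. tBu, CF3) still count in this simple model
    n <- n + 1L
  }
  n
}

#' Physicochemical property vector per record
#'
#' @param library an `sr_library` (curated).
#' @return data frame with one row per record: `record_id`, `mw`, `clogp`,
#'   `hbd`, `hba`, `rotb`, `psa`, `hbond_count`.
#' @export
compute_properties <- function(library) {
  sdf <- lib_obrefs(library)
  p <- ChemmineOB::prop_OB(sdf)
  rotb <- vapply(library$records, function(r) count_rotatable(r$mol), 0L)
  out <- data.frame(
    record_id = lib_ids(library),
    mw = as.numeric(p$MW),
    clogp = as.numeric(p$logP),
    hbd = as.integer(p$HBD),
    hba = as.integer(p$HBA1),
    rotb = rotb,
    psa = as.numeric(p$TPSA),
    stringsAsFactors = FALSE
  )
  out$hbond_count <- out$hbd + out$hba
  out
}

#' Lipinski rule-of-five violation count
#'
#' Counts strict violations among H-bond donors > 5, molecular weight > 500,
#' CLogP > 5 and H-bond acceptors > 10.  A compound fails the filter when it
#' violates more than one criterion.
#'
#' @param props data frame with columns `hbd`, `mw`, `clogp`, `hba`.
#' @return integer vector in 0..4.
#' @export
lipinski_violations <- function(props) {
  as.integer((props$hbd > 5) + (props$mw > 500) + (props$clogp > 5) +
               (props$hba > 10))
}

#' Veber filter
#'
#' Passes when rotatable bonds <= 10 and (polar surface area <= 140 A^2 or
#' total H-bond count <= 12).
#'
#' @param props data frame with columns `rotb`, `psa`, `hbond_count`.
#' @return logical vector.
#' @export
veber_pass <- function(props) {
  props$rotb <= 10 & (props$psa <= 140 | props$hbond_count <= 12)
}

# ---- logBB model -------------------------------------------------------

#' Parse a logBB model parameter file
#'
#' Plain-text format, tab/space separated: an `intercept` line, `linear
#' <descriptor> <coefficient>` lines and `spline <descriptor> <knot>
#' <coefficient> <below|above>` lines.  `below` denotes a term
#' coefficient * max(0, knot - x); `above` coefficient * max(0, x - knot).
#'
#' @param path parameter file; default: the shipped model.
#' @return an object of class `logbb_model`.
#' @export
read_logbb_model <- function(path = NULL) {
  if (is.null(path)) path <- sr_extdata("logbb_model.txt")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  intercept <- 0
  linear <- data.frame(descriptor = character(), coefficient = numeric())
  spline <- data.frame(descriptor = character(), knot = numeric(),
                       coefficient = numeric(), orientation = character())
  for (ln in lines) {
    f <- strsplit(ln, "[\t ]+")[[1]]
    if (f[1] == "intercept") {
      intercept <- as.numeric(f[2])
    } else if (f[1] == "linear") {
      linear <- rbind(linear, data.frame(descriptor = f[2],
                                         coefficient = as.numeric(f[3])))
    } else if (f[1] == "spline") {
      if (!f[5] %in% c("below", "above")) stop("bad spline orientation: ", f[5])
      spline <- rbind(spline, data.frame(descriptor = f[2], knot = as.numeric(f[3]),
                                         coefficient = as.numeric(f[4]),
                                         orientation = f[5]))
    } else stop("unrecognized model line: ", ln)
  }
  structure(list(intercept = intercept, linear = linear, spline = spline),
            class = "logbb_model")
}

#' Write a logBB model parameter file
#' @param model a `logbb_model`.
#' @param path output path.
#' @export
write_logbb_model <- function(model, path) {
  lines <- c(sprintf("intercept\t%.10g", model$intercept))
  for (i in seq_len(nrow(model$linear))) {
    lines <- c(lines, sprintf("linear\t%s\t%.10g", model$linear$descriptor[i],
                              model$linear$coefficient[i]))
  }
  for (i in seq_len(nrow(model$spline))) {
    lines <- c(lines, sprintf("spline\t%s\t%.10g\t%.10g\t%s",
                              model$spline$descriptor[i], model$spline$knot[i],
                              model$spline$coefficient[i], model$spline$orientation[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.logbb_model <- function(x, ...) {
  cat("logBB model: intercept", x$intercept, "+", nrow(x$linear), "linear +",
      nrow(x$spline), "spline terms\n")
  invisible(x)
}

#' Evaluate a logBB model on descriptor values
#'
#' @param d data frame (or named list) of descriptor values; must contain
#'   every descriptor named by the model, all finite.
#' @param model a `logbb_model` (default: the shipped equation).
#' @return numeric vector of predicted logBB.
#' @export
predict_logbb <- function(d, model = read_logbb_model()) {
  d <- as.data.frame(as.list(d))
  needed <- unique(c(model$linear$descriptor, model$spline$descriptor))
  for (nm in needed) {
    if (is.null(d[[nm]])) stop("missing descriptor: ", nm)
    if (any(!is.finite(d[[nm]]))) stop("non-finite descriptor: ", nm)
  }
  out <- rep(model$intercept, nrow(d))
  for (i in seq_len(nrow(model$linear))) {
    out <- out + model$linear$coefficient[i] * d[[model$linear$descriptor[i]]]
  }
  for (i in seq_len(nrow(model$spline))) {
    x <- d[[model$spline$descriptor[i]]]
    arg <- if (model$spline$orientation[i] == "below") model$spline$knot[i] - x
           else x - model$spline$knot[i]
    out <- out + model$spline$coefficient[i] * pmax(0, arg)
  }
  out
}

#' Binary blood-brain barrier class from logBB
#'
#' @param logbb numeric vector.
#' @return factor with levels `permeable` (logBB >= 0) and `impermeable`.
#' @export
classify_bbb <- function(logbb) {
  stopifnot(all(is.finite(logbb)))
  factor(ifelse(logbb >= 0, "permeable", "impermeable"),
         levels = c("permeable", "impermeable"))
}

#' Compute the logBB descriptors of one record
#'
#' alogp98 is the atom-contribution logP; dpsa1 the positive-minus-negative
#' partial-charge solvent-accessible surface area on a single embedded
#' conformer (NA when embedding fails; such records are excluded from BBB
#' statistics with a logged count); num_h_acceptors the standard acceptor
#' count; s_sssN and s_ssCH2 E-state sums (0 when no matching atom).
#'
#' @param record an `sr_record`.
#' @param clogp optional precomputed logP (saves one conversion).
#' @param hba optional precomputed acceptor count.
#' @return one-row data frame of the five descriptors.
#' @export
compute_logbb_descriptors <- function(record, clogp = NULL, hba = NULL) {
  if (is.null(clogp) || is.null(hba)) {
    lib1 <- new_library("tmp", list(record))
    p <- ChemmineOB::prop_OB(lib_obrefs(lib1))
    clogp <- as.numeric(p$logP)
    hba <- as.integer(p$HBA2)
  }
  data.frame(
    alogp98 = clogp,
    dpsa1 = compute_dpsa1(record$smiles),
    num_h_acceptors = hba,
    s_sssN = estate_sum(record$mol, "sssN"),
    s_ssCH2 = estate_sum(record$mol, "ssCH2")
  )
}

#' ADME/T profile of a library
#'
#' @param library a curated `sr_library`.
#' @param model logBB model.
#' @return list with `compounds` (per-record table: properties, Lipinski
#'   violations and fail flag, Veber pass, logBB, BBB class) and `summary`
#'   (one row: `pct_fail_lipinski`, `pct_fail_veber`, `pct_logbb_neg`,
#'   `n_descriptor_failures`).
#' @export
admet_profile <- function(library, model = read_logbb_model()) {
  props <- compute_properties(library)
  sdf <- lib_obrefs(library)
  p <- ChemmineOB::prop_OB(sdf)
  desc <- do.call(rbind, lapply(seq_along(library$records), function(i) {
    compute_logbb_descriptors(library$records[[i]],
                              clogp = as.numeric(p$logP[i]),
                              hba = as.integer(p$HBA2[i]))
  }))
  usable <- is.finite(desc$dpsa1)
  logbb <- rep(NA_real_, nrow(desc))
  if (any(usable)) logbb[usable] <- predict_logbb(desc[usable, , drop = FALSE], model)
  if (any(!usable)) {
    message("admet_profile: ", sum(!usable),
            " record(s) excluded from BBB statistics (embedding failure)")
  }
  compounds <- cbind(props, desc,
                     lipinski_violations = lipinski_violations(props),
                     veber_pass = veber_pass(props),
                     logbb = logbb)
  compounds$fail_lipinski <- compounds$lipinski_violations > 1
  compounds$bbb <- ifelse(is.na(logbb), NA,
                          ifelse(logbb >= 0, "permeable", "impermeable"))
  n <- nrow(compounds)
  summary <- data.frame(
    library = library$name,
    n = n,
    pct_fail_lipinski = 100 * sum(compounds$fail_lipinski) / n,
    pct_fail_veber = 100 * sum(!compounds$veber_pass) / n,
    pct_logbb_neg = 100 * sum(logbb < 0, na.rm = TRUE) / sum(usable),
    n_descriptor_failures = sum(!usable),
    stringsAsFactors = FALSE
  )
  list(compounds = compounds, summary = summary)
}
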
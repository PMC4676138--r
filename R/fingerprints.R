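#' Molecular fingerprints
#'
#' Implements the 2D fingerprint dialects used for diversity and similarity
#' scoring: extended-connectivity circular fingerprints (ECFP_2/4/6) and
#' their functional-class variants (FCFP_2/4/6) as sparse sets of stable
#' 32-bit feature hashes, the 166-key public structural-key set (MDL_keys),
#' and topological n-point pharmacophore fingerprints in binary and count
#' forms over three feature-type palettes:
#'
#' * `PHFP_n` / `PHFC_n` - six types (donor, acceptor, positive, negative,
#'   aromatic, hydrophobe), binary / count;
#' * `PHPFP_n` / `PHPFC_n` - coarse four-type palette merging donors with
#'   acceptors (polar) and the two ionizable types;
#' * `PHRFP_n` / `PHRFC_n` - ring-aware seven-type palette adding aliphatic
#'   ring systems.
#'
#' Circular-feature hashing uses an explicit FNV-1a over canonical invariant
#' strings: identifiers are stable across runs and platforms, and the
#' feature set of a smaller diameter is contained in that of a larger one by
#' construction.
#'
#' @name fingerprints
NULL

# ---- stable 32-bit FNV-1a ----------------------------------------------

fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (if (h >= 2^31) 2^31 else 0)
    # 32-bit multiply by 16777619 without losing precision
    a1 <- h %/% 65536
    a0 <- h %% 65536
    h <- (a0 * 16777619 + ((a1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

new_fp <- function(dialect, form, features, flagged = FALSE) {
  structure(list(dialect = dialect, form = form, features = features,
                 flagged = flagged), class = "sr_fp")
}

#' @export
print.sr_fp <- function(x, ...) {
  nf <- if (x$form == "count") length(x$features) else length(x$features)
  cat("<fingerprint ", x$dialect, "> ", nf, " features",
      if (x$flagged) " (flagged)", "\n", sep = "")
  invisible(x)
}

# ---- circular (ECFP / FCFP) --------------------------------------------

ecfp_initial_invariants <- function(mol, functional_class) {
  deg <- sr_degree(mol)
  if (functional_class) {
    ph <- pharmacophore_atom_classes(mol)
    vapply(seq_len(mol$n), function(i) {
      fnv1a(paste0("fc:", paste(as.integer(ph[i, ]), collapse = "")))
    }, 0)
  } else {
    vapply(seq_len(mol$n), function(i) {
      fnv1a(paste("ec", mol$element[i], deg[i], mol$nH[i], mol$charge[i],
                  as.integer(mol$aromatic[i]), as.integer(mol$ring_atom[i]),
                  sep = ":"))
    }, 0)
  }
}

#' Circular substructure fingerprint (ECFP / FCFP)
#'
#' @param record an `sr_record`.
#' @param diameter 2, 4 or 6 (max feature diameter in bonds; radius =
#'   diameter / 2 iterations).
#' @param functional_class use pharmacophoric atom classes instead of
#'   element/connectivity invariants (FCFP).
#' @param form `"binary"` or `"count"`.
#' @return an `sr_fp` whose features are sparse stable hashes.
#' @export
circular_fp <- function(record, diameter = 4L, functional_class = FALSE,
                        form = c("binary", "count")) {
  form <- match.arg(form)
  stopifnot(diameter %in% c(2L, 4L, 6L))
  mol <- record$mol
  dialect <- paste0(if (functional_class) "FCFP_" else "ECFP_", diameter)
  if (mol$n == 0L) return(new_fp(dialect, form, numeric(0), flagged = TRUE))
  inv <- ecfp_initial_invariants(mol, functional_class)
  nb <- sr_nbrs(mol)
  feats <- inv
  for (it in seq_len(diameter %/% 2L)) {
    newinv <- numeric(mol$n)
    for (i in seq_len(mol$n)) {
      pairs <- character(0)
      if (nrow(nb[[i]])) {
        code <- ifelse(nb[[i]]$aromatic, 4L, nb[[i]]$order)
        p <- paste0(code, ",", format(inv[nb[[i]]$nbr], scientific = FALSE, trim = TRUE))
        pairs <- sort(p)
      }
      newinv[i] <- fnv1a(paste0("it", it, ";", format(inv[i], scientific = FALSE, trim = TRUE),
                                ";", paste(pairs, collapse = ";")))
    }
    inv <- newinv
    feats <- c(feats, inv)
  }
  if (form == "binary") {
    new_fp(dialect, form, sort(unique(feats)))
  } else {
    tab <- table(feats)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    new_fp(dialect, form, counts)
  }
}

# ---- structural keys (166-bit public key set) --------------------------

#' Structural-key fingerprint (166 public keys)
#'
#' @param record an `sr_record`.
#' @return binary `sr_fp` of set key indices (dialect `MDL_keys`).
#' @export
structural_keys <- function(record) {
  lib1 <- new_library("tmp", list(record))
  lib_structural_keys(lib1)[[1]]
}

lib_structural_keys <- function(library) {
  m <- ChemmineOB::fingerprint_OB(lib_obrefs(library), "MACCS")
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  lapply(seq_len(nrow(m)), function(i) {
    new_fp("MDL_keys", "binary", which(m[i, ] == 1))
  })
}

# ---- pharmacophore typing ----------------------------------------------

# per-atom logical matrix of base feature classes
pharmacophore_atom_classes <- function(mol) {
  nb <- sr_nbrs(mol)
  n <- mol$n
  donor <- acceptor <- pos <- neg <- arom <- hydro <- logical(n)
  for (i in seq_len(n)) {
    el <- mol$element[i]
    q <- mol$charge[i]
    if (el %in% c("N", "O") && mol$nH[i] >= 1L && q >= 0L) donor[i] <- TRUE
    if (el == "O" && q <= 0L) acceptor[i] <- TRUE
    if (el == "N" && q <= 0L) {
      amide <- any(vapply(seq_len(nrow(nb[[i]])), function(k) {
        j <- nb[[i]]$nbr[k]
        mol$element[j] == "C" &&
          any(nb[[j]]$order == 2L & mol$element[nb[[j]]$nbr] %in% c("O", "S"))
      }, TRUE))
      pyrrole <- mol$aromatic[i] && mol$nH[i] >= 1L
      if (!amide && !pyrrole) acceptor[i] <- TRUE
    }
    if (q > 0L && el %in% c("N", "C")) pos[i] <- TRUE
    if (q < 0L && el %in% c("O", "S", "C")) neg[i] <- TRUE
    arom[i] <- mol$aromatic[i]
    if (el == "C" && !mol$aromatic[i]) {
      het <- any(!(mol$element[nb[[i]]$nbr] %in% c("C", "H")))
      hydro[i] <- !het
    }
  }
  cbind(donor = donor, acceptor = acceptor, pos = pos, neg = neg,
        aromatic = arom, hydrophobe = hydro)
}

# collapse group-type features (aromatic systems, hydrophobic patches,
# aliphatic rings) to one representative atom per connected component
group_representatives <- function(mol, member) {
  if (!any(member)) return(integer(0))
  comps <- sr_components(mol, which(member))
  # keep only components whose internal bonds exist (sr_components already
  # splits on connectivity); representative = lowest atom index
  vapply(comps, min, 0L)
}

# feature table (type, atom) for a palette: "base", "coarse", "ring"
pharmacophore_features <- function(mol, palette = c("base", "coarse", "ring")) {
  palette <- match.arg(palette)
  cls <- pharmacophore_atom_classes(mol)
  feats <- data.frame(type = character(), atom = integer())
  add <- function(type, atoms) {
    if (length(atoms)) {
      feats <<- rbind(feats, data.frame(type = type, atom = as.integer(atoms)))
    }
  }
  arom_rep <- group_representatives(mol, cls[, "aromatic"])
  hydro_rep <- group_representatives(mol, cls[, "hydrophobe"])
  if (palette == "coarse") {
    add("PL", which(cls[, "donor"] | cls[, "acceptor"]))
    add("IO", which(cls[, "pos"] | cls[, "neg"]))
    add("AR", arom_rep)
    add("HY", hydro_rep)
  } else {
    add("D", which(cls[, "donor"]))
    add("A", which(cls[, "acceptor"]))
    add("P", which(cls[, "pos"]))
    add("N", which(cls[, "neg"]))
    add("AR", arom_rep)
    add("HY", hydro_rep)
    if (palette == "ring") {
      ali_ring <- mol$ring_atom & !mol$aromatic
      add("RG", group_representatives(mol, ali_ring))
    }
  }
  feats
}

# topological distance bins: 1 | 2-3 | 4-6 | 7-10 | >10 (0 = same atom)
ph_bin <- function(d) {
  ifelse(d == 0, 0L,
  ifelse(d == 1, 1L,
  ifelse(d <= 3, 2L,
  ifelse(d <= 6, 3L,
  ifelse(d <= 10, 4L, 5L)))))
}

# canonical string for an n-point feature: lexicographic minimum over
# point permutations of "types|upper-triangle distance bins"
ph_canonical <- function(types, binmat) {
  k <- length(types)
  perms <- permutations_of(k)
  best <- NULL
  for (p in perms) {
    tp <- types[p]
    bm <- binmat[p, p, drop = FALSE]
    tri <- bm[upper.tri(bm)]
    s <- paste(paste(tp, collapse = ","), paste(tri, collapse = ","), sep = "|")
    if (is.null(best) || s < best) best <- s
  }
  best
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutations_of(k - 1L)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Topological pharmacophore fingerprint
#'
#' Features are canonicalized n-tuples of pharmacophore feature types plus
#' binned topological distances between the feature atoms.  Molecules with
#' fewer than `points` features yield an empty, flagged fingerprint (such
#' compounds are excluded from fingerprint statistics downstream).
#'
#' @param record an `sr_record`.
#' @param points 2, 3 or 4.
#' @param form `"binary"` or `"count"`.
#' @param palette `"base"`, `"coarse"` or `"ring"` feature-type palette.
#' @export
pharmacophore_fp <- function(record, points = 2L, form = c("binary", "count"),
                             palette = c("base", "coarse", "ring")) {
  form <- match.arg(form)
  palette <- match.arg(palette)
  stopifnot(points %in% 2:4)
  mol <- record$mol
  tag <- paste0("PH", switch(palette, base = "", coarse = "P", ring = "R"),
                "F", if (form == "binary") "P" else "C", "_", points)
  feats <- pharmacophore_features(mol, palette)
  if (nrow(feats) < points) {
    return(new_fp(tag, form, if (form == "count") integer(0) else numeric(0),
                  flagged = TRUE))
  }
  D <- sr_dist_matrix(mol)
  combos <- utils::combn(seq_len(nrow(feats)), points)
  keys <- character(ncol(combos))
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    atoms <- feats$atom[sel]
    binmat <- matrix(0L, points, points)
    for (a in seq_len(points - 1L)) {
      for (b in seq((a + 1L), points)) {
        d <- D[atoms[a], atoms[b]]
        binmat[a, b] <- binmat[b, a] <- ph_bin(if (is.infinite(d)) 11 else d)
      }
    }
    keys[c_i] <- ph_canonical(feats$type[sel], binmat)
  }
  if (form == "binary") {
    new_fp(tag, form, sort(unique(vapply(keys, fnv1a, 0, USE.NAMES = FALSE))))
  } else {
    tab <- table(vapply(keys, fnv1a, 0, USE.NAMES = FALSE))
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    new_fp(tag, form, counts)
  }
}

# ---- dialect dispatch --------------------------------------------------

#' All supported fingerprint dialect tags
#' @export
fingerprint_dialects <- function() {
  c(paste0("ECFP_", c(2, 4, 6)), paste0("FCFP_", c(2, 4, 6)), "MDL_keys",
    as.vector(outer(c("PHFP", "PHFC", "PHPFP", "PHPFC", "PHRFP", "PHRFC"),
                    2:4, paste, sep = "_")))
}

#' Compute a fingerprint by dialect tag
#'
#' @param record an `sr_record`.
#' @param dialect one of [fingerprint_dialects()].
#' @export
compute_fingerprint <- function(record, dialect = "ECFP_4") {
  if (grepl("^ECFP_[246]$", dialect)) {
    circular_fp(record, as.integer(sub("ECFP_", "", dialect)), FALSE)
  } else if (grepl("^FCFP_[246]$", dialect)) {
    circular_fp(record, as.integer(sub("FCFP_", "", dialect)), TRUE)
  } else if (dialect == "MDL_keys") {
    structural_keys(record)
  } else if (grepl("^PH[PR]?F[PC]_[234]$", dialect)) {
    mid <- sub("^PH([PR]?)F([PC])_([234])$", "\\1", dialect)
    frm <- sub("^PH([PR]?)F([PC])_([234])$", "\\2", dialect)
    pts <- as.integer(sub("^PH([PR]?)F([PC])_([234])$", "\\3", dialect))
    pharmacophore_fp(record, pts,
                     form = if (frm == "P") "binary" else "count",
                     palette = switch(mid, "P" = "coarse", "R" = "ring", "base"))
  } else stop("unknown fingerprint dialect: ", dialect)
}

#' Fingerprints for every record of a library
#'
#' @param library an `sr_library`.
#' @param dialect dialect tag.
#' @return list of `sr_fp`, one per record (structural keys are computed in
#'   one batched pass).
#' @export
lib_fingerprints <- function(library, dialect = "ECFP_4") {
  if (dialect == "MDL_keys") return(lib_structural_keys(library))
  lapply(library$records, compute_fingerprint, dialect = dialect)
}

#' Tanimoto similarity between two fingerprints
#'
#' Binary form: |intersection| / |union| of feature sets; count form:
#' sum(min) / sum(max) over the union of features.  Two empty fingerprints
#' have similarity 0 (with a warning).
#'
#' @param a,b `sr_fp` objects of the same dialect.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (!identical(a$dialect, b$dialect)) {
    stop("fingerprint dialect mismatch: ", a$dialect, " vs ", b$dialect)
  }
  if (a$form == "count") {
    keys <- union(names(a$features), names(b$features))
    if (length(keys) == 0L) {
      warning("both fingerprints empty; similarity defined as 0")
      return(0)
    }
    av <- a$features[keys]; av[is.na(av)] <- 0L
    bv <- b$features[keys]; bv[is.na(bv)] <- 0L
    sum(pmin(av, bv)) / sum(pmax(av, bv))
  } else {
    if (length(a$features) == 0L && length(b$features) == 0L) {
      warning("both fingerprints empty; similarity defined as 0")
      return(0)
    }
    length(intersect(a$features, b$features)) /
      length(union(a$features, b$features))
  }
}
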
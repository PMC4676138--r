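# Kier-Hall electrotopological state (E-state) indices.
#
# Intrinsic state I = ((2/N)^2 * dv + 1) / d, with d the heavy-atom degree,
# dv the valence-electron count minus bound hydrogens (scaled for rows > 2),
# and N the principal quantum number.  The E-state of an atom adds the
# graph-distance-damped perturbations from all other atoms:
# S_i = I_i + sum_j (I_i - I_j) / (d_ij + 1)^2.

ESTATE_ZV <- c(C = 4, N = 5, O = 6, F = 7, S = 6, P = 5, Cl = 7, Br = 7,
               I = 7, B = 3, Se = 6)
ESTATE_PQN <- c(C = 2, N = 2, O = 2, F = 2, B = 2, S = 3, P = 3, Cl = 3,
                Br = 4, Se = 4, I = 5)
ESTATE_Z <- c(C = 6, N = 7, O = 8, F = 9, B = 5, S = 16, P = 15, Cl = 17,
              Br = 35, Se = 34, I = 53)

#' Per-atom E-state values of a molecule
#'
#' @param mol internal molecular graph.
#' @return numeric vector (NA for elements without parameters).
#' @noRd
estate_values <- function(mol) {
  el <- mol$element
  d <- sr_degree(mol)
  zv <- ESTATE_ZV[el]
  pqn <- ESTATE_PQN[el]
  z <- ESTATE_Z[el]
  h <- mol$nH
  dv <- ifelse(pqn == 2, zv - h, (zv - h) / (z - zv - 1))
  I <- ifelse(d > 0, ((2 / pqn)^2 * dv + 1) / d, (2 / pqn)^2 * dv + 1)
  n <- mol$n
  if (n == 1L) return(as.numeric(I))
  D <- sr_dist_matrix(mol)
  S <- numeric(n)
  for (i in seq_len(n)) {
    dI <- I[i] - I
    w <- 1 / (D[i, ] + 1)^2
    w[i] <- 0
    w[is.infinite(D[i, ])] <- 0  # disconnected fragments do not perturb
    S[i] <- I[i] + sum(dI * w, na.rm = TRUE)
  }
  S
}

# atom-type predicates for the two E-state sums used by the logBB model
is_sssN <- function(mol) {
  nb <- sr_nbrs(mol)
  vapply(seq_len(mol$n), function(i) {
    mol$element[i] == "N" && !mol$aromatic[i] && mol$charge[i] == 0L &&
      mol$nH[i] == 0L && nrow(nb[[i]]) == 3L &&
      all(nb[[i]]$order == 1L) && !any(nb[[i]]$aromatic)
  }, TRUE)
}

is_ssCH2 <- function(mol) {
  nb <- sr_nbrs(mol)
  vapply(seq_len(mol$n), function(i) {
    mol$element[i] == "C" && !mol$aromatic[i] && mol$nH[i] == 2L &&
      nrow(nb[[i]]) == 2L && all(nb[[i]]$order == 1L) && !any(nb[[i]]$aromatic)
  }, TRUE)
}

#' Sum of E-state values over an atom type
#'
#' `s_sssN` sums over trisubstituted amine nitrogens (three single bonds, no
#' hydrogens); `s_ssCH2` over methylene carbons (-CH2- with two single
#' bonds).  Returns 0 when no atom matches.
#'
#' @param mol internal molecular graph.
#' @noRd
estate_sum <- function(mol, type = c("sssN", "ssCH2")) {
  type <- match.arg(type)
  sel <- if (type == "sssN") is_sssN(mol) else is_ssCH2(mol)
  if (!any(sel)) return(0)
  sum(estate_values(mol)[sel])
}
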
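# Shrake-Rupley solvent-accessible surface area on one 3D conformer,
# used for the DPSA1 descriptor (positive minus negative partial-charge SASA).

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, S = 1.80,
               P = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90)

# deterministic golden-spiral unit sphere points
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# coords: n x 3; elements: character; returns per-atom accessible area (A^2)
shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 96L) {
  n <- nrow(coords)
  radii <- unname(VDW_RADII[elements])
  radii[is.na(radii)] <- 1.7
  R <- radii + probe
  pts <- sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, coords[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      free <- free & d2 > R[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  area
}

# DPSA1 of a SMILES: embed one conformer (OpenBabel --gen3d), Gasteiger
# charges, SASA difference (positive minus negative atoms, hydrogens
# included).  NA when embedding fails.
compute_dpsa1 <- function(smiles, probe = 1.4, n_points = 96L) {
  m2 <- ob_convert("SMI", "MOL2", smiles, options = ob_opts("gen3d", "h"))
  if (!nzchar(m2)) return(NA_real_)
  t2 <- parse_mol2(m2)
  if (is.null(t2) || nrow(t2$atoms) == 0L) return(NA_real_)
  coords <- as.matrix(t2$atoms[, c("x", "y", "z")])
  if (nrow(coords) > 1L && all(abs(coords[, 3]) < 1e-8) && all(abs(coords) < 1e-8))
    return(NA_real_)  # embedding silently failed (all-zero coordinates)
  area <- shrake_rupley(coords, t2$atoms$element, probe, n_points)
  q <- t2$atoms$pcharge
  if (all(is.na(q))) return(NA_real_)
  sum(area[q > 0], na.rm = TRUE) - sum(area[q < 0], na.rm = TRUE)
}
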
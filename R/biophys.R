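# Coarse structural properties: SASA, burial fraction, coil fraction.

#' SASA numerical parameters
#'
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param n_sphere_points Test points per atom on the golden-spiral lattice
#'   (default 960; at least 60).
#' @return An object of class `fc_sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L) {
  stopifnot(probe_radius >= 0)
  n_sphere_points <- as.integer(n_sphere_points)
  if (is.na(n_sphere_points) || n_sphere_points < 60L) {
    stop("n_sphere_points must be at least 60")
  }
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "fc_sasa_params")
}

#' Van der Waals radius by element
#'
#' Bondi-set radii for the elements common in protein heavy atoms; unknown
#' elements fall back to carbon's 1.70 Angstrom.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(element) {
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
             P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)
  r <- radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Reference maximally-exposed per-residue surface areas
#'
#' Theoretical maximum accessible surface areas of the 20 standard amino
#' acids in an isolated, fully exposed state (Angstrom squared; Tien et al.
#' 2013 theoretical values). The denominator of the burial fraction; the
#' table is substitutable via the `ref_table` argument of
#' [burial_fraction()].
#'
#' @return Named numeric vector of 20 areas with a `provenance` attribute.
#' @export
reference_areas <- function() {
  x <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
         Q = 225, E = 223, G = 104, H = 224, I = 197,
         L = 201, K = 236, M = 224, F = 240, P = 159,
         S = 155, T = 172, W = 285, Y = 263, V = 174)
  x <- x[AA_ALPHABET]
  attr(x, "provenance") <- "Tien et al. 2013 theoretical maximum ASA"
  x
}

# Deterministic golden-spiral lattice of n near-uniform points on the unit
# sphere.
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# Molecule-intrinsic orthonormal frame (principal axes of the coordinate
# cloud with deterministic sign conventions). Orienting the test-point
# lattice in this frame makes the discretized SASA exactly invariant under
# rigid motions of the molecule, instead of invariant only up to lattice
# discretization error. Degenerate principal axes (perfectly symmetric
# clouds) fall back to the identity frame.
principal_frame <- function(xyz) {
  if (nrow(xyz) < 2L) return(diag(3))
  X <- sweep(xyz, 2L, colMeans(xyz))
  C <- crossprod(X)
  if (max(abs(C)) < 1e-12) return(diag(3))
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:2) {
    y <- X %*% V[, j]
    s <- sum(y^3)
    if (abs(s) > 1e-9) {
      if (s < 0) V[, j] <- -V[, j]
    } else {
      k <- which.max(abs(y))
      if (y[k] < 0) V[, j] <- -V[, j]
    }
  }
  # right-handed completion fixes the third axis
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic test-point SASA: each atom's sphere of radius `vdw + probe` is
#' covered by a deterministic golden-spiral lattice; a test point is
#' accessible when it lies outside every neighbouring atom's expanded
#' sphere. The per-atom area is `4 * pi * (r + probe)^2` times the
#' accessible fraction. The lattice is oriented in the molecule's principal
#' axis frame, so the computed area is exactly invariant under rigid
#' motions of the structure (up to floating-point error), not merely up to
#' lattice discretization.
#'
#' @param atoms `data.frame` with columns `x`, `y`, `z` (Angstrom) and
#'   `radius` (van der Waals, Angstrom), e.g. from [read_pdb_atoms()].
#' @param params A [sasa_params()] object.
#' @return Numeric vector of per-atom areas (Angstrom squared); sum for the
#'   total SASA.
#' @export
shrake_rupley_sasa <- function(atoms, params = sasa_params()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L,
            all(c("x", "y", "z", "radius") %in% names(atoms)))
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("atom coordinates must be finite")
  probe <- params$probe_radius
  n <- nrow(xyz)
  pts <- golden_spiral(params$n_sphere_points) %*% t(principal_frame(xyz))
  R <- atoms$radius + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can reach atom i's test sphere
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * R[i]^2
      next
    }
    P <- pts * R[i]
    px <- P[, 1] + xyz[i, 1]; py <- P[, 2] + xyz[i, 2]; pz <- P[, 3] + xyz[i, 3]
    acc <- rep(TRUE, nrow(P))
    for (j in nb) {
      dj2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
      acc <- acc & (dj2 > R[j]^2)
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  areas
}

#' Burial fraction of amino-acid surface area
#'
#' Compactness measure: one minus the ratio of a structure's SASA to the
#' summed reference areas of its residues in the maximally exposed
#' (isolated-residue) state. Typically in `[0, 1)`; slightly negative values
#' (structure more exposed than the reference) are reported with a warning,
#' never clamped.
#'
#' @param atoms Atom `data.frame` (columns `residue_index`, `x`, `y`, `z`,
#'   `radius`).
#' @param sequence One-letter residue string matching the structure's
#'   residue count.
#' @param ref_table Named per-residue reference areas (default
#'   [reference_areas()]).
#' @param params A [sasa_params()] object.
#' @return List with `burial_fraction`, `sasa_total` and `ref_total`.
#' @export
burial_fraction <- function(atoms, sequence, ref_table = reference_areas(),
                            params = sasa_params()) {
  aa <- strsplit(sequence, "")[[1L]]
  n_res <- length(unique(atoms$residue_index))
  if (length(aa) != n_res) {
    stop("sequence length (", length(aa), ") != residue count (", n_res, ")")
  }
  missing <- setdiff(aa, names(ref_table))
  if (length(missing)) {
    stop("residues absent from reference table: ",
         paste(unique(missing), collapse = ", "))
  }
  sasa_total <- sum(shrake_rupley_sasa(atoms, params))
  ref_total <- sum(ref_table[aa])
  bf <- 1 - sasa_total / ref_total
  if (bf < 0) {
    warning("negative burial fraction (", format(bf, digits = 3),
            "): structure more exposed than the reference state")
  }
  list(burial_fraction = bf, sasa_total = sasa_total, ref_total = ref_total)
}

# DSSP per-residue code alphabet (including the modern P code, the
# unassigned '-' and blank).
DSSP_CODES <- c("H", "G", "I", "E", "B", "T", "S", "P", "C", "-", " ")

#' Coil fraction from a secondary-structure string
#'
#' Fraction of residues whose DSSP code is not a helix (`H`, `G`, `I`) or
#' strand/bridge (`E`, `B`) code, i.e. turns, bends, poly-proline and
#' unassigned residues all count as coil. The structured code set is
#' configurable because DSSP dialects differ on what "coil" means.
#'
#' @param ss_string Per-residue DSSP-style code string.
#' @param structured_codes Codes counted as non-coil (default
#'   `c("H","G","I","E","B")`).
#' @return Fraction in `[0, 1]`.
#' @export
coil_fraction <- function(ss_string,
                          structured_codes = c("H", "G", "I", "E", "B")) {
  stopifnot(is.character(ss_string), length(ss_string) == 1L)
  if (!nzchar(ss_string)) stop("empty secondary-structure string")
  codes <- strsplit(ss_string, "")[[1L]]
  unknown <- which(!codes %in% DSSP_CODES)
  if (length(unknown)) {
    stop("unknown secondary-structure code '", codes[unknown[1L]],
         "' at position ", unknown[1L])
  }
  mean(!codes %in% structured_codes)
}
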
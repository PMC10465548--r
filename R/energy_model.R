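#' Interaction energy parameters
#'
#' Parameters of the pairwise rigid-molecule energy: hard core plus a
#' scaled Lennard-Jones nonpolar attraction and a scaled Debye-Hueckel
#' electrostatic term,
#' `u_ij = u_st + s1 * u_np + s2 * u_elec`, truncated sharply at `cutoff`.
#' The energy function is evaluated once at the reference temperature; only
#' the Boltzmann beta changes with temperature downstream, so the Debye
#' screening parameter kappa is frozen at `temperature_ref`.
#'
#' @param s1 nonpolar scaling factor (default 0.16).
#' @param s2 electrostatic scaling factor (default 1.6).
#' @param dielectric relative dielectric constant (default 78.5).
#' @param ionic_strength ionic strength, mol/l (default 0.24).
#' @param temperature_ref reference temperature, K (default 298).
#' @param cutoff pair cutoff, Angstrom (default 12).
#' @return list of class `energy_params`; includes the derived `kappa`
#'   (1/Angstrom), the Coulomb constant 332 kcal A/(mol e^2) and
#'   kB = 0.0019872 kcal/(mol K).
#' @export
energy_params <- function(s1 = 0.16, s2 = 1.6, dielectric = 78.5,
                          ionic_strength = 0.24, temperature_ref = 298,
                          cutoff = 12) {
  stopifnot(s1 > 0, s2 > 0, dielectric > 0, cutoff > 0)
  p <- list(s1 = s1, s2 = s2, dielectric = dielectric,
            ionic_strength = ionic_strength,
            temperature_ref = temperature_ref, cutoff = cutoff,
            coulomb_const = 332, kB = 0.0019872)
  p$kappa <- debye_kappa(ionic_strength, temperature_ref, dielectric)
  class(p) <- "energy_params"
  p
}

#' Inverse thermal energy
#' @param temperature K.
#' @param params an [energy_params()] (for kB).
#' @return beta in (kcal/mol)^-1.
#' @export
beta_at <- function(temperature, params = energy_params()) {
  1 / (params$kB * temperature)
}

#' Debye screening parameter
#'
#' Standard aqueous Debye length: at 298 K and dielectric 78.5,
#' 1/kappa = 3.047/sqrt(I) Angstrom; other conditions scale as
#' sqrt(dielectric * T).
#'
#' @param ionic_strength mol/l (>= 0).
#' @param temperature K.
#' @param dielectric relative dielectric constant.
#' @return kappa in 1/Angstrom; 0 at zero ionic strength.
#' @export
debye_kappa <- function(ionic_strength, temperature = 298, dielectric = 78.5) {
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  if (ionic_strength == 0) return(0)
  sqrt(ionic_strength) / (3.047 * sqrt(dielectric * temperature / (78.5 * 298)))
}

# Raw (unscaled) kernels, sharply truncated at the cutoff. Vectorised in r.
kernel_np_raw <- function(r, eps_ij, sigma_ij, cutoff) {
  sr6 <- (sigma_ij / r)^6
  ifelse(r <= cutoff, 4 * eps_ij * (sr6^2 - sr6), 0)
}

kernel_elec_raw <- function(r, qq, params) {
  ifelse(r <= params$cutoff,
         params$coulomb_const * qq * exp(-params$kappa * r) /
           (params$dielectric * r),
         0)
}

#' Pair energy of two atoms
#'
#' Hard-core clash when `r < (sigma_ii + sigma_jj)/2`; otherwise the scaled
#' sum of a Lennard-Jones term (geometric-mean combining rules for both
#' epsilon and sigma) and a Debye-Hueckel term, both zero beyond the
#' cutoff.
#'
#' @param i,j single-row atom records (with `charge`, `lj_epsilon`,
#'   `lj_sigma`).
#' @param r interatomic distance, Angstrom (> 0).
#' @param params an [energy_params()].
#' @return list of class `pair_energy`: `total` (Inf on clash),
#'   `steric_clash`, `nonpolar`, `electrostatic` (both already scaled by
#'   s1/s2; NA on clash).
#' @export
atom_pair_energy <- function(i, j, r, params = energy_params()) {
  stopifnot(r > 0)
  if (r < (i$lj_sigma + j$lj_sigma) / 2) {
    return(structure(list(total = Inf, steric_clash = TRUE,
                          nonpolar = NA_real_, electrostatic = NA_real_),
                     class = "pair_energy"))
  }
  eps_ij <- sqrt(i$lj_epsilon * j$lj_epsilon)
  sigma_ij <- sqrt(i$lj_sigma * j$lj_sigma)
  np <- params$s1 * kernel_np_raw(r, eps_ij, sigma_ij, params$cutoff)
  el <- params$s2 * kernel_elec_raw(r, i$charge * j$charge, params)
  structure(list(total = np + el, steric_clash = FALSE,
                 nonpolar = np, electrostatic = el),
            class = "pair_energy")
}

# Transform a molecule's centred coordinates by a pose.
pose_coords <- function(mol, position = c(0, 0, 0), quat = identity_quat()) {
  xyz <- molecule_coords(mol) %*% t(quat_to_matrix(quat))
  sweep(xyz, 2, position, "+")
}

min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

# All cross-pair distances between two coordinate sets (minimum image if
# box given). Returns matrix nA x nB.
cross_distances <- function(xa, xb, box = NULL) {
  dx <- outer(xa[, 1], xb[, 1], "-")
  dy <- outer(xa[, 2], xb[, 2], "-")
  dz <- outer(xa[, 3], xb[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box); dy <- min_image(dy, box); dz <- min_image(dz, box)
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

# Vectorised cross-pair energy components between two atom tables at given
# coordinates. Returns list(clash, np_raw_mat, el_raw_mat) with raw
# (unscaled) per-pair matrices, zero beyond cutoff.
pair_energy_matrices <- function(atomsA, xa, atomsB, xb, params, box = NULL) {
  r <- cross_distances(xa, xb, box)
  core <- outer(atomsA$lj_sigma, atomsB$lj_sigma, "+") / 2
  clash <- any(r < core)
  w12a <- sqrt(atomsA$lj_epsilon) * atomsA$lj_sigma^6
  w12b <- sqrt(atomsB$lj_epsilon) * atomsB$lj_sigma^6
  w6a <- sqrt(atomsA$lj_epsilon) * atomsA$lj_sigma^3
  w6b <- sqrt(atomsB$lj_epsilon) * atomsB$lj_sigma^3
  inside <- r <= params$cutoff
  np <- 4 * (outer(w12a, w12b) / r^12 - outer(w6a, w6b) / r^6) * inside
  el <- params$coulomb_const * outer(atomsA$charge, atomsB$charge) *
    exp(-params$kappa * r) / (params$dielectric * r) * inside
  list(clash = clash, np_raw = np, el_raw = el)
}

#' Pair interaction energy of two rigid molecules
#'
#' Sum of [atom_pair_energy()] over all cross pairs of atoms within the
#' cutoff; any clashing atom pair makes the whole molecule pair a clash.
#' This direct double loop is the ground-truth oracle for the FFT engine.
#'
#' @param A,B `rigid_molecule` objects.
#' @param poseA,poseB lists with `position` (3-vector, Angstrom) and `quat`
#'   (unit quaternion).
#' @param params an [energy_params()].
#' @param box periodic cubic box side (Angstrom) for minimum-image
#'   distances, or NULL for open boundaries.
#' @return a `pair_energy` (see [atom_pair_energy()]).
#' @export
molecule_pair_energy <- function(A, poseA, B, poseB,
                                 params = energy_params(), box = NULL) {
  xa <- pose_coords(A, poseA$position, poseA$quat)
  xb <- pose_coords(B, poseB$position, poseB$quat)
  m <- pair_energy_matrices(A$atoms, xa, B$atoms, xb, params, box)
  if (m$clash) {
    return(structure(list(total = Inf, steric_clash = TRUE,
                          nonpolar = NA_real_, electrostatic = NA_real_),
                     class = "pair_energy"))
  }
  np <- params$s1 * sum(m$np_raw)
  el <- params$s2 * sum(m$el_raw)
  structure(list(total = np + el, steric_clash = FALSE,
                 nonpolar = np, electrostatic = el),
            class = "pair_energy")
}

#' Per-residue decomposition of a molecule pair energy
#'
#' Decomposes the pair interaction energy into contributions of the
#' individual residues of one molecule interacting with the whole of the
#' other; entries sum to the pair total.
#'
#' @param A,B `rigid_molecule` objects.
#' @param poseA,poseB poses as in [molecule_pair_energy()].
#' @param params an [energy_params()].
#' @param decompose which molecule to split by residue, `"A"` or `"B"`.
#' @param box optional periodic box side.
#' @return named numeric vector over the residues of the decomposed
#'   molecule (kcal/mol).
#' @export
residue_decompose <- function(A, poseA, B, poseB, params = energy_params(),
                              decompose = c("A", "B"), box = NULL) {
  decompose <- match.arg(decompose)
  xa <- pose_coords(A, poseA$position, poseA$quat)
  xb <- pose_coords(B, poseB$position, poseB$quat)
  m <- pair_energy_matrices(A$atoms, xa, B$atoms, xb, params, box)
  if (m$clash) stop("residue decomposition undefined for a clashing pose")
  per_pair <- params$s1 * m$np_raw + params$s2 * m$el_raw
  if (decompose == "A") {
    mol <- A; per_atom <- rowSums(per_pair)
  } else {
    mol <- B; per_atom <- colSums(per_pair)
  }
  out <- vapply(mol$residues$residue_index, function(ri) {
    sum(per_atom[mol$atoms$residue_index == ri])
  }, numeric(1))
  names(out) <- paste0(mol$residues$residue_name, mol$residues$residue_index)
  out
}
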
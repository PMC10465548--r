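#' Deterministic uniform covering of SO(3)
#'
#' Hopf-style grid: rotated-z-axis directions on a spherical Fibonacci
#' lattice (pole included, so the identity is in the set) combined with
#' uniformly spaced twist angles about the new axis. Counts scale as
#' resolution^-3; at 6 degrees the set has 60 x 1146 = 68760 rotations.
#'
#' @param angular_resolution target nearest-neighbour spacing, degrees
#'   (in \[2, 30\]).
#' @return n x 4 matrix of unit quaternions (first row the identity).
#' @export
deterministic_orientations <- function(angular_resolution = 6) {
  if (angular_resolution < 2 || angular_resolution > 30) {
    stop("angular_resolution must be in [2, 30] degrees")
  }
  theta <- angular_resolution * pi / 180
  n_twist <- max(1L, as.integer(round(2 * pi / theta)))
  n_axis <- max(1L, as.integer(round(4 * pi / theta^2)))
  golden <- pi * (3 - sqrt(5))
  i <- 0:(n_axis - 1)
  z <- if (n_axis == 1) 1 else 1 - 2 * i / (n_axis - 1)
  rxy <- sqrt(pmax(0, 1 - z^2))
  phi <- i * golden
  # quaternion rotating +z onto the axis v (shortest arc)
  axis_quat <- function(vx, vy, vz) {
    if (vz >= 1 - 1e-15) return(c(1, 0, 0, 0))
    if (vz <= -1 + 1e-15) return(c(0, 1, 0, 0))
    ang <- acos(vz)
    ax <- c(-vy, vx, 0)
    axis_angle_quat(ax, ang)
  }
  psis <- 2 * pi * (0:(n_twist - 1)) / n_twist
  out <- matrix(0, nrow = n_axis * n_twist, ncol = 4)
  row <- 1L
  for (k in seq_len(n_axis)) {
    qa <- axis_quat(rxy[k] * cos(phi[k]), rxy[k] * sin(phi[k]), z[k])
    for (ps in psis) {
      qz <- c(cos(ps / 2), 0, 0, sin(ps / 2))
      out[row, ] <- quat_multiply(qa, qz)
      row <- row + 1L
    }
  }
  out
}

#' Second virial coefficient by FFT Mayer-function integration (FMAPB2)
#'
#' The periodic box holds a single central copy; the test molecule is
#' scanned over the full translational grid for each orientation of a
#' deterministic SO(3) covering. Clashed points contribute -1 to the Mayer
#' average, clash-free points `exp(-beta U) - 1`; one energy histogram
#' serves the whole temperature grid.
#'
#' @param central central `rigid_molecule`.
#' @param test test `rigid_molecule` (defaults to `central`).
#' @param box_side periodic box side, Angstrom; must be at least twice the
#'   molecular diameter plus cutoff so periodic images cannot interact.
#' @param spacing grid spacing, Angstrom.
#' @param orientations n x 4 quaternion matrix (default
#'   [deterministic_orientations()] at `angular_resolution`).
#' @param angular_resolution degrees, used when `orientations` is NULL.
#' @param params an [energy_params()].
#' @param temps_celsius temperature grid for B2(T).
#' @param bin_width energy-histogram bin width, kcal/mol.
#' @param save_threshold poses below this energy are archived (kcal/mol,
#'   default -6).
#' @param mass molar mass for per-mass units (defaults to
#'   [molecule_mass()] of the central copy).
#' @return list of class `b2_result`: `table` (data.frame with
#'   `temperature_celsius`, `B2_A3` in Angstrom^3, `B2` in mol ml/g^2,
#'   `B2_over_Vst`), `B2_st_A3`, `Vst_A3`, `Vst` (mol ml/g^2), `mass`,
#'   `clash_fraction`, `hist` (sparse energy histogram), `saved_poses`.
#' @export
fmapb2 <- function(central, test = central, box_side = 200, spacing = 0.6,
                   orientations = NULL, angular_resolution = 6,
                   params = energy_params(),
                   temps_celsius = seq(-10, 60, by = 5),
                   bin_width = 0.016, save_threshold = -6, mass = NULL) {
  diam <- 2 * max(molecule_radius(central), molecule_radius(test))
  if (box_side < 2 * (diam + params$cutoff)) {
    stop("box too small: need box_side >= 2 * (molecular diameter + cutoff) = ",
         signif(2 * (diam + params$cutoff), 4), " Angstrom")
  }
  if (is.null(orientations)) {
    orientations <- deterministic_orientations(angular_resolution)
  }
  if (is.null(mass)) {
    mass <- tryCatch(molecule_mass(central), error = function(e) NA_real_)
  }
  grid <- grid_spec(box_side, spacing)
  cfg <- solution_config(box_side, matrix(box_side / 2, 1, 3),
                         matrix(identity_quat(), 1, 4))
  fields <- build_solution_fields(cfg, central, grid, params,
                                  test_core_radii = unique(test$atoms$core_radius))
  counts <- numeric(0)
  n_clash <- 0; n_tot <- 0
  saved <- list()
  for (oi in seq_len(nrow(orientations))) {
    sc <- fmap_scan(test, orientations[oi, ], fields, components = FALSE)
    free <- !sc$clash
    u <- sc$energy[free]
    n_clash <- n_clash + sum(sc$clash)
    n_tot <- n_tot + length(sc$clash)
    if (length(u)) {
      idx <- floor(u / bin_width + 0.5)
      tb <- table(idx)
      counts <- merge_sparse_counts(counts, names(tb), as.numeric(tb))
      low <- which(free & sc$energy < save_threshold, arr.ind = TRUE)
      if (nrow(low)) {
        saved[[length(saved) + 1]] <- data.frame(
          x = (low[, 1] - 1) * grid$h, y = (low[, 2] - 1) * grid$h,
          z = (low[, 3] - 1) * grid$h,
          qw = orientations[oi, 1], qx = orientations[oi, 2],
          qy = orientations[oi, 3], qz = orientations[oi, 4],
          energy = sc$energy[low], orientation = oi
        )
      }
    }
  }
  ord <- order(as.numeric(names(counts)))
  counts <- counts[ord]
  u_centers <- as.numeric(names(counts)) * bin_width
  V <- box_side^3
  clash_fraction <- n_clash / n_tot
  b2_st_A3 <- V / 2 * clash_fraction
  n_avogadro <- 6.02214076e23
  to_molar <- function(b2_A3) b2_A3 * 1e-24 * n_avogadro / mass^2
  temps_K <- celsius_to_kelvin(temps_celsius)
  b2_A3 <- vapply(temps_K, function(tk) {
    beta <- 1 / (params$kB * tk)
    mayer_sum <- -n_clash + sum(counts * (exp(-beta * u_centers) - 1))
    -V / 2 * mayer_sum / n_tot
  }, numeric(1))
  vst_A3 <- b2_st_A3 / 4
  structure(list(
    table = data.frame(temperature_celsius = temps_celsius, B2_A3 = b2_A3,
                       B2 = to_molar(b2_A3), B2_over_Vst = b2_A3 / vst_A3),
    B2_st_A3 = b2_st_A3, Vst_A3 = vst_A3, Vst = to_molar(vst_A3),
    mass = mass, clash_fraction = clash_fraction,
    hist = list(u_centers = u_centers, counts = counts, bin_width = bin_width),
    saved_poses = if (length(saved)) do.call(rbind, saved) else NULL,
    n_orientations = nrow(orientations)
  ), class = "b2_result")
}

#' Steric volume
#'
#' `Vst = B2_st / 4`, with `B2_st` the steric-only (hard-core) second
#' virial coefficient; temperature independent.
#'
#' @param central,test `rigid_molecule`s.
#' @param ... passed to [fmapb2()].
#' @return list with `Vst_A3` (Angstrom^3), `Vst` (mol ml/g^2),
#'   `B2_st_A3`.
#' @export
steric_volume <- function(central, test = central, ...) {
  r <- fmapb2(central, test, ...)
  list(Vst_A3 = r$Vst_A3, Vst = r$Vst, B2_st_A3 = r$B2_st_A3)
}

#' Average B2 over a structure library (FMAPB23)
#'
#' Runs [fmapb2()] for every ordered (central, test) pair of library
#' structures and averages arithmetically.
#'
#' @param library list of `rigid_molecule`s with identical residue
#'   sequences.
#' @param ... passed to [fmapb2()].
#' @return list with `B2_A3_mean` (per temperature), `B2_mean`,
#'   `temperature_celsius`, `pairs` (n^2 per-pair tables).
#' @export
fmapb23_average <- function(library, ...) {
  if (!length(library)) stop("empty structure library")
  seqs <- vapply(library, function(m) {
    paste(m$residues$residue_name, collapse = "-")
  }, character(1))
  if (length(unique(seqs)) != 1L) {
    stop("library structures have mixed residue sequences")
  }
  pairs <- list()
  for (i in seq_along(library)) for (j in seq_along(library)) {
    r <- fmapb2(library[[i]], library[[j]], ...)
    pairs[[length(pairs) + 1]] <- r$table
  }
  b2a3 <- Reduce(`+`, lapply(pairs, function(t) t$B2_A3)) / length(pairs)
  b2 <- Reduce(`+`, lapply(pairs, function(t) t$B2)) / length(pairs)
  list(B2_A3_mean = b2a3, B2_mean = b2,
       temperature_celsius = pairs[[1]]$temperature_celsius, pairs = pairs)
}

#' Welch two-sample comparison of B2 groups
#'
#' Unequal-variance (Welch) t test between low- and high-Tc group values.
#'
#' @param values_low,values_high numeric vectors (n >= 2 each).
#' @return list with `t`, `p`, `df`, `mean_low`, `mean_high`.
#' @export
group_compare <- function(values_low, values_high) {
  stopifnot(length(values_low) >= 2, length(values_high) >= 2)
  if (stats::var(values_low) == 0 && stats::var(values_high) == 0) {
    d <- mean(values_low) - mean(values_high)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0, df = NA_real_,
                mean_low = mean(values_low), mean_high = mean(values_high)))
  }
  ht <- stats::t.test(values_low, values_high, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_low = mean(values_low), mean_high = mean(values_high))
}
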
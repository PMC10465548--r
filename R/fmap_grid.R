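#' Translational grid specification
#'
#' Cubic periodic grid over the simulation box. The number of points per
#' dimension is `round(box_side/spacing)`; the effective spacing
#' `box_side/n_per_dim` is stored as `h`.
#'
#' @param box_side box side length, Angstrom.
#' @param spacing requested grid resolution, Angstrom (default 0.6).
#' @return list of class `grid_spec` with `box_side`, `n_per_dim`, `h`.
#' @export
grid_spec <- function(box_side, spacing = 0.6) {
  stopifnot(box_side > 0, spacing > 0)
  n <- max(2L, as.integer(round(box_side / spacing)))
  structure(list(box_side = box_side, n_per_dim = n, h = box_side / n),
            class = "grid_spec")
}

# Minimum-image distance array over all voxel offsets (n^3).
grid_min_image_r <- function(grid) {
  n <- grid$n_per_dim; h <- grid$h
  ax <- (0:(n - 1))
  ax <- pmin(ax, n - ax) * h
  dx2 <- ax^2
  r2 <- outer(outer(dx2, dx2, "+"), dx2, "+")
  array(sqrt(r2), dim = c(n, n, n))
}

# Truncated, capped interaction kernels on the voxel-offset lattice.
# The r^-12 / r^-6 / Debye-Hueckel kernels are capped at their value at
# r = cap_radius (at least one voxel; callers pass the smallest possible
# clash-free atom-pair distance). The capped region lies strictly inside
# every hard core, so it never affects clash-free energies, while keeping
# kernel magnitudes small enough that FFT round-off stays negligible.
grid_kernels <- function(grid, params, cap_radius = grid$h) {
  r <- grid_min_image_r(grid)
  h <- grid$h
  rc <- pmax(r, max(h, cap_radius))
  inside <- r <= params$cutoff
  k12 <- rc^-12 * inside
  k6 <- rc^-6 * inside
  kq <- params$coulomb_const * exp(-params$kappa * rc) /
    (params$dielectric * rc) * inside
  list(k12 = k12, k6 = k6, kq = kq)
}

# Trilinear rasterization of point weights onto the periodic grid.
rasterize_trilinear <- function(positions, weights, grid) {
  n <- grid$n_per_dim; h <- grid$h
  g <- array(0, dim = c(n, n, n))
  if (!nrow(positions)) return(g)
  u <- positions / h
  i0 <- floor(u)
  f <- u - i0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - f[, 1] else f[, 1]
    wy <- if (cy == 0) 1 - f[, 2] else f[, 2]
    wz <- if (cz == 0) 1 - f[, 3] else f[, 3]
    ii <- ((i0[, 1] + cx) %% n) + 1
    jj <- ((i0[, 2] + cy) %% n) + 1
    kk <- ((i0[, 3] + cz) %% n) + 1
    idx <- ii + n * (jj - 1) + n * n * (kk - 1)
    contrib <- weights * wx * wy * wz
    for (m in seq_along(idx)) g[idx[m]] <- g[idx[m]] + contrib[m]
  }
  g
}

# Nearest-voxel rasterization of point counts/weights.
rasterize_nearest <- function(positions, weights, grid) {
  n <- grid$n_per_dim; h <- grid$h
  g <- array(0, dim = c(n, n, n))
  if (!nrow(positions)) return(g)
  ii <- (round(positions[, 1] / h) %% n) + 1
  jj <- (round(positions[, 2] / h) %% n) + 1
  kk <- (round(positions[, 3] / h) %% n) + 1
  idx <- ii + n * (jj - 1) + n * n * (kk - 1)
  for (m in seq_along(idx)) g[idx[m]] <- g[idx[m]] + weights[m]
  g
}

# Stamp a ball indicator (voxel centres strictly inside radius) around each
# position; radii may differ per position. Periodic wrap.
stamp_balls <- function(positions, radii, grid) {
  n <- grid$n_per_dim; h <- grid$h
  g <- array(0, dim = c(n, n, n))
  box <- n * h
  axis_range <- function(p1, rad) {
    lo <- ceiling((p1 - rad) / h); hi <- floor((p1 + rad) / h)
    if (hi - lo + 1 >= n) { lo <- 0; hi <- n - 1 }
    if (lo > hi) return(NULL)
    iv <- lo:hi
    d <- iv * h - p1
    d <- d - box * round(d / box)
    list(iv = iv, d2 = d^2)
  }
  for (m in seq_len(nrow(positions))) {
    p <- positions[m, ]; rad <- radii[m]
    rx <- axis_range(p[1], rad); ry <- axis_range(p[2], rad)
    rz <- axis_range(p[3], rad)
    if (is.null(rx) || is.null(ry) || is.null(rz)) next
    inside <- outer(outer(rx$d2, ry$d2, "+"), rz$d2, "+") < rad^2
    ii <- (rx$iv %% n) + 1; jj <- (ry$iv %% n) + 1; kk <- (rz$iv %% n) + 1
    g[ii, jj, kk] <- pmax(g[ii, jj, kk], inside + 0)
  }
  g
}

# All-atom coordinates of a solution configuration, wrapped into [0, box).
config_atom_coords <- function(config, mol) {
  xs <- lapply(seq_len(config$n_copies), function(i) {
    pose_coords(mol, config$positions[i, ], config$quats[i, ])
  })
  x <- do.call(rbind, xs)
  x %% config$box_side
}

#' Build the solution interaction fields for FFT scanning
#'
#' Rasterizes one configuration of the solution onto the grid and returns
#' Fourier-space fields: the repulsive r^-12 and attractive r^-6 potential
#' fields (per-atom weights sqrt(eps)*sigma^6 and sqrt(eps)*sigma^3 under
#' the geometric combining rule), the Debye-Hueckel potential field from
#' the charge grid, and one steric indicator field per distinct test-atom
#' core radius (each solution atom stamped as a ball of radius
#' `core_radius + b`, making the clash criterion exact on the lattice).
#'
#' @param config a [solution_config()].
#' @param mol the `rigid_molecule` replicated in the solution.
#' @param grid a [grid_spec()] with `box_side` equal to the config's box.
#' @param params an [energy_params()].
#' @param test_core_radii distinct core radii of the test molecule that
#'   will be scanned (defaults to those of `mol`).
#' @return list of class `solution_fields` holding Fourier-transformed
#'   fields, ready for [fmap_scan()].
#' @export
build_solution_fields <- function(config, mol, grid, params = energy_params(),
                                  test_core_radii =
                                    sort(unique(mol$atoms$core_radius))) {
  if (abs(config$box_side - grid$box_side) > 1e-9) {
    stop("grid box_side does not match configuration box_side")
  }
  if (config$n_copies > 0 &&
      (any(config$positions < 0) || any(config$positions >= config$box_side))) {
    stop("molecule copy outside the periodic box; wrap positions first")
  }
  test_core_radii <- sort(unique(round(test_core_radii, 9)))
  cap_radius <- min(mol$atoms$core_radius) + min(test_core_radii)
  kern <- grid_kernels(grid, params, cap_radius)
  if (config$n_copies == 0) {
    x <- matrix(numeric(0), ncol = 3)
    w12 <- w6 <- q <- radii <- numeric(0)
  } else {
    x <- config_atom_coords(config, mol)
    a <- mol$atoms[rep(seq_len(nrow(mol$atoms)), config$n_copies), ]
    w12 <- sqrt(a$lj_epsilon) * a$lj_sigma^6
    w6 <- sqrt(a$lj_epsilon) * a$lj_sigma^3
    q <- a$charge
    radii <- a$core_radius
  }
  phi_hat <- function(w, k) stats::fft(rasterize_trilinear(x, w, grid)) * stats::fft(k)
  occ_hat <- lapply(test_core_radii, function(b) {
    if (!nrow(x)) return(stats::fft(array(0, dim = rep(grid$n_per_dim, 3))))
    stats::fft(stamp_balls(x, radii + b, grid))
  })
  structure(list(
    grid = grid, params = params,
    phi12_hat = phi_hat(w12, kern$k12),
    phi6_hat = phi_hat(w6, kern$k6),
    phiq_hat = phi_hat(q, kern$kq),
    occ_hat = occ_hat, occ_radii = test_core_radii,
    n_copies = config$n_copies
  ), class = "solution_fields")
}

cross_correlate_hat <- function(test_grid, field_hat) {
  n3 <- length(field_hat)
  Re(stats::fft(Conj(stats::fft(test_grid)) * field_hat, inverse = TRUE)) / n3
}

#' FFT scan of a test molecule over the translational grid
#'
#' Places the test molecule, in a fixed orientation, at every grid point
#' (its centre of geometry on the lattice) and returns the interaction
#' energy with the whole solution at each clash-free point. Energies come
#' from cross-correlating the test molecule's weight/charge grids with the
#' solution potential fields; clashes from correlating per-radius-class
#' point stamps with the steric indicator fields.
#'
#' @param test test `rigid_molecule`.
#' @param quat orientation (unit quaternion).
#' @param fields a [build_solution_fields()] result.
#' @param components keep the separate raw nonpolar/electrostatic arrays
#'   (needed for s1/s2 rescans), default TRUE.
#' @return list of class `energy_landscape`: `energy` (n^3 array, kcal/mol,
#'   NA at clashed points), `clash` (logical array), `n_clash_free`,
#'   optionally `np_raw`, `el_raw`, and the `grid`.
#' @export
fmap_scan <- function(test, quat, fields, components = TRUE) {
  grid <- fields$grid
  params <- fields$params
  xyz <- molecule_coords(test) %*% t(quat_to_matrix(quat))
  a <- test$atoms
  w12 <- sqrt(a$lj_epsilon) * a$lj_sigma^6
  w6 <- sqrt(a$lj_epsilon) * a$lj_sigma^3
  t12 <- rasterize_trilinear(xyz, w12, grid)
  t6 <- rasterize_trilinear(xyz, w6, grid)
  tq <- rasterize_trilinear(xyz, a$charge, grid)
  np_raw <- 4 * (cross_correlate_hat(t12, fields$phi12_hat) -
                   cross_correlate_hat(t6, fields$phi6_hat))
  el_raw <- cross_correlate_hat(tq, fields$phiq_hat)
  clash_count <- array(0, dim = dim(np_raw))
  rr <- round(a$core_radius, 9)
  for (bi in seq_along(fields$occ_radii)) {
    sel <- rr == fields$occ_radii[bi]
    if (!any(sel)) next
    tb <- rasterize_nearest(xyz[sel, , drop = FALSE],
                            rep(1, sum(sel)), grid)
    clash_count <- clash_count + cross_correlate_hat(tb, fields$occ_hat[[bi]])
  }
  clash <- clash_count > 0.5
  energy <- params$s1 * np_raw + params$s2 * el_raw
  energy[clash] <- NA_real_
  out <- list(energy = energy, clash = clash,
              n_clash_free = sum(!clash), grid = grid)
  if (components) {
    out$np_raw <- np_raw
    out$el_raw <- el_raw
  }
  structure(out, class = "energy_landscape")
}

#' Pooled clash-free fraction over scans
#'
#' The fraction of test-molecule placements free of steric clashes, pooled
#' over configurations and orientations and treated as a constant.
#'
#' @param landscapes list of `energy_landscape` objects (or a single one).
#' @return f_CF in \[0, 1\].
#' @export
clash_free_fraction <- function(landscapes) {
  if (inherits(landscapes, "energy_landscape")) landscapes <- list(landscapes)
  if (!length(landscapes)) stop("need at least one landscape")
  cf <- sum(vapply(landscapes, function(l) l$n_clash_free, numeric(1)))
  tot <- sum(vapply(landscapes, function(l) length(l$clash), numeric(1)))
  cf / tot
}
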
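#' Temperature helpers
#' @param celsius temperature in degrees Celsius.
#' @return Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

logsumexp <- function(x, w = NULL) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  if (is.null(w)) m + log(sum(exp(x - m))) else m + log(sum(w * exp(x - m)))
}

merge_sparse_counts <- function(counts, idx, add) {
  key <- as.character(idx)
  hit <- key %in% names(counts)
  if (any(hit)) counts[key[hit]] <- counts[key[hit]] + add[hit]
  if (any(!hit)) counts <- c(counts, stats::setNames(add[!hit], key[!hit]))
  counts
}

#' Accumulate insertion-energy histograms over a trajectory
#'
#' For every snapshot and every test orientation, runs the FFT scan and
#' pools the clash-free insertion energies into a fine histogram (the
#' sufficient statistic for the excess chemical potential at any
#' temperature). Raw nonpolar/electrostatic components are kept in a
#' coarser two-dimensional sub-histogram so the s1/s2 scaling factors can
#' be rescanned without re-running FFTs. Per-orientation Boltzmann sums
#' (for blocking errors) and per-orientation lowest energies (for the
#' block-minimum bound fit) are retained, and poses below `save_threshold`
#' are saved.
#'
#' @param traj a [run_sampler()] trajectory (or a list with `snapshots`).
#' @param test test `rigid_molecule`.
#' @param n_orientations number of random test orientations
#'   (production-scale default 500; tests use far fewer).
#' @param grid a [grid_spec()] matching the trajectory box.
#' @param params an [energy_params()].
#' @param seed RNG seed for the orientation draw.
#' @param bin_width histogram bin width, kcal/mol (default 0.016).
#' @param sub_bin_width bin width of the raw-component 2D sub-histogram.
#' @param save_threshold energy below which poses are archived (kcal/mol).
#' @param temps_celsius temperature grid for per-orientation Boltzmann sums.
#' @param mol solution molecule (defaults to `test`).
#' @return list of class `energy_histogram`.
#' @export
accumulate_insertions <- function(traj, test, n_orientations = 500,
                                  grid, params = energy_params(), seed = 1,
                                  bin_width = 0.016, sub_bin_width = 0.05,
                                  save_threshold = -8,
                                  temps_celsius = seq(-2, 50, by = 2),
                                  mol = test) {
  snapshots <- traj$snapshots
  if (!length(snapshots)) stop("trajectory has no snapshots")
  if (abs(snapshots[[1]]$box_side - grid$box_side) > 1e-9) {
    stop("grid box does not match trajectory box")
  }
  set.seed(seed)
  quats <- random_quaternions(n_orientations)
  temps_K <- celsius_to_kelvin(temps_celsius)
  betas <- 1 / (params$kB * temps_K)

  counts <- numeric(0)
  sub_counts <- numeric(0)
  m_cf <- 0; m_tot <- 0
  ori_boltz <- matrix(0, nrow = n_orientations, ncol = length(betas))
  ori_mcf <- numeric(n_orientations)
  ori_mtot <- numeric(n_orientations)
  ori_min <- rep(Inf, n_orientations)
  saved <- list()
  u_min_obs <- Inf; u_max_obs <- -Inf

  for (ci in seq_along(snapshots)) {
    fields <- build_solution_fields(snapshots[[ci]], mol, grid, params,
                                    test_core_radii = unique(test$atoms$core_radius))
    for (oi in seq_len(n_orientations)) {
      sc <- fmap_scan(test, quats[oi, ], fields, components = TRUE)
      free <- !sc$clash
      u <- sc$energy[free]
      m_cf <- m_cf + length(u)
      m_tot <- m_tot + length(sc$clash)
      ori_mcf[oi] <- ori_mcf[oi] + length(u)
      ori_mtot[oi] <- ori_mtot[oi] + length(sc$clash)
      if (length(u)) {
        u_min_obs <- min(u_min_obs, min(u)); u_max_obs <- max(u_max_obs, max(u))
        ori_min[oi] <- min(ori_min[oi], min(u))
        idx <- floor(u / bin_width + 0.5)
        tb <- table(idx)
        counts <- merge_sparse_counts(counts, names(tb), as.numeric(tb))
        np_i <- floor(sc$np_raw[free] / sub_bin_width + 0.5)
        el_i <- floor(sc$el_raw[free] / sub_bin_width + 0.5)
        tb2 <- table(paste(np_i, el_i))
        sub_counts <- merge_sparse_counts(sub_counts, names(tb2), as.numeric(tb2))
        for (ti in seq_along(betas)) {
          ori_boltz[oi, ti] <- ori_boltz[oi, ti] + sum(exp(-betas[ti] * u))
        }
        low <- which(free & sc$energy < save_threshold, arr.ind = TRUE)
        if (nrow(low)) {
          saved[[length(saved) + 1]] <- data.frame(
            x = (low[, 1] - 1) * grid$h, y = (low[, 2] - 1) * grid$h,
            z = (low[, 3] - 1) * grid$h,
            qw = quats[oi, 1], qx = quats[oi, 2], qy = quats[oi, 3],
            qz = quats[oi, 4],
            energy = sc$energy[low], config = ci, orientation = oi
          )
        }
      }
    }
  }
  ord <- order(as.numeric(names(counts)))
  counts <- counts[ord]
  structure(list(
    bin_width = bin_width, counts = counts,
    u_centers = as.numeric(names(counts)) * bin_width,
    U_range = c(u_min_obs, u_max_obs),
    f_CF = m_cf / m_tot, M_CF = m_cf, M_total = m_tot,
    n_configs = length(snapshots), n_orientations = n_orientations,
    per_orientation = data.frame(
      orientation = seq_len(n_orientations), m_cf = ori_mcf,
      m_total = ori_mtot, min_energy = ori_min
    ),
    ori_boltz = ori_boltz, temps_celsius = temps_celsius,
    sub_bin_width = sub_bin_width, sub_counts = sub_counts,
    saved_poses = if (length(saved)) do.call(rbind, saved) else NULL,
    kB = params$kB
  ), class = "energy_histogram")
}

#' @export
print.energy_histogram <- function(x, ...) {
  cat("<energy_histogram>", x$M_CF, "clash-free energies, f_CF =",
      signif(x$f_CF, 4), ", U in [", signif(x$U_range[1], 4), ",",
      signif(x$U_range[2], 4), "] kcal/mol\n")
  invisible(x)
}

#' Raw excess chemical potential from an energy histogram
#'
#' `beta*mu_ex = -ln[(f_CF/M_CF) * sum H(U) exp(-beta U)]`, evaluated by
#' log-sum-exp. The histogram energies were computed once at the reference
#' temperature; only beta varies here.
#'
#' @param hist an [accumulate_insertions()] histogram.
#' @param temperature temperature, K.
#' @return list of class `mu_point` with `beta_mu_ex`, `temperature_K`,
#'   `temperature_C`, `corrected = FALSE`.
#' @export
mu_ex_raw <- function(hist, temperature) {
  if (!hist$M_CF) stop("histogram has no clash-free energies")
  beta <- 1 / (hist$kB * temperature)
  ls <- logsumexp(-beta * hist$u_centers, w = hist$counts)
  bmu <- -(log(hist$f_CF) + ls - log(hist$M_CF))
  if (is.nan(bmu)) stop("beta*mu_ex is NaN")
  structure(list(beta_mu_ex = bmu, temperature_K = temperature,
                 temperature_C = temperature - 273.15, corrected = FALSE),
            class = "mu_point")
}

#' Excess chemical potential with rescanned scaling factors
#'
#' Re-evaluates beta*mu_ex from the stored raw-component 2D sub-histogram
#' under new s1/s2 values, without re-running any FFT.
#'
#' @param hist an [accumulate_insertions()] histogram.
#' @param temperature K.
#' @param s1,s2 new scaling factors.
#' @return beta*mu_ex (dimensionless).
#' @export
mu_ex_rescaled <- function(hist, temperature, s1, s2) {
  if (!length(hist$sub_counts)) stop("no component sub-histogram stored")
  beta <- 1 / (hist$kB * temperature)
  ij <- do.call(rbind, strsplit(names(hist$sub_counts), " "))
  u <- (as.numeric(ij[, 1]) * s1 + as.numeric(ij[, 2]) * s2) *
    hist$sub_bin_width
  ls <- logsumexp(-beta * u, w = hist$sub_counts)
  -(log(hist$f_CF) + ls - log(hist$M_CF))
}

#' Ideal chemical potential
#'
#' `beta*mu_id = ln(rho/rho0)`; the reference concentration cancels in the
#' equal-area construction.
#'
#' @param rho concentration, mg/ml (> 0).
#' @param rho0 reference concentration, mg/ml (default 1).
#' @return dimensionless beta*mu_id.
#' @export
mu_ideal <- function(rho, rho0 = 1) {
  if (any(rho <= 0) || rho0 <= 0) stop("concentrations must be positive")
  log(rho / rho0)
}

#' Flyvbjerg-Petersen blocking standard error
#'
#' Repeatedly pair-averages a series of (possibly correlated) sample means
#' and estimates the standard error at each blocking level; the plateau is
#' detected as the first level whose increase over the previous level is
#' within one standard deviation of the SE estimate itself (falling back to
#' the maximum over levels).
#'
#' @param x numeric vector of per-block averages (>= 16 values).
#' @return list with `se`, `level`, `se_by_level`, `n_by_level`.
#' @export
blocking_error <- function(x) {
  if (length(x) < 16) stop("blocking needs at least 16 base-level samples")
  if (stats::var(x) == 0) {
    return(list(se = 0, level = 0L, se_by_level = 0,
                n_by_level = length(x)))
  }
  se <- numeric(0); nn <- integer(0); dse <- numeric(0)
  while (length(x) >= 16) {
    n <- length(x)
    s <- sqrt(stats::var(x) / (n - 1))
    se <- c(se, s); nn <- c(nn, n)
    dse <- c(dse, s / sqrt(2 * (n - 1)))
    if (n %% 2 == 1) x <- x[-n]
    x <- (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / 2
  }
  lev <- length(se)
  for (k in seq_len(length(se) - 1)) {
    if (se[k + 1] - se[k] <= dse[k]) { lev <- k; break }
  }
  list(se = se[lev], level = lev, se_by_level = se, n_by_level = nn)
}

#' Blocking error of beta*mu_ex at a stored temperature
#'
#' Applies [blocking_error()] to the per-orientation average Boltzmann
#' factors and propagates through the logarithm, giving asymmetric bounds.
#'
#' @param hist an [accumulate_insertions()] histogram.
#' @param temperature_celsius one of the temperatures stored at
#'   accumulation time.
#' @return list with `beta_mu_ex`, `se_plus`, `se_minus`, `se`.
#' @export
mu_blocking_error <- function(hist, temperature_celsius) {
  ti <- match(temperature_celsius, hist$temps_celsius)
  if (is.na(ti)) stop("temperature not in the stored grid")
  ok <- hist$per_orientation$m_cf > 0
  xbar <- hist$ori_boltz[ok, ti] / hist$per_orientation$m_cf[ok]
  b <- blocking_error(xbar)
  m <- sum(hist$ori_boltz[ok, ti]) / sum(hist$per_orientation$m_cf[ok])
  bmu <- -log(hist$f_CF * m)
  up <- if (m - b$se > 0) -log(hist$f_CF * (m - b$se)) else Inf
  dn <- -log(hist$f_CF * (m + b$se))
  list(beta_mu_ex = bmu, se_plus = up - bmu, se_minus = bmu - dn,
       se = (up - dn) / 2)
}
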
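#' Solution configuration
#'
#' N rigid-body poses in a periodic cubic box.
#'
#' @param box_side box side, Angstrom.
#' @param positions n x 3 matrix of copy centres (wrapped into the box).
#' @param quats n x 4 matrix of unit quaternions.
#' @return list of class `solution_config` with `n_copies`.
#' @export
solution_config <- function(box_side, positions, quats) {
  stopifnot(box_side > 0)
  positions <- matrix(positions, ncol = 3)
  quats <- matrix(quats, ncol = 4)
  stopifnot(nrow(positions) == nrow(quats))
  positions <- positions %% box_side
  quats <- quats / sqrt(rowSums(quats^2))
  structure(list(box_side = box_side, positions = positions, quats = quats,
                 n_copies = nrow(positions)),
            class = "solution_config")
}

#' Concentration of n copies in a cubic box
#'
#' @param n copy number.
#' @param box_side box side, Angstrom.
#' @param mass molecular mass, Da.
#' @return concentration in mg/ml.
#' @export
concentration_mg_ml <- function(n, box_side, mass) {
  if (box_side <= 0) stop("box_side must be positive")
  stopifnot(n >= 0)
  n_avogadro <- 6.02214076e23
  # Da/A^3 -> g/cm^3 is 1e24/N_A; mg/ml = 1000 * g/cm^3
  n * mass / (box_side^3) * 1e24 / n_avogadro * 1000
}

#' Copy number achieving a target concentration
#' @param conc target concentration, mg/ml.
#' @param box_side box side, Angstrom.
#' @param mass molecular mass, Da.
#' @return nearest integer copy number.
#' @export
copies_for_concentration <- function(conc, box_side, mass) {
  round(conc / concentration_mg_ml(1, box_side, mass))
}

config_has_clash <- function(config, mol, pos_i, quat_i, i) {
  if (config$n_copies == 0) return(FALSE)
  others <- setdiff(seq_len(config$n_copies), i)
  for (j in others) {
    e <- molecule_pair_energy(
      mol, list(position = pos_i, quat = quat_i),
      mol, list(position = config$positions[j, ], quat = config$quats[j, ]),
      params = energy_params(), box = config$box_side
    )
    if (e$steric_clash) return(TRUE)
  }
  FALSE
}

# Interaction energy of copy i (at a candidate pose) with all other copies.
copy_energy <- function(config, mol, params, i, position, quat) {
  total <- 0
  for (j in seq_len(config$n_copies)) {
    if (j == i) next
    e <- molecule_pair_energy(
      mol, list(position = position, quat = quat),
      mol, list(position = config$positions[j, ], quat = config$quats[j, ]),
      params = params, box = config$box_side
    )
    if (e$steric_clash) return(Inf)
    total <- total + e$total
  }
  total
}

config_total_energy <- function(config, mol, params) {
  total <- 0
  n <- config$n_copies
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- molecule_pair_energy(
      mol, list(position = config$positions[i, ], quat = config$quats[i, ]),
      mol, list(position = config$positions[j, ], quat = config$quats[j, ]),
      params = params, box = config$box_side
    )
    if (e$steric_clash) return(Inf)
    total <- total + e$total
  }
  total
}

#' Random clash-free initial configuration
#'
#' Random sequential insertion: each copy gets a uniform random position
#' and orientation, retried until clash-free against all placed copies.
#'
#' @param n copy number.
#' @param box_side box side, Angstrom.
#' @param mol the `rigid_molecule`.
#' @param seed RNG seed (deterministic output).
#' @param max_attempts total insertion-attempt budget (default 1e6).
#' @return a [solution_config()].
#' @export
init_config <- function(n, box_side, mol, seed = 1, max_attempts = 1e6) {
  set.seed(seed)
  positions <- matrix(0, nrow = 0, ncol = 3)
  quats <- matrix(0, nrow = 0, ncol = 4)
  cfg <- solution_config(box_side, positions, quats)
  attempts <- 0
  while (cfg$n_copies < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("clash-free insertion failed after ", max_attempts,
           " attempts; lower the concentration")
    }
    pos <- stats::runif(3, 0, box_side)
    qt <- random_quaternions(1)[1, ]
    if (!config_has_clash(cfg, mol, pos, qt, i = 0)) {
      cfg$positions <- rbind(cfg$positions, pos)
      cfg$quats <- rbind(cfg$quats, qt)
      cfg$n_copies <- cfg$n_copies + 1
    }
  }
  rownames(cfg$positions) <- NULL
  rownames(cfg$quats) <- NULL
  cfg
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change `dE` with probability `min(1, exp(-beta*dE))`.
#' Exposed so detailed balance can be property-tested directly.
#'
#' @param dE energy change, kcal/mol (may be Inf for a clash).
#' @param beta inverse temperature, (kcal/mol)^-1.
#' @param u uniform random deviate in \[0,1).
#' @return logical.
#' @export
metropolis_accept <- function(dE, beta, u = stats::runif(1)) {
  if (!is.finite(dE)) return(dE < 0)
  dE <= 0 || u < exp(-beta * dE)
}

#' Rigid-body Metropolis Monte Carlo sampling
#'
#' Samples equilibrium configurations of N rigid copies in the periodic box
#' under the pairwise energy of [molecule_pair_energy()] at the reference
#' temperature. Moves are single-molecule Gaussian translations plus small
#' axis-angle rotations; move sizes are auto-tuned toward 30-50% acceptance
#' during equilibration only.
#'
#' @param config starting [solution_config()].
#' @param mol the `rigid_molecule`.
#' @param params an [energy_params()].
#' @param n_sweeps production sweeps (one sweep = one attempted move per
#'   copy).
#' @param n_equil equilibration sweeps (auto-tuning active).
#' @param sample_every sweeps between stored snapshots.
#' @param move_trans initial translation sigma, Angstrom.
#' @param move_rot initial rotation sigma, radians.
#' @param temperature sampling temperature, K (default the reference).
#' @param seed RNG seed.
#' @return list of class `trajectory`: `snapshots` (list of configs),
#'   `energies` (per-snapshot total energy), `acceptance`, `move_trans`,
#'   `move_rot`, `seed`, `box_side`, `n_copies`.
#' @export
run_sampler <- function(config, mol, params = energy_params(),
                        n_sweeps = 200, n_equil = 100, sample_every = 5,
                        move_trans = 2, move_rot = 0.3,
                        temperature = params$temperature_ref, seed = 1) {
  if (move_trans <= 0 || move_rot <= 0) stop("move sizes must be positive")
  set.seed(seed)
  beta <- beta_at(temperature, params)
  n <- config$n_copies
  snapshots <- list()
  energies <- numeric(0)
  acc <- 0; tries <- 0
  for (sweep in seq_len(n_equil + n_sweeps)) {
    for (i in seq_len(n)) {
      tries <- tries + 1
      old_pos <- config$positions[i, ]; old_q <- config$quats[i, ]
      new_pos <- (old_pos + stats::rnorm(3, 0, move_trans)) %% config$box_side
      dq <- axis_angle_quat(stats::rnorm(3), abs(stats::rnorm(1, 0, move_rot)))
      new_q <- quat_multiply(dq, old_q)
      e_old <- copy_energy(config, mol, params, i, old_pos, old_q)
      e_new <- copy_energy(config, mol, params, i, new_pos, new_q)
      if (metropolis_accept(e_new - e_old, beta)) {
        config$positions[i, ] <- new_pos
        config$quats[i, ] <- new_q
        acc <- acc + 1
      }
    }
    if (sweep <= n_equil && sweep %% 25 == 0 && tries > 0) {
      rate <- acc / tries
      if (rate < 0.3) { move_trans <- move_trans * 0.8; move_rot <- move_rot * 0.8 }
      if (rate > 0.5) { move_trans <- move_trans * 1.2; move_rot <- move_rot * 1.2 }
      acc <- 0; tries <- 0
    }
    if (sweep == n_equil) { acc <- 0; tries <- 0 }
    if (sweep > n_equil && (sweep - n_equil) %% sample_every == 0) {
      snapshots[[length(snapshots) + 1]] <- config
      energies <- c(energies, config_total_energy(config, mol, params))
    }
  }
  structure(list(snapshots = snapshots, energies = energies,
                 acceptance = if (tries > 0) acc / tries else NA_real_,
                 move_trans = move_trans, move_rot = move_rot, seed = seed,
                 box_side = config$box_side, n_copies = n),
            class = "trajectory")
}

#' Radial distribution function of molecule centres
#'
#' Minimum-image, shell-normalised g(r) over snapshot pairs.
#'
#' @param traj a [run_sampler()] trajectory.
#' @param r_max maximum distance (default half the box).
#' @param dr bin width, Angstrom.
#' @return data.frame with `r` (bin centres) and `g`.
#' @export
pair_distribution <- function(traj, r_max = traj$box_side / 2, dr = 0.5) {
  if (dr <= 0) stop("bin width must be positive")
  if (length(traj$snapshots) < 1) stop("empty trajectory")
  box <- traj$box_side
  breaks <- seq(0, r_max, by = dr)
  counts <- numeric(length(breaks) - 1)
  n <- traj$n_copies
  for (snap in traj$snapshots) {
    d <- cross_distances(snap$positions, snap$positions, box)
    dd <- d[upper.tri(d)]
    counts <- counts + graphics::hist(dd[dd < r_max], breaks = breaks,
                                      plot = FALSE)$counts
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell_v <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  npairs <- n * (n - 1) / 2 * length(traj$snapshots)
  expected <- npairs * shell_v / box^3
  data.frame(r = centers, g = counts / expected)
}
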
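# Shared fixtures and independent oracles, built in code at test time.

# A toy molecule whose atom offsets are exact multiples of `h`, so that
# trilinear rasterization reduces to a delta and FFT energies can be
# compared against the direct pair-energy oracle exactly.
lattice_tetramer <- function(h = 0.5, lj_sigma = 3, lj_epsilon = 0.2,
                             charge = 0.5) {
  make_toy("tetramer", lj_sigma = lj_sigma, lj_epsilon = lj_epsilon,
           charge = charge, separation = 4 * h)
}

# Sum of molecule_pair_energy over all solution copies: the brute-force
# double-loop oracle for one test placement.
oracle_insertion_energy <- function(cfg, mol, test, position, quat, params) {
  total <- 0
  for (j in seq_len(cfg$n_copies)) {
    e <- molecule_pair_energy(
      test, list(position = position, quat = quat),
      mol, list(position = cfg$positions[j, ], quat = cfg$quats[j, ]),
      params = params, box = cfg$box_side
    )
    if (e$steric_clash) return(list(clash = TRUE, total = Inf))
    total <- total + e$total
  }
  list(clash = FALSE, total = total)
}

# Minimal energy_histogram for unit tests of mu/tail functions.
synthetic_histogram <- function(u_centers, counts, f_CF = 1,
                                M_total = NULL, kB = 0.0019872,
                                bin_width = NULL) {
  if (is.null(bin_width)) {
    bin_width <- if (length(u_centers) > 1) min(diff(sort(u_centers))) else 0.016
  }
  M_CF <- sum(counts)
  if (is.null(M_total)) M_total <- M_CF / f_CF
  structure(list(bin_width = bin_width, counts = counts,
                 u_centers = u_centers,
                 U_range = range(u_centers), f_CF = f_CF, M_CF = M_CF,
                 M_total = M_total, kB = kB),
            class = "energy_histogram")
}

# Exact exponential CDF histogram: counts per fine bin from
# C(U) = A exp(alpha U) on [u_min, u_max).
exponential_histogram <- function(alpha, A, u_min, u_max = -1e-3,
                                  bin_width = 0.016, f_CF = 1) {
  edges <- seq(u_min, u_max, by = bin_width)
  centers <- edges + bin_width / 2
  counts <- A * exp(alpha * (edges + bin_width)) - A * exp(alpha * edges)
  synthetic_histogram(centers, counts, f_CF = f_CF, bin_width = bin_width)
}

# Temperature (K) that gives a requested beta, for a histogram's kB.
temperature_for_beta <- function(beta, kB = 0.0019872) 1 / (kB * beta)

# Build a pose record data.frame.
pose_df <- function(x, y, z, energy, qw = 1, qx = 0, qy = 0, qz = 0) {
  data.frame(x = x, y = y, z = z, qw = qw, qx = qx, qy = qy, qz = qz,
             energy = energy)
}
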
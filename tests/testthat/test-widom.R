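test_that("an empty box gives f_CF = 1 and beta*mu_ex = 0", {
  grid <- grid_spec(8, 1)
  mol <- make_toy("sphere", lj_sigma = 2, lj_epsilon = 0.2, charge = 0.3)
  empty <- solution_config(8, matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 4))
  traj <- list(snapshots = list(empty))
  hist <- accumulate_insertions(traj, mol, n_orientations = 2, grid = grid,
                                seed = 1)
  expect_equal(hist$f_CF, 1)
  expect_equal(length(hist$counts), 1L)
  expect_equal(hist$u_centers, 0)
  expect_equal(mu_ex_raw(hist, 298)$beta_mu_ex, 0)
})

test_that("pooled histogram equals exhaustive enumeration on a toy box", {
  params <- energy_params()
  grid <- grid_spec(8, 1)
  mol <- make_toy("sphere", lj_sigma = 3, lj_epsilon = 0.4, charge = 0.5)
  cfg1 <- solution_config(8, rbind(c(2, 2, 2), c(6, 5, 3)),
                          rbind(identity_quat(), identity_quat()))
  cfg2 <- solution_config(8, rbind(c(1, 4, 6), c(5, 1, 2)),
                          rbind(identity_quat(), identity_quat()))
  traj <- list(snapshots = list(cfg1, cfg2))
  n_ori <- 2
  hist <- accumulate_insertions(traj, mol, n_orientations = n_ori,
                                grid = grid, params = params, seed = 4,
                                bin_width = 0.016)
  # brute force: every (config, orientation, grid point); spheres are
  # orientation-independent, so any orientation gives the same energies
  us <- c(); n_clash <- 0
  for (cfg in list(cfg1, cfg2)) {
    for (i in 0:7) for (j in 0:7) for (k in 0:7) {
      o <- oracle_insertion_energy(cfg, mol, mol, c(i, j, k), identity_quat(),
                                   params)
      if (o$clash) n_clash <- n_clash + 1 else us <- c(us, o$total)
    }
  }
  expect_equal(hist$M_CF, n_ori * length(us))
  expect_equal(hist$M_total, n_ori * 2 * 8^3)
  expect_equal(hist$f_CF, length(us) / (length(us) + n_clash))
  want <- table(floor(us / 0.016 + 0.5)) * n_ori
  expect_equal(sort(as.numeric(names(hist$counts))),
               sort(as.numeric(names(want))))
  expect_equal(unname(hist$counts[names(want)]), unname(as.numeric(want)))
})

test_that("mu_ex_raw reproduces hand-computed Boltzmann sums and limits", {
  h <- synthetic_histogram(u_centers = c(0, -1), counts = c(1, 1), f_CF = 1)
  t_beta1 <- temperature_for_beta(1)
  expect_equal(mu_ex_raw(h, t_beta1)$beta_mu_ex, -log((1 + exp(1)) / 2),
               tolerance = 1e-12)
  # beta -> 0 limit: -ln f_CF
  h2 <- synthetic_histogram(u_centers = c(-2, 0, 1), counts = c(5, 3, 2),
                            f_CF = 0.37)
  t_hot <- temperature_for_beta(1e-7)
  expect_equal(mu_ex_raw(h2, t_hot)$beta_mu_ex, -log(0.37), tolerance = 1e-6)
})

test_that("beta*mu_ex decreases when a count moves to a lower-energy bin", {
  h1 <- synthetic_histogram(u_centers = c(-1, 0), counts = c(10, 90))
  h2 <- synthetic_histogram(u_centers = c(-1, 0), counts = c(11, 89))
  expect_lt(mu_ex_raw(h2, 298)$beta_mu_ex, mu_ex_raw(h1, 298)$beta_mu_ex)
})

test_that("halving the bin width barely moves beta*mu_ex", {
  params <- energy_params()
  grid <- grid_spec(10, 0.5)
  mol <- make_toy("sphere", lj_sigma = 3, lj_epsilon = 0.4, charge = 0.3)
  cfg <- solution_config(10, rbind(c(2, 2, 2), c(7, 6, 4)),
                         rbind(identity_quat(), identity_quat()))
  traj <- list(snapshots = list(cfg))
  h1 <- accumulate_insertions(traj, mol, n_orientations = 1, grid = grid,
                              params = params, seed = 2, bin_width = 0.016)
  h2 <- accumulate_insertions(traj, mol, n_orientations = 1, grid = grid,
                              params = params, seed = 2, bin_width = 0.008)
  expect_lt(abs(mu_ex_raw(h1, 280)$beta_mu_ex - mu_ex_raw(h2, 280)$beta_mu_ex),
            1e-3)
})

test_that("s1/s2 rescanning from the component sub-histogram is consistent", {
  params <- energy_params()
  grid <- grid_spec(10, 0.5)
  mol <- make_toy("sphere", lj_sigma = 3, lj_epsilon = 0.4, charge = 0.3)
  cfg <- solution_config(10, rbind(c(2, 2, 2), c(7, 6, 4)),
                         rbind(identity_quat(), identity_quat()))
  h <- accumulate_insertions(list(snapshots = list(cfg)), mol,
                             n_orientations = 1, grid = grid,
                             params = params, seed = 2,
                             sub_bin_width = 0.004)
  raw <- mu_ex_raw(h, 298)$beta_mu_ex
  res <- mu_ex_rescaled(h, 298, s1 = params$s1, s2 = params$s2)
  expect_equal(res, raw, tolerance = 0.02)
  # stronger attraction must lower mu_ex
  expect_lt(mu_ex_rescaled(h, 298, s1 = 2 * params$s1, s2 = params$s2), res)
})

test_that("ideal chemical potential is logarithmic and additive", {
  expect_equal(mu_ideal(5, 5), 0)
  expect_equal(mu_ideal(10, 5), log(2))
  expect_equal(mu_ideal(7, 1), mu_ideal(7, 3) + mu_ideal(3, 1))
  expect_error(mu_ideal(-1), "positive")
})

test_that("blocking error matches sampling theory", {
  set.seed(21)
  # i.i.d.: blocking SE within 20% of sigma/sqrt(n)
  x <- rnorm(1024, mean = 1, sd = 0.2)
  b <- blocking_error(x)
  expect_equal(b$se, 0.2 / sqrt(1024), tolerance = 0.2)
  # constant data: zero error
  expect_equal(blocking_error(rep(3.3, 64))$se, 0)
  # AR(1), phi = 0.9: true SE is sqrt((1+phi)/(1-phi)) ~ 4.4x the naive SE
  phi <- 0.9
  e <- rnorm(4096)
  y <- as.vector(stats::filter(e, phi, method = "recursive"))
  naive <- sd(y) / sqrt(length(y))
  expect_gte(blocking_error(y)$se, 2 * naive)
  expect_error(blocking_error(rnorm(8)), "16")
})

test_that("per-orientation blocking propagates through the log", {
  params <- energy_params()
  grid <- grid_spec(10, 1)
  mol <- make_toy("sphere", lj_sigma = 3, lj_epsilon = 0.5, charge = 0)
  cfg <- solution_config(10, rbind(c(2, 2, 2), c(7, 6, 4)),
                         rbind(identity_quat(), identity_quat()))
  h <- accumulate_insertions(list(snapshots = list(cfg)), mol,
                             n_orientations = 16, grid = grid,
                             params = params, seed = 3,
                             temps_celsius = c(-2, 25))
  be <- mu_blocking_error(h, 25)
  # the blocking path uses unbinned Boltzmann sums; agreement with the
  # binned histogram is limited by the 0.016 kcal/mol bin width
  expect_equal(be$beta_mu_ex, mu_ex_raw(h, celsius_to_kelvin(25))$beta_mu_ex,
               tolerance = 0.02)
  expect_gte(be$se_plus, 0)
  expect_gte(be$se_minus, 0)
})
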
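test_that("deterministic orientation set covers SO(3) at its resolution", {
  q20 <- deterministic_orientations(20)
  expect_equal(q20[1, ], c(1, 0, 0, 0))  # identity by convention
  # count scales as resolution^-3: halving within 15% of 8x
  q10 <- deterministic_orientations(10)
  expect_equal(nrow(q10) / nrow(q20), 8, tolerance = 0.15)
  # covering radius: every random rotation is near some set member
  set.seed(41)
  probes <- random_quaternions(10000)
  dots <- abs(probes %*% t(q20))
  worst <- max(2 * acos(pmin(1, apply(dots, 1, max))))
  expect_lte(worst, 1.5 * 20 * pi / 180)
  expect_error(deterministic_orientations(1), "resolution")
})

test_that("the 6-degree set has the canonical size", {
  # 60 twist angles x 1146 axis points
  theta <- 6 * pi / 180
  expect_equal(round(2 * pi / theta) * round(4 * pi / theta^2), 68760)
})

test_that("hard-sphere B2 matches the analytic excluded volume within 1%", {
  # contact distance incommensurate with the lattice avoids a degenerate
  # shell of boundary points sitting exactly on the clash sphere
  sph <- make_toy("sphere", lj_sigma = 8.1, lj_epsilon = 1e-12, charge = 0)
  r <- fmapb2(sph, box_side = 42, spacing = 0.5,
              orientations = matrix(identity_quat(), 1, 4),
              temps_celsius = 25)
  want <- (2 * pi / 3) * 8.1^3
  expect_equal(r$B2_st_A3, want, tolerance = 0.01)
  expect_equal(r$table$B2_A3, want, tolerance = 0.01)  # no attraction
  expect_equal(r$Vst_A3, r$B2_st_A3 / 4)
})

test_that("a near-point molecule has a vanishing B2", {
  pt <- make_toy("sphere", lj_sigma = 0.2, lj_epsilon = 0, charge = 0)
  r <- fmapb2(pt, box_side = 26, spacing = 0.5,
              orientations = matrix(identity_quat(), 1, 4),
              temps_celsius = c(0, 25))
  expect_true(all(abs(r$table$B2_A3) <= 0.5^3))
})

test_that("B2(T) of an attractive sphere matches radial quadrature within 2%", {
  params <- energy_params()
  sph <- make_toy("sphere", lj_sigma = 6.1, lj_epsilon = 1.5, charge = 0)
  # fine grid for the lattice -> continuum comparison and a fine energy
  # bin so the far-field shell (|u| < one default bin) is resolved
  r <- fmapb2(sph, box_side = 40, spacing = 0.3125, bin_width = 0.002,
              orientations = matrix(identity_quat(), 1, 4), params = params,
              temps_celsius = c(-10, 10, 25, 60))
  # the attraction component is smooth and converges fast on the lattice;
  # the steric component is checked against its analytic value in the
  # hard-sphere test above (its lattice count oscillates at the few-A^3
  # level with commensurability, so it is compared separately)
  for (tc in c(-10, 60)) {
    beta <- 1 / (params$kB * celsius_to_kelvin(tc))
    u <- function(rr) {
      sr6 <- (6.1 / rr)^6
      ifelse(rr <= params$cutoff, params$s1 * 4 * 1.5 * (sr6^2 - sr6), 0)
    }
    mayer <- stats::integrate(function(rr) (1 - exp(-beta * u(rr))) * rr^2,
                              6.1, 13, rel.tol = 1e-10)$value
    want_attr <- 2 * pi * mayer  # negative: attraction lowers B2
    got_attr <- r$table$B2_A3[r$table$temperature_celsius == tc] - r$B2_st_A3
    expect_equal(got_attr, want_attr, tolerance = 0.02)
    expect_equal(r$B2_st_A3, 2 * pi / 3 * 6.1^3, tolerance = 0.02)
  }
  # monotone increasing in T for hard core + attraction
  expect_true(all(diff(r$table$B2_A3) > 0))
  # box precondition
  expect_error(fmapb2(sph, box_side = 20, spacing = 0.5), "box too small")
})

test_that("B2 is robust to the orientation count", {
  dumb <- make_toy("charged_dumbbell", lj_sigma = 4, lj_epsilon = 0.8,
                   charge = 0.5, separation = 4)
  r30 <- fmapb2(dumb, box_side = 40, spacing = 1.25,
                angular_resolution = 30, temps_celsius = 25)
  r24 <- fmapb2(dumb, box_side = 40, spacing = 1.25,
                angular_resolution = 24, temps_celsius = 25)
  expect_gt(r24$n_orientations / r30$n_orientations, 1.5)
  expect_equal(r24$table$B2_A3, r30$table$B2_A3, tolerance = 0.01)
})

test_that("library averaging reduces to fmapb2 and enumerates all pairs", {
  sph <- make_toy("sphere", lj_sigma = 5, lj_epsilon = 0.5)
  one <- fmapb2(sph, box_side = 36, spacing = 1,
                orientations = matrix(identity_quat(), 1, 4),
                temps_celsius = 25)
  lib1 <- fmapb23_average(list(sph), box_side = 36, spacing = 1,
                          orientations = matrix(identity_quat(), 1, 4),
                          temps_celsius = 25)
  expect_equal(lib1$B2_A3_mean, one$table$B2_A3, tolerance = 1e-12)
  lib2 <- fmapb23_average(list(sph, sph), box_side = 36, spacing = 1,
                          orientations = matrix(identity_quat(), 1, 4),
                          temps_celsius = 25)
  expect_equal(lib2$B2_A3_mean, one$table$B2_A3, tolerance = 1e-12)

  # two distinct structures: mean of the four explicit ordered pairs
  sphB <- make_toy("sphere", lj_sigma = 5, lj_epsilon = 1.2)
  mix <- fmapb23_average(list(sph, sphB), box_side = 36, spacing = 1,
                         orientations = matrix(identity_quat(), 1, 4),
                         temps_celsius = 25)
  parts <- vapply(list(list(sph, sph), list(sph, sphB),
                       list(sphB, sph), list(sphB, sphB)), function(pp) {
    fmapb2(pp[[1]], pp[[2]], box_side = 36, spacing = 1,
           orientations = matrix(identity_quat(), 1, 4),
           temps_celsius = 25)$table$B2_A3
  }, numeric(1))
  expect_equal(mix$B2_A3_mean, mean(parts), tolerance = 1e-12)

  dumb <- make_toy("charged_dumbbell", lj_sigma = 5, lj_epsilon = 0.5)
  expect_error(fmapb23_average(list(sph, dumb), box_side = 36), "mixed")
})

test_that("Welch comparison matches the closed-form t statistic", {
  # construct groups with exact means and SDs
  fix <- function(x, m, s) m + (x - mean(x)) / sd(x) * s
  set.seed(44)
  lo <- fix(rnorm(10), -1.3, 0.5)
  hi <- fix(rnorm(5), -2.1, 0.3)
  out <- group_compare(lo, hi)
  t_hand <- (-1.3 - (-2.1)) / sqrt(0.5^2 / 10 + 0.3^2 / 5)
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$t, 3.86, tolerance = 0.01)
  swapped <- group_compare(hi, lo)
  expect_equal(swapped$t, -out$t, tolerance = 1e-12)
  expect_equal(swapped$p, out$p, tolerance = 1e-12)
  same <- group_compare(c(1, 1, 1), c(1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})
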
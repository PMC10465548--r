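test_that("CDF construction is a running sum ending at M_CF", {
  h <- synthetic_histogram(u_centers = c(-2), counts = c(7))
  cdf <- cdf_from_hist(h)
  expect_equal(cdf$C, 7)
  h2 <- synthetic_histogram(u_centers = c(-3, -1, 0), counts = c(1, 4, 10))
  cdf2 <- cdf_from_hist(h2)
  expect_true(all(diff(cdf2$C) >= 0))
  expect_equal(cdf2$C[nrow(cdf2)], h2$M_CF)
})

test_that("log-CDF fit recovers the exponential slope within 2%", {
  for (alpha in c(1.5, 1.7, 2.1)) {
    h <- exponential_histogram(alpha, A = 1e12, u_min = -14)
    cdf <- cdf_from_hist(h)
    m <- fit_log_cdf(cdf)
    expect_equal(m$alpha, alpha, tolerance = 0.02)
    # ln CDF is linear over the window with the same slope (1% check)
    sel <- cdf$C >= 1e4 & cdf$U <= -4
    slope <- coef(lm(log(cdf$C[sel]) ~ cdf$U[sel]))[2]
    expect_equal(unname(slope), alpha, tolerance = 0.01)
  }
})

test_that("extrapolation reproduces an exactly linear log-CDF", {
  alpha <- 1.7
  h <- exponential_histogram(alpha, A = 1e12, u_min = -14)
  m <- fit_log_cdf(cdf_from_hist(h))
  u <- c(-16, -15, -14.2)
  want <- log(1e12) + alpha * u
  expect_equal(m$predict_log(u), want, tolerance = 0.05)
  expect_error(fit_log_cdf(cdf_from_hist(
    synthetic_histogram(c(-1, 0), c(5, 5)))), "window|sparse")
})

test_that("f_CF endpoint rule inverts the exponential CDF in closed form", {
  alpha <- 1.7; A <- 1e12
  h <- exponential_histogram(alpha, A = A, u_min = -14)
  m <- fit_log_cdf(cdf_from_hist(h))
  for (f in c(1, 0.5, 0.1)) {
    want <- log(f^0.25 / A) / alpha
    expect_equal(umin_from_fcf(f, m), want, tolerance = 0.03)
  }
  # monotone: halving f_CF lowers the CDF target, extending the
  # extrapolation to a lower (more negative) U_min
  expect_lt(umin_from_fcf(0.5, m), umin_from_fcf(1, m))
})

test_that("block-minimum fit recovers a known power-law bound", {
  # block minima sampled exactly from the minimum distribution of
  # U = -ln(x)/beta with x ~ power law on (1, b], b = exp(-beta*U_min)
  set.seed(31)
  beta <- 1.688; alpha <- 1.7
  a_exp <- alpha / beta + 1
  u_true <- c("60" = -8, "170" = -10)  # per-concentration bounds
  blocks <- do.call(rbind, lapply(names(u_true), function(cc) {
    b <- exp(-beta * u_true[[cc]])
    Ms <- c(1e2, 1e3, 1e4, 1e5, 1e6, 1e7, 1e8, 1e9)
    u_hat <- vapply(Ms, function(M) {
      v <- runif(400)
      # inverse of F(x)^M for the power-law CDF F
      q <- v^(1 / M)
      xmax <- (1 - q * (1 - b^(1 - a_exp)))^(1 / (1 - a_exp))
      mean(-log(xmax) / beta)
    }, numeric(1))
    data.frame(M = Ms, u_hat = u_hat, concentration = cc)
  }))
  fit <- estimate_umin_blocks(blocks)
  expect_equal(unname(fit$U_min["60"]), -8, tolerance = 0.05)
  expect_equal(unname(fit$U_min["170"]), -10, tolerance = 0.05)
  expect_true(all(fit$delta >= 0.6 & fit$delta <= 1))
  expect_length(fit$D, 1)
})

test_that("block-minimum fit handles plateau data and monotonicity", {
  d <- data.frame(M = c(10, 100, 1000, 1e4, 1e5), u_hat = rep(-5.5, 5))
  fit <- estimate_umin_blocks(d)
  expect_equal(unname(fit$U_min), -5.5, tolerance = 1e-3)
  expect_lt(unname(fit$E), 0.01)
  # block minima are non-increasing in block size by construction
  set.seed(32)
  u <- -rexp(10000, rate = 1.7)
  u_hat <- vapply(c(10, 100, 1000), function(M) {
    mean(vapply(1:50, function(i) min(sample(u, M, replace = TRUE)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(u_hat) <= 0))
})

test_that("tail correction preserves an exactly exponential histogram", {
  alpha <- 1.7
  h <- exponential_histogram(alpha, A = 1e12, u_min = -14, f_CF = 0.8)
  m <- fit_log_cdf(cdf_from_hist(h))
  # endpoint equal to the histogram's true bound (bin-centre aligned), as
  # the block-minimum route would supply for data that reach their bound
  u_min <- min(h$u_centers)
  t_ref <- temperature_for_beta(1.7)
  raw <- mu_ex_raw(h, t_ref)$beta_mu_ex
  corr <- corrected_mu_ex(h, m, u_min, t_ref)
  expect_true(corr$corrected)
  expect_equal(corr$beta_mu_ex, raw, tolerance = 1e-3)
  # beta -> 0: correction cannot move the steric limit
  t_hot <- temperature_for_beta(1e-7)
  expect_equal(corrected_mu_ex(h, m, u_min, t_hot)$beta_mu_ex, -log(0.8),
               tolerance = 1e-6)
})

test_that("the corrected mu_ex is insensitive to a single outlier count", {
  # A = 1e9 puts the expected CDF = 1 endpoint at -12.2 kcal/mol, so a
  # stray count at -16 is a genuine outlier
  alpha <- 1.7
  h <- exponential_histogram(alpha, A = 1e9, u_min = -12)
  # one spurious energy far below the true bound
  out <- h
  out$u_centers <- c(-16, out$u_centers)
  out$counts <- c(1, out$counts)
  out$M_CF <- out$M_CF + 1
  t_cold <- temperature_for_beta(2.6)
  raw_shift <- abs(mu_ex_raw(out, t_cold)$beta_mu_ex -
                     mu_ex_raw(h, t_cold)$beta_mu_ex)
  expect_gt(raw_shift, 0.1)
  m_h <- fit_log_cdf(cdf_from_hist(h))
  m_o <- fit_log_cdf(cdf_from_hist(out))
  u_h <- umin_from_fcf(1, m_h); u_o <- umin_from_fcf(1, m_o)
  corr_shift <- abs(corrected_mu_ex(out, m_o, u_o, t_cold)$beta_mu_ex -
                      corrected_mu_ex(h, m_h, u_h, t_cold)$beta_mu_ex)
  expect_lt(corr_shift, 1e-3)
  # and the outlier detector fires on it, but not at the boundary
  expect_true(detect_outlier(m_o, observed_lowest_U = -16))
  u_at_1 <- m_h$U_lo - m_h$log_C_lo / m_h$alpha
  expect_false(detect_outlier(m_h, u_at_1))
  expect_false(detect_outlier(m_h, u_at_1 - 0.99))
  expect_true(detect_outlier(m_h, u_at_1 - 1.5))
})

test_that("corrected histogram mass stays within 0.1% of M_CF", {
  alpha <- 1.7
  h <- exponential_histogram(alpha, A = 1e12, u_min = -14)
  m <- fit_log_cdf(cdf_from_hist(h))
  u_min <- umin_from_fcf(1, m)
  tail_top <- m$U_lo - h$bin_width / 2
  u_tail <- seq(u_min, tail_top, by = h$bin_width)
  h_tail <- m$alpha * exp(m$log_C_lo + m$alpha * (u_tail - m$U_lo)) *
    h$bin_width
  total <- sum(h_tail) + sum(h$counts[h$u_centers >= m$U_lo])
  expect_lt(abs(total - h$M_CF) / h$M_CF, 1e-3)
})
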
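#' Cumulative distribution of insertion energies
#'
#' Running sum of histogram counts from the lowest observed energy upward;
#' ends at M_CF.
#'
#' @param hist an [accumulate_insertions()] histogram, or any list with
#'   `u_centers` and `counts`.
#' @return data.frame with `U` (bin centres, ascending) and `C` (cumulative
#'   counts).
#' @export
cdf_from_hist <- function(hist) {
  if (!length(hist$counts)) stop("empty histogram")
  ord <- order(hist$u_centers)
  data.frame(U = hist$u_centers[ord], C = cumsum(hist$counts[ord]))
}

#' Fit the logarithm of the energy CDF
#'
#' Locally weighted linear regression (loess, degree 1, span 0.75) of
#' ln C(U) against U over the window bounded below by `C = cdf_floor`
#' (default 1e4) and above by `U = u_max` (default -4 kcal/mol).
#' Extrapolation below the window continues linearly with the local slope
#' at the window's lower edge, preserving value and derivative.
#'
#' @param cdf a [cdf_from_hist()] table.
#' @param cdf_floor lower window boundary as a CDF value.
#' @param u_max upper window boundary in energy.
#' @param span loess span.
#' @return list of class `cdf_model` with `alpha` (slope at the lower edge,
#'   1/(kcal/mol)), `U_lo`, `log_C_lo`, `window`, `fit`, and `predict_log`
#'   (a function of U valid in and below the window).
#' @export
fit_log_cdf <- function(cdf, cdf_floor = 1e4, u_max = -4, span = 0.75) {
  sel <- cdf$C >= cdf_floor & cdf$U <= u_max & cdf$C > 0
  if (sum(sel) < 10) {
    stop("fewer than 10 CDF points in the fit window; ",
         "histogram too sparse for tail correction")
  }
  d <- data.frame(U = cdf$U[sel], lC = log(cdf$C[sel]))
  fit <- stats::loess(lC ~ U, data = d, degree = 1, span = span,
                      control = stats::loess.control(surface = "direct"))
  U_lo <- min(d$U); U_hi <- max(d$U)
  # local slope at the lower edge by a small finite difference
  eps <- max(1e-4, (U_hi - U_lo) * 1e-3)
  p <- stats::predict(fit, newdata = data.frame(U = c(U_lo, U_lo + eps)))
  alpha <- (p[2] - p[1]) / eps
  if (!is.finite(alpha) || alpha <= 0) {
    stop("fitted CDF slope is not positive; tail model invalid")
  }
  log_C_lo <- p[1]
  predict_log <- function(U) {
    out <- numeric(length(U))
    below <- U < U_lo
    out[below] <- log_C_lo + alpha * (U[below] - U_lo)
    if (any(!below)) {
      out[!below] <- stats::predict(fit, newdata = data.frame(U = U[!below]))
    }
    out
  }
  structure(list(alpha = unname(alpha), U_lo = U_lo, U_hi = U_hi,
                 log_C_lo = unname(log_C_lo), window = c(U_lo, U_hi),
                 fit = fit, predict_log = predict_log),
            class = "cdf_model")
}

#' Bound of the insertion-energy distribution from block minima
#'
#' Fits the mean lowest energy per block, as a function of block sample
#' size M, to `U_hat = U_min + E / (1 + (M/D)^delta)` with delta bounded in
#' \[0.6, 1\]. When several concentrations are fitted jointly, D is shared
#' across them while U_min, E and delta are per concentration
#' (Levenberg-Marquardt with box constraints).
#'
#' @param blocks a data.frame with columns `M` (block sample size), `u_hat`
#'   (mean block-lowest energy) and optionally `concentration`; or a list
#'   of such data.frames.
#' @return list of class `umin_fit` with `U_min` (per concentration), `E`,
#'   `delta`, shared `D`, `residuals`, `converged`.
#' @export
estimate_umin_blocks <- function(blocks) {
  if (is.data.frame(blocks)) {
    if (is.null(blocks$concentration)) blocks$concentration <- 1
    blocks <- split(blocks, blocks$concentration)
  }
  ng <- length(blocks)
  for (b in blocks) {
    if (length(unique(b$M)) < 4) stop("need >= 4 distinct block sizes")
  }
  umin0 <- vapply(blocks, function(b) min(b$u_hat), numeric(1))
  e0 <- vapply(blocks, function(b) max(b$u_hat) - min(b$u_hat) + 1e-6,
               numeric(1))
  d0 <- stats::median(unlist(lapply(blocks, function(b) b$M)))
  # parameters: U_min[1..ng], E[1..ng], delta[1..ng], log(D)
  p0 <- c(umin0 - 0.1 * abs(umin0), e0, rep(0.8, ng), log(d0))
  lower <- c(rep(-Inf, ng), rep(0, ng), rep(0.6, ng), log(1e-6))
  upper <- c(rep(0, ng), rep(Inf, ng), rep(1, ng), log(1e12))
  resid_fn <- function(p) {
    um <- p[1:ng]; ee <- p[ng + 1:ng]; dl <- p[2 * ng + 1:ng]
    D <- exp(p[3 * ng + 1])
    unlist(lapply(seq_len(ng), function(g) {
      b <- blocks[[g]]
      b$u_hat - (um[g] + ee[g] / (1 + (b$M / D)^dl[g]))
    }))
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(fit$info %in% 1:4)) {
    stop("block-minimum fit did not converge (info = ", fit$info,
         "); residual norm ", signif(sqrt(sum(fit$fvec^2)), 4))
  }
  p <- fit$par
  structure(list(
    U_min = stats::setNames(p[1:ng], names(blocks)),
    E = stats::setNames(p[ng + 1:ng], names(blocks)),
    delta = stats::setNames(p[2 * ng + 1:ng], names(blocks)),
    D = exp(p[3 * ng + 1]),
    residuals = fit$fvec, converged = TRUE
  ), class = "umin_fit")
}

#' Endpoint of the CDF extrapolation from the clash-free fraction
#'
#' Solves `CDF(U_min) = B * f_CF^gamma` on the extrapolated log-linear CDF
#' (defaults B = 1, gamma = 0.25).
#'
#' @param f_CF clash-free fraction.
#' @param cdf_model a [fit_log_cdf()] model.
#' @param B,gamma endpoint-rule constants.
#' @return U_min, kcal/mol.
#' @export
umin_from_fcf <- function(f_CF, cdf_model, B = 1, gamma = 0.25) {
  target <- log(B) + gamma * log(f_CF)
  if (target >= cdf_model$log_C_lo) {
    stop("endpoint target lies above the fit window; no extrapolated solution")
  }
  cdf_model$U_lo + (target - cdf_model$log_C_lo) / cdf_model$alpha
}

#' Tail-corrected excess chemical potential
#'
#' Replaces the histogram below the fit window's lower edge with the
#' derivative of the extrapolated CDF, truncated at `U_min`, and
#' re-evaluates the Boltzmann sum. Above the window edge the original
#' counts are used unchanged.
#'
#' @param hist an [accumulate_insertions()] histogram.
#' @param cdf_model a [fit_log_cdf()] model.
#' @param U_min lower truncation energy (e.g. from [umin_from_fcf()]).
#' @param temperature K.
#' @return a `mu_point` with `corrected = TRUE`.
#' @export
corrected_mu_ex <- function(hist, cdf_model, U_min, temperature) {
  if (U_min > cdf_model$U_lo) stop("U_min lies above the fit window")
  beta <- 1 / (hist$kB * temperature)
  keep <- hist$u_centers >= cdf_model$U_lo
  tail_top <- cdf_model$U_lo - hist$bin_width / 2
  u_tail <- if (U_min <= tail_top) seq(U_min, tail_top, by = hist$bin_width)
            else numeric(0)
  # H*(U) = dC/dU * bin_width on the extrapolated exponential branch
  h_tail <- cdf_model$alpha *
    exp(cdf_model$log_C_lo + cdf_model$alpha * (u_tail - cdf_model$U_lo)) *
    hist$bin_width
  u_all <- c(u_tail, hist$u_centers[keep])
  w_all <- c(h_tail, hist$counts[keep])
  ls <- logsumexp(-beta * u_all, w = w_all)
  bmu <- -(log(hist$f_CF) + ls - log(hist$M_CF))
  structure(list(beta_mu_ex = bmu, temperature_K = temperature,
                 temperature_C = temperature - 273.15, corrected = TRUE,
                 U_min = U_min),
            class = "mu_point")
}

#' Flag an outlying lowest insertion energy
#'
#' TRUE when the observed lowest energy lies more than `threshold`
#' (1.0 kcal/mol) below the energy at which the extrapolated CDF reaches 1.
#'
#' @param cdf_model a [fit_log_cdf()] model.
#' @param observed_lowest_U observed minimum insertion energy, kcal/mol.
#' @param threshold deviation threshold, kcal/mol.
#' @return logical.
#' @export
detect_outlier <- function(cdf_model, observed_lowest_U, threshold = 1.0) {
  u_at_1 <- cdf_model$U_lo - cdf_model$log_C_lo / cdf_model$alpha
  (u_at_1 - observed_lowest_U) > threshold
}
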
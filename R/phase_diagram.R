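#' Fifth-order polynomial fit of the excess chemical potential
#'
#' Least-squares fit of `beta*mu_ex = sum_{l=1..5} b_l rho^l` (no
#' intercept: the excess part vanishes at zero concentration). The
#' first-order coefficient is twice the second virial coefficient in the
#' same units.
#'
#' @param rho concentrations, mg/ml (>= 6 values).
#' @param beta_mu_ex dimensionless excess chemical potentials.
#' @param temperature_celsius temperature label, degrees C.
#' @return list of class `mu_polynomial` with `coefficients` (b1..b5),
#'   `b1`, `b1_se`, `residuals`, `temperature_celsius`.
#' @export
fit_mu_polynomial <- function(rho, beta_mu_ex, temperature_celsius = NA) {
  if (length(rho) < 6) stop("need at least 6 concentrations for a 5th-order fit")
  X <- outer(rho, 1:5, "^")
  colnames(X) <- paste0("b", 1:5)
  fit <- stats::lm.fit(X, beta_mu_ex)
  cf <- stats::setNames(fit$coefficients, paste0("b", 1:5))
  dof <- length(rho) - 5
  b1_se <- if (dof > 0) {
    s2 <- sum(fit$residuals^2) / dof
    sqrt((s2 * chol2inv(chol(crossprod(X))))[1, 1])
  } else NA_real_
  structure(list(coefficients = cf, b1 = unname(cf[1]), b1_se = b1_se,
                 residuals = fit$residuals,
                 temperature_celsius = temperature_celsius),
            class = "mu_polynomial")
}

#' Total chemical potential curve
#'
#' `beta*mu = ln(rho/rho0) + sum b_l rho^l`.
#'
#' @param poly a [fit_mu_polynomial()] object (or numeric b1..b5).
#' @param rho concentration(s), mg/ml (> 0).
#' @param rho0 reference concentration.
#' @return dimensionless beta*mu.
#' @export
total_mu <- function(poly, rho, rho0 = 1) {
  b <- if (inherits(poly, "mu_polynomial")) poly$coefficients else poly
  stopifnot(all(rho > 0))
  log(rho / rho0) + as.vector(outer(rho, seq_along(b), "^") %*% b)
}

find_loop_extrema <- function(f, lo, hi, n_scan = 2000) {
  x <- seq(lo, hi, length.out = n_scan)
  y <- f(x)
  dy <- diff(y)
  sgn <- sign(dy)
  turns <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  ext <- list()
  for (t in turns) {
    a <- x[t]; b <- x[t + 2]
    if (sgn[t] > 0) {
      op <- stats::optimize(f, c(a, b), maximum = TRUE, tol = 1e-12)
      ext[[length(ext) + 1]] <- list(rho = op$maximum, mu = op$objective,
                                     kind = "max")
    } else {
      op <- stats::optimize(f, c(a, b), maximum = FALSE, tol = 1e-12)
      ext[[length(ext) + 1]] <- list(rho = op$minimum, mu = op$objective,
                                     kind = "min")
    }
  }
  ext
}

#' Equal-area (Maxwell) construction on a chemical-potential curve
#'
#' Finds the horizontal line that bisects the van der Waals loop of
#' `beta*mu(rho)` with equal areas above and below. The first and last
#' intersections give the binodal (dilute/dense coexisting concentrations);
#' the loop extrema give the spinodal. A monotone curve returns a
#' `no_loop` result rather than an error.
#'
#' @param mu_fun function of rho returning beta*mu (e.g. built from
#'   [total_mu()]).
#' @param rho_range search interval `c(lo, hi)`, mg/ml.
#' @param temperature_celsius label carried into the result.
#' @return list of class `phase_point`: `no_loop` flag; when a loop exists,
#'   `mu_star`, `rho_dilute`, `rho_dense`, `rho_spin_lo`, `rho_spin_hi`.
#' @export
equal_area <- function(mu_fun, rho_range, temperature_celsius = NA) {
  ext <- find_loop_extrema(mu_fun, rho_range[1], rho_range[2])
  kinds <- vapply(ext, function(e) e$kind, character(1))
  imax <- which(kinds == "max"); imin <- which(kinds == "min")
  valid <- length(imax) == 1 && length(imin) == 1 &&
    ext[[imax]]$rho < ext[[imin]]$rho
  if (!valid) {
    return(structure(list(no_loop = TRUE,
                          temperature_celsius = temperature_celsius),
                     class = "phase_point"))
  }
  rho_max <- ext[[imax]]$rho; mu_max <- ext[[imax]]$mu
  rho_min <- ext[[imin]]$rho; mu_min <- ext[[imin]]$mu
  outer_roots <- function(mu_star) {
    g <- function(r) mu_fun(r) - mu_star
    r1 <- stats::uniroot(g, c(rho_range[1], rho_max), tol = 1e-12)$root
    r2 <- stats::uniroot(g, c(rho_min, rho_range[2]), tol = 1e-12)$root
    c(r1, r2)
  }
  # the bisection line must intersect the curve inside the search range
  mu_floor <- max(mu_min, mu_fun(rho_range[1]))
  mu_ceil <- min(mu_max, mu_fun(rho_range[2]))
  # quadrature tolerance scaled to the loop size; the induced uncertainty
  # in mu_star is abs.tol / loop width, far below the bisection tolerance
  atol <- max(1e-12, 1e-10 * (mu_ceil - mu_floor) *
                (rho_range[2] - rho_range[1]))
  area <- function(mu_star) {
    r <- outer_roots(mu_star)
    stats::integrate(function(x) mu_fun(x) - mu_star, r[1], r[2],
                     rel.tol = 1e-8, abs.tol = atol,
                     subdivisions = 1000L)$value
  }
  eps <- (mu_ceil - mu_floor) * 1e-9
  mu_star <- stats::uniroot(area, c(mu_floor + eps, mu_ceil - eps),
                            tol = 1e-13)$root
  r <- outer_roots(mu_star)
  structure(list(no_loop = FALSE, mu_star = mu_star,
                 rho_dilute = r[1], rho_dense = r[2],
                 rho_spin_lo = rho_max, rho_spin_hi = rho_min,
                 temperature_celsius = temperature_celsius),
            class = "phase_point")
}

#' Assemble a phase diagram over temperatures
#'
#' Runs the equal-area construction at each temperature and collects the
#' binodal/spinodal points. The critical temperature is reported as the
#' midpoint between the warmest temperature with a loop and the coolest
#' without one (plus that bracket); if all temperatures have loops only a
#' lower bound is known, if none an upper bound.
#'
#' @param polys list of [fit_mu_polynomial()] objects, each carrying its
#'   `temperature_celsius`.
#' @param rho_range concentration search range, mg/ml.
#' @param rho0 reference concentration for the ideal term.
#' @return list of class `phase_diagram` with `points` (data.frame ordered
#'   by temperature), `Tc_estimate`, `Tc_bracket`.
#' @export
build_phase_diagram <- function(polys, rho_range, rho0 = 1) {
  temps <- vapply(polys, function(p) p$temperature_celsius, numeric(1))
  ord <- order(temps)
  polys <- polys[ord]; temps <- temps[ord]
  pts <- lapply(polys, function(p) {
    equal_area(function(r) total_mu(p, r, rho0), rho_range,
               temperature_celsius = p$temperature_celsius)
  })
  has_loop <- !vapply(pts, function(p) p$no_loop, logical(1))
  df <- do.call(rbind, lapply(pts[has_loop], function(p) {
    data.frame(temperature_celsius = p$temperature_celsius,
               rho_dilute = p$rho_dilute, rho_spin_lo = p$rho_spin_lo,
               rho_spin_hi = p$rho_spin_hi, rho_dense = p$rho_dense,
               mu_star = p$mu_star)
  }))
  if (!any(has_loop)) {
    tc <- NA_real_; bracket <- c(NA_real_, min(temps))
  } else if (all(has_loop)) {
    tc <- NA_real_; bracket <- c(max(temps), NA_real_)
  } else {
    t_lo <- max(temps[has_loop])
    above <- temps[!has_loop & temps > t_lo]
    if (length(above)) {
      t_hi <- min(above)
      tc <- (t_lo + t_hi) / 2; bracket <- c(t_lo, t_hi)
    } else {
      tc <- NA_real_; bracket <- c(t_lo, NA_real_)
    }
  }
  structure(list(points = df, Tc_estimate = tc, Tc_bracket = bracket),
            class = "phase_diagram")
}

#' Critical temperature from the Vliegenthart-Lekkerkerker rule
#'
#' Locates the temperature at which `B2(T)/Vst = -6` by bisection on a
#' reduced-virial curve.
#'
#' @param temps_celsius temperatures of the curve.
#' @param b2_over_vst B2/Vst at those temperatures.
#' @return list with `Tc_celsius` (NA if no crossing) and `status`
#'   (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
vliegenthart_lekkerkerker_tc <- function(temps_celsius, b2_over_vst) {
  ord <- order(temps_celsius)
  t <- temps_celsius[ord]; y <- b2_over_vst[ord] + 6
  if (all(y > 0)) return(list(Tc_celsius = NA_real_, status = "below_range"))
  if (all(y < 0)) return(list(Tc_celsius = NA_real_, status = "above_range"))
  f <- stats::approxfun(t, y)
  i <- which(y[-1] * y[-length(y)] <= 0)[1]
  root <- stats::uniroot(f, c(t[i], t[i + 1]), tol = 1e-10)$root
  list(Tc_celsius = root, status = "ok")
}
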
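#' Run the full phase-equilibrium pipeline on a configuration list
#'
#' Binds the stages end to end: toy/PQR preparation, Monte Carlo sampling
#' at each requested copy number, Widom insertion histograms, tail-corrected
#' chemical potentials over temperatures, polynomial fit and equal-area
#' phase diagram; optionally an FMAPB2 sweep with the
#' Vliegenthart-Lekkerkerker critical-temperature estimate. Every stage's
#' output and a manifest (seeds, parameters, package version) are written
#' to `out_dir` when given.
#'
#' @param config nested list; see Details. Recognised sections: `molecule`
#'   (either `toy = list(kind, ...)` arguments for [make_toy()] or
#'   `pqr = "path"`), `energy` ([energy_params()] arguments), `grid`
#'   (`spacing`), `sampler` (`box_side`, `n_copies` vector, `n_sweeps`,
#'   `n_equil`, `sample_every`), `mu` (`n_orientations`, `temps_celsius`,
#'   `tail_correct`), `phase` (`rho_range`), `b2` (`box_side`,
#'   `angular_resolution`, `temps_celsius`, `spacing`), `seed`.
#' @param out_dir optional output directory for CSV artifacts and the JSON
#'   manifest.
#' @return list with `molecule`, `mu_table` (per concentration x
#'   temperature), `polys`, `diagram`, `b2`, `vl_tc`, `manifest`.
#' @export
pipeline_run <- function(config, out_dir = NULL) {
  seed <- config$seed %||% 1
  params <- do.call(energy_params, config$energy %||% list())
  mol <- if (!is.null(config$molecule$pqr)) {
    read_pqr(config$molecule$pqr)
  } else {
    do.call(make_toy, config$molecule$toy %||% list(kind = "sphere"))
  }
  smp <- config$sampler %||% list()
  box <- smp$box_side %||% 60
  n_copies <- smp$n_copies %||% c(1, 2, 3, 4, 5, 6)
  mu_cfg <- config$mu %||% list()
  temps <- mu_cfg$temps_celsius %||% seq(-2, 50, by = 13)
  n_ori <- mu_cfg$n_orientations %||% 8
  grid <- grid_spec(box, (config$grid$spacing %||% 1))
  mass <- molecule_mass(mol)

  mu_rows <- list()
  hists <- list()
  for (nc in n_copies) {
    cfg0 <- init_config(nc, box, mol, seed = seed + nc)
    traj <- run_sampler(cfg0, mol, params,
                        n_sweeps = smp$n_sweeps %||% 50,
                        n_equil = smp$n_equil %||% 25,
                        sample_every = smp$sample_every %||% 5,
                        seed = seed + 1000 + nc)
    hist <- accumulate_insertions(traj, mol, n_orientations = n_ori,
                                  grid = grid, params = params,
                                  seed = seed + 2000 + nc,
                                  temps_celsius = temps)
    hists[[as.character(nc)]] <- hist
    rho <- concentration_mg_ml(nc, box, mass)
    for (tc in temps) {
      mp <- mu_ex_raw(hist, celsius_to_kelvin(tc))
      corrected <- FALSE
      if (isTRUE(mu_cfg$tail_correct)) {
        mp <- tryCatch({
          cdfm <- fit_log_cdf(cdf_from_hist(hist))
          um <- umin_from_fcf(hist$f_CF, cdfm)
          corrected <- TRUE
          corrected_mu_ex(hist, cdfm, um, celsius_to_kelvin(tc))
        }, error = function(e) mp)
      }
      mu_rows[[length(mu_rows) + 1]] <- data.frame(
        n_copies = nc, concentration = rho, temperature_celsius = tc,
        beta_mu_ex = mp$beta_mu_ex, corrected = corrected, f_CF = hist$f_CF
      )
    }
  }
  mu_table <- do.call(rbind, mu_rows)

  polys <- NULL; diagram <- NULL
  if (length(n_copies) >= 6) {
    polys <- lapply(temps, function(tc) {
      sub <- mu_table[mu_table$temperature_celsius == tc, ]
      fit_mu_polynomial(sub$concentration, sub$beta_mu_ex, tc)
    })
    rho_range <- config$phase$rho_range %||%
      c(min(mu_table$concentration) / 10, max(mu_table$concentration) * 1.2)
    diagram <- build_phase_diagram(polys, rho_range)
  }

  b2 <- NULL; vl <- NULL
  if (!is.null(config$b2)) {
    b2c <- config$b2
    b2 <- fmapb2(mol, box_side = b2c$box_side %||% 40,
                 spacing = b2c$spacing %||% 1,
                 angular_resolution = b2c$angular_resolution %||% 30,
                 params = params,
                 temps_celsius = b2c$temps_celsius %||% seq(-10, 60, 5),
                 mass = mass)
    vl <- vliegenthart_lekkerkerker_tc(b2$table$temperature_celsius,
                                       b2$table$B2_over_Vst)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phasemap")),
    seed = seed, molecule = mol$label, mass_Da = mass,
    energy = params[c("s1", "s2", "dielectric", "ionic_strength",
                      "cutoff", "kappa")],
    grid = list(box_side = box, spacing = grid$h, n_per_dim = grid$n_per_dim),
    sampler = list(n_copies = n_copies, n_sweeps = smp$n_sweeps %||% 50),
    mu = list(n_orientations = n_ori, temps_celsius = temps),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mu_table, file.path(out_dir, "mu_ex.csv"),
                     row.names = FALSE)
    if (!is.null(diagram) && !is.null(diagram$points) &&
        nrow(diagram$points) > 0) {
      utils::write.csv(diagram$points, file.path(out_dir, "binodal.csv"),
                       row.names = FALSE)
    }
    if (!is.null(b2)) {
      utils::write.csv(b2$table, file.path(out_dir, "b2.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(molecule = mol, mu_table = mu_table, polys = polys, diagram = diagram,
       b2 = b2, vl_tc = vl, histograms = hists, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
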
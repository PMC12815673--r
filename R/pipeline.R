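# End-to-end reproducible scenario runs over synthetic data:
# simulation -> image processing -> stoichiometry (+ FRAP, FRET).

# Ground-truth population for each shipped scenario. Both share the same
# total composition; they differ only in which orders are mobile, which is
# exactly the confound aperture-based stoichiometry is subject to:
#  - control: every order mobile with probability 0.86, so the overall
#    mobile fraction is 86%.
#  - cholesterol_depleted: trimers and tetramers immobilised, monomers and
#    dimers mobile with probability 0.9, so the overall mobile fraction is
#    0.9 * (0.55 + 0.25) = 72%.
scenario_mixture <- function(scenario, fractions = c(0.55, 0.25, 0.15, 0.05)) {
  switch(scenario,
         control = oligomer_mixture(fractions,
                                    mobile_fraction_by_order = 0.86),
         cholesterol_depleted = oligomer_mixture(
           fractions, mobile_fraction_by_order = c(0.9, 0.9, 0, 0)),
         stop_arg("unknown scenario '", scenario, "'"))
}

default_run_config <- function() {
  list(
    seed = 1L,
    scenario = "control",
    camera = list(offset = 100, gain = 2, readout_sd = 1, em_excess = TRUE),
    psf = list(sigma_px = 1.1, pixel_size_nm = 160),
    brightness = list(mean = 400, cv = 0.35),
    field = list(density_per_um2 = 0.4, field_size_um = 16,
                 diffusion_um2_s = 0.1),
    fractions = c(0.55, 0.25, 0.15, 0.05),
    protocol = list(bleach_ms = 2000, recovery_s = 15),
    n_runs = 10L,
    n_calibration_frames = 10L,
    calibration_density_per_um2 = 0.05,
    detection = list(threshold = 3, min_separation_px = NULL,
                     aperture_margin_um = 0.5),
    stoichiometry = list(bin_width = NULL, n_max = 4L,
                         bootstrap_fraction = 0.5, bootstrap_reps = 100L),
    frap = list(K_per_s = 0.02, I0 = 1000, noise_sd = 0.02,
                t_max_s = 400, dt_s = 10),
    fret = list(coupling = list(control = 0.10, cholesterol_depleted = 0.15),
                n_rois = 20L, intensity = 100, noise_sd = 0.05)
  )
}

check_unknown_keys <- function(x, ref, path = "") {
  errs <- character(0)
  for (k in names(x)) {
    if (!k %in% names(ref)) {
      errs <- c(errs, paste0("unknown key: ", path, k))
    } else if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
               is.list(x[[k]])) {
      errs <- c(errs, check_unknown_keys(x[[k]], ref[[k]],
                                         paste0(path, k, "$")))
    }
  }
  errs
}

#' Validate and normalize a run configuration
#'
#' Fills defaults (2000 ms bleach, 15 s recovery, 50%/100-rep bootstrap,
#' n_max = 4, the control scenario) into a partial configuration, coerces
#' types, and returns a human-readable error list on failure. Unknown keys
#' are errors, never silently ignored.
#'
#' @param config A list, a path to a JSON file, or \code{NULL}/empty list for
#'   a fully defaulted configuration.
#' @return The normalized configuration list (with attribute \code{hash}),
#'   or an error listing every offending key.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_arg("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop_arg("'config' must be a list or a JSON path")
  defaults <- default_run_config()
  errs <- check_unknown_keys(config, defaults)
  if (length(errs)) stop_arg(paste(errs, collapse = "; "))
  cfg <- utils::modifyList(defaults, config)
  if (is.character(cfg$seed)) {
    coerced <- suppressWarnings(as.integer(cfg$seed))
    if (is.na(coerced)) errs <- c(errs, "seed: not coercible to integer")
    else {
      warning("seed given as string; coerced to integer", call. = FALSE)
      cfg$seed <- coerced
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed))
    errs <- c(errs, "seed: must be a single integer")
  if (!cfg$scenario %in% c("control", "cholesterol_depleted"))
    errs <- c(errs, "scenario: must be 'control' or 'cholesterol_depleted'")
  pos <- c("camera$gain" = cfg$camera$gain,
           "psf$sigma_px" = cfg$psf$sigma_px,
           "psf$pixel_size_nm" = cfg$psf$pixel_size_nm,
           "brightness$mean" = cfg$brightness$mean,
           "field$density_per_um2" = cfg$field$density_per_um2,
           "field$field_size_um" = cfg$field$field_size_um,
           "protocol$bleach_ms" = cfg$protocol$bleach_ms,
           "frap$K_per_s" = cfg$frap$K_per_s,
           "calibration_density_per_um2" = cfg$calibration_density_per_um2)
  for (k in names(pos))
    if (!is.numeric(pos[[k]]) || pos[[k]] <= 0)
      errs <- c(errs, paste0(k, ": must be > 0"))
  if (abs(sum(cfg$fractions) - 1) > 1e-8)
    errs <- c(errs, "fractions: must sum to 1")
  if (length(errs)) stop_arg(paste(errs, collapse = "; "))
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_runs <- as.integer(cfg$n_runs)
  cfg$n_calibration_frames <- as.integer(cfg$n_calibration_frames)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Run a full synthetic scenario end to end
#'
#' Generates the scenario's synthetic data (TOCCSL image sequences on
#' \code{n_runs} simulated cells plus sparse monomer calibration frames and
#' a FRAP trace and FRET triplets), processes the images to a brightness
#' table, fits the oligomer mixture with bootstrap uncertainties, fits the
#' FRAP mobile fraction, and summarizes NFRET — all under one integer seed,
#' so that a rerun with the same configuration is bit-identical. When
#' \code{outdir} is given, artifacts (TIFF stacks, CSV tables, JSON results
#' stamped with the config hash) are written there.
#'
#' @param config A configuration list or JSON path (see
#'   \code{\link{validate_config}}).
#' @param outdir Optional output directory.
#' @return Results list of class \code{scenario_result}; element
#'   \code{results} is the JSON-serializable record.
#' @export
run_scenario <- function(config = list(), outdir = NULL) {
  cfg <- validate_config(config)
  camera <- camera_model(cfg$camera$offset, cfg$camera$gain,
                         cfg$camera$readout_sd, cfg$camera$em_excess)
  psf <- psf_model(cfg$psf$sigma_px, cfg$psf$pixel_size_nm)
  bmodel <- monomer_brightness_model(cfg$brightness$mean, cfg$brightness$cv)
  mixture <- scenario_mixture(cfg$scenario, cfg$fractions)
  L <- cfg$field$field_size_um
  px_um <- psf$pixel_size_nm / 1000
  min_sep <- cfg$detection$min_separation_px
  if (is.null(min_sep)) min_sep <- 4 * psf$sigma_px

  with_seed(cfg$seed, {
    # --- monomer calibration frames (sparse, monomeric) ------------------
    cal_mix <- oligomer_mixture(1, mobile_fraction_by_order = 1)
    cal_frames <- lapply(seq_len(cfg$n_calibration_frames), function(i) {
      f <- build_molecule_field(cal_mix, cfg$calibration_density_per_um2, L,
                                cfg$field$diffusion_um2_s)
      render_frame(f, psf, camera, bmodel)
    })

    # --- TOCCSL runs ------------------------------------------------------
    protocol <- toccsl_protocol(bleach_ms = cfg$protocol$bleach_ms,
                                recovery_s = cfg$protocol$recovery_s)
    runs <- lapply(seq_len(cfg$n_runs), function(r) {
      f <- build_molecule_field(mixture, cfg$field$density_per_um2, L,
                                cfg$field$diffusion_um2_s)
      simulate_toccsl_sequence(f, protocol, psf, camera, bmodel)
    })
    aperture <- runs[[1]]$aperture
    margin <- cfg$detection$aperture_margin_um
    aperture_px <- (c(aperture[1] + margin, aperture[2] - margin)) / px_um

    frames <- c(cal_frames,
                unlist(lapply(runs, function(r)
                  r$frames[c("prebleach", "toccsl")]), recursive = FALSE))
    roles <- c(rep("calibration", length(cal_frames)),
               rep(c("prebleach", "toccsl"), length(runs)))
    btab <- extract_brightness_table(frames, roles, camera,
                                     expected_sigma = psf$sigma_px,
                                     threshold = cfg$detection$threshold,
                                     min_separation = min_sep,
                                     aperture_px = aperture_px)

    sto <- analyze_toccsl_run(
      btab, btab,
      config = list(bin_width = cfg$stoichiometry$bin_width,
                    n_max = cfg$stoichiometry$n_max,
                    bootstrap_fraction = cfg$stoichiometry$bootstrap_fraction,
                    bootstrap_reps = cfg$stoichiometry$bootstrap_reps,
                    seed = cfg$seed,
                    prebleach_area_um2 = L^2))

    # --- ledger composition ----------------------------------------------
    ledger <- do.call(rbind, lapply(seq_along(runs), function(i)
      cbind(run = i, runs[[i]]$ledger)))
    n_max <- cfg$stoichiometry$n_max
    comp <- function(orders) {
      if (length(orders) == 0) return(rep(NA_real_, n_max))
      tabulate(orders, nbins = n_max) / length(orders)
    }
    total_comp <- comp(ledger$order)
    analyzable_comp <- comp(ledger$order[ledger$analyzable])

    # --- FRAP -------------------------------------------------------------
    mf_true <- mixture_mobile_fraction(mixture)
    trace <- simulate_frap_trace(mf_true, cfg$frap$K_per_s, cfg$frap$I0,
                                 times = seq(0, cfg$frap$t_max_s,
                                             by = cfg$frap$dt_s),
                                 noise_sd = cfg$frap$noise_sd)
    frap <- fit_frap(normalize_frap_trace(trace, cfg$frap$I0))

    # --- FRET -------------------------------------------------------------
    coupling <- cfg$fret$coupling[[cfg$scenario]]
    bt <- bleedthrough()
    triplets <- do.call(rbind, lapply(seq_len(cfg$fret$n_rois), function(i) {
      iD <- cfg$fret$intensity * stats::rlnorm(1, 0, 0.3)
      iA <- cfg$fret$intensity * stats::rlnorm(1, 0, 0.3)
      simulate_fret_triplet(iD, iA, coupling, bt, cfg$fret$noise_sd)
    }))
    nfret <- compute_nfret(triplets$i_fret, triplets$i_donor,
                           triplets$i_acceptor, bt)
    nfret_sum <- summarize_nfret(data.frame(condition = cfg$scenario,
                                            nfret = nfret))

    results <- list(
      scenario = cfg$scenario,
      seed = cfg$seed,
      config_hash = attr(cfg, "hash"),
      stoichiometry = list(
        alpha = as.numeric(sto$fractions$alpha),
        bootstrap_sd = as.numeric(sto$fractions$sd),
        n_max = n_max,
        n_spots = sto$qc$n_toccsl_spots,
        n_excluded = sto$qc$n_excluded,
        n_calibration_spots = sto$qc$n_calibration_spots,
        density_per_um2 = sto$density_per_um2),
      ledger = list(
        total_composition = as.numeric(total_comp),
        analyzable_composition = as.numeric(analyzable_comp),
        n_molecules = nrow(ledger),
        n_analyzable = sum(ledger$analyzable),
        true_mobile_fraction = mf_true),
      frap = list(mf = frap$mf, K_per_s = frap$K_per_s,
                  se_mf = frap$se_mf, flags = as.list(frap$flags)),
      fret = list(coupling_truth = coupling,
                  mean_nfret_x100 = nfret_sum$mean_x100[1],
                  sd_nfret_x100 = nfret_sum$sd_x100[1],
                  n_rois = nfret_sum$n[1])
    )

    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_stack_tiff(cal_frames, file.path(outdir, "calibration.tif"))
      for (i in seq_along(runs))
        write_stack_tiff(runs[[i]]$frames,
                         file.path(outdir, sprintf("toccsl_run%02d.tif", i)))
      utils::write.csv(btab, file.path(outdir, "brightness_table.csv"),
                       row.names = FALSE)
      utils::write.csv(ledger, file.path(outdir, "ledger.csv"),
                       row.names = FALSE)
      utils::write.csv(trace, file.path(outdir, "frap_trace.csv"),
                       row.names = FALSE)
      write_results_json(results, file.path(outdir, "results.json"))
    }

    structure(list(results = results, brightness_table = btab,
                   ledger = ledger, stoichiometry = sto, frap = frap,
                   config = cfg),
              class = "scenario_result")
  })
}
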
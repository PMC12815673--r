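# Michaelis-Menten, one-site binding, turnover, release, and the
# electrophysiology kinetics summaries.

mm_design <- function(km) km * c(0.1, 0.3, 1, 3, 10, 30)

test_that("Michaelis-Menten fits recover noiseless parameters exactly", {
  d <- simulate_saturation_data(654, 4.4, mm_design(4.4),
                                nonspecific_slope = 5, noise_sd = 0)
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$amplitude, 654, tolerance = 1e-6)
  expect_equal(fit$half_saturation, 4.4, tolerance = 1e-6)
  # model identity: fitted curve at C = Km is Vmax / 2
  v_at_km <- fit$amplitude * fit$half_saturation /
    (fit$half_saturation + fit$half_saturation)
  expect_equal(v_at_km, fit$amplitude / 2)
  expect_error(fit_michaelis_menten(d[d$conc < 2, ]), "concentrations")
})

test_that("Km is recovered within 15% median error at 5% noise", {
  km_err <- vapply(1:100, function(s) {
    d <- simulate_saturation_data(654, 4.4, mm_design(4.4),
                                  noise_sd = 0.05, replicates = 3, seed = s)
    abs(fit_michaelis_menten(d)$half_saturation - 4.4) / 4.4
  }, numeric(1))
  expect_lte(median(km_err), 0.15)
})

test_that("one-site binding fits recover Kd and reject degenerate input", {
  d <- simulate_saturation_data(120, 13.3, mm_design(13.3),
                                nonspecific_slope = 0.4, noise_sd = 0)
  fit <- fit_one_site_binding(d)
  expect_equal(fit$half_saturation, 13.3, tolerance = 1e-6)
  expect_equal(fit$amplitude, 120, tolerance = 1e-6)
  expect_equal(fit$role, "Bmax")

  d$nonspecific <- d$total  # specific binding identically zero
  expect_error(fit_one_site_binding(d), "degenerate")
})

test_that("turnover is the Vmax/Bmax ratio with delta-method errors", {
  v <- toccsl:::saturation_fit(100, 4, 10, 1, "Vmax")
  b <- toccsl:::saturation_fit(50, 13, 5, 1, "Bmax")
  tr <- turnover_rate(v, b)
  expect_equal(tr$turnover_per_min, 2)
  expect_equal(tr$se, 2 * sqrt((10 / 100)^2 + (5 / 50)^2))

  b2 <- toccsl:::saturation_fit(100, 13, 10, 1, "Bmax")
  expect_equal(turnover_rate(v, b2)$turnover_per_min, 1)

  v0 <- toccsl:::saturation_fit(100, 4, 0, 0, "Vmax")
  b0 <- toccsl:::saturation_fit(50, 13, 0, 0, "Bmax")
  expect_equal(turnover_rate(v0, b0)$se, 0)
  expect_error(turnover_rate(b, v), "Vmax")
})

test_that("release normalization conserves counts and normalizes to basal", {
  plate <- data.frame(condition = c("basal", "basal", "amph", "amph", "block"),
                      cells = c(800, 820, 600, 580, 920),
                      supernatant = c(200, 180, 400, 420, 80))
  res <- normalize_release(plate, basal = "basal", blocker = "block")
  s <- res$summary
  expect_equal(s$released_percent[s$condition == "basal"], 19, tolerance = 1e-9)
  expect_equal(s$normalized[s$condition == "basal"], 1)
  expect_equal(s$released_percent[s$condition == "amph"], 41, tolerance = 1e-9)
  expect_equal(s$specific_percent[s$condition == "amph"], 41 - 8,
               tolerance = 1e-9)
  expect_true(all(abs(s$mean_total - 1000) < 1e-9))

  # doubled stimulated fraction on a synthetic plate gives normalized ~ 2
  p <- simulate_release_plate(c(basal = 0.1, stim = 0.2), total = 8000,
                              wells = 6, noise_sd = 0.03, seed = 5)
  r <- normalize_release(p, basal = "basal")
  expect_lt(abs(r$summary$normalized[r$summary$condition == "stim"] - 2),
            0.15)

  # zero-total wells are excluded, not propagated
  plate2 <- rbind(plate, data.frame(condition = "amph", cells = 0,
                                    supernatant = 0))
  expect_message(res2 <- normalize_release(plate2, basal = "basal"),
                 "excluded")
  expect_equal(res2$excluded_wells, 1)
})

test_that("steady-state dose response is normalized per cell then fitted", {
  conc <- c(0.1, 0.3, 1, 3, 10)
  hyper <- function(C, A, k) A * C / (k + C)
  cells <- do.call(rbind, lapply(1:3, function(cell) {
    scale <- c(1, 2.5, 0.4)[cell]  # cell-to-cell amplitude variation
    data.frame(cell = cell, conc = conc,
               amplitude = scale * hyper(conc, 1.8, 0.64))
  }))
  fit <- fit_steady_state_dose(cells, ref_conc = 10)
  expect_equal(fit$half_saturation, 0.64, tolerance = 1e-6)
  expect_equal(attr(fit, "n_cells"), 3)

  # a cell without the reference pulse is excluded
  cells2 <- rbind(cells, data.frame(cell = 4, conc = c(0.1, 1),
                                    amplitude = c(0.2, 0.9)))
  fit2 <- fit_steady_state_dose(cells2, ref_conc = 10)
  expect_equal(attr(fit2, "n_cells"), 3)

  expect_error(fit_steady_state_dose(
    data.frame(cell = 1, conc = 10, amplitude = 1), ref_conc = 10),
    "concentrations")
})

test_that("relaxation kinetics yield k_on from the initial slope", {
  conc <- c(0.5, 1, 2, 5, 10, 30)
  d <- data.frame(conc = conc, rate = 2 + 7.78 * conc)
  ks <- fit_relaxation_kinetics(d)
  expect_equal(ks$k_on, 7.78, tolerance = 1e-9)
  expect_length(ks$flags, 0)

  flat <- data.frame(conc = conc, rate = 5)
  ksf <- fit_relaxation_kinetics(flat)
  expect_equal(ksf$k_on, 0, tolerance = 1e-12)
  expect_true("no_association" %in% ksf$flags)

  expect_error(fit_relaxation_kinetics(d[1:2, ]), "at least")

  # hyperbola-generated rates: the 3-point secant underestimates the true
  # initial slope k_max / k_0.5 and converges to it as the design shrinks
  k_max <- 40; k05 <- 2
  slope_for <- function(cmax) {
    cs <- cmax * c(0.25, 0.5, 1, 5, 20)
    d <- data.frame(conc = cs, rate = k_max * cs / (k05 + cs))
    fit_relaxation_kinetics(d)$k_on
  }
  tangent <- k_max / k05
  s_wide <- slope_for(2)
  s_tight <- slope_for(0.004)
  expect_lt(s_wide, tangent)
  expect_lt(s_tight, tangent)
  expect_lt(abs(s_tight - tangent) / tangent, 0.01)
  expect_gt(s_tight, s_wide)
})

test_that("peak recovery fits a mono-exponential rise to maximum", {
  t <- c(1, 2, 5, 10, 20, 40)
  d <- data.frame(interval_s = t, amplitude = 0.95 * (1 - exp(-0.11 * t)))
  fit <- fit_peak_recovery(d)
  expect_equal(fit$k_per_s, 0.11, tolerance = 1e-6)
  expect_equal(fit$A_max, 0.95, tolerance = 1e-6)

  # rate is invariant to amplitude rescaling
  d2 <- transform(d, amplitude = 3.7 * amplitude)
  expect_equal(fit_peak_recovery(d2)$k_per_s, fit$k_per_s, tolerance = 1e-6)

  flat <- data.frame(interval_s = t, amplitude = 1)
  ff <- fit_peak_recovery(flat)
  expect_true("k_unidentifiable" %in% ff$flags)
  expect_true(is.na(ff$k_per_s))
})
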
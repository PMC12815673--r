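# Synthetic-data generator: brightness draws, molecule fields, frame
# rendering, the TOCCSL sequence, and the trace/assay generators.

test_that("monomer brightness sampling is correct and reproducible", {
  deg <- monomer_brightness_model(mean = 250, cv = 0)
  expect_equal(sample_monomer_brightness(deg, 20), rep(250, 20))

  m <- monomer_brightness_model(mean = 400, cv = 0.35)
  s <- sample_monomer_brightness(m, 1e5, seed = 42)
  expect_true(all(s > 0))
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 400), 3 * se)

  expect_identical(sample_monomer_brightness(m, 1000, seed = 7),
                   sample_monomer_brightness(m, 1000, seed = 7))
  expect_error(sample_monomer_brightness(m, 0), "n_samples")
})

test_that("molecule fields follow the mixture, density and mobility rules", {
  mono <- oligomer_mixture(1)
  f <- build_molecule_field(mono, density = 2, field_size = 10, seed = 1)
  expect_true(all(f$order == 1L))
  expect_true(all(f$x >= 0 & f$x <= 10 & f$y >= 0 & f$y <= 10))

  mix <- oligomer_mixture(c(0.4, 0.3, 0.2, 0.1),
                          mobile_fraction_by_order = c(1, 1, 0, 0))
  f <- build_molecule_field(mix, density = 5, field_size = 10, seed = 2)
  expect_true(all(!f$mobile[f$order >= 3]))
  expect_true(all(f$d_um2_s[!f$mobile] == 0))
  expect_true(all(f$n_active <= f$order))

  counts <- vapply(1:200, function(s)
    nrow(build_molecule_field(mono, 0.5, 10, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 200))

  expect_error(oligomer_mixture(c(0.5, 0.4)), "sum to 1")
})

test_that("realized molecule counts follow the Poisson law", {
  mono <- oligomer_mixture(1)
  lambda <- 0.5 * 100
  counts <- vapply(1:150, function(s)
    nrow(build_molecule_field(mono, 0.5, 10, seed = 1000 + s)), numeric(1))
  # chi-square GOF against Poisson(lambda), tails pooled to keep expected
  # counts reasonable
  brk <- c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), lambda), Inf)
  obs <- table(cut(counts, brk))
  p <- diff(ppois(brk, lambda))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("rendered frames implement the forward model exactly", {
  cam <- noiseless_camera()
  psf <- test_psf()
  empty <- manual_field(numeric(0), numeric(0), integer(0), numeric(0),
                        field_size = 3.2)
  fr <- render_frame(empty, psf, cam, noise = FALSE)
  expect_true(all(fr == cam$offset))

  one <- manual_field(1.6, 1.6, 1L, 400, field_size = 3.2)
  fr <- render_frame(one, psf, cam, noise = FALSE)
  expect_lt(abs((sum(fr) - cam$offset * length(fr)) - cam$gain * 400),
            0.01 * cam$gain * 400)

  dimer <- manual_field(1.6, 1.6, 2L, 400, field_size = 3.2)
  fr2 <- render_frame(dimer, psf, cam, noise = FALSE)
  expect_equal(attr(fr2, "flux"), 2 * attr(fr, "flux"))
  expect_equal(sum(fr2) - cam$offset * length(fr2),
               2 * (sum(fr) - cam$offset * length(fr)), tolerance = 1e-12)
})

test_that("n-mer flux equals the sum of n monomer draws", {
  m <- monomer_brightness_model(400, 0.35)
  mix <- oligomer_mixture(c(0.25, 0.25, 0.25, 0.25))
  f <- build_molecule_field(mix, density = 0.2, field_size = 10, seed = 3)
  fr <- render_frame(f, test_psf(), noiseless_camera(),
                     brightness_model = m, noise = FALSE, seed = 99)
  flux <- attr(fr, "flux")
  # reproduce the per-fluorophore draws independently under the same seed
  set.seed(99)
  draws <- rlnorm(sum(f$n_active), m$meanlog, m$sdlog)
  expected <- as.numeric(tapply(draws, rep(seq_len(nrow(f)), f$n_active), sum))
  expect_equal(flux, expected, tolerance = 1e-12)
})

test_that("TOCCSL sequence bleaches the aperture and moves only mobile molecules", {
  cam <- noiseless_camera()
  psf <- test_psf()
  m <- monomer_brightness_model(400, 0.35)
  protocol <- toccsl_protocol()

  immob <- oligomer_mixture(c(0.6, 0.4), mobile_fraction_by_order = 0)
  f <- build_molecule_field(immob, 0.5, 12.8, seed = 4)
  seq1 <- simulate_toccsl_sequence(f, protocol, psf, cam, m, noise = FALSE,
                                   seed = 4)
  ap_px <- seq1$aperture / (psf$pixel_size_nm / 1000)
  # clear the renderer's +-5 sigma patch reach of molecules just outside
  margin <- ceiling(5 * psf$sigma_px) + 2
  cols <- (floor(ap_px[1]) + margin):(ceiling(ap_px[2]) - margin)
  expect_true(all(abs(seq1$frames$toccsl[, cols] - cam$offset) < 1e-6))
  expect_true(all(abs(seq1$frames$postbleach_control[, cols] - cam$offset) < 1e-6))
  expect_equal(sum(seq1$ledger$analyzable), 0)
  # conservation: bleaching only changed molecules inside the aperture
  expect_equal(nrow(seq1$ledger), nrow(f))
  changed <- seq1$ledger$n_active != seq1$ledger$n_active_pre
  expect_true(all(seq1$ledger$bleached[changed]))
  # immobile molecules never move
  expect_equal(seq1$ledger$x, seq1$ledger$x0, tolerance = 1e-12)

  # mobile monomers, very long recovery: uniform redistribution of the
  # unbleached pool, so E[analyzable] = N_unbleached * aperture fraction
  mob <- oligomer_mixture(1, mobile_fraction_by_order = 1)
  long <- toccsl_protocol(recovery_s = 1e5, aperture = c(4, 8))
  stats <- vapply(1:50, function(s) {
    f <- build_molecule_field(mob, 1, 16, seed = 100 + s)
    sq <- simulate_toccsl_sequence(f, long, psf, cam, m, noise = FALSE,
                                   seed = 100 + s)
    c(sum(sq$ledger$analyzable), sum(!sq$ledger$bleached))
  }, numeric(2))
  ap_frac <- 4 / 16
  expect_lt(abs(mean(stats[1, ]) - ap_frac * mean(stats[2, ])),
            3 * sqrt(mean(stats[1, ]) / 50))
})

test_that("FRAP traces follow the one-phase association model", {
  tr <- simulate_frap_trace(mf = 0.5, K = 0.1, I0 = 100, noise_sd = 0)
  expect_equal(tr$intensity[tr$time_s == 0], 0)

  late <- simulate_frap_trace(mf = 0.7, K = 5, I0 = 1, times = c(0, 100, 400),
                              noise_sd = 0)
  expect_equal(late$intensity[late$time_s == 400], 0.7, tolerance = 1e-9)

  # direct evaluation at t = log(2)/K: 0.86 * (1 - e^{-0.6932}) = 0.430
  tr <- simulate_frap_trace(mf = 0.86, K = 0.02, I0 = 1,
                            times = c(0, 34.66), noise_sd = 0)
  expect_equal(tr$intensity[2], 0.430, tolerance = 1e-3)
  expect_error(simulate_frap_trace(mf = 1.2, K = 0.1), "mf")
})

test_that("FRET triplets invert to the generating coupling", {
  bt <- bleedthrough(0.57, 0.04)
  t0 <- simulate_fret_triplet(100, 100, 0, bt, noise_sd = 0)
  expect_equal(compute_nfret(t0$i_fret, t0$i_donor, t0$i_acceptor, bt), 0)

  t1 <- simulate_fret_triplet(100, 100, 0.2, bt, noise_sd = 0)
  expect_equal(t1$i_fret, 81)  # 57 + 4 + 20

  t10 <- simulate_fret_triplet(1000, 1000, 0.2, bt, noise_sd = 0)
  expect_equal(compute_nfret(t10$i_fret, t10$i_donor, t10$i_acceptor, bt),
               compute_nfret(t1$i_fret, t1$i_donor, t1$i_acceptor, bt),
               tolerance = 1e-12)
  expect_error(simulate_fret_triplet(100, 100, -0.1), "coupling")
})

test_that("saturation data generator honours the hyperbola identities", {
  d <- simulate_saturation_data(654, 4.4, concentrations = 4.4,
                                noise_sd = 0)
  expect_equal(d$total, 327)  # half-max at C = Km

  d <- simulate_saturation_data(100, 2, concentrations = c(2, 2e6),
                                noise_sd = 0)
  expect_equal(d$total[1], 50)
  expect_equal(d$total[2], 100, tolerance = 1e-4)
})

test_that("release plates conserve totals and fractions", {
  p <- simulate_release_plate(c(basal = 0.2), total = 1000, wells = 1,
                              noise_sd = 0)
  expect_equal(p$cells, 800)
  expect_equal(p$supernatant, 200)

  p <- simulate_release_plate(c(basal = 0.1, stim = 0.1), total = 5000,
                              wells = 3, noise_sd = 0)
  expect_true(all(p$cells + p$supernatant == 5000))
  r <- normalize_release(p, basal = "basal")
  expect_equal(r$summary$normalized[r$summary$condition == "stim"], 1)
  expect_error(simulate_release_plate(c(a = 1.2)), "fractions")
})

test_that("generators are deterministic under a fixed seed", {
  m <- monomer_brightness_model(400, 0.35)
  mix <- oligomer_mixture(c(0.5, 0.5))
  f1 <- build_molecule_field(mix, 0.5, 10, seed = 5)
  f2 <- build_molecule_field(mix, 0.5, 10, seed = 5)
  expect_identical(f1, f2)
  r1 <- render_frame(f1, test_psf(), camera_model(), brightness_model = m,
                     seed = 6)
  r2 <- render_frame(f2, test_psf(), camera_model(), brightness_model = m,
                     seed = 6)
  expect_identical(r1, r2)
  expect_identical(simulate_frap_trace(0.8, 0.02, noise_sd = 0.05, seed = 8),
                   simulate_frap_trace(0.8, 0.02, noise_sd = 0.05, seed = 8))
})
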
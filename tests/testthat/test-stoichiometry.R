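# Monomer PDF estimation, autoconvolution, mixture fitting, bootstrap.

test_that("monomer PDF estimation produces a normalized histogram", {
  s <- rep(123, 500)
  rho <- estimate_monomer_pdf(s, bin_width = 10, n_max = 4)
  expect_equal(sum(rho$mass), 1, tolerance = 1e-12)
  expect_equal(sum(rho$mass > 0), 1)

  set.seed(11)
  s <- rlnorm(1e4, log(400), 0.3)
  rho <- estimate_monomer_pdf(s, n_max = 4)
  se <- sd(s) / sqrt(length(s))
  # bin-center mean is within half a bin width of the sample mean anyway;
  # 3 SE plus half a bin covers discretisation
  expect_lt(abs(pdf_mean(rho) - mean(s)), 3 * se + rho$width / 2)

  expect_error(estimate_monomer_pdf(numeric(0)), "samples")
  expect_error(estimate_monomer_pdf(rep(1, 50)), ">= 100")
})

test_that("autoconvolution matches enumeration and preserves mass and mean", {
  # two-point distribution on bin centers 1 and 2 (width 1)
  rho <- brightness_pdf(c(0.5, 0.5), width = 1, offset = 0.5)
  rho2 <- autoconvolve(rho, 2)
  expect_equal(pdf_centers(rho2), c(2, 3, 4))
  expect_equal(rho2$mass, c(0.25, 0.5, 0.25), tolerance = 1e-15)

  expect_identical(autoconvolve(rho, 1), rho)

  set.seed(12)
  m <- runif(30); m <- m / sum(m)
  rho <- brightness_pdf(m, width = 7.5, offset = 0)
  for (n in 2:4) {
    rn <- autoconvolve(rho, n)
    expect_equal(sum(rn$mass), 1, tolerance = 1e-12)
    expect_equal(pdf_mean(rn), n * pdf_mean(rho), tolerance = 1e-9)
  }
})

test_that("autoconvolution equals brute-force outcome enumeration", {
  set.seed(13)
  for (npts in 2:4) {
    for (n in 2:4) {
      mass <- runif(npts)
      mass <- mass / sum(mass)
      rho <- brightness_pdf(mass, width = 1, offset = 0.5)
      rn <- autoconvolve(rho, n)
      oracle <- brute_force_autoconv(rho, n, rn)
      expect_lt(max(abs(rn$mass - oracle)), 1e-12)
    }
  }
})

test_that("mixture fitting recovers weights and satisfies the constraints", {
  m <- monomer_brightness_model(400, 0.35)
  set.seed(14)
  cal <- sample_monomer_brightness(m, 3000)
  rho1 <- estimate_monomer_pdf(cal, n_max = 4)

  # samples from rho1 itself are classified as monomers
  fit <- fit_mixture(sample_monomer_brightness(m, 5000), rho1, 4)
  expect_gte(fit$alpha[1], 0.95)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-6)

  # 50/50 monomer/dimer mixture over 20 seeds
  a2 <- vapply(1:20, function(s) {
    set.seed(100 + s)
    B <- draw_mixture_sample(m, c(0.5, 0.5), 5000)
    fit_mixture(B, rho1, 4)$alpha[2]
  }, numeric(1))
  expect_lt(abs(mean(a2) - 0.5), 0.05)

  # n_max = 1 forces a pure monomer answer
  fit1 <- fit_mixture(draw_mixture_sample(m, c(0.5, 0.5), 500), rho1, 1)
  expect_equal(fit1$alpha, 1)

  # deterministic: repeated fits on the same input are identical
  B <- draw_mixture_sample(m, c(0.7, 0.3), 2000)
  expect_identical(fit_mixture(B, rho1, 4), fit_mixture(B, rho1, 4))

  # least-squares mode agrees roughly with ML on clean data
  fls <- fit_mixture(B, rho1, 4, method = "ls")
  fml <- fit_mixture(B, rho1, 4)
  expect_lt(max(abs(fls$alpha - fml$alpha)), 0.05)
})

test_that("spots brighter than the n_max envelope are excluded, not fitted", {
  m <- monomer_brightness_model(400, 0.1)
  set.seed(15)
  cal <- sample_monomer_brightness(m, 2000)
  rho1 <- estimate_monomer_pdf(cal, n_max = 2)
  B <- c(sample_monomer_brightness(m, 500), rep(5000, 7))
  fit <- fit_mixture(B, rho1, 2)
  expect_equal(fit$n_excluded, 7)
  expect_equal(fit$n_used, 500)
})

test_that("higher dimer content increases mean brightness in expectation", {
  m <- monomer_brightness_model(400, 0.35)
  means <- vapply(c(0.1, 0.3, 0.5, 0.7), function(a2) {
    mean(vapply(1:10, function(s) {
      set.seed(200 + round(100 * a2) + s)
      mean(draw_mixture_sample(m, c(1 - a2, a2), 2000))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("bootstrap SDs behave as subsampling theory predicts", {
  m <- monomer_brightness_model(400, 0.35)
  set.seed(16)
  cal <- sample_monomer_brightness(m, 2000)
  rho1 <- estimate_monomer_pdf(cal, n_max = 4)

  # degenerate pure-monomer data: every subsample gives alpha = (1,0,0,0)
  deg <- monomer_brightness_model(400, 0)
  rho_deg <- estimate_monomer_pdf(rep(400, 500), bin_width = 10, n_max = 4)
  boot <- bootstrap_fractions(rep(400, 400), rho_deg, 4, seed = 1)
  expect_equal(boot$sd, rep(0, 4))

  # SDs shrink with sample size, same truth and seed bank
  B_small <- draw_mixture_sample(m, c(0.6, 0.4), 500)
  B_large <- draw_mixture_sample(m, c(0.6, 0.4), 5000)
  b_small <- bootstrap_fractions(B_small, rho1, 4, seed = 2, reps = 50)
  b_large <- bootstrap_fractions(B_large, rho1, 4, seed = 2, reps = 50)
  expect_lt(mean(b_large$sd), mean(b_small$sd))

  # fixed seed reproduces SDs exactly; defaults are 50% and 100 reps
  b1 <- bootstrap_fractions(B_small, rho1, 4, seed = 3)
  b2 <- bootstrap_fractions(B_small, rho1, 4, seed = 3)
  expect_identical(b1$sd, b2$sd)
  expect_equal(nrow(b1$alphas), 100)
  expect_error(bootstrap_fractions(B_small, rho1, 4, reps = 1), "reps")
})

test_that("analyze_toccsl_run chains the stages and reports QC", {
  cam <- noiseless_camera()
  psf <- test_psf()
  m <- monomer_brightness_model(400, 0.35)
  mono <- oligomer_mixture(1)
  frames <- lapply(1:12, function(s)
    render_frame(build_molecule_field(mono, 0.06, 16, seed = 40 + s),
                 psf, cam, brightness_model = m, noise = FALSE,
                 seed = 40 + s))
  tab <- extract_brightness_table(frames, rep("calibration", 12), cam,
                                  expected_sigma = psf$sigma_px,
                                  threshold = 3)
  # calibration table reused as the TOCCSL table: monomer-dominated answer
  tab2 <- tab
  tab2$frame_role <- "toccsl"
  res <- analyze_toccsl_run(tab2, tab, config = list(seed = 1))
  expect_gte(res$fractions$alpha[1], 0.9)
  expect_equal(sum(res$fractions$alpha), 1, tolerance = 1e-6)
  expect_equal(res$qc$n_toccsl_spots, res$qc$n_calibration_spots)
  expect_error(analyze_toccsl_run(tab2, tab, config = list(bogus = 1)),
               "unknown config")
})
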
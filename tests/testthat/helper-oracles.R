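# Independent oracles and small fixture builders used across the suite.

# Brute-force n-fold autoconvolution of a discrete brightness distribution:
# enumerate every n-tuple of bin-center outcomes, sum values, multiply
# probabilities, and accumulate the mass onto the grid of a reference
# brightness_pdf by nearest bin center. Independent of the production
# convolution path.
brute_force_autoconv <- function(rho, n, out_grid) {
  centers <- pdf_centers(rho)
  occ <- which(rho$mass > 0)
  combos <- expand.grid(rep(list(occ), n))
  out_centers <- pdf_centers(out_grid)
  mass <- numeric(length(out_centers))
  for (r in seq_len(nrow(combos))) {
    idx <- as.integer(combos[r, ])
    v <- sum(centers[idx])
    p <- prod(rho$mass[idx])
    k <- which.min(abs(out_centers - v))
    mass[k] <- mass[k] + p
  }
  mass
}

# Tiny in-memory molecule field with fixed per-fluorophore brightness,
# bypassing the stochastic generator for exact forward-model tests.
manual_field <- function(x, y, n_active, brightness, field_size,
                         order = n_active, mobile = FALSE) {
  mobile <- rep_len(mobile, length(x))
  f <- data.frame(x = x, y = y, order = as.integer(order),
                  n_active = as.integer(n_active),
                  mobile = mobile, d_um2_s = ifelse(mobile, 0.1, 0),
                  brightness = rep_len(brightness, length(x)))
  attr(f, "field_size") <- field_size
  class(f) <- c("molecule_field", "data.frame")
  f
}

noiseless_camera <- function(gain = 2, offset = 100)
  camera_model(offset = offset, gain = gain, readout_sd = 0,
               em_excess = FALSE)

test_psf <- function() psf_model(sigma_px = 1.1, pixel_size_nm = 160)

# Mixed oligomer brightness sample with known composition, drawn directly
# from the monomer model (no imaging): the generator-level oracle for the
# deconvolution stage.
draw_mixture_sample <- function(model, truth, n) {
  ord <- sample(seq_along(truth), n, replace = TRUE, prob = truth)
  vapply(ord, function(k) sum(sample_monomer_brightness(model, k)),
         numeric(1))
}
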
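# Forward imaging model: molecules -> diffraction-limited spots -> EMCCD ADU.
#
# Pixel geometry: the image covers [0, field_size] x [0, field_size] um;
# pixel (ix, iy) (0-based, x = column, y = row) covers
# [ix*px, (ix+1)*px) x [iy*px, (iy+1)*px) um with its center at
# (ix + 0.5, iy + 0.5) * px. Matrices are stored with rows = y, columns = x.

# Exact pixel-integrated 2-D Gaussian: photons deposited by a point emitter
# of total flux `flux` at (x0, y0) um with isotropic sd `sigma_um` into the
# pixels of an `npx` x `npx` image, restricted to a +-5 sigma window.
# Returns list(rows, cols, photons) for sparse accumulation.
spot_photon_patch <- function(x0, y0, flux, sigma_um, px_um, npx) {
  half <- 5 * sigma_um
  cx <- floor(max(0, (x0 - half)) / px_um)
  cx2 <- ceiling(min(npx * px_um, x0 + half) / px_um) - 1
  cy <- floor(max(0, (y0 - half)) / px_um)
  cy2 <- ceiling(min(npx * px_um, y0 + half) / px_um) - 1
  if (cx2 < cx || cy2 < cy) return(NULL)
  ex <- (cx:(cx2 + 1)) * px_um
  ey <- (cy:(cy2 + 1)) * px_um
  fx <- diff(stats::pnorm(ex, mean = x0, sd = sigma_um))
  fy <- diff(stats::pnorm(ey, mean = y0, sd = sigma_um))
  list(rows = (cy:cy2) + 1L, cols = (cx:cx2) + 1L,
       photons = flux * outer(fy, fx))
}

#' Render one camera frame of a molecule field
#'
#' Forward model for diffraction-limited single-molecule images. Each
#' molecule with at least one active fluorophore contributes an integrated
#' photon flux equal to the sum of one independent monomer-brightness draw
#' per active fluorophore (or \code{n_active * brightness} if the field
#' carries a per-fluorophore \code{brightness} column), spread over pixels as
#' an exactly pixel-integrated 2-D Gaussian of the PSF width. Pixel values
#' are then \code{offset + gain * photons} with (optionally) Poisson shot
#' noise, EM excess noise and Gaussian readout noise.
#'
#' @param field A \code{\link{build_molecule_field}} result. An optional
#'   numeric column \code{brightness} fixes the per-fluorophore flux instead
#'   of drawing it.
#' @param psf A \code{\link{psf_model}}.
#' @param camera A \code{\link{camera_model}}.
#' @param brightness_model A \code{\link{monomer_brightness_model}} used when
#'   the field has no \code{brightness} column.
#' @param exposure_scale Relative excitation/exposure factor multiplying all
#'   fluxes (default 1).
#' @param noise Logical; \code{FALSE} renders the noiseless expectation
#'   (still digitised through offset and gain, but with no shot, EM excess or
#'   readout noise).
#' @param seed Optional integer seed.
#' @return Numeric matrix of ADU values (rows = y). Attributes: \code{flux}
#'   (the per-molecule integrated photon flux actually used, 0 for dark
#'   molecules) and \code{pixel_size_um}.
#' @export
render_frame <- function(field, psf, camera, brightness_model = NULL,
                         exposure_scale = 1, noise = TRUE, seed = NULL) {
  if (!inherits(psf, "psf_model")) stop_arg("'psf' must be a psf_model")
  if (!inherits(camera, "camera_model"))
    stop_arg("'camera' must be a camera_model")
  check_scalar(exposure_scale, "exposure_scale", lower = 0)
  field_size <- attr(field, "field_size")
  if (is.null(field_size)) stop_arg("'field' lacks a field_size attribute")
  px_um <- psf$pixel_size_nm / 1000
  sigma_um <- psf$sigma_px * px_um
  npx <- ceiling(field_size / px_um - 1e-9)
  n <- nrow(field)
  with_seed(seed, {
    flux <- numeric(n)
    if (n > 0) {
      if (!is.null(field$brightness)) {
        flux <- field$n_active * field$brightness
      } else {
        if (is.null(brightness_model))
          stop_arg("'brightness_model' required when field has no 'brightness' column")
        total_fluor <- sum(field$n_active)
        draws <- sample_monomer_brightness(brightness_model,
                                           max(1L, total_fluor))
        idx <- rep.int(seq_len(n), field$n_active)
        flux <- as.numeric(tapply(draws[seq_along(idx)], factor(idx, levels = seq_len(n)),
                                  sum, default = 0))
        flux[is.na(flux)] <- 0
      }
      flux <- flux * exposure_scale
    }
    photons <- matrix(0, nrow = npx, ncol = npx)
    for (i in seq_len(n)) {
      if (flux[i] <= 0) next
      if (field$x[i] < 0 || field$x[i] > field_size ||
          field$y[i] < 0 || field$y[i] > field_size)
        stop_arg("molecule position outside field bounds")
      p <- spot_photon_patch(field$x[i], field$y[i], flux[i], sigma_um,
                             px_um, npx)
      if (!is.null(p))
        photons[p$rows, p$cols] <- photons[p$rows, p$cols] + p$photons
    }
    if (noise) {
      lam <- photons
      photons <- matrix(stats::rpois(length(lam), lam),
                        nrow = npx, ncol = npx)
      if (camera$em_excess)
        photons <- photons + stats::rnorm(length(lam), sd = sqrt(lam))
    }
    adu <- camera$offset + camera$gain * photons
    if (noise && camera$readout_sd > 0)
      adu <- adu + stats::rnorm(length(adu), sd = camera$readout_sd)
    attr(adu, "flux") <- flux
    attr(adu, "pixel_size_um") <- px_um
    adu
  })
}
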
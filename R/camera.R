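#' EMCCD camera model
#'
#' Describes the photon-to-count conversion of the detector: pixel counts in
#' analog-digital units (ADU) are \code{offset + gain * photons}, with Poisson
#' shot noise on the photons, an optional electron-multiplying excess-noise
#' term (which doubles the variance of the shot term), and Gaussian readout
#' noise added in ADU.
#'
#' @param offset Bias level in ADU added to every pixel (>= 0).
#' @param gain Conversion gain in ADU per photon (> 0); photon calibration
#'   multiplies by the inverse gain.
#' @param readout_sd Standard deviation of Gaussian readout noise, in ADU
#'   (>= 0).
#' @param em_excess Logical; if \code{TRUE} the electron-multiplication
#'   register's excess noise is modelled by doubling the variance of the
#'   photon shot term.
#' @return An object of class \code{camera_model}.
#' @examples
#' cam <- camera_model(offset = 100, gain = 2)
#' pixels_to_photons(matrix(110, 2, 2), cam)  # 5 photons everywhere
#' @export
camera_model <- function(offset = 100, gain = 2, readout_sd = 1,
                         em_excess = TRUE) {
  check_scalar(offset, "offset", lower = 0)
  check_scalar(gain, "gain", lower = 0, strict_lower = TRUE)
  check_scalar(readout_sd, "readout_sd", lower = 0)
  structure(list(offset = offset, gain = gain, readout_sd = readout_sd,
                 em_excess = isTRUE(em_excess)),
            class = "camera_model")
}

#' Gaussian point-spread-function model
#'
#' @param sigma_px Standard deviation of the Gaussian PSF, in pixels (> 0).
#' @param pixel_size_nm Physical pixel pitch in the sample plane, in
#'   nanometres (> 0).
#' @return An object of class \code{psf_model}.
#' @export
psf_model <- function(sigma_px = 1.1, pixel_size_nm = 160) {
  check_scalar(sigma_px, "sigma_px", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_size_nm, "pixel_size_nm", lower = 0, strict_lower = TRUE)
  structure(list(sigma_px = sigma_px, pixel_size_nm = pixel_size_nm),
            class = "psf_model")
}

#' Convert pixel counts to photon counts
#'
#' Applies the affine photon calibration: offset subtraction followed by
#' multiplication with the inverse gain. Values may be negative where readout
#' noise pushes a pixel below the offset; no clipping is applied, so the
#' conversion is exactly invertible.
#'
#' @param frame Numeric matrix of pixel counts (ADU).
#' @param camera A \code{\link{camera_model}}.
#' @return Numeric matrix of photon counts, same dimensions as \code{frame}.
#' @export
pixels_to_photons <- function(frame, camera) {
  if (!inherits(camera, "camera_model"))
    stop_arg("'camera' must be a camera_model")
  if (!is.numeric(frame)) stop_arg("'frame' must be numeric")
  (frame - camera$offset) / camera$gain
}
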
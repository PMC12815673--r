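#' TOCCSL acquisition protocol
#'
#' Timing and geometry of a TOCCSL run: a prebleach image for density
#' assessment, an aperture-confined high-intensity bleach, a recovery delay
#' during which mobile unbleached molecules diffuse into the bleached region,
#' and the TOCCSL readout frame of the now well-separated entrants. Defaults
#' follow the original protocol: 2000 ms bleach and 15 s recovery.
#'
#' @param bleach_ms Bleach duration in ms (> 0).
#' @param recovery_s Recovery delay in s (>= 0).
#' @param prebleach_ms Prebleach exposure in ms (informational; the
#'   stroboscopic exposure is short relative to diffusion).
#' @param aperture Numeric length-2 vector: the x-range (um) of the
#'   slit-shaped bleach/analysis aperture, spanning the full y extent.
#'   \code{NULL} selects the central half of the field at simulation time.
#' @param excitation_relative Named relative excitation intensities for the
#'   \code{prebleach} and \code{toccsl} frames (flux multipliers).
#' @return An object of class \code{toccsl_protocol}.
#' @export
toccsl_protocol <- function(bleach_ms = 2000, recovery_s = 15,
                            prebleach_ms = 5, aperture = NULL,
                            excitation_relative = c(prebleach = 1, toccsl = 1)) {
  check_scalar(bleach_ms, "bleach_ms", lower = 0, strict_lower = TRUE)
  check_scalar(recovery_s, "recovery_s", lower = 0)
  check_scalar(prebleach_ms, "prebleach_ms", lower = 0)
  if (!is.null(aperture) &&
      (!is.numeric(aperture) || length(aperture) != 2L ||
       aperture[2] <= aperture[1]))
    stop_arg("'aperture' must be c(xmin, xmax) with xmax > xmin")
  structure(list(bleach_ms = bleach_ms, recovery_s = recovery_s,
                 prebleach_ms = prebleach_ms, aperture = aperture,
                 excitation_relative = excitation_relative),
            class = "toccsl_protocol")
}

# Reflecting 2-D Brownian displacement over time t for mobile molecules.
diffuse_positions <- function(field, t_s, field_size) {
  mob <- which(field$mobile & field$d_um2_s > 0)
  if (length(mob) == 0 || t_s <= 0) return(field)
  sd_step <- sqrt(2 * field$d_um2_s[mob] * t_s)
  reflect <- function(z, L) {
    z <- z %% (2 * L)
    ifelse(z > L, 2 * L - z, z)
  }
  field$x[mob] <- reflect(field$x[mob] + stats::rnorm(length(mob), sd = sd_step),
                          field_size)
  field$y[mob] <- reflect(field$y[mob] + stats::rnorm(length(mob), sd = sd_step),
                          field_size)
  field
}

#' Simulate a full TOCCSL image sequence with ground truth
#'
#' Runs the protocol on a molecule field: renders the prebleach frame,
#' propagates mobile molecules through the bleach interval, sets the active
#' fluorophore count of every molecule inside the aperture to zero (the
#' bleach), renders a postbleach control frame, propagates mobile molecules
#' through the recovery delay, and renders the TOCCSL frame. Immobile
#' molecules never move, so the TOCCSL frame's aperture contains only mobile
#' molecules that entered from outside. The returned ledger records, per
#' molecule, everything a test needs so ground truth never has to be
#' reverse-engineered from pixels.
#'
#' @param field A \code{\link{build_molecule_field}} result.
#' @param protocol A \code{\link{toccsl_protocol}}.
#' @param psf,camera,brightness_model Imaging models as in
#'   \code{\link{render_frame}}.
#' @param noise Logical; passed to the renderer.
#' @param seed Optional integer seed for the whole sequence.
#' @return List of class \code{toccsl_sequence}: \code{frames} (named list
#'   \code{prebleach}, \code{postbleach_control}, \code{toccsl} of ADU
#'   matrices), \code{ledger} (data frame: initial and final positions,
#'   order, active fluorophores before/after bleach, mobile flag, bleached
#'   flag, in-aperture flags, per-molecule TOCCSL flux, and
#'   \code{analyzable}), \code{aperture}, \code{field_size}.
#' @export
simulate_toccsl_sequence <- function(field, protocol, psf, camera,
                                     brightness_model, noise = TRUE,
                                     seed = NULL) {
  if (!inherits(protocol, "toccsl_protocol"))
    stop_arg("'protocol' must be a toccsl_protocol")
  field_size <- attr(field, "field_size")
  aperture <- protocol$aperture
  if (is.null(aperture))
    aperture <- c(field_size / 4, 3 * field_size / 4)
  if (aperture[1] < 0 || aperture[2] > field_size)
    stop_arg("aperture must lie inside the field")
  exc <- protocol$excitation_relative
  with_seed(seed, {
    prebleach <- render_frame(field, psf, camera, brightness_model,
                              exposure_scale = unname(exc["prebleach"]),
                              noise = noise)
    x0 <- field$x; y0 <- field$y
    n_active_pre <- field$n_active

    # molecules drift during the (long) bleach interval, then bleaching
    # zeroes every active fluorophore inside the aperture
    field <- diffuse_positions(field, protocol$bleach_ms / 1000, field_size)
    bleached <- field$x >= aperture[1] & field$x <= aperture[2]
    field$n_active[bleached] <- 0L
    postbleach <- render_frame(field, psf, camera, brightness_model,
                               exposure_scale = unname(exc["toccsl"]),
                               noise = noise)

    field <- diffuse_positions(field, protocol$recovery_s, field_size)
    toccsl <- render_frame(field, psf, camera, brightness_model,
                           exposure_scale = unname(exc["toccsl"]),
                           noise = noise)

    in_ap_final <- field$x >= aperture[1] & field$x <= aperture[2]
    ledger <- data.frame(
      molecule = seq_len(nrow(field)),
      x0 = x0, y0 = y0,
      x = field$x, y = field$y,
      order = field$order,
      n_active_pre = n_active_pre,
      n_active = field$n_active,
      mobile = field$mobile,
      bleached = bleached,
      in_aperture_final = in_ap_final,
      toccsl_flux = attr(toccsl, "flux"),
      analyzable = in_ap_final & field$n_active > 0L
    )
    structure(list(frames = list(prebleach = prebleach,
                                 postbleach_control = postbleach,
                                 toccsl = toccsl),
                   ledger = ledger, aperture = aperture,
                   field_size = field_size),
              class = "toccsl_sequence")
  })
}
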
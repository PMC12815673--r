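# Single-molecule spot detection and 2-D Gaussian fitting on photon images.

# Separable Gaussian smoothing (matched filter for spot detection).
# Kernel truncated at +-4 sigma and renormalised; edges handled by
# renormalising the kernel mass inside the image (no padding artefacts).
gaussian_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (j in -r:r) {
      w <- k[j + r + 1L]
      src <- pmin(pmax(seq_len(n) + j, 1L), n)
      valid <- (seq_len(n) + j >= 1L) & (seq_len(n) + j <= n)
      out[valid, ] <- out[valid, ] + w * m[seq_len(n)[valid] + j, ]
      norm[valid] <- norm[valid] + w
    }
    out / norm
  }
  t(smooth_1d(t(smooth_1d(img))))
}

#' Detect candidate single-molecule spots
#'
#' Matched-filter detection: the photon image is smoothed with a Gaussian of
#' the expected PSF width, local maxima above a photon threshold are taken as
#' candidates, and any pair of candidates closer than \code{min_separation}
#' is discarded entirely (both members). Pairwise rejection rather than
#' merging is deliberate: brightness-based stoichiometry is only valid for
#' spots that are single diffusing entities, so near-coincident detections
#' must not be combined into one pseudo-spot.
#'
#' @param img Photon image (matrix, rows = y).
#' @param expected_sigma Expected PSF sd in pixels.
#' @param threshold Detection threshold on the smoothed, background-subtracted
#'   image, in photons/pixel.
#' @param min_separation Minimum allowed distance between spots, in pixels.
#' @return Data frame \code{x}, \code{y} (pixel coordinates of the maximum,
#'   where pixel centers sit at integer + 0.5) — possibly zero rows.
#' @export
detect_spots <- function(img, expected_sigma, threshold,
                         min_separation = 4 * expected_sigma) {
  check_scalar(expected_sigma, "expected_sigma", lower = 0,
               strict_lower = TRUE)
  check_scalar(min_separation, "min_separation", lower = 0,
               strict_lower = TRUE)
  sm <- gaussian_smooth(img, expected_sigma)
  sm <- sm - stats::median(sm)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3 || nc < 3) return(data.frame(x = numeric(0), y = numeric(0)))
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- sm[2:(nr - 1) + dy, 2:(nc - 1) + dx]
    # ties broken by raster order so a flat-topped maximum yields exactly
    # one candidate instead of a mutually-rejecting pair
    if (dy < 0 || (dy == 0 && dx < 0)) is_max <- is_max & (core > nb)
    else is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  # pixel-center coordinates: row i (1-based) -> y = i - 0.5
  cand <- data.frame(x = idx[, "col"] + 1 - 0.5, y = idx[, "row"] + 1 - 0.5)
  if (nrow(cand) > 1) {
    d <- as.matrix(stats::dist(cand))
    diag(d) <- Inf
    keep <- apply(d, 1, min) >= min_separation
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

# Pixel-integrated symmetric 2-D Gaussian + constant background over a
# window. Exactly matches the renderer's forward model, so noiseless spots
# fit to machine precision.
spot_model <- function(par, xe, ye) {
  fx <- diff(stats::pnorm(xe, mean = par[["x0"]], sd = par[["sigma"]]))
  fy <- diff(stats::pnorm(ye, mean = par[["y0"]], sd = par[["sigma"]]))
  par[["bg"]] + par[["B"]] * outer(fy, fx)
}

#' Fit a 2-D Gaussian to one spot
#'
#' Least-squares fit of a pixel-integrated symmetric 2-D Gaussian plus a
#' constant per-window background to a square window around a candidate. The
#' integrated brightness B (photons) is a free parameter of the fit, so no
#' \code{2*pi*sigma^2*amplitude} conversion step is needed. A spot is
#' accepted iff the optimiser converged, \code{B >= min_brightness}, the
#' fitted sigma lies within \code{sigma_bounds * expected_sigma}, and the
#' residual RMS does not exceed \code{max_residual}.
#'
#' @param img Photon image.
#' @param x,y Candidate position (pixel coordinates).
#' @param expected_sigma Expected PSF sd (pixels).
#' @param window_halfwidth Half-width of the square fit window in pixels;
#'   default \code{ceiling(4 * expected_sigma)}. Windows clipped by the image
#'   edge are rejected, not padded.
#' @param sigma_bounds Acceptance interval for sigma as multiples of
#'   \code{expected_sigma}.
#' @param min_brightness Minimum accepted integrated brightness (photons).
#' @param max_residual Maximum accepted residual RMS (photons/pixel;
#'   \code{Inf} disables the check).
#' @return One-row data frame of class \code{spot_fit}: \code{x}, \code{y},
#'   \code{sigma}, \code{B}, \code{background}, \code{residual_norm},
#'   \code{accepted}, \code{reason}.
#' @export
fit_gaussian_spot <- function(img, x, y, expected_sigma,
                              window_halfwidth = ceiling(4 * expected_sigma),
                              sigma_bounds = c(0.5, 2),
                              min_brightness = 10,
                              max_residual = Inf) {
  reject <- function(reason, x0 = x, y0 = y)
    data.frame(x = x0, y = y0, sigma = NA_real_, B = NA_real_,
               background = NA_real_, residual_norm = NA_real_,
               accepted = FALSE, reason = reason)
  w <- window_halfwidth
  cx <- floor(x); cy <- floor(y)
  if (cx - w < 0 || cy - w < 0 || cx + w + 1 > ncol(img) ||
      cy + w + 1 > nrow(img))
    return(reject("edge"))
  rows <- (cy - w + 1):(cy + w + 1)
  cols <- (cx - w + 1):(cx + w + 1)
  patch <- img[rows, cols]
  xe <- (cx - w):(cx + w + 1)   # pixel edges in image coordinates
  ye <- (cy - w):(cy + w + 1)
  bg0 <- min(patch)
  B0 <- max(sum(patch) - bg0 * length(patch), min_brightness)
  start <- c(x0 = x, y0 = y, sigma = expected_sigma, B = B0, bg = bg0)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) as.numeric(patch - spot_model(p, xe, ye)),
      lower = c(min(xe), min(ye), 0.2 * expected_sigma, 0, -Inf),
      upper = c(max(xe), max(ye), 5 * expected_sigma, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(reject("fit_failed"))
  p <- fit$par
  rms <- sqrt(mean(fit$fvec^2))
  out <- data.frame(x = p[["x0"]], y = p[["y0"]], sigma = p[["sigma"]],
                    B = p[["B"]], background = p[["bg"]],
                    residual_norm = rms, accepted = TRUE, reason = "")
  if (p[["B"]] < min_brightness) {
    out$accepted <- FALSE; out$reason <- "no_signal"
  } else if (p[["sigma"]] < sigma_bounds[1] * expected_sigma ||
             p[["sigma"]] > sigma_bounds[2] * expected_sigma) {
    out$accepted <- FALSE; out$reason <- "sigma_out_of_bounds"
  } else if (rms > max_residual) {
    out$accepted <- FALSE; out$reason <- "residual"
  }
  class(out) <- c("spot_fit", "data.frame")
  out
}

#' Extract a brightness table from labelled frames
#'
#' Runs detection and per-spot Gaussian fitting over a named list of photon
#' frames with one role per frame and collects the results in one table
#' usable by the stoichiometry stage. Frames in the \code{prebleach} role are
#' only used for surface-density estimation, so they are processed with
#' detection alone (their rows carry \code{B = NA}); dense prebleach fields
#' with overlapping signals are thereby never force-fitted.
#'
#' @param frames List of ADU matrices.
#' @param roles Character vector, one role per frame: \code{"prebleach"},
#'   \code{"calibration"} or \code{"toccsl"} (frames with other roles, e.g.
#'   postbleach controls, are skipped).
#' @param camera A \code{\link{camera_model}} for photon conversion.
#' @param expected_sigma Expected PSF sd (pixels).
#' @param threshold Detection threshold (photons/pixel on the smoothed
#'   image).
#' @param min_separation Minimum spot separation (pixels).
#' @param aperture_px Optional \code{c(xmin, xmax)} in pixels: restrict
#'   TOCCSL-role spots to the analysis aperture.
#' @param ... Further arguments passed to \code{\link{fit_gaussian_spot}}.
#' @return Data frame with columns \code{frame}, \code{frame_role}, \code{x},
#'   \code{y}, \code{sigma}, \code{B}, \code{background},
#'   \code{residual_norm}, \code{accepted}, \code{reason}.
#' @export
extract_brightness_table <- function(frames, roles, camera, expected_sigma,
                                     threshold, min_separation = 4 * expected_sigma,
                                     aperture_px = NULL, ...) {
  if (length(frames) != length(roles))
    stop_arg("one role per frame is required")
  known <- c("prebleach", "calibration", "toccsl", "postbleach_control")
  if (any(!roles %in% known))
    stop_arg("unknown frame role(s): ",
             paste(setdiff(roles, known), collapse = ", "))
  rows <- list()
  for (i in seq_along(frames)) {
    role <- roles[i]
    if (role == "postbleach_control") next
    ph <- pixels_to_photons(frames[[i]], camera)
    cand <- detect_spots(ph, expected_sigma, threshold, min_separation)
    if (role == "toccsl" && !is.null(aperture_px) && nrow(cand) > 0)
      cand <- cand[cand$x >= aperture_px[1] & cand$x <= aperture_px[2], ,
                   drop = FALSE]
    if (nrow(cand) == 0) next
    if (role == "prebleach") {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = i, frame_role = role, x = cand$x, y = cand$y,
        sigma = NA_real_, B = NA_real_, background = NA_real_,
        residual_norm = NA_real_, accepted = TRUE, reason = "density_only")
    } else {
      for (j in seq_len(nrow(cand))) {
        f <- fit_gaussian_spot(ph, cand$x[j], cand$y[j], expected_sigma, ...)
        rows[[length(rows) + 1L]] <- cbind(frame = i, frame_role = role,
                                           as.data.frame(f))
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(frame = integer(0), frame_role = character(0),
                      x = numeric(0), y = numeric(0), sigma = numeric(0),
                      B = numeric(0), background = numeric(0),
                      residual_norm = numeric(0), accepted = logical(0),
                      reason = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
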
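# FRAP: one-phase association fitting of fluorescence recovery traces,
# I(t)/I0 = mf * (1 - exp(-K t)).

#' Normalize a FRAP trace
#'
#' Divides raw intensities by the prebleach signal I0 after subtracting the
#' postbleach baseline, so that the model value at t = 0 is 0 and full
#' recovery of the mobile pool plateaus at the mobile fraction.
#'
#' @param trace Data frame with columns \code{time_s} and \code{intensity}.
#' @param I0 Prebleach fluorescence signal (> 0).
#' @param baseline Postbleach baseline in raw units; default: the intensity
#'   at the earliest time point (the first postbleach sample defines t = 0).
#' @return Data frame \code{time_s}, \code{intensity} (normalized).
#' @export
normalize_frap_trace <- function(trace, I0, baseline = NULL) {
  if (!all(c("time_s", "intensity") %in% names(trace)))
    stop_arg("'trace' needs columns time_s and intensity")
  check_scalar(I0, "I0", lower = 0, strict_lower = TRUE)
  if (is.null(baseline)) baseline <- trace$intensity[which.min(trace$time_s)]
  data.frame(time_s = trace$time_s,
             intensity = (trace$intensity - baseline) / I0)
}

#' Fit the one-phase association recovery model
#'
#' Bounded nonlinear least squares of \code{mf * (1 - exp(-K t))} to a
#' normalized recovery trace. The mobile fraction is constrained to [0, 1]
#' (its physical range) and K to positive values. Initialisation: mf from
#' the mean of the last quartile of the trace, K from a log-linear fit of
#' the early, unsaturated points.
#'
#' @param trace Normalized trace (\code{time_s}, \code{intensity}).
#' @return Object of class \code{frap_fit}: \code{mf}, \code{K_per_s},
#'   \code{se_mf}, \code{se_K}, \code{flags} (character vector, possibly
#'   empty: \code{"k_unidentifiable"}, \code{"plateau_not_reached"}),
#'   \code{fitted} (model values at the data times).
#' @export
fit_frap <- function(trace) {
  t <- trace$time_s
  y <- trace$intensity
  if (length(t) < 4) stop_arg("need >= 4 time points")
  flags <- character(0)
  mf0 <- mean(y[t >= stats::quantile(t, 0.75)])
  if (mf0 <= 1e-6) {
    # no recovery at all: mf = 0, rate has no information
    return(structure(list(mf = 0, K_per_s = NA_real_, se_mf = NA_real_,
                          se_K = NA_real_, flags = "k_unidentifiable",
                          fitted = rep(0, length(t))),
                     class = "frap_fit"))
  }
  mf0 <- min(mf0, 1)
  # log-linear initial rate from points below ~80% of the plateau estimate
  early <- which(y > 0 & y < 0.8 * mf0 & t > 0)
  K0 <- if (length(early) >= 2) {
    z <- log(pmax(1e-12, 1 - y[early] / mf0))
    -stats::coef(stats::lm(z ~ t[early]))[[2]]
  } else 1 / max(t)
  if (!is.finite(K0) || K0 <= 0) K0 <- 1 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ mf * (1 - exp(-K * time_s)),
                      data = data.frame(time_s = t, intensity = y),
                      start = list(mf = mf0, K = K0),
                      lower = c(mf = 0, K = 1e-10),
                      upper = c(mf = 1, K = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop_arg("FRAP fit did not converge")
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(mf = NA_real_, K = NA_real_))
  if (co[["K"]] * max(t) < 1) flags <- c(flags, "plateau_not_reached")
  structure(list(mf = co[["mf"]], K_per_s = co[["K"]],
                 se_mf = unname(se["mf"]), se_K = unname(se["K"]),
                 flags = flags, fitted = stats::fitted(fit)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: mf = %.4f (se %.2g), K = %.4g /s (se %.2g)\n",
              x$mf, x$se_mf, x$K_per_s, x$se_K))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
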
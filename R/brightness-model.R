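#' Monomer brightness model
#'
#' Generative model for the integrated brightness (in photons) of a single
#' fluorophore-tagged monomer during one exposure. The default family is
#' log-normal: strictly positive support and the right-skew typical of
#' single-fluorophore brightness distributions. Setting \code{cv = 0} gives a
#' degenerate point mass at \code{mean}, useful for exact tests.
#'
#' @param mean Mean brightness in photons (> 0).
#' @param cv Coefficient of variation (sd/mean, >= 0).
#' @param family Distribution family; \code{"lognormal"} is currently the
#'   only stochastic family.
#' @return An object of class \code{monomer_brightness_model} with the
#'   natural-scale \code{mean} and \code{cv} plus the log-scale parameters.
#' @examples
#' m <- monomer_brightness_model(mean = 400, cv = 0.35)
#' b <- sample_monomer_brightness(m, 5, seed = 1)
#' @export
monomer_brightness_model <- function(mean = 400, cv = 0.35,
                                     family = "lognormal") {
  check_scalar(mean, "mean", lower = 0, strict_lower = TRUE)
  check_scalar(cv, "cv", lower = 0)
  family <- match.arg(family, "lognormal")
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  structure(list(mean = mean, cv = cv, family = family,
                 meanlog = meanlog, sdlog = sdlog),
            class = "monomer_brightness_model")
}

#' Sample single-monomer brightness values
#'
#' @param model A \code{\link{monomer_brightness_model}}.
#' @param n_samples Number of draws (>= 1).
#' @param seed Optional integer seed; fixed seed gives identical samples.
#' @return Numeric vector of \code{n_samples} positive brightness values
#'   (photons).
#' @export
sample_monomer_brightness <- function(model, n_samples, seed = NULL) {
  if (!inherits(model, "monomer_brightness_model"))
    stop_arg("'model' must be a monomer_brightness_model")
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop_arg("'n_samples' must be >= 1")
  n_samples <- as.integer(n_samples)
  with_seed(seed, {
    if (model$sdlog == 0) rep(model$mean, n_samples)
    else stats::rlnorm(n_samples, meanlog = model$meanlog, sdlog = model$sdlog)
  })
}
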
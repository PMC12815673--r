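#' Simulate a FRAP recovery trace
#'
#' Generates a fluorescence-recovery-after-photobleaching time course under
#' the one-phase association model I(t)/I0 = mf * (1 - exp(-K t)), with
#' multiplicative Gaussian noise. Default sampling matches the acquisition:
#' one point every 10 s over 400 s.
#'
#' @param mf Mobile fraction in [0, 1].
#' @param K Recovery rate constant in 1/s (> 0).
#' @param I0 Prebleach fluorescence signal (> 0; arbitrary units).
#' @param times Sampling times in s, sorted ascending, first >= 0.
#' @param noise_sd Relative (multiplicative) Gaussian noise sd.
#' @param seed Optional integer seed.
#' @return Data frame \code{time_s}, \code{intensity} (raw units) with
#'   attribute \code{I0}; \code{intensity = I0 * mf * (1 - exp(-K t))} times
#'   \code{(1 + noise)}.
#' @export
simulate_frap_trace <- function(mf, K, I0 = 1000,
                                times = seq(0, 400, by = 10),
                                noise_sd = 0, seed = NULL) {
  check_scalar(mf, "mf", lower = 0, upper = 1)
  check_scalar(K, "K", lower = 0, strict_lower = TRUE)
  check_scalar(I0, "I0", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (is.unsorted(times) || times[1] < 0)
    stop_arg("'times' must be sorted ascending with first time >= 0")
  with_seed(seed, {
    mu <- I0 * mf * (1 - exp(-K * times))
    eps <- if (noise_sd > 0) stats::rnorm(length(times), sd = noise_sd) else 0
    out <- data.frame(time_s = times, intensity = mu * (1 + eps))
    attr(out, "I0") <- I0
    out
  })
}

#' Simulate a three-channel FRET intensity triplet
#'
#' Constructs background-subtracted ROI intensities for the donor, acceptor
#' and FRET channels so that the noiseless normalized FRET of the triplet
#' equals \code{coupling} exactly:
#' \code{i_fret = bt_donor*i_donor + bt_acceptor*i_acceptor +
#' coupling*sqrt(i_donor*i_acceptor)}.
#'
#' @param true_donor,true_acceptor Non-negative channel intensities.
#' @param coupling Non-negative FRET coupling (the NFRET value the noiseless
#'   triplet inverts to).
#' @param bt A \code{\link{bleedthrough}} object.
#' @param noise_sd Relative Gaussian noise applied per channel.
#' @param seed Optional integer seed.
#' @return One-row data frame \code{i_fret}, \code{i_donor},
#'   \code{i_acceptor}.
#' @export
simulate_fret_triplet <- function(true_donor, true_acceptor, coupling,
                                  bt = bleedthrough(), noise_sd = 0,
                                  seed = NULL) {
  check_scalar(true_donor, "true_donor", lower = 0)
  check_scalar(true_acceptor, "true_acceptor", lower = 0)
  if (!is.numeric(coupling) || length(coupling) != 1L || coupling < 0)
    stop_arg("'coupling' must be >= 0")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    i_fret <- bt$bt_donor * true_donor + bt$bt_acceptor * true_acceptor +
      coupling * sqrt(true_donor * true_acceptor)
    v <- c(i_fret, true_donor, true_acceptor)
    if (noise_sd > 0) v <- v * (1 + stats::rnorm(3L, sd = noise_sd))
    data.frame(i_fret = v[1], i_donor = v[2], i_acceptor = v[3])
  })
}

#' Simulate saturation (uptake/binding/dose-response) data
#'
#' Generates a concentration-response table with a total and a nonspecific
#' arm: specific response follows the rectangular hyperbola
#' \code{amplitude * C / (half_saturation + C)}; the nonspecific arm is
#' linear-free (a constant fraction-free model is deliberately not imposed:
#' the nonspecific level is taken proportional to concentration, as for
#' nonspecific uptake/binding that does not saturate).
#'
#' @param amplitude Saturating amplitude (Vmax/Bmax/k_max role; > 0).
#' @param half_saturation Half-saturating concentration (Km/Kd/k0.5; > 0).
#' @param concentrations Positive concentrations.
#' @param nonspecific_slope Nonspecific response per unit concentration
#'   (>= 0).
#' @param noise_sd Relative Gaussian noise per well.
#' @param replicates Wells per concentration per arm.
#' @param seed Optional integer seed.
#' @return Data frame \code{conc}, \code{replicate}, \code{total},
#'   \code{nonspecific}.
#' @export
simulate_saturation_data <- function(amplitude, half_saturation,
                                     concentrations,
                                     nonspecific_slope = 0,
                                     noise_sd = 0, replicates = 1,
                                     seed = NULL) {
  check_scalar(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  check_scalar(half_saturation, "half_saturation", lower = 0,
               strict_lower = TRUE)
  if (any(concentrations <= 0)) stop_arg("'concentrations' must be > 0")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        conc = concentrations)
    spec <- amplitude * grid$conc / (half_saturation + grid$conc)
    nonspec <- nonspecific_slope * grid$conc
    noisy <- function(mu) {
      if (noise_sd > 0) mu * (1 + stats::rnorm(length(mu), sd = noise_sd))
      else mu
    }
    data.frame(conc = grid$conc, replicate = grid$replicate,
               total = noisy(spec + nonspec),
               nonspecific = noisy(nonspec))
  })
}

#' Simulate a substrate-release (efflux) plate
#'
#' Generates per-well (cells, supernatant) radioactivity count pairs for a
#' set of conditions: before noise, \code{supernatant / (cells +
#' supernatant)} equals the condition's released fraction and the per-well
#' total is conserved.
#'
#' @param fractions Named numeric vector of released fractions per condition
#'   (each in [0, 1]); names are condition identifiers.
#' @param total Total radioactivity per well (counts).
#' @param wells Wells per condition.
#' @param noise_sd Relative Gaussian noise applied to the released fraction.
#' @param seed Optional integer seed.
#' @return Data frame \code{condition}, \code{well}, \code{cells},
#'   \code{supernatant}.
#' @export
simulate_release_plate <- function(fractions, total = 10000, wells = 3,
                                   noise_sd = 0, seed = NULL) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop_arg("'fractions' must be a named vector of conditions")
  if (any(fractions < 0 | fractions > 1))
    stop_arg("released fractions must lie in [0, 1]")
  check_scalar(total, "total", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    grid <- expand.grid(well = seq_len(wells),
                        condition = names(fractions),
                        stringsAsFactors = FALSE)
    f <- fractions[grid$condition]
    if (noise_sd > 0)
      f <- pmin(1, pmax(0, f * (1 + stats::rnorm(length(f), sd = noise_sd))))
    sup <- total * f
    data.frame(condition = grid$condition, well = grid$well,
               cells = total - sup, supernatant = sup,
               row.names = NULL)
  })
}
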
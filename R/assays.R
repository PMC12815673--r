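# Functional assay fitting: Michaelis-Menten uptake, one-site binding,
# turnover rates, efflux normalization, and patch-clamp kinetics summaries.

saturation_fit <- function(amplitude, half_saturation, se_amplitude,
                           se_half_saturation, role, units = "") {
  structure(list(amplitude = amplitude, half_saturation = half_saturation,
                 se_amplitude = se_amplitude,
                 se_half_saturation = se_half_saturation,
                 role = role, units = units),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  lab <- switch(x$role,
                Vmax = c("Vmax", "Km"), Bmax = c("Bmax", "Kd"),
                k_max = c("k_max", "k_0.5"), c("amplitude", "half_saturation"))
  cat(sprintf("%s fit: %s = %.4g +- %.2g, %s = %.4g +- %.2g %s\n",
              x$role, lab[1], x$amplitude, x$se_amplitude,
              lab[2], x$half_saturation, x$se_half_saturation, x$units))
  invisible(x)
}

# Shared hyperbola fitter: y = A * x / (k + x), unweighted least squares.
fit_hyperbola <- function(x, y, role, units) {
  if (length(unique(x)) < 2)
    stop_arg("need responses at >= 2 distinct concentrations")
  if (all(y <= 0) || stats::sd(y) == 0)
    stop_arg("degenerate response data: no saturable signal to fit")
  A0 <- max(y)
  k0 <- x[which.min(abs(y - A0 / 2))]
  if (k0 <= 0) k0 <- stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * x / (k + x),
                      data = data.frame(x = x, y = y),
                      start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop_arg("saturation fit did not converge")
  co <- stats::coef(fit)
  if (co[["A"]] <= 0 || co[["k"]] <= 0)
    stop_arg("saturation fit returned non-positive estimates")
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(A = NA_real_, k = NA_real_))
  saturation_fit(co[["A"]], co[["k"]], unname(se["A"]), unname(se["k"]),
                 role, units)
}

# Subtract the nonspecific arm from the total arm, per concentration
# (default) or as a fitted constant level.
specific_response <- function(data, mode = c("per_concentration", "constant")) {
  mode <- match.arg(mode)
  ns <- if (is.null(data$nonspecific)) 0 else data$nonspecific
  if (mode == "constant") ns <- mean(ns)
  data$total - ns
}

#' Fit Michaelis-Menten uptake kinetics
#'
#' Nonspecific uptake is subtracted from the total arm and the specific
#' velocity is fitted by unweighted nonlinear least squares of
#' \code{Vmax * C / (Km + C)}.
#'
#' @param data Data frame with columns \code{conc}, \code{total} and
#'   optionally \code{nonspecific} (same rows; absent means zero).
#' @param nonspecific Subtraction mode: per concentration (default) or the
#'   mean nonspecific level as a constant.
#' @param units Free-text units string carried on the result (amplitudes are
#'   reported in whatever unit the velocities came in).
#' @return A \code{saturation_fit} with role \code{"Vmax"}.
#' @export
fit_michaelis_menten <- function(data,
                                 nonspecific = c("per_concentration",
                                                 "constant"),
                                 units = "") {
  if (!all(c("conc", "total") %in% names(data)))
    stop_arg("'data' needs columns conc and total")
  if (length(unique(data$conc)) < 4)
    stop_arg("need >= 4 distinct concentrations")
  v <- specific_response(data, match.arg(nonspecific))
  fit_hyperbola(data$conc, v, role = "Vmax", units = units)
}

#' Fit one-site specific binding
#'
#' Specific binding (total minus nonspecific) is fitted by least squares of
#' the one-site model \code{Bmax * L / (Kd + L)}.
#'
#' @inheritParams fit_michaelis_menten
#' @return A \code{saturation_fit} with role \code{"Bmax"}.
#' @export
fit_one_site_binding <- function(data,
                                 nonspecific = c("per_concentration",
                                                 "constant"),
                                 units = "") {
  if (!all(c("conc", "total") %in% names(data)))
    stop_arg("'data' needs columns conc and total")
  if (length(unique(data$conc)) < 4)
    stop_arg("need >= 4 distinct concentrations")
  b <- specific_response(data, match.arg(nonspecific))
  fit_hyperbola(data$conc, b, role = "Bmax", units = units)
}

#' Transporter turnover rate
#'
#' Ratio of the maximal uptake velocity to the maximal binding (the
#' transporter count proxy): turnover = Vmax / Bmax, with first-order
#' (delta-method) propagation of the two standard errors.
#'
#' @param vmax_fit A \code{saturation_fit} with role \code{"Vmax"}.
#' @param bmax_fit A \code{saturation_fit} with role \code{"Bmax"}.
#' @return List: \code{turnover_per_min}, \code{se}.
#' @export
turnover_rate <- function(vmax_fit, bmax_fit) {
  if (!inherits(vmax_fit, "saturation_fit") || vmax_fit$role != "Vmax")
    stop_arg("'vmax_fit' must be a saturation_fit with role Vmax")
  if (!inherits(bmax_fit, "saturation_fit") || bmax_fit$role != "Bmax")
    stop_arg("'bmax_fit' must be a saturation_fit with role Bmax")
  tr <- vmax_fit$amplitude / bmax_fit$amplitude
  se <- abs(tr) * sqrt((vmax_fit$se_amplitude / vmax_fit$amplitude)^2 +
                         (bmax_fit$se_amplitude / bmax_fit$amplitude)^2)
  list(turnover_per_min = tr, se = se)
}

#' Normalize a substrate-release (efflux) plate
#'
#' Per well, the released fraction is \code{supernatant / (cells +
#' supernatant) * 100} (percent of total radioactivity); condition means are
#' then expressed relative to the basal condition, and — when a transport
#' blocker condition is supplied — as specific release after subtracting the
#' blocker-insensitive (nonspecific) fraction. The per-condition total
#' radioactivity is reported so equal loading across conditions can be
#' verified.
#'
#' @param plate Data frame with columns \code{condition}, \code{cells},
#'   \code{supernatant} (one row per well).
#' @param basal Condition id of the unstimulated (basal) wells.
#' @param blocker Optional condition id of the blocker (nonspecific) wells.
#' @return Object of class \code{release_result}: per-condition data frame
#'   \code{summary} (\code{condition}, \code{n_wells},
#'   \code{released_percent}, \code{normalized}, \code{specific_percent},
#'   \code{mean_total}), plus \code{excluded_wells}.
#' @export
normalize_release <- function(plate, basal, blocker = NULL) {
  need <- c("condition", "cells", "supernatant")
  if (!all(need %in% names(plate)))
    stop_arg("'plate' needs columns ", paste(need, collapse = ", "))
  if (!basal %in% plate$condition) stop_arg("basal condition not in plate")
  total <- plate$cells + plate$supernatant
  bad <- total <= 0
  if (any(bad))
    message(sum(bad), " well(s) with zero total radioactivity excluded")
  plate <- plate[!bad, ]
  total <- total[!bad]
  frac <- plate$supernatant / total * 100
  sp <- split(seq_len(nrow(plate)), plate$condition)
  cond_mean <- vapply(sp, function(i) mean(frac[i]), numeric(1))
  cond_total <- vapply(sp, function(i) mean(total[i]), numeric(1))
  basal_mean <- cond_mean[[basal]]
  nonspec <- if (!is.null(blocker)) {
    if (!blocker %in% names(cond_mean)) stop_arg("blocker condition not in plate")
    cond_mean[[blocker]]
  } else 0
  out <- data.frame(condition = names(cond_mean),
                    n_wells = as.integer(lengths(sp)),
                    released_percent = unname(cond_mean),
                    normalized = unname(cond_mean / basal_mean),
                    specific_percent = unname(cond_mean - nonspec),
                    mean_total = unname(cond_total))
  rownames(out) <- NULL
  structure(list(summary = out, basal = basal, blocker = blocker,
                 excluded_wells = sum(bad)),
            class = "release_result")
}

#' Fit the steady-state current dose response
#'
#' Per cell, current amplitudes are normalized to the amplitude elicited by
#' the reference substrate pulse (10 uM by default), then all cells' ratios
#' are pooled and fitted by the hyperbola \code{A_max * C / (k_0.5 + C)}.
#' Cells lacking the reference concentration are excluded.
#'
#' @param data Data frame with columns \code{cell}, \code{conc},
#'   \code{amplitude}.
#' @param ref_conc Reference concentration (default 10).
#' @return A \code{saturation_fit} with role \code{"k_max"} (its
#'   \code{half_saturation} is k_0.5) plus attribute \code{n_cells}.
#' @export
fit_steady_state_dose <- function(data, ref_conc = 10) {
  need <- c("cell", "conc", "amplitude")
  if (!all(need %in% names(data)))
    stop_arg("'data' needs columns ", paste(need, collapse = ", "))
  sp <- split(data, data$cell)
  norm <- lapply(sp, function(d) {
    ref <- d$amplitude[d$conc == ref_conc]
    if (length(ref) == 0 || ref[1] <= 0) return(NULL)
    data.frame(conc = d$conc, ratio = d$amplitude / ref[1])
  })
  kept <- !vapply(norm, is.null, logical(1))
  if (!any(kept)) stop_arg("no cell has a usable reference pulse")
  pooled <- do.call(rbind, norm[kept])
  fit <- fit_hyperbola(pooled$conc, pooled$ratio, role = "k_max",
                       units = "ratio of reference-pulse amplitude")
  attr(fit, "n_cells") <- sum(kept)
  fit
}

#' Summarize peak-current relaxation kinetics
#'
#' Two complementary reads of the relaxation rate vs substrate concentration
#' relation: (i) a full-curve hyperbola fit \code{k_max * C / (k_0.5 + C)},
#' and (ii) an ordinary least-squares line through the lowest
#' \code{n_linear} concentrations, whose slope is the substrate association
#' rate constant k_on. With concentrations in uM and rates in 1/s the slope
#' is numerically on the 10^6 M^-1 s^-1 scale. A non-positive slope is
#' flagged as no concentration-dependent association.
#'
#' @param data Data frame with columns \code{conc} (uM, will be sorted
#'   ascending) and \code{rate} (1/s).
#' @param n_linear Number of lowest concentrations defining the linear
#'   portion (default 3).
#' @return Object of class \code{kinetics_summary}: \code{k_on} (10^6 M^-1
#'   s^-1), \code{se_k_on}, \code{hyperbola} (a \code{saturation_fit} or
#'   NULL if that fit fails), \code{flags}.
#' @export
fit_relaxation_kinetics <- function(data, n_linear = 3) {
  if (!all(c("conc", "rate") %in% names(data)))
    stop_arg("'data' needs columns conc and rate")
  if (nrow(data) < n_linear)
    stop_arg("need at least ", n_linear, " concentrations")
  data <- data[order(data$conc), ]
  low <- utils::head(data, n_linear)
  lf <- stats::lm(rate ~ conc, data = low)
  slope <- stats::coef(lf)[["conc"]]
  se <- tryCatch(
    suppressWarnings(summary(lf)$coefficients["conc", "Std. Error"]),
    error = function(e) NA_real_)
  flags <- character(0)
  if (slope <= 0 ||
      abs(slope) * diff(range(low$conc)) < 1e-9 * max(abs(low$rate)))
    flags <- "no_association"
  hyp <- tryCatch(fit_hyperbola(data$conc, data$rate, role = "k_max",
                                units = "1/s"),
                  error = function(e) NULL)
  structure(list(k_on = slope, se_k_on = se, hyperbola = hyp,
                 flags = flags, n_linear = n_linear),
            class = "kinetics_summary")
}

#' Fit peak-current recovery
#'
#' Mono-exponential rise to a maximum of the peak amplitude as a function of
#' the wash interval between paired substrate pulses:
#' \code{A(t) = A_max * (1 - exp(-k t))}. The recovery rate is a surrogate of
#' the substrate turnover rate. Intervals with no amplitude variation make k
#' unidentifiable and are flagged instead of fitted.
#'
#' @param data Data frame with columns \code{interval_s} and
#'   \code{amplitude} (normalized to the reference peak).
#' @return List: \code{k_per_s}, \code{A_max}, \code{se_k}, \code{flags}.
#' @export
fit_peak_recovery <- function(data) {
  if (!all(c("interval_s", "amplitude") %in% names(data)))
    stop_arg("'data' needs columns interval_s and amplitude")
  if (nrow(data) < 4) stop_arg("need >= 4 wash intervals")
  if (stats::sd(data$amplitude) == 0)
    return(list(k_per_s = NA_real_, A_max = data$amplitude[1],
                se_k = NA_real_, flags = "k_unidentifiable"))
  A0 <- max(data$amplitude)
  k0 <- 1 / stats::median(data$interval_s[data$interval_s > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(amplitude ~ A * (1 - exp(-k * interval_s)),
                      data = data, start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 1e-10),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop_arg("peak-recovery fit did not converge")
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(A = NA_real_, k = NA_real_))
  list(k_per_s = co[["k"]], A_max = co[["A"]], se_k = unname(se["k"]),
       flags = character(0))
}
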
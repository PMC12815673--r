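# Brightness-distribution stoichiometry: estimate the monomer brightness
# distribution rho_1(B), build the n-mer distributions rho_n(B) by
# autoconvolution, and fit the overall single-spot brightness distribution
# rho(B) = sum_n alpha_n rho_n(B), sum_n alpha_n = 1.

#' Discretized brightness probability distribution
#'
#' Uniform-width histogram representation of a brightness PDF. The
#' \code{offset} is the left edge of the first bin; bin k (1-based) covers
#' \code{[offset + (k-1)*width, offset + k*width)} with its mass treated as
#' concentrated at the bin center. Carrying the offset explicitly is what
#' keeps autoconvolution exact: the sum of n bin-center values lands on a
#' grid shifted by \code{(n-1)*width/2}, and the representation records that
#' shift instead of rounding it away, so \code{mean(rho_n) = n * mean(rho_1)}
#' holds to machine precision.
#'
#' @param mass Non-negative bin masses summing to 1 (tolerance 1e-9).
#' @param width Bin width in photons (> 0).
#' @param offset Left edge of the first bin (>= 0 for brightness data).
#' @return Object of class \code{brightness_pdf}.
#' @export
brightness_pdf <- function(mass, width, offset = 0) {
  if (!is.numeric(mass) || length(mass) < 1L || any(mass < 0))
    stop_arg("'mass' must be non-negative")
  if (abs(sum(mass) - 1) > 1e-9)
    stop_arg("'mass' must sum to 1 (got ", format(sum(mass)), ")")
  check_scalar(width, "width", lower = 0, strict_lower = TRUE)
  check_scalar(offset, "offset", lower = 0)
  structure(list(mass = as.numeric(mass), width = width, offset = offset),
            class = "brightness_pdf")
}

#' Bin centers of a brightness PDF
#' @param rho A \code{\link{brightness_pdf}}.
#' @return Numeric vector of bin-center brightness values (photons).
#' @export
pdf_centers <- function(rho) {
  rho$offset + (seq_along(rho$mass) - 0.5) * rho$width
}

#' Mean of a brightness PDF
#' @param rho A \code{\link{brightness_pdf}}.
#' @return Mean brightness in photons.
#' @export
pdf_mean <- function(rho) {
  sum(rho$mass * pdf_centers(rho))
}

#' Estimate the monomer brightness distribution rho_1(B)
#'
#' Normalized histogram of calibration-frame single-molecule brightness
#' values on a uniform grid whose support extends to \code{n_max *
#' max(samples)} (plus margin), so that all autoconvolutions up to order
#' \code{n_max} fit on the grid without truncation.
#'
#' @param samples Positive monomer brightness values (photons).
#' @param bin_width Histogram bin width; default \code{sd(samples) / 5}.
#' @param n_max Highest oligomer order the grid must accommodate.
#' @param min_samples Minimum required calibration sample size.
#' @return A \code{\link{brightness_pdf}} (rho_1).
#' @export
estimate_monomer_pdf <- function(samples, bin_width = NULL, n_max = 4,
                                 min_samples = 100) {
  if (length(samples) == 0) stop_arg("no monomer brightness samples")
  if (length(samples) < min_samples)
    stop_arg("calibration requires >= ", min_samples, " samples, got ",
             length(samples))
  if (any(!is.finite(samples) | samples < 0))
    stop_arg("brightness samples must be finite and non-negative")
  if (is.null(bin_width)) {
    bin_width <- stats::sd(samples) / 5
    if (!is.finite(bin_width) || bin_width <= 0)
      bin_width <- max(samples) / 50   # degenerate samples: arbitrary fine grid
  }
  check_scalar(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  n_bins <- ceiling((n_max * max(samples)) / bin_width) + n_max + 1L
  idx <- pmin(floor(samples / bin_width) + 1L, n_bins)
  mass <- tabulate(idx, nbins = n_bins) / length(samples)
  brightness_pdf(mass, width = bin_width, offset = 0)
}

#' n-fold autoconvolution of a brightness distribution
#'
#' Computes rho_n, the distribution of the sum of n independent draws from
#' rho_1, by direct discrete self-convolution of the bin masses (no FFT, no
#' approximation beyond the shared binning). Total mass is preserved exactly
#' and the output grid's offset absorbs the half-bin shifts so that
#' \code{mean(rho_n) = n * mean(rho_1)}.
#'
#' @param rho1 A \code{\link{brightness_pdf}}.
#' @param n Oligomer order (integer >= 1); \code{n = 1} returns \code{rho1}.
#' @return A \code{\link{brightness_pdf}} (rho_n).
#' @export
autoconvolve <- function(rho1, n) {
  if (!inherits(rho1, "brightness_pdf"))
    stop_arg("'rho1' must be a brightness_pdf")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_arg("'n' must be an integer >= 1")
  n <- as.integer(n)
  if (n == 1L) return(rho1)
  m <- rho1$mass
  out <- m
  for (i in seq_len(n - 1L)) {
    # direct convolution: out_k = sum_j out_j * m_{k-j}
    len <- length(out) + length(m) - 1L
    acc <- numeric(len)
    nz <- which(m > 0)
    for (j in nz) acc[(j - 1L) + seq_along(out)] <-
        acc[(j - 1L) + seq_along(out)] + m[j] * out
    out <- acc
  }
  brightness_pdf(out, width = rho1$width,
                 offset = n * rho1$offset + (n - 1L) * rho1$width / 2)
}

# Project a brightness_pdf onto a target uniform grid (same width, offset
# grid possibly shifted by a non-integer number of bins). Mass within each
# source bin is split between the two overlapping target bins in proportion
# to the overlap. Exact for aligned and half-bin-shifted grids.
# Returns list(mass = vector over target bins, lost = mass off-grid).
project_to_grid <- function(rho, target_offset, n_bins) {
  s <- (rho$offset - target_offset) / rho$width  # shift in bins
  k <- floor(s + 1e-12)
  f <- s - k                                     # in [0, 1)
  if (abs(f) < 1e-12) f <- 0
  mass <- numeric(n_bins)
  lost <- 0
  place <- function(mass, idx, m) {
    ok <- idx >= 1L & idx <= n_bins
    if (any(ok)) {
      tab <- tapply(m[ok], idx[ok], sum)
      mass[as.integer(names(tab))] <- mass[as.integer(names(tab))] + tab
    }
    lost <<- lost + sum(m[!ok])
    mass
  }
  src_idx <- seq_along(rho$mass) + k
  mass <- place(mass, src_idx, rho$mass * (1 - f))
  if (f > 0) mass <- place(mass, src_idx + 1L, rho$mass * f)
  list(mass = mass, lost = lost)
}

#' Fit oligomer mixture weights to a brightness sample
#'
#' Fits the overall single-spot brightness distribution as the linear
#' combination \code{rho(B) = sum_n alpha_n rho_n(B)} with \code{alpha_n >=
#' 0} and \code{sum_n alpha_n = 1}, where each rho_n is the n-fold
#' autoconvolution of the calibrated monomer distribution. The default
#' criterion is the multinomial maximum likelihood of the binned sample,
#' maximised by expectation-maximisation on the simplex: the problem is
#' convex in alpha, the EM iteration respects the constraints exactly, and a
#' fixed initialisation (uniform weights), iteration cap and tolerance make
#' the fit deterministic. A least-squares criterion on the binned relative
#' frequencies is available for sensitivity checks.
#'
#' Spots brighter than the n_max-mer envelope (off the mixture's support)
#' cannot be explained by any component; they are excluded from the fit and
#' counted in \code{n_excluded}.
#'
#' @param samples Spot brightness values (photons) from the analysis frames.
#' @param rho1 Monomer distribution from \code{\link{estimate_monomer_pdf}}.
#' @param n_max Highest oligomer order to fit (>= 1).
#' @param method \code{"ml"} (multinomial maximum likelihood, default) or
#'   \code{"ls"} (least squares on binned frequencies).
#' @param max_iter,tol EM iteration cap and convergence tolerance on
#'   \code{max |delta alpha|}.
#' @return Object of class \code{oligomer_fractions}: \code{alpha} (length
#'   n_max, sums to 1), \code{sd} (NA until bootstrapped), \code{n_max},
#'   \code{n_used}, \code{n_excluded}, \code{iterations}, \code{converged},
#'   \code{loglik}, \code{method}.
#' @export
fit_mixture <- function(samples, rho1, n_max = 4, method = c("ml", "ls"),
                        max_iter = 10000, tol = 1e-10) {
  method <- match.arg(method)
  if (!inherits(rho1, "brightness_pdf"))
    stop_arg("'rho1' must be a brightness_pdf")
  if (!is.numeric(n_max) || n_max < 1 || n_max != round(n_max))
    stop_arg("'n_max' must be an integer >= 1")
  n_max <- as.integer(n_max)
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) stop_arg("no brightness samples to fit")
  w <- rho1$width
  K <- length(rho1$mass)
  # component matrix on rho1's grid
  P <- matrix(0, nrow = K, ncol = n_max)
  for (n in seq_len(n_max)) {
    rn <- autoconvolve(rho1, n)
    pr <- project_to_grid(rn, rho1$offset, K)
    if (pr$lost > 1e-6)
      stop_arg("autoconvolution mass lost to grid truncation (",
               format(pr$lost), "); extend the rho1 grid (larger n_max ",
               "margin or wider support)")
    P[, n] <- pr$mass
  }
  idx <- floor((samples - rho1$offset) / w) + 1L
  in_grid <- idx >= 1L & idx <= K
  counts <- tabulate(idx[in_grid], nbins = K)
  support <- rowSums(P) > 0
  n_excluded <- sum(!in_grid) + sum(counts[!support])
  counts[!support] <- 0L
  n_used <- sum(counts)
  if (n_used == 0) stop_arg("all samples fall outside the mixture support")
  occ <- which(counts > 0)
  cj <- counts[occ]
  Pj <- P[occ, , drop = FALSE]

  if (n_max == 1L) {
    alpha <- 1
    iter <- 0L; conv <- TRUE
  } else if (method == "ml") {
    alpha <- rep(1 / n_max, n_max)
    conv <- FALSE
    for (iter in seq_len(max_iter)) {
      num <- Pj * rep(alpha, each = nrow(Pj))      # responsibilities
      denom <- rowSums(num)
      if (any(denom == 0)) {                        # unexplained occupied bin
        drop <- denom == 0
        n_excluded <- n_excluded + sum(cj[drop])
        n_used <- n_used - sum(cj[drop])
        cj <- cj[!drop]; Pj <- Pj[!drop, , drop = FALSE]
        num <- num[!drop, , drop = FALSE]; denom <- denom[!drop]
        if (length(cj) == 0) stop_arg("no samples on the mixture support")
      }
      new_alpha <- colSums(num * (cj / denom)) / sum(cj)
      delta <- max(abs(new_alpha - alpha))
      alpha <- new_alpha
      if (delta < tol) { conv <- TRUE; break }
    }
  } else {
    # exact simplex-constrained least squares: enumerate active sets (the
    # problem is a tiny convex QP; with n_max <= ~8 this is both exact and
    # deterministic), solving each support's equality-constrained normal
    # equations and keeping the best feasible solution
    fj <- cj / sum(cj)
    best <- NULL; best_sse <- Inf
    for (mask in seq_len(2^n_max - 1L)) {
      S <- which(bitwAnd(mask, 2^(seq_len(n_max) - 1L)) > 0)
      Ps <- Pj[, S, drop = FALSE]
      k <- length(S)
      kkt <- rbind(cbind(2 * crossprod(Ps), rep(1, k)),
                   c(rep(1, k), 0))
      sol <- tryCatch(solve(kkt, c(2 * crossprod(Ps, fj), 1)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      a <- sol[seq_len(k)]
      if (any(a < -1e-10)) next
      a <- pmax(a, 0); a <- a / sum(a)
      sse <- sum((fj - as.numeric(Ps %*% a))^2)
      if (sse < best_sse - 1e-15) {
        best_sse <- sse
        best <- numeric(n_max); best[S] <- a
      }
    }
    if (is.null(best)) stop_arg("least-squares mixture fit failed")
    alpha <- best
    iter <- 0L; conv <- TRUE
  }
  if (!conv)
    stop_arg("mixture fit did not converge within ", max_iter, " iterations")
  alpha <- alpha / sum(alpha)
  ll <- {
    mix <- as.numeric(Pj %*% alpha)
    sum(cj * log(mix))
  }
  structure(list(alpha = alpha, sd = rep(NA_real_, n_max), n_max = n_max,
                 n_used = n_used, n_excluded = n_excluded,
                 iterations = iter, converged = conv, loglik = ll,
                 method = method),
            class = "oligomer_fractions")
}

#' @export
print.oligomer_fractions <- function(x, ...) {
  cat("Oligomer fractions (", x$method, " fit, n_max = ", x$n_max, ")\n",
      sep = "")
  for (n in seq_len(x$n_max)) {
    cat(sprintf("  alpha_%d = %.4f", n, x$alpha[n]))
    if (is.finite(x$sd[n])) cat(sprintf(" +- %.4f", x$sd[n]))
    cat("\n")
  }
  cat("  spots used:", x$n_used, " excluded:", x$n_excluded, "\n")
  invisible(x)
}

#' Bootstrap standard deviations for mixture fractions
#'
#' Refits the mixture on random subsamples of the spot brightness data —
#' by default 50% of the spots, drawn without replacement, in 100
#' repetitions — and reports the standard deviation of each fitted
#' \code{alpha_n} over the repetitions.
#'
#' @param samples Spot brightness values.
#' @param rho1 Monomer distribution.
#' @param n_max Highest order.
#' @param subsample_fraction Fraction of spots per repetition (default 0.5).
#' @param reps Number of repetitions (default 100, >= 2).
#' @param seed Optional integer seed.
#' @param method Fit criterion, as in \code{\link{fit_mixture}}.
#' @return List: \code{sd} (per-component SDs), \code{alphas} (reps x n_max
#'   matrix of subsample fits), \code{n_skipped}.
#' @export
bootstrap_fractions <- function(samples, rho1, n_max = 4,
                                subsample_fraction = 0.5, reps = 100,
                                seed = NULL, method = "ml") {
  if (reps < 2) stop_arg("'reps' must be >= 2")
  check_scalar(subsample_fraction, "subsample_fraction", lower = 0,
               upper = 1, strict_lower = TRUE)
  N <- length(samples)
  m <- floor(subsample_fraction * N)
  with_seed(seed, {
    alphas <- matrix(NA_real_, nrow = reps, ncol = n_max)
    skipped <- 0L
    for (r in seq_len(reps)) {
      if (m < 1) { skipped <- skipped + 1L; next }
      sub <- samples[sample.int(N, m)]
      fit <- tryCatch(fit_mixture(sub, rho1, n_max, method = method),
                      error = function(e) NULL)
      if (is.null(fit)) skipped <- skipped + 1L
      else alphas[r, ] <- fit$alpha
    }
    if (skipped > 0.2 * reps)
      stop_arg(skipped, " of ", reps, " bootstrap repetitions failed")
    list(sd = apply(alphas, 2, stats::sd, na.rm = TRUE),
         alphas = alphas, n_skipped = skipped)
  })
}

#' Full TOCCSL stoichiometry analysis of one run
#'
#' Chains the stages: monomer calibration (rho_1 from the calibration-frame
#' brightness values), autoconvolution to rho_2 .. rho_n_max, constrained
#' mixture fit of the TOCCSL-frame brightness values, and bootstrap
#' uncertainties; additionally reports the prebleach surface density and
#' spot counts as quality control.
#'
#' @param brightness_table Output of \code{\link{extract_brightness_table}}
#'   containing accepted \code{toccsl}-role rows (and optionally
#'   \code{prebleach}-role rows for density).
#' @param calibration_table Table containing accepted \code{calibration}-role
#'   rows whose \code{B} values calibrate rho_1. May be the same object as
#'   \code{brightness_table}.
#' @param config List of settings: \code{bin_width} (NULL for the default),
#'   \code{n_max} (default 4), \code{bootstrap_fraction} (0.5),
#'   \code{bootstrap_reps} (100), \code{seed}, \code{method} ("ml"),
#'   \code{min_calibration} (100), \code{prebleach_area_um2} (per-frame field
#'   area, for density).
#' @return Object of class \code{toccsl_result}: \code{fractions} (an
#'   \code{oligomer_fractions} with bootstrap SDs filled in),
#'   \code{density_per_um2} (NA without prebleach information), \code{qc}
#'   (spot counts, exclusions, EM iterations, config echo).
#' @export
analyze_toccsl_run <- function(brightness_table, calibration_table,
                               config = list()) {
  defaults <- list(bin_width = NULL, n_max = 4, bootstrap_fraction = 0.5,
                   bootstrap_reps = 100, seed = NULL, method = "ml",
                   min_calibration = 100, prebleach_area_um2 = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_arg("unknown config entries: ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (nrow(brightness_table) == 0 || nrow(calibration_table) == 0)
    stop_arg("brightness and calibration tables must be non-empty")
  cal <- calibration_table[calibration_table$frame_role == "calibration" &
                             calibration_table$accepted &
                             is.finite(calibration_table$B), ]
  toc <- brightness_table[brightness_table$frame_role == "toccsl" &
                            brightness_table$accepted &
                            is.finite(brightness_table$B), ]
  if (nrow(toc) == 0) stop_arg("no accepted TOCCSL spots")
  rho1 <- estimate_monomer_pdf(cal$B, bin_width = config$bin_width,
                               n_max = config$n_max,
                               min_samples = config$min_calibration)
  fit <- fit_mixture(toc$B, rho1, n_max = config$n_max,
                     method = config$method)
  boot <- bootstrap_fractions(toc$B, rho1, n_max = config$n_max,
                              subsample_fraction = config$bootstrap_fraction,
                              reps = config$bootstrap_reps,
                              seed = config$seed, method = config$method)
  fit$sd <- boot$sd
  density <- NA_real_
  pre <- brightness_table[brightness_table$frame_role == "prebleach", ]
  if (nrow(pre) > 0 && !is.null(config$prebleach_area_um2)) {
    n_frames <- length(unique(pre$frame))
    density <- nrow(pre) / (n_frames * config$prebleach_area_um2)
  }
  structure(list(fractions = fit, rho1 = rho1,
                 density_per_um2 = density,
                 qc = list(n_toccsl_spots = nrow(toc),
                           n_calibration_spots = nrow(cal),
                           n_prebleach_spots = nrow(pre),
                           n_excluded = fit$n_excluded,
                           em_iterations = fit$iterations,
                           bootstrap_skipped = boot$n_skipped,
                           config = config)),
            class = "toccsl_result")
}

#' @export
print.toccsl_result <- function(x, ...) {
  print(x$fractions)
  cat(sprintf("  prebleach density: %s /um^2\n",
              format(x$density_per_um2, digits = 4)))
  invisible(x)
}
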
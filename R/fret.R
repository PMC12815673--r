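# Sensitized-emission FRET: spectral bleed-through correction and
# normalized FRET (NFRET) per cell/ROI.

#' Spectral bleed-through coefficients
#'
#' Fractions of pure donor-only and acceptor-only signal appearing in the
#' FRET channel. Defaults are the CFP/YFP pair's measured values (donor 0.57,
#' acceptor 0.04).
#'
#' @param bt_donor Donor bleed-through (>= 0, < 1).
#' @param bt_acceptor Acceptor bleed-through (>= 0).
#' @return Object of class \code{bleedthrough}.
#' @export
bleedthrough <- function(bt_donor = 0.57, bt_acceptor = 0.04) {
  check_scalar(bt_donor, "bt_donor", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_scalar(bt_acceptor, "bt_acceptor", lower = 0)
  structure(list(bt_donor = bt_donor, bt_acceptor = bt_acceptor),
            class = "bleedthrough")
}

#' Estimate bleed-through from single-label controls
#'
#' Cells expressing only the donor or only the acceptor fluorophore measure
#' how much of each pure signal leaks into the FRET channel: the donor
#' coefficient is the mean of \code{i_fret / i_donor} over donor-only ROIs,
#' the acceptor coefficient the mean of \code{i_fret / i_acceptor} over
#' acceptor-only ROIs. ROIs with a non-positive denominator are rejected.
#'
#' @param donor_only Data frame with columns \code{i_fret}, \code{i_donor}.
#' @param acceptor_only Data frame with columns \code{i_fret},
#'   \code{i_acceptor}.
#' @return A \code{\link{bleedthrough}} object.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only) {
  dk <- donor_only$i_donor > 0
  ak <- acceptor_only$i_acceptor > 0
  if (!any(dk) || !any(ak))
    stop_arg("need at least one usable donor-only and acceptor-only ROI")
  bleedthrough(
    bt_donor = mean(donor_only$i_fret[dk] / donor_only$i_donor[dk]),
    bt_acceptor = mean(acceptor_only$i_fret[ak] / acceptor_only$i_acceptor[ak]))
}

#' Compute normalized FRET
#'
#' NFRET = (I_FRET - BT_donor * I_donor - BT_acceptor * I_acceptor) /
#' sqrt(I_donor * I_acceptor), on background-subtracted ROI mean intensities
#' in a common arbitrary unit. The value is dimensionless, invariant under
#' uniform rescaling of all three intensities, and may be negative for noisy
#' ROIs (negative values are deliberately retained: clipping would bias
#' condition means upward).
#'
#' @param i_fret,i_donor,i_acceptor Channel intensities (vectors of equal
#'   length; \code{i_donor} and \code{i_acceptor} must be > 0).
#' @param bt A \code{\link{bleedthrough}} object.
#' @return Numeric vector of NFRET values.
#' @export
compute_nfret <- function(i_fret, i_donor, i_acceptor, bt = bleedthrough()) {
  if (!inherits(bt, "bleedthrough")) stop_arg("'bt' must be a bleedthrough")
  if (any(i_donor <= 0) || any(i_acceptor <= 0))
    stop_arg("donor and acceptor intensities must be > 0")
  (i_fret - bt$bt_donor * i_donor - bt$bt_acceptor * i_acceptor) /
    sqrt(i_donor * i_acceptor)
}

#' Summarize NFRET values per condition
#'
#' Mean and standard deviation of per-ROI NFRET values by condition, on the
#' x100 scale conventionally used for plotting.
#'
#' @param data Data frame with columns \code{condition} and \code{nfret}.
#' @return Data frame \code{condition}, \code{n}, \code{mean_x100},
#'   \code{sd_x100}; conditions with fewer than 2 ROIs are dropped with a
#'   warning.
#' @export
summarize_nfret <- function(data) {
  if (!all(c("condition", "nfret") %in% names(data)))
    stop_arg("'data' needs columns condition and nfret")
  sp <- split(data$nfret, data$condition)
  small <- names(sp)[lengths(sp) < 2]
  if (length(small)) {
    warning("dropping condition(s) with < 2 ROIs: ",
            paste(small, collapse = ", "), call. = FALSE)
    sp <- sp[lengths(sp) >= 2]
  }
  if (length(sp) == 0) stop_arg("no condition has >= 2 ROIs")
  out <- data.frame(
    condition = names(sp),
    n = as.integer(lengths(sp)),
    mean_x100 = vapply(sp, function(v) 100 * mean(v), numeric(1)),
    sd_x100 = vapply(sp, function(v) 100 * stats::sd(v), numeric(1)))
  rownames(out) <- NULL
  out
}
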
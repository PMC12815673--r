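#' Ground-truth oligomer mixture
#'
#' Molecule-level composition of the simulated transporter population:
#' the fraction of molecules (not of subunits) in each oligomeric state
#' n = 1..n_max, together with the per-order probability that a molecule is
#' laterally mobile in the membrane. Keeping mobility per order is what lets
#' the simulator reproduce the mobility confound of aperture-based
#' single-molecule stoichiometry: only mobile molecules re-enter the bleached
#' region, so the analyzable population can differ from the total one.
#'
#' @param fractions Numeric vector of molecule fractions per oligomer order
#'   (order 1 first); must be non-negative and sum to 1.
#' @param mobile_fraction_by_order Probability that a molecule of each order
#'   is mobile; recycled to \code{length(fractions)}; each in [0, 1].
#' @param p_active Probability that a subunit carries an active (matured,
#'   non-bleached) fluorophore; default 1.
#' @return An object of class \code{oligomer_mixture}.
#' @export
oligomer_mixture <- function(fractions,
                             mobile_fraction_by_order = 1,
                             p_active = 1) {
  if (!is.numeric(fractions) || length(fractions) < 1L || any(fractions < 0))
    stop_arg("'fractions' must be non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_arg("'fractions' must sum to 1 (got ", format(sum(fractions)), ")")
  mob <- rep_len(mobile_fraction_by_order, length(fractions))
  if (any(mob < 0 | mob > 1))
    stop_arg("'mobile_fraction_by_order' entries must lie in [0, 1]")
  check_scalar(p_active, "p_active", lower = 0, upper = 1)
  structure(list(fractions = as.numeric(fractions),
                 mobile_fraction_by_order = mob,
                 p_active = p_active,
                 n_max = length(fractions)),
            class = "oligomer_mixture")
}

#' Overall mobile fraction implied by an oligomer mixture
#'
#' Molecule-weighted average of the per-order mobility probabilities; this is
#' the mobile fraction a FRAP experiment on the same population measures.
#'
#' @param mixture An \code{\link{oligomer_mixture}}.
#' @return Scalar in [0, 1].
#' @export
mixture_mobile_fraction <- function(mixture) {
  sum(mixture$fractions * mixture$mobile_fraction_by_order)
}

#' Simulate a field of membrane molecules
#'
#' Places molecules in a square membrane patch: the molecule count is Poisson
#' with mean \code{density * field_size^2}, positions are uniform, the
#' oligomer order of each molecule is drawn from the mixture fractions, its
#' mobility flag from the order-specific mobility probability, and the number
#' of active fluorophores is Binomial(order, p_active).
#'
#' @param mixture An \code{\link{oligomer_mixture}}.
#' @param density Molecule surface density in molecules/um^2 (> 0).
#' @param field_size Side length of the square field in um (> 0).
#' @param diffusion_um2_s Diffusion coefficient assigned to mobile molecules
#'   (um^2/s).
#' @param seed Optional integer seed.
#' @return A \code{data.frame} of class \code{molecule_field} with columns
#'   \code{x}, \code{y} (um), \code{order}, \code{n_active}, \code{mobile},
#'   \code{d_um2_s}; attributes \code{field_size} and \code{mixture}.
#' @export
build_molecule_field <- function(mixture, density, field_size,
                                 diffusion_um2_s = 0.1, seed = NULL) {
  if (!inherits(mixture, "oligomer_mixture"))
    stop_arg("'mixture' must be an oligomer_mixture")
  check_scalar(density, "density", lower = 0, strict_lower = TRUE)
  check_scalar(field_size, "field_size", lower = 0, strict_lower = TRUE)
  check_scalar(diffusion_um2_s, "diffusion_um2_s", lower = 0)
  with_seed(seed, {
    n <- stats::rpois(1L, density * field_size^2)
    order <- if (n > 0)
      sample.int(mixture$n_max, n, replace = TRUE, prob = mixture$fractions)
    else integer(0)
    mobile <- stats::runif(n) < mixture$mobile_fraction_by_order[order]
    n_active <- if (mixture$p_active >= 1) order
                else stats::rbinom(n, size = order, prob = mixture$p_active)
    field <- data.frame(
      x = stats::runif(n, 0, field_size),
      y = stats::runif(n, 0, field_size),
      order = order,
      n_active = as.integer(n_active),
      mobile = mobile,
      d_um2_s = ifelse(mobile, diffusion_um2_s, 0)
    )
    attr(field, "field_size") <- field_size
    attr(field, "mixture") <- mixture
    class(field) <- c("molecule_field", "data.frame")
    field
  })
}
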
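#' Förster parameters
#'
#' Bundle of photophysical parameters for distance/efficiency conversion:
#' the Förster radius \eqn{R} of the dye pair (distance of half-maximal
#' transfer; 50 Å for the Atto-495/Atto-565 pair used throughout) and the
#' excitation wavelength used in the spectroscopic estimators.
#'
#' @param forster_radius Förster radius in Å. Must be positive.
#' @param excitation_wavelength Excitation wavelength in nm.
#' @return An object of class `"fret_params"`.
#' @examples
#' p <- fret_params()
#' forward_efficiency(50, p)
#' @export
fret_params <- function(forster_radius = 50, excitation_wavelength = 470) {
  stopifnot(is.numeric(forster_radius), length(forster_radius) == 1L,
            is.finite(forster_radius))
  if (forster_radius <= 0)
    stop("'forster_radius' must be positive", call. = FALSE)
  structure(list(forster_radius = forster_radius,
                 excitation_wavelength = excitation_wavelength),
            class = "fret_params")
}

#' @export
print.fret_params <- function(x, ...) {
  cat("FRET parameters: R =", x$forster_radius, "A, excitation",
      x$excitation_wavelength, "nm\n")
  invisible(x)
}

#' Forward Förster efficiency
#'
#' Transfer efficiency of a single donor–acceptor pair at distance `r`:
#' \deqn{E = \frac{1}{1 + (r/R)^6}}
#' Strictly decreasing in `r`, equal to 1 at `r = 0` and 0.5 at `r = R`.
#'
#' @param r Donor–acceptor distance(s) in Å, nonnegative.
#' @param params A [fret_params()] object.
#' @return Efficiency value(s) in `[0, 1]`.
#' @export
forward_efficiency <- function(r, params = fret_params()) {
  stopifnot(inherits(params, "fret_params"), is.numeric(r))
  if (any(!is.finite(r)) || any(r < 0))
    stop("distances 'r' must be finite and nonnegative", call. = FALSE)
  1 / (1 + (r / params$forster_radius)^6)
}

#' Relative donor–acceptor distance from an efficiency
#'
#' Inverts the Förster law to the dimensionless distance
#' \eqn{r/R = (1/E - 1)^{1/6}}. Only defined on the open interval (0, 1);
#' a measured efficiency of exactly 0 or 1 carries no finite distance.
#'
#' @param efficiency Efficiency value(s), each strictly inside (0, 1).
#' @return Relative distance(s) `r/R` (dimensionless).
#' @export
relative_distance <- function(efficiency) {
  stopifnot(is.numeric(efficiency))
  if (any(!is.finite(efficiency)) || any(efficiency <= 0) || any(efficiency >= 1))
    stop("'efficiency' must lie strictly inside (0, 1)", call. = FALSE)
  (1 / efficiency - 1)^(1 / 6)
}

#' Apparent donor–acceptor distance
#'
#' `relative_distance(efficiency) * R`, in Å. For a multi-label measurement
#' this is an effective, not a physical, separation: the single distance
#' whose Förster efficiency equals the aggregate measured efficiency.
#'
#' @inheritParams relative_distance
#' @inheritParams forward_efficiency
#' @return Apparent distance(s) in Å.
#' @export
apparent_distance <- function(efficiency, params = fret_params()) {
  stopifnot(inherits(params, "fret_params"))
  relative_distance(efficiency) * params$forster_radius
}

#' Occupancy-weighted monomer efficiency
#'
#' Aggregates the pairwise efficiencies between one acceptor-bearing monomer
#' and every candidate donor site into a single expected efficiency,
#' \eqn{E_m = \sum_j w_j E_{mj}}, where the weights are the assumed occupancy
#' distribution of the (single) donor label over its candidate attachment
#' sites. Weights must be nonnegative and sum to 1; the default is uniform.
#'
#' @param pair_efficiencies Numeric vector of pairwise efficiencies, one per
#'   donor site, each in `[0, 1]`.
#' @param weights Occupancy weights, same length, nonnegative, summing to 1
#'   within 1e-9. Default uniform.
#' @return A single efficiency in `[0, 1]`.
#' @export
aggregate_monomer_efficiency <- function(pair_efficiencies, weights = NULL) {
  stopifnot(is.numeric(pair_efficiencies), length(pair_efficiencies) >= 1L)
  if (any(!is.finite(pair_efficiencies)) ||
      any(pair_efficiencies < 0) || any(pair_efficiencies > 1))
    stop("pair efficiencies must lie in [0, 1]", call. = FALSE)
  n <- length(pair_efficiencies)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n)
    stop("'weights' length (", length(weights),
         ") does not match number of pair efficiencies (", n, ")", call. = FALSE)
  if (any(weights < 0))
    stop("'weights' must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1 (got ", format(sum(weights)), ")", call. = FALSE)
  sum(weights * pair_efficiencies)
}

#' Combine the two monomer efficiencies of a doubly labeled dimer
#'
#' With one acceptor on each monomer of the dimer, the probability that the
#' excited donor transfers to at least one of them is
#' \deqn{E_{total} = 1 - (1 - E_1)(1 - E_2).}
#' Symmetric, bounded by `max(e1, e2) <= e_total <= min(1, e1 + e2)`.
#'
#' @param e1,e2 Monomer aggregate efficiencies, each in `[0, 1]`.
#' @return Combined efficiency in `[0, 1]`.
#' @export
combine_total <- function(e1, e2) {
  stopifnot(is.numeric(e1), is.numeric(e2))
  if (any(!is.finite(c(e1, e2))) || any(c(e1, e2) < -1e-12) ||
      any(c(e1, e2) > 1 + 1e-12))
    stop("'e1' and 'e2' must lie in [0, 1]", call. = FALSE)
  out <- 1 - (1 - e1) * (1 - e2)
  clamp_unit(out)
}

# Absorb floating error <= 1e-12 outside [0,1]; anything larger is a logic
# error upstream and must surface.
clamp_unit <- function(x, tol = 1e-12) {
  bad <- x < -tol | x > 1 + tol
  if (any(bad, na.rm = TRUE))
    stop("efficiency outside [0, 1] beyond floating tolerance: ",
         paste(format(x[bad]), collapse = ", "), call. = FALSE)
  pmin(pmax(x, 0), 1)
}
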
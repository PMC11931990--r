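#' Default Gaussian band parameters for the synthetic dye pair
#'
#' Band positions emulate the Atto-495-like donor (absorbance maximum at
#' 500 nm with a non-fluorescent 475 nm satellite produced by
#' protein-bound dye, emission maximum 530 nm) and the Atto-565-like
#' acceptor (absorbance maximum 565 nm with a blue vibronic shoulder that
#' gives the dye its residual absorbance at the 470 nm excitation
#' wavelength, emission maximum 595 nm).
#'
#' @return Nested list of Gaussian band definitions (`center`, `sigma`,
#'   `amplitude`, all vectors of equal length) for `donor_absorbance`,
#'   `donor_emission`, `acceptor_absorbance`, `acceptor_emission`.
#' @export
default_band_params <- function() {
  list(donor_absorbance = list(center = c(500, 475), sigma = c(18, 15),
                               amplitude = c(0.50, 0.15)),
       donor_emission = list(center = 530, sigma = 20, amplitude = 1.0),
       acceptor_absorbance = list(center = c(565, 520), sigma = c(25, 35),
                                  amplitude = c(0.90, 0.30)),
       acceptor_emission = list(center = 595, sigma = 22, amplitude = 1.2))
}

gaussian_bands <- function(grid, band) {
  v <- numeric(length(grid))
  for (i in seq_along(band$center))
    v <- v + band$amplitude[i] *
      exp(-(grid - band$center[i])^2 / (2 * band$sigma[i]^2))
  v
}

#' Synthetic donor/acceptor/mixture spectra for a known FRET efficiency
#'
#' Generates the six spectra of a FRET experiment — absorbance and
#' emission for the donor-only, acceptor-only and mixed sample — from
#' Gaussian bands, wired so that on noiseless data both spectroscopic
#' estimators ([efret_donor_quenching()], [efret_stimulated_emission()],
#' via [efret_from_spectra()]) recover `efficiency` exactly:
#'
#' * mixture absorbance is the concentration-weighted sum of the two
#'   component absorbances (absorbance does not change upon FRET);
#' * mixture donor emission is scaled by `(1 - E)` relative to its
#'   direct-excitation expectation;
#' * mixture acceptor emission receives the transferred quanta on top of
#'   direct excitation: proportional to `A_acceptor(470) + E * A_donor(470)`.
#'
#' Emission amplitudes are proportional to the component's absorbance at
#' the excitation wavelength, as for dilute samples. With `efficiency = 0`
#' and equal concentrations the mixture spectra equal the sums of the
#' component spectra exactly.
#'
#' @param efficiency Ground-truth transfer efficiency in `[0, 1)`.
#' @param band_params Band definitions, see [default_band_params()].
#' @param noise_sd Additive Gaussian noise SD (AU / emission units)
#'   applied to every spectrum (0 = noiseless).
#' @param seed Integer seed for the noise.
#' @param grid Wavelength grid in nm.
#' @param params A [fret_params()]; supplies the excitation wavelength.
#' @param conc_donor,conc_acceptor Relative component concentrations in
#'   the mixture (1 = same as the single-component samples).
#' @return List with elements `absorbance` and `emission` (each a list of
#'   `donor`, `acceptor`, `mixture` [spectrum()] objects) and `truth`
#'   (the ground-truth efficiency and generation settings).
#' @export
make_synthetic_spectra <- function(efficiency,
                                   band_params = default_band_params(),
                                   noise_sd = 0, seed = 1,
                                   grid = seq(400, 700, by = 1),
                                   params = fret_params(),
                                   conc_donor = 1, conc_acceptor = 1) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency < 0 || efficiency >= 1)
    stop("'efficiency' must be a single value in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  exc <- params$excitation_wavelength

  abs_d <- gaussian_bands(grid, band_params$donor_absorbance)
  abs_a <- gaussian_bands(grid, band_params$acceptor_absorbance)
  em_shape_d <- gaussian_bands(grid, band_params$donor_emission)
  em_shape_a <- gaussian_bands(grid, band_params$acceptor_emission)

  a_d_exc <- stats::approx(grid, abs_d, exc)$y   # donor absorbance at 470
  a_a_exc <- stats::approx(grid, abs_a, exc)$y   # acceptor absorbance at 470

  em_d <- a_d_exc * em_shape_d
  em_a <- a_a_exc * em_shape_a
  em_mix <- conc_donor * a_d_exc * (1 - efficiency) * em_shape_d +
    (conc_acceptor * a_a_exc + efficiency * conc_donor * a_d_exc) * em_shape_a
  abs_mix <- conc_donor * abs_d + conc_acceptor * abs_a

  set.seed(seed)
  noisy <- function(v) if (noise_sd > 0)
    v + stats::rnorm(length(v), 0, noise_sd) else v
  mk <- function(v, kind) {
    v <- noisy(v)
    if (kind == "absorbance") v <- pmax(v, -1e-3 + 1e-12)
    spectrum(grid, v, kind = kind)
  }
  list(absorbance = list(donor = mk(abs_d, "absorbance"),
                         acceptor = mk(abs_a, "absorbance"),
                         mixture = mk(abs_mix, "absorbance")),
       emission = list(donor = mk(em_d, "emission"),
                       acceptor = mk(em_a, "emission"),
                       mixture = mk(em_mix, "emission")),
       truth = list(efficiency = efficiency, noise_sd = noise_sd,
                    seed = seed, conc_donor = conc_donor,
                    conc_acceptor = conc_acceptor))
}
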
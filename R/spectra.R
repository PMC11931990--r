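#' Construct a spectrum
#'
#' A wavelength-gridded absorbance or fluorescence-emission trace. The grid
#' must be strictly increasing; absorbance values may dip slightly below
#' zero (baseline noise) but not beyond -1e-3 AU.
#'
#' @param wavelengths Strictly increasing numeric grid in nm, length >= 2.
#' @param values Numeric values, same length (AU for absorbance, arbitrary
#'   counts for emission).
#' @param kind Either `"absorbance"` or `"emission"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths, values, kind = c("emission", "absorbance")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(wavelengths), is.numeric(values))
  if (length(wavelengths) != length(values) || length(wavelengths) < 2L)
    stop("'wavelengths' and 'values' must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be a finite, strictly increasing grid", call. = FALSE)
  if (any(!is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  if (kind == "absorbance" && any(values < -1e-3))
    stop("absorbance values below -1e-3 AU are not a plausible baseline",
         call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values), kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.0f-%.0f nm>\n", x$kind,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$wavelengths, x$values, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = if (x$kind == "absorbance") "absorbance (AU)"
                        else "emission (a.u.)", ...)
  invisible(x)
}

#' Read / write two-column spectrum files
#'
#' Plain delimited text with two columns (wavelength, value); lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @param kind Spectrum kind, see [spectrum()].
#' @return `read_spectrum()` returns a `"spectrum"`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, kind = c("emission", "absorbance")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such spectrum file: ", path, call. = FALSE)
  tab <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(tab) < 2L)
    stop("spectrum file must have two columns (wavelength, value): ", path,
         call. = FALSE)
  spectrum(tab[[1]], tab[[2]], kind = kind)
}

#' @rdname read_spectrum
#' @param s A `"spectrum"` object.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", s$kind), con)
  utils::write.table(data.frame(s$wavelengths, s$values), con,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation restricted to the spectrum's own wavelength range;
#' any requested point outside that range is an error (no extrapolation).
#'
#' @param s A `"spectrum"`.
#' @param grid Target wavelength grid (nm), strictly increasing.
#' @return A `"spectrum"` on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"), is.numeric(grid))
  rng <- range(s$wavelengths)
  if (any(grid < rng[1] - 1e-9) || any(grid > rng[2] + 1e-9))
    stop("resampling grid extends outside the measured range [",
         rng[1], ", ", rng[2], "] nm; extrapolation is not supported",
         call. = FALSE)
  v <- stats::approx(s$wavelengths, s$values, xout = grid, rule = 1)$y
  spectrum(grid, v, kind = s$kind)
}

#' Interpolated spectrum value at given wavelengths
#'
#' @param s A `"spectrum"`.
#' @param wavelength Wavelength(s) in nm, inside the grid range.
#' @return Interpolated value(s).
#' @export
spectrum_value <- function(s, wavelength) {
  stopifnot(inherits(s, "spectrum"))
  rng <- range(s$wavelengths)
  if (any(wavelength < rng[1]) || any(wavelength > rng[2]))
    stop("wavelength ", paste(wavelength[wavelength < rng[1] | wavelength > rng[2]],
                              collapse = ", "),
         " nm outside the measured range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  stats::approx(s$wavelengths, s$values, xout = wavelength, rule = 1)$y
}

#' Decompose a mixture spectrum into donor and acceptor components
#'
#' Least-squares unmixing: finds coefficients (a, b) minimising
#' \eqn{\|mix - a\,donor - b\,acceptor\|_2} after resampling both reference
#' spectra onto the mixture grid (restricted to the common wavelength
#' overlap). With `nonnegative = TRUE` (default) negative coefficients are
#' replaced by the constrained optimum on the boundary, since negative
#' component amounts are unphysical.
#'
#' @param mixture,donor_ref,acceptor_ref `"spectrum"` objects of the same
#'   kind with overlapping wavelength ranges.
#' @param nonnegative Constrain coefficients to be >= 0 (default `TRUE`).
#' @return An object of class `"decomposition"`: list with `coeff_donor`,
#'   `coeff_acceptor`, `residual_rms`.
#' @export
decompose_mixture <- function(mixture, donor_ref, acceptor_ref,
                              nonnegative = TRUE) {
  stopifnot(inherits(mixture, "spectrum"), inherits(donor_ref, "spectrum"),
            inherits(acceptor_ref, "spectrum"))
  lo <- max(min(mixture$wavelengths), min(donor_ref$wavelengths),
            min(acceptor_ref$wavelengths))
  hi <- min(max(mixture$wavelengths), max(donor_ref$wavelengths),
            max(acceptor_ref$wavelengths))
  grid <- mixture$wavelengths[mixture$wavelengths >= lo & mixture$wavelengths <= hi]
  if (length(grid) < 3L)
    stop("wavelength ranges of mixture and references barely overlap",
         call. = FALSE)
  y <- spectrum_value(mixture, grid)
  X <- cbind(donor = spectrum_value(donor_ref, grid),
             acceptor = spectrum_value(acceptor_ref, grid))
  qrX <- qr(X)
  if (qrX$rank < 2L)
    stop("donor and acceptor reference spectra are collinear; ",
         "decomposition is rank-deficient", call. = FALSE)
  beta <- qr.coef(qrX, y)
  if (nonnegative && any(beta < 0)) {
    # 2-variable NNLS by case analysis: best of each single-component fit
    # and the origin, keeping only feasible candidates.
    cand <- list(c(max(0, sum(X[, 1] * y) / sum(X[, 1]^2)), 0),
                 c(0, max(0, sum(X[, 2] * y) / sum(X[, 2]^2))),
                 c(0, 0))
    sse <- vapply(cand, function(b) sum((y - X %*% b)^2), numeric(1))
    beta <- cand[[which.min(sse)]]
  }
  res <- y - X %*% beta
  structure(list(coeff_donor = unname(beta[1]),
                 coeff_acceptor = unname(beta[2]),
                 residual_rms = sqrt(mean(res^2)),
                 n_points = length(grid)),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("spectral decomposition: donor %.4f, acceptor %.4f (rms %.3g, %d points)\n",
              x$coeff_donor, x$coeff_acceptor, x$residual_rms, x$n_points))
  invisible(x)
}

#' Trapezoidal band integral of a spectrum
#'
#' Integrates the trace over `[lo, hi]` by the trapezoid rule, including
#' linearly interpolated values at the band edges. Additive over adjacent
#' bands.
#'
#' @param s A `"spectrum"`.
#' @param lo,hi Band limits in nm, `lo < hi`, inside the grid range.
#' @return Integrated intensity (value units x nm).
#' @export
integrate_band <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum"), is.numeric(lo), is.numeric(hi))
  if (lo >= hi) stop("'lo' must be < 'hi'", call. = FALSE)
  rng <- range(s$wavelengths)
  if (lo < rng[1] || hi > rng[2])
    stop("band [", lo, ", ", hi, "] nm outside the measured range [",
         rng[1], ", ", rng[2], "]", call. = FALSE)
  inside <- s$wavelengths > lo & s$wavelengths < hi
  w <- c(lo, s$wavelengths[inside], hi)
  v <- c(spectrum_value(s, lo), s$values[inside], spectrum_value(s, hi))
  sum(diff(w) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' FRET efficiency from donor quenching
#'
#' \deqn{E = 1 - \frac{I_{DA} A_D}{I_D A_{DA}}}
#' where `I_DA`/`I_D` are the integrated donor emission with/without the
#' acceptor present and `A_DA`/`A_D` the donor absorbance at the excitation
#' wavelength with/without the acceptor. The absorbance ratio normalises
#' away concentration differences between the two samples.
#'
#' @param I_DA,I_D Integrated donor emission intensities (arbitrary units).
#' @param A_D,A_DA Donor absorbances at the excitation wavelength (AU).
#' @return Estimated efficiency (can be negative under noise; not clamped).
#' @export
efret_donor_quenching <- function(I_DA, I_D, A_D, A_DA) {
  stopifnot(is.numeric(I_DA), is.numeric(I_D), is.numeric(A_D), is.numeric(A_DA))
  if (any(I_D <= 0) || any(A_DA <= 0))
    stop("'I_D' and 'A_DA' must be positive", call. = FALSE)
  1 - (I_DA * A_D) / (I_D * A_DA)
}

#' FRET efficiency from stimulated acceptor emission
#'
#' \deqn{E = \frac{I_{AD} A_A - I_A A_{AD}}{I_A A_{DA}}}
#' where `I_AD` is the integrated acceptor emission in the mixture (after
#' unmixing), `I_A` the acceptor-alone emission, `A_A` the acceptor-alone
#' absorbance, `A_AD` the acceptor absorbance in the mixture, and `A_DA`
#' the donor absorbance in the mixture — absorbances all taken at the same
#' reference wavelength (the excitation wavelength by default elsewhere in
#' the package; see [efret_from_spectra()]). The first term scales the
#' mixture's acceptor emission to the acceptor-alone concentration; what
#' exceeds direct excitation, relative to the donor absorbance, is
#' transferred energy.
#'
#' A negative value (acceptor emission below its direct-excitation
#' expectation) is returned as-is with a warning so that noise-driven sign
#' flips stay visible.
#'
#' @param I_AD,I_A Integrated acceptor emission in mixture / alone.
#' @param A_A,A_AD Acceptor absorbance alone / in mixture (AU).
#' @param A_DA Donor absorbance in the mixture (AU).
#' @return Estimated efficiency.
#' @export
efret_stimulated_emission <- function(I_AD, I_A, A_A, A_AD, A_DA) {
  stopifnot(is.numeric(I_AD), is.numeric(I_A), is.numeric(A_A),
            is.numeric(A_AD), is.numeric(A_DA))
  if (any(I_A <= 0) || any(A_DA <= 0))
    stop("'I_A' and 'A_DA' must be positive", call. = FALSE)
  e <- (I_AD * A_A - I_A * A_AD) / (I_A * A_DA)
  if (any(e < 0))
    warning("stimulated-emission estimate is negative (acceptor emission ",
            "below its direct-excitation expectation)", call. = FALSE)
  e
}

#' Acceptor/donor emission-peak ratio
#'
#' Ratio of the emission value at the acceptor maximum (590 nm by default)
#' to the value at the donor maximum (523 nm by default); a relative,
#' concentration-robust FRET indicator that rises monotonically with the
#' transfer efficiency.
#'
#' @param s An emission `"spectrum"`.
#' @param num_wavelength,den_wavelength Numerator / denominator wavelengths
#'   in nm.
#' @return Dimensionless ratio.
#' @export
emission_ratio <- function(s, num_wavelength = 590, den_wavelength = 523) {
  num <- spectrum_value(s, num_wavelength)
  den <- spectrum_value(s, den_wavelength)
  if (abs(den) < .Machine$double.eps)
    stop("denominator emission at ", den_wavelength, " nm is zero", call. = FALSE)
  num / den
}

#' Molar incorporation ratio from absorbances
#'
#' Ratio of chromophore (or fluorophore) concentration to protein
#' concentration, each obtained from an absorbance and its molar extinction
#' coefficient: `(a_signal / (eps_signal * correction)) / (a_280 / eps_280)`.
#' `correction` accounts for a reduced extinction coefficient of the bound
#' versus the free dye (0.7 for protein-bound Atto-495).
#'
#' @param a_signal Absorbance at the chromophore/dye band (AU).
#' @param eps_signal Its molar extinction coefficient (M^-1 cm^-1).
#' @param a_280 Absorbance at 280 nm (AU), the protein measure.
#' @param eps_280 Protein extinction coefficient at 280 nm (M^-1 cm^-1).
#' @param correction Bound/free extinction scale factor in (0, 1].
#' @return Dimensionless molar ratio.
#' @export
molar_ratio <- function(a_signal, eps_signal, a_280, eps_280, correction = 1.0) {
  vals <- c(a_signal, eps_signal, a_280, eps_280, correction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs to molar_ratio() must be positive", call. = FALSE)
  (a_signal / (eps_signal * correction)) / (a_280 / eps_280)
}
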
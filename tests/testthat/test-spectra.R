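gauss_spec <- function(center, sigma, amp = 1, grid = seq(400, 700, 1),
                       kind = "emission") {
  spectrum(grid, amp * exp(-(grid - center)^2 / (2 * sigma^2)), kind = kind)
}

test_that("spectrum construction validates its grid and values", {
  expect_s3_class(spectrum(1:5, rnorm(5)), "spectrum")
  expect_error(spectrum(c(1, 1, 2), 1:3), "strictly increasing")
  expect_error(spectrum(1:3, 1:2), "equal length")
  expect_error(spectrum(1:3, c(-0.5, 1, 1), kind = "absorbance"), "baseline")
})

test_that("spectrum files round-trip through the two-column text format", {
  s <- gauss_spec(530, 20)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, kind = "emission")
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$values, s$values)
})

test_that("mixture decomposition recovers known coefficients", {
  don <- gauss_spec(530, 20)
  acc <- gauss_spec(595, 22)
  mix <- spectrum(don$wavelengths, 0.3 * don$values + 0.7 * acc$values)
  # exact identity case
  d0 <- decompose_mixture(don, don, acc)
  expect_equal(d0$coeff_donor, 1, tolerance = 1e-10)
  expect_equal(d0$coeff_acceptor, 0, tolerance = 1e-10)
  expect_lt(d0$residual_rms, 1e-10)
  # noiseless linear combination, checked against a normal-equations oracle
  d <- decompose_mixture(mix, don, acc)
  X <- cbind(don$values, acc$values)
  oracle <- solve(t(X) %*% X, t(X) %*% mix$values)
  expect_equal(d$coeff_donor, oracle[1], tolerance = 1e-8)
  expect_equal(d$coeff_acceptor, oracle[2], tolerance = 1e-8)
  expect_equal(c(d$coeff_donor, d$coeff_acceptor), c(0.3, 0.7),
               tolerance = 1e-8)
  # noisy recovery within 0.02 (Monte-Carlo, fixed seed)
  set.seed(42)
  noisy <- spectrum(mix$wavelengths,
                    mix$values + rnorm(length(mix$values),
                                       sd = 0.01 * max(mix$values)))
  dn <- decompose_mixture(noisy, don, acc)
  expect_equal(dn$coeff_donor, 0.3, tolerance = 0.02)
  expect_equal(dn$coeff_acceptor, 0.7, tolerance = 0.02)
  # collinear references are rejected
  don2 <- spectrum(don$wavelengths, 2 * don$values)
  expect_error(decompose_mixture(mix, don, don2), "collinear")
})

test_that("nonnegative decomposition clips unphysical coefficients", {
  don <- gauss_spec(530, 20)
  acc <- gauss_spec(595, 22)
  # mixture = donor minus a bit of acceptor: unconstrained fit would go
  # negative on the acceptor coefficient
  mix <- spectrum(don$wavelengths, don$values - 0.05 * acc$values)
  d <- decompose_mixture(mix, don, acc, nonnegative = TRUE)
  expect_gte(d$coeff_acceptor, 0)
  du <- decompose_mixture(mix, don, acc, nonnegative = FALSE)
  expect_lt(du$coeff_acceptor, 0)
})

test_that("band integration is trapezoidal, additive and exact on triangles", {
  flat <- spectrum(490:520, rep(2, 31))
  expect_equal(integrate_band(flat, 500, 510), 20)
  # triangular peak of base 20 and height 3: area 30
  tri <- spectrum(490:530, pmax(0, 3 * (1 - abs(500 - (490:530)) / 10)))
  expect_equal(integrate_band(tri, 490, 530), 30, tolerance = 1e-6)
  # additivity over adjacent bands
  s <- gauss_spec(530, 20)
  expect_equal(integrate_band(s, 450, 520) + integrate_band(s, 520, 600),
               integrate_band(s, 450, 600), tolerance = 1e-9)
  expect_equal(integrate_band(spectrum(1:10, rep(0, 10)), 2, 8), 0)
  expect_error(integrate_band(s, 300, 500), "outside")
  expect_error(integrate_band(s, 510, 510), "'lo' must be")
})

test_that("the two efficiency estimators follow their defining arithmetic", {
  expect_equal(efret_donor_quenching(I_DA = 100, I_D = 100,
                                     A_D = 0.1, A_DA = 0.1), 0)
  expect_equal(efret_donor_quenching(I_DA = 0, I_D = 100,
                                     A_D = 0.1, A_DA = 0.1), 1)
  expect_equal(efret_donor_quenching(I_DA = 80, I_D = 100,
                                     A_D = 0.10, A_DA = 0.10), 0.20)
  expect_equal(efret_stimulated_emission(I_AD = 100, I_A = 100, A_A = 0.1,
                                         A_AD = 0.1, A_DA = 0.1), 0)
  expect_equal(efret_stimulated_emission(I_AD = 120, I_A = 100, A_A = 0.10,
                                         A_AD = 0.10, A_DA = 0.10), 0.20)
  expect_warning(
    e <- efret_stimulated_emission(I_AD = 80, I_A = 100, A_A = 0.1,
                                   A_AD = 0.1, A_DA = 0.1),
    "negative")
  expect_lt(e, 0)
  expect_error(efret_donor_quenching(1, 0, 0.1, 0.1), "positive")
  expect_error(efret_stimulated_emission(1, 1, 0.1, 0.1, 0), "positive")
})

test_that("emission peak ratio matches closed-form Gaussian evaluation", {
  grid <- seq(450, 700, 0.5)
  v <- 1.0 * exp(-(grid - 523)^2 / (2 * 20^2)) +
    0.6 * exp(-(grid - 590)^2 / (2 * 25^2))
  s <- spectrum(grid, v)
  at <- function(w) 1.0 * exp(-(w - 523)^2 / 800) + 0.6 * exp(-(w - 590)^2 / 1250)
  expect_equal(emission_ratio(s), at(590) / at(523), tolerance = 1e-6)
  flat <- spectrum(500:600, rep(3, 101))
  expect_equal(emission_ratio(flat), 1.0)
  expect_error(emission_ratio(spectrum(540:650, rep(1, 111))), "outside")
})

test_that("emission ratio grows monotonically with the true efficiency", {
  ratios <- sapply(c(0, 0.1, 0.2, 0.3, 0.4), function(E) {
    ss <- make_synthetic_spectra(E)
    emission_ratio(ss$emission$mixture)
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("molar incorporation ratios respect the bound-dye correction", {
  expect_equal(molar_ratio(0.5, 1e5, 0.5, 1e5), 1.0)
  # labeled-donor bookkeeping with the 0.7 bound-dye correction
  expect_equal(molar_ratio(0.0448, 80000, 0.813, 81300, correction = 0.7),
               0.08, tolerance = 1e-10)
  r1 <- molar_ratio(0.1, 8e4, 0.5, 1e5, correction = 1)
  expect_equal(molar_ratio(0.1, 8e4, 0.5, 1e5, correction = 0.5), 2 * r1)
  expect_error(molar_ratio(-0.1, 8e4, 0.5, 1e5), "positive")
})
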
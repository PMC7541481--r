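#' Gaussian spectral band
#'
#' Absorption bands are modelled as Gaussians in wavelength (a transparent
#' simplification against wavelength-domain difference spectra; a lognormal
#' or wavenumber-domain band would be marginally more physical).
#'
#' @param center band maximum (nm).
#' @param width Gaussian sigma (nm), positive.
#' @param amplitude relative extinction at the maximum, non-negative.
#' @return An object of class `spectral_band`.
#' @export
spectral_band <- function(center, width, amplitude = 1) {
  if (width <= 0) stop("band width must be positive")
  if (amplitude < 0) stop("band amplitude must be non-negative")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "spectral_band")
}

band_eval <- function(band, wl) {
  band$amplitude * exp(-(wl - band$center)^2 / (2 * band$width^2))
}

#' Sequential K -> M -> O photocycle model
#'
#' Minimal irreversible first-order chain for a proton-pumping rhodopsin
#' photocycle: a flash promotes a fraction `f` of the ground state into the
#' red-shifted K intermediate, which decays into the blue-shifted M
#' intermediate (deprotonated Schiff base), then into the red-shifted O
#' intermediate, and back to the ground state. No back-reactions and no
#' L/N-type states are modelled; light/dark adaptation is ignored (a single
#' all-trans ground state).
#'
#' The defaults describe the N2098R pump at pH 7: ground-state maximum
#' 550 nm; K, M and O bands near 620, 405 and 645 nm; M-decay rate
#' k2 = 0.016 ms^-1. The K-formation-side rate k1 = 2 ms^-1 and O-decay rate
#' k3 = 0.05 ms^-1 are modelling defaults chosen so that M rises within a
#' couple of milliseconds and the cycle completes by roughly 300 ms, matching
#' the observed timing bounds.
#'
#' @param ground,k_band,m_band,o_band [spectral_band()]s for the ground state
#'   and the three intermediates.
#' @param k1 K -> M rate (ms^-1). @param k2 M -> O rate (ms^-1, the M-decay
#'   rate constant). @param k3 O -> ground rate (ms^-1). All non-negative.
#' @param excited_fraction fraction of molecules cycled by the flash, in
#'   (0, 1].
#' @return An object of class `photocycle_model`.
#' @export
photocycle_model <- function(ground = spectral_band(550, 40, 1.0),
                             k_band = spectral_band(620, 40, 0.9),
                             m_band = spectral_band(405, 30, 0.8),
                             o_band = spectral_band(645, 40, 0.35),
                             k1 = 2, k2 = 0.016, k3 = 0.05,
                             excited_fraction = 0.3) {
  if (any(c(k1, k2, k3) < 0)) stop("rates must be non-negative")
  if (excited_fraction <= 0 || excited_fraction > 1)
    stop("excited_fraction must lie in (0, 1]")
  structure(list(ground = ground, k_band = k_band, m_band = m_band,
                 o_band = o_band, k1 = k1, k2 = k2, k3 = k3,
                 excited_fraction = excited_fraction),
            class = "photocycle_model")
}

#' Intermediate populations of the sequential photocycle
#'
#' Closed-form (Bateman) solution of the irreversible chain
#' K -> M -> O -> ground with K(0) = f. Near-degenerate rate pairs
#' (relative gap below 1e-9) are handled by the analytic t*exp(-kt) limits,
#' not by numerical cancellation-prone formulas. Mass is conserved exactly:
#' K + M + O + recovered = f.
#'
#' @param model a [photocycle_model()].
#' @param t non-negative times (ms).
#' @return Matrix with columns `K`, `M`, `O`, `recovered` (ground-state
#'   population regained), one row per time.
#' @export
concentrations <- function(model, t) {
  if (any(t < 0)) stop("times must be non-negative")
  f <- model$excited_fraction
  k1 <- model$k1; k2 <- model$k2; k3 <- model$k3
  near <- function(a, b) abs(a - b) < 1e-9 * max(a, b, 1e-300)
  K <- f * exp(-k1 * t)

  M <- if (k1 == 0) {
    rep(0, length(t))
  } else if (near(k1, k2)) {
    f * k1 * t * exp(-k1 * t)
  } else {
    f * k1 * (exp(-k1 * t) - exp(-k2 * t)) / (k2 - k1)
  }

  O <- if (k1 == 0 || k2 == 0) {
    rep(0, length(t))
  } else if (near(k1, k2) && near(k2, k3)) {
    f * k1^2 * t^2 / 2 * exp(-k1 * t)
  } else if (near(k1, k2)) {
    # M = f a t e^{-at}; convolve with e^{-k3 (t-s)}
    a <- k1; b <- a - k3
    f * a^2 * exp(-k3 * t) * (1 - (1 + b * t) * exp(-b * t)) / b^2
  } else if (near(k2, k3)) {
    c0 <- k2
    f * k1 * c0 * exp(-c0 * t) / (c0 - k1) *
      ((exp((c0 - k1) * t) - 1) / (c0 - k1) - t)
  } else if (near(k1, k3)) {
    a <- k1
    f * k1 * k2 * exp(-a * t) / (k2 - a) *
      (t + (exp((a - k2) * t) - 1) / (k2 - a))
  } else {
    f * k1 * k2 * (exp(-k1 * t) / ((k2 - k1) * (k3 - k1)) +
                   exp(-k2 * t) / ((k1 - k2) * (k3 - k2)) +
                   exp(-k3 * t) / ((k1 - k3) * (k2 - k3)))
  }
  O <- pmax(O, 0)  # guard tiny negative round-off
  cbind(K = K, M = M, O = O, recovered = f - K - M - O)
}

#' Flash-induced difference absorption spectra
#'
#' Forward model of a flash-photolysis experiment:
#' `dA(lambda, t) = K(t) bK + M(t) bM + O(t) bO - (K + M + O)(t) bG`,
#' i.e. the intermediate bands weighted by their populations minus the ground
#' band weighted by the still-depleted ground population. The matrix decays
#' to zero everywhere as the cycle completes.
#'
#' @param model a [photocycle_model()].
#' @param wavelength strictly increasing wavelength grid (nm); default
#'   370-700 nm in 5-nm steps.
#' @param t strictly increasing time grid (ms); default 100 log-spaced points
#'   spanning 0.01-977 ms.
#' @return A `flash_dataset`: list with `wavelength`, `time`, `dA`
#'   (wavelength x time matrix) and `noise_sigma = 0`.
#' @export
synth_difference_spectra <- function(model,
                                     wavelength = default_wavelength_grid(),
                                     t = default_time_grid()) {
  check_grid(wavelength, "wavelength"); check_grid(t, "time")
  pop <- concentrations(model, t)
  depleted <- pop[, "K"] + pop[, "M"] + pop[, "O"]
  bG <- band_eval(model$ground, wavelength)
  bK <- band_eval(model$k_band, wavelength)
  bM <- band_eval(model$m_band, wavelength)
  bO <- band_eval(model$o_band, wavelength)
  dA <- outer(bK, pop[, "K"]) + outer(bM, pop[, "M"]) +
        outer(bO, pop[, "O"]) - outer(bG, depleted)
  flash_dataset(wavelength, t, dA, noise_sigma = 0)
}

#' @rdname synth_difference_spectra
#' @export
default_wavelength_grid <- function() seq(370, 700, by = 5)

#' @rdname synth_difference_spectra
#' @param n number of log-spaced time points.
#' @param from,to time range (ms).
#' @export
default_time_grid <- function(n = 100L, from = 0.01, to = 977)
  exp(seq(log(from), log(to), length.out = n))

check_grid <- function(x, what) {
  if (length(x) < 1L || any(diff(x) <= 0))
    stop(what, " grid must be non-empty and strictly increasing")
  invisible(x)
}

#' Flash-photolysis dataset container
#'
#' @param wavelength,time strictly increasing grids (nm, ms).
#' @param dA wavelength-by-time difference-absorbance matrix.
#' @param noise_sigma metadata: the Gaussian noise sigma applied (0 = none).
#' @return An object of class `flash_dataset`.
#' @export
flash_dataset <- function(wavelength, time, dA, noise_sigma = 0) {
  check_grid(wavelength, "wavelength"); check_grid(time, "time")
  if (!is.matrix(dA) || nrow(dA) != length(wavelength) || ncol(dA) != length(time))
    stop("dA must be a wavelength-by-time matrix matching the grids")
  structure(list(wavelength = wavelength, time = time, dA = dA,
                 noise_sigma = noise_sigma), class = "flash_dataset")
}

#' Simulate a noisy flash-photolysis dataset
#'
#' Forward model plus i.i.d. Gaussian noise on every matrix cell.
#'
#' @param model a [photocycle_model()].
#' @param noise_sigma Gaussian sigma in dA units (non-negative).
#' @param seed RNG seed.
#' @param wavelength,t grids as in [synth_difference_spectra()].
#' @return A `flash_dataset`.
#' @export
gen_flash_dataset <- function(model, noise_sigma = 0, seed = 1L,
                              wavelength = default_wavelength_grid(),
                              t = default_time_grid()) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  ds <- synth_difference_spectra(model, wavelength, t)
  if (noise_sigma > 0) {
    ds$dA <- ds$dA + with_seed(seed, matrix(rnorm(length(ds$dA), 0, noise_sigma),
                                            nrow = nrow(ds$dA)))
  }
  ds$noise_sigma <- noise_sigma
  ds
}

#' Wavelength of maximal absorbance
#'
#' Argmax on the grid; ties resolve to the lower wavelength. An all-equal
#' spectrum has no peak and errors.
#'
#' @param spectrum absorbance values on `wavelength`.
#' @param wavelength the grid (nm).
#' @return The peak wavelength (nm).
#' @export
find_peak <- function(spectrum, wavelength) {
  if (length(spectrum) == 0L || length(spectrum) != length(wavelength))
    stop("spectrum and wavelength must be non-empty and of equal length")
  if (diff(range(spectrum)) == 0) stop("no peak: spectrum is constant")
  wavelength[which.max(spectrum)]
}

#' Pyranine proton-flux trace
#'
#' Under 1:1 stoichiometry with release on M-formation and uptake on M-decay,
#' the bulk acid excess at time t equals the current M population, so the
#' pyranine absorbance change (alkaline dye form bleached by released
#' protons) is `-coupling * M(t)`: the trace dips as M forms and returns as M
#' decays.
#'
#' @param model a [photocycle_model()].
#' @param t times (ms).
#' @param coupling non-negative dye response scale.
#' @return Numeric trace, one value per time.
#' @export
pyranine_trace <- function(model, t, coupling = 1) {
  if (coupling < 0) stop("coupling must be non-negative")
  -coupling * concentrations(model, t)[, "M"]
}
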
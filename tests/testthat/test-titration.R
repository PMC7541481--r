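test_that("Henderson-Hasselbalch occupancy identities hold", {
  expect_equal(hh_occupancy(7, 7), 0.5)
  expect_equal(hh_occupancy(9, 7), 100 / 101)
  expect_equal(hh_occupancy(4, 7), 1 / 1001)
  x <- seq(0.1, 4, by = 0.3)
  expect_equal(hh_occupancy(7 + x, 7) + hh_occupancy(7 - x, 7),
               rep(1, length(x)))
  expect_true(all(diff(hh_occupancy(seq(0, 14, 0.5), 7)) > 0))
})

test_that("noiseless datasets are the exact two-species forward model", {
  ds <- gen_titration_dataset(7, acid_side = FALSE, ph_grid = seq(4, 10, 0.5),
                              noise_sigma = 0, seed = 1)
  theta <- hh_occupancy(ds$ph, 7)
  expect_equal(theta[ds$ph == 7], 0.5)
  # absorbance at each pH is the occupancy-weighted mix of the end members
  i550 <- which(ds$wavelength == 550)
  mix <- ds$A[i550, ]
  recon <- mix[1] + (mix[length(mix)] - mix[1]) *
    (theta - theta[1]) / (theta[length(theta)] - theta[1])
  expect_equal(unname(mix), unname(recon), tolerance = 1e-12)
})

test_that("fit_pka recovers a bracketed midpoint to 1e-6 on noiseless data", {
  ds <- gen_titration_dataset(7, acid_side = FALSE, ph_grid = seq(4, 10, 0.5),
                              noise_sigma = 0, seed = 1)
  fit <- fit_pka(ds)
  expect_equal(fit$censored, "none")
  expect_lt(abs(fit$pka_estimate - 7), 1e-6)
  expect_gt(fit$stderr, 0)
})

test_that("the alkaline Schiff-base midpoint near 10.7 is recovered to 0.1", {
  ests <- vapply(1:10, function(s)
    fit_pka(gen_titration_dataset(10.7, acid_side = FALSE,
                                  ph_grid = seq(7, 12, 0.25),
                                  noise_sigma = 0.002, seed = s))$pka_estimate,
    numeric(1))
  expect_lt(abs(mean(ests) - 10.7), 0.1)
})

test_that("an acid-side midpoint at the sampling boundary is left-censored", {
  ds <- gen_titration_dataset(acid_side = TRUE, noise_sigma = 0, seed = 1)
  fit <- fit_pka(ds)
  expect_identical(fit$censored, "left")
  expect_equal(fit$bound, min(ds$ph) + 1)   # reported as "pKa < 2.0"
  expect_lte(fit$reported, 2.0)
})

test_that("censoring triggers whenever the true midpoint is at or below the grid", {
  set.seed(601)
  for (r in 1:20) {
    lo <- runif(1, 1, 6)
    pka <- lo - runif(1, 0, 1.5)
    grid <- seq(lo, lo + 4, by = 0.25)
    ds <- gen_titration_dataset(pka, acid_side = TRUE, ph_grid = grid,
                                noise_sigma = 0, seed = r)
    fit <- fit_pka(ds)
    expect_identical(fit$censored, "left",
                     label = sprintf("pka %.2f grid from %.2f", pka, lo))
  }
})

test_that("the alkaline side censors symmetrically", {
  ds <- gen_titration_dataset(12.2, acid_side = FALSE,
                              ph_grid = seq(7, 12, 0.25), noise_sigma = 0, seed = 2)
  fit <- fit_pka(ds)
  expect_identical(fit$censored, "right")
  expect_equal(fit$bound, 11)
})

test_that("a flat series raises 'no transition'", {
  ds <- gen_titration_dataset(7, acid_side = FALSE, ph_grid = seq(4, 10, 0.5),
                              noise_sigma = 0.002, seed = 3)
  ds$A[] <- 0.5 + ds$A * 0  # constant absorbance everywhere
  expect_error(fit_pka(ds), "no transition")
})

test_that("auto mode tracks the wavelength of maximal change", {
  ds <- gen_titration_dataset(10.7, acid_side = FALSE, noise_sigma = 0, seed = 1)
  fit <- fit_pka(ds)
  rng <- apply(ds$A, 1, function(r) diff(range(r)))
  expect_equal(fit$wavelength_used, ds$wavelength[which.max(rng)])
})
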
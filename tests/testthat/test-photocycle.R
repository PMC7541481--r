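library(deSolve)

test_that("all-zero rates freeze the cycle in K", {
  m <- photocycle_model(k1 = 0, k2 = 0, k3 = 0, excited_fraction = 0.3)
  pop <- concentrations(m, c(0, 1, 100))
  expect_equal(unname(pop[, "K"]), rep(0.3, 3))
  expect_equal(unname(pop[, "M"]), rep(0, 3))
  expect_equal(unname(pop[, "O"]), rep(0, 3))
})

test_that("closed-form populations match the Runge-Kutta oracle at the default rates", {
  m <- photocycle_model(k1 = 1, k2 = 0.016, k3 = 0.05)
  t <- exp(seq(log(0.01), log(977), length.out = 50))
  ana <- concentrations(m, t)
  num <- ode_concentrations(m, t)
  expect_lt(max(abs(ana[, c("K", "M", "O")] - num[, c("K", "M", "O")])), 1e-8)
})

test_that("closed form matches the ODE oracle over random rate triples", {
  set.seed(501)
  t <- exp(seq(log(0.01), log(977), length.out = 25))
  for (r in 1:100) {
    k <- 10^runif(3, -4, 1)
    m <- photocycle_model(k1 = k[1], k2 = k[2], k3 = k[3])
    ana <- concentrations(m, t)
    num <- ode_concentrations(m, t)
    expect_lt(max(abs(ana[, 1:3] - num[, 1:3])), 1e-8)
  }
})

test_that("degenerate equal-rate limits agree with the ODE oracle", {
  t <- exp(seq(log(0.01), log(977), length.out = 30))
  cases <- list(c(0.1, 0.1, 0.05), c(0.1, 0.016, 0.016),
                c(0.05, 0.016, 0.05), c(0.02, 0.02, 0.02))
  for (k in cases) {
    m <- photocycle_model(k1 = k[1], k2 = k[2], k3 = k[3])
    expect_lt(max(abs(concentrations(m, t)[, 1:3] - ode_concentrations(m, t)[, 1:3])),
              1e-7, label = paste(k, collapse = "/"))
  }
})

test_that("mass is conserved to 1e-9 at all times for random parameterizations", {
  set.seed(502)
  t <- c(0, exp(seq(log(0.01), log(977), length.out = 40)))
  for (r in 1:50) {
    k <- 10^runif(3, -4, 1)
    f <- runif(1, 0.05, 1)
    m <- photocycle_model(k1 = k[1], k2 = k[2], k3 = k[3], excited_fraction = f)
    pop <- concentrations(m, t)
    expect_lt(max(abs(rowSums(pop) - f)), 1e-9)
    # K decays monotonically for k1 > 0 (ties only at float resolution)
    expect_true(all(diff(pop[, "K"]) <= 0))
    expect_lt(pop[nrow(pop), "K"], pop[1, "K"])
  }
})

test_that("time of maximal M matches the calculus identity ln(k1/k2)/(k1-k2)", {
  m <- photocycle_model()
  tfine <- seq(0.01, 50, by = 0.01)
  tmax_grid <- tfine[which.max(concentrations(m, tfine)[, "M"])]
  tmax_formula <- log(m$k1 / m$k2) / (m$k1 - m$k2)
  expect_lt(abs(tmax_grid - tmax_formula), 0.01 + 1e-12)
})

test_that("difference spectra close to zero after full recovery", {
  ds <- synth_difference_spectra(photocycle_model())
  expect_lt(max(abs(ds$dA[, ncol(ds$dA)])), 1e-6)
})

test_that("when M dominates, the positive peak is the M band and the minimum the ground bleach", {
  m <- photocycle_model()
  tm <- log(m$k1 / m$k2) / (m$k1 - m$k2)
  ds <- synth_difference_spectra(m, t = c(tm, tm + 1))
  spec1 <- ds$dA[, 1]
  expect_equal(ds$wavelength[which.max(spec1)], 405)
  expect_equal(ds$wavelength[which.min(spec1)], 550)
})

test_that("the matrix equals band-by-band manual summation on a toy grid", {
  m <- photocycle_model()
  wl <- c(405, 550, 645); t <- c(0.5, 10, 200)
  ds <- synth_difference_spectra(m, wavelength = wl, t = t)
  pop <- concentrations(m, t)
  gauss <- function(b, x) b$amplitude * exp(-(x - b$center)^2 / (2 * b$width^2))
  for (i in 1:3) for (j in 1:3) {
    manual <- pop[j, "K"] * gauss(m$k_band, wl[i]) +
      pop[j, "M"] * gauss(m$m_band, wl[i]) +
      pop[j, "O"] * gauss(m$o_band, wl[i]) -
      (pop[j, "K"] + pop[j, "M"] + pop[j, "O"]) * gauss(m$ground, wl[i])
    expect_equal(ds$dA[i, j], unname(manual))
  }
})

test_that("find_peak returns the ground-state maximum and rounds to the grid", {
  wl <- default_wavelength_grid()
  m <- photocycle_model()
  ground <- m$ground$amplitude * exp(-(wl - m$ground$center)^2 / (2 * m$ground$width^2))
  expect_equal(find_peak(ground, wl), 550)
  off <- exp(-(wl - 502)^2 / (2 * 40^2))
  expect_equal(find_peak(off, wl), 500)
  expect_error(find_peak(rep(1, 5), 1:5), "no peak")
})

test_that("find_peak tolerates realistic noise", {
  wl <- default_wavelength_grid()
  m <- photocycle_model()
  truth <- m$ground$center
  band <- m$ground$amplitude * exp(-(wl - truth)^2 / (2 * m$ground$width^2))
  ok <- 0
  set.seed(503)
  for (r in 1:200) {
    pk <- find_peak(band + rnorm(length(wl), 0, 0.002), wl)
    if (abs(pk - truth) <= 5) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.95)
})

test_that("pyranine trace mirrors the M population", {
  m <- photocycle_model()
  t <- default_time_grid()
  expect_equal(unname(pyranine_trace(m, t, coupling = 0)), rep(0, length(t)))
  tr <- pyranine_trace(m, t, coupling = 0.4)
  popM <- concentrations(m, t)[, "M"]
  expect_equal(which.min(tr), which.max(popM))
  # proton release then uptake: the dip falls between 0.1 and 100 ms
  tmin <- t[which.min(tr)]
  expect_gt(tmin, 0.1); expect_lt(tmin, 100)
  expect_lt(tr[which.min(tr)], 0)
  expect_gt(tr[length(tr)], tr[which.min(tr)])  # recovers after the dip
})

test_that("ground-state bleach at 550 nm recovers by about 300 ms", {
  ds <- synth_difference_spectra(photocycle_model(),
                                 t = sort(c(default_time_grid(), 240, 300, 360)))
  i550 <- which(ds$wavelength == 550)
  trace <- ds$dA[i550, ]
  bleach <- min(trace)
  recovery <- 1 - trace / bleach  # 0 at full bleach, 1 at baseline
  for (tt in c(240, 300, 360)) {
    expect_gte(recovery[which(ds$time == tt)], 0.95)
  }
})
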
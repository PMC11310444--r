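test_that("growth rate recovers exact doubling and flat cultures", {
  tc <- tibble::tibble(time_h = c(0, 24, 48), cells_e6 = 0.3 * 2^(c(0, 1, 2)))
  expect_equal(fit_growth_rate(tc)$mu, log(2) / 24, tolerance = 1e-12)
  flat <- tibble::tibble(time_h = c(0, 24, 48), cells_e6 = rep(0.5, 3))
  expect_equal(fit_growth_rate(flat)$mu, 0, tolerance = 1e-12)
  expect_error(fit_growth_rate(tibble::tibble(time_h = 0, cells_e6 = 1)),
               "two timepoints")
  expect_error(fit_growth_rate(tibble::tibble(time_h = c(0, 1), cells_e6 = c(1, -1))),
               "positive")
})

test_that("noisy exponential growth is recovered within uncertainty", {
  set.seed(31)
  mu <- 0.03
  tc <- tibble::tibble(
    time_h = rep(c(0, 12, 24, 36, 48), each = 3),
    cells_e6 = 0.3 * exp(mu * rep(c(0, 12, 24, 36, 48), each = 3)) *
      exp(rnorm(15, 0, 0.05))
  )
  g <- fit_growth_rate(tc)
  expect_lt(abs(g$mu - mu), 3 * g$mu_sd)
})

test_that("rate estimators obey definitions and unit arithmetic", {
  # 24 nmol consumed by 1e6 cells over 24 h -> 1 nmol/1e6 cells/h
  expect_equal(rate_quiescent(24, 1, 24), 1)
  expect_equal(rate_quiescent(0, 1, 24), 0)
  expect_equal(rate_proliferating(0, 1, 0.02, 24), 0)
  expect_error(rate_proliferating(1, 1, 0, 24), "quiescent")
  expect_error(rate_quiescent(1, 0, 24), "positive")
})

test_that("proliferating estimator converges to the quiescent one as mu -> 0", {
  for (mu in c(1e-3, 1e-6, 1e-9)) {
    qp <- rate_proliferating(48, 0.4, mu, 24)
    qq <- rate_quiescent(48, 0.4, 24)
    # first-order gap is mu * dt / 2, so mu * dt bounds it comfortably
    expect_lt(abs(qp - qq) / abs(qq), max(mu * 24, 1e-6))
  }
})

test_that("inverting a numerically integrated concentration recovers the rate", {
  set.seed(8)
  for (i in 1:5) {
    mu <- runif(1, 0.01, 0.05)
    q <- runif(1, -5, 5)
    x0 <- runif(1, 0.2, 0.5)
    dt <- 24
    # oracle: integrate dC/dt = -q x0 exp(mu t) on a fine grid
    tt <- seq(0, dt, length.out = 20001)
    consumed <- sum(q * x0 * exp(mu * head(tt, -1)) * diff(tt))
    expect_lt(abs(rate_proliferating(consumed, x0, mu, dt) - q) / max(abs(q), 1e-6),
              1e-4)
  }
})

test_that("external_rates picks the right estimator and propagates scatter", {
  fx <- build_fixture("P")
  st <- simulate_study(fx, seed = 77)
  r <- external_rates(st$media, st$cells)
  expect_setequal(r$species, names(fx$media0))
  expect_true(all(r$estimator == "proliferating"))
  expect_true(all(r$sd >= 0))
  truth <- compflux:::true_external_rates(fx)
  # signs preserved end-to-end: glucose/glutamine uptake (+), lactate/alanine
  # secretion (-)
  expect_gt(r$rate[r$species == "glc"], 0)
  expect_gt(r$rate[r$species == "gln"], 0)
  expect_lt(r$rate[r$species == "lac"], 0)
  expect_lt(r$rate[r$species == "ala"], 0)
  for (s in names(truth)) {
    est <- r$rate[r$species == s]
    expect_lt(abs(est - truth[[s]]), max(0.15 * abs(truth[[s]]), 1))
  }
  stq <- simulate_study(build_fixture("Q"), seed = 78)
  rq <- external_rates(stq$media, stq$cells)
  expect_true(all(rq$estimator == "quiescent"))
})

test_that("scaling all concentrations scales all rates alike (internal standard)", {
  fx <- build_fixture("Q")
  st <- simulate_study(fx, seed = 5)
  r1 <- external_rates(st$media, st$cells)
  st$media$conc <- st$media$conc * 3
  r3 <- external_rates(st$media, st$cells)
  expect_equal(r3$rate, 3 * r1$rate, tolerance = 1e-12)
})
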
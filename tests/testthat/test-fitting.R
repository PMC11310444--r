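test_that("chi-square verdict uses the two-sided interval", {
  v <- chi_square_test(10, 10)
  # quantile oracle
  expect_equal(v$lower, qchisq(0.025, 10), tolerance = 1e-12)
  expect_equal(v$upper, qchisq(0.975, 10), tolerance = 1e-12)
  expect_equal(round(c(v$lower, v$upper), 3), c(3.247, 20.483))
  expect_true(v$accept)
  # SSR = 0 signals overfit and is rejected
  expect_false(chi_square_test(0, 10)$accept)
  # SSR = dof is accepted for every dof (quantile oracle over a grid)
  for (dof in c(1:10, 50, 100, 200)) {
    expect_true(chi_square_test(dof, dof)$accept)
  }
  expect_error(chi_square_test(1, 0), "degree")
})

test_that("the objective is the variance-weighted sum of squared residuals", {
  truth <- toy_study_truth()
  study <- simulate_toy_study(noise = FALSE)
  net <- toy_study_net()
  ssr0 <- flux_ssr(net, truth, study$mids, study$rates,
                   tracers = toy_tracers(), fragments = toy_fragments(),
                   rate_map = toy_rate_map())
  expect_lt(ssr0, 1e-4)
  # one residual of exactly 2 SD -> SSR = 4
  study2 <- study
  i <- which(study2$mids$fragment == "D" & study2$mids$mass_shift == 1)
  study2$mids$fraction[i] <- study2$mids$fraction[i] + 2 * study2$mids$sd[i]
  ssr2 <- flux_ssr(net, truth, study2$mids, study2$rates,
                   tracers = toy_tracers(), fragments = toy_fragments(),
                   rate_map = toy_rate_map())
  expect_equal(ssr2 - ssr0, 4, tolerance = 1e-2)
  # random perturbations match a naive summation oracle
  set.seed(12)
  study3 <- study
  eps <- rnorm(nrow(study3$mids), 0, 0.002)
  study3$mids$fraction <- study3$mids$fraction + eps
  pred <- simulate_mids(net, truth, toy_tracers()$trA, fragments = toy_fragments())
  naive <- 0
  for (k in seq_len(nrow(study3$mids))) {
    row <- study3$mids[k, ]
    p <- pred$fraction[pred$fragment == row$fragment &
                         pred$mass_shift == row$mass_shift]
    naive <- naive + ((p - row$fraction) / row$sd)^2
  }
  naive <- naive + ((truth$net_flux[["up"]] - study3$rates$rate) /
                      study3$rates$sd)^2
  ssr3 <- flux_ssr(net, truth, study3$mids, study3$rates,
                   tracers = toy_tracers(), fragments = toy_fragments(),
                   rate_map = toy_rate_map())
  expect_equal(ssr3, naive, tolerance = 1e-6)
})

test_that("noise-free toy data are refit to near-zero SSR with flux recovery", {
  study <- simulate_toy_study(noise = FALSE)
  study$mids$sd <- 0.003
  fit <- fit_toy(study, restarts = 5, seed = 3)
  expect_lt(fit$ssr, 1e-3)
  truth <- toy_study_truth()
  for (r in c("up", "left", "right")) {
    expect_lt(abs(fit$flux$net_flux[[r]] - truth$net_flux[[r]]) /
                truth$net_flux[[r]], 1e-3)
  }
})

test_that("fit results carry bookkeeping that satisfies the contracts", {
  set.seed(21)
  study <- simulate_toy_study()
  fit <- fit_toy(study, restarts = 4, seed = 9)
  expect_s3_class(fit, "flux_fit")
  expect_gte(fit$ssr, 0)
  expect_equal(fit$dof, fit$n_indep - fit$n_par)
  expect_gt(fit$dof, 0)
  expect_equal(nrow(fit$restart_log), 5L)  # restart 0 + 4 random
  g <- glance(fit)
  expect_equal(g$ssr, fit$ssr)
  td <- tidy(fit)
  expect_true(all(c("reaction", "net_flux", "exchange") %in% names(td)))
  expect_lt(max(abs(balance_residuals(toy_study_net(), fit$flux$net_flux))), 1e-6)
})

test_that("best-restart SSR is non-increasing in the number of restarts", {
  set.seed(4)
  study <- simulate_toy_study()
  ssrs <- vapply(c(1, 3, 6), function(k) {
    fit_toy(study, restarts = k, seed = 11)$ssr
  }, 0)
  expect_true(all(diff(ssrs) <= 1e-8))
})

test_that("the fit is invariant to dataset row order", {
  set.seed(14)
  study <- simulate_toy_study()
  f1 <- fit_toy(study, restarts = 2, seed = 5)
  study2 <- study
  study2$mids <- study2$mids[rev(seq_len(nrow(study2$mids))), ]
  f2 <- fit_toy(study2, restarts = 2, seed = 5)
  expect_equal(f1$ssr, f2$ssr, tolerance = 1e-6)
  expect_equal(f1$flux$net_flux, f2$flux$net_flux, tolerance = 1e-4)
})

test_that("profile CI matches the closed-form linear-regression interval", {
  # a model where the profiled flux enters the residuals linearly: rates only,
  # huge MID SDs make the labeling terms negligible
  study <- simulate_toy_study(noise = FALSE)
  study$mids$sd <- 1e4
  study$rates <- tibble::tibble(species = "A", rate = 100, sd = 8)
  fit <- fit_toy(study, restarts = 3, seed = 2)
  fit <- profile_ci(fit, "up")
  ci <- fit$ci
  # closed form: estimate +- sqrt(qchisq(0.95, 1)) * sd
  half <- sqrt(qchisq(0.95, 1)) * 8
  expect_equal(ci$lo95, ci$estimate - half, tolerance = 1e-2)
  expect_equal(ci$hi95, ci$estimate + half, tolerance = 1e-2)
})

test_that("noise-free profile intervals collapse onto the truth", {
  study <- simulate_toy_study(noise = FALSE)
  study$mids$sd <- 0.003
  fit <- fit_toy(study, restarts = 3, seed = 6)
  fit <- profile_ci(fit, "left")
  ci <- fit$ci
  # noise-free: interval tight around the truth relative to the flux scale
  expect_lt(ci$hi95 - ci$lo95, 0.3 * 70)
  expect_true(ci$lo95 <= 70 && 70 <= ci$hi95)
  expect_lt(abs(ci$estimate - 70), 0.5)
})
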
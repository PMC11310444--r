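test_that("fixtures carry the published anchors and a consistent steady state", {
  manifest <- mef_anchors()
  for (cond in c("P", "Q")) {
    fx <- build_fixture(cond)
    anc <- manifest[manifest$condition == cond, ]
    for (i in seq_len(nrow(anc))) {
      expect_equal(unname(fx$flux$net_flux[[anc$reaction[i]]]),
                   anc$net_flux[i], tolerance = 1e-6)
    }
    expect_lt(max(abs(balance_residuals(fx$net, fx$flux$net_flux))), 1e-9)
    rev_ids <- names(fx$flux$exchange)
    irrev <- setdiff(names(fx$flux$net_flux), rev_ids)
    expect_true(all(fx$flux$net_flux[irrev] >= -1e-9))
  }
})

test_that("infeasible anchors are rejected with the violated balance", {
  net <- mef_network()
  expect_error(
    complete_fluxes(net, c(HK = 2500)),
    "infeasible|bound"
  )
})

test_that("fixtures encode the qualitative P-versus-Q physiology", {
  p <- build_fixture("P")$flux$net_flux
  q <- build_fixture("Q")$flux$net_flux
  # quiescent cells: less lactate secretion, more mitochondrial pyruvate
  # uptake, higher TCA flux, more anaplerosis, induced malate export and
  # proline synthesis
  expect_lt(q[["LACS"]], p[["LACS"]])
  expect_gt(q[["MPC"]], p[["MPC"]])
  expect_gt(q[["CS"]], p[["CS"]])
  expect_gt(q[["AKGD"]], p[["AKGD"]])
  expect_gt(q[["PC"]], 5 * p[["PC"]])
  expect_gt(q[["MALT"]], p[["MALT"]])
  expect_gte(q[["PROS"]], p[["PROS"]])
  # glycolysis roughly halved, glucose uptake only modestly reduced
  expect_lt(q[["PK"]] - q[["PCK1"]], 0.7 * (p[["PK"]] - p[["PCK1"]]))
  expect_gt(q[["HK"]], 0.5 * p[["HK"]])
})

test_that("5SA variants restore glycolysis on the quiescent background", {
  q <- build_fixture("Q")$flux$net_flux
  q5 <- build_fixture("Q-5SA")$flux$net_flux
  expect_gt(q5[["LACS"]], q[["LACS"]])
  expect_gt(q5[["HK"]], q[["HK"]])
  expect_gt(q5[["CS"]], 0.9 * q[["CS"]])
})

test_that("simulated studies are reproducible and respect the noise switch", {
  fx <- build_fixture("P")
  s1 <- simulate_study(fx, seed = 33)
  s2 <- simulate_study(fx, seed = 33)
  expect_identical(s1$mids, s2$mids)
  expect_identical(s1$media, s2$media)
  s3 <- simulate_study(fx, seed = 34)
  expect_false(identical(s1$mids$fraction, s3$mids$fraction))
  clean <- simulate_study(fx, seed = 33, noise = FALSE)
  sim <- simulate_mids(fx$net, fx$flux, fx$tracers$glc12,
                       fragments = mef_fragments())
  direct <- clean$mids[clean$mids$tracer_id == "glc12" &
                         clean$mids$replicate == 1, ]
  m <- merge(as.data.frame(direct), as.data.frame(sim),
             by = c("fragment", "mass_shift"))
  expect_equal(m$fraction.x, m$fraction.y, tolerance = 1e-12)
})

test_that("simulated MIDs are valid and carry the declared noise scale", {
  fx <- build_fixture("Q")
  st <- simulate_study(fx, seed = 13)
  expect_true(all(st$mids$fraction >= 0))
  sums <- tapply(st$mids$fraction,
                 paste(st$mids$fragment, st$mids$tracer_id, st$mids$replicate),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(unique(st$mids$sd), fx$mid_sd)
  expect_equal(sort(unique(st$mids$tracer_id)), c("glc12", "glnU"))
  expect_equal(max(st$mids$replicate), fx$replicates)
  expect_equal(sort(unique(st$media$time_h)), c(0, 6, 18, 24))
})
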
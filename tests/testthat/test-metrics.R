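test_that("PPP split ratio follows its definition on plain MIDs", {
  expect_equal(ppp_split_ratio(c(0.5, 0, 0.5, 0)), 0)
  expect_equal(ppp_split_ratio(c(0.4, 0.2, 0.2, 0.2)), 1)
  expect_warning(r <- ppp_split_ratio(c(0.5, 0.5, 0, 0)), "undefined")
  expect_true(is.na(r))
})

test_that("LDH partition and fragment enrichment follow their definitions", {
  m <- c(0.2, 0.2, 0.3, 0.3)
  expect_equal(ldh_partition_ratio(m, m), 1)
  expect_equal(ldh_partition_ratio(c(1, 0, 0, 0), m), 0)
  expect_warning(r <- ldh_partition_ratio(m, c(1, 0, 0, 0)), "undefined")
  expect_true(is.na(r))
  expect_equal(fragment_enrichment(c(1, 0, 0), 0), 1)
  expect_equal(fragment_enrichment(c(0.7, 0.2, 0.1), 2), 0.1)
  expect_error(fragment_enrichment(c(0.7, 0.2, 0.1), 5), "outside")
})

test_that("metrics are invariant to renormalization scale of inputs", {
  m <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(ppp_split_ratio(m), ppp_split_ratio(m / sum(m)))
})

test_that("DHAP M+1/M+2 rises monotonically with the oxPPP share", {
  net <- glypp_net()
  tr <- tracer_spec("glc.x", c(1, 2))
  ratios <- vapply(seq(0, 0.5, length.out = 6), function(share) {
    hk <- 100
    ox <- hk * share
    # complete the rest of the network around the chosen split
    v <- complete_fluxes(net, c(hk = hk, oxppp = ox, dhaps = 10, p5ps = 1),
                         prior = c(pgi = hk - ox, pfk = 80, ald = 80, tpi = 60,
                                   gapd = 150, ldh = 140, lacs = 140))
    fm <- flux_map(net, v)
    sim <- simulate_mids(net, fm, tr, fragments = c(dhap = "dhap.c"))
    ppp_split_ratio(mid_of(sim, "dhap"))
  }, 0)
  expect_equal(ratios[1], 0, tolerance = 1e-9)
  expect_true(all(diff(ratios) > 0))
})

test_that("lactate fully derived from glycolytic pyruvate gives ratio 1", {
  net <- glypp_net()
  v <- complete_fluxes(net, c(hk = 100, oxppp = 10, dhaps = 5),
                       prior = c(pgi = 90, pfk = 85, ald = 85, gapd = 170,
                                 ldh = 165, lacs = 165))
  fm <- flux_map(net, v)
  sim <- simulate_mids(net, fm, tracer_spec("glc.x", 1:6),
                       fragments = c(lac = "lac.c", pyr = "pyr.c"))
  expect_equal(ldh_partition_ratio(mid_of(sim, "lac"), mid_of(sim, "pyr")), 1,
               tolerance = 1e-9)
})

test_that("citrate M+2 under U-13C glucose falls when pyruvate transport drops", {
  fx <- build_fixture("P")
  enr <- function(mpc) {
    pri <- fx$flux$net_flux
    v <- complete_fluxes(fx$net, c(MPC = mpc, HK = pri[["HK"]],
                                   GLNUP = pri[["GLNUP"]],
                                   ALTM = pri[["ALTM"]]), prior = pri)
    fm <- flux_map(fx$net, v, exchange = fx$flux$exchange,
                   mixing = fx$flux$mixing, tol = 1e-6)
    sim <- simulate_mids(fx$net, fm, tracer_spec("glc.x", 1:6),
                         fragments = mef_fragments())
    fragment_enrichment(mid_of(sim, "cit"), 2)
  }
  base <- unname(fx$flux$net_flux[["MPC"]])
  expect_gt(enr(base), enr(base / 5))
})

test_that("data-frame methods summarize per replicate with mean and SEM", {
  d <- do.call(rbind, lapply(1:3, function(rep) {
    data.frame(fragment = "dhap", tracer_id = "glc12", replicate = rep,
               mass_shift = 0:3,
               fraction = c(0.5, 0.1 * rep / 2, 0.2, 0.3 - 0.1 * rep / 2))
  }))
  pr <- ppp_split_ratio(d, fragment = "dhap")
  expect_equal(nrow(pr), 3L)
  s <- metric_summary(pr)
  expect_equal(s$n, 3L)
  expect_equal(s$mean, mean(pr$value))
})
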
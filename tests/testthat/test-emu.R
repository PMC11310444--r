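test_that("unlabeled tracer leaves every fragment at M+0", {
  fx <- toy_study_truth()
  sim <- simulate_mids(toy_study_net(), fx, tracer_spec("A.x", integer(0)),
                       fragments = toy_fragments())
  m0 <- sim$fraction[sim$mass_shift == 0]
  expect_true(all(abs(m0 - 1) < 1e-12))
  expect_true(all(abs(sim$fraction[sim$mass_shift > 0]) < 1e-12))
})

test_that("a fully labeled tracer through a linear chain arrives fully labeled", {
  net <- chain_net()
  fm <- flux_map(net, c(v1 = 5, v2 = 5))
  sim <- simulate_mids(net, fm, tracer_spec("A.x", 1:3), fragments = c(B = "B.c"))
  expect_equal(sim$fraction[sim$mass_shift == 3], 1, tolerance = 1e-12)
})

test_that("condensation products are convolutions of their parts", {
  net <- parse_network(c(
    "u1\t0\texchange\tCa.x (ab) -> C.c (ab)",
    "u2\t0\texchange\tDa.x (a) -> D.c (a)",
    "u3\t0\tenzymatic\tC.c (ab) + D.c (c) -> E.c (abc)",
    "u4\t0\texchange\tE.c (abc) -> E.x (abc)"
  ))
  fm <- flux_map(net, c(u1 = 5, u2 = 5, u3 = 5, u4 = 5))
  tr <- list(tracer_spec("Ca.x", 1, 0.5), tracer_spec("Da.x", 1, 1))
  sim <- simulate_mids(net, fm, tr, fragments = c(E = "E.c"))
  # E = conv((0.5, 0.5, 0) over two carbons of C, (0, 1) of D)
  expect_equal(sim$fraction, c(0, 0.5, 0.5, 0), tolerance = 1e-12)
})

test_that("every simulated MID is a probability vector", {
  fx <- build_fixture("P")
  sys <- emu_decompose(fx$net, mef_fragments())
  for (tr in fx$tracers) {
    sim <- simulate_mids(fx$net, fx$flux, tr, system = sys)
    expect_true(all(sim$fraction >= 0))
    sums <- tapply(sim$fraction, sim$fragment, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("EMU decomposition matches a breadth-first reachability oracle", {
  net <- glypp_net()
  sys <- emu_decompose(net, c(dhap = "dhap.c"))
  tab <- tidy(sys)
  expect_true(all(tab$size >= 1))
  expect_true(all(c("inlet", "unknown") %in% tab$type))
  # independent oracle: exhaustive backwards reachability over reactions,
  # tracking (metabolite, atom-subset) states from the target fragment
  carbons <- stats::setNames(net$metabolites$carbons, net$metabolites$metabolite)
  rxns <- Filter(function(r) r$kind != "mixing", net$reactions)
  expand <- list()
  for (r in rxns) {
    expand[[length(expand) + 1L]] <- r
    if (r$reversible) {
      expand[[length(expand) + 1L]] <- list(substrates = r$products,
                                            products = r$substrates)
    }
  }
  key <- function(met, atoms) paste0(met, "|", paste(sort(atoms), collapse = ","))
  seen <- character()
  queue <- list(list(met = "dhap.c", atoms = 1:3))
  seen <- key("dhap.c", 1:3)
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    for (r in expand) {
      for (pt in r$products) {
        if (pt$metabolite != e$met) next
        letters_needed <- pt$map[e$atoms]
        for (st in r$substrates) {
          pos <- which(st$map %in% letters_needed)
          if (!length(pos)) next
          k <- key(st$metabolite, pos)
          if (!k %in% seen) {
            seen <- c(seen, k)
            queue[[length(queue) + 1L]] <- list(met = st$metabolite, atoms = pos)
          }
        }
      }
    }
  }
  expect_setequal(tab$emu, seen)
  # per-size counts agree with the oracle enumeration
  oracle_sizes <- lengths(regmatches(seen, gregexpr(",", seen))) + 1L
  expect_equal(sort(as.integer(table(tab$size))),
               sort(as.integer(table(oracle_sizes))))
  disconnected <- parse_network(c(
    "a\t0\texchange\tA.x (a) -> B.c (a)",
    "b\t0\texchange\tB.c (a) -> B.x (a)",
    "c\t1\tenzymatic\tC.c (a) -> D.c (a)",
    "d\t1\tenzymatic\tD.c (a) -> C.c (a)"
  ))
  expect_error(emu_decompose(disconnected, c(C = "C.c")), NA)
  # a dead pool at simulate time is reported
  fm <- flux_map(disconnected, c(a = 1, b = 1, c = 0, d = 0))
  expect_error(
    simulate_mids(disconnected, fm, tracer_spec("A.x", 1), fragments = c(C = "C.c")),
    "singular|zero consumption"
  )
})

test_that("EMU cascade agrees with the brute-force isotopomer oracle on random networks", {
  worst <- 0
  for (seed in 1:40) {
    rs <- random_small_network(seed)
    s1 <- simulate_mids(rs$net, rs$fmap, rs$tracer, fragments = rs$fragments)
    s2 <- isotopomer_mids(rs$net, rs$fmap, rs$tracer, fragments = rs$fragments)
    m <- merge(as.data.frame(s1), as.data.frame(s2),
               by = c("fragment", "mass_shift"))
    worst <- max(worst, max(abs(m$fraction.x - m$fraction.y)))
  }
  expect_lt(worst, 1e-8)
})

test_that("EMU cascade agrees with the oracle on the full MEF model", {
  fx <- build_fixture("Q")
  for (tr in fx$tracers) {
    s1 <- simulate_mids(fx$net, fx$flux, tr, fragments = mef_fragments())
    s2 <- isotopomer_mids(fx$net, fx$flux, tr, fragments = mef_fragments())
    m <- merge(as.data.frame(s1), as.data.frame(s2),
               by = c("fragment", "mass_shift"))
    expect_lt(max(abs(m$fraction.x - m$fraction.y)), 1e-8)
  }
})

test_that("steady-state MIDs are invariant to scaling all fluxes", {
  fx <- build_fixture("P")
  sys <- emu_decompose(fx$net, mef_fragments())
  s1 <- simulate_mids(fx$net, fx$flux, fx$tracers$glc12, system = sys)
  scaled <- fx$flux
  scaled$net_flux <- scaled$net_flux * 3.7
  scaled$exchange <- scaled$exchange * 3.7
  s2 <- simulate_mids(fx$net, scaled, fx$tracers$glc12, system = sys)
  expect_equal(s1$fraction, s2$fraction, tolerance = 1e-10)
})

test_that("a pool mixture of tracers averages the steady-state MIDs on a chain", {
  net <- chain_net()
  fm <- flux_map(net, c(v1 = 10, v2 = 10))
  trA <- tracer_spec("A.x", 1, 1)
  trB <- tracer_spec("A.x", 2:3, 1)
  mix <- tracer_mixture(trA, trB, weights = c(0.5, 0.5))
  s_mix <- simulate_mids(net, fm, mix, fragments = c(B = "B.c"))
  sA <- simulate_mids(net, fm, trA, fragments = c(B = "B.c"))
  sB <- simulate_mids(net, fm, trB, fragments = c(B = "B.c"))
  expect_equal(s_mix$fraction, 0.5 * sA$fraction + 0.5 * sB$fraction,
               tolerance = 1e-12)
})

test_that("the isotopomer oracle refuses oversized state spaces", {
  net <- parse_network(c(
    "a\t0\texchange\tA.x (abcdefghijklmn) -> B.c (abcdefghijklmn)",
    "b\t0\texchange\tB.c (abcdefghijklmn) -> B.x (abcdefghijklmn)"
  ))
  fm <- flux_map(net, c(a = 1, b = 1))
  expect_error(isotopomer_mids(net, fm, tracer_spec("A.x", 1),
                               fragments = c(B = "B.c")),
               "state space too large")
})
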
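test_that("a minimal linear chain parses with the expected structure", {
  net <- parse_network(c(
    "v1\t0\tenzymatic\tA.x (ab) -> B.c (ab)",
    "v2\t0\tenzymatic\tB.c (ab) -> C.x (ba)"
  ))
  expect_s3_class(net, "flux_network")
  expect_equal(length(net$reactions), 2L)
  expect_equal(nrow(net$metabolites), 3L)
  expect_equal(net$balanced, "B.c")
  expect_equal(network_dof(net), 1L)
})

test_that("carbon-map imbalance and malformed input are rejected with context", {
  expect_error(
    parse_network("bad\t0\tenzymatic\tA.c (abc) -> B.c (ab)"),
    "carbon maps are not balanced.*bad|bad.*carbon"
  )
  expect_error(parse_network("x\t0\tenzymatic"), "4 tab-separated fields")
  expect_error(parse_network("x\t2\tenzymatic\tA.c (a) -> B.c (a)"),
               "reversible flag")
  expect_error(parse_network("x\t0\tweird\tA.c (a) -> B.c (a)"), "unknown kind")
  # balanced metabolite with no consumer
  expect_error(parse_network("v\t0\texchange\tA.x (a) -> B.c (a)"),
               "no consuming reaction")
})

test_that("a fuzz over permuted carbon maps rejects all imbalanced variants", {
  set.seed(42)
  for (i in 1:25) {
    maps <- sample(letters[1:4])
    sub <- paste(maps[1:3], collapse = "")
    prod <- paste(maps[c(1, 2, 4)], collapse = "")  # letter swapped: imbalance
    expect_error(parse_network(sprintf(
      "v\t0\tenzymatic\tA.c (%s) -> B.c (%s)", sub, prod)),
      "not balanced")
  }
})

test_that("degrees of freedom match the dense rank oracle on all built-in networks", {
  for (net in list(chain_net(), diamond_net(), glypp_net(), mef_network())) {
    S <- stoichiometry(net)
    # independent oracle: nullity via brute-force SVD rank of the dense matrix
    rank_svd <- sum(svd(S)$d > 1e-10 * max(dim(S)))
    expect_equal(network_dof(net), ncol(S) - rank_svd)
  }
  expect_equal(network_dof(chain_net()), 1L)
  expect_equal(network_dof(diamond_net()), 2L)
})

test_that("the shipped MEF network matches its recorded shape", {
  net <- mef_network()
  # counts established by an independent line scan over the shipped file
  path <- system.file("extdata", "mef_network.tsv", package = "compflux")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "@") & nzchar(lines)]
  expect_equal(length(net$reactions), length(body))
  expect_equal(sum(vapply(net$reactions, function(r) r$kind == "mixing", TRUE)), 6L)
  expect_setequal(unique(net$metabolites$compartment),
                  c("extracellular", "cytosol", "mitochondrion", "measurement"))
  expect_true(all(c("pyr.c", "pyr.m", "mal.c", "mal.m", "oac.c", "oac.m") %in%
                    net$metabolites$metabolite))
  expect_equal(net$symmetric, "suc.m")
})

test_that("flux_basis reconstructs steady-state flux vectors exactly", {
  net <- mef_network()
  fb <- flux_basis(net)
  set.seed(7)
  u <- rnorm(length(fb$free), 0, 50)
  v <- fb$expand(u)
  expect_lt(max(abs(balance_residuals(net, v))), 1e-9)
  expect_equal(unname(v[fb$free]), u)
})

test_that("flux_map enforces steady state, irreversibility and mixing bounds", {
  net <- diamond_net()
  expect_error(flux_map(net, c(up = 10, left = 5, right = 5, dl = 5, dr = 4,
                               out = 9)),
               "steady state")
  expect_error(flux_map(net, c(up = -1, left = -1, right = 0, dl = -1, dr = 0,
                               out = -1)),
               "negative net flux")
  ok <- flux_map(net, c(up = 10, left = 6, right = 4, dl = 6, dr = 4, out = 10))
  expect_s3_class(ok, "flux_map")
  expect_error(flux_map(chain_net(), c(v1 = 1, v2 = 1), mixing = c(zz = 0.5)),
               "unknown mixing")
})
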
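# Shared fixtures built in code: toy networks, random atom-transition
# networks for property tests, and a small two-branch study used by the
# calibration and coverage checks.

chain_net <- function() toy_network("chain")
diamond_net <- function() toy_network("diamond")
glypp_net <- function() toy_network("glypp")

# random linear/branched network with few carbons, guaranteed reachable and
# consumable; returns net + a feasible flux map + a random tracer
random_small_network <- function(seed) {
  set.seed(seed)
  nc <- sample(2:3, 1)
  shuffle <- function(x) if (length(x) > 1) sample(x) else x
  la <- letters[seq_len(nc)]
  lb <- shuffle(la)
  split_n <- sample(seq_len(nc - 1), 1)
  lc <- lb[seq_len(split_n)]
  ld <- lb[-seq_len(split_n)]
  rev_cnd <- sample(0:1, 1)
  lines <- c(
    sprintf("in\t0\texchange\tA.x (%s) -> B.c (%s)", paste(la, collapse = ""),
            paste(la, collapse = "")),
    sprintf("spl\t0\tenzymatic\tB.c (%s) -> C.c (%s) + D.c (%s)",
            paste(lb, collapse = ""), paste(lc, collapse = ""),
            paste(ld, collapse = "")),
    sprintf("cnd\t%d\tenzymatic\tC.c (%s) + D.c (%s) -> E.c (%s)",
            rev_cnd, paste(lc, collapse = ""), paste(ld, collapse = ""),
            paste(shuffle(lb), collapse = "")),
    sprintf("out\t0\texchange\tE.c (%s) -> E.x (%s)",
            paste(la, collapse = ""), paste(la, collapse = ""))
  )
  net <- parse_network(lines)
  v <- stats::runif(1, 1, 20)
  fmap <- flux_map(net, c(`in` = v, spl = v, cnd = v, out = v),
                   exchange = if (rev_cnd == 1)
                     c(cnd = stats::runif(1, 0, 5)) else NULL)
  tracer <- tracer_spec("A.x", sample(seq_len(nc), sample(nc, 1)),
                        enrichment = stats::runif(1, 0.3, 1))
  list(net = net, fmap = fmap, tracer = tracer,
       fragments = c(E = "E.c", C = "C.c"))
}

# two-branch toy study used for chi-square calibration and CI coverage:
# one tracer, three measured fragments, one measured rate
toy_study_net <- function() diamond_net()

toy_study_truth <- function() {
  net <- toy_study_net()
  flux_map(net, c(up = 100, left = 70, right = 30, dl = 70, dr = 30, out = 100))
}

# asymmetric per-position enrichment: keeps every MID entry well away from
# 0 and 1 (so additive noise stays approximately Gaussian after clipping)
# while the positional D1 fragment still identifies the branch split
toy_tracers <- function() {
  list(trA = tracer_spec("A.x", 1:2, c(0.9, 0.3), id = "trA"))
}

toy_rate_map <- function() {
  tibble::tibble(species = "A", reaction = "up", sign = 1)
}

# D1 is a positional (single-carbon) fragment of the combined pool: the two
# branches deliver opposite orientations, so it identifies the split that
# the full-backbone mass distributions cannot see
toy_fragments <- function() {
  list(L = list(fragment = "L", metabolite = "L.c", atoms = NULL),
       R = list(fragment = "R", metabolite = "R.c", atoms = NULL),
       D = list(fragment = "D", metabolite = "D.c", atoms = NULL),
       D1 = list(fragment = "D1", metabolite = "D.c", atoms = 1L))
}

simulate_toy_study <- function(fmap = toy_study_truth(), mid_sd = 0.003,
                               rate_cv = 0.05, noise = TRUE) {
  net <- toy_study_net()
  mids <- simulate_mids(net, fmap, toy_tracers()$trA,
                        fragments = toy_fragments())
  if (noise) {
    mids$fraction <- pmax(mids$fraction + stats::rnorm(nrow(mids), 0, mid_sd), 0)
    mids$fraction <- stats::ave(mids$fraction, mids$fragment,
                                FUN = function(x) x / sum(x))
  }
  mids$tracer_id <- "trA"
  mids$replicate <- 1L
  mids$sd <- mid_sd
  q <- fmap$net_flux[["up"]]
  rates <- tibble::tibble(
    species = "A",
    rate = q * (if (noise) 1 + stats::rnorm(1, 0, rate_cv) else 1),
    sd = q * rate_cv
  )
  list(mids = mids, rates = rates)
}

fit_toy <- function(study, restarts = 3, seed = 1, ...) {
  fit_fluxes(toy_study_net(), study$mids, study$rates,
             tracers = toy_tracers(), fragments = toy_fragments(),
             rate_map = toy_rate_map(), restarts = restarts, seed = seed, ...)
}

mid_of <- function(tbl, frag) {
  d <- tbl[tbl$fragment == frag, ]
  d$fraction[order(d$mass_shift)]
}
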
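#' Complete a flux map from anchors and a prior
#'
#' Bounded least-norm completion: finds the net-flux vector closest (least
#' squares) to a prior guess subject to steady state on all balanced
#' metabolites, fixed values for anchored reactions, and non-negativity of
#' irreversible fluxes. Deterministic, so fixtures built from it are stable.
#'
#' @param net A `flux_network`.
#' @param anchors Named numeric vector: reaction id -> required net flux.
#' @param prior Named numeric vector of prior net fluxes (defaults to zero
#'   for unnamed reactions).
#' @param upper Upper bound for all net fluxes.
#' @param extra_eq Optional additional soft linear targets as
#'   `list(mat =, rhs =)` with `mat` columns in reaction order; pulled
#'   toward strongly but not enforced exactly (used to seed fits with the
#'   measured external rates).
#' @return Named numeric net-flux vector satisfying the constraints.
#' @export
complete_fluxes <- function(net, anchors, prior = NULL, upper = 2000,
                            extra_eq = NULL) {
  S <- stoichiometry(net)
  ids <- colnames(S)
  n <- length(ids)
  p <- setNames(numeric(n), ids)
  if (!is.null(prior)) {
    bad <- setdiff(names(prior), ids)
    if (length(bad)) abort(sprintf("unknown reaction in prior: %s", bad[1]))
    p[names(prior)] <- prior
  }
  bad <- setdiff(names(anchors), ids)
  if (length(bad)) abort(sprintf("unknown reaction in anchors: %s", bad[1]))
  Aeq <- S
  beq <- rep(0, nrow(S))
  for (a in names(anchors)) {
    row <- numeric(n)
    row[match(a, ids)] <- 1
    Aeq <- rbind(Aeq, row)
    beq <- c(beq, anchors[[a]])
  }
  # soft targets enter the quadratic objective with a strong weight
  H <- diag(n)
  g <- p
  if (!is.null(extra_eq)) {
    w2 <- 30^2
    H <- H + w2 * crossprod(extra_eq$mat)
    g <- g + w2 * drop(crossprod(extra_eq$mat, extra_eq$rhs))
  }
  rev_ids <- vapply(Filter(function(r) r$reversible, core_reactions(net)), `[[`, "", "id")
  lower_bounded <- !(ids %in% rev_ids)

  # equality-constrained least squares via KKT, with a small active-set loop
  # pinning violated irreversibility bounds to zero
  solve_eq <- function(Aeq_all, beq_all) {
    K <- rbind(cbind(2 * H, t(Aeq_all)),
               cbind(Aeq_all, matrix(0, nrow(Aeq_all), nrow(Aeq_all))))
    rhs <- c(2 * g, beq_all)
    sol <- tryCatch(qr.solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      # redundant constraints (e.g. pinned fluxes duplicating a balance row):
      # minimum-norm KKT solution via the pseudoinverse
      sv <- svd(K)
      keep <- sv$d > max(sv$d) * 1e-10
      sol <- sv$v[, keep, drop = FALSE] %*%
        ((crossprod(sv$u[, keep, drop = FALSE], rhs)) / sv$d[keep])
      if (max(abs(K %*% sol - rhs)) > 1e-6 * max(1, max(abs(rhs)))) {
        abort("anchor values are infeasible at steady state")
      }
      sol <- drop(sol)
    }
    sol[seq_len(n)]
  }
  active <- logical(n)
  v <- solve_eq(Aeq, beq)
  for (iter in seq_len(50L)) {
    viol <- lower_bounded & !active & v < -1e-9
    if (!any(viol)) break
    active <- active | viol
    Apin <- diag(n)[active, , drop = FALSE]
    v <- solve_eq(rbind(Aeq, Apin), c(beq, rep(0, sum(active))))
    if (iter == 50L) abort("flux completion did not converge")
  }
  if (any(abs(v) > upper)) {
    abort(sprintf("flux completion exceeded bound %g on '%s'", upper,
                  ids[which.max(abs(v))]))
  }
  res <- drop(S %*% v)
  if (max(abs(res)) > 1e-6) {
    abort(sprintf("completion failed: balance residual %.3g on '%s'",
                  max(abs(res)), rownames(S)[which.max(abs(res))]))
  }
  # polish to machine-precision steady state by projecting onto null space
  N <- qr.Q(qr(t(S)), complete = TRUE)[, (qr(S)$rank + 1L):n, drop = FALSE]
  v <- drop(N %*% crossprod(N, v))
  setNames(v, ids)
}

#' Build a synthetic study fixture
#'
#' Constructs a steady-state flux map for the requested condition whose
#' anchored reactions (ME1, MDH1, PCK1) carry the published values, with all
#' remaining fluxes filled by deterministic bounded least-norm completion
#' around a prior encoding the qualitative flux directions of the study
#' (quiescent cells: lower glycolysis and lactate secretion, strongly
#' increased mitochondrial pyruvate uptake, TCA flux, anaplerosis and
#' malate export, elevated proline synthesis). The fixture also carries the
#' tracer panel, replicate counts, growth model and noise model used by
#' [simulate_study].
#'
#' @param condition `"P"` (proliferating), `"Q"` (quiescent), or the
#'   qualitative variants `"P-5SA"` / `"Q-5SA"` (constitutively active YAP:
#'   glycolysis restored in Q with maintained TCA flux; no numeric anchors).
#' @param seed Base seed stored in the fixture (used by [simulate_study]).
#' @param mid_sd Additive MID noise SD (mole fraction).
#' @param rate_cv Relative SD of external-rate measurements.
#' @param replicates Biological replicates per tracer.
#' @return A `study_fixture` object.
#' @export
build_fixture <- function(condition = c("P", "Q", "P-5SA", "Q-5SA"), seed = 1L,
                          mid_sd = 0.003, rate_cv = 0.10, replicates = 2L) {
  condition <- match.arg(condition)
  net <- mef_network()
  pri <- fixture_prior(condition)
  anchors <- fixture_anchors(condition)
  v <- complete_fluxes(net, anchors, pri$net_flux)
  fmap <- flux_map(net, v, exchange = pri$exchange, mixing = pri$mixing)
  tracers <- list(
    glc12 = tracer_spec("glc.x", c(1, 2), id = "glc12"),
    glnU  = tracer_spec("gln.x", 1:5, id = "glnU")
  )
  growing <- condition %in% c("P", "P-5SA")
  structure(list(
    condition = condition, net = net, flux = fmap, anchors = anchors,
    tracers = tracers, replicates = as.integer(replicates),
    mid_sd = mid_sd, rate_cv = rate_cv, rate_sd_floor = 0.1,
    growth = list(mu = if (growing) log(2) / 24 else 0, x0 = 0.3),
    media0 = c(glc = 50000, gln = 8000, lac = 0, ala = 0, pyr = 400,
               glu = 200, pro = 0),
    seed = as.integer(seed)
  ), class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("<study_fixture> condition %s: %d tracers x %d replicates, MID sd %.3g, rate CV %.0f%%\n",
              x$condition, length(x$tracers), x$replicates, x$mid_sd, 100 * x$rate_cv))
  anc <- fixture_anchors(x$condition)
  for (a in names(anc)) cat(sprintf("  anchor %s = %g\n", a, anc[[a]]))
  invisible(x)
}

fixture_anchors <- function(condition) {
  man <- mef_anchors()
  base <- sub("-5SA$", "", condition)
  if (condition %in% c("P", "Q")) {
    anc <- man[man$condition == condition, ]
    setNames(anc$net_flux, anc$reaction)
  } else {
    # 5SA variants carry no printed anchors; fixtures are qualitative only
    numeric(0)
  }
}

# priors encode the qualitative picture of the flux maps; anchored reactions
# are set exactly by completion, everything else is filled nearby
fixture_prior <- function(condition) {
  exchange <- c(PGI = 40, TPI = 40, LDH = 60, MDH2 = 40,
                MALT = 10, MDH1 = 25, GOT1 = 8, GOT2 = 15, RPI = 5, RPE = 5,
                TKT1 = 2, TALA = 2, TKT2 = 2)
  net_flux <- switch(condition,
    P = c(HK = 150, PGI = 122, PFK = 134, ALD = 134, TPI = 128, GAPD = 268,
          ENO = 268, PK = 275, LDH = 230, LACS = 230, G6PD = 28, RPI = 16,
          RPE = 12, TKT1 = 6, TALA = 6, TKT2 = 6, RNAS = 10, GPD1 = 5,
          LIPS = 5, MPC = 75, PDH = 66, PC = 6, CS = 66, IDH = 45, AKGD = 62,
          SDH = 62, MDH2 = 58, ME2 = 4, MALT = 7, CITT = 21, ACL = 21,
          FAS = 21, MDH1 = 24.4, ME1 = 31.6, PCK1 = 7.4, GLNUP = 30,
          GLS = 30, GDH = 12, PROS = 2, PROSEC = 2, GOT2 = 8, GOT1 = -6,
          AKGT = 6, GLUT = 4, ASPT = 4, ASPBM = 12, GLUBM = 10, ALTM = 6,
          ALAT = 6, ALASEC = 6, DILGLU = 6, DILASP = 4, DILPYR = 5),
    Q = c(HK = 90, PGI = 62, PFK = 74, ALD = 74, TPI = 49, GAPD = 129,
          ENO = 129, PK = 233, LDH = 57, LACS = 57, G6PD = 28, RPI = 14,
          RPE = 13, TKT1 = 6.5, TALA = 6.5, TKT2 = 6.5, RNAS = 7, GPD1 = 25,
          LIPS = 25, MPC = 200, PDH = 139, PC = 90, CS = 139, IDH = 135,
          AKGD = 158, SDH = 158, MDH2 = 54, ME2 = 17, MALT = 87, CITT = 4,
          ACL = 4, FAS = 4, MDH1 = -86.6, ME1 = 0, PCK1 = 104, GLNUP = 35,
          GLS = 35, GDH = 17, PROS = 8, PROSEC = 8, GOT2 = 5, GOT1 = -3,
          AKGT = 3, GLUT = 2, ASPT = 4, ASPBM = 9, GLUBM = 8, ALTM = 3,
          ALAT = 3, ALASEC = 3, DILGLU = 6, DILASP = 4, DILPYR = 4),
    # YAP-5SA variants: glycolysis restored (or kept high) on top of the
    # elevated mitochondrial program; qualitative only
    `P-5SA` = {
      p <- fixture_prior("P")$net_flux
      p
    },
    `Q-5SA` = {
      q <- fixture_prior("Q")$net_flux
      p <- fixture_prior("P")$net_flux
      q[c("HK", "PGI", "PFK", "ALD", "TPI", "GAPD", "ENO", "PK", "LDH",
          "LACS")] <-
        p[c("HK", "PGI", "PFK", "ALD", "TPI", "GAPD", "ENO", "PK", "LDH",
            "LACS")] * 1.1
      q["G6PD"] <- 4    # PPP silenced in Q-5SA
      q["ME1"] <- 90    # malate-to-pyruvate flux increased ~3-fold
      q
    })
  mixing <- switch(sub("-5SA$", "", condition),
    P = c(MIXPYR = 0.8, MIXALA = 0.6, MIXMAL = 0.4, MIXASP = 0.5,
          MIXAKG = 0.4, MIXCIT = 0.3),
    Q = c(MIXPYR = 0.6, MIXALA = 0.5, MIXMAL = 0.3, MIXASP = 0.4,
          MIXAKG = 0.3, MIXCIT = 0.25))
  list(net_flux = net_flux, exchange = exchange, mixing = mixing)
}

#' Simulate a complete parallel-labeling study
#'
#' Generates everything the pipeline consumes: noisy steady-state MIDs for
#' every measured fragment under each tracer and replicate, spent-media
#' concentration time courses at 0/6/18/24 h with replicate wells, cell
#' counts (exponential growth for proliferating fixtures, constant density
#' for quiescent ones) and a noisy external-rate table. All randomness is
#' driven by `seed`.
#'
#' @param fixture A `study_fixture` from [build_fixture].
#' @param seed Integer seed (defaults to the fixture's).
#' @param noise If `FALSE`, return noise-free data.
#' @return List with tibbles `mids` (`fragment`, `tracer_id`, `replicate`,
#'   `mass_shift`, `fraction`, `sd`), `rates` (`species`, `rate`, `sd`),
#'   `media` (`time_h`, `well`, `species`, `conc`), `cells`
#'   (`time_h`, `well`, `cells_e6`), plus `truth` (the fixture).
#' @export
simulate_study <- function(fixture, seed = fixture$seed, noise = TRUE) {
  set.seed(seed)
  net <- fixture$net
  system <- emu_decompose(net, mef_fragments())
  mids <- purrr::map_dfr(fixture$tracers, function(tr) {
    clean <- simulate_mids(net, fixture$flux, tr, system = system)
    purrr::map_dfr(seq_len(fixture$replicates), function(rep) {
      d <- clean
      if (noise) {
        d <- d %>%
          dplyr::group_by(.data$fragment) %>%
          dplyr::mutate(fraction = {
            f <- pmax(.data$fraction + rnorm(dplyr::n(), 0, fixture$mid_sd), 0)
            f / sum(f)
          }) %>%
          dplyr::ungroup()
      }
      d$tracer_id <- tr$id
      d$replicate <- rep
      d$sd <- fixture$mid_sd
      d
    })
  })

  q_true <- true_external_rates(fixture)
  rates <- tibble::tibble(
    species = names(q_true),
    rate = unname(q_true) * (if (noise) 1 + rnorm(length(q_true), 0, fixture$rate_cv) else 1),
    sd = pmax(abs(q_true) * fixture$rate_cv, fixture$rate_sd_floor)
  )

  times <- c(0, 6, 18, 24)
  wells <- 3L
  mu <- fixture$growth$mu
  x0 <- fixture$growth$x0
  xt <- if (mu > 0) x0 * exp(mu * times) else rep(x0, length(times))
  cells <- purrr::map_dfr(seq_len(wells), function(w) {
    tibble::tibble(time_h = times, well = w,
                   cells_e6 = xt * (if (noise) exp(rnorm(length(times), 0, 0.03)) else 1))
  })
  # medium amount consumed by time t under the growth model
  consumed <- function(q, t) {
    if (mu > 0) q * x0 * (exp(mu * t) - 1) / mu else q * x0 * t
  }
  media <- purrr::map_dfr(seq_len(wells), function(w) {
    purrr::map_dfr(names(q_true), function(s) {
      c0 <- fixture$media0[[s]]
      conc <- c0 - consumed(q_true[[s]], times)
      tibble::tibble(time_h = times, well = w, species = s,
                     conc = conc * (if (noise) exp(rnorm(length(times), 0, 0.02)) else 1))
    })
  })

  list(mids = mids, rates = rates, media = media, cells = cells, truth = fixture)
}

# true external rates (nmol/10^6 cells/h, + uptake / - secretion)
true_external_rates <- function(fixture) {
  map <- mef_rate_map()
  v <- fixture$flux$net_flux
  out <- tapply(map$sign * v[map$reaction], map$species, sum)
  # keep declared species order; plain named numeric, not a 1-d array
  setNames(as.numeric(out[unique(map$species)]), unique(map$species))
}
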
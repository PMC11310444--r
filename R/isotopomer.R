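#' Brute-force positional-isotopomer simulation (validation oracle)
#'
#' Solves the full positional-isotopomer balance of the network by
#' Gauss-Seidel fixed-point iteration on the complete 2^n labeling-state
#' distribution of every balanced metabolite, then marginalizes to fragment
#' MIDs. Exact at convergence under the same well-mixed steady-state
#' assumptions as the EMU cascade, but exponential in carbon count: intended
#' as an independent cross-check of [simulate_mids] on small networks, not
#' for production use.
#'
#' @inheritParams simulate_mids
#' @param max_carbons Refuse metabolites with more carbons than this
#'   (state-space bound).
#' @param tol Fixed-point convergence tolerance (max absolute change).
#' @param max_iter Iteration cap.
#' @return A tibble with columns `fragment`, `mass_shift`, `fraction`.
#' @export
isotopomer_mids <- function(net, fmap, tracer, fragments = NULL,
                            max_carbons = 12L, tol = 1e-13, max_iter = 50000L) {
  if (is.null(fragments)) fragments <- default_fragments(net)
  targets <- normalize_targets(net, fragments)
  if (any(net$metabolites$carbons > max_carbons)) {
    abort(sprintf("isotopomer state space too large: '%s' has more than %d carbons",
                  net$metabolites$metabolite[which.max(net$metabolites$carbons)],
                  max_carbons))
  }
  tracers <- as_tracer_list(tracer)
  uni <- expand_unidirectional(net)
  ub <- unidirectional_fluxes(net, fmap)
  uf <- vapply(uni, function(u) if (u$dir == "fwd") ub$fwd[[u$rxn]] else ub$bwd[[u$rxn]], 0)

  carbons <- setNames(net$metabolites$carbons, net$metabolites$metabolite)
  comp <- setNames(net$metabolites$compartment, net$metabolites$metabolite)
  mets <- net$metabolites$metabolite

  # bit patterns: bits[[m]] is (2^nc x nc) 0/1 matrix
  bitmat <- function(nc) {
    if (nc == 0L) return(matrix(0L, 1, 0))
    idx <- 0:(2^nc - 1)
    sapply(seq_len(nc), function(b) bitwAnd(idx, bitwShiftL(1L, b - 1L)) > 0) * 1L
  }
  bits <- lapply(carbons[mets], function(nc) bitmat(nc))
  names(bits) <- mets

  dist <- list()
  for (m in mets) {
    nc <- carbons[[m]]
    if (comp[[m]] == "extracellular") {
      p <- vapply(seq_len(max(nc, 0)), function(i) NA_real_, 0)
      # per-position labeling probability; mixtures handled via component average
      d <- isotopomer_inlet_dist(tracers, m, nc, bits[[m]])
      dist[[m]] <- d
    } else {
      dist[[m]] <- c(1, rep(0, 2^nc - 1))
    }
  }

  balanced <- net$balanced
  # precompile production routes: per balanced metabolite, list of
  # (uni index, and for each substrate term: source met + lookup index vector)
  prod_routes <- setNames(vector("list", length(balanced)), balanced)
  cons_flux <- setNames(numeric(length(balanced)), balanced)
  for (i in seq_along(uni)) {
    u <- uni[[i]]
    for (st in u$substrates) {
      if (st$metabolite %in% balanced) {
        cons_flux[[st$metabolite]] <- cons_flux[[st$metabolite]] + u$weight * uf[[i]]
      }
    }
    for (pt in u$products) {
      m <- pt$metabolite
      if (!m %in% balanced) next
      ncp <- carbons[[m]]
      pb <- bits[[m]]
      terms <- list()
      for (st in u$substrates) {
        spos <- which(st$map %in% pt$map)
        if (!length(spos)) next
        ppos <- match(st$map[spos], pt$map)
        ncs <- carbons[[st$metabolite]]
        sb <- bits[[st$metabolite]]
        # marginal group of substrate isotopomers onto spos (1-based index)
        marg_group <- as.integer(sb[, spos, drop = FALSE] %*% 2^(seq_along(spos) - 1L)) + 1L
        # lookup: product isotopomer -> marginal index via bits at ppos
        lookup <- as.integer(pb[, ppos, drop = FALSE] %*% 2^(seq_along(spos) - 1L)) + 1L
        terms[[length(terms) + 1L]] <- list(src = st$metabolite, n = 2^length(spos),
                                            marg_group = marg_group, lookup = lookup)
      }
      prod_routes[[m]] <- c(prod_routes[[m]],
                            list(list(uni = i, w = u$weight, terms = terms)))
    }
  }
  if (any(cons_flux <= 1e-12)) {
    abort(sprintf("dead pool: zero consumption flux for balanced metabolite '%s'",
                  balanced[cons_flux <= 1e-12][1]))
  }

  # damped Gauss-Seidel: the undamped bilinear fixed point can oscillate
  # when exchange fluxes are large relative to net fluxes
  omega <- 0.7
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (m in balanced) {
      acc <- numeric(2^carbons[[m]])
      for (rt in prod_routes[[m]]) {
        v <- rt$w * uf[[rt$uni]]
        if (v == 0) next
        pd <- rep(1, length(acc))
        for (tm in rt$terms) {
          marg <- rowsum(dist[[tm$src]], tm$marg_group)[, 1]
          pd <- pd * marg[tm$lookup]
        }
        acc <- acc + v * pd
      }
      new <- (1 - omega) * dist[[m]] + omega * acc / cons_flux[[m]]
      if (!all(is.finite(new)) || sum(new) <= 0) {
        abort("isotopomer fixed point diverged; check the flux map for dead or runaway cycles")
      }
      # project onto the simplex: the bilinear recycle system admits
      # spurious sub-stochastic fixed points, but every true distribution
      # sums to one
      new <- new / sum(new)
      delta <- max(delta, max(abs(new - dist[[m]])))
      dist[[m]] <- new
    }
    if (delta < tol * omega) break
    if (it == max_iter) {
      abort(sprintf("isotopomer fixed point did not converge (last change %.3g)", delta))
    }
  }

  frags <- targets$fragments
  purrr::map_dfr(names(frags), function(fr) {
    fg <- frags[[fr]]
    frag_mid <- function(met, atoms) {
      weight <- rowSums(bits[[met]][, atoms, drop = FALSE])
      full <- numeric(length(atoms) + 1L)
      full[sort(unique(weight)) + 1L] <- rowsum(dist[[met]], weight)[, 1]
      full
    }
    mid <- if (fg$kind == "mixed") {
      f <- fmap$mixing[[fg$mixing]]
      f * frag_mid(fg$cyt$met, fg$cyt$atoms) + (1 - f) * frag_mid(fg$mito$met, fg$mito$atoms)
    } else {
      frag_mid(fg$met, fg$atoms)
    }
    tibble::tibble(fragment = fr, mass_shift = seq_along(mid) - 1L, fraction = mid)
  })
}

isotopomer_inlet_dist <- function(tracers, met, nc, bitsm) {
  for (tr in tracers) {
    if (inherits(tr, "tracer_mixture") && tr$species == met) {
      d <- 0
      for (i in seq_along(tr$components)) {
        d <- d + tr$weights[[i]] *
          isotopomer_inlet_dist(list(tr$components[[i]]), met, nc, bitsm)
      }
      return(d)
    }
  }
  p <- rep(0, nc)
  for (tr in tracers) {
    if (inherits(tr, "tracer_spec") && tr$species == met && length(tr$positions)) {
      p[tr$positions] <- tr$enrichment
    }
  }
  if (nc == 0L) return(1)
  apply(bitsm, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
}
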
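#' EMU decomposition of an atom-transition network
#'
#' Decomposes the network into the elementary metabolite units (EMUs --
#' subsets of a metabolite's carbon atoms) required to simulate the mass
#' isotopomer distributions (MIDs) of a set of target fragments. The
#' decomposition yields, per EMU size, a linear steady-state balance system
#' whose inputs are tracer EMUs and convolutions of smaller EMUs, so the
#' size-k system depends only on sizes < k and the whole cascade is solved
#' by ascending size.
#'
#' Reversible reactions are expanded into forward/backward unidirectional
#' fluxes (`fwd = exch + max(net, 0)`, `bwd = exch + max(-net, 0)`), and
#' reactions producing rotationally symmetric metabolites are split into two
#' half-weight variants with forward and reversed atom maps.
#'
#' @param net A `flux_network`.
#' @param targets Character vector of metabolite ids (full-carbon fragments),
#'   or a list of `list(metabolite =, atoms =)` entries for partial fragments.
#'   Measurement-pool ids (`*.meas`) are resolved to their cytosolic and
#'   mitochondrial source pools.
#' @return An `emu_system` object (opaque compiled representation); its
#'   `$emus` field tabulates every EMU with its size and whether it is an
#'   inlet (extracellular, labeling fixed by the tracer) or an unknown.
#' @export
emu_decompose <- function(net, targets) {
  targets <- normalize_targets(net, targets)
  uni <- expand_unidirectional(net)
  carbons <- setNames(net$metabolites$carbons, net$metabolites$metabolite)
  is_inlet <- setNames(net$metabolites$compartment == "extracellular",
                       net$metabolites$metabolite)

  emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

  emus <- list()     # key -> list(met, atoms, size, type)
  routes <- list()   # key -> list of list(src = keys, uni = i, w = weight)
  queue <- list()
  push <- function(met, atoms) {
    atoms <- sort(unique(as.integer(atoms)))
    if (length(atoms) == 0L || any(atoms < 1L) || any(atoms > carbons[[met]])) {
      abort(sprintf("invalid EMU atom set for '%s'", met))
    }
    key <- emu_key(met, atoms)
    if (is.null(emus[[key]])) {
      emus[[key]] <<- list(met = met, atoms = atoms, size = length(atoms),
                           type = if (is_inlet[[met]]) "inlet" else "unknown")
      if (!is_inlet[[met]]) queue[[length(queue) + 1L]] <<- key
    }
    key
  }
  for (tg in targets$emu_targets) push(tg$metabolite, tg$atoms)

  while (length(queue)) {
    key <- queue[[1L]]
    queue <- queue[-1L]
    e <- emus[[key]]
    rts <- list()
    for (i in seq_along(uni)) {
      u <- uni[[i]]
      for (pt in u$products) {
        if (pt$metabolite != e$met) next
        letters <- pt$map[e$atoms]
        srcs <- character()
        for (st in u$substrates) {
          pos <- which(st$map %in% letters)
          if (length(pos)) srcs <- c(srcs, push(st$metabolite, pos))
        }
        if (length(srcs) == 0L) {
          abort(sprintf("internal error: no source atoms found for EMU %s in reaction %s",
                        key, u$id))
        }
        rts[[length(rts) + 1L]] <- list(src = sort(srcs), uni = i, w = u$weight)
      }
    }
    if (length(rts) == 0L) {
      abort(sprintf("EMU %s of '%s' is unreachable: no reaction produces it", key, e$met))
    }
    routes[[key]] <- rts
  }

  # per-metabolite consumption triplets (uni index, weight * n substrate terms)
  cons <- list()
  for (i in seq_along(uni)) {
    u <- uni[[i]]
    for (st in u$substrates) {
      cons[[st$metabolite]] <- c(cons[[st$metabolite]],
                                 list(list(uni = i, w = u$weight)))
    }
  }

  key_index <- setNames(seq_along(emus), names(emus))
  unknown_keys <- names(emus)[vapply(emus, function(e) e$type == "unknown", TRUE)]
  sizes <- sort(unique(vapply(emus[unknown_keys], `[[`, 0L, "size")))
  blocks <- lapply(sizes, function(k) {
    keys <- unknown_keys[vapply(emus[unknown_keys], `[[`, 0L, "size") == k]
    compile_block(keys, k, emus, routes, cons, key_index)
  })
  names(blocks) <- as.character(sizes)
  inlet_keys <- names(emus)[vapply(emus, function(e) e$type == "inlet", TRUE)]

  structure(list(net = net, uni = uni, emus = emus, routes = routes,
                 sizes = sizes, blocks = blocks, targets = targets,
                 carbons = carbons, key_index = key_index,
                 inlet_keys = inlet_keys),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  szs <- vapply(x$emus, `[[`, 0L, "size")
  typ <- vapply(x$emus, `[[`, "", "type")
  cat(sprintf("<emu_system> %d EMUs (%d unknown) across sizes {%s}\n",
              length(x$emus), sum(typ == "unknown"),
              paste(x$sizes, collapse = ", ")))
  tab <- table(szs[typ == "unknown"])
  for (s in names(tab)) cat(sprintf("  size %s: %d unknown EMUs\n", s, tab[[s]]))
  invisible(x)
}

#' @describeIn emu_decompose EMU table as a tibble.
#' @param x An `emu_system`.
#' @param ... Unused.
#' @export
tidy.emu_system <- function(x, ...) {
  tibble::tibble(
    emu = names(x$emus),
    metabolite = vapply(x$emus, `[[`, "", "met"),
    size = vapply(x$emus, `[[`, 0L, "size"),
    type = vapply(x$emus, `[[`, "", "type")
  )
}

# resolve target spec to EMU targets and fragment definitions
normalize_targets <- function(net, targets) {
  if (is.character(targets)) {
    if (is.null(names(targets))) names(targets) <- sub("\\.[a-z]+$", "", targets)
    targets <- lapply(seq_along(targets), function(i) {
      list(fragment = names(targets)[[i]], metabolite = targets[[i]])
    })
  }
  carbons <- setNames(net$metabolites$carbons, net$metabolites$metabolite)
  mix <- mixing_reactions(net)
  mix_prod <- vapply(mix, function(r) r$products[[1]]$metabolite, "")
  frags <- list()
  emu_targets <- list()
  for (tg in targets) {
    met <- tg$metabolite
    if (!met %in% net$metabolites$metabolite) {
      abort(sprintf("target metabolite '%s' is not declared in the network", met))
    }
    frag <- if (!is.null(tg$fragment)) tg$fragment else sub("\\.[a-z]+$", "", met)
    if (met %in% mix_prod) {
      r <- mix[[match(met, mix_prod)]]
      pools <- vapply(r$substrates, `[[`, "", "metabolite")
      cyt <- pools[metabolite_compartment(pools) == "cytosol"]
      mito <- pools[metabolite_compartment(pools) == "mitochondrion"]
      atoms <- if (!is.null(tg$atoms)) tg$atoms else seq_len(carbons[[cyt]])
      frags[[frag]] <- list(kind = "mixed", mixing = r$id,
                            cyt = list(met = cyt, atoms = atoms),
                            mito = list(met = mito, atoms = atoms))
      emu_targets <- c(emu_targets, list(list(metabolite = cyt, atoms = atoms),
                                         list(metabolite = mito, atoms = atoms)))
    } else {
      atoms <- if (!is.null(tg$atoms)) tg$atoms else seq_len(carbons[[met]])
      frags[[frag]] <- list(kind = "plain", met = met, atoms = atoms)
      emu_targets <- c(emu_targets, list(list(metabolite = met, atoms = atoms)))
    }
  }
  list(fragments = frags, emu_targets = emu_targets)
}

# expand core reactions into unidirectional variants with symmetric scrambling
expand_unidirectional <- function(net) {
  uni <- list()
  rxns <- core_reactions(net)
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    uni <- c(uni, symmetric_variants(
      list(id = r$id, rxn = j, dir = "fwd", weight = 1,
           substrates = r$substrates, products = r$products),
      net$symmetric))
    if (r$reversible) {
      uni <- c(uni, symmetric_variants(
        list(id = r$id, rxn = j, dir = "bwd", weight = 1,
             substrates = r$products, products = r$substrates),
        net$symmetric))
    }
  }
  uni
}

symmetric_variants <- function(u, symmetric) {
  out <- list(u)
  for (ti in seq_along(u$products)) {
    if (u$products[[ti]]$metabolite %in% symmetric) {
      out <- unlist(lapply(out, function(v) {
        v1 <- v2 <- v
        v1$weight <- v$weight / 2
        v2$weight <- v$weight / 2
        v2$products[[ti]]$map <- rev(v2$products[[ti]]$map)
        list(v1, v2)
      }), recursive = FALSE)
    }
  }
  out
}

# compile the size-k balance block into index triplets for fast assembly
compile_block <- function(keys, k, emus, routes, cons, key_index) {
  n <- length(keys)
  col_of <- setNames(seq_len(n), keys)
  diag_row <- integer(); diag_uni <- integer(); diag_w <- numeric()
  a_row <- integer(); a_col <- integer(); a_uni <- integer(); a_w <- numeric()
  rhs <- list()
  for (i in seq_len(n)) {
    key <- keys[[i]]
    met <- emus[[key]]$met
    cl <- cons[[met]]
    if (is.null(cl)) {
      abort(sprintf("metabolite '%s' has no consuming reaction; EMU %s cannot be balanced",
                    met, key))
    }
    for (c0 in cl) {
      diag_row <- c(diag_row, i); diag_uni <- c(diag_uni, c0$uni); diag_w <- c(diag_w, c0$w)
    }
    for (rt in routes[[key]]) {
      if (length(rt$src) == 1L && !is.na(col_of[rt$src])) {
        a_row <- c(a_row, i); a_col <- c(a_col, unname(col_of[rt$src]))
        a_uni <- c(a_uni, rt$uni); a_w <- c(a_w, rt$w)
      } else {
        rhs[[length(rhs) + 1L]] <- list(row = i, src = unname(key_index[rt$src]),
                                        uni = rt$uni, w = rt$w)
      }
    }
  }
  list(keys = keys, ids = unname(key_index[keys]), n = n, size = k,
       diag = list(row = diag_row, uni = diag_uni, w = diag_w,
                   cell = cbind(diag_row, diag_row)),
       amat = list(row = a_row, col = a_col, uni = a_uni, w = a_w,
                   cell = (a_col - 1L) * n + a_row),
       rhs = rhs)
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Forward model: for a flux map and tracer, solves the EMU balance cascade
#' and returns the MID of each target fragment. Fragments backed by a mixing
#' reaction are blended as `f * MID_cytosol + (1 - f) * MID_mitochondrion`
#' with the map's mixing fraction `f`.
#'
#' @param net A `flux_network`.
#' @param fmap A `flux_map`.
#' @param tracer A `tracer_spec`, `tracer_mixture`, or list of them (one per
#'   labeled species; all unlisted extracellular species are unlabeled).
#' @param fragments Targets as in [emu_decompose]; defaults to all
#'   measurement pools of the network.
#' @param system Optional precompiled `emu_system` (for repeated evaluation
#'   with different flux maps).
#' @return A tibble with columns `fragment`, `mass_shift`, `fraction`.
#' @export
simulate_mids <- function(net, fmap, tracer, fragments = NULL, system = NULL) {
  if (is.null(system)) {
    if (is.null(fragments)) fragments <- default_fragments(net)
    system <- emu_decompose(net, fragments)
  }
  sol <- solve_emu_system(system, fmap, tracer)
  fm <- fragment_mids(system, sol, fmap)
  tibble::tibble(
    fragment = rep(names(fm), lengths(fm)),
    mass_shift = unlist(lapply(fm, function(m) seq_along(m) - 1L), use.names = FALSE),
    fraction = unlist(fm, use.names = FALSE)
  )
}

default_fragments <- function(net) {
  mix <- mixing_reactions(net)
  if (length(mix)) {
    vapply(mix, function(r) r$products[[1]]$metabolite, "")
  } else {
    net$balanced
  }
}

as_tracer_list <- function(tracer) {
  if (inherits(tracer, "tracer_spec") || inherits(tracer, "tracer_mixture")) {
    list(tracer)
  } else {
    tracer
  }
}

# precompute flux-independent inlet EMU MIDs for a tracer panel
inlet_mids <- function(system, tracer) {
  tracers <- as_tracer_list(tracer)
  vals <- vector("list", length(system$emus))
  for (key in system$inlet_keys) {
    e <- system$emus[[key]]
    vals[[system$key_index[[key]]]] <- inlet_mid_any(tracers, e$met, e$atoms)
  }
  vals
}

# core solver: returns list indexed by key_index -> MID vector; access by
# emu key through system$key_index. Dispatches to the compiled block solver;
# solve_emu_system_r is the plain-R reference implementation.
solve_emu_system <- function(system, fmap, tracer, inlets = NULL, uf = NULL) {
  if (is.null(uf)) uf <- uni_flux_vector(system, fmap)
  mids <- if (is.null(inlets)) inlet_mids(system, tracer) else inlets
  .emu_solve_cpp(system$blocks, uf, mids)
}

solve_emu_system_r <- function(system, fmap, tracer, inlets = NULL, uf = NULL) {
  if (is.null(uf)) uf <- uni_flux_vector(system, fmap)
  mids <- if (is.null(inlets)) inlet_mids(system, tracer) else inlets
  for (bi in seq_along(system$blocks)) {
    blk <- system$blocks[[bi]]
    n <- blk$n
    k <- blk$size
    A <- matrix(0, n, n)
    dvals <- blk$diag$w * uf[blk$diag$uni]
    dsum <- rowsum(dvals, blk$diag$row)
    drows <- as.integer(rownames(dsum))
    if (any(dsum[, 1] <= 1e-12)) {
      dead <- blk$keys[drows[dsum[, 1] <= 1e-12][1]]
      abort(sprintf("singular EMU balance: zero consumption flux for pool of EMU %s",
                    dead))
    }
    A[cbind(drows, drows)] <- dsum[, 1]
    if (length(blk$amat$row)) {
      avals <- blk$amat$w * uf[blk$amat$uni]
      asum <- rowsum(avals, blk$amat$cell)
      cells <- as.integer(rownames(asum))
      A[cells] <- A[cells] - asum[, 1]
    }
    RHS <- matrix(0, n, k + 1L)
    for (entry in blk$rhs) {
      v <- entry$w * uf[entry$uni]
      if (v == 0) next
      src_mid <- mids[[entry$src[[1L]]]]
      if (length(entry$src) > 1L) {
        for (s in entry$src[-1L]) src_mid <- convolve_mid(src_mid, mids[[s]])
      }
      RHS[entry$row, ] <- RHS[entry$row, ] + v * src_mid
    }
    X <- tryCatch(solve(A, RHS), error = function(e) {
      abort(sprintf("singular EMU balance system at size %d (dead or unreachable pool): %s",
                    k, conditionMessage(e)))
    })
    X[X < 0 & X > -1e-12] <- 0
    ids <- blk$ids
    for (i in seq_len(n)) mids[[ids[[i]]]] <- X[i, ]
  }
  mids
}

# fragment MID extraction from a solved system (fast numeric path)
fragment_mids <- function(system, sol, fmap) {
  frags <- system$targets$fragments
  ki <- system$key_index
  out <- vector("list", length(frags))
  names(out) <- names(frags)
  for (fr in names(frags)) {
    fg <- frags[[fr]]
    out[[fr]] <- if (fg$kind == "mixed") {
      f <- fmap$mixing[[fg$mixing]]
      f * sol[[ki[[paste0(fg$cyt$met, "|", paste(fg$cyt$atoms, collapse = ","))]]]] +
        (1 - f) * sol[[ki[[paste0(fg$mito$met, "|", paste(fg$mito$atoms, collapse = ","))]]]]
    } else {
      sol[[ki[[paste0(fg$met, "|", paste(fg$atoms, collapse = ","))]]]]
    }
  }
  out
}

uni_flux_vector <- function(system, fmap) {
  ub <- unidirectional_fluxes(system$net, fmap)
  vapply(system$uni, function(u) {
    if (u$dir == "fwd") ub$fwd[[u$rxn]] else ub$bwd[[u$rxn]]
  }, 0)
}

inlet_mid_any <- function(tracers, met, atoms) {
  for (tr in tracers) {
    if (inherits(tr, "tracer_mixture") && tr$species == met) {
      mid <- 0
      for (i in seq_along(tr$components)) {
        mid <- mid + tr$weights[[i]] * inlet_emu_mid(list(tr$components[[i]]), met, atoms)
      }
      return(mid)
    }
  }
  inlet_emu_mid(tracers, met, atoms)
}

#' Pool mixture of tracers of one species
#'
#' Represents a medium pool that is a physical mixture of differently labeled
#' preparations of the same metabolite (e.g. 50% `[U-13C]` + 50% unlabeled
#' glucose). Inlet EMU distributions are the weight-averaged component
#' distributions, which is exact for a well-mixed pool.
#'
#' @param ... `tracer_spec` objects of the same species.
#' @param weights Numeric mixture weights (normalized to sum to 1).
#' @return A `tracer_mixture`.
#' @export
tracer_mixture <- function(..., weights) {
  components <- list(...)
  if (length(components) == 1L && is.list(components[[1]]) &&
      !inherits(components[[1]], "tracer_spec")) {
    components <- components[[1]]
  }
  species <- unique(vapply(components, `[[`, "", "species"))
  if (length(species) != 1L) abort("all mixture components must share one species")
  if (length(weights) != length(components) || any(weights < 0)) {
    abort("weights must be non-negative, one per component")
  }
  structure(list(species = species, components = components,
                 weights = weights / sum(weights)),
            class = "tracer_mixture")
}
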
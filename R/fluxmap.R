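#' Flux maps
#'
#' A `flux_map` assigns to every non-mixing reaction a net flux
#' (nmol/10^6 cells/h; negative values allowed for reversible reactions), to
#' every reversible reaction a non-negative exchange flux, and to every mixing
#' reaction a mixing fraction `f` in `[0, 1]` (the share of the cytosolic pool
#' in the measured pool). Net fluxes must satisfy steady state on the
#' balanced metabolites.
#'
#' @param net A `flux_network`.
#' @param net_flux Named numeric vector of net fluxes (one per non-mixing
#'   reaction; missing entries default to 0).
#' @param exchange Named numeric vector of exchange fluxes for reversible
#'   reactions (missing entries default to 0). Must be non-negative.
#' @param mixing Named numeric vector of mixing fractions, one per mixing
#'   reaction (missing entries default to 0.5).
#' @param tol Steady-state residual tolerance.
#' @return A `flux_map` object.
#' @export
flux_map <- function(net, net_flux, exchange = NULL, mixing = NULL, tol = 1e-9) {
  rxns <- core_reactions(net)
  ids <- vapply(rxns, `[[`, "", "id")
  rev_ids <- ids[vapply(rxns, `[[`, TRUE, "reversible")]
  mix_ids <- vapply(mixing_reactions(net), `[[`, "", "id")

  v <- setNames(numeric(length(ids)), ids)
  known <- intersect(names(net_flux), ids)
  v[known] <- net_flux[known]
  extra <- setdiff(names(net_flux), ids)
  if (length(extra)) abort(sprintf("unknown reaction in net_flux: %s", extra[1]))

  ex <- setNames(numeric(length(rev_ids)), rev_ids)
  if (!is.null(exchange)) {
    bad <- setdiff(names(exchange), rev_ids)
    if (length(bad)) abort(sprintf("exchange flux given for non-reversible reaction: %s", bad[1]))
    ex[names(exchange)] <- exchange
  }
  if (any(ex < 0)) abort("exchange fluxes must be non-negative")

  f <- setNames(rep(0.5, length(mix_ids)), mix_ids)
  if (!is.null(mixing)) {
    bad <- setdiff(names(mixing), mix_ids)
    if (length(bad)) abort(sprintf("unknown mixing reaction: %s", bad[1]))
    f[names(mixing)] <- mixing
  }
  if (any(f < 0 | f > 1)) abort("mixing fractions must lie in [0, 1]")

  irrev <- setdiff(ids, rev_ids)
  if (any(v[irrev] < -tol)) {
    abort(sprintf("negative net flux on irreversible reaction '%s'",
                  irrev[which(v[irrev] < -tol)[1]]))
  }

  res <- balance_residuals(net, v)
  if (any(abs(res) > tol)) {
    worst <- names(res)[which.max(abs(res))]
    abort(sprintf("flux map violates steady state: balance residual %.3g on '%s'",
                  res[[worst]], worst))
  }

  structure(list(net_flux = v, exchange = ex, mixing = f), class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat(sprintf("<flux_map> %d net fluxes, %d exchange fluxes, %d mixing fractions\n",
              length(x$net_flux), length(x$exchange), length(x$mixing)))
  invisible(x)
}

#' @describeIn flux_map Flux map as a tibble (one row per parameter).
#' @param x A `flux_map`.
#' @param ... Unused.
#' @export
tidy.flux_map <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(parameter = names(x$net_flux), type = "net", value = unname(x$net_flux)),
    tibble::tibble(parameter = names(x$exchange), type = "exchange", value = unname(x$exchange)),
    tibble::tibble(parameter = names(x$mixing), type = "mixing", value = unname(x$mixing))
  )
}

# forward/backward unidirectional fluxes per core reaction:
# fwd = exch + max(net, 0); bwd = exch + max(-net, 0) (bwd only if reversible)
unidirectional_fluxes <- function(net, fmap) {
  rxns <- core_reactions(net)
  ids <- vapply(rxns, `[[`, "", "id")
  v <- fmap$net_flux[ids]
  ex <- setNames(numeric(length(ids)), ids)
  ex[names(fmap$exchange)] <- fmap$exchange
  list(fwd = ex + pmax(v, 0), bwd = ex + pmax(-v, 0))
}

#' Tracer specification
#'
#' Describes an isotopic tracer applied to a medium metabolite: which carbon
#' positions carry the label and with what fractional enrichment.
#'
#' @param species Extracellular metabolite id (e.g. `"glc.x"`).
#' @param positions Integer vector of labeled carbon positions (1-based).
#' @param enrichment Fractional 13C enrichment of each labeled position
#'   (scalar recycled, or one value per position).
#' @param id Optional tracer label used in data tables; defaults to a
#'   compact description.
#' @return A `tracer_spec` object.
#' @examples
#' tracer_spec("glc.x", c(1, 2))            # [1,2-13C2]glucose
#' tracer_spec("gln.x", 1:5)                # [U-13C5]glutamine
#' @export
tracer_spec <- function(species, positions, enrichment = 1, id = NULL) {
  positions <- as.integer(positions)
  if (length(positions) && (any(positions < 1L) || anyDuplicated(positions))) {
    abort("tracer positions must be distinct positive carbon indices")
  }
  enrichment <- rep_len(enrichment, max(1L, length(positions)))
  if (any(enrichment < 0 | enrichment > 1)) {
    abort("tracer enrichment must lie in [0, 1]")
  }
  if (is.null(id)) {
    id <- sprintf("%s[%s]", sub("\\.x$", "", species), paste(positions, collapse = ","))
  }
  structure(list(species = species, positions = positions,
                 enrichment = enrichment, id = id),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("<tracer_spec> %s: positions %s at enrichment %s\n", x$species,
              paste(x$positions, collapse = ","),
              paste(signif(x$enrichment, 3), collapse = ",")))
  invisible(x)
}

# MID of an EMU (subset of atoms) of an inlet metabolite under a tracer panel.
# Positions not covered by any tracer of that species are unlabeled.
inlet_emu_mid <- function(tracers, metabolite, atoms) {
  p_label <- rep(0, length(atoms))
  for (tr in tracers) {
    if (tr$species == metabolite && length(tr$positions)) {
      hit <- match(atoms, tr$positions)
      p_label[!is.na(hit)] <- tr$enrichment[hit[!is.na(hit)]]
    }
  }
  mid <- 1
  for (p in p_label) mid <- convolve_mid(mid, c(1 - p, p))
  mid
}

# open discrete convolution of two MID vectors
convolve_mid <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[[i]] * b
  }
  out
}
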
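#' Built-in networks
#'
#' `mef_network()` loads the shipped compartmentalized mouse embryonic
#' fibroblast (MEF) central-carbon reconstruction: glycolysis, oxidative and
#' non-oxidative pentose phosphate pathway, TCA cycle, pyruvate carboxylase
#' anaplerosis, cytosolic and mitochondrial malic enzyme (ME1/ME2) and malate
#' dehydrogenase (MDH1/MDH2), PEP carboxykinase (PCK1), proline synthesis
#' from glutamine, dual cytosolic/mitochondrial pools with mixing reactions
#' for the six dually compartmented measured metabolites, and unlabeled CO2
#' and medium dilution inflows. `toy_network()` returns small networks used
#' in examples and validation.
#'
#' @return A `flux_network`.
#' @export
mef_network <- function() {
  read_network(system.file("extdata", "mef_network.tsv", package = "compflux",
                           mustWork = TRUE))
}

#' @rdname mef_network
#' @param name One of `"chain"` (3-carbon linear chain), `"diamond"`
#'   (one split, two degrees of freedom), `"glypp"` (glycolysis plus
#'   oxidative/non-oxidative PPP feeding a DHAP readout).
#' @export
toy_network <- function(name = c("chain", "diamond", "glypp")) {
  name <- match.arg(name)
  lines <- switch(name,
    chain = c(
      "v1\t0\texchange\tA.x (abc) -> B.c (abc)",
      "v2\t0\texchange\tB.c (abc) -> C.x (abc)"
    ),
    diamond = c(
      "up\t0\texchange\tA.x (ab) -> B.c (ab)",
      "left\t0\tenzymatic\tB.c (ab) -> L.c (ab)",
      "right\t0\tenzymatic\tB.c (ab) -> R.c (ba)",
      "dl\t0\tenzymatic\tL.c (ab) -> D.c (ab)",
      "dr\t0\tenzymatic\tR.c (ab) -> D.c (ab)",
      "out\t0\texchange\tD.c (ab) -> D.x (ab)"
    ),
    glypp = c(
      "hk\t0\texchange\tglc.x (abcdef) -> g6p.c (abcdef)",
      "pgi\t1\tenzymatic\tg6p.c (abcdef) -> f6p.c (abcdef)",
      "pfk\t0\tenzymatic\tf6p.c (abcdef) -> fbp.c (abcdef)",
      "ald\t0\tenzymatic\tfbp.c (abcdef) -> dhap.c (cba) + gap.c (def)",
      "tpi\t1\tenzymatic\tdhap.c (abc) -> gap.c (abc)",
      "oxppp\t0\tenzymatic\tg6p.c (abcdef) -> p5p.c (bcdef) + co2.x (a)",
      "tkt1\t1\tenzymatic\tp5p.c (abcde) + p5p.c (fghij) -> s7p.c (abfghij) + gap.c (cde)",
      "tala\t1\tenzymatic\ts7p.c (abcdefg) + gap.c (hij) -> f6p.c (abchij) + e4p.c (defg)",
      "tkt2\t1\tenzymatic\tp5p.c (abcde) + e4p.c (fghi) -> f6p.c (abfghi) + gap.c (cde)",
      "gapd\t0\tenzymatic\tgap.c (abc) -> pyr.c (abc)",
      "ldh\t1\tenzymatic\tpyr.c (abc) -> lac.c (abc)",
      "lacs\t0\texchange\tlac.c (abc) -> lac.x (abc)",
      "dhaps\t0\texchange\tdhap.c (abc) -> dhap.x (abc)",
      "p5ps\t0\texchange\tp5p.c (abcde) -> rna.x (abcde)"
    ))
  parse_network(lines)
}

#' Measured GC-MS fragments of the MEF model
#'
#' Fragment definitions for the twelve measured metabolites (measurement
#' pools for dually compartmented species). Besides the full-backbone
#' `[M-57]+` ions, the TBDMS chemistry yields partial-backbone ions (loss
#' of the C1 carboxyl, analogous to the `[M-85]+` series) for malate,
#' aspartate and alpha-ketoglutarate; these carry positional information
#' that the full-carbon ions cannot (e.g. they see the rotational
#' scrambling of succinate-derived malate), and are required to resolve
#' the cytosolic malate/oxaloacetate fluxes.
#'
#' @return Named list of `list(fragment, metabolite, atoms)` entries
#'   (`atoms = NULL` means the full backbone).
#' @export
mef_fragments <- function() {
  full <- c(pyr = "pyr.meas", lac = "lac.c", ala = "ala.meas", mal = "mal.meas",
            asp = "asp.meas", akg = "akg.meas", gln = "gln.c", cit = "cit.meas",
            g3p = "g3p.c", pep = "pep.c", `3pg` = "3pg.c", r5p = "r5p.c")
  out <- lapply(seq_along(full), function(i) {
    list(fragment = names(full)[[i]], metabolite = full[[i]], atoms = NULL)
  })
  names(out) <- names(full)
  out$mal234 <- list(fragment = "mal234", metabolite = "mal.meas", atoms = 2:4)
  out$asp234 <- list(fragment = "asp234", metabolite = "asp.meas", atoms = 2:4)
  out$akg2345 <- list(fragment = "akg2345", metabolite = "akg.meas", atoms = 2:5)
  out
}

#' External-rate measurement map of the MEF model
#'
#' Maps each measured spent-media species to the signed combination of
#' network reactions whose net fluxes it reports (positive = uptake,
#' negative = secretion), matching the seven rates fitted in the study.
#'
#' @return Tibble with columns `species`, `reaction`, `sign`.
#' @export
mef_rate_map <- function() {
  tibble::tribble(
    ~species, ~reaction, ~sign,
    "glc", "HK", 1,
    "gln", "GLNUP", 1,
    "lac", "LACS", -1,
    "ala", "ALASEC", -1,
    "pyr", "DILPYR", 1,
    "glu", "DILGLU", 1,
    "pro", "PROSEC", -1
  )
}

#' The paper-anchored fluxes of the MEF fixtures
#'
#' Machine-readable manifest of the anchored reactions of the proliferating
#' (P) and quiescent (Q) fixtures: cytosolic malic enzyme (ME1), cytosolic
#' malate dehydrogenase (MDH1, net flux positive in the OAC.c to Mal.c
#' direction) and PEP carboxykinase (PCK1), in nmol/10^6 cells/h.
#'
#' @return Tibble with columns `condition`, `reaction`, `net_flux`,
#'   `description`.
#' @export
mef_anchors <- function() {
  path <- system.file("extdata", "mef_anchors.csv", package = "compflux",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
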
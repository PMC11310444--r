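#' Natural isotope abundances used for GC-MS correction
#'
#' Representative terrestrial isotopic compositions for the elements of
#' MOX-TBDMS-derivatized fragments. Each entry is the mass-shift
#' distribution of one atom relative to its lightest isotope.
#'
#' @return Named list of numeric vectors (index 1 = shift 0).
#' @export
isotope_abundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    P  = 1
  )
}

#' Fragment elemental formula
#'
#' Elemental composition of a derivatized GC-MS fragment together with the
#' number of tracer-derived (backbone) carbons `n`. Only the `n` backbone
#' carbons can carry tracer label; all other atoms contribute natural
#' isotope abundance.
#'
#' @param C,H,N,O,Si,S,P Atom counts of the fragment.
#' @param n Number of tracer-derived carbons (`n <= C`).
#' @return A `fragment_formula` object.
#' @examples
#' fragment_formula(C = 6, H = 12, N = 1, O = 3, Si = 1, n = 3)  # pyruvate MOX-TBDMS
#' @export
fragment_formula <- function(C = 0, H = 0, N = 0, O = 0, Si = 0, S = 0, P = 0, n) {
  counts <- c(C = C, H = H, N = N, O = O, Si = Si, S = S, P = P)
  if (any(counts < 0) || n < 0) abort("atom counts must be non-negative")
  if (n > C) abort("labeled carbon count n cannot exceed total carbon count")
  structure(list(counts = counts, n = as.integer(n)), class = "fragment_formula")
}

#' @export
print.fragment_formula <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat(sprintf("<fragment_formula> %s, %d tracer carbons\n",
              paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = ""), x$n))
  invisible(x)
}

#' Correction matrix for natural isotope abundance
#'
#' Builds the matrix mapping a corrected MID (length `n + 1`) to the
#' expected raw mass-spectral pattern over the measured mass window.
#' Column `j` is the natural-abundance mass distribution of the fragment
#' with `j` backbone carbons forced to 13C: the convolution of the
#' per-element natural distributions of all atoms except the `n` backbone
#' carbons, shifted by `j`, truncated to shifts `0..window`.
#'
#' @param formula A `fragment_formula`.
#' @param window Largest measured mass shift (default `n + 1`, capturing
#'   the Si/O isotope tail of TBDMS fragments).
#' @param abundances Isotope table, as from [isotope_abundances].
#' @return A `correction_matrix`: numeric matrix of dim
#'   `(window + 1) x (n + 1)` with the formula attached.
#' @export
build_correction_matrix <- function(formula, window = formula$n + 1L,
                                    abundances = isotope_abundances()) {
  n <- formula$n
  if (window < n) abort("mass window must cover at least shifts 0..n")
  counts <- formula$counts
  counts[["C"]] <- counts[["C"]] - n
  base <- 1
  for (el in names(counts)) {
    k <- counts[[el]]
    if (k == 0) next
    d <- abundances[[el]]
    if (is.null(d)) abort(sprintf("no abundance entry for element '%s'", el))
    for (i in seq_len(k)) base <- convolve_mid(base, d)
  }
  M <- matrix(0, nrow = window + 1L, ncol = n + 1L,
              dimnames = list(paste0("M+", 0:window), paste0("x", 0:n)))
  for (j in 0:n) {
    col <- c(rep(0, j), base, rep(0, window + 1L))
    M[, j + 1L] <- col[seq_len(window + 1L)]
  }
  structure(M, class = c("correction_matrix", "matrix"), formula = formula)
}

#' Correct a raw measurement for natural isotope abundance
#'
#' Recovers the tracer MID from a raw intensity pattern by non-negative
#' least squares against the correction matrix, renormalized to sum 1.
#' NNLS (rather than matrix inversion) tolerates truncated mass windows and
#' measurement noise while guaranteeing a valid MID.
#'
#' @param raw Numeric vector of raw intensities, shifts `0..window`.
#' @param M A `correction_matrix`.
#' @return Numeric MID vector (length `n + 1`) with attribute `residual`
#'   (relative norm of the unexplained raw signal).
#' @export
correct_mid <- function(raw, M) {
  if (length(raw) != nrow(M)) {
    abort(sprintf("raw vector has length %d but the correction matrix expects %d masses",
                  length(raw), nrow(M)))
  }
  if (any(raw < 0)) abort("raw intensities must be non-negative")
  tot <- sum(raw)
  if (tot <= 0) abort("all-zero raw measurement cannot be corrected")
  fit <- pracma::lsqnonneg(unclass(M), raw / tot)
  x <- fit$x
  if (sum(x) <= 0) abort("correction produced an all-zero MID")
  out <- x / sum(x)
  attr(out, "residual") <- sqrt(max(fit$resnorm, 0)) / sqrt(sum((raw / tot)^2))
  out
}

#' Correct a table of raw intensities
#'
#' Tibble-first wrapper over [correct_mid]: groups a long table of raw
#' intensities by fragment (and any extra keys such as tracer or replicate)
#' and corrects each group with its fragment's formula.
#'
#' @param data Data frame with columns `fragment`, `mass_shift`,
#'   `intensity`, plus optional grouping columns (e.g. `tracer_id`,
#'   `replicate`).
#' @param formulas Named list of `fragment_formula` objects keyed by
#'   fragment id.
#' @return Tibble with columns of `data` minus `intensity`, plus
#'   `fraction` (corrected MID) and `residual`.
#' @export
correct_mid_table <- function(data, formulas) {
  keys <- setdiff(names(data), c("mass_shift", "intensity"))
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(d, key) {
      fr <- key$fragment
      f <- formulas[[fr]]
      if (is.null(f)) abort(sprintf("no fragment formula for '%s'", fr))
      d <- dplyr::arrange(d, .data$mass_shift)
      M <- build_correction_matrix(f, window = max(d$mass_shift))
      mid <- correct_mid(d$intensity, M)
      tibble::tibble(mass_shift = 0:f$n, fraction = as.vector(mid),
                     residual = attr(mid, "residual"))
    }) %>%
    dplyr::ungroup()
}

#' MOX-TBDMS fragment formulas of the MEF study metabolites
#'
#' Reconstructed elemental compositions of the derivatized `[M-57]+`
#' fragments (loss of a tert-butyl group) of the twelve measured
#' metabolites, derived from the parent formula plus one TBDMS group per
#' exchangeable proton (and a methoxime group per ketone). The exact m/z
#' table of the original study is not published; these synthetic formulas
#' reproduce the standard derivatization chemistry and are used by the
#' simulated studies.
#'
#' @return Named list of `fragment_formula` objects.
#' @export
mef_fragment_formulas <- function() {
  list(
    pyr   = fragment_formula(C = 6,  H = 12, N = 1, O = 3, Si = 1, n = 3),
    lac   = fragment_formula(C = 11, H = 25, O = 3, Si = 2, n = 3),
    ala   = fragment_formula(C = 11, H = 26, N = 1, O = 2, Si = 2, n = 3),
    mal   = fragment_formula(C = 18, H = 39, O = 5, Si = 3, n = 4),
    asp   = fragment_formula(C = 18, H = 40, N = 1, O = 4, Si = 3, n = 4),
    akg   = fragment_formula(C = 14, H = 28, N = 1, O = 5, Si = 2, n = 5),
    gln   = fragment_formula(C = 19, H = 43, N = 2, O = 3, Si = 3, n = 5),
    cit   = fragment_formula(C = 26, H = 55, O = 7, Si = 4, n = 6),
    g3p   = fragment_formula(C = 17, H = 42, O = 6, Si = 3, P = 1, n = 3),
    pep   = fragment_formula(C = 17, H = 38, O = 6, Si = 3, P = 1, n = 3),
    `3pg` = fragment_formula(C = 23, H = 54, O = 7, Si = 4, P = 1, n = 3),
    r5p   = fragment_formula(C = 25, H = 57, O = 5, Si = 4, n = 5),
    # C1-carboxyl-loss ions (M-85 series): backbone carbons 2..n
    mal234  = fragment_formula(C = 11, H = 24, O = 3, Si = 2, n = 3),
    asp234  = fragment_formula(C = 11, H = 25, N = 1, O = 2, Si = 2, n = 3),
    akg2345 = fragment_formula(C = 13, H = 28, N = 1, O = 3, Si = 2, n = 4)
  )
}
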
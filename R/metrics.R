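#' Model-free tracer ratio statistics
#'
#' Ratios computed directly from corrected MIDs, without fitting the network
#' model. `ppp_split_ratio` is the relative pentose-phosphate-pathway versus
#' glycolysis indicator under `[1,2-13C2]`glucose: the M+1 fraction of a
#' triose fragment (DHAP) arises from carbon-1 loss in the oxidative PPP
#' while M+2 arises from intact glycolytic transfer, so the m1/m2 ratio
#' rises with the oxPPP share. `ldh_partition_ratio` is the M+3 lactate over
#' M+3 pyruvate ratio under `[U-13C]`glucose, reporting how much glycolytic
#' pyruvate is reduced to lactate. `fragment_enrichment` extracts a single
#' mass-shift fraction (e.g. M+2 citrate under `[U-13C]`glucose, an index of
#' mitochondrial pyruvate entry).
#'
#' Data-frame methods compute the metric per replicate; use
#' [metric_summary] for the mean and SEM across replicates.
#'
#' @param x A numeric MID vector (fractions at shifts `0..n`), or a data
#'   frame of MIDs with columns `fragment`, `mass_shift`, `fraction` and
#'   optional `replicate` / `tracer_id`.
#' @param ... Passed between methods.
#' @return Numeric scalar for MID vectors; a tibble with columns
#'   (`tracer_id`), (`replicate`), `metric`, `value` for data frames.
#' @name tracer_ratios
NULL

#' @rdname tracer_ratios
#' @param fragment Fragment id of the triose readout (default `"dhap"`).
#' @export
ppp_split_ratio <- function(x, ...) UseMethod("ppp_split_ratio")

#' @rdname tracer_ratios
#' @export
ppp_split_ratio.numeric <- function(x, ...) {
  check_mid(x, min_len = 3L)
  if (x[[3L]] <= 0) {
    warn("M+2 fraction is zero: PPP split ratio undefined")
    return(NA_real_)
  }
  x[[2L]] / x[[3L]]
}

#' @rdname tracer_ratios
#' @export
ppp_split_ratio.data.frame <- function(x, fragment = "dhap", ...) {
  per_replicate_metric(x, "ppp_split", function(d) {
    ppp_split_ratio(mid_vector(d, fragment))
  })
}

#' @rdname tracer_ratios
#' @param pyruvate For `ldh_partition_ratio.numeric`: the pyruvate MID
#'   vector; for the data-frame method, the pyruvate fragment id.
#' @param lactate Lactate fragment id (data-frame method).
#' @export
ldh_partition_ratio <- function(x, ...) UseMethod("ldh_partition_ratio")

#' @rdname tracer_ratios
#' @export
ldh_partition_ratio.numeric <- function(x, pyruvate, ...) {
  check_mid(x, min_len = 4L)
  check_mid(pyruvate, min_len = 4L)
  if (pyruvate[[4L]] <= 0) {
    warn("M+3 pyruvate fraction is zero: LDH partition ratio undefined")
    return(NA_real_)
  }
  x[[4L]] / pyruvate[[4L]]
}

#' @rdname tracer_ratios
#' @export
ldh_partition_ratio.data.frame <- function(x, lactate = "lac", pyruvate = "pyr", ...) {
  per_replicate_metric(x, "ldh_partition", function(d) {
    ldh_partition_ratio(mid_vector(d, lactate), mid_vector(d, pyruvate))
  })
}

#' @rdname tracer_ratios
#' @param shift Mass shift to extract.
#' @export
fragment_enrichment <- function(x, ...) UseMethod("fragment_enrichment")

#' @rdname tracer_ratios
#' @export
fragment_enrichment.numeric <- function(x, shift, ...) {
  check_mid(x, min_len = 1L)
  if (shift < 0 || shift > length(x) - 1L) {
    abort(sprintf("mass shift %d outside the fragment range 0..%d", shift, length(x) - 1L))
  }
  x[[shift + 1L]]
}

#' @rdname tracer_ratios
#' @export
fragment_enrichment.data.frame <- function(x, fragment, shift, ...) {
  per_replicate_metric(x, sprintf("%s_m%d", fragment, shift), function(d) {
    fragment_enrichment(mid_vector(d, fragment), shift)
  })
}

#' Summarize per-replicate metrics as mean and SEM
#'
#' @param data Output of a data-frame tracer-ratio method.
#' @return Tibble with `metric`, `mean`, `sem`, `n` (grouped by `tracer_id`
#'   if present).
#' @export
metric_summary <- function(data) {
  keys <- intersect(c("tracer_id", "metric"), names(data))
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

check_mid <- function(m, min_len) {
  if (!is.numeric(m) || length(m) < min_len) {
    abort(sprintf("MID must be a numeric vector of length >= %d", min_len))
  }
  if (any(m < -1e-9) || abs(sum(m) - 1) > 0.02) {
    abort("MID must be non-negative and sum to 1")
  }
  invisible(m)
}

mid_vector <- function(d, fragment) {
  d <- d[d$fragment == fragment, , drop = FALSE]
  if (nrow(d) == 0L) abort(sprintf("fragment '%s' not found in MID table", fragment))
  d$fraction[order(d$mass_shift)]
}

per_replicate_metric <- function(data, metric, f) {
  keys <- intersect(c("tracer_id", "replicate"), names(data))
  if (length(keys) == 0L) {
    return(tibble::tibble(metric = metric, value = f(data)))
  }
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(d, key) tibble::tibble(metric = metric, value = f(d))) %>%
    dplyr::ungroup()
}
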
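#' Growth-rate estimation from cell counts
#'
#' Fits the specific growth rate by log-linear regression of cell density on
#' time. For contact-inhibited (quiescent) cultures the fitted slope is
#' statistically indistinguishable from zero and the quiescent rate
#' estimator should be used downstream.
#'
#' @param data A data frame with columns `time_h` and `cells_e6`
#'   (10^6 cells/well). Replicate rows per timepoint are allowed.
#' @return A one-row tibble: `mu` (1/h), `mu_sd`, `x0` (intercept density),
#'   `n`.
#' @examples
#' tc <- tibble::tibble(time_h = c(0, 24, 48), cells_e6 = c(0.3, 0.6, 1.2))
#' fit_growth_rate(tc)   # mu = log(2)/24
#' @export
fit_growth_rate <- function(data) {
  if (nrow(data) < 2L) abort("growth fit needs at least two timepoints")
  if (any(data$cells_e6 <= 0)) abort("cell densities must be positive")
  fit <- lm(log(cells_e6) ~ time_h, data = data)
  # noise-free inputs fit exactly; the SE is then reported as NA anyway
  est <- suppressWarnings(summary(fit)$coefficients)
  mu_sd <- if (nrow(data) > 2L) est["time_h", "Std. Error"] else NA_real_
  tibble::tibble(mu = unname(coef(fit)[["time_h"]]), mu_sd = mu_sd,
                 x0 = exp(unname(coef(fit)[["(Intercept)"]])), n = nrow(data))
}

#' Uptake/secretion rate estimators
#'
#' Per-cell exchange rates from the change in medium amount over a culture
#' interval. For an exponentially growing culture the concentration change
#' is integrated against the growing biomass:
#' \deqn{q = \mu \, \Delta C / (X_0 (e^{\mu \Delta t} - 1))}
#' and for a quiescent (constant-density) culture it reduces to
#' \deqn{q = \Delta C / (X \Delta t).}
#' The proliferating estimator converges to the quiescent one as
#' `mu -> 0`. Sign convention: `delta_c` is the amount consumed
#' (`C(0) - C(t)`), so uptake is positive and secretion negative.
#'
#' @param delta_c Consumed amount (nmol/well) over the interval.
#' @param x0 Cell density at the start of the interval (10^6 cells/well).
#' @param mu Specific growth rate (1/h); must be > 0 for the proliferating
#'   estimator.
#' @param delta_t Interval length (h).
#' @return Rate in nmol/10^6 cells/h.
#' @export
rate_proliferating <- function(delta_c, x0, mu, delta_t) {
  if (delta_t <= 0) abort("delta_t must be positive")
  if (mu <= 0) {
    abort("mu must be positive for the proliferating estimator; use rate_quiescent for non-growing cultures")
  }
  mu * delta_c / (x0 * (exp(mu * delta_t) - 1))
}

#' @rdname rate_proliferating
#' @param x Constant cell density (10^6 cells/well).
#' @export
rate_quiescent <- function(delta_c, x, delta_t) {
  if (delta_t <= 0) abort("delta_t must be positive")
  if (x <= 0) abort("cell density must be positive")
  delta_c / (x * delta_t)
}

#' External rates from a spent-media time course
#'
#' Computes per-cell uptake/secretion rates for every measured species from
#' replicate spent-media concentrations and cell counts, using the
#' proliferating estimator when the fitted growth rate is positive (at the
#' `mu_threshold`) and the quiescent estimator otherwise. Rate SDs are
#' propagated first-order from the replicate scatter of the consumed amount.
#'
#' @param media A data frame with columns `time_h`, `species`, `conc`
#'   (nmol/well) and optionally `well` (replicate id).
#' @param cells A data frame with columns `time_h`, `cells_e6`.
#' @param mu_threshold Growth rates below this are treated as quiescent.
#' @return Tibble: `species`, `rate` (nmol/10^6 cells/h, + uptake /
#'   - secretion), `sd`, `estimator`.
#' @export
external_rates <- function(media, cells, mu_threshold = 1e-3) {
  growth <- fit_growth_rate(cells)
  mu <- growth$mu
  # growing only if the fitted rate is both material and statistically
  # distinguishable from zero
  proliferating <- is.finite(mu) && mu > mu_threshold &&
    (is.na(growth$mu_sd) || mu > 2 * growth$mu_sd)
  t0 <- min(media$time_h)
  t1 <- max(media$time_h)
  if (t1 <= t0) abort("media time course needs at least two timepoints")
  x0 <- mean(cells$cells_e6[cells$time_h == min(cells$time_h)])
  xbar <- mean(cells$cells_e6)
  media %>%
    dplyr::filter(.data$time_h %in% c(t0, t1)) %>%
    dplyr::group_by(.data$species) %>%
    dplyr::group_modify(function(d, key) {
      c0 <- d$conc[d$time_h == t0]
      c1 <- d$conc[d$time_h == t1]
      dc <- mean(c0) - mean(c1)
      # first-order propagation from replicate scatter at both endpoints
      dc_sd <- sqrt(var(c0) / length(c0) + var(c1) / length(c1))
      if (!is.finite(dc_sd)) dc_sd <- 0
      if (proliferating) {
        q <- rate_proliferating(dc, x0, mu, t1 - t0)
        q_sd <- abs(rate_proliferating(dc_sd, x0, mu, t1 - t0))
        tibble::tibble(rate = q, sd = q_sd, estimator = "proliferating")
      } else {
        q <- rate_quiescent(dc, xbar, t1 - t0)
        q_sd <- abs(rate_quiescent(dc_sd, xbar, t1 - t0))
        tibble::tibble(rate = q, sd = q_sd, estimator = "quiescent")
      }
    }) %>%
    dplyr::ungroup()
}
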
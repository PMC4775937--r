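#' @include AllClasses.R AllGenerics.R
NULL

#' Hill pharmacodynamic kill rate
#'
#' Evaluates the kill rate \eqn{\mu(a)} of the four-parameter Hill model in
#' its zMIC parameterisation,
#' \deqn{\mu(a) = \frac{(\psi_{max}-\psi_{min})\,(a/zMIC)^\kappa}{
#'   (a/zMIC)^\kappa - \psi_{min}/\psi_{max}},}
#' which is 0 at `a = 0`, equals `psiMax` at `a = zmic` (so the net growth
#' rate crosses zero exactly at the pharmacodynamic MIC), and saturates at
#' `Emax = psiMax - psiMin` as `a` grows. Strictly increasing in `a` for
#' `kappa > 0`.
#'
#' @param a numeric vector of doses, >= 0, in the units of `params@zmic`.
#' @param params a [PDParams-class].
#' @return numeric vector of kill rates in h^-1.
#' @examples
#' p <- PDParams(psiMax = 1, psiMin = -5, kappa = 2, zmic = 1)
#' killRate(c(0, 1, 2), p)   # 0, 1, 8/3
#' @export
killRate <- function(a, params) {
  stopifnot(is(params, "PDParams"), all(a >= 0))
  x <- (a / params@zmic)^params@kappa
  r <- params@psiMin / params@psiMax  # < 0, so denominator never vanishes
  mu <- (params@psiMax - params@psiMin) * x / (x - r)
  mu[is.infinite(x)] <- params@psiMax - params@psiMin
  mu
}

#' Net bacterial growth rate under treatment
#'
#' \eqn{\psi(a) = \psi_{max} - \mu(a)}: strictly decreasing from `psiMax`
#' at zero dose, through 0 at `a = zmic`, to `psiMin` at saturating dose.
#'
#' @inheritParams killRate
#' @return numeric vector of net growth rates in h^-1.
#' @examples
#' p <- PDParams(1, -5, 2, 1)
#' netGrowth(c(0, 1, 2), p)   # 1, 0, -5/3
#' @export
netGrowth <- function(a, params) {
  params@psiMax - killRate(a, params)
}

#' Isoeffective concentration (inverse of the Hill kill curve)
#'
#' Returns the unique dose at which the kill rate reaches a given fraction
#' of the curve's own maximal effect, \eqn{\mu(a) = f\,E_{max}}. Closed
#' form:
#' \deqn{a = zMIC\left(\frac{f\,|\psi_{min}|}{\psi_{max}(1-f)}\right)^{1/\kappa}.}
#' The round trip `killRate(isoeffectiveConc(f, p), p) / emax(p) == f`
#' holds to ~1e-10. At `f = psiMax/Emax` the result is exactly `zmic`
#' (the zero-growth effect level); at `f = 0.5` it equals [ec50()].
#'
#' @param fraction numeric vector of effect fractions, strictly in (0, 1).
#' @param params a [PDParams-class].
#' @return numeric vector of doses in the units of `params@zmic`.
#' @examples
#' p <- PDParams(1, -5, 2, 1)
#' isoeffectiveConc(0.5, p)   # sqrt(5)
#' @export
isoeffectiveConc <- function(fraction, params) {
  stopifnot(is(params, "PDParams"))
  if (any(fraction <= 0 | fraction >= 1))
    stop("'fraction' must lie strictly in (0, 1); the maximal effect is ",
         "reached only in the limit of infinite dose")
  x <- fraction * abs(params@psiMin) / (params@psiMax * (1 - fraction))
  params@zmic * x^(1 / params@kappa)
}

# Dose of a drug achieving an absolute kill rate E in (0, Emax); used by the
# Loewe additive-null construction where curves with different Emax must be
# compared on a common effect scale.
doseForKillRate <- function(E, params) {
  Emax <- params@psiMax - params@psiMin
  stopifnot(all(E > 0), all(E < Emax))
  x <- E * abs(params@psiMin) / params@psiMax / (Emax - E)
  params@zmic * x^(1 / params@kappa)
}

#' Fit the Hill pharmacodynamic model by weighted least squares
#'
#' Deterministic point fit of (psi_max, psi_min, kappa, zMIC) to a table of
#' net growth rates versus concentration, by multi-start quasi-Newton
#' minimisation of the weighted sum of squares. Weights are `1/se^2` where
#' a positive standard error is available and 1 otherwise. Starts are laid
#' on a deterministic grid of kappa values crossed with candidate zMIC
#' values around the observed growth-to-kill sign change; ties in the final
#' loss are broken toward the smallest kappa. Serves both as a standalone
#' estimator and as the initialiser for [fitPDMCMC()].
#'
#' @param rates data.frame with numeric columns `concentration` and `rate`
#'   (h^-1), optionally `se` (h^-1) and logical `bound` (left-censored rate
#'   bounds, excluded unless `includeBounds = TRUE`). Typically one row per
#'   concentration from [estimateRates()].
#' @param includeBounds logical; include left-censored rate bounds at their
#'   bound value (default FALSE).
#' @param control list passed to [stats::nlminb()] (`iter.max` etc.).
#' @return A [PDParams-class] with attributes `loss` (weighted SSE),
#'   `nStarts`, and `fitted` (data.frame of dose, observed and fitted rate).
#' @examples
#' p <- PDParams(1, -5, 2, 1)
#' a <- 2^seq(-4, 5)
#' fitPDLS(data.frame(concentration = a, rate = netGrowth(a, p)))
#' @export
fitPDLS <- function(rates, includeBounds = FALSE, control = list()) {
  rates <- as.data.frame(rates)
  stopifnot(all(c("concentration", "rate") %in% names(rates)))
  if (!is.null(rates$bound) && !includeBounds)
    rates <- rates[!rates$bound, , drop = FALSE]
  rates <- rates[is.finite(rates$rate) & is.finite(rates$concentration), ,
                 drop = FALSE]
  if (nrow(rates) < 4L)
    stop("need >= 4 usable rate estimates to fit 4 parameters")
  if (!any(rates$rate > 0) || !any(rates$rate < 0))
    stop("rates show no growth-to-kill sign change: zMIC is not ",
         "identifiable from these data (all rates have one sign)")
  a <- rates$concentration
  y <- rates$rate
  se <- rates$se %||% rep(0, length(y))
  se[!is.finite(se)] <- 0
  w <- ifelse(se > 0, 1 / se^2, 1)

  obj <- function(th) {
    p <- th2params(th)
    if (is.null(p)) return(1e300)
    r <- y - netGrowth(a, p)
    sum(w * r * r)
  }

  # zMIC candidates: geometric midpoints around the observed sign change,
  # plus quartiles of the positive dose range
  pos <- sort(unique(a[a > 0]))
  ord <- order(a)
  sgn <- sign(y[ord])
  cross <- which(diff(sgn) < 0)
  zCand <- if (length(cross)) {
    sqrt(pmax(a[ord][cross], min(pos)) * a[ord][cross + 1L])
  } else exp(stats::median(log(pos)))
  zCand <- unique(c(zCand, exp(stats::quantile(log(pos), c(0.25, 0.5, 0.75)))))
  kCand <- c(0.5, 1, 2, 4, 8)
  psiMax0 <- max(max(y), 1e-3)
  psiMin0 <- min(min(y), -1e-3)

  best <- NULL
  ctrl <- modifyList(list(iter.max = 500L, eval.max = 1000L,
                          rel.tol = 1e-12, x.tol = 1e-12), control)
  for (z0 in zCand) for (k0 in kCand) {
    th0 <- c(psiMax0, psiMin0, log(k0), log(z0))
    fit <- tryCatch(
      stats::nlminb(th0, obj, control = ctrl,
                    lower = c(1e-8, -Inf, -12, -Inf),
                    upper = c(Inf, -1e-8, 12, Inf)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    cand <- list(loss = fit$objective, th = fit$par)
    if (is.null(best) ||
        cand$loss < best$loss * (1 - 1e-10) ||
        (abs(cand$loss - best$loss) <= 1e-10 * max(best$loss, 1) &&
         exp(cand$th[3]) < exp(best$th[3]))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("least-squares optimisation failed on all starts")
  p <- th2params(best$th)
  attr(p, "loss") <- best$loss
  attr(p, "nStarts") <- length(zCand) * length(kCand)
  attr(p, "fitted") <- data.frame(concentration = a, rate = y,
                                  fitted = netGrowth(a, p))
  p
}

# sampling/optimisation parameterisation: (psiMax, psiMin, ln kappa, ln zMIC)
th2params <- function(th) {
  if (any(!is.finite(th)) || th[1] <= 0 || th[2] >= 0) return(NULL)
  PDParams(th[1], th[2], exp(th[3]), exp(th[4]))
}
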
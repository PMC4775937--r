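#' @include pdmodel.R
NULL

#' Sampler settings for the Bayesian Hill-model fit
#'
#' @param chains number of independent chains (default 4).
#' @param warmup adaptation iterations discarded per chain (default 2000).
#' @param iter retained iterations per chain after warmup (default 2000).
#' @param thin keep every `thin`-th retained draw (default 1).
#' @param sigmaMode observation-noise model: `"global"` samples a single
#'   observation SD shared by all rate points (lognormal prior, default);
#'   `"se"` plugs in each rate's regression standard error (points with
#'   `se = 0` get a small floor).
#' @param priors list overriding the weakly-informative defaults:
#'   `psiMaxMean/psiMaxSD` (normal, truncated > 0), `psiMinMean/psiMinSD`
#'   (normal, truncated < 0), `logKappaMean/logKappaSD` (normal on ln
#'   kappa), `logZmicSD` (normal on ln zMIC, centred on the log-midpoint of
#'   the positive dose grid), `logSigmaMean/logSigmaSD` (normal on ln sigma,
#'   global mode only).
#' @param rhatThreshold split-Rhat convergence threshold (default 1.05).
#' @return list of sampler settings for [fitPDMCMC()].
#' @export
pdMCMCControl <- function(chains = 4L, warmup = 2000L, iter = 2000L,
                          thin = 1L, sigmaMode = c("global", "se"),
                          priors = list(), rhatThreshold = 1.05) {
  sigmaMode <- match.arg(sigmaMode)
  if (chains < 1L || warmup < 0L || iter < 1L || thin < 1L)
    stop("invalid sampler configuration")
  pri <- modifyList(list(
    psiMaxMean = 1, psiMaxSD = 1,
    psiMinMean = -5, psiMinSD = 5,
    logKappaMean = 0, logKappaSD = 1,
    logZmicSD = 2,
    logSigmaMean = log(0.25), logSigmaSD = 1.5), priors)
  list(chains = as.integer(chains), warmup = as.integer(warmup),
       iter = as.integer(iter), thin = as.integer(thin),
       sigmaMode = sigmaMode, priors = pri,
       rhatThreshold = rhatThreshold)
}

#' Bayesian fit of the Hill pharmacodynamic model by MCMC
#'
#' Samples the posterior of (psi_max, psi_min, kappa, zMIC) under a Gaussian
#' likelihood for the estimated net growth rates, with weakly-informative
#' priors, using an adaptive random-walk Metropolis sampler on the
#' unconstrained parameterisation (psi_max, psi_min, ln kappa, ln zMIC).
#' Chains are initialised by jittering the [fitPDLS()] point fit; during
#' warmup the proposal scale adapts toward a 30% acceptance rate
#' (Robbins-Monro) and proposal directions follow the running covariance
#' of the warmup draws. Split-Rhat and effective sample size are computed
#' per parameter; the fit is flagged unconverged (with a warning) when any
#' split-Rhat exceeds the configured threshold.
#'
#' @inheritParams fitPDLS
#' @param config sampler settings from [pdMCMCControl()].
#' @param seed integer seed; draws are bit-reproducible given
#'   (rates, config, seed).
#' @return A [PDPosterior-class].
#' @examples
#' p <- PDParams(1, -5, 2, 1)
#' a <- 2^seq(-4, 5)
#' rates <- data.frame(concentration = a,
#'                     rate = netGrowth(a, p) + 0.05 * sin(seq_along(a)),
#'                     se = 0.1)
#' fit <- fitPDMCMC(rates, pdMCMCControl(chains = 2, warmup = 200, iter = 200),
#'                  seed = 1)
#' pointEstimate(fit)
#' @export
fitPDMCMC <- function(rates, config = pdMCMCControl(), seed = 1L,
                      includeBounds = FALSE) {
  rates <- as.data.frame(rates)
  stopifnot(all(c("concentration", "rate") %in% names(rates)))
  if (!is.null(rates$bound) && !includeBounds)
    rates <- rates[!rates$bound, , drop = FALSE]
  rates <- rates[is.finite(rates$rate), , drop = FALSE]
  if (nrow(rates) < 4L)
    stop("need >= 4 usable rate estimates")
  a <- rates$concentration
  y <- rates$rate
  pri <- config$priors
  pos <- a[a > 0]
  logZmicMean <- stats::median(log(pos))

  useSE <- config$sigmaMode == "se"
  seVec <- NULL
  if (useSE) {
    seVec <- rates$se %||% rep(NA_real_, length(y))
    seVec[!is.finite(seVec) | seVec <= 0] <- 0.05  # floor for exact points
  }
  nPar <- if (useSE) 4L else 5L
  pnames <- c("psi_max", "psi_min", "kappa", "zmic",
              if (!useSE) "sigma")

  logPost <- function(th) {
    psiMax <- th[1]; psiMin <- th[2]
    if (psiMax <= 0 || psiMin >= 0) return(-Inf)
    k <- exp(th[3]); z <- exp(th[4])
    lp <- stats::dnorm(psiMax, pri$psiMaxMean, pri$psiMaxSD, log = TRUE) +
      stats::dnorm(psiMin, pri$psiMinMean, pri$psiMinSD, log = TRUE) +
      stats::dnorm(th[3], pri$logKappaMean, pri$logKappaSD, log = TRUE) +
      stats::dnorm(th[4], logZmicMean, pri$logZmicSD, log = TRUE)
    x <- (a / z)^k
    mu <- psiMax - (psiMax - psiMin) * x / (x - psiMin / psiMax)
    mu[is.infinite(x)] <- psiMin
    sd <- if (useSE) seVec else exp(th[5])
    if (!useSE)
      lp <- lp + stats::dnorm(th[5], pri$logSigmaMean, pri$logSigmaSD,
                              log = TRUE)
    ll <- sum(stats::dnorm(y, mu, sd, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }

  ls <- tryCatch(fitPDLS(rates, includeBounds = includeBounds),
                 error = function(e) NULL)
  th0 <- if (!is.null(ls)) {
    c(ls@psiMax, ls@psiMin, log(ls@kappa), log(ls@zmic))
  } else {
    c(max(max(y), 0.5), min(min(y), -0.5), 0, logZmicMean)
  }
  if (!useSE) {
    res <- if (!is.null(ls))
      sqrt(max(attr(ls, "loss") / max(length(y) - 4, 1), 1e-4)) else 0.25
    th0 <- c(th0, log(res))
  }

  nKeep <- config$iter %/% config$thin
  draws <- matrix(NA_real_, nrow = config$chains * nKeep, ncol = nPar,
                  dimnames = list(NULL, pnames))
  chainIdx <- rep(seq_len(config$chains), each = nKeep)
  accRates <- numeric(config$chains)

  baseScale <- pmax(abs(th0), 0.5) * 0.1
  for (ch in seq_len(config$chains)) {
    set.seed(as.integer((seed + 104729 * ch) %% 2147483647))
    th <- th0 + stats::rnorm(nPar, 0, 0.05 * pmax(abs(th0), 0.2))
    lpCur <- logPost(th)
    tries <- 0L
    while (!is.finite(lpCur) && tries < 50L) {
      th <- th0 + stats::rnorm(nPar, 0, 0.05)
      lpCur <- logPost(th)
      tries <- tries + 1L
    }
    if (!is.finite(lpCur)) stop("could not initialise chain ", ch)

    scale <- 1
    L <- diag(baseScale)
    warmDraws <- matrix(NA_real_, nrow = config$warmup, ncol = nPar)
    nAcc <- 0L
    total <- config$warmup + config$iter
    kept <- 0L
    for (it in seq_len(total)) {
      prop <- th + scale * as.vector(L %*% stats::rnorm(nPar))
      lpProp <- logPost(prop)
      accept <- is.finite(lpProp) &&
        (lpProp - lpCur >= 0 || stats::runif(1) < exp(lpProp - lpCur))
      if (accept) {
        th <- prop
        lpCur <- lpProp
        if (it > config$warmup) nAcc <- nAcc + 1L
      }
      if (it <= config$warmup) {
        # Robbins-Monro scale adaptation toward 30% acceptance
        gain <- min(1, 5 / it^0.6)
        scale <- scale * exp(gain * ((if (accept) 1 else 0) - 0.3) * 0.5)
        warmDraws[it, ] <- th
        # re-estimate proposal shape from the recent half of warmup draws,
        # leaving the tail of warmup for the scale to re-equilibrate
        if (it >= 100L && it %% 100L == 0L && it <= config$warmup - 200L) {
          recent <- warmDraws[max(1L, it %/% 2L):it, , drop = FALSE]
          S <- stats::cov(recent) + diag(1e-9, nPar)
          Lt <- tryCatch(t(chol(S)), error = function(e) NULL)
          if (!is.null(Lt)) {
            L <- Lt * (2.38 / sqrt(nPar))
            scale <- 1
          }
        }
      } else if ((it - config$warmup) %% config$thin == 0L) {
        kept <- kept + 1L
        row <- (ch - 1L) * nKeep + kept
        draws[row, 1:2] <- th[1:2]
        draws[row, 3] <- exp(th[3])
        draws[row, 4] <- exp(th[4])
        if (!useSE) draws[row, 5] <- exp(th[5])
      }
    }
    accRates[ch] <- nAcc / config$iter
  }

  diag_df <- data.frame(parameter = pnames, rhat = NA_real_, ess = NA_real_)
  for (j in seq_len(nPar)) {
    chs <- lapply(seq_len(config$chains), function(ch)
      draws[chainIdx == ch, j])
    diag_df$rhat[j] <- rhatSplit(chs)
    diag_df$ess[j] <- essBasic(chs)
  }
  converged <- all(diag_df$rhat <= config$rhatThreshold, na.rm = TRUE)
  if (!converged)
    warning("MCMC not converged: max split-Rhat = ",
            signif(max(diag_df$rhat), 4),
            " > ", config$rhatThreshold,
            "; posterior returned but flagged", call. = FALSE)

  med <- apply(draws[, 1:4, drop = FALSE], 2L, stats::median)
  new("PDPosterior", draws = draws, diagnostics = diag_df,
      pointEstimate = PDParams(med[1], med[2], med[3], med[4]),
      converged = converged, seed = as.integer(seed),
      config = c(config, list(acceptance = accRates)))
}

#' Wrap point parameters as a degenerate posterior
#'
#' Utility for propagating a fixed [PDParams-class] through machinery that
#' expects posterior draws (all draws identical, zero-width intervals).
#'
#' @param params a [PDParams-class].
#' @param n number of identical draws (default 1000).
#' @return A [PDPosterior-class].
#' @export
asPosterior <- function(params, n = 1000L) {
  stopifnot(is(params, "PDParams"))
  draws <- matrix(rep(c(params@psiMax, params@psiMin, params@kappa,
                        params@zmic), each = n), nrow = n,
                  dimnames = list(NULL, c("psi_max", "psi_min", "kappa",
                                          "zmic")))
  new("PDPosterior", draws = draws,
      diagnostics = data.frame(parameter = colnames(draws), rhat = 1,
                               ess = as.numeric(n)),
      pointEstimate = params, converged = TRUE, seed = 0L,
      config = list(degenerate = TRUE, chains = 1L))
}
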
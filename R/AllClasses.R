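#' @import methods
NULL

#' Four-parameter Hill pharmacodynamic model parameters
#'
#' `PDParams` holds the pharmacodynamic parameters of the Hill model of net
#' bacterial growth under an antimicrobial: the maximal net growth rate
#' `psiMax` (h^-1, drug-free), the minimal net growth rate `psiMin` (h^-1,
#' saturating drug), the Hill coefficient `kappa` (dimensionless steepness),
#' and the zero-growth concentration `zmic` (the pharmacodynamic MIC, in the
#' concentration units of the treatment's dose axis).
#'
#' The kill rate at dose `a` is
#' \deqn{\mu(a) = \frac{(\psi_{max}-\psi_{min})(a/zMIC)^\kappa}{
#'   (a/zMIC)^\kappa - \psi_{min}/\psi_{max}}}
#' and the net growth rate is \eqn{\psi(a) = \psi_{max} - \mu(a)}, so that
#' \eqn{\psi(0)=\psi_{max}}, \eqn{\psi(zMIC)=0} and
#' \eqn{\psi(a)\to\psi_{min}} as \eqn{a\to\infty}.
#'
#' @slot psiMax numeric(1), maximal net growth rate in h^-1; must be > 0.
#' @slot psiMin numeric(1), minimal net growth rate in h^-1; must be < 0
#'   (a bactericidal plateau is required for a zero-growth dose to exist).
#' @slot kappa numeric(1), Hill coefficient; must be > 0.
#' @slot zmic numeric(1), zero-growth concentration; must be > 0.
#'
#' @seealso [PDParams()], [killRate()], [netGrowth()],
#'   [isoeffectiveConc()], [ec50()]
#' @name PDParams-class
#' @aliases PDParams-class
#' @exportClass PDParams
setClass("PDParams",
  representation(
    psiMax = "numeric",
    psiMin = "numeric",
    kappa  = "numeric",
    zmic   = "numeric"
  )
)

setValidity("PDParams", function(object) {
  msg <- character()
  for (s in c("psiMax", "psiMin", "kappa", "zmic")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (!length(msg)) {
    if (object@psiMax <= 0) msg <- c(msg, "'psiMax' must be > 0")
    if (object@psiMin >= 0) msg <- c(msg, "'psiMin' must be < 0")
    if (object@kappa <= 0)  msg <- c(msg, "'kappa' must be > 0")
    if (object@zmic <= 0)   msg <- c(msg, "'zmic' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct PDParams
#'
#' @param psiMax maximal net growth rate (h^-1), > 0.
#' @param psiMin minimal net growth rate (h^-1), < 0.
#' @param kappa Hill coefficient, > 0.
#' @param zmic zero-growth concentration, > 0, in the dose-axis units of the
#'   treatment (MIC-multiples for single drugs, stock fraction for mixtures).
#' @return A validated [PDParams-class] object.
#' @examples
#' p <- PDParams(psiMax = 1, psiMin = -5, kappa = 2, zmic = 1)
#' netGrowth(c(0, 1, 2), p)
#' @export
PDParams <- function(psiMax, psiMin, kappa, zmic) {
  new("PDParams", psiMax = as.numeric(psiMax), psiMin = as.numeric(psiMin),
      kappa = as.numeric(kappa), zmic = as.numeric(zmic))
}

#' Posterior sample of Hill pharmacodynamic parameters
#'
#' Holds retained MCMC draws of (psi_max, psi_min, kappa, zMIC), per-parameter
#' convergence diagnostics (split-Rhat, effective sample size), and the
#' posterior-median point estimate. A fit is flagged unconverged when any
#' split-Rhat exceeds 1.05.
#'
#' @slot draws numeric matrix, one row per retained draw, columns
#'   `psi_max`, `psi_min`, `kappa`, `zmic` (and `sigma` when a global
#'   observation SD was sampled).
#' @slot diagnostics data.frame with columns `parameter`, `rhat`, `ess`.
#' @slot pointEstimate [PDParams-class] posterior medians.
#' @slot converged logical(1), all split-Rhat <= 1.05.
#' @slot seed integer(1), RNG seed used by the sampler.
#' @slot config list, sampler settings used.
#' @name PDPosterior-class
#' @aliases PDPosterior-class
#' @exportClass PDPosterior
setClass("PDPosterior",
  representation(
    draws = "matrix",
    diagnostics = "data.frame",
    pointEstimate = "PDParams",
    converged = "logical",
    seed = "integer",
    config = "list"
  )
)

setValidity("PDPosterior", function(object) {
  d <- object@draws
  need <- c("psi_max", "psi_min", "kappa", "zmic")
  if (!all(need %in% colnames(d)))
    return("draws must have columns psi_max, psi_min, kappa, zmic")
  if (nrow(d) > 0) {
    bad <- d[, "psi_max"] <= 0 | d[, "psi_min"] >= 0 |
      d[, "kappa"] <= 0 | d[, "zmic"] <= 0 | !is.finite(rowSums(d))
    if (any(bad))
      return("every draw must satisfy the PDParams sign constraints")
  }
  if (!all(need %in% object@diagnostics$parameter))
    return("diagnostics must cover every model parameter")
  TRUE
})

#' Fixed-ratio mixture design
#'
#' Describes how an n-component AMP mixture is built from single-drug stocks:
#' each component is stocked at `stockMultiplier` times its own MIC
#' (100x MIC in the study design) and the stocks are combined at the given
#' volume ratio (1:1 or 1:1:1 in the study; unequal ratios are supported).
#' At stock fraction `g` of the combined stock, component `i` is present at
#' `g * stockMultiplier * ratio[i]` multiples of its own MIC — so at
#' `g = 1/stockMultiplier` every component sits at `ratio[i]` of its MIC,
#' making Loewe additivity predict a mixture MIC exactly equal to each
#' single-drug MIC on its own axis.
#'
#' @slot components character, ordered component names (>= 2).
#' @slot mic numeric, per-component MIC in ug/ml (named as `components`).
#' @slot ratio numeric, per-component volume fractions, > 0, summing to 1.
#' @slot stockMultiplier numeric(1), stock strength in MIC-multiples
#'   (default 100).
#' @name MixtureDesign-class
#' @aliases MixtureDesign-class
#' @exportClass MixtureDesign
setClass("MixtureDesign",
  representation(
    components = "character",
    mic = "numeric",
    ratio = "numeric",
    stockMultiplier = "numeric"
  )
)

setValidity("MixtureDesign", function(object) {
  msg <- character()
  k <- length(object@components)
  if (k < 2L) msg <- c(msg, "a mixture needs >= 2 components")
  if (anyDuplicated(object@components))
    msg <- c(msg, "component names must be unique")
  if (length(object@mic) != k || any(!is.finite(object@mic)) ||
      any(object@mic <= 0))
    msg <- c(msg, "'mic' must be positive, one value per component")
  if (length(object@ratio) != k || any(object@ratio <= 0))
    msg <- c(msg, "'ratio' entries must be > 0, one per component")
  else if (abs(sum(object@ratio) - 1) > 1e-9)
    msg <- c(msg, "'ratio' must sum to 1 (tolerance 1e-9)")
  if (length(object@stockMultiplier) != 1L || object@stockMultiplier <= 0)
    msg <- c(msg, "'stockMultiplier' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureDesign
#'
#' @param components character vector of component drug names (>= 2).
#' @param mic per-component MICs in ug/ml (recycled if length 1).
#' @param ratio per-component volume fractions; default equal.
#' @param stockMultiplier stock strength in MIC-multiples; default 100.
#' @return A validated [MixtureDesign-class].
#' @examples
#' MixtureDesign(c("pexiganan", "melittin"), mic = c(16, 2))
#' @export
MixtureDesign <- function(components, mic, ratio = NULL,
                          stockMultiplier = 100) {
  k <- length(components)
  if (is.null(ratio)) ratio <- rep(1 / k, k)
  mic <- rep_len(as.numeric(mic), k)
  names(mic) <- components
  new("MixtureDesign", components = as.character(components), mic = mic,
      ratio = as.numeric(ratio) / sum(ratio),
      stockMultiplier = as.numeric(stockMultiplier))
}

#' Simulation scenario for synthetic time-kill experiments
#'
#' Bundles the ground truth and experimental design for the synthetic-data
#' generator: true [PDParams-class] per drug, fixed-ratio mixtures with a
#' dimensionless interaction factor `gamma` (gamma = 1 is exactly
#' Loewe-additive; gamma > 1 divides every isoeffective mixture dose by
#' gamma, i.e. synergy with true combination index 1/gamma), plus the
#' kill-curve design: inoculum, sampling times, 2-fold dilution series from
#' `stockMultiplier` x MIC, plating detection limit, noise model and
#' replicate count.
#'
#' @slot drugs named list of [PDParams-class], true single-drug parameters
#'   on each drug's own MIC-multiple dose axis.
#' @slot mic named numeric, MIC of each drug in ug/ml.
#' @slot mixtures named list of [MixtureDesign-class].
#' @slot gamma named numeric, interaction factor per mixture (> 0).
#' @slot inoculum numeric(1), CFU at t = 0 (default 2e6 per 100 ul).
#' @slot times numeric, sampling times in minutes, strictly increasing
#'   from 0 (default 0, 20, 40, 60).
#' @slot dilutionLevels integer(1), number of 2-fold steps down from the
#'   top concentration (100x MIC for singles, g = 1 for mixtures).
#' @slot detectionLimit numeric(1), plating detection limit in CFU
#'   (default 100).
#' @slot noise list with elements `poisson` (logical; Poisson plating
#'   noise), `sigma` (log-normal overdispersion SD on the ln scale, 0
#'   disables it).
#' @slot replicates integer(1), replicates per concentration.
#' @slot seed integer(1), top-level RNG seed; per-(treatment, replicate)
#'   sub-streams are derived from it so adding treatments never perturbs
#'   existing ones.
#' @name SimulationScenario-class
#' @aliases SimulationScenario-class
#' @exportClass SimulationScenario
setClass("SimulationScenario",
  representation(
    drugs = "list",
    mic = "numeric",
    mixtures = "list",
    gamma = "numeric",
    inoculum = "numeric",
    times = "numeric",
    dilutionLevels = "integer",
    detectionLimit = "numeric",
    noise = "list",
    replicates = "integer",
    seed = "integer"
  )
)

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (!length(object@drugs) || is.null(names(object@drugs)))
    msg <- c(msg, "'drugs' must be a named list of PDParams")
  for (d in object@drugs)
    if (!is(d, "PDParams")) msg <- c(msg, "every drug needs PDParams truth")
  if (length(object@mic) != length(object@drugs) ||
      any(object@mic <= 0))
    msg <- c(msg, "'mic' must be positive, one per drug")
  if (length(object@mixtures)) {
    if (length(object@gamma) != length(object@mixtures) ||
        any(object@gamma <= 0))
      msg <- c(msg, "'gamma' must be > 0, one per mixture")
    for (m in object@mixtures) {
      if (!is(m, "MixtureDesign"))
        msg <- c(msg, "'mixtures' must contain MixtureDesign objects")
      else if (!all(m@components %in% names(object@drugs)))
        msg <- c(msg, "mixture components must be scenario drugs")
    }
  }
  if (object@inoculum < object@detectionLimit)
    msg <- c(msg, "'inoculum' must be >= 'detectionLimit'")
  if (length(object@times) < 2L || object@times[1] != 0 ||
      any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing and start at 0")
  if (object@dilutionLevels < 1L)
    msg <- c(msg, "'dilutionLevels' must be >= 1")
  if (object@replicates < 1L) msg <- c(msg, "'replicates' must be >= 1")
  if (!is.logical(object@noise$poisson) ||
      !is.numeric(object@noise$sigma) || object@noise$sigma < 0)
    msg <- c(msg, "'noise' needs logical $poisson and numeric $sigma >= 0")
  if (length(msg)) msg else TRUE
})

#' Combination-index profile across the effect range
#'
#' Combination index (CI) of a fixed-ratio mixture evaluated on a grid of
#' effect fractions in [0.05, 0.95], with a 95% interval per fraction from
#' posterior propagation and an interaction call per fraction:
#' `synergistic` when the interval lies below 1, `antagonistic` when above,
#' and `additive` exactly when the interval contains 1. The summary call is
#' the call at the 50% effect level (E50).
#'
#' @slot treatment character(1), mixture treatment id.
#' @slot fractions numeric, strictly increasing effect fractions in
#'   [0.05, 0.95].
#' @slot ci numeric, posterior-median CI per fraction.
#' @slot ciLo,ciHi numeric, 2.5% and 97.5% posterior percentiles.
#' @slot calls character, per-fraction interaction call.
#' @slot summaryCall character(1), call at the E50 fraction.
#' @slot ciE50 numeric(1), median CI at the E50 fraction.
#' @name CIProfile-class
#' @aliases CIProfile-class
#' @exportClass CIProfile
setClass("CIProfile",
  representation(
    treatment = "character",
    fractions = "numeric",
    ci = "numeric",
    ciLo = "numeric",
    ciHi = "numeric",
    calls = "character",
    summaryCall = "character",
    ciE50 = "numeric"
  )
)

setValidity("CIProfile", function(object) {
  msg <- character()
  f <- object@fractions
  n <- length(f)
  if (any(f < 0.05 - 1e-12) || any(f > 0.95 + 1e-12) || any(diff(f) <= 0))
    msg <- c(msg, "'fractions' must be strictly increasing in [0.05, 0.95]")
  if (length(object@ci) != n || length(object@ciLo) != n ||
      length(object@ciHi) != n || length(object@calls) != n)
    msg <- c(msg, "ci, ciLo, ciHi, calls must match fractions in length")
  ok <- is.finite(object@ci)
  if (any(object@ci[ok] <= 0))
    msg <- c(msg, "CI must be > 0 wherever defined")
  if (!length(msg)) {
    ok <- ok & is.finite(object@ciLo) & is.finite(object@ciHi)
    contains1 <- object@ciLo[ok] <= 1 & object@ciHi[ok] >= 1
    if (any((object@calls[ok] == "additive") != contains1))
      msg <- c(msg, "call must be 'additive' exactly when [ciLo, ciHi] contains 1")
  }
  if (length(msg)) msg else TRUE
})
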
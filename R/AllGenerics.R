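#' @include AllClasses.R
NULL

#' Accessors for pharmacodynamic parameter objects
#'
#' `psiMax()`, `psiMin()`, `hillKappa()` and `zmic()` return the four Hill
#' parameters; `emax()` returns the maximal kill effect
#' `Emax = psiMax - psiMin`; `ec50()` returns the half-maximal-effect
#' concentration implied by the zMIC parameterisation,
#' `EC50 = zMIC * (|psiMin|/psiMax)^(1/kappa)`. All are defined for both
#' [PDParams-class] (scalar) and [PDPosterior-class] (the posterior-median
#' point estimate).
#'
#' @param object a [PDParams-class] or [PDPosterior-class].
#' @return numeric(1).
#' @examples
#' p <- PDParams(1, -5, 2, 1)
#' emax(p)   # 6
#' ec50(p)   # sqrt(5)
#' @name pd-accessors
NULL

#' @rdname pd-accessors
#' @export
setGeneric("psiMax", function(object) standardGeneric("psiMax"))
#' @rdname pd-accessors
#' @export
setGeneric("psiMin", function(object) standardGeneric("psiMin"))
#' @rdname pd-accessors
#' @export
setGeneric("hillKappa", function(object) standardGeneric("hillKappa"))
#' @rdname pd-accessors
#' @export
setGeneric("zmic", function(object) standardGeneric("zmic"))
#' @rdname pd-accessors
#' @export
setGeneric("emax", function(object) standardGeneric("emax"))
#' @rdname pd-accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @rdname pd-accessors
#' @export
setMethod("psiMax", "PDParams", function(object) object@psiMax)
#' @rdname pd-accessors
#' @export
setMethod("psiMin", "PDParams", function(object) object@psiMin)
#' @rdname pd-accessors
#' @export
setMethod("hillKappa", "PDParams", function(object) object@kappa)
#' @rdname pd-accessors
#' @export
setMethod("zmic", "PDParams", function(object) object@zmic)
#' @rdname pd-accessors
#' @export
setMethod("emax", "PDParams", function(object) object@psiMax - object@psiMin)
#' @rdname pd-accessors
#' @export
setMethod("ec50", "PDParams", function(object)
  object@zmic * (abs(object@psiMin) / object@psiMax)^(1 / object@kappa))

#' @rdname pd-accessors
#' @export
setMethod("psiMax", "PDPosterior", function(object) psiMax(object@pointEstimate))
#' @rdname pd-accessors
#' @export
setMethod("psiMin", "PDPosterior", function(object) psiMin(object@pointEstimate))
#' @rdname pd-accessors
#' @export
setMethod("hillKappa", "PDPosterior", function(object) hillKappa(object@pointEstimate))
#' @rdname pd-accessors
#' @export
setMethod("zmic", "PDPosterior", function(object) zmic(object@pointEstimate))
#' @rdname pd-accessors
#' @export
setMethod("emax", "PDPosterior", function(object) emax(object@pointEstimate))
#' @rdname pd-accessors
#' @export
setMethod("ec50", "PDPosterior", function(object) ec50(object@pointEstimate))

#' Posterior draws and diagnostics
#'
#' @param object a [PDPosterior-class].
#' @return `pdDraws()` the draw matrix; `pdDiagnostics()` a data.frame of
#'   split-Rhat and effective sample size per parameter; `isConverged()`
#'   whether all split-Rhat <= 1.05; `pointEstimate()` the posterior-median
#'   [PDParams-class].
#' @name posterior-accessors
NULL

#' @rdname posterior-accessors
#' @export
setGeneric("pdDraws", function(object) standardGeneric("pdDraws"))
#' @rdname posterior-accessors
#' @export
setMethod("pdDraws", "PDPosterior", function(object) object@draws)

#' @rdname posterior-accessors
#' @export
setGeneric("pdDiagnostics", function(object) standardGeneric("pdDiagnostics"))
#' @rdname posterior-accessors
#' @export
setMethod("pdDiagnostics", "PDPosterior", function(object) object@diagnostics)

#' @rdname posterior-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname posterior-accessors
#' @export
setMethod("isConverged", "PDPosterior", function(object) object@converged)

#' @rdname posterior-accessors
#' @export
setGeneric("pointEstimate", function(object) standardGeneric("pointEstimate"))
#' @rdname posterior-accessors
#' @export
setMethod("pointEstimate", "PDPosterior", function(object) object@pointEstimate)

#' CIProfile accessors
#'
#' @param object a [CIProfile-class].
#' @return `ciTable()` a data.frame (treatment, fraction, ci, ci_lo, ci_hi,
#'   call); `interactionCall()` the summary call at E50; `ciAtE50()` the
#'   median CI at E50.
#' @name ciprofile-accessors
NULL

#' @rdname ciprofile-accessors
#' @export
setGeneric("ciTable", function(object) standardGeneric("ciTable"))
#' @rdname ciprofile-accessors
#' @export
setMethod("ciTable", "CIProfile", function(object)
  data.frame(treatment_id = object@treatment, fraction = object@fractions,
             ci = object@ci, ci_lo = object@ciLo, ci_hi = object@ciHi,
             call = object@calls, row.names = NULL))

#' @rdname ciprofile-accessors
#' @export
setGeneric("interactionCall", function(object) standardGeneric("interactionCall"))
#' @rdname ciprofile-accessors
#' @export
setMethod("interactionCall", "CIProfile", function(object) object@summaryCall)

#' @rdname ciprofile-accessors
#' @export
setGeneric("ciAtE50", function(object) standardGeneric("ciAtE50"))
#' @rdname ciprofile-accessors
#' @export
setMethod("ciAtE50", "CIProfile", function(object) object@ciE50)

setMethod("show", "PDParams", function(object) {
  cat("PDParams (Hill pharmacodynamic model)\n")
  cat(sprintf("  psi_max: %.4g h^-1   psi_min: %.4g h^-1\n",
              object@psiMax, object@psiMin))
  cat(sprintf("  kappa:   %.4g        zMIC:    %.4g\n",
              object@kappa, object@zmic))
  cat(sprintf("  Emax = %.4g h^-1, EC50 = %.4g\n",
              emax(object), ec50(object)))
  invisible(object)
})

setMethod("show", "PDPosterior", function(object) {
  cat(sprintf("PDPosterior: %d retained draws, %d chains\n",
              nrow(object@draws), object@config$chains %||% NA_integer_))
  cat(sprintf("  converged: %s (split-Rhat threshold 1.05)\n",
              if (object@converged) "yes" else "NO"))
  q <- apply(object@draws[, c("psi_max", "psi_min", "kappa", "zmic"),
                          drop = FALSE], 2L, stats::quantile,
             probs = c(0.025, 0.5, 0.975))
  print(signif(t(q), 4))
  invisible(object)
})

setMethod("show", "MixtureDesign", function(object) {
  cat(sprintf("MixtureDesign: %s (%s, %gx MIC stocks)\n",
              paste(object@components, collapse = " + "),
              paste(signif(object@ratio, 3), collapse = ":"),
              object@stockMultiplier))
  invisible(object)
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf("SimulationScenario: %d drug(s), %d mixture(s)\n",
              length(object@drugs), length(object@mixtures)))
  cat(sprintf("  inoculum %.3g CFU, times %s min, %d dilution levels, %d replicate(s)\n",
              object@inoculum, paste(object@times, collapse = "/"),
              object@dilutionLevels, object@replicates))
  cat(sprintf("  detection limit %g CFU; noise: poisson=%s sigma=%g; seed %d\n",
              object@detectionLimit, object@noise$poisson,
              object@noise$sigma, object@seed))
  invisible(object)
})

setMethod("show", "CIProfile", function(object) {
  cat(sprintf("CIProfile for '%s': %d fractions in [%.2f, %.2f]\n",
              object@treatment, length(object@fractions),
              min(object@fractions), max(object@fractions)))
  cat(sprintf("  CI at E50 = %.3g; summary call: %s\n",
              object@ciE50, object@summaryCall))
  invisible(object)
})
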
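#' @include synthdata.R killrates.R mcmc.R combination.R
NULL

#' Pipeline configuration
#'
#' Exactly one of `scenario` (a [SimulationScenario-class] to simulate) or
#' `inputCsv` (a tidy kill-curve CSV to analyse) must be given. The seed is
#' recorded in every output artifact.
#'
#' @param scenario a [SimulationScenario-class], or NULL.
#' @param inputCsv path to a tidy kill-curve CSV, or NULL. Mixture
#'   treatments are recognised by a `components` field containing `+`;
#'   their designs (ratio, stock multiplier) are reconstructed from the
#'   `ratio` column and `stockMultiplier`.
#' @param outdir output directory (created if missing).
#' @param seed integer seed governing every stochastic stage.
#' @param mcmc sampler settings from [pdMCMCControl()].
#' @param fractions CI effect-fraction grid.
#' @param fractionMode `"own"` or `"absolute"`, see [combinationIndex()].
#' @param includeBounds include left-censored rate bounds in fits.
#' @param stockMultiplier stock strength assumed when reconstructing
#'   designs from an input CSV (default 100).
#' @param verbose logical, log stage progress to stderr.
#' @return validated config list (class `"ampSynergyRunConfig"`).
#' @export
runConfig <- function(scenario = NULL, inputCsv = NULL, outdir = tempfile("ampsynergy_run_"),
                      seed = 1L, mcmc = pdMCMCControl(),
                      fractions = seq(0.05, 0.95, by = 0.05),
                      fractionMode = c("own", "absolute"),
                      includeBounds = FALSE, stockMultiplier = 100,
                      verbose = FALSE) {
  fractionMode <- match.arg(fractionMode)
  if (is.null(scenario) == is.null(inputCsv))
    stop("exactly one of 'scenario' or 'inputCsv' must be provided")
  if (!is.null(scenario)) stopifnot(is(scenario, "SimulationScenario"))
  if (!is.null(inputCsv) && !file.exists(inputCsv))
    stop("input CSV not found: ", inputCsv)
  structure(list(scenario = scenario, inputCsv = inputCsv,
                 outdir = outdir, seed = as.integer(seed), mcmc = mcmc,
                 fractions = fractions, fractionMode = fractionMode,
                 includeBounds = includeBounds,
                 stockMultiplier = stockMultiplier, verbose = verbose),
            class = "ampSynergyRunConfig")
}

#' Run the full kill-curve analysis pipeline
#'
#' Stages, each writing its artifact under `config$outdir`:
#' \enumerate{
#'   \item simulate (or read) kill curves — `killcurves.csv` (+
#'     `truth.yaml` when simulated);
#'   \item rate estimation — `rates.csv`;
#'   \item pharmacodynamic fits (least squares + MCMC) per treatment —
#'     `fits.json`;
#'   \item combination-index profiles per mixture — `ci_profile.csv`,
#'     `summary.json`;
#'   \item `manifest.json` — config hash, seed, per-stage record counts,
#'     file list, interaction calls.
#' }
#' Reruns with an identical config are bit-identical: every stochastic
#' stage derives its stream from `config$seed`. Warnings are raised (not
#' suppressed) for censoring-heavy treatments and unconverged fits; a
#' stage failure writes a `FAILED` marker naming the stage and offending
#' treatment before rethrowing.
#'
#' @param config a [runConfig()] object.
#' @param stopAfter run only up to this stage: `"simulate"` (data stage),
#'   `"rates"`, `"fit"`, `"ci"`, or `"all"` (default).
#' @return the manifest, invisibly (list).
#' @export
runPipeline <- function(config, stopAfter = c("all", "simulate", "rates",
                                              "fit", "ci")) {
  stopAfter <- match.arg(stopAfter)
  done <- function(st) stopAfter != "all" && st == stopAfter
  stopifnot(inherits(config, "ampSynergyRunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logmsg <- function(...) if (isTRUE(config$verbose))
    message("[ampsynergy] ", sprintf(...))
  stage <- "init"
  treatmentCtx <- NA_character_
  fail <- function(e) {
    writeLines(sprintf("stage=%s treatment=%s error=%s", stage,
                       treatmentCtx, conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s' (treatment %s): %s", stage,
                 treatmentCtx, conditionMessage(e)), call. = FALSE)
  }
  # hash the analytic configuration only: where outputs land (and logging)
  # must not change what is computed
  manifest <- list(config_hash = configHash(unclass(config)[
    setdiff(names(config), c("verbose", "outdir"))]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ampsynergy")),
    stages = list(), files = character())

  tryCatch({ repeat {
    stage <- "data"
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      sc@seed <- config$seed
      records <- simulateScenario(sc)
      writeScenarioTruth(sc, file.path(config$outdir, "truth.yaml"))
      manifest$files <- c(manifest$files, "truth.yaml")
    } else {
      records <- readKillCurves(config$inputCsv)
    }
    writeKillCurves(records, file.path(config$outdir, "killcurves.csv"))
    manifest$files <- c(manifest$files, "killcurves.csv")
    manifest$stages$data <- list(records = nrow(records),
                                 treatments = length(unique(records$treatment_id)))
    logmsg("data: %d records, %d treatments", nrow(records),
           length(unique(records$treatment_id)))
    if (done("simulate")) break

    stage <- "rates"
    rates <- estimateRates(records)
    censHeavy <- tapply(rates$censored_used, rates$treatment_id, mean)
    for (tid in names(censHeavy)[censHeavy > 0.5])
      warning("treatment '", tid, "' is censoring-heavy (",
              round(100 * censHeavy[tid]), "% of concentrations); kill ",
              "rates may be underestimated", call. = FALSE)
    utils::write.csv(
      rates[c("treatment_id", "concentration", "rate", "se", "n_points",
              "censored_used", "bound")],
      file.path(config$outdir, "rates.csv"), row.names = FALSE)
    manifest$files <- c(manifest$files, "rates.csv")
    manifest$stages$rates <- list(records = nrow(rates))
    logmsg("rates: %d estimates", nrow(rates))
    if (done("rates")) break

    stage <- "fit"
    treatments <- unique(rates$treatment_id)
    fits <- list()
    posteriors <- list()
    for (tid in treatments) {
      treatmentCtx <- tid
      rt <- rates[rates$treatment_id == tid, , drop = FALSE]
      ls <- fitPDLS(rt, includeBounds = config$includeBounds)
      post <- fitPDMCMC(rt, config = config$mcmc,
                        seed = subSeed(config$seed, paste0("mcmc\x1f", tid)),
                        includeBounds = config$includeBounds)
      posteriors[[tid]] <- post
      qs <- apply(post@draws[, c("psi_max", "psi_min", "kappa", "zmic")],
                  2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
      fits[[tid]] <- list(
        ls = list(psi_max = ls@psiMax, psi_min = ls@psiMin,
                  kappa = ls@kappa, zmic = ls@zmic,
                  loss = attr(ls, "loss")),
        posterior_median = as.list(qs["50%", ]),
        ci95 = list(lo = as.list(qs["2.5%", ]), hi = as.list(qs["97.5%", ])),
        diagnostics = post@diagnostics, converged = post@converged,
        seed = post@seed)
      if (!post@converged)
        warning("fit for treatment '", tid, "' did not converge",
                call. = FALSE)
    }
    treatmentCtx <- NA_character_
    jsonlite::write_json(fits, file.path(config$outdir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest$files <- c(manifest$files, "fits.json")
    manifest$stages$fit <- list(
      treatments = length(fits),
      unconverged = sum(!vapply(posteriors, isConverged, TRUE)))
    logmsg("fit: %d treatments", length(fits))
    if (done("fit")) break

    stage <- "ci"
    designs <- pipelineDesigns(config, records)
    ciTabs <- list()
    summaries <- list()
    for (tid in names(designs)) {
      treatmentCtx <- tid
      d <- designs[[tid]]
      if (!all(c(d@components, tid) %in% names(posteriors))) next
      prof <- ciProfile(posteriors[d@components], posteriors[[tid]], d,
                        fractions = config$fractions,
                        mode = config$fractionMode,
                        seed = subSeed(config$seed, paste0("ci\x1f", tid)),
                        treatment = tid)
      ciTabs[[tid]] <- ciTable(prof)
      summaries[[tid]] <- list(call = interactionCall(prof),
                               ci_e50 = ciAtE50(prof),
                               components = d@components)
    }
    treatmentCtx <- NA_character_
    if (length(ciTabs)) {
      utils::write.csv(do.call(rbind, ciTabs),
                       file.path(config$outdir, "ci_profile.csv"),
                       row.names = FALSE)
      manifest$files <- c(manifest$files, "ci_profile.csv")
    }
    jsonlite::write_json(summaries, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$files <- c(manifest$files, "summary.json")
    manifest$stages$ci <- list(mixtures = length(ciTabs))
    manifest$calls <- lapply(summaries, `[[`, "call")
    logmsg("ci: %d mixture profiles", length(ciTabs))
    break
  } }, error = fail)

  manifest$files <- c(manifest$files, "manifest.json")
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Mixture designs analysed by the pipeline: from the scenario when
# simulating, otherwise reconstructed from components/ratio columns.
pipelineDesigns <- function(config, records) {
  if (!is.null(config$scenario)) return(config$scenario@mixtures)
  mix <- unique(records[grepl("+", records$components, fixed = TRUE),
                        c("treatment_id", "components", "ratio")])
  designs <- list()
  for (i in seq_len(nrow(mix))) {
    comps <- strsplit(mix$components[i], "+", fixed = TRUE)[[1]]
    ratio <- as.numeric(strsplit(as.character(mix$ratio[i]), ":")[[1]])
    designs[[mix$treatment_id[i]]] <-
      MixtureDesign(comps, mic = rep(1, length(comps)),
                    ratio = ratio / sum(ratio),
                    stockMultiplier = config$stockMultiplier)
  }
  designs
}
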
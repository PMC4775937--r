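#' @include AllClasses.R pdmodel.R
NULL

#' Construct a simulation scenario
#'
#' Defaults reproduce the kill-curve study design: inoculum 2e6 CFU per
#' 100 ul, sampling at 0/20/40/60 min, 2-fold dilution series from 100x
#' MIC, plating detection limit 100 CFU, three replicates, Poisson plating
#' noise with log-normal overdispersion (sigma = 0.1 on the ln scale).
#'
#' @param drugs named list of [PDParams-class]: true single-drug parameters
#'   on each drug's MIC-multiple axis (so a true `zmic` of 1 means the
#'   pharmacodynamic MIC coincides with the assay MIC).
#' @param mic named numeric, MIC in ug/ml per drug (default 8 each; only
#'   unit bookkeeping, the dose axes are MIC-scaled).
#' @param mixtures named list of [MixtureDesign-class] (default none).
#' @param gamma numeric interaction factor per mixture (recycled);
#'   gamma = 1 is exactly Loewe-additive, gamma > 1 divides every
#'   isoeffective mixture dose by gamma (true CI = 1/gamma at every effect
#'   fraction), gamma < 1 is antagonism.
#' @param inoculum CFU at t = 0.
#' @param times sampling times in minutes, strictly increasing from 0.
#' @param dilutionLevels number of 2-fold steps down from the top dose.
#' @param detectionLimit plating detection limit in CFU.
#' @param noise list(poisson = TRUE, sigma = 0.1); set
#'   `list(poisson = FALSE, sigma = 0)` for noise-free expectations.
#' @param replicates replicates per concentration.
#' @param seed top-level integer seed.
#' @return A validated [SimulationScenario-class].
#' @examples
#' sc <- simScenario(
#'   drugs = list(A = PDParams(1.2, -8, 3, 1), B = PDParams(1.2, -6, 2, 1)),
#'   mixtures = list(AB = MixtureDesign(c("A", "B"), mic = c(8, 16))),
#'   gamma = 1)
#' sc
#' @export
simScenario <- function(drugs, mic = NULL, mixtures = list(), gamma = 1,
                        inoculum = 2e6, times = c(0, 20, 40, 60),
                        dilutionLevels = 10L, detectionLimit = 100,
                        noise = list(poisson = TRUE, sigma = 0.1),
                        replicates = 3L, seed = 1L) {
  if (is.null(mic)) mic <- stats::setNames(rep(8, length(drugs)), names(drugs))
  mic <- mic[names(drugs)]
  gamma <- stats::setNames(rep_len(as.numeric(gamma), length(mixtures)),
                           names(mixtures))
  noise <- modifyList(list(poisson = TRUE, sigma = 0.1), noise)
  new("SimulationScenario", drugs = drugs, mic = mic, mixtures = mixtures,
      gamma = gamma, inoculum = as.numeric(inoculum),
      times = as.numeric(times), dilutionLevels = as.integer(dilutionLevels),
      detectionLimit = as.numeric(detectionLimit), noise = noise,
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Net growth rate of the Loewe-additive mixture null
#'
#' The ground-truth dose-response of a simulated mixture. At stock fraction
#' `g`, component `i` is present at `g * stockMultiplier * ratio_i`
#' MIC-multiples. Under Loewe additivity the mixture's kill rate E at an
#' (interaction-adjusted) dose solves the isobole equation
#' \deqn{\sum_i C_{iso,i}(g) / C_i(E) = 1,}
#' found by bracketed one-dimensional root finding over E between 0 and the
#' smallest component Emax; the interaction factor gamma rescales potency,
#' \eqn{\mu_{mix}(g) = E^*(\gamma g)}, so every isoeffective dose is divided
#' by gamma and the analytic combination index is 1/gamma at every effect
#' fraction. Doses beyond the range where the additive null is defined
#' (possible when component Emax values differ) are clipped to the
#' attainable maximal effect, with a warning.
#'
#' The mixture's drug-free growth rate is the mean of the component
#' `psiMax` values (the same bacterial culture grows beneath every curve).
#'
#' @param g numeric vector of stock fractions in [0, 1].
#' @param singles named list of [PDParams-class] for the components.
#' @param design a [MixtureDesign-class].
#' @param gamma interaction factor, > 0.
#' @return numeric vector of net growth rates psi_mix(g) in h^-1.
#' @export
loeweMixtureGrowth <- function(g, singles, design, gamma = 1) {
  stopifnot(is(design, "MixtureDesign"), gamma > 0)
  singles <- singles[design@components]
  if (any(vapply(singles, is.null, TRUE)))
    stop("missing PDParams for some mixture component")
  psiMaxMix <- mean(vapply(singles, function(p) p@psiMax, 0))
  EmaxMin <- min(vapply(singles, function(p) p@psiMax - p@psiMin, 0))
  lo <- EmaxMin * 1e-12
  hi <- EmaxMin * (1 - 1e-9)
  clipped <- FALSE
  Estar <- vapply(g, function(gi) {
    if (gi <= 0) return(0)
    ci <- componentConcentrations(gamma * gi, design)
    h <- function(E) sum(ci / vapply(singles, function(p)
      doseForKillRate(E, p), 0)) - 1
    if (h(hi) > 0) {           # additive null saturates before this dose
      clipped <<- TRUE
      return(hi)
    }
    # at very small doses the root sits below the default bracket; extend it
    loi <- lo
    while (h(loi) < 0 && loi > EmaxMin * 1e-290) loi <- loi * 1e-12
    stats::uniroot(h, c(loi, hi), tol = 1e-13)$root
  }, 0)
  if (clipped)
    warning("additive null undefined above effect ", signif(hi, 6),
            " h^-1 (component Emax ranges differ); clipped to the ",
            "attainable maximum", call. = FALSE)
  psiMaxMix - Estar
}

#' Simulate kill curves for a single drug
#'
#' Generates time-kill records for one drug over the 2-fold dilution series
#' from `stockMultiplier` x MIC down (`dilutionLevels` steps) plus a
#' drug-free control, at the scenario's sampling times and replicate count.
#' The expected count is `inoculum * exp(psi(a) * t)`; noise (if enabled)
#' is multiplicative log-normal overdispersion followed by Poisson plating
#' at a 1:`detectionLimit` plated fraction, so observed counts are
#' multiples of the detection limit. Counts falling below the detection
#' limit are recorded AT the limit with `censored = TRUE`. One RNG
#' sub-stream per (treatment, replicate) makes output reproducible
#' bit-for-bit and independent of which other treatments are simulated.
#'
#' @param scenario a [SimulationScenario-class].
#' @param drug drug name present in `scenario@drugs`.
#' @return data.frame with columns `treatment_id`, `components`, `ratio`,
#'   `concentration` (MIC-multiples), `conc_units`, `replicate`,
#'   `time_min`, `cfu`, `censored`.
#' @export
simulateSingleDrug <- function(scenario, drug) {
  stopifnot(is(scenario, "SimulationScenario"))
  if (!drug %in% names(scenario@drugs))
    stop("unknown drug '", drug, "'")
  params <- scenario@drugs[[drug]]
  doses <- c(100 * 2^(-(seq_len(scenario@dilutionLevels) - 1L)), 0)
  psi <- netGrowth(doses, params)
  simulateTreatment(scenario, treatment = drug, components = drug,
                    ratio = "1", doses = doses, psi = psi,
                    units = "xMIC")
}

#' Simulate kill curves for a fixed-ratio mixture
#'
#' As [simulateSingleDrug()], but on the mixture's stock-fraction dose axis
#' `g` (2-fold series from g = 1 down, plus control) with the ground-truth
#' response from [loeweMixtureGrowth()] at the mixture's interaction factor
#' gamma. A sham mixture (all components the same drug, gamma = 1) has a
#' dose-response identical to that drug's own curve re-expressed on the g
#' axis.
#'
#' @param scenario a [SimulationScenario-class].
#' @param mixture name of a mixture in `scenario@mixtures`.
#' @return data.frame as [simulateSingleDrug()], `conc_units`
#'   `"stock_fraction"`.
#' @export
simulateMixture <- function(scenario, mixture) {
  stopifnot(is(scenario, "SimulationScenario"))
  if (!mixture %in% names(scenario@mixtures))
    stop("unknown mixture '", mixture, "'")
  design <- scenario@mixtures[[mixture]]
  gamma <- scenario@gamma[[mixture]]
  doses <- c(2^(-(seq_len(scenario@dilutionLevels) - 1L)), 0)
  psi <- loeweMixtureGrowth(doses, scenario@drugs, design, gamma)
  simulateTreatment(scenario, treatment = mixture,
                    components = paste(design@components, collapse = "+"),
                    ratio = paste(signif(design@ratio, 6), collapse = ":"),
                    doses = doses, psi = psi, units = "stock_fraction")
}

# shared kill-curve generator: deterministic expectation + noise + censoring
simulateTreatment <- function(scenario, treatment, components, ratio,
                              doses, psi, units) {
  tmin <- scenario@times
  th <- tmin / 60
  dl <- scenario@detectionLimit
  out <- vector("list", scenario@replicates)
  capped <- FALSE
  for (rep_i in seq_len(scenario@replicates)) {
    set.seed(subSeed(scenario@seed, paste(treatment, rep_i, sep = "\x1f")))
    cfu <- numeric(length(doses) * length(tmin))
    cens <- logical(length(cfu))
    k <- 0L
    for (j in seq_along(doses)) {
      for (ti in seq_along(tmin)) {
        k <- k + 1L
        expected <- scenario@inoculum * exp(psi[j] * th[ti])
        if (!is.finite(expected) || expected > 1e15) {
          expected <- 1e15
          capped <- TRUE
        }
        if (scenario@noise$sigma > 0) {
          s <- scenario@noise$sigma
          expected <- expected * exp(stats::rnorm(1, -s^2 / 2, s))
        }
        if (scenario@noise$poisson) {
          plated <- stats::rpois(1, expected / dl)
          obs <- plated * dl
        } else {
          obs <- expected
        }
        if (obs < dl) {
          cfu[k] <- dl
          cens[k] <- TRUE
        } else {
          cfu[k] <- obs
        }
      }
    }
    out[[rep_i]] <- data.frame(
      treatment_id = treatment, components = components, ratio = ratio,
      concentration = rep(doses, each = length(tmin)),
      conc_units = units, replicate = rep_i,
      time_min = rep(tmin, times = length(doses)),
      cfu = cfu, censored = cens)
  }
  if (capped)
    warning("expected count overflowed (psi * t too large); capped at 1e15",
            call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate every treatment of a scenario
#'
#' All single drugs followed by all mixtures, in scenario order.
#'
#' @param scenario a [SimulationScenario-class].
#' @return tidy kill-curve data.frame (see [simulateSingleDrug()]).
#' @export
simulateScenario <- function(scenario) {
  singles <- lapply(names(scenario@drugs), simulateSingleDrug,
                    scenario = scenario)
  mixes <- lapply(names(scenario@mixtures), simulateMixture,
                  scenario = scenario)
  res <- do.call(rbind, c(singles, mixes))
  rownames(res) <- NULL
  res
}

#' Read / write tidy kill-curve tables
#'
#' CSV with header `treatment_id, components, ratio, concentration,
#' conc_units, replicate, time_min, cfu, censored`.
#'
#' @param records tidy kill-curve data.frame.
#' @param path file path.
#' @return `readKillCurves()` the data.frame; the writer returns `path`
#'   invisibly.
#' @export
writeKillCurves <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeKillCurves
#' @export
readKillCurves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$censored <- as.logical(df$censored)
  df
}

#' Write scenario ground truth as a YAML sidecar
#'
#' Records the true parameters, interaction factors, design constants and
#' seed of a simulation scenario so test harnesses can compare pipeline
#' output against the generating truth.
#'
#' @param scenario a [SimulationScenario-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeScenarioTruth <- function(scenario, path) {
  tr <- list(
    drugs = lapply(scenario@drugs, function(p)
      list(psi_max = p@psiMax, psi_min = p@psiMin, kappa = p@kappa,
           zmic = p@zmic)),
    mic = as.list(scenario@mic),
    mixtures = lapply(names(scenario@mixtures), function(nm) {
      m <- scenario@mixtures[[nm]]
      list(name = nm, components = as.list(m@components),
           ratio = as.list(m@ratio), stock_multiplier = m@stockMultiplier,
           gamma = unname(scenario@gamma[[nm]]))
    }),
    design = list(inoculum = scenario@inoculum,
                  times_min = as.list(scenario@times),
                  dilution_levels = scenario@dilutionLevels,
                  detection_limit = scenario@detectionLimit,
                  replicates = scenario@replicates),
    noise = scenario@noise,
    seed = scenario@seed)
  yaml::write_yaml(tr, path)
  invisible(path)
}
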
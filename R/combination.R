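#' @include AllClasses.R pdmodel.R mcmc.R
NULL

#' Per-component concentrations delivered by a mixture dose
#'
#' At stock fraction `g` of the combined `stockMultiplier` x MIC stocks,
#' component `i` is present at `g * stockMultiplier * ratio_i` multiples of
#' its own MIC. With equal ratios this is the design in which two-way
#' mixtures halve and three-way mixtures third each component's
#' concentration, so Loewe additivity predicts a mixture MIC (in g units,
#' `g = 1/stockMultiplier`) at which every component sits at `1/n` of its
#' own MIC.
#'
#' @param g stock fraction, 0 < g <= 1 (values above 1 are allowed for
#'   bookkeeping of hypothetical super-stock doses).
#' @param design a [MixtureDesign-class].
#' @return named numeric, per-component doses in MIC-multiples.
#' @examples
#' d <- MixtureDesign(c("A", "B"), mic = c(8, 16))
#' componentConcentrations(1, d)      # 50, 50
#' componentConcentrations(0.01, d)   # 0.5, 0.5 — the Loewe-additive MIC
#' @export
componentConcentrations <- function(g, design) {
  stopifnot(is(design, "MixtureDesign"), length(g) == 1L, g > 0)
  stats::setNames(g * design@stockMultiplier * design@ratio,
                  design@components)
}

#' Loewe combination index at one effect fraction
#'
#' For an effect fraction f, finds the mixture dose achieving f of the
#' mixture's own maximal effect (`g* = isoeffectiveConc(f, combo)` on the
#' stock-fraction axis), converts it to per-component concentrations
#' `C_iso,i`, divides by each single drug's own isoeffective concentration
#' `C_i = isoeffectiveConc(f, singles[[i]])`, and sums:
#' \deqn{CI = \sum_i C_{iso,i} / C_i.}
#' CI < 1 is synergy (the mixture needs less of each drug than Loewe
#' additivity predicts), CI = 1 additivity, CI > 1 antagonism. A sham
#' combination — a drug combined with itself, the mixture curve being the
#' drug's own re-expressed on the g axis — returns exactly 1 at every
#' fraction, ratio and kappa.
#'
#' By default the fraction refers to each curve's OWN maximal effect.
#' `mode = "absolute"` instead interprets the fraction on the mixture's
#' effect scale and requires every single drug to attain the same absolute
#' kill rate; fractions a component cannot reach give `NA` with a warning
#' (never extrapolated).
#'
#' @param singles named list of [PDParams-class] per component, doses in
#'   each drug's own MIC-multiples.
#' @param combo [PDParams-class] of the mixture fitted on the
#'   stock-fraction g axis.
#' @param design a [MixtureDesign-class].
#' @param fraction numeric vector of effect fractions in [0.05, 0.95].
#' @param mode `"own"` (default) or `"absolute"`, see Details.
#' @return numeric vector of combination indices (NA where undefined).
#' @export
combinationIndex <- function(singles, combo, design, fraction,
                             mode = c("own", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is(combo, "PDParams"), is(design, "MixtureDesign"))
  if (any(fraction < 0.05 - 1e-12 | fraction > 0.95 + 1e-12))
    stop("'fraction' must lie in [0.05, 0.95]")
  singles <- singles[design@components]
  if (any(vapply(singles, is.null, TRUE)))
    stop("missing single-drug parameters for some mixture component")
  vapply(fraction, function(f) {
    gStar <- isoeffectiveConc(f, combo)
    cIso <- componentConcentrations(gStar, design)
    cSingle <- if (mode == "own") {
      vapply(singles, function(p) isoeffectiveConc(f, p), 0)
    } else {
      E <- f * (combo@psiMax - combo@psiMin)
      ok <- vapply(singles, function(p) E < p@psiMax - p@psiMin, TRUE)
      if (!all(ok)) {
        warning("effect level ", signif(E, 4), " h^-1 unattainable by: ",
                paste(design@components[!ok], collapse = ", "),
                "; CI undefined at fraction ", f, call. = FALSE)
        return(NA_real_)
      }
      vapply(singles, function(p) doseForKillRate(E, p), 0)
    }
    sum(cIso / cSingle)
  }, 0)
}

#' Combination-index profile with posterior uncertainty
#'
#' Profiles the combination index across a grid of effect fractions,
#' propagating parameter uncertainty by evaluating the CI for each tuple of
#' posterior draws. Draws from the independently fitted treatment
#' posteriors are aligned to the smallest draw count and paired by index
#' after a seeded random permutation (treatments were fitted independently,
#' so independent pairing is the faithful propagation). Per fraction the
#' point estimate is the median and the interval the 2.5/97.5 percentiles;
#' the per-fraction call is `synergistic` / `additive` / `antagonistic`
#' according to the interval's position relative to 1, and the summary call
#' is the call at the 50% effect level (E50).
#'
#' @param singlesPosteriors named list of [PDPosterior-class] (or
#'   [PDParams-class], wrapped via [asPosterior()]) per component.
#' @param comboPosterior [PDPosterior-class] (or [PDParams-class]) of the
#'   mixture on the g axis.
#' @param design a [MixtureDesign-class].
#' @param fractions fraction grid, default `seq(0.05, 0.95, by = 0.05)`.
#' @param mode fraction convention, see [combinationIndex()].
#' @param seed seed for the draw-pairing permutation.
#' @param treatment label for the profile (default the design components).
#' @return A [CIProfile-class].
#' @export
ciProfile <- function(singlesPosteriors, comboPosterior, design,
                      fractions = seq(0.05, 0.95, by = 0.05),
                      mode = c("own", "absolute"), seed = 1L,
                      treatment = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(design, "MixtureDesign"))
  if (is(comboPosterior, "PDParams"))
    comboPosterior <- asPosterior(comboPosterior)
  singlesPosteriors <- lapply(singlesPosteriors, function(p)
    if (is(p, "PDParams")) asPosterior(p) else p)
  singlesPosteriors <- singlesPosteriors[design@components]
  if (any(vapply(singlesPosteriors, is.null, TRUE)))
    stop("missing posterior for some mixture component")
  nd <- c(vapply(singlesPosteriors, function(p) nrow(p@draws), 0L),
          nrow(comboPosterior@draws))
  n <- min(nd)
  if (n < 100L)
    stop("need >= 100 posterior draws per treatment (have ", n, ")")

  set.seed(as.integer(seed %% 2147483647))
  pick <- function(post) {
    idx <- sample.int(nrow(post@draws))[seq_len(n)]
    post@draws[idx, c("psi_max", "psi_min", "kappa", "zmic"), drop = FALSE]
  }
  comboD <- pick(comboPosterior)
  singleD <- lapply(singlesPosteriors, pick)

  sm <- design@stockMultiplier
  ratio <- design@ratio
  ciMat <- matrix(NA_real_, nrow = n, ncol = length(fractions))
  isoDose <- function(D, f) {
    # vectorised closed-form inversion over draws
    x <- f * abs(D[, "psi_min"]) / (D[, "psi_max"] * (1 - f))
    D[, "zmic"] * x^(1 / D[, "kappa"])
  }
  for (j in seq_along(fractions)) {
    f <- fractions[j]
    gStar <- isoDose(comboD, f)
    tot <- 0
    if (mode == "own") {
      for (i in seq_along(singleD))
        tot <- tot + gStar * sm * ratio[i] / isoDose(singleD[[i]], f)
    } else {
      E <- f * (comboD[, "psi_max"] - comboD[, "psi_min"])
      for (i in seq_along(singleD)) {
        D <- singleD[[i]]
        Emax <- D[, "psi_max"] - D[, "psi_min"]
        x <- E * abs(D[, "psi_min"]) / D[, "psi_max"] / (Emax - E)
        Ci <- ifelse(E < Emax, D[, "zmic"] * x^(1 / D[, "kappa"]), NA_real_)
        tot <- tot + gStar * sm * ratio[i] / Ci
      }
    }
    ciMat[, j] <- tot
  }

  ci <- apply(ciMat, 2L, stats::median, na.rm = TRUE)
  lo <- apply(ciMat, 2L, stats::quantile, probs = 0.025, na.rm = TRUE,
              names = FALSE)
  hi <- apply(ciMat, 2L, stats::quantile, probs = 0.975, na.rm = TRUE,
              names = FALSE)
  calls <- ifelse(hi < 1, "synergistic",
                  ifelse(lo > 1, "antagonistic", "additive"))
  e50 <- which.min(abs(fractions - 0.5))
  new("CIProfile",
      treatment = treatment %||% paste(design@components, collapse = "+"),
      fractions = as.numeric(fractions), ci = ci, ciLo = lo, ciHi = hi,
      calls = calls, summaryCall = calls[e50], ciE50 = ci[e50])
}

#' Compare interaction strength and parameters across combination sizes
#'
#' Reproduces the study's group-level analyses on user data: a Welch
#' t-test on combination-index values pooled across the effect-fraction
#' grid between two- and three-component mixtures, and one-way regression
#' ANOVA (combination size as a numeric covariate, 1 numerator df) of MIC
#' (zMIC), kappa and psi_min across sizes.
#'
#' @param profiles list of [CIProfile-class] (or their [ciTable()]
#'   data.frames) — the group of each profile is its component count,
#'   taken from `sizes` or parsed from the treatment label.
#' @param sizes integer vector, combination size per profile (optional if
#'   treatment labels are of the form "A+B" / "A+B+C").
#' @param params optional data.frame with columns `size`, `zmic`, `kappa`,
#'   `psi_min` (one row per fitted treatment) for the parameter ANOVAs.
#' @return list with `t_test` (statistic, df, p, group means, mean ratio
#'   three/two) and `anova` (per-parameter F, df, p), carrying class
#'   `"ampSynergyGroupComparison"` for printing.
#' @export
compareGroups <- function(profiles, sizes = NULL, params = NULL) {
  tabs <- lapply(profiles, function(p)
    if (is(p, "CIProfile")) ciTable(p) else as.data.frame(p))
  if (is.null(sizes))
    sizes <- vapply(tabs, function(tb)
      length(strsplit(tb$treatment_id[1], "+", fixed = TRUE)[[1]]), 0L)
  if (length(sizes) != length(tabs))
    stop("'sizes' must have one entry per profile")
  ciBySize <- split(
    unlist(lapply(tabs, function(tb) tb$ci[is.finite(tb$ci)])),
    rep(sizes, vapply(tabs, function(tb) sum(is.finite(tb$ci)), 0L)))
  if (!all(c("2", "3") %in% names(ciBySize)))
    stop("need both two- and three-component profiles for the t-test")
  ci2 <- ciBySize[["2"]]
  ci3 <- ciBySize[["3"]]
  if (length(ci2) < 2L || length(ci3) < 2L)
    stop("each group needs >= 2 CI values for a variance-based test")
  tt <- stats::t.test(ci3, ci2)
  tRes <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_two = mean(ci2), mean_three = mean(ci3),
               ratio_three_vs_two = mean(ci3) / mean(ci2))

  aRes <- NULL
  if (!is.null(params)) {
    params <- as.data.frame(params)
    stopifnot("size" %in% names(params))
    aRes <- list()
    for (v in intersect(c("zmic", "kappa", "psi_min"), names(params))) {
      ok <- is.finite(params[[v]])
      if (sum(ok) < 3L || length(unique(params$size[ok])) < 2L) next
      fit <- stats::lm(params[[v]][ok] ~ as.numeric(params$size[ok]))
      an <- stats::anova(fit)
      aRes[[v]] <- list(F = an$`F value`[1], df1 = an$Df[1],
                        df2 = an$Df[2], p = an$`Pr(>F)`[1])
    }
  }
  structure(list(t_test = tRes, anova = aRes),
            class = "ampSynergyGroupComparison")
}

#' @export
print.ampSynergyGroupComparison <- function(x, ...) {
  tt <- x$t_test
  cat("Welch t-test, CI pooled across fractions (3- vs 2-component):\n")
  cat(sprintf("  t = %.4g, df = %.2f, p = %.3g\n", tt$statistic, tt$df, tt$p))
  cat(sprintf("  mean CI: two-way %.3g, three-way %.3g (ratio %.3g)\n",
              tt$mean_two, tt$mean_three, tt$ratio_three_vs_two))
  if (length(x$anova)) {
    cat("ANOVA across combination sizes (size as numeric covariate):\n")
    for (v in names(x$anova)) {
      a <- x$anova[[v]]
      cat(sprintf("  %-8s F(%d,%d) = %.4g, p = %.3g\n", v, a$df1, a$df2,
                  a$F, a$p))
    }
  }
  invisible(x)
}

#' Plot a combination-index profile
#'
#' CI versus effect fraction with its 95% band and the additivity line at
#' CI = 1 (requires ggplot2).
#'
#' @param profile a [CIProfile-class].
#' @return a ggplot object.
#' @export
plotCIProfile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- ciTable(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = fraction, y = ci)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "effect fraction", y = "combination index",
                  title = df$treatment_id[1]) +
    ggplot2::theme_minimal()
}
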
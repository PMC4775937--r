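test_that("component concentrations follow the fixed-ratio stock design", {
  d2 <- MixtureDesign(c("A", "B"), mic = c(8, 16))
  expect_equal(componentConcentrations(1, d2), c(A = 50, B = 50))
  d3 <- MixtureDesign(c("A", "B", "C"), mic = c(8, 16, 4))
  expect_equal(componentConcentrations(1, d3),
               c(A = 100 / 3, B = 100 / 3, C = 100 / 3))
  # the Loewe-additive MIC point: each component at half its own MIC
  expect_equal(componentConcentrations(0.01, d2), c(A = 0.5, B = 0.5))
  # unequal ratios and the ratio-sum validity
  d37 <- MixtureDesign(c("A", "B"), mic = c(8, 16), ratio = c(0.3, 0.7))
  expect_equal(componentConcentrations(0.1, d37), c(A = 3, B = 7))
  expect_error(MixtureDesign("A", mic = 8), "2 components")
})

test_that("sham combinations give CI = 1 at every fraction, kappa and ratio", {
  fr <- seq(0.05, 0.95, by = 0.05)
  for (k in c(0.5, 1.7, 6)) {
    for (ratio in list(NULL, c(0.3, 0.7))) {
      sham <- shamCombo(PDParams(1.1, -7, k, 1.3), ratio = ratio)
      ci <- combinationIndex(sham$singles, sham$combo, sham$design, fr)
      expect_equal(ci, rep(1, length(fr)), tolerance = 1e-8)
    }
  }
})

test_that("CI is invariant to component relabeling and MIC unit rescaling", {
  singles <- demoDrugs()[c("A", "B")]
  combo <- PDParams(1.2, -8, 3.5, 0.008)
  d <- MixtureDesign(c("A", "B"), mic = c(8, 16))
  dRev <- MixtureDesign(c("B", "A"), mic = c(16, 8))
  fr <- c(0.1, 0.5, 0.9)
  expect_equal(combinationIndex(singles, combo, d, fr),
               combinationIndex(singles, combo, dRev, fr), tolerance = 1e-12)
  # MICs in ug/ml are bookkeeping only: all dose axes are MIC-scaled
  dScaled <- MixtureDesign(c("A", "B"), mic = 1000 * c(8, 16))
  expect_equal(combinationIndex(singles, combo, d, fr),
               combinationIndex(singles, combo, dScaled, fr),
               tolerance = 1e-12)
})

test_that("scaling the mixture's zMIC scales CI proportionally", {
  singles <- demoDrugs()[c("A", "B")]
  d <- MixtureDesign(c("A", "B"), mic = c(8, 16))
  combo <- PDParams(1.2, -8, 3, 0.01)
  f0 <- combo@psiMax / emax(combo)   # the zero-growth effect fraction
  base <- combinationIndex(singles, combo, d, f0)
  for (c_ in c(0.5, 2, 3)) {
    scaled <- PDParams(1.2, -8, 3, 0.01 * c_)
    expect_equal(combinationIndex(singles, scaled, d, f0), c_ * base,
                 tolerance = 1e-10)
  }
})

test_that("fractions outside the profiled range are rejected, NA when unattainable", {
  sham <- shamCombo(PDParams(1.2, -8, 3, 1))
  expect_error(combinationIndex(sham$singles, sham$combo, sham$design, 0.99),
               "0.05, 0.95")
  # absolute-effect mode: a weaker component cannot reach the mixture's E
  singles <- list(A = PDParams(1.2, -8, 3, 1), B = PDParams(1.2, -2, 3, 1))
  combo <- PDParams(1.2, -8, 3, 0.01)
  expect_warning(
    ci <- combinationIndex(singles, combo,
                           MixtureDesign(c("A", "B"), mic = c(8, 8)),
                           c(0.2, 0.9), mode = "absolute"),
    "unattainable")
  expect_true(is.finite(ci[1]) && is.na(ci[2]))
})

test_that("ciProfile propagates posteriors: degenerate draws, calls, refusal", {
  sham <- shamCombo(PDParams(1.2, -8, 3, 1))
  prof <- ciProfile(sham$singles, sham$combo, sham$design, seed = 3)
  tb <- ciTable(prof)
  expect_equal(tb$ci, tb$ci_lo)   # zero-width posterior => zero-width band
  expect_equal(tb$ci, tb$ci_hi)
  expect_equal(tb$ci, rep(1, 19), tolerance = 1e-8)
  expect_equal(interactionCall(prof), "additive")
  expect_equal(ciAtE50(prof), 1, tolerance = 1e-8)

  # synergistic mixture: zMIC half the additive prediction
  syn <- PDParams(1.2, -8, 3, 0.005)
  prof2 <- ciProfile(sham$singles, syn, sham$design, seed = 3)
  expect_equal(interactionCall(prof2), "synergistic")
  expect_equal(ciAtE50(prof2), 0.5, tolerance = 1e-8)

  expect_error(ciProfile(lapply(sham$singles, asPosterior, n = 50),
                         asPosterior(sham$combo, n = 50), sham$design),
               ">= 100 posterior draws")
})

test_that("per-fraction call is additive exactly when the interval spans 1", {
  sc <- demoScenario(seed = 5)
  rates <- estimateRates(simulateScenario(sc))
  posts <- list()
  for (tid in c("A", "B", "AB"))
    posts[[tid]] <- quietFit(rates[rates$treatment_id == tid, ],
                             seed = 100 + nchar(tid))
  prof <- ciProfile(posts[c("A", "B")], posts$AB, sc@mixtures$AB, seed = 5)
  tb <- ciTable(prof)
  expect_true(all(tb$ci_lo <= tb$ci & tb$ci <= tb$ci_hi))
  expect_identical(tb$call == "additive", tb$ci_lo <= 1 & tb$ci_hi >= 1)
  expect_true(all(tb$ci > 0))
})

test_that("compareGroups reproduces hand-computed t and F statistics", {
  # identical groups: no difference
  tb <- data.frame(treatment_id = "A+B", fraction = seq(0.05, 0.95, 0.05),
                   ci = rep(c(0.9, 1, 1.1), length.out = 19),
                   ci_lo = 0.8, ci_hi = 1.2, call = "additive")
  res <- compareGroups(list(tb, tb), sizes = c(2L, 3L))
  expect_equal(res$t_test$statistic, 0, tolerance = 1e-12)
  expect_equal(res$t_test$p, 1, tolerance = 1e-12)

  # constructed 30% reduction with tiny spread
  set.seed(8)
  tb2 <- tb; tb2$ci <- 1.0 + rnorm(19, 0, 1e-4)
  tb3 <- tb; tb3$ci <- 0.7 + rnorm(19, 0, 1e-4)
  res <- compareGroups(list(tb2, tb3), sizes = c(2L, 3L))
  expect_equal(res$t_test$ratio_three_vs_two, 0.7, tolerance = 1e-3)
  expect_lt(res$t_test$p, 1e-10)
  expect_equal(res$t_test$statistic,
               unname(t.test(tb3$ci, tb2$ci)$statistic), tolerance = 1e-12)

  # regression ANOVA against explicit sum-of-squares arithmetic
  set.seed(9)
  params <- data.frame(size = rep(1:3, each = 7),
                       zmic = rnorm(21, rep(c(1, 0.7, 0.4), each = 7), 0.2),
                       kappa = rnorm(21, rep(c(2, 3, 4), each = 7), 0.5),
                       psi_min = rnorm(21, -8, 1))
  res <- compareGroups(list(tb2, tb3), sizes = c(2L, 3L), params = params)
  for (v in c("zmic", "kappa", "psi_min")) {
    x <- params$size; y <- params[[v]]
    b <- cov(x, y) / var(x)
    ssr <- b^2 * sum((x - mean(x))^2)
    sse <- sum((y - mean(y) - b * (x - mean(x)))^2)
    Fref <- (ssr / 1) / (sse / (length(y) - 2))
    expect_equal(res$anova[[v]]$F, Fref, tolerance = 1e-8)
    expect_equal(res$anova[[v]]$df1, 1L)
  }
  expect_output(print(res), "Welch t-test")
})
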
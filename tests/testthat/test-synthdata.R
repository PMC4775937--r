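test_that("noise-free expectations follow N0 * exp(psi t), with exact anchors", {
  # near-zero growth, no drug: counts stay at the inoculum
  still <- simScenario(drugs = list(S = PDParams(1e-9, -1, 1, 1)),
                       mic = c(S = 8), noise = noiseOff, replicates = 1L)
  recs <- simulateSingleDrug(still, "S")
  ctrl <- recs[recs$concentration == 0, ]
  expect_equal(ctrl$cfu, rep(2e6, 4), tolerance = 1e-8)

  # at a = zMIC the net growth is zero: constant CFU at that dilution
  p <- PDParams(1.2, -8, 3, zmic = 100 / 2^6)   # zMIC on the dilution grid
  sc <- simScenario(drugs = list(D = p), mic = c(D = 8), noise = noiseOff,
                    replicates = 1L)
  recs <- simulateSingleDrug(sc, "D")
  atZ <- recs[abs(recs$concentration - p@zmic) < 1e-12, ]
  expect_equal(nrow(atZ), 4L)
  expect_equal(atZ$cfu, rep(2e6, 4), tolerance = 1e-10)

  # drug-free doubling: psi_max = ln 2 per hour doubles the count in 1 h
  gr <- simScenario(drugs = list(G = PDParams(log(2), -1, 1, 1)),
                    mic = c(G = 8), noise = noiseOff, replicates = 1L)
  ctrl <- simulateSingleDrug(gr, "G")
  ctrl <- ctrl[ctrl$concentration == 0, ]
  expect_equal(ctrl$cfu[ctrl$time_min == 60], 4e6, tolerance = 1e-10)
})

test_that("counts below the detection limit are floored and flagged", {
  p <- PDParams(1.2, -15, 3, 1)   # fast kill: 2e6*exp(-15) << 100 at 60 min
  sc <- simScenario(drugs = list(F = p), mic = c(F = 8), noise = noiseOff,
                    replicates = 1L)
  recs <- simulateSingleDrug(sc, "F")
  expect_true(any(recs$censored))
  expect_true(all(recs$cfu[recs$censored] == 100))
  expect_true(all(recs$cfu >= 100 | !recs$censored))
  truth <- sc@inoculum * exp(netGrowth(recs$concentration, p) *
                               recs$time_min / 60)
  expect_identical(recs$censored, truth < 100)
})

test_that("simulation is reproducible and per-treatment streams independent", {
  sc1 <- demoScenario(seed = 42)
  sc2 <- demoScenario(seed = 42)
  expect_identical(simulateScenario(sc1), simulateScenario(sc2))
  expect_false(identical(simulateScenario(demoScenario(seed = 43)),
                         simulateScenario(sc1)))
  # dropping a mixture must not perturb the remaining treatments
  a1 <- simulateSingleDrug(sc1, "A")
  scSub <- simScenario(drugs = demoDrugs(), mic = demoMics,
                       noise = list(poisson = TRUE, sigma = 0.1), seed = 42)
  expect_identical(simulateSingleDrug(scSub, "A"), a1)
})

test_that("sham mixture reproduces the single drug's curve on the g axis", {
  p <- demoDrugs()$A
  sham <- shamCombo(p)
  g <- 2^-(0:9)
  psiMix <- loeweMixtureGrowth(g, sham$singles, sham$design, gamma = 1)
  # total drug at stock fraction g is g*100 MIC-multiples of the same drug
  expect_equal(psiMix, netGrowth(100 * g, p), tolerance = 1e-8)
  # and with unequal volume ratio the identity still holds
  sham37 <- shamCombo(p, ratio = c(0.3, 0.7))
  expect_equal(loeweMixtureGrowth(g, sham37$singles, sham37$design, 1),
               netGrowth(100 * g, p), tolerance = 1e-8)
})

test_that("additive-null dose solves the isobole equation (grid oracle)", {
  singles <- demoDrugs()[c("A", "B")]
  design <- MixtureDesign(c("A", "B"), mic = demoMics[c("A", "B")])
  psiMaxMix <- mean(c(singles$A@psiMax, singles$B@psiMax))
  EmaxMix <- psiMaxMix - min(singles$A@psiMin, singles$B@psiMin)
  target <- 0.5 * EmaxMix

  # root-find the mixture dose g* achieving half-maximal kill
  gStar <- uniroot(function(g)
    (psiMaxMix - loeweMixtureGrowth(g, singles, design, 1)) - target,
    c(1e-6, 1), tol = 1e-12)$root
  # the isobole sum at g* must be 1
  cIso <- componentConcentrations(gStar, design)
  cA <- isoeffectiveConc(target / emax(singles$A), singles$A)
  cB <- isoeffectiveConc(target / emax(singles$B), singles$B)
  expect_equal(cIso[["A"]] / cA + cIso[["B"]] / cB, 1, tolerance = 1e-8)

  # brute-force grid search over g at 1e-4 resolution agrees
  gg <- seq(1e-4, 1, by = 1e-4)
  sums <- gg * 100 * 0.5 / cA + gg * 100 * 0.5 / cB
  gGrid <- gg[which.min(abs(sums - 1))]
  expect_lt(abs(gStar - gGrid), 1e-4)   # grid resolution
})

test_that("gamma rescales potency: analytic CI equals 1/gamma", {
  singles <- demoDrugs()[c("A", "B")]
  design <- MixtureDesign(c("A", "B"), mic = demoMics[c("A", "B")])
  psiMaxMix <- 1.2
  for (gamma in c(0.5, 2)) {
    for (f in c(0.25, 0.5, 0.75)) {
      EmaxMix <- psiMaxMix - (-8)
      target <- f * EmaxMix
      g <- uniroot(function(g)
        (psiMaxMix - loeweMixtureGrowth(g, singles, design, gamma)) - target,
        c(1e-9, 10), tol = 1e-13)$root
      cIso <- componentConcentrations(g, design)
      ci <- cIso[["A"]] / isoeffectiveConc(target / emax(singles$A), singles$A) +
        cIso[["B"]] / isoeffectiveConc(target / emax(singles$B), singles$B)
      expect_equal(ci, 1 / gamma, tolerance = 1e-6)
    }
  }
})

test_that("round-trip through CSV and the truth sidecar preserves the data", {
  sc <- demoScenario(seed = 2, replicates = 1L)
  recs <- simulateSingleDrug(sc, "A")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeKillCurves(recs, csv)
  back <- readKillCurves(csv)
  expect_equal(back$cfu, recs$cfu)
  expect_identical(back$censored, recs$censored)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeScenarioTruth(sc, yml)
  tr <- yaml::read_yaml(yml)
  expect_equal(tr$drugs$A$kappa, 3)
  expect_equal(tr$mixtures[[2]]$gamma, 2)
  expect_equal(tr$design$detection_limit, 100)
  expect_equal(tr$seed, 2)
})

test_that("scenario validity catches malformed designs", {
  expect_error(simScenario(drugs = list(A = demoDrugs()$A), mic = c(A = 8),
                           times = c(10, 20)), "start at 0")
  expect_error(simScenario(drugs = list(A = demoDrugs()$A), mic = c(A = 8),
                           inoculum = 10), "detectionLimit")
  expect_error(
    simScenario(drugs = list(A = demoDrugs()$A), mic = c(A = 8),
                mixtures = list(AX = MixtureDesign(c("A", "X"),
                                                   mic = c(8, 8)))),
    "scenario drugs")
  expect_error(simulateSingleDrug(demoScenario(), "nosuch"), "unknown drug")
})
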
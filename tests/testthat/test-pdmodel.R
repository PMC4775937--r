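test_that("kill rate matches hand-evaluated values and zMIC semantics", {
  p <- PDParams(psiMax = 1, psiMin = -5, kappa = 2, zmic = 1)
  expect_identical(killRate(0, p), 0)
  # at a = zMIC the kill rate equals psi_max, so net growth is exactly 0
  expect_equal(killRate(1, p), 1)
  expect_equal(killRate(2, p), 8 / 3)           # 6*4/(4+5)
  expect_equal(netGrowth(0, p), 1)
  expect_equal(netGrowth(2, p), 1 - 8 / 3)
  for (q in randomParams(20, seed = 11)) {
    expect_equal(netGrowth(q@zmic, q), 0, tolerance = 1e-12)
    expect_equal(netGrowth(0, q), q@psiMax)
  }
})

test_that("EC50 parameterisation reproduces the zMIC form on a dose grid", {
  for (q in randomParams(40, seed = 7)) {
    a <- q@zmic * 10^seq(-4, 4, length.out = 101)
    viaEC50 <- emax(q) * (a / ec50(q))^q@kappa /
      (1 + (a / ec50(q))^q@kappa)
    expect_equal(viaEC50, killRate(a, q), tolerance = 1e-12)
    # EC50 is the half-maximal-effect dose
    expect_equal(ec50(q), isoeffectiveConc(0.5, q), tolerance = 1e-12)
  }
})

test_that("isoeffective inversion: closed form, bisection oracle, round trip", {
  p <- PDParams(1, -5, 2, 1)
  expect_equal(isoeffectiveConc(0.5, p), sqrt(5), tolerance = 1e-12)

  bisect <- function(f, params, lo = 1e-12, hi = 1e12) {
    target <- f * emax(params)
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (killRate(mid, params) < target) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  expect_equal(isoeffectiveConc(0.5, p), bisect(0.5, p), tolerance = 1e-9)

  set.seed(3)
  for (q in randomParams(25, seed = 3)) {
    f <- runif(3, 0.02, 0.98)
    a <- isoeffectiveConc(f, q)
    expect_equal(killRate(a, q) / emax(q), f, tolerance = 1e-10)
    expect_equal(a, vapply(f, bisect, 0, params = q), tolerance = 1e-7)
    # the zero-growth effect level maps back to zMIC exactly
    expect_equal(isoeffectiveConc(q@psiMax / emax(q), q), q@zmic,
                 tolerance = 1e-12)
  }
  expect_error(isoeffectiveConc(1, p), "strictly in")
  expect_error(isoeffectiveConc(0, p), "strictly in")
})

test_that("kill curve is strictly increasing and steeper for larger kappa", {
  for (q in randomParams(25, seed = 9)) {
    # grid kept within +/-1.5 decades of zMIC: far beyond that the curve is
    # numerically flat at its plateaus and strict ordering is meaningless
    a <- q@zmic * 10^seq(-1.5, 1.5, length.out = 200)
    expect_true(all(diff(killRate(a, q)) > 0))
    expect_true(all(diff(netGrowth(a, q)) < 0))
  }
  # |d psi / d ln a| at zMIC grows with kappa, all else fixed
  slopeAtZmic <- function(k) {
    q <- PDParams(1.2, -8, k, 1)
    h <- 1e-6
    abs(netGrowth(exp(h), q) - netGrowth(exp(-h), q)) / (2 * h)
  }
  ks <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(vapply(ks, slopeAtZmic, 0)) > 0))
})

test_that("invalid parameter sets are rejected", {
  expect_error(PDParams(-1, -5, 2, 1), "psiMax")
  expect_error(PDParams(1, 0.5, 2, 1), "psiMin")
  expect_error(PDParams(1, -5, -2, 1), "kappa")
  expect_error(PDParams(1, -5, 2, 0), "zmic")
})

test_that("least-squares fit recovers generating parameters on clean rates", {
  doses <- c(100 * 2^-(0:9), 0)
  for (truth in list(PDParams(1.2, -8, 3, 1), PDParams(0.7, -3, 1.2, 2.3),
                     PDParams(2, -20, 5, 0.6))) {
    rates <- data.frame(concentration = doses, rate = netGrowth(doses, truth))
    fit <- fitPDLS(rates)
    expect_equal(fit@psiMax, truth@psiMax, tolerance = 1e-6)
    expect_equal(fit@psiMin, truth@psiMin, tolerance = 1e-6)
    expect_equal(fit@kappa, truth@kappa, tolerance = 1e-6)
    expect_equal(fit@zmic, truth@zmic, tolerance = 1e-6)
  }
})

test_that("least-squares fit refuses unidentifiable data, ignores duplication", {
  doses <- 2^-(0:6)
  p <- PDParams(1.2, -8, 3, 1e3)   # zMIC far above the sampled range
  rates <- data.frame(concentration = doses, rate = netGrowth(doses, p))
  expect_error(fitPDLS(rates), "sign change")

  truth <- PDParams(1.2, -8, 3, 1)
  doses <- c(100 * 2^-(0:9), 0)
  r1 <- data.frame(concentration = doses,
                   rate = netGrowth(doses, truth) + 0.01 * sin(seq_along(doses)))
  f1 <- fitPDLS(r1)
  f2 <- fitPDLS(rbind(r1, r1))   # every point duplicated: same weights ratio
  expect_equal(f2@psiMax, f1@psiMax, tolerance = 1e-8)
  expect_equal(f2@kappa, f1@kappa, tolerance = 1e-8)
  expect_equal(f2@zmic, f1@zmic, tolerance = 1e-8)
})

test_that("MCMC draws are bit-reproducible and concentrate on the LS fit", {
  truth <- PDParams(1.2, -8, 3, 1)
  doses <- c(100 * 2^-(0:9), 0)
  set.seed(21)
  rates <- data.frame(concentration = doses,
                      rate = netGrowth(doses, truth) + rnorm(11, 0, 0.05),
                      se = 0.05)
  cfg <- pdMCMCControl(chains = 2, warmup = 400, iter = 300)
  p1 <- quietFit(rates, cfg, seed = 5)
  p2 <- quietFit(rates, cfg, seed = 5)
  expect_identical(pdDraws(p1), pdDraws(p2))
  p3 <- quietFit(rates, cfg, seed = 6)
  expect_false(identical(pdDraws(p1), pdDraws(p3)))

  # near-noise-free data with tight plug-in SE: posterior hugs the LS fit
  rates2 <- data.frame(concentration = doses, rate = netGrowth(doses, truth),
                       se = 0.005)
  ls <- fitPDLS(rates2)
  post <- quietFit(rates2, pdMCMCControl(chains = 2, warmup = 1500,
                                         iter = 1500, sigmaMode = "se"),
                   seed = 2)
  med <- pointEstimate(post)
  expect_equal(med@psiMax, ls@psiMax, tolerance = 0.01)
  expect_equal(med@psiMin, ls@psiMin, tolerance = 0.01)
  expect_equal(med@kappa, ls@kappa, tolerance = 0.01)
  expect_equal(med@zmic, ls@zmic, tolerance = 0.01)

  d <- pdDiagnostics(post)
  expect_setequal(d$parameter, c("psi_max", "psi_min", "kappa", "zmic"))
  expect_true(all(is.finite(d$rhat)) && all(d$ess > 0))
  expect_true(all(pdDraws(post)[, "psi_max"] > 0))
  expect_true(all(pdDraws(post)[, "psi_min"] < 0))
})

test_that("degenerate posterior wrapper preserves the point parameters", {
  p <- PDParams(1, -5, 2, 1)
  post <- asPosterior(p, n = 200)
  expect_true(isConverged(post))
  expect_equal(pointEstimate(post)@kappa, 2)
  expect_true(all(pdDraws(post)[, "zmic"] == 1))
})
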
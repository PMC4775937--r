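# Shared fixtures: ground-truth parameter sets and scenario builders.
# Drugs share psi_max/psi_min and differ in kappa, matching the empirical
# pattern that the drug-free growth rate and the bactericidal plateau are
# common to all treatments while steepness and potency vary.

demoDrugs <- function() {
  list(A = PDParams(psiMax = 1.2, psiMin = -8, kappa = 3, zmic = 1),
       B = PDParams(psiMax = 1.2, psiMin = -8, kappa = 2, zmic = 1),
       C = PDParams(psiMax = 1.2, psiMin = -8, kappa = 4, zmic = 1))
}

demoMics <- c(A = 8, B = 16, C = 4)

noiseOff <- list(poisson = FALSE, sigma = 0)

# scenario with one 2-way additive, one 2-way synergistic (gamma = 2) and
# one 3-way additive mixture
demoScenario <- function(seed = 1L, gamma = c(AB = 1, AB2 = 2, ABC = 1),
                         noise = list(poisson = TRUE, sigma = 0.1),
                         replicates = 3L) {
  d <- demoDrugs()
  simScenario(
    drugs = d, mic = demoMics,
    mixtures = list(
      AB  = MixtureDesign(c("A", "B"), mic = demoMics[c("A", "B")]),
      AB2 = MixtureDesign(c("A", "B"), mic = demoMics[c("A", "B")]),
      ABC = MixtureDesign(c("A", "B", "C"), mic = demoMics)),
    gamma = gamma, noise = noise, replicates = replicates, seed = seed)
}

# reduced sampler budget for repetition loops; the default 4x(2000+2000)
# budget is exercised in the single-fit tests
fastMCMC <- function() pdMCMCControl(chains = 2L, warmup = 1000L, iter = 1000L)

quietFit <- function(rates, config = fastMCMC(), seed = 1L)
  suppressWarnings(fitPDMCMC(rates, config = config, seed = seed))

# random valid PDParams for property-style loops
randomParams <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    PDParams(psiMax = runif(1, 0.2, 2.5),
             psiMin = -runif(1, 0.5, 40),
             kappa = exp(runif(1, log(0.3), log(8))),
             zmic = exp(runif(1, log(0.05), log(20)))))
}

# sham design: one drug "combined" with itself under two labels; the
# mixture curve is the drug's own re-expressed on the stock-fraction axis
shamCombo <- function(params, ratio = NULL, stockMultiplier = 100) {
  design <- MixtureDesign(c("X1", "X2"), mic = c(8, 8), ratio = ratio,
                          stockMultiplier = stockMultiplier)
  list(design = design,
       singles = list(X1 = params, X2 = params),
       combo = PDParams(params@psiMax, params@psiMin, params@kappa,
                        params@zmic / stockMultiplier))
}
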
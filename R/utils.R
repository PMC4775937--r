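`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a character scalar; used for config manifests and
# for deriving deterministic per-(treatment, replicate) RNG sub-streams.
# Arithmetic kept in double precision (exact for < 2^53) with explicit
# mod-2^32 reduction after each multiply.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# bitwXor on doubles in [0, 2^32)
bitwXor2 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# Deterministic sub-seed in [0, 2^31 - 2] from a top-level seed and a key
# string; independent treatments/replicates get independent streams and
# adding new treatments leaves existing streams untouched.
subSeed <- function(seed, key) {
  as.integer((fnv1a32(paste0(seed, "\x1f", key))) %% 2147483647)
}

configHash <- function(x) {
  h <- fnv1a32(paste(deparse(x), collapse = "\n"))
  sprintf("%08x", as.integer(h %% 2147483648))
}

# split-Rhat (Gelman et al.): chains split in half, between/within variance
rhatSplit <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    m <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(m)], ch[(n - m + 1L):n]))
  }
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial monotone positive sequence,
# averaged chain autocorrelations.
essBasic <- function(chains) {
  n <- min(lengths(chains))
  chains <- lapply(chains, function(ch) ch[seq_len(n)])
  m <- length(chains)
  W <- mean(vapply(chains, stats::var, 0))
  if (W <= 0) return(m * n)
  maxLag <- min(n - 1L, 250L)
  acfs <- vapply(chains, function(ch)
    stats::acf(ch, lag.max = maxLag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1], numeric(maxLag + 1L))
  rho <- rowMeans(acfs)
  # sum paired autocorrelations while positive
  s <- 0
  t <- 1L
  while (t + 1L <= maxLag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  max(1, min(ess, m * n))
}
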
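#' @include AllClasses.R
NULL

#' Estimate the net growth rate from one time-kill series
#'
#' Fits an ordinary least-squares regression of ln(CFU) on time, pooling
#' all replicates of one treatment x concentration, starting at the first
#' measurement, and reports the slope converted to h^-1. Counts at or below
#' the plating detection limit are left-censored: observations are used up
#' to and including the FIRST censored time point (at the detection-limit
#' value), later censored points are discarded — dropping them entirely
#' would bias fast-kill rates toward zero, while the retained floor value
#' still understates the true kill rate, which the `censored_used` flag
#' propagates downstream. When only censored observations remain after the
#' baseline, the slope through the first censored point is only an upper
#' bound on the true (more negative) rate; it is returned with
#' `bound = TRUE` and excluded from Hill fitting by default.
#'
#' @param records data.frame for a single treatment x concentration with
#'   columns `time_min`, `cfu`, `censored` (logical), and optionally
#'   `treatment_id`, `concentration`, `replicate`.
#' @return One-row data.frame: `treatment_id`, `concentration`, `rate`
#'   (h^-1), `se` (h^-1), `n_points`, `censored_used`, `bound`.
#' @examples
#' tk <- data.frame(time_min = c(0, 20, 40, 60),
#'                  cfu = 2e6 * exp(-3 * c(0, 20, 40, 60) / 60),
#'                  censored = FALSE)
#' estimateRate(tk)   # rate = -3 h^-1
#' @export
estimateRate <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("time_min", "cfu", "censored") %in% names(records)))
  if (any(records$cfu <= 0 & !records$censored))
    stop(errorCondition(
      "zero or negative CFU without a censored flag: malformed input",
      class = "ampsynergy_malformed"))
  tid <- as.character(records$treatment_id[1] %||% NA_character_)
  conc <- as.numeric(records$concentration[1] %||% NA_real_)

  times <- sort(unique(records$time_min))
  # a time point counts as censored when every replicate at it is censored
  censTime <- vapply(times, function(tt)
    all(records$censored[records$time_min == tt]), logical(1))
  firstCens <- which(censTime)[1]
  keepTimes <- if (is.na(firstCens)) times else times[seq_len(firstCens)]
  censKeep <- if (is.na(firstCens)) -1 else times[firstCens]
  use <- records$time_min %in% keepTimes &
    (!records$censored | records$time_min == censKeep)
  dat <- records[use, , drop = FALSE]
  if (length(unique(dat$time_min)) < 2L)
    stop("fewer than 2 usable time points (complete kill faster than the ",
         "sampling resolution); no rate can be estimated")

  fit <- stats::lm(log(cfu) ~ time_min, data = dat)
  rate <- unname(stats::coef(fit)["time_min"]) * 60  # per-minute -> h^-1
  # slope SE computed directly (summary.lm warns on exact noise-free fits)
  n <- nrow(dat)
  sxx <- sum((dat$time_min - mean(dat$time_min))^2)
  s2 <- sum(stats::residuals(fit)^2) / max(n - 2L, 1L)
  se <- sqrt(s2 / sxx) * 60
  if (!is.finite(se)) se <- 0
  censUsed <- any(dat$censored)
  # all post-baseline usable points censored => only a bound on the rate
  postBase <- dat$time_min > min(dat$time_min)
  bound <- censUsed && all(dat$censored[postBase])
  data.frame(treatment_id = tid, concentration = conc, rate = rate,
             se = se, n_points = nrow(dat), censored_used = censUsed,
             bound = bound, row.names = NULL)
}

#' Estimate net growth rates for every treatment x concentration
#'
#' Applies [estimateRate()] to each (treatment_id, concentration) group of
#' a tidy kill-curve table. Groups that cannot yield a rate (fewer than two
#' usable time points) are dropped with a warning naming them. Output rows
#' are ordered by treatment then descending concentration.
#'
#' @param dataset tidy kill-curve data.frame (see [simulateScenario()] /
#'   [readKillCurves()]): columns `treatment_id`, `concentration`,
#'   `replicate`, `time_min`, `cfu`, `censored`.
#' @return data.frame of rate estimates, one row per group.
#' @export
estimateRates <- function(dataset) {
  dataset <- as.data.frame(dataset)
  need <- c("treatment_id", "concentration", "replicate", "time_min",
            "cfu", "censored")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(dataset)) stop("empty dataset")
  key <- paste(dataset$treatment_id, dataset$concentration,
               dataset$replicate, dataset$time_min, sep = "\x1f")
  if (anyDuplicated(key))
    stop("duplicate (treatment, concentration, replicate, time) records")

  groups <- unique(dataset[c("treatment_id", "concentration")])
  groups <- groups[order(groups$treatment_id, -groups$concentration), ,
                   drop = FALSE]
  out <- vector("list", nrow(groups))
  dropped <- character()
  for (i in seq_len(nrow(groups))) {
    g <- dataset[dataset$treatment_id == groups$treatment_id[i] &
                 dataset$concentration == groups$concentration[i], ,
                 drop = FALSE]
    out[[i]] <- tryCatch(estimateRate(g), error = function(e) {
      if (inherits(e, "ampsynergy_malformed")) stop(e)  # data error: rethrow
      dropped <<- c(dropped, sprintf("%s @ %g: %s", groups$treatment_id[i],
                                     groups$concentration[i],
                                     conditionMessage(e)))
      NULL
    })
  }
  if (length(dropped))
    warning("rate estimation skipped for ", length(dropped), " group(s):\n  ",
            paste(dropped, collapse = "\n  "), call. = FALSE)
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) stop("no group yielded a usable rate")
  rownames(res) <- NULL
  res
}
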
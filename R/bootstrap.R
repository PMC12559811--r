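#' Founder-resampling bootstrap intervals for life-table parameters
#'
#' Percentile confidence intervals for R0, T, r or mean lifespan of each
#' cohort, obtained by resampling founding females within the cohort.
#'
#' The census aggregates founders, so founder records are first
#' reconstructed from it. Death days follow from the daily survivor drops.
#' Births are attributed to founders by a multinomial split among the
#' females alive each day: for independent per-female Poisson fecundity the
#' per-founder counts conditional on the daily total are exactly multinomial
#' with equal weights, so the reconstruction draws from the correct
#' conditional distribution (the split is seeded and deterministic). Because
#' the life-table identities reduce to `R0 = sum(b_x)/n0` and
#' `T = sum(x b_x)/sum(b_x)`, the point estimates are independent of the
#' split; only the resampling spread uses it. Each bootstrap replicate
#' resamples whole founders (death day plus her reconstructed birth record)
#' and recomputes the metric. Resamples with `R0* = 0` leave T and r
#' undefined; if more than half the resamples are undefined the interval is
#' computed from the defined ones and flagged with a warning.
#'
#' @param census A census table (one or more cohorts, each with at least two
#'   founders).
#' @param metric `"R0"`, `"T"`, `"r"` or `"lifespan"`.
#' @param B Number of bootstrap resamples (at least 200).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param conf Confidence level.
#' @return A tibble, one row per cohort: `cohort_id`, `estimate`,
#'   `conf.low`, `conf.high`, `B`, `prop_defined`, `flagged`.
#' @export
bootstrap_ci <- function(census, metric = c("R0", "T", "r", "lifespan"),
                         B = 1000, seed, conf = 0.95) {
  metric <- match.arg(metric)
  if (missing(seed)) stop_validation("A seed is required for the bootstrap.")
  if (B < 200) stop_validation("Use at least B = 200 bootstrap resamples.")
  sched <- life_schedules(census)
  withr::local_seed(substream_seed(seed, "bootstrap"))
  alpha <- (1 - conf) / 2

  rows <- map(unique(sched$cohort_id), function(id) {
    cc <- sched[sched$cohort_id == id, ]
    n0 <- cc$survivors[1]
    if (n0 < 2) {
      stop_validation(paste0("cohort ", id, ": bootstrap needs at least 2 founders."))
    }
    deaths <- -diff(cc$survivors)
    last_day <- cc$day[nrow(cc)]
    last_n <- cc$survivors[nrow(cc)]
    D <- c(rep(cc$day[-1], times = deaths), rep(last_day, times = last_n))
    # survivors at the final census are still alive on the final day
    alive_through <- D + c(rep(0L, length(D) - last_n), rep(1L, last_n))

    # multinomial split of each day's neonates among the founders alive then
    Fi <- numeric(n0)
    Gi <- numeric(n0)
    for (i in which(cc$neonates > 0)) {
      day_i <- cc$day[i]
      alive <- which(alive_through > day_i)
      picks <- alive[sample.int(length(alive), cc$neonates[i], replace = TRUE)]
      tab <- tabulate(picks, nbins = n0)
      Fi <- Fi + tab
      Gi <- Gi + tab * day_i
    }

    stat <- function(fbar, gbar, dbar) {
      switch(metric,
        R0 = fbar,
        T = if (fbar > 0) gbar / fbar else NA_real_,
        r = if (fbar > 0 && gbar > 0) log(fbar) / (gbar / fbar) else NA_real_,
        lifespan = dbar
      )
    }
    est <- stat(mean(Fi), mean(Gi), mean(D))

    pick <- matrix(sample.int(n0, n0 * B, replace = TRUE), nrow = n0)
    fbar <- colMeans(matrix(Fi[pick], nrow = n0))
    gbar <- colMeans(matrix(Gi[pick], nrow = n0))
    dbar <- colMeans(matrix(D[pick], nrow = n0))
    boots <- map_dbl(seq_len(B), function(j) stat(fbar[j], gbar[j], dbar[j]))

    defined <- sum(!is.na(boots))
    flagged <- defined < B / 2
    if (flagged) {
      warn(paste0(
        "cohort ", id, ": `", metric, "` undefined in ",
        B - defined, "/", B, " resamples; interval uses defined resamples only."
      ))
    }
    qs <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    tibble(
      cohort_id = id, estimate = est,
      conf.low = qs[1], conf.high = qs[2],
      B = B, prop_defined = defined / B, flagged = flagged
    )
  })
  list_rbind(rows)
}
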
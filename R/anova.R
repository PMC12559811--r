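#' Two-way ANOVA on exposure survival proportions
#'
#' Factorial analysis of the proportion of rotifers alive 48 h after UVB
#' exposure, with UVB treatment and generation as crossed factors. Sums of
#' squares are sequential (Type I): the residual sum of squares of nested
#' least-squares fits (intercept, +treatment, +generation, +interaction) is
#' computed by QR projection and differenced. For balanced designs (the
#' study's 4 treatments x 3 generations x 16 replicates) sequential and
#' marginal decompositions coincide. F statistics use the residual mean
#' square; p-values come from the F distribution.
#'
#' The response is the per-replicate proportion `n_alive / n_exposed`
#' (optionally arcsine-square-root transformed, off by default).
#'
#' @param outcomes Exposure outcomes (see [read_exposure()] or
#'   [simulate_exposure()]) with columns `generation`, `treatment`,
#'   `n_exposed`, `n_alive` (or a precomputed `proportion`).
#' @param transform `"none"` (default) or `"asinsqrt"`.
#' @return An object of class `rl_anova` with a [tidy()] method returning
#'   the ANOVA table (`term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`) and a [glance()] method (N, total SS, residual df). If all
#'   observations are equal, all factor SS are zero and F is undefined; the
#'   statistics are returned as `NA` and `degenerate` is set.
#' @examples
#' set.seed(1)
#' x <- expand.grid(
#'   generation = c("F0", "F2", "F4"), treatment = uvb_treatments(),
#'   rep = 1:4
#' )
#' x$n_exposed <- 50
#' x$n_alive <- rbinom(nrow(x), 50, 0.8)
#' tidy(two_way_anova(x))
#' @export
two_way_anova <- function(outcomes, transform = c("none", "asinsqrt")) {
  transform <- match.arg(transform)
  if (!"proportion" %in% names(outcomes)) {
    outcomes$proportion <- outcomes$n_alive / outcomes$n_exposed
  }
  d <- tibble(
    y = outcomes$proportion,
    A = factor(as.character(outcomes$treatment)),
    B = factor(as.character(outcomes$generation))
  )
  if (any(is.na(d$y))) stop_validation("Survival proportions contain NA.")
  tab_n <- table(d$A, d$B)
  if (any(tab_n < 1)) {
    stop_validation("Every treatment x generation cell needs at least one observation.")
  }
  n <- nrow(d)
  a <- nlevels(d$A)
  b <- nlevels(d$B)
  df_res <- n - a * b
  if (df_res <= 0) {
    stop_validation("No residual degrees of freedom (need replication within cells).")
  }
  y <- if (transform == "asinsqrt") asin(sqrt(d$y)) else d$y

  rss <- function(formula) {
    X <- stats::model.matrix(formula, data = d)
    q <- qr(X)
    sum((y - qr.fitted(q, y))^2)
  }
  rss0 <- rss(~1)
  rss_a <- rss(~A)
  rss_ab <- rss(~ A + B)
  rss_full <- rss(~ A * B)

  # sequential RSS differences are mathematically non-negative; clamp the
  # floating-point noise so constant responses give exact zeros
  eps <- 1e-10 * (sum(y^2) + 1)
  ss <- pmax(0, c(rss0 - rss_a, rss_a - rss_ab, rss_ab - rss_full))
  ss[ss < eps] <- 0
  rss_full <- if (rss_full < eps) 0 else rss_full
  df <- c(a - 1, b - 1, (a - 1) * (b - 1))
  ms <- ss / df
  ms_res <- rss_full / df_res
  degenerate <- rss0 < eps || ms_res == 0
  f <- if (degenerate) rep(NA_real_, 3) else ms / ms_res
  p <- if (degenerate) rep(NA_real_, 3) else pf(f, df, df_res, lower.tail = FALSE)

  table <- tibble(
    term = c("UVB intensity", "Generation", "UVB intensity:Generation", "Residuals"),
    df = c(df, df_res),
    sumsq = c(ss, rss_full),
    meansq = c(ms, ms_res),
    statistic = c(f, NA_real_),
    p.value = c(p, NA_real_)
  )
  structure(
    list(
      table = table, data = d, y = y, transform = transform,
      ms_res = ms_res, df_res = df_res, total_ss = rss0, n = n,
      degenerate = degenerate
    ),
    class = "rl_anova"
  )
}

#' @export
tidy.rl_anova <- function(x, ...) x$table

#' @export
glance.rl_anova <- function(x, ...) {
  tibble(
    nobs = x$n,
    total_ss = x$total_ss,
    df.residual = x$df_res,
    ms.residual = x$ms_res,
    r.squared = if (x$total_ss > 0) 1 - x$table$sumsq[4] / x$total_ss else NA_real_,
    degenerate = x$degenerate
  )
}

#' @export
print.rl_anova <- function(x, ...) {
  cat("Two-way ANOVA on survival proportions (sequential SS)\n")
  print(x$table)
  invisible(x)
}

#' Tukey honest significant differences
#'
#' All pairwise comparisons between levels of one ANOVA factor (or between
#' the crossed cells), using the studentized-range distribution with the
#' residual mean square of the fitted two-way ANOVA. Unequal group sizes use
#' the Tukey-Kramer standard error.
#'
#' @param fit An `rl_anova` object.
#' @param term `"treatment"`, `"generation"`, or `"cell"` (the crossed
#'   treatment:generation groups).
#' @param conf.level Confidence level for the simultaneous intervals.
#' @return A tibble: `contrast`, `estimate`, `conf.low`, `conf.high`,
#'   `adj.p.value`.
#' @export
tukey_hsd <- function(fit, term = c("treatment", "generation", "cell"),
                      conf.level = 0.95) {
  stopifnot(inherits(fit, "rl_anova"))
  term <- match.arg(term)
  if (fit$degenerate) {
    stop_numerical("Tukey HSD is undefined: the ANOVA residual mean square is zero.")
  }
  g <- switch(term,
    treatment = fit$data$A,
    generation = fit$data$B,
    cell = interaction(fit$data$A, fit$data$B, sep = ":", drop = TRUE)
  )
  y <- fit$y
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  k <- length(means)
  pairs <- utils::combn(names(means), 2)
  est <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(fit$ms_res / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  qcrit <- qtukey(conf.level, k, fit$df_res)
  tibble(
    contrast = paste(pairs[2, ], "-", pairs[1, ]),
    estimate = as.numeric(est),
    conf.low = as.numeric(est - qcrit * se),
    conf.high = as.numeric(est + qcrit * se),
    adj.p.value = as.numeric(ptukey(abs(est) / se, k, fit$df_res, lower.tail = FALSE))
  )
}
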
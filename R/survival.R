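#' Kaplan-Meier product-limit survival estimate
#'
#' Nonparametric survival curve for founder lifespans with optional right
#' censoring (individuals lost at weekly plate transfers, or alive at the end
#' of observation). At each distinct event time t with d deaths out of n at
#' risk the curve multiplies by (1 - d/n); S(0) = 1. With no censoring the
#' estimate equals the empirical survival function exactly.
#'
#' @param time Positive lifespans (days).
#' @param event 1 = death observed, 0 = right-censored (default: all deaths).
#' @return An object of class `rl_km`. [tidy()] returns the step table
#'   (`time`, `n.risk`, `n.event`, `n.censor`, `estimate`); [glance()]
#'   returns n, events and the restricted median; [autoplot()] draws the step
#'   curve.
#' @examples
#' fit <- kaplan_meier(c(1, 2), c(1, 1))
#' tidy(fit) # S = 0.5 after day 1, 0 after day 2
#' @export
kaplan_meier <- function(time, event = rep(1L, length(time))) {
  if (length(time) == 0) stop_validation("Kaplan-Meier needs at least one observation.")
  if (length(event) != length(time)) {
    stop_validation("`event` must have the same length as `time`.")
  }
  if (any(is.na(time)) || any(time <= 0)) {
    stop_validation("Lifespans must be positive and non-missing.")
  }
  if (!all(event %in% c(0, 1))) stop_validation("`event` must be 0/1.")
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  times <- sort(unique(time))
  n_risk <- map_dbl(times, function(t) sum(time >= t))
  n_event <- map_dbl(times, function(t) sum(time == t & event == 1))
  n_censor <- map_dbl(times, function(t) sum(time == t & event == 0))
  estimate <- cumprod(1 - n_event / n_risk)
  steps <- tibble(
    time = times, n.risk = n_risk, n.event = n_event,
    n.censor = n_censor, estimate = estimate
  )
  structure(
    list(steps = steps, n = length(time), events = sum(event)),
    class = "rl_km"
  )
}

#' @export
tidy.rl_km <- function(x, ...) x$steps

#' @export
glance.rl_km <- function(x, ...) {
  med <- with(x$steps, if (any(estimate <= 0.5)) time[which(estimate <= 0.5)[1]] else NA_real_)
  tibble(nobs = x$n, events = x$events, median = med)
}

#' @export
print.rl_km <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "individuals,", x$events, "events\n")
  print(x$steps)
  invisible(x)
}

#' @export
autoplot.rl_km <- function(object, ...) {
  d <- object$steps
  d0 <- bind_rows(tibble(time = 0, estimate = 1), d[, c("time", "estimate")])
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Age (days)", y = "Survival probability",
      title = "Kaplan-Meier survivorship"
    ) +
    ggplot2::ylim(0, 1)
}

#' Two-sample log-rank test
#'
#' Compares the survival experience of two groups of lifespans (with
#' optional right censoring) by the observed-minus-expected event counts at
#' each distinct death time, with the hypergeometric variance. The statistic
#' is chi-squared with 1 df under the null of equal hazards.
#'
#' @param time Lifespans (days).
#' @param group A two-level grouping vector.
#' @param event 1 = death, 0 = censored (default: all deaths).
#' @return An object of class `rl_logrank` with `statistic`, `p.value`,
#'   observed and expected counts; [tidy()]/[glance()] return them as a
#'   one-row tibble. A group with zero events is allowed (the statistic is
#'   still defined) but triggers a warning.
#' @export
logrank_test <- function(time, group, event = rep(1L, length(time))) {
  g <- factor(group)
  if (nlevels(g) != 2) stop_validation("The log-rank test requires exactly two groups.")
  if (length(time) != length(g) || length(event) != length(time)) {
    stop_validation("`time`, `group` and `event` must have equal lengths.")
  }
  lev <- levels(g)
  ev_by_group <- tapply(event, g, sum)
  if (any(ev_by_group == 0)) {
    warn(paste0(
      "Group(s) with zero observed events: ",
      toString(lev[ev_by_group == 0])
    ))
  }
  times <- sort(unique(time[event == 1]))
  O1 <- 0
  E1 <- 0
  V <- 0
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g == lev[1])
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & g == lev[1])
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  structure(
    list(
      statistic = stat, df = 1L,
      p.value = pchisq(stat, df = 1, lower.tail = FALSE),
      observed = c(O1, sum(event) - O1),
      expected = c(E1, sum(event) - E1),
      groups = lev
    ),
    class = "rl_logrank"
  )
}

#' @export
tidy.rl_logrank <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    observed1 = x$observed[1], expected1 = x$expected[1]
  )
}

#' @export
glance.rl_logrank <- function(x, ...) tidy(x)

#' @export
print.rl_logrank <- function(x, ...) {
  cat(
    "Log-rank test (", paste(x$groups, collapse = " vs "), "): chi-sq = ",
    format(x$statistic, digits = 4), ", df = 1, p = ",
    format(x$p.value, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}
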
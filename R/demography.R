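#' Validate a daily cohort census table
#'
#' A census table is tidy/long: one row per cohort per day, with columns
#' `cohort_id`, `day`, `survivors`, `neonates` (plus any metadata such as
#' `generation`, `treatment`, `feeding`, `replicate_id`, and optionally
#' `censored`). Validation enforces the structural invariants the life-table
#' equations assume:
#'
#' * days start at 0 (hatch) and increase by exactly 1;
#' * counts are non-negative integers and `survivors` is non-increasing;
#' * no neonates are recorded on a day with zero survivors;
#' * the founding count `n0` (survivors at day 0) is positive;
#' * when a `censored` column is present, censored exits on a day cannot
#'   exceed the drop in survivors on that day.
#'
#' @param census A data frame of daily census rows.
#' @return The input, invisibly, as a tibble sorted by cohort and day.
#'   Violations raise a classed validation error naming the cohort and the
#'   offending day(s).
#' @examples
#' census <- tibble::tibble(
#'   cohort_id = "c1", day = 0:2, survivors = c(9, 8, 8), neonates = c(0, 3, 5)
#' )
#' validate_census(census)
#' @export
validate_census <- function(census) {
  census <- as_tibble(census)
  need <- c("cohort_id", "day", "survivors", "neonates")
  missing_cols <- setdiff(need, names(census))
  if (length(missing_cols) > 0) {
    stop_validation(paste0(
      "Census table is missing required column(s): ", toString(missing_cols)
    ))
  }
  for (col in c("day", "survivors", "neonates")) {
    bad <- which(!is_count(census[[col]]))
    if (length(bad) > 0) {
      stop_validation(paste0(
        "Column `", col, "` must hold non-negative integers; bad row(s): ",
        toString(head(bad, 10))
      ))
    }
  }
  if ("censored" %in% names(census)) {
    bad <- which(!is_count(census$censored))
    if (length(bad) > 0) {
      stop_validation(paste0(
        "Column `censored` must hold non-negative integers; bad row(s): ",
        toString(head(bad, 10))
      ))
    }
  }
  census <- arrange(census, .data$cohort_id, .data$day)

  problems <- character()
  for (id in unique(census$cohort_id)) {
    cc <- census[census$cohort_id == id, ]
    if (anyDuplicated(cc$day)) {
      problems <- c(problems, paste0(
        "cohort ", id, ": duplicated day(s) ",
        toString(unique(cc$day[duplicated(cc$day)]))
      ))
      next
    }
    if (cc$day[1] != 0 || any(diff(cc$day) != 1)) {
      gap <- if (cc$day[1] != 0) 0 else cc$day[which(diff(cc$day) != 1)[1] + 1]
      problems <- c(problems, paste0(
        "cohort ", id, ": days must run 0, 1, 2, ... without gaps (problem at day ",
        gap, ")"
      ))
      next
    }
    if (cc$survivors[1] == 0) {
      abort(paste0("cohort ", id, ": founding count n0 is zero"),
        class = c("rl_error_invalid_cohort", "rl_error")
      )
    }
    rises <- which(diff(cc$survivors) > 0)
    if (length(rises) > 0) {
      problems <- c(problems, paste0(
        "cohort ", id, ": survivors increase on day ",
        toString(cc$day[rises + 1])
      ))
    }
    ghost <- which(cc$survivors == 0 & cc$neonates > 0)
    if (length(ghost) > 0) {
      problems <- c(problems, paste0(
        "cohort ", id, ": neonates recorded with zero survivors on day ",
        toString(cc$day[ghost])
      ))
    }
    if ("censored" %in% names(cc) && nrow(cc) > 1) {
      drop <- -diff(cc$survivors)
      over <- which(cc$censored[-1] > drop)
      if (length(over) > 0) {
        problems <- c(problems, paste0(
          "cohort ", id, ": censored exits exceed the survivor drop on day ",
          toString(cc$day[over + 1])
        ))
      }
    }
  }
  if (length(problems) > 0) {
    stop_validation(paste0(
      "Census validation failed:\n", paste0("- ", problems, collapse = "\n")
    ))
  }
  invisible(census)
}

#' Age-specific survivorship and fecundity schedules
#'
#' `compute_survivorship()` adds the survivorship column
#' `l_x = n_x / n0` (fraction of founders alive at age x days);
#' `compute_fecundity()` adds per-capita fecundity
#' `m_x = b_x / n_x` (neonates per surviving female per day), defined as 0 on
#' days with no survivors (such days contribute nothing to R0 or T).
#' `life_schedules()` returns both together.
#'
#' @param census A validated census table (see [validate_census()]).
#' @return A tibble with one row per cohort-day: `cohort_id`, `day`,
#'   `survivors`, `neonates`, plus `l_x` and/or `m_x`.
#' @examples
#' census <- tibble::tibble(
#'   cohort_id = "c1", day = 0:2, survivors = c(10, 5, 0), neonates = c(0, 10, 0)
#' )
#' life_schedules(census)
#' @export
compute_survivorship <- function(census) {
  census <- validate_census(census)
  census |>
    group_by(.data$cohort_id) |>
    mutate(l_x = .data$survivors / .data$survivors[1]) |>
    ungroup()
}

#' @rdname compute_survivorship
#' @export
compute_fecundity <- function(census) {
  census <- validate_census(census)
  census |>
    mutate(m_x = ifelse(.data$survivors > 0, .data$neonates / .data$survivors, 0))
}

#' @rdname compute_survivorship
#' @export
life_schedules <- function(census) {
  out <- compute_survivorship(census)
  out <- mutate(out, m_x = ifelse(.data$survivors > 0, .data$neonates / .data$survivors, 0))
  class(out) <- c("rl_schedules", class(out))
  out
}

#' Life-table summary statistics
#'
#' Scalar life-history parameters from survivorship/fecundity schedules:
#'
#' * `net_reproductive_rate()`: \eqn{R_0 = \sum_x l_x m_x}, the expected
#'   lifetime offspring per founding female;
#' * `generation_time()`: \eqn{T = \sum_x x\, l_x m_x / R_0}, the mean age of
#'   mothers at offspring production (days); undefined when \eqn{R_0 = 0};
#' * `intrinsic_rate_approx()`: \eqn{r \approx \ln(R_0)/T} (per day), the
#'   standard life-table approximation; negative whenever \eqn{R_0 < 1};
#' * `intrinsic_rate_exact()`: the unique root of the Euler-Lotka equation
#'   \eqn{\sum_x e^{-rx} l_x m_x = 1}, found by bracketed root-finding. The
#'   two coincide exactly when all reproduction occurs at a single age.
#'
#' @param x Integer ages (days since hatch).
#' @param lx Survivorship at each age (l_0 = 1, non-increasing, in `[0, 1]`).
#' @param mx Per-capita fecundity at each age (non-negative).
#' @param R0 Net reproductive rate.
#' @param T Generation time in days.
#' @param tol Absolute tolerance on the Euler-Lotka residual.
#' @return A scalar. `generation_time()` and the rate functions return `NA`
#'   with a warning-free contract handled by [lifetable()]'s flags; calling
#'   them directly with `R0 = 0` raises an undefined-parameter error.
#' @examples
#' # reproduction only at age 5: R0 = 4, T = 5, r = log(4)/5 exactly
#' lx <- rep(1, 6); mx <- c(0, 0, 0, 0, 0, 4)
#' net_reproductive_rate(lx, mx)
#' generation_time(0:5, lx, mx)
#' intrinsic_rate_exact(0:5, lx, mx)
#' @export
net_reproductive_rate <- function(lx, mx) {
  check_schedule_vectors(lx, mx)
  sum(lx * mx)
}

#' @rdname net_reproductive_rate
#' @export
generation_time <- function(x, lx, mx) {
  check_schedule_vectors(lx, mx, x)
  R0 <- sum(lx * mx)
  if (R0 == 0) {
    abort("Generation time is undefined when R0 = 0 (no reproduction).",
      class = c("rl_error_undefined", "rl_error")
    )
  }
  sum(x * lx * mx) / R0
}

#' @rdname net_reproductive_rate
#' @export
intrinsic_rate_approx <- function(R0, T) {
  if (any(R0 < 0, na.rm = TRUE)) {
    stop_validation("R0 must be non-negative.")
  }
  if (any(R0 == 0, na.rm = TRUE)) {
    abort("Intrinsic rate is undefined when R0 = 0.",
      class = c("rl_error_undefined", "rl_error")
    )
  }
  log(R0) / T
}

#' @rdname net_reproductive_rate
#' @export
intrinsic_rate_exact <- function(x, lx, mx, tol = 1e-10) {
  check_schedule_vectors(lx, mx, x)
  phi <- lx * mx
  if (sum(phi) == 0) {
    abort("Euler-Lotka rate is undefined when no l_x * m_x term is positive.",
      class = c("rl_error_undefined", "rl_error")
    )
  }
  f <- function(r) sum(exp(-r * x) * phi) - 1
  lo <- -2
  hi <- 2
  expand <- 0
  while (f(lo) < 0 && expand < 60) {
    lo <- lo * 2
    expand <- expand + 1
  }
  expand <- 0
  while (f(hi) > 0 && expand < 60) {
    hi <- hi * 2
    expand <- expand + 1
  }
  # f is strictly decreasing in r, so a sign change must exist in [lo, hi]
  if (f(lo) < 0 || f(hi) > 0) {
    stop_numerical("Euler-Lotka solver failed to bracket a root.")
  }
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # polish by bisection until the residual meets the requested tolerance
  a <- root - 1e-6
  b <- root + 1e-6
  if (f(a) < 0) a <- lo
  if (f(b) > 0) b <- hi
  it <- 0
  while (abs(f(root)) > tol && it < 200) {
    if (f(root) > 0) a <- root else b <- root
    root <- (a + b) / 2
    it <- it + 1
  }
  if (abs(f(root)) > tol) {
    stop_numerical("Euler-Lotka solver did not converge to the requested tolerance.")
  }
  root
}

check_schedule_vectors <- function(lx, mx, x = NULL) {
  if (length(lx) != length(mx)) {
    stop_validation("l_x and m_x must have the same length.")
  }
  if (!is.null(x) && length(x) != length(lx)) {
    stop_validation("ages x must have the same length as the schedules.")
  }
  if (any(lx < 0 | lx > 1)) stop_validation("l_x values must lie in [0, 1].")
  if (length(lx) > 0 && abs(lx[1] - 1) > 1e-12) {
    stop_validation("l_x must start at 1 (l_0 = 1).")
  }
  if (any(diff(lx) > 1e-12)) stop_validation("l_x must be non-increasing.")
  if (any(mx < 0)) stop_validation("m_x values must be non-negative.")
  invisible(TRUE)
}

#' Full life-table analysis of census cohorts
#'
#' Composes the schedule and scalar computations for every cohort in a census
#' table: survivorship and fecundity schedules, net reproductive rate `R0`,
#' generation time `T`, the approximate intrinsic rate `r_approx = ln(R0)/T`,
#' the exact Euler-Lotka rate `r_exact`, and the cohort mean lifespan.
#'
#' A founder's death day is the first census day on which it is no longer
#' counted; cohort mean lifespan is the mean of founder death days (survivors
#' at the final census, if any, enter at the final day and set `truncated`).
#' When `R0 = 0` the parameters `T`, `r_approx` and `r_exact` are undefined:
#' they are returned as `NA` with `r_defined = FALSE`, never as silent
#' numbers. `negative_growth` flags cohorts with `R0 < 1` (for which both
#' rates are legitimately negative).
#'
#' @param census A census table (validated internally); metadata columns
#'   `generation`, `treatment`, `feeding`, `replicate_id` are carried through
#'   when present.
#' @return A tibble with one row per cohort: metadata, `n0`, `lifespan`,
#'   `R0`, `T`, `r_approx`, `r_exact`, `r_defined`, `negative_growth`,
#'   `truncated`.
#' @examples
#' census <- tibble::tibble(
#'   cohort_id = "c1", day = 0:6,
#'   survivors = c(10, 10, 10, 10, 10, 10, 0),
#'   neonates = c(0, 0, 0, 0, 0, 40, 0)
#' )
#' lifetable(census) # R0 = 4, T = 5, r = log(4)/5
#' @export
lifetable <- function(census) {
  sched <- life_schedules(census)
  meta_cols <- intersect(
    c("generation", "treatment", "feeding", "replicate_id"),
    names(sched)
  )
  split_ids <- unique(sched$cohort_id)
  rows <- map(split_ids, function(id) {
    cc <- sched[sched$cohort_id == id, ]
    n0 <- cc$survivors[1]
    R0 <- sum(cc$l_x * cc$m_x)
    defined <- R0 > 0
    T <- if (defined) sum(cc$day * cc$l_x * cc$m_x) / R0 else NA_real_
    r_approx <- if (defined) log(R0) / T else NA_real_
    r_exact <- if (defined) {
      intrinsic_rate_exact(cc$day, cc$l_x, cc$m_x)
    } else {
      NA_real_
    }
    # deaths on day x are the survivor drop from day x-1 to x
    deaths <- -diff(cc$survivors)
    last_n <- cc$survivors[nrow(cc)]
    life_sum <- sum(cc$day[-1] * deaths) + last_n * cc$day[nrow(cc)]
    meta <- cc[1, meta_cols, drop = FALSE]
    bind_cols(
      tibble(cohort_id = id),
      meta,
      tibble(
        n0 = n0,
        lifespan = life_sum / n0,
        R0 = R0,
        T = T,
        r_approx = r_approx,
        r_exact = r_exact,
        r_defined = defined,
        negative_growth = R0 < 1,
        truncated = last_n > 0
      )
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("rl_lifetable", class(out))
  out
}

#' Founder-level event times from a census table
#'
#' Expands a cohort census into one row per founding female with her death
#' (or censoring) day, for Kaplan-Meier and log-rank analyses. Deaths on day
#' x are survivor drops not explained by the optional `censored` column;
#' females still alive at the final census are right-censored there.
#'
#' @param census A census table.
#' @return A tibble: metadata columns, `cohort_id`, `time` (days), `event`
#'   (1 = death observed, 0 = censored).
#' @export
census_to_events <- function(census) {
  census <- validate_census(census)
  meta_cols <- intersect(
    c("generation", "treatment", "feeding", "replicate_id"),
    names(census)
  )
  rows <- map(unique(census$cohort_id), function(id) {
    cc <- census[census$cohort_id == id, ]
    drop <- -diff(cc$survivors)
    cens <- if ("censored" %in% names(cc)) cc$censored[-1] else rep(0L, length(drop))
    deaths <- drop - cens
    last_n <- cc$survivors[nrow(cc)]
    time <- c(
      rep(cc$day[-1], times = deaths),
      rep(cc$day[-1], times = cens),
      rep(cc$day[nrow(cc)], times = last_n)
    )
    event <- c(
      rep(1L, sum(deaths)),
      rep(0L, sum(cens)),
      rep(0L, last_n)
    )
    bind_cols(
      tibble(cohort_id = id),
      cc[rep(1, length(time)), meta_cols, drop = FALSE],
      tibble(time = time, event = event)
    )
  })
  list_rbind(rows)
}
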
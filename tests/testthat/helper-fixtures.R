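# Small cohorts and scenarios shared across test files; everything is built
# in code so the suite carries no data files.

# constant-survival cohort reproducing only at age 5: R0 = 4, T = 5,
# r_exact = log(4)/5 (single-age reproduction makes the approximation exact)
toy_census_single_age <- function() {
  tibble::tibble(
    cohort_id = "toy1",
    generation = "F1", treatment = "control", feeding = "fed",
    replicate_id = "r1",
    day = 0:6,
    survivors = c(10, 10, 10, 10, 10, 10, 0),
    neonates = c(0, 0, 0, 0, 0, 40, 0)
  )
}

# two reproductive ages (3 and 7), no deaths until the end: R0 = 4, T = 5
toy_census_two_age <- function() {
  tibble::tibble(
    cohort_id = "toy2",
    generation = "F1", treatment = "control", feeding = "fed",
    replicate_id = "r1",
    day = 0:8,
    survivors = c(rep(10L, 8), 0L),
    neonates = c(0, 0, 0, 20, 0, 0, 0, 20, 0)
  )
}

# a small homogeneous scenario for fast simulations
tiny_scenario <- function(...) {
  scenario(
    founders = 9, cohort_replicates = 2, h0 = 0.02, g = 0.12,
    a_m = 3, plateau = 8, decline = 8, lambda_max = 1.5,
    exposure_replicates = 4, n_exposed = 20, exposure_p = 0.8, ...
  )
}

# independent loop-based recomputation of every life-table quantity for one
# cohort, used as the brute-force oracle against the vectorised pipeline
oracle_lifetable <- function(census_one) {
  cc <- census_one[order(census_one$day), ]
  n0 <- cc$survivors[1]
  lx <- numeric(nrow(cc))
  mx <- numeric(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    lx[i] <- cc$survivors[i] / n0
    mx[i] <- if (cc$survivors[i] > 0) cc$neonates[i] / cc$survivors[i] else 0
  }
  R0 <- 0
  Tnum <- 0
  for (i in seq_len(nrow(cc))) {
    R0 <- R0 + lx[i] * mx[i]
    Tnum <- Tnum + cc$day[i] * lx[i] * mx[i]
  }
  list(lx = lx, mx = mx, R0 = R0, T = if (R0 > 0) Tnum / R0 else NA_real_)
}

# dense grid search for the Euler-Lotka root over r in [-1, 1]; the residual
# is strictly decreasing in r, so a coarse pass plus 1e-6 refinement around
# the sign change is equivalent to the full 1e-6 grid
oracle_euler_lotka_grid <- function(x, lx, mx) {
  f <- function(r) vapply(r, function(ri) sum(exp(-ri * x) * lx * mx) - 1, 0)
  coarse <- seq(-1, 1, by = 1e-4)
  i <- which.min(abs(f(coarse)))
  fine <- seq(coarse[max(1, i - 2)], coarse[min(length(coarse), i + 2)], by = 1e-6)
  fine[which.min(abs(f(fine)))]
}
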
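test_that("survivorship and fecundity follow their defining ratios", {
  no_deaths <- tibble::tibble(
    cohort_id = "a", day = 0:2, survivors = c(10, 10, 10), neonates = 0
  )
  expect_equal(compute_survivorship(no_deaths)$l_x, c(1, 1, 1))

  halving <- tibble::tibble(
    cohort_id = "a", day = 0:2, survivors = c(10, 5, 0), neonates = 0
  )
  expect_equal(compute_survivorship(halving)$l_x, c(1, 0.5, 0))

  births <- tibble::tibble(
    cohort_id = "a", day = 0:1, survivors = c(10, 10), neonates = c(0, 20)
  )
  expect_equal(compute_fecundity(births)$m_x, c(0, 2))

  # m_x is defined as 0 on extinct days
  extinct <- tibble::tibble(
    cohort_id = "a", day = 0:2, survivors = c(5, 0, 0), neonates = 0
  )
  expect_equal(compute_fecundity(extinct)$m_x, c(0, 0, 0))
})

test_that("census validation rejects structural violations with the offending day", {
  rising <- tibble::tibble(
    cohort_id = "a", day = 0:4, survivors = c(9, 8, 7, 9, 6), neonates = 0
  )
  expect_error(validate_census(rising), "day 3", class = "rl_error_validation")

  ghost_births <- tibble::tibble(
    cohort_id = "a", day = 0:2, survivors = c(9, 0, 0), neonates = c(0, 0, 4)
  )
  expect_error(validate_census(ghost_births), "day 2", class = "rl_error_validation")

  gap <- tibble::tibble(
    cohort_id = "a", day = c(0, 1, 3), survivors = c(9, 8, 7), neonates = 0
  )
  expect_error(validate_census(gap), "without gaps", class = "rl_error_validation")

  empty_founding <- tibble::tibble(
    cohort_id = "a", day = 0:1, survivors = c(0, 0), neonates = 0
  )
  expect_error(validate_census(empty_founding), class = "rl_error_invalid_cohort")
})

test_that("scalar parameters match hand-computable schedules", {
  # reproduction only at age 5 with m_5 = 4
  lx <- rep(1, 6)
  mx <- c(0, 0, 0, 0, 0, 4)
  expect_equal(net_reproductive_rate(lx, mx), 4)
  expect_equal(generation_time(0:5, lx, mx), 5)

  # two-term weighted mean: (3*2 + 7*2) / 4 = 5
  lx2 <- rep(1, 8)
  mx2 <- c(0, 0, 0, 2, 0, 0, 0, 2)
  expect_equal(generation_time(0:7, lx2, mx2), 5)

  expect_equal(net_reproductive_rate(lx, rep(0, 6)), 0)
  expect_error(generation_time(0:5, lx, rep(0, 6)), class = "rl_error_undefined")

  expect_equal(intrinsic_rate_approx(1, 10), 0)
  expect_equal(intrinsic_rate_approx(exp(1), 1), 1)
  expect_lt(intrinsic_rate_approx(0.5, 5), 0)
  expect_error(intrinsic_rate_approx(0, 5), class = "rl_error_undefined")
})

test_that("Euler-Lotka root matches the approximation for single-age reproduction", {
  lx <- rep(1, 6)
  mx <- c(0, 0, 0, 0, 0, 4)
  expect_equal(intrinsic_rate_exact(0:5, lx, mx), log(4) / 5, tolerance = 1e-9)

  # R0 = 1 concentrated at one age gives r = 0
  mx1 <- c(0, 0, 0, 1, 0, 0)
  expect_equal(intrinsic_rate_exact(0:5, lx, mx1), 0, tolerance = 1e-9)
})

test_that("Euler-Lotka solver agrees with a dense grid search", {
  lx <- rep(1, 8)
  mx <- c(0, 0, 0, 2, 0, 0, 0, 2)
  solved <- intrinsic_rate_exact(0:7, lx, mx)
  grid <- oracle_euler_lotka_grid(0:7, lx, mx)
  expect_lt(abs(solved - grid), 1e-5)

  # and across several simulated schedules
  scen <- tiny_scenario()
  for (s in 1:5) {
    cen <- simulate_cohort(scen, "F1", "control", "fed", seed = s)
    sch <- life_schedules(cen)
    if (sum(sch$l_x * sch$m_x) <= 1) next
    solved <- intrinsic_rate_exact(sch$day, sch$l_x, sch$m_x)
    grid <- oracle_euler_lotka_grid(sch$day, sch$l_x, sch$m_x)
    expect_lt(abs(solved - grid), 1e-5)
  }
})

test_that("lifetable matches the brute-force loop oracle on simulated cohorts", {
  scen <- tiny_scenario()
  cen <- simulate_cohort(scen, "F1", "control", "fed", seed = 1)
  lt <- lifetable(cen)
  orc <- oracle_lifetable(cen)
  sch <- life_schedules(cen)
  expect_equal(sch$l_x, orc$lx)
  expect_equal(sch$m_x, orc$mx)
  expect_equal(lt$R0, orc$R0)
  expect_equal(lt$T, orc$T)
  expect_equal(lt$r_approx, log(orc$R0) / orc$T)
})

test_that("undefined parameters are flagged, never silent numbers", {
  dead_day_one <- tibble::tibble(
    cohort_id = "a", generation = "F1", treatment = "control", feeding = "fed",
    replicate_id = "r1", day = 0:1, survivors = c(9, 0), neonates = c(0, 0)
  )
  lt <- lifetable(dead_day_one)
  expect_equal(lt$R0, 0)
  expect_true(is.na(lt$T))
  expect_true(is.na(lt$r_approx))
  expect_true(is.na(lt$r_exact))
  expect_false(lt$r_defined)
  expect_true(lt$negative_growth)
})

test_that("composite lifetable reproduces the two-age toy cohort", {
  lt <- lifetable(toy_census_two_age())
  expect_equal(lt$R0, 4)
  expect_equal(lt$T, 5)
  expect_equal(lt$r_approx, log(4) / 5)
  # exact rate exceeds the approximation when reproduction is spread out
  expect_gt(lt$r_exact, lt$r_approx)
})

test_that("scaling fecundity scales R0 and leaves T unchanged; survival shifts add to T", {
  scen <- tiny_scenario()
  cen <- simulate_cohort(scen, "F1", "low", "fed", seed = 3)
  sch <- life_schedules(cen)
  R0 <- net_reproductive_rate(sch$l_x, sch$m_x)
  T0 <- generation_time(sch$day, sch$l_x, sch$m_x)
  for (c_mult in c(1.5, 3, 10)) {
    expect_equal(net_reproductive_rate(sch$l_x, c_mult * sch$m_x), c_mult * R0)
    expect_equal(generation_time(sch$day, sch$l_x, c_mult * sch$m_x), T0)
  }
  # prepending d days of full survival with no reproduction adds d to T
  for (d in c(2, 7)) {
    lx_shift <- c(rep(1, d), sch$l_x)
    mx_shift <- c(rep(0, d), sch$m_x)
    x_shift <- 0:(length(lx_shift) - 1)
    expect_equal(
      generation_time(x_shift, lx_shift, mx_shift), T0 + d,
      tolerance = 1e-12
    )
    # delaying reproduction at fixed R0 lowers the exact growth rate
    expect_lt(
      intrinsic_rate_exact(x_shift, lx_shift, mx_shift),
      intrinsic_rate_exact(sch$day, sch$l_x, sch$m_x)
    )
  }
})

test_that("founder event expansion is consistent with the census counts", {
  cen <- rbind(toy_census_single_age(), toy_census_two_age())
  ev <- census_to_events(cen)
  expect_equal(nrow(ev), 20) # 10 founders per cohort
  expect_true(all(ev$event == 1))
  # with censoring, censored exits are split out from deaths
  cen2 <- tibble::tibble(
    cohort_id = "c", day = 0:2, survivors = c(5, 3, 0),
    neonates = 0, censored = c(0, 1, 0)
  )
  ev2 <- census_to_events(cen2)
  expect_equal(sum(ev2$event), 4)
  expect_equal(sum(ev2$event == 0), 1)
  expect_equal(ev2$time[ev2$event == 0], 1)
})
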
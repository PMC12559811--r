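test_that("degenerate scenarios behave exactly as their parameters force", {
  # certain death from day 0 and no fecundity: everyone dies at day 1, R0 = 0
  scen <- scenario(h0 = 1, g = 0, lambda_max = 0, founders = 9)
  cen <- simulate_cohort(scen, "F1", "control", "fed", seed = 1)
  expect_equal(max(cen$day), 1)
  expect_equal(cen$survivors, c(9L, 0L))
  lt <- lifetable(cen)
  expect_equal(lt$R0, 0)
  expect_false(lt$r_defined)

  # zero fecundity: no neonates ever
  scen2 <- scenario(lambda_max = 0)
  cen2 <- simulate_cohort(scen2, "F1", "low", "starved", seed = 2)
  expect_true(all(cen2$neonates == 0))

  # exposure extremes
  p1 <- scenario(exposure_p = 1)
  expect_true(all(simulate_exposure(p1, seed = 1)$n_alive == 50))
  p0 <- scenario(exposure_p = 0)
  expect_true(all(simulate_exposure(p0, seed = 1)$n_alive == 0))

  # invalid probabilities are a scenario error
  expect_error(scenario(exposure_p = 1.2), class = "rl_error_scenario")
})

test_that("simulated censuses always satisfy the census invariants", {
  scen <- tiny_scenario()
  for (s in 1:10) {
    cen <- simulate_cohort(scen, "F5", "mid", "starved", seed = s)
    expect_silent(validate_census(cen))
    expect_equal(cen$survivors[1], scen$cohort$founders)
    expect_equal(cen$survivors[nrow(cen)], 0L)
  }
})

test_that("exposure proportions land within binomial error of their cell probabilities", {
  scen <- paper_like_scenario()
  out <- simulate_exposure(scen, seed = 11)
  byc <- merge(
    aggregate(proportion ~ generation + treatment, data = out, FUN = mean),
    scen$exposure$p
  )
  se <- sqrt(byc$p * (1 - byc$p) / (50 * 16))
  expect_true(all(abs(byc$proportion - byc$p) <= 3 * pmax(se, 1e-3)))
})

test_that("simulation is deterministic and seeds separate streams", {
  scen <- tiny_scenario()
  a <- simulate_design(scen, seed = 5)
  b <- simulate_design(scen, seed = 5)
  expect_identical(a, b)
  c <- simulate_design(scen, seed = 6)
  expect_false(identical(a, c))
  # per-cohort re-simulation reproduces the corresponding design slice
  one <- simulate_cohort(scen, "F1", "control", "fed", replicate_id = "r2", seed = 5)
  slice <- a[a$cohort_id == one$cohort_id[1], ]
  expect_equal(as.data.frame(slice), as.data.frame(one))
})

test_that("pipeline R0 and T are unbiased for the analytic expectations (500 founders)", {
  scen <- tiny_scenario()
  truth <- cell_expectations(scen)
  truth <- truth[
    truth$generation == "F1" & truth$treatment == "control" & truth$feeding == "fed",
  ]
  n_rep <- 200
  R0s <- numeric(n_rep)
  Ts <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cen <- simulate_cohort(scen, "F1", "control", "fed",
      seed = 5000 + i, founders = 500
    )
    lt <- lifetable(cen)
    R0s[i] <- lt$R0
    Ts[i] <- lt$T
  }
  expect_lt(
    abs(mean(R0s) - truth$E_R0), 3 * sd(R0s) / sqrt(n_rep)
  )
  expect_lt(
    abs(mean(Ts) - truth$E_T), 3 * sd(Ts) / sqrt(n_rep)
  )
})

test_that("fecundity multipliers above 1 raise R0 (paired seeds, sign test)", {
  base <- tiny_scenario()
  boosted <- tiny_scenario(
    effects = tibble::tibble(
      generation = "F1", treatment = "control", feeding = "fed",
      lambda_mult = 1.5
    )
  )
  n_rep <- 100
  wins <- 0
  for (i in seq_len(n_rep)) {
    r_base <- lifetable(simulate_cohort(base, "F1", "control", "fed", seed = 900 + i))$R0
    r_boost <- lifetable(simulate_cohort(boosted, "F1", "control", "fed", seed = 900 + i))$R0
    if (r_boost > r_base) wins <- wins + 1
  }
  # one-sided binomial sign test against p = 0.5
  p <- stats::pbinom(wins - 1, n_rep, 0.5, lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("the calibrated scenario lands simulated cell means near the published means", {
  scen <- paper_like_scenario()
  # published F1 fed control lifespan 32.1 (SD 9.8): mean of 50 founders
  # falls within 1 published SD
  cen <- simulate_cohort(scen, "F1", "control", "fed", seed = 2025, founders = 50)
  expect_gt(lifetable(cen)$lifespan, 32.1 - 9.8)
  expect_lt(lifetable(cen)$lifespan, 32.1 + 9.8)
  # published F1 fed low R0 32.3: within [27, 37]
  cen2 <- simulate_cohort(scen, "F1", "low", "fed", seed = 2025, founders = 50)
  expect_gt(lifetable(cen2)$R0, 27)
  expect_lt(lifetable(cen2)$R0, 37)
  # analytic expectations equal the published targets for every cell
  exp_tab <- cell_expectations(scen)
  ref <- reference_cell_means() |>
    dplyr::filter(feeding %in% c("fed", "starved"), !is.na(mean)) |>
    tidyr::pivot_wider(
      id_cols = c("generation", "treatment", "feeding"),
      names_from = "metric", values_from = "mean"
    )
  m <- dplyr::inner_join(exp_tab, ref, by = c("generation", "treatment", "feeding"))
  expect_equal(nrow(m), 14)
  expect_equal(m$E_lifespan, m$lifespan, tolerance = 1e-8)
  expect_equal(m$E_R0, m$R0, tolerance = 1e-8)
  expect_equal(m$E_T, m$T, tolerance = 1e-8)
})

test_that("different seeds draw from the same distribution (two-sample KS)", {
  scen <- tiny_scenario()
  lifespans <- function(seeds) {
    unlist(lapply(seeds, function(s) {
      census_to_events(simulate_cohort(scen, "F1", "control", "fed", seed = s))$time
    }))
  }
  a <- lifespans(1:25)
  b <- lifespans(26:50)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})
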
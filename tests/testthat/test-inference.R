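simulate_balanced_exposure <- function(seed, reps = 16) {
  scen <- paper_like_scenario()
  scen$exposure$replicates <- as.integer(reps)
  simulate_exposure(scen, seed = seed)
}

test_that("two-way ANOVA reproduces the design-forced degrees of freedom", {
  out <- simulate_balanced_exposure(seed = 3)
  tab <- tidy(two_way_anova(out))
  expect_equal(tab$df, c(3, 2, 6, 180))
  expect_equal(sum(tab$df), 192 - 1)
})

test_that("sequential SS match the reference linear-model decomposition to 1e-8", {
  for (seed in c(3, 17)) {
    out <- simulate_balanced_exposure(seed = seed, reps = 6)
    tab <- tidy(two_way_anova(out))
    ref <- anova(lm(
      proportion ~ treatment * generation,
      data = transform(as.data.frame(out),
        treatment = factor(as.character(treatment)),
        generation = factor(as.character(generation))
      )
    ))
    expect_equal(tab$sumsq, ref$`Sum Sq`, tolerance = 1e-8)
    expect_equal(tab$df, ref$Df)
    expect_equal(tab$statistic[1:3], ref$`F value`[1:3], tolerance = 1e-8)
    expect_equal(tab$p.value[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-8)
    # SS decomposition is exact: factor SS + residual SS = total SS
    fit <- two_way_anova(out)
    expect_lt(abs(sum(tab$sumsq) - fit$total_ss), 1e-9)
  }
})

test_that("constant responses give zero SS and flagged, NA statistics", {
  out <- tidyr::expand_grid(
    generation = c("F0", "F2"), treatment = c("control", "low"), rep = 1:3
  )
  out$n_exposed <- 50L
  out$n_alive <- 40L
  fit <- two_way_anova(out)
  expect_true(fit$degenerate)
  expect_equal(tidy(fit)$sumsq[1:3], rep(0, 3))
  expect_true(all(is.na(tidy(fit)$statistic[1:3])))
})

test_that("Tukey HSD matches stats::TukeyHSD on a balanced design to 1e-6", {
  out <- simulate_balanced_exposure(seed = 5, reps = 6)
  fit <- two_way_anova(out)
  got <- tukey_hsd(fit, "treatment")
  ref <- stats::TukeyHSD(
    stats::aov(proportion ~ treatment * generation,
      data = transform(as.data.frame(out),
        treatment = factor(as.character(treatment)),
        generation = factor(as.character(generation))
      )
    ),
    "treatment"
  )$treatment
  ref_key <- gsub("-", " - ", rownames(ref), fixed = TRUE)
  idx <- match(got$contrast, ref_key)
  expect_false(anyNA(idx))
  expect_equal(got$estimate, unname(ref[idx, "diff"]), tolerance = 1e-6)
  expect_equal(got$conf.low, unname(ref[idx, "lwr"]), tolerance = 1e-6)
  expect_equal(got$conf.high, unname(ref[idx, "upr"]), tolerance = 1e-6)
  expect_equal(got$adj.p.value, unname(ref[idx, "p adj"]), tolerance = 1e-6)
})

test_that("Tukey HSD flags only genuinely shifted groups", {
  # two identical groups: difference 0, p near 1
  out <- tibble::tibble(
    generation = rep(c("F0", "F2"), each = 6),
    treatment = "control",
    n_exposed = 50L,
    n_alive = rep(c(40L, 41L, 39L), 4)
  )
  fit <- two_way_anova(transform(out, treatment = rep(c("control", "low"), 6)))
  tuk <- tukey_hsd(fit, "generation")
  expect_equal(tuk$estimate, 0)
  expect_gt(tuk$adj.p.value, 0.99)
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  fit <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(tidy(fit)$estimate, c(0.5, 0))

  # all censored: S stays at 1
  fit2 <- kaplan_meier(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(tidy(fit2)$estimate == 1))

  set.seed(31)
  t <- sample(1:40, 60, replace = TRUE)
  fit3 <- kaplan_meier(t)
  ecdf_surv <- vapply(tidy(fit3)$time, function(u) mean(t > u), 0)
  expect_equal(tidy(fit3)$estimate, ecdf_surv)

  expect_error(kaplan_meier(numeric(0)), class = "rl_error_validation")
})

test_that("Kaplan-Meier matches the survival package at every event time", {
  set.seed(42)
  t <- round(rexp(80, 1 / 25)) + 1
  ev <- rbinom(80, 1, 0.8)
  got <- tidy(kaplan_meier(t, ev))
  ref <- survival::survfit(survival::Surv(t, ev) ~ 1)
  ref_times <- summary(ref, times = got$time)$surv
  expect_equal(got$estimate, ref_times, tolerance = 1e-6)
})

test_that("log-rank statistic matches a hand-worked table and the survival package", {
  # identical groups: statistic exactly 0
  same <- logrank_test(c(2, 4, 6, 2, 4, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)

  # hand-worked 4 + 4 example, no censoring, distinct times
  # group a dies at 1,2,3,4; group b at 5,6,7,8
  # event times 1..8; O_a = 4
  # E_a = 4/8 + 3/7 + 2/6 + 1/5 (+0 afterwards) = 1.5929...
  # V = sum over times of d (n_a/n)(1-n_a/n)(n-d)/(n-1)
  ta <- 1:4
  tb <- 5:8
  n_a <- c(4, 3, 2, 1, 0, 0, 0, 0)
  n_tot <- 8:1
  E_a <- sum(n_a / n_tot)
  V <- sum((n_a / n_tot) * (1 - n_a / n_tot))
  hand <- (4 - E_a)^2 / V
  got <- logrank_test(c(ta, tb), rep(c("a", "b"), each = 4))
  expect_equal(got$statistic, hand, tolerance = 1e-12)

  ref <- survival::survdiff(
    survival::Surv(c(ta, tb)) ~ rep(c("a", "b"), each = 4)
  )
  expect_equal(got$statistic, ref$chisq, tolerance = 1e-6)

  # with ties and censoring, still matches the reference
  set.seed(9)
  t <- round(rexp(60, 1 / 20)) + 1
  g <- rep(c("a", "b"), 30)
  ev <- rbinom(60, 1, 0.85)
  got2 <- logrank_test(t, g, ev)
  ref2 <- survival::survdiff(survival::Surv(t, ev) ~ g)
  expect_equal(got2$statistic, ref2$chisq, tolerance = 1e-6)

  expect_warning(
    logrank_test(c(1, 2, 3, 4), rep(c("a", "b"), 2), c(1, 0, 1, 0)),
    "zero observed events"
  )
})

test_that("log-rank type-I error is near nominal under the null", {
  withr::local_seed(104)
  n_rej <- 0
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    t <- rexp(60, 1 / 25)
    g <- rep(c("a", "b"), each = 30)
    p <- logrank_test(t, g)$p.value
    if (p < 0.05) n_rej <- n_rej + 1
  }
  expect_gt(n_rej / n_rep, 0.03)
  expect_lt(n_rej / n_rep, 0.07)
})

test_that("bootstrap intervals are seeded, contain the estimate, and degenerate at zero variance", {
  # all founders die the same day: zero-variance lifespan, degenerate CI
  cen <- toy_census_single_age()
  ci <- bootstrap_ci(cen, "lifespan", B = 300, seed = 1)
  expect_equal(ci$conf.low, ci$estimate)
  expect_equal(ci$conf.high, ci$estimate)
  # the R0 point estimate is split-invariant: total births / founders
  ci_r0 <- bootstrap_ci(cen, "R0", B = 300, seed = 1)
  expect_equal(ci_r0$estimate, 4)

  scen <- tiny_scenario()
  sim <- simulate_cohort(scen, "F1", "control", "fed", seed = 8, founders = 30)
  for (metric in c("R0", "T", "r", "lifespan")) {
    ci <- bootstrap_ci(sim, metric, B = 400, seed = 2)
    expect_lte(ci$conf.low, ci$estimate)
    expect_gte(ci$conf.high, ci$estimate)
  }
  # deterministic given the seed
  expect_identical(
    bootstrap_ci(sim, "R0", B = 400, seed = 2),
    bootstrap_ci(sim, "R0", B = 400, seed = 2)
  )
  expect_error(bootstrap_ci(sim, "R0", B = 50, seed = 1), class = "rl_error_validation")
})

test_that("bootstrap R0 intervals achieve near-nominal coverage over simulated cohorts", {
  scen <- tiny_scenario()
  truth <- cell_expectations(scen)
  true_R0 <- truth$E_R0[
    truth$generation == "F1" & truth$treatment == "control" & truth$feeding == "fed"
  ]
  n_cohort <- 500
  covered <- 0
  for (i in seq_len(n_cohort)) {
    sim <- simulate_cohort(scen, "F1", "control", "fed",
      seed = 20000 + i, founders = 50
    )
    ci <- bootstrap_ci(sim, "R0", B = 400, seed = 30000 + i)
    if (ci$conf.low <= true_R0 && true_R0 <= ci$conf.high) covered <- covered + 1
  }
  expect_gt(covered / n_cohort, 0.92)
  expect_lt(covered / n_cohort, 0.98)
})
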
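#' Simulate exposure-survival outcomes
#'
#' Draws the full exposure design from a scenario: for every generation x
#' treatment cell, `replicates` dishes of `n_exposed` rotifers whose number
#' alive at 48 h is `Binomial(n_exposed, p(cell))`, independently per
#' replicate. The default design (3 generations x 4 treatments x 16
#' replicates) yields 192 outcomes.
#'
#' @param scen An `rl_scenario`.
#' @param seed Integer seed (mandatory; fixed seed gives identical output).
#' @return An exposure tibble: `generation`, `treatment`, `replicate_id`,
#'   `n_exposed`, `n_alive`, `proportion`.
#' @export
simulate_exposure <- function(scen, seed) {
  validate_scenario(scen)
  if (missing(seed)) stop_validation("A seed is required for simulation.")
  withr::local_seed(substream_seed(seed, "exposure"))
  grid <- scen$exposure$p |>
    tidyr::expand_grid(rep = seq_len(scen$exposure$replicates)) |>
    arrange(
      match(.data$generation, exposure_generations()),
      match(.data$treatment, uvb_treatments()), .data$rep
    )
  grid |>
    mutate(
      replicate_id = paste0("r", .data$rep),
      n_exposed = scen$exposure$n_exposed,
      n_alive = rbinom(n(), size = .data$n_exposed, prob = .data$p),
      proportion = .data$n_alive / .data$n_exposed
    ) |>
    select(all_of(c(
      "generation", "treatment", "replicate_id", "n_exposed",
      "n_alive", "proportion"
    )))
}

#' Simulate a life-table cohort census
#'
#' One replicate cohort for a design cell: each of `founders` females is
#' followed daily from hatch (day 0). A female alive at day x is recorded in
#' the census, produces neonates with mean `lambda(x)` (Poisson), and then
#' survives to day x + 1 with probability `1 - h(x)` (Bernoulli with the
#' discrete Gompertz hazard). The census aggregates founders into daily
#' `survivors` and `neonates` counts and runs until the last founder dies,
#' so it satisfies all census invariants by construction.
#'
#' @param scen An `rl_scenario`.
#' @param generation,treatment,feeding Design-cell labels.
#' @param replicate_id Replicate label stored in the census.
#' @param seed Integer seed (mandatory).
#' @param founders Override the scenario's founders per cohort (used for
#'   large parameter-recovery cohorts).
#' @return A census tibble (`cohort_id`, `generation`, `treatment`,
#'   `feeding`, `replicate_id`, `day`, `survivors`, `neonates`).
#' @export
simulate_cohort <- function(scen, generation, treatment, feeding,
                            replicate_id = "r1", seed, founders = NULL) {
  validate_scenario(scen)
  if (missing(seed)) stop_validation("A seed is required for simulation.")
  pr <- scen$cohort$params |>
    filter(
      .data$generation == !!generation, .data$treatment == !!treatment,
      .data$feeding == !!feeding
    )
  if (nrow(pr) != 1) {
    stop_validation(paste0(
      "Scenario has no parameters for cell ", generation, "/", treatment,
      "/", feeding
    ))
  }
  n0 <- founders %||% scen$cohort$founders
  withr::local_seed(substream_seed(
    seed, paste(generation, treatment, feeding, replicate_id)
  ))
  cur <- cell_curves(pr)
  nx_days <- length(cur$x)
  # daily Bernoulli survival: founder i dies between day x and x+1 when its
  # uniform draw falls below h(x); the final h is 1, so death is certain
  U <- matrix(runif(nx_days * n0), nrow = nx_days)
  first_fail <- apply(U < cur$h, 2, which.max)
  death_day <- cur$x[first_fail] + 1

  max_day <- max(death_day)
  days <- 0:max_day
  survivors <- map_int(days, function(d) sum(death_day > d))
  lambda <- c(cur$lambda, rep(0, max(0, max_day + 1 - nx_days)))[seq_along(days)]
  # sum of independent Poisson births over the females alive that day
  neonates <- rpois(length(days), survivors * lambda)
  neonates[survivors == 0] <- 0L

  tibble(
    cohort_id = paste(generation, treatment, feeding, replicate_id, sep = "_"),
    generation = generation, treatment = treatment, feeding = feeding,
    replicate_id = replicate_id,
    day = days, survivors = as.integer(survivors), neonates = as.integer(neonates)
  )
}

#' Simulate the full life-table census design
#'
#' Every design cell with a positive replicate count in the scenario is
#' simulated with [simulate_cohort()]; cells with zero replicates (the F5
#' high-UVB cells in the study design) are absent, which downstream reports
#' render as "ND". Each cohort consumes an independent sub-seed derived from
#' `seed` and its cell/replicate labels, so the full design is reproducible
#' and individual cohorts can be re-simulated in isolation.
#'
#' @param scen An `rl_scenario`.
#' @param seed Integer seed (mandatory).
#' @return A census tibble covering all simulated cohorts.
#' @export
simulate_design <- function(scen, seed) {
  validate_scenario(scen)
  if (missing(seed)) stop_validation("A seed is required for simulation.")
  reps <- scen$cohort$replicates |> filter(.data$n_rep > 0)
  rows <- pmap(reps, function(generation, treatment, feeding, n_rep) {
    list_rbind(map(seq_len(n_rep), function(k) {
      simulate_cohort(
        scen, generation, treatment, feeding,
        replicate_id = paste0("r", k), seed = seed
      )
    }))
  })
  # canonical (cohort_id, day) order, the same order census files read back in
  arrange(list_rbind(rows), .data$cohort_id, .data$day)
}
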
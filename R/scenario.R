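#' Construct a simulation scenario
#'
#' A scenario fully parameterises the synthetic experiment:
#'
#' * **Exposure design**: replicate dishes per generation x treatment cell
#'   (default 16) of `n_exposed` rotifers (default 50), each with a
#'   cell-specific probability `p` of being alive at 48 h; `n_alive` is
#'   binomial.
#' * **Cohort design**: life-table cohorts of `founders` females per
#'   replicate (default 9, one 9-well plate). Each founder dies by a daily
#'   Bernoulli trial with a discrete Gompertz hazard
#'   `h(x) = min(1, h0 * exp(g * x))` and, while alive, produces
#'   `Poisson(lambda(x))` neonates per day, where `lambda(x) = lambda_max *
#'   w(x)` follows a trapezoid: zero before the maturation age `a_m`, a
#'   plateau of length `plateau`, then a linear senescent decline over
#'   `decline` days. The trapezoid edges are fractional so expectations vary
#'   continuously in the parameters.
#'
#' Cell-specific parameters are the baseline values times the multiplicative
#' `effects` for each generation x treatment x feeding cell, mirroring how
#' maternal UVB exposure and starvation shift hazard and fecundity.
#'
#' @param founders Founding females per cohort replicate.
#' @param cohort_replicates Replicate cohorts per cell, or a tibble
#'   (`generation`, `treatment`, `feeding`, `n_rep`) for unbalanced designs.
#' @param h0,g Baseline Gompertz hazard level and slope (per day).
#' @param a_m Baseline maturation age (days, >= 1).
#' @param plateau,decline Baseline fecundity plateau length and senescent
#'   decline length (days).
#' @param lambda_max Baseline peak fecundity (neonates per female per day).
#' @param effects Optional tibble of multiplicative cell effects with columns
#'   `generation`, `treatment`, `feeding` and any of `h0_mult`, `g_mult`,
#'   `a_m_mult`, `lambda_mult` (missing cells default to 1).
#' @param exposure_replicates,n_exposed Exposure design sizes.
#' @param exposure_p Survival probability at 48 h: a single number for all
#'   cells or a tibble (`generation`, `treatment`, `p`).
#' @param name Scenario label.
#' @return An object of class `rl_scenario`.
#' @seealso [paper_like_scenario()] for the calibrated default,
#'   [simulate_cohort()], [simulate_exposure()], [cell_expectations()].
#' @export
scenario <- function(founders = 9, cohort_replicates = 3,
                     h0 = 0.01, g = 0.10, a_m = 3, plateau = 12,
                     decline = 15, lambda_max = 1.2, effects = NULL,
                     exposure_replicates = 16, n_exposed = 50,
                     exposure_p = 0.9, name = "default") {
  grid <- tidyr::expand_grid(
    generation = lifetable_generations(),
    treatment = uvb_treatments(),
    feeding = feeding_levels()
  )
  mults <- grid |>
    mutate(h0_mult = 1, g_mult = 1, a_m_mult = 1, lambda_mult = 1)
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    keys <- c("generation", "treatment", "feeding")
    if (!all(keys %in% names(effects))) {
      stop_validation("`effects` must have generation, treatment and feeding columns.")
    }
    for (col in c("h0_mult", "g_mult", "a_m_mult", "lambda_mult")) {
      if (!col %in% names(effects)) next
      m <- left_join(mults[keys], effects[c(keys, col)], by = keys)
      mults[[col]] <- ifelse(is.na(m[[col]]), mults[[col]], m[[col]])
    }
  }
  params <- mults |>
    mutate(
      h0 = h0 * .data$h0_mult,
      g = g * .data$g_mult,
      a_m = pmax(1, a_m * .data$a_m_mult),
      plateau = plateau,
      decline = decline,
      lambda_max = lambda_max * .data$lambda_mult
    ) |>
    select(all_of(c(
      "generation", "treatment", "feeding", "h0", "g", "a_m",
      "plateau", "decline", "lambda_max"
    )))

  if (is.numeric(cohort_replicates) && length(cohort_replicates) == 1) {
    reps <- grid |> mutate(n_rep = as.integer(cohort_replicates))
  } else {
    reps <- as_tibble(cohort_replicates)
  }

  if (is.numeric(exposure_p) && length(exposure_p) == 1) {
    p_tab <- tidyr::expand_grid(
      generation = exposure_generations(),
      treatment = uvb_treatments()
    ) |> mutate(p = exposure_p)
  } else {
    p_tab <- as_tibble(exposure_p)
  }

  out <- structure(
    list(
      name = name,
      exposure = list(
        replicates = as.integer(exposure_replicates),
        n_exposed = as.integer(n_exposed),
        p = p_tab
      ),
      cohort = list(
        founders = as.integer(founders),
        replicates = reps,
        params = params
      )
    ),
    class = "rl_scenario"
  )
  validate_scenario(out)
}

#' Validate a scenario
#'
#' Checks the probabilistic and biological constraints: survival
#' probabilities in `[0, 1]`, non-negative fecundity, maturation age >= 1,
#' positive hazard slope structure, positive design sizes.
#'
#' @param x An `rl_scenario`.
#' @return The scenario, invisibly; violations raise a scenario error.
#' @export
validate_scenario <- function(x) {
  if (!inherits(x, "rl_scenario")) stop_validation("Not an rl_scenario object.")
  p <- x$exposure$p$p
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("Exposure survival probabilities must lie in [0, 1].",
      class = c("rl_error_scenario", "rl_error")
    )
  }
  pr <- x$cohort$params
  if (any(pr$lambda_max < 0)) {
    abort("Fecundity lambda_max must be non-negative.",
      class = c("rl_error_scenario", "rl_error")
    )
  }
  if (any(pr$a_m < 1)) {
    abort("Maturation age a_m must be at least 1 day.",
      class = c("rl_error_scenario", "rl_error")
    )
  }
  if (any(pr$h0 < 0) || any(pr$h0 > 1)) {
    abort("Baseline hazard h0 must lie in [0, 1].",
      class = c("rl_error_scenario", "rl_error")
    )
  }
  if (x$cohort$founders < 1 || x$exposure$n_exposed < 1 ||
    x$exposure$replicates < 1) {
    abort("Design sizes must be positive.",
      class = c("rl_error_scenario", "rl_error")
    )
  }
  invisible(x)
}

#' @export
print.rl_scenario <- function(x, ...) {
  cat(
    "Scenario '", x$name, "': ", x$exposure$replicates, " exposure replicates x ",
    x$exposure$n_exposed, " individuals; cohorts of ", x$cohort$founders,
    " founders\n",
    sep = ""
  )
  invisible(x)
}

# discrete hazard, survivorship and fecundity curves for one cell ------------

trapezoid_shape <- function(x, a_m, plateau, decline) {
  pmax(0, pmin(1, x - a_m + 1, 1 - (x - (a_m + plateau)) / decline))
}

cell_curves <- function(par, max_day = 400) {
  x <- 0:max_day
  h <- pmin(1, par$h0 * exp(par$g * x))
  stop_at <- which(h >= 1)[1]
  if (!is.na(stop_at)) {
    x <- x[seq_len(stop_at)]
    h <- h[seq_len(stop_at)]
  }
  S <- c(1, cumprod(1 - h))[seq_along(x)] # S(x) = prod_{u < x} (1 - h(u))
  lambda <- par$lambda_max * trapezoid_shape(x, par$a_m, par$plateau, par$decline)
  list(x = x, h = h, S = S, lambda = lambda)
}

#' Analytic expectations per design cell
#'
#' The closed-form expectations implied by a scenario's hazard and fecundity
#' curves, against which simulated cohorts can be checked: mean founder
#' lifespan `sum_x S(x)`, net reproductive rate `sum_x S(x) lambda(x)`,
#' generation time `sum_x x S(x) lambda(x) / R0`, and the implied
#' r = `ln(R0)/T`, where `S(x) = prod_{u<x} (1 - h(u))`.
#'
#' @param scen An `rl_scenario`.
#' @return A tibble with one row per generation x treatment x feeding cell:
#'   `E_lifespan`, `E_R0`, `E_T`, `E_r`.
#' @export
cell_expectations <- function(scen) {
  validate_scenario(scen)
  pr <- scen$cohort$params
  rows <- map(seq_len(nrow(pr)), function(i) {
    cur <- cell_curves(pr[i, ])
    R0 <- sum(cur$S * cur$lambda)
    T <- if (R0 > 0) sum(cur$x * cur$S * cur$lambda) / R0 else NA_real_
    tibble(
      generation = pr$generation[i], treatment = pr$treatment[i],
      feeding = pr$feeding[i],
      E_lifespan = sum(cur$S), E_R0 = R0, E_T = T,
      E_r = if (!is.na(T) && R0 > 0) log(R0) / T else NA_real_
    )
  })
  list_rbind(rows)
}

#' Scenario calibrated to the published life-history tables
#'
#' Builds a scenario whose analytic cell expectations match the published
#' cell means of lifespan, R0 and generation time for every generation x
#' treatment x feeding cell (the bundled reference means, see
#' [reference_cell_means()]): the Gompertz level `h0` is solved so the
#' expected founder lifespan equals the published cell mean (slope `g` fixed
#' at 0.10/day), the maturation age (or, for very early-reproducing cells,
#' the plateau length) is solved so the expected generation time matches, and
#' `lambda_max` then scales the expected R0 onto the published value. The F5
#' high-UVB cells have no cohorts (too few F4 offspring) and get zero
#' replicates. Exposure survival probabilities follow the reported relative
#' declines across generations and intensities (controls near 0.95,
#' monotone decline with dose, steepest in F4).
#'
#' @param founders Founders per cohort replicate (default 9).
#' @return An `rl_scenario` with the unbalanced replicate design of the study
#'   (3 cohorts per cell, but 5 for F1 low fed and F5 low/mid fed).
#' @export
paper_like_scenario <- function(founders = 9) {
  ref <- reference_cell_means() |>
    filter(.data$feeding %in% feeding_levels(), !is.na(.data$mean)) |>
    tidyr::pivot_wider(
      id_cols = all_of(c("generation", "treatment", "feeding")),
      names_from = "metric", values_from = "mean"
    ) |>
    filter(!is.na(.data$lifespan), !is.na(.data$R0), !is.na(.data$T))

  params <- list_rbind(map(seq_len(nrow(ref)), function(i) {
    tgt <- ref[i, ]
    cal <- calibrate_cell(tgt$lifespan, tgt$R0, tgt$T)
    bind_cols(tgt[c("generation", "treatment", "feeding")], cal)
  }))

  reps <- tidyr::expand_grid(
    generation = lifetable_generations(),
    treatment = uvb_treatments(),
    feeding = feeding_levels()
  ) |>
    mutate(n_rep = case_when(
      .data$generation == "F5" & .data$treatment == "high" ~ 0L,
      .data$feeding == "starved" ~ 3L,
      .data$generation == "F1" & .data$treatment == "low" ~ 5L,
      .data$generation == "F5" & .data$treatment %in% c("low", "mid") ~ 5L,
      TRUE ~ 3L
    ))

  p_tab <- tibble(
    generation = rep(exposure_generations(), each = 4),
    treatment = rep(uvb_treatments(), times = 3),
    p = c(
      0.96, 0.85, 0.76, 0.66,
      0.95, 0.80, 0.62, 0.52,
      0.95, 0.74, 0.48, 0.39
    )
  )

  out <- structure(
    list(
      name = "paper_like",
      exposure = list(replicates = 16L, n_exposed = 50L, p = p_tab),
      cohort = list(
        founders = as.integer(founders),
        replicates = reps,
        params = params
      )
    ),
    class = "rl_scenario"
  )
  validate_scenario(out)
}

# solve (h0, a_m or plateau, lambda_max) so the cell expectations hit the
# target (lifespan, R0, T); all three relations are monotone, so uniroot on
# nested brackets suffices
calibrate_cell <- function(L_target, R0_target, T_target,
                           g = 0.10, plateau0 = 12, decline0 = 15) {
  exp_life <- function(h0) {
    cur <- cell_curves(list(
      h0 = h0, g = g, a_m = 1, plateau = plateau0,
      decline = decline0, lambda_max = 0
    ))
    sum(cur$S)
  }
  h0 <- uniroot(
    function(lh) exp_life(exp(lh)) - L_target,
    c(log(1e-8), log(0.995)), tol = 1e-12
  )$root
  h0 <- exp(h0)

  exp_T <- function(a_m, plateau, decline) {
    cur <- cell_curves(list(
      h0 = h0, g = g, a_m = a_m, plateau = plateau,
      decline = decline, lambda_max = 1
    ))
    w <- cur$S * cur$lambda
    sum(cur$x * w) / sum(w)
  }
  # oldest age with positive survivorship bounds the maturation-age search
  a_hi <- max(cell_curves(list(
    h0 = h0, g = g, a_m = 1, plateau = plateau0,
    decline = decline0, lambda_max = 1
  ))$x) - 1
  if (exp_T(1, plateau0, decline0) <= T_target) {
    if (exp_T(a_hi, plateau0, decline0) < T_target) {
      stop_numerical("Target generation time exceeds what the hazard allows.")
    }
    a_m <- uniroot(
      function(a) exp_T(a, plateau0, decline0) - T_target,
      c(1, a_hi), tol = 1e-10
    )$root
    plateau <- plateau0
    decline <- decline0
  } else {
    # very early reproduction: shrink the plateau (and decline with it)
    a_m <- 1
    plateau <- uniroot(
      function(q) exp_T(1, q, max(q, 0.05)) - T_target,
      c(0.01, plateau0), tol = 1e-10
    )$root
    decline <- max(plateau, 0.05)
  }
  cur <- cell_curves(list(
    h0 = h0, g = g, a_m = a_m, plateau = plateau,
    decline = decline, lambda_max = 1
  ))
  lambda_max <- R0_target / sum(cur$S * cur$lambda)
  tibble(
    h0 = h0, g = g, a_m = a_m, plateau = plateau, decline = decline,
    lambda_max = lambda_max
  )
}

#' Read or write a scenario as YAML
#'
#' Scenarios serialise to a plain YAML file (design sizes, probability
#' table, per-cell hazard/fecundity parameters) and read back identically.
#'
#' @param scen An `rl_scenario`.
#' @param path File path.
#' @return `write_scenario()`: the path, invisibly; `read_scenario()`: an
#'   `rl_scenario`.
#' @export
write_scenario <- function(scen, path) {
  validate_scenario(scen)
  obj <- list(
    name = scen$name,
    exposure = list(
      replicates = scen$exposure$replicates,
      n_exposed = scen$exposure$n_exposed,
      p = as.list(as.data.frame(scen$exposure$p))
    ),
    cohort = list(
      founders = scen$cohort$founders,
      replicates = as.list(as.data.frame(scen$cohort$replicates)),
      params = as.list(as.data.frame(scen$cohort$params))
    )
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  out <- structure(
    list(
      name = obj$name,
      exposure = list(
        replicates = as.integer(obj$exposure$replicates),
        n_exposed = as.integer(obj$exposure$n_exposed),
        p = as_tibble(obj$exposure$p)
      ),
      cohort = list(
        founders = as.integer(obj$cohort$founders),
        replicates = as_tibble(obj$cohort$replicates) |>
          mutate(n_rep = as.integer(.data$n_rep)),
        params = as_tibble(obj$cohort$params)
      )
    ),
    class = "rl_scenario"
  )
  validate_scenario(out)
  out
}

#' Published reference cell means
#'
#' The bundled table of published cell means and SDs (lifespan in days, R0,
#' generation time T in days, intrinsic rate r per day) for every generation
#' x treatment x feeding cell of the transgenerational UVB experiment,
#' including the published per-generation "mean" rows. The F5 high-UVB cells
#' are ND (no cohorts could be raised) and carry `NA`.
#'
#' One published inconsistency is preserved as printed: the F1 low "mean"
#' lifespan row (55.7) differs from the unweighted mean of the printed fed
#' and starved cells (57.8); the published contrast percentages reproduce
#' from the printed row.
#'
#' @return A tibble: `metric`, `generation`, `feeding`, `treatment`, `mean`,
#'   `sd`.
#' @export
reference_cell_means <- function() {
  path <- system.file("extdata", "reference_cell_means.csv", package = "rotilife")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, comment = "#")
}

#' Published contrast percentages
#'
#' The percent-change contrasts reported in the source study that are
#' exactly reproducible from its printed cell means: each UVB treatment
#' against the generation control, and F5 against F1 within treatment, for
#' lifespan, R0 and T. The `scope` column records whether the published
#' value is on the fed-only cells or the fed/starved mean rows (the
#' published high-UVB lifespan contrast is fed-only).
#'
#' @return A tibble: `metric`, `family`, `generation`, `treatment`, `scope`,
#'   `published_pct`.
#' @export
reference_contrasts <- function() {
  path <- system.file("extdata", "reference_contrasts.csv", package = "rotilife")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, comment = "#")
}
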
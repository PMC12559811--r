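#' Aggregate replicate cohorts into design cells
#'
#' Summarises per-cohort life-table results into the experiment's design
#' cells (generation x treatment x feeding): mean, sample SD (denominator
#' n - 1) and replicate count of each metric (lifespan, R0, T, r). Following
#' the layout of the reference tables, a per-generation `feeding = "mean"`
#' row is added for every treatment: the unweighted mean of the fed and
#' starved cell means, with its SD taken descriptively across those two cell
#' means. Cells with no cohorts are absent (rendered "ND" by
#' [report_table()]); a cohort with undefined r contributes `NA` to the r
#' cell, which is dropped with `na.rm = TRUE`.
#'
#' The `r` metric averages the per-replicate `r_approx` values (the rate is a
#' nonlinear function of R0 and T, so the mean of per-replicate rates differs
#' from `log(mean R0)/mean T`; see [rate_from_cell_means()] for the latter).
#'
#' @param results A per-cohort tibble from [lifetable()] with `generation`,
#'   `treatment`, `feeding` metadata.
#' @return A tibble: `metric`, `generation`, `treatment`, `feeding`, `mean`,
#'   `sd`, `n`.
#' @export
aggregate_cells <- function(results) {
  need <- c("generation", "treatment", "feeding")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols) > 0) {
    stop_validation(paste0(
      "Cell aggregation needs metadata column(s): ", toString(missing_cols)
    ))
  }
  long <- results |>
    mutate(r = .data$r_approx) |>
    select(all_of(c(need, "lifespan", "R0", "T", "r"))) |>
    tidyr::pivot_longer(c("lifespan", "R0", "T", "r"),
      names_to = "metric", values_to = "value"
    )
  base <- long |>
    group_by(.data$metric, .data$generation, .data$treatment, .data$feeding) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    mutate(
      mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean),
      feeding = as.character(.data$feeding)
    )
  mean_rows <- base |>
    group_by(.data$metric, .data$generation, .data$treatment) |>
    summarise(
      cell_mean = if (sum(!is.na(.data$mean)) == 2) mean(.data$mean) else NA_real_,
      cell_sd = if (sum(!is.na(.data$mean)) == 2) sd(.data$mean) else NA_real_,
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    rename(mean = "cell_mean", sd = "cell_sd") |>
    mutate(feeding = "mean")
  out <- bind_rows(base, mean_rows) |>
    arrange(
      match(.data$metric, names(report_digits())),
      .data$generation,
      match(.data$feeding, c(feeding_levels(), "mean")),
      match(as.character(.data$treatment), uvb_treatments())
    )
  out
}

#' Cell-level intrinsic rate from mean R0 and T
#'
#' The alternative to averaging per-replicate rates: apply r = `ln(R0)/T` to
#' cell means of R0 and T. Reported alongside, never silently substituted.
#'
#' @param cells Output of [aggregate_cells()].
#' @return A tibble with `generation`, `treatment`, `feeding` and
#'   `r_from_means`.
#' @export
rate_from_cell_means <- function(cells) {
  wide <- cells |>
    filter(.data$metric %in% c("R0", "T")) |>
    select(all_of(c("metric", "generation", "treatment", "feeding", "mean"))) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
  wide |>
    mutate(
      r_from_means = ifelse(
        !is.na(.data$R0) & .data$R0 > 0 & !is.na(.data$T),
        log(.data$R0) / .data$T, NA_real_
      )
    ) |>
    select(-all_of(c("R0", "T")))
}

#' Percent change of a focal mean against a baseline mean
#'
#' `100 * (focal - baseline) / baseline`, the contrast used throughout the
#' transgenerational comparisons (each UVB treatment against its generation
#' control, and F5 against F1 within treatment). Signed; vectorised.
#'
#' @param focal,baseline Numeric means; `baseline` must be nonzero.
#' @return Percent change (unrounded; reports round half-up to one decimal).
#' @examples
#' percent_change(55.7, 28.3) # +96.8 % at report precision
#' @export
percent_change <- function(focal, baseline) {
  if (any(baseline == 0, na.rm = TRUE)) {
    abort("Percent change is undefined against a zero baseline.",
      class = c("rl_error_undefined", "rl_error")
    )
  }
  100 * (focal - baseline) / baseline
}

#' Treatment and generation contrasts over design cells
#'
#' Emits both contrast families for every metric:
#'
#' * `vs_control`: each UVB treatment cell against the same-generation
#'   control cell;
#' * `f5_vs_f1`: the F5 cell against the F1 cell within each treatment.
#'
#' By default contrasts use the per-generation `"mean"` rows (unweighted mean
#' of fed and starved cells); `scope = "fed"` or `"starved"` restricts to one
#' feeding arm, which matters because some published percentages are on the
#' fed-only scope. Missing baseline or focal cells are skipped with a
#' warning.
#'
#' @param cells Output of [aggregate_cells()].
#' @param scope `"mean"`, `"fed"` or `"starved"`.
#' @return A tibble of class `rl_contrasts`: `metric`, `family`,
#'   `generation`, `treatment`, `scope`, `focal_mean`, `baseline_mean`,
#'   `focal_n`, `baseline_n`, `percent_change`.
#' @export
run_contrasts <- function(cells, scope = c("mean", "fed", "starved")) {
  scope <- match.arg(scope)
  sub <- cells |>
    filter(.data$feeding == scope, !is.na(.data$mean)) |>
    mutate(
      generation = as.character(.data$generation),
      treatment = as.character(.data$treatment)
    )
  cell_of <- function(metric, generation, treatment) {
    hit <- sub[
      sub$metric == metric & sub$generation == generation &
        sub$treatment == treatment,
    ]
    if (nrow(hit) == 0) NULL else hit[1, ]
  }
  out <- list()
  skipped <- character()
  for (metric in names(report_digits())) {
    for (gen in lifetable_generations()) {
      base <- cell_of(metric, gen, "control")
      for (trt in setdiff(uvb_treatments(), "control")) {
        foc <- cell_of(metric, gen, trt)
        if (is.null(foc) || is.null(base)) {
          skipped <- c(skipped, paste(metric, gen, trt, "vs control"))
          next
        }
        out[[length(out) + 1]] <- tibble(
          metric = metric, family = "vs_control", generation = gen,
          treatment = trt, scope = scope,
          focal_mean = foc$mean, baseline_mean = base$mean,
          focal_n = foc$n, baseline_n = base$n,
          percent_change = percent_change(foc$mean, base$mean)
        )
      }
    }
    for (trt in uvb_treatments()) {
      foc <- cell_of(metric, "F5", trt)
      base <- cell_of(metric, "F1", trt)
      if (is.null(foc) || is.null(base)) {
        skipped <- c(skipped, paste(metric, trt, "F5 vs F1"))
        next
      }
      out[[length(out) + 1]] <- tibble(
        metric = metric, family = "f5_vs_f1", generation = "F5",
        treatment = trt, scope = scope,
        focal_mean = foc$mean, baseline_mean = base$mean,
        focal_n = foc$n, baseline_n = base$n,
        percent_change = percent_change(foc$mean, base$mean)
      )
    }
  }
  if (length(skipped) > 0) {
    warn(paste0(
      "Skipped contrast(s) with missing cells: ",
      toString(unique(skipped))
    ))
  }
  empty <- tibble(
    metric = character(), family = character(), generation = character(),
    treatment = character(), scope = character(), focal_mean = numeric(),
    baseline_mean = numeric(), focal_n = integer(), baseline_n = integer(),
    percent_change = numeric()
  )
  res <- bind_rows(empty, list_rbind(out))
  class(res) <- c("rl_contrasts", class(res))
  res
}

#' Classify xerosome pigmentation from percent red digital number
#'
#' Pigment levels are assigned from the percentage of red-channel digital
#' number in a xerosome image: highly pigmented (HP) above 45, moderately
#' pigmented (MP) 38-42, lightly pigmented (LP) 36-37.4, non-pigmented (NP)
#' below 36. Values falling in the unassigned gaps between published bands
#' (37.4-38 and 42-45) are labelled `"boundary"` rather than forced into a
#' class.
#'
#' @param percent_red Numeric vector in `[0, 100]`.
#' @return A factor with levels HP, MP, LP, NP, boundary.
#' @examples
#' classify_pigment(c(45.8, 40.4, 36.2, 30))
#' @export
classify_pigment <- function(percent_red) {
  if (any(is.na(percent_red)) || any(percent_red < 0 | percent_red > 100)) {
    stop_validation("percent_red must lie in [0, 100].")
  }
  lev <- ifelse(percent_red > 45, "HP",
    ifelse(percent_red > 42, "boundary",
      ifelse(percent_red >= 38, "MP",
        ifelse(percent_red > 37.4, "boundary",
          ifelse(percent_red >= 36, "LP", "NP")
        )
      )
    )
  )
  factor(lev, levels = c("HP", "MP", "LP", "NP", "boundary"))
}
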
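#' Simulate a full experiment to files
#'
#' Writes the exposure-survival table and the life-table census from a
#' scenario to `exposure.csv` and `census.csv` under `out_dir`, both in the
#' schemas read back by [read_exposure()] and [read_census()]. A scenario
#' file (YAML) or an `rl_scenario` object may be supplied. With
#' `dry_run = TRUE` the scenario is validated and the planned outputs are
#' reported, but nothing is written.
#'
#' @param scen An `rl_scenario`, or the path to a scenario YAML file; the
#'   default is [paper_like_scenario()].
#' @param seed Integer seed; mandatory since both stages are stochastic.
#' @param out_dir Output directory (created if needed).
#' @param dry_run Validate and report without writing.
#' @return Invisibly, a named list of output paths (empty for a dry run).
#' @export
cmd_simulate <- function(scen = paper_like_scenario(), seed, out_dir,
                         dry_run = FALSE) {
  if (is.character(scen)) scen <- read_scenario(scen)
  validate_scenario(scen)
  if (missing(seed)) {
    stop_validation("A seed is required: the simulate stage is stochastic.")
  }
  exposure <- simulate_exposure(scen, seed = seed)
  census <- simulate_design(scen, seed = seed)
  if (dry_run) {
    inform(paste0(
      "[dry run] scenario '", scen$name, "': ", nrow(exposure),
      " exposure rows, ", length(unique(census$cohort_id)),
      " cohorts (", nrow(census), " census rows); nothing written."
    ))
    return(invisible(list()))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    exposure = file.path(out_dir, "exposure.csv"),
    census = file.path(out_dir, "census.csv")
  )
  write_exposure(exposure, paths$exposure)
  write_census(census, paths$census)
  inform(paste0(
    "Simulated scenario '", scen$name, "' (seed ", seed, "): ",
    nrow(exposure), " exposure rows, ",
    length(unique(census$cohort_id)), " cohorts."
  ))
  invisible(paths)
}

#' Analyse census and exposure files into report tables
#'
#' The full analysis pipeline over validated input files:
#' per-cohort life tables (`lifetable_summary.tsv`), aggregated cell tables
#' per metric (`cells_<metric>.tsv`), percent-change contrasts
#' (`contrasts.tsv`), Kaplan-Meier survival curves per design cell
#' (`survival_curves.tsv`) and, when an exposure file is given, the two-way
#' ANOVA table (`anova.tsv`) with Tukey HSD pairwise comparisons
#' (`tukey.tsv`). Outputs are deterministic: rerunning on the same inputs
#' gives byte-identical files.
#'
#' @param census_file Census CSV path (see [read_census()]).
#' @param exposure_file Optional exposure CSV path.
#' @param out_dir Output directory (created if needed).
#' @param scope Contrast baseline scope: `"mean"`, `"fed"` or `"starved"`.
#' @param bootstrap_B,bootstrap_seed If both supplied, founder-resampling
#'   bootstrap CIs for R0 are written to `bootstrap_R0.tsv`.
#' @return Invisibly, the named list of files written.
#' @export
cmd_analyze <- function(census_file, exposure_file = NULL, out_dir,
                        scope = c("mean", "fed", "starved"),
                        bootstrap_B = NULL, bootstrap_seed = NULL) {
  scope <- match.arg(scope)
  census <- read_census(census_file)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()

  lt <- lifetable(census)
  inform(paste0("Life tables: ", nrow(lt), " cohorts."))
  paths$lifetable <- file.path(out_dir, "lifetable_summary.tsv")
  readr::write_tsv(round_numeric(as_tibble(lt), 6), paths$lifetable, progress = FALSE)

  cells <- aggregate_cells(lt)
  paths$cells <- write_report(cells, out_dir)

  contrasts <- run_contrasts(cells, scope = scope)
  contrasts$percent_change <- round_half_up(contrasts$percent_change, 1)
  paths$contrasts <- file.path(out_dir, "contrasts.tsv")
  readr::write_tsv(
    round_numeric(as_tibble(contrasts), 6), paths$contrasts,
    progress = FALSE
  )
  inform(paste0("Contrasts (", scope, " scope): ", nrow(contrasts), " rows."))

  events <- census_to_events(census)
  curves <- events |>
    group_by(.data$generation, .data$treatment, .data$feeding) |>
    group_modify(function(d, key) tidy(kaplan_meier(d$time, d$event))) |>
    ungroup()
  paths$survival <- file.path(out_dir, "survival_curves.tsv")
  readr::write_tsv(round_numeric(curves, 6), paths$survival, progress = FALSE)

  if (!is.null(exposure_file)) {
    exposure <- read_exposure(exposure_file)
    fit <- two_way_anova(exposure)
    paths$anova <- file.path(out_dir, "anova.tsv")
    readr::write_tsv(round_numeric(tidy(fit), 6), paths$anova, progress = FALSE)
    paths$tukey <- file.path(out_dir, "tukey.tsv")
    readr::write_tsv(
      round_numeric(tukey_hsd(fit, "treatment"), 6), paths$tukey,
      progress = FALSE
    )
    inform(paste0("ANOVA: ", nrow(exposure), " exposure replicates."))
  }

  if (!is.null(bootstrap_B) && !is.null(bootstrap_seed)) {
    ci <- bootstrap_ci(census, metric = "R0", B = bootstrap_B, seed = bootstrap_seed)
    paths$bootstrap <- file.path(out_dir, "bootstrap_R0.tsv")
    readr::write_tsv(round_numeric(ci, 6), paths$bootstrap, progress = FALSE)
  }

  invisible(paths)
}

round_numeric <- function(df, digits) {
  mutate(df, across(where(is.numeric), ~ round(.x, digits)))
}

#' Recompute the published contrasts from the printed cell means
#'
#' Takes the bundled published cell means ([reference_cell_means()]),
#' recomputes every reproducible percent-change contrast with
#' [percent_change()] at report precision, and compares against the
#' published percentages ([reference_contrasts()]). Also checks the
#' intrinsic-rate identity on the fed F1 control cell: `ln(R0)/T` applied to
#' the printed cell means of R0 and T reproduces the printed r at two
#' decimals.
#'
#' @param out_dir Optional directory; when given, the pass/fail table is
#'   written to `replication.tsv` there.
#' @return A tibble: `check`, `computed`, `published`, `pass` (agreement at
#'   the published precision).
#' @export
cmd_replicate_paper <- function(out_dir = NULL) {
  ref <- reference_cell_means()
  targets <- reference_contrasts()

  mean_of <- function(metric, generation, feeding, treatment) {
    hit <- ref[
      ref$metric == metric & ref$generation == generation &
        ref$feeding == feeding & ref$treatment == treatment,
    ]
    if (nrow(hit) != 1) {
      stop_validation(paste0(
        "Reference cell not found: ", paste(metric, generation, feeding,
          treatment,
          sep = "/"
        )
      ))
    }
    hit$mean
  }

  rows <- pmap(targets, function(metric, family, generation, treatment,
                                 scope, published_pct) {
    if (family == "vs_control") {
      focal <- mean_of(metric, generation, scope, treatment)
      baseline <- mean_of(metric, generation, scope, "control")
      label <- paste0(metric, " ", generation, " ", treatment, " vs control")
    } else {
      focal <- mean_of(metric, "F5", scope, treatment)
      baseline <- mean_of(metric, "F1", scope, treatment)
      label <- paste0(metric, " F5 vs F1 (", treatment, ")")
    }
    if (scope != "mean") label <- paste0(label, " [", scope, " only]")
    computed <- round_half_up(percent_change(focal, baseline), 1)
    tibble(
      check = label, computed = computed, published = published_pct,
      pass = abs(computed - published_pct) < 0.05 + 1e-9
    )
  })
  out <- list_rbind(rows)

  r_computed <- round_half_up(
    intrinsic_rate_approx(
      mean_of("R0", "F1", "fed", "control"),
      mean_of("T", "F1", "fed", "control")
    ), 2
  )
  r_published <- mean_of("r", "F1", "fed", "control")
  out <- bind_rows(out, tibble(
    check = "r = ln(R0)/T on F1 fed control cell means",
    computed = r_computed, published = r_published,
    pass = abs(r_computed - r_published) < 0.005 + 1e-9
  ))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "replication.tsv"), progress = FALSE)
  }
  out
}
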
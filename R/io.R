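#' Read a daily census CSV
#'
#' Expects a long-format, comma-separated, UTF-8 table with header columns
#' `cohort_id, generation, treatment, feeding, replicate_id, day, survivors,
#' neonates` and optionally `censored`. Every structural problem found
#' (missing columns, non-integer counts, unknown category labels,
#' non-contiguous days, rising survivor counts) is reported with row numbers
#' in a single validation error; a file never half-parses.
#'
#' @param path Path to a CSV file.
#' @return A validated census tibble with `generation`, `treatment` and
#'   `feeding` as factors over the closed design vocabularies.
#' @seealso [validate_census()], [write_census()]
#' @export
read_census <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(
    "cohort_id", "generation", "treatment", "feeding", "replicate_id",
    "day", "survivors", "neonates"
  )
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop_validation(paste0(
      "Census file ", path, " is missing column(s): ", toString(missing_cols)
    ))
  }
  problems <- character()
  for (col in c("day", "survivors", "neonates", intersect("censored", names(raw)))) {
    bad <- which(!is_count(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "column `", col, "`: non-integer or negative values at row(s) ",
        toString(head(bad, 10))
      ))
    }
  }
  problems <- c(
    problems,
    check_vocab(raw$generation, lifetable_generations(), "generation"),
    check_vocab(raw$treatment, uvb_treatments(), "treatment"),
    check_vocab(raw$feeding, feeding_levels(), "feeding")
  )
  dup <- duplicated(raw[, c("cohort_id", "day")])
  if (any(dup)) {
    problems <- c(problems, paste0(
      "duplicated (cohort_id, day) at row(s) ", toString(head(which(dup), 10))
    ))
  }
  if (length(problems) > 0) {
    stop_validation(paste0(
      "Census file ", path, " failed validation:\n",
      paste0("- ", problems, collapse = "\n")
    ))
  }
  out <- raw |>
    mutate(
      generation = factor(.data$generation, levels = lifetable_generations()),
      treatment = factor(.data$treatment, levels = uvb_treatments()),
      feeding = factor(.data$feeding, levels = feeding_levels()),
      day = as.integer(.data$day),
      survivors = as.integer(.data$survivors),
      neonates = as.integer(.data$neonates)
    )
  validate_census(out)
  arrange(out, .data$cohort_id, .data$day)
}

check_vocab <- function(x, vocab, name) {
  bad <- which(!is.na(x) & !(x %in% vocab))
  if (length(bad) > 0) {
    paste0(
      "column `", name, "`: value(s) outside {", toString(vocab),
      "} at row(s) ", toString(head(bad, 10))
    )
  } else {
    character()
  }
}

#' @rdname read_census
#' @param census A census tibble.
#' @export
write_census <- function(census, path) {
  census <- validate_census(census)
  readr::write_csv(census, path, progress = FALSE)
  invisible(path)
}

#' Read or write an exposure-survival CSV
#'
#' Exposure tables record, for each replicate dish of (by default) 50
#' rotifers, how many showed trophi (jaw) movement 48 h after a 2-h UVB
#' exposure. Columns: `generation, treatment, replicate_id, n_exposed,
#' n_alive`. The derived column `proportion = n_alive / n_exposed` is added
#' on read.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of exposure outcomes.
#' @export
read_exposure <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("generation", "treatment", "replicate_id", "n_exposed", "n_alive")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop_validation(paste0(
      "Exposure file ", path, " is missing column(s): ", toString(missing_cols)
    ))
  }
  problems <- character()
  for (col in c("n_exposed", "n_alive")) {
    bad <- which(!is_count(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "column `", col, "`: non-integer or negative values at row(s) ",
        toString(head(bad, 10))
      ))
    }
  }
  over <- which(raw$n_alive > raw$n_exposed)
  if (length(over) > 0) {
    problems <- c(problems, paste0(
      "n_alive exceeds n_exposed at row(s) ", toString(head(over, 10))
    ))
  }
  problems <- c(
    problems,
    check_vocab(raw$generation, exposure_generations(), "generation"),
    check_vocab(raw$treatment, uvb_treatments(), "treatment")
  )
  if (length(problems) > 0) {
    stop_validation(paste0(
      "Exposure file ", path, " failed validation:\n",
      paste0("- ", problems, collapse = "\n")
    ))
  }
  raw |>
    mutate(
      generation = factor(.data$generation, levels = exposure_generations()),
      treatment = factor(.data$treatment, levels = uvb_treatments()),
      n_exposed = as.integer(.data$n_exposed),
      n_alive = as.integer(.data$n_alive),
      proportion = .data$n_alive / .data$n_exposed
    )
}

#' @rdname read_exposure
#' @param outcomes An exposure tibble.
#' @export
write_exposure <- function(outcomes, path) {
  cols <- c("generation", "treatment", "replicate_id", "n_exposed", "n_alive")
  readr::write_csv(outcomes[, cols], path, progress = FALSE)
  invisible(path)
}

#' Publication-style cell report tables
#'
#' `report_table()` lays one metric out the way the reference life-history
#' tables do: one row per generation x feeding group (plus the per-generation
#' "mean" rows), one column per UVB treatment, each cell rendered as
#' `"mean ± sd"` at the metric's reporting precision ([report_digits()]).
#' Empty design cells render as the literal `"ND"` (no data).
#' `write_report()` writes one such TSV per metric, deterministically (stable
#' row and column order, fixed rounding), so identical inputs give
#' byte-identical files.
#'
#' @param cells Aggregated cell summaries from [aggregate_cells()].
#' @param metric One of `"lifespan"`, `"R0"`, `"T"`, `"r"`.
#' @param dir Output directory (created if needed).
#' @return `report_table()`: a tibble in wide layout; `write_report()`: the
#'   paths written, invisibly.
#' @export
report_table <- function(cells, metric) {
  metric <- match.arg(metric, names(report_digits()))
  digits <- report_digits()[[metric]]
  sub <- cells[cells$metric == metric, ]
  gens <- intersect(lifetable_generations(), unique(as.character(sub$generation)))
  groups <- expand.grid(
    feeding = c(feeding_levels(), "mean"),
    generation = gens,
    stringsAsFactors = FALSE
  )
  groups <- groups[order(match(groups$generation, gens)), ]
  rows <- pmap(groups, function(feeding, generation) {
    label <- if (feeding == "mean") {
      paste("Mean", generation, metric)
    } else {
      paste(generation, feeding)
    }
    vals <- map_chr(uvb_treatments(), function(trt) {
      hit <- sub[
        as.character(sub$generation) == generation &
          as.character(sub$feeding) == feeding &
          as.character(sub$treatment) == trt,
      ]
      if (nrow(hit) == 0 || is.na(hit$mean[1])) {
        "ND"
      } else {
        s <- if (is.na(hit$sd[1])) 0 else hit$sd[1]
        paste0(
          format_fixed(hit$mean[1], digits), " ± ", format_fixed(s, digits)
        )
      }
    })
    bind_cols(tibble(group = label), as_tibble(as.list(setNames(vals, uvb_treatments()))))
  })
  list_rbind(rows)
}

#' @rdname report_table
#' @export
write_report <- function(cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- map_chr(names(report_digits()), function(metric) {
    tab <- report_table(cells, metric)
    path <- file.path(dir, paste0("cells_", metric, ".tsv"))
    readr::write_tsv(tab, path, progress = FALSE)
    path
  })
  invisible(paths)
}

format_fixed <- function(x, digits) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
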
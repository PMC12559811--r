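#' UVB treatment vocabulary
#'
#' The experimental design uses four UVB dose groups. `uvb_treatments()`
#' returns the closed vocabulary in design order; `uvb_intensity()` maps
#' treatment labels to lamp intensities in W/m^2 (2-h exposures).
#'
#' @param treatment Character vector of treatment labels.
#' @return `uvb_treatments()`: character vector; `uvb_intensity()`: numeric
#'   vector of intensities (W/m^2), named by treatment.
#' @examples
#' uvb_intensity(c("control", "high"))
#' @export
uvb_treatments <- function() c("control", "low", "mid", "high")

#' @rdname uvb_treatments
#' @export
uvb_intensity <- function(treatment = uvb_treatments()) {
  map <- c(control = 0, low = 1.3, mid = 3.7, high = 5.0)
  bad <- setdiff(unique(treatment), names(map))
  if (length(bad) > 0) {
    abort(
      paste0("Unknown UVB treatment label(s): ", toString(bad)),
      class = "rl_error_validation"
    )
  }
  map[treatment]
}

#' Generations used in the design
#'
#' Exposure survival is scored in the exposed generations (F0, F2, F4);
#' life-table cohorts are their offspring (F1, F5).
#'
#' @return Character vector of generation labels.
#' @export
exposure_generations <- function() c("F0", "F2", "F4")

#' @rdname exposure_generations
#' @export
lifetable_generations <- function() c("F1", "F5")

feeding_levels <- function() c("fed", "starved")

#' Round half away from zero
#'
#' Report tables round half-up on the magnitude (so 0.25 -> 0.3 and
#' -0.25 -> -0.3 at one decimal), matching the precision conventions of the
#' published life-history tables, rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(96.85, -33.05), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Decimal places used in report tables, per metric
#'
#' Lifespan, R0 and T are reported to one decimal; the intrinsic rate of
#' increase r to two, matching the precision of the reference tables.
#'
#' @return Named integer vector.
#' @export
report_digits <- function() c(lifespan = 1L, R0 = 1L, T = 1L, r = 2L)

# internal: assert scalar-ish helpers -----------------------------------------

stop_validation <- function(msg) {
  abort(msg, class = c("rl_error_validation", "rl_error"))
}

stop_numerical <- function(msg) {
  abort(msg, class = c("rl_error_numerical", "rl_error"))
}

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

# derive an independent 32-bit sub-seed from a base seed and a stream label
substream_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) + offs * 1009L) %% 2147483629L
}
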
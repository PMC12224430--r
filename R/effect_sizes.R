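# Effect-size module: Cohen's d -> small-sample correction J -> Hedges' g,
# active-minus-control contrasts, corpus subsetting and the cumulative mean.

#' Cohen's d from condition summary statistics
#'
#' Standardized mean difference between an active and a control condition
#' using the pooled standard deviation. Positive values mean the active
#' condition scored higher on the raw scale; see [orient_for_improvement()]
#' for the improvement sign convention on reaction times.
#'
#' All arguments are vectorized and recycled by row, so a whole outcomes
#' table can be processed in one call.
#'
#' @param mean_active,mean_control Condition means (task units).
#' @param sd_active,sd_control Condition standard deviations (> 0).
#' @param n_active,n_control Condition sample sizes (integers >= 2).
#' @return Numeric vector of Cohen's d values.
#' @examples
#' cohens_d(12, 4, 20, 10, 4, 20) # 0.5
#' @export
cohens_d <- function(mean_active, sd_active, n_active,
                     mean_control, sd_control, n_control) {
  check_number(mean_active, "mean_active"); check_number(mean_control, "mean_control")
  check_number(sd_active, "sd_active"); check_number(sd_control, "sd_control")
  if (any(sd_active <= 0) || any(sd_control <= 0)) {
    abort_input("Condition standard deviations must be > 0.")
  }
  if (any(n_active < 2) || any(n_control < 2)) {
    abort_input("Condition sample sizes must be >= 2.")
  }
  pooled <- sqrt(((n_active - 1) * sd_active^2 + (n_control - 1) * sd_control^2) /
                   (n_active + n_control - 2))
  (mean_active - mean_control) / pooled
}

#' Hedges' g with the small-sample correction
#'
#' Applies the Hedges–Olkin correction factor J = 1 - 3 / (4 df - 1),
#' df = n_active + n_control - 2, to Cohen's d, shrinking effect sizes from
#' small studies toward zero. Returns the whole d -> J -> g chain.
#'
#' @inheritParams cohens_d
#' @return A tibble with columns `d`, `J`, `g`, `df`, one row per input.
#' @examples
#' hedges_g(12, 4, 20, 10, 4, 20)
#' @export
hedges_g <- function(mean_active, sd_active, n_active,
                     mean_control, sd_control, n_control) {
  d <- cohens_d(mean_active, sd_active, n_active,
                mean_control, sd_control, n_control)
  df <- n_active + n_control - 2
  if (any(df <= 0)) abort_input("Degrees of freedom must be positive.")
  J <- 1 - 3 / (4 * df - 1)
  tibble(d = d, J = J, g = J * d, df = as.integer(df))
}

#' Contrast two effect sizes (active minus control)
#'
#' Studies reporting active-vs-baseline and sham-vs-baseline effects are
#' contrasted by subtraction, so a positive result signifies working-memory
#' improvement attributable to stimulation; when a study reports an
#' active-vs-sham effect directly, pass `g_control = 0`.
#'
#' @param g_active,g_control Effect sizes (unitless, finite).
#' @return `g_active - g_control`.
#' @export
contrast_effect <- function(g_active, g_control) {
  check_number(g_active, "g_active"); check_number(g_control, "g_control")
  g_active - g_control
}

#' Orient an effect size so that positive means improvement
#'
#' Reaction-time effects computed on raw times have improvement pointing
#' downward; they are sign-flipped so that one positive-is-better axis holds
#' across all outcome measures. Accuracy and other measures pass through.
#'
#' @param g Effect size(s) computed on the raw scale.
#' @param measure Character vector in `c("accuracy", "reaction_time", "other")`,
#'   recycled against `g`.
#' @return Oriented effect size(s).
#' @export
orient_for_improvement <- function(g, measure) {
  check_number(g, "g")
  measure <- check_measure(measure)
  ifelse(measure == "reaction_time", -g, g)
}

measure_levels <- c("accuracy", "reaction_time", "other")
wm_type_levels <- c("verbal", "visuospatial")
timing_levels  <- c("online", "offline")

check_measure <- function(measure) {
  measure <- as.character(measure)
  bad <- setdiff(unique(measure), measure_levels)
  if (length(bad)) {
    abort_input(sprintf("Unknown measure label(s): %s.", paste(bad, collapse = ", ")))
  }
  measure
}

check_outcomes <- function(outcomes) {
  need <- c("study_id", "outcome_id", "montage_id", "g",
            "measure", "wm_type", "timing")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) {
    abort_input(sprintf("Outcomes table is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  if (anyNA(outcomes$g) || !all(is.finite(outcomes$g))) {
    abort_input("Effect sizes `g` must be finite.")
  }
  if (any(!nzchar(outcomes$montage_id))) abort_input("montage_id must be nonempty.")
  check_measure(outcomes$measure)
  if (length(bad <- setdiff(unique(outcomes$wm_type), wm_type_levels))) {
    abort_input(sprintf("Unknown wm_type label(s): %s.", paste(bad, collapse = ", ")))
  }
  if (length(bad <- setdiff(unique(outcomes$timing), timing_levels))) {
    abort_input(sprintf("Unknown timing label(s): %s.", paste(bad, collapse = ", ")))
  }
  invisible(outcomes)
}

#' Read an outcomes table from delimited text
#'
#' One row per outcome measure. Columns `study_id`, `outcome_id`,
#' `montage_id`, `measure`, `wm_type`, `timing`, `n_active`, `n_control` are
#' required, plus either a precomputed `g` column or the six condition
#' summary-statistic columns (`mean_active`, `sd_active`, `mean_control`,
#' `sd_control`, with the n's above), from which Hedges' g is computed.
#' Reaction-time rows are sign-oriented at ingest so that positive g means
#' improvement; the `oriented` provenance column records which rows were
#' flipped.
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @param orient Logical; flip raw reaction-time effects at ingest
#'   (default `TRUE`). Set to `FALSE` when the source table is already
#'   improvement-oriented.
#' @return A tibble of study outcomes with columns `g` and `oriented` added.
#' @export
read_outcomes <- function(path, orient = TRUE) {
  if (!file.exists(path)) abort_input(sprintf("Outcomes file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("study_id", "outcome_id", "montage_id", "measure", "wm_type",
            "timing", "n_active", "n_control")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_input(sprintf("Outcomes file is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  out <- as_tibble(raw)
  if (!"g" %in% names(out)) {
    stat_cols <- c("mean_active", "sd_active", "mean_control", "sd_control")
    if (!all(stat_cols %in% names(out))) {
      abort_input("Outcomes file needs either a `g` column or condition summary statistics.")
    }
    eff <- hedges_g(out$mean_active, out$sd_active, out$n_active,
                    out$mean_control, out$sd_control, out$n_control)
    out$g <- eff$g
  }
  if (orient) {
    flip <- out$measure == "reaction_time"
    out$g <- orient_for_improvement(out$g, out$measure)
    out$oriented <- flip
  } else {
    out$oriented <- FALSE
  }
  check_outcomes(out)
  out
}

#' Cumulative (average) effect size over a set of outcomes
#'
#' The unweighted arithmetic mean of outcome-level Hedges' g, written G-bar;
#' each extracted outcome counts once regardless of its study of origin.
#'
#' @param outcomes Outcomes tibble with a `g` column (see [read_outcomes()]).
#' @return A one-row tibble with `g_bar` and `n_outcomes`.
#' @export
cumulative_effect <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) {
    abort_input("Cannot average an empty outcome set.")
  }
  check_number(outcomes$g, "g")
  tibble(g_bar = mean(outcomes$g), n_outcomes = nrow(outcomes))
}

#' Subset an outcomes table by domain labels
#'
#' Filters on any combination of the three label axes; unspecified axes are
#' unconstrained and row order is preserved. An empty result is allowed.
#'
#' @param outcomes Outcomes tibble.
#' @param measure,wm_type,timing Optional label values to keep
#'   (`"accuracy"`/`"reaction_time"`/`"other"`, `"verbal"`/`"visuospatial"`,
#'   `"online"`/`"offline"`).
#' @return The matching rows, original order.
#' @export
select_subset <- function(outcomes, measure = NULL, wm_type = NULL, timing = NULL) {
  check_outcomes(outcomes)
  check_axis <- function(value, levels, axis) {
    if (!is.null(value) && length(setdiff(value, levels))) {
      abort_input(sprintf("Unknown %s label(s): %s.", axis,
                          paste(setdiff(value, levels), collapse = ", ")))
    }
  }
  check_axis(measure, measure_levels, "measure")
  check_axis(wm_type, wm_type_levels, "wm_type")
  check_axis(timing, timing_levels, "timing")
  keep <- rep(TRUE, nrow(outcomes))
  if (!is.null(measure)) keep <- keep & outcomes$measure %in% measure
  if (!is.null(wm_type)) keep <- keep & outcomes$wm_type %in% wm_type
  if (!is.null(timing))  keep <- keep & outcomes$timing %in% timing
  outcomes[keep, , drop = FALSE]
}
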
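# End-to-end orchestration: subset -> field matrix -> PEC -> robust max ->
# permutation null -> p-values -> parcel table, with deterministic text
# exports and a recomputable run summary.

#' Run the full PEC meta-modeling pipeline on one outcome subset
#'
#' Chains the analysis stages: subset the outcomes table, assemble the
#' nodes-by-outcomes field matrix, compute the PEC map and its robust
#' maximum, build the permutation null, derive node-wise p-values and the
#' parcel significance table. All randomness comes from `plan$seed`; two
#' runs with the same inputs and plan produce byte-identical exports
#' (floating point rendered at 12 significant digits; no timestamps are
#' written into persisted files).
#'
#' @param outcomes Outcomes tibble (see [read_outcomes()]).
#' @param fields Named list of per-montage field vectors.
#' @param parcellation A `pec_parcellation`.
#' @param nodes Optional node coordinate tibble (`node_id`, `x`, `y`, `z`).
#' @param measure,wm_type,timing Optional subset labels (see [select_subset()]).
#' @param percentile Robust-maximum percentile (default 0.999).
#' @param plan A [permutation_plan()].
#' @param method Correlation type passed to [compute_pec()].
#' @param out_dir Optional directory; when given, writes `pec_map.tsv`,
#'   `pvalues.tsv`, `parcels.tsv` and `summary.json` there.
#' @return A `pec_run` object: list with `summary` (named list), `pec`
#'   (`pec_map`), `pvalues` (`pec_pvalues`), `parcels` (`parcel_table`),
#'   `robust_max` (tibble row).
#' @export
run_pec_pipeline <- function(outcomes, fields, parcellation, nodes = NULL,
                             measure = NULL, wm_type = NULL, timing = NULL,
                             percentile = 0.999,
                             plan = permutation_plan(),
                             method = "pearson", out_dir = NULL) {
  subset_desc <- describe_subset(measure, wm_type, timing)
  sub <- select_subset(outcomes, measure = measure, wm_type = wm_type,
                       timing = timing)
  if (nrow(sub) < 3) {
    abort_input(sprintf(
      "Subset '%s' matches %d outcomes; at least 3 are required.",
      subset_desc, nrow(sub)))
  }
  message(sprintf("[pecmap] subset '%s': %d outcomes, %d montages",
                  subset_desc, nrow(sub), length(unique(sub$montage_id))))
  fmat <- assemble_field_matrix(sub, fields, nodes = nodes)
  pec <- compute_pec(fmat, sub$g, method = method, subset = subset_desc)
  if (sum(pec$degenerate)) {
    rlang::warn(sprintf("%d degenerate (zero-variance) node(s) flagged.",
                        sum(pec$degenerate)))
  }
  rmax <- robust_max(pec, percentile)
  null <- permutation_null(fmat, sub$g, plan)
  pv <- permutation_pvalues(pec, null, plan)
  parcels <- parcel_significance(pv, parcellation)
  gbar <- cumulative_effect(sub)

  summary <- list(
    subset = subset_desc,
    n_outcomes = nrow(sub),
    g_bar = gbar$g_bar,
    robust_max = list(value = rmax$value, percentile = rmax$percentile,
                      node_id = rmax$node_id,
                      mni = c(rmax$x, rmax$y, rmax$z)),
    n_significant_nodes = sum(pv$significant & !pv$degenerate),
    n_significant_parcels = sum(parcels$significant),
    significant_parcels = parcels$parcel[parcels$significant],
    plan = list(n_perm = plan$n_perm, seed = plan$seed,
                sidedness = plan$sidedness, alpha = plan$alpha),
    method = method,
    quantile_method = "linear interpolation (type 7)",
    p_estimator = "add-one Monte Carlo",
    version = as.character(utils::packageVersion("pecmap")))
  run <- structure(list(summary = summary, pec = pec, pvalues = pv,
                        parcels = parcels, robust_max = rmax),
                   class = "pec_run")
  if (!is.null(out_dir)) export_run(run, out_dir)
  run
}

describe_subset <- function(measure, wm_type, timing) {
  parts <- c(
    if (!is.null(measure)) paste0("measure=", paste(measure, collapse = "|")),
    if (!is.null(wm_type)) paste0("wm_type=", paste(wm_type, collapse = "|")),
    if (!is.null(timing)) paste0("timing=", paste(timing, collapse = "|")))
  if (!length(parts)) "all" else paste(parts, collapse = ",")
}

export_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
  write_tsv_exact(as.data.frame(run$pec), file.path(out_dir, "pec_map.tsv"))
  write_tsv_exact(as.data.frame(run$pvalues), file.path(out_dir, "pvalues.tsv"))
  write_tsv_exact(as.data.frame(run$parcels), file.path(out_dir, "parcels.tsv"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  ok <- TRUE
  invisible(out_dir)
}

#' @export
print.pec_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pec_run> subset '%s' (%d outcomes)\n", s$subset, s$n_outcomes))
  cat(sprintf("  G-bar = %.3f; robust max PEC = %.3f (%.1fth pct) at node %d\n",
              s$g_bar, s$robust_max$value, 100 * s$robust_max$percentile,
              s$robust_max$node_id))
  cat(sprintf("  %d significant nodes; %d significant parcels%s\n",
              s$n_significant_nodes, s$n_significant_parcels,
              if (s$n_significant_parcels)
                paste0(" (", paste(s$significant_parcels, collapse = ", "), ")")
              else ""))
  invisible(x)
}

canonical_domains <- function() {
  list(accuracy = list(measure = "accuracy"),
       reaction_time = list(measure = "reaction_time"),
       verbal = list(wm_type = "verbal"),
       visuospatial = list(wm_type = "visuospatial"),
       online = list(timing = "online"),
       offline = list(timing = "offline"))
}

#' Run the pipeline over the six canonical domain subsets
#'
#' Accuracy, reaction time, verbal, visuospatial, online and offline — the
#' standard one-axis subsets — each analysed with the same plan (shared
#' seed policy), plus a combined comparison table.
#'
#' @inheritParams run_pec_pipeline
#' @param out_dir Optional root directory; each domain exports into a
#'   subdirectory.
#' @return A `pec_domains` object: list with `runs` (named list of
#'   `pec_run`) and `comparison` (tibble, one row per domain).
#' @export
run_all_domains <- function(outcomes, fields, parcellation, nodes = NULL,
                            percentile = 0.999, plan = permutation_plan(),
                            method = "pearson", out_dir = NULL) {
  check_outcomes(outcomes)
  domains <- canonical_domains()
  runs <- lapply(names(domains), function(nm) {
    args <- domains[[nm]]
    do.call(run_pec_pipeline, c(
      list(outcomes = outcomes, fields = fields, parcellation = parcellation,
           nodes = nodes, percentile = percentile, plan = plan,
           method = method,
           out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, nm)),
      args))
  })
  names(runs) <- names(domains)
  comparison <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    s <- runs[[nm]]$summary
    tibble(domain = nm, subset = s$subset, n_outcomes = s$n_outcomes,
           g_bar = s$g_bar, robust_max_pec = s$robust_max$value,
           n_significant_nodes = s$n_significant_nodes,
           n_significant_parcels = s$n_significant_parcels)
  }))
  if (!is.null(out_dir)) {
    write_tsv_exact(as.data.frame(comparison),
                    file.path(out_dir, "domain_comparison.tsv"))
  }
  structure(list(runs = runs, comparison = comparison),
            class = "pec_domains")
}

#' @export
print.pec_domains <- function(x, ...) {
  cat("<pec_domains> six canonical subsets\n")
  print(x$comparison)
  invisible(x)
}

#' Run the pipeline from a configuration list or YAML file
#'
#' File-driven front end used by the `pecmap` command-line script: reads
#' the outcomes table, every field file in the configured directory, the
#' parcellation and optional node coordinates, then calls
#' [run_pec_pipeline()].
#'
#' @param config A named list or path to a YAML file with entries
#'   `outcomes`, `fields_dir`, `parcellation`, optional `nodes`, `out_dir`,
#'   `subset` (named list over measure/wm_type/timing), `n_perm`, `seed`,
#'   `alpha`, `sidedness`, `percentile`, `method`.
#' @return A `pec_run`.
#' @export
run_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_input(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  need <- c("outcomes", "fields_dir", "parcellation")
  if (length(miss <- setdiff(need, names(config)))) {
    abort_input(sprintf("Config is missing field(s): %s.", paste(miss, collapse = ", ")))
  }
  outcomes <- read_outcomes(config$outcomes)
  field_files <- list.files(config$fields_dir,
                            pattern = "\\.(tsv|csv|txt|msh)$", full.names = TRUE)
  if (!length(field_files)) {
    abort_input(sprintf("No field files found in %s.", config$fields_dir))
  }
  nodes <- if (!is.null(config$nodes)) {
    as_tibble(utils::read.delim(config$nodes))
  }
  # node count from the first field file's record count via the parcellation
  probe <- read_delim_or_msh_length(field_files[[1]])
  fields <- lapply(field_files, read_node_field, node_count = probe)
  names(fields) <- vapply(fields, attr, "", "montage_id")
  parcellation <- read_parcellation(config$parcellation, probe)
  plan <- permutation_plan(
    n_perm = config$n_perm %||% 1000,
    seed = config$seed %||% 1,
    sidedness = config$sidedness %||% "one_sided_positive",
    alpha = config$alpha %||% 0.05)
  subset <- config$subset %||% list()
  run_pec_pipeline(outcomes, fields, parcellation, nodes = nodes,
                   measure = subset$measure, wm_type = subset$wm_type,
                   timing = subset$timing,
                   percentile = config$percentile %||% 0.999,
                   plan = plan, method = config$method %||% "pearson",
                   out_dir = config$out_dir)
}

read_delim_or_msh_length <- function(path) {
  if (grepl("\\.msh$", path, ignore.case = TRUE)) {
    length(read_msh_nodedata(path))
  } else {
    length(read_delim_field(path))
  }
}
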
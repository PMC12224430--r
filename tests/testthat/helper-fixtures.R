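# Shared fixtures: tiny outcome tables, field sets and meshes built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_outcomes <- function(n = 6, g = NULL, montage_id = NULL) {
  tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n)),
    outcome_id = sprintf("O%02d", seq_len(n)),
    montage_id = montage_id %||% rep(c("MA", "MB"), length.out = n),
    g = g %||% seq(0.1, by = 0.1, length.out = n),
    measure = rep(c("accuracy", "reaction_time"), length.out = n),
    wm_type = c(rep("verbal", min(4, n)), rep("visuospatial", max(0, n - 4))),
    timing = rep(c("online", "offline"), length.out = n),
    n_active = 20L, n_control = 20L, oriented = FALSE)
}

toy_fields <- function(n_nodes = 5, montage_ids = c("MA", "MB"), seed = 42) {
  set.seed(seed)
  fields <- lapply(montage_ids, function(id) abs(rnorm(n_nodes, 1, 0.5)))
  names(fields) <- montage_ids
  fields
}

# Reference Pearson correlation straight from the covariance definition.
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Reference interpolated quantile: sort + linear interpolation between
# order statistics at h = (n-1)p + 1.
naive_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

small_field_matrix <- function(values, montage_per_col = NULL, nodes = NULL) {
  n <- ncol(values)
  outcomes <- toy_outcomes(n, montage_id = montage_per_col %||% sprintf("M%d", seq_len(n)))
  first <- !duplicated(outcomes$montage_id)
  fields <- lapply(which(first), function(j) values[, j])
  names(fields) <- outcomes$montage_id[first]
  assemble_field_matrix(outcomes, fields, nodes = nodes)
}
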
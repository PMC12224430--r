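# PEC engine: node-wise performance-electric-field correlation and the
# robust (percentile) maximum summary.

# Row-wise Pearson correlation of V (nodes x m) against columns of G (m x k),
# in one BLAS call: cor_i,k = <Vc_i, Gc_k> / ((m-1) sd_i sd_k).
# Zero-variance rows get 0 and a degenerate flag.
row_cor <- function(V, G) {
  m <- ncol(V)
  Vc <- V - rowMeans(V)
  row_sd <- sqrt(rowSums(Vc^2) / (m - 1))
  degenerate <- row_sd == 0
  Gc <- sweep(G, 2, colMeans(G))
  g_sd <- sqrt(colSums(Gc^2) / (m - 1))
  if (any(g_sd == 0)) abort_input("Effect-size vector is constant; correlation undefined.")
  out <- (Vc %*% Gc) / ((m - 1) * outer(ifelse(degenerate, 1, row_sd), g_sd))
  out[degenerate, ] <- 0
  # clamp tiny floating excursions outside [-1, 1]
  out[out > 1] <- 1; out[out < -1] <- -1
  list(cor = out, degenerate = degenerate)
}

#' Compute the node-wise performance-electric-field correlation (PEC) map
#'
#' For every node, correlates that node's electric-field magnitudes across
#' outcomes with the outcomes' effect sizes. Nodes where PEC > 0 are regions
#' whose stimulation dose relates to better performance; PEC < 0 to worse.
#' Nodes with zero field variance across outcomes are flagged degenerate and
#' assigned PEC 0 (they carry no dose information for this montage set).
#'
#' @param matrix A `field_matrix` from [assemble_field_matrix()].
#' @param g Effect-size vector aligned with the matrix columns (length >= 3,
#'   not all equal).
#' @param method `"pearson"` (default; PEC squared is explained variance) or
#'   `"spearman"` (rank correlation on both vectors).
#' @param subset Optional character descriptor of the outcome subset,
#'   carried into summaries.
#' @return A `pec_map`: tibble with columns `node_id`, `pec`, `degenerate`,
#'   plus attributes `n_outcomes`, `subset`, `method`, `nodes`.
#' @export
compute_pec <- function(matrix, g, method = c("pearson", "spearman"),
                        subset = "all") {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "field_matrix"))
  check_number(g, "g")
  if (length(g) != ncol(matrix$values)) {
    rlang::abort(sprintf(
      "Effect-size vector length (%d) does not match outcome count (%d).",
      length(g), ncol(matrix$values)),
      class = c("pecmap_alignment_error", "pecmap_error"))
  }
  if (length(g) < 3) abort_input("At least 3 outcomes are required to correlate.")
  if (length(unique(g)) == 1L) {
    abort_input("Effect-size vector is constant; correlation undefined.")
  }
  V <- matrix$values
  if (method == "spearman") {
    V <- t(apply(V, 1, rank))
    g <- rank(g)
  }
  rc <- row_cor(V, cbind(g))
  new_pec_map(pec = as.numeric(rc$cor), degenerate = rc$degenerate,
              n_outcomes = length(g), subset = subset, method = method,
              nodes = matrix$nodes)
}

new_pec_map <- function(pec, degenerate, n_outcomes, subset, method, nodes) {
  out <- tibble(node_id = seq_along(pec) - 1L, pec = pec,
                degenerate = degenerate)
  structure(out,
            n_outcomes = n_outcomes, subset = subset, method = method,
            nodes = nodes,
            class = c("pec_map", class(out)))
}

#' Robust maximum of a PEC map
#'
#' The high percentile (default 99.9th) of the non-degenerate PEC
#' distribution, used instead of the raw maximum so an isolated extreme node
#' cannot define the map's peak. The reported location is the node sitting
#' at the quantile boundary: the non-degenerate node with the smallest PEC
#' at or above the quantile value.
#'
#' @param map A `pec_map` from [compute_pec()].
#' @param percentile Fraction in (0, 1], default `0.999`.
#' @return A one-row tibble: `value`, `percentile`, `node_id`, `x`, `y`, `z`
#'   (MNI millimetres when node coordinates are attached).
#' @export
robust_max <- function(map, percentile = 0.999) {
  stopifnot(inherits(map, "pec_map"))
  if (percentile <= 0 || percentile > 1) abort_input("`percentile` must be in (0, 1].")
  ok <- !map$degenerate
  if (!any(ok)) abort_input("All nodes are degenerate; robust maximum undefined.")
  pec_ok <- map$pec[ok]
  value <- pec_quantile(pec_ok, percentile)
  cand <- which(ok & map$pec >= value)
  node <- cand[which.min(map$pec[cand])]
  nodes <- attr(map, "nodes")
  coords <- if (!is.null(nodes)) nodes[node, c("x", "y", "z")] else
    tibble(x = NA_real_, y = NA_real_, z = NA_real_)
  tibble(value = value, percentile = percentile,
         node_id = map$node_id[node],
         x = coords$x[[1]], y = coords$y[[1]], z = coords$z[[1]])
}

#' Explained variance of a correlation
#'
#' Squares a correlation coefficient; `as_percent = TRUE` expresses it as a
#' percentage of behavioral effect-size variance explained by field dose
#' (e.g. a robust maximum PEC of 0.2 explains 4%).
#'
#' @param pec Correlation value(s).
#' @param as_percent Return a percentage instead of a fraction.
#' @return Numeric vector.
#' @export
explained_variance <- function(pec, as_percent = FALSE) {
  check_number(pec, "pec")
  r2 <- pec^2
  if (as_percent) 100 * r2 else r2
}

#' @export
print.pec_map <- function(x, ...) {
  cat(sprintf("<pec_map> %d nodes (%d degenerate), subset '%s', %d outcomes, %s\n",
              nrow(x), sum(x$degenerate), attr(x, "subset"),
              attr(x, "n_outcomes"), attr(x, "method")))
  NextMethod()
}
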
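# Field I/O: per-montage node-wise |E| vectors, node parcellation, and the
# aligned nodes x outcomes field matrix. Node indexing is 0-based and
# contiguous internally; 1-based file dialects are converted at the boundary.

abort_format <- function(msg) {
  rlang::abort(msg, class = c("pecmap_format_error", "pecmap_error"))
}

#' Read a node-wise electric-field magnitude vector
#'
#' Accepts either a two-column delimited file (`node_id`, magnitude; comma,
#' tab or whitespace separated, optional header) or an ASCII Gmsh-dialect
#' `.msh` file carrying one scalar `$NodeData` block, as written by field
#' simulators. Magnitudes are field strengths |E| in mV/mm and are taken
#' as-is; negative or non-finite values are rejected.
#'
#' @param path Path to the field file.
#' @param node_count Expected number of nodes; a mismatch is an error.
#' @param montage_id Montage identifier attached to the result (defaults to
#'   the file name without extension).
#' @return A numeric vector of length `node_count`, ordered by node id
#'   (0-based internal indexing), with attributes `montage_id` and `source`.
#' @export
read_node_field <- function(path, node_count, montage_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("Field file not found: %s", path))
  if (is.null(montage_id)) {
    montage_id <- sub("\\.[^.]*$", "", basename(path))
  }
  values <- if (grepl("\\.msh$", path, ignore.case = TRUE)) {
    read_msh_nodedata(path)
  } else {
    read_delim_field(path)
  }
  if (length(values) != node_count) {
    abort_format(sprintf(
      "Field file %s has %d node values, expected %d.",
      basename(path), length(values), node_count))
  }
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values))[1]
    abort_format(sprintf("Non-finite field value at node %d in %s.",
                         bad - 1L, basename(path)))
  }
  if (any(values < 0)) {
    bad <- which(values < 0)[1]
    abort_format(sprintf(
      "Negative field magnitude (%g) at node %d in %s; |E| must be >= 0.",
      values[bad], bad - 1L, basename(path)))
  }
  structure(values, montage_id = montage_id, source = path)
}

read_delim_field <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_format(sprintf("Empty field file: %s", path))
  # tolerate a header row
  first <- strsplit(trimws(lines[1]), "[,\t ]+")[[1]]
  if (suppressWarnings(anyNA(as.numeric(first)))) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  n_col <- lengths(parts)
  if (any(n_col != 2)) {
    abort_format(sprintf("Record %d of %s does not have two columns.",
                         which(n_col != 2)[1], basename(path)))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    abort_format(sprintf("Non-numeric record %d in %s.",
                         which(rowSums(is.na(m)) > 0)[1], basename(path)))
  }
  ids <- m[, 1]
  # accept 0- or 1-based contiguous ids; convert to 0-based
  if (setequal(ids, seq_along(ids) - 1)) {
    base <- 0L
  } else if (setequal(ids, seq_along(ids))) {
    base <- 1L
  } else {
    abort_format(sprintf(
      "Node ids in %s are not contiguous from 0 or 1 (first id %g).",
      basename(path), ids[1]))
  }
  m[order(ids), 2][seq_along(ids)]
}

# Minimal ASCII Gmsh v2.2 $NodeData reader: one scalar value per node.
read_msh_nodedata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- which(lines == "$NodeData")
  end <- which(lines == "$EndNodeData")
  if (length(start) != 1L || length(end) != 1L || end < start) {
    abort_format(sprintf("%s: expected exactly one $NodeData block.", basename(path)))
  }
  body <- lines[(start + 1):(end - 1)]
  i <- 1
  n_str <- as.integer(body[i]); i <- i + 1 + n_str   # string tags
  n_real <- as.integer(body[i]); i <- i + 1 + n_real # real tags
  n_int <- as.integer(body[i]); i <- i + 1
  int_tags <- as.integer(body[i:(i + n_int - 1)]); i <- i + n_int
  if (n_int < 3) abort_format(sprintf("%s: malformed $NodeData tags.", basename(path)))
  n_comp <- int_tags[2]
  n_rows <- int_tags[3]
  if (n_comp != 1L) {
    abort_format(sprintf("%s: expected scalar node data, got %d components.",
                         basename(path), n_comp))
  }
  rows <- body[i:(i + n_rows - 1)]
  parts <- strsplit(trimws(rows), "[ \t]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort_format(sprintf("%s: malformed node-data record %d.", basename(path), bad[1]))
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  ids <- m[, 1] # gmsh node ids are 1-based
  if (!setequal(ids, seq_len(nrow(m)))) {
    abort_format(sprintf("%s: node ids are not contiguous from 1.", basename(path)))
  }
  m[order(ids), 2]
}

#' Write a field vector as an ASCII Gmsh `$NodeData` block
#'
#' Companion writer to [read_node_field()], mainly for tests and for
#' exporting synthetic fields in a simulator-compatible dialect (Gmsh v2.2,
#' 1-based node ids).
#'
#' @param field Numeric vector of node magnitudes.
#' @param path Output path (`.msh`).
#' @param name Data name recorded in the block.
#' @return `path`, invisibly.
#' @export
write_node_field_msh <- function(field, path, name = "E_magnitude") {
  check_number(field, "field")
  lines <- c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$NodeData",
    "1", sprintf("\"%s\"", name),
    "1", "0.0",
    "3", "0", "1", as.character(length(field)),
    paste(seq_along(field), fmt_num(field)),
    "$EndNodeData")
  writeLines(lines, path)
  invisible(path)
}

#' Read a node parcellation table
#'
#' Delimited file (`node_id`, `parcel_label`), comma/tab/whitespace
#' separated with optional header; every node must appear exactly once.
#' Nodes labeled `"none"` are kept in the labeling but excluded from the
#' parcel inventory used for inference.
#'
#' @param path Path to the parcellation file.
#' @param node_count Expected number of nodes.
#' @return A list with `labels` (character vector over nodes, 0-based order)
#'   and `inventory` (tibble `parcel`, `n_nodes`, excluding `"none"`).
#' @export
read_parcellation <- function(path, node_count) {
  if (!file.exists(path)) abort_format(sprintf("Parcellation file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  if (suppressWarnings(is.na(as.numeric(parts[[1]][1])))) parts <- parts[-1]
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort_format(sprintf("Parcellation record %d does not have two columns.", bad[1]))
  }
  ids <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  labels <- vapply(parts, `[`, "", 2)
  if (anyNA(ids)) abort_format("Non-numeric node id in parcellation file.")
  if (anyDuplicated(ids)) {
    abort_format(sprintf("Duplicate node id %g in parcellation file.",
                         ids[anyDuplicated(ids)]))
  }
  if (setequal(ids, seq_len(length(ids)))) ids <- ids - 1
  if (!setequal(ids, seq_len(length(ids)) - 1) || length(ids) != node_count) {
    abort_format(sprintf(
      "Parcellation must label all %d nodes exactly once (got %d).",
      node_count, length(ids)))
  }
  labels <- labels[order(ids)]
  new_parcellation(labels)
}

new_parcellation <- function(labels) {
  labeled <- labels[labels != "none"]
  inv <- as_tibble(table(parcel = labeled))
  names(inv) <- c("parcel", "n_nodes")
  inv$n_nodes <- as.integer(inv$n_nodes)
  structure(list(labels = labels, inventory = inv), class = "pec_parcellation")
}

#' @export
print.pec_parcellation <- function(x, ...) {
  cat(sprintf("<pec_parcellation> %d nodes, %d parcels (%d unlabeled)\n",
              length(x$labels), nrow(x$inventory), sum(x$labels == "none")))
  invisible(x)
}

#' Assemble the aligned nodes-by-outcomes field matrix
#'
#' Column j holds the field vector of outcome j's montage, so outcomes
#' sharing a montage share (duplicated) columns and the matrix lines up
#' elementwise with the effect-size vector for the node-wise correlation.
#'
#' @param outcomes Outcomes tibble (see [read_outcomes()]).
#' @param fields Named list of field vectors, names = montage ids, all of
#'   one shared length (the node count).
#' @param nodes Optional node coordinate tibble (`node_id`, `x`, `y`, `z`,
#'   millimetres) used to report robust-maximum locations.
#' @return A `field_matrix` object: list with `values` (nodes x outcomes),
#'   `outcome_ids`, `montage_ids`, `nodes`.
#' @export
assemble_field_matrix <- function(outcomes, fields, nodes = NULL) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) {
    abort_input("Cannot assemble a field matrix for zero outcomes.")
  }
  check_outcomes(outcomes)
  if (is.null(names(fields)) || any(!nzchar(names(fields)))) {
    abort_input("`fields` must be a named list keyed by montage_id.")
  }
  lens <- lengths(fields)
  if (length(unique(lens)) != 1L) {
    rlang::abort(sprintf(
      "Field vectors disagree on node count: %s.",
      paste(unique(lens), collapse = " vs ")),
      class = c("pecmap_alignment_error", "pecmap_error"))
  }
  missing <- setdiff(unique(outcomes$montage_id), names(fields))
  if (length(missing)) {
    rlang::abort(sprintf("No field for montage id(s): %s.",
                         paste(missing, collapse = ", ")),
                 class = c("pecmap_lookup_error", "pecmap_error"))
  }
  n_nodes <- lens[[1]]
  values <- vapply(outcomes$montage_id,
                   function(id) as.numeric(fields[[id]]),
                   numeric(n_nodes), USE.NAMES = FALSE)
  values <- matrix(values, nrow = n_nodes)
  if (anyNA(values) || !all(is.finite(values)) || any(values < 0)) {
    abort_format("Field matrix contains negative or non-finite magnitudes.")
  }
  if (is.null(nodes)) {
    nodes <- tibble(node_id = seq_len(n_nodes) - 1L,
                    x = NA_real_, y = NA_real_, z = NA_real_)
  }
  structure(list(values = values,
                 outcome_ids = outcomes$outcome_id,
                 montage_ids = outcomes$montage_id,
                 nodes = nodes),
            class = "field_matrix")
}

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf("<field_matrix> %d nodes x %d outcomes (%d distinct montages)\n",
              nrow(x$values), ncol(x$values), length(unique(x$montage_ids))))
  invisible(x)
}

#' Cache a field matrix as delimited text
#'
#' Writes `values.tsv` (nodes x outcomes, 12 significant digits) and
#' `outcome_ids.txt` under `dir`; [read_field_matrix_cache()] restores them.
#'
#' @param matrix A `field_matrix`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_field_matrix_cache <- function(matrix, dir) {
  stopifnot(inherits(matrix, "field_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(matrix$values)
  names(df) <- matrix$outcome_ids
  write_tsv_exact(df, file.path(dir, "values.tsv"))
  writeLines(matrix$outcome_ids, file.path(dir, "outcome_ids.txt"))
  write_tsv_exact(as.data.frame(matrix$nodes), file.path(dir, "nodes.tsv"))
  invisible(dir)
}

#' @rdname write_field_matrix_cache
#' @export
read_field_matrix_cache <- function(dir) {
  values <- as.matrix(utils::read.delim(file.path(dir, "values.tsv"),
                                        check.names = FALSE))
  outcome_ids <- readLines(file.path(dir, "outcome_ids.txt"))
  nodes <- as_tibble(utils::read.delim(file.path(dir, "nodes.tsv")))
  dimnames(values) <- NULL
  structure(list(values = values, outcome_ids = outcome_ids,
                 montage_ids = rep(NA_character_, length(outcome_ids)),
                 nodes = nodes),
            class = "field_matrix")
}
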
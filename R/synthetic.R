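# Synthetic data: toy meshes, distance-decay montage fields, and outcome
# corpora with a planted field->performance relationship. Stands in for
# head-model simulations and the digitized study corpus so the whole
# pipeline is testable at desk scale.

#' Build a toy node mesh with a contiguous parcellation
#'
#' Two layouts: a square planar `"grid"` (tiles as parcels) or a
#' `"sphere_surface"` Fibonacci lattice (equal-count latitude bands as
#' parcels). Coordinates are MNI-like millimetres; parcels are contiguous
#' spatial blocks with near-equal node counts, labeled `P01`, `P02`, ...
#'
#' @param n_nodes Number of nodes (>= `n_parcels`).
#' @param layout `"grid"` or `"sphere_surface"`.
#' @param n_parcels Number of parcels.
#' @param seed Master seed (only consumed when `jitter_sd > 0`).
#' @param spacing Grid spacing in mm (default 1.5, giving a cortex-scale
#'   patch of ~15 cm at 10,000 nodes).
#' @param radius Sphere radius in mm (default 70, head-sized).
#' @param jitter_sd Gaussian coordinate jitter in mm (default 0); used to
#'   emulate anatomical variability across head models.
#' @return List with `nodes` (tibble `node_id`, `x`, `y`, `z`) and
#'   `parcellation` (a `pec_parcellation`).
#' @export
build_toy_mesh <- function(n_nodes, layout = c("grid", "sphere_surface"),
                           n_parcels = 1, seed = 1, spacing = 1.5,
                           radius = 70, jitter_sd = 0) {
  layout <- match.arg(layout)
  if (n_parcels > n_nodes) abort_input("`n_parcels` cannot exceed `n_nodes`.")
  if (n_parcels < 1) abort_input("`n_parcels` must be >= 1.")
  if (layout == "grid") {
    nr <- floor(sqrt(n_nodes))
    nc <- ceiling(n_nodes / nr)
    row <- rep(seq_len(nr), each = nc)[seq_len(n_nodes)]
    col <- rep(seq_len(nc), times = nr)[seq_len(n_nodes)]
    x <- (col - (nc + 1) / 2) * spacing
    y <- (row - (nr + 1) / 2) * spacing
    z <- rep(0, n_nodes)
    # parcel tiles: factor n_parcels into the most square pr x pc split
    pr <- max(Filter(function(k) n_parcels %% k == 0, seq_len(floor(sqrt(n_parcels)))))
    pc <- n_parcels %/% pr
    band_r <- pmin(pr, 1L + floor((row - 1) * pr / nr))
    band_c <- pmin(pc, 1L + floor((col - 1) * pc / nc))
    parcel_idx <- (band_r - 1L) * pc + band_c
  } else {
    i <- seq_len(n_nodes) - 0.5
    golden <- pi * (3 - sqrt(5))
    zf <- 1 - 2 * i / n_nodes
    r <- sqrt(pmax(0, 1 - zf^2))
    theta <- golden * (seq_len(n_nodes) - 1)
    x <- radius * r * cos(theta)
    y <- radius * r * sin(theta)
    z <- radius * zf
    # equal-count latitude bands (spherical caps/slices)
    ord <- order(z)
    band <- integer(n_nodes)
    band[ord] <- 1L + floor((seq_len(n_nodes) - 1) * n_parcels / n_nodes)
    parcel_idx <- band
  }
  if (jitter_sd > 0) {
    with_stream_seed(seed, "mesh", 0L, {
      x <- x + rnorm(n_nodes, 0, jitter_sd)
      y <- y + rnorm(n_nodes, 0, jitter_sd)
      z <- z + rnorm(n_nodes, 0, jitter_sd)
    })
  }
  labels <- sprintf("P%02d", parcel_idx)
  list(nodes = tibble(node_id = seq_len(n_nodes) - 1L, x = x, y = y, z = z),
       parcellation = new_parcellation(labels))
}

#' Generate a set of toy stimulation montages
#'
#' Places anode/cathode centers at seeded random mesh nodes (cathode drawn
#' to be distant from the anode), so each montage induces a distinct smooth
#' field distribution over the mesh, as real electrode placements do.
#'
#' @param n_montages Number of montages (>= 2 for a usable corpus).
#' @param mesh A mesh from [build_toy_mesh()].
#' @param seed Master seed (stream `"montage"`).
#' @param current Stimulation intensity in mA (default 2, the common upper
#'   end of experimental protocols).
#' @param decay_length Spatial decay length lambda in mm (default 30).
#' @return Tibble with one row per montage: `montage_id`, anode/cathode
#'   coordinates, `current`, `decay_length`.
#' @export
toy_montages <- function(n_montages, mesh, seed = 1, current = 2,
                         decay_length = 30) {
  nodes <- mesh$nodes
  with_stream_seed(seed, "montage", 0L, {
    anodes <- sample(nrow(nodes), n_montages, replace = FALSE)
    cath <- vapply(anodes, function(a) {
      d <- sqrt((nodes$x - nodes$x[a])^2 + (nodes$y - nodes$y[a])^2 +
                  (nodes$z - nodes$z[a])^2)
      far <- which(d >= stats::median(d))
      far[sample.int(length(far), 1)]
    }, integer(1))
  })
  tibble(montage_id = sprintf("M%02d", seq_len(n_montages)),
         anode_x = nodes$x[anodes], anode_y = nodes$y[anodes],
         anode_z = nodes$z[anodes],
         cathode_x = nodes$x[cath], cathode_y = nodes$y[cath],
         cathode_z = nodes$z[cath],
         current = current, decay_length = decay_length)
}

#' Toy electric-field map for one montage
#'
#' Distance-decay kernel standing in for a finite-element field solution:
#' `|E|(node) = current * (exp(-d_a / lambda) + exp(-d_c / lambda))` with
#' `d_a`, `d_c` the Euclidean distances (mm) to the anode and cathode
#' centers and `lambda` the decay length. Strictly positive, maximal near
#' the electrodes, and linear in current — the properties the downstream
#' statistics actually consume.
#'
#' @param montage One-row tibble as produced by [toy_montages()].
#' @param mesh A mesh from [build_toy_mesh()].
#' @return Numeric field vector over nodes (mV/mm scale), with attribute
#'   `montage_id`.
#' @export
toy_field <- function(montage, mesh) {
  stopifnot(nrow(montage) == 1L)
  if (montage$current < 0) abort_input("`current` must be >= 0.")
  nodes <- mesh$nodes
  d_a <- sqrt((nodes$x - montage$anode_x)^2 + (nodes$y - montage$anode_y)^2 +
                (nodes$z - montage$anode_z)^2)
  d_c <- sqrt((nodes$x - montage$cathode_x)^2 + (nodes$y - montage$cathode_y)^2 +
                (nodes$z - montage$cathode_z)^2)
  f <- montage$current * (exp(-d_a / montage$decay_length) +
                            exp(-d_c / montage$decay_length))
  structure(f, montage_id = montage$montage_id)
}

# Mean field over the planted region, one value per montage.
planted_mean_field <- function(fields, labels, planted_parcels) {
  idx <- which(labels %in% planted_parcels)
  if (!length(idx)) abort_input("Planted parcel(s) contain no nodes.")
  vapply(fields, function(f) mean(f[idx]), numeric(1))
}

#' Solve for the planted slope giving a target population PEC
#'
#' Under the generative model `g = beta * meanE + noise`, the population PEC
#' at a planted node i is
#' `rho_i = beta * cov(E_i, meanE) / (sd(E_i) * sqrt(beta^2 var(meanE) + noise_sd^2))`,
#' with moments taken over the montage list (population denominator n,
#' matching round-robin assignment). Averaging `cov(E_i, meanE) / sd(E_i)`
#' over the planted nodes to a constant `A`, the mean planted-node PEC
#' equals the target when
#' `beta = target * noise_sd / sqrt(A^2 - target^2 var(meanE))`.
#' When `node_fields` is omitted the region is treated as a single node
#' (`A = sd(meanE)`), i.e. the target applies to the parcel-mean dose.
#'
#' @param target_pec Desired mean population PEC over the planted nodes,
#'   in (0, 1).
#' @param noise_sd Noise standard deviation of the effect sizes.
#' @param mean_field Per-montage mean field over the planted region.
#' @param node_fields Optional matrix (planted nodes x montages) of field
#'   values used to average the node-level coupling.
#' @return The slope beta (effect-size units per mV/mm).
#' @export
calibrate_beta <- function(target_pec, noise_sd, mean_field, node_fields = NULL) {
  if (target_pec <= 0 || target_pec >= 1) abort_input("`target_pec` must be in (0, 1).")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  var_m <- pop_sd(mean_field)^2
  if (var_m == 0) abort_input("Planted mean field is constant across montages.")
  A <- if (is.null(node_fields)) {
    sqrt(var_m)
  } else {
    mc <- mean_field - mean(mean_field)
    mean(apply(node_fields, 1, function(e) {
      s <- pop_sd(e)
      if (s == 0) 0 else mean((e - mean(e)) * mc) / s
    }))
  }
  if (A^2 <= target_pec^2 * var_m) {
    abort_input("Target PEC is unattainable: planted nodes couple too weakly to the regional dose.")
  }
  target_pec * noise_sd / sqrt(A^2 - target_pec^2 * var_m)
}

# Corpus label proportions mirrored from the meta-analytic study sample:
# accuracy/reaction-time/other 181/144/29, verbal/visuospatial 271/73,
# online/offline 164/190.
label_proportions <- list(
  measure = c(accuracy = 181, reaction_time = 144, other = 29),
  wm_type = c(verbal = 271, visuospatial = 73),
  timing  = c(online = 164, offline = 190))

#' Generate a synthetic study corpus with a planted dose-response effect
#'
#' Builds (or accepts) a toy mesh and montage set, simulates per-montage
#' field maps, and draws outcome-level effect sizes from
#' `g_j = beta * meanE_j + noise`, where `meanE_j` is the mean field of
#' outcome j's montage over the planted parcels. With `beta = 0` the corpus
#' is a pure null. Montages are assigned round-robin; domain labels are
#' drawn independently with the corpus proportions of the meta-analytic
#' sample, so all six canonical subsets are populated.
#'
#' @param n_outcomes Number of outcomes (>= 3; default 354, the corpus size
#'   emulated).
#' @param mesh Optional mesh from [build_toy_mesh()]; built from
#'   `mesh_nodes`/`layout`/`n_parcels` when `NULL`.
#' @param mesh_nodes,layout,n_parcels Mesh parameters used when `mesh` is
#'   `NULL` (defaults 5000 grid nodes, 16 parcels).
#' @param montages Optional montage tibble; `n_montages` random montages are
#'   placed when `NULL`.
#' @param n_montages Number of montages when placing them (default 12).
#' @param planted_parcels Character vector of parcel labels carrying the
#'   true effect (empty for a null corpus).
#' @param beta Planted slope; ignored when `target_pec` is given.
#' @param target_pec If non-`NULL`, `beta` is solved with [calibrate_beta()]
#'   so the population correlation between planted-region dose and g equals
#'   this value.
#' @param noise_sd Independent effect-size noise sd (default 0.3, the
#'   dispersion scale of small-effect behavioral corpora).
#' @param seed Master seed; mesh jitter, montage placement, labels, sample
#'   sizes and noise each consume a derived stream.
#' @param jitter_sd Coordinate jitter in mm passed to the mesh build.
#' @param current,decay_length Montage parameters (see [toy_montages()]).
#' @return A `synthetic_dataset` list: `outcomes` (tibble), `fields` (named
#'   list of field vectors), `mesh`, `parcellation`, `montages`, and `truth`
#'   (`planted_parcels`, `beta`, `target_pec`, `noise_sd`, `seed`).
#' @export
generate_study_set <- function(n_outcomes = 354, mesh = NULL,
                               mesh_nodes = 5000, layout = "grid",
                               n_parcels = 16, montages = NULL,
                               n_montages = 12,
                               planted_parcels = character(0),
                               beta = 0, target_pec = NULL, noise_sd = 0.3,
                               seed = 1, jitter_sd = 0, current = 2,
                               decay_length = 30) {
  if (n_outcomes < 3) abort_input("`n_outcomes` must be >= 3.")
  if (noise_sd < 0) abort_input("`noise_sd` must be >= 0.")
  if (is.null(mesh)) {
    mesh <- build_toy_mesh(mesh_nodes, layout, n_parcels, seed = seed,
                           jitter_sd = jitter_sd)
  }
  if (is.null(montages)) {
    montages <- toy_montages(n_montages, mesh, seed = seed,
                             current = current, decay_length = decay_length)
  }
  if (nrow(montages) < 2) {
    abort_input("At least 2 distinct montages are required (PEC is degenerate otherwise).")
  }
  fields <- lapply(seq_len(nrow(montages)),
                   function(i) as.numeric(toy_field(montages[i, ], mesh)))
  names(fields) <- montages$montage_id

  if (length(planted_parcels)) {
    known <- unique(mesh$parcellation$labels)
    if (length(bad <- setdiff(planted_parcels, known))) {
      abort_input(sprintf("Unknown planted parcel(s): %s.", paste(bad, collapse = ", ")))
    }
    mean_field <- planted_mean_field(fields, mesh$parcellation$labels, planted_parcels)
    if (!is.null(target_pec)) {
      idx <- which(mesh$parcellation$labels %in% planted_parcels)
      node_fields <- do.call(cbind, fields)[idx, , drop = FALSE]
      beta <- calibrate_beta(target_pec, noise_sd, mean_field, node_fields)
    }
  } else {
    mean_field <- rep(0, nrow(montages))
    beta <- 0
  }

  montage_of <- rep(montages$montage_id, length.out = n_outcomes)
  dose <- mean_field[match(montage_of, montages$montage_id)]

  draw_labels <- function(weights, n) {
    sample(names(weights), n, replace = TRUE, prob = weights / sum(weights))
  }
  outcomes <- with_stream_seed(seed, "labels", 0L, {
    tibble(
      study_id = sprintf("S%03d", 1L + (seq_len(n_outcomes) - 1L) %/% 5L),
      outcome_id = sprintf("O%04d", seq_len(n_outcomes)),
      montage_id = montage_of,
      measure = draw_labels(label_proportions$measure, n_outcomes),
      wm_type = draw_labels(label_proportions$wm_type, n_outcomes),
      timing = draw_labels(label_proportions$timing, n_outcomes),
      n_active = sample(12:30, n_outcomes, replace = TRUE),
      n_control = sample(12:30, n_outcomes, replace = TRUE))
  })
  noise <- with_stream_seed(seed, "noise", 0L, rnorm(n_outcomes, 0, noise_sd))
  outcomes$g <- as.numeric(beta * dose + noise)
  outcomes$oriented <- FALSE
  check_outcomes(outcomes)

  structure(list(outcomes = outcomes, fields = fields, mesh = mesh,
                 parcellation = mesh$parcellation, montages = montages,
                 truth = list(planted_parcels = planted_parcels, beta = beta,
                              target_pec = target_pec, noise_sd = noise_sd,
                              seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d outcomes, %d montages, %d nodes, %d parcels\n",
    nrow(x$outcomes), length(x$fields), nrow(x$mesh$nodes),
    nrow(x$parcellation$inventory)))
  if (length(x$truth$planted_parcels)) {
    cat(sprintf("  planted: %s (beta = %.4g)\n",
                paste(x$truth$planted_parcels, collapse = ", "), x$truth$beta))
  } else {
    cat("  null corpus (beta = 0)\n")
  }
  invisible(x)
}

#' Persist a synthetic dataset in the pipeline's input formats
#'
#' Writes `outcomes.csv`, one delimited field file per montage under
#' `fields/`, `parcellation.tsv`, `nodes.tsv`, and `truth.json`, so a
#' generated corpus can be re-ingested through the same readers real data
#' would use.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(file.path(dir, "fields"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(dataset$fields)) {
    f <- dataset$fields[[id]]
    write_tsv_exact(data.frame(node_id = seq_along(f) - 1L, value = f),
                    file.path(dir, "fields", paste0(id, ".tsv")))
  }
  write_tsv_exact(
    data.frame(node_id = seq_along(dataset$parcellation$labels) - 1L,
               parcel = dataset$parcellation$labels),
    file.path(dir, "parcellation.tsv"))
  write_tsv_exact(as.data.frame(dataset$mesh$nodes), file.path(dir, "nodes.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
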
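test_that("toy meshes tile parcels evenly and are reproducible", {
  mesh <- build_toy_mesh(100, "grid", 4)
  expect_equal(nrow(mesh$nodes), 100L)
  inv <- mesh$parcellation$inventory
  expect_equal(nrow(inv), 4L)
  expect_true(all(inv$n_nodes == 25L))
  # single parcel covers everything
  one <- build_toy_mesh(50, "grid", 1)
  expect_equal(nrow(one$parcellation$inventory), 1L)
  expect_equal(one$parcellation$inventory$n_nodes, 50L)
  # determinism under a fixed seed (jittered build)
  m1 <- build_toy_mesh(200, "sphere_surface", 8, seed = 3, jitter_sd = 2)
  m2 <- build_toy_mesh(200, "sphere_surface", 8, seed = 3, jitter_sd = 2)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$parcellation$labels, m2$parcellation$labels)
  # sphere bands are near-equal and contiguous in z
  sp <- build_toy_mesh(1000, "sphere_surface", 10)
  expect_true(all(abs(sp$parcellation$inventory$n_nodes - 100L) <= 1L))
  expect_error(build_toy_mesh(3, "grid", 5), class = "pecmap_invalid_input")
})

test_that("toy fields follow the closed-form distance-decay kernel", {
  mesh <- list(nodes = tibble::tibble(node_id = 0:2,
                                      x = c(0, 30, 100), y = 0, z = 0))
  montage <- tibble::tibble(montage_id = "M", anode_x = 0, anode_y = 0,
                            anode_z = 0, cathode_x = 60, cathode_y = 0,
                            cathode_z = 0, current = 1, decay_length = 30)
  f <- toy_field(montage, mesh)
  # node equidistant (lambda) from both electrodes: field = 2/e
  expect_equal(f[2], 2 * exp(-1), tolerance = 1e-12)
  expect_equal(f[1], exp(0) + exp(-2), tolerance = 1e-12)
  # linear in current; zero current kills the field
  montage2 <- montage; montage2$current <- 2
  expect_equal(as.numeric(toy_field(montage2, mesh)), 2 * as.numeric(f),
               tolerance = 1e-12)
  montage0 <- montage; montage0$current <- 0
  expect_true(all(toy_field(montage0, mesh) == 0))
  expect_true(all(f > 0))
})

test_that("beta calibration hits the target population correlation", {
  set.seed(17)
  mean_field <- runif(12, 1, 3)
  for (target in c(0.1, 0.3, 0.6)) {
    beta <- calibrate_beta(target, 0.3, mean_field)
    # population correlation under the generative model, computed directly
    sd_m <- sqrt(mean((mean_field - mean(mean_field))^2))
    rho <- beta * sd_m / sqrt(beta^2 * sd_m^2 + 0.3^2)
    expect_equal(rho, target, tolerance = 1e-12)
  }
  expect_error(calibrate_beta(1.2, 0.3, mean_field), class = "pecmap_invalid_input")
  expect_error(calibrate_beta(0.3, 0.3, rep(1, 5)), class = "pecmap_invalid_input")
  # node-level route: the mean population PEC over planted nodes hits the target
  E <- matrix(runif(5 * 12, 0.5, 3), nrow = 5)
  meanE <- colMeans(E)
  beta <- calibrate_beta(0.3, 0.3, meanE, E)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_g <- sqrt(beta^2 * pop_sd(meanE)^2 + 0.3^2)
  rho <- apply(E, 1, function(e) {
    beta * mean((e - mean(e)) * (meanE - mean(meanE))) / (pop_sd(e) * sd_g)
  })
  expect_equal(mean(rho), 0.3, tolerance = 1e-12)
})

test_that("generated corpora are seed-reproducible and internally aligned", {
  ds1 <- generate_study_set(n_outcomes = 60, mesh_nodes = 300, n_parcels = 4,
                            n_montages = 4, planted_parcels = "P03",
                            target_pec = 0.3, seed = 5)
  ds2 <- generate_study_set(n_outcomes = 60, mesh_nodes = 300, n_parcels = 4,
                            n_montages = 4, planted_parcels = "P03",
                            target_pec = 0.3, seed = 5)
  expect_identical(ds1$outcomes, ds2$outcomes)
  expect_identical(ds1$fields, ds2$fields)
  # every montage in the table has a field of mesh length
  expect_true(all(ds1$outcomes$montage_id %in% names(ds1$fields)))
  expect_true(all(lengths(ds1$fields) == nrow(ds1$mesh$nodes)))
  # truth is recorded verbatim
  expect_identical(ds1$truth$planted_parcels, "P03")
  expect_equal(ds1$truth$target_pec, 0.3)
  # a different seed moves the noise
  ds3 <- generate_study_set(n_outcomes = 60, mesh_nodes = 300, n_parcels = 4,
                            n_montages = 4, planted_parcels = "P03",
                            target_pec = 0.3, seed = 6)
  expect_false(identical(ds1$outcomes$g, ds3$outcomes$g))
  expect_error(generate_study_set(n_outcomes = 10, n_montages = 1),
               class = "pecmap_invalid_input")
})

test_that("degenerate null config yields all-equal g that PEC rejects", {
  ds <- generate_study_set(n_outcomes = 12, mesh_nodes = 100, n_parcels = 4,
                           n_montages = 3, beta = 0, noise_sd = 0, seed = 2)
  expect_true(all(ds$outcomes$g == 0))
  fm <- assemble_field_matrix(ds$outcomes, ds$fields)
  expect_error(compute_pec(fm, ds$outcomes$g), class = "pecmap_invalid_input")
})

test_that("label scheme mirrors the corpus proportions", {
  ds <- generate_study_set(n_outcomes = 4000, mesh_nodes = 100, n_parcels = 4,
                           n_montages = 4, seed = 9)
  tab <- table(ds$outcomes$measure) / 4000
  expect_equal(unname(tab["accuracy"]), 181 / 354, tolerance = 0.05)
  expect_equal(unname(tab["reaction_time"]), 144 / 354, tolerance = 0.05)
  wt <- table(ds$outcomes$wm_type) / 4000
  expect_equal(unname(wt["verbal"]), 271 / 344, tolerance = 0.05)
  tm <- table(ds$outcomes$timing) / 4000
  expect_equal(unname(tm["online"]), 164 / 354, tolerance = 0.05)
})

test_that("planted signal raises PEC inside the planted parcel", {
  # sample PEC gap (inside minus outside) is positive in almost all replicates
  gaps <- vapply(1:10, function(rep) {
    ds <- generate_study_set(n_outcomes = 200, mesh_nodes = 400, n_parcels = 4,
                             n_montages = 8, planted_parcels = "P02",
                             target_pec = 0.3, noise_sd = 0.3, seed = 100 + rep)
    fm <- assemble_field_matrix(ds$outcomes, ds$fields, nodes = ds$mesh$nodes)
    map <- compute_pec(fm, ds$outcomes$g)
    inside <- ds$parcellation$labels == "P02"
    mean(map$pec[inside & !map$degenerate]) -
      mean(map$pec[!inside & !map$degenerate])
  }, 0)
  expect_true(mean(gaps > 0) >= 0.9)
})

test_that("synthetic datasets round-trip through the pipeline's file formats", {
  ds <- generate_study_set(n_outcomes = 20, mesh_nodes = 64, n_parcels = 4,
                           n_montages = 3, planted_parcels = "P01",
                           target_pec = 0.3, seed = 4)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  out <- read_outcomes(file.path(dir, "outcomes.csv"), orient = FALSE)
  expect_equal(out$g, ds$outcomes$g, tolerance = 1e-11)
  f <- read_node_field(file.path(dir, "fields", "M01.tsv"), 64)
  expect_equal(as.numeric(f), ds$fields$M01, tolerance = 1e-11)
  pc <- read_parcellation(file.path(dir, "parcellation.tsv"), 64)
  expect_identical(pc$labels, ds$parcellation$labels)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$planted_parcels, "P01")
})
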
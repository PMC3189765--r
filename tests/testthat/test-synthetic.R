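test_that("spec validation enforces the documented bounds", {
  expect_error(synthetic_spec(n_compounds = 0), ">= 8")
  expect_error(synthetic_spec(n_compounds = 5), ">= 8")
  expect_error(synthetic_spec(endpoint_r2 = 1.5), "endpoint_r2")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(substituent_library = character(0)), "empty")
  expect_error(synthetic_spec(substituent_library = c("Me", "Xx")), "unknown")
})

test_that("the scaffold is identical across the series and output is seeded", {
  sset <- synthetic_series(n = 10, seed = 4)
  n_scaf <- qsar3d:::.scaffold_template()$n_scaffold_atoms
  ref <- qsar3d:::coords(sset$mols[[1]])[1:n_scaf, ]
  for (m in sset$mols)
    expect_lt(max(abs(qsar3d:::coords(m)[1:n_scaf, ] - ref)), 1e-12)
  # same spec -> byte-identical SDF
  spec <- synthetic_spec(n_compounds = 10, seed = 4)
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(make_congeneric_series(spec), p1)
  write_molecules(make_congeneric_series(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated molecules are chemically coherent", {
  sset <- synthetic_series(n = 12, seed = 6)
  for (m in sset$mols) {
    expect_lt(abs(sum(m$atoms$partial_charge) - sum(m$atoms$formal_charge)),
              1e-6)
    # no catastrophic overlap (idealized geometry allows mild bay-region
    # crowding, as unminimized structures do)
    D <- as.matrix(stats::dist(qsar3d:::coords(m)))
    diag(D) <- Inf
    expect_gt(min(D), 0.75)
  }
})

test_that("planted activities behave as configured", {
  sset <- synthetic_series(n = 20, seed = 3)
  acts <- sset$activities
  expect_identical(nrow(acts), 40L)           # two endpoints
  expect_identical(sort(unique(acts$endpoint)), c("I", "II"))
  expect_identical(sum(acts$set_label == "test"), 2L * sset$spec$n_test)
  # truth weights reproduce the noiseless part of endpoint I exactly
  tr <- sset$truth
  y1 <- acts$pic50[acts$endpoint == "I"]
  G <- lattice_points(sset$lattice)
  V <- matrix(NA_real_, length(sset$mols), nrow(tr$planted))
  for (f in unique(tr$planted$field)) {
    jj <- which(tr$planted$field == f)
    pts <- G[tr$planted$cell[jj], , drop = FALSE]
    for (i in seq_along(sset$mols))
      V[i, jj] <- qsar3d:::.field_values_at(sset$mols[[i]], pts, f)
  }
  recon <- as.numeric(V %*% tr$planted$weight)
  recon <- recon - mean(recon) + mean(y1 - tr$noise)
  expect_lt(max(abs(recon - (y1 - tr$noise))), 1e-9)
})

test_that("endpoint_r2 = 1 makes the endpoints exactly affine", {
  spec <- synthetic_spec(n_compounds = 10, endpoint_r2 = 1, seed = 2)
  mols <- make_congeneric_series(spec)
  pa <- plant_activities(mols, build_lattice(mols, 2, 4), spec)
  a <- pa$activities
  fit <- stats::lm(a$pic50[a$endpoint == "II"] ~ a$pic50[a$endpoint == "I"])
  expect_lt(max(abs(stats::resid(fit))), 1e-9)
})

test_that("recovery degrades monotonically with planted noise", {
  q2s <- vapply(c(0, 0.2, 0.5, 1.0), function(ns) {
    sset <- synthetic_series(n = 40, seed = 9, noise_sd = ns, n_test = 8)
    acts <- sset$activities[sset$activities$endpoint == "I", ]
    fb <- compute_fields(sset$mols, sset$lattice, probe_spec(), "comfa")
    y <- stats::setNames(acts$pic50, acts$compound_id)
    dm <- assemble_descriptors(fb, sigma_min = 1.0)
    loo <- loo_validate(dm, y, c_max = 5)
    loo$q2[loo$opn]
  }, numeric(1))
  expect_true(all(diff(q2s) < 0.05))    # non-increasing within replicate noise
  expect_gt(q2s[1], q2s[4])
})

test_that("benchmark bundles are complete, consistent and reproducible", {
  dir1 <- withr::local_tempdir()
  spec <- synthetic_spec(n_compounds = 10, seed = 5)
  b1 <- generate_benchmark(spec, file.path(dir1, "b1"))
  expect_setequal(basename(b1$paths),
                  c("molecules.sdf", "activities.csv", "truth.json",
                    "config.json"))
  expect_length(dir(file.path(dir1, "b1")), 4L)
  acts <- read_activities(file.path(dir1, "b1", "activities.csv"))
  expect_identical(nrow(acts), 20L)       # 2 * n_compounds
  # refusal to overwrite
  expect_error(generate_benchmark(spec, file.path(dir1, "b1")), "not empty")
  # truth cells re-locatable on the rebuilt lattice
  truth <- jsonlite::read_json(file.path(dir1, "b1", "truth.json"),
                               simplifyVector = TRUE)
  mols <- read_molecules(file.path(dir1, "b1", "molecules.sdf"), "sdf")
  lat <- build_lattice(mols, truth$lattice$spacing, 4.0)
  expect_identical(lat$dims, truth$lattice$dims)
  expect_equal(as.numeric(lat$origin), truth$lattice$origin, tolerance = 1e-4)
  expect_true(all(truth$planted$cell >= 1 &
                    truth$planted$cell <= prod(lat$dims)))
  # bit-identical regeneration
  b2 <- generate_benchmark(spec, file.path(dir1, "b2"))
  for (f in c("molecules.sdf", "activities.csv", "truth.json", "config.json"))
    expect_identical(readLines(file.path(dir1, "b1", f)),
                     readLines(file.path(dir1, "b2", f)))
})

test_that("generated feature geometry survives SDF round-trip and re-perception", {
  sset <- synthetic_series(n = 8, seed = 2)
  mol <- sset$mols[[1]]
  f1 <- perceive_features(mol)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mol, path)
  back <- prepare_molecules(read_molecules(path, "sdf"))[[1]]
  f2 <- perceive_features(back)
  expect_identical(f2$kind, f1$kind)
  expect_lt(max(abs(as.matrix(f2[, c("x", "y", "z")]) -
                      as.matrix(f1[, c("x", "y", "z")]))), 1e-3)
})
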
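test_that("feature perception applies the typing rules", {
  bz <- prep(fix_benzene())
  f <- perceive_features(bz)
  expect_identical(sort(unique(f$kind)), c("AR", "HP"))
  expect_identical(sum(f$kind == "AR"), 1L)
  expect_identical(sum(f$kind == "HP"), 1L)
  expect_lt(max(abs(as.numeric(f[f$kind == "AR", c("x", "y", "z")]))), 1e-9)

  ph <- prep(fix_phenol())
  fp <- perceive_features(ph)
  expect_true(all(c("HD", "HA", "DS", "AR") %in% fp$kind))
  ds <- as.numeric(fp[fp$kind == "DS", c("x", "y", "z")])
  o <- as.numeric(ph$atoms[7, c("x", "y", "z")])
  h <- as.numeric(ph$atoms[8, c("x", "y", "z")])
  expect_equal(ds, o + 2.9 * (h - o) / sqrt(sum((h - o)^2)), tolerance = 1e-9)
  expect_equal(sqrt(sum((ds - o)^2)), 2.9, tolerance = 1e-6)

  tma <- prep(fix_trimethylammonium())
  ft <- perceive_features(tma)
  expect_identical(sum(ft$kind == "PN"), 1L)
  expect_false(any(ft$kind == "HA" & ft$parent == 1L))
  expect_error(perceive_features(fix_benzene()), "charges")
})

test_that("conformer generation is bounded, seeded and trivial for rigid input", {
  bz <- prep(fix_benzene())
  bz <- generate_conformers(bz, pharm_params())
  expect_length(bz$conformers, 1L)

  sset <- synthetic_series(n = 8, seed = 2)
  mol <- sset$mols[[2]]
  pp <- pharm_params(n_conformers_max = 20L, n_conformers_select = 5L, seed = 7L)
  c1 <- generate_conformers(mol, pp)
  expect_lte(length(c1$conformers), 5L)
  c2 <- generate_conformers(mol, pp)
  expect_identical(c1$conformers, c2$conformers)
  # bond lengths are preserved by torsion sampling
  X0 <- qsar3d:::coords(mol)
  for (X in c1$conformers) {
    d0 <- sqrt(rowSums((X0[mol$bonds$a1, ] - X0[mol$bonds$a2, ])^2))
    d1 <- sqrt(rowSums((X[mol$bonds$a1, ] - X[mol$bonds$a2, ])^2))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("planted six-feature sets are recovered exactly", {
  pp <- pharm_params()
  set <- make_planted_pharmacophore_set(5)
  models <- disco_search(set$mols, "act_01", pp, features = set$features)
  expect_gte(length(models), 1L)
  top <- models[[1]]
  expect_identical(top$size, 6L)
  expect_identical(sort(top$features$kind),
                   sort(c("HD", "HA", "DS", "HP", "HP", "AR")))
  expect_identical(top$hits, 5L)
  D <- stats::dist(as.matrix(set$planted[, c("x", "y", "z")]))
  expect_equal(top$dmean, mean(D), tolerance = 1e-9)
  expect_equal(top$score, 6, tolerance = 1e-9)   # zero deviation
})

test_that("a feature jittered beyond tolerance is dropped from the model", {
  pp <- pharm_params()
  set <- make_planted_pharmacophore_set(5, jitter_feature = 2, jitter = 1.0)
  models <- disco_search(set$mols, "act_01", pp, features = set$features)
  top <- models[[1]]
  expect_identical(top$size, 5L)
  expect_false("HA" %in% top$features$kind)
  expect_identical(top$hits, 5L)
})

test_that("too few common features yields an empty result, not an error", {
  pp <- pharm_params(min_features = 4L)
  set <- make_planted_pharmacophore_set(3)
  # leave only 3 common features per non-reference molecule
  for (i in 2:3) set$features[[i]] <- set$features[[i]][1:3, ]
  models <- disco_search(set$mols, "act_01", pp, features = set$features)
  expect_length(models, 0L)
  expect_error(disco_search(set$mols, "missing", pp, features = set$features),
               "not in molecule set")
})

test_that("model metrics match hand geometry", {
  # 3-4-5 triangle of features: dmean = 4
  f <- data.frame(kind = c("HD", "HA", "AR"),
                  x = c(0, 3, 0), y = c(0, 0, 4), z = 0, parent = 1L)
  mols <- make_planted_pharmacophore_set(2)$mols[1:2]
  feats <- list(act_01 = f, act_02 = f)
  pp <- pharm_params(min_features = 3L)
  models <- disco_search(mols, "act_01", pp, features = feats)
  m <- models[[1]]
  expect_equal(m$dmean, 4, tolerance = 1e-12)
  met <- model_metrics(m, mols, pp, features = feats)
  expect_identical(met$hits, 2L)
  expect_equal(met$score, 3, tolerance = 1e-12)
})

test_that("distance tables are symmetric with zero diagonal and exact values", {
  sq <- data.frame(kind = c("HD", "HA", "HP", "AR"),
                   x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0, parent = 1L)
  mols <- make_planted_pharmacophore_set(2)$mols[1:2]
  pp <- pharm_params(min_features = 4L)
  models <- disco_search(mols, "act_01", pp,
                         features = list(act_01 = sq, act_02 = sq))
  D <- distance_table(models[[1]])
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  offd <- sort(unique(round(D[upper.tri(D)], 10)))
  expect_equal(offd, c(1, sqrt(2)), tolerance = 1e-10)
  # brute-force pairwise distances
  P <- as.matrix(sq[, c("x", "y", "z")])
  ref <- as.matrix(stats::dist(P))
  expect_lt(max(abs(unname(D) - unname(ref))), 1e-12)
})

test_that("every returned model satisfies the tolerance for every hit", {
  pp <- pharm_params()
  sset <- synthetic_series(n = 8, seed = 2)
  mols <- sset$mols[1:4]
  mols <- molecule_set(lapply(mols, generate_conformers,
                              params = pharm_params(n_conformers_max = 10L,
                                                    n_conformers_select = 3L)))
  models <- disco_search(mols, names(mols)[1], pp)
  expect_gte(length(models), 1L)
  # independent checker: best assignment exists within 2*tolerance per pair
  for (m in models[seq_len(min(3, length(models)))]) {
    for (id in names(mols)) {
      ok <- FALSE
      for (X in mols[[id]]$conformers) {
        fm <- perceive_features(mols[[id]], xyz = X)
        if (!is.null(qsar3d:::.best_assignment(m, fm, 2 * pp$tolerance)))
          ok <- TRUE
      }
      expect_true(ok)
    }
    expect_identical(m$hits, length(mols))
  }
})

test_that("the search is invariant under rigid transformation of one input", {
  pp <- pharm_params()
  set <- make_planted_pharmacophore_set(4)
  models1 <- disco_search(set$mols, "act_01", pp, features = set$features)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  f3 <- set$features
  P <- as.matrix(f3$act_03[, c("x", "y", "z")]) %*% t(R)
  f3$act_03$x <- P[, 1] + 4; f3$act_03$y <- P[, 2] - 2; f3$act_03$z <- P[, 3]
  models2 <- disco_search(set$mols, "act_01", pp, features = f3)
  expect_identical(models1[[1]]$size, models2[[1]]$size)
  expect_equal(models1[[1]]$dmean, models2[[1]]$dmean, tolerance = 1e-9)
  expect_identical(models1[[1]]$hits, models2[[1]]$hits)
})
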
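fake_fieldblock <- function(M, name = "comfa_steric", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(nrow(M)))
  rownames(M) <- ids
  vals <- list(); vals[[name]] <- M
  structure(list(values = vals, clash = NULL,
                 lattice = structure(list(origin = c(0, 0, 0), spacing = 1,
                                          dims = c(ncol(M), 1L, 1L)),
                                     class = "lattice"),
                 ids = ids), class = "field_block_set")
}

test_that("column filtering masks flat lattice columns and spares extras", {
  M <- cbind(rep(2, 6),                # constant -> sd 0
             c(0, 0.5, 1, 0, 0.5, 1), # sd ~ 0.45 < 1
             c(0, 4, 8, 0, 4, 8))     # sd 3.58 >= 1
  fb <- fake_fieldblock(M)
  extras <- data.frame(ClogP = rep(1.5, 6),
                       row.names = sprintf("m%02d", 1:6))
  dm <- assemble_descriptors(fb, extras = extras, sigma_min = 1.0)
  expect_identical(unname(dm$retained), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(stats::sd(c(0, 0.5, 1, 0, 0.5, 1)), 0.4472136, tolerance = 1e-6)
  expect_error(assemble_descriptors(fb, extras = extras[1:3, , drop = FALSE]),
               "missing extra")
})

test_that("clash points are mean-filled from the training rows", {
  M <- matrix(rnorm(24), 6, 4)
  M[1, 2] <- NA; M[5, 2] <- NA
  fb <- fake_fieldblock(M, "comfa_elec")
  dm <- assemble_descriptors(fb, sigma_min = 0,
                             train_ids = sprintf("m%02d", 1:4))
  expect_equal(dm$X[1, 2], mean(M[2:4, 2]))
  expect_equal(dm$X[5, 2], mean(M[2:4, 2]))
})

test_that("block scaling equalizes block variance and leaves 'none' untouched", {
  set.seed(5)
  M1 <- matrix(rnorm(40, sd = 9), 8, 5)
  M2 <- matrix(rnorm(40, sd = 0.1), 8, 5)
  fb <- fake_fieldblock(M1)
  fb$values$comfa_elec <- M2
  rownames(fb$values$comfa_elec) <- fb$ids
  dm <- assemble_descriptors(fb, sigma_min = 0)
  sc <- block_scale(dm, "comfa_std")
  tv <- function(X) sum(apply(X, 2, var))
  v1 <- tv(sc$X[, sc$col_field == "comfa_steric"])
  v2 <- tv(sc$X[, sc$col_field == "comfa_elec"])
  expect_equal(v1, 5, tolerance = 1e-9)   # total variance = column count
  expect_equal(v1, v2, tolerance = 1e-9)
  un <- block_scale(dm, "none")
  expect_identical(un$X, dm$X)
})

test_that("NIPALS recovers exact single-column relations and closed forms", {
  set.seed(2)
  # y proportional to the sole predictor: one component fits exactly
  X1 <- matrix(rnorm(12), 12, 1)
  y1 <- 3 * X1[, 1] - 1
  f1 <- nipals_pls(X1, y1, 1)
  expect_lt(max(abs(predict(f1, X1) - y1)), 1e-10)
  X <- matrix(rnorm(60), 12, 5)
  y <- 3 * X[, 2] - 1
  f <- nipals_pls(X, y, 1)
  # c = 1 weight is proportional to X'y on centered data
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w_ref <- crossprod(Xc, yc); w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_lt(min(max(abs(f$W[, 1] - w_ref)), max(abs(f$W[, 1] + w_ref))), 1e-10)
  expect_error(nipals_pls(X, rep(1, 12), 1), "constant")
  expect_error(nipals_pls(X, y, 12), "smaller")
})

test_that("NIPALS predictions match an independent PLS implementation", {
  set.seed(1)
  X <- matrix(rnorm(80), 10, 8)
  colnames(X) <- paste0("v", 1:8)
  y <- rnorm(10)
  fit <- nipals_pls(X, y, 3)
  for (cc in 1:3) {
    ref <- mixOmics::pls(X, y, ncomp = cc, mode = "regression", scale = FALSE)
    p_ref <- predict(ref, X)$predict[, 1, cc]
    expect_lt(max(abs(p_ref - predict(fit, X, ncomp = cc))), 1e-8)
  }
  # successive scores are mutually orthogonal
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("LOO equals an explicit per-row refit loop exactly", {
  set.seed(3)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  got <- loo_validate(X, y, c_max = 3, scheme = "none")
  for (cc in 1:3) {
    pred <- vapply(seq_len(8), function(k) {
      f <- nipals_pls(X[-k, ], y[-k], cc)
      predict(f, X[k, , drop = FALSE], ncomp = min(cc, f$ncomp))
    }, numeric(1))
    q2_ref <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
    expect_equal(got$q2[cc], q2_ref, tolerance = 1e-10)
  }
})

test_that("LOO on noiseless low-rank data is essentially perfect at c = 1", {
  set.seed(4)
  t1 <- rnorm(20)
  X <- outer(t1, rnorm(6)) + 1e-9 * matrix(rnorm(120), 20, 6)
  y <- 2 * t1 + 5
  got <- loo_validate(X, y, c_max = 2, scheme = "none")
  expect_gte(got$q2[1], 0.999)
})

test_that("permuting the response destroys cross-validated predictivity", {
  sset <- synthetic_series(n = 20, seed = 3)
  acts <- sset$activities[sset$activities$endpoint == "I", ]
  fb <- compute_fields(sset$mols, sset$lattice, probe_spec(), "comfa")
  dm <- assemble_descriptors(fb, sigma_min = 1.0)
  y <- stats::setNames(acts$pic50, acts$compound_id)
  y_scr <- qsar3d:::.with_seed(99, function() sample(y))
  names(y_scr) <- names(y)
  got <- loo_validate(dm, y_scr, c_max = 3)
  expect_true(all(got$q2 <= 0.2))
})

test_that("F statistics reproduce the printed summary-table arithmetic", {
  # activity II models: F from printed (R2, n, OPN) matches the printed F
  f_comfa <- model_summary(r2 = 0.715, n = 57, c = 6)$f_stat
  expect_lt(abs(f_comfa - 20.907) / 20.907, 0.005)
  f_comsia <- model_summary(r2 = 0.657, n = 57, c = 4)$f_stat
  expect_lt(abs(f_comsia - 24.927) / 24.927, 0.005)
  expect_equal(model_summary(r2 = 0.5, n = 12, c = 1)$f_stat, 10)
  expect_error(model_summary(r2 = 0.5, n = 3, c = 2), "exceed")
})

test_that("a perfect fit reports SEE 0 and infinite F", {
  set.seed(6)
  M <- matrix(rnorm(6), 6, 1)
  fb <- fake_fieldblock(M)
  dm <- assemble_descriptors(fb, sigma_min = 0)
  y <- stats::setNames(2 * M[, 1] + 1, rownames(dm$X))
  model <- fit_qsar(dm, y, ncomp = 1, scheme = "none")
  s <- model_summary(model)
  expect_equal(s$see, 0, tolerance = 1e-7)
  expect_true(is.infinite(s$f_stat) || s$f_stat > 1e10)
})

test_that("field fractions are normalized shares of |coef|*sd", {
  set.seed(7)
  M <- matrix(rnorm(60), 10, 6)
  fb1 <- fake_fieldblock(M)
  dm1 <- assemble_descriptors(fb1, sigma_min = 0)
  y <- stats::setNames(rnorm(10), rownames(dm1$X))
  m1 <- fit_qsar(dm1, y, ncomp = 2, scheme = "none")
  expect_equal(unname(field_fractions(m1)), 1)
  # duplicated block: identical columns split the contribution evenly
  fb2 <- fake_fieldblock(M)
  fb2$values$comfa_elec <- M
  rownames(fb2$values$comfa_elec) <- fb2$ids
  dm2 <- assemble_descriptors(fb2, sigma_min = 0)
  m2 <- fit_qsar(dm2, y, ncomp = 2, scheme = "none")
  fr <- field_fractions(m2)
  expect_equal(unname(fr), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("training fit improves monotonically with components", {
  set.seed(8)
  X <- matrix(rnorm(200), 20, 10)
  y <- stats::setNames(X %*% rnorm(10) + rnorm(20, sd = 0.5),
                       sprintf("m%02d", 1:20))
  fb <- fake_fieldblock(X, ids = names(y))
  dm <- assemble_descriptors(fb, sigma_min = 0)
  r2 <- vapply(1:6, function(cc)
    model_summary(fit_qsar(dm, y, ncomp = cc, scheme = "none"))$r2_ncv,
    numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("Q2 and external r2 match hand arithmetic", {
  expect_equal(q2_statistic(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(q2_statistic(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(q2_statistic(c(1, 2, 3), c(1.1, 1.9, 3.2), y_mean = 2),
               1 - 0.06 / 2, tolerance = 1e-12)
  expect_error(q2_statistic(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_equal(r2_pred(c(1, 3), c(1, 3), 2), 1)
  expect_equal(r2_pred(c(1, 3), c(2, 2), 2), 0)
  expect_equal(r2_pred(c(1, 3), c(1.5, 2.5), 2), 0.75, tolerance = 1e-12)
  expect_error(r2_pred(c(2, 2), c(1, 3), 2), "training mean")
})

test_that("stratified splits reproduce the published set sizes deterministically", {
  acts137 <- data.frame(compound_id = sprintf("c%03d", 1:137),
                        pic50 = seq(4.4, 8.7, length.out = 137))
  s1 <- split_train_test(acts137, n_test = 27, seed = 5)
  expect_identical(sum(s1$set_label == "train"), 110L)
  expect_identical(sum(s1$set_label == "test"), 27L)
  acts69 <- data.frame(compound_id = sprintf("c%03d", 1:69),
                       pic50 = seq(4.4, 8.7, length.out = 69))
  s2 <- split_train_test(acts69, n_test = 12, seed = 5)
  expect_identical(sum(s2$set_label == "train"), 57L)
  expect_identical(split_train_test(acts69, 12, seed = 5), s2)
  # test compounds span the activity range (one per quantile bin)
  qs <- quantile(acts69$pic50, c(0.25, 0.75))
  tst <- acts69$pic50[s2$set_label == "test"]
  expect_true(any(tst < qs[1]) && any(tst > qs[2]))
  expect_error(split_train_test(acts69, 0, 1), "positive")
})

test_that("endpoint correlation equals the least-squares r-squared", {
  x <- c(1, 2, 3, 5)
  expect_equal(endpoint_correlation(x, x), 1)
  expect_equal(endpoint_correlation(x, -2 * x + 1), 1)
  p <- table6_pairs()
  got <- endpoint_correlation(p$pic50_I, p$pic50_II)
  ref <- summary(stats::lm(p$pic50_II ~ p$pic50_I))$r.squared
  expect_equal(got, ref, tolerance = 1e-10)
  expect_error(endpoint_correlation(rep(1, 5), 1:5), "constant")
})
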
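test_that("SDF round-trips preserve atoms, bonds, coordinates and properties", {
  m1 <- fix_phenol()
  m1$properties$pIC50_I <- "8.6990"
  m2 <- fix_trimethylammonium()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(molecule_set(list(m1, m2)), path)
  back <- read_molecules(path, "sdf")
  expect_length(back, 2L)
  expect_identical(names(back), c("phenol", "tman"))
  for (pair in list(list(m1, back[[1]]), list(m2, back[[2]]))) {
    a <- pair[[1]]; b <- pair[[2]]
    expect_identical(b$atoms$element, a$atoms$element)
    expect_lt(max(abs(qsar3d:::coords(b) - qsar3d:::coords(a))), 1e-4)
    expect_identical(b$bonds[, c("a1", "a2", "order")],
                     a$bonds[, c("a1", "a2", "order")])
    expect_identical(b$atoms$formal_charge, a$atoms$formal_charge)
  }
  expect_identical(back[[1]]$properties$pIC50_I, "8.6990")
})

test_that("SDF reader rejects empty and malformed files with record context", {
  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_error(read_molecules(empty, "sdf"), "empty")
  bad <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("m1", "", "", "  x  y junk", "M  END", "$$$$"), bad)
  expect_error(read_molecules(bad, "sdf"), "record 1")
  expect_error(read_molecules(tempfile(), "sdf"), "not found")
})

test_that("MOL2 TRIPOS records are read", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "eth", " 2 1 0 0 0", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM",
               "  1 C1  0.0000 0.0000 0.0000 C.3",
               "  2 O1  1.4300 0.0000 0.0000 O.3",
               "@<TRIPOS>BOND", "  1 1 2 1"), path)
  ms <- read_molecules(path, "mol2")
  expect_length(ms, 1L)
  expect_identical(ms[[1]]$atoms$element, c("C", "O"))
  expect_equal(ms[[1]]$atoms$x, c(0, 1.43))
  expect_identical(nrow(ms[[1]]$bonds), 1L)
})

test_that("activity tables are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(compound_id = c("a", "b", "c"), endpoint = "I",
                   pic50 = c(7.1, 6.5, 8.0), set_label = "train")
  write.csv(df, path, row.names = FALSE)
  rec <- read_activities(path)
  expect_identical(nrow(rec), 3L)

  df$endpoint <- c("I", "III", "I")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_activities(path), "endpoint")

  df$endpoint <- "I"; df$compound_id <- c("a", "a", "c")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_activities(path), "duplicate")

  df$compound_id <- c("a", "b", "c"); df$pic50 <- c("7.1", "x", "8")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_activities(path), "non-numeric")
})

test_that("the tabulated dual-endpoint compounds load as 30 records", {
  p <- table6_pairs()
  long <- rbind(data.frame(compound_id = p$compound_id, endpoint = "I",
                           pic50 = p$pic50_I, set_label = "train"),
                data.frame(compound_id = p$compound_id, endpoint = "II",
                           pic50 = p$pic50_II, set_label = "train"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  rec <- read_activities(path)
  expect_identical(nrow(rec), 30L)
  expect_setequal(unique(rec$endpoint), c("I", "II"))
})

test_that("pIC50 conversion matches -log10 arithmetic and rejects bad input", {
  expect_equal(pic50_from_ic50(1e-5), 5.0)
  expect_equal(pic50_from_ic50(2e-9), 8.69897, tolerance = 1e-6)
  expect_equal(pic50_from_ic50(10^(-5.1938)), 5.1938)
  expect_error(pic50_from_ic50(0), "> 0")
  expect_error(pic50_from_ic50(-1e-6), "> 0")
  # strictly decreasing
  x <- sort(10^runif(20, -9, -3))
  expect_true(all(diff(pic50_from_ic50(x)) < 0))
})

test_that("Gasteiger charges match the frozen cross-implementation values", {
  w <- assign_partial_charges(fix_water())
  # reference: independent PEOE implementation, converged iteration
  expect_equal(w$atoms$partial_charge, c(-0.41153, 0.20576, 0.20576),
               tolerance = 1e-3)
  expect_lt(abs(sum(w$atoms$partial_charge)), 1e-6)
})

test_that("charges respect symmetry and conserve total charge", {
  m <- assign_partial_charges(fix_methane())
  expect_lt(abs(sum(m$atoms$partial_charge)), 1e-6)
  expect_lt(diff(range(m$atoms$partial_charge[2:5])), 1e-9)
  e <- assign_partial_charges(fix_ethane())
  expect_lt(abs(e$atoms$partial_charge[1] - e$atoms$partial_charge[2]), 1e-9)
  tma <- assign_partial_charges(fix_trimethylammonium())
  expect_equal(sum(tma$atoms$partial_charge), 1, tolerance = 1e-6)
  expect_error(assign_partial_charges(
    molecule("bad", data.frame(element = "Xe", x = 0, y = 0, z = 0))),
    "Xe")
})

test_that("donor/acceptor flags follow the element, hydrogen and charge rules", {
  ph <- prep(fix_phenol())
  expect_true(ph$atoms$is_hbd[7] && ph$atoms$is_hba[7])   # phenol O-H
  bz <- prep(fix_benzene())
  expect_false(any(bz$atoms$is_hbd) || any(bz$atoms$is_hba))
  tma <- prep(fix_trimethylammonium())
  expect_false(tma$atoms$is_hba[1])     # positively charged N
  expect_true(tma$atoms$is_hbd[1])      # but it carries an H
})

test_that("calculated logP is additive and orders hexane above ethanol", {
  ph <- compute_logp(prep(fix_phenol()))
  single <- ph$properties$ClogP
  # two disconnected copies in one record
  a2 <- ph$atoms; a2$x <- a2$x + 20
  b2 <- ph$bonds; b2$a1 <- b2$a1 + nrow(ph$atoms); b2$a2 <- b2$a2 + nrow(ph$atoms)
  dimer <- compute_logp(prep(molecule("dimer", rbind(ph$atoms, a2),
                                      rbind(ph$bonds, b2))))
  expect_equal(dimer$properties$ClogP, 2 * single, tolerance = 1e-10)
  hexane <- molecule("hexane",
                     data.frame(element = rep("C", 6), x = 1.54 * (0:5),
                                y = rep(c(0, 0.5), 3), z = 0),
                     data.frame(a1 = 1:5, a2 = 2:6, order = 1L))
  ethanol <- molecule("ethanol",
                      data.frame(element = c("C", "C", "O", "H"),
                                 x = c(0, 1.54, 2.9, 3.4),
                                 y = c(0, 0.2, 0, 0.7), z = 0),
                      data.frame(a1 = 1:3, a2 = 2:4, order = 1L))
  lp <- function(m) compute_logp(prep(m))$properties$ClogP
  expect_gt(lp(hexane), lp(ethanol))
})

test_that("topologically equivalent atoms get identical derived parameters", {
  bz <- compute_logp(prep(fix_benzene()))
  expect_lt(diff(range(bz$atoms$partial_charge[1:6])), 1e-9)
  expect_lt(diff(range(bz$atoms$hydrophobic_w[1:6])), 1e-12)
  expect_true(all(bz$atoms$is_aromatic[1:6]))
})
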
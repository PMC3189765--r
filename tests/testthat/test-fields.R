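unit_charge_atom <- function() {
  m <- prep(assign_partial_charges(
    molecule("probe_target", data.frame(element = "C", x = 0, y = 0, z = 0))))
  m$atoms$partial_charge <- 1.0
  m
}

test_that("lattice construction follows the bounding-box arithmetic", {
  a <- molecule("a", data.frame(element = "C", x = 0, y = 0, z = 0))
  lat <- build_lattice(molecule_set(list(a)), spacing = 2, margin = 4)
  expect_equal(lat$origin, c(-4, -4, -4), ignore_attr = TRUE)
  expect_identical(lat$dims, c(5L, 5L, 5L))
  expect_error(build_lattice(molecule_set(list(a)), spacing = 0), "spacing")

  sset <- synthetic_series(n = 20, seed = 3)
  lat2 <- sset$lattice
  G <- lattice_points(lat2)
  hi <- lat2$origin + (lat2$dims - 1L) * lat2$spacing
  for (m in sset$mols) {
    X <- qsar3d:::coords(m)
    expect_true(all(t(X) >= lat2$origin - 1e-9) && all(t(X) <= hi + 1e-9))
  }
})

test_that("CoMFA values reproduce the probe arithmetic and truncation", {
  m <- unit_charge_atom()
  pr <- probe_spec()
  # Coulomb at 5 A with distance-dependent dielectric: 332.17/25
  f5 <- comfa_fields(m, point_lattice(c(5, 0, 0)), pr)
  expect_equal(f5$electrostatic$values, 332.17 / 25, tolerance = 1e-10)
  # grid point at the atom center: truncated steric, flagged clash
  f0 <- comfa_fields(m, point_lattice(c(0, 0, 0)), pr)
  expect_identical(f0$steric$values, 30)
  expect_true(f0$steric$clash)
  expect_true(is.na(f0$electrostatic$values))
  # Lennard-Jones minimum at r_min gives -sqrt(eps_i eps_probe)
  rmin <- m$atoms$vdw_radius[1] + pr$lj_radius
  fm <- comfa_fields(m, point_lattice(c(rmin, 0, 0)), pr)
  expect_equal(fm$steric$values, -sqrt(m$atoms$lj_epsilon[1] * pr$lj_epsilon),
               tolerance = 1e-10)
  # constant dielectric switch (far enough that no clamping occurs)
  f15 <- comfa_fields(m, point_lattice(c(15, 0, 0)),
                      probe_spec(dielectric = "constant"))
  expect_equal(f15$electrostatic$values, 332.17 / 15, tolerance = 1e-10)
})

test_that("CoMSIA indices follow the Gaussian similarity formula", {
  m <- unit_charge_atom()
  pr <- probe_spec()
  at0 <- comsia_fields(m, point_lattice(c(0, 0, 0)), pr)
  expect_equal(at0$electrostatic$values, 1.0)     # exp(0) * w
  at1 <- comsia_fields(m, point_lattice(c(1, 0, 0)), pr)
  expect_equal(at1$electrostatic$values, exp(-0.3), tolerance = 1e-12)
  # two atoms at 1 and 2 A from the grid point
  m2 <- m
  m2$atoms <- rbind(m$atoms, m$atoms)
  m2$atoms$x <- c(1, 2)
  v <- qsar3d:::.comsia_at(m2, matrix(c(0, 0, 0), 1), pr)
  expect_equal(v$electrostatic, exp(-0.3) + exp(-1.2), tolerance = 1e-12)
  expect_error(comsia_fields(m, point_lattice(c(0, 0, 0)),
                             probe_spec(attenuation = -1)), "attenuation")
})

test_that("vectorized fields agree with a naive double loop", {
  sset <- synthetic_series(n = 8, seed = 2)
  mol <- sset$mols[[1]]
  small <- mol
  small$atoms <- small$atoms[1:8, ]
  small$bonds <- small$bonds[small$bonds$a1 <= 8 & small$bonds$a2 <= 8, ]
  lat <- structure(list(origin = c(-2, -2, -2), spacing = 2,
                        dims = c(3L, 3L, 3L)), class = "lattice")
  G <- lattice_points(lat)
  pr <- probe_spec()
  got <- qsar3d:::.comfa_at(small, G, pr)
  gotc <- qsar3d:::.comsia_at(small, G, pr)
  for (q in seq_len(nrow(G))) {
    st <- 0; el <- 0; cs <- 0
    for (i in seq_len(nrow(small$atoms))) {
      r <- sqrt(sum((G[q, ] - qsar3d:::coords(small)[i, ])^2))
      rmin <- small$atoms$vdw_radius[i] + pr$lj_radius
      eps <- sqrt(small$atoms$lj_epsilon[i] * pr$lj_epsilon)
      s6 <- (rmin / max(r, 1e-12))^6
      st <- st + eps * (s6^2 - 2 * s6)
      el <- el + 332.17 * small$atoms$partial_charge[i] / max(r^2, 1e-12)
      cs <- cs + small$atoms$partial_charge[i] * exp(-0.3 * r^2)
    }
    clash <- st >= 30
    expect_equal(got$steric[q], min(max(st, -30), 30), tolerance = 1e-10)
    if (!clash)
      expect_equal(got$elec[q], min(max(el, -30), 30), tolerance = 1e-10)
    expect_equal(gotc$electrostatic[q], cs, tolerance = 1e-10)
  }
})

test_that("fields are invariant under rigid co-transformation", {
  sset <- synthetic_series(n = 8, seed = 2)
  mol <- sset$mols[[2]]
  pr <- probe_spec()
  pts <- matrix(c(1, 2, 0.5, -3, 0, 1), 2, 3, byrow = TRUE)
  th <- 0.9; u <- c(0, 0, 1)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  shift <- c(1, -2, 3)
  mol2 <- mol
  X2 <- sweep(qsar3d:::coords(mol) %*% t(R), 2, shift, `+`)
  mol2$atoms$x <- X2[, 1]; mol2$atoms$y <- X2[, 2]; mol2$atoms$z <- X2[, 3]
  pts2 <- sweep(pts %*% t(R), 2, shift, `+`)
  expect_equal(qsar3d:::.comfa_at(mol, pts, pr)$steric,
               qsar3d:::.comfa_at(mol2, pts2, pr)$steric, tolerance = 1e-9)
  expect_equal(qsar3d:::.comsia_at(mol, pts, pr)$hydrophobic,
               qsar3d:::.comsia_at(mol2, pts2, pr)$hydrophobic,
               tolerance = 1e-9)
})

test_that("CoMSIA grids are additive over atoms (two-molecule overlay)", {
  sset <- synthetic_series(n = 8, seed = 2)
  m1 <- sset$mols[[1]]; m2 <- sset$mols[[2]]
  pr <- probe_spec()
  pts <- matrix(c(0, 0, 4, 2, -1, 3), 2, 3, byrow = TRUE)
  both <- m1
  both$atoms <- rbind(m1$atoms, m2$atoms)
  b2 <- m2$bonds; b2$a1 <- b2$a1 + nrow(m1$atoms); b2$a2 <- b2$a2 + nrow(m1$atoms)
  both$bonds <- rbind(m1$bonds, b2)
  v_both <- qsar3d:::.comsia_at(both, pts, pr)
  v1 <- qsar3d:::.comsia_at(m1, pts, pr)
  v2 <- qsar3d:::.comsia_at(m2, pts, pr)
  for (k in names(v_both))
    expect_equal(v_both[[k]], v1[[k]] + v2[[k]], tolerance = 1e-9)
})

test_that("CoMFA values are bounded and single-atom CoMSIA decays with distance", {
  sset <- synthetic_series(n = 8, seed = 2)
  fb <- compute_fields(sset$mols, sset$lattice, probe_spec(), "comfa")
  expect_true(all(fb$values$comfa_steric >= -30 & fb$values$comfa_steric <= 30))
  el <- fb$values$comfa_elec
  expect_true(all(el[!is.na(el)] >= -30 & el[!is.na(el)] <= 30))
  m <- unit_charge_atom()
  r <- seq(0.5, 6, by = 0.5)
  v <- qsar3d:::.comsia_at(m, cbind(r, 0, 0), probe_spec())$steric
  expect_true(all(diff(v) < 0))
})
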
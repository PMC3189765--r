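#' Specification for a synthetic congeneric series
#'
#' The generator emulates the setting in which field-based 3D-QSAR is
#' valid: a rigid shared scaffold (a planar fused tricycle with an
#' exocyclic carboxamide, providing aromatic, hydrophobic, donor and
#' acceptor chemistry) with substituents varied at four ring positions,
#' activities linear in local field values plus Gaussian noise, and a
#' second endpoint coupled to the first at a tunable squared correlation.
#'
#' @param n_compounds number of molecules (>= 8)
#' @param substituent_library substituent names drawn at the variable
#'   positions; see [substituent_library()]
#' @param noise_sd activity noise standard deviation (pIC50 units)
#' @param endpoint_r2 target squared Pearson correlation between the two
#'   endpoints (0..1)
#' @param activity_spread standard deviation of the planted signal in
#'   pIC50 units
#' @param activity_mean center of the simulated pIC50 scale
#' @param planted_fields field blocks carrying planted coefficients; the
#'   default plants on the steric field only, whose short range makes the
#'   attribution of a lattice cell to a substituent site unambiguous
#' @param planted_radius radius (A) around each substituent site within
#'   which lattice cells receive planted weight
#' @param n_test external test-set size used when labelling records
#' @param seed integer seed; every output is a pure function of the spec
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_compounds = 75L,
                           substituent_library = NULL,
                           noise_sd = 0.2, endpoint_r2 = 0.39,
                           activity_spread = 1.0, activity_mean = 6.5,
                           planted_fields = "comfa_steric",
                           planted_radius = 6.0,
                           n_test = max(2L, round(n_compounds / 5)),
                           seed = 1L) {
  if (n_compounds < 8L) stop("n_compounds must be >= 8", call. = FALSE)
  if (endpoint_r2 < 0 || endpoint_r2 > 1)
    stop("endpoint_r2 must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(substituent_library)) substituent_library <- names(.SUBSTITUENTS)
  if (length(substituent_library) == 0L)
    stop("empty substituent library", call. = FALSE)
  bad <- setdiff(substituent_library, names(.SUBSTITUENTS))
  if (length(bad)) stop(sprintf("unknown substituent(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 substituent_library = substituent_library,
                 noise_sd = noise_sd, endpoint_r2 = endpoint_r2,
                 activity_spread = activity_spread,
                 activity_mean = activity_mean,
                 planted_fields = planted_fields,
                 planted_radius = planted_radius,
                 n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# ---- scaffold geometry --------------------------------------------------

.RING_BL <- 1.40    # aromatic C-C (A)
.CH_BL <- 1.09      # C-H

# rigid planar linear tricycle (anthracene-like, aromatic bonds written as
# order 4) with an exocyclic primary carboxamide on the right edge; four
# substituent sites spread over the outer rings.  Returns atoms, bonds,
# site atom indices and their outward unit vectors.
.scaffold_template <- function() {
  h <- .RING_BL * cos(pi / 6)       # 1.2124
  half <- .RING_BL / 2              # 0.70
  centers <- list(c(0, 0), c(2 * h, 0), c(4 * h, 0))
  # 14 ring carbons
  xy <- rbind(
    c(0, .RING_BL), c(0, -.RING_BL),            # C1  C2   (ring A top/bottom)
    c(-h, half), c(-h, -half),                  # C3  C4   (left edge)
    c(h, half), c(h, -half),                    # C5  C6   (fusion A/B)
    c(2 * h, .RING_BL), c(2 * h, -.RING_BL),    # C7  C8   (ring B top/bottom)
    c(3 * h, half), c(3 * h, -half),            # C9  C10  (fusion B/C)
    c(4 * h, .RING_BL), c(4 * h, -.RING_BL),    # C11 C12  (ring C top/bottom)
    c(5 * h, half), c(5 * h, -half))            # C13 C14  (right edge)
  atoms <- data.frame(element = rep("C", 14), x = xy[, 1], y = xy[, 2], z = 0,
                      formal_charge = 0L)
  ring_bonds <- rbind(
    c(3, 1), c(1, 5), c(5, 6), c(6, 2), c(2, 4), c(4, 3),      # ring A
    c(5, 7), c(7, 9), c(9, 10), c(10, 8), c(8, 6),             # ring B
    c(9, 11), c(11, 13), c(13, 14), c(14, 12), c(12, 10))      # ring C
  bonds <- data.frame(a1 = ring_bonds[, 1], a2 = ring_bonds[, 2], order = 4L)
  ring_center_of <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  outward <- function(i) {
    cc <- centers[[ring_center_of[i]]]
    v <- c(xy[i, 1] - cc[1], xy[i, 2] - cc[2])
    v / sqrt(sum(v^2))
  }
  # carboxamide on C13: C(=O)NH2, planar, in the ring plane
  u <- outward(13)
  rot <- function(v, ang) c(cos(ang) * v[1] - sin(ang) * v[2],
                            sin(ang) * v[1] + cos(ang) * v[2])
  c15 <- c(xy[13, ] + 1.50 * u, 0)
  d_back <- -u
  o16 <- c(c15[1:2] + 1.23 * rot(d_back, 2 * pi / 3), 0)
  n17 <- c(c15[1:2] + 1.35 * rot(d_back, -2 * pi / 3), 0)
  un <- (n17[1:2] - c15[1:2]) / 1.35
  h18 <- c(n17[1:2] + 1.01 * rot(-un, 2 * pi / 3), 0)
  h19 <- c(n17[1:2] + 1.01 * rot(-un, -2 * pi / 3), 0)
  atoms <- rbind(atoms,
                 data.frame(element = c("C", "O", "N", "H", "H"),
                            x = c(c15[1], o16[1], n17[1], h18[1], h19[1]),
                            y = c(c15[2], o16[2], n17[2], h18[2], h19[2]),
                            z = 0, formal_charge = 0L))
  bonds <- rbind(bonds,
                 data.frame(a1 = c(13L, 15L, 15L, 17L, 17L),
                            a2 = c(15L, 16L, 17L, 18L, 19L),
                            order = c(1L, 2L, 1L, 1L, 1L)))
  # four variable positions chosen far apart (so their field-variation
  # regions are geometrically distinct) and never ortho to the amide:
  # left edge, ring A bottom, ring B top, ring C bottom
  sites <- c(3L, 2L, 7L, 12L)
  site_u <- t(vapply(sites, outward, numeric(2)))
  # hydrogens on the remaining peripheral carbons
  fused <- c(5L, 6L, 9L, 10L)
  peripheral <- setdiff(1:14, c(fused, sites, 13L))
  for (i in peripheral) {
    u <- outward(i)
    atoms <- rbind(atoms, data.frame(element = "H",
                                     x = xy[i, 1] + .CH_BL * u[1],
                                     y = xy[i, 2] + .CH_BL * u[2],
                                     z = 0, formal_charge = 0L))
    bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1L))
  }
  list(atoms = atoms, bonds = bonds, sites = sites, site_u = site_u,
       n_scaffold_atoms = nrow(atoms))
}

# ---- substituent library -----------------------------------------------

#' Built-in substituent library
#'
#' Idealized-geometry fragments attachable at a scaffold position: a name
#' per entry; geometries use fixed bond lengths and tetrahedral/planar
#' angles so no force field is involved.
#'
#' @return named list of substituent builders (internal structure)
#' @export
substituent_library <- function() {
  .SUBSTITUENTS
}

# each builder: function(base, u, n1, n2) -> list(atoms, bonds, attach)
# base = site atom position, u = outward unit vector, n1/n2 = in-plane and
# out-of-plane perpendicular unit vectors; bonds are local 1-based and the
# scaffold bond attaches to atom `attach` with the given order
.tet <- function(u, n1, n2, theta) {
  ct <- 1 / 3; st <- sqrt(1 - ct^2)
  ct * u + st * (cos(theta) * n1 + sin(theta) * n2)
}

# orthonormal frame perpendicular to a direction
.ortho_frame <- function(d) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- .cross3(d, ref); n1 <- n1 / sqrt(sum(n1^2))
  list(n1 = n1, n2 = .cross3(d, n1))
}

.frag <- function(el, xyz, bonds, attach_order = 1L) {
  list(atoms = data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], formal_charge = 0L),
       bonds = bonds, attach = 1L, attach_order = attach_order)
}

.methyl_at <- function(p, dir_in) {
  # carbon at p approached along unit vector dir_in; three tetrahedral H
  # point onward (109.5 degrees from the incoming bond)
  fr <- .ortho_frame(dir_in)
  t(vapply(c(0, 2, 4) * pi / 3, function(th)
    p + .CH_BL * .tet(dir_in, fr$n1, fr$n2, th), numeric(3)))
}

.SUBSTITUENTS <- local({
  mk <- list()
  mk$H <- function(base, u, n1, n2)
    .frag("H", matrix(base + .CH_BL * u, 1), NULL)
  mk$Me <- function(base, u, n1, n2) {
    c1 <- base + 1.50 * u
    hs <- .methyl_at(c1, u)
    .frag(c("C", "H", "H", "H"), rbind(c1, hs),
          data.frame(a1 = 1L, a2 = 2:4, order = 1L))
  }
  mk$Et <- function(base, u, n1, n2) {
    c1 <- base + 1.50 * u
    th0 <- pi / 2        # chain leaves the ring plane, avoiding neighbours
    d2 <- .tet(u, n1, n2, th0)
    c2 <- c1 + 1.53 * d2
    h1 <- c1 + .CH_BL * .tet(u, n1, n2, th0 + 2 * pi / 3)
    h2 <- c1 + .CH_BL * .tet(u, n1, n2, th0 + 4 * pi / 3)
    hs <- .methyl_at(c2, d2)
    .frag(c("C", "C", "H", "H", "H", "H", "H"),
          rbind(c1, c2, h1, h2, hs),
          data.frame(a1 = c(1L, 1L, 1L, 2L, 2L, 2L),
                     a2 = c(2L, 3L, 4L, 5L, 6L, 7L), order = 1L))
  }
  mk$iPr <- function(base, u, n1, n2) {
    c1 <- base + 1.50 * u
    th0 <- pi / 2
    d2 <- .tet(u, n1, n2, th0); d3 <- .tet(u, n1, n2, th0 + 2 * pi / 3)
    c2 <- c1 + 1.53 * d2; c3 <- c1 + 1.53 * d3
    h1 <- c1 + .CH_BL * .tet(u, n1, n2, th0 + 4 * pi / 3)
    hs2 <- .methyl_at(c2, d2)
    hs3 <- .methyl_at(c3, d3)
    .frag(rep(c("C", "H"), c(3, 7)), rbind(c1, c2, c3, h1, hs2, hs3),
          data.frame(a1 = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
                     a2 = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L), order = 1L))
  }
  mk$tBu <- function(base, u, n1, n2) {
    c1 <- base + 1.50 * u
    ds <- lapply(pi / 2 + c(0, 2, 4) * pi / 3, function(th)
      .tet(u, n1, n2, th))
    cs <- t(vapply(ds, function(d) c1 + 1.53 * d, numeric(3)))
    hs <- do.call(rbind, lapply(1:3, function(k)
      .methyl_at(cs[k, ], ds[[k]])))
    .frag(rep(c("C", "H"), c(4, 9)), rbind(c1, cs, hs),
          data.frame(a1 = c(1L, 1L, 1L, rep(2:4, each = 3)),
                     a2 = c(2L, 3L, 4L, 5:13), order = 1L))
  }
  mk$OH <- function(base, u, n1, n2) {
    o <- base + 1.36 * u
    h <- o + 0.96 * .tet(u, n1, n2, 0)
    .frag(c("O", "H"), rbind(o, h), data.frame(a1 = 1L, a2 = 2L, order = 1L))
  }
  mk$OMe <- function(base, u, n1, n2) {
    o <- base + 1.36 * u
    d <- .tet(u, n1, n2, pi / 2)
    c1 <- o + 1.43 * d
    hs <- .methyl_at(c1, d)
    .frag(c("O", "C", "H", "H", "H"), rbind(o, c1, hs),
          data.frame(a1 = c(1L, 2L, 2L, 2L), a2 = c(2L, 3L, 4L, 5L), order = 1L))
  }
  mk$NH2 <- function(base, u, n1, n2) {
    n <- base + 1.40 * u
    h1 <- n + 1.01 * .tet(u, n1, n2, 0)
    h2 <- n + 1.01 * .tet(u, n1, n2, 2 * pi / 3)
    .frag(c("N", "H", "H"), rbind(n, h1, h2),
          data.frame(a1 = c(1L, 1L), a2 = c(2L, 3L), order = 1L))
  }
  mk$F <- function(base, u, n1, n2) .frag("F", matrix(base + 1.33 * u, 1), NULL)
  mk$Cl <- function(base, u, n1, n2) .frag("Cl", matrix(base + 1.74 * u, 1), NULL)
  mk$Br <- function(base, u, n1, n2) .frag("Br", matrix(base + 1.90 * u, 1), NULL)
  mk$CF3 <- function(base, u, n1, n2) {
    c1 <- base + 1.50 * u
    fs <- t(vapply(c(0, 2, 4) * pi / 3, function(th)
      c1 + 1.33 * .tet(u, n1, n2, th), numeric(3)))
    .frag(c("C", "F", "F", "F"), rbind(c1, fs),
          data.frame(a1 = 1L, a2 = 2:4, order = 1L))
  }
  mk$CN <- function(base, u, n1, n2) {
    c1 <- base + 1.43 * u
    n1p <- c1 + 1.16 * u
    .frag(c("C", "N"), rbind(c1, n1p),
          data.frame(a1 = 1L, a2 = 2L, order = 3L))
  }
  mk$Ph <- function(base, u, n1, n2) {
    ipso <- base + 1.48 * u
    center <- ipso + .RING_BL * u
    verts <- t(vapply(0:5, function(k) {
      th <- k * pi / 3
      # ring plane perpendicular to the scaffold plane (biphenyl-like twist)
      center + .RING_BL * (cos(th) * (-u) + sin(th) * n2)
    }, numeric(3)))
    ring_bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = 4L)
    hs <- t(vapply(2:6, function(k) {
      d <- verts[k, ] - center
      verts[k, ] + .CH_BL * d / sqrt(sum(d^2))
    }, numeric(3)))
    .frag(rep(c("C", "H"), c(6, 5)), rbind(verts, hs),
          rbind(ring_bonds, data.frame(a1 = 2:6, a2 = 7:11, order = 1L)))
  }
  mk
})

# cross product (named to avoid masking); used for local frames
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic congeneric series
#'
#' Every molecule contains the identical rigid scaffold at identical
#' coordinates (pre-aligned by construction); 1-3 of the four variable
#' positions carry substituents drawn seeded-uniformly from the library,
#' the rest carry hydrogen.  Charges, field parameters and calculated logP
#' are assigned.  Byte-identical output for identical specs.
#'
#' @param spec a [synthetic_spec()]
#' @return a [molecule_set()]
#' @export
make_congeneric_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tpl <- .scaffold_template()
  lib <- spec$substituent_library
  lib_nonH <- setdiff(lib, "H")
  if (length(lib_nonH) == 0L) stop("substituent library needs non-H entries",
                                   call. = FALSE)
  choices <- .with_seed(spec$seed, function() {
    lapply(seq_len(spec$n_compounds), function(i) {
      k <- sample(1:3, 1L)
      sites <- sort(sample(seq_along(tpl$sites), k))
      groups <- sample(lib_nonH, k, replace = TRUE)
      assign <- rep("H", length(tpl$sites))
      assign[sites] <- groups
      assign
    })
  })
  mols <- lapply(seq_len(spec$n_compounds), function(i)
    .build_from_scaffold(tpl, choices[[i]], sprintf("cmpd_%03d", i)))
  prepare_molecules(molecule_set(mols))
}

.build_from_scaffold <- function(tpl, assignment, id) {
  atoms <- tpl$atoms; bonds <- tpl$bonds
  z <- c(0, 0, 1)
  for (s in seq_along(tpl$sites)) {
    site <- tpl$sites[s]
    u <- c(tpl$site_u[s, ], 0)
    n1 <- .cross3(z, u); n1 <- n1 / sqrt(sum(n1^2))
    base <- as.numeric(atoms[site, c("x", "y", "z")])
    fr <- .SUBSTITUENTS[[assignment[s]]](base, u, n1, z)
    off <- nrow(atoms)
    atoms <- rbind(atoms, fr$atoms)
    if (!is.null(fr$bonds) && nrow(fr$bonds) > 0L)
      bonds <- rbind(bonds, data.frame(a1 = fr$bonds$a1 + off,
                                       a2 = fr$bonds$a2 + off,
                                       order = fr$bonds$order))
    bonds <- rbind(bonds, data.frame(a1 = site, a2 = off + fr$attach,
                                     order = fr$attach_order))
  }
  m <- molecule(id, atoms, bonds)
  m$properties$substituents <- paste(assignment, collapse = ",")
  m
}

#' Plant linear activities on a series
#'
#' Lattice cells within `planted_radius` of each substituent site receive
#' planted coefficients for each planted field: within a site's region the
#' coefficient sign is constant (alternating +/-/+/- over the four sites;
#' contested cells take the sign of the nearest site), and the per-cell
#' magnitude standardizes the local field value and tapers as a Gaussian
#' of the distance to the site center (sigma 2 A), so the planted effect
#' is concentrated at the substituent positions while its sign is defined
#' over the whole surrounding halo.  Endpoint I is the planted linear
#' combination rescaled to `activity_spread` pIC50 units around
#' `activity_mean`, plus `N(0, noise_sd^2)` noise; endpoint II mixes
#' endpoint I with fresh Gaussian noise so the expected squared
#' correlation equals `endpoint_r2`.
#'
#' @param mols series from [make_congeneric_series()]
#' @param lattice shared lattice from [build_lattice()]
#' @param spec the [synthetic_spec()]
#' @param probe a [probe_spec()]
#' @return list with `activities` (data frame: compound_id, endpoint,
#'   pic50, set_label) and `truth` (planted cells, effective raw-unit
#'   weights per cell, noise draws, calibration constants)
#' @export
plant_activities <- function(mols, lattice, spec, probe = probe_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tpl <- .scaffold_template()
  G <- lattice_points(lattice)
  site_xy <- tpl$atoms[tpl$sites, c("x", "y", "z")]
  site_centers <- as.matrix(site_xy) + cbind(2.5 * tpl$site_u, 0)
  signs <- rep(c(1, -1), length.out = nrow(site_centers))
  # each in-reach cell belongs to its nearest site, so where two spheres
  # meet the nearer substituent position determines the planted sign
  dmat <- vapply(seq_len(nrow(site_centers)), function(s)
    sqrt(rowSums(sweep(G, 2, site_centers[s, ])^2)), numeric(nrow(G)))
  nearest <- max.col(-dmat, ties.method = "first")
  planted <- list()
  for (s in seq_len(nrow(site_centers))) {
    cells <- which(dmat[, s] <= spec$planted_radius & nearest == s)
    if (length(cells) == 0L)
      stop("planted site lies outside the lattice", call. = FALSE)
    for (f in spec$planted_fields)
      planted[[length(planted) + 1L]] <-
        data.frame(field = f, cell = cells, sign = signs[s], site = s,
                   dist = dmat[cells, s])
  }
  planted <- do.call(rbind, planted)
  # field values of every molecule at the planted cells
  n <- length(mols)
  V <- matrix(NA_real_, n, nrow(planted))
  for (f in unique(planted$field)) {
    jj <- which(planted$field == f)
    pts <- G[planted$cell[jj], , drop = FALSE]
    for (i in seq_len(n))
      V[i, jj] <- .field_values_at(mols[[i]], pts, f, probe)
  }
  sds <- apply(V, 2, stats::sd)
  usable <- sds > 1e-8
  # orient each cell's weight with its site's dominant local field pattern
  # (cells anti-correlated with the pattern get the opposite raw sign, so
  # the planted effect is a coherent regional signal rather than a
  # self-cancelling one) and drop cells that barely track it
  orient <- numeric(ncol(V))
  for (s in unique(planted$site)) for (f in unique(planted$field)) {
    jj <- which(planted$site == s & planted$field == f & usable)
    if (length(jj) == 0L) next
    Z <- scale(V[, jj, drop = FALSE])
    ref <- rowMeans(Z)
    if (stats::sd(ref) < 1e-8) { orient[jj] <- 1; next }
    cc <- as.numeric(stats::cor(ref, V[, jj, drop = FALSE]))
    orient[jj] <- ifelse(abs(cc) >= 0.5, sign(cc), 0)
  }
  # Gaussian taper of the weight magnitude with distance to the site
  # center keeps the signal concentrated while the halo stays labelled
  taper <- exp(-planted$dist^2 / (2 * 2.0^2))
  w_std <- ifelse(usable & orient != 0,
                  planted$sign * orient * taper / pmax(sds, 1e-8), 0)
  planted <- planted[w_std != 0, , drop = FALSE]
  V <- V[, w_std != 0, drop = FALSE]
  w_std <- w_std[w_std != 0]
  signal <- as.numeric(V %*% w_std)
  s_sd <- stats::sd(signal)
  if (s_sd == 0) stop("planted signal is constant; enlarge the library",
                      call. = FALSE)
  gamma <- spec$activity_spread / s_sd
  eps <- .with_seed(spec$seed + 1L, function() stats::rnorm(n, 0, spec$noise_sd))
  y1 <- spec$activity_mean + gamma * (signal - mean(signal)) + eps
  rho <- sqrt(spec$endpoint_r2)
  eta <- .with_seed(spec$seed + 2L, function() stats::rnorm(n))
  sd1 <- stats::sd(y1)
  y2 <- spec$activity_mean + 0.1 + rho * (y1 - mean(y1)) +
    sqrt(1 - rho^2) * sd1 * eta
  ids <- names(mols)
  split <- split_train_test(data.frame(compound_id = ids, pic50 = y1),
                            n_test = spec$n_test, seed = spec$seed + 3L)
  lab <- split$set_label[match(ids, split$compound_id)]
  activities <- rbind(
    data.frame(compound_id = ids, endpoint = "I", pic50 = y1, set_label = lab),
    data.frame(compound_id = ids, endpoint = "II", pic50 = y2, set_label = lab))
  truth <- list(
    planted = data.frame(field = planted$field, cell = planted$cell,
                         site = planted$site, sign = planted$sign,
                         weight = gamma * w_std),
    gamma = gamma, intercept = spec$activity_mean,
    noise = eps, endpoint_r2 = spec$endpoint_r2,
    lattice = list(origin = as.numeric(lattice$origin),
                   spacing = lattice$spacing,
                   dims = as.integer(lattice$dims)),
    seed = spec$seed)
  list(activities = activities, truth = truth)
}

#' Write a complete synthetic benchmark bundle
#'
#' Four files: `molecules.sdf`, `activities.csv`, `truth.json`,
#' `config.json`.  Regeneration from the same spec is bit-identical.
#'
#' @param spec a [synthetic_spec()]
#' @param out_dir output directory (created if absent)
#' @param force overwrite a non-empty directory
#' @param spacing,margin lattice construction parameters
#' @return invisible list with the generated objects and file paths
#' @export
generate_benchmark <- function(spec, out_dir, force = FALSE,
                               spacing = 2.0, margin = 4.0) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop(sprintf("directory %s is not empty (use force = TRUE)", out_dir),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mols <- make_congeneric_series(spec)
  lattice <- build_lattice(mols, spacing = spacing, margin = margin)
  pa <- plant_activities(mols, lattice, spec)
  paths <- file.path(out_dir, c("molecules.sdf", "activities.csv",
                                "truth.json", "config.json"))
  write_molecules(mols, paths[1])
  utils::write.csv(pa$activities, paths[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(pa$truth, paths[3], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(spec), paths[4], auto_unbox = TRUE, digits = NA)
  invisible(list(molecules = mols, lattice = lattice,
                 activities = pa$activities, truth = pa$truth, paths = paths))
}

#' Sign agreement between a fitted model and planted coefficients
#'
#' Ranks retained lattice columns by |stdev*coeff| and checks, within the
#' top `top_frac` fraction, how many carry a planted coefficient of the
#' same sign as the fitted one.  Unplanted cells in the top set count as
#' disagreements, so the statistic is a strict recovery measure.
#'
#' @param model a [fit_qsar()] model
#' @param truth the `truth` component of [plant_activities()]
#' @param top_frac fraction of top-ranked cells examined (default decile)
#' @return list with `agreement`, `n_top`, `n_planted_in_top`
#' @export
sign_agreement <- function(model, truth, top_frac = 0.10) {
  stopifnot(inherits(model, "qsar_model"))
  jj <- which(model$col_field %in% unique(truth$planted$field) & model$retained)
  contrib <- abs(model$coefficients[jj]) * model$train_sds[jj]
  n_top <- max(1L, ceiling(top_frac * length(jj)))
  top <- jj[order(-contrib)][seq_len(n_top)]
  key_truth <- paste(truth$planted$field, truth$planted$cell)
  key_top <- paste(model$col_field[top], model$col_cell[top])
  idx <- match(key_top, key_truth)
  planted_sign <- ifelse(is.na(idx), 0, sign(truth$planted$weight[idx]))
  agree <- planted_sign != 0 & planted_sign == sign(model$coefficients[top])
  list(agreement = mean(agree), n_top = n_top,
       n_planted_in_top = sum(planted_sign != 0))
}

#' Construct a planted common-feature benchmark set
#'
#' Builds `n_molecules` rigid dummy molecules sharing one fixed set of six
#' pharmacophore features (HD, HA, DS, two HP, AR) at identical, verified
#' asymmetric positions -- a synthetic stand-in for a series of actives
#' with a known common pharmacophore.  Optionally one feature is displaced
#' in every non-reference molecule to test that the search drops it.
#'
#' @param n_molecules number of molecules (>= 2)
#' @param jitter_feature index (1..6) of the feature to displace in
#'   molecules 2..n, or NULL
#' @param jitter displacement in A applied along +x
#' @return list with `mols` (a [molecule_set()] of one-atom placeholders),
#'   `features` (named list of per-molecule feature frames) and `planted`
#'   (the reference feature frame)
#' @export
make_planted_pharmacophore_set <- function(n_molecules = 5L,
                                           jitter_feature = NULL,
                                           jitter = 1.0) {
  stopifnot(n_molecules >= 2L)
  planted <- data.frame(
    kind = c("HD", "HA", "DS", "HP", "HP", "AR"),
    x = c(0.0, 3.1, 1.4, 0.6, 4.2, 2.3),
    y = c(0.0, 0.2, 2.6, -2.1, 1.3, 2.2),
    z = c(0.0, 0.3, 0.1, 1.2, 2.0, -1.6),
    parent = 1L)
  mols <- molecule_set(lapply(seq_len(n_molecules), function(i)
    molecule(sprintf("act_%02d", i),
             data.frame(element = "C", x = 0, y = 0, z = 0))))
  features <- lapply(seq_len(n_molecules), function(i) {
    f <- planted
    if (!is.null(jitter_feature) && i > 1L)
      f$x[jitter_feature] <- f$x[jitter_feature] + jitter
    f
  })
  names(features) <- names(mols)
  list(mols = mols, features = features, planted = planted)
}
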
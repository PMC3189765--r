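# shared fixture builders: tiny molecules with exact, hand-placed geometry

fix_water <- function() {
  molecule("water",
           data.frame(element = c("O", "H", "H"),
                      x = c(0, 0.9572, -0.2400),
                      y = c(0, 0, 0.9270), z = 0),
           data.frame(a1 = 1L, a2 = c(2L, 3L), order = 1L))
}

fix_methane <- function() {
  s <- 1.09 / sqrt(3)
  molecule("methane",
           data.frame(element = c("C", "H", "H", "H", "H"),
                      x = c(0, s, -s, -s, s), y = c(0, s, -s, s, -s),
                      z = c(0, s, s, -s, -s)),
           data.frame(a1 = 1L, a2 = 2:5, order = 1L))
}

fix_ethane <- function() {
  s <- 1.09 / sqrt(3)
  molecule("ethane",
           data.frame(element = c("C", "C", "H", "H", "H", "H", "H", "H"),
                      x = c(0, 1.54, -s, -s, -s, 1.54 + s, 1.54 + s, 1.54 + s),
                      y = c(0, 0, s, -s, 0, s, -s, 0),
                      z = c(0, 0, s / 2, s / 2, -s, -s / 2, -s / 2, s)),
           data.frame(a1 = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
                      a2 = c(2L, 3L, 4L, 5L, 6L, 7L, 8L), order = 1L))
}

# benzene, Kekule form, with hydrogens
fix_benzene <- function() {
  ang <- (0:5) * pi / 3
  molecule("benzene",
           rbind(data.frame(element = "C", x = 1.4 * cos(ang),
                            y = 1.4 * sin(ang), z = 0),
                 data.frame(element = "H", x = 2.49 * cos(ang),
                            y = 2.49 * sin(ang), z = 0)),
           rbind(data.frame(a1 = 1:6, a2 = c(2:6, 1L),
                            order = c(2L, 1L, 2L, 1L, 2L, 1L)),
                 data.frame(a1 = 1:6, a2 = 7:12, order = 1L)))
}

# phenol with a bent O-H (so the acceptor lone-pair direction is defined)
fix_phenol <- function() {
  ang <- (0:5) * pi / 3
  o <- c(2.76, 0, 0)
  h_on_o <- o + 0.96 * c(cos(pi / 3), sin(pi / 3), 0)
  molecule("phenol",
           rbind(data.frame(element = "C", x = 1.4 * cos(ang),
                            y = 1.4 * sin(ang), z = 0),
                 data.frame(element = "O", x = o[1], y = o[2], z = o[3]),
                 data.frame(element = "H", x = h_on_o[1], y = h_on_o[2],
                            z = h_on_o[3]),
                 data.frame(element = "H", x = 2.49 * cos(ang[2:6]),
                            y = 2.49 * sin(ang[2:6]), z = 0)),
           rbind(data.frame(a1 = 1:6, a2 = c(2:6, 1L),
                            order = c(2L, 1L, 2L, 1L, 2L, 1L)),
                 data.frame(a1 = c(1L, 7L), a2 = c(7L, 8L), order = 1L),
                 data.frame(a1 = 2:6, a2 = 9:13, order = 1L)))
}

# trimethylammonium cation: N+ with three methyls and one H
fix_trimethylammonium <- function() {
  s <- 1 / sqrt(3)
  ds <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) * s
  atoms <- data.frame(element = "N", x = 0, y = 0, z = 0,
                      formal_charge = 1L)
  bonds <- NULL
  for (k in 1:3) {
    ck <- 1.50 * ds[k, ]
    atoms <- rbind(atoms, data.frame(element = "C", x = ck[1], y = ck[2],
                                     z = ck[3], formal_charge = 0L))
    ci <- nrow(atoms)
    bonds <- rbind(bonds, data.frame(a1 = 1L, a2 = ci, order = 1L))
    for (hh in 1:3) {
      hv <- ck + 1.09 * qsar3d:::.tet(ds[k, ],
                                      c(-ds[k, 2], ds[k, 1], 0) /
                                        sqrt(ds[k, 1]^2 + ds[k, 2]^2),
                                      c(0, 0, 1), hh * 2 * pi / 3)
      atoms <- rbind(atoms, data.frame(element = "H", x = hv[1], y = hv[2],
                                       z = hv[3], formal_charge = 0L))
      bonds <- rbind(bonds, data.frame(a1 = ci, a2 = nrow(atoms), order = 1L))
    }
  }
  hn <- -1.01 * c(-1, -1, 1) * s
  atoms <- rbind(atoms, data.frame(element = "H", x = hn[1], y = hn[2],
                                   z = hn[3], formal_charge = 0L))
  bonds <- rbind(bonds, data.frame(a1 = 1L, a2 = nrow(atoms), order = 1L))
  molecule("tman", atoms, bonds)
}

prep <- function(m) assign_field_params(assign_partial_charges(m))

# single-point lattice at a given position
point_lattice <- function(p) {
  structure(list(origin = p, spacing = 1, dims = c(1L, 1L, 1L)),
            class = "lattice")
}

# dual-endpoint activity pairs as printed for the 15 tabulated compounds
# carrying both endpoints
table6_pairs <- function() {
  data.frame(
    compound_id = c("2", "15c", "15m", "15q", "7o", "7z", "7ac", "8a",
                    "8h", "8y", "8aa", "8ae", "8aj", "8ao", "8av"),
    pic50_I = c(7.4685, 7.6990, 7.7447, 7.6990, 7.5086, 7.9586, 7.5376,
                7.9208, 8.3979, 7.5850, 7.8861, 8.3010, 8.2218, 8.6990,
                8.3979),
    pic50_II = c(7.7696, 7.7959, 7.8861, 7.7696, 7.4437, 7.8539, 7.1308,
                 7.7212, 7.9586, 7.5229, 8.3010, 8.0000, 7.3010, 8.3979,
                 8.6990))
}

# small prepared congeneric series (cached per session to keep tests fast)
synthetic_series <- local({
  cache <- list()
  function(n = 20, seed = 3, noise_sd = 0.2, n_test = 4, ...) {
    key <- paste(n, seed, noise_sd, n_test, ...)
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- synthetic_spec(n_compounds = n, noise_sd = noise_sd,
                           seed = seed, n_test = n_test, ...)
    mols <- make_congeneric_series(spec)
    lattice <- build_lattice(mols, 2, 4)
    pa <- plant_activities(mols, lattice, spec)
    out <- list(spec = spec, mols = mols, lattice = lattice,
                activities = pa$activities, truth = pa$truth)
    cache[[key]] <<- out
    out
  }
})
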
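#' Probe atom specification
#'
#' The CoMFA probe is an sp3 carbon bearing a +1 charge; the CoMSIA probe
#' has radius 1 A and value +1 in every property channel.  `attenuation`
#' is the Gaussian attenuation factor of the similarity index, `truncation`
#' the CoMFA energy cutoff in kcal/mol.
#'
#' @param lj_radius probe van der Waals radius for the Lennard-Jones term (A)
#' @param lj_epsilon probe well depth (kcal/mol)
#' @param charge probe charge (e)
#' @param comsia_radius CoMSIA probe radius (A); its cube is the steric
#'   probe property
#' @param attenuation Gaussian attenuation factor alpha (1/A^2)
#' @param truncation CoMFA truncation level (kcal/mol)
#' @param dielectric `"distance"` for the distance-dependent dielectric
#'   D(r) = r, `"constant"` for D = 1
#' @return object of class `probe_spec`
#' @export
probe_spec <- function(lj_radius = 1.70, lj_epsilon = 0.1094, charge = 1,
                       comsia_radius = 1.0, attenuation = 0.3,
                       truncation = 30,
                       dielectric = c("distance", "constant")) {
  dielectric <- match.arg(dielectric)
  if (attenuation <= 0) stop("attenuation factor must be > 0", call. = FALSE)
  if (truncation <= 0) stop("truncation must be > 0", call. = FALSE)
  structure(list(lj_radius = lj_radius, lj_epsilon = lj_epsilon,
                 charge = charge, comsia_radius = comsia_radius,
                 attenuation = attenuation, truncation = truncation,
                 dielectric = dielectric),
            class = "probe_spec")
}

#' Build the shared lattice around an aligned series
#'
#' Axis-aligned box: the union bounding box of all atoms, expanded by
#' `margin` on each side, discretized at `spacing`.
#'
#' @param mols a [molecule_set()] of aligned molecules
#' @param spacing grid spacing in A
#' @param margin box margin in A beyond the bounding box
#' @return object of class `lattice`: `origin`, `spacing`, `dims`
#' @export
build_lattice <- function(mols, spacing = 2.0, margin = 4.0) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (length(mols) == 0L) stop("empty molecule set", call. = FALSE)
  if (inherits(mols, "molecule")) mols <- molecule_set(list(mols))
  allxyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(allxyz, 2, min) - margin
  hi <- apply(allxyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Coordinates of all lattice points
#'
#' Points are ordered with the x index varying fastest, matching how grid
#' vectors map onto `array(values, lattice$dims)`.
#'
#' @param lattice a [build_lattice()] object
#' @return matrix (n_points x 3)
#' @export
lattice_points <- function(lattice) {
  ax <- lapply(1:3, function(k)
    lattice$origin[k] + lattice$spacing * (seq_len(lattice$dims[k]) - 1L))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

# squared distances between grid points (m x 3) and atom coords (n x 3)
.dist2 <- function(G, A) {
  outer(rowSums(G^2), rowSums(A^2), `+`) - 2 * G %*% t(A)
}

#' CoMFA steric and electrostatic fields of one molecule
#'
#' Steric: Lennard-Jones 12-6 energy of the probe summed over atoms, with
#' `r_min = vdw_radius_atom + lj_radius_probe` and
#' `eps = sqrt(lj_epsilon_atom * lj_epsilon_probe)`, clamped to
#' `[-truncation, +truncation]`.  Electrostatic: Coulomb sum
#' `332.17 * q_i * q_probe / (D(r) r)` with the distance-dependent
#' dielectric `D(r) = r` by default, also clamped.  Grid points whose
#' unclamped steric energy reaches the truncation level are flagged in
#' `clash`; their electrostatic values are set to `NA` and are meant to be
#' mean-filled per column across the training set when the descriptor
#' matrix is assembled.
#'
#' @param mol prepared, aligned molecule
#' @param lattice shared [build_lattice()] lattice
#' @param probe a [probe_spec()]
#' @return list of two `field_grid` objects, `steric` and `electrostatic`
#' @export
comfa_fields <- function(mol, lattice, probe = probe_spec()) {
  if (any(is.na(mol$atoms$partial_charge)))
    stop(sprintf("molecule %s: charges not assigned", mol$id), call. = FALSE)
  if (any(is.na(mol$atoms$vdw_radius)))
    stop(sprintf("molecule %s: field parameters not assigned", mol$id), call. = FALSE)
  G <- lattice_points(lattice)
  res <- .comfa_at(mol, G, probe)
  list(steric = structure(list(molecule_id = mol$id, field = "comfa_steric",
                               values = res$steric, clash = res$clash,
                               lattice = lattice), class = "field_grid"),
       electrostatic = structure(list(molecule_id = mol$id,
                                      field = "comfa_elec",
                                      values = res$elec, clash = res$clash,
                                      lattice = lattice), class = "field_grid"))
}

.comfa_at <- function(mol, G, probe) {
  A <- coords(mol)
  d2 <- .dist2(G, A)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  rmin <- mol$atoms$vdw_radius + probe$lj_radius
  eps <- sqrt(mol$atoms$lj_epsilon * probe$lj_epsilon)
  # (rmin/r)^6 per point x atom; coincident points give Inf -> truncated
  s6 <- sweep(1 / pmax(r, 1e-12)^6, 2, rmin^6, `*`)
  lj <- sweep(s6^2 - 2 * s6, 2, eps, `*`)
  steric_raw <- rowSums(lj)
  clash <- steric_raw >= probe$truncation
  steric <- pmin(pmax(steric_raw, -probe$truncation), probe$truncation)
  denom <- if (probe$dielectric == "distance") d2 else r
  ec <- sweep(1 / pmax(denom, 1e-12), 2,
              .COULOMB_K * mol$atoms$partial_charge * probe$charge, `*`)
  elec <- rowSums(ec)
  elec <- pmin(pmax(elec, -probe$truncation), probe$truncation)
  elec[clash] <- NA_real_
  list(steric = steric, elec = elec, clash = clash)
}

#' CoMSIA similarity-index fields of one molecule
#'
#' For each property `k`, the similarity index at grid point `q` is
#' `A_k(q) = sum_i w_probe_k * w_ik * exp(-alpha * r_iq^2)` with the
#' positive sign convention of the original similarity-index formulation
#' (the global sign is immaterial to the regression).  Atomic property
#' values `w_ik`: steric = vdw_radius^3, electrostatic = partial charge,
#' hydrophobic = atomic hydrophobicity, donor/acceptor = 0/1 flags on heavy
#' atoms.  Probe values are +1 in every channel (radius 1 A, so the steric
#' probe property is also 1).
#'
#' @inheritParams comfa_fields
#' @return named list of five `field_grid` objects: `steric`,
#'   `electrostatic`, `hydrophobic`, `donor`, `acceptor`
#' @export
comsia_fields <- function(mol, lattice, probe = probe_spec()) {
  if (any(is.na(mol$atoms$partial_charge)))
    stop(sprintf("molecule %s: charges not assigned", mol$id), call. = FALSE)
  if (any(is.na(mol$atoms$vdw_radius)))
    stop(sprintf("molecule %s: field parameters not assigned", mol$id), call. = FALSE)
  if (probe$attenuation <= 0) stop("attenuation factor must be > 0", call. = FALSE)
  G <- lattice_points(lattice)
  vals <- .comsia_at(mol, G, probe)
  out <- lapply(names(vals), function(nm)
    structure(list(molecule_id = mol$id, field = paste0("comsia_", nm),
                   values = vals[[nm]], clash = NULL, lattice = lattice),
              class = "field_grid"))
  names(out) <- names(vals)
  out
}

.comsia_at <- function(mol, G, probe) {
  A <- coords(mol)
  d2 <- .dist2(G, A)
  d2[d2 < 0] <- 0
  K <- exp(-probe$attenuation * d2)       # points x atoms
  wp <- probe$comsia_radius^3             # steric probe property (radius^3)
  props <- list(
    steric       = wp * mol$atoms$vdw_radius^3,
    electrostatic = mol$atoms$partial_charge,
    hydrophobic  = mol$atoms$hydrophobic_w,
    donor        = as.numeric(mol$atoms$is_hbd),
    acceptor     = as.numeric(mol$atoms$is_hba))
  lapply(props, function(w) as.numeric(K %*% w))
}

#' Evaluate all requested fields for a whole series
#'
#' @param mols prepared, aligned [molecule_set()]
#' @param lattice shared lattice
#' @param probe a [probe_spec()]
#' @param fields `"comfa"`, `"comsia"`, or both
#' @return object of class `field_block_set`: list with `values` (named list
#'   of per-field matrices, molecules x lattice points), `clash` (logical
#'   matrix for the CoMFA fields, or NULL), `lattice`, `ids`
#' @export
compute_fields <- function(mols, lattice, probe = probe_spec(),
                           fields = c("comfa", "comsia")) {
  fields <- match.arg(fields, several.ok = TRUE)
  G <- lattice_points(lattice)
  npt <- nrow(G)
  ids <- names(mols)
  values <- list(); clash <- NULL
  if ("comfa" %in% fields) {
    st <- matrix(NA_real_, length(mols), npt)
    el <- matrix(NA_real_, length(mols), npt)
    cl <- matrix(FALSE, length(mols), npt)
    for (i in seq_along(mols)) {
      r <- .comfa_at(mols[[i]], G, probe)
      st[i, ] <- r$steric; el[i, ] <- r$elec; cl[i, ] <- r$clash
    }
    values$comfa_steric <- st; values$comfa_elec <- el
    clash <- cl
  }
  if ("comsia" %in% fields) {
    nm <- c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")
    mats <- lapply(nm, function(x) matrix(NA_real_, length(mols), npt))
    names(mats) <- nm
    for (i in seq_along(mols)) {
      r <- .comsia_at(mols[[i]], G, probe)
      for (x in nm) mats[[x]][i, ] <- r[[x]]
    }
    names(mats) <- paste0("comsia_", c("steric", "elec", "hydrophobic",
                                       "donor", "acceptor"))
    values <- c(values, mats)
  }
  for (nm in names(values)) rownames(values[[nm]]) <- ids
  structure(list(values = values, clash = clash, lattice = lattice, ids = ids),
            class = "field_block_set")
}

# field values of one molecule at arbitrary points (used by the synthetic
# generator to evaluate planted cells without a full lattice sweep)
.field_values_at <- function(mol, points, field, probe = probe_spec()) {
  points <- matrix(points, ncol = 3)
  if (startsWith(field, "comfa")) {
    r <- .comfa_at(mol, points, probe)
    if (field == "comfa_steric") r$steric else {
      v <- r$elec
      v[is.na(v)] <- 0  # clashed cells carry no electrostatic signal
      v
    }
  } else {
    v <- .comsia_at(mol, points, probe)
    key <- sub("comsia_", "", field)
    key <- c(steric = "steric", elec = "electrostatic",
             hydrophobic = "hydrophobic", donor = "donor",
             acceptor = "acceptor")[[key]]
    v[[key]]
  }
}
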
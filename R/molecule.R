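#' Construct a molecule object
#'
#' A `molecule` is the package's container for a small molecule: an atom
#' table with 3D coordinates and per-atom physicochemical parameters, a bond
#' list, optional extra conformers, and a free-form property list (SDF data
#' fields end up here).
#'
#' @param id compound identifier (unique within a [molecule_set()])
#' @param atoms data frame with at least `element`, `x`, `y`, `z`; optional
#'   `formal_charge`.  Further per-atom columns (`partial_charge`,
#'   `vdw_radius`, `lj_epsilon`, `hydrophobic_w`, `is_hbd`, `is_hba`,
#'   `is_aromatic`, `hyb`) are filled by [assign_partial_charges()] and
#'   [assign_field_params()].
#' @param bonds data frame with columns `a1`, `a2`, `order` (1, 2, 3, or 4
#'   for aromatic); indices are 1-based into `atoms`
#' @param properties named list of molecule-level properties
#' @param conformers list of additional coordinate matrices (n_atoms x 3)
#' @return an object of class `molecule`
#' @export
molecule <- function(id, atoms, bonds = NULL, properties = list(),
                     conformers = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns element, x, y, z", call. = FALSE)
  if (nrow(atoms) == 0L) stop("molecule must contain at least one atom", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite", call. = FALSE)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  for (col in c("partial_charge", "vdw_radius", "lj_epsilon", "hydrophobic_w"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  for (col in c("is_hbd", "is_hba", "is_aromatic"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA
  if (is.null(atoms$hyb)) atoms$hyb <- NA_character_
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    if (!all(c("a1", "a2", "order") %in% names(bonds)))
      stop("bonds must have columns a1, a2, order", call. = FALSE)
    n <- nrow(atoms)
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n))
      stop("bond atom indices out of range", call. = FALSE)
    if (any(bonds$a1 == bonds$a2)) stop("self-bonds are not allowed", call. = FALSE)
  }
  for (cf in conformers) {
    cf <- as.matrix(cf)
    if (nrow(cf) != nrow(atoms) || ncol(cf) != 3L)
      stop("every conformer needs one coordinate triple per atom", call. = FALSE)
  }
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 properties = properties, conformers = conformers),
            class = "molecule")
}

#' Bundle molecules into a set
#'
#' @param mols list of [molecule()] objects with unique ids
#' @return object of class `molecule_set` (a named list)
#' @export
molecule_set <- function(mols) {
  if (length(mols) == 0L) stop("empty molecule set", call. = FALSE)
  ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids in set", call. = FALSE)
  names(mols) <- ids
  structure(mols, class = "molecule_set")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds, %d extra conformer(s)>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set of %d molecules: %s%s>\n", length(x),
              paste(utils::head(names(x), 5), collapse = ", "),
              if (length(x) > 5) ", ..." else ""))
  invisible(x)
}

#' @export
`[.molecule_set` <- function(x, i) {
  structure(unclass(x)[i], class = "molecule_set")
}

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

`coords<-` <- function(mol, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == nrow(mol$atoms), ncol(value) == 3L)
  mol$atoms$x <- value[, 1]; mol$atoms$y <- value[, 2]; mol$atoms$z <- value[, 3]
  mol
}

# molecular graph as igraph object; vertices carry element labels
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds) > 0L)
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  igraph::set_vertex_attr(g, "element", value = mol$atoms$element)
}

# neighbor lists: indices of atoms bonded to each atom
.neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# enumerate simple rings of size 3..max_size by DFS from each bond.
# Returns a list of integer vectors (atom index cycles, deduplicated).
.find_rings <- function(mol, max_size = 7L) {
  nb <- .neighbors(mol)
  n <- nrow(mol$atoms)
  rings <- list()
  seen <- character(0)
  dfs <- function(path, target) {
    last <- path[length(path)]
    for (nx in nb[[last]]) {
      if (nx == target && length(path) >= 3L) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nx %in% path) && length(path) < max_size && nx > path[1L]) {
        dfs(c(path, nx), target)
      }
    }
  }
  for (s in seq_len(n)) if (length(nb[[s]]) >= 2L) dfs(s, s)
  # keep only smallest rings: drop rings that are unions of smaller ones
  # (sufficient here: drop any ring strictly containing another ring's atoms)
  if (length(rings) > 1L) {
    keep <- rep(TRUE, length(rings))
    sets <- lapply(rings, sort)
    ord <- order(lengths(sets))
    for (ii in seq_along(ord)) for (jj in seq_along(ord)) {
      if (ii < jj && keep[ord[jj]] &&
          all(sets[[ord[ii]]] %in% sets[[ord[jj]]]) &&
          length(sets[[ord[ii]]]) < length(sets[[ord[jj]]]))
        keep[ord[jj]] <- FALSE
    }
    rings <- rings[keep]
  }
  rings
}

.bond_order_lookup <- function(mol) {
  bo <- new.env(hash = TRUE)
  if (nrow(mol$bonds) > 0L) for (k in seq_len(nrow(mol$bonds))) {
    key <- paste(sort(c(mol$bonds$a1[k], mol$bonds$a2[k])), collapse = "-")
    assign(key, mol$bonds$order[k], envir = bo)
  }
  function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "-")
    if (exists(key, envir = bo)) get(key, envir = bo) else NA_integer_
  }
}

# hybridization from bond orders: sp if a triple bond or >=2 doubles,
# sp2 if any double or aromatic bond, else sp3
.perceive_hybridization <- function(mol) {
  n <- nrow(mol$atoms)
  hyb <- rep("sp3", n)
  if (nrow(mol$bonds) > 0L) {
    for (i in seq_len(n)) {
      b <- mol$bonds[mol$bonds$a1 == i | mol$bonds$a2 == i, ]
      nd <- sum(b$order == 2L); nt <- sum(b$order == 3L); na <- sum(b$order == 4L)
      if (nt >= 1L || nd >= 2L) hyb[i] <- "sp"
      else if (nd >= 1L || na >= 1L) hyb[i] <- "sp2"
    }
  }
  hyb
}

# aromatic perception: bonds of order 4 mark their atoms aromatic; in
# addition, 5-7 membered rings of C/N/O/S in which every carbon carries a
# double bond within the ring are marked aromatic (covers Kekule benzene
# and pyridine-type rings written with alternating single/double bonds)
.perceive_aromaticity <- function(mol) {
  n <- nrow(mol$atoms)
  arom <- rep(FALSE, n)
  if (nrow(mol$bonds) > 0L) {
    b4 <- mol$bonds[mol$bonds$order == 4L, ]
    arom[unique(c(b4$a1, b4$a2))] <- TRUE
  }
  bo <- .bond_order_lookup(mol)
  for (ring in .find_rings(mol)) {
    if (length(ring) < 5L || length(ring) > 7L) next
    el <- mol$atoms$element[ring]
    if (!all(el %in% c("C", "N", "O", "S"))) next
    m <- length(ring)
    ring_orders <- vapply(seq_len(m), function(k)
      bo(ring[k], ring[k %% m + 1L]), integer(1))
    if (all(ring_orders == 4L)) { arom[ring] <- TRUE; next }
    # Kekule form: every ring carbon has exactly one double bond in the ring
    ok <- TRUE
    for (k in seq_len(m)) {
      if (el[k] != "C") next
      prev <- ring[(k - 2L) %% m + 1L]; nxt <- ring[k %% m + 1L]
      ndbl <- sum(c(bo(ring[k], prev), bo(ring[k], nxt)) == 2L, na.rm = TRUE)
      if (ndbl != 1L) { ok <- FALSE; break }
    }
    if (ok && sum(el == "C") >= 2L && sum(ring_orders == 2L) >= 2L)
      arom[ring] <- TRUE
  }
  arom
}

# aromatic rings (lists of atom indices) for AR pharmacophore features;
# ring perception is cached on the molecule by assign_field_params
.aromatic_rings <- function(mol) {
  arom <- if (all(!is.na(mol$atoms$is_aromatic))) mol$atoms$is_aromatic
          else .perceive_aromaticity(mol)
  rings <- if (!is.null(mol$rings)) mol$rings else .find_rings(mol)
  Filter(function(r) all(arom[r]), rings)
}

# count of hydrogens bonded to each atom
.h_counts <- function(mol) {
  n <- nrow(mol$atoms)
  hc <- integer(n)
  if (nrow(mol$bonds) > 0L) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    if (mol$atoms$element[j] == "H") hc[i] <- hc[i] + 1L
    if (mol$atoms$element[i] == "H") hc[j] <- hc[j] + 1L
  }
  hc
}
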
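#' Parse a line-notation substructure pattern
#'
#' A deliberately small SMILES-like query language, sufficient to name a
#' shared scaffold: element symbols (`C`, `N`, `O`, `S`, `F`, `Cl`, `Br`,
#' `I`, `H`), lowercase aromatic atoms (`c`, `n`, `o`, `s`), branches in
#' parentheses, ring-closure digits, and explicit bonds `-`, `=`, `#`, `:`,
#' `~` (any).  Unspecified bonds match any bond order, the usual
#' substructure-query semantics; an aromatic pattern atom only matches an
#' aromatic molecule atom.
#'
#' @param pattern query string
#' @return list with `atoms` (element, aromatic) and `bonds` (a1, a2, order;
#'   0 = any)
#' @export
parse_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "")[[1]]
  atoms <- data.frame(element = character(0), aromatic = logical(0))
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  prev_stack <- integer(0); prev <- NA_integer_
  pending_bond <- NA_integer_
  ring_open <- list()
  i <- 1L
  add_atom <- function(el, arom) {
    atoms[nrow(atoms) + 1L, ] <<- list(el, arom)
    idx <- nrow(atoms)
    if (!is.na(prev)) {
      ord <- if (is.na(pending_bond)) 0L else pending_bond
      bonds[nrow(bonds) + 1L, ] <<- list(prev, idx, ord)
    }
    pending_bond <<- NA_integer_
    prev <<- idx
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    two <- if (i < length(chars)) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) { add_atom(two, FALSE); i <- i + 2L; next }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "H")) {
      add_atom(ch, FALSE); i <- i + 1L; next
    }
    if (ch %in% c("c", "n", "o", "s")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L, "~" = 0L)
      i <- i + 1L; next
    }
    if (ch == "(") { prev_stack <- c(prev_stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (length(prev_stack) == 0L) stop("unbalanced ')' in pattern", call. = FALSE)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L; next
    }
    if (grepl("[0-9]", ch)) {
      if (!is.null(ring_open[[ch]])) {
        opn <- ring_open[[ch]]
        ord <- if (is.na(pending_bond)) 0L else pending_bond
        bonds[nrow(bonds) + 1L, ] <- list(opn, prev, ord)
        ring_open[[ch]] <- NULL
      } else ring_open[[ch]] <- prev
      pending_bond <- NA_integer_
      i <- i + 1L; next
    }
    stop(sprintf("unsupported character '%s' in pattern", ch), call. = FALSE)
  }
  if (length(ring_open) > 0L) stop("unclosed ring bond in pattern", call. = FALSE)
  if (length(prev_stack) > 0L) stop("unbalanced '(' in pattern", call. = FALSE)
  if (nrow(atoms) == 0L) stop("pattern contains no atoms", call. = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# all substructure matches of pattern in mol; each match is an integer
# vector mapping pattern atom k to molecule atom match[k]
.match_pattern <- function(mol, pat) {
  arom <- if (any(is.na(mol$atoms$is_aromatic))) .perceive_aromaticity(mol)
          else mol$atoms$is_aromatic
  n <- nrow(mol$atoms)
  # candidate domains: element identity, and aromatic query atoms must map
  # to aromatic molecule atoms
  domains <- lapply(seq_len(nrow(pat$atoms)), function(k) {
    ok <- mol$atoms$element == pat$atoms$element[k]
    if (pat$atoms$aromatic[k]) ok <- ok & arom
    which(ok)
  })
  if (any(lengths(domains) == 0L)) return(list())
  pg <- igraph::make_empty_graph(n = nrow(pat$atoms), directed = FALSE)
  if (nrow(pat$bonds) > 0L)
    pg <- igraph::add_edges(pg, rbind(pat$bonds$a1, pat$bonds$a2))
  mg <- mol_graph(mol)
  maps <- igraph::subgraph_isomorphisms(pattern = pg, target = mg,
                                        method = "lad", induced = FALSE,
                                        domains = domains)
  maps <- lapply(maps, as.integer)
  # honour explicit bond orders in the pattern
  if (nrow(pat$bonds) > 0L && any(pat$bonds$order > 0L)) {
    bo <- .bond_order_lookup(mol)
    keep <- vapply(maps, function(mp) {
      all(vapply(which(pat$bonds$order > 0L), function(b) {
        ord <- bo(mp[pat$bonds$a1[b]], mp[pat$bonds$a2[b]])
        !is.na(ord) && ord == pat$bonds$order[b]
      }, logical(1)))
    }, logical(1))
    maps <- maps[keep]
  }
  # collapse automorphic duplicates mapping to the same ordered atom set is
  # NOT done here: callers decide (rmsd-minimal match selection needs all)
  maps
}

#' Find the scaffold correspondence between a molecule and a template
#'
#' Matches `scaffold_pattern` in both template and molecule.  The pattern
#' must cover a unique atom set in the template; among all molecule matches
#' (including automorphic re-orderings) the one minimizing the rigid-body
#' superposition RMSD is selected, ties broken by the lexicographically
#' smallest atom index sequence.
#'
#' @param mol molecule to map
#' @param template template molecule
#' @param scaffold_pattern query string for [parse_pattern()]
#' @return object of class `scaffold_mapping`: list with `template_atoms`,
#'   `molecule_atoms`, `rmsd`
#' @export
find_scaffold_mapping <- function(mol, template, scaffold_pattern) {
  pat <- parse_pattern(scaffold_pattern)
  tmaps <- .match_pattern(template, pat)
  if (length(tmaps) == 0L)
    stop("scaffold pattern does not match the template", call. = FALSE)
  tsets <- unique(lapply(tmaps, sort))
  if (length(tsets) > 1L)
    stop("ambiguous template match: pattern hits more than one atom set",
         call. = FALSE)
  # canonical template ordering: lexicographically smallest mapping
  tkey <- vapply(tmaps, function(m) paste(m, collapse = ","), character(1))
  tmap <- tmaps[[order(tkey)[1L]]]
  mmaps <- .match_pattern(mol, pat)
  if (length(mmaps) == 0L) stop("scaffold absent", call. = FALSE)
  rmsds <- vapply(mmaps, function(mp) {
    .kabsch_rmsd(coords(mol)[mp, , drop = FALSE],
                 coords(template)[tmap, , drop = FALSE])$rmsd
  }, numeric(1))
  mkey <- vapply(mmaps, function(m) paste(m, collapse = ","), character(1))
  best <- order(round(rmsds, 10), mkey)[1L]
  structure(list(template_atoms = tmap, molecule_atoms = mmaps[[best]],
                 rmsd = rmsds[best]),
            class = "scaffold_mapping")
}

#' @export
print.scaffold_mapping <- function(x, ...) {
  cat(sprintf("<scaffold_mapping: %d atoms, rmsd %.4f A>\n",
              length(x$template_atoms), x$rmsd))
  invisible(x)
}

# Kabsch least-squares rigid superposition of P onto Q (both n x 3).
# Returns rotation R, translation, rmsd; det(R) = +1 always.
.kabsch_rmsd <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L)
  if (nrow(P) < 3L) stop("need at least 3 mapped atoms", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    stop("degenerate geometry: mapped atoms are collinear", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(R = R, center_p = cp, center_q = cq, rmsd = rmsd)
}

#' Rigid-body superposition onto a template
#'
#' Least-squares (Kabsch) rotation + translation of the whole molecule so
#' that the mapped atoms best overlay their template counterparts.  No
#' scaling, no reflection (the fitted rotation always has determinant +1).
#'
#' @param mol molecule to transform
#' @param template template molecule
#' @param mapping a `scaffold_mapping` from [find_scaffold_mapping()]
#' @return list with `molecule` (transformed) and `rmsd` over mapped atoms
#' @export
superpose <- function(mol, template, mapping) {
  mi <- mapping$molecule_atoms; ti <- mapping$template_atoms
  stopifnot(length(mi) == length(ti))
  if (length(mi) < 3L) stop("need at least 3 mapped atoms", call. = FALSE)
  if (anyDuplicated(mi) || anyDuplicated(ti))
    stop("mapping indices must be unique", call. = FALSE)
  fit <- .kabsch_rmsd(coords(mol)[mi, , drop = FALSE],
                      coords(template)[ti, , drop = FALSE])
  X <- coords(mol)
  Xc <- sweep(X, 2, fit$center_p)
  Xn <- sweep(Xc %*% t(fit$R), 2, fit$center_q, `+`)
  coords(mol) <- Xn
  list(molecule = mol, rmsd = fit$rmsd)
}

#' Align a whole series onto a template via a shared scaffold
#'
#' @param mols a [molecule_set()]
#' @param template_id id of the template compound within `mols`
#' @param scaffold_pattern substructure query for the shared scaffold
#' @return list with the aligned `molecule_set` and a data frame of per-
#'   compound scaffold RMSDs
#' @export
align_series <- function(mols, template_id, scaffold_pattern) {
  if (!template_id %in% names(mols))
    stop(sprintf("template '%s' not in molecule set", template_id), call. = FALSE)
  template <- mols[[template_id]]
  aligned <- vector("list", length(mols))
  rmsd <- numeric(length(mols))
  for (i in seq_along(mols)) {
    mp <- find_scaffold_mapping(mols[[i]], template, scaffold_pattern)
    sp <- superpose(mols[[i]], template, mp)
    aligned[[i]] <- sp$molecule
    rmsd[i] <- sp$rmsd
  }
  list(molecules = molecule_set(aligned),
       rmsd = data.frame(compound_id = names(mols), rmsd = rmsd))
}
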
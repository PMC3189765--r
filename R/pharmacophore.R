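#' Pharmacophore search parameters
#'
#' Defaults follow common practice for distance-comparison pharmacophore
#' elucidation: a 0.25 A pairwise distance tolerance, models of 4 to 16
#' features, conformer pools of at most 50 with 7 retained, and a 0.6
#' similarity threshold for pruning near-duplicate conformers.
#'
#' @param tolerance pairwise distance tolerance in A; two inter-feature
#'   distances are considered equivalent when they differ by at most twice
#'   this value
#' @param min_features,max_features model size bounds
#' @param n_conformers_max stochastic sampling pool size per molecule
#' @param n_conformers_select conformers retained after energy sorting and
#'   diversity pruning
#' @param tanimoto_threshold conformers whose feature-distance profiles are
#'   at least this similar (continuous Tanimoto) count as duplicates
#' @param projection_distance distance (A) at which donor/acceptor site
#'   points are projected along the idealized hydrogen-bond vector
#' @param node_cap correspondence-graph size limit; beyond it the search
#'   aborts with an error rather than silently truncating
#' @param seed RNG seed for conformer sampling
#' @return object of class `pharm_params`
#' @export
pharm_params <- function(tolerance = 0.25, min_features = 4L,
                         max_features = 16L, n_conformers_max = 50L,
                         n_conformers_select = 7L,
                         tanimoto_threshold = 0.6,
                         projection_distance = 2.9,
                         node_cap = 10000L, seed = 1L) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (min_features > max_features)
    stop("min_features must not exceed max_features", call. = FALSE)
  structure(list(tolerance = tolerance, min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 n_conformers_max = as.integer(n_conformers_max),
                 n_conformers_select = as.integer(n_conformers_select),
                 tanimoto_threshold = tanimoto_threshold,
                 projection_distance = projection_distance,
                 node_cap = as.integer(node_cap), seed = as.integer(seed)),
            class = "pharm_params")
}

#' Perceive pharmacophore features of a molecule
#'
#' Feature kinds:
#' * `HD` hydrogen-bond donor heavy atoms, `HA` acceptor heavy atoms
#'   (flags from [assign_field_params()]);
#' * `DS` donor site points, projected `projection_distance` A from the
#'   donor along each donor-H bond vector;
#' * `AS` acceptor site points, projected along the lone-pair bisector
#'   (opposite the mean of the acceptor's bond vectors);
#' * `AR` aromatic ring centroids;
#' * `HP` centroids of connected clusters of at least 3 low-polarity heavy
#'   atoms (|partial charge| < 0.2; carbon or halogen);
#' * `PN` positively charged or protonatable basic nitrogen.
#'
#' @param mol prepared [molecule()] (charges + field parameters assigned)
#' @param xyz optional alternative coordinate matrix (a conformer)
#' @param projection_distance see [pharm_params()]
#' @return data frame with columns `kind`, `x`, `y`, `z`, `parent`
#' @export
perceive_features <- function(mol, xyz = NULL, projection_distance = 2.9) {
  if (any(is.na(mol$atoms$partial_charge)))
    stop(sprintf("molecule %s: charges not assigned", mol$id), call. = FALSE)
  if (any(is.na(mol$atoms$is_hbd)))
    stop(sprintf("molecule %s: field parameters not assigned", mol$id), call. = FALSE)
  X <- if (is.null(xyz)) coords(mol) else as.matrix(xyz)
  el <- mol$atoms$element
  nb <- .neighbors(mol)
  kinds <- character(0); locs <- list(); parents <- integer(0)
  add <- function(kind, loc, parent) {
    kinds[[length(kinds) + 1L]] <<- kind
    locs[[length(locs) + 1L]] <<- loc
    parents[[length(parents) + 1L]] <<- parent
  }
  for (i in which(mol$atoms$is_hbd)) {
    add("HD", X[i, ], i)
    for (h in nb[[i]][el[nb[[i]]] == "H"]) {
      v <- X[h, ] - X[i, ]
      add("DS", X[i, ] + projection_distance * v / sqrt(sum(v^2)), i)
    }
  }
  for (i in which(mol$atoms$is_hba)) {
    add("HA", X[i, ], i)
    heavy <- nb[[i]]
    if (length(heavy) > 0L) {
      vs <- X[heavy, , drop = FALSE] - matrix(X[i, ], length(heavy), 3, byrow = TRUE)
      vs <- vs / sqrt(rowSums(vs^2))
      dir <- -colSums(vs)
      nd <- sqrt(sum(dir^2))
      # symmetric environments (e.g. planar N with three 120-degree bonds)
      # have no defined lone-pair direction; the threshold is well above
      # coordinate round-off so file round-trips cannot flip the decision
      if (nd > 1e-3)
        add("AS", X[i, ] + projection_distance * dir / nd, i)
    }
  }
  for (ring in .aromatic_rings(mol))
    add("AR", colMeans(X[ring, , drop = FALSE]), ring[1])
  # hydrophobic clusters: low-polarity C/halogen heavy atoms
  lp <- which(el %in% c("C", "F", "Cl", "Br", "I") &
                abs(mol$atoms$partial_charge) < 0.2)
  if (length(lp) >= 3L) {
    g <- mol_graph(mol)
    sub <- igraph::induced_subgraph(g, lp)
    comp <- igraph::components(sub)
    for (k in seq_len(comp$no)) {
      members <- lp[comp$membership == k]
      if (length(members) >= 3L)
        add("HP", colMeans(X[members, , drop = FALSE]), members[1])
    }
  }
  n_cand <- which(el == "N")
  bo <- if (length(n_cand)) .bond_order_lookup(mol) else NULL
  for (i in n_cand) {
    basic <- mol$atoms$formal_charge[i] > 0L ||
      (mol$atoms$hyb[i] == "sp3" && !mol$atoms$is_aromatic[i] &&
         !.adjacent_to_carbonyl(mol, i, nb, bo))
    if (basic) add("PN", X[i, ], i)
  }
  if (length(kinds) == 0L)
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), parent = integer(0)))
  L <- do.call(rbind, locs)
  data.frame(kind = kinds, x = L[, 1], y = L[, 2], z = L[, 3],
             parent = parents)
}

# amide-type N (adjacent carbon double-bonded to O) is not basic
.adjacent_to_carbonyl <- function(mol, i, nb = .neighbors(mol),
                                  bo = .bond_order_lookup(mol)) {
  for (j in nb[[i]]) {
    if (mol$atoms$element[j] != "C") next
    for (k in nb[[j]])
      if (mol$atoms$element[k] == "O" && !is.na(bo(j, k)) && bo(j, k) == 2L)
        return(TRUE)
  }
  FALSE
}

# ---- conformer generation ----------------------------------------------

.rotatable_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(data.frame(a1 = integer(), a2 = integer()))
  g <- mol_graph(mol)
  deg <- igraph::degree(g)
  ring_atoms <- unique(unlist(.find_rings(mol, max_size = 12L)))
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 1L) next
    if (deg[b$a1] < 2L || deg[b$a2] < 2L) next
    if (b$a1 %in% ring_atoms && b$a2 %in% ring_atoms) {
      # a bond inside a ring cannot rotate; check it is actually a ring bond
      in_ring <- any(vapply(.find_rings(mol, max_size = 12L), function(r) {
        m <- length(r)
        any((r == b$a1 & c(r[-1], r[1]) == b$a2) |
              (r == b$a2 & c(r[-1], r[1]) == b$a1))
      }, logical(1)))
      if (in_ring) next
    }
    out[[length(out) + 1L]] <- data.frame(a1 = b$a1, a2 = b$a2)
  }
  if (length(out) == 0L) data.frame(a1 = integer(), a2 = integer())
  else do.call(rbind, out)
}

# atoms on the a2 side of the a1-a2 bond (the side that rotates)
.bond_side <- function(mol, a1, a2) {
  g <- mol_graph(mol)
  eid <- igraph::get_edge_ids(g, c(a1, a2))
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)
  which(comp$membership == comp$membership[a2])
}

.rotate_about_axis <- function(X, p0, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) * c_ + s_ * K + (1 - c_) * (u %o% u)
  sweep(sweep(X, 2, p0) %*% t(R), 2, p0, `+`)
}

# atom pairs separated by more than two bonds (the pairs that feel strain)
.strain_pairs <- function(mol) {
  g <- mol_graph(mol)
  topo <- igraph::distances(g)
  idx <- which(upper.tri(topo) & (!is.finite(topo) | topo > 2), arr.ind = TRUE)
  r <- .VDW[mol$atoms$element]
  list(i = idx[, 1], j = idx[, 2], rsum = r[idx[, 1]] + r[idx[, 2]])
}

# crude steric strain: clash-dominated repulsive score over the pair list
.conformer_energy <- function(pairs, X) {
  if (length(pairs$i) == 0L) return(0)
  d <- sqrt(rowSums((X[pairs$i, , drop = FALSE] -
                       X[pairs$j, , drop = FALSE])^2))
  sum(pmin((pairs$rsum * 0.8 / pmax(d, 0.1))^12, 1e3))
}

.feature_profile <- function(feats) {
  if (nrow(feats) < 2L) return(numeric(0))
  sort(as.numeric(stats::dist(as.matrix(feats[, c("x", "y", "z")]))))
}

.profile_tanimoto <- function(p, q) {
  if (length(p) == 0L && length(q) == 0L) return(1)
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p))); q <- c(q, rep(0, n - length(q)))
  s <- sum(pmin(p, q)) / sum(pmax(p, q))
  s
}

#' Generate a conformer ensemble by stochastic torsion sampling
#'
#' Rotatable (acyclic, single, non-terminal) bonds are assigned uniform
#' random torsion offsets for each of `n_conformers_max` trials; trial
#' geometries are scored with a clash-dominated steric strain term, sorted
#' by score, and pruned for diversity: a conformer whose feature-distance
#' profile is at least `tanimoto_threshold` similar to one already kept is
#' treated as a duplicate.  At most `n_conformers_select` conformers are
#' kept (the input geometry is always first).  Rigid molecules yield
#' exactly one conformer.  Deterministic for a given seed.
#'
#' @param mol prepared [molecule()]
#' @param params a [pharm_params()]
#' @return the molecule with `conformers` replaced by the selected ensemble
#'   (each an n_atoms x 3 matrix; the first is the input geometry)
#' @export
generate_conformers <- function(mol, params = pharm_params()) {
  rb <- .rotatable_bonds(mol)
  base <- coords(mol)
  if (nrow(rb) == 0L) { mol$conformers <- list(base); return(mol) }
  sides <- lapply(seq_len(nrow(rb)), function(k)
    .bond_side(mol, rb$a1[k], rb$a2[k]))
  pool <- .with_seed(params$seed, function() {
    lapply(seq_len(params$n_conformers_max - 1L), function(t) {
      X <- base
      ang <- stats::runif(nrow(rb), 0, 2 * pi)
      for (k in seq_len(nrow(rb))) {
        axis <- X[rb$a2[k], ] - X[rb$a1[k], ]
        X[sides[[k]], ] <- .rotate_about_axis(X[sides[[k]], , drop = FALSE],
                                              X[rb$a1[k], ], axis, ang[k])
      }
      X
    })
  })
  pool <- c(list(base), pool)
  pairs <- .strain_pairs(mol)
  energies <- vapply(pool, function(X) .conformer_energy(pairs, X), numeric(1))
  ord <- order(energies)
  profiles <- lapply(pool, function(X)
    .feature_profile(perceive_features(mol, xyz = X,
                                       projection_distance = params$projection_distance)))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) >= params$n_conformers_select) break
    dup <- any(vapply(kept, function(j)
      .profile_tanimoto(profiles[[i]], profiles[[j]]) >= params$tanimoto_threshold,
      logical(1)))
    if (!dup) kept <- c(kept, i)
  }
  # fill up with the next-best by energy if diversity pruning was too strict
  for (i in ord) {
    if (length(kept) >= params$n_conformers_select) break
    if (!(i %in% kept)) kept <- c(kept, i)
  }
  # the input geometry always participates
  if (!(1L %in% kept)) kept <- c(1L, kept[-length(kept)])
  mol$conformers <- pool[sort(kept)]
  mol
}

# ---- DISCO-style common-feature search ---------------------------------

.feat_xyz <- function(f) as.matrix(f[, c("x", "y", "z")])

# maximal consistent correspondences between a reference feature set and a
# molecule conformer feature set; returns list of integer vectors of
# reference feature indices (sorted)
.consistent_subsets <- function(ref, fm, tol2, node_cap) {
  nodes <- list()
  for (i in seq_len(nrow(ref))) {
    js <- which(fm$kind == ref$kind[i])
    for (j in js) nodes[[length(nodes) + 1L]] <- c(i, j)
  }
  if (length(nodes) == 0L) return(list())
  if (length(nodes) > node_cap)
    stop("pharmacophore search too large: correspondence graph exceeds node cap",
         call. = FALSE)
  Dr <- as.matrix(stats::dist(.feat_xyz(ref)))
  Dm <- as.matrix(stats::dist(.feat_xyz(fm)))
  nn <- length(nodes)
  if (nn == 1L) return(list(nodes[[1L]][1L]))
  ni <- vapply(nodes, `[`, integer(1), 1L)
  np <- vapply(nodes, `[`, integer(1), 2L)
  adj <- abs(Dr[ni, ni] - Dm[np, np]) <= tol2 &
    outer(ni, ni, `!=`) & outer(np, np, `!=`)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g, min = 1L)
  out <- lapply(cl, function(v) sort(vapply(nodes[as.integer(v)], `[`, integer(1), 1L)))
  unique(out)
}

#' Common-feature pharmacophore search
#'
#' Distance-comparison search over a set of active molecules: for the
#' reference molecule's features, a correspondence graph against every
#' other molecule (over its conformers) pairs same-kind features whose
#' pairwise distances agree within twice the tolerance; maximal cliques
#' give each molecule's consistent feature subsets, and the models are the
#' maximal reference-feature subsets supported by every molecule.  Models
#' are sized between `min_features` and `max_features`, deduplicated, and
#' ranked by score (see [model_metrics()]).
#'
#' @param mols a [molecule_set()] of prepared molecules (run
#'   [generate_conformers()] first for flexible molecules)
#' @param reference_id id of the reference (most active) compound
#' @param params a [pharm_params()]
#' @param features optional named list of precomputed feature data frames
#'   (one per molecule, or a list of per-conformer data frames per
#'   molecule); when NULL, features are perceived from each conformer
#' @return list of `pharm_model` objects, ranked by decreasing score
#' @export
disco_search <- function(mols, reference_id, params = pharm_params(),
                         features = NULL) {
  if (!reference_id %in% names(mols))
    stop(sprintf("reference '%s' not in molecule set", reference_id), call. = FALSE)
  featsets <- .all_feature_sets(mols, params, features)
  others <- setdiff(names(mols), reference_id)
  tol2 <- 2 * params$tolerance
  models <- list()
  for (ref in featsets[[reference_id]]) {
    if (nrow(ref) < params$min_features) next
    cands <- NULL
    dead <- FALSE
    for (m in others) {
      sets_m <- list()
      for (fm in featsets[[m]])
        sets_m <- c(sets_m, .consistent_subsets(ref, fm, tol2, params$node_cap))
      sets_m <- unique(sets_m)
      sets_m <- sets_m[lengths(sets_m) > 0L]
      if (length(sets_m) == 0L) { dead <- TRUE; break }
      if (is.null(cands)) cands <- sets_m
      else {
        new <- list()
        for (a in cands) for (b in sets_m) {
          iv <- intersect(a, b)
          if (length(iv) > 0L) new[[length(new) + 1L]] <- sort(iv)
        }
        cands <- unique(new)
        # cap the frontier deterministically: largest first
        if (length(cands) > 5000L)
          cands <- cands[order(-lengths(cands))][1:5000]
      }
      if (length(cands) == 0L) { dead <- TRUE; break }
    }
    if (dead || is.null(cands)) next
    cands <- cands[lengths(cands) >= params$min_features &
                     lengths(cands) <= params$max_features]
    if (length(cands) == 0L) next
    # maximal sets only
    keep <- rep(TRUE, length(cands))
    for (a in seq_along(cands)) for (b in seq_along(cands)) {
      if (a != b && keep[a] && all(cands[[a]] %in% cands[[b]]) &&
          length(cands[[a]]) < length(cands[[b]])) keep[a] <- FALSE
    }
    cands <- unique(cands[keep])
    for (S in cands) {
      feats <- ref[S, , drop = FALSE]
      mm <- .build_model(feats, mols, featsets, params)
      models[[length(models) + 1L]] <- mm
    }
  }
  if (length(models) == 0L) return(list())
  # deduplicate: same kind multiset and matching distance profile
  sig <- vapply(models, function(m)
    paste(paste(sort(m$features$kind), collapse = ","),
          paste(round(.feature_profile(m$features) / params$tolerance),
                collapse = ","), sep = "|"),
    character(1))
  models <- models[!duplicated(sig)]
  models[order(-vapply(models, function(m) m$score, numeric(1)))]
}

.all_feature_sets <- function(mols, params, features = NULL) {
  out <- vector("list", length(mols)); names(out) <- names(mols)
  for (id in names(mols)) {
    if (!is.null(features) && !is.null(features[[id]])) {
      f <- features[[id]]
      out[[id]] <- if (is.data.frame(f)) list(f) else f
    } else {
      cfs <- if (length(mols[[id]]$conformers) > 0L) mols[[id]]$conformers
             else list(coords(mols[[id]]))
      out[[id]] <- lapply(cfs, function(X)
        perceive_features(mols[[id]], xyz = X,
                          projection_distance = params$projection_distance))
    }
  }
  out
}

.build_model <- function(feats, mols, featsets, params) {
  D <- as.matrix(stats::dist(.feat_xyz(feats)))
  rownames(D) <- colnames(D) <- paste0(feats$kind, seq_len(nrow(feats)))
  model <- structure(list(features = feats, size = nrow(feats),
                          distance_table = D,
                          dmean = mean(D[upper.tri(D)]),
                          tolerance = params$tolerance,
                          hits = NA_integer_, score = NA_real_),
                     class = "pharm_model")
  mt <- .score_model(model, featsets, params)
  model$hits <- mt$hits; model$score <- mt$score
  model$mean_deviation <- mt$mean_deviation
  model
}

# best injective same-kind assignment of model features onto a feature set,
# under the pairwise tolerance; returns mean |distance discrepancy| or NULL
.best_assignment <- function(model, fm, tol2) {
  k <- model$size
  Dm <- as.matrix(stats::dist(.feat_xyz(fm)))
  Dr <- model$distance_table
  cand <- lapply(seq_len(k), function(i) which(fm$kind == model$features$kind[i]))
  if (any(lengths(cand) == 0L)) return(NULL)
  best <- NULL
  assign_rec <- function(level, used, devsum, npairs) {
    if (level > k) {
      md <- if (npairs > 0) devsum / npairs else 0
      if (is.null(best) || md < best) best <<- md
      return()
    }
    for (j in cand[[level]]) {
      if (j %in% used) next
      ok <- TRUE; ds <- 0
      if (level > 1L) for (p in seq_len(level - 1L)) {
        dd <- abs(Dr[p, level] - Dm[used[p], j])
        if (dd > tol2) { ok <- FALSE; break }
        ds <- ds + dd
      }
      if (ok) assign_rec(level + 1L, c(used, j), devsum + ds,
                         npairs + level - 1L)
    }
  }
  assign_rec(1L, integer(0), 0, 0L)
  best
}

#' Score a pharmacophore model against a molecule set
#'
#' `hits` counts molecules with at least one conformer whose features can
#' be injectively assigned to every model feature with all pairwise
#' distances agreeing within twice the tolerance.  `mean_deviation`
#' averages the absolute distance discrepancies of the best assignment
#' over all hit molecules and feature pairs, and
#' `score = size * (1 - mean_deviation / tolerance)` -- an explicit,
#' documented stand-in for the unpublished score of the original
#' distance-comparison program: it grows with model size and shrinks as
#' the common geometry degrades.
#'
#' @param model a `pharm_model`
#' @param mols molecule set (with conformers) to score against
#' @param params a [pharm_params()]
#' @param features optional precomputed features, as in [disco_search()]
#' @return list with `score`, `hits`, `dmean`, `mean_deviation`
#' @export
model_metrics <- function(model, mols, params = pharm_params(),
                          features = NULL) {
  stopifnot(inherits(model, "pharm_model"))
  if (model$size == 0L) stop("empty model", call. = FALSE)
  featsets <- .all_feature_sets(mols, params, features)
  mt <- .score_model(model, featsets, params)
  list(score = mt$score, hits = mt$hits, dmean = model$dmean,
       mean_deviation = mt$mean_deviation)
}

.score_model <- function(model, featsets, params) {
  tol2 <- 2 * params$tolerance
  devs <- numeric(0); hits <- 0L
  for (id in names(featsets)) {
    best <- NULL
    for (fm in featsets[[id]]) {
      b <- .best_assignment(model, fm, tol2)
      if (!is.null(b) && (is.null(best) || b < best)) best <- b
    }
    if (!is.null(best)) { hits <- hits + 1L; devs <- c(devs, best) }
  }
  md <- if (length(devs)) mean(devs) else NA_real_
  score <- if (is.na(md)) 0 else model$size * (1 - md / params$tolerance)
  list(hits = hits, score = score, mean_deviation = md)
}

#' Inter-feature distance table of a model
#'
#' @param model a `pharm_model`
#' @return symmetric matrix of Euclidean distances, labeled by feature
#'   kind and index
#' @export
distance_table <- function(model) {
  stopifnot(inherits(model, "pharm_model"))
  if (model$size == 0L) stop("empty model", call. = FALSE)
  model$distance_table
}

#' @export
print.pharm_model <- function(x, ...) {
  cat(sprintf("<pharm_model: SIZE %d [%s], HITS %d, SCORE %.4f, TOLERANCE %.2f, DMEAN %.4f>\n",
              x$size, paste(x$features$kind, collapse = " "), x$hits,
              x$score, x$tolerance, x$dmean))
  invisible(x)
}

#' Format pharmacophore models as a plain-text summary table
#'
#' @param models list of `pharm_model` objects
#' @return character vector of table lines (MODEL, SIZE, HITS, SCORE,
#'   TOLERANCE, DMEAN)
#' @export
pharm_table <- function(models) {
  if (length(models) == 0L) return("no pharmacophore models")
  hdr <- sprintf("%-10s %5s %5s %8s %10s %8s",
                 "MODEL", "SIZE", "HITS", "SCORE", "TOLERANCE", "DMEAN")
  rows <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    sprintf("MODEL_%03d  %5d %5d %8.4f %10.2f %8.4f", i, m$size, m$hits,
            m$score, m$tolerance, m$dmean)
  }, character(1))
  c(hdr, rows)
}
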
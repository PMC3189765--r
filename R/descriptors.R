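#' Assemble the descriptor matrix from field blocks and extra descriptors
#'
#' One row per compound; one column per (field, lattice point) plus one
#' column per extra descriptor (e.g. ClogP), appended last.  CoMFA
#' electrostatic values at steric-clash points are mean-filled per column
#' from the training rows before anything else.  Lattice columns whose
#' standard deviation over the training rows falls below `sigma_min`
#' (the "minimum sigma" column filter, in field units) are masked out;
#' extra-descriptor columns are never masked.
#'
#' @param fields a `field_block_set` from [compute_fields()]
#' @param extras data frame of extra descriptors (rownames or `compound_id`
#'   column matching the field set ids), or NULL
#' @param sigma_min column filtering threshold (kcal/mol for CoMFA blocks)
#' @param train_ids compounds whose rows define column means and standard
#'   deviations (defaults to all); keeps test-set information out of
#'   filtering and fill-in
#' @return object of class `descriptor_matrix`
#' @export
assemble_descriptors <- function(fields, extras = NULL, sigma_min = 1.0,
                                 train_ids = NULL) {
  stopifnot(inherits(fields, "field_block_set"))
  ids <- fields$ids
  if (is.null(train_ids)) train_ids <- ids
  if (!all(train_ids %in% ids)) stop("train_ids not all present", call. = FALSE)
  tr <- ids %in% train_ids
  blocks <- fields$values
  Xs <- list(); col_field <- character(0); col_cell <- integer(0)
  for (nm in names(blocks)) {
    M <- blocks[[nm]]
    if (anyNA(M)) {           # mean-fill clash columns from training rows
      for (j in which(colSums(is.na(M)) > 0L)) {
        mu <- mean(M[tr, j], na.rm = TRUE)
        if (is.nan(mu)) mu <- 0
        M[is.na(M[, j]), j] <- mu
      }
    }
    Xs[[nm]] <- M
    col_field <- c(col_field, rep(nm, ncol(M)))
    col_cell <- c(col_cell, seq_len(ncol(M)))
  }
  X <- do.call(cbind, Xs)
  if (!is.null(extras)) {
    extras <- as.data.frame(extras)
    if ("compound_id" %in% names(extras)) {
      rownames(extras) <- extras$compound_id
      extras$compound_id <- NULL
    }
    miss <- setdiff(ids, rownames(extras))
    if (length(miss)) stop(sprintf("missing extra descriptor value(s) for: %s",
                                   paste(miss, collapse = ", ")), call. = FALSE)
    E <- as.matrix(extras[ids, , drop = FALSE])
    if (anyNA(E)) stop("missing extra descriptor value", call. = FALSE)
    X <- cbind(X, E)
    col_field <- c(col_field, rep("extra", ncol(E)))
    col_cell <- c(col_cell, rep(NA_integer_, ncol(E)))
    colnames(X) <- c(paste0(col_field[col_field != "extra"], ".",
                            col_cell[col_field != "extra"]), colnames(E))
  } else {
    colnames(X) <- paste0(col_field, ".", col_cell)
  }
  rownames(X) <- ids
  sds <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  retained <- (sds >= sigma_min) | (col_field == "extra")
  structure(list(X = X, col_field = col_field, col_cell = col_cell,
                 retained = retained, sigma_min = sigma_min,
                 lattice = fields$lattice, ids = ids,
                 col_scale = rep(1, ncol(X)), scheme = "none"),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix: %d compounds x %d columns (%d retained), blocks: %s>\n",
              nrow(x$X), ncol(x$X), sum(x$retained),
              paste(unique(x$col_field), collapse = ", ")))
  invisible(x)
}

#' Block scaling of a descriptor matrix
#'
#' `comfa_std`: each field block's retained columns are divided by the
#' block's pooled standard deviation (square root of the mean per-column
#' variance), so every block contributes total variance equal to its column
#' count and no single field dominates the regression; extra-descriptor
#' columns are scaled to unit variance individually.  `none` leaves the
#' matrix untouched.
#'
#' @param dm a [assemble_descriptors()] result
#' @param scheme `"comfa_std"` or `"none"`
#' @param train_ids rows used to estimate the scaling (defaults to all)
#' @return the descriptor matrix with `X` scaled and `col_scale` recorded
#' @export
block_scale <- function(dm, scheme = c("comfa_std", "none"), train_ids = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dm, "descriptor_matrix"))
  if (scheme == "none") { dm$scheme <- "none"; return(dm) }
  ids <- rownames(dm$X)
  if (is.null(train_ids)) train_ids <- ids
  tr <- ids %in% train_ids
  scale_vec <- rep(1, ncol(dm$X))
  for (blk in unique(dm$col_field)) {
    jj <- which(dm$col_field == blk & dm$retained)
    if (length(jj) == 0L) next
    if (blk == "extra") {
      s <- apply(dm$X[tr, jj, drop = FALSE], 2, stats::sd)
      if (any(s == 0)) stop("zero-variance extra descriptor cannot be scaled",
                            call. = FALSE)
      scale_vec[jj] <- s
    } else {
      v <- apply(dm$X[tr, jj, drop = FALSE], 2, stats::var)
      pooled <- sqrt(mean(v))
      if (pooled == 0) stop(sprintf("zero-variance block '%s'", blk), call. = FALSE)
      scale_vec[jj] <- pooled
    }
  }
  dm$X <- sweep(dm$X, 2, scale_vec, `/`)
  dm$col_scale <- dm$col_scale * scale_vec
  dm$scheme <- scheme
  dm
}

#' Stratified train/test split over activity quantile bins
#'
#' Compounds are ordered by activity and cut into `n_test` contiguous bins
#' of near-equal size; one test compound is drawn uniformly from each bin,
#' so the test set spans the activity range.  Deterministic for a given
#' seed.
#'
#' @param activities data frame with `compound_id` and `pic50` (one row per
#'   compound)
#' @param n_test number of test compounds
#' @param seed integer RNG seed
#' @return data frame `compound_id`, `set_label`
#' @export
split_train_test <- function(activities, n_test, seed = 1L) {
  if (n_test <= 0L) stop("n_test must be positive", call. = FALSE)
  n <- nrow(activities)
  if (n_test >= n) stop("n_test must be smaller than the number of compounds",
                        call. = FALSE)
  ord <- order(activities$pic50, activities$compound_id)
  bins <- split(ord, cut(seq_len(n), breaks = n_test, labels = FALSE))
  test_idx <- .with_seed(seed, function()
    vapply(bins, function(b) b[sample.int(length(b), 1L)], integer(1)))
  lab <- rep("train", n)
  lab[test_idx] <- "test"
  data.frame(compound_id = activities$compound_id, set_label = lab)
}

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fun()
}

#' Squared Pearson correlation between two activity endpoints
#'
#' @param pic50_a,pic50_b paired activity vectors
#' @return squared Pearson correlation coefficient
#' @export
endpoint_correlation <- function(pic50_a, pic50_b) {
  stopifnot(length(pic50_a) == length(pic50_b))
  if (length(pic50_a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(pic50_a) == 0 || stats::sd(pic50_b) == 0)
    stop("constant activity vector", call. = FALSE)
  stats::cor(pic50_a, pic50_b)^2
}
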
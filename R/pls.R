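#' NIPALS partial least squares regression
#'
#' Univariate-response PLS1 by the nonlinear iterative partial least
#' squares algorithm.  `X` and `y` are mean-centered internally (no
#' scaling; apply [block_scale()] beforehand if wanted).  For a single
#' response the weight of each component has the closed form
#' `w = X't / ||X't||` and the score vectors come out mutually orthogonal.
#' Regression coefficients are back-transformed to the original column
#' space for every component count up to `ncomp`.
#'
#' @param X predictor matrix (n x p)
#' @param y response vector (length n)
#' @param ncomp number of latent components (>= 1, < n)
#' @return object of class `pls_model` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, per-component coefficient matrix `B`
#'   (p x ncomp) and intercepts
#' @export
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  if (ncomp >= n) stop("ncomp must be smaller than the number of rows",
                       call. = FALSE)
  if (stats::sd(y) == 0) stop("response is constant", call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { ncomp <- a - 1L; break }   # X deflated to noise floor
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
  }
  if (ncomp == 0L) stop("no usable PLS component could be extracted", call. = FALSE)
  W <- W[, seq_len(ncomp), drop = FALSE]; P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]; q <- q[seq_len(ncomp)]
  # coefficients for each component count c: B_c = W_c (P_c' W_c)^-1 q_c
  B <- matrix(0, p, ncomp)
  for (cc in seq_len(ncomp)) {
    Wc <- W[, 1:cc, drop = FALSE]; Pc <- P[, 1:cc, drop = FALSE]
    B[, cc] <- Wc %*% solve(crossprod(Pc, Wc), q[1:cc])
  }
  intercepts <- ym - as.numeric(crossprod(B, xm))
  structure(list(ncomp = ncomp, x_means = xm, y_mean = ym,
                 W = W, P = P, q = q, scores = Tm,
                 B = B, intercepts = intercepts,
                 colnames = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), %d columns>\n",
              x$ncomp, nrow(x$B)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a [nipals_pls()] model
#' @param newdata matrix with the same columns the model was fitted on
#' @param ncomp component count to use (default: all fitted)
#' @param ... unused
#' @return numeric vector of predictions
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 1L, ncomp <= object$ncomp)
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$B[, ncomp] + object$intercepts[ncomp])
}

#' Cross-validated Q-squared
#'
#' `1 - sum((pred - obs)^2) / sum((obs - mean)^2)`; the reference mean is
#' the observed (training) mean unless given explicitly.
#'
#' @param y_obs observed values
#' @param y_pred predicted values
#' @param y_mean reference mean (default `mean(y_obs)`)
#' @return Q^2
#' @export
q2_statistic <- function(y_obs, y_pred, y_mean = mean(y_obs)) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  ss <- sum((y_obs - y_mean)^2)
  if (ss == 0) stop("observed values are constant", call. = FALSE)
  1 - sum((y_pred - y_obs)^2) / ss
}

#' External predictive r-squared
#'
#' `1 - PRESS/SD`, where PRESS sums squared test-set residuals and SD sums
#' squared deviations of the test-set observations from the training-set
#' mean activity.
#'
#' @param y_test_obs observed test-set activities
#' @param y_test_pred predicted test-set activities
#' @param y_train_mean mean activity of the training set
#' @return r^2_pred
#' @export
r2_pred <- function(y_test_obs, y_test_pred, y_train_mean) {
  stopifnot(length(y_test_obs) == length(y_test_pred))
  if (length(y_test_obs) < 2L) stop("need at least 2 test compounds", call. = FALSE)
  sd_ <- sum((y_test_obs - y_train_mean)^2)
  if (sd_ == 0) stop("test activities coincide with the training mean", call. = FALSE)
  1 - sum((y_test_pred - y_test_obs)^2) / sd_
}

# ---- QSAR-level fitting on a descriptor matrix --------------------------

# re-filter and re-scale a raw descriptor matrix on a row subset, returning
# the processed predictor matrix and the per-column scale/mask bookkeeping
.prep_descriptor <- function(dm, rows, scheme) {
  ids <- rownames(dm$X)[rows]
  sds <- apply(dm$X[rows, , drop = FALSE], 2, stats::sd)
  retained <- (sds >= dm$sigma_min) | (dm$col_field == "extra")
  scale_vec <- rep(1, ncol(dm$X))
  if (scheme == "comfa_std") {
    for (blk in unique(dm$col_field)) {
      jj <- which(dm$col_field == blk & retained)
      if (length(jj) == 0L) next
      if (blk == "extra") {
        s <- sds[jj]
        s[s == 0] <- 1          # constant extra stays, unscaled
        scale_vec[jj] <- s
      } else {
        pooled <- sqrt(mean(sds[jj]^2))
        scale_vec[jj] <- pooled
      }
    }
  }
  list(retained = retained, scale = scale_vec,
       Xp = sweep(dm$X[, retained, drop = FALSE], 2,
                  scale_vec[retained], `/`))
}

#' Fit a field-based QSAR model
#'
#' Filters and block-scales the descriptor matrix on the training rows,
#' fits NIPALS PLS with `ncomp` components, and back-transforms the
#' coefficients to raw descriptor units (masked columns get coefficient
#' zero).
#'
#' @param dm a raw (unscaled) [assemble_descriptors()] matrix
#' @param y named response vector (names = compound ids) or vector aligned
#'   with the training ids
#' @param ncomp number of PLS components
#' @param train_ids compounds to fit on (default: all rows of `dm`)
#' @param scheme scaling scheme, see [block_scale()]
#' @return object of class `qsar_model`
#' @export
fit_qsar <- function(dm, y, ncomp, train_ids = NULL,
                     scheme = c("comfa_std", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dm, "descriptor_matrix"))
  ids <- rownames(dm$X)
  if (is.null(train_ids)) train_ids <- ids
  rows <- which(ids %in% train_ids)
  if (!is.null(names(y))) y <- y[ids[rows]]
  stopifnot(length(y) == length(rows), !anyNA(y))
  prep <- .prep_descriptor(dm, rows, scheme)
  pls <- nipals_pls(prep$Xp[rows, , drop = FALSE], y, ncomp)
  coef_raw <- numeric(ncol(dm$X))
  coef_raw[prep$retained] <- pls$B[, pls$ncomp] / prep$scale[prep$retained]
  intercept <- pls$intercepts[pls$ncomp]
  fitted <- as.numeric(dm$X[rows, , drop = FALSE] %*% coef_raw + intercept)
  structure(list(pls = pls, ncomp = pls$ncomp, scheme = scheme,
                 retained = prep$retained, col_scale = prep$scale,
                 col_field = dm$col_field, col_cell = dm$col_cell,
                 lattice = dm$lattice,
                 coefficients = coef_raw, intercept = intercept,
                 train_ids = ids[rows], y = y, fitted = fitted,
                 train_sds = apply(dm$X[rows, , drop = FALSE], 2, stats::sd)),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<qsar_model: %d components, n = %d, R2_ncv = %.3f, SEE = %.3f>\n",
              x$ncomp, length(x$y), s$r2_ncv, s$see))
  invisible(x)
}

#' Predict activities for new compounds
#'
#' @param object a [fit_qsar()] model
#' @param dm the descriptor matrix the model was assembled from (raw scale)
#' @param ids compounds to predict (default: all rows)
#' @param ... unused
#' @return named numeric vector
#' @export
predict.qsar_model <- function(object, dm, ids = NULL, ...) {
  X <- if (inherits(dm, "descriptor_matrix")) dm$X else as.matrix(dm)
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  out <- as.numeric(X %*% object$coefficients + object$intercept)
  names(out) <- rownames(X)
  out
}

#' Leave-one-out cross-validation
#'
#' For every component count `c <= c_max` and every training row, the model
#' is refitted on the remaining rows -- column filtering and block scaling
#' are recomputed inside each fold so no information from the held-out
#' compound leaks into the fold model -- and the held-out activity is
#' predicted.  Reports `q2(c)` (cross-validated Q^2 about the full training
#' mean), `sep(c) = sqrt(PRESS / (n - c - 1))`, and the optimal component
#' count `opn = argmax q2` (ties to the smaller count).
#'
#' @param dm descriptor matrix (raw), or a plain numeric matrix (treated as
#'   one unfiltered block)
#' @param y response vector
#' @param c_max largest component count to evaluate (`< n - 1`)
#' @param train_ids rows to use (default all)
#' @param scheme scaling scheme recomputed per fold
#' @return list with `q2` (by component), `sep`, `press`, `opn`,
#'   `predictions` (n x c_max matrix of LOO predictions)
#' @export
loo_validate <- function(dm, y, c_max, train_ids = NULL,
                         scheme = c("comfa_std", "none")) {
  scheme <- match.arg(scheme)
  if (!inherits(dm, "descriptor_matrix")) dm <- .as_plain_dm(dm)
  ids <- rownames(dm$X)
  if (is.null(train_ids)) train_ids <- ids
  rows <- which(ids %in% train_ids)
  n <- length(rows)
  if (n < 4L) stop("need at least 4 training rows", call. = FALSE)
  if (c_max >= n - 1L) stop("c_max must be < n - 1", call. = FALSE)
  if (!is.null(names(y))) y <- y[ids[rows]]
  stopifnot(length(y) == n)
  pred <- matrix(NA_real_, n, c_max)
  for (k in seq_len(n)) {
    keep <- rows[-k]
    prep <- .prep_descriptor(dm, keep, scheme)
    pls <- nipals_pls(prep$Xp[keep, , drop = FALSE], y[-k], c_max)
    xnew <- prep$Xp[rows[k], , drop = FALSE]
    for (cc in seq_len(c_max)) {
      cc_eff <- min(cc, pls$ncomp)
      pred[k, cc] <- as.numeric(xnew %*% pls$B[, cc_eff] + pls$intercepts[cc_eff])
    }
  }
  press <- colSums((pred - y)^2)
  ss <- sum((y - mean(y))^2)
  q2 <- 1 - press / ss
  sep <- sqrt(press / (n - seq_len(c_max) - 1L))
  opn <- which.max(q2)          # which.max takes the first (smallest) on ties
  list(q2 = q2, sep = sep, press = press, opn = opn, predictions = pred,
       y = y)
}

.as_plain_dm <- function(X) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("row%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  structure(list(X = X, col_field = rep("x", ncol(X)),
                 col_cell = seq_len(ncol(X)),
                 retained = rep(TRUE, ncol(X)), sigma_min = 0,
                 lattice = NULL, ids = rownames(X),
                 col_scale = rep(1, ncol(X)), scheme = "none"),
            class = "descriptor_matrix")
}

#' Fit statistics of a QSAR model
#'
#' `r2_ncv = 1 - RSS/TSS` on the training fit, `see = sqrt(RSS/(n-c-1))`,
#' and the F statistic in the form `F = [R2/(1-R2)] * [(n-c-1)/c]` (the
#' ratio of explained to unexplained variance on a per-degree-of-freedom
#' basis).  A perfect fit reports `f_stat = Inf`.
#'
#' @param model a [fit_qsar()] model, or NULL when `r2`, `n`, `c` are given
#'   directly
#' @param r2,n,c optional explicit values; when `model` is NULL the F
#'   statistic is computed from these printed/rounded inputs
#' @return list with `r2_ncv`, `see`, `f_stat`, `n`, `ncomp`
#' @export
model_summary <- function(model = NULL, r2 = NULL, n = NULL, c = NULL) {
  if (is.null(model)) {
    stopifnot(!is.null(r2), !is.null(n), !is.null(c))
    if (n <= c + 1L) stop("n must exceed c + 1", call. = FALSE)
    f <- if (r2 >= 1) Inf else (r2 / (1 - r2)) * ((n - c - 1) / c)
    return(list(r2_ncv = r2, see = NA_real_, f_stat = f, n = n, ncomp = c))
  }
  stopifnot(inherits(model, "qsar_model"))
  y <- model$y; n <- length(y); cc <- model$ncomp
  if (n <= cc + 1L) stop("n must exceed ncomp + 1", call. = FALSE)
  rss <- sum((model$fitted - y)^2)
  tss <- sum((y - mean(y))^2)
  r2_ncv <- 1 - rss / tss
  see <- sqrt(rss / (n - cc - 1))
  f <- if (rss == 0) Inf else (r2_ncv / (1 - r2_ncv)) * ((n - cc - 1) / cc)
  list(r2_ncv = r2_ncv, see = see, f_stat = f, n = n, ncomp = cc)
}

#' Per-field contribution fractions
#'
#' The share of each descriptor block in the model:
#' `fraction(block) = sum_{j in block} |coef_j| sd_j / sum_all |coef_j| sd_j`
#' over retained columns, with coefficient and standard deviation taken on
#' the scaled training data (the product is identical on raw or scaled
#' units).  Extra descriptors are reported as their own named blocks.
#'
#' @param model a [fit_qsar()] model
#' @return named numeric vector summing to 1
#' @export
field_fractions <- function(model) {
  stopifnot(inherits(model, "qsar_model"))
  contrib <- abs(model$coefficients) * model$train_sds
  blk <- model$col_field
  if (any(blk == "extra")) {
    nm <- model$pls$colnames
    full_nm <- rep(NA_character_, length(blk))
    full_nm[model$retained] <- nm
    blk[blk == "extra"] <- ifelse(is.na(full_nm[blk == "extra"]), "extra",
                                  full_nm[blk == "extra"])
  }
  tot <- tapply(contrib, blk, sum)
  out <- stats::setNames(as.numeric(tot) / sum(tot), names(tot))
  out[order(names(out))]
}
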
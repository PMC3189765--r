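#' stdev*coeff grid for one field
#'
#' The classical field contribution map: for every retained lattice column
#' of the chosen field, the product of the column standard deviation
#' (training rows) and the model coefficient; masked columns contribute
#' zero.  The result is arranged on the lattice.
#'
#' @param model a [fit_qsar()] model carrying lattice metadata
#' @param field field block name, e.g. `"comfa_steric"`
#' @return numeric vector of `prod(lattice$dims)` values (x index fastest),
#'   with attribute `lattice`
#' @export
stdev_coeff_grid <- function(model, field) {
  stopifnot(inherits(model, "qsar_model"))
  if (!field %in% model$col_field)
    stop(sprintf("unknown field '%s'", field), call. = FALSE)
  if (is.null(model$lattice))
    stop("model was not fitted on lattice descriptors", call. = FALSE)
  jj <- which(model$col_field == field)
  vals <- numeric(length(jj))
  sel <- model$retained[jj]
  vals[sel] <- (model$train_sds[jj] * model$coefficients[jj])[sel]
  grid <- numeric(prod(model$lattice$dims))
  grid[model$col_cell[jj]] <- vals
  attr(grid, "lattice") <- model$lattice
  grid
}

#' Favored/disfavored contour levels
#'
#' Interprets the conventional "80% / 20% contribution" display levels as
#' quantiles of the nonzero stdev*coeff distribution, with
#' linear-interpolation quantiles.
#'
#' @param grid stdev*coeff values (zeros from masked columns are excluded)
#' @param favored_pct quantile for the favored level (default 0.80)
#' @param disfavored_pct quantile for the disfavored level (default 0.20)
#' @return list with `favored_level` and `disfavored_level`
#' @export
contour_levels <- function(grid, favored_pct = 0.80, disfavored_pct = 0.20) {
  nz <- grid[grid != 0]
  if (length(nz) == 0L) stop("all-zero grid has no contour levels", call. = FALSE)
  if (max(nz) == min(nz)) stop("constant grid has no contour levels", call. = FALSE)
  qs <- stats::quantile(nz, c(favored_pct, disfavored_pct), names = FALSE,
                        type = 7)
  list(favored_level = qs[1], disfavored_level = qs[2])
}

#' Extract a contour set for one field
#'
#' @param model a [fit_qsar()] model
#' @param field field block name
#' @param favored_pct,disfavored_pct quantile levels, see [contour_levels()]
#' @return object of class `contour_set`: grid, levels, and the lattice
#'   indices of favored (value >= favored level) and disfavored
#'   (value <= disfavored level) points
#' @export
contour_set <- function(model, field, favored_pct = 0.80,
                        disfavored_pct = 0.20) {
  grid <- stdev_coeff_grid(model, field)
  lv <- contour_levels(grid, favored_pct, disfavored_pct)
  structure(list(field = field, grid = as.numeric(grid),
                 lattice = attr(grid, "lattice"),
                 favored_level = lv$favored_level,
                 disfavored_level = lv$disfavored_level,
                 favored_points = which(grid != 0 & grid >= lv$favored_level),
                 disfavored_points = which(grid != 0 & grid <= lv$disfavored_level)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set %s: %d favored >= %.4g, %d disfavored <= %.4g>\n",
              x$field, length(x$favored_points), x$favored_level,
              length(x$disfavored_points), x$disfavored_level))
  invisible(x)
}

#' Export a contour set or field grid as a volumetric file
#'
#' Writes the grid in Gaussian cube format (z index fastest, one voxel
#' value stream after a two-comment header; the contour levels are recorded
#' in the first comment) or OpenDX general array format.
#'
#' @param cs a `contour_set`, or a `field_grid` from [comfa_fields()]
#' @param path output file
#' @param format `"cube"` or `"dx"`
#' @return `path`, invisibly
#' @export
export_contours <- function(cs, path, format = c("cube", "dx")) {
  format <- match.arg(format)
  if (inherits(cs, "field_grid")) {
    grid <- cs$values; lattice <- cs$lattice
    header <- sprintf("qsar3d field %s molecule %s", cs$field, cs$molecule_id)
  } else {
    grid <- cs$grid; lattice <- cs$lattice
    header <- sprintf("qsar3d stdev*coeff %s favored %.6g disfavored %.6g",
                      cs$field, cs$favored_level, cs$disfavored_level)
  }
  if (format == "cube") .write_cube(grid, lattice, path, header)
  else .write_dx(grid, lattice, path, header)
  invisible(path)
}
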
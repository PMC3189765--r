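# Volumetric grid writers/readers.  Our in-memory grids are ordered with
# the x index fastest (R array convention); the cube format streams voxels
# with z fastest, so writing permutes the array and reading permutes back.
# Units: cube headers are conventionally Bohr when the atom count is
# positive; we write a negative atom count and Angstrom axes, the common
# convention for non-quantum volumetric data.

.BOHR <- 0.529177210903  # retained for readers that assume Bohr; see note

.write_cube <- function(grid, lattice, path, comment = "qsar3d grid") {
  d <- lattice$dims
  stopifnot(length(grid) == prod(d))
  arr <- array(grid, dim = d)
  lines <- c(comment, "qsar3d volumetric export (Angstrom axes)")
  lines <- c(lines, sprintf("%5d%12.6f%12.6f%12.6f", -1L,
                            lattice$origin[1], lattice$origin[2], lattice$origin[3]))
  lines <- c(lines,
             sprintf("%5d%12.6f%12.6f%12.6f", d[1], lattice$spacing, 0, 0),
             sprintf("%5d%12.6f%12.6f%12.6f", d[2], 0, lattice$spacing, 0),
             sprintf("%5d%12.6f%12.6f%12.6f", d[3], 0, 0, lattice$spacing))
  # one dummy atom record (atom count -1 above flags Angstrom/no atoms)
  lines <- c(lines, sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 1L, 0, 0, 0, 0))
  # cube streams voxels with outer x, then y, inner z
  stream <- numeric(length(grid))
  k <- 1L
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    stream[k:(k + d[3] - 1L)] <- arr[ix, iy, ]
    k <- k + d[3]
  }
  chunks <- split(stream, ceiling(seq_along(stream) / 6))
  lines <- c(lines, vapply(chunks, function(v)
    paste(sprintf("%13.6e", v), collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

.read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr3 <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  natoms <- as.integer(hdr3[1])
  origin <- as.numeric(hdr3[2:4])
  ax <- lapply(4:6, function(i) strsplit(trimws(lines[i]), "\\s+")[[1]])
  dims <- vapply(ax, function(v) as.integer(v[1]), integer(1))
  spacing <- as.numeric(ax[[1]][2])
  nskip <- 6L + abs(natoms)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(nskip + 1L):length(lines)]),
                                     "\\s+")))
  arr <- array(NA_real_, dim = dims)
  k <- 1L
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    arr[ix, iy, ] <- vals[k:(k + dims[3] - 1L)]
    k <- k + dims[3]
  }
  list(grid = as.numeric(arr),
       lattice = structure(list(origin = origin, spacing = spacing,
                                dims = dims), class = "lattice"))
}

.write_dx <- function(grid, lattice, path, comment = "qsar3d grid") {
  d <- lattice$dims
  stopifnot(length(grid) == prod(d))
  arr <- array(grid, dim = d)
  # OpenDX expects the z index fastest as well
  stream <- numeric(length(grid))
  k <- 1L
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    stream[k:(k + d[3] - 1L)] <- arr[ix, iy, ]
    k <- k + d[3]
  }
  lines <- c(sprintf("# %s", comment),
             sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]),
             sprintf("origin %.6f %.6f %.6f",
                     lattice$origin[1], lattice$origin[2], lattice$origin[3]),
             sprintf("delta %.6f 0.000000 0.000000", lattice$spacing),
             sprintf("delta 0.000000 %.6f 0.000000", lattice$spacing),
             sprintf("delta 0.000000 0.000000 %.6f", lattice$spacing),
             sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]),
             sprintf("object 3 class array type double rank 0 items %d data follows",
                     length(grid)))
  chunks <- split(stream, ceiling(seq_along(stream) / 3))
  lines <- c(lines, vapply(chunks, function(v)
    paste(sprintf("%.6e", v), collapse = " "), character(1)),
    'attribute "dep" string "positions"')
  writeLines(lines, path)
  invisible(path)
}

.read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(utils::tail(strsplit(trimws(cl), "\\s+")[[1]], 3))
  ol <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(ol), "\\s+")[[1]][2:4])
  dl <- grep("^delta", lines, value = TRUE)[1]
  spacing <- as.numeric(strsplit(trimws(dl), "\\s+")[[1]][2])
  start <- grep("data follows", lines) + 1L
  end <- grep("^attribute", lines)
  end <- if (length(end)) end[1] - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  arr <- array(NA_real_, dim = dims)
  k <- 1L
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    arr[ix, iy, ] <- vals[k:(k + dims[3] - 1L)]
    k <- k + dims[3]
  }
  list(grid = as.numeric(arr),
       lattice = structure(list(origin = origin, spacing = spacing,
                                dims = dims), class = "lattice"))
}

#' Read a volumetric grid file written by [export_contours()]
#'
#' @param path file to read
#' @param format `"cube"` or `"dx"`
#' @return list with `grid` (x index fastest) and `lattice`
#' @export
read_grid <- function(path, format = c("cube", "dx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "cube") .read_cube(path) else .read_dx(path)
}
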
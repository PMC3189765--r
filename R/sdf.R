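#' Read molecules from an SDF or MOL2 file
#'
#' The SDF reader handles V2000 connection tables: the title line supplies
#' the compound id, `M  CHG` lines set formal charges (the old atom-block
#' charge column is also honoured), and trailing `> <tag>` data fields are
#' copied into `properties`.  The MOL2 reader consumes the TRIPOS
#' `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` records only; SYBYL atom types are
#' reduced to their element.
#'
#' Formal charges matter downstream (hydrogen-bond acceptor rules, positive
#' nitrogen pharmacophore features), which is why the package carries its own
#' V2000 codec rather than delegating to a reader that drops `M  CHG`.
#'
#' @param path file to read
#' @param format `"sdf"` or `"mol2"`
#' @return a [molecule_set()]
#' @export
read_molecules <- function(path, format = c("sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0L || all(!nzchar(trimws(lines))))
    stop(sprintf("empty file: %s", path), call. = FALSE)
  if (format == "sdf") .read_sdf_lines(lines, path) else .read_mol2_lines(lines, path)
}

# V2000 charge column code -> formal charge (0 = none, 1 = +3 ... 7 = -3)
.V2000_CHG <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)

.read_sdf_lines <- function(lines, path) {
  # split into records on $$$$
  recs <- list(); cur <- character(0)
  for (ln in lines) {
    if (trimws(ln) == "$$$$") { recs[[length(recs) + 1L]] <- cur; cur <- character(0) }
    else cur <- c(cur, ln)
  }
  if (length(cur) > 0L && any(nzchar(trimws(cur)))) recs[[length(recs) + 1L]] <- cur
  if (length(recs) == 0L) stop(sprintf("no records in %s", path), call. = FALSE)
  mols <- vector("list", length(recs))
  for (ri in seq_along(recs)) {
    mols[[ri]] <- tryCatch(.parse_v2000(recs[[ri]], ri),
      error = function(e) stop(sprintf("record %d of %s: %s", ri, path,
                                       conditionMessage(e)), call. = FALSE))
  }
  molecule_set(mols)
}

.parse_v2000 <- function(rec, record_index) {
  if (length(rec) < 4L) stop("truncated record")
  id <- trimws(rec[1L])
  if (!nzchar(id)) id <- sprintf("mol_%03d", record_index)
  counts <- rec[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) stop("unparsable counts line")
  if (length(rec) < 4L + natoms + nbonds) stop("truncated atom/bond block")
  at <- rec[5:(4L + natoms)]
  x <- as.numeric(substr(at, 1, 10)); y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  element <- trimws(substr(at, 31, 34))
  chg_code <- trimws(substr(at, 35, 37)); chg_code[!nzchar(chg_code)] <- "0"
  fc <- .V2000_CHG[chg_code]; fc[is.na(fc)] <- 0L
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(element)))
    stop("unparsable atom block")
  bonds <- NULL
  if (nbonds > 0L) {
    bl <- rec[(5L + natoms):(4L + natoms + nbonds)]
    bonds <- data.frame(a1 = as.integer(substr(bl, 1, 3)),
                        a2 = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)))
    if (any(is.na(bonds))) stop("unparsable bond block")
  }
  rest <- if (length(rec) > 4L + natoms + nbonds)
    rec[(5L + natoms + nbonds):length(rec)] else character(0)
  # M CHG overrides the atom-block charge column
  for (ln in rest[startsWith(rest, "M  CHG")]) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nset <- toks[1L]
    for (k in seq_len(nset)) fc[toks[2L * k]] <- toks[2L * k + 1L]
  }
  # data fields: "> <tag>" followed by value lines until blank
  props <- list()
  i <- 1L
  while (i <= length(rest)) {
    ln <- rest[i]
    if (startsWith(ln, ">")) {
      tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", ln)
      vals <- character(0); i <- i + 1L
      while (i <= length(rest) && nzchar(trimws(rest[i]))) {
        vals <- c(vals, rest[i]); i <- i + 1L
      }
      props[[tag]] <- paste(vals, collapse = "\n")
    }
    i <- i + 1L
  }
  molecule(id, data.frame(element = element, x = x, y = y, z = z,
                          formal_charge = as.integer(fc)),
           bonds, properties = props)
}

.read_mol2_lines <- function(lines, path) {
  idx <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(idx) == 0L) stop(sprintf("no TRIPOS MOLECULE record in %s", path),
                              call. = FALSE)
  bounds <- c(idx, length(lines) + 1L)
  mols <- vector("list", length(idx))
  for (ri in seq_along(idx)) {
    rec <- lines[bounds[ri]:(bounds[ri + 1L] - 1L)]
    id <- trimws(rec[2L])
    if (!nzchar(id)) id <- sprintf("mol_%03d", ri)
    a0 <- grep("^@<TRIPOS>ATOM", rec)[1L]
    b0 <- grep("^@<TRIPOS>BOND", rec)[1L]
    if (is.na(a0)) stop(sprintf("record %d of %s: missing ATOM block", ri, path),
                        call. = FALSE)
    stop_at <- function(start) {
      nxt <- grep("^@<TRIPOS>", rec)
      nxt <- nxt[nxt > start]
      if (length(nxt)) nxt[1L] - 1L else length(rec)
    }
    at <- rec[(a0 + 1L):stop_at(a0)]
    at <- at[nzchar(trimws(at))]
    f <- strsplit(trimws(at), "\\s+")
    element <- vapply(f, function(v) sub("\\..*$", "", v[6L]), character(1))
    atoms <- data.frame(
      element = element,
      x = vapply(f, function(v) as.numeric(v[3L]), numeric(1)),
      y = vapply(f, function(v) as.numeric(v[4L]), numeric(1)),
      z = vapply(f, function(v) as.numeric(v[5L]), numeric(1)))
    bonds <- NULL
    if (!is.na(b0)) {
      bl <- rec[(b0 + 1L):stop_at(b0)]
      bl <- bl[nzchar(trimws(bl))]
      fb <- strsplit(trimws(bl), "\\s+")
      ord <- vapply(fb, function(v) v[4L], character(1))
      ord_num <- ifelse(ord == "ar", 4L, ifelse(ord == "am", 1L,
                        suppressWarnings(as.integer(ord))))
      ord_num[is.na(ord_num)] <- 1L
      bonds <- data.frame(a1 = vapply(fb, function(v) as.integer(v[2L]), integer(1)),
                          a2 = vapply(fb, function(v) as.integer(v[3L]), integer(1)),
                          order = ord_num)
    }
    mols[[ri]] <- molecule(id, atoms, bonds)
  }
  molecule_set(mols)
}

#' Write molecules to an SDF V2000 file
#'
#' Coordinates are written at `%10.4f` precision; formal charges are emitted
#' as `M  CHG` lines; entries of `properties` become SDF data fields.
#' Output is byte-deterministic for a given molecule set.
#'
#' @param mols a [molecule_set()] or single [molecule()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_molecules <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- molecule_set(list(mols))
  out <- character(0)
  for (m in mols) {
    n <- nrow(m$atoms); nb <- nrow(m$bonds)
    lines <- c(m$id, "  qsar3d", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              m$atoms$x, m$atoms$y, m$atoms$z, m$atoms$element))
    if (nb > 0L)
      lines <- c(lines, sprintf("%3d%3d%3d  0", m$bonds$a1, m$bonds$a2, m$bonds$order))
    chg <- which(m$atoms$formal_charge != 0L)
    if (length(chg) > 0L) for (start in seq(1L, length(chg), by = 8L)) {
      grp <- chg[start:min(start + 7L, length(chg))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp,
                                             m$atoms$formal_charge[grp]), collapse = "")))
    }
    lines <- c(lines, "M  END")
    for (tag in names(m$properties)) {
      val <- m$properties[[tag]]
      lines <- c(lines, sprintf(">  <%s>", tag),
                 if (is.numeric(val)) sprintf("%.6g", val) else as.character(val), "")
    }
    out <- c(out, lines, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an activity table
#'
#' Expects a comma-separated UTF-8 file with header columns `compound_id`,
#' `endpoint` (\code{I} or \code{II}), `pic50`, `set_label` (\code{train} or
#' \code{test}).
#'
#' @param path CSV file
#' @return data frame of validated activity records
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "endpoint", "pic50", "set_label")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("activity table lacks column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!is.numeric(df$pic50)) {
    suppressWarnings(p <- as.numeric(df$pic50))
    if (any(is.na(p) & !is.na(df$pic50)))
      stop("non-numeric pic50 value(s) in activity table", call. = FALSE)
    df$pic50 <- p
  }
  if (any(!is.finite(df$pic50))) stop("pic50 values must be finite", call. = FALSE)
  bad_ep <- setdiff(unique(df$endpoint), c("I", "II"))
  if (length(bad_ep)) stop(sprintf("invalid endpoint value(s): %s",
                                   paste(bad_ep, collapse = ", ")), call. = FALSE)
  bad_sl <- setdiff(unique(df$set_label), c("train", "test"))
  if (length(bad_sl)) stop(sprintf("invalid set_label value(s): %s",
                                   paste(bad_sl, collapse = ", ")), call. = FALSE)
  key <- paste(df$compound_id, df$endpoint)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (compound_id, endpoint) pair(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")), call. = FALSE)
  df[, req]
}

#' Convert a molar IC50 to pIC50
#'
#' @param ic50 molar concentration(s), strictly positive
#' @return `-log10(ic50)`
#' @export
pic50_from_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be finite and > 0", call. = FALSE)
  -log10(ic50)
}
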
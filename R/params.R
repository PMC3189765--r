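#' @title Built-in atomic parameter tables
#' @description
#' All per-element parameters used by the field and charge machinery live in
#' one place.  Elements outside the table are a hard error everywhere in the
#' package: silent defaults would corrupt field values without warning.
#'
#' * `vdw_radius` (Angstrom) and `lj_epsilon` (kcal/mol) parameterize the
#'   Lennard-Jones steric probe interaction (values of the common
#'   general-purpose force-field type, fixed here so results are reproducible
#'   from the input file alone).
#' * `logp` is an atomic octanol/water partition contribution (unitless) of
#'   the classical atomic-additive type; hydrogens contribute through
#'   `logp_h` of the heavy atom they are bonded to.  The same contributions,
#'   summed united-atom style, provide the CoMSIA hydrophobicity property.
#' @keywords internal
#' @name qsar3d-params
NULL

# supported elements; anything else raises an error in .elem_check()
.ELEMENTS <- c("H", "C", "N", "O", "F", "S", "Cl", "Br", "I")

.VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
          S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

.LJ_EPS <- c(H = 0.0157, C = 0.1094, N = 0.0774, O = 0.0957, F = 0.0610,
             S = 0.2500, Cl = 0.2650, Br = 0.3200, I = 0.4000)

# atomic logP contributions: heavy-atom term + per-attached-hydrogen term
.LOGP_ATOM <- c(H = 0.0, C = 0.1441, N = -0.6000, O = -0.3500, F = 0.4202,
                S = 0.6482, Cl = 0.6895, Br = 0.8456, I = 0.8857)
.LOGP_C_AROM <- 0.1581              # aromatic carbon replaces the C value
.LOGP_H_ON_C <- 0.1230              # H bonded to carbon
.LOGP_H_ON_HET <- -0.2000           # H bonded to N/O/S

# Coulomb conversion constant, kcal*Angstrom/(mol*e^2)
.COULOMB_K <- 332.17

# Gasteiger PEOE electronegativity polynomials chi(q) = a + b q + c q^2,
# by element and hybridization.  The classical published parameter set;
# hydrogen uses the special cation electronegativity 20.02.
.GASTEIGER <- data.frame(
  element = c("H", "C",  "C",  "C",  "N",  "N",  "N",  "O",  "O",
              "F", "Cl", "Br", "I",  "S",  "S"),
  hyb     = c("*", "sp3","sp2","sp", "sp3","sp2","sp", "sp3","sp2",
              "*", "*",  "*",  "*",  "sp3","sp2"),
  a = c(7.17, 7.98, 8.79, 10.39, 11.54, 12.87, 15.68, 14.18, 17.07,
        14.66, 11.00, 10.08, 9.90, 10.14, 10.88),
  b = c(6.24, 9.18, 9.32, 9.45, 10.82, 11.15, 11.70, 12.92, 13.79,
        13.85, 9.69, 8.47, 7.96, 9.13, 9.49),
  c = c(-0.56, 1.88, 1.51, 0.73, 1.36, 0.85, -0.27, 1.39, 0.47,
        2.31, 1.35, 1.16, 0.96, 1.38, 1.33),
  stringsAsFactors = FALSE
)
.GASTEIGER_H_PLUS <- 20.02

.elem_check <- function(elements, context = "molecule") {
  bad <- setdiff(unique(elements), .ELEMENTS)
  if (length(bad) > 0L) {
    stop(sprintf("unparameterized element(s) in %s: %s",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.gasteiger_params <- function(element, hyb) {
  tab <- .GASTEIGER
  out <- matrix(NA_real_, length(element), 3)
  for (i in seq_along(element)) {
    hit <- which(tab$element == element[i] & (tab$hyb == hyb[i] | tab$hyb == "*"))
    if (length(hit) == 0L) {
      # fall back to the sp3 row of the element (e.g. sp nitrogen in nitriles
      # has its own row; sp oxygen does not occur in valid structures)
      hit <- which(tab$element == element[i])
      if (length(hit) == 0L)
        stop(sprintf("no Gasteiger parameters for element %s", element[i]),
             call. = FALSE)
    }
    out[i, ] <- as.numeric(tab[hit[1L], c("a", "b", "c")])
  }
  colnames(out) <- c("a", "b", "c")
  out
}
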
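#' Assign Gasteiger partial charges
#'
#' Iterative partial equalization of orbital electronegativity (PEOE) with
#' the classical published parameter set.  Charges start from the formal
#' charges, and at iteration `n` the charge transferred across each bond is
#' damped by `0.5^n`; iteration stops when the largest per-atom update falls
#' below `tol` (at most `max_iter` iterations, enough for full convergence
#' at double precision scale).  Total charge is conserved exactly, so the
#' molecular sum equals the sum of formal charges.
#'
#' SYBYL-style "Gasteiger-Huckel" charges add a Huckel pi-charge term whose
#' exact recipe is unpublished; this implementation is plain sigma-system
#' Gasteiger, which is the documented, reproducible choice.
#'
#' @param mol a [molecule()] with explicit hydrogens
#' @param method only `"gasteiger"` is available
#' @param tol convergence threshold on the largest charge update
#' @param max_iter maximum number of damped iterations
#' @return the molecule with `partial_charge` filled in
#' @export
assign_partial_charges <- function(mol, method = c("gasteiger"),
                                   tol = 1e-8, max_iter = 64L) {
  method <- match.arg(method)
  .elem_check(mol$atoms$element, mol$id)
  if (all(is.na(mol$atoms$hyb)) || any(is.na(mol$atoms$hyb)))
    mol$atoms$hyb <- .perceive_hybridization(mol)
  if (any(is.na(mol$atoms$is_aromatic)))
    mol$atoms$is_aromatic <- .perceive_aromaticity(mol)
  par <- .gasteiger_params(mol$atoms$element, mol$atoms$hyb)
  chi_plus <- par[, "a"] + par[, "b"] + par[, "c"]
  chi_plus[mol$atoms$element == "H"] <- .GASTEIGER_H_PLUS
  q <- as.numeric(mol$atoms$formal_charge)
  a1 <- mol$bonds$a1; a2 <- mol$bonds$a2
  if (length(a1) > 0L) {
    damp <- 0.5
    for (n in seq_len(max_iter)) {
      chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q * q
      d <- chi[a2] - chi[a1]
      denom <- ifelse(d > 0, chi_plus[a1], chi_plus[a2])
      dq <- d / denom * damp^n
      upd <- numeric(length(q))
      for (k in seq_along(a1)) {
        upd[a1[k]] <- upd[a1[k]] + dq[k]
        upd[a2[k]] <- upd[a2[k]] - dq[k]
      }
      q <- q + upd
      if (max(abs(upd)) < tol) break
    }
  }
  mol$atoms$partial_charge <- q
  mol
}

#' Assign per-atom field parameters
#'
#' Fills the van der Waals radius and Lennard-Jones well depth from the
#' built-in element table, the atomic hydrophobicity contribution
#' (united-atom: attached hydrogens are folded into their heavy atom), and
#' the hydrogen-bond donor/acceptor flags:
#' * donor: N or O carrying at least one bonded hydrogen;
#' * acceptor: N or O with non-positive formal charge.
#'
#' @param mol a [molecule()]; charges should already be assigned
#' @return the molecule with field parameter columns filled in
#' @export
assign_field_params <- function(mol) {
  .elem_check(mol$atoms$element, mol$id)
  el <- mol$atoms$element
  if (any(is.na(mol$atoms$is_aromatic)))
    mol$atoms$is_aromatic <- .perceive_aromaticity(mol)
  if (any(is.na(mol$atoms$hyb)))
    mol$atoms$hyb <- .perceive_hybridization(mol)
  mol$atoms$vdw_radius <- unname(.VDW[el])
  mol$atoms$lj_epsilon <- unname(.LJ_EPS[el])
  mol$atoms$hydrophobic_w <- .atomic_logp(mol)
  hc <- .h_counts(mol)
  mol$atoms$is_hbd <- el %in% c("N", "O") & hc > 0L
  mol$atoms$is_hba <- el %in% c("N", "O") & mol$atoms$formal_charge <= 0L
  mol$rings <- .find_rings(mol)
  mol
}

# per-atom logP contributions (heavy atoms carry their hydrogens' share;
# H atoms themselves contribute 0 so sums can run over all atoms)
.atomic_logp <- function(mol) {
  el <- mol$atoms$element
  arom <- if (any(is.na(mol$atoms$is_aromatic))) .perceive_aromaticity(mol)
          else mol$atoms$is_aromatic
  hc <- .h_counts(mol)
  w <- unname(.LOGP_ATOM[el])
  w[el == "C" & arom] <- .LOGP_C_AROM
  hterm <- ifelse(el == "C", .LOGP_H_ON_C,
           ifelse(el %in% c("N", "O", "S"), .LOGP_H_ON_HET, 0))
  w <- w + hc * hterm
  w[el == "H"] <- 0
  w
}

#' Calculated logP from atomic contributions
#'
#' Sum of the built-in atomic octanol/water contributions (additive over
#' atoms, hence exactly additive over disconnected copies).  The value is
#' stored in `properties$ClogP`; the name follows the conventional report
#' label for a calculated logP descriptor.
#'
#' @param mol a [molecule()]
#' @return the molecule with `properties$ClogP` set
#' @export
compute_logp <- function(mol) {
  if (nrow(mol$atoms) == 0L) stop("empty molecule", call. = FALSE)
  .elem_check(mol$atoms$element, mol$id)
  mol$properties$ClogP <- sum(.atomic_logp(mol))
  mol
}

#' Prepare every molecule of a set for field analysis
#'
#' Convenience wrapper: aromaticity/hybridization perception, Gasteiger
#' charges, field parameters and calculated logP for each molecule.
#'
#' @param mols a [molecule_set()]
#' @return the prepared set
#' @export
prepare_molecules <- function(mols) {
  molecule_set(lapply(mols, function(m)
    compute_logp(assign_field_params(assign_partial_charges(m)))))
}
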
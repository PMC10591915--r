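#' Specification of a two-ligand competitive binding equilibrium
#'
#' Describes one well of the displacement assay: a protein P binding its
#' native ligand L (all-trans-retinol, dissociation constant `kd_retinol`)
#' and a competing inhibitor I (`ki_inhibitor`), all in molar units.
#'
#' @param protein_total total protein concentration (M).
#' @param retinol_total total retinol concentration (M).
#' @param inhibitor_total total inhibitor concentration (M).
#' @param kd_retinol dissociation constant of the protein-retinol complex
#'   (M, > 0). The assay's own literature does not fix this number; the
#'   simulation default is 10 nM.
#' @param ki_inhibitor dissociation constant of the protein-inhibitor
#'   complex (M, > 0); `Inf` is accepted and means "does not bind".
#' @return An object of class `equilibrium_spec`.
#' @export
equilibrium_spec <- function(protein_total, retinol_total, inhibitor_total,
                             kd_retinol = 10e-9, ki_inhibitor) {
  vals <- c(protein_total, retinol_total, inhibitor_total)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("total concentrations must be finite and >= 0")
  if (!(kd_retinol > 0) || !(ki_inhibitor > 0))
    stop("dissociation constants must be > 0")
  structure(
    list(protein_total = protein_total, retinol_total = retinol_total,
         inhibitor_total = inhibitor_total, kd_retinol = kd_retinol,
         ki_inhibitor = ki_inhibitor),
    class = "equilibrium_spec")
}

#' Solve a competitive two-ligand binding equilibrium
#'
#' Computes the equilibrium concentrations of all five species (free
#' protein, free retinol, free inhibitor, protein-retinol, and
#' protein-inhibitor) for one protein competitively bound by retinol and an
#' inhibitor. Writing the two binding isotherms in terms of free protein
#' `Pf` gives free-ligand concentrations `Lf = Lt / (1 + Pf/Kd)` and
#' `If = It / (1 + Pf/Ki)`; substituting into the protein mass balance
#' yields a single equation in `Pf` whose left side is strictly increasing,
#' so the root is found by bisection-safe `uniroot` on `[0, Pt]`.
#'
#' @param spec an [equilibrium_spec()].
#' @param tol relative convergence tolerance of the root solve.
#' @return A list with free species (`protein_free`, `retinol_free`,
#'   `inhibitor_free`), complexes (`protein_retinol`,
#'   `protein_inhibitor`), and the largest relative mass-balance residual
#'   (`mass_balance_error`), all molar.
#' @examples
#' eq <- competitive_equilibrium(
#'   equilibrium_spec(1e-6, 1e-6, 5e-6, kd_retinol = 1e-7,
#'                    ki_inhibitor = 7.1e-6))
#' eq$protein_retinol
#' @export
competitive_equilibrium <- function(spec, tol = 1e-14) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  Pt <- spec$protein_total; Lt <- spec$retinol_total
  It <- spec$inhibitor_total
  Kd <- spec$kd_retinol; Ki <- spec$ki_inhibitor

  if (Pt == 0) {
    return(species_list(0, Lt, It, 0, 0, Pt, Lt, It))
  }
  lig_free <- function(total, K, Pf) {
    if (is.infinite(K)) total else total / (1 + Pf / K)
  }
  balance <- function(Pf) {
    Lf <- lig_free(Lt, Kd, Pf)
    If <- lig_free(It, Ki, Pf)
    Pf * (1 + Lf / Kd + ifelse(is.infinite(Ki), 0, If / Ki)) - Pt
  }
  root <- tryCatch(
    stats::uniroot(balance, lower = 0, upper = Pt,
                   tol = tol * max(Pt, 1e-300), extendInt = "no"),
    error = function(e)
      stop("competitive_equilibrium failed to converge: ",
           conditionMessage(e),
           sprintf(" [Pt=%g Lt=%g It=%g Kd=%g Ki=%g]", Pt, Lt, It, Kd, Ki)))
  Pf <- root$root
  Lf <- lig_free(Lt, Kd, Pf)
  If <- lig_free(It, Ki, Pf)
  PL <- Pf * Lf / Kd
  PI <- if (is.infinite(Ki)) 0 else Pf * If / Ki
  species_list(Pf, Lf, If, PL, PI, Pt, Lt, It)
}

species_list <- function(Pf, Lf, If, PL, PI, Pt, Lt, It) {
  rel_err <- function(total, parts) {
    if (total == 0) return(abs(sum(parts)))
    abs(sum(parts) - total) / total
  }
  err <- max(rel_err(Pt, c(Pf, PL, PI)),
             rel_err(Lt, c(Lf, PL)),
             rel_err(It, c(If, PI)))
  list(protein_free = Pf, retinol_free = Lf, inhibitor_free = If,
       protein_retinol = PL, protein_inhibitor = PI,
       mass_balance_error = err)
}

#' Retinol occupancy without a competitor (two-component quadratic)
#'
#' Closed-form bound concentration for a single ligand binding one site:
#' the root of `PL^2 - (Pt + Lt + Kd) PL + Pt Lt = 0` lying in
#' `[0, min(Pt, Lt)]`.
#'
#' @param protein_total,ligand_total totals (M).
#' @param kd dissociation constant (M).
#' @return bound complex concentration (M).
#' @export
two_component_bound <- function(protein_total, ligand_total, kd) {
  s <- protein_total + ligand_total + kd
  (s - sqrt(s^2 - 4 * protein_total * ligand_total)) / 2
}
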
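#' Boltzmann constant in kcal mol^-1 K^-1
#' @export
KB_KCAL <- 0.0019872041

#' Dual-boost acceleration parameters from conventional-MD energy averages
#'
#' Accelerated MD with a dual boost raises the potential energy surface both
#' globally (total potential energy) and on the dihedral term, each below its
#' own threshold. The standard parameter recipe sets, in kcal/mol,
#' \deqn{E_{threshP} = \langle E_{tot}\rangle + 0.16\,N_{atoms},\quad
#'       \alpha_P = 0.16\,N_{atoms}}
#' \deqn{E_{threshD} = \langle E_{dih}\rangle + 4\,N_{residues},\quad
#'       \alpha_D = \tfrac{4}{5}\,N_{residues}}
#' where the averages come from an equilibrated conventional-MD run.
#'
#' @param e_tot_avg average total potential energy, kcal/mol.
#' @param e_dih_avg average dihedral energy, kcal/mol.
#' @param n_atoms number of atoms in the system.
#' @param n_residues number of residues in the system.
#' @return list with `e_thresh_p`, `alpha_p`, `e_thresh_d`, `alpha_d`
#'   (kcal/mol).
#' @export
dual_boost_parameters <- function(e_tot_avg, e_dih_avg, n_atoms, n_residues) {
  if (n_atoms < 1 || n_residues < 1)
    stop("atom and residue counts must be positive")
  list(e_thresh_p = e_tot_avg + 0.16 * n_atoms,
       alpha_p    = 0.16 * n_atoms,
       e_thresh_d = e_dih_avg + 4 * n_residues,
       alpha_d    = (4 / 5) * n_residues)
}

#' Accelerated-MD boost potential
#'
#' The bias added to the true potential when it falls below the threshold:
#' \deqn{\Delta V(r) = \frac{(E_{thresh} - V(r))^2}{E_{thresh} - V(r) + \alpha}}
#' for \eqn{V < E_{thresh}}, and 0 otherwise. The boost is non-negative,
#' continuous at the threshold, and grows as V drops, flattening barriers
#' while keeping the ordering of conformations by energy.
#'
#' @param v potential energy (vectorised), kcal/mol.
#' @param e_thresh boost threshold, kcal/mol.
#' @param alpha acceleration parameter, kcal/mol; must be positive.
#' @return boost energy, kcal/mol.
#' @export
boost_potential <- function(v, e_thresh, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  b <- e_thresh - v
  ifelse(b > 0, b^2 / (b + alpha), 0)
}

#' Accelerated-MD modified potential
#'
#' The potential actually propagated: \eqn{V^*(r) = V(r) + \Delta V(r)} below
#' the threshold and \eqn{V^*(r) = V(r)} at or above it. On the boosted branch
#' \eqn{V^*} is strictly increasing in \eqn{V}, bounded above by
#' \eqn{E_{thresh}}, and approaches \eqn{E_{thresh} - \alpha} as
#' \eqn{V \to -\infty}.
#'
#' @inheritParams boost_potential
#' @return modified potential, kcal/mol.
#' @export
modified_potential <- function(v, e_thresh, alpha) {
  v + boost_potential(v, e_thresh, alpha)
}

#' Derivative scale of the boosted force
#'
#' On the boosted branch, forces from the modified potential equal the true
#' forces scaled by \eqn{(\alpha / (E_{thresh} - V + \alpha))^2}; above the
#' threshold the scale is 1. Used by the synthetic-dimer integrator.
#'
#' @inheritParams boost_potential
#' @return dimensionless force scale in (0, 1].
#' @export
boost_force_scale <- function(v, e_thresh, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  b <- e_thresh - v
  ifelse(b > 0, (alpha / (b + alpha))^2, 1)
}

#' Exponential reweighting of boosted frames
#'
#' Canonical-ensemble weights for frames sampled on the modified potential:
#' \eqn{w_i \propto \exp(\Delta V_i / k_B T)}, normalised to sum to one. The
#' maximum boost is subtracted before exponentiation to avoid overflow.
#' Landscape estimation uses raw (unweighted) frames by default; reweighting
#' is an explicit opt-in.
#'
#' @param delta_v per-frame boost energies, kcal/mol.
#' @param temperature K.
#' @return numeric vector of normalised weights.
#' @export
reweight_frames <- function(delta_v, temperature = 300) {
  if (!all(is.finite(delta_v))) stop("non-finite boost energies")
  w <- exp((delta_v - max(delta_v)) / (KB_KCAL * temperature))
  w / sum(w)
}
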
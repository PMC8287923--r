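#' Operator-competent fraction of a transcription factor
#'
#' For a corepressor-mode TF (TrpR-like) the DNA-binding form only exists
#' in the presence of its ligand, so the competent fraction is
#' \eqn{L^h / (K_L^h + L^h)}.  For an inducer-mode TF (LacI-like) the apo
#' form binds DNA and the ligand releases it; the competent fraction falls
#' from 1 to a residual \eqn{1/f} at saturation, where \eqn{f} is the
#' induction fold:
#' \eqn{(K_L^h + L^h/f) / (K_L^h + L^h)}.
#'
#' @param tf A [tf_spec()].
#' @param ligand_conc Ligand concentration(s), uM (vectorised).
#' @return Fraction(s) in `[0, 1]`.
#' @export
active_tf_fraction <- function(tf, ligand_conc) {
  stopifnot(inherits(tf, "tf_spec"))
  if (!is.numeric(ligand_conc) || anyNA(ligand_conc))
    stop("ligand_conc must be numeric")
  if (any(ligand_conc < 0))
    stop("ligand_conc must be >= 0")
  h <- tf$ligand_hill
  Lh <- ligand_conc^h
  Kh <- tf$ligand_kd^h
  if (tf$mode == "corepressor") {
    ifelse(ligand_conc == 0, 0, Lh / (Kh + Lh))
  } else {
    (Kh + Lh / tf$induction_fold) / (Kh + Lh)
  }
}

#' Equilibrium TF-bound template concentration
#'
#' Exact solution of the two-species binding equilibrium
#' \eqn{TF + T \rightleftharpoons TF{\cdot}T} with dissociation constant
#' `kd_eff`:
#' the bound concentration is the smaller root of
#' \eqn{b^2 - (P + T + K_d) b + P T = 0}, evaluated in a numerically
#' stable form.  Bound is always below both totals, increases with TF and
#' decreases with `kd_eff`.
#'
#' @param tf_total Total (operator-competent) TF concentration, nM
#'   (vectorised).
#' @param template_total Total template concentration, nM.
#' @param kd_eff Effective dissociation constant, nM (> 0).
#' @return Bound template concentration(s), nM.
#' @export
template_occupancy <- function(tf_total, template_total, kd_eff) {
  if (!is.numeric(tf_total) || any(tf_total < 0) ||
      !is.numeric(template_total) || any(template_total < 0))
    stop("concentrations must be >= 0")
  if (!is.numeric(kd_eff) || any(kd_eff <= 0))
    stop("kd_eff must be > 0")
  s <- tf_total + template_total + kd_eff
  q <- tf_total * template_total
  # stable smaller quadratic root: 2q / (s + sqrt(s^2 - 4q))
  disc <- pmax(s^2 - 4 * q, 0)
  2 * q / (s + sqrt(disc))
}

#' Total TF needed to reach a target template occupancy
#'
#' Inverts [template_occupancy()] in its first argument by bisection.
#'
#' @param fraction Target bound fraction of the template pool, in (0, 1).
#' @param template_total Total template concentration, nM.
#' @param kd_eff Effective dissociation constant, nM.
#' @return Total TF concentration, nM.
#' @export
tf_for_occupancy <- function(fraction, template_total, kd_eff) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction < 1)
  target <- fraction * template_total
  f <- function(p) template_occupancy(p, template_total, kd_eff) - target
  upper <- template_total + kd_eff
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}
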
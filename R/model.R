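#' Hill activation and repression fractions
#'
#' `hill_activation()` returns `x^n / (x^n + K^n)`, the fractional
#' saturation of an activating Hill term; `hill_repression()` returns the
#' complementary `K^n / (K^n + x^n)` used for transcriptional repression.
#'
#' @param x non-negative input abundance.
#' @param K threshold, strictly positive.
#' @param n Hill coefficient, strictly positive.
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' hill_activation(2, K = 2, n = 2)  # 0.5
hill_activation <- function(x, K, n) {
  if (any(K <= 0) || any(n <= 0)) {
    abort("Hill threshold K and coefficient n must be > 0.")
  }
  if (any(x < 0)) abort("Hill input must be non-negative.")
  xn <- x^n
  ifelse(x == 0, 0, xn / (xn + K^n))
}

#' @rdname hill_activation
#' @export
hill_repression <- function(x, K, n) {
  if (any(K <= 0) || any(n <= 0)) {
    abort("Hill threshold K and coefficient n must be > 0.")
  }
  if (any(x < 0)) abort("Hill input must be non-negative.")
  Kn <- K^n
  ifelse(x == 0, 1, Kn / (Kn + x^n))
}

#' Glucose-bound active repressor
#'
#' The active (glucose-bound) fraction of the total catabolite repressor
#' pool, an algebraic function of intracellular glucose:
#' `Rs = gluc_in^nRs / (gluc_in^nRs + KRs^nRs) * Rtot`.
#'
#' @param Rtot total repressor abundance (>= 0).
#' @param gluc_in intracellular glucose (>= 0).
#' @param params a `gal_params` object (uses `KRs`, `nRs`).
#' @return active repressor abundance, between 0 and `Rtot`.
#' @export
active_repressor <- function(Rtot, gluc_in, params) {
  if (any(Rtot < 0) || any(gluc_in < 0)) {
    abort("Abundances must be non-negative.")
  }
  hill_activation(gluc_in, params[["KRs"]], params[["nRs"]]) * Rtot
}

#' Zero model state
#'
#' @return named numeric vector of the 12 dynamic species, all zero.
#' @export
zero_state <- function() {
  structure(numeric(12), names = .gal_state_names)
}

#' Time derivatives of the GAL network model
#'
#' Evaluates the right-hand side of the 12-species ODE system: the GAL
#' regulon proteins (Gal1p, Gal2p, Gal3p, activated Gal3p, Gal80p, Gal4p),
#' the Gal3p*-Gal80p and Gal4p-Gal80p complexes, the aggregate hexose
#' transporter HXT, the total repressor pool, and intracellular glucose
#' and galactose. The active repressor `Rs` is computed algebraically from
#' intracellular glucose. The galactose bound by the Gal3p sensor is
#' intracellular galactose (`gal_in`). Sugar uptake uses shared-transporter
#' competitive Michaelis kinetics with relative affinities `rG2` (Gal2p)
#' and `rHXT` (HXT) and HXT catalytic scaling `rcat * kG2`. External
#' sugars are held constant during an integration.
#'
#' @param state named numeric vector of the 12 species (see
#'   [zero_state()]); all components must be non-negative.
#' @param params a `gal_params` object.
#' @param condition a [sugar_condition()] (external % w/v).
#' @return named numeric vector of the 12 time derivatives.
#' @export
#' @examples
#' gal_rhs(zero_state(), reference_parameters(), sugar_condition(0, 0))
gal_rhs <- function(state, params, condition) {
  if (any(state < 0)) {
    abort("Invalid state: negative component(s). The integrator clips tiny undershoot before calling.")
  }
  p <- as.list(as.numeric(params))
  names(p) <- names(params)
  glucex <- condition[["glucose"]]
  galex <- condition[["galactose"]]
  s <- as.list(as.numeric(state))
  names(s) <- .gal_state_names

  with(c(p, s), {
    Rs <- hill_activation(gluc_in, KRs, nRs) * Rtot
    bind3 <- kf3 * gal_in * G3 - kr3 * G3s
    bind83 <- kf83 * G3s * G80 - kr83 * C83
    bind84 <- kf84 * G4 * G80 - kr84 * C84
    up_gluc <- kG2 * G2 * glucex / (galex / rG2 + glucex + KGgluc) +
      rcat * kG2 * HXT * glucex / (galex / rHXT + glucex + KHXTgluc)
    up_gal <- kG2 * G2 * galex / (rG2 * glucex + galex + rG2 * KGgluc) +
      rcat * kG2 * HXT * galex / (rHXT * glucex + galex + rHXT * KHXTgluc)
    c(
      G1 = a1 + ag1 * hill_activation(G4, KG1, n1) *
        hill_repression(Rs, KR1, nR1) - d * G1,
      G2 = a2 + ag2 * hill_activation(G4, KG2, n2) - d * G2,
      G3 = a3 + ag3 * hill_activation(G4, KG3, n3) *
        hill_repression(Rs, KR3, nR3) - bind3 - d * G3,
      G3s = bind3 - bind83 - d * G3s,
      G80 = a80 + ag80 * hill_activation(G4, KG80, n80) -
        bind83 - bind84 - d * G80,
      G4 = a4 + ag4 * hill_repression(Rs, KR4, nR4) - bind84 - d * G4,
      C83 = bind83 - d * C83,
      C84 = bind84 - d * C84,
      HXT = a0HXT + aHXT * hill_repression(G4, KHXT, nHXT) - d * HXT,
      Rtot = aR - d * Rtot,
      gluc_in = up_gluc - dsugar * gluc_in,
      gal_in = up_gal - bind3 - dsugar * gal_in
    )
  })
}

## parameter vector in the order expected by the compiled derivs
compiled_parms <- function(params, condition) {
  c(as.numeric(params), condition[["glucose"]], condition[["galactose"]])
}
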
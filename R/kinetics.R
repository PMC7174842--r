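# Four-species dot-stripe kinetics.
#
# Dot subsystem (A, S): activator-substrate circuit — S fuels autocatalytic
# production of A (A^2 S), A consumes S, both have constant production; A is
# linearly degraded. Stripe subsystem (B, I): saturated activator-inhibitor
# circuit — B self-activates (B^2 / I, saturating in B), induces its fast
# inhibitor I, both degrade. The dot field gates the stripe field so that
# stripes (joints) form between dots (phalanx centres).
#
# Symbol notes: the degradation rate of A is mu_A (the source literature
# overloads "k_A" for both activation and degradation of A); likewise the
# degradation of I is mu_I and of B is mu_B.

#' Dot-subsystem (A, S) parameters
#'
#' @param k_A Cross-activation rate of A by S (the A^2 S autocatalysis).
#' @param mu_A Linear degradation rate of A.
#' @param k_S Consumption rate of S by A (the A^2 S depletion).
#' @param h_A,h_S Constant, concentration-independent production rates.
#' @param D_A,D_S Diffusivities; Turing instability requires `D_S > D_A`
#'   (the substrate must outrange the activator).
#' @return Object of class `dot_params`.
#' @export
dot_params <- function(k_A = 1, mu_A = 1, k_S = 1, h_A = 0.15, h_S = 1,
                       D_A = 1, D_S = 20) {
  p <- list(k_A = k_A, mu_A = mu_A, k_S = k_S, h_A = h_A, h_S = h_S,
            D_A = D_A, D_S = D_S)
  if (any(unlist(p) < 0)) stop("dot parameters must be non-negative")
  if (D_S <= D_A) stop("need D_S > D_A for the dot subsystem")
  structure(p, class = "dot_params")
}

#' Stripe-subsystem (B, I) parameters
#'
#' @param k_B Self-activation rate of B.
#' @param kappa_B Saturation constant: self-activation is self-limiting at
#'   high B through `1 + kappa_B * B^2`.
#' @param mu_B Linear degradation rate of B.
#' @param k_I Activation rate of I by B.
#' @param mu_I Linear degradation rate of I.
#' @param D_B,D_I Diffusivities; requires `D_I > D_B`.
#' @param I_floor Small positive constant regularising the division by I.
#' @return Object of class `stripe_params`.
#' @export
stripe_params <- function(k_B = 1, kappa_B = 0.25, mu_B = 1, k_I = 1,
                          mu_I = 2, D_B = 0.3, D_I = 6, I_floor = 1e-6) {
  p <- list(k_B = k_B, kappa_B = kappa_B, mu_B = mu_B, k_I = k_I,
            mu_I = mu_I, D_B = D_B, D_I = D_I, I_floor = I_floor)
  if (any(unlist(p) < 0)) stop("stripe parameters must be non-negative")
  if (D_I <= D_B) stop("need D_I > D_B for the stripe subsystem")
  if (I_floor <= 0) stop("I_floor must be positive")
  structure(p, class = "stripe_params")
}

#' Dot-to-stripe coupling, variant selection and boundary rates
#'
#' The dot subsystem gates the stripe subsystem in two ways: S activates B
#' (strength `s_act`) and A raises the self-activation saturation of B
#' (strength `s_thr`), both expressed relative to the homogeneous steady
#' state so the strengths are dimensionless. Outside the digit only A is
#' degraded (rate `k_deg`); optional decay of B and I outside is off by
#' default. The digital crescent adds production of A (`h_A_DC`) and a linear
#' sink of B (`h_B_DC`).
#'
#' @param variant One of "full", "stripe_only" (B,I alone with constant
#'   k_B, kappa_B; I is the joint marker), "dot_hole" (A,S alone; S is the
#'   joint marker).
#' @param s_act,s_thr Dimensionless coupling strengths (>= 0).
#' @param k_deg Outside-digit degradation rate of A.
#' @param h_A_DC,h_B_DC Crescent activation (of A) and repression (of B) rates.
#' @param outside_decay_BI Also decay B and I outside the digit?
#' @return Object of class `coupling_params`.
#' @export
coupling_params <- function(variant = c("full", "stripe_only", "dot_hole"),
                            s_act = 1, s_thr = 1, k_deg = 0.5,
                            h_A_DC = 0, h_B_DC = 0,
                            outside_decay_BI = FALSE) {
  variant <- match.arg(variant)
  if (any(c(s_act, s_thr, k_deg, h_A_DC, h_B_DC) < 0))
    stop("coupling rates must be non-negative")
  if (variant == "stripe_only") { s_act <- 0; s_thr <- 0 }
  structure(list(variant = variant, s_act = s_act, s_thr = s_thr,
                 k_deg = k_deg, h_A_DC = h_A_DC, h_B_DC = h_B_DC,
                 outside_decay_BI = outside_decay_BI),
            class = "coupling_params")
}

check_fields <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    f <- args[[nm]]
    if (anyNA(f) || any(!is.finite(f))) stop("field ", nm, " contains non-finite values")
    if (any(f < 0)) stop("field ", nm, " contains negative values")
  }
  invisible(TRUE)
}

#' Reaction rates of the dot (A, S) subsystem
#'
#' Inside the digit: `dA = h_A + k_A A^2 S - mu_A A`, `dS = h_S - k_S A^2 S`.
#' Outside: `dA = -k_deg A`, `dS = 0`. In the crescent, `h_A_DC` is added to
#' `dA`. Diffusion is handled separately by the solver.
#'
#' @param A,S Concentration field matrices (non-negative, finite).
#' @param p A [dot_params()].
#' @param c A [coupling_params()].
#' @param masks A `domain_masks` object.
#' @return List with matrices `dA`, `dS`.
#' @export
dot_rates <- function(A, S, p, c, masks) {
  check_fields(A = A, S = S)
  om <- masks$omega
  A2S <- A * A * S
  dA <- om * (p$h_A + p$k_A * A2S - p$mu_A * A) - (1 - om) * c$k_deg * A
  dS <- om * (p$h_S - p$k_S * A2S)
  if (c$h_A_DC > 0 && any(masks$crescent > 0))
    dA <- dA + c$h_A_DC * masks$crescent
  list(dA = dA, dS = dS)
}

#' Effective stripe self-activation rate gated by S
#'
#' Power-law in S, normalised by the reference steady state: `k_B *
#' (S/S*)^s_act` — equal to `k_B` at `S = S*`, zero at `S = 0`, strictly
#' increasing in S for `s_act > 0`; `s_act` sets the gate steepness.
#' Constant `k_B` in the stripe-only variant.
#'
#' @param S Substrate field (matrix or scalar).
#' @param c A [coupling_params()].
#' @param sp A [stripe_params()].
#' @param S_star Reference steady-state value of S (> 0).
#' @return Rate field, same shape as `S`.
#' @export
k_B_eff <- function(S, c, sp, S_star) {
  if (c$variant == "stripe_only") return(S * 0 + sp$k_B)
  if (is.null(S_star) || S_star <= 0) stop("reference steady state S* must be positive")
  sp$k_B * pmax(S / S_star, 0)^c$s_act
}

#' Effective stripe saturation constant raised by A
#'
#' Linear in A: `kappa_B * (1 + s_thr * A/A*)` — equal to `kappa_B` at
#' `A = 0`, monotone increasing in A. Constant `kappa_B` in the stripe-only
#' variant.
#'
#' @param A Activator field (matrix or scalar).
#' @inheritParams k_B_eff
#' @param A_star Reference steady-state value of A (> 0).
#' @return Saturation field, same shape as `A`.
#' @export
kappa_eff <- function(A, c, sp, A_star) {
  if (c$variant == "stripe_only") return(A * 0 + sp$kappa_B)
  if (is.null(A_star) || A_star <= 0) stop("reference steady state A* must be positive")
  sp$kappa_B * (1 + c$s_thr * pmax(A, 0) / A_star)
}

#' Reaction rates of the stripe (B, I) subsystem
#'
#' Inside the digit: `dB = k_B_eff(S) B^2 / (max(I, I_floor) (1 +
#' kappa_eff(A) B^2)) - mu_B B`, `dI = k_I B^2 - mu_I I`. Outside: zero
#' (or decay if `outside_decay_BI`). In the crescent, a sink `-h_B_DC B` is
#' added to `dB`.
#'
#' @param B,I Stripe activator / inhibitor fields.
#' @param A,S Dot fields (used through the coupling; may be scalars).
#' @param sp A [stripe_params()].
#' @param c A [coupling_params()].
#' @param masks A `domain_masks` object.
#' @param ref Named list with steady-state references `A`, `S` (from
#'   [homogeneous_steady_state()]); ignored in the stripe-only variant.
#' @return List with matrices `dB`, `dI`.
#' @export
stripe_rates <- function(B, I, A, S, sp, c, masks, ref = NULL) {
  check_fields(B = B, I = I)
  om <- masks$omega
  kb <- k_B_eff(S, c, sp, ref$S)
  kap <- kappa_eff(A, c, sp, ref$A)
  B2 <- B * B
  auto <- kb * B2 / (pmax(I, sp$I_floor) * (1 + kap * B2))
  dB <- om * (auto - sp$mu_B * B)
  dI <- om * (sp$k_I * B2 - sp$mu_I * I)
  if (c$outside_decay_BI) {
    dB <- dB - (1 - om) * sp$mu_B * B
    dI <- dI - (1 - om) * sp$mu_I * I
  }
  if (c$h_B_DC > 0 && any(masks$crescent > 0))
    dB <- dB - c$h_B_DC * masks$crescent * B
  list(dB = dB, dI = dI)
}

#' Homogeneous steady state of the full kinetics
#'
#' The dot pair has the closed form `A* = (h_A + k_A h_S / k_S) / mu_A`,
#' `S* = h_S / (k_S A*^2)`. The stripe pair is solved numerically at
#' `(A*, S*)`: `B*` is the positive root of `mu_B B (1 + kappa_eff B^2) =
#' k_B_eff mu_I / k_I` (found by bisection on a positive bracket), and
#' `I* = k_I B*^2 / mu_I`.
#'
#' @param p A [dot_params()].
#' @param sp A [stripe_params()].
#' @param c A [coupling_params()].
#' @return Named list `A`, `S`, `B`, `I` of steady-state values (stripe
#'   entries are `NA` in the dot-hole variant, dot entries are still the
#'   coupling references in stripe-only).
#' @export
homogeneous_steady_state <- function(p, sp, c = coupling_params()) {
  if (p$mu_A <= 0 || p$k_S <= 0)
    stop("dot subsystem: no positive steady state (mu_A and k_S must be positive)")
  A_star <- (p$h_A + p$k_A * p$h_S / p$k_S) / p$mu_A
  if (A_star <= 0) stop("dot subsystem: no positive steady state")
  S_star <- p$h_S / (p$k_S * A_star^2)
  if (c$variant == "dot_hole")
    return(list(A = A_star, S = S_star, B = NA_real_, I = NA_real_))
  ref <- list(A = A_star, S = S_star)
  kb <- k_B_eff(S_star, c, sp, S_star)
  kap <- kappa_eff(A_star, c, sp, A_star)
  if (sp$mu_B <= 0 || sp$mu_I <= 0 || sp$k_I <= 0 || kb <= 0)
    stop("stripe subsystem: no positive steady state for these parameters")
  rhs <- kb * sp$mu_I / sp$k_I
  g <- function(B) sp$mu_B * B * (1 + kap * B^2) - rhs
  hi <- 1
  while (g(hi) < 0) hi <- hi * 2
  B_star <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
  I_star <- sp$k_I * B_star^2 / sp$mu_I
  list(A = A_star, S = S_star, B = B_star, I = I_star)
}

# growth rate of the fastest mode of a 2-species reaction-diffusion pair,
# from its Jacobian J (2x2) and diffusivities, as a function of k^2
two_species_sigma <- function(J, D1, D2, k2) {
  a <- J[1, 1] - D1 * k2
  d <- J[2, 2] - D2 * k2
  tr <- a + d
  det <- a * d - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  re <- ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
  re
}

#' Linear stability of the dot subsystem
#'
#' Computes the Jacobian of the (A, S) reaction kinetics at the homogeneous
#' steady state, the dispersion relation `sigma(k)` = largest real part of
#' the eigenvalues of `J - k^2 diag(D_A, D_S)` over a dense wavenumber grid,
#' its maximiser `k_max`, and the predicted pattern wavelength `2*pi/k_max`.
#' A positive `sigma_max` indicates a Turing (diffusion-driven) instability.
#'
#' @param p A [dot_params()].
#' @param k_max_search Upper end of the wavenumber grid (default 2).
#' @param nk Number of grid points (default 4000).
#' @return List: `k_max`, `lambda_pred`, `sigma_max`, `turing` (logical),
#'   `k` and `sigma` (the sampled dispersion curve), `jacobian`, and the
#'   steady state used.
#' @export
dot_linear_stability <- function(p, k_max_search = 2, nk = 4000) {
  ss <- homogeneous_steady_state(p, stripe_params(),
                                 coupling_params(variant = "dot_hole"))
  A <- ss$A; S <- ss$S
  J <- matrix(c(2 * p$k_A * A * S - p$mu_A, -2 * p$k_S * A * S,
                p$k_A * A^2,               -p$k_S * A^2), 2, 2)
  k <- seq(0, k_max_search, length.out = nk)
  sig <- two_species_sigma(J, p$D_A, p$D_S, k^2)
  i <- which.max(sig)
  sigma_max <- sig[i]
  turing <- sigma_max > 0 && k[i] > 0
  list(k_max = k[i], lambda_pred = if (k[i] > 0) 2 * pi / k[i] else Inf,
       sigma_max = sigma_max, turing = turing, k = k, sigma = sig,
       jacobian = J, steady_state = ss)
}

#' Linear stability of the stripe subsystem under a uniform (A, S) clamp
#'
#' Evaluates the (B, I) Jacobian (by central finite differences of the
#' reaction rates) at the subsystem steady state for the given clamped
#' (A, S) values, and scans the dispersion relation as in
#' [dot_linear_stability()]. Used to place default parameters and to predict
#' the outcome of clamp experiments.
#'
#' @param sp A [stripe_params()].
#' @param c A [coupling_params()].
#' @param A_val,S_val Clamped uniform values of A and S.
#' @param ref Steady-state reference list (`A`, `S`) for the coupling.
#' @param k_max_search,nk Wavenumber grid, as in [dot_linear_stability()].
#' @return Same structure as [dot_linear_stability()].
#' @export
stripe_linear_stability <- function(sp, c, A_val, S_val, ref,
                                    k_max_search = 4, nk = 4000) {
  kb <- k_B_eff(S_val, c, sp, ref$S)
  kap <- kappa_eff(A_val, c, sp, ref$A)
  if (kb <= 0) {
    return(list(k_max = 0, lambda_pred = Inf, sigma_max = -sp$mu_B,
                turing = FALSE, steady_state = list(B = 0, I = 0)))
  }
  rhs <- kb * sp$mu_I / sp$k_I
  g <- function(B) sp$mu_B * B * (1 + kap * B^2) - rhs
  hi <- 1; while (g(hi) < 0) hi <- hi * 2
  B0 <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
  I0 <- sp$k_I * B0^2 / sp$mu_I
  f <- function(B, I) kb * B^2 / (pmax(I, sp$I_floor) * (1 + kap * B^2)) - sp$mu_B * B
  gI <- function(B, I) sp$k_I * B^2 - sp$mu_I * I
  eB <- max(1e-6, 1e-6 * B0); eI <- max(1e-6, 1e-6 * I0)
  J <- matrix(c((f(B0 + eB, I0) - f(B0 - eB, I0)) / (2 * eB),
                (gI(B0 + eB, I0) - gI(B0 - eB, I0)) / (2 * eB),
                (f(B0, I0 + eI) - f(B0, I0 - eI)) / (2 * eI),
                (gI(B0, I0 + eI) - gI(B0, I0 - eI)) / (2 * eI)), 2, 2)
  k <- seq(0, k_max_search, length.out = nk)
  sig <- two_species_sigma(J, sp$D_B, sp$D_I, k^2)
  i <- which.max(sig)
  list(k_max = k[i], lambda_pred = if (k[i] > 0) 2 * pi / k[i] else Inf,
       sigma_max = sig[i], turing = sig[i] > 0 && k[i] > 0,
       k = k, sigma = sig, jacobian = J,
       steady_state = list(B = B0, I = I0))
}
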
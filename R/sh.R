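# Generic dot-stripe mechanism: two coupled Swift-Hohenberg equations.
#
# The dot field u obeys a generalized Swift-Hohenberg equation whose
# quadratic term gamma selects dots over stripes; the stripe field v obeys a
# Swift-Hohenberg equation with an additive bias h and relative timescale
# tau. Coupling makes both the stripe instability parameter alpha and the
# bias h decreasing functions of the (rectified, normalised) dot field, so
# stripes self-organize between dots and lock their phase to run
# perpendicular to dot spacing.

#' Parameters of the generic (Swift-Hohenberg) dot-stripe model
#'
#' The dot equation is `du/dt = alpha_dot u - (1 + ell_dot^2 lap)^2 u +
#' gamma u^2 - u^3` inside the domain, with decay `-k_deg_sh u` replacing
#' the local terms outside (the fourth-order operator acts everywhere). The
#' stripe equation is `tau dv/dt = alpha_eff(u) v - (1 + ell_stripe^2 lap)^2
#' v - v^3 + h_eff(u)` with `alpha_eff = alpha0 - s_alpha rect(u)` and
#' `h_eff = h0 - s_h rect(u)`, where `rect(u) = max(u, 0) / u_scale` and
#' `u_scale` is the running spatial maximum of `|u|` (floored).
#'
#' @param alpha_dot Dot instability parameter; dots form for `alpha_dot > 0`.
#' @param ell_dot Intrinsic dot length scale; dot spacing is about
#'   `2*pi*ell_dot`.
#' @param gamma Quadratic coefficient; large enough gamma makes dots, not
#'   stripes.
#' @param k_deg_sh Outside-domain decay rate of the dot field.
#' @param alpha0 Baseline stripe instability parameter.
#' @param ell_stripe Stripe length scale (defaults to `ell_dot`).
#' @param h0 Baseline stripe bias.
#' @param tau Relative timescale of the stripe equation (> 0).
#' @param s_alpha,s_h Coupling slopes: how strongly the dot field lowers
#'   `alpha` and `h`.
#' @param coupling_mode One of "both", "h_only", "alpha_only", "none";
#'   zeroes the corresponding slope(s).
#' @param u_scale_floor Lower bound for the normalisation of `rect(u)`.
#' @return Object of class `sh_params`.
#' @export
sh_params <- function(alpha_dot = 0.2, ell_dot = 2, gamma = 1.5,
                      k_deg_sh = 1, alpha0 = 0.3, ell_stripe = ell_dot,
                      h0 = 0, tau = 2, s_alpha = 1, s_h = 0.6,
                      coupling_mode = c("both", "h_only", "alpha_only", "none"),
                      u_scale_floor = 0.1) {
  coupling_mode <- match.arg(coupling_mode)
  if (ell_dot <= 0 || ell_stripe <= 0) stop("length scales must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (u_scale_floor <= 0) stop("u_scale_floor must be positive")
  structure(list(alpha_dot = alpha_dot, ell_dot = ell_dot, gamma = gamma,
                 k_deg_sh = k_deg_sh, alpha0 = alpha0,
                 ell_stripe = ell_stripe, h0 = h0, tau = tau,
                 s_alpha = s_alpha, s_h = s_h,
                 coupling_mode = coupling_mode,
                 u_scale_floor = u_scale_floor),
            class = "sh_params")
}

#' Local (non-operator) part of the Swift-Hohenberg dot equation
#'
#' Returns the reaction part of `du/dt`: inside the domain `alpha_dot u +
#' gamma u^2 - u^3`, outside `-k_deg_sh u`. The stiff fourth-order operator
#' `-(1 + ell_dot^2 lap)^2 u` is applied spectrally by the solver (see
#' [implicit_sh_linear_step()]); its linear symbol is exposed through
#' [sh_dispersion()].
#'
#' @param u Dot field matrix (finite, sign-indefinite).
#' @param p An [sh_params()].
#' @param masks A `domain_masks` object.
#' @return Matrix `du/dt` (local part).
#' @export
sh_dot_rhs <- function(u, p, masks) {
  if (any(!is.finite(u))) stop("dot field contains non-finite values")
  om <- masks$omega
  om * (p$alpha_dot * u + p$gamma * u * u - u^3) - (1 - om) * p$k_deg_sh * u
}

# rectified, normalised dot field used as the coupling argument
sh_rect <- function(u, p) {
  u_scale <- max(abs(u), p$u_scale_floor)
  pmax(u, 0) / u_scale
}

#' Local part of the coupled Swift-Hohenberg stripe equation
#'
#' Returns the reaction part of `dv/dt` (the 1/tau factor included): inside
#' the domain `(alpha_eff(u) v - v^3 + h_eff(u)) / tau`, zero outside. The
#' operator part `-(1 + ell_stripe^2 lap)^2 v / tau` is applied spectrally.
#'
#' @param v Stripe field matrix.
#' @param u Dot field matrix (coupling input).
#' @param p An [sh_params()].
#' @param masks A `domain_masks` object.
#' @param coupling_mode Override of `p$coupling_mode` (optional).
#' @return Matrix `dv/dt` (local part).
#' @export
sh_stripe_rhs <- function(v, u, p, masks, coupling_mode = p$coupling_mode) {
  if (any(!is.finite(v))) stop("stripe field contains non-finite values")
  s_alpha <- if (coupling_mode %in% c("both", "alpha_only")) p$s_alpha else 0
  s_h <- if (coupling_mode %in% c("both", "h_only")) p$s_h else 0
  r <- if (s_alpha > 0 || s_h > 0) sh_rect(u, p) else 0
  alpha_eff <- p$alpha0 - s_alpha * r
  h_eff <- p$h0 - s_h * r
  masks$omega * (alpha_eff * v - v^3 + h_eff) / p$tau
}

#' Swift-Hohenberg linear growth rate
#'
#' Closed form of the linearised growth rate at wavenumber k:
#' `sigma(k) = alpha - (1 - ell^2 k^2)^2`. The band centre `k = 1/ell` grows
#' at rate `alpha`; the uniform mode `k = 0` at `alpha - 1`.
#'
#' @param alpha Instability parameter.
#' @param ell Length scale (> 0).
#' @param k Wavenumber (vectorised).
#' @return Growth rate(s).
#' @export
sh_dispersion <- function(alpha, ell, k) {
  if (ell <= 0) stop("ell must be positive")
  alpha - (1 - ell^2 * k^2)^2
}
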
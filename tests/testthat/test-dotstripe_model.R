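# Four-species kinetics: rates, steady states, coupling, linear stability.

test_that("dot rates reduce to bare production at the origin and decay outside", {
  g <- fix_grid(); m <- fix_rect_masks(g)
  p <- dot_params(h_A = 0.3, h_S = 1.2)
  cp <- coupling_params(k_deg = 0.7)
  Z <- matrix(0, g$nx, g$ny)
  r <- dot_rates(Z, Z, p, cp, m)
  expect_equal(unique(r$dA[m$omega > 0]), 0.3)
  expect_equal(unique(r$dS[m$omega > 0]), 1.2)
  # outside: pure decay of A, S inert
  A1 <- matrix(2, g$nx, g$ny)
  r2 <- dot_rates(A1, Z, p, cp, m)
  expect_true(all(r2$dA[m$omega == 0] == -0.7 * 2))
  expect_true(all(r2$dS[m$omega == 0] == 0))
  expect_error(dot_rates(Z - 1, Z, p, cp, m), "negative")
})

test_that("dot steady state follows the closed-form algebra and is a fixed point", {
  # h_A = 0, unit rates: A* = S* = 1
  p0 <- dot_params(h_A = 0, h_S = 1, k_A = 1, k_S = 1, mu_A = 1)
  ss0 <- homogeneous_steady_state(p0, stripe_params(),
                                  coupling_params(variant = "dot_hole"))
  expect_equal(ss0$A, 1); expect_equal(ss0$S, 1)
  # generic parameters: rates vanish at the root
  p <- dot_params(h_A = 0.07, h_S = 1.4, k_A = 0.8, k_S = 1.1, mu_A = 0.9)
  cp <- coupling_params()
  ss <- homogeneous_steady_state(p, stripe_params(), cp)
  g <- fix_grid(16, 12); m <- fix_rect_masks(g, W = 8, L = 10)
  r <- dot_rates(matrix(ss$A, 16, 12), matrix(ss$S, 16, 12), p, cp, m)
  expect_lt(max(abs(r$dA[m$omega > 0])), 1e-10)
  expect_lt(max(abs(r$dS[m$omega > 0])), 1e-10)
  # well-mixed root is stable: Jacobian has negative trace, positive det
  J <- dot_linear_stability(p)$jacobian
  expect_lt(sum(diag(J)), 0)
  expect_gt(det(J), 0)
  # when A is not self-activating at the root (dfA/dA < 0), a pure A
  # perturbation decays on its own
  p2 <- dot_params(k_A = 0.2, h_A = 1, h_S = 0.3, k_S = 1, mu_A = 1)
  ss2 <- homogeneous_steady_state(p2, stripe_params(),
                                  coupling_params(variant = "dot_hole"))
  expect_lt(2 * p2$k_A * ss2$A * ss2$S - p2$mu_A, 0)
  rp <- dot_rates(matrix(ss2$A * 1.01, 16, 12), matrix(ss2$S, 16, 12), p2,
                  coupling_params(variant = "dot_hole"), m)
  expect_lt(max(rp$dA[m$omega > 0]), 0)
})

test_that("stripe rates: B = 0 is invariant and the clamped fixed points match a root oracle", {
  g <- fix_grid(16, 12); m <- fix_rect_masks(g, W = 8, L = 10)
  sp <- stripe_params(); cp <- coupling_params(variant = "stripe_only")
  Z <- matrix(0, 16, 12); I1 <- matrix(0.8, 16, 12)
  r <- stripe_rates(Z, I1, 1, 1, sp, cp, m)
  expect_true(all(r$dB == 0))
  expect_equal(r$dI[m$omega > 0], rep(-sp$mu_I * 0.8, sum(m$omega)))
  # kappa -> 0, I clamped at 1, k_B = 1, mu_B = 0.5: roots of B^2 = 0.5 B
  # are B = 0 and B = 0.5 (root-finding oracle)
  f <- function(B) B^2 / 1 - 0.5 * B
  roots <- sort(c(stats::uniroot(f, c(-0.1, 0.2), tol = 1e-12)$root,
                  stats::uniroot(f, c(0.2, 4), tol = 1e-12)$root))
  expect_equal(roots, c(0, 0.5), tolerance = 1e-8)
  roots <- pmax(roots, 0)
  sp2 <- stripe_params(k_B = 1, kappa_B = 0, mu_B = 0.5)
  for (B0 in roots) {
    r0 <- stripe_rates(matrix(B0, 16, 12), matrix(1, 16, 12), 1, 1, sp2,
                       coupling_params(variant = "stripe_only"), m)
    expect_lt(max(abs(r0$dB[m$omega > 0])), 1e-8)
  }
})

test_that("coupling gates are monotone with the stated anchor values", {
  sp <- stripe_params(k_B = 2, kappa_B = 0.5)
  cp <- coupling_params(s_act = 1, s_thr = 1)
  ref <- list(A = 1.2, S = 0.8)
  expect_equal(k_B_eff(0, cp, sp, ref$S), 0)
  expect_equal(k_B_eff(ref$S, cp, sp, ref$S), 2)
  expect_equal(kappa_eff(0, cp, sp, ref$A), 0.5)
  expect_equal(kappa_eff(ref$A, cp, sp, ref$A), 1)  # 2 * kappa_B
  # strict monotonicity on random fields (any positive s_act / s_thr)
  set.seed(42)
  S <- sort(runif(50, 0.01, 3)); A <- sort(runif(50, 0, 3))
  cp2 <- coupling_params(s_act = 0.1, s_thr = 12)
  expect_true(all(diff(k_B_eff(S, cp2, sp, ref$S)) > 0))
  expect_true(all(diff(kappa_eff(A, cp2, sp, ref$A)) > 0))
  # stripe-only variant: both gates constant
  cpo <- coupling_params(variant = "stripe_only")
  expect_equal(unique(k_B_eff(S, cpo, sp, ref$S)), sp$k_B)
  expect_equal(unique(kappa_eff(A, cpo, sp, ref$A)), sp$kappa_B)
})

test_that("variant reduction: zero coupling with (A,S) at steady state equals bare stripe rates", {
  g <- fix_grid(16, 12); m <- fix_rect_masks(g, W = 8, L = 10)
  sp <- stripe_params()
  cp0 <- coupling_params(s_act = 0, s_thr = 0)
  cpo <- coupling_params(variant = "stripe_only")
  ss <- homogeneous_steady_state(dot_params(), sp, cp0)
  set.seed(7)
  B <- matrix(runif(16 * 12, 0.1, 2), 16, 12)
  I <- matrix(runif(16 * 12, 0.1, 2), 16, 12)
  A <- matrix(ss$A, 16, 12); S <- matrix(ss$S, 16, 12)
  r_coupled <- stripe_rates(B, I, A, S, sp, cp0, m, ref = list(A = ss$A, S = ss$S))
  r_bare <- stripe_rates(B, I, A, S, sp, cpo, m)
  expect_identical(r_coupled$dB, r_bare$dB)
  expect_identical(r_coupled$dI, r_bare$dI)
})

test_that("dot dispersion: diffusivity rescaling shifts the peak as k_max ~ 1/sqrt(D)", {
  p1 <- dot_params(D_A = 1, D_S = 20)
  p4 <- dot_params(D_A = 4, D_S = 80)
  l1 <- dot_linear_stability(p1); l4 <- dot_linear_stability(p4)
  expect_true(l1$turing); expect_true(l4$turing)
  expect_equal(l4$lambda_pred / l1$lambda_pred, 2, tolerance = 0.01)
  expect_equal(l4$sigma_max, l1$sigma_max, tolerance = 1e-6)
})

test_that("equal diffusivities admit no Turing instability; k = 0 recovers well-mixed stability", {
  # D_A = D_S is disallowed by construction; approach it from below
  p <- dot_params(D_A = 5, D_S = 5.0001)
  l <- dot_linear_stability(p)
  expect_lte(l$sigma_max, 0)
  # growth rate at k = 0 equals the largest real eigenvalue of the Jacobian
  p2 <- dot_params()
  l2 <- dot_linear_stability(p2)
  eig <- eigen(l2$jacobian)$values
  expect_equal(l2$sigma[1], max(Re(eig)), tolerance = 1e-12)
})
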
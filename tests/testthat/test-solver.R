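# Spectral steps, reaction steps, initialisation and the simulation loop.

test_that("implicit diffusion is exact on discrete Neumann cosine eigenmodes", {
  # 1-D mode cos(pi*m*(i+1/2)/N), N = 4, m = 1, embedded in a 4 x 8 grid
  g <- grid_spec(8, 8, h = 1)   # minimum grid size; use mode along x
  N <- g$nx; m <- 1
  lam <- (2 / g$h^2) * (1 - cos(pi * m / N))
  mode <- cos(pi * m * ((1:N) - 0.5) / N)
  f <- matrix(mode, g$nx, g$ny)
  out <- implicit_diffusion_step(f, D = 1, dt = 1, g)
  expect_equal(out, f / (1 + lam), tolerance = 1e-10)
  # the N = 4, m = 1 eigenvalue algebra: lambda = 0.5858, factor 0.6306
  lam4 <- (2) * (1 - cos(pi / 4))
  expect_equal(lam4, 0.5858, tolerance = 1e-4)
  expect_equal(1 / (1 + lam4), 0.6306, tolerance = 1e-4)
  mode4 <- cos(pi * 1 * ((1:4) - 0.5) / 4)
  # verify against an explicit dense solve of (I - dt D L) u_new = u_old
  L <- matrix(0, 4, 4)
  for (i in 1:4) {
    if (i > 1) { L[i, i - 1] <- 1; L[i, i] <- L[i, i] - 1 }
    if (i < 4) { L[i, i + 1] <- 1; L[i, i] <- L[i, i] - 1 }
  }
  dense <- solve(diag(4) - L, mode4)
  expect_equal(dense, mode4 / (1 + lam4), tolerance = 1e-10)
})

test_that("diffusion preserves uniform fields and the field total", {
  g <- grid_spec(16, 12, h = 0.5)
  u <- matrix(3.7, g$nx, g$ny)
  expect_equal(implicit_diffusion_step(u, 2, 0.3, g), u, tolerance = 1e-12)
  set.seed(11)
  r <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  out <- implicit_diffusion_step(r, 5, 0.7, g)
  expect_equal(sum(out), sum(r), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(out, r)))
})

test_that("SH linear step: uniform decay 1/(1+dt), band-centre mode untouched, linear", {
  g <- grid_spec(16, 16, h = 1)
  u <- matrix(2, g$nx, g$ny)
  expect_equal(implicit_sh_linear_step(u, ell = 1.5, dt = 1, g), u / 2,
               tolerance = 1e-12)
  # eigenmode whose discrete eigenvalue hits the band centre: ell^2 lam = 1
  m <- 3; lam <- 2 * (1 - cos(pi * m / g$nx))
  ell <- 1 / sqrt(lam)
  mode <- matrix(cos(pi * m * ((1:g$nx) - 0.5) / g$nx), g$nx, g$ny)
  expect_equal(implicit_sh_linear_step(mode, ell, dt = 5, g), mode,
               tolerance = 1e-10)
  set.seed(2)
  r <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  expect_equal(implicit_sh_linear_step(3 * r, 1.2, 0.4, g),
               3 * implicit_sh_linear_step(r, 1.2, 0.4, g), tolerance = 1e-12)
})

test_that("explicit reaction step: identity on zero rates, clipping, first-order accuracy", {
  f <- list(A = matrix(1.5, 4, 4))
  expect_identical(explicit_reaction_step(f, list(A = matrix(0, 4, 4)), 0.1)$A,
                   f$A)
  clipped <- explicit_reaction_step(f, list(A = matrix(-100, 4, 4)), 0.1,
                                    clip_negative = TRUE)
  expect_true(all(clipped$A == 0))
  # Richardson check on du/dt = -u + sin(u): halving dt halves the error
  step_to <- function(dt, nsteps) {
    u <- list(x = matrix(0.8, 2, 2))
    for (i in seq_len(nsteps))
      u <- explicit_reaction_step(u, list(x = -u$x + sin(u$x)), dt,
                                  clip_negative = FALSE)
    u$x[1, 1]
  }
  ref <- step_to(1e-4, 20000)      # tight-dt reference at t = 2
  e1 <- abs(step_to(0.02, 100) - ref)
  e2 <- abs(step_to(0.01, 200) - ref)
  expect_equal(e1 / e2, 2, tolerance = 0.15)
})

test_that("initialisation is seeded and homogeneous at zero noise", {
  g <- fix_grid()
  ss <- list(A = 1.05, S = 0.9, B = 1.2, I = 0.7)
  f0 <- initialize_state("dotstripe", g, ss, noise_amp = 0)
  for (nm in names(ss)) expect_equal(unique(as.vector(f0[[nm]])), ss[[nm]])
  set.seed(5); f1 <- initialize_state("dotstripe", g, ss, 0.02)
  set.seed(5); f2 <- initialize_state("dotstripe", g, ss, 0.02)
  set.seed(6); f3 <- initialize_state("dotstripe", g, ss, 0.02)
  expect_identical(f1, f2)
  expect_false(identical(f1$A, f3$A))
})

test_that("a pure-diffusion run conserves the field total over 1000 steps", {
  g <- grid_spec(48, 24, h = 1)
  ops <- grid_operators(g)
  set.seed(9)
  u <- matrix(runif(48 * 24, 0, 2), 48, 24)
  total0 <- sum(u)
  for (i in 1:1000) u <- implicit_diffusion_step(u, D = 3, dt = 0.1, g, ops)
  expect_equal(sum(u), total0, tolerance = 1e-8)
  # and has relaxed far towards the uniform state (the slowest grid mode
  # decays by 1/(1 + dt D lambda_1) per step)
  expect_lt(stats::sd(u), 0.01)
})

test_that("identical config and seed give bit-identical trajectories", {
  cfg <- preset("fig1F_wildtype", seed = 123)
  cfg$schedule$T <- 40; cfg$schedule$T_i <- 10
  r1 <- simulate_pattern(cfg)
  r2 <- simulate_pattern(cfg)
  expect_identical(r1$final$fields, r2$final$fields)
  expect_identical(r1$times, r2$times)
  cfg$solver$seed <- 124L
  r3 <- simulate_pattern(cfg)
  expect_false(identical(r1$final$fields$A, r3$final$fields$A))
})

test_that("committed bins stay frozen while the active zone evolves", {
  cfg <- preset("fig2C_committed", seed = 2)
  cfg$schedule$T <- 150; cfg$schedule$T_i <- 30
  run <- simulate_pattern(cfg)
  snaps <- run$snapshots
  last <- snaps[[length(snaps)]]
  cm <- last$masks$committed > 0
  expect_gt(sum(cm), 0)
  # bins committed in an earlier snapshot (after the settling period, when
  # freezing engages) hold their values to the end
  for (si in seq_along(snaps)) {
    if (snaps[[si]]$t <= run$schedule$T_i) next
    cm_i <- snaps[[si]]$masks$committed > 0
    both <- cm_i & cm
    if (sum(both) > 0 && si < length(snaps)) {
      expect_identical(snaps[[si]]$fields$A[both], last$fields$A[both])
    }
  }
  # while active-zone values do change between snapshots
  act <- last$masks$omega > 0 & !cm
  expect_false(identical(snaps[[1]]$fields$A[act], last$fields$A[act]))
})
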
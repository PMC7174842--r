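# Pattern quantification: maxima, wavelength, orientation, joints,
# classification, Voronoi agreement.

test_that("dot maxima: single bump, flat field, twin bumps", {
  masks <- fix_full_masks(48, 32)
  one <- fix_bumps(48, 32, cbind(24, 16), width = 2)
  p1 <- find_dot_maxima(one, masks)
  expect_equal(nrow(p1), 1)
  expect_equal(unlist(p1[1, c("x", "y")]), c(x = 24, y = 16))
  expect_equal(nrow(find_dot_maxima(matrix(1, 48, 32), masks)), 0)
  two <- fix_bumps(48, 32, cbind(c(14, 24), c(16, 16)), width = 2)
  p2 <- find_dot_maxima(two, masks)
  expect_equal(nrow(p2), 2)
  expect_true(all(abs(sort(p2$x) - c(14, 24)) <= 1))
})

test_that("wavelength estimation recovers a planted period and rejects noise", {
  masks <- fix_full_masks(128, 128)
  f <- matrix(cos(2 * pi * (1:128) / 8), 128, 128)
  wl <- estimate_wavelength(f, masks)
  expect_gt(wl, 7.5); expect_lt(wl, 8.5)
  # amplitude invariance
  expect_equal(estimate_wavelength(5 * f, masks), wl)
  expect_equal(estimate_wavelength(f + 3, masks), wl)
  set.seed(1)
  noise <- matrix(rnorm(128 * 128), 128, 128)
  expect_error(estimate_wavelength(noise, masks), "no dominant scale")
})

test_that("orientation: transverse, longitudinal and oblique band fixtures", {
  masks <- fix_full_masks(96, 96)
  X <- matrix(1:96, 96, 96); Y <- t(X)
  transverse <- cos(2 * pi * X / 10)   # varies along x: ridges along y
  expect_equal(dominant_orientation(transverse, masks), 90, tolerance = 0.03)
  longitudinal <- cos(2 * pi * Y / 10)
  expect_lt(dominant_orientation(longitudinal, masks), 2)
  oblique <- cos(2 * pi * (X + Y) / 14)
  expect_equal(dominant_orientation(oblique, masks), 45, tolerance = 0.08)
  expect_error(dominant_orientation(matrix(1, 96, 96), masks),
               "no dominant orientation")
})

test_that("transverse joint counting requires bands to span the midline", {
  g <- grid_spec(64, 24, h = 1)
  geom <- digit_geometry(L0 = 50, L = 50, W = 12, eps = 0)
  m <- build_digit_mask(geom, g, current_length = 50)
  f <- matrix(0, 64, 24)
  yc_bins <- round(m$yc)  # midline row
  for (x0 in c(12, 24)) f[x0 + (-1:1), (yc_bins - 5):(yc_bins + 5)] <- 1  # full bands
  f[40 + (-1:1), (yc_bins + 2):(yc_bins + 5)] <- 1                        # half blob
  f <- f * m$omega
  jc <- count_transverse_joints(f, m, width = 12, grid = g)
  expect_equal(as.integer(jc), 2)
  expect_equal(length(attr(jc, "positions")), 2)
  expect_equal(as.integer(count_transverse_joints(matrix(1, 64, 24), m,
                                                  width = 12, grid = g)), 0)
})

test_that("classification separates dots, holes, stripes and lattices", {
  masks <- fix_full_masks(64, 64)
  ctr <- as.matrix(expand.grid(seq(8, 56, 12), seq(8, 56, 12)))
  dots_f <- fix_bumps(64, 64, ctr, width = 2)
  expect_equal(classify_pattern(dots_f, masks), "dots")
  expect_equal(classify_pattern(-dots_f, masks), "holes")
  bands <- matrix(sin(2 * pi * (1:64) / 10), 64, 64)
  expect_equal(classify_pattern(bands, masks), "stripes")
  # lattice: paint the Voronoi edges of a jittered grid (its Euler
  # characteristic is 1 - n_cells < 0: a connected net with many holes)
  set.seed(1)
  pts <- ctr + matrix(runif(nrow(ctr) * 2, -2, 2), ncol = 2)
  lab <- matrix(0L, 64, 64)
  for (i in 1:64) for (j in 1:64)
    lab[i, j] <- which.min((pts[, 1] - i)^2 + (pts[, 2] - j)^2)
  edge <- matrix(0, 64, 64)
  edge[-1, ][lab[-1, ] != lab[-64, ]] <- 1
  edge[, -1][lab[, -1] != lab[, -64]] <- 1
  expect_equal(classify_pattern(edge, masks), "lattice")
  # metrics are invariant to affine rescaling of the field
  expect_equal(classify_pattern(3 * dots_f + 10, masks), "dots")
})

test_that("voronoi agreement: exact edge painting scores ~0, half-cell shift ~0.5", {
  n <- 60
  pts <- as.matrix(expand.grid(seq(5, 55, 10), seq(5, 55, 10)))
  colnames(pts) <- c("x", "y")
  masks <- fix_full_masks(n, n)
  # rasterised Voronoi edges of the exact lattice
  lab <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n)
    lab[i, j] <- which.min((pts[, 1] - (i - 0.5))^2 + (pts[, 2] - (j - 0.5))^2)
  edge <- matrix(0, n, n)
  edge[-1, ][lab[-1, ] != lab[-n, ]] <- 1
  edge[, -1][lab[, -1] != lab[, -n]] <- 1
  edge[-n, ][lab[-n, ] != lab[-1, ]] <- 1
  edge[, -n][lab[, -n] != lab[, -1]] <- 1
  sc <- voronoi_agreement(pts, edge, masks, wavelength = 10)
  expect_lt(sc, 0.02)
  # shifting the painted edges by half a cell: oracle = direct distance of
  # each painted bin to the true (continuous) edge lines of the lattice;
  # on a square grid the cross-lines cap the median at about a quarter cell
  shifted <- edge[c((n - 4):n, 1:(n - 5)), c((n - 4):n, 1:(n - 5))]
  idx <- which(shifted > 0, arr.ind = TRUE)
  cx <- idx[, 1] - 0.5; cy <- idx[, 2] - 0.5
  dline <- function(z) abs((z %% 10) - 0)   # vertical/horizontal edges at 0 mod 10
  dmin <- pmin(pmin(dline(cx), 10 - dline(cx)), pmin(dline(cy), 10 - dline(cy)))
  oracle <- stats::median(dmin) / 10
  sc2 <- voronoi_agreement(pts, shifted, masks, wavelength = 10)
  expect_equal(sc2, oracle, tolerance = 0.4)
  expect_gt(sc2, 0.15)
  # collinear points are rejected
  collinear <- cbind(x = c(10, 20, 30), y = c(10, 10, 10))
  expect_error(voronoi_agreement(collinear, edge, masks, 10), "collinear")
})

test_that("band curvature distinguishes straight bands from bowed arcs", {
  g <- grid_spec(64, 32, h = 1)
  geom <- digit_geometry(L0 = 50, L = 50, W = 20, eps = 0)
  m <- build_digit_mask(geom, g, current_length = 50)
  straight <- matrix(0, 64, 32)
  straight[20 + (-1:1), 8:24] <- 1
  arc <- matrix(0, 64, 32)
  for (j in 8:24) {
    xo <- 20 + round(6 * sin(pi * (j - 8) / 16))
    arc[xo + (-1:1), j] <- 1
  }
  cs <- mean_band_curvature(straight * m$omega, m)
  ca <- mean_band_curvature(arc * m$omega, m)
  expect_lt(cs, 0.02)
  expect_gt(ca, 3 * cs)
})
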
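# Shared fixtures: small grids, simple masks, painted fields, and a cache of
# preset runs so expensive simulations are shared across test files.

fix_grid <- function(nx = 32, ny = 24, h = 1) grid_spec(nx, ny, h)

# rectangle-only digit filling most of a small grid
fix_rect_masks <- function(grid = fix_grid(), W = 12, L = 20, eps = 0) {
  geom <- digit_geometry(L0 = L, L = L, W = W, eps = eps)
  build_digit_mask(geom, grid, current_length = L)
}

# full-grid "masks" (everything inside) for analysis fixtures
fix_full_masks <- function(nx, ny) {
  list(omega = matrix(1, nx, ny), committed = matrix(0, nx, ny),
       crescent = matrix(0, nx, ny), yc = ny / 2, x0 = 0,
       current_length = nx)
}

# sum of isotropic Gaussian bumps at given centres (bin-index coordinates)
fix_bumps <- function(nx, ny, centers, width = 2, amp = 1) {
  f <- matrix(0, nx, ny)
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    f <- f + amp * exp(-((X - centers[k, 1])^2 + (Y - centers[k, 2])^2) /
                         (2 * width^2))
  }
  f
}

# run cache: presets simulated once per session, shared by test files
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(name, seed = 1, mutate = NULL) {
  key <- paste0(name, "_", seed, "_",
                if (is.null(mutate)) "" else digest_cfg(mutate))
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cfg <- preset(name, seed = seed)
  if (!is.null(mutate)) cfg <- utils::modifyList(cfg, mutate)
  run <- simulate_pattern(cfg)
  .run_cache[[key]] <- run
  run
}
digest_cfg <- function(x) {
  paste(unlist(x), collapse = "_")
}
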
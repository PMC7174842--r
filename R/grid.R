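# Discretized domain, digit mask and growth.
#
# All fields live on a single regular grid of square bins; a digit is a
# rectangle capped by half-ellipses, encoded as a binary mask Omega that can
# advance distally over time.

#' Define the simulation grid
#'
#' The domain is a rectangle of `nx` by `ny` square bins of edge length `h`.
#' Fields are stored as `nx` x `ny` matrices; the first index runs along the
#' digit (proximo-distal) axis, the second across it.
#'
#' @param nx,ny Number of bins along and across the digit axis (>= 8).
#' @param h Bin edge length (arbitrary length units, > 0).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(128, 40)
#' @export
grid_spec <- function(nx, ny, h = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("grid must be at least 8 bins in each direction")
  if (!is.numeric(h) || h <= 0) stop("bin size h must be positive")
  structure(list(nx = nx, ny = ny, h = h), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d bins, h = %g (extent %g x %g)\n",
              x$nx, x$ny, x$h, x$nx * x$h, x$ny * x$h))
  invisible(x)
}

# bin-centre coordinates
grid_centers <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$h,
       y = (seq_len(grid$ny) - 0.5) * grid$h)
}

#' Describe a digit shape
#'
#' A digit is a rectangle of length L (growing from L0) and width W, rounded
#' at both ends by half-ellipses of along-axis extent `eps` and width W. The
#' caps are appended to the rectangle, so the full extent is `L + 2*eps`. The
#' proximal rectangle edge sits at `anchor` along the axis and never moves;
#' growth advances the distal end. The digit is centred across the axis at
#' `center`.
#'
#' @param L0 Initial rectangle length (0 < L0 <= L).
#' @param L Final rectangle length.
#' @param W Digit width (> 0).
#' @param eps Half-ellipse cap length (>= 0). Default `W/4`.
#' @param anchor Along-axis coordinate of the proximal rectangle edge.
#'   Default `eps + 2*h` at mask-build time (two-bin proximal margin).
#' @param center Across-axis coordinate of the digit midline. Default: the
#'   grid midline.
#' @return An object of class `digit_geometry`.
#' @export
digit_geometry <- function(L0, L, W, eps = W / 4, anchor = NULL, center = NULL) {
  if (L0 <= 0 || L0 > L) stop("need 0 < L0 <= L")
  if (W <= 0) stop("width W must be positive")
  if (eps < 0) stop("cap length eps must be non-negative")
  structure(list(L0 = L0, L = L, W = W, eps = eps,
                 anchor = anchor, center = center),
            class = "digit_geometry")
}

#' @export
print.digit_geometry <- function(x, ...) {
  cat(sprintf("<digit_geometry> L0 = %g, L = %g, W = %g, eps = %g\n",
              x$L0, x$L, x$W, x$eps))
  invisible(x)
}

#' Define a growth schedule
#'
#' Rectangle length varies piecewise linearly in time: constant at L0 up to
#' the settling time `T_i`, then linear from L0 to L at time `T`. In `tip`
#' mode all elongation happens at the distal tip; in `tip_and_stretch` mode a
#' fraction `stretch_ratio` of each length increment is realised by uniformly
#' stretching the existing digit and the rest by tip extension. `static`
#' keeps the digit at its final length L throughout.
#'
#' @param mode One of "static", "tip", "tip_and_stretch".
#' @param T Total simulated time.
#' @param T_i Settling time before growth starts (0 <= T_i < T).
#' @param stretch_ratio Fraction of growth realised by uniform stretching
#'   (`tip_and_stretch` only), in \[0, 1\].
#' @return An object of class `growth_schedule`.
#' @export
growth_schedule <- function(mode = c("static", "tip", "tip_and_stretch"),
                            T = 100, T_i = 0, stretch_ratio = 0.5) {
  mode <- match.arg(mode)
  if (T_i < 0 || T_i >= T) stop("need 0 <= T_i < T")
  if (stretch_ratio < 0 || stretch_ratio > 1) stop("stretch_ratio must lie in [0,1]")
  structure(list(mode = mode, T = T, T_i = T_i, stretch_ratio = stretch_ratio),
            class = "growth_schedule")
}

#' Rectangle length at a given time
#'
#' @param sched A [growth_schedule()].
#' @param geom A [digit_geometry()].
#' @param t Time in \[0, T\].
#' @return Length of the digit rectangle at time `t` (static mode: always L).
#' @export
digit_length_at <- function(sched, geom, t) {
  if (sched$mode == "static") return(geom$L)
  if (t <= sched$T_i) return(geom$L0)
  frac <- min(1, (t - sched$T_i) / (sched$T - sched$T_i))
  geom$L0 + frac * (geom$L - geom$L0)
}

# resolved anchor / centre with defaults
digit_frame <- function(geom, grid) {
  x0 <- if (is.null(geom$anchor)) geom$eps + 2 * grid$h else geom$anchor
  yc <- if (is.null(geom$center)) grid$ny * grid$h / 2 else geom$center
  list(x0 = x0, yc = yc)
}

#' Build the binary digit mask
#'
#' A bin belongs to the digit iff its centre lies inside the continuous
#' stadium-like shape: the rectangle `current_length` x W plus the two
#' half-ellipse caps. Also returns (empty) committed and crescent masks; see
#' [build_committed_mask()] and [build_crescent_mask()].
#'
#' @param geom A [digit_geometry()].
#' @param grid A [grid_spec()].
#' @param current_length Current rectangle length, in \[L0, L\].
#' @return An object of class `domain_masks`: list of 0/1 matrices `omega`,
#'   `committed`, `crescent`, plus the resolved frame.
#' @export
build_digit_mask <- function(geom, grid, current_length = geom$L) {
  fr <- digit_frame(geom, grid)
  x0 <- fr$x0; yc <- fr$yc
  Lc <- current_length; W2 <- geom$W / 2; eps <- geom$eps
  xmax <- x0 + Lc + eps
  if (x0 - eps < 0)
    stop("digit exceeds grid: proximal cap extends to ", x0 - eps, " < 0")
  if (xmax > grid$nx * grid$h - 2 * grid$h)
    stop("digit exceeds grid: distal extent ", xmax,
         " leaves < 2-bin margin at nx*h = ", grid$nx * grid$h)
  if (yc - W2 < 2 * grid$h || yc + W2 > grid$ny * grid$h - 2 * grid$h)
    stop("digit exceeds grid: width leaves < 2-bin lateral margin")

  ctr <- grid_centers(grid)
  X <- matrix(ctr$x, grid$nx, grid$ny)
  Y <- matrix(ctr$y, grid$nx, grid$ny, byrow = TRUE)

  inside <- (X >= x0 & X <= x0 + Lc & abs(Y - yc) <= W2)
  if (eps > 0) {
    # proximal cap, centred on the proximal rectangle edge
    prox <- X < x0 & ((X - x0) / eps)^2 + ((Y - yc) / W2)^2 <= 1
    dist <- X > x0 + Lc & ((X - (x0 + Lc)) / eps)^2 + ((Y - yc) / W2)^2 <= 1
    inside <- inside | prox | dist
  }
  empty <- matrix(0, grid$nx, grid$ny)
  structure(list(omega = inside + 0, committed = empty, crescent = empty,
                 x0 = x0, yc = yc, current_length = Lc),
            class = "domain_masks")
}

#' @export
print.domain_masks <- function(x, ...) {
  cat(sprintf("<domain_masks> |omega| = %d, |committed| = %d, |crescent| = %d bins (rect length %g)\n",
              sum(x$omega), sum(x$committed), sum(x$crescent), x$current_length))
  invisible(x)
}

#' Advance the digit geometry to time t
#'
#' Rebuilds the digit mask at the schedule's length for time `t`, rounded to
#' the bin resolution. In `tip` (and `tip_and_stretch`) mode the proximal end
#' is fixed and the distal cap advances, so the mask only gains bins over
#' time.
#'
#' @inheritParams build_digit_mask
#' @param sched A [growth_schedule()].
#' @param t Time in \[0, T\].
#' @return A `domain_masks` object at the new length.
#' @export
advance_geometry <- function(geom, sched, t, grid) {
  len <- digit_length_at(sched, geom, t)
  len <- round(len / grid$h) * grid$h
  build_digit_mask(geom, grid, current_length = len)
}

#' Mark the committed (frozen) proximal zone
#'
#' Bins whose along-axis distance from the distal-most digit column exceeds
#' `L_P` are committed: their state is frozen, but they still influence the
#' active zone by diffusion. Distance is measured along the axis (not
#' Euclidean) with strict inequality, so `L_P = 0` commits everything except
#' the distal tip column.
#'
#' @param masks A `domain_masks` object.
#' @param grid A [grid_spec()].
#' @param L_P Commitment distance from the distal end (>= 0; `Inf` disables).
#' @return The masks with `committed` filled in.
#' @export
build_committed_mask <- function(masks, grid, L_P) {
  if (L_P < 0) stop("L_P must be non-negative")
  om <- masks$omega
  masks$committed <- matrix(0, nrow(om), ncol(om))
  if (is.finite(L_P) && any(om > 0)) {
    xc <- grid_centers(grid)$x
    tip <- max(xc[rowSums(om) > 0])
    far <- (tip - xc) > L_P
    masks$committed <- om * matrix(far + 0, nrow(om), ncol(om))
  }
  masks
}

#' Mark the digital-crescent strip at the distal cap
#'
#' The crescent is the layer of inside bins lying within `thickness` of the
#' outer boundary, restricted to the distal cap region (beyond the rectangle
#' end). It hosts extra production of A and repression of B.
#'
#' @param masks A `domain_masks` object.
#' @param geom A [digit_geometry()].
#' @param grid A [grid_spec()].
#' @param thickness Strip thickness (0 disables; must be < W/2).
#' @return The masks with `crescent` filled in.
#' @export
build_crescent_mask <- function(masks, geom, grid, thickness) {
  om <- masks$omega
  masks$crescent <- matrix(0, nrow(om), ncol(om))
  if (thickness <= 0) return(masks)
  if (thickness >= geom$W / 2) stop("crescent thickness must be < W/2")
  # distance (in bins) from each inside bin to the nearest outside bin
  dmap <- EBImage::distmap(om)
  xc <- grid_centers(grid)$x
  distal <- matrix(xc > masks$x0 + masks$current_length, nrow(om), ncol(om))
  masks$crescent <- (om > 0 & distal & dmap * grid$h <= thickness + 1e-9) + 0
  masks
}

#' Uniformly stretch the digit and its fields along the axis
#'
#' Resamples each field along the digit axis by linear interpolation about
#' the proximal anchor with the given factor, rebuilds the mask at the
#' stretched rectangle length, and leaves values outside the digit untouched
#' except where newly covered.
#'
#' @param fields Named list of field matrices.
#' @param masks Current `domain_masks`.
#' @param geom,grid Geometry and grid.
#' @param factor Stretch factor (>= 1).
#' @return List with elements `fields` and `masks`.
#' @export
stretch_uniform <- function(fields, masks, geom, grid, factor) {
  if (factor < 1) stop("stretch factor must be >= 1")
  if (factor == 1) return(list(fields = fields, masks = masks))
  new_len <- masks$current_length * factor
  new_masks <- build_digit_mask(geom, grid, current_length = new_len)
  xc <- grid_centers(grid)$x
  x0 <- masks$x0
  # source coordinate for each target bin centre beyond the anchor
  src <- x0 + (xc - x0) / factor
  tgt <- which(xc >= x0)
  out <- fields
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stretched <- f
    for (j in seq_len(ncol(f))) {
      stretched[tgt, j] <- stats::approx(xc, f[, j], xout = src[tgt],
                                         rule = 2)$y
    }
    # only bins covered by the stretched digit take resampled values
    take <- new_masks$omega > 0
    f[take] <- stretched[take]
    out[[nm]] <- f
  }
  list(fields = out, masks = new_masks)
}

#' Export a mask as a 0/1 CSV matrix
#'
#' @param mask A 0/1 matrix (e.g. `masks$omega`).
#' @param path Output file path.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.table(mask, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
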
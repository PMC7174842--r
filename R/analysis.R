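# Pattern quantification: dot maxima, wavelength, orientation, joint
# counting, Voronoi agreement, pattern classification, and the clamp
# experiments that probe how the stripe subsystem responds to imposed dot
# fields.

# --- small image helpers -----------------------------------------------------

# shift a matrix by (di, dj), padding with `fill`
shift_mat <- function(M, di, dj, fill = -Inf) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(fill, n, m)
  si <- max(1, 1 - di):min(n, n - di)
  sj <- max(1, 1 - dj):min(m, m - dj)
  out[si + di, sj + dj] <- M[si, sj]
  out
}

# 3x3 box smoothing with replicated edges, applied `times` times
smooth3x3 <- function(M, times = 1) {
  for (r in seq_len(times)) {
    acc <- M * 0; cnt <- M * 0
    for (di in -1:1) for (dj in -1:1) {
      s <- shift_mat(M, di, dj, fill = NA)
      ok <- !is.na(s); s[!ok] <- 0
      acc <- acc + s; cnt <- cnt + ok
    }
    M <- acc / cnt
  }
  M
}

# connected-component labelling (EBImage, direct-neighbour connectivity)
label_components <- function(mask) {
  l <- EBImage::bwlabel(mask * 1)
  array(as.numeric(l), dim = dim(mask))
}

# squared-distance matrix between two 2-column coordinate sets
pdist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

component_stats <- function(lab, min_bins = 4) {
  ids <- setdiff(unique(as.vector(lab)), 0)
  out <- list()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_bins) next
    cv <- stats::cov(idx * 1)
    ed <- eigen(cv, symmetric = TRUE)
    ev <- pmax(ed$values, 1e-9)
    # principal-axis direction relative to the x axis, folded into [0, 90]
    ang <- abs(atan2(ed$vectors[2, 1], ed$vectors[1, 1]) * 180 / pi) %% 180
    if (ang > 90) ang <- 180 - ang
    out[[length(out) + 1L]] <- list(id = id, n = nrow(idx),
                                    x = mean(idx[, 1]), y = mean(idx[, 2]),
                                    imin = min(idx[, 1]), imax = max(idx[, 1]),
                                    jmin = min(idx[, 2]), jmax = max(idx[, 2]),
                                    elongation = sqrt(ev[1] / ev[2]),
                                    roundness = sqrt(ev[2] / ev[1]),
                                    angle = ang)
  }
  out
}

# --- dot maxima --------------------------------------------------------------

#' Locate dot maxima in a field
#'
#' Finds local maxima (8-neighbourhood) inside the digit whose prominence —
#' height above the minimum of a square window of radius `window` bins —
#' exceeds `min_prominence`. Plateau ties are merged and resolved to the
#' centroid bin.
#'
#' @param field Field matrix.
#' @param masks A `domain_masks` object.
#' @param min_prominence Required prominence; default 20% of the field range
#'   inside the digit.
#' @param window Prominence window radius in bins.
#' @param grid Optional [grid_spec()] to report coordinates in length units
#'   (bin indices otherwise).
#' @return Data frame with columns `x`, `y`, `value` (possibly 0 rows).
#' @export
find_dot_maxima <- function(field, masks, min_prominence = NULL, window = 3L,
                            grid = NULL) {
  if (any(!is.finite(field))) stop("field contains non-finite values")
  om <- masks$omega > 0
  if (is.null(min_prominence)) {
    rng <- range(field[om])
    min_prominence <- 0.2 * (rng[2] - rng[1])
  }
  # neighbourhood maximum (excluding centre)
  nb <- matrix(-Inf, nrow(field), ncol(field))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pmax(nb, shift_mat(field, di, dj))
  }
  is_max <- field >= nb & om
  # prominence over the window
  wmin <- field
  for (r in seq_len(window)) {
    lo <- matrix(Inf, nrow(field), ncol(field))
    for (di in -1:1) for (dj in -1:1)
      lo <- pmin(lo, shift_mat(wmin, di, dj, fill = Inf))
    wmin <- lo
  }
  cand <- is_max & (field - wmin) > min_prominence
  if (!any(cand)) return(data.frame(x = numeric(0), y = numeric(0),
                                    value = numeric(0)))
  lab <- label_components(cand)
  ids <- setdiff(unique(as.vector(lab)), 0)
  pts <- t(vapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]),
      max(field[lab == id]))
  }, numeric(3)))
  h <- if (is.null(grid)) 1 else grid$h
  off <- if (is.null(grid)) 0 else -0.5
  data.frame(x = (pts[, 1] + off) * h, y = (pts[, 2] + off) * h,
             value = pts[, 3])
}

# --- wavelength --------------------------------------------------------------

#' Dominant pattern wavelength from the radial power spectrum
#'
#' Windows the mean-subtracted field to the digit, computes the 2-D power
#' spectrum, averages it over rings of constant wavenumber and returns
#' `2*pi/k_peak`. Errors if no ring clearly dominates (flat spectrum).
#'
#' @param field Field matrix.
#' @param masks A `domain_masks` object (or NULL for the full grid).
#' @param grid A [grid_spec()] (for physical units); defaults to h = 1.
#' @param min_peak_ratio Peak must exceed this multiple of the median ring
#'   power.
#' @return Wavelength in length units.
#' @export
estimate_wavelength <- function(field, masks = NULL, grid = NULL,
                                min_peak_ratio = 3) {
  h <- if (is.null(grid)) 1 else grid$h
  nx <- nrow(field); ny <- ncol(field)
  om <- if (is.null(masks)) matrix(1, nx, ny) else masks$omega
  f <- (field - mean(field[om > 0])) * om
  P <- Mod(stats::fft(f))^2
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / (nx * h)
  ky <- 2 * pi * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / (ny * h)
  K <- sqrt(outer(kx^2, ky^2, "+"))
  dk <- 2 * pi / (max(nx, ny) * h)
  ring <- round(K / dk)
  # drop the window-dominated lowest rings
  keep <- ring >= 4 & ring <= round(pi / h / dk) # up to Nyquist
  pw <- tapply(P[keep], ring[keep], mean)
  ks <- as.numeric(names(pw)) * dk
  if (length(pw) < 4) stop("no dominant scale: spectrum support too small")
  i <- which.max(pw)
  if (pw[i] < min_peak_ratio * stats::median(pw))
    stop("no dominant scale: spectrum is flat")
  2 * pi / ks[i]
}

# --- orientation -------------------------------------------------------------

#' Dominant stripe orientation from the structure tensor
#'
#' Averages the gradient structure tensor over the digit interior (boundary
#' bins excluded to avoid mask-edge gradients) and reports the dominant
#' ridge orientation in degrees relative to the digit (x) axis, folded into
#' \[0, 90\]: 90 means transverse stripes, 0 longitudinal. Errors when the
#' tensor is nearly isotropic.
#'
#' @param field Field matrix.
#' @param masks A `domain_masks` object (NULL for full grid).
#' @param min_coherence Required tensor anisotropy, in \[0, 1\].
#' @return Orientation in degrees, in \[0, 90\].
#' @export
dominant_orientation <- function(field, masks = NULL, min_coherence = 0.15) {
  nx <- nrow(field); ny <- ncol(field)
  om <- if (is.null(masks)) matrix(1, nx, ny) else masks$omega
  # interior: at least 2 bins from the mask boundary (or grid edge)
  interior <- if (is.null(masks)) {
    m <- matrix(0, nx, ny); m[3:(nx - 2), 3:(ny - 2)] <- 1; m > 0
  } else EBImage::distmap(om) > 2.5
  gx <- (shift_mat(field, -1, 0, NA) - shift_mat(field, 1, 0, NA)) / 2
  gy <- (shift_mat(field, 0, -1, NA) - shift_mat(field, 0, 1, NA)) / 2
  ok <- interior & is.finite(gx) & is.finite(gy)
  if (sum(ok) < 16) stop("no dominant orientation: too few interior bins")
  Jxx <- sum(gx[ok]^2); Jyy <- sum(gy[ok]^2); Jxy <- sum(gx[ok] * gy[ok])
  coh <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / (Jxx + Jyy + 1e-300)
  if (!is.finite(coh) || coh < min_coherence)
    stop("no dominant orientation: field is isotropic (coherence = ",
         signif(coh, 2), ")")
  phi_grad <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi  # gradient direction
  ang <- phi_grad + 90                                     # ridge direction
  ang <- ang %% 180
  if (ang > 90) ang <- 180 - ang
  ang
}

# --- joint counting ----------------------------------------------------------

#' Count transverse joint bands
#'
#' Thresholds the joint-marker field at its mean plus one standard deviation
#' inside the digit and counts connected components that span the midline,
#' reaching at least `W/6` into each lateral half. The along-axis centroid
#' positions of the counted bands are attached as attribute `positions`.
#'
#' @param stripe_field Joint-marker field matrix.
#' @param masks A `domain_masks` object (provides the midline).
#' @param width Digit width W (sets the required reach into each half; 0
#'   requires only crossing the midline).
#' @param grid Optional [grid_spec()] for physical positions.
#' @param n_sd Threshold offset in standard deviations.
#' @return Integer count with attribute `positions`.
#' @export
count_transverse_joints <- function(stripe_field, masks, width = 0,
                                    grid = NULL, n_sd = 1) {
  h <- if (is.null(grid)) 1 else grid$h
  om <- masks$omega > 0
  v <- stripe_field[om]
  th <- mean(v) + n_sd * stats::sd(v)
  bw <- (stripe_field > th) & om
  if (!any(bw)) return(structure(0L, positions = numeric(0)))
  jc_mid <- masks$yc / h + 0.5   # midline in bin-index units
  reach <- width / 6 / h
  lab <- label_components(bw)
  comps <- component_stats(lab, min_bins = 3)
  pos <- numeric(0)
  for (cc in comps) {
    if (cc$jmin <= jc_mid - reach && cc$jmax >= jc_mid + reach)
      pos <- c(pos, (cc$x - 0.5) * h)
  }
  structure(length(pos), positions = sort(pos))
}

# --- classification ----------------------------------------------------------

# sub-threshold components fully enclosed by the supra-threshold phase:
# connected sets of `!bw` inside the domain with no bin on the domain edge
# (touching outside or the grid boundary) and a deep interior (component
# minimum well below the threshold), so shallow oscillatory skirts around
# isolated peaks do not count as cells
count_enclosed_cells <- function(bw, om, f, depth_floor, min_bins = 6) {
  inside_sub <- (!bw) & om > 0
  lab <- label_components(inside_sub)
  # domain-edge bins: inside bins adjacent to outside (or grid border)
  edge <- (om > 0) & (shift_mat(om, 1, 0, 0) == 0 | shift_mat(om, -1, 0, 0) == 0 |
                        shift_mat(om, 0, 1, 0) == 0 | shift_mat(om, 0, -1, 0) == 0)
  touching <- unique(lab[edge & inside_sub])
  ids <- setdiff(unique(as.vector(lab)), c(0, touching))
  sum(vapply(ids, function(id) {
    sel <- lab == id
    sum(sel) >= min_bins && min(f[sel]) < depth_floor
  }, TRUE))
}

#' Classify a pattern as dots, stripes, holes, lattice or none
#'
#' Decision rule on the skewness of the (smoothed) field inside the domain
#' and the connectivity of its thresholded phases. A supra-median phase that
#' fully encloses four or more interior cells is a network: "lattice" when
#' the field is positively skewed (bright thin walls), "holes" when
#' negatively skewed (dark wells punched into a bright background).
#' Otherwise the phases are split at the mean: a disconnected positive
#' phase on a connected background with positive skew is "dots"; the mirror
#' image is "holes"; balanced phases with several components are "stripes".
#' All thresholds are documented constants.
#'
#' @param field Field matrix.
#' @param masks A `domain_masks` object (NULL for full grid).
#' @param skew_thresh Skewness magnitude for the skew-gated calls.
#' @return One of "dots", "stripes", "holes", "lattice", "none".
#' @export
classify_pattern <- function(field, masks = NULL, skew_thresh = 0.2) {
  om <- if (is.null(masks)) matrix(1, nrow(field), ncol(field)) else masks$omega
  f <- smooth3x3(field, times = 1)
  v <- f[om > 0]
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return("none")
  z <- (f - mean(v)) * om
  skew <- mean(((v - mean(v)) / s)^3)
  # enclosure topology: supra-quantile walls, closed with a 3x3 kernel to
  # bridge sub-resolution gaps; cells must dip 0.7 SD below the threshold
  enclosed <- 0
  for (q in c(0.5, 0.35)) {
    th_q <- stats::quantile(v, q)
    bw <- (f > th_q) & om > 0
    bw <- EBImage::closing(bw * 1, EBImage::makeBrush(3, "box")) > 0 & om > 0
    enclosed <- max(enclosed,
                    count_enclosed_cells(bw, om, f,
                                         depth_floor = th_q - 0.7 * s))
  }
  if (enclosed >= 4 && skew >= skew_thresh) return("lattice")
  if (enclosed >= 4 && skew <= -skew_thresh) return("holes")
  # phase counts at the mean threshold
  pos <- component_stats(label_components(z > 0 & om > 0), min_bins = 4)
  neg <- component_stats(label_components(z < 0 & om > 0), min_bins = 4)
  n_pos <- length(pos); n_neg <- length(neg)
  elong <- mean(vapply(c(pos, neg), function(cc) cc$elongation, 0))
  if (n_pos >= 4 && n_neg <= 2 && skew > skew_thresh) return("dots")
  if (n_neg >= 4 && n_pos <= 2) {
    if (skew < -skew_thresh) return("holes")
    if (skew > skew_thresh) return("lattice")
  }
  if (n_pos >= 2 && n_neg >= 2 && is.finite(elong)) return("stripes")
  if ((n_pos >= 1 || n_neg >= 1) && is.finite(elong) && elong > 2.5)
    return("stripes")
  "none"
}

#' Mean centerline curvature (bow) of joint bands
#'
#' For each supra-threshold band (mean + `n_sd` SD), rotates its bins into
#' the principal frame, slices the band along its major axis, traces the
#' centerline through the slice centroids, and measures how far the
#' centerline bows away from a straight line, relative to the band length.
#' Near 0 for straight bands; large for the crescent- and ring-shaped
#' joints of the dot-hole model. Returns the band-size-weighted mean.
#'
#' @inheritParams count_transverse_joints
#' @param n_slices Number of slices along the band's major axis.
#' @return Mean relative centerline bow (NA when no bands).
#' @export
mean_band_curvature <- function(stripe_field, masks, n_sd = 1, n_slices = 7) {
  om <- masks$omega > 0
  v <- stripe_field[om]
  th <- mean(v) + n_sd * stats::sd(v)
  lab <- label_components((stripe_field > th) & om)
  ids <- setdiff(unique(as.vector(lab)), 0)
  ws <- c(); bows <- c()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE) * 1
    if (nrow(idx) < 8) next
    ctd <- sweep(idx, 2, colMeans(idx))
    ed <- eigen(stats::cov(ctd), symmetric = TRUE)
    rot <- ctd %*% ed$vectors                # column 1: major axis
    len <- diff(range(rot[, 1]))
    if (len < 3) next
    sl <- cut(rot[, 1], breaks = n_slices)
    cen <- tapply(rot[, 2], sl, mean)
    cen <- cen[!is.na(cen)]
    if (length(cen) < 3) next
    # bow: spread of the centerline about its own straight-line fit
    xc <- seq_along(cen)
    resid <- stats::lm.fit(cbind(1, xc), cen)$residuals
    bows <- c(bows, sqrt(mean(resid^2)) / len)
    ws <- c(ws, nrow(idx))
  }
  if (!length(bows)) return(NA_real_)
  sum(ws * bows) / sum(ws)
}

#' Per-band statistics of the supra-threshold joint pattern
#'
#' Thresholds the joint-marker field at mean + `n_sd` SD inside the digit,
#' labels connected components, and reports each band's size, centroid,
#' principal-axis orientation (degrees from the digit axis, in \[0, 90\]),
#' elongation and roundness.
#'
#' @inheritParams count_transverse_joints
#' @param min_bins Smallest component reported.
#' @return Data frame with one row per band.
#' @export
joint_band_stats <- function(stripe_field, masks, n_sd = 1, min_bins = 6) {
  om <- masks$omega > 0
  v <- stripe_field[om]
  th <- mean(v) + n_sd * stats::sd(v)
  comps <- component_stats(label_components((stripe_field > th) & om),
                           min_bins = min_bins)
  if (!length(comps)) {
    return(data.frame(n = integer(0), x = numeric(0), y = numeric(0),
                      angle = numeric(0), elongation = numeric(0),
                      roundness = numeric(0)))
  }
  do.call(rbind, lapply(comps, function(cc)
    data.frame(n = cc$n, x = cc$x, y = cc$y, angle = cc$angle,
               elongation = cc$elongation, roundness = cc$roundness)))
}

# --- Voronoi agreement -------------------------------------------------------

#' Agreement between a stripe pattern and the Voronoi tessellation of dots
#'
#' Labels every inside bin by its nearest dot point, takes the bins where
#' the label changes as the (rasterised) Voronoi edges, extracts stripe
#' ridge bins as the top `ridge_quantile` of the stripe field inside the
#' digit, and scores the agreement symmetrically: the larger of (median
#' distance from ridge bins to the nearest Voronoi edge) and (median
#' distance from Voronoi-edge bins to the nearest ridge bin), divided by
#' the pattern wavelength. Small scores mean the stripes trace the
#' predicted joint lattice and every predicted edge carries stripe
#' material; either direction alone can be fooled (a dense point set puts
#' an edge near every ridge bin).
#'
#' @param dot_points Data frame / matrix with columns x, y (>= 3 points,
#'   not collinear), in the same units as the grid.
#' @param stripe_field Joint-marker field matrix.
#' @param masks A `domain_masks` object.
#' @param wavelength Normalising wavelength (> 0).
#' @param grid Optional [grid_spec()] (defaults h = 1).
#' @param ridge_quantile Ridge extraction quantile.
#' @return Dimensionless agreement score (>= 0).
#' @export
voronoi_agreement <- function(dot_points, stripe_field, masks, wavelength,
                              grid = NULL, ridge_quantile = 0.9) {
  h <- if (is.null(grid)) 1 else grid$h
  pts <- as.matrix(as.data.frame(dot_points)[, c("x", "y")])
  if (nrow(pts) < 3) stop("need at least 3 dot points")
  ctd <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctd)$d
  if (sv[2] < 1e-6 * max(sv[1], 1e-12))
    stop("degenerate dot configuration: points are collinear")
  om <- masks$omega > 0
  idx <- which(om, arr.ind = TRUE)
  coords <- cbind((idx[, 1] - 0.5) * h, (idx[, 2] - 0.5) * h)
  lab_v <- max.col(-pdist2(coords, pts), ties.method = "first")
  lab <- matrix(0L, nrow(stripe_field), ncol(stripe_field))
  lab[idx] <- lab_v
  # both bins flanking a label change are Voronoi-edge bins
  edge <- matrix(FALSE, nrow(lab), ncol(lab))
  for (sh in list(c(1, 0), c(0, 1))) {
    nb <- shift_mat(lab, sh[1], sh[2], fill = NA)
    d <- om & !is.na(nb) & nb > 0 & nb != lab
    edge <- edge | d
    nb2 <- shift_mat(lab, -sh[1], -sh[2], fill = NA)
    edge <- edge | (om & !is.na(nb2) & nb2 > 0 & nb2 != lab)
  }
  if (!any(edge)) stop("degenerate Voronoi diagram: no edges inside domain")
  v <- stripe_field[om]
  th <- stats::quantile(v, ridge_quantile)
  ridge <- which(stripe_field >= th & om, arr.ind = TRUE)
  eidx <- which(edge, arr.ind = TRUE)
  rc <- cbind((ridge[, 1] - 0.5) * h, (ridge[, 2] - 0.5) * h)
  ec <- cbind((eidx[, 1] - 0.5) * h, (eidx[, 2] - 0.5) * h)
  d2 <- pdist2(rc, ec)
  ridge_to_edge <- stats::median(sqrt(apply(d2, 1, min)))
  edge_to_ridge <- stats::median(sqrt(apply(d2, 2, min)))
  max(ridge_to_edge, edge_to_ridge) / wavelength
}

# --- composite metrics -------------------------------------------------------

#' Compute all pattern metrics for a run
#'
#' Applies the analysis suite to a snapshot of a [simulate_pattern()] run:
#' dot maxima (from the configured dot marker, or from the smoothed negated
#' joint marker when the model has no dot field), wavelength, orientation,
#' transverse joint count, Voronoi agreement and pattern class.
#'
#' @param run A `ds_run`.
#' @param snapshot Snapshot index (default: final state).
#' @return Object of class `pattern_metrics`.
#' @export
pattern_metrics <- function(run, snapshot = NULL) {
  snap <- if (is.null(snapshot)) run$final else run$snapshots[[snapshot]]
  acfg <- run$config$analysis
  masks <- snap$masks
  grid <- run$grid
  marker <- snap$fields[[acfg$joint_marker]]
  dotf <- if (acfg$dot_marker == "cells") {
    smooth3x3(-marker, times = 3)
  } else snap$fields[[acfg$dot_marker]]
  wl <- tryCatch(estimate_wavelength(marker, masks, grid), error = function(e) NA_real_)
  wl_dot <- tryCatch(estimate_wavelength(dotf, masks, grid), error = function(e) NA_real_)
  # maxima separated by at least about a third of the dot wavelength
  win <- if (is.finite(wl_dot)) max(3L, as.integer(round(wl_dot / grid$h / 3))) else 3L
  pts <- find_dot_maxima(dotf, masks, min_prominence = acfg$min_prominence,
                         window = win, grid = grid)
  ori <- tryCatch(dominant_orientation(marker, masks), error = function(e) NA_real_)
  jc <- count_transverse_joints(marker, masks, width = run$geometry$W,
                                grid = grid, n_sd = acfg$joint_sd)
  vs <- if (nrow(pts) >= 3 && is.finite(wl_dot)) {
    tryCatch(voronoi_agreement(pts, marker, masks, wl_dot, grid,
                               ridge_quantile = acfg$ridge_quantile),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(dot_points = pts, wavelength = wl, wavelength_dot = wl_dot,
                 orientation_deg = ori, joint_count = as.integer(jc),
                 joint_positions = attr(jc, "positions"),
                 voronoi_score = vs,
                 band_curvature = mean_band_curvature(marker, masks,
                                                      n_sd = acfg$joint_sd),
                 pattern_class = classify_pattern(marker, masks),
                 t = snap$t),
            class = "pattern_metrics")
}

#' @export
print.pattern_metrics <- function(x, ...) {
  cat(sprintf("<pattern_metrics> t = %g: %s; %d joints, %d dots, lambda = %s, orientation = %s\n",
              x$t, x$pattern_class, x$joint_count, nrow(x$dot_points),
              if (is.na(x$wavelength)) "NA" else sprintf("%.2f", x$wavelength),
              if (is.na(x$orientation_deg)) "NA" else sprintf("%.1f", x$orientation_deg)))
  invisible(x)
}

#' One-row data frame of scalar metrics (for sweep tables)
#'
#' @param m A `pattern_metrics`.
#' @return A one-row data frame.
#' @export
metrics_row <- function(m) {
  data.frame(t = m$t, pattern_class = m$pattern_class,
             joint_count = m$joint_count, n_dots = nrow(m$dot_points),
             wavelength = m$wavelength, wavelength_dot = m$wavelength_dot,
             orientation_deg = m$orientation_deg,
             voronoi_score = m$voronoi_score,
             band_curvature = m$band_curvature)
}

# --- clamp experiments -------------------------------------------------------

#' Uniform (A, S) clamp: stripe response amplitude
#'
#' Freezes A and S at spatially uniform values, lets the (B, I) subsystem
#' run from its noisy steady state, and returns the final spatial standard
#' deviation of B inside the domain. The attribute `noise_floor` holds the
#' SD of the initial noise for comparison.
#'
#' @param A_val,S_val Clamped uniform values.
#' @param config Base configuration (e.g. `preset("figS3A_clamp")`).
#' @return Final SD of B inside the digit (attributes `noise_floor`, `run`).
#' @export
clamp_uniform <- function(A_val, S_val, config = preset("figS3A_clamp")) {
  cfg <- resolve_config(config)
  cfg$clamp <- list(A = A_val, S = S_val)
  run <- simulate_pattern(cfg)
  om <- run$final$masks$omega > 0
  amp <- stats::sd(run$final$fields$B[om])
  nf <- cfg$solver$noise_amp * run$steady_state$B / sqrt(3)
  structure(amp, noise_floor = nf, run = run)
}

#' Gradient (A, S) clamp: stripe orientation
#'
#' Freezes a linear (A, S) profile running from dot-centre-like values
#' (A high, S low) to far-from-dot values (A low, S high) along `direction`,
#' lets (B, I) self-organize, and returns the dominant stripe orientation in
#' degrees relative to the gradient direction (90 = perpendicular).
#'
#' @param direction Gradient direction as an angle in degrees from the x
#'   axis (0 or 90 supported) or a unit vector.
#' @param config Base configuration (e.g. `preset("figS3B_gradient")`).
#' @param A_range,S_range Clamp end values c(near-dot, far-from-dot) as
#'   multiples of the steady state.
#' @return Orientation in \[0, 90\] relative to the gradient (attribute
#'   `run`).
#' @export
clamp_gradient <- function(direction = 0, config = preset("figS3B_gradient"),
                           A_range = c(2.5, 0.2), S_range = c(0.2, 1.8)) {
  cfg <- resolve_config(config)
  if (length(direction) == 2) direction <- atan2(direction[2], direction[1]) * 180 / pi
  grid <- do.call(grid_spec, cfg$grid)
  ss <- homogeneous_steady_state(do.call(dot_params, cfg$dot),
                                 do.call(stripe_params, cfg$stripe),
                                 do.call(coupling_params, cfg$coupling))
  ramp1 <- function(n) (seq_len(n) - 1) / (n - 1)
  sfun <- if (abs(direction %% 180) < 45) {
    matrix(ramp1(grid$nx), grid$nx, grid$ny)
  } else {
    matrix(ramp1(grid$ny), grid$nx, grid$ny, byrow = TRUE)
  }
  A <- ss$A * (A_range[1] + (A_range[2] - A_range[1]) * sfun)
  S <- ss$S * (S_range[1] + (S_range[2] - S_range[1]) * sfun)
  cfg$clamp <- list(A = A, S = S)
  run <- simulate_pattern(cfg)
  ori_axis <- dominant_orientation(run$final$fields$B, run$final$masks)
  # orientation relative to the gradient direction, folded into [0, 90]
  rel <- abs(ori_axis - (direction %% 180))
  if (rel > 90) rel <- 180 - rel
  structure(rel, run = run)
}
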
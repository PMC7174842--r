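# Operator-splitting solver on the masked, growing domain.
#
# Each time step: (1) implicit spectral step for the stiff linear operator —
# backward-Euler diffusion in the discrete cosine basis (exact for the
# discrete Neumann Laplacian, hence reflective boundaries), or the analogous
# solve for the Swift-Hohenberg biharmonic operator; (2) forward-Euler
# reaction step with mask-dependent rates; (3) periodic geometry updates;
# (4) committed bins reset to their frozen values (they still feed
# neighbours by diffusion).

# Orthonormal DCT-II matrix for bin-centred samples: row m, column i holds
# cos(pi*m*(i - 1/2)/n), scaled so C %*% t(C) = I. The corresponding discrete
# Neumann-Laplacian eigenvalue of mode m is (2/h^2)(1 - cos(pi*m/n)).
dct_matrix <- function(n) {
  m <- 0:(n - 1)
  C <- cos(pi * outer(m, (1:n) - 0.5) / n)
  C[1, ] <- C[1, ] / sqrt(n)
  C[-1, ] <- C[-1, ] * sqrt(2 / n)
  C
}

#' Precompute spectral operators for a grid
#'
#' Builds the orthonormal DCT-II matrices for both grid directions and the
#' table of discrete Neumann-Laplacian eigenvalues
#' `lambda_m = (2/h^2)(1 - cos(pi m / n))`, used by the implicit steps.
#'
#' @param grid A [grid_spec()].
#' @return List with transform matrices and the eigenvalue matrix `LAM`
#'   (`lambda_mx + lambda_my` for every mode pair).
#' @export
grid_operators <- function(grid) {
  Cx <- dct_matrix(grid$nx)
  Cy <- dct_matrix(grid$ny)
  lam <- function(n) (2 / grid$h^2) * (1 - cos(pi * (0:(n - 1)) / n))
  list(Cx = Cx, tCx = t(Cx), Cy = Cy, tCy = t(Cy),
       LAM = outer(lam(grid$nx), lam(grid$ny), "+"))
}

dct2 <- function(U, ops) ops$Cx %*% U %*% ops$tCy
idct2 <- function(V, ops) ops$tCx %*% V %*% ops$Cy

#' Backward-Euler diffusion step in the cosine basis
#'
#' Solves `(1 - dt D lap_discrete) u_new = u_old` under zero-flux boundaries
#' exactly for the discrete operator: each cosine mode is divided by
#' `1 + dt D lambda_m`. The zero mode is untouched, so the field total is
#' conserved to round-off.
#'
#' @param field Field matrix (nx x ny).
#' @param D Diffusivity.
#' @param dt Time step.
#' @param grid A [grid_spec()].
#' @param ops Optional precomputed [grid_operators()] (recomputed if NULL).
#' @return The diffused field.
#' @export
implicit_diffusion_step <- function(field, D, dt, grid, ops = NULL) {
  if (is.null(ops)) ops <- grid_operators(grid)
  idct2(dct2(field, ops) / (1 + dt * D * ops$LAM), ops)
}

#' Implicit step for the Swift-Hohenberg linear operator
#'
#' Solves `(1 + dt (1 + ell^2 lap)^2) u_new = u_old` in the cosine basis:
#' each mode is divided by `1 + dt (1 - ell^2 lambda_m)^2`. The uniform mode
#' decays by `1/(1 + dt)`; the band-centre mode (`ell^2 lambda = 1`) is
#' untouched.
#'
#' @param field Field matrix.
#' @param ell Swift-Hohenberg length scale.
#' @param dt Time step (divide by tau beforehand for the stripe equation).
#' @inheritParams implicit_diffusion_step
#' @return The filtered field.
#' @export
implicit_sh_linear_step <- function(field, ell, dt, grid, ops = NULL) {
  if (is.null(ops)) ops <- grid_operators(grid)
  idct2(dct2(field, ops) / (1 + dt * (1 - ell^2 * ops$LAM)^2), ops)
}

#' Forward-Euler reaction step
#'
#' Adds `dt` times the reaction rates to each field; optionally clips
#' negative concentrations to zero (four-species model only).
#'
#' @param fields Named list of field matrices.
#' @param rates Named list of rate matrices (names matched to `fields`).
#' @param dt Time step.
#' @param clip_negative Clip fields at zero after the step?
#' @return Updated field list.
#' @export
explicit_reaction_step <- function(fields, rates, dt, clip_negative = TRUE) {
  for (nm in names(rates)) {
    f <- fields[[nm]] + dt * rates[[nm]]
    if (anyNA(f)) stop("reaction step produced NaN in field ", nm)
    if (clip_negative) f[f < 0] <- 0
    fields[[nm]] <- f
  }
  fields
}

#' Initial state: homogeneous steady state plus seeded noise
#'
#' Four-species models start at the homogeneous steady state of the
#' kinetics; Swift-Hohenberg models start at zero. Independent uniform noise
#' of relative amplitude `noise_amp` (absolute, for the sign-indefinite SH
#' fields) is added to every bin, inside and outside alike. The RNG state at
#' call time determines the draw, so a fixed seed gives a bit-identical
#' state.
#'
#' @param model "dotstripe" or "sh".
#' @param grid A [grid_spec()].
#' @param steady Named list of steady-state values (four-species).
#' @param noise_amp Noise amplitude (0 disables).
#' @param species Character vector of species to create.
#' @return Named list of field matrices.
#' @export
initialize_state <- function(model, grid, steady = NULL, noise_amp = 0.02,
                             species = NULL) {
  n <- grid$nx * grid$ny
  if (is.null(species))
    species <- if (model == "sh") c("u", "v") else c("A", "S", "B", "I")
  out <- list()
  for (nm in species) {
    if (model == "sh") {
      base <- 0; amp <- noise_amp
    } else {
      base <- steady[[nm]]
      amp <- noise_amp * base
    }
    noise <- if (noise_amp > 0) stats::runif(n, -amp, amp) else 0
    f <- matrix(base + noise, grid$nx, grid$ny)
    if (model != "sh") f[f < 0] <- 0
    out[[nm]] <- f
  }
  out
}

#' Solver settings
#'
#' @param dt Time step (> 0).
#' @param seed RNG seed for the initial noise.
#' @param noise_amp Initial noise amplitude (relative, four-species;
#'   absolute for SH).
#' @param snapshot_every Record a snapshot every this many steps.
#' @param growth_every Update geometry every this many steps.
#' @param clip_negative Clip negative concentrations (four-species only).
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.1, seed = 1, noise_amp = 0.02,
                          snapshot_every = 200, growth_every = 20,
                          clip_negative = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (snapshot_every < 1 || growth_every < 1)
    stop("snapshot_every and growth_every must be >= 1")
  structure(list(dt = dt, seed = as.integer(seed), noise_amp = noise_amp,
                 snapshot_every = as.integer(snapshot_every),
                 growth_every = as.integer(growth_every),
                 clip_negative = clip_negative),
            class = "solver_config")
}

# species integrated for each model/variant
active_species <- function(model, variant, clamp = NULL) {
  sp <- switch(model,
    sh = c("u", "v"),
    dotstripe = switch(variant,
      full = c("A", "S", "B", "I"),
      stripe_only = c("B", "I"),
      dot_hole = c("A", "S")))
  setdiff(sp, names(clamp))
}

#' Run a dot-stripe or Swift-Hohenberg simulation
#'
#' The main driver. Takes a resolved configuration (see [default_config()],
#' [preset()], [load_config()]) and integrates the chosen model on the
#' masked, possibly growing digit domain. Per step: implicit spectral step
#' for diffusion (each species with its own diffusivity) or the SH operator;
#' forward-Euler reactions with mask-dependent rates; every `growth_every`
#' steps the geometry advances (newly covered bins keep their prior state);
#' committed bins are reset to their frozen values after every step.
#' Deterministic given the seed.
#'
#' @param config A configuration list, as returned by [default_config()] or
#'   [preset()] (possibly modified).
#' @return An object of class `ds_run`: the trajectory (snapshots of fields
#'   and masks at the configured cadence), final state, steady-state
#'   reference, and the resolved configuration.
#' @examples
#' \donttest{
#' run <- simulate_pattern(preset("fig1F_wildtype"))
#' summary(run)
#' }
#' @export
simulate_pattern <- function(config) {
  cfg <- resolve_config(config)
  grid <- do.call(grid_spec, cfg$grid)
  geom <- geometry_from_config(cfg)
  sched <- do.call(growth_schedule, cfg$schedule)
  sol <- do.call(solver_config, cfg$solver)
  ops <- grid_operators(grid)
  model <- if (cfg$model == "sh") "sh" else "dotstripe"
  variant <- cfg$coupling$variant

  dotp <- do.call(dot_params, cfg$dot)
  stripep <- do.call(stripe_params, cfg$stripe)
  coup <- do.call(coupling_params, cfg$coupling)
  shp <- if (model == "sh") do.call(sh_params, cfg$sh) else NULL

  # geometry at t = 0 (full_domain: no digit, the whole grid is inside)
  full_domain <- isTRUE(cfg$geometry$full_domain)
  len0 <- round(digit_length_at(sched, geom, 0) / grid$h) * grid$h
  rebuild_masks <- function(len) {
    if (full_domain) {
      e <- matrix(0, grid$nx, grid$ny)
      return(structure(list(omega = e + 1, committed = e, crescent = e,
                            x0 = 0, yc = grid$ny * grid$h / 2,
                            current_length = grid$nx * grid$h),
                       class = "domain_masks"))
    }
    m <- build_digit_mask(geom, grid, current_length = len)
    m <- build_committed_mask(m, grid, cfg$geometry$L_P)
    build_crescent_mask(m, geom, grid, cfg$geometry$crescent_thickness)
  }
  masks <- rebuild_masks(len0)

  steady <- if (model == "sh") NULL else
    homogeneous_steady_state(dotp, stripep, coup)
  ref <- if (model == "sh") NULL else list(A = steady$A, S = steady$S)

  set.seed(sol$seed)
  species <- if (model == "sh") c("u", "v") else
    switch(variant, full = c("A", "S", "B", "I"),
           stripe_only = c("B", "I"), dot_hole = c("A", "S"))
  fields <- initialize_state(model, grid, steady, sol$noise_amp, species)
  # clamped species: fixed fields supplied programmatically (scalar or matrix)
  clamp <- cfg$clamp
  for (nm in names(clamp)) {
    fields[[nm]] <- matrix(clamp[[nm]], grid$nx, grid$ny)
  }
  moving <- active_species(model, variant, clamp)

  # implicit-step spectral factors, one per moving species
  dt <- sol$dt
  fac <- list()
  for (nm in moving) {
    fac[[nm]] <- if (model == "sh") {
      ell <- if (nm == "u") shp$ell_dot else shp$ell_stripe
      dte <- if (nm == "u") dt else dt / shp$tau
      1 / (1 + dte * (1 - ell^2 * ops$LAM)^2)
    } else {
      D <- switch(nm, A = dotp$D_A, S = dotp$D_S,
                  B = stripep$D_B, I = stripep$D_I)
      1 / (1 + dt * D * ops$LAM)
    }
  }

  # committed bins freeze once the settling period is over (the pattern must
  # exist before it can be committed); values are captured at that moment
  frozen <- lapply(fields, function(f) f)
  cm_idx <- integer(0)
  committed_active <- FALSE

  scale_guard <- if (model == "sh") 1e6 else
    1e6 * max(1, unlist(steady[species]), na.rm = TRUE)

  rates_for <- function(fields) {
    r <- list()
    if (model == "sh") {
      r$u <- sh_dot_rhs(fields$u, shp, masks)
      r$v <- sh_stripe_rhs(fields$v, fields$u, shp, masks)
    } else {
      if (any(c("A", "S") %in% moving)) {
        dr <- dot_rates(fields$A, fields$S, dotp, coup, masks)
        r$A <- dr$dA; r$S <- dr$dS
      }
      if (any(c("B", "I") %in% moving)) {
        Av <- if (is.null(fields$A)) steady$A else fields$A
        Sv <- if (is.null(fields$S)) steady$S else fields$S
        sr <- stripe_rates(fields$B, fields$I, Av, Sv, stripep, coup,
                           masks, ref)
        r$B <- sr$dB; r$I <- sr$dI
      }
    }
    r[moving]
  }

  nsteps <- ceiling(sched$T / dt)
  times <- c(); snapshots <- list()
  take_snapshot <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<- list(t = t, fields = fields,
                                                 masks = masks)
    times <<- c(times, t)
  }
  take_snapshot(0)

  growing <- sched$mode != "static"
  t0 <- Sys.time()
  for (step in seq_len(nsteps)) {
    t <- step * dt
    # (1) implicit linear step; spectral overshoot can leave tiny negatives
    # on sharp gradients, clipped for concentration fields
    for (nm in moving) {
      f <- idct2(dct2(fields[[nm]], ops) * fac[[nm]], ops)
      if (model != "sh" && sol$clip_negative) f[f < 0] <- 0
      fields[[nm]] <- f
    }
    # (2) explicit reactions
    fields <- tryCatch(
      explicit_reaction_step(fields, rates_for(fields), dt,
                             clip_negative = model != "sh" &&
                               sol$clip_negative),
      error = function(e) stop("solver failure at step ", step, " (t = ", t,
                               "): ", conditionMessage(e),
                               "; consider reducing dt below ", dt,
                               call. = FALSE))
    # clamped species stay fixed despite diffusion bookkeeping
    for (nm in names(clamp))
      fields[[nm]] <- matrix(clamp[[nm]], grid$nx, grid$ny)
    # (3) committed bins revert to their frozen values (active after T_i)
    if (!committed_active && t > sched$T_i) {
      committed_active <- TRUE
      cm_idx <- which(masks$committed > 0)
      for (nm in moving) frozen[[nm]][cm_idx] <- fields[[nm]][cm_idx]
    }
    if (length(cm_idx)) {
      for (nm in moving) fields[[nm]][cm_idx] <- frozen[[nm]][cm_idx]
    }
    # (4) growth events
    if (growing && t > sched$T_i && step %% sol$growth_every == 0L) {
      target <- round(digit_length_at(sched, geom, t) / grid$h) * grid$h
      cur <- masks$current_length
      if (target > cur) {
        if (sched$mode == "tip_and_stretch" && sched$stretch_ratio > 0) {
          f <- (cur + sched$stretch_ratio * (target - cur)) / cur
          st <- stretch_uniform(fields, masks, geom, grid, factor = f)
          fields <- st$fields
        }
        masks <- rebuild_masks(target)
        if (committed_active) {
          cm_idx <- which(masks$committed > 0)
          # re-freeze: newly committed bins store their current values
          for (nm in moving) frozen[[nm]][cm_idx] <- fields[[nm]][cm_idx]
        }
      }
    }
    if (step %% 100L == 0L) {
      mx <- max(vapply(fields[moving], function(f) max(abs(f)), 0))
      if (mx > scale_guard)
        stop("solver instability at step ", step, " (|field| = ",
             signif(mx, 3), "); reduce dt below ", dt)
    }
    if (step %% sol$snapshot_every == 0L || step == nsteps) take_snapshot(t)
  }

  structure(list(config = cfg, model = model, variant = variant,
                 grid = grid, geometry = geom, schedule = sched,
                 steady_state = steady, seed = sol$seed,
                 times = times, snapshots = snapshots,
                 final = list(t = times[length(times)], fields = fields,
                              masks = masks),
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 nsteps = nsteps),
            class = "ds_run")
}

#' @export
print.ds_run <- function(x, ...) {
  cat(sprintf("<ds_run> model = %s (%s), %d steps to T = %g, %d snapshots, seed %d\n",
              x$model, x$variant, x$nsteps, x$schedule$T,
              length(x$snapshots), x$seed))
  cat(sprintf("  grid %d x %d (h = %g); digit L = %g, W = %g; %.1f s elapsed\n",
              x$grid$nx, x$grid$ny, x$grid$h, x$geometry$L, x$geometry$W,
              x$elapsed))
  invisible(x)
}

#' @export
summary.ds_run <- function(object, ...) {
  m <- pattern_metrics(object)
  cat("Pattern metrics of final snapshot:\n")
  cat(sprintf("  class       : %s\n", m$pattern_class))
  cat(sprintf("  joint count : %d\n", m$joint_count))
  cat(sprintf("  wavelength  : %s\n",
              if (is.na(m$wavelength)) "undefined" else sprintf("%.2f", m$wavelength)))
  cat(sprintf("  orientation : %s deg from digit axis\n",
              if (is.na(m$orientation_deg)) "undefined" else sprintf("%.1f", m$orientation_deg)))
  cat(sprintf("  dot maxima  : %d\n", nrow(m$dot_points)))
  cat(sprintf("  voronoi     : %s\n",
              if (is.na(m$voronoi_score)) "undefined" else sprintf("%.3f", m$voronoi_score)))
  invisible(m)
}

#' Plot a simulation snapshot
#'
#' Draws the joint-marker field (or a chosen field) as an image with the
#' digit outline overlaid.
#'
#' @param x A `ds_run`.
#' @param field Field name (default: the configured joint marker).
#' @param snapshot Snapshot index (default: final).
#' @param ... Passed to [graphics::image()].
#' @export
plot.ds_run <- function(x, field = NULL, snapshot = NULL, ...) {
  snap <- if (is.null(snapshot)) x$final else x$snapshots[[snapshot]]
  if (is.null(field)) field <- x$config$analysis$joint_marker
  f <- snap$fields[[field]]
  if (is.null(f)) stop("no field named ", field, " in this run")
  ctr <- grid_centers(x$grid)
  graphics::image(ctr$x, ctr$y, f, asp = 1, xlab = "x", ylab = "y",
                  main = sprintf("%s at t = %g", field, snap$t),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(ctr$x, ctr$y, snap$masks$omega, levels = 0.5,
                    add = TRUE, drawlabels = FALSE, col = "white")
  invisible(x)
}
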
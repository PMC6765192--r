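#' Behaviour-simulation parameters
#'
#' Parameters of the synthetic larva: a three-state (inactive/low/high)
#' continuous-time Markov chain for locomotor state, a correlated random walk
#' for the path, a divider-crossing rule that sets light/dark preference, and
#' wall attraction for thigmotaxis. State speeds must sit inside the tracker's
#' class bands (< 3.3, [3.3, 6.4), >= 6.4 mm/s) so recovered budgets are
#' interpretable.
#'
#' @param p_light target long-run fraction of time in the light half,
#'   between 0 and 1. The realised long-run value is validated against a long single
#'   simulation, not a closed form.
#' @param state_rates 3x3 transition-rate matrix (rows: from inactive, low,
#'   high; off-diagonal rates in 1/s; rows sum to zero).
#' @param speed_means mm/s per state, ascending, one inside each class band.
#' @param heading_persistence concentration kappa >= 0 of the per-step turn
#'   (wrapped-normal sd `1/sqrt(kappa)`); 0 means uniform random headings.
#' @param wall_attraction steering gain (1/s) toward the outward radial
#'   direction; larger values give stronger thigmotaxis.
#' @param crossing_bias non-negative. Crossings into the preferred side are always
#'   accepted; crossings out of it are accepted with probability
#'   `((1 - p_light)/p_light) / crossing_bias` (capped at 1, sides swapped
#'   when `p_light < 0.5`). `Inf` never leaves the preferred side.
#' @param duration recording length (s).
#' @param dt frame interval (s), <= 1. Default 0.2 s (5 Hz), the synthetic
#'   stand-in for the tracker's unstated frame rate.
#' @param seed integer seed; generators are pure functions of (params, seed).
#' @return object of class `behaviour_params`.
#' @export
behaviour_params <- function(p_light = 0.8,
                             state_rates = default_state_rates(),
                             speed_means = c(1.0, 4.8, 9.0),
                             heading_persistence = 4,
                             wall_attraction = 0.8,
                             crossing_bias = 1,
                             duration = 3600, dt = 0.2, seed = 1) {
  stopifnot(p_light >= 0, p_light <= 1,
            is.matrix(state_rates), all(dim(state_rates) == c(3, 3)),
            heading_persistence >= 0, wall_attraction >= 0,
            crossing_bias >= 0, duration > 0, dt > 0, dt <= 1)
  if (any(state_rates[row(state_rates) != col(state_rates)] < 0))
    stop("off-diagonal state rates must be non-negative")
  if (any(abs(rowSums(state_rates)) > 1e-9))
    stop("state_rates rows must sum to zero")
  if (length(speed_means) != 3 || is.unsorted(speed_means, strictly = TRUE))
    stop("speed_means must be 3 ascending values")
  th <- speed_thresholds()
  if (!(speed_means[1] < th$inactive_below &&
        speed_means[2] >= th$inactive_below &&
        speed_means[2] < th$high_at_or_above &&
        speed_means[3] >= th$high_at_or_above))
    stop("speed_means must lie inside the inactive/low/high class bands")
  structure(list(p_light = p_light, state_rates = state_rates,
                 speed_means = speed_means,
                 heading_persistence = heading_persistence,
                 wall_attraction = wall_attraction,
                 crossing_bias = crossing_bias,
                 duration = duration, dt = dt, seed = as.integer(seed)),
            class = "behaviour_params")
}

# Baseline locomotor rate matrix: mean dwells ~4 s inactive, ~2 s low,
# ~1 s high, mostly stepping between neighbouring activity levels.
default_state_rates <- function() {
  matrix(c(-0.25, 0.20, 0.05,
           0.30, -0.50, 0.20,
           0.30, 0.70, -1.00),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("inactive", "low", "high"),
                         c("inactive", "low", "high")))
}

#' Treatment-group behaviour presets
#'
#' Parameter presets encoding the qualitative treatment effects: relative to
#' the shared control baseline (mannitol; SNP co-treatments model the full
#' rescue and equal it), the glucose preset lowers light preference, raises
#' activity rates and divider-crossing rate, and strengthens wall attraction.
#' Effect directions are the modelled claim; the magnitudes are arbitrary
#' package defaults.
#'
#' @param effect `"control"`, `"glucose"`, `"glucose_snp"` or
#'   `"mannitol_snp"`.
#' @param seed,duration,dt passed to [behaviour_params()].
#' @return a [behaviour_params()].
#' @export
group_presets <- function(effect = c("control", "glucose", "glucose_snp",
                                     "mannitol_snp"),
                          seed = 1, duration = 3600, dt = 0.2) {
  effect <- match.arg(effect)
  if (effect == "glucose") {
    rates <- matrix(c(-0.45, 0.35, 0.10,
                      0.20, -0.40, 0.20,
                      0.20, 0.60, -0.80),
                    nrow = 3, byrow = TRUE)
    behaviour_params(p_light = 0.55, state_rates = rates,
                     heading_persistence = 4, wall_attraction = 1.6,
                     crossing_bias = 0.5, duration = duration, dt = dt,
                     seed = seed)
  } else {
    behaviour_params(duration = duration, dt = dt, seed = seed)
  }
}

crossing_acceptance <- function(p_light, crossing_bias) {
  # acceptance probabilities for light->dark and dark->light crossings
  if (p_light >= 0.5) {
    a_out <- if (p_light == 1) 0 else (1 - p_light) / p_light
    a_ld <- if (is.infinite(crossing_bias)) 0 else min(1, a_out / crossing_bias)
    c(light_to_dark = a_ld, dark_to_light = 1)
  } else {
    a_out <- if (p_light == 0) 0 else p_light / (1 - p_light)
    a_dl <- if (is.infinite(crossing_bias)) 0 else min(1, a_out / crossing_bias)
    c(light_to_dark = 1, dark_to_light = a_dl)
  }
}

#' Simulate one larva's swim trajectory with known ground truth
#'
#' Correlated random walk in a half-darkened circular well: the locomotor
#' state follows a continuous-time Markov chain sampled at `dt`, the step
#' length is the state speed times `dt`, the heading accumulates
#' wrapped-normal turns plus wall-attraction steering, divider crossings are
#' accepted by the side-dependent rule in [behaviour_params()], and wall
#' hits reflect specularly. Larvae start in the light half (they are placed
#' there), with a uniform random position and heading.
#'
#' @param params a [behaviour_params()].
#' @param well a [well_geometry()].
#' @param larva_id,group identification attached to the trajectory.
#' @return list with `trajectory` (a [trajectory()]) and `truth`: latent
#'   `states` (factor per point), `zones` (per point), `transitions` (true
#'   light/dark transition count).
#' @export
simulate_trajectory <- function(params, well = well_geometry(),
                                larva_id = "sim", group = NULL) {
  stopifnot(inherits(params, "behaviour_params"))
  n <- floor(params$duration / params$dt)
  with_seed(params$seed, {
    P <- as.matrix(Matrix::expm(params$state_rates * params$dt))
    Pcum <- t(apply(P, 1, cumsum))
    Pcum[, 3] <- 1
    # stationary initial state
    ev <- eigen(t(P))
    pi0 <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
    pi0 <- pi0 / sum(pi0)
    s0 <- sample.int(3, 1, prob = pi0)
    states <- .markov_chain(n, s0, Pcum, runif(n))
    # start uniformly in the light half
    repeat {
      r0 <- well$radius * sqrt(runif(1))
      a0 <- runif(1, 0, 2 * pi)
      x0 <- well$centre[1] + r0 * cos(a0)
      y0 <- well$centre[2] + r0 * sin(a0)
      if (divider_offset(well, x0, y0) <= 0) break
    }
    turns <- if (params$heading_persistence > 0)
      rnorm(n, 0, sqrt(1 / params$heading_persistence))
    else runif(n, -pi, pi)
    acc <- crossing_acceptance(params$p_light, params$crossing_bias)
    w <- .walk_engine(params$speed_means[states[-(n + 1)]], turns, runif(n),
                      x0, y0, runif(1, 0, 2 * pi),
                      well$centre[1], well$centre[2], well$radius,
                      well$divider_normal[1], well$divider_normal[2],
                      params$wall_attraction,
                      acc[["light_to_dark"]], acc[["dark_to_light"]],
                      params$dt)
    zones <- c("light", "dark")[w$dark + 1L]
    traj <- trajectory(t = seq(0, by = params$dt, length.out = n + 1),
                       x = w$x, y = w$y, larva_id = larva_id, group = group,
                       well = well, tol_mm = 1e-6)
    list(trajectory = traj,
         truth = list(
           states = factor(c("inactive", "low", "high")[states],
                           levels = c("inactive", "low", "high")),
           zones = zones,
           transitions = sum(zones[-1] != zones[-length(zones)])))
  })
}

#' Simulate a cohort of larvae across the 2x2 design
#'
#' Per-larva seeds are derived deterministically as `seed + index`, so a
#' cohort is a pure function of its base seed. The four design cells map to
#' presets: mannitol -> control, glucose -> glucose, and both SNP
#' co-treatments -> the rescued (control-equal) presets. With `null = TRUE`
#' every cell uses the control preset (group labels kept), giving a
#' no-effect cohort for type-I checks.
#'
#' @param n_per_group larvae per design cell.
#' @param seed base integer seed.
#' @param well a [well_geometry()].
#' @param duration,dt recording length and frame interval (s).
#' @param groups subset of design cells to simulate (default all four).
#' @param null simulate all cells from the control preset.
#' @return list with `trajectories` (list of [trajectory()]) and `truths`.
#' @export
simulate_cohort <- function(n_per_group = 12, seed = 1,
                            well = well_geometry(), duration = 3600,
                            dt = 0.2,
                            groups = c("mannitol", "mannitol_snp",
                                       "glucose", "glucose_snp"),
                            null = FALSE) {
  preset_of <- c(mannitol = "control", mannitol_snp = "mannitol_snp",
                 glucose = "glucose", glucose_snp = "glucose_snp")
  stopifnot(all(groups %in% names(preset_of)))
  trajs <- list(); truths <- list()
  idx <- 0L
  for (g in groups) {
    grp <- treatment_group(osmolyte = if (grepl("glucose", g)) "glucose"
                           else "mannitol",
                           snp = grepl("snp", g))
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      pr <- group_presets(if (null) "control" else preset_of[[g]],
                          seed = seed + idx, duration = duration, dt = dt)
      sim <- simulate_trajectory(pr, well = well,
                                 larva_id = sprintf("%s_%02d", g, i),
                                 group = grp)
      trajs[[idx]] <- sim$trajectory
      truths[[idx]] <- sim$truth
    }
  }
  list(trajectories = trajs, truths = truths)
}

# ---- calcium ----------------------------------------------------------------

#' Calcium-trace simulation parameters
#'
#' @param rate spontaneous transient rate (events/s), >= 0.
#' @param tau_decay transient decay time constant (s).
#' @param amplitude transient amplitude in dF/F0 units.
#' @param baseline resting fluorescence F0 (a.u.).
#' @param drift_amplitude slow sinusoidal baseline drift amplitude (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param duration,dt trace length and sampling interval (s).
#' @param seed integer seed.
#' @return object of class `calcium_params`.
#' @export
calcium_params <- function(rate = 0.05, tau_decay = 1.5, amplitude = 0.5,
                           baseline = 100, drift_amplitude = 5, noise_sd = 2,
                           duration = 300, dt = 0.1, seed = 1) {
  stopifnot(rate >= 0, tau_decay > 0, amplitude > 0, baseline > 0,
            drift_amplitude >= 0, noise_sd >= 0, duration > 0, dt > 0,
            dt < duration)
  structure(list(rate = rate, tau_decay = tau_decay, amplitude = amplitude,
                 baseline = baseline, drift_amplitude = drift_amplitude,
                 noise_sd = noise_sd, duration = duration, dt = dt,
                 seed = as.integer(seed)),
            class = "calcium_params")
}

#' Simulate a fluorescence trace with Poisson-timed transients
#'
#' `F(t) = baseline + drift + sum_k amplitude * baseline *
#' exp(-(t - t_k)/tau_decay) * [t >= t_k] + noise`, with event times a
#' homogeneous Poisson process of the given rate and the drift a slow
#' sinusoid (period one third of the trace). Fluorescence is clipped at 0.
#'
#' @param params a [calcium_params()].
#' @return list with `trace` (tibble `t`, `F`) and `event_times` (s).
#' @export
simulate_calcium_trace <- function(params) {
  stopifnot(inherits(params, "calcium_params"))
  with_seed(params$seed, {
    t <- seq(0, params$duration, by = params$dt)
    n_ev <- rpois(1, params$rate * params$duration)
    ev <- sort(runif(n_ev, 0, params$duration))
    F <- params$baseline +
      params$drift_amplitude * sin(2 * pi * t / (params$duration / 3))
    for (tk in ev) {
      on <- t >= tk
      F[on] <- F[on] + params$amplitude * params$baseline *
        exp(-(t[on] - tk) / params$tau_decay)
    }
    if (params$noise_sd > 0) F <- F + rnorm(length(t), 0, params$noise_sd)
    list(trace = tibble::tibble(t = t, F = pmax(F, 0)), event_times = ev)
  })
}

# ---- tectum-like stacks -----------------------------------------------------

#' Tectum-stack simulation parameters
#'
#' Describes a two-channel 3-D stack: tubular vessels (Gaussian cross-section
#' around 3-D centreline polylines) plus bright mural-nuclei blobs in the red
#' channel, and vessel-localised expression in the green channel.
#'
#' @param shape voxel counts, named (z, y, x).
#' @param voxel_size um per axis, named (x, y, z).
#' @param vessel_polylines list of polylines; each a list with `points`
#'   (n x 3 matrix of x, y, z in um, inside the volume) and `radius` (um).
#'   `NULL` gives a default two-vessel arrangement.
#' @param vessel_level red-channel tube intensity (a.u.).
#' @param green_level green-channel tube intensity; scalar or one value per
#'   polyline.
#' @param n_nuclei number of mural nuclei (>= 0).
#' @param nuclei_level nucleus peak intensity (a.u.); default well above the
#'   vessel level, as nuclear-localised reporters are much brighter than
#'   membrane label.
#' @param nuclei_sigma nucleus Gaussian sigma (um).
#' @param nuclei_min_sep minimum centre separation (um).
#' @param background,noise_sd background level and Gaussian noise sd (a.u.).
#' @param seed integer seed.
#' @return object of class `stack_params`.
#' @export
stack_params <- function(shape = c(z = 40, y = 120, x = 160),
                         voxel_size = c(x = 0.6, y = 0.6, z = 1.0),
                         vessel_polylines = NULL,
                         vessel_level = 80, green_level = 120,
                         n_nuclei = 10, nuclei_level = 220,
                         nuclei_sigma = 1.5, nuclei_min_sep = 6,
                         background = 10, noise_sd = 3, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 4), n_nuclei >= 0,
            vessel_level >= 0, all(green_level >= 0), nuclei_level >= 0,
            nuclei_sigma > 0, background >= 0, noise_sd >= 0)
  shape <- setNames(as.integer(shape), c("z", "y", "x"))
  voxel_size <- setNames(as.numeric(voxel_size), c("x", "y", "z"))
  extent <- c(x = (shape[["x"]] - 1) * voxel_size[["x"]],
              y = (shape[["y"]] - 1) * voxel_size[["y"]],
              z = (shape[["z"]] - 1) * voxel_size[["z"]])
  if (is.null(vessel_polylines)) {
    mk <- function(fy) {
      xs <- seq(0.1, 0.9, length.out = 8) * extent[["x"]]
      cbind(x = xs,
            y = fy(xs / extent[["x"]]) * extent[["y"]],
            z = rep(0.5 * extent[["z"]], length(xs)))
    }
    vessel_polylines <- list(
      list(points = mk(function(s) 0.35 + 0.10 * sin(2 * pi * s)), radius = 2.5),
      list(points = mk(function(s) 0.65 + 0.10 * cos(2 * pi * s)), radius = 2.5))
  }
  for (pl in vessel_polylines) {
    stopifnot(is.matrix(pl$points), ncol(pl$points) == 3, pl$radius > 0)
    if (any(pl$points < 0) ||
        any(sweep(pl$points, 2, extent[c("x", "y", "z")]) > 0))
      stop("vessel polyline outside volume")
  }
  if (length(green_level) == 1)
    green_level <- rep(green_level, length(vessel_polylines))
  stopifnot(length(green_level) == length(vessel_polylines))
  structure(list(shape = shape, voxel_size = voxel_size,
                 vessel_polylines = vessel_polylines,
                 vessel_level = vessel_level, green_level = green_level,
                 n_nuclei = as.integer(n_nuclei),
                 nuclei_level = nuclei_level, nuclei_sigma = nuclei_sigma,
                 nuclei_min_sep = nuclei_min_sep, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "stack_params")
}

polyline_length <- function(points) {
  sum(sqrt(rowSums(diff(points)^2)))
}

# Minimum distance from every voxel centre to a polyline (um).
# X, Y, Z are voxel-centre coordinate arrays of a common shape.
dist_to_polyline <- function(X, Y, Z, points) {
  dmin <- NULL
  for (i in seq_len(nrow(points) - 1)) {
    p <- points[i, ]; q <- points[i + 1, ]
    v <- q - p
    L2 <- sum(v^2)
    tt <- ((X - p[1]) * v[1] + (Y - p[2]) * v[2] + (Z - p[3]) * v[3]) / L2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    d2 <- (X - p[1] - tt * v[1])^2 + (Y - p[2] - tt * v[2])^2 +
      (Z - p[3] - tt * v[3])^2
    dmin <- if (is.null(dmin)) d2 else pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Simulate a two-channel tectum-like image stack with ground truth
#'
#' Red channel: vessel tubes (Gaussian cross-section of the polyline
#' distance field) plus mural-nuclei blobs plus background and noise. Green
#' channel: the same tube geometry at per-vessel expression levels. Nuclei
#' centres are drawn uniformly inside the volume (2-sigma margin) with a
#' minimum mutual separation. Intensities are rounded to integer counts, so
#' TIFF round trips are voxel-identical.
#'
#' @param params a [stack_params()].
#' @return list with `stack` (an [image_stack()], channels `red`, `green`)
#'   and `truth`: `total_length_um` (centreline length), `green_level`
#'   (per vessel), `n_nuclei`, `nuclei_centres_um`.
#' @export
simulate_tectum_stack <- function(params) {
  stopifnot(inherits(params, "stack_params"))
  with_seed(params$seed, {
    nz <- params$shape[["z"]]; ny <- params$shape[["y"]]
    nx <- params$shape[["x"]]
    vx <- params$voxel_size[["x"]]; vy <- params$voxel_size[["y"]]
    vz <- params$voxel_size[["z"]]
    xs <- (seq_len(nx) - 1) * vx
    ys <- (seq_len(ny) - 1) * vy
    zs <- (seq_len(nz) - 1) * vz
    X <- array(rep(xs, each = ny, times = nz), c(ny, nx, nz))
    Y <- array(rep(ys, times = nx * nz), c(ny, nx, nz))
    Z <- array(rep(zs, each = ny * nx), c(ny, nx, nz))
    red <- array(0, c(ny, nx, nz))
    green <- array(0, c(ny, nx, nz))
    for (k in seq_along(params$vessel_polylines)) {
      pl <- params$vessel_polylines[[k]]
      d <- dist_to_polyline(X, Y, Z, pl$points)
      prof <- exp(-d^2 / (2 * pl$radius^2))
      red <- pmax(red, params$vessel_level * prof)
      green <- pmax(green, params$green_level[k] * prof)
    }
    # nuclei centres: uniform with minimum separation, 2-sigma margin
    m <- 2 * params$nuclei_sigma
    centres <- matrix(numeric(0), 0, 3)
    guard <- 0
    while (nrow(centres) < params$n_nuclei) {
      guard <- guard + 1
      if (guard > 10000) stop("cannot place nuclei at this separation")
      cand <- c(runif(1, m, max(xs) - m), runif(1, m, max(ys) - m),
                runif(1, min(m, max(zs) / 2), max(zs) - min(m, max(zs) / 2)))
      if (!nrow(centres) ||
          min(sqrt(rowSums(sweep(centres, 2, cand)^2))) >= params$nuclei_min_sep)
        centres <- rbind(centres, cand)
    }
    for (i in seq_len(nrow(centres))) {
      d2 <- (X - centres[i, 1])^2 + (Y - centres[i, 2])^2 +
        (Z - centres[i, 3])^2
      red <- red + params$nuclei_level *
        exp(-d2 / (2 * params$nuclei_sigma^2))
    }
    finish <- function(img) {
      img <- img + params$background
      if (params$noise_sd > 0)
        img <- img + array(rnorm(length(img), 0, params$noise_sd), dim(img))
      array(pmin(pmax(round(img), 0), 65535), dim(img))
    }
    stack <- image_stack(list(red = finish(red), green = finish(green)),
                         voxel_size = params$voxel_size)
    list(stack = stack,
         truth = list(
           total_length_um = sum(vapply(params$vessel_polylines,
                                        function(pl) polyline_length(pl$points),
                                        0)),
           green_level = params$green_level,
           n_nuclei = params$n_nuclei,
           nuclei_centres_um = centres))
  })
}
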
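# Seeded simulators for every input the analysis stages consume: dwell
# samples, trajectory sets, rendered movies, adsorption traces, and
# surface-catalysis traces.

#' Acquisition parameters
#'
#' Describes the imaging geometry and timing shared by the simulators and the
#' analysis stages: the camera frame interval, the pixel size, an optional
#' image geometry, and the observed membrane area.
#'
#' @param frame_interval_s Seconds per camera frame (default 0.052, i.e. 52 ms).
#' @param pixel_size_um Micrometers per pixel.
#' @param image_shape Optional integer vector `c(rows, cols)` in pixels. When
#'   set, `field_area_um2` is derived as `rows * cols * pixel_size_um^2`.
#' @param field_area_um2 Observed membrane area in um^2. Required if
#'   `image_shape` is not given and an area-dependent simulator is used.
#' @param n_frames Number of frames in a movie or track simulation.
#' @return An object of class `AcquisitionParams`.
#' @export
acquisition_params <- function(frame_interval_s = 0.052, pixel_size_um = 0.1,
                               image_shape = NULL, field_area_um2 = NULL,
                               n_frames = 100L) {
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(n_frames, "n_frames")
  if (!is.null(image_shape)) {
    stopifnot(length(image_shape) == 2L, all(image_shape >= 1))
    image_shape <- as.integer(image_shape)
    derived <- image_shape[1] * image_shape[2] * pixel_size_um^2
    if (!is.null(field_area_um2) &&
        abs(field_area_um2 - derived) > 1e-8 * derived)
      stop("`field_area_um2` is inconsistent with `image_shape` and `pixel_size_um`",
           call. = FALSE)
    field_area_um2 <- derived
  }
  structure(list(frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 image_shape = image_shape,
                 field_area_um2 = field_area_um2,
                 n_frames = as.integer(n_frames)),
            class = "AcquisitionParams")
}

#' Membrane binding simulation configuration
#'
#' Ground-truth parameters for the binding/diffusion forward model: Poisson
#' arrival rate of new membrane binders, the two-component exponential dwell
#' mixture (weight `dwell_alpha` on the fast component `dwell_tau1_s`), the
#' two-species diffusion mixture (weight `diff_alpha` on the slow species
#' `D1_um2_s`), optional rebinding ("membrane hopping") and photobleaching.
#'
#' @param arrival_rate New particles per um^2 per second.
#' @param dwell_alpha,dwell_tau1_s,dwell_tau2_s Dwell mixture weight and time
#'   constants (s), `dwell_tau1_s <= dwell_tau2_s`.
#' @param diff_alpha,D1_um2_s,D2_um2_s Diffusion mixture weight and
#'   coefficients (um^2/s), `D1_um2_s <= D2_um2_s`.
#' @param couple_states If `TRUE` the dwell component drawn for a particle
#'   forces the matching diffusion species; independent draws otherwise
#'   (the default, matching how the two mixtures are fit).
#' @param rebind_prob,rebind_radius_um Optional hopping model: on dissociation
#'   the particle re-inserts within `rebind_radius_um` with probability
#'   `rebind_prob` and continues as the same track. Off by default.
#' @param bleach_rate_s Photobleaching hazard (1/s); 0 disables bleaching.
#' @param seed Integer seed; all randomness of a simulation flows from it.
#' @return An object of class `BindingSimConfig`.
#' @export
binding_sim_config <- function(arrival_rate = 0.05,
                               dwell_alpha = 0.5, dwell_tau1_s = 0.5,
                               dwell_tau2_s = 2,
                               diff_alpha = 0.5, D1_um2_s = 0.3,
                               D2_um2_s = 1,
                               couple_states = FALSE,
                               rebind_prob = 0, rebind_radius_um = 0.1,
                               bleach_rate_s = 0, seed = NULL) {
  check_positive(arrival_rate, "arrival_rate", strict = FALSE)
  check_fraction(dwell_alpha, "dwell_alpha")
  check_fraction(diff_alpha, "diff_alpha")
  check_fraction(rebind_prob, "rebind_prob")
  check_positive(dwell_tau1_s, "dwell_tau1_s")
  check_positive(dwell_tau2_s, "dwell_tau2_s")
  check_positive(D1_um2_s, "D1_um2_s", strict = FALSE)
  check_positive(D2_um2_s, "D2_um2_s", strict = FALSE)
  check_positive(rebind_radius_um, "rebind_radius_um", strict = FALSE)
  check_positive(bleach_rate_s, "bleach_rate_s", strict = FALSE)
  if (dwell_tau1_s > dwell_tau2_s)
    stop("`dwell_tau1_s` must not exceed `dwell_tau2_s`", call. = FALSE)
  if (D1_um2_s > D2_um2_s)
    stop("`D1_um2_s` must not exceed `D2_um2_s`", call. = FALSE)
  structure(list(arrival_rate = arrival_rate,
                 dwell_alpha = dwell_alpha, dwell_tau1_s = dwell_tau1_s,
                 dwell_tau2_s = dwell_tau2_s,
                 diff_alpha = diff_alpha, D1_um2_s = D1_um2_s,
                 D2_um2_s = D2_um2_s,
                 couple_states = isTRUE(couple_states),
                 rebind_prob = rebind_prob,
                 rebind_radius_um = rebind_radius_um,
                 bleach_rate_s = bleach_rate_s, seed = seed),
            class = "BindingSimConfig")
}

#' Imaging parameters for movie rendering
#'
#' @param psf_sigma_px Gaussian point-spread-function standard deviation in
#'   pixels.
#' @param photons_per_particle Mean integrated photon count per spot per frame.
#' @param background_photons Mean background photons per pixel per frame.
#' @param read_noise_sd Additive Gaussian read noise SD (counts).
#' @param seed Integer seed.
#' @return An object of class `ImagingParams`.
#' @export
imaging_params <- function(psf_sigma_px = 1.5, photons_per_particle = 500,
                           background_photons = 10, read_noise_sd = 2,
                           seed = NULL) {
  check_positive(psf_sigma_px, "psf_sigma_px")
  check_positive(photons_per_particle, "photons_per_particle", strict = FALSE)
  check_positive(background_photons, "background_photons", strict = FALSE)
  check_positive(read_noise_sd, "read_noise_sd", strict = FALSE)
  structure(list(psf_sigma_px = psf_sigma_px,
                 photons_per_particle = photons_per_particle,
                 background_photons = background_photons,
                 read_noise_sd = read_noise_sd, seed = seed),
            class = "ImagingParams")
}

#' Surface catalysis simulation configuration
#'
#' Forward model for substrate-depleting lipid kinase reactions on a supported
#' bilayer monitored by a product-lipid biosensor.
#'
#' @param kcat_per_enzyme Product lipids per second per membrane-bound enzyme.
#' @param enzyme_density Enzymes per um^2.
#' @param substrate_density0 Initial substrate lipids per um^2.
#' @param t_grid_s Strictly increasing sampling times in seconds.
#' @param noise_sd_frac Multiplicative Gaussian sensor noise SD (fraction of
#'   the signal).
#' @param seed Integer seed.
#' @return An object of class `CatalysisSimConfig`.
#' @export
catalysis_sim_config <- function(kcat_per_enzyme, enzyme_density,
                                 substrate_density0,
                                 t_grid_s, noise_sd_frac = 0, seed = NULL) {
  check_positive(kcat_per_enzyme, "kcat_per_enzyme", strict = FALSE)
  check_positive(enzyme_density, "enzyme_density", strict = FALSE)
  check_positive(substrate_density0, "substrate_density0", strict = FALSE)
  check_positive(noise_sd_frac, "noise_sd_frac", strict = FALSE)
  if (length(t_grid_s) < 2L || any(diff(t_grid_s) <= 0))
    stop("`t_grid_s` must be strictly increasing with at least two points",
         call. = FALSE)
  structure(list(kcat_per_enzyme = kcat_per_enzyme,
                 enzyme_density = enzyme_density,
                 substrate_density0 = substrate_density0,
                 t_grid_s = as.numeric(t_grid_s),
                 noise_sd_frac = noise_sd_frac, seed = seed),
            class = "CatalysisSimConfig")
}

# Draw n dwell times from the two-component exponential mixture.
draw_dwell_mixture <- function(n, alpha, tau1_s, tau2_s) {
  comp <- stats::runif(n) < alpha
  t <- numeric(n)
  t[comp] <- stats::rexp(sum(comp), rate = 1 / tau1_s)
  t[!comp] <- stats::rexp(sum(!comp), rate = 1 / tau2_s)
  list(t = t, comp = ifelse(comp, 1L, 2L))
}

#' Simulate a discretized dwell-time sample
#'
#' Draws raw dwell times from the two-component exponential mixture
#' `f(t) = alpha * exp(-t/tau1) + (1 - alpha) * exp(-t/tau2)` and discretizes
#' each draw to the camera clock: a molecule bound for time `t` is observed in
#' `floor(t / dt) + 1` frames and its recorded dwell is
#' `(frames - 1) * dt`. Events observed for fewer than `min_frames` frames are
#' either redrawn (conditioning the sample on detectability, the default) or
#' dropped, per `short_events`.
#'
#' @param n Number of recorded dwell times to return (for `"redraw"`) or raw
#'   draws to attempt (for `"drop"`).
#' @param alpha Mixture weight of the fast component `tau1_s`.
#' @param tau1_s,tau2_s Mixture time constants in seconds. `tau2_s` defaults to
#'   `tau1_s` (single-exponential sample).
#' @param frame_interval_s Camera frame interval in seconds.
#' @param min_frames Minimum number of observed frames for an event to be
#'   recorded (default 2, mirroring a "tracked >= 2 frames" filter).
#' @param short_events `"redraw"` or `"drop"`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `DwellSample`: list with `durations` (seconds,
#'   multiples of the frame interval), `frame_interval_s`, and `n`.
#' @examples
#' s <- simulate_dwell_sample(1000, alpha = 0.54, tau1_s = 0.55,
#'                            tau2_s = 1.44, seed = 1)
#' mean(s$durations)
#' @export
simulate_dwell_sample <- function(n, alpha, tau1_s, tau2_s = tau1_s,
                                  frame_interval_s = 0.052, min_frames = 2L,
                                  short_events = c("redraw", "drop"),
                                  seed = NULL) {
  short_events <- match.arg(short_events)
  check_positive(n, "n")
  check_fraction(alpha, "alpha")
  check_positive(tau1_s, "tau1_s")
  check_positive(tau2_s, "tau2_s")
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(min_frames, "min_frames", strict = FALSE)
  n <- as.integer(n)
  dt <- frame_interval_s
  with_seed(seed, {
    draw <- draw_dwell_mixture(n, alpha, tau1_s, tau2_s)
    frames <- floor(draw$t / dt) + 1L
    if (short_events == "redraw") {
      # Redraw whole events (component and duration) until detectable, i.e.
      # condition the mixture on >= min_frames observed frames.
      bad <- which(frames < min_frames)
      while (length(bad) > 0L) {
        redraw <- draw_dwell_mixture(length(bad), alpha, tau1_s, tau2_s)
        frames[bad] <- floor(redraw$t / dt) + 1L
        bad <- bad[frames[bad] < min_frames]
      }
    } else {
      frames <- frames[frames >= min_frames]
    }
    durations <- (frames - 1L) * dt
    dwell_sample(durations, dt)
  })
}

#' Construct a dwell sample from recorded durations
#'
#' @param durations Recorded dwell times in seconds (multiples of the frame
#'   interval).
#' @param frame_interval_s Camera frame interval in seconds.
#' @return An object of class `DwellSample`.
#' @export
dwell_sample <- function(durations, frame_interval_s) {
  check_positive(frame_interval_s, "frame_interval_s")
  if (any(durations < 0)) stop("durations must be non-negative", call. = FALSE)
  structure(list(durations = as.numeric(durations),
                 frame_interval_s = frame_interval_s,
                 n = length(durations)),
            class = "DwellSample")
}

#' Simulate a set of membrane-binding trajectories
#'
#' Particles arrive on the field as a spatially uniform Poisson process at
#' `arrival_rate * field_area_um2` per second. Each particle draws a dwell
#' time from the exponential mixture and a diffusion coefficient from the
#' two-species mixture (coupled to the dwell component or independent per
#' `couple_states`), then performs 2D Brownian motion with per-axis step
#' variance `2 * D * dt` between frames. Optional photobleaching truncates the
#' observation; optional rebinding re-inserts a dissociating particle within
#' `rebind_radius_um` with probability `rebind_prob` as a continuation of the
#' same track.
#'
#' @param config A [binding_sim_config()].
#' @param acq An [acquisition_params()] with a positive `field_area_um2` (or
#'   an `image_shape`).
#' @return A [track_set()] whose `tracks` data frame has columns `track_id`,
#'   `frame`, `x_um`, `y_um`.
#' @export
simulate_track_set <- function(config, acq) {
  stopifnot(inherits(config, "BindingSimConfig"),
            inherits(acq, "AcquisitionParams"))
  area <- acq$field_area_um2
  if (is.null(area) || area <= 0)
    stop("`acq$field_area_um2` must be positive (set `field_area_um2` or `image_shape`)",
         call. = FALSE)
  dt <- acq$frame_interval_s
  n_frames <- acq$n_frames
  # Field extent: image geometry when present, square field otherwise.
  if (!is.null(acq$image_shape)) {
    lx <- acq$image_shape[2] * acq$pixel_size_um
    ly <- acq$image_shape[1] * acq$pixel_size_um
  } else {
    lx <- ly <- sqrt(area)
  }
  with_seed(config$seed, {
    total_t <- n_frames * dt
    n_arrivals <- stats::rpois(1, config$arrival_rate * area * total_t)
    if (n_arrivals == 0L)
      return(track_set(data.frame(track_id = integer(), frame = integer(),
                                  x_um = numeric(), y_um = numeric()), acq))
    arrive_t <- stats::runif(n_arrivals, 0, total_t)
    out <- vector("list", n_arrivals)
    for (i in seq_len(n_arrivals)) {
      x <- stats::runif(1, 0, lx)
      y <- stats::runif(1, 0, ly)
      t_now <- arrive_t[i]
      frames <- integer(0); xs <- numeric(0); ys <- numeric(0)
      repeat {
        comp <- if (stats::runif(1) < config$dwell_alpha) 1L else 2L
        dwell <- stats::rexp(1, 1 / if (comp == 1L) config$dwell_tau1_s else
                                    config$dwell_tau2_s)
        if (config$bleach_rate_s > 0)
          dwell <- min(dwell, stats::rexp(1, config$bleach_rate_s))
        dcomp <- if (config$couple_states) comp else
          if (stats::runif(1) < config$diff_alpha) 1L else 2L
        D <- if (dcomp == 1L) config$D1_um2_s else config$D2_um2_s
        # Frames whose timestamps fall inside this bound interval.
        k0 <- ceiling(t_now / dt)
        k1 <- floor((t_now + dwell) / dt)
        k1 <- min(k1, n_frames - 1L)
        if (k1 >= k0) {
          ks <- k0:k1
          sd_step <- sqrt(2 * D * dt)
          nx <- length(ks)
          # Continue from last recorded position if rebinding.
          x0 <- if (length(xs)) xs[length(xs)] else x
          y0 <- if (length(ys)) ys[length(ys)] else y
          xs_new <- x0 + cumsum(c(0, stats::rnorm(nx - 1, 0, sd_step)))
          ys_new <- y0 + cumsum(c(0, stats::rnorm(nx - 1, 0, sd_step)))
          frames <- c(frames, ks)
          xs <- c(xs, xs_new)
          ys <- c(ys, ys_new)
        }
        t_now <- t_now + dwell
        if (t_now >= total_t || stats::runif(1) >= config$rebind_prob) break
        # Membrane hopping: re-insert nearby and continue the track.
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- config$rebind_radius_um * sqrt(stats::runif(1))
        if (length(xs)) {
          xs[length(xs)] <- xs[length(xs)] + rad * cos(ang)
          ys[length(ys)] <- ys[length(ys)] + rad * sin(ang)
        }
      }
      if (length(frames))
        out[[i]] <- data.frame(track_id = i, frame = frames,
                               x_um = xs, y_um = ys)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
      return(track_set(data.frame(track_id = integer(), frame = integer(),
                                  x_um = numeric(), y_um = numeric()), acq))
    tracks <- do.call(rbind, out)
    # Renumber ids consecutively in arrival order.
    tracks$track_id <- match(tracks$track_id, unique(tracks$track_id))
    track_set(tracks, acq)
  })
}

#' Render a synthetic TIRF movie from a track set
#'
#' Each live particle contributes a 2D Gaussian spot whose integrated
#' intensity is Poisson-distributed around `photons_per_particle`; the
#' Gaussian is integrated over pixel areas. Per-pixel Poisson background and
#' Gaussian read noise are added. The stack is stored as a `rows x cols x
#' n_frames` double array (clamped and rounded to 16-bit on TIFF export).
#' Particles outside the image are clipped, not an error.
#'
#' @param tracks A [track_set()].
#' @param acq An [acquisition_params()] with `image_shape` set.
#' @param imaging An [imaging_params()].
#' @return An object of class `ImageStack`: 3D array with attributes
#'   `pixel_size_um` and `frame_interval_s`.
#' @export
render_movie <- function(tracks, acq, imaging) {
  stopifnot(inherits(tracks, "TrackSet"), inherits(acq, "AcquisitionParams"),
            inherits(imaging, "ImagingParams"))
  if (is.null(acq$image_shape))
    stop("`acq$image_shape` must be set to render a movie", call. = FALSE)
  check_positive(imaging$psf_sigma_px, "psf_sigma_px")
  nr <- acq$image_shape[1]; nc <- acq$image_shape[2]
  nf <- acq$n_frames
  px <- acq$pixel_size_um
  sigma <- imaging$psf_sigma_px
  half <- ceiling(5 * sigma)
  with_seed(imaging$seed, {
    stack <- array(0, dim = c(nr, nc, nf))
    tr <- tracks$tracks
    if (nrow(tr)) {
      tr <- tr[tr$frame >= 0 & tr$frame < nf, , drop = FALSE]
      for (i in seq_len(nrow(tr))) {
        # 0-based pixel coordinates with origin at the top-left pixel center.
        cx <- tr$x_um[i] / px
        cy <- tr$y_um[i] / px
        photons <- stats::rpois(1, imaging$photons_per_particle)
        if (photons == 0) next
        j0 <- max(0L, floor(cx) - half); j1 <- min(nc - 1L, ceiling(cx) + half)
        i0 <- max(0L, floor(cy) - half); i1 <- min(nr - 1L, ceiling(cy) + half)
        if (j0 > j1 || i0 > i1) next
        jj <- j0:j1; ii <- i0:i1
        wx <- stats::pnorm(jj + 0.5, cx, sigma) - stats::pnorm(jj - 0.5, cx, sigma)
        wy <- stats::pnorm(ii + 0.5, cy, sigma) - stats::pnorm(ii - 0.5, cy, sigma)
        f <- tr$frame[i] + 1L
        stack[ii + 1L, jj + 1L, f] <- stack[ii + 1L, jj + 1L, f] +
          photons * outer(wy, wx)
      }
    }
    if (imaging$background_photons > 0)
      stack <- stack + stats::rpois(length(stack), imaging$background_photons)
    if (imaging$read_noise_sd > 0)
      stack <- stack + stats::rnorm(length(stack), 0, imaging$read_noise_sd)
    structure(stack, class = "ImageStack",
              pixel_size_um = px, frame_interval_s = acq$frame_interval_s)
  })
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' @param stack An `ImageStack` (from [render_movie()]) or a 3D numeric array.
#' @param path Output file path.
#' @export
write_movie_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  frames <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- pmin(pmax(round(unclass(stack)[, , k]), 0), 65535)
    m / 65535  # tiff package expects [0,1]; 16-bit on disk
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s Acquisition metadata to attach.
#' @return An `ImageStack` in raw counts (0-65535).
#' @export
read_movie_tiff <- function(path, pixel_size_um = 0.1,
                            frame_interval_s = 0.052) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  for (k in seq_along(frames)) stack[, , k] <- frames[[k]] * 65535
  structure(stack, class = "ImageStack",
            pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s)
}

#' Simulate a substrate-depleting surface catalysis trace
#'
#' Product density follows first-order substrate depletion,
#' `P(t) = S0 * (1 - exp(-kcat * E * t / S0))`, whose initial slope is exactly
#' `kcat * E`. The sensor intensity is `P(t)/S0` scaled to an arbitrary
#' plateau and multiplied by `(1 + noise)` with Gaussian multiplicative noise.
#'
#' @param config A [catalysis_sim_config()].
#' @param plateau_au Arbitrary plateau intensity of the sensor (default 1).
#' @return An object of class `SensorTrace`: list with `times_s`,
#'   `intensities`, plus attribute `truth` carrying the generating parameters.
#' @export
simulate_catalysis_trace <- function(config, plateau_au = 1) {
  stopifnot(inherits(config, "CatalysisSimConfig"))
  S0 <- config$substrate_density0
  k0 <- config$kcat_per_enzyme * config$enzyme_density  # initial rate
  t <- config$t_grid_s
  P <- if (k0 == 0 || S0 == 0) rep(0, length(t)) else
    S0 * (1 - exp(-k0 * t / S0))
  with_seed(config$seed, {
    frac <- if (S0 > 0) P / S0 else rep(0, length(t))
    noise <- if (config$noise_sd_frac > 0)
      stats::rnorm(length(t), 0, config$noise_sd_frac) else 0
    intens <- plateau_au * frac * (1 + noise)
    sensor_trace(t, intens, truth = list(product_density = P,
                                         initial_rate = k0,
                                         substrate_density0 = S0))
  })
}

#' Simulate a bulk membrane adsorption (equilibration) trace
#'
#' Pseudo-first-order association: `I(t) = plateau * (1 - exp(-k_obs * t))`
#' plus additive Gaussian noise.
#'
#' @param k_obs Observed equilibration rate constant (1/s).
#' @param plateau Plateau intensity (a.u.).
#' @param t_grid_s Strictly increasing sampling times (s).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param seed Integer seed.
#' @return A `SensorTrace`.
#' @export
simulate_adsorption_trace <- function(k_obs, plateau, t_grid_s, noise_sd = 0,
                                      seed = NULL) {
  check_positive(k_obs, "k_obs", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (any(diff(t_grid_s) <= 0))
    stop("`t_grid_s` must be strictly increasing", call. = FALSE)
  with_seed(seed, {
    I <- plateau * (1 - exp(-k_obs * t_grid_s))
    if (noise_sd > 0) I <- I + stats::rnorm(length(t_grid_s), 0, noise_sd)
    sensor_trace(t_grid_s, I)
  })
}

#' Simulate a pooled frame-to-frame step-size sample
#'
#' Convenience generator for the two-species diffusion mixture: tracks are
#' assigned a diffusion species (weight `alpha` on `D1_um2_s`) and contribute
#' `steps_per_track` Rayleigh-distributed displacements with scale
#' `sqrt(2 * D * lag)` each, mirroring pooled displacements of tracked
#' particles at a single lag.
#'
#' @param n_steps Total number of displacements to return.
#' @param alpha Fraction of particles with coefficient `D1_um2_s`.
#' @param D1_um2_s,D2_um2_s Diffusion coefficients, `D1 <= D2` (um^2/s).
#' @param lag_s Lag time (frame interval) in seconds.
#' @param steps_per_track Steps contributed by each particle (default 10).
#' @param seed Integer seed.
#' @return A `StepSample` (see [compute_steps()]).
#' @export
simulate_step_sample <- function(n_steps, alpha, D1_um2_s, D2_um2_s,
                                 lag_s = 0.052, steps_per_track = 10L,
                                 seed = NULL) {
  check_positive(n_steps, "n_steps")
  check_fraction(alpha, "alpha")
  check_positive(D1_um2_s, "D1_um2_s")
  check_positive(D2_um2_s, "D2_um2_s")
  check_positive(lag_s, "lag_s")
  with_seed(seed, {
    n_tracks <- ceiling(n_steps / steps_per_track)
    comp <- stats::runif(n_tracks) < alpha
    D <- ifelse(comp, D1_um2_s, D2_um2_s)
    D <- rep(D, each = steps_per_track)[seq_len(n_steps)]
    # 2D Brownian step length at lag tau is Rayleigh with scale sqrt(2*D*tau).
    r <- sqrt(-4 * D * lag_s * log(stats::runif(n_steps)))
    step_sample(r, lag_s)
  })
}
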
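# Frame-to-frame displacement extraction and one/two-species 2D diffusion
# (Rayleigh step-size) fits.

#' Construct a step sample
#'
#' @param r Frame-to-frame displacements in um (non-negative).
#' @param lag_s Lag time between steps in seconds (the frame interval).
#' @return An object of class `StepSample`: list with `r`, `lag_s`, `n_steps`.
#' @export
step_sample <- function(r, lag_s) {
  check_positive(lag_s, "lag_s")
  if (any(r < 0)) stop("displacements must be non-negative", call. = FALSE)
  structure(list(r = as.numeric(r), lag_s = lag_s, n_steps = length(r)),
            class = "StepSample")
}

#' Compute frame-to-frame displacements from a track set
#'
#' Euclidean displacement between consecutive observed frames within each
#' track. Pairs spanning a linking gap (frame difference > 1) are excluded so
#' every step shares the single lag `frame_interval_s`.
#'
#' @param tracks A [track_set()].
#' @return A [step_sample()].
#' @export
compute_steps <- function(tracks) {
  stopifnot(inherits(tracks, "TrackSet"))
  tr <- tracks$tracks
  if (!nrow(tr)) stop("track set is empty", call. = FALSE)
  by_id <- split(seq_len(nrow(tr)), tr$track_id)
  r <- unlist(lapply(by_id, function(idx) {
    if (length(idx) < 2L) return(numeric(0))
    df <- diff(tr$frame[idx])
    dx <- diff(tr$x_um[idx]); dy <- diff(tr$y_um[idx])
    sqrt(dx^2 + dy^2)[df == 1L]
  }), use.names = FALSE)
  step_sample(r, tracks$acquisition$frame_interval_s)
}

#' Step-size probability density histogram
#'
#' Histogram of displacements with fixed-width bins starting at 0; density is
#' the bin frequency divided by the bin width, so it integrates to 1.
#'
#' @param sample A [step_sample()].
#' @param bin_width_um Bin width in um (default 0.01).
#' @return An object of class `StepHistogram`: data frame with `bin_center_um`
#'   and `density`, plus attribute `bin_width_um`.
#' @export
step_density <- function(sample, bin_width_um = 0.01) {
  stopifnot(inherits(sample, "StepSample"))
  check_positive(bin_width_um, "bin_width_um")
  if (sample$n_steps < 1L) stop("empty step sample", call. = FALSE)
  nb <- max(1L, ceiling(max(sample$r) / bin_width_um + 1e-9))
  breaks <- seq(0, nb * bin_width_um, by = bin_width_um)
  counts <- tabulate(pmin(findInterval(sample$r, breaks,
                                       rightmost.closed = TRUE,
                                       left.open = FALSE), nb), nbins = nb)
  structure(data.frame(bin_center_um = breaks[-length(breaks)] +
                         bin_width_um / 2,
                       density = counts / sample$n_steps / bin_width_um),
            class = c("StepHistogram", "data.frame"),
            bin_width_um = bin_width_um)
}

# 2D Brownian step-size (Rayleigh) density at lag tau.
rayleigh_step_density <- function(r, D, tau) {
  r / (2 * D * tau) * exp(-r^2 / (4 * D * tau))
}

#' Fit one/two-species diffusion models to a step-size distribution
#'
#' Unweighted least squares of the binned probability density (default
#' 0.01-um bins) against the single-species model
#' `f(r) = r/(2 D tau) exp(-r^2 / (4 D tau))` or the two-species mixture with
#' weight `alpha` on the slow species `D1`. Deterministic multistart over
#' `D in {0.1, 0.5, 1.5} * (mean r^2 / 4 tau)` and `alpha in {0.3, 0.7}`;
#' canonical ordering `D1 <= D2`.
#'
#' @param sample A [step_sample()].
#' @param n_species 1 or 2.
#' @param bin_width_um Histogram bin width (default 0.01 um).
#' @return An object of class `DiffMixtureFit`: list with `n_species`,
#'   `alpha` (weight of `D1_um2_s`; 1 for single fits), `D1_um2_s`,
#'   `D2_um2_s` (NA for single fits), `ssr`, `n_steps`, `lag_s`, `converged`.
#' @export
fit_step_distribution <- function(sample, n_species = 2L,
                                  bin_width_um = 0.01) {
  stopifnot(inherits(sample, "StepSample"))
  if (!n_species %in% c(1L, 2L))
    stop("`n_species` must be 1 or 2", call. = FALSE)
  if (all(sample$r == 0))
    stop("degenerate step sample: all displacements zero", call. = FALSE)
  if (n_species == 2L && sample$n_steps < 500L)
    stop("need >= 500 steps for a two-species fit", call. = FALSE)
  h <- step_density(sample, bin_width_um)
  tau <- sample$lag_s
  D_mom <- mean(sample$r^2) / (4 * tau)   # moment estimate of D
  fit <- fit_stepdens_ls(h$bin_center_um, h$density, tau, n_species, D_mom)
  if (!fit$converged)
    stop("step-size fit did not converge after multistart", call. = FALSE)
  structure(list(n_species = as.integer(n_species), alpha = fit$alpha,
                 D1_um2_s = fit$D1, D2_um2_s = fit$D2, ssr = fit$ssr,
                 n_steps = sample$n_steps, lag_s = tau, converged = TRUE),
            class = "DiffMixtureFit")
}

# Core least-squares engine for binned step-density fits.
fit_stepdens_ls <- function(r, y, tau, n_species, D_mom) {
  if (n_species == 1L) {
    obj <- function(p) sum((y - rayleigh_step_density(r, exp(p), tau))^2)
    best <- NULL
    for (sc in c(0.1, 0.5, 1.5)) {
      op <- stats::optim(log(D_mom * sc), obj, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-12,
                                        ndeps = 1e-6))
      if (is.null(best) || op$value < best$value) best <- op
    }
    return(list(alpha = 1, D1 = exp(best$par), D2 = NA_real_,
                ssr = best$value, converged = best$convergence == 0))
  }
  obj <- function(p) {
    a <- stats::plogis(p[1])
    D1 <- exp(p[2])
    D2 <- D1 * (1 + exp(p[3]))
    m <- a * rayleigh_step_density(r, D1, tau) +
      (1 - a) * rayleigh_step_density(r, D2, tau)
    sum((y - m)^2)
  }
  Ds <- D_mom * c(0.1, 0.5, 1.5)
  starts <- expand.grid(i = 1:2, j = 2:3, a = c(0.3, 0.7))
  starts <- starts[starts$i < starts$j, , drop = FALSE]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    D1_0 <- Ds[starts$i[s]]; D2_0 <- Ds[starts$j[s]]
    p0 <- c(stats::qlogis(starts$a[s]), log(D1_0), log(D2_0 / D1_0 - 1))
    op <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                                control = list(maxit = 1000,
                                               reltol = 1e-12,
                                               ndeps = rep(1e-6, 3))),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value - 1e-15))
      best <- op
  }
  if (is.null(best))
    return(list(alpha = NA, D1 = NA, D2 = NA, ssr = Inf, converged = FALSE))
  a <- stats::plogis(best$par[1])
  D1 <- exp(best$par[2])
  D2 <- D1 * (1 + exp(best$par[3]))
  if (D2 < D1) { tmp <- D1; D1 <- D2; D2 <- tmp; a <- 1 - a }
  list(alpha = a, D1 = D1, D2 = D2, ssr = best$value,
       converged = best$convergence == 0)
}

#' Summary statistics of particle mobility
#'
#' Median and mean step size and mean squared displacement at the sample lag.
#' Fold changes in mobility between conditions are taken as ratios of mean
#' steps.
#'
#' @param sample A [step_sample()].
#' @return List with `median_step_um`, `mean_step_um`, `mean_r2_um2`,
#'   `n_steps`, `lag_s`.
#' @export
summarize_mobility <- function(sample) {
  stopifnot(inherits(sample, "StepSample"))
  if (sample$n_steps < 1L) stop("empty step sample", call. = FALSE)
  list(median_step_um = stats::median(sample$r),
       mean_step_um = mean(sample$r),
       mean_r2_um2 = mean(sample$r^2),
       n_steps = sample$n_steps,
       lag_s = sample$lag_s)
}
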
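# Biosensor trace normalization, product-density conversion, initial rates,
# per-enzyme kcat, adsorption fits, and localization-normalized synergy.

#' Construct a sensor trace
#'
#' @param times_s Strictly increasing times in seconds.
#' @param intensities Sensor intensities (a.u.).
#' @param truth Optional list of generating parameters (attached by the
#'   simulators for round-trip checks).
#' @return An object of class `SensorTrace`.
#' @export
sensor_trace <- function(times_s, intensities, truth = NULL) {
  if (length(times_s) != length(intensities))
    stop("`times_s` and `intensities` must have equal length", call. = FALSE)
  if (any(diff(times_s) <= 0))
    stop("`times_s` must be strictly increasing", call. = FALSE)
  structure(list(times_s = as.numeric(times_s),
                 intensities = as.numeric(intensities)),
            class = "SensorTrace", truth = truth)
}

#' Read/write two-column sensor trace CSVs
#'
#' Plain CSV with columns `time_s`, `intensity`.
#' @param trace A [sensor_trace()].
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "SensorTrace"))
  utils::write.csv(data.frame(time_s = trace$times_s,
                              intensity = trace$intensities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  sensor_trace(df$time_s, df$intensity)
}

window_mean <- function(trace, window, what) {
  sel <- trace$times_s >= window[1] & trace$times_s <= window[2]
  if (!any(sel))
    stop(sprintf("%s window [%g, %g] contains no samples", what,
                 window[1], window[2]), call. = FALSE)
  mean(trace$intensities[sel])
}

#' Normalize a sensor trace between baseline and plateau
#'
#' Rescales intensities to `(I - baseline) / (plateau - baseline)` using the
#' mean intensity inside each window, clipping to `[0, 1.05]` (clipping is
#' flagged in the `clipped` attribute). For a product sensor whose plateau
#' corresponds to complete substrate conversion, the normalized trace is the
#' converted substrate fraction.
#'
#' @param trace A [sensor_trace()].
#' @param baseline_window,plateau_window Two-element `c(t0, t1)` time ranges
#'   (s); must not overlap, and the plateau mean must exceed the baseline
#'   mean (otherwise the reaction did not complete and normalization is
#'   refused).
#' @return A normalized `SensorTrace` (dimensionless intensities).
#' @export
normalize_sensor_trace <- function(trace, baseline_window, plateau_window) {
  stopifnot(inherits(trace, "SensorTrace"),
            length(baseline_window) == 2L, length(plateau_window) == 2L)
  if (max(baseline_window[1], plateau_window[1]) <=
      min(baseline_window[2], plateau_window[2]))
    stop("baseline and plateau windows must not overlap", call. = FALSE)
  b <- window_mean(trace, baseline_window, "baseline")
  p <- window_mean(trace, plateau_window, "plateau")
  if (p <= b)
    stop("plateau mean <= baseline mean: reaction did not complete",
         call. = FALSE)
  norm <- (trace$intensities - b) / (p - b)
  clipped <- any(norm < 0 | norm > 1.05)
  out <- sensor_trace(trace$times_s, pmin(pmax(norm, 0), 1.05),
                      truth = attr(trace, "truth"))
  attr(out, "clipped") <- clipped
  out
}

#' Convert a normalized sensor trace to product lipid density
#'
#' Product density = normalized intensity x total product density at
#' completion, clipped at the total (substrate conservation).
#'
#' @param norm A normalized [sensor_trace()] (values in `[0, 1.05]`).
#' @param total_density Total product lipids/um^2 at completion.
#' @return An object of class `ProductTrace`: list with `times_s`,
#'   `product_density`, `total_density`.
#' @export
trace_to_product_density <- function(norm, total_density) {
  stopifnot(inherits(norm, "SensorTrace"))
  check_positive(total_density, "total_density")
  if (any(norm$intensities < 0 | norm$intensities > 1.05))
    stop("`norm` must be a normalized trace in [0, 1.05]", call. = FALSE)
  structure(list(times_s = norm$times_s,
                 product_density = pmin(norm$intensities * total_density,
                                        total_density),
                 total_density = total_density),
            class = "ProductTrace")
}

#' Initial reaction rate from a product trace
#'
#' Ordinary least-squares slope of product density versus time over the
#' maximal prefix of the trace with product below `depletion_cap` x total
#' density (default cap 0.1, which keeps the secant-vs-tangent bias of the
#' substrate-depletion model below ~5%).
#'
#' @param product A [trace_to_product_density()] result.
#' @param depletion_cap Fraction of the total density delimiting the linear
#'   window.
#' @return List with `rate` (lipids/um^2/s), `window_s` (time range used),
#'   `n_points`.
#' @export
initial_rate <- function(product, depletion_cap = 0.1) {
  stopifnot(inherits(product, "ProductTrace"))
  check_fraction(depletion_cap, "depletion_cap")
  below <- product$product_density <= depletion_cap * product$total_density
  n_pref <- if (all(below)) length(below) else which(!below)[1] - 1L
  if (n_pref < 5L)
    stop("fewer than 5 points below the depletion cap; lower the cap or ",
         "sample the early phase more densely", call. = FALSE)
  t <- product$times_s[seq_len(n_pref)]
  y <- product$product_density[seq_len(n_pref)]
  fit <- stats::lm.fit(cbind(1, t), y)
  list(rate = unname(fit$coefficients[2]),
       window_s = range(t), n_points = n_pref)
}

#' Per-enzyme catalytic rate
#'
#' `kcat = initial rate / enzyme surface density`, in product lipids per
#' second per membrane-bound enzyme.
#'
#' @param rate Initial bulk rate in lipids/um^2/s.
#' @param enzyme_density Membrane-bound enzymes per um^2 (> 0).
#' @return kcat (lipids/s per enzyme).
#' @export
compute_kcat <- function(rate, enzyme_density) {
  check_positive(enzyme_density, "enzyme_density")
  rate / enzyme_density
}

#' Full trace-to-kcat pipeline
#'
#' Normalize a raw catalysis sensor trace, convert it to product density,
#' measure the initial rate below the depletion cap, and divide by the enzyme
#' surface density.
#'
#' @param trace Raw [sensor_trace()] of the product biosensor.
#' @param total_density Product lipids/um^2 at completion (e.g. the substrate
#'   density from [lipid_surface_density()]).
#' @param enzyme_density Membrane-bound enzymes per um^2.
#' @param baseline_window,plateau_window Normalization windows (s); by
#'   default the baseline is the first sample (a catalysis trace starts at
#'   reaction start, where the product sensor reads zero) and the plateau the
#'   last 10% of the trace. Traces with a pre-reaction phase should pass an
#'   explicit baseline window.
#' @param depletion_cap Initial-rate window cap (default 0.1).
#' @return An object of class `KineticsResult`: list with `initial_rate`,
#'   `enzyme_density`, `kcat`, `window_s`, `n_points`.
#' @export
estimate_kcat_from_trace <- function(trace, total_density, enzyme_density,
                                     baseline_window = NULL,
                                     plateau_window = NULL,
                                     depletion_cap = 0.1) {
  stopifnot(inherits(trace, "SensorTrace"))
  tspan <- range(trace$times_s)
  if (is.null(baseline_window))
    baseline_window <- c(tspan[1], tspan[1])
  if (is.null(plateau_window))
    plateau_window <- c(tspan[2] - 0.1 * diff(tspan), tspan[2])
  norm <- normalize_sensor_trace(trace, baseline_window, plateau_window)
  product <- trace_to_product_density(norm, total_density)
  ir <- initial_rate(product, depletion_cap)
  structure(list(initial_rate = ir$rate, enzyme_density = enzyme_density,
                 kcat = compute_kcat(ir$rate, enzyme_density),
                 window_s = ir$window_s, n_points = ir$n_points),
            class = "KineticsResult")
}

#' Fit a pseudo-first-order adsorption model to an equilibration trace
#'
#' Least squares of `I(t) = plateau * (1 - exp(-k_obs * t))`. Warns when the
#' trace spans less than `3 / k_obs` (plateau poorly constrained).
#'
#' @param trace A [sensor_trace()].
#' @return List with `k_obs` (1/s), `plateau` (a.u.), `ssr`.
#' @export
fit_adsorption <- function(trace) {
  stopifnot(inherits(trace, "SensorTrace"))
  t <- trace$times_s; I <- trace$intensities
  if (stats::sd(I) == 0 || max(I) <= 0)
    stop("degenerate trace: no signal change to fit", call. = FALSE)
  plateau0 <- mean(I[t >= stats::quantile(t, 0.8)])
  if (plateau0 <= 0) plateau0 <- max(I)
  i_half <- which(I >= 0.5 * plateau0)[1]
  k0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else
    1 / max(t[t > 0][1], diff(range(t)) / 10)
  obj <- function(p) {
    m <- exp(p[2]) * (1 - exp(-exp(p[1]) * t))
    sum((I - m)^2)
  }
  best <- NULL
  for (sc in c(0.3, 1, 3)) {
    op <- tryCatch(stats::optim(c(log(k0 * sc), log(abs(plateau0))), obj,
                                method = "BFGS",
                                control = list(maxit = 500)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("adsorption fit did not converge", call. = FALSE)
  k_obs <- exp(best$par[1])
  if (diff(range(t)) < 3 / k_obs)
    warning("trace spans less than 3/k_obs; plateau may be poorly constrained")
  list(k_obs = k_obs, plateau = exp(best$par[2]), ssr = best$value)
}

#' Localization-normalized activation fold (synergy)
#'
#' Ratio of per-enzyme rates between a test and a reference condition:
#' `fold = (rate_test / rate_ref) / (density_test / density_ref)`. In the
#' two-phase (ATP-spike) design, densities are measured during the pre-ATP
#' equilibration phase and rates after ATP addition.
#'
#' @param rate_test,rate_ref Bulk initial rates (lipids/um^2/s), > 0.
#' @param density_test,density_ref Membrane-bound enzyme densities
#'   (enzymes/um^2), > 0.
#' @return Fold activation after accounting for localization.
#' @export
synergy_fold <- function(rate_test, rate_ref, density_test, density_ref) {
  for (v in c(rate_test, rate_ref, density_test, density_ref))
    check_positive(v, "synergy inputs")
  (rate_test / rate_ref) / (density_test / density_ref)
}
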
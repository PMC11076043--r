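# Pipeline orchestration: run simulate -> track -> dwell/diffusion/kinetics
# stages from a single configuration with uniform seeding and serialization.

#' Run an analysis pipeline from a configuration
#'
#' Executes the configured stages in order, writing versioned outputs
#' (CSV/JSON) and a manifest recording inputs, parameters, per-stage seeds,
#' and the package version. Per-stage seeds are derived deterministically
#' from the global seed and the stage name, so adding stages never shifts the
#' randomness of existing ones; re-running the same configuration reproduces
#' identical numeric outputs.
#'
#' Supported stage kinds and their parameter blocks:
#' \describe{
#'   \item{`simulate_dwell`}{`n_events, alpha, tau1_s, tau2_s,
#'     frame_interval_s, min_frames` -> `dwell.csv` (`n_events` rather than
#'     `n`, which YAML 1.1 parses as a boolean)}
#'   \item{`simulate_tracks`}{fields of [binding_sim_config()] plus
#'     `n_frames`, `field_area_um2` (or `image_shape`, `pixel_size_um`),
#'     `frame_interval_s` -> `tracks.csv`}
#'   \item{`dwell_fit`}{`tracks` (CSV path or prior stage name),
#'     `n_components` -> `dwell_fit.json`}
#'   \item{`diffusion_fit`}{`tracks` (CSV path or prior stage name),
#'     `n_species`, `bin_width_um` -> `diffusion_fit.json`}
#'   \item{`simulate_catalysis`}{fields of [catalysis_sim_config()] ->
#'     `catalysis.csv`}
#'   \item{`kcat`}{`trace` (CSV path or prior stage name), `total_density`,
#'     `enzyme_density`, `depletion_cap` -> `kcat.json`}
#' }
#'
#' @param config Path to a YAML/JSON file, or an equivalent list, with fields
#'   `seed` (global integer seed), `out_dir`, and `stages` (a named list:
#'   stage name -> list with `kind` and parameters).
#' @return The run manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$stages))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  global_seed <- config$seed %||% 1L
  manifest <- list(package = "smtirf",
                   version = as.character(utils::packageVersion("smtirf")),
                   global_seed = global_seed,
                   stages = list())
  results <- list()
  for (name in names(config$stages)) {
    st <- config$stages[[name]]
    seed <- derive_seed(global_seed, name)
    rec <- list(kind = st$kind, seed = seed, params = st[names(st) != "kind"])
    res <- tryCatch(
      run_stage(st, seed, name, out_dir, results),
      error = function(e) {
        manifest$stages[[name]] <- c(rec, list(status = "failed",
                                               error = conditionMessage(e)))
        write_manifest(manifest, out_dir)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      })
    results[[name]] <- res$value
    manifest$stages[[name]] <- c(rec, list(status = "ok",
                                           outputs = res$outputs))
  }
  write_manifest(manifest, out_dir)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

resolve_input <- function(x, results, out_dir) {
  if (!is.null(results[[x]])) return(results[[x]])
  if (file.exists(x)) return(x)
  if (file.exists(file.path(out_dir, x))) return(file.path(out_dir, x))
  stop(sprintf("input '%s' is neither a prior stage nor an existing file", x),
       call. = FALSE)
}

run_stage <- function(st, seed, name, out_dir, results) {
  kind <- st$kind
  if (is.null(kind)) stop("stage has no `kind`", call. = FALSE)
  switch(kind,
    simulate_dwell = {
      s <- simulate_dwell_sample(st$n_events %||% st$n, st$alpha, st$tau1_s,
                                 st$tau2_s %||% st$tau1_s,
                                 st$frame_interval_s %||% 0.052,
                                 st$min_frames %||% 2L, seed = seed)
      path <- file.path(out_dir, paste0(name, "_dwell.csv"))
      utils::write.csv(data.frame(duration_s = s$durations), path,
                       row.names = FALSE)
      list(value = s, outputs = path)
    },
    simulate_tracks = {
      acq <- acquisition_params(st$frame_interval_s %||% 0.052,
                                st$pixel_size_um %||% 0.1,
                                st$image_shape,
                                st$field_area_um2,
                                st$n_frames %||% 1000L)
      cfg <- binding_sim_config(
        arrival_rate = st$arrival_rate %||% 0.05,
        dwell_alpha = st$dwell_alpha %||% 0.5,
        dwell_tau1_s = st$dwell_tau1_s %||% 0.5,
        dwell_tau2_s = st$dwell_tau2_s %||% 2,
        diff_alpha = st$diff_alpha %||% 0.5,
        D1_um2_s = st$D1_um2_s %||% 0.3,
        D2_um2_s = st$D2_um2_s %||% 1,
        couple_states = st$couple_states %||% FALSE,
        rebind_prob = st$rebind_prob %||% 0,
        rebind_radius_um = st$rebind_radius_um %||% 0.1,
        bleach_rate_s = st$bleach_rate_s %||% 0,
        seed = seed)
      ts <- simulate_track_set(cfg, acq)
      path <- file.path(out_dir, paste0(name, "_tracks.csv"))
      write_tracks_csv(ts, path)
      list(value = ts, outputs = path)
    },
    dwell_fit = {
      inp <- resolve_input(st$tracks, results, out_dir)
      ts <- if (inherits(inp, "TrackSet")) inp else
        read_tracks_csv(inp, acquisition_params(
          frame_interval_s = st$frame_interval_s %||% 0.052,
          n_frames = st$n_frames %||% 1000L))
      ts <- filter_tracks(ts, filter_rules(
        drop_present_at_start = st$drop_present_at_start %||% TRUE,
        drop_present_at_end = st$drop_present_at_end %||% TRUE))
      s <- compute_dwell_times(ts)
      fit <- fit_survival(s, st$n_components %||% 2L)
      path <- file.path(out_dir, paste0(name, "_dwell_fit.json"))
      jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      list(value = fit, outputs = path)
    },
    diffusion_fit = {
      inp <- resolve_input(st$tracks, results, out_dir)
      ts <- if (inherits(inp, "TrackSet")) inp else
        read_tracks_csv(inp, acquisition_params(
          frame_interval_s = st$frame_interval_s %||% 0.052,
          n_frames = st$n_frames %||% 1000L))
      s <- compute_steps(ts)
      fit <- fit_step_distribution(s, st$n_species %||% 2L,
                                   st$bin_width_um %||% 0.01)
      path <- file.path(out_dir, paste0(name, "_diffusion_fit.json"))
      jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      list(value = fit, outputs = path)
    },
    simulate_catalysis = {
      cfg <- catalysis_sim_config(st$kcat_per_enzyme, st$enzyme_density,
                                  st$substrate_density0,
                                  st$t_grid_s %||%
                                    seq(st$t_min_s %||% 0, st$t_max_s,
                                        length.out = st$n_points %||% 2000L),
                                  st$noise_sd_frac %||% 0, seed = seed)
      tr <- simulate_catalysis_trace(cfg)
      path <- file.path(out_dir, paste0(name, "_catalysis.csv"))
      write_trace_csv(tr, path)
      list(value = tr, outputs = path)
    },
    kcat = {
      inp <- resolve_input(st$trace, results, out_dir)
      tr <- if (inherits(inp, "SensorTrace")) inp else read_trace_csv(inp)
      res <- estimate_kcat_from_trace(tr, st$total_density,
                                      st$enzyme_density,
                                      depletion_cap = st$depletion_cap %||%
                                        0.1)
      path <- file.path(out_dir, paste0(name, "_kcat.json"))
      jsonlite::write_json(unclass(res), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      list(value = res, outputs = path)
    },
    stop(sprintf("unknown stage kind '%s'", kind), call. = FALSE)
  )
}
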
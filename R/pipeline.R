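#' Pipeline configuration
#'
#' One structured home for every tunable parameter shared across stages;
#' the config is echoed verbatim into each run manifest so that every
#' emitted number is traceable to config plus inputs.
#'
#' @param frame_interval_s Frame interval (s).
#' @param pixel_size_um Camera pixel size (um).
#' @param bp_per_um Position calibration (default 3750 bp/um, i.e.
#'   0.08 um ~ 300 bp).
#' @param collision_zone_half_width_um Collision-zone half-width (um).
#' @param n_max_lags MSD lags used for the diffusion fit.
#' @param noise_sigma_um Localization noise sd used by the mobility
#'   classifier.
#' @param n_bootstrap Bootstrap resamples for all CIs.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param paths Named list of input/output paths.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(frame_interval_s = 0.05, pixel_size_um = 0.1,
                            bp_per_um = 3750,
                            collision_zone_half_width_um = 0.08,
                            n_max_lags = 10L, noise_sigma_um = 0.08 / 3,
                            n_bootstrap = 1000L, seed = 1L,
                            paths = list()) {
  for (nm in c("frame_interval_s", "pixel_size_um", "bp_per_um",
               "collision_zone_half_width_um", "noise_sigma_um")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a non-negative finite number", nm), call. = FALSE)
    }
  }
  structure(list(
    frame_interval_s = frame_interval_s,
    pixel_size_um = pixel_size_um,
    bp_per_um = bp_per_um,
    collision_zone_half_width_um = collision_zone_half_width_um,
    n_max_lags = as.integer(n_max_lags),
    noise_sigma_um = noise_sigma_um,
    n_bootstrap = as.integer(n_bootstrap),
    seed = as.integer(seed),
    paths = paths
  ), class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config A `"pipeline_config"`.
#' @param path YAML file path.
#' @return `path` invisibly (write); a `"pipeline_config"` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v)
}

# Small stable polynomial hash of a serialized object; enough to
# fingerprint configs and inputs in the manifest without external
# dependencies. Arithmetic stays below 2^52 so doubles are exact.
fnv1a <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) h <- (h * 8191 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

derive_seed <- function(seed, offset) (seed + 104729L * offset) %% .Machine$integer.max

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order on simulated data:
#' `simulate` (trajectories + image stack), `track` (localize and link),
#' `diffusion` (MSD fits and condition summary), `bypass` (collision
#' scoring at configured nucleosome positions). Outputs are written
#' under `output_dir` together with a JSON run manifest recording the
#' package version, config hash, per-stage records and output file
#' hashes. Identical seed and config give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "track", "diffusion", "bypass")`.
#' @param output_dir Output directory (created if missing).
#' @param sim_config Optional [simulation_config()] overriding the
#'   simulated conditions; defaults derive from `config`.
#' @param n_molecules Number of simulated molecules.
#' @param nucleosome_positions Obstacle / zone positions (um) used by
#'   `simulate` and `bypass`.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, stages = c("simulate", "track",
                                            "diffusion", "bypass"),
                         output_dir = tempfile("smcurtain_run_"),
                         sim_config = NULL, n_molecules = 10L,
                         nucleosome_positions = numeric(0)) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "track", "diffusion", "bypass")
  stages <- if (length(stages)) match.arg(stages, all_stages, several.ok = TRUE) else character(0)
  # dependency check before any stage runs
  need <- list(track = "simulate", diffusion = "track", bypass = "track")
  for (s in stages) {
    dep <- need[[s]]
    if (!is.null(dep) && !dep %in% stages && is.null(config$paths[[dep]])) {
      stop(sprintf("stage `%s` requires stage `%s` (or a path for its output)",
                   s, dep), call. = FALSE)
    }
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "smcurtain",
    version = as.character(utils::packageVersion("smcurtain")),
    config = unclass(config),
    config_hash = fnv1a(unclass(config)),
    stages = list()
  )
  log_stage <- function(name, ...) {
    message(sprintf("[smcurtain] stage %s: %s", name, sprintf(...)))
  }
  trajectories <- NULL

  if ("simulate" %in% stages) {
    scfg <- sim_config %||% simulation_config(
      frame_interval = config$frame_interval_s,
      n_frames = 400L,
      localization_sigma = config$noise_sigma_um,
      obstacle_positions = nucleosome_positions,
      obstacle_bypass_prob = 0.3,
      bp_per_um = config$bp_per_um,
      seed = derive_seed(config$seed, 1L))
    if (is.null(scfg$seed)) scfg$seed <- derive_seed(config$seed, 1L)
    sims <- simulate_ensemble(scfg, n_molecules)
    stack <- simulate_image_stack(sims$trajectories,
                                  pixel_size = config$pixel_size_um,
                                  seed = derive_seed(config$seed, 2L))
    tpath <- file.path(output_dir, "simulated_trajectories.tsv")
    write_trajectories(sims$trajectories, tpath, bp_per_um = config$bp_per_um)
    spath <- file.path(output_dir, "simulated_stack.tiff")
    write_image_stack(stack, spath)
    log_stage("simulate", "%d molecules, %d frames", n_molecules,
              scfg$n_frames)
    manifest$stages$simulate <- list(
      n_molecules = n_molecules, n_frames = scfg$n_frames,
      trajectories = basename(tpath), stack = basename(spath),
      trajectories_hash = fnv1a(readLines(tpath)))
  }

  if ("track" %in% stages) {
    spath <- config$paths$simulate %||% file.path(output_dir, "simulated_stack.tiff")
    stack <- read_image_stack(spath)
    trajectories <- track_stack(stack)
    tpath <- file.path(output_dir, "tracked_trajectories.tsv")
    write_trajectories(trajectories, tpath, bp_per_um = config$bp_per_um)
    log_stage("track", "%d trajectories recovered", length(trajectories))
    manifest$stages$track <- list(
      n_trajectories = length(trajectories), trajectories = basename(tpath),
      trajectories_hash = fnv1a(readLines(tpath)))
  }

  get_tracked <- function() {
    trajectories %||% read_trajectories(
      config$paths$track %||% file.path(output_dir, "tracked_trajectories.tsv"),
      bp_per_um = config$bp_per_um)
  }

  if ("diffusion" %in% stages) {
    trs <- get_tracked()
    ests <- lapply(trs, function(tr) {
      fit_diffusion_coefficient(compute_msd(tr, n_max = config$n_max_lags))
    })
    summ <- summarize_condition(ests, condition = "pipeline",
                                noise_sigma = config$noise_sigma_um)
    per <- data.frame(
      molecule_id = vapply(ests, function(e) as.character(e$molecule_id), ""),
      slope = vapply(ests, function(e) e$slope, 1),
      intercept = vapply(ests, function(e) e$intercept, 1),
      diffusion_coefficient = vapply(ests, function(e) e$diffusion_coefficient, 1),
      r_squared = vapply(ests, function(e) e$r_squared, 1),
      nonphysical = vapply(ests, function(e) e$nonphysical, TRUE))
    utils::write.csv(per, file.path(output_dir, "diffusion_per_molecule.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      summ[c("condition", "mean", "sem", "n_molecules", "percent_mobile")],
      file.path(output_dir, "diffusion_summary.json"), auto_unbox = TRUE,
      digits = NA)
    log_stage("diffusion", "mean D = %.4g um^2/s over %d molecules",
              summ$mean, summ$n_molecules)
    manifest$stages$diffusion <- list(mean_D = summ$mean, sem = summ$sem,
                                      n = summ$n_molecules)
  }

  if ("bypass" %in% stages) {
    if (!length(nucleosome_positions)) {
      log_stage("bypass", "no nucleosome positions configured; skipped")
    } else {
      trs <- get_tracked()
      zones <- collision_zones(nucleosome_positions,
                               half_width = config$collision_zone_half_width_um)
      recs <- do.call(rbind, lapply(trs, segment_collisions, zones = zones))
      utils::write.csv(recs, file.path(output_dir, "collision_records.csv"),
                       row.names = FALSE)
      if (any(recs$outcome != "censored")) {
        summ <- summarize_bypass(recs, n_bootstrap = config$n_bootstrap,
                                 seed = derive_seed(config$seed, 3L),
                                 condition = "pipeline")
        jsonlite::write_json(
          summ[c("condition", "n_collisions", "n_bypass", "p_bypass",
                 "ci_low", "ci_high")],
          file.path(output_dir, "bypass_summary.json"), auto_unbox = TRUE,
          digits = NA)
        log_stage("bypass", "p_bypass = %.3f over %d collisions",
                  summ$p_bypass, summ$n_collisions)
        manifest$stages$bypass <- list(p_bypass = summ$p_bypass,
                                       n_collisions = summ$n_collisions)
      } else {
        log_stage("bypass", "no scorable collisions")
        manifest$stages$bypass <- list(p_bypass = NA, n_collisions = 0L)
      }
    }
  }

  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
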
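#' Configuration for trajectory simulation
#'
#' Collects the physical parameters of a simulated 1D sliding experiment
#' on a doubly tethered DNA: Brownian diffusion with reflecting tethered
#' ends, optional partially permeable nucleosome obstacles, and Gaussian
#' localization noise added to the emitted positions.
#'
#' @param diffusion_coefficient 1D diffusion coefficient D in um^2/s (>= 0).
#' @param frame_interval Frame interval in seconds (default 0.05 s; typical
#'   acquisitions run at 50-100 ms frame rates).
#' @param n_frames Number of frames to simulate.
#' @param dna_length Extended DNA length in um. Default is 48.5 kb at the
#'   3750 bp/um calibration (0.08 um ~ 300 bp), about 12.93 um.
#' @param localization_sigma Standard deviation of the Gaussian
#'   localization noise added to emitted positions (um). The default
#'   0.08/3 um corresponds to a collision-zone half-width of three
#'   standard deviations equal to 0.08 um.
#' @param obstacle_positions Positions of nucleosome obstacles (um),
#'   each inside `[0, dna_length]`.
#' @param obstacle_bypass_prob Probability that an attempted crossing of
#'   an obstacle succeeds; failed attempts reflect the particle back to
#'   its pre-step side.
#' @param bp_per_um Calibration between micrometers and base pairs.
#' @param start_position Initial position (um); `NULL` draws uniformly on
#'   the DNA.
#' @param blink_prob Per-frame probability that the emitted position is
#'   dropped (`NA`), emulating fluorophore blinking. Off by default.
#' @param seed Integer seed; identical seed and config give identical
#'   output.
#'
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(diffusion_coefficient = 0.5,
                              frame_interval = 0.05,
                              n_frames = 1000L,
                              dna_length = 48500 / 3750,
                              localization_sigma = 0.08 / 3,
                              obstacle_positions = numeric(0),
                              obstacle_bypass_prob = 1,
                              bp_per_um = 3750,
                              start_position = NULL,
                              blink_prob = 0,
                              seed = NULL) {
  chk <- function(x, nm, lo = 0, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= lo) || (!strict && x < lo)) {
      stop(sprintf("`%s` must be a finite number %s %g", nm,
                   if (strict) ">" else ">=", lo), call. = FALSE)
    }
  }
  chk(diffusion_coefficient, "diffusion_coefficient")
  chk(frame_interval, "frame_interval", strict = TRUE)
  chk(dna_length, "dna_length", strict = TRUE)
  chk(localization_sigma, "localization_sigma")
  chk(bp_per_um, "bp_per_um", strict = TRUE)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  if (obstacle_bypass_prob < 0 || obstacle_bypass_prob > 1 ||
      !is.finite(obstacle_bypass_prob)) {
    stop("`obstacle_bypass_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (blink_prob < 0 || blink_prob >= 1) stop("`blink_prob` must lie in [0, 1)", call. = FALSE)
  obstacle_positions <- as.numeric(obstacle_positions)
  if (any(!is.finite(obstacle_positions)) ||
      any(obstacle_positions < 0 | obstacle_positions > dna_length)) {
    stop("all `obstacle_positions` must lie within [0, dna_length]", call. = FALSE)
  }
  if (!is.null(start_position)) {
    chk(start_position, "start_position")
    if (start_position > dna_length) stop("`start_position` exceeds `dna_length`", call. = FALSE)
  }
  structure(list(
    diffusion_coefficient = diffusion_coefficient,
    frame_interval = frame_interval,
    n_frames = n_frames,
    dna_length = dna_length,
    localization_sigma = localization_sigma,
    obstacle_positions = sort(obstacle_positions),
    obstacle_bypass_prob = obstacle_bypass_prob,
    bp_per_um = bp_per_um,
    start_position = start_position,
    blink_prob = blink_prob,
    seed = seed
  ), class = "simulation_config")
}

# Reflect a proposed position into [0, L] (mirror reflection at the
# tethered ends; preserves the equilibrium occupancy of the interval).
reflect_into <- function(x, L) {
  # fold onto [0, 2L] then mirror the upper half
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate a 1D sliding trajectory with obstacles
#'
#' Positions follow reflected Brownian motion on `[0, dna_length]`:
#' per-frame displacements are zero-mean Gaussian with variance
#' `2 * D * dt`. A step whose path crosses an obstacle succeeds with
#' probability `obstacle_bypass_prob`; otherwise the endpoint is mirrored
#' back across the obstacle onto the pre-step side. Independent Gaussian
#' localization noise of sd `localization_sigma` is added to the emitted
#' positions; the noise-free path and every attempted obstacle crossing
#' are returned as ground truth.
#'
#' @param config A [simulation_config()].
#' @param molecule_id Identifier stored in the emitted trajectory.
#' @return A list with elements `trajectory` (a [trajectory()], emitted
#'   noisy positions) and `ground_truth`: a list with `true_positions`
#'   (noise-free path) and `crossings`, a data frame with one row per
#'   attempted obstacle crossing (`frame`, `obstacle`, `crossed`).
#' @export
#' @examples
#' cfg <- simulation_config(diffusion_coefficient = 0.1, n_frames = 200,
#'                          seed = 1)
#' sim <- simulate_trajectory(cfg)
#' sim$trajectory
simulate_trajectory <- function(config, molecule_id = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_frames
  L <- config$dna_length
  obs <- config$obstacle_positions
  p_by <- config$obstacle_bypass_prob
  sd_step <- sqrt(2 * config$diffusion_coefficient * config$frame_interval)

  x <- numeric(n)
  x[1L] <- if (is.null(config$start_position)) stats::runif(1L, 0, L) else config$start_position
  steps <- if (sd_step > 0) stats::rnorm(n - 1L, 0, sd_step) else numeric(n - 1L)

  cross_frame <- integer(0); cross_obs <- integer(0); cross_ok <- logical(0)

  for (i in seq_len(n - 1L)) {
    prev <- x[i]
    prop <- prev + steps[i]
    if (length(obs)) {
      cleared <- rep(FALSE, length(obs))
      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (iter > 100L) { prop <- prev; break }
        if (prop < 0 || prop > L) { prop <- reflect_into(prop, L); next }
        lo <- min(prev, prop); hi <- max(prev, prop)
        hit <- which(!cleared & obs > lo & obs < hi)
        if (!length(hit)) break
        # resolve the obstacle nearest the pre-step position first
        j <- hit[which.min(abs(obs[hit] - prev))]
        ok <- stats::runif(1L) < p_by
        cross_frame <- c(cross_frame, i + 1L)
        cross_obs <- c(cross_obs, j)
        cross_ok <- c(cross_ok, ok)
        if (ok) {
          cleared[j] <- TRUE
        } else {
          prop <- 2 * obs[j] - prop  # mirror back onto the pre-step side
          cleared[] <- FALSE
          cleared[j] <- TRUE  # already rejected; do not re-test this step
        }
      }
    } else {
      prop <- reflect_into(prop, L)
    }
    x[i + 1L] <- reflect_into(prop, L)
  }

  emitted <- x
  if (config$localization_sigma > 0) {
    emitted <- emitted + stats::rnorm(n, 0, config$localization_sigma)
  }
  if (config$blink_prob > 0) {
    off <- stats::runif(n) < config$blink_prob
    off[1L] <- FALSE
    emitted[off] <- NA_real_
    # keep the trajectory finite: bridge blinks by linear interpolation
    emitted <- stats::approx(seq_len(n)[!is.na(emitted)],
                             emitted[!is.na(emitted)],
                             xout = seq_len(n), rule = 2)$y
  }

  list(
    trajectory = trajectory(emitted, frame_interval = config$frame_interval,
                            molecule_id = molecule_id, source = "simulated"),
    ground_truth = list(
      true_positions = x,
      crossings = data.frame(frame = cross_frame, obstacle = cross_obs,
                             crossed = cross_ok)
    )
  )
}

#' Simulate an ensemble of trajectories
#'
#' Convenience wrapper running [simulate_trajectory()] `n` times with
#' molecule ids `1..n`. When `config$seed` is set, per-molecule seeds are
#' derived deterministically from it.
#'
#' @param config A [simulation_config()].
#' @param n Number of molecules.
#' @return A list with `trajectories` (list of [trajectory()]) and
#'   `ground_truths` (list of ground-truth records).
#' @export
simulate_ensemble <- function(config, n) {
  base_seed <- config$seed
  trs <- vector("list", n); gts <- vector("list", n)
  for (k in seq_len(n)) {
    cfg <- config
    if (!is.null(base_seed)) cfg$seed <- (base_seed + 7919L * k) %% .Machine$integer.max
    sim <- simulate_trajectory(cfg, molecule_id = k)
    trs[[k]] <- sim$trajectory
    gts[[k]] <- sim$ground_truth
  }
  list(trajectories = trs, ground_truths = gts)
}

#' Render trajectories as a synthetic TIRF image stack
#'
#' Each frame contains one diffraction-limited 2D Gaussian spot per
#' molecule, centered at the molecule's position along the DNA axis, on a
#' constant background with Poisson or Gaussian noise. The DNA axis maps
#' to the image x (column) axis. As on a curtain, where parallel DNA
#' molecules are spaced across the field, each trajectory is rendered at
#' its own transverse offset (`row_spacing_um` apart) unless explicit
#' `y_positions` are given.
#'
#' @param trajectories List of [trajectory()] objects with equal frame
#'   counts.
#' @param psf_sigma Point-spread-function sd in um (default 0.17 um,
#'   diffraction-limited for visible light).
#' @param amplitude Peak signal photons per molecule per frame.
#' @param background Background photons per pixel per frame.
#' @param noise_model `"poisson"` (shot noise on signal + background) or
#'   `"gaussian"` (additive, sd `gaussian_sd`), or `"none"`.
#' @param pixel_size Pixel size in um (default 0.1).
#' @param row_spacing_um Transverse spacing between consecutive DNA rows.
#' @param y_positions Optional explicit transverse position (um) per
#'   trajectory; overrides `row_spacing_um`.
#' @param gaussian_sd Noise sd for the Gaussian model (default
#'   `sqrt(background)`).
#' @param seed Integer seed.
#' @return An object of class `"image_stack"`: list with `frames` (list
#'   of numeric matrices, rows = y), `pixel_size_um`, `frame_interval_s`.
#' @export
simulate_image_stack <- function(trajectories, psf_sigma = 0.17,
                                 amplitude = 1000, background = 20,
                                 noise_model = c("poisson", "gaussian", "none"),
                                 pixel_size = 0.1, row_spacing_um = 1,
                                 y_positions = NULL,
                                 gaussian_sd = sqrt(background),
                                 seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories)) stop("need at least one trajectory", call. = FALSE)
  nf <- unique(vapply(trajectories, function(t) length(t$positions), 1L))
  if (length(nf) != 1L) stop("trajectories have mismatched frame counts", call. = FALSE)
  if (psf_sigma <= 0 || pixel_size <= 0) {
    stop("`psf_sigma` and `pixel_size` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  dt <- trajectories[[1L]]$frame_interval
  xmax <- max(vapply(trajectories, function(t) max(t$positions), 1))
  pad <- 6 * psf_sigma
  nx <- as.integer(ceiling((xmax + pad) / pixel_size)) + 1L
  if (is.null(y_positions)) {
    y_positions <- pad + (seq_along(trajectories) - 1L) * row_spacing_um
  }
  if (length(y_positions) != length(trajectories)) {
    stop("`y_positions` must have one entry per trajectory", call. = FALSE)
  }
  ny <- as.integer(ceiling((max(y_positions) + pad) / pixel_size)) + 1L
  # pixel-center coordinates in um
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size

  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- matrix(background, nrow = ny, ncol = nx)
    for (k in seq_along(trajectories)) {
      x0 <- trajectories[[k]]$positions[f]
      gx <- exp(-(xc - x0)^2 / (2 * psf_sigma^2))
      gy <- exp(-(yc - y_positions[k])^2 / (2 * psf_sigma^2))
      img <- img + amplitude * (gy %o% gx)
    }
    if (noise_model == "poisson") {
      img <- matrix(stats::rpois(length(img), img), nrow = ny)
    } else if (noise_model == "gaussian") {
      img <- img + matrix(stats::rnorm(length(img), 0, gaussian_sd), nrow = ny)
    }
    frames[[f]] <- img
  }
  structure(list(frames = frames, pixel_size_um = pixel_size,
                 frame_interval_s = dt),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, pixel %g um, dt %g s\n",
              length(x$frames), d[1L], d[2L], x$pixel_size_um,
              x$frame_interval_s))
  invisible(x)
}

#' Write an image stack as multi-page TIFF with a metadata sidecar
#'
#' Intensities are stored as 32-bit float scaled to `[0, 1]`; the scale
#' factor, pixel size and frame interval are written to a YAML sidecar
#' (`<path>.meta.yaml`) so that [read_image_stack()] restores the stack
#' exactly.
#'
#' @param stack An `"image_stack"`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1, max(vapply(stack$frames, max, 1)))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / scale), path,
                  bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size_um,
                        frame_interval_s = stack$frame_interval_s,
                        intensity_scale = scale),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path; the sidecar `<path>.meta.yaml` must exist.
#' @return An `"image_stack"`.
#' @export
read_image_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) f * meta$intensity_scale)
  structure(list(frames = frames, pixel_size_um = meta$pixel_size_um,
                 frame_interval_s = meta$frame_interval_s),
            class = "image_stack")
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Each of `n_fluorophores` bleaches independently at a geometric time
#' with per-frame probability `bleach_prob_per_frame`; the trace starts at
#' `n_fluorophores * unit_intensity` plus noise and drops by
#' `unit_intensity` at each bleaching event. Values below `background` are
#' clipped and flagged.
#'
#' @param n_fluorophores Number of fluorophores in the punctum (>= 0).
#' @param unit_intensity Intensity of one fluorophore (a.u.).
#' @param bleach_prob_per_frame Per-frame bleaching probability.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param n_frames Trace length in frames.
#' @param frame_interval Frame interval in seconds.
#' @param background Baseline intensity after all fluorophores bleach.
#' @param seed Integer seed.
#' @return An object of class `"intensity_trace"`: list with `times`,
#'   `intensities`, `frame_interval`, `acquisition_mode`, ground-truth
#'   `bleach_frames`, and a `clipped` flag.
#' @export
simulate_bleach_trace <- function(n_fluorophores, unit_intensity = 100,
                                  bleach_prob_per_frame = 0.008,
                                  noise_sd = 0, n_frames = 600L,
                                  frame_interval = 0.25, background = 0,
                                  seed = NULL) {
  if (n_fluorophores < 0) stop("`n_fluorophores` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_frames <- as.integer(n_frames)
  n_alive <- rep(n_fluorophores, n_frames)
  bleach_frames <- integer(0)
  if (n_fluorophores > 0 && bleach_prob_per_frame > 0) {
    # geometric bleaching time of each fluorophore (first frame at the
    # reduced level)
    bt <- stats::rgeom(n_fluorophores, bleach_prob_per_frame) + 2L
    for (b in bt) if (b <= n_frames) n_alive[b:n_frames] <- n_alive[b:n_frames] - 1L
    bleach_frames <- sort(bt[bt <= n_frames])
  }
  intens <- background + n_alive * unit_intensity
  if (noise_sd > 0) intens <- intens + stats::rnorm(n_frames, 0, noise_sd)
  clipped <- any(intens < background)
  intens[intens < background] <- background
  structure(list(
    punctum_id = 1L,
    times = (seq_len(n_frames) - 1L) * frame_interval,
    intensities = intens,
    frame_interval = frame_interval,
    acquisition_mode = "continuous",
    bleach_frames = bleach_frames,
    n_fluorophores = n_fluorophores,
    clipped = clipped
  ), class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> punctum %s: %d frames, range %.1f-%.1f a.u.\n",
              format(x$punctum_id), length(x$intensities),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Mutation events in each culture are Poisson with mean
#' `m = mutation_rate * final_population`. Each event is assigned to a
#' division drawn with probability proportional to the number of cells
#' present (so late divisions, which are exponentially more numerous,
#' carry most events) and founds a clone that doubles until harvest,
#' producing the characteristic heavy-tailed "jackpot" distribution of
#' mutant counts.
#'
#' @param n_cultures Number of parallel cultures.
#' @param final_population Cells per culture at plating (N).
#' @param mutation_rate Mutations per cell per division (mu).
#' @param seed Integer seed.
#' @param label Strain label.
#' @return An object of class `"fluctuation_assay"`: data frame with
#'   columns `culture_id`, `mutant_count`, `total_cells`, plus attributes
#'   `label` and `mutation_rate` (ground truth).
#' @export
simulate_fluctuation_cultures <- function(n_cultures, final_population,
                                          mutation_rate, seed = NULL,
                                          label = "simulated") {
  if (final_population < 1) stop("`final_population` must be >= 1", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("`mutation_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- max(1L, as.integer(round(log2(final_population))))
  # P(event at generation k) proportional to cells newly made at k: 2^(k-1)
  gen_w <- 2^(seq_len(g) - 1)
  gen_p <- gen_w / sum(gen_w)
  m <- mutation_rate * final_population
  counts <- integer(n_cultures)
  for (j in seq_len(n_cultures)) {
    ne <- stats::rpois(1L, m)
    if (ne == 0L) next
    ks <- sample.int(g, ne, replace = TRUE, prob = gen_p)
    counts[j] <- sum(2^(g - ks))
  }
  out <- data.frame(culture_id = seq_len(n_cultures),
                    mutant_count = counts,
                    total_cells = rep(final_population, n_cultures))
  attr(out, "label") <- label
  attr(out, "mutation_rate") <- mutation_rate
  class(out) <- c("fluctuation_assay", "data.frame")
  out
}

#' Write or read fluctuation-assay culture tables
#'
#' CSV with columns `culture_id`, `mutant_count`, `total_cells`.
#'
#' @param assay A `"fluctuation_assay"` (or compatible data frame).
#' @param path File path.
#' @return `path` invisibly (write); a `"fluctuation_assay"` (read).
#' @export
write_fluctuation_csv <- function(assay, path) {
  utils::write.csv(as.data.frame(assay)[c("culture_id", "mutant_count",
                                          "total_cells")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fluctuation_csv
#' @param label Strain label attached on read.
#' @export
read_fluctuation_csv <- function(path, label = "imported") {
  tab <- utils::read.csv(path)
  need <- c("culture_id", "mutant_count", "total_cells")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("fluctuation table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tab$mutant_count < 0) || any(tab$total_cells < tab$mutant_count)) {
    stop("mutant counts must satisfy 0 <= mutants <= total cells", call. = FALSE)
  }
  attr(tab, "label") <- label
  class(tab) <- c("fluctuation_assay", "data.frame")
  tab
}
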
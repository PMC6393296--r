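#' Construct a single-molecule trajectory
#'
#' A trajectory is the time-ordered 1D position of one tracked molecule
#' along the DNA axis of a double-tethered curtain, sampled at a uniform
#' frame interval. Positions are in micrometers with 0 at one tether.
#'
#' @param positions Numeric vector of positions along the DNA axis (um).
#' @param frame_interval Frame interval in seconds (> 0).
#' @param molecule_id Identifier (integer or character).
#' @param frames Integer frame indices; defaults to `seq_along(positions)`.
#' @param source One of `"simulated"`, `"tracked"`, `"imported"`.
#' @param transverse Optional transverse (off-axis) coordinate, kept for QC
#'   only; never used by downstream estimators.
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `molecule_id`, `frames`, `times`, `positions`, `frame_interval`,
#'   `source`.
#' @export
#' @examples
#' tr <- trajectory(c(0, 0.1, 0.05, 0.2), frame_interval = 0.05)
#' tr$times
trajectory <- function(positions, frame_interval, molecule_id = 1L,
                       frames = seq_along(positions),
                       source = c("simulated", "tracked", "imported"),
                       transverse = NULL) {
  source <- match.arg(source)
  positions <- as.numeric(positions)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a single positive finite number", call. = FALSE)
  }
  if (any(!is.finite(positions))) {
    stop("trajectory positions must be finite", call. = FALSE)
  }
  frames <- as.integer(frames)
  if (length(frames) != length(positions)) {
    stop("`frames` and `positions` must have the same length", call. = FALSE)
  }
  if (length(frames) > 1L && any(diff(frames) != 1L)) {
    stop("trajectory frames must be consecutive integers", call. = FALSE)
  }
  obj <- list(
    molecule_id = molecule_id,
    frames = frames,
    times = (frames - frames[1L]) * frame_interval,
    positions = positions,
    frame_interval = frame_interval,
    source = source
  )
  if (!is.null(transverse)) attr(obj, "transverse") <- as.numeric(transverse)
  class(obj) <- "trajectory"
  obj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> molecule %s: %d frames, dt = %g s, span %.3f-%.3f um (%s)\n",
    format(x$molecule_id), length(x$positions), x$frame_interval,
    min(x$positions), max(x$positions), x$source
  ))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$positions)

#' Convert a trajectory to a data frame
#'
#' @param x A `trajectory`.
#' @param row.names,optional Unused, for S3 compatibility.
#' @param bp_per_um Calibration used to add a `position_bp` column
#'   (default 3750 bp/um, from the equivalence 0.08 um ~ 300 bp).
#' @param ... Unused.
#' @return A data frame with columns `molecule_id`, `frame`, `time_s`,
#'   `position_um`, `position_bp`.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     bp_per_um = 3750, ...) {
  data.frame(
    molecule_id = rep(x$molecule_id, length(x$positions)),
    frame = x$frames,
    time_s = x$times,
    position_um = x$positions,
    position_bp = x$positions * bp_per_um,
    stringsAsFactors = FALSE
  )
}

#' Write trajectories to a tab-separated table
#'
#' The interchange format between tracking and all downstream stages:
#' columns `molecule_id`, `frame`, `time_s`, `position_um`, `position_bp`.
#'
#' @param trajectories A `trajectory` or list of them.
#' @param path Output file path.
#' @param bp_per_um Calibration for the base-pair column.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, bp_per_um = 3750) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  tab <- do.call(rbind, lapply(trajectories, as.data.frame, bp_per_um = bp_per_um))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from a tab-separated table
#'
#' Validates that each molecule's rows form a uniformly sampled series:
#' rows are sorted by frame on read, the frame interval must be consistent
#' to within 1%, and positions must be finite. Either `position_um` or
#' `position_bp` may be present; missing one is reconstructed through
#' `bp_per_um`.
#'
#' @param path Input file path.
#' @param bp_per_um Calibration between micrometers and base pairs.
#' @return A list of `trajectory` objects.
#' @export
read_trajectories <- function(path, bp_per_um = 3750) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "time_s")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("trajectory table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"position_um" %in% names(tab)) {
    if (!"position_bp" %in% names(tab)) {
      stop("trajectory table needs `position_um` or `position_bp`", call. = FALSE)
    }
    tab$position_um <- tab$position_bp / bp_per_um
  }
  if (any(!is.finite(tab$position_um))) {
    stop("trajectory table contains non-finite positions", call. = FALSE)
  }
  out <- lapply(split(tab, tab$molecule_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (nrow(d) > 1L) {
      dts <- diff(d$time_s) / diff(d$frame)
      dt <- stats::median(dts)
      if (any(abs(dts - dt) > 0.01 * dt)) {
        stop(sprintf(
          "molecule %s: frame interval varies by more than 1%%",
          format(d$molecule_id[1L])), call. = FALSE)
      }
    } else {
      dt <- d$time_s[1L]
      if (!is.finite(dt) || dt <= 0) dt <- 1
    }
    trajectory(d$position_um, frame_interval = dt,
               molecule_id = d$molecule_id[1L], frames = d$frame,
               source = "imported")
  })
  names(out) <- NULL
  out
}
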
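#' Detect candidate fluorescent spots in one frame
#'
#' Finds local maxima that exceed the background by
#' `detection_threshold` robust standard deviations, then applies
#' non-maximum suppression so that no two candidates are closer than
#' `min_separation` pixels (about one PSF width). The background level
#' and scale are the image median and MAD.
#'
#' @param frame_image Numeric matrix (rows = y, columns = x).
#' @param detection_threshold Threshold in multiples of the background sd.
#' @param min_separation Suppression radius in pixels.
#' @return A data frame with columns `row`, `col`, `value`; zero rows if
#'   nothing exceeds the threshold.
#' @export
detect_spots <- function(frame_image, detection_threshold = 5,
                         min_separation = 3) {
  stopifnot(is.matrix(frame_image))
  bg <- stats::median(frame_image)
  s <- stats::mad(frame_image)
  if (s == 0) s <- stats::sd(frame_image)
  cut <- bg + detection_threshold * s
  ny <- nrow(frame_image); nx <- ncol(frame_image)
  if (ny < 3L || nx < 3L) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  core <- frame_image[2:(ny - 1L), 2:(nx - 1L), drop = FALSE]
  is_max <- core > cut
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- frame_image[(2 + dr):(ny - 1L + dr), (2 + dc):(nx - 1L + dc), drop = FALSE]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  cand <- data.frame(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L,
                     value = core[idx])
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    if (all(d2 > min_separation^2)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a 2D Gaussian to a candidate spot
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the model
#' `b + A * exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2))` over a
#' square window around the candidate pixel. Initialization comes from
#' centroid moments of the background-subtracted window. Non-convergence
#' is reported in the `converged` flag rather than by dropping the spot.
#'
#' @param frame_image Numeric matrix.
#' @param candidate One-row data frame (or list) with `row` and `col`.
#' @param window_radius Half-width of the fit window in pixels.
#' @return A one-row data frame (class also `"spot_fit"`): `center_x`,
#'   `center_y` (pixel units, 1-based pixel centers), `sigma_x`,
#'   `sigma_y`, `amplitude`, `background`, `fit_residual` (RMS), and
#'   `converged`.
#' @export
fit_gaussian_2d <- function(frame_image, candidate, window_radius = 3L) {
  r <- as.integer(window_radius)
  ro <- as.integer(candidate$row[1L]); co <- as.integer(candidate$col[1L])
  ny <- nrow(frame_image); nx <- ncol(frame_image)
  if (ro - r < 1L || ro + r > ny || co - r < 1L || co + r > nx) {
    stop("candidate too close to the image edge for the fit window", call. = FALSE)
  }
  rows <- (ro - r):(ro + r); cols <- (co - r):(co + r)
  w <- frame_image[rows, cols, drop = FALSE]
  d <- data.frame(z = as.vector(w),
                  y = rep(rows, times = length(cols)),
                  x = rep(cols, each = length(rows)))
  b0 <- min(d$z)
  mass <- d$z - b0
  fail <- function(reason) {
    data.frame(center_x = NA_real_, center_y = NA_real_,
               sigma_x = NA_real_, sigma_y = NA_real_,
               amplitude = NA_real_, background = b0,
               fit_residual = NA_real_, converged = FALSE,
               reason = reason, stringsAsFactors = FALSE)
  }
  if (sum(mass) <= 0) return(fail("no signal above background in window"))
  x0 <- sum(d$x * mass) / sum(mass)
  y0 <- sum(d$y * mass) / sum(mass)
  sx0 <- sqrt(max(sum((d$x - x0)^2 * mass) / sum(mass), 0.25))
  sy0 <- sqrt(max(sum((d$y - y0)^2 * mass) / sum(mass), 0.25))
  a0 <- max(d$z) - b0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-(x - x0)^2 / (2 * sx^2) - (y - y0)^2 / (2 * sy^2)),
      data = d,
      start = list(b = b0, A = a0, x0 = x0, y0 = y0, sx = sx0, sy = sy0),
      lower = c(b = -Inf, A = 0, x0 = min(d$x) - 1, y0 = min(d$y) - 1,
                sx = 0.1, sy = 0.1),
      upper = c(b = Inf, A = Inf, x0 = max(d$x) + 1, y0 = max(d$y) + 1,
                sx = 4 * r, sy = 4 * r),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(fail("nonlinear fit failed"))
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::resid(fit)^2))
  # a window without a real spot converges onto a noise bump whose
  # amplitude is not significant; require A to stand 3 standard errors
  # above zero
  se_a <- tryCatch(summary(fit)$coefficients["A", "Std. Error"],
                   error = function(e) Inf)
  if (cf[["A"]] <= 0 || cf[["sx"]] <= 0 || cf[["sy"]] <= 0 ||
      !is.finite(se_a) || cf[["A"]] < 3 * se_a) {
    return(fail("no significant spot in window"))
  }
  data.frame(center_x = cf[["x0"]], center_y = cf[["y0"]],
             sigma_x = cf[["sx"]], sigma_y = cf[["sy"]],
             amplitude = cf[["A"]], background = cf[["b"]],
             fit_residual = rms,
             converged = TRUE, reason = "", stringsAsFactors = FALSE)
}

#' Detect and fit all spots in every frame of a stack
#'
#' @param stack An `"image_stack"`.
#' @param detection_threshold Passed to [detect_spots()].
#' @param window_radius Passed to [fit_gaussian_2d()].
#' @param min_separation Passed to [detect_spots()].
#' @return A data frame of converged fits with columns `frame`, `x_um`,
#'   `y_um` (pixel centers converted through the stack pixel size) plus
#'   the [fit_gaussian_2d()] columns.
#' @export
locate_stack <- function(stack, detection_threshold = 5, window_radius = 3L,
                         min_separation = 3) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixel_size_um
  out <- list()
  for (f in seq_along(stack$frames)) {
    img <- stack$frames[[f]]
    cand <- detect_spots(img, detection_threshold, min_separation)
    if (!nrow(cand)) next
    fits <- list()
    for (i in seq_len(nrow(cand))) {
      ft <- tryCatch(fit_gaussian_2d(img, cand[i, ], window_radius),
                     error = function(e) NULL)
      if (is.null(ft) || !ft$converged) next
      ft$frame <- f
      ft$x_um <- (ft$center_x - 0.5) * px
      ft$y_um <- (ft$center_y - 0.5) * px
      fits[[length(fits) + 1L]] <- ft
    }
    if (!length(fits)) next
    # deduplicate: a candidate on a spot's shoulder can converge onto the
    # same spot; keep the brighter of any two fits closer than the
    # suppression radius
    fits <- do.call(rbind, fits)
    fits <- fits[order(-fits$amplitude), , drop = FALSE]
    keep <- rep(TRUE, nrow(fits))
    for (i in seq_len(nrow(fits))) {
      if (!keep[i]) next
      if (i < nrow(fits)) {
        d2 <- (fits$center_x[i] - fits$center_x)^2 +
          (fits$center_y[i] - fits$center_y)^2
        close_later <- d2 < min_separation^2 & seq_len(nrow(fits)) > i
        keep[close_later] <- FALSE
      }
    }
    out[[length(out) + 1L]] <- fits[keep, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0)))
  }
  do.call(rbind, out)
}

#' Link per-frame spot fits into trajectories
#'
#' Greedy nearest-neighbor linking: within each frame, candidate
#' (track, detection) pairs are sorted by distance and assigned smallest
#' first, subject to a per-frame jump limit of `max_jump` um (scaled by
#' the gap length when frames were missed); ties are broken toward the
#' lower molecule id. Tracks unmatched for more than `max_gap` frames are
#' closed; missed frames inside a kept track are bridged by linear
#' interpolation so trajectories stay uniformly sampled. The position
#' used downstream is the coordinate along the DNA axis (`x_um`); the
#' transverse coordinate is retained as an attribute for QC.
#'
#' @param spots Data frame from [locate_stack()] (needs `frame`, `x_um`,
#'   `y_um`).
#' @param frame_interval Frame interval in seconds.
#' @param max_jump Maximum per-frame displacement in um.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @param min_length Minimum trajectory length (frames) to keep.
#' @return A list of [trajectory()] objects (`source = "tracked"`).
#' @export
link_trajectories <- function(spots, frame_interval, max_jump = 1,
                              max_gap = 2L, min_length = 10L) {
  if (!nrow(spots)) return(list())
  spots <- spots[order(spots$frame), , drop = FALSE]
  tracks <- list()  # each: list(frames, x, y, last_frame, open)
  for (f in sort(unique(spots$frame))) {
    det <- spots[spots$frame == f, , drop = FALSE]
    open <- which(vapply(tracks, function(t) t$open, TRUE))
    # close stale tracks
    for (k in open) {
      if (f - tracks[[k]]$last_frame > max_gap + 1L) tracks[[k]]$open <- FALSE
    }
    open <- which(vapply(tracks, function(t) t$open, TRUE))
    assigned_det <- rep(FALSE, nrow(det))
    if (length(open) && nrow(det)) {
      pairs <- expand.grid(trk = open, det = seq_len(nrow(det)))
      gap <- f - vapply(tracks[pairs$trk], function(t) t$last_frame, 1L)
      lastx <- vapply(tracks[pairs$trk], function(t) t$x[length(t$x)], 1)
      lasty <- vapply(tracks[pairs$trk], function(t) t$y[length(t$y)], 1)
      dist <- sqrt((det$x_um[pairs$det] - lastx)^2 +
                   (det$y_um[pairs$det] - lasty)^2)
      ok <- dist <= max_jump * gap
      pairs <- pairs[ok, , drop = FALSE]; dist <- dist[ok]
      if (nrow(pairs)) {
        ord <- order(dist, pairs$trk)  # ties toward lower molecule id
        used_trk <- logical(length(tracks))
        for (q in ord) {
          k <- pairs$trk[q]; j <- pairs$det[q]
          if (used_trk[k] || assigned_det[j]) next
          used_trk[k] <- TRUE; assigned_det[j] <- TRUE
          tracks[[k]]$frames <- c(tracks[[k]]$frames, f)
          tracks[[k]]$x <- c(tracks[[k]]$x, det$x_um[j])
          tracks[[k]]$y <- c(tracks[[k]]$y, det$y_um[j])
          tracks[[k]]$last_frame <- f
        }
      }
    }
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(frames = f, x = det$x_um[j],
                                            y = det$y_um[j], last_frame = f,
                                            open = TRUE)
    }
  }
  out <- list(); id <- 0L
  for (t in tracks) {
    if (length(t$frames) < min_length) next
    id <- id + 1L
    full <- t$frames[1L]:t$frames[length(t$frames)]
    x <- stats::approx(t$frames, t$x, xout = full)$y
    y <- stats::approx(t$frames, t$y, xout = full)$y
    out[[id]] <- trajectory(x, frame_interval = frame_interval,
                            molecule_id = id, frames = full,
                            source = "tracked", transverse = y)
  }
  out
}

#' Track an image stack end to end
#'
#' Runs [locate_stack()] then [link_trajectories()].
#'
#' @inheritParams locate_stack
#' @inheritParams link_trajectories
#' @return A list of [trajectory()] objects.
#' @export
track_stack <- function(stack, detection_threshold = 5, window_radius = 3L,
                        min_separation = 3, max_jump = 1, max_gap = 2L,
                        min_length = 10L) {
  spots <- locate_stack(stack, detection_threshold, window_radius,
                        min_separation)
  link_trajectories(spots, frame_interval = stack$frame_interval_s,
                    max_jump = max_jump, max_gap = max_gap,
                    min_length = min_length)
}

#' Theoretical localization precision of a fitted Gaussian spot
#'
#' Standard shot-noise-limited precision for centroid/Gaussian
#' localization with finite pixels and background (Thompson-Larson-Webb):
#' `var = s^2/N + a^2/(12 N) + 8 pi s^4 b^2 / (a^2 N^2)`, where `s` is
#' the PSF sd, `a` the pixel size, `N` the collected signal photons and
#' `b` the background noise per pixel.
#'
#' @param psf_sigma PSF sd in um.
#' @param photons Total signal photons per spot per frame.
#' @param pixel_size Pixel size in um.
#' @param background_sd Background noise sd per pixel (photons).
#' @return Localization sd in um.
#' @export
localization_precision <- function(psf_sigma, photons, pixel_size,
                                   background_sd = 0) {
  v <- psf_sigma^2 / photons + pixel_size^2 / (12 * photons) +
    8 * pi * psf_sigma^4 * background_sd^2 / (pixel_size^2 * photons^2)
  sqrt(v)
}
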
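#' Mean squared displacement of a trajectory
#'
#' For a trajectory of N positions y_i sampled every dt seconds, the MSD
#' at lag n is the average over all N - n overlapping pairs:
#' `MSD(n dt) = 1/(N - n) * sum_i (y_{i+n} - y_i)^2`. By convention only
#' the first `n_max` time intervals are used (default 10), which keeps
#' the per-lag averages well populated for trajectories a few hundred
#' frames long.
#'
#' @param trajectory A [trajectory()].
#' @param n_max Largest lag (in frames) to evaluate.
#' @return An object of class `"msd_curve"`: list with `lags` (seconds),
#'   `msd` (um^2), `n_pairs`, `frame_interval`, `molecule_id`.
#' @export
#' @examples
#' tr <- trajectory(c(0, 1, 0, 1, 0), frame_interval = 1)
#' compute_msd(tr, n_max = 4)$msd  # 1, 0, 1, 0
compute_msd <- function(trajectory, n_max = 10L) {
  stopifnot(inherits(trajectory, "trajectory"))
  y <- trajectory$positions
  N <- length(y)
  n_max <- as.integer(n_max)
  if (N <= n_max) {
    stop(sprintf("trajectory has %d frames; need more than n_max = %d",
                 N, n_max), call. = FALSE)
  }
  msd <- vapply(seq_len(n_max), function(n) {
    mean((y[(n + 1L):N] - y[seq_len(N - n)])^2)
  }, 1)
  structure(list(
    lags = seq_len(n_max) * trajectory$frame_interval,
    msd = msd,
    n_pairs = N - seq_len(n_max),
    frame_interval = trajectory$frame_interval,
    molecule_id = trajectory$molecule_id
  ), class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> molecule %s: %d lags, MSD(%.3g s) = %.4g um^2\n",
              format(x$molecule_id), length(x$lags), max(x$lags),
              x$msd[length(x$msd)]))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lags, x$msd, xlab = "lag (s)", ylab = "MSD (um^2)",
                 pch = 16, ...)
  est <- fit_diffusion_coefficient(x)
  graphics::abline(est$intercept, est$slope, lty = 2)
  invisible(x)
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary (unweighted) least-squares line through the (lag, MSD)
#' points. In 1D, Brownian motion gives MSD = 2 D t, so the diffusion
#' coefficient is `slope / 2`; the intercept absorbs the static
#' localization-noise offset (2 sigma^2). A negative slope is reported as
#' D = 0 with `nonphysical = TRUE` rather than dropped, so condition
#' denominators stay auditable.
#'
#' @param msd An `"msd_curve"`.
#' @return An object of class `"diffusion_estimate"`: list with
#'   `molecule_id`, `slope` (um^2/s), `intercept` (um^2),
#'   `diffusion_coefficient` (um^2/s), `r_squared`, `nonphysical`.
#' @export
fit_diffusion_coefficient <- function(msd) {
  stopifnot(inherits(msd, "msd_curve"))
  if (length(msd$lags) < 3L) {
    stop("need at least 3 lags to fit a diffusion coefficient", call. = FALSE)
  }
  fit <- stats::lm(msd$msd ~ msd$lags)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  tss <- sum((msd$msd - mean(msd$msd))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(
    molecule_id = msd$molecule_id,
    slope = slope,
    intercept = intercept,
    diffusion_coefficient = max(slope, 0) / 2,
    r_squared = r2,
    nonphysical = slope < 0,
    msd_max = msd$msd[length(msd$msd)]
  ), class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "<diffusion_estimate> molecule %s: D = %.4g um^2/s (slope %.4g, r^2 %.3f)%s\n",
    format(x$molecule_id), x$diffusion_coefficient, x$slope, x$r_squared,
    if (x$nonphysical) " [non-physical slope]" else ""))
  invisible(x)
}

#' Classify a molecule as mobile or immobile
#'
#' A static molecule observed with localization noise sigma has an
#' expected MSD of `2 * sigma^2` at every lag (the static noise floor).
#' A molecule is called mobile when its MSD at the largest fitted lag
#' exceeds that floor by at least a factor of 3.
#'
#' @param estimate A `"diffusion_estimate"` (carries the MSD at the
#'   largest fitted lag).
#' @param noise_sigma Localization noise sd in um.
#' @return Logical flag.
#' @export
classify_mobile <- function(estimate, noise_sigma) {
  stopifnot(inherits(estimate, "diffusion_estimate"))
  floor_msd <- 2 * noise_sigma^2
  if (floor_msd == 0) return(estimate$msd_max > 0)
  estimate$msd_max >= 3 * floor_msd
}

#' Summarize diffusion estimates for one condition
#'
#' @param estimates List of `"diffusion_estimate"` objects.
#' @param condition Condition label.
#' @param noise_sigma Localization noise sd used for the mobility call.
#' @return An object of class `"condition_summary"`: list with
#'   `condition`, `diffusion_coefficients`, `mean`, `sem`, `n_molecules`,
#'   `n_mobile`, `percent_mobile` (rounded to the nearest percent), and
#'   `reportable` (`TRUE` when n >= 30, the conventional minimum for a
#'   reported mean +- SEM).
#' @export
summarize_condition <- function(estimates, condition = "condition",
                                noise_sigma = 0.08 / 3) {
  if (inherits(estimates, "diffusion_estimate")) estimates <- list(estimates)
  d <- vapply(estimates, function(e) e$diffusion_coefficient, 1)
  mobile <- vapply(estimates, classify_mobile, TRUE, noise_sigma = noise_sigma)
  n <- length(d)
  structure(list(
    condition = condition,
    diffusion_coefficients = d,
    mean = mean(d),
    sem = stats::sd(d) / sqrt(n),
    n_molecules = n,
    n_mobile = sum(mobile),
    percent_mobile = percent_mobile(sum(mobile), n),
    reportable = n >= 30L
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "<condition_summary> %s: D = %.4g +- %.4g um^2/s (mean +- SEM), N = %d%s; mobile %d/%d (%d%%)\n",
    x$condition, x$mean, x$sem, x$n_molecules,
    if (x$reportable) "" else " [n < 30, not reportable]",
    x$n_mobile, x$n_molecules, x$percent_mobile))
  invisible(x)
}

#' Percent of mobile molecules from counts
#'
#' @param n_mobile,n_total Mobile and total molecule counts.
#' @return Percentage rounded to the nearest integer (e.g. 62 of 64
#'   gives 97).
#' @export
percent_mobile <- function(n_mobile, n_total) {
  if (n_total < 1L) stop("`n_total` must be >= 1", call. = FALSE)
  round(100 * n_mobile / n_total)
}

#' Compare diffusion coefficients between two conditions
#'
#' Two-sample Kolmogorov-Smirnov test on the per-molecule diffusion
#' coefficients: the statistic is the exact supremum distance between
#' the two empirical CDFs, with the asymptotic p-value. Significance is
#' judged at alpha = 0.05.
#'
#' @param a,b `"condition_summary"` objects or numeric vectors of
#'   per-molecule diffusion coefficients.
#' @param alpha Significance threshold.
#' @return List with `statistic` (D_KS), `p_value`, `significant`,
#'   `alpha`.
#' @export
compare_diffusion <- function(a, b, alpha = 0.05) {
  xa <- if (inherits(a, "condition_summary")) a$diffusion_coefficients else as.numeric(a)
  xb <- if (inherits(b, "condition_summary")) b$diffusion_coefficients else as.numeric(b)
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("each group needs at least 2 molecules", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(xa, xb, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value < alpha, alpha = alpha)
}
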
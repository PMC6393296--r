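#' Solve the Drake equation for a mutation rate
#'
#' The median-based fluctuation-assay estimator solves the implicit
#' equation `mu = f / ln(N * mu)` for the mutation rate `mu`, where `f`
#' is the observed mutant frequency and `N` the number of cells per
#' culture at plating. The equation is solved on the physically
#' meaningful branch `N * mu > 1` (where `ln(N * mu) > 0`) by bracketed
#' root-finding on `g(mu) = mu * ln(N * mu) - f`, then polished by
#' Newton steps to a relative residual below 1e-12. The spurious branch
#' `N * mu < 1` is never returned.
#'
#' @param f Mutant frequency (median mutants per cell), > 0. `f = 0` is
#'   reported as below detection with an upper bound obtained at
#'   `f = 1/N` (one mutant in the median culture), not as an error.
#' @param n Cells per culture (N), > 0.
#' @return The rate `mu` (mutations per cell per division) with
#'   attributes `residual` (`|mu ln(N mu) - f|`) and, when `f = 0`,
#'   `below_detection = TRUE` and `upper_bound`.
#' @export
#' @examples
#' solve_drake(2e-7, 1e8)
#' solve_drake(exp(1) / 1e8, 1e8)  # fixed point: mu == f
solve_drake <- function(f, n) {
  if (!is.finite(n) || n <= 0) stop("`n` must be positive", call. = FALSE)
  if (!is.finite(f) || f < 0) stop("`f` must be >= 0", call. = FALSE)
  if (f == 0) {
    ub <- solve_drake(1 / n, n)
    return(structure(0, residual = 0, below_detection = TRUE,
                     upper_bound = as.numeric(ub)))
  }
  g <- function(mu) mu * log(n * mu) - f
  lo <- (1 + 1e-9) / n
  if (g(lo) >= 0) {
    stop(sprintf(
      "no root with N*mu > 1: f = %g is at or below the branch boundary %g",
      f, g(lo) + f), call. = FALSE)
  }
  hi <- max(f, exp(1) / n)
  while (g(hi) < 0) hi <- hi * 2
  mu <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps)$root
  # Newton polish for the residual contract
  for (i in 1:5) {
    r <- g(mu)
    if (abs(r) <= 1e-13 * f) break
    mu <- mu - r / (log(n * mu) + 1)
  }
  structure(mu, residual = abs(g(mu)), below_detection = FALSE)
}

#' Estimate a mutation rate from a fluctuation assay
#'
#' Takes `f` as the median per-culture mutant frequency and `N` as the
#' median culture size, solves the Drake equation, and attaches a 95%
#' nonparametric bootstrap confidence interval obtained by resampling
#' cultures with replacement and re-solving on each resample.
#'
#' @param assay A `"fluctuation_assay"` (data frame with `mutant_count`,
#'   `total_cells`).
#' @param n_bootstrap Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param min_cultures Minimum number of cultures required.
#' @return An object of class `"rate_estimate"`: list with `label`,
#'   `mu`, `ci_low`, `ci_high`, `f_used`, `n_used`, `n_cultures`,
#'   `solver_residual`, `below_detection`, and the bootstrap replicates
#'   in `boot_mu` (used for paired fold-change CIs).
#' @export
estimate_rate <- function(assay, n_bootstrap = 1000L, seed = NULL,
                          min_cultures = 5L) {
  if (!all(c("mutant_count", "total_cells") %in% names(assay))) {
    stop("`assay` needs columns `mutant_count` and `total_cells`", call. = FALSE)
  }
  if (nrow(assay) < min_cultures) {
    stop(sprintf("need at least %d cultures (got %d)", min_cultures,
                 nrow(assay)), call. = FALSE)
  }
  freq <- assay$mutant_count / assay$total_cells
  point <- function(fr, tc) {
    f <- stats::median(fr)
    n <- stats::median(tc)
    if (f == 0) return(c(mu = 0, f = 0, n = n, res = 0))
    mu <- solve_drake(f, n)
    c(mu = as.numeric(mu), f = f, n = n, res = attr(mu, "residual"))
  }
  pt <- point(freq, assay$total_cells)
  below <- pt[["f"]] == 0
  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(assay)
  boot_mu <- vapply(seq_len(n_bootstrap), function(i) {
    idx <- sample.int(nb, replace = TRUE)
    point(freq[idx], assay$total_cells[idx])[["mu"]]
  }, 1)
  ci <- stats::quantile(boot_mu, c(0.025, 0.975), names = FALSE)
  if (below) {
    ub <- attr(solve_drake(0, pt[["n"]]), "upper_bound")
    ci <- c(0, max(ci[2L], ub))
  }
  structure(list(
    label = attr(assay, "label") %||% "assay",
    mu = pt[["mu"]],
    ci_low = ci[1L],
    ci_high = ci[2L],
    f_used = pt[["f"]],
    n_used = pt[["n"]],
    n_cultures = nb,
    solver_residual = pt[["res"]],
    below_detection = below,
    boot_mu = boot_mu
  ), class = "rate_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rate_estimate <- function(x, ...) {
  if (x$below_detection) {
    cat(sprintf(
      "<rate_estimate> %s: below detection (all cultures mutant-free); mu < %.3g\n",
      x$label, x$ci_high))
  } else {
    cat(sprintf(
      "<rate_estimate> %s: mu = %.3g [95%% CI %.3g, %.3g] per cell per division (N = %d cultures)\n",
      x$label, x$mu, x$ci_low, x$ci_high, x$n_cultures))
  }
  invisible(x)
}

#' Fold difference between two mutation rates
#'
#' The fold change is the ratio of the point estimates; its 95% CI pairs
#' the bootstrap replicates of the two estimates index by index (the
#' replicates are independent resamples, so pairing is a convenience
#' that preserves each margin). When the denominator is below detection
#' the fold is reported as a lower bound against the denominator's upper
#' bound.
#'
#' @param a,b `"rate_estimate"` objects (fold = a / b).
#' @return List with `fold`, `ci_low`, `ci_high`, `lower_bound_only`.
#' @export
compare_rates <- function(a, b) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  if (b$below_detection) {
    return(list(fold = a$mu / b$ci_high, ci_low = NA_real_,
                ci_high = NA_real_, lower_bound_only = TRUE))
  }
  if (a$mu <= 0 || b$mu <= 0) stop("both rates must be positive", call. = FALSE)
  nb <- min(length(a$boot_mu), length(b$boot_mu))
  ratio <- a$boot_mu[seq_len(nb)] / b$boot_mu[seq_len(nb)]
  ratio <- ratio[is.finite(ratio) & ratio > 0]
  ci <- stats::quantile(ratio, c(0.025, 0.975), names = FALSE)
  list(fold = a$mu / b$mu, ci_low = ci[1L], ci_high = ci[2L],
       lower_bound_only = FALSE)
}
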
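#' Define nucleosome collision zones
#'
#' A collision zone is the interval around a nucleosome's estimated
#' position within which a diffusing molecule is deemed to have
#' encountered the nucleosome. The default half-width of 0.08 um is
#' three standard deviations of the single-molecule spatial resolution
#' (about 300 bp at 3750 bp/um).
#'
#' @param centers Nucleosome positions along the DNA (um).
#' @param half_width Zone half-width in um (> 0).
#' @param nucleosome_id Identifiers; default `1..k`.
#' @return A data frame of class `"collision_zones"` with columns
#'   `nucleosome_id`, `center`, `half_width`.
#' @export
collision_zones <- function(centers, half_width = 0.08,
                            nucleosome_id = seq_along(centers)) {
  if (any(half_width <= 0)) stop("`half_width` must be positive", call. = FALSE)
  z <- data.frame(nucleosome_id = nucleosome_id, center = as.numeric(centers),
                  half_width = half_width)
  z <- z[order(z$center), , drop = FALSE]
  rownames(z) <- NULL
  class(z) <- c("collision_zones", "data.frame")
  z
}

# Merge overlapping zones into compound zones (dense arrays); each
# compound zone keeps the ids of its members.
merge_zones <- function(zones) {
  lo <- zones$center - zones$half_width
  hi <- zones$center + zones$half_width
  grp <- integer(nrow(zones)); g <- 1L; grp[1L] <- 1L
  if (nrow(zones) > 1L) {
    for (i in 2:nrow(zones)) {
      if (lo[i] < max(hi[grp == g])) grp[i] <- g else { g <- g + 1L; grp[i] <- g }
    }
  }
  out <- lapply(split(seq_len(nrow(zones)), grp), function(ii) {
    list(lo = min(lo[ii]), hi = max(hi[ii]),
         id = paste(zones$nucleosome_id[ii], collapse = "+"),
         compound = length(ii) > 1L)
  })
  names(out) <- NULL
  out
}

#' Segment nucleosome collisions from a trajectory
#'
#' A collision is one maximal contiguous excursion of the sampled
#' positions inside a zone. The entry side is taken from the last
#' position outside the zone before entry and the exit side from the
#' first outside position after exit; a collision is a bypass when the
#' two sides differ. Excursions truncated by the start or end of the
#' trajectory are censored (kept in the record, excluded from bypass
#' denominators). Overlapping zones are merged into compound zones with
#' a message.
#'
#' @param trajectory A [trajectory()].
#' @param zones A [collision_zones()] data frame.
#' @return A data frame of class `"collision_records"`: one row per
#'   collision with columns `molecule_id`, `nucleosome_id`,
#'   `entry_frame`, `exit_frame`, `entry_side` (`"left"`/`"right"`/`NA`),
#'   `exit_side` (`"left"`/`"right"`/`"censored"`), `outcome`
#'   (`"bypass"`/`"no_bypass"`/`"censored"`).
#' @export
#' @examples
#' tr <- trajectory(c(-0.2, -0.05, 0.05, 0.2) + 1, frame_interval = 0.05)
#' segment_collisions(tr, collision_zones(1))  # one bypass
segment_collisions <- function(trajectory, zones) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (!nrow(zones)) stop("`zones` is empty", call. = FALSE)
  zs <- merge_zones(zones)
  if (any(vapply(zs, function(z) z$compound, TRUE))) {
    message("overlapping collision zones merged into compound zones")
  }
  y <- trajectory$positions
  n <- length(y)
  rec <- list()
  for (z in zs) {
    inside <- y >= z$lo & y <= z$hi
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      entry_side <- if (s > 1L) {
        if (y[s - 1L] < z$lo) "left" else "right"
      } else NA_character_
      if (s == 1L || e == n) {
        exit_side <- "censored"; outcome <- "censored"
      } else {
        exit_side <- if (y[e + 1L] < z$lo) "left" else "right"
        outcome <- if (!is.na(entry_side) && exit_side != entry_side) "bypass" else "no_bypass"
      }
      rec[[length(rec) + 1L]] <- data.frame(
        molecule_id = trajectory$molecule_id, nucleosome_id = z$id,
        entry_frame = trajectory$frames[s], exit_frame = trajectory$frames[e],
        entry_side = entry_side, exit_side = exit_side, outcome = outcome,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(molecule_id = character(0), nucleosome_id = character(0),
               entry_frame = integer(0), exit_frame = integer(0),
               entry_side = character(0), exit_side = character(0),
               outcome = character(0), stringsAsFactors = FALSE)
  class(out) <- c("collision_records", "data.frame")
  out
}

#' Pooled bypass probability with bootstrap confidence interval
#'
#' Each non-censored collision is coded 1 (bypass) or 0 (no bypass); the
#' point estimate is the bypass fraction and the 95% CI comes from a
#' percentile bootstrap (resampling codes with replacement). Resampling
#' by molecule is available for robustness to within-molecule
#' correlation.
#'
#' @param records A `"collision_records"` data frame (possibly pooled
#'   over molecules via `rbind`).
#' @param n_bootstrap Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param unit Resampling unit: `"event"` (default, matches the binary
#'   coding of collisions) or `"molecule"`.
#' @param condition Condition label.
#' @return An object of class `"bypass_summary"`: list with `condition`,
#'   `n_collisions` (non-censored), `n_bypass`, `n_censored`, `p_bypass`,
#'   `ci_low`, `ci_high`, `binary_codes`.
#' @export
summarize_bypass <- function(records, n_bootstrap = 1000L, seed = NULL,
                             unit = c("event", "molecule"),
                             condition = "condition") {
  unit <- match.arg(unit)
  obs <- records[records$outcome != "censored", , drop = FALSE]
  if (!nrow(obs)) stop("all collision records are censored", call. = FALSE)
  codes <- as.integer(obs$outcome == "bypass")
  p <- mean(codes)
  if (!is.null(seed)) set.seed(seed)
  boot <- if (unit == "event") {
    vapply(seq_len(n_bootstrap), function(i) {
      mean(codes[sample.int(length(codes), replace = TRUE)])
    }, 1)
  } else {
    by_mol <- split(codes, obs$molecule_id)
    vapply(seq_len(n_bootstrap), function(i) {
      mean(unlist(by_mol[sample.int(length(by_mol), replace = TRUE)]))
    }, 1)
  }
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(
    condition = condition,
    n_collisions = length(codes),
    n_bypass = sum(codes),
    n_censored = nrow(records) - nrow(obs),
    p_bypass = p,
    ci_low = ci[1L],
    ci_high = ci[2L],
    binary_codes = codes
  ), class = "bypass_summary")
}

#' @export
print.bypass_summary <- function(x, ...) {
  cat(sprintf(
    "<bypass_summary> %s: bypass %.1f%% (%d/%d collisions), 95%% CI [%.1f, %.1f]%%, %d censored\n",
    x$condition, 100 * x$p_bypass, x$n_bypass, x$n_collisions,
    100 * x$ci_low, 100 * x$ci_high, x$n_censored))
  invisible(x)
}

#' Compare bypass probabilities between two conditions
#'
#' Logistic (binary) regression of the collision outcome on a condition
#' indicator; the reported p-value is the Wald test for the condition
#' coefficient, judged at alpha = 0.05. Under complete separation the
#' Wald test is meaningless, so the comparison falls back to Fisher's
#' exact test on the 2x2 table, flagged in `method`.
#'
#' @param a,b `"bypass_summary"` objects.
#' @param alpha Significance threshold.
#' @return List with `p_value`, `log_odds_ratio`, `method`
#'   (`"logistic"`/`"fisher"`), `significant`, `alpha`.
#' @export
compare_bypass <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "bypass_summary"), inherits(b, "bypass_summary"))
  code <- c(a$binary_codes, b$binary_codes)
  cond <- factor(rep(c("a", "b"), c(length(a$binary_codes),
                                    length(b$binary_codes))))
  sep <- length(unique(a$binary_codes)) == 1L ||
    length(unique(b$binary_codes)) == 1L
  if (!sep) {
    fit <- stats::glm(code ~ cond, family = stats::binomial())
    sm <- summary(fit)$coefficients
    if (max(abs(stats::coef(fit))) < 15) {
      return(list(p_value = sm["condb", "Pr(>|z|)"],
                  log_odds_ratio = unname(stats::coef(fit)["condb"]),
                  method = "logistic",
                  significant = sm["condb", "Pr(>|z|)"] < alpha,
                  alpha = alpha))
    }
  }
  tab <- rbind(c(a$n_bypass, a$n_collisions - a$n_bypass),
               c(b$n_bypass, b$n_collisions - b$n_bypass))
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, log_odds_ratio = log(unname(ft$estimate)),
       method = "fisher", significant = ft$p.value < alpha, alpha = alpha)
}

#' Free-random-walk bypass reference
#'
#' Scores collisions at a mid-DNA zone for unobstructed simulated
#' trajectories, giving the ceiling against which measured nucleosome
#' bypass is compared: a molecule performing an unbiased 1D random walk
#' steps forward or backward with probability 1/2, so 50% is the maximum
#' bypass probability attainable without an obstacle.
#'
#' The classifier reads sampled positions, so the reference must be run
#' in a regime where the per-frame rms displacement `sqrt(2 D dt)` is at
#' least about 2.5x the full zone width; with finer sampling, entry
#' positions concentrate near the entry edge of the zone and same-side
#' exits are over-counted, biasing the measured fraction below the
#' ceiling (see the methods vignette). The defaults (D = 1 um^2/s,
#' dt = 0.1 s, zone half-width 0.08 um) satisfy this condition.
#'
#' @param config A [simulation_config()] without obstacles; `NULL` uses
#'   the defaults above with noise-free emitted positions.
#' @param zone A [collision_zones()] row; `NULL` places one zone of
#'   half-width 0.08 um at mid-DNA.
#' @param n_trajectories Number of simulated molecules.
#' @param n_bootstrap,seed Passed to [summarize_bypass()] (the seed also
#'   drives the simulation).
#' @return A `"bypass_summary"` for condition `"free_walk"`.
#' @export
free_walk_bypass_reference <- function(config = NULL, zone = NULL,
                                       n_trajectories = 200L,
                                       n_bootstrap = 1000L, seed = NULL) {
  if (is.null(config)) {
    config <- simulation_config(diffusion_coefficient = 1,
                                frame_interval = 0.1, n_frames = 2000L,
                                localization_sigma = 0, seed = seed)
  }
  if (length(config$obstacle_positions)) {
    stop("the free-walk reference requires a config without obstacles",
         call. = FALSE)
  }
  if (!is.null(seed)) config$seed <- seed
  if (is.null(zone)) zone <- collision_zones(config$dna_length / 2)
  sims <- simulate_ensemble(config, n_trajectories)
  recs <- do.call(rbind, lapply(sims$trajectories, segment_collisions,
                                zones = zone))
  summarize_bypass(recs, n_bootstrap = n_bootstrap, seed = seed,
                   condition = "free_walk")
}
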
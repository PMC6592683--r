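# Per-trajectory and per-cell mean-square-displacement analysis.
#
# The MSD of a track is time-averaged: at lag k frames it is the mean squared
# Euclidean displacement over every frame pair (i, i + k) present in the
# track, so gapped tracks contribute all available pairs. The first lags are
# fitted by MSD(t) = a + 4 D t, and tracks are called immobile when
# log10(D) <= -1.6.

#' Time-averaged MSD of one trajectory
#'
#' @param traj data.frame with columns `frame` (strictly increasing
#'   integers), `x_um`, `y_um`; at least 2 rows.
#' @param max_lag largest lag in frames; truncated to the track span.
#' @param dt frame interval, seconds.
#' @return data.frame of class `msd_profile` with columns `lag` (frames),
#'   `lag_s` (seconds), `msd` (um^2) and `n_pairs`; lags with no pair are
#'   omitted.
#' @export
compute_msd <- function(traj, max_lag = Inf, dt = 0.02) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 2, dt > 0, max_lag >= 1)
  f <- as.integer(traj$frame)
  if (any(diff(f) <= 0)) stop("trajectory frames must be strictly increasing")
  x <- traj$x_um; y <- traj$y_um
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite positions")
  span <- f[length(f)] - f[1]
  lags <- seq_len(min(max_lag, span))
  msd <- numeric(0); np <- integer(0); keep <- integer(0)
  for (k in lags) {
    j <- match(f + k, f)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    keep <- c(keep, k)
    msd <- c(msd, mean(d2))
    np <- c(np, sum(ok))
  }
  structure(data.frame(lag = keep, lag_s = keep * dt, msd = msd, n_pairs = np),
            class = c("msd_profile", "data.frame"), dt = dt)
}

#' Fit MSD(t) = a + 4 D t over the first lags
#'
#' Ordinary least squares through the first `n_points` (lag time, MSD)
#' pairs; `D` is the slope divided by 4. Noise-driven non-positive slopes
#' are floored at `d_floor` and flagged.
#'
#' @param profile `msd_profile` from [compute_msd()] (any data.frame with
#'   `lag_s` and `msd` columns works).
#' @param n_points lags used in the fit.
#' @param d_floor lower bound applied to `D` before any log10 transform,
#'   um^2/s.
#' @return list of class `diffusion_fit`: `D`, `D_raw`, `intercept_a`,
#'   `n_points_fit`, `floored`; or `NULL` (no-fit signal) when fewer than 2
#'   lags are available.
#' @export
fit_diffusion <- function(profile, n_points = 4, d_floor = 1e-5) {
  if (is.null(profile) || nrow(profile) < 2) return(NULL)
  n <- min(n_points, nrow(profile))
  t <- profile$lag_s[seq_len(n)]
  m <- profile$msd[seq_len(n)]
  tb <- mean(t); mb <- mean(m)
  slope <- sum((t - tb) * (m - mb)) / sum((t - tb)^2)
  a <- mb - slope * tb
  D_raw <- slope / 4
  floored <- D_raw < d_floor
  structure(list(D = max(D_raw, d_floor), D_raw = D_raw, intercept_a = a,
                 n_points_fit = n, floored = floored),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit: D = %.4g um^2/s (a = %.4g um^2, %d lags%s)\n",
              x$D, x$intercept_a, x$n_points_fit,
              if (x$floored) ", floored" else ""))
  invisible(x)
}

#' Immobile/mobile classification of fitted diffusion coefficients
#'
#' A trajectory is immobile when `log10(D) <= threshold_log10`; the boundary
#' value itself is immobile.
#'
#' @param D numeric vector of (post-floor, positive) diffusion
#'   coefficients, or a single `diffusion_fit`.
#' @param threshold_log10 classification threshold on the log10 scale.
#' @return character vector, `"immobile"` or `"mobile"`.
#' @export
classify_mobility <- function(D, threshold_log10 = -1.6) {
  if (inherits(D, "diffusion_fit")) D <- D$D
  stopifnot(is.numeric(D), all(D > 0))
  # 1e-12 guard keeps the boundary inclusive under floating-point round trip
  ifelse(log10(D) <= threshold_log10 + 1e-12, "immobile", "mobile")
}

# Lag-wise mean of per-track MSD profiles: at each lag, average msd over the
# tracks that possess that lag. Returns an msd_profile (n_pairs = number of
# contributing tracks).
average_msd <- function(profiles, max_lag = 12, dt = 0.02) {
  profiles <- Filter(Negate(is.null), profiles)
  if (!length(profiles)) return(NULL)
  acc <- numeric(max_lag); cnt <- integer(max_lag)
  for (p in profiles) {
    k <- p$lag[p$lag <= max_lag]
    acc[k] <- acc[k] + p$msd[p$lag <= max_lag]
    cnt[k] <- cnt[k] + 1L
  }
  keep <- cnt > 0
  structure(data.frame(lag = which(keep), lag_s = which(keep) * dt,
                       msd = acc[keep] / cnt[keep], n_pairs = cnt[keep]),
            class = c("msd_profile", "data.frame"), dt = dt)
}

# Trapezoidal area under an MSD curve over lag times within `window` (s).
msd_auc <- function(profile, window = c(0.02, 0.24)) {
  sel <- profile$lag_s >= window[1] - 1e-12 & profile$lag_s <= window[2] + 1e-12
  t <- profile$lag_s[sel]; m <- profile$msd[sel]
  if (length(t) < 2) return(NA_real_)
  sum(diff(t) * (utils::head(m, -1) + utils::tail(m, -1)) / 2)
}

#' Per-cell mobility summary
#'
#' Filters tracks shorter than `min_track_frames`, fits each track's MSD,
#' and summarizes the cell: lag-wise mean MSD curve, its trapezoidal area
#' (AUC) over `auc_window`, the log10 diffusion-coefficient histogram, and
#' the immobile fraction. Cells with fewer than `min_trajectories` retained
#' tracks are flagged (`below_min_trajectories = TRUE`), not dropped.
#'
#' @param loc localization table for one cell.
#' @param dt frame interval, s.
#' @param min_track_frames shortest track analyzed (frames).
#' @param min_trajectories per-cell inclusion floor.
#' @param auc_window lag-time window for the AUC, s.
#' @param n_fit_points MSD lags in the per-track linear fit.
#' @param threshold_log10 immobile threshold on log10(D).
#' @param max_lag lags kept in the mean MSD curve.
#' @param hist_breaks log10(D) histogram breaks.
#' @return list of class `cell_mobility`: `cell_id`, `n_trajectories`,
#'   `below_min_trajectories`, `mean_msd` (`msd_profile`), `auc`,
#'   `immobile_fraction`, `diffusion_histogram`, `track_table` (per-track
#'   `track_id`, `n_frames`, `D`, `intercept_a`, `floored`, `class`); or
#'   `NULL` when no track passes the filter.
#' @export
summarize_cell <- function(loc, dt = 0.02, min_track_frames = 8,
                           min_trajectories = 1000,
                           auc_window = c(0.02, 0.24), n_fit_points = 4,
                           threshold_log10 = -1.6, max_lag = 12,
                           hist_breaks = seq(-5, 2, by = 0.25)) {
  loc <- validate_localizations(loc)
  cell_id <- if (nrow(loc)) as.character(loc$cell_id[1]) else NA_character_
  if (length(unique(loc$cell_id)) > 1) {
    stop("summarize_cell expects a single cell; got ",
         length(unique(loc$cell_id)))
  }
  tracks <- split_tracks(loc)
  tracks <- tracks[vapply(tracks, nrow, 0L) >= min_track_frames]
  if (!length(tracks)) {
    warning("summarize_cell: no track of >= ", min_track_frames,
            " frames in cell ", cell_id)
    return(NULL)
  }
  profiles <- lapply(tracks, compute_msd, max_lag = max_lag, dt = dt)
  fits <- lapply(profiles, fit_diffusion, n_points = n_fit_points)
  ok <- !vapply(fits, is.null, TRUE)
  D <- vapply(fits[ok], function(f) f$D, 0)
  tab <- data.frame(
    track_id = names(tracks)[ok],
    n_frames = vapply(tracks[ok], nrow, 0L),
    D = D,
    intercept_a = vapply(fits[ok], function(f) f$intercept_a, 0),
    floored = vapply(fits[ok], function(f) f$floored, TRUE),
    class = classify_mobility(D, threshold_log10),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  mean_curve <- average_msd(profiles[ok], max_lag = max_lag, dt = dt)
  lg <- pmin(pmax(log10(D), min(hist_breaks)), max(hist_breaks))
  h <- graphics::hist(lg, breaks = hist_breaks, plot = FALSE)
  structure(list(
    cell_id = cell_id,
    n_trajectories = nrow(tab),
    below_min_trajectories = nrow(tab) < min_trajectories,
    mean_msd = mean_curve,
    auc = msd_auc(mean_curve, auc_window),
    immobile_fraction = mean(tab$class == "immobile"),
    diffusion_histogram = list(breaks = h$breaks, counts = h$counts),
    track_table = tab,
    params = list(dt = dt, min_track_frames = min_track_frames,
                  min_trajectories = min_trajectories,
                  auc_window = auc_window, n_fit_points = n_fit_points,
                  threshold_log10 = threshold_log10, max_lag = max_lag)),
    class = "cell_mobility")
}

#' @export
print.cell_mobility <- function(x, ...) {
  cat(sprintf(
    "cell_mobility %s: %d tracks%s, AUC = %.4g um^2 s, immobile fraction = %.3f\n",
    x$cell_id, x$n_trajectories,
    if (x$below_min_trajectories) " (below inclusion floor)" else "",
    x$auc, x$immobile_fraction))
  invisible(x)
}

#' Effective diffusion coefficient of an ROI
#'
#' Lag-wise mean MSD over all member trajectories of one ROI (a spine or a
#' shaft segment), fitted by [fit_diffusion()]. ROIs with fewer than
#' `min_trajectories` member tracks yield `NULL` (no-value signal).
#'
#' @param loc localization table restricted to one ROI's trajectories.
#' @param dt frame interval, s.
#' @param min_trajectories membership floor (default 50).
#' @param min_track_frames shortest track used.
#' @param n_fit_points,max_lag fit settings as in [summarize_cell()].
#' @return `diffusion_fit` with an added `n_trajectories` field, or `NULL`.
#' @export
effective_diffusion <- function(loc, dt = 0.02, min_trajectories = 50,
                                min_track_frames = 8, n_fit_points = 4,
                                max_lag = 12) {
  tracks <- split_tracks(loc)
  tracks <- tracks[vapply(tracks, nrow, 0L) >= min_track_frames]
  if (length(tracks) < min_trajectories) return(NULL)
  profiles <- lapply(tracks, compute_msd, max_lag = max_lag, dt = dt)
  fit <- fit_diffusion(average_msd(profiles, max_lag = max_lag, dt = dt),
                       n_points = n_fit_points)
  if (!is.null(fit)) fit$n_trajectories <- length(tracks)
  fit
}
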
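# Moment-scaling-spectrum (MSS) motion-type analysis.
#
# For a track, the order-nu displacement moment at lag k*dt is the mean of
# |displacement|^nu over all frame pairs at that lag. Each moment scales as
# lag^gamma_nu; the slope S_MSS of gamma_nu against nu classifies the whole
# trajectory: ~0 immobile, between 0 and 0.5 confined, ~0.5 free, ~1 directed.

#' Moment scaling spectrum of one trajectory
#'
#' Computes displacement moments of orders `0..nu_max` over the first
#' `n_lag_fit` lags, estimates each scaling exponent `gamma_nu` as the OLS
#' slope of `log(moment)` vs `log(lag)`, and summarizes them by `s_mss`, the
#' through-origin slope of `gamma_nu` against `nu` (so `gamma_0 = 0` holds
#' by construction), clipped to [0, 1].
#'
#' @param traj data.frame with `frame`, `x_um`, `y_um`; at least
#'   `min_frames` rows.
#' @param dt frame interval, s.
#' @param nu_max largest moment order.
#' @param n_lag_fit lags entering each log-log fit.
#' @param min_frames shortest track analyzed (default 20 frames).
#' @return list of class `mss_result` with `gamma` (named by order),
#'   `s_mss`, `n_frames`; or `NULL` with attribute-free `NULL` when the
#'   track is shorter than `min_frames` or a fitted lag has a zero moment
#'   (log undefined).
#' @export
compute_mss <- function(traj, dt = 0.02, nu_max = 6, n_lag_fit = 5,
                        min_frames = 20) {
  if (nrow(traj) < min_frames) return(NULL)
  f <- as.integer(traj$frame)
  if (any(diff(f) <= 0)) stop("trajectory frames must be strictly increasing")
  x <- traj$x_um; y <- traj$y_um
  nus <- 0:nu_max
  lags <- seq_len(n_lag_fit)
  mom <- matrix(NA_real_, length(lags), length(nus))
  for (ki in seq_along(lags)) {
    k <- lags[ki]
    j <- match(f + k, f)
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    r <- sqrt((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2)
    for (vi in seq_along(nus)) mom[ki, vi] <- mean(r^nus[vi])
  }
  if (any(mom[, -1] <= 0)) return(NULL)  # stationary at some lag: log undefined
  lt <- log(lags * dt)
  ltc <- lt - mean(lt)
  gamma <- vapply(seq_along(nus), function(vi) {
    lm <- log(mom[, vi])
    sum(ltc * (lm - mean(lm))) / sum(ltc^2)
  }, 0)
  gamma[1] <- 0  # order 0: moment is identically 1
  s <- sum(nus * gamma) / sum(nus^2)
  structure(list(gamma = stats::setNames(gamma, paste0("nu", nus)),
                 s_mss = min(max(s, 0), 1), n_frames = nrow(traj)),
            class = "mss_result")
}

#' Per-track MSS table for a localization set
#'
#' Applies [compute_mss()] to every track with at least `min_frames`
#' localizations.
#'
#' @param loc localization table.
#' @inheritParams compute_mss
#' @return data.frame with `track_id`, `n_frames`, `s_mss` (tracks excluded
#'   by length or by zero moments are absent).
#' @export
mss_table <- function(loc, dt = 0.02, nu_max = 6, n_lag_fit = 5,
                      min_frames = 20) {
  tracks <- split_tracks(loc)
  res <- lapply(tracks, compute_mss, dt = dt, nu_max = nu_max,
                n_lag_fit = n_lag_fit, min_frames = min_frames)
  ok <- !vapply(res, is.null, TRUE)
  data.frame(track_id = names(tracks)[ok],
             n_frames = vapply(res[ok], function(r) r$n_frames, 0L),
             s_mss = vapply(res[ok], function(r) r$s_mss, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}
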
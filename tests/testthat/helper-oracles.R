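# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's optimized code paths.

# Brute-force time-averaged MSD: double loop over all frame pairs.
naive_msd <- function(traj, max_lag, dt = 0.02) {
  f <- traj$frame; x <- traj$x_um; y <- traj$y_um
  out <- data.frame(lag = integer(0), msd = numeric(0), n_pairs = integer(0))
  for (k in seq_len(max_lag)) {
    acc <- 0; cnt <- 0L
    for (i in seq_along(f)) {
      for (j in seq_along(f)) {
        if (f[j] - f[i] == k) {
          acc <- acc + (x[j] - x[i])^2 + (y[j] - y[i])^2
          cnt <- cnt + 1L
        }
      }
    }
    if (cnt > 0) out <- rbind(out, data.frame(lag = k, msd = acc / cnt,
                                              n_pairs = cnt))
  }
  out
}

# Free Brownian track generated directly (independent of the package's
# simulator): cumulative Gaussian steps, optional localization noise.
free_track <- function(n_frames, D, dt = 0.02, sigma_um = 0, start = c(0, 0)) {
  x <- start[1] + cumsum(c(0, rnorm(n_frames - 1, 0, sqrt(2 * D * dt))))
  y <- start[2] + cumsum(c(0, rnorm(n_frames - 1, 0, sqrt(2 * D * dt))))
  if (sigma_um > 0) {
    x <- x + rnorm(n_frames, 0, sigma_um)
    y <- y + rnorm(n_frames, 0, sigma_um)
  }
  data.frame(frame = 0:(n_frames - 1), x_um = x, y_um = y)
}

# Localization table from a list of track data.frames.
tracks_to_loc <- function(tracks, cell_id = "cellA") {
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    cbind(cell_id = cell_id, track_id = sprintf("t%04d", i), tracks[[i]])
  }))
}

# Uniform points in a disc (fixture builder for cluster tests).
disc_points <- function(n, center, r) {
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

# One-exponential (single-state) CDF least squares on an ECDF grid; the
# collapsed-submodel oracle for the three-state fit comparison.
one_state_rss <- function(r, dt = 0.02) {
  r <- sort(r); n <- length(r)
  mid <- (r[-n] + r[-1]) / 2
  val <- seq_len(n - 1) / n
  keep <- mid > 0 & c(diff(mid) > 0, TRUE)
  mid <- mid[keep]; val <- val[keep]
  if (length(mid) > 500) {
    i <- unique(round(seq(1, length(mid), length.out = 500)))
    mid <- mid[i]; val <- val[i]
  }
  f <- function(logD) sum((val - (1 - exp(-mid^2 / (4 * exp(logD) * dt))))^2)
  opt <- optimize(f, c(log(1e-6), log(10)))
  opt$objective
}
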
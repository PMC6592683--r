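# Three-diffusive-state inference from single-frame displacement CDFs.
#
# The displacement r of a molecule diffusing freely at coefficient D for one
# frame interval dt has CDF 1 - exp(-r^2 / (4 D dt)). A population mixing
# three states (immobile, confined, apparently free) with occupancies
# f1 + f2 + f3 = 1 has
#
#   C(r, dt) = 1 - f1 e^{-r^2/4 D1 dt} - f2 e^{-r^2/4 D2 dt} - f3 e^{-r^2/4 D3 dt}
#
# The fit is global across cells: D1 < D2 < D3 are shared, occupancies vary
# per cell. To avoid over-weighting long tracks, each track contributes only
# its first seven displacements.

#' First-seven single-frame displacements of a cell
#'
#' Per track of at least `min_track_frames` localizations, collects the
#' magnitudes of the first `max_steps` consecutive-frame displacements
#' (gaps truncate the contribution), pooled over the cell.
#'
#' @param loc localization table for one cell.
#' @param cell_id optional check that the table is that cell.
#' @param max_steps displacements contributed per track (default 7).
#' @param min_track_frames shortest track contributing (default 8).
#' @return list of class `displacement_sample`: `cell_id`, `r` (um),
#'   `n_tracks`, `per_track` (named contribution counts).
#' @export
collect_displacements <- function(loc, cell_id = NULL, max_steps = 7,
                                  min_track_frames = 8) {
  loc <- validate_localizations(loc)
  ids <- unique(loc$cell_id)
  if (length(ids) > 1) stop("collect_displacements expects one cell")
  if (!is.null(cell_id) && nrow(loc) && !identical(as.character(ids), as.character(cell_id))) {
    stop("table holds cell ", ids, ", not ", cell_id)
  }
  tracks <- split_tracks(loc)
  tracks <- tracks[vapply(tracks, nrow, 0L) >= min_track_frames]
  rs <- lapply(tracks, function(tr) {
    consecutive <- which(diff(tr$frame) == 1L)
    # stop at the first gap so "first seven" means the first seven frames
    if (length(consecutive)) {
      run_end <- which(consecutive != seq_along(consecutive))[1]
      if (!is.na(run_end)) consecutive <- consecutive[seq_len(run_end - 1)]
    }
    i <- utils::head(consecutive, max_steps)
    sqrt((tr$x_um[i + 1] - tr$x_um[i])^2 + (tr$y_um[i + 1] - tr$y_um[i])^2)
  })
  structure(list(cell_id = if (length(ids)) as.character(ids) else NA_character_,
                 r = unlist(rs, use.names = FALSE),
                 n_tracks = length(tracks),
                 per_track = vapply(rs, length, 0L)),
            class = "displacement_sample")
}

#' Empirical CDF of a displacement sample
#'
#' @param sample `displacement_sample` (or bare numeric vector of
#'   displacements).
#' @return right-continuous step function (class `ecdf`), or `NULL` for an
#'   empty sample (no-value signal).
#' @export
displacement_ecdf <- function(sample) {
  r <- if (inherits(sample, "displacement_sample")) sample$r else sample
  if (!length(r)) return(NULL)
  stats::ecdf(r)
}

#' Three-state displacement CDF model
#'
#' @param r displacement, um (vectorized).
#' @param D three diffusion coefficients, um^2/s.
#' @param f three occupancies summing to 1.
#' @param dt frame interval, s.
#' @return model CDF values in [0, 1].
#' @export
three_state_cdf <- function(r, D, f, dt = 0.02) {
  stopifnot(length(D) == 3, length(f) == 3)
  1 - f[1] * exp(-r^2 / (4 * D[1] * dt)) -
      f[2] * exp(-r^2 / (4 * D[2] * dt)) -
      f[3] * exp(-r^2 / (4 * D[3] * dt))
}

# --- parameterization ---------------------------------------------------
# D: log-increment transform guaranteeing 0 < D1 < D2 < D3;
# f: per-cell softmax with the third logit pinned at 0.
theta_to_D <- function(th) {
  D1 <- exp(th[1]); D2 <- D1 + exp(th[2]); D3 <- D2 + exp(th[3])
  c(D1, D2, D3)
}
D_to_theta <- function(D) c(log(D[1]), log(D[2] - D[1]), log(D[3] - D[2]))
logits_to_f <- function(g) {
  e <- exp(c(g, 0) - max(c(g, 0)))
  e / sum(e)
}

# Evaluation grid: midpoints of the sorted displacement jump points, where
# the ECDF takes value i/n; uniformly subsampled to at most max_points.
ecdf_midpoints <- function(r, max_points = 500) {
  r <- sort(r)
  n <- length(r)
  if (n < 2) return(NULL)
  mid <- (r[-n] + r[-1]) / 2
  val <- seq_len(n - 1) / n
  keep <- mid > 0 & c(diff(mid) > 0, TRUE)
  mid <- mid[keep]; val <- val[keep]
  if (length(mid) > max_points) {
    i <- unique(round(seq(1, length(mid), length.out = max_points)))
    mid <- mid[i]; val <- val[i]
  }
  list(r = mid, cdf = val)
}

#' Global three-state fit of displacement CDFs across cells
#'
#' Minimizes the summed squared deviation between every cell's empirical
#' displacement CDF (evaluated at its jump midpoints, subsampled to at most
#' `max_points` per cell) and the three-state model, with the three
#' diffusion coefficients shared across cells and the occupancies free per
#' cell on the simplex. The ordering D1 < D2 < D3 and the simplex constraint
#' hold by construction of the parameterization. Levenberg-Marquardt local
#' optimization from `n_starts` seeded random starts (log-uniform diffusion
#' initialization over `d_init_range`); the best start is returned.
#'
#' @param samples list of `displacement_sample`s, one per cell (each with at
#'   least ~100 displacements; smaller cells are flagged in diagnostics).
#' @param dt frame interval, s.
#' @param n_starts random multistarts.
#' @param seed integer seed for the starts.
#' @param max_points CDF evaluation points per cell.
#' @param d_init_range range of the log-uniform diffusion initialization,
#'   um^2/s.
#' @return object of class `three_state_fit`: `D` (sorted, shared),
#'   `occupancy` (cells x 3 matrix, rows named by cell), `diagnostics`
#'   (per-start residual norms, convergence flags, degenerate-collapse
#'   flag, small-sample flags), `dt`.
#' @export
fit_three_state_global <- function(samples, dt = 0.02, n_starts = 10,
                                   seed = 1L, max_points = 500,
                                   d_init_range = c(1e-3, 1)) {
  stopifnot(length(samples) >= 1)
  grids <- lapply(samples, function(s) {
    r <- if (inherits(s, "displacement_sample")) s$r else s
    ecdf_midpoints(r, max_points)
  })
  ok <- !vapply(grids, is.null, TRUE)
  if (!any(ok)) stop("no cell has enough displacements to fit")
  grids <- grids[ok]
  cells <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (inherits(s, "displacement_sample") && !is.na(s$cell_id)) s$cell_id
    else paste0("cell", i)
  }, "")[ok]
  n_disp <- vapply(samples[ok], function(s)
    length(if (inherits(s, "displacement_sample")) s$r else s), 0L)
  nc <- length(grids)
  resid_fn <- function(par) {
    D <- theta_to_D(par[1:3])
    unlist(lapply(seq_len(nc), function(i) {
      g <- par[3 + 2 * (i - 1) + 1:2]
      f <- logits_to_f(g)
      grids[[i]]$cdf - three_state_cdf(grids[[i]]$r, D, f, dt)
    }), use.names = FALSE)
  }
  runs <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      D0 <- sort(exp(stats::runif(3, log(d_init_range[1]), log(d_init_range[2]))))
      # keep increments finite under the log-increment transform
      D0 <- D0 * c(1, 1.05, 1.1)^(seq_len(3) - 1)
      par0 <- c(D_to_theta(D0), stats::rnorm(2 * nc, 0, 1))
      fit <- try(minpack.lm::nls.lm(
        par = par0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
      if (inherits(fit, "try-error")) return(list(ok = FALSE, rss = Inf))
      list(ok = fit$info %in% 1:4, rss = sum(fit$fvec^2), par = fit$par,
           info = fit$info)
    })
  })
  rss <- vapply(runs, function(r) r$rss, 0)
  if (!any(is.finite(rss))) {
    stop("three-state fit failed to converge from any start; residuals: ",
         paste(signif(rss, 3), collapse = ", "))
  }
  best <- runs[[which.min(rss)]]
  D <- theta_to_D(best$par[1:3])
  occ <- t(vapply(seq_len(nc), function(i)
    logits_to_f(best$par[3 + 2 * (i - 1) + 1:2]), numeric(3)))
  dimnames(occ) <- list(cells, c("f1", "f2", "f3"))
  structure(list(
    D = D, occupancy = occ, dt = dt,
    diagnostics = list(
      residual_norm = sqrt(min(rss)), per_start_rss = rss,
      converged = best$ok, n_starts = n_starts,
      degenerate = any(D[-1] / D[-3] < 1.01),
      small_sample_cells = cells[n_disp < 100],
      n_displacements = stats::setNames(n_disp, cells))),
    class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat("three_state_fit: D =", paste(signif(x$D, 3), collapse = ", "),
      "um^2/s over", nrow(x$occupancy), "cell(s);",
      "residual norm", signif(x$diagnostics$residual_norm, 3), "\n")
  cat("mean occupancy:", paste(signif(colMeans(x$occupancy), 3), collapse = ", "), "\n")
  if (x$diagnostics$degenerate) cat("warning: near-degenerate state pair\n")
  invisible(x)
}

#' Per-state comparison of occupancies between two fitted conditions
#'
#' Compares per-cell occupancies state by state between two
#' `three_state_fit`s, using the per-cell testing route of
#' [select_test()] (paired or unpaired).
#'
#' @param model_a,model_b fitted `three_state_fit`s.
#' @param paired compare cell-by-cell (requires equal cell counts).
#' @return data.frame with one row per state: mean occupancies, difference
#'   `mean_b - mean_a`, direction sign, test used and p value.
#' @export
compare_occupancies <- function(model_a, model_b, paired = FALSE) {
  stopifnot(inherits(model_a, "three_state_fit"),
            inherits(model_b, "three_state_fit"))
  if (paired && nrow(model_a$occupancy) != nrow(model_b$occupancy)) {
    stop("paired comparison requires matched cells")
  }
  out <- lapply(1:3, function(s) {
    a <- model_a$occupancy[, s]; b <- model_b$occupancy[, s]
    d <- mean(b) - mean(a)
    res <- if (length(a) >= 3 && length(b) >= 3) {
      run_two_group_test(a, b, paired = paired)
    } else list(test = "none", p = NA_real_, statistic = NA_real_)
    data.frame(state = paste0("S", s), mean_a = mean(a), mean_b = mean(b),
               difference = d,
               direction = if (abs(d) < 1e-12) "0" else if (d > 0) "+" else "-",
               test = res$test, p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
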
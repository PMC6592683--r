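# MSD computation, diffusion fitting, mobility classification and per-cell /
# per-ROI summaries.

test_that("MSD matches closed forms and the all-pairs oracle", {
  # stationary point
  tr <- data.frame(frame = 0:9, x_um = rep(1, 10), y_um = rep(2, 10))
  expect_true(all(compute_msd(tr)$msd == 0))

  # ballistic line at spacing s: msd(k) = (k s)^2
  s <- 0.03
  tr <- data.frame(frame = 0:19, x_um = (0:19) * s, y_um = 0)
  prof <- compute_msd(tr, max_lag = 6)
  expect_equal(prof$msd, (prof$lag * s)^2, tolerance = 1e-12)

  # random tracks, including gapped ones, against the double-loop oracle
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    f <- sort(sample(0:(n + 6), n))
    tr <- data.frame(frame = f, x_um = rnorm(n), y_um = rnorm(n))
    prof <- compute_msd(tr, max_lag = 8)
    ora <- naive_msd(tr, max_lag = 8)
    expect_equal(prof$lag, ora$lag)
    expect_equal(prof$msd, ora$msd, tolerance = 1e-12)
    expect_equal(prof$n_pairs, ora$n_pairs)
  }

  # gap-free tracks have non-increasing pair counts
  tr <- free_track(30, 0.1)
  expect_true(all(diff(compute_msd(tr, max_lag = 20)$n_pairs) <= 0))

  expect_error(compute_msd(data.frame(frame = c(3, 2, 5), x_um = 1:3,
                                      y_um = 1:3)),
               "strictly increasing")
})

test_that("diffusion fit recovers exact lines and floors negative slopes", {
  t <- (1:6) * 0.02
  f1 <- fit_diffusion(data.frame(lag_s = t, msd = 4 * 0.1 * t))
  expect_equal(f1$D, 0.1, tolerance = 1e-12)
  expect_equal(f1$intercept_a, 0, tolerance = 1e-12)

  f2 <- fit_diffusion(data.frame(lag_s = t, msd = 4 * 0.05 * t + 0.002))
  expect_equal(f2$D, 0.05, tolerance = 1e-12)
  expect_equal(f2$intercept_a, 0.002, tolerance = 1e-12)

  f3 <- fit_diffusion(data.frame(lag_s = t, msd = rev(4 * 0.1 * t)))
  expect_true(f3$floored)
  expect_equal(f3$D, 1e-5)

  expect_null(fit_diffusion(data.frame(lag_s = 0.02, msd = 1)[0, ]))
})

test_that("immobile threshold is boundary-inclusive and monotone", {
  expect_identical(classify_mobility(1e-2), "immobile")
  expect_identical(classify_mobility(1e-1), "mobile")
  expect_identical(classify_mobility(10^-1.6), "immobile")
  # raising the threshold never decreases the immobile fraction
  set.seed(1)
  D <- 10^runif(500, -4, 0)
  fr <- vapply(seq(-3, 0, by = 0.25), function(th)
    mean(classify_mobility(D, th) == "immobile"), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("cell summary honours filters, flags and degenerate ensembles", {
  s <- 0.02
  tr <- data.frame(frame = 0:11, x_um = (0:11) * s, y_um = 0)
  loc <- tracks_to_loc(replicate(40, tr, simplify = FALSE))
  sm <- summarize_cell(loc, min_trajectories = 30)
  expect_false(sm$below_min_trajectories)
  # mean curve equals the single-track curve
  single <- compute_msd(tr, max_lag = 12)
  expect_equal(sm$mean_msd$msd, single$msd, tolerance = 1e-12)
  # all tracks share one D, so the immobile fraction is 0 or 1
  expect_true(sm$immobile_fraction %in% c(0, 1))
  expect_equal(sum(sm$diffusion_histogram$counts), sm$n_trajectories)

  sm2 <- summarize_cell(loc, min_trajectories = 41)
  expect_true(sm2$below_min_trajectories)

  # short tracks are filtered out
  short <- tracks_to_loc(list(data.frame(frame = 0:5, x_um = rnorm(6),
                                         y_um = rnorm(6))))
  expect_warning(expect_null(summarize_cell(short)), "no track")

  expect_error(summarize_cell(rbind(cbind(loc[1:24, 0], loc[1:24, ]),
                                    transform(loc[1:24, ], cell_id = "other"))),
               "single cell")
})

test_that("immobile fraction recovers a 50/50 slow/fast mixture", {
  set.seed(31)
  tracks <- c(replicate(300, free_track(15, 0.003), simplify = FALSE),
              replicate(300, free_track(15, 0.3), simplify = FALSE))
  sm <- summarize_cell(tracks_to_loc(tracks), min_trajectories = 500)
  expect_lt(abs(sm$immobile_fraction - 0.5), 0.05)
})

test_that("summary invariants: reordering, rigid motion, AUC scaling", {
  set.seed(32)
  tracks <- replicate(60, free_track(sample(8:25, 1), 10^runif(1, -3, -0.5)),
                      simplify = FALSE)
  loc <- tracks_to_loc(tracks)
  sm <- summarize_cell(loc, min_trajectories = 10)

  perm <- loc[sample(nrow(loc)), ]
  expect_equal(summarize_cell(perm, min_trajectories = 10)$immobile_fraction,
               sm$immobile_fraction)

  th <- 0.83
  rot <- transform(loc,
                   x_um = cos(th) * x_um - sin(th) * y_um + 5,
                   y_um = sin(th) * x_um + cos(th) * y_um - 2)
  expect_equal(summarize_cell(rot, min_trajectories = 10)$immobile_fraction,
               sm$immobile_fraction)
  expect_equal(summarize_cell(rot, min_trajectories = 10)$auc, sm$auc,
               tolerance = 1e-9)

  # AUC is non-negative and linear in the MSD scale
  expect_gte(sm$auc, 0)
  scaled <- transform(loc, x_um = 2 * x_um, y_um = 2 * y_um)
  expect_equal(summarize_cell(scaled, min_trajectories = 10)$auc, 4 * sm$auc,
               tolerance = 1e-9)
})

test_that("fitted intercept is centred on zero for noise-free free diffusion", {
  # the intercept estimator is mean-unbiased; its median is slightly
  # positive (skewed short-track fits), so the check is on the mean
  set.seed(33)
  a <- vapply(1:400, function(i) {
    fit_diffusion(compute_msd(free_track(20, 0.1)))$intercept_a
  }, 0)
  expect_gt(t.test(a)$p.value, 0.01)
})

test_that("ROI effective diffusion enforces the 50-trajectory floor", {
  tr <- data.frame(frame = 0:11, x_um = (0:11) * 0.02, y_um = 0)
  single_D <- fit_diffusion(compute_msd(tr, max_lag = 12))$D

  loc49 <- tracks_to_loc(replicate(49, tr, simplify = FALSE))
  expect_null(effective_diffusion(loc49))

  loc50 <- tracks_to_loc(replicate(50, tr, simplify = FALSE))
  fit <- effective_diffusion(loc50)
  expect_equal(fit$D, single_D, tolerance = 1e-12)
  expect_identical(fit$n_trajectories, 50L)

  set.seed(34)
  sim <- tracks_to_loc(replicate(200, free_track(sample(8:30, 1), 0.05),
                                 simplify = FALSE))
  expect_lt(abs(effective_diffusion(sim)$D - 0.05) / 0.05, 0.15)
})
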
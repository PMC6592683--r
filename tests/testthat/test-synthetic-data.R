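# Generator: layout construction, the Brownian mixture, photophysics,
# determinism and ground-truth bookkeeping.

test_that("default layout respects geometry contracts", {
  expect_length(build_default_layout(0, seed = 1)$spines, 0)

  a <- build_default_layout(5, seed = 1)
  b <- build_default_layout(5, seed = 1)
  expect_identical(a, b)

  # every nanodomain disc wholly inside its host polygon (boundary sampling)
  lay <- build_default_layout(5, seed = 3)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  for (k in seq_len(nrow(lay$nanodomains))) {
    nd <- lay$nanodomains[k, ]
    poly <- if (nd$compartment_id == "shaft") lay$shaft else
      lay$spines[[nd$compartment_id]]
    inside <- sptnano:::points_in_polygon(nd$x_um + nd$radius_um * cos(th),
                                          nd$y_um + nd$radius_um * sin(th),
                                          poly)
    expect_true(all(inside))
  }

  expect_error(build_default_layout(40, seed = 1), "non-overlapping")
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(state_occupancy = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(simulation_config(state_diffusion = c(0.3, 0.03, 0.003)),
               "strictly increasing")
  expect_error(simulation_config(frame_interval = 0), "frame_interval")
})

test_that("single slow state barely moves and free state has Brownian steps", {
  box <- big_box_layout(20)
  slow <- simulate_cell(simulation_config(
    state_occupancy = c(1, 0, 0), state_diffusion = c(1e-4, 0.03, 0.3),
    localization_sigma = 0, n_molecules = 300, seed = 5, layout = box))
  for (tr in split_tracks(slow$localizations)) {
    n <- nrow(tr)
    d <- sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2)
    expect_lt(d, 0.15)  # >8 frames at D = 1e-4: far inside the Gaussian tail
  }

  free <- simulate_cell(simulation_config(
    state_occupancy = c(0, 0, 1), state_diffusion = c(0.003, 0.03, 0.3),
    localization_sigma = 0, n_molecules = 1200, seed = 6, layout = box))
  steps2 <- unlist(lapply(split_tracks(free$localizations), function(tr) {
    i <- which(diff(tr$frame) == 1L)
    (tr$x_um[i + 1] - tr$x_um[i])^2 + (tr$y_um[i + 1] - tr$y_um[i])^2
  }))
  expect_gt(length(steps2), 1e4)
  expect_lt(abs(mean(steps2) - 4 * 0.3 * 0.02) / (4 * 0.3 * 0.02), 0.05)
})

test_that("simulation is deterministic and does not disturb the caller's RNG", {
  lay <- build_default_layout(3, seed = 2)
  cfg <- simulation_config(n_molecules = 200, seed = 9, layout = lay)
  set.seed(123); probe1 <- runif(1)
  a <- simulate_cell(cfg)
  set.seed(123); b_pre <- runif(1)
  b <- simulate_cell(cfg)
  expect_identical(a$localizations, b$localizations)
  expect_identical(probe1, b_pre)
  set.seed(42); x <- runif(1)
  set.seed(42); invisible(simulate_cell(cfg)); y <- runif(1)
  expect_identical(x, y)
})

test_that("state occupancies are recovered multinomially and truth is consistent", {
  box <- big_box_layout(20)
  occ <- c(0.2, 0.3, 0.5)
  cell <- simulate_cell(simulation_config(
    state_occupancy = occ, n_molecules = 2000, seed = 10, layout = box))
  tab <- table(factor(cell$truth$true_state, levels = 1:3))
  n <- sum(tab)
  for (s in 1:3) {
    se <- sqrt(occ[s] * (1 - occ[s]) * n)
    expect_lt(abs(tab[[s]] - occ[s] * n), 3 * se)
  }
  expect_setequal(unique(cell$truth$compartment_id), "shaft")
  expect_setequal(cell$truth$track_id, unique(cell$localizations$track_id))
})

test_that("trapped molecules never leave their disc (true positions)", {
  lay <- build_default_layout(4, seed = 4)
  cell <- simulate_cell(simulation_config(
    state_occupancy = c(0, 1, 0), n_molecules = 300, seed = 11,
    layout = lay, p_spine = 0.6))
  nd <- lay$nanodomains
  trapped <- cell$truth[!is.na(cell$truth$nanodomain_id), ]
  expect_gt(nrow(trapped), 50)
  tracks <- split_tracks(cell$true_positions)
  for (i in seq_len(nrow(trapped))) {
    k <- match(trapped$nanodomain_id[i], nd$nanodomain_id)
    tr <- tracks[[trapped$track_id[i]]]
    d <- sqrt((tr$x_um - nd$x_um[k])^2 + (tr$y_um - nd$y_um[k])^2)
    expect_true(all(d <= nd$radius_um[k] + 1e-12))
  }
})

test_that("track lengths honour the minimum and zero survivors warn", {
  box <- big_box_layout(20)
  cell <- simulate_cell(simulation_config(
    n_molecules = 400, min_track_length = 8, seed = 12, layout = box))
  expect_true(all(table(cell$localizations$track_id) >= 8))
  expect_warning(
    empty <- simulate_cell(simulation_config(
      n_molecules = 5, mean_track_length = 2, min_track_length = 200,
      seed = 13, layout = box)),
    "no trajectory")
  expect_identical(nrow(empty$localizations), 0L)
})

test_that("fixture suite is complete, labelled and byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_suite(d1, seed = 7)
  m2 <- write_fixture_suite(d2, seed = 7)
  expect_gte(length(m1$datasets), 4)
  for (ds in m1$datasets) {
    expect_true(file.exists(file.path(d1, ds$files$truth)))
    expect_true(file.exists(file.path(d1, ds$files$localizations)))
  }
  # byte-identical re-run
  for (i in seq_along(m1$datasets)) {
    for (f in unlist(m1$datasets[[i]]$files)) {
      expect_identical(unname(tools::md5sum(file.path(d1, f))),
                       unname(tools::md5sum(file.path(d2, f))))
    }
  }
  # empirical state frequencies of the three-state fixture within 3 binomial SE
  ds <- m1$datasets[[which(vapply(m1$datasets, function(d) d$name, "") == "three_state")]]
  tru <- read.csv(file.path(d1, ds$files$truth))
  occ <- unlist(ds$parameters$state_occupancy)
  n <- nrow(tru)
  for (s in 1:3) {
    se <- sqrt(occ[s] * (1 - occ[s]) / n)
    expect_lt(abs(mean(tru$true_state == s) - occ[s]), 3 * se + 1e-9)
  }
})

test_that("apparent single-lag MSD carries the static localization-error offset", {
  box <- big_box_layout(20)
  D <- 0.1; sig <- 0.04
  cell <- simulate_cell(simulation_config(
    state_occupancy = c(0, 0, 1), state_diffusion = c(0.003, 0.03, D),
    localization_sigma = sig * 1000, n_molecules = 1200, seed = 14,
    layout = box))
  steps2 <- unlist(lapply(split_tracks(cell$localizations), function(tr) {
    i <- which(diff(tr$frame) == 1L)
    (tr$x_um[i + 1] - tr$x_um[i])^2 + (tr$y_um[i + 1] - tr$y_um[i])^2
  }))
  expected <- 4 * D * 0.02 + 4 * sig^2
  expect_lt(abs(mean(steps2) - expected) / expected, 0.05)
})
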
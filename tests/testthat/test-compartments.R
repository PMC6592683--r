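# ROI loading/validation, trajectory assignment and the compartment report.

make_roi_json <- function(path, rois, cell_id = "c1") {
  jsonlite::write_json(list(cell_id = cell_id, rois = rois), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

square <- function(x0, y0, s = 1) {
  lapply(list(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)),
         as.list)
}

test_that("ROI files round-trip and invalid ones are rejected by name", {
  f <- withr::local_tempfile(fileext = ".json")
  make_roi_json(f, list(
    list(roi_id = "shaft1", label = "shaft", vertices_um = square(0, 0, 4)),
    list(roi_id = "sp1", label = "spine", paired_shaft_id = "shaft1",
         vertices_um = square(0, 4, 0.5)),
    list(roi_id = "sp2", label = "spine", vertices_um = square(2, 4, 0.5))))
  set <- load_rois(f)
  expect_identical(length(set$rois), 3L)
  expect_identical(vapply(set$rois, function(r) r$label, ""),
                   c("shaft", "spine", "spine"))
  # writing and re-reading preserves geometry
  f2 <- withr::local_tempfile(fileext = ".json")
  write_rois(set, f2, cell_id = "c1")
  set2 <- load_rois(f2)
  expect_equal(set2$rois[[2]]$polygon, set$rois[[2]]$polygon)

  # self-intersecting polygon named in the error
  f3 <- withr::local_tempfile(fileext = ".json")
  bow <- lapply(list(c(0, 0), c(1, 1), c(1, 0), c(0, 1)), as.list)
  make_roi_json(f3, list(list(roi_id = "bad", label = "shaft",
                              vertices_um = bow)))
  expect_error(load_rois(f3), "bad")

  # pairing must point at a shaft
  f4 <- withr::local_tempfile(fileext = ".json")
  make_roi_json(f4, list(
    list(roi_id = "spA", label = "spine", vertices_um = square(0, 0)),
    list(roi_id = "spB", label = "spine", paired_shaft_id = "spA",
         vertices_um = square(2, 0))))
  expect_error(load_rois(f4), "not a shaft")

  # duplicate ids and unknown labels
  f5 <- withr::local_tempfile(fileext = ".json")
  make_roi_json(f5, list(
    list(roi_id = "x", label = "shaft", vertices_um = square(0, 0)),
    list(roi_id = "x", label = "spine", vertices_um = square(2, 0))))
  expect_error(load_rois(f5), "duplicate")
  f6 <- withr::local_tempfile(fileext = ".json")
  make_roi_json(f6, list(list(roi_id = "x", label = "axon",
                              vertices_um = square(0, 0))))
  expect_error(load_rois(f6), "unknown label")
})

test_that("majority assignment follows the stated rules", {
  rois <- layout_to_rois(build_default_layout(2, seed = 3))
  spine_poly <- rois$rois[[2]]$polygon
  cx <- mean(range(spine_poly[, 1])); cy <- max(spine_poly[, 2]) - 0.1
  inside <- data.frame(cell_id = "c", track_id = "in",
                       frame = 0:9, x_um = cx + seq(-0.02, 0.02, length.out = 10),
                       y_um = cy)
  asg <- assign_trajectories(inside, rois)
  expect_identical(asg$status, "assigned")
  expect_identical(asg$roi_id, rois$rois[[2]]$roi_id)
  expect_equal(asg$fraction_inside, 1.0)

  # 3 of 10 points inside any ROI: unassigned
  part <- data.frame(cell_id = "c", track_id = "part", frame = 0:9,
                     x_um = c(rep(5, 3), rep(-10, 7)), y_um = 0.5)
  expect_identical(assign_trajectories(part, rois)$status, "unassigned")

  # overlap with an excluded ROI wins over everything
  rois_ex <- rois
  rois_ex$rois <- c(rois_ex$rois, list(structure(
    list(roi_id = "zz_excl", label = "excluded",
         polygon = cbind(c(4.9, 5.3, 5.3, 4.9), c(0.3, 0.3, 0.7, 0.7)),
         paired_shaft_id = NA_character_), class = "compartment_roi")))
  touch <- data.frame(cell_id = "c", track_id = "t", frame = 0:9,
                      x_um = seq(4.5, 5.2, length.out = 10), y_um = 0.5)
  expect_identical(assign_trajectories(touch, rois_ex)$status, "excluded")

  # ROI list order never changes the outcome
  rois_rev <- rois; rois_rev$rois <- rev(rois_rev$rois)
  set.seed(61)
  cell <- simulate_cell(simulation_config(
    n_molecules = 300, seed = 17, layout = build_default_layout(2, seed = 3),
    p_spine = 0.5))
  a1 <- assign_trajectories(cell$localizations, rois)
  a2 <- assign_trajectories(cell$localizations, rois_rev)
  expect_identical(a1[order(a1$track_id), ], a2[order(a2$track_id), ])
  # no track appears twice
  expect_identical(anyDuplicated(a1$track_id), 0L)
})

test_that("assignment agrees with generator ground truth for compartment-born tracks", {
  lay <- build_default_layout(5, seed = 4)
  cell <- simulate_cell(simulation_config(
    n_molecules = 800, seed = 18, layout = lay, p_spine = 0.5))
  asg <- assign_trajectories(cell$localizations, layout_to_rois(lay))
  m <- merge(asg[asg$status == "assigned", ], cell$truth, by = "track_id")
  expect_gt(nrow(m) / nrow(cell$truth), 0.9)
  expect_gte(mean(m$roi_id == m$compartment_id), 0.95)
})

test_that("compartment report matches recomputed per-compartment metrics", {
  lay <- build_default_layout(3, seed = 5)
  cell <- simulate_cell(simulation_config(
    n_molecules = 900, seed = 19, layout = lay, p_spine = 0.45))
  rois <- layout_to_rois(lay)
  asg <- assign_trajectories(cell$localizations, rois)
  rep <- compartment_report(cell$localizations, asg, rois)

  # consistency oracle: shaft row equals summarize_cell on shaft tracks alone
  lab <- setNames(vapply(rois$rois, function(r) r$label, ""),
                  vapply(rois$rois, function(r) r$roi_id, ""))
  shaft_ids <- asg$track_id[asg$status == "assigned" & lab[asg$roi_id] == "shaft"]
  sub <- cell$localizations[cell$localizations$track_id %in% shaft_ids, ]
  ora <- summarize_cell(sub, min_trajectories = 1)
  row <- rep$compartments[rep$compartments$label == "shaft", ]
  expect_equal(row$auc, ora$auc, tolerance = 1e-12)
  expect_equal(row$immobile_fraction, ora$immobile_fraction, tolerance = 1e-12)
  expect_identical(row$n_trajectories, ora$n_trajectories)

  # paired rows reference existing ROI d_eff values
  expect_identical(nrow(rep$paired), 3L)
  expect_true(all(rep$paired$shaft_id == "shaft"))

  # all tracks in the shaft: spine columns empty-flagged
  shaft_only <- cell$localizations[cell$localizations$track_id %in% shaft_ids, ]
  rep2 <- compartment_report(shaft_only, asg[asg$track_id %in% shaft_ids, ], rois)
  expect_true(rep2$compartments$empty[rep2$compartments$label == "spine"])
  expect_false(rep2$compartments$empty[rep2$compartments$label == "shaft"])
})
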
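# Voronoi tessellation, density-based object segmentation and nanodomain
# detection/geometry.

test_that("tessellation reproduces grid geometry and flags boundary cells", {
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  map <- tessellate(g)
  interior <- map$finite
  expect_true(any(interior))
  expect_equal(unname(map$area[which(interior)]),
               rep(1, sum(interior)), tolerance = 1e-9)
  # convex-hull points are flagged unbounded and carry zero density
  hull <- chull(g)
  expect_true(all(!map$finite[hull]))
  expect_true(all(map$delta[hull] == 0))
})

test_that("tessellation input validation: duplicates jittered, collinear rejected", {
  set.seed(51)
  pts <- cbind(runif(50), runif(50))
  expect_warning(map <- tessellate(rbind(pts, pts[1, , drop = FALSE])),
                 "duplicate")
  expect_identical(map$n, 51L)
  expect_error(tessellate(cbind(1:20, 2 * (1:20) + 3)), "collinear")
  expect_error(tessellate(pts[1:3, ]), "at least 4")
})

test_that("cluster points rank above background in first-rank density", {
  set.seed(52)
  bg <- cbind(runif(1000, 0, 4), runif(1000, 0, 4))
  cl <- rbind(disc_points(100, c(1, 1), 0.12), disc_points(100, c(3, 3), 0.12))
  map <- tessellate(rbind(bg, cl))
  bg_med <- median(map$delta[1:1000][map$finite[1:1000]])
  expect_gt(mean(map$delta[1001:1200] > bg_med), 0.95)
})

test_that("object segmentation recovers a compact region and splits distant ones", {
  set.seed(53)
  region <- cbind(runif(1500, 1, 3), runif(1500, 1, 3))
  map <- tessellate(region, window = c(0, 4, 0, 4))
  objs <- segment_objects(map)
  expect_gte(length(objs), 1)
  expect_gt(length(objs[[1]]$members) / 1500, 0.95)

  two <- rbind(cbind(runif(400, 0, 1), runif(400, 0, 1)),
               cbind(runif(400, 5, 6), runif(400, 5, 6)))
  map2 <- tessellate(two, window = c(-1, 7, -1, 7))
  objs2 <- segment_objects(map2)
  expect_identical(length(objs2), 2L)

  # nothing above an absurd threshold
  expect_identical(segment_objects(map, object_factor = 1e9), list())
})

test_that("planted nanodomains are detected and filters are monotone", {
  set.seed(54)
  bg <- cbind(runif(2800, 0.5, 3.5), runif(2800, 0.5, 3.5))
  pts <- rbind(bg, disc_points(100, c(1.5, 1.5), 0.1),
               disc_points(100, c(2.5, 2.5), 0.1))
  res <- analyze_nanodomains(pts, first_rank = TRUE)
  expect_identical(nrow(res$table), 2L)
  planted <- list(2801:2900, 2901:3000)
  for (pl in planted) {
    rec <- max(vapply(res$domains, function(d) mean(pl %in% d$members), 0))
    expect_gte(rec, 0.9)
  }
  # post-hoc: every domain re-satisfies its defining thresholds
  for (oi in unique(res$table$object)) {
    obj <- res$objects[[oi]]
    for (d in res$domains[res$table$object == oi]) {
      expect_gte(length(d$members), 50)
      expect_true(all(res$map$delta[d$members] >= 2 * obj$mean_density))
    }
  }
  # domains are pairwise disjoint and within the object membership
  mem <- lapply(res$domains, function(d) d$members)
  expect_identical(anyDuplicated(unlist(mem)), 0L)

  # monotone filtering in both thresholds
  n_base <- nrow(res$table)
  stricter <- analyze_nanodomains(pts, density_factor = 3)$table
  expect_lte(nrow(stricter), n_base)
  bigger <- analyze_nanodomains(pts, min_detections = 150)$table
  expect_lte(nrow(bigger), n_base)

  # a 40-detection cluster at the same 10x density yields nothing
  r40 <- sqrt(40 / (10 * (2800 / 9) * pi))
  pts40 <- rbind(bg, disc_points(40, c(2, 2), r40))
  expect_identical(nrow(analyze_nanodomains(pts40)$table), 0L)
})

test_that("nanodomain sets survive rigid motion of all localizations", {
  set.seed(55)
  bg <- cbind(runif(2000, 0.5, 3.5), runif(2000, 0.5, 3.5))
  pts <- rbind(bg, disc_points(120, c(2, 2), 0.1))
  base <- analyze_nanodomains(pts)
  th <- 0.4; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% R, 2, c(10, -3), "+")
  rot <- analyze_nanodomains(moved)
  expect_identical(nrow(rot$table), nrow(base$table))
  planted <- 2001:2120
  rec_b <- max(vapply(base$domains, function(d) mean(planted %in% d$members), 0))
  rec_r <- max(vapply(rot$domains, function(d) mean(planted %in% d$members), 0))
  expect_gte(rec_b, 0.9); expect_gte(rec_r, 0.9)
  expect_equal(rot$table$diameter_nm, base$table$diameter_nm, tolerance = 0.02)
})

test_that("PCA diameter and outline geometry follow their conventions", {
  set.seed(56)
  d <- disc_points(4000, c(0, 0), 0.1)
  g <- nanodomain_geometry(d)
  expect_lt(abs(g$diameter_nm - 200) / 200, 0.15)

  # circle: isotropic principal components
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(0.2 * cos(th), 0.2 * sin(th))
  gc <- nanodomain_geometry(circ)
  expect_equal(gc$pca_sd[1], gc$pca_sd[2], tolerance = 1e-9)

  # rigid invariance of diameter and hull area
  rot <- sweep(d %*% matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2), 2,
               c(7, 9), "+")
  gr <- nanodomain_geometry(rot)
  expect_equal(gr$diameter_nm, g$diameter_nm, tolerance = 1e-9)
  expect_equal(gr$area_um2, g$area_um2, tolerance = 1e-9)

  # collinear members degenerate to zero area, flagged
  line <- cbind(seq(0, 1, length.out = 10), seq(0, 2, length.out = 10))
  gl <- nanodomain_geometry(line)
  expect_true(gl$degenerate)
  expect_identical(gl$area_um2, 0)
})

test_that("nanodomain counts per ROI assign centroids with a deterministic tie-break", {
  rois <- layout_to_rois(build_default_layout(3, seed = 6))
  doms <- data.frame(domain_id = 1:2,
                     x_um = c(5, -10), y_um = c(0.6, 0.6))
  counts <- nanodomains_per_roi(doms, rois)
  expect_identical(sum(counts$n_nanodomains), 1L)
  expect_identical(attr(counts, "n_unassigned"), 1L)
  expect_identical(counts$n_nanodomains[counts$roi_id == "shaft"], 1L)

  # empty set: all-zero counts over every ROI
  zero <- nanodomains_per_roi(doms[0, ], rois)
  expect_true(all(zero$n_nanodomains == 0L))
  expect_identical(nrow(zero), 4L)

  # centroid on a shared boundary goes to the lexicographically lowest id
  sq1 <- structure(list(roi_id = "a2", label = "shaft",
                        polygon = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                        paired_shaft_id = NA_character_),
                   class = "compartment_roi")
  sq2 <- structure(list(roi_id = "a1", label = "shaft",
                        polygon = cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)),
                        paired_shaft_id = NA_character_),
                   class = "compartment_roi")
  set <- structure(list(cell_id = "c", rois = list(sq1, sq2)),
                   class = "roi_set")
  ondary <- nanodomains_per_roi(data.frame(x_um = 1, y_um = 0.5), set)
  expect_identical(ondary$n_nanodomains[ondary$roi_id == "a1"], 1L)
})
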
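# Voronoi-tessellation-based nanodomain (nanocluster) detection.
#
# Pooled localizations are tessellated into polygons centred on each point;
# a first-rank neighbour-averaged density is attached to every localization.
# Objects (e.g. the cell outline) are density-connected components above the
# global average density; nanodomains are components within an object that
# hold >= 50 detections at >= 2x the object's average density.

#' Voronoi tessellation and local density of a localization set
#'
#' Builds the Voronoi diagram of the points (via the Delaunay/Dirichlet
#' tessellation of `deldir`), records each cell's polygon area and flags
#' cells clipped by the enclosing window as unbounded. The local density of
#' point i is first-rank neighbour-averaged:
#' `delta_i = (1 + |N_i|) / (A_i + sum_{j in N_i} A_j)` over the Voronoi
#' neighbours `N_i` with finite (unclipped) cells; unbounded cells carry
#' density 0 and are excluded from the global average, which is the count of
#' finite-cell points divided by their total area.
#'
#' The global average density is the localization count divided by the area
#' of the enclosing window — the quantity an object threshold is naturally
#' expressed against when, as in real acquisitions, the imaged field
#' contains empty space around the cell.
#'
#' @param points localization table or two-column matrix/data.frame of
#'   coordinates in um; at least 4 non-collinear points.
#' @param first_rank use neighbour-averaged density (default); `FALSE` uses
#'   the bare inverse cell area `1 / A_i`.
#' @param window optional enclosing window `c(xmin, xmax, ymin, ymax)`
#'   (e.g. the imaged field of view); defaults to the point bounding box
#'   expanded by 10%.
#' @return object of class `voronoi_map`: `xy`, `area`, `finite`, `delta`,
#'   `neighbors` (adjacency list), `tiles` (cell polygons),
#'   `global_density`, `window`, `n`.
#' @export
tessellate <- function(points, first_rank = TRUE, window = NULL) {
  xy <- if (is.data.frame(points) && all(c("x_um", "y_um") %in% names(points))) {
    cbind(points$x_um, points$y_um)
  } else {
    as.matrix(points)[, 1:2, drop = FALSE]
  }
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n < 4) stop("tessellation needs at least 4 points")
  dup <- duplicated(xy)
  if (any(dup)) {
    warning(sum(dup), " duplicate localization(s) perturbed by <= 1e-9 um")
    jit <- with_seed(n, matrix(stats::runif(2 * sum(dup), -1e-9, 1e-9), ncol = 2))
    xy[dup, ] <- xy[dup, ] + jit
  }
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-12 * max(sv[1], 1)) stop("all points are collinear")
  dd <- if (is.null(window)) deldir::deldir(xy[, 1], xy[, 2])
        else deldir::deldir(xy[, 1], xy[, 2], rw = window)
  if (nrow(dd$summary) != n) stop("tessellation dropped points unexpectedly")
  tiles <- deldir::tile.list(dd)
  finite <- !vapply(tiles, function(tl) any(tl$bp), TRUE)
  area <- vapply(tiles, function(tl)
    polygon_area(cbind(tl$x, tl$y)), 0)
  nb <- vector("list", n)
  e1 <- dd$delsgs$ind1; e2 <- dd$delsgs$ind2
  for (i in seq_along(e1)) {
    nb[[e1[i]]] <- c(nb[[e1[i]]], e2[i])
    nb[[e2[i]]] <- c(nb[[e2[i]]], e1[i])
  }
  nb <- lapply(nb, unique)
  delta <- numeric(n)
  if (first_rank) {
    for (i in seq_len(n)) {
      if (!finite[i]) next
      nbf <- nb[[i]][finite[nb[[i]]]]
      delta[i] <- (1 + length(nbf)) / (area[i] + sum(area[nbf]))
    }
  } else {
    delta[finite] <- 1 / area[finite]
  }
  rw <- dd$rw
  structure(list(
    xy = xy, area = area, finite = finite, delta = delta, neighbors = nb,
    tiles = lapply(tiles, function(tl) list(x = tl$x, y = tl$y)),
    global_density = n / ((rw[2] - rw[1]) * (rw[4] - rw[3])),
    window = rw, n = n, first_rank = first_rank), class = "voronoi_map")
}

#' @export
print.voronoi_map <- function(x, ...) {
  cat(sprintf("voronoi_map: %d points (%d finite cells), global density %.4g um^-2\n",
              x$n, sum(x$finite), x$global_density))
  invisible(x)
}

# Union-find over a vertex subset of the Voronoi adjacency graph; returns a
# list of components (integer index vectors into the map).
adjacency_components <- function(map, subset) {
  sel <- sort(subset)
  pos <- integer(map$n); pos[sel] <- seq_along(sel)
  parent <- seq_along(sel)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (si in seq_along(sel)) {
    i <- sel[si]
    for (j in map$neighbors[[i]]) {
      if (j > i && pos[j] > 0) {
        ri <- find(si); rj <- find(pos[j])
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_along(sel), find, 0L)
  unname(split(sel, roots))
}

# Union of Voronoi cell polygons of `members`; returns list(paths, area).
tiles_union <- function(map, members) {
  paths <- map$tiles[members]
  if (!length(paths)) return(list(paths = list(), area = 0))
  u <- polyclip::polyclip(paths, paths, op = "union",
                          fillA = "nonzero", fillB = "nonzero")
  area <- abs(sum(vapply(u, function(p)
    polygon_area_signed(cbind(p$x, p$y)), 0)))
  list(paths = u, area = area)
}

#' Segment density-connected objects
#'
#' Localizations at or above `object_factor` times the global average
#' density seed connected components through the Voronoi adjacency; the
#' object then comprises the seeds plus every finite-cell localization
#' adjacent to a seed (an object is a region, so interstitial and rim
#' points below the threshold belong to it; components claim shared rim
#' points largest-first). Objects under `min_members` localizations are
#' discarded. The outline is the union of the members' Voronoi cells and
#' the object's average density is its member count over the outline area.
#'
#' @param map `voronoi_map` from [tessellate()].
#' @param object_factor density threshold as a multiple of the global
#'   average density.
#' @param min_members smallest retained object.
#' @return list of `segmented_object`s, largest first: `members` (indices
#'   into the map), `seeds`, `outline` (list of polygon paths), `area`
#'   (um^2), `mean_density` (members / area, um^-2).
#' @export
segment_objects <- function(map, object_factor = 1.0, min_members = 10) {
  stopifnot(inherits(map, "voronoi_map"))
  sel <- which(map$finite & map$delta >= object_factor * map$global_density)
  if (!length(sel)) return(list())
  comps <- adjacency_components(map, sel)
  comps <- comps[order(-vapply(comps, length, 0L))]
  claimed <- logical(map$n)
  claimed[sel] <- TRUE
  objs <- lapply(comps, function(seeds) {
    ring <- unique(unlist(map$neighbors[seeds], use.names = FALSE))
    ring <- ring[map$finite[ring] & !claimed[ring]]
    claimed[ring] <<- TRUE
    members <- sort(c(seeds, ring))
    u <- tiles_union(map, members)
    structure(list(members = members, seeds = seeds, outline = u$paths,
                   area = u$area, mean_density = length(members) / u$area),
              class = "segmented_object")
  })
  objs[vapply(objs, function(o) length(o$members), 0L) >= min_members]
}

#' Detect nanodomains within a segmented object
#'
#' Localizations of the object whose local density reaches `density_factor`
#' times the object's average density are merged through Voronoi adjacency;
#' components with at least `min_detections` members become nanodomains.
#' Both defining thresholds are re-verified post hoc on every reported
#' domain.
#'
#' @param map `voronoi_map`.
#' @param object `segmented_object` from [segment_objects()].
#' @param min_detections membership floor (default 50).
#' @param density_factor density multiple of the object average (default 2).
#' @return list of `nanodomain`s: `members`, `centroid` (um), `diameter_nm`,
#'   `area_um2`, `outline`, `mean_member_density`.
#' @export
detect_nanodomains <- function(map, object, min_detections = 50,
                               density_factor = 2.0) {
  stopifnot(inherits(map, "voronoi_map"), inherits(object, "segmented_object"))
  thr <- density_factor * object$mean_density
  sel <- object$members[map$delta[object$members] >= thr]
  if (!length(sel)) return(list())
  comps <- adjacency_components(map, sel)
  comps <- comps[vapply(comps, length, 0L) >= min_detections]
  out <- lapply(comps, function(m) {
    geom <- nanodomain_geometry(map$xy[m, , drop = FALSE], map = map, members = m)
    structure(list(members = m,
                   centroid = colMeans(map$xy[m, , drop = FALSE]),
                   diameter_nm = geom$diameter_nm,
                   area_um2 = geom$area_um2,
                   outline = geom$outline,
                   mean_member_density = mean(map$delta[m])),
              class = "nanodomain")
  })
  # post-hoc re-check of the defining rules (assertions, not assumptions)
  for (d in out) {
    stopifnot(length(d$members) >= min_detections,
              all(map$delta[d$members] >= thr))
  }
  out
}

#' Nanodomain diameter and area
#'
#' Diameter convention: the members' coordinates are decomposed by principal
#' component analysis and the diameter is `2 * sqrt(2 * (sd1^2 + sd2^2))`
#' (equivalently four times the root-mean-square of the two component
#' standard deviations), which equals the true diameter for points uniformly
#' filling a disc. The area is that of the outer outline polygon: the union
#' of the members' Voronoi cells when a map is supplied, otherwise the
#' convex hull (flagged in `outline_method`).
#'
#' @param coords members' coordinates, um (>= 3 rows).
#' @param map optional `voronoi_map` providing the member cell polygons.
#' @param members indices into `map` matching `coords`.
#' @return list: `diameter_nm`, `area_um2`, `outline`, `outline_method`,
#'   `pca_sd` (the two component standard deviations, um), `degenerate`.
#' @export
nanodomain_geometry <- function(coords, map = NULL, members = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 3)
  sdv <- stats::prcomp(coords, center = TRUE)$sdev
  if (length(sdv) < 2) sdv <- c(sdv, 0)
  degenerate <- sdv[2] < 1e-12
  diameter_nm <- 2 * sqrt(2 * sum(sdv^2)) * 1000
  if (!is.null(map) && !is.null(members)) {
    u <- tiles_union(map, members)
    outline <- u$paths; area <- u$area; method <- "voronoi_union"
  } else if (!degenerate) {
    h <- grDevices::chull(coords)
    outline <- list(list(x = coords[h, 1], y = coords[h, 2]))
    area <- polygon_area(coords[h, , drop = FALSE])
    method <- "convex_hull"
  } else {
    outline <- list(); area <- 0; method <- "degenerate"
  }
  list(diameter_nm = diameter_nm, area_um2 = area, outline = outline,
       outline_method = method, pca_sd = sdv[1:2], degenerate = degenerate)
}

#' One-call nanodomain analysis of a localization set
#'
#' Chains [tessellate()], [segment_objects()] and [detect_nanodomains()]
#' over every object.
#'
#' @inheritParams tessellate
#' @inheritParams segment_objects
#' @inheritParams detect_nanodomains
#' @return list with `map`, `objects`, `domains` (flat list over objects)
#'   and `table` (one row per domain: centroid, diameter, area, members,
#'   host object).
#' @export
analyze_nanodomains <- function(points, object_factor = 1.0,
                                min_members = 10, min_detections = 50,
                                density_factor = 2.0, first_rank = TRUE) {
  map <- tessellate(points, first_rank = first_rank)
  objects <- segment_objects(map, object_factor, min_members)
  domains <- list()
  host <- integer(0)
  for (oi in seq_along(objects)) {
    d <- detect_nanodomains(map, objects[[oi]], min_detections, density_factor)
    domains <- c(domains, d)
    host <- c(host, rep(oi, length(d)))
  }
  tab <- if (length(domains)) data.frame(
    domain_id = seq_along(domains),
    x_um = vapply(domains, function(d) d$centroid[1], 0),
    y_um = vapply(domains, function(d) d$centroid[2], 0),
    diameter_nm = vapply(domains, function(d) d$diameter_nm, 0),
    area_um2 = vapply(domains, function(d) d$area_um2, 0),
    n_detections = vapply(domains, function(d) length(d$members), 0L),
    object = host)
  else data.frame(domain_id = integer(0), x_um = numeric(0), y_um = numeric(0),
                  diameter_nm = numeric(0), area_um2 = numeric(0),
                  n_detections = integer(0), object = integer(0))
  list(map = map, objects = objects, domains = domains, table = tab,
       params = list(object_factor = object_factor, min_members = min_members,
                     min_detections = min_detections,
                     density_factor = density_factor,
                     diameter_convention = "2*sqrt(2*(sd1^2+sd2^2)) over PCA sds"))
}

#' Count nanodomains per ROI
#'
#' Assigns each nanodomain to the ROI polygon containing its centroid; a
#' centroid on a shared boundary goes to the ROI with the lexicographically
#' lowest id. Counts are zero-inclusive over all ROIs; centroids inside no
#' ROI are tallied as unassigned.
#'
#' @param domains list of `nanodomain`s or the `table` from
#'   [analyze_nanodomains()].
#' @param rois `roi_set` (see [load_rois()]).
#' @return data.frame `roi_id`, `label`, `n_nanodomains`, with attribute
#'   `n_unassigned`.
#' @export
nanodomains_per_roi <- function(domains, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.data.frame(domains)) {
    cx <- domains$x_um; cy <- domains$y_um
  } else {
    cx <- vapply(domains, function(d) d$centroid[1], 0)
    cy <- vapply(domains, function(d) d$centroid[2], 0)
  }
  ids <- vapply(rois$rois, function(r) r$roi_id, "")
  ord <- order(ids)
  counts <- stats::setNames(integer(length(ids)), ids)
  unassigned <- 0L
  for (k in seq_along(cx)) {
    hit <- NA_character_
    for (i in ord) {  # lowest roi_id wins boundary ties
      if (points_in_polygon(cx[k], cy[k], rois$rois[[i]]$polygon)) {
        hit <- ids[i]; break
      }
    }
    if (is.na(hit)) unassigned <- unassigned + 1L else
      counts[hit] <- counts[hit] + 1L
  }
  out <- data.frame(roi_id = ids,
                    label = vapply(rois$rois, function(r) r$label, ""),
                    n_nanodomains = as.integer(counts), row.names = NULL)
  attr(out, "n_unassigned") <- unassigned
  out
}
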
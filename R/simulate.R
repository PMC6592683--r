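# Ground-truth-labelled Brownian-dynamics simulator emulating sptPALM
# acquisitions of membrane molecules in dendritic spine/shaft geometries:
# a static mixture of three diffusive states, optional trapping of the
# confined state in nanodomain discs, reflecting boundaries, geometric
# (bleaching-limited) track lengths and isotropic Gaussian localization error.

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so that one seeded stage never perturbs another's
#' randomness. All stochastic package internals route their seeds through
#' this helper.
#'
#' @param seed integer seed (taken modulo the machine integer maximum).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Build a dendrite-like compartment layout
#'
#' Constructs a rectangular dendritic-shaft segment with `n_spines`
#' mushroom-shaped spine polygons (neck + ~0.5 um head) attached to its upper
#' edge, and places circular trapping nanodomains: by default one per spine
#' head plus a sparse set in the shaft.
#'
#' @param n_spines number of spines (>= 0).
#' @param seed integer seed; identical seeds give identical layouts.
#' @param shaft_length,shaft_width shaft rectangle dimensions, um.
#' @param spine_head_diameter spine head diameter, um.
#' @param neck_width,neck_length spine neck dimensions, um.
#' @param nanodomain_diameter nanodomain disc diameter, nm.
#' @param nanodomains_per_spine trapping discs placed in each spine head.
#' @param nanodomains_in_shaft trapping discs placed in the shaft.
#' @return object of class `sim_layout`: list with `shaft` (polygon matrix),
#'   `spines` (named list of polygon matrices, ids `"spine1"`, ...),
#'   `nanodomains` (data.frame `nanodomain_id`, `x_um`, `y_um`, `radius_um`,
#'   `compartment_id`) and the generating parameters.
#' @export
build_default_layout <- function(n_spines, seed = 1L,
                                 shaft_length = 10, shaft_width = 1.2,
                                 spine_head_diameter = 0.5,
                                 neck_width = 0.15, neck_length = 0.25,
                                 nanodomain_diameter = 170,
                                 nanodomains_per_spine = 1,
                                 nanodomains_in_shaft = 2) {
  stopifnot(n_spines >= 0, shaft_length > 0, shaft_width > 0)
  rh <- spine_head_diameter / 2
  pitch <- 2 * rh + 0.2
  if (n_spines > 0 && n_spines * pitch > shaft_length - 0.4) {
    stop("cannot place ", n_spines, " non-overlapping spines on a ",
         shaft_length, " um shaft")
  }
  rd <- nanodomain_diameter / 2 / 1000  # nm -> um radius
  with_seed(seed, {
    shaft <- cbind(c(0, shaft_length, shaft_length, 0),
                   c(0, 0, shaft_width, shaft_width))
    spines <- list()
    nd <- list()
    if (n_spines > 0) {
      # evenly spaced attachment points with a small jitter
      slots <- seq(0.2 + pitch / 2, shaft_length - 0.2 - pitch / 2,
                   length.out = max(n_spines, 1))
      jit <- stats::runif(n_spines, -0.05, 0.05)
      for (s in seq_len(n_spines)) {
        cx <- slots[s] + jit[s]
        yc <- shaft_width + neck_length + rh
        phi <- acos(pmin(1, (neck_width / 2) / rh))
        attach_y <- yc - rh * sin(phi)
        arc <- seq(-phi, pi + phi, length.out = 33)
        poly <- rbind(
          c(cx - neck_width / 2, shaft_width),
          c(cx + neck_width / 2, shaft_width),
          cbind(cx + rh * cos(arc), yc + rh * sin(arc)))
        id <- paste0("spine", s)
        spines[[id]] <- poly
        if (nanodomains_per_spine > 0) {
          ctr <- sample_in_disc(nanodomains_per_spine, c(cx, yc),
                                max(rh - rd - 0.01, 0))
          for (k in seq_len(nanodomains_per_spine)) {
            nd[[length(nd) + 1]] <- data.frame(
              x_um = ctr[k, 1], y_um = ctr[k, 2], radius_um = rd,
              compartment_id = id)
          }
        }
      }
    }
    if (nanodomains_in_shaft > 0) {
      sx <- stats::runif(nanodomains_in_shaft, rd + 0.05, shaft_length - rd - 0.05)
      sy <- stats::runif(nanodomains_in_shaft, rd + 0.05, shaft_width - rd - 0.05)
      for (k in seq_len(nanodomains_in_shaft)) {
        nd[[length(nd) + 1]] <- data.frame(
          x_um = sx[k], y_um = sy[k], radius_um = rd, compartment_id = "shaft")
      }
    }
    nanodomains <- if (length(nd)) do.call(rbind, nd) else
      data.frame(x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
                 compartment_id = character(0))
    if (nrow(nanodomains)) {
      nanodomains <- cbind(nanodomain_id = paste0("nd", seq_len(nrow(nanodomains))),
                           nanodomains)
    } else {
      nanodomains <- cbind(nanodomain_id = character(0), nanodomains)
    }
    layout <- structure(list(
      shaft = shaft, spines = spines, nanodomains = nanodomains,
      params = list(n_spines = n_spines, seed = seed,
                    shaft_length = shaft_length, shaft_width = shaft_width,
                    spine_head_diameter = spine_head_diameter,
                    neck_width = neck_width, neck_length = neck_length,
                    nanodomain_diameter = nanodomain_diameter)),
      class = "sim_layout")
    validate_layout(layout)
    layout
  })
}

#' Validate a compartment layout
#'
#' Checks that all polygons are simple and that every nanodomain disc lies
#' wholly inside its host compartment (disc boundary sampled at 64 points).
#'
#' @param layout `sim_layout` object.
#' @return `layout`, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "sim_layout"))
  if (!is_simple_polygon(layout$shaft)) stop("shaft polygon is not simple")
  for (id in names(layout$spines)) {
    if (!is_simple_polygon(layout$spines[[id]])) {
      stop("spine polygon ", id, " is not simple")
    }
  }
  nd <- layout$nanodomains
  if (nrow(nd)) {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    for (k in seq_len(nrow(nd))) {
      poly <- compartment_polygon(layout, nd$compartment_id[k])
      bx <- nd$x_um[k] + nd$radius_um[k] * cos(th)
      by <- nd$y_um[k] + nd$radius_um[k] * sin(th)
      if (!all(points_in_polygon(bx, by, poly))) {
        stop("nanodomain ", nd$nanodomain_id[k],
             " is not contained in compartment ", nd$compartment_id[k])
      }
    }
  }
  invisible(layout)
}

# Polygon of a named compartment ("shaft" or a spine id).
compartment_polygon <- function(layout, id) {
  if (identical(id, "shaft")) return(layout$shaft)
  poly <- layout$spines[[id]]
  if (is.null(poly)) stop("unknown compartment id: ", id)
  poly
}

#' @export
print.sim_layout <- function(x, ...) {
  cat("sim_layout:", length(x$spines), "spine(s),",
      nrow(x$nanodomains), "nanodomain(s), shaft",
      x$params$shaft_length, "x", x$params$shaft_width, "um\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults reproduce the
#' acquisition regime the analysis assumes: 50 Hz frame rate over 16,000
#' frames, three diffusive states, ~170 nm trapping nanodomains, geometric
#' bleaching-limited track lengths, 25 nm localization precision.
#'
#' @param frame_interval frame interval, s.
#' @param n_frames frames in the acquisition.
#' @param state_diffusion three strictly increasing apparent diffusion
#'   coefficients (immobile, confined, free), um^2/s.
#' @param state_occupancy three state probabilities summing to 1.
#' @param spine_state_occupancy optional distinct occupancy vector for
#'   molecules born in spines (compartment-dependent mobility); `NULL` uses
#'   `state_occupancy` everywhere.
#' @param localization_sigma isotropic Gaussian localization error per
#'   coordinate, nm.
#' @param mean_track_length mean of the geometric track-length law, frames.
#' @param min_track_length shortest track retained, frames.
#' @param n_molecules molecules photoconverted over the acquisition.
#' @param p_spine probability that a molecule is born in a spine; `NULL`
#'   means proportional to compartment area.
#' @param seed integer seed.
#' @param layout `sim_layout` (see [build_default_layout()]).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(frame_interval = 0.02, n_frames = 16000,
                              state_diffusion = c(0.003, 0.03, 0.3),
                              state_occupancy = c(0.30, 0.40, 0.30),
                              spine_state_occupancy = NULL,
                              localization_sigma = 25,
                              mean_track_length = 15,
                              min_track_length = 8,
                              n_molecules = 3000,
                              p_spine = NULL,
                              seed = 1L,
                              layout = build_default_layout(4, seed = 1L)) {
  cfg <- list(frame_interval = frame_interval, n_frames = n_frames,
              state_diffusion = state_diffusion,
              state_occupancy = state_occupancy,
              spine_state_occupancy = spine_state_occupancy,
              localization_sigma = localization_sigma,
              mean_track_length = mean_track_length,
              min_track_length = min_track_length,
              n_molecules = n_molecules, p_spine = p_spine,
              seed = seed, layout = layout)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!(frame_interval > 0)) stop("frame_interval must be > 0")
    if (length(state_diffusion) != 3 || any(state_diffusion <= 0) ||
        any(diff(state_diffusion) <= 0)) {
      stop("state_diffusion must be three strictly increasing positive values")
    }
    check_occ <- function(f, what) {
      if (length(f) != 3 || any(f < 0) || any(f > 1) ||
          abs(sum(f) - 1) > 1e-9) {
        stop(what, " must be three probabilities in [0,1] summing to 1")
      }
    }
    check_occ(state_occupancy, "state_occupancy")
    if (!is.null(spine_state_occupancy)) {
      check_occ(spine_state_occupancy, "spine_state_occupancy")
    }
    if (localization_sigma < 0) stop("localization_sigma must be >= 0")
    if (min_track_length < 2) stop("min_track_length must be >= 2")
    if (n_molecules < 1) stop("n_molecules must be >= 1")
  })
  invisible(cfg)
}

# Simulate one molecule's true positions (matrix) inside polygon `poly` at
# diffusion D, optionally trapped in a disc (center, radius). Start position
# `p0`, `len` frames.
simulate_walk <- function(p0, len, D, dt, poly, disc = NULL) {
  pos <- matrix(NA_real_, len, 2)
  pos[1, ] <- p0
  if (len == 1) return(pos)
  sd_step <- sqrt(2 * D * dt)
  steps <- matrix(stats::rnorm(2 * (len - 1), 0, sd_step), ncol = 2)
  if (!is.null(disc)) {
    p <- p0
    for (i in 2:len) {
      p <- reflect_in_disc(p + steps[i - 1, ], disc$center, disc$r)
      pos[i, ] <- p
    }
    return(pos)
  }
  # free walk: vectorized cumulative sum, sequential fix-up only on exit
  cand <- cbind(p0[1] + cumsum(steps[, 1]), p0[2] + cumsum(steps[, 2]))
  if (all(points_in_polygon(cand[, 1], cand[, 2], poly))) {
    pos[2:len, ] <- cand
    return(pos)
  }
  p <- p0
  for (i in 2:len) {
    p <- reflect_in_polygon(p, p + steps[i - 1, ], poly)
    pos[i, ] <- p
  }
  pos
}

#' Simulate one cell's sptPALM acquisition
#'
#' Each molecule is assigned a birth compartment and one of three diffusive
#' states (a static mixture; no switching), appears at a uniformly random
#' start frame, performs an isotropic Gaussian random walk with per-axis
#' step variance `2 * D * dt`, reflecting at its compartment boundary.
#' Confined-state molecules whose birth compartment contains a nanodomain
#' start uniformly inside one of its discs and reflect at the disc boundary;
#' if the compartment has no disc they diffuse freely at the confined-state
#' coefficient. Track lengths are geometric with the configured mean,
#' truncated at the acquisition end; tracks shorter than `min_track_length`
#' are discarded. Reported positions carry independent Gaussian localization
#' error.
#'
#' @param config `sim_config` from [simulation_config()].
#' @param cell_id cell identifier written into the table.
#' @return list of class `sim_cell`:
#'   * `localizations`: localization table (reported, noisy positions);
#'   * `true_positions`: same table without localization error;
#'   * `truth`: per-track data.frame `track_id`, `true_state`,
#'     `nanodomain_id` (`NA` if untrapped), `compartment_id`;
#'   * `config`: the generating configuration.
#'   A cell in which no track survives the length filter is returned with
#'   zero-row tables and a warning.
#' @export
simulate_cell <- function(config, cell_id = "cell01") {
  validate_sim_config(config)
  lay <- config$layout
  comp_ids <- c("shaft", names(lay$spines))
  comp_polys <- c(list(shaft = lay$shaft), lay$spines)
  areas <- vapply(comp_polys, polygon_area, 0)
  p_spine <- config$p_spine
  if (is.null(p_spine)) p_spine <- sum(areas[-1]) / sum(areas)
  if (length(lay$spines) == 0) p_spine <- 0
  with_seed(config$seed, {
    n <- config$n_molecules
    in_spine <- stats::runif(n) < p_spine
    comp <- character(n)
    comp[!in_spine] <- "shaft"
    if (any(in_spine)) {
      spine_ids <- names(lay$spines)
      w <- areas[spine_ids] / sum(areas[spine_ids])
      comp[in_spine] <- spine_ids[
        sample.int(length(spine_ids), sum(in_spine), replace = TRUE, prob = w)]
    }
    occ_shaft <- config$state_occupancy
    occ_spine <- if (is.null(config$spine_state_occupancy)) occ_shaft else
      config$spine_state_occupancy
    state <- integer(n)
    state[!in_spine] <- sample.int(3, sum(!in_spine), replace = TRUE, prob = occ_shaft)
    if (any(in_spine)) {
      state[in_spine] <- sample.int(3, sum(in_spine), replace = TRUE, prob = occ_spine)
    }
    start <- sample.int(config$n_frames, n, replace = TRUE)
    len <- stats::rgeom(n, prob = 1 / config$mean_track_length) + 1L
    len <- pmin(len, config$n_frames - start + 1L)
    sig_um <- config$localization_sigma / 1000
    nd <- lay$nanodomains
    loc_list <- vector("list", n)
    true_list <- vector("list", n)
    truth <- data.frame(track_id = character(n), true_state = state,
                        nanodomain_id = NA_character_,
                        compartment_id = comp, stringsAsFactors = FALSE)
    kept <- logical(n)
    for (m in seq_len(n)) {
      if (len[m] < config$min_track_length) next
      poly <- comp_polys[[comp[m]]]
      disc <- NULL
      nd_id <- NA_character_
      if (state[m] == 2L && nrow(nd)) {
        cand <- which(nd$compartment_id == comp[m])
        if (length(cand)) {
          k <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
          disc <- list(center = c(nd$x_um[k], nd$y_um[k]), r = nd$radius_um[k])
          nd_id <- nd$nanodomain_id[k]
        }
      }
      p0 <- if (!is.null(disc)) sample_in_disc(1, disc$center, disc$r)[1, ]
            else sample_in_polygon(1, poly)[1, ]
      D <- config$state_diffusion[state[m]]
      pos <- simulate_walk(p0, len[m], D, config$frame_interval, poly, disc)
      tid <- sprintf("t%05d", m)
      frames <- seq.int(start[m] - 1L, length.out = len[m])
      true_list[[m]] <- data.frame(
        cell_id = cell_id, track_id = tid, frame = frames,
        x_um = pos[, 1], y_um = pos[, 2], stringsAsFactors = FALSE)
      if (sig_um > 0) {
        pos <- pos + matrix(stats::rnorm(2 * len[m], 0, sig_um), ncol = 2)
      }
      loc_list[[m]] <- data.frame(
        cell_id = cell_id, track_id = tid, frame = frames,
        x_um = pos[, 1], y_um = pos[, 2], stringsAsFactors = FALSE)
      truth$track_id[m] <- tid
      truth$nanodomain_id[m] <- nd_id
      kept[m] <- TRUE
    }
    empty <- data.frame(cell_id = character(0), track_id = character(0),
                        frame = integer(0), x_um = numeric(0),
                        y_um = numeric(0), stringsAsFactors = FALSE)
    loc <- if (any(kept)) do.call(rbind, loc_list[kept]) else empty
    tru <- if (any(kept)) do.call(rbind, true_list[kept]) else empty
    rownames(loc) <- rownames(tru) <- NULL
    if (!any(kept)) {
      warning("simulate_cell: no trajectory survived the ",
              config$min_track_length, "-frame filter for ", cell_id)
    }
    structure(list(localizations = loc, true_positions = tru,
                   truth = truth[kept, , drop = FALSE], config = config),
              class = "sim_cell")
  })
}

#' @export
print.sim_cell <- function(x, ...) {
  cat("sim_cell:", length(unique(x$localizations$track_id)), "tracks,",
      nrow(x$localizations), "localizations\n")
  invisible(x)
}

#' Write the canonical simulated fixture suite
#'
#' Emits a small, fully seeded set of datasets covering the regimes the
#' analysis distinguishes: a single free state, a three-state mixture without
#' trapping, a spine-rich clustered cell with nanodomain trapping, and a
#' spatially uniform (cluster-free) field. Each dataset gets a localization
#' CSV, a ground-truth sidecar CSV and a layout/ROI JSON; a manifest records
#' the generating parameters and file checksums.
#'
#' @param output_dir writable directory (created if needed).
#' @param seed master seed; dataset seeds are derived from it.
#' @return manifest list, invisibly written to `manifest.json`.
#' @export
write_fixture_suite <- function(output_dir, seed = 42L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2) != 0) stop("not writable: ", output_dir)
  box <- big_box_layout(10)
  mk <- function(name, cfg) {
    cell <- simulate_cell(cfg, cell_id = name)
    loc_f <- file.path(output_dir, paste0(name, "_localizations.csv"))
    tru_f <- file.path(output_dir, paste0(name, "_truth.csv"))
    roi_f <- file.path(output_dir, paste0(name, "_rois.json"))
    write_localization_table(cell$localizations, loc_f)
    utils::write.csv(cell$truth, tru_f, row.names = FALSE, quote = FALSE)
    write_layout_rois(cfg$layout, roi_f, cell_id = name)
    list(name = name,
         files = list(localizations = basename(loc_f), truth = basename(tru_f),
                      rois = basename(roi_f)),
         md5 = as.list(tools::md5sum(c(loc_f, tru_f, roi_f))),
         parameters = list(
           seed = cfg$seed, n_molecules = cfg$n_molecules,
           state_diffusion = cfg$state_diffusion,
           state_occupancy = cfg$state_occupancy,
           localization_sigma = cfg$localization_sigma,
           mean_track_length = cfg$mean_track_length))
  }
  sets <- list(
    mk("single_state",
       simulation_config(state_occupancy = c(0, 0, 1), n_molecules = 800,
                         localization_sigma = 0, seed = seed + 1L, layout = box)),
    mk("three_state",
       simulation_config(n_molecules = 2000, localization_sigma = 0,
                         seed = seed + 2L, layout = box)),
    mk("clustered",
       simulation_config(n_molecules = 1500, seed = seed + 3L,
                         p_spine = 0.5,
                         layout = build_default_layout(5, seed = seed + 3L))),
    mk("uniform_field",
       simulation_config(state_occupancy = c(0, 0, 1), n_molecules = 1200,
                         state_diffusion = c(0.003, 0.03, 0.5),
                         seed = seed + 4L, layout = box)))
  manifest <- list(suite = "sptnano-fixtures", master_seed = seed,
                   datasets = sets)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Large featureless square layout
#'
#' A single square "shaft" compartment with no spines and no nanodomains;
#' the near-boundary-free setting used for estimator calibration.
#'
#' @param side side length, um.
#' @return `sim_layout`.
#' @export
big_box_layout <- function(side = 20) {
  structure(list(
    shaft = cbind(c(0, side, side, 0), c(0, 0, side, side)),
    spines = list(),
    nanodomains = data.frame(nanodomain_id = character(0), x_um = numeric(0),
                             y_um = numeric(0), radius_um = numeric(0),
                             compartment_id = character(0)),
    params = list(n_spines = 0, side = side)), class = "sim_layout")
}
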
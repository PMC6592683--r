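# End-to-end orchestration: a validated configuration drives
# simulate -> metrics -> motion_states -> nanodomains -> compartments ->
# stats_reporting, each stage writing its outputs (with checksums and
# timings in a manifest) before the next starts.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    input = list(localizations = NULL, rois = NULL, unit_hint = "um"),
    simulate = list(enabled = TRUE, n_cells = 1L, n_spines = 4L,
                    n_molecules = 3000L,
                    state_diffusion = c(0.003, 0.03, 0.3),
                    state_occupancy = c(0.30, 0.40, 0.30),
                    spine_state_occupancy = NULL,
                    localization_sigma = 25, mean_track_length = 15,
                    min_track_length = 8, p_spine = NULL,
                    frame_interval = 0.02, n_frames = 16000L),
    msd = list(dt = 0.02, n_fit_points = 4L, min_track_frames = 8L,
               min_trajectories = 1000L, auc_window = c(0.02, 0.24),
               threshold_log10 = -1.6, max_lag = 12L),
    mss = list(nu_max = 6L, n_lag_fit = 5L, min_frames = 20L),
    cdf = list(max_steps = 7L, n_starts = 10L, max_points = 500L),
    nanodomains = list(object_factor = 1.0, min_members = 10L,
                       min_detections = 50L, density_factor = 2.0,
                       first_rank = TRUE),
    compartments = list(majority = 0.5, min_roi_trajectories = 50L),
    stats = list(alpha = 0.05))
}

merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key '", full, "'")
    }
    if (is.list(defaults[[key]]) && !is.null(overrides[[key]]) &&
        is.list(overrides[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]], full)
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (every tunable of every stage, at the
#' values documented in the respective functions) and applies the supplied
#' overrides; unknown keys at any nesting level are rejected by name rather
#' than silently ignored.
#'
#' @param ... named overrides, e.g. `seed = 7`,
#'   `simulate = list(n_molecules = 500)`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  cfg <- merge_config(default_run_config(), overrides)
  structure(cfg, class = "run_config")
}

# Fixed per-stage seed derivation so that toggling one stage never perturbs
# another stage's randomness. Kept below 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, metrics = 211L, motion_states = 307L,
            nanodomains = 401L, compartments = 503L, stats = 601L)
  (as.integer(seed) %% 2000000L) * 1000L + offs[[stage]]
}

#' Run the full analysis pipeline
#'
#' Executes the six stages in order on either a simulated cell set (the
#' default) or user-supplied localization and ROI files, writing each
#' stage's outputs to `output_dir` before the next stage starts. A failure
#' aborts with the manifest of the completed stages attached to the error
#' condition.
#'
#' @param config `run_config` from [run_config()] (must carry a non-`NULL`
#'   `output_dir`).
#' @return manifest list (also written to `manifest.json`): config echo,
#'   package version, per-stage output files with MD5 checksums, wall-clock
#'   seconds and warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = config[setdiff(names(config), "layout")],
    version = as.character(utils::packageVersion("sptnano")),
    stages = list())
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(
      withCallingHandlers(fn(), warning = function(w) {
        note(w); invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        manifest$warnings <<- warnings_log
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    manifest$stages[[name]] <<- list(
      status = "complete",
      files = as.list(files),
      md5 = as.list(tools::md5sum(file.path(out, unlist(files)))),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  env <- new.env()

  run_stage("simulate", function() {
    if (isTRUE(config$simulate$enabled)) {
      sc <- config$simulate
      files <- character(0)
      locs <- list()
      for (ci in seq_len(sc$n_cells)) {
        seed_i <- stage_seed(config$seed, "simulate") + ci
        lay <- build_default_layout(sc$n_spines, seed = seed_i)
        cfg <- simulation_config(
          frame_interval = sc$frame_interval, n_frames = sc$n_frames,
          state_diffusion = sc$state_diffusion,
          state_occupancy = sc$state_occupancy,
          spine_state_occupancy = sc$spine_state_occupancy,
          localization_sigma = sc$localization_sigma,
          mean_track_length = sc$mean_track_length,
          min_track_length = sc$min_track_length,
          n_molecules = sc$n_molecules, p_spine = sc$p_spine,
          seed = seed_i, layout = lay)
        id <- sprintf("cell%02d", ci)
        cell <- simulate_cell(cfg, cell_id = id)
        locs[[id]] <- cell$localizations
        f_tru <- paste0(id, "_truth.csv")
        utils::write.csv(cell$truth, file.path(out, f_tru),
                         row.names = FALSE, quote = FALSE)
        f_roi <- paste0(id, "_rois.json")
        write_rois(lay, file.path(out, f_roi), cell_id = id)
        files <- c(files, f_tru, f_roi)
        if (ci == 1L) env$rois <- layout_to_rois(lay, cell_id = id)
      }
      env$loc <- do.call(rbind, locs)
      write_localization_table(env$loc, file.path(out, "localizations.csv"))
      c("localizations.csv", files)
    } else {
      if (is.null(config$input$localizations)) {
        stop("simulate disabled and no input localization file given")
      }
      env$loc <- read_localization_table(config$input$localizations,
                                         unit_hint = config$input$unit_hint)
      env$rois <- if (!is.null(config$input$rois))
        load_rois(config$input$rois) else NULL
      write_localization_table(env$loc, file.path(out, "localizations.csv"))
      "localizations.csv"
    }
  })

  run_stage("metrics", function() {
    mc <- config$msd
    cells <- split(env$loc, env$loc$cell_id)
    env$summaries <- lapply(cells, function(cl) summarize_cell(
      cl, dt = mc$dt, min_track_frames = mc$min_track_frames,
      min_trajectories = mc$min_trajectories, auc_window = mc$auc_window,
      n_fit_points = mc$n_fit_points, threshold_log10 = mc$threshold_log10,
      max_lag = mc$max_lag))
    ok <- !vapply(env$summaries, is.null, TRUE)
    env$summaries <- env$summaries[ok]
    cell_tab <- do.call(rbind, lapply(env$summaries, function(s)
      data.frame(cell_id = s$cell_id, n_trajectories = s$n_trajectories,
                 auc = s$auc, immobile_fraction = s$immobile_fraction,
                 below_min_trajectories = s$below_min_trajectories)))
    utils::write.csv(cell_tab, file.path(out, "cell_summary.csv"),
                     row.names = FALSE)
    track_tab <- do.call(rbind, lapply(env$summaries, function(s)
      cbind(cell_id = s$cell_id, s$track_table)))
    utils::write.csv(track_tab, file.path(out, "track_diffusion.csv"),
                     row.names = FALSE)
    c("cell_summary.csv", "track_diffusion.csv")
  })

  run_stage("motion_states", function() {
    sc <- config$mss; cc <- config$cdf; mc <- config$msd
    cells <- split(env$loc, env$loc$cell_id)
    mss <- do.call(rbind, lapply(names(cells), function(id)
      cbind(cell_id = id, mss_table(cells[[id]], dt = mc$dt,
                                    nu_max = sc$nu_max,
                                    n_lag_fit = sc$n_lag_fit,
                                    min_frames = sc$min_frames))))
    env$mss <- mss
    utils::write.csv(mss, file.path(out, "mss.csv"), row.names = FALSE)
    samples <- lapply(cells, collect_displacements,
                      max_steps = cc$max_steps,
                      min_track_frames = mc$min_track_frames)
    fit <- fit_three_state_global(samples, dt = mc$dt,
                                  n_starts = cc$n_starts,
                                  seed = stage_seed(config$seed, "motion_states"),
                                  max_points = cc$max_points)
    env$three_state <- fit
    jsonlite::write_json(
      list(D = fit$D, occupancy = as.data.frame(cbind(
             cell_id = rownames(fit$occupancy), as.data.frame(fit$occupancy))),
           diagnostics = fit$diagnostics[c("residual_norm", "converged",
                                           "degenerate", "n_starts")]),
      file.path(out, "three_state_fit.json"), auto_unbox = TRUE, digits = NA)
    c("mss.csv", "three_state_fit.json")
  })

  run_stage("nanodomains", function() {
    nc <- config$nanodomains
    res <- analyze_nanodomains(env$loc, object_factor = nc$object_factor,
                               min_members = nc$min_members,
                               min_detections = nc$min_detections,
                               density_factor = nc$density_factor,
                               first_rank = nc$first_rank)
    env$nanodomains <- res
    utils::write.csv(res$table, file.path(out, "nanodomains.csv"),
                     row.names = FALSE)
    "nanodomains.csv"
  })

  run_stage("compartments", function() {
    if (is.null(env$rois)) {
      utils::write.csv(data.frame(), file.path(out, "assignments.csv"),
                       row.names = FALSE)
      return("assignments.csv")
    }
    cp <- config$compartments
    env$assignments <- assign_trajectories(env$loc, env$rois,
                                           majority = cp$majority)
    utils::write.csv(env$assignments, file.path(out, "assignments.csv"),
                     row.names = FALSE)
    env$report <- compartment_report(
      env$loc, env$assignments, env$rois, dt = config$msd$dt,
      min_roi_trajectories = cp$min_roi_trajectories)
    utils::write.csv(env$report$compartments,
                     file.path(out, "compartment_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(env$report$roi_deff, file.path(out, "roi_deff.csv"),
                     row.names = FALSE)
    if (!is.null(env$nanodomains) && nrow(env$nanodomains$table)) {
      counts <- nanodomains_per_roi(env$nanodomains$table, env$rois)
      utils::write.csv(counts, file.path(out, "nanodomains_per_roi.csv"),
                       row.names = FALSE)
      return(c("assignments.csv", "compartment_summary.csv", "roi_deff.csv",
               "nanodomains_per_roi.csv"))
    }
    c("assignments.csv", "compartment_summary.csv", "roi_deff.csv")
  })

  run_stage("stats", function() {
    rows <- list()
    if (!is.null(env$report)) {
      rd <- env$report$roi_deff
      sp <- rd$d_eff[rd$label == "spine" & rd$status == "ok"]
      sh <- rd$d_eff[rd$label == "shaft" & rd$status == "ok"]
      if (length(sp) >= 3 && length(sh) >= 3) {
        r <- run_two_group_test(sp, sh)
        rows$d_eff <- data.frame(metric = "roi_d_eff", test = r$test,
                                 statistic = r$statistic, p = r$p,
                                 n = paste(length(sp), length(sh), sep = "/"))
      }
    }
    if (!is.null(env$mss) && !is.null(env$assignments) && !is.null(env$rois)) {
      lab <- stats::setNames(vapply(env$rois$rois, function(r) r$label, ""),
                             vapply(env$rois$rois, function(r) r$roi_id, ""))
      asg <- env$assignments[env$assignments$status == "assigned", ]
      smss_lab <- lab[asg$roi_id[match(env$mss$track_id, asg$track_id)]]
      xs <- env$mss$s_mss[smss_lab == "spine" & !is.na(smss_lab)]
      ys <- env$mss$s_mss[smss_lab == "shaft" & !is.na(smss_lab)]
      if (length(xs) >= 10 && length(ys) >= 10) {
        r <- compare_distributions(xs, ys)
        rows$smss <- data.frame(metric = "s_mss_distribution", test = r$test,
                                statistic = r$statistic, p = r$p, n = r$n)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(metric = character(0), test = character(0),
                 statistic = numeric(0), p = numeric(0), n = character(0))
    utils::write.csv(tab, file.path(out, "stats.csv"), row.names = FALSE)
    "stats.csv"
  })

  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
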
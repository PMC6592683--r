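# Spine/shaft compartment assignment. ROIs are labelled polygons in the
# localization coordinate frame; a trajectory is attributed to the ROI
# holding the majority of its localizations.
#
# ROI JSON schema:
#   {"cell_id": "...", "rois": [{"roi_id": "...", "label": "spine"|"shaft"|
#    "excluded", "paired_shaft_id": "..." (optional, spines only),
#    "vertices_um": [[x, y], ...]}]}

ROI_LABELS <- c("spine", "shaft", "excluded")

#' Load compartment ROIs from JSON
#'
#' Validates polygon simplicity, labels, id uniqueness and spine-to-shaft
#' pairing references.
#'
#' @param path ROI JSON file.
#' @return object of class `roi_set`: `cell_id` plus `rois`, a list of
#'   `compartment_roi`s (`roi_id`, `label`, `polygon` matrix,
#'   `paired_shaft_id` or `NA`).
#' @export
load_rois <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$rois)) stop(path, ": no 'rois' array")
  rois <- lapply(doc$rois, function(r) {
    if (is.null(r$roi_id) || is.null(r$label) || is.null(r$vertices_um)) {
      stop(path, ": ROI entries need roi_id, label and vertices_um")
    }
    poly <- do.call(rbind, lapply(r$vertices_um, function(v) as.numeric(v)))
    structure(list(roi_id = as.character(r$roi_id),
                   label = as.character(r$label),
                   polygon = poly,
                   paired_shaft_id = if (is.null(r$paired_shaft_id))
                     NA_character_ else as.character(r$paired_shaft_id)),
              class = "compartment_roi")
  })
  validate_rois(structure(list(cell_id = as.character(doc$cell_id %||% NA),
                               rois = rois), class = "roi_set"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_rois <- function(set) {
  ids <- vapply(set$rois, function(r) r$roi_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate roi_id: ", ids[duplicated(ids)][1])
  }
  labels <- vapply(set$rois, function(r) r$label, "")
  bad <- !(labels %in% ROI_LABELS)
  if (any(bad)) stop("unknown label '", labels[bad][1], "' in roi ", ids[bad][1])
  for (r in set$rois) {
    if (nrow(r$polygon) < 3 || !is_simple_polygon(r$polygon)) {
      stop("polygon of roi ", r$roi_id, " is not a simple polygon")
    }
    if (!is.na(r$paired_shaft_id)) {
      j <- match(r$paired_shaft_id, ids)
      if (is.na(j)) stop("roi ", r$roi_id, ": paired_shaft_id '",
                         r$paired_shaft_id, "' not found")
      if (set$rois[[j]]$label != "shaft") {
        stop("roi ", r$roi_id, ": paired_shaft_id '", r$paired_shaft_id,
             "' is not a shaft ROI")
      }
    }
  }
  set
}

#' Write a ROI set (or a simulated layout) to JSON
#'
#' @param x `roi_set`, or `sim_layout` (shaft and spines become ROIs).
#' @param path output path.
#' @param cell_id cell id recorded in the file.
#' @return `path`, invisibly.
#' @export
write_rois <- function(x, path, cell_id = "cell01") {
  if (inherits(x, "sim_layout")) x <- layout_to_rois(x, cell_id)
  stopifnot(inherits(x, "roi_set"))
  doc <- list(cell_id = x$cell_id,
              rois = lapply(x$rois, function(r) {
                out <- list(roi_id = r$roi_id, label = r$label,
                            vertices_um = lapply(seq_len(nrow(r$polygon)),
                                                 function(i) as.numeric(r$polygon[i, ])))
                if (!is.na(r$paired_shaft_id)) out$paired_shaft_id <- r$paired_shaft_id
                out
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
write_layout_rois <- function(x, path, cell_id = "cell01") {
  write_rois(x, path, cell_id = cell_id)
}

#' Convert a simulated layout to a ROI set
#'
#' @param layout `sim_layout`.
#' @param cell_id cell id for the set.
#' @return `roi_set` with one shaft ROI and one spine ROI per spine, all
#'   spines paired to the shaft.
#' @export
layout_to_rois <- function(layout, cell_id = "cell01") {
  stopifnot(inherits(layout, "sim_layout"))
  rois <- c(
    list(structure(list(roi_id = "shaft", label = "shaft",
                        polygon = layout$shaft,
                        paired_shaft_id = NA_character_),
                   class = "compartment_roi")),
    lapply(names(layout$spines), function(id) {
      structure(list(roi_id = id, label = "spine",
                     polygon = layout$spines[[id]],
                     paired_shaft_id = "shaft"),
                class = "compartment_roi")
    }))
  validate_rois(structure(list(cell_id = cell_id, rois = rois),
                          class = "roi_set"))
}

#' Assign trajectories to compartment ROIs by majority of localizations
#'
#' For every track, the fraction of its localizations inside each ROI is
#' computed; the track is assigned to the ROI with the largest fraction
#' provided that fraction exceeds `majority`. Ties and sub-majority tracks
#' are unassigned. A track with any localization inside an `excluded` ROI is
#' excluded.
#'
#' @param loc localization table.
#' @param rois `roi_set`.
#' @param majority assignment threshold on the inside fraction.
#' @return data.frame `track_id`, `roi_id` (`NA` unless assigned),
#'   `fraction_inside`, `status` in assigned/unassigned/excluded.
#' @export
assign_trajectories <- function(loc, rois, majority = 0.5) {
  stopifnot(inherits(rois, "roi_set"))
  tracks <- split_tracks(loc)
  ids <- vapply(rois$rois, function(r) r$roi_id, "")
  labels <- vapply(rois$rois, function(r) r$label, "")
  usable <- which(labels != "excluded")
  rows <- lapply(names(tracks), function(tid) {
    tr <- tracks[[tid]]
    frac <- vapply(seq_along(ids), function(i)
      mean(points_in_polygon(tr$x_um, tr$y_um, rois$rois[[i]]$polygon)), 0)
    if (any(labels == "excluded" & frac > 0)) {
      return(data.frame(track_id = tid, roi_id = NA_character_,
                        fraction_inside = max(frac[labels == "excluded"]),
                        status = "excluded", stringsAsFactors = FALSE))
    }
    fu <- frac[usable]
    best <- which(fu == max(fu))
    if (max(fu) > majority && length(best) == 1) {
      data.frame(track_id = tid, roi_id = ids[usable][best],
                 fraction_inside = max(fu), status = "assigned",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(track_id = tid, roi_id = NA_character_,
                 fraction_inside = max(fu), status = "unassigned",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compartment-resolved mobility report
#'
#' Per compartment label (spine/shaft): pooled mean MSD curve, AUC and
#' immobile fraction over the tracks assigned to ROIs of that label; per
#' ROI: the effective diffusion coefficient under the membership floor of
#' [effective_diffusion()]; and paired spine-vs-adjacent-shaft rows where
#' spines carry a `paired_shaft_id`.
#'
#' @param loc localization table (one cell).
#' @param assignments output of [assign_trajectories()].
#' @param rois `roi_set`.
#' @param dt frame interval, s.
#' @param min_roi_trajectories per-ROI floor for the effective diffusion
#'   coefficient.
#' @param ... further arguments for [summarize_cell()] (fit points,
#'   thresholds, AUC window).
#' @return list of class `compartment_report`: `compartments` (per-label
#'   data.frame with `n_trajectories`, `auc`, `immobile_fraction` and the
#'   summary objects in `summaries`), `roi_deff` (per-ROI data.frame with
#'   `d_eff`, `n_trajectories`, `status`), `paired` (spine vs adjacent shaft
#'   `d_eff` rows).
#' @export
compartment_report <- function(loc, assignments, rois, dt = 0.02,
                               min_roi_trajectories = 50, ...) {
  stopifnot(inherits(rois, "roi_set"))
  loc <- validate_localizations(loc)
  ids <- vapply(rois$rois, function(r) r$roi_id, "")
  labels <- stats::setNames(vapply(rois$rois, function(r) r$label, ""), ids)
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  roi_of_track <- stats::setNames(asg$roi_id, asg$track_id)

  comp_rows <- list(); summaries <- list()
  for (lab in c("spine", "shaft")) {
    tids <- asg$track_id[labels[asg$roi_id] == lab]
    sub <- loc[as.character(loc$track_id) %in% tids, , drop = FALSE]
    if (nrow(sub)) {
      s <- summarize_cell(sub, dt = dt, min_trajectories = 1, ...)
      summaries[[lab]] <- s
      comp_rows[[lab]] <- data.frame(
        label = lab, n_trajectories = s$n_trajectories, auc = s$auc,
        immobile_fraction = s$immobile_fraction, empty = FALSE,
        stringsAsFactors = FALSE)
    } else {
      comp_rows[[lab]] <- data.frame(
        label = lab, n_trajectories = 0L, auc = NA_real_,
        immobile_fraction = NA_real_, empty = TRUE, stringsAsFactors = FALSE)
    }
  }

  roi_rows <- lapply(seq_along(ids), function(i) {
    if (labels[ids[i]] == "excluded") return(NULL)
    tids <- asg$track_id[asg$roi_id == ids[i]]
    sub <- loc[as.character(loc$track_id) %in% tids, , drop = FALSE]
    fit <- if (nrow(sub)) effective_diffusion(
      sub, dt = dt, min_trajectories = min_roi_trajectories) else NULL
    data.frame(roi_id = ids[i], label = labels[ids[i]],
               n_trajectories = length(tids),
               d_eff = if (is.null(fit)) NA_real_ else fit$D,
               status = if (is.null(fit)) "below_floor" else "ok",
               stringsAsFactors = FALSE)
  })
  roi_deff <- do.call(rbind, roi_rows)
  rownames(roi_deff) <- NULL

  paired <- NULL
  spines <- Filter(function(r) r$label == "spine" && !is.na(r$paired_shaft_id),
                   rois$rois)
  if (length(spines)) {
    paired <- do.call(rbind, lapply(spines, function(r) {
      s <- roi_deff[roi_deff$roi_id == r$roi_id, , drop = FALSE]
      h <- roi_deff[roi_deff$roi_id == r$paired_shaft_id, , drop = FALSE]
      data.frame(spine_id = r$roi_id, shaft_id = r$paired_shaft_id,
                 spine_d_eff = s$d_eff, shaft_d_eff = h$d_eff,
                 stringsAsFactors = FALSE)
    }))
    rownames(paired) <- NULL
  }

  structure(list(compartments = do.call(rbind, comp_rows),
                 summaries = summaries, roi_deff = roi_deff, paired = paired),
            class = "compartment_report")
}

#' @export
print.compartment_report <- function(x, ...) {
  cat("compartment_report:\n")
  print(x$compartments, row.names = FALSE)
  invisible(x)
}
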
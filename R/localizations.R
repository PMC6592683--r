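# Localization-table layer: the tabular exchange format every stage consumes.
# A localization table is a data.frame with columns
#   cell_id, track_id, frame, x_um, y_um
# frame is a 0-based integer; coordinates are micrometres.

LOC_COLUMNS <- c("cell_id", "track_id", "frame", "x_um", "y_um")

#' Validate a localization table
#'
#' Checks the mandatory columns, coordinate finiteness and per-track frame
#' monotonicity used throughout the package.
#'
#' @param loc data.frame with columns `cell_id`, `track_id`, `frame`,
#'   `x_um`, `y_um`.
#' @return `loc`, with `frame` coerced to integer, invisibly ordered by
#'   cell, track and frame.
#' @export
validate_localizations <- function(loc) {
  stopifnot(is.data.frame(loc))
  missing <- setdiff(LOC_COLUMNS, names(loc))
  if (length(missing)) {
    stop("localization table lacks column(s): ", paste(missing, collapse = ", "))
  }
  loc$frame <- as.integer(loc$frame)
  loc <- loc[order(loc$cell_id, loc$track_id, loc$frame), , drop = FALSE]
  rownames(loc) <- NULL
  if (nrow(loc)) {
    if (!all(is.finite(loc$x_um)) || !all(is.finite(loc$y_um))) {
      stop("non-finite coordinates in localization table")
    }
    key <- paste(loc$cell_id, loc$track_id, sep = "\r")
    dup <- duplicated(cbind(key, loc$frame))
    if (any(dup)) stop("duplicated (track, frame) rows in localization table")
  }
  loc
}

#' Read a localization table CSV
#'
#' CSV dialect: comma separator, decimal point, header with columns
#' `cell_id`, `track_id`, `frame`, `x_um`, `y_um` (or `x_nm`/`y_nm` when
#' `unit_hint = "nm"`, converted to micrometres on read). Rows with
#' non-finite coordinates are dropped with a counted warning.
#'
#' @param path CSV file path.
#' @param unit_hint `"um"` (default) or `"nm"`; with `"nm"`, coordinate
#'   columns (named either `x_um`/`y_um` or `x_nm`/`y_nm`) are divided by
#'   1000.
#' @return validated localization table (see [validate_localizations()]).
#' @export
read_localization_table <- function(path, unit_hint = c("um", "nm")) {
  unit_hint <- match.arg(unit_hint)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (unit_hint == "nm") {
    for (ax in c("x", "y")) {
      nm <- paste0(ax, "_nm"); um <- paste0(ax, "_um")
      if (nm %in% names(raw)) names(raw)[names(raw) == nm] <- um
    }
    raw$x_um <- raw$x_um / 1000
    raw$y_um <- raw$y_um / 1000
  }
  missing <- setdiff(LOC_COLUMNS, names(raw))
  if (length(missing)) {
    stop(path, ": missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  bad <- !is.finite(raw$x_um) | !is.finite(raw$y_um) | !is.finite(raw$frame)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite values dropped from ", path)
    raw <- raw[!bad, , drop = FALSE]
  }
  validate_localizations(raw[, LOC_COLUMNS, drop = FALSE])
}

#' Write a localization table CSV
#'
#' @param loc localization table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(loc, path) {
  loc <- validate_localizations(loc)
  utils::write.csv(loc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a localization table into per-track matrices
#'
#' @param loc localization table.
#' @return named list (by track id, within cell) of data.frames with columns
#'   `frame`, `x_um`, `y_um`, ordered by frame.
#' @export
split_tracks <- function(loc) {
  loc <- validate_localizations(loc)
  if (!nrow(loc)) return(list())
  key <- paste(loc$cell_id, loc$track_id, sep = "\r")
  idx <- split(seq_len(nrow(loc)), key)
  # keep first-appearance order
  idx <- idx[unique(key)]
  out <- lapply(idx, function(i) loc[i, c("frame", "x_um", "y_um"), drop = FALSE])
  names(out) <- vapply(idx, function(i) as.character(loc$track_id[i[1]]), "")
  out
}

# Track lengths (number of localizations) per track, in split_tracks order.
track_lengths <- function(loc) {
  vapply(split_tracks(loc), nrow, 0L)
}
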
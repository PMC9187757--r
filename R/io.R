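#' Read trajectories from a delimited localization/tracking table
#'
#' Reads a CSV/TSV table with one row per localization, groups rows into
#' trajectories by track id, sorts by frame, and converts coordinates to
#' metres. The `"dom"` dialect is a preset column map for tables exported by
#' the DoM (Detection of Molecules) ImageJ plug-in; entries of `column_map`
#' always override the preset, since column naming varies between exporter
#' versions. Localizations without a track id become single-point
#' trajectories with generated ids.
#'
#' A JSON sidecar `<path>.json` with fields `dt`, `pixel_size` and optionally
#' `units` ("pixels" or "physical") supplies calibration when the arguments
#' are left `NULL`.
#'
#' @param path path to the delimited table.
#' @param dialect `"generic"` (user-supplied column map) or `"dom"`.
#' @param column_map named character vector mapping the logical names
#'   `id`, `frame`, `x`, `y`, `z` to column names in the file.
#' @param pixel_size pixel size in metres/pixel, used to convert pixel
#'   coordinates to metres. Ignored when `units = "physical"`.
#' @param dt frame interval in seconds.
#' @param units are the file's coordinates `"pixels"` (converted via
#'   `pixel_size`) or already `"physical"` metres?
#' @return a [track_set()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,frame,x,y", "1,0,0,0", "1,1,1,0", "1,2,2,0"), f)
#' read_trajectories(f, pixel_size = 1e-7, dt = 0.05)
#' @export
read_trajectories <- function(path,
                              dialect = c("generic", "dom"),
                              column_map = NULL,
                              pixel_size = NULL,
                              dt = NULL,
                              units = c("pixels", "physical")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(dt) && !is.null(meta$dt)) dt <- meta$dt
    if (is.null(pixel_size) && !is.null(meta$pixel_size)) pixel_size <- meta$pixel_size
    if (missing(units) && !is.null(meta$units)) units <- meta$units
  }
  units <- match.arg(units)
  if (is.null(dt)) stop("`dt` must be given (argument or JSON sidecar)", call. = FALSE)
  if (is.null(pixel_size)) {
    if (units == "physical") pixel_size <- 1 else
      stop("`pixel_size` must be given for pixel-unit tables", call. = FALSE)
  }

  map <- c(id = "id", frame = "frame", x = "x", y = "y", z = "z")
  if (dialect == "dom") {
    map <- c(id = "Track_ID", frame = "Frame_Number",
             x = "X_(px)", y = "Y_(px)", z = "Z_(px)")
  }
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  raw <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  for (key in c("frame", "x", "y")) {
    if (!map[[key]] %in% names(raw)) {
      stop("format error: required column `", map[[key]], "` (", key,
           ") not found in ", path, call. = FALSE)
    }
  }
  has_z <- map[["z"]] %in% names(raw)
  has_id <- map[["id"]] %in% names(raw)
  has_label <- "label" %in% names(raw)

  num <- function(key) {
    v <- suppressWarnings(as.numeric(raw[[map[[key]]]]))
    bad <- which(is.na(v) & !(is.na(raw[[map[[key]]]]) | raw[[map[[key]]]] == ""))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value in column `", map[[key]],
           "` at data row ", bad[1], call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    id = if (has_id) as.character(raw[[map[["id"]]]]) else NA_character_,
    frame = as.integer(num("frame")),
    x = num("x"),
    y = num("y")
  )
  if (has_z) out$z <- num("z")
  if (has_label) out$label <- as.character(raw$label)

  # untracked localizations: one single-point trajectory each
  orphan <- is.na(out$id) | out$id == ""
  if (any(orphan)) {
    out$id[orphan] <- sprintf("loc%06d", which(orphan))
  }
  scale <- if (units == "pixels") pixel_size else 1
  for (cc in intersect(c("x", "y", "z"), names(out))) out[[cc]] <- out[[cc]] * scale
  track_set(out, dt = dt, pixel_size = pixel_size)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Keep only trajectories with enough localizations
#'
#' Short tracks and unlinked localizations carry ill-defined descriptors
#' (a minimum bounding circle of two points, a one-point MSD curve) and are
#' enriched in spurious detections; the conventional cut keeps tracks with
#' at least five localizations, giving MSD curves of at least four points.
#'
#' @param tracks a [track_set()].
#' @param min_n minimum number of localizations to retain a track.
#' @return the filtered `track_set`; track order is preserved.
#' @export
filter_min_localizations <- function(tracks, min_n = 5) {
  stopifnot(is.numeric(min_n), length(min_n) == 1, min_n >= 1)
  sizes <- track_sizes(tracks)
  keep <- names(sizes)[sizes >= min_n]
  out <- dplyr::filter(tibble::as_tibble(tracks), .data$id %in% keep)
  new_track_set(out, dt = track_dt(tracks), pixel_size = track_pixel_size(tracks))
}

#' Write a track set to a delimited table
#'
#' Writes a CSV in metres with full double precision (17 significant
#' digits), plus a JSON sidecar `<path>.json` holding `dt`, `pixel_size` and
#' `units = "physical"` so that [read_trajectories()] round-trips the set
#' exactly.
#'
#' @param tracks a [track_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  df <- tibble::as_tibble(tracks)
  cols <- intersect(c("id", "frame", "x", "y", "z", "label"), names(df))
  df <- df[cols]
  for (cc in intersect(c("x", "y", "z"), cols)) {
    df[[cc]] <- sprintf("%.17g", df[[cc]])
  }
  readr::write_csv(df, path, progress = FALSE)
  jsonlite::write_json(
    list(dt = track_dt(tracks), pixel_size = track_pixel_size(tracks),
         units = "physical"),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
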
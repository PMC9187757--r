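#' Build a track set from a localization table
#'
#' A track set is a tibble with one row per localization and columns `id`
#' (track identifier), `frame` (0-based integer frame index), `x`, `y` and
#' optionally `z` (positions in metres), and optionally `label` (population
#' assignment). The frame interval `dt` (seconds) and the pixel size used at
#' import (metres/pixel) travel with the object as attributes; use
#' [track_dt()] to retrieve them. Rows are sorted by id, then frame.
#'
#' @param data data frame with columns `id`, `frame`, `x`, `y` and optional
#'   `z`, `label`. Coordinates must already be in metres.
#' @param dt frame interval in seconds (> 0).
#' @param pixel_size pixel size in metres/pixel recorded at import (> 0);
#'   purely metadata once coordinates are in metres.
#' @return a `track_set` tibble.
#' @examples
#' tr <- track_set(
#'   data.frame(id = "a", frame = 0:2, x = (0:2) * 1e-7, y = 0),
#'   dt = 0.05
#' )
#' track_dt(tr)
#' @export
track_set <- function(data, dt, pixel_size = 1e-7) {
  stopifnot(is.data.frame(data))
  required <- c("id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (metres)", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$id <- as.character(out$id)
  out$frame <- as.integer(out$frame)
  coord_cols <- intersect(c("x", "y", "z"), names(out))
  for (cc in coord_cols) {
    if (!is.numeric(out[[cc]])) stop("column `", cc, "` must be numeric", call. = FALSE)
    if (any(!is.finite(out[[cc]]))) {
      stop("non-finite coordinate in column `", cc, "`", call. = FALSE)
    }
  }
  out <- dplyr::arrange(out, .data$id, .data$frame)
  dup <- duplicated(out[c("id", "frame")])
  if (any(dup)) {
    bad <- out[dup, c("id", "frame")][1, ]
    stop("duplicate (track, frame) pair: id ", bad$id, ", frame ", bad$frame,
         call. = FALSE)
  }
  new_track_set(out, dt = dt, pixel_size = pixel_size)
}

new_track_set <- function(data, dt, pixel_size) {
  structure(
    tibble::as_tibble(data),
    dt = dt,
    pixel_size = pixel_size,
    class = c("track_set", class(tibble::tibble()))
  )
}

#' @rdname track_set
#' @param tracks a `track_set` (or any data frame carrying a `dt` attribute).
#' @export
track_dt <- function(tracks) {
  dt <- attr(tracks, "dt", exact = TRUE)
  if (is.null(dt)) stop("`dt` attribute missing; rebuild with track_set()", call. = FALSE)
  dt
}

#' @rdname track_set
#' @export
track_pixel_size <- function(tracks) {
  ps <- attr(tracks, "pixel_size", exact = TRUE)
  if (is.null(ps)) NA_real_ else ps
}

#' @export
print.track_set <- function(x, ...) {
  n_tracks <- dplyr::n_distinct(x$id)
  cat(sprintf("# track_set: %d localizations in %d trajectories, dt = %g s\n",
              nrow(x), n_tracks, attr(x, "dt")))
  NextMethod()
  invisible(x)
}

# number of localizations per trajectory, in id order of appearance
track_sizes <- function(tracks) {
  tab <- dplyr::count(tibble::as_tibble(tracks), .data$id, name = "n")
  stats::setNames(tab$n, tab$id)
}
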
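#' Time-averaged mean squared displacement per trajectory
#'
#' For each trajectory and each frame lag `n` with at least one displacement
#' pair, computes the average of `|x_{i+n} - x_i|^2` over all pairs of
#' localizations separated by `n` frames. Lags are defined on frame indices,
#' so trajectories with missed frames (gaps) are handled correctly; for
#' gap-free tracks this reduces to the familiar sliding-window average with
#' `N - n + 1` terms. Lags with no pair are omitted.
#'
#' @param tracks a [track_set()]. Single-point trajectories contribute no
#'   rows; an input with no displacement pair at all is an error.
#' @param max_lag largest frame lag to evaluate (default: all available).
#' @return tibble of class `msd_curve` with columns `id`, `lag` (frames),
#'   `delay` (seconds), `msd` (m^2) and `n_pairs`; attribute `kind =
#'   "time-averaged"` and the set's `dt`.
#' @examples
#' tr <- track_set(data.frame(id = "a", frame = 0:3, x = (0:3) * 1e-6, y = 0),
#'                 dt = 1)
#' t_msd(tr)
#' @export
t_msd <- function(tracks, max_lag = Inf) {
  dt <- track_dt(tracks)
  df <- tibble::as_tibble(tracks)
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  out <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ msd_one(.x, coord_cols, max_lag)) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    stop("no displacement pairs: every trajectory has a single localization",
         call. = FALSE)
  }
  out$delay <- out$lag * dt
  out <- out[c("id", "lag", "delay", "msd", "n_pairs")]
  structure(out, kind = "time-averaged", dt = dt,
            class = c("msd_curve", class(out)))
}

msd_one <- function(sub, coord_cols, max_lag) {
  f <- sub$frame
  n <- length(f)
  if (n < 2) {
    return(tibble::tibble(lag = integer(), msd = numeric(), n_pairs = integer()))
  }
  xm <- as.matrix(sub[coord_cols])
  span <- f[n] - f[1]
  n_lags <- min(span, max_lag)
  contiguous <- span == n - 1
  msd <- numeric(n_lags)
  n_pairs <- integer(n_lags)
  for (L in seq_len(n_lags)) {
    if (contiguous) {
      i <- seq_len(n - L)
      d2 <- rowSums((xm[i + L, , drop = FALSE] - xm[i, , drop = FALSE])^2)
    } else {
      j <- match(f + L, f)
      ok <- which(!is.na(j))
      if (length(ok) == 0) next
      d2 <- rowSums((xm[j[ok], , drop = FALSE] - xm[ok, , drop = FALSE])^2)
    }
    msd[L] <- mean(d2)
    n_pairs[L] <- length(d2)
  }
  has <- n_pairs > 0L
  tibble::tibble(lag = which(has), msd = msd[has], n_pairs = n_pairs[has])
}

#' Time-ensemble averaged mean squared displacement
#'
#' At each lag `n`, averages the per-trajectory time-averaged MSD over the
#' ensemble of trajectories long enough to contribute at that lag, each
#' trajectory weighted equally. Ensemble averaging over trajectories washes
#' out the correlated-displacement bias of single-track curves, so the
#' resulting curve is interpretable over a longer delay range and is the
#' estimator of choice for population-level diffusion constants.
#'
#' @inheritParams t_msd
#' @return tibble of class `msd_curve` with columns `lag`, `delay`, `msd`,
#'   `n_tracks` (the ensemble size at each lag) and `se_msd` (standard error
#'   of the ensemble mean from the track-to-track scatter; `NA` where a
#'   single track contributes); attribute `kind = "time-ensemble-averaged"`.
#' @export
te_msd <- function(tracks, max_lag = Inf) {
  per <- t_msd(tracks, max_lag = max_lag)
  out <- per |>
    dplyr::group_by(.data$lag, .data$delay) |>
    dplyr::summarise(n_tracks = dplyr::n(), se_msd = stats::sd(.data$msd),
                     msd = mean(.data$msd), .groups = "drop") |>
    dplyr::arrange(.data$lag) |>
    dplyr::mutate(se_msd = .data$se_msd / sqrt(.data$n_tracks))
  out <- out[c("lag", "delay", "msd", "n_tracks", "se_msd")]
  structure(out, kind = "time-ensemble-averaged", dt = attr(per, "dt"),
            class = c("msd_curve", class(out)))
}

#' Motion blur coefficient of a detection scheme
#'
#' The apparent MSD offset produced by emitter motion within the camera
#' exposure is `-8 R D dt` (in 2-D), where the blur coefficient `R` depends
#' only on the normalized cumulative illumination profile `S` of one frame:
#' `R = (1/dt) * integral of S(tau) (1 - S(tau)) dtau` over `[0, dt]`. `R`
#' lies in `[0, 1/4]`: 0 for an instantaneous exposure, 1/6 when the
#' exposure time equals the frame time (continuous illumination).
#'
#' @param S cumulative illumination profile: a function on `[0, dt]`,
#'   monotone non-decreasing from 0 to 1.
#' @param dt frame interval, seconds.
#' @return blur coefficient in `[0, 0.25]`.
#' @examples
#' motion_blur_coefficient(function(t) t, dt = 1)      # 1/6
#' motion_blur_coefficient(function(t) t >= 0, dt = 1) # 0
#' @export
motion_blur_coefficient <- function(S, dt = 1) {
  stopifnot(is.function(S), dt > 0)
  grid <- seq(0, dt, length.out = 2001)
  sv <- as.numeric(S(grid))
  if (any(diff(sv) < -1e-12) || sv[1] < -1e-9 || sv[length(sv)] > 1 + 1e-9) {
    stop("S must be monotone non-decreasing from 0 to 1 on [0, dt]", call. = FALSE)
  }
  f <- function(tau) {
    s <- pmin(pmax(as.numeric(S(tau)), 0), 1)
    s * (1 - s)
  }
  val <- stats::integrate(f, 0, dt, rel.tol = 1e-12, abs.tol = 1e-14,
                          subdivisions = 4000L)$value / dt
  min(max(val, 0), 0.25)
}

#' Fit the normal-diffusion model to an MSD curve
#'
#' Weighted linear least squares of `MSD(t) = 2 d D t + b` over the shortest
#' delays, where the offset `b = 2 d (sigma^2 - 2 R D dt)` collects the
#' localization-error inflation (`+2 d sigma^2`) and the motion-blur
#' deflation (`-4 d R D dt`). Only the shortest `max(min_points,
#' ceiling(fraction * n))` delays enter the fit, where single-track MSD
#' estimates are least biased. For time-ensemble curves the points are
#' weighted by the number of contributing trajectories and parameter
#' standard errors are propagated from the per-point ensemble scatter
#' (`se_msd`), since neighbouring delays share trajectories and residual
#' scatter alone badly understates the uncertainty; time-averaged curves
#' are fitted unweighted with ordinary least-squares errors. The
#' localization error `sigma` is recovered
#' from the intercept given the (user-supplied) blur coefficient `R`; when
#' the implied `sigma^2` is negative, `sigma` is `NA`.
#'
#' @param curve an `msd_curve` from [t_msd()] (single trajectory) or
#'   [te_msd()], or any data frame with `delay` and `msd` columns.
#' @param fraction fraction of the shortest delay times to include.
#' @param min_points minimum number of curve points in the fit.
#' @param d spatial dimensionality of the coordinates (2 for xy tracks).
#' @param R motion blur coefficient in `[0, 0.25]`; see
#'   [motion_blur_coefficient()]. Not estimable from a single intercept, so
#'   it must be supplied; 1/6 corresponds to full-frame exposure.
#' @param dt frame interval, seconds; taken from the curve when omitted.
#' @return object of class `msd_fit` with elements `D`, `se_D`, `intercept`,
#'   `se_intercept`, `sigma`, `se_sigma`, `R`, `d`, `dt`, `n_points_used`,
#'   and the fitted subset in `$data`. Negative `D` estimates are reported
#'   as-is; they occur for noise-dominated immobile tracks.
#' @export
fit_msd <- function(curve, fraction = 0.25, min_points = 3, d = 2,
                    R = 1 / 6, dt = NULL) {
  stopifnot(all(c("delay", "msd") %in% names(curve)),
            fraction > 0, fraction <= 1, min_points >= 3,
            d %in% c(1, 2, 3), R >= 0, R <= 0.25)
  curve <- dplyr::arrange(tibble::as_tibble(curve), .data$delay)
  n <- nrow(curve)
  if (n < min_points) {
    stop("MSD curve has ", n, " point(s); need at least ", min_points, call. = FALSE)
  }
  if (is.null(dt)) {
    dt <- attr(curve, "dt", exact = TRUE)
    if (is.null(dt) && "lag" %in% names(curve)) dt <- curve$delay[1] / curve$lag[1]
    if (is.null(dt)) stop("`dt` must be supplied", call. = FALSE)
  }
  n_used <- min(n, max(min_points, ceiling(fraction * n)))
  sub <- curve[seq_len(n_used), ]
  w <- if ("n_tracks" %in% names(sub)) sub$n_tracks else rep(1, n_used)
  fit <- stats::lm(msd ~ delay, data = sub, weights = w)
  # summary() warns on numerically exact curves; the coefficients are fine
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["delay", "Estimate"]
  b <- sm["(Intercept)", "Estimate"]
  se_slope <- sm["delay", "Std. Error"]
  se_b <- sm["(Intercept)", "Std. Error"]
  # Ensemble curves carry per-point standard errors from the track-to-track
  # scatter; residual-based OLS errors would be far too small there because
  # neighbouring delays share trajectories. Keep the weighted point estimate
  # and take the coefficient covariance from the known per-point variances
  # (sandwich form).
  if ("se_msd" %in% names(sub) && all(is.finite(sub$se_msd)) &&
      all(sub$se_msd > 0)) {
    X <- cbind(1, sub$delay)
    xtwx_inv <- solve(crossprod(X * w, X))
    meat <- crossprod(X * (w * sub$se_msd), X * (w * sub$se_msd))
    covb <- xtwx_inv %*% meat %*% xtwx_inv
    se_b <- sqrt(covb[1, 1])
    se_slope <- sqrt(covb[2, 2])
  }
  D <- slope / (2 * d)
  se_D <- se_slope / (2 * d)
  sigma2 <- b / (2 * d) + 2 * R * D * dt
  sigma <- if (is.finite(sigma2) && sigma2 >= 0) sqrt(sigma2) else NA_real_
  # delta-method SE on sigma, ignoring the (small) slope-intercept covariance
  se_sigma <- if (!is.na(sigma) && sigma > 0) {
    sqrt((se_b / (2 * d))^2 + (2 * R * dt * se_D)^2) / (2 * sigma)
  } else NA_real_
  structure(
    list(D = D, se_D = se_D, intercept = b, se_intercept = se_b,
         sigma = sigma, se_sigma = se_sigma, sigma2 = sigma2,
         R = R, d = d, dt = dt, n_points_used = n_used,
         kind = attr(curve, "kind", exact = TRUE) %||% "unknown",
         data = dplyr::mutate(sub, weight = w)),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("# msd_fit (%s, %d points): D = %.4g +/- %.2g m^2/s, sigma = %s m\n",
              x$kind, x$n_points_used, x$D, x$se_D,
              if (is.na(x$sigma)) "NA" else sprintf("%.3g", x$sigma)))
  invisible(x)
}

#' Tidy / summarise an MSD fit
#'
#' @param x an `msd_fit` from [fit_msd()].
#' @param ... unused.
#' @return `tidy()`: one row per parameter (`D`, `intercept`, `sigma`) with
#'   estimate and standard error. `glance()`: a one-row summary.
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("D", "intercept", "sigma"),
    estimate = c(x$D, x$intercept, x$sigma),
    std.error = c(x$se_D, x$se_intercept, x$se_sigma)
  )
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(D = x$D, se_D = x$se_D, sigma = x$sigma,
                 intercept = x$intercept, R = x$R, d = x$d,
                 n_points_used = x$n_points_used, kind = x$kind)
}

#' Per-trajectory diffusion constants
#'
#' Applies [t_msd()] then [fit_msd()] to every trajectory. Per-trajectory
#' failures (too few MSD points) are recorded in the output, not raised, so
#' a whole data set can be processed in one call. Negative `D` estimates are
#' retained: for noise-dominated (immobile) tracks the fitted slope
#' scatters around zero and its sign carries no meaning.
#'
#' @inheritParams fit_msd
#' @param tracks a [track_set()].
#' @return tibble with one row per trajectory: `id`, `n_points`, `D`,
#'   `se_D`, `intercept`, `sigma`, `ok` (logical), `error` (message for
#'   failed fits), and `label` when the set is classified.
#' @export
per_trajectory_D <- function(tracks, fraction = 0.25, min_points = 3, d = 2,
                             R = 1 / 6) {
  dt <- track_dt(tracks)
  df <- tibble::as_tibble(tracks)
  per <- t_msd(tracks)
  labels <- if ("label" %in% names(df)) {
    stats::setNames(dplyr::distinct(df, .data$id, .data$label)$label,
                    dplyr::distinct(df, .data$id, .data$label)$id)
  } else NULL
  sizes <- track_sizes(tracks)
  rows <- lapply(split(per, per$id), function(sub) {
    id <- sub$id[1]
    res <- tryCatch(
      fit_msd(sub, fraction = fraction, min_points = min_points, d = d,
              R = R, dt = dt),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(id = id, n_points = unname(sizes[id]), D = NA_real_,
                     se_D = NA_real_, intercept = NA_real_, sigma = NA_real_,
                     ok = FALSE, error = conditionMessage(res))
    } else {
      tibble::tibble(id = id, n_points = unname(sizes[id]), D = res$D,
                     se_D = res$se_D, intercept = res$intercept,
                     sigma = res$sigma, ok = TRUE, error = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  # single-point tracks never reach t_msd output; report them as failures
  missing_ids <- setdiff(names(sizes), out$id)
  if (length(missing_ids) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      id = missing_ids, n_points = unname(sizes[missing_ids]), D = NA_real_,
      se_D = NA_real_, intercept = NA_real_, sigma = NA_real_,
      ok = FALSE, error = "no displacement pairs"
    ))
  }
  if (!is.null(labels)) out$label <- unname(labels[out$id])
  dplyr::arrange(out, .data$id)
}
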
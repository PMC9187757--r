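#' Minimum enclosing circle of a 2-D point set
#'
#' Smallest circle containing every point, computed with Welzl's randomized
#' incremental algorithm (expected linear time). The working order is drawn
#' from a fixed internal generator, so the result is deterministic for a
#' given input and independent of R's RNG state.
#'
#' @param points two-column matrix or data frame of xy positions (metres).
#' @return list with `center` (length-2 numeric) and `radius`.
#' @examples
#' min_enclosing_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
#' @export
min_enclosing_circle <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) stop("empty point set", call. = FALSE)
  if (ncol(pts) < 2) stop("points must have x and y columns", call. = FALSE)
  storage.mode(pts) <- "double"
  res <- .mec_cpp(pts[, 1:2, drop = FALSE])
  list(center = res[1:2], radius = res[3])
}

#' Per-trajectory shape and size descriptors
#'
#' Computes, for every trajectory, the scalar properties used to classify
#' motion behaviour:
#'
#' * `n_points`: number of localizations.
#' * `length`: total path length, the sum of consecutive step distances
#'   (metres; uses all coordinate dimensions).
#' * `tortuosity`: path length divided by end-to-end distance; 1 for a
#'   monotone straight path, `Inf` for a closed path.
#' * `elongation`: `1 - lambda2/lambda1` with `lambda1 >= lambda2` the
#'   eigenvalues of the xy gyration tensor; 0 for an isotropic cloud, 1 for
#'   a perfectly linear track.
#' * `elongation_angle`: orientation of the major gyration axis, radians in
#'   (-pi/2, pi/2].
#' * `entropy`: Shannon entropy (bits) of localization counts over a square
#'   grid of cell size `entropy_bin` covering the track's bounding box.
#' * `mbcr`: minimum bounding circle radius of the xy localizations (metres).
#' * `mbcc_com`: distance between the bounding-circle centre and the centre
#'   of mass of the localizations (metres); large values flag spatially
#'   asymmetric tracks such as those with an immobile segment followed by a
#'   mobile excursion.
#'
#' Descriptors that are undefined for a degenerate trajectory (too few
#' points, zero spatial extent) are returned as `NaN` rather than raising.
#'
#' @param tracks a [track_set()].
#' @param entropy_bin grid cell size for the entropy descriptor, metres.
#'   The default 100 nm is on the order of a localization error footprint,
#'   so immobile tracks concentrate in one or two cells.
#' @return tibble with one row per trajectory, keyed by `id`. The `label`
#'   column is carried over when present.
#' @export
compute_properties <- function(tracks, entropy_bin = 1e-7) {
  stopifnot(entropy_bin > 0)
  df <- tibble::as_tibble(tracks)
  has_z <- "z" %in% names(df)
  has_label <- "label" %in% names(df)
  one <- function(sub) {
    xy <- cbind(sub$x, sub$y)
    full <- if (has_z) cbind(xy, sub$z) else xy
    n <- nrow(full)
    path_len <- if (n >= 2) sum(sqrt(rowSums(diff(full)^2))) else NaN
    e2e <- if (n >= 2) sqrt(sum((full[n, ] - full[1, ])^2)) else NaN
    tort <- if (n >= 2) {
      if (e2e == 0 && path_len == 0) NaN else path_len / e2e
    } else NaN
    gyr <- gyration_descriptors(xy)
    circ <- min_enclosing_circle(xy)
    com <- colMeans(xy)
    tibble::tibble(
      n_points = n,
      length = path_len,
      tortuosity = tort,
      elongation = gyr$elongation,
      elongation_angle = gyr$angle,
      entropy = grid_entropy(xy, entropy_bin),
      mbcr = circ$radius,
      mbcc_com = sqrt(sum((circ$center - com)^2))
    )
  }
  out <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  if (has_label) {
    lab <- dplyr::distinct(df, .data$id, .data$label)
    out <- dplyr::left_join(out, lab, by = "id")
  }
  out
}

# elongation and orientation from the xy gyration tensor
gyration_descriptors <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(list(elongation = NaN, angle = NaN))
  centred <- sweep(xy, 2, colMeans(xy))
  sxx <- mean(centred[, 1]^2)
  syy <- mean(centred[, 2]^2)
  sxy <- mean(centred[, 1] * centred[, 2])
  tr <- sxx + syy
  if (tr == 0) return(list(elongation = NaN, angle = NaN))
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  list(elongation = 1 - l2 / l1, angle = ang)
}

# Shannon entropy (base 2) of localization counts on a square grid anchored
# at the bounding-box corner
grid_entropy <- function(xy, bin) {
  ix <- floor((xy[, 1] - min(xy[, 1])) / bin)
  iy <- floor((xy[, 2] - min(xy[, 2])) / bin)
  counts <- table(paste(ix, iy))
  p <- as.numeric(counts) / sum(counts)
  -sum(p * log2(p))
}

#' Probability that an immobile track stays within a circle threshold
#'
#' Monte-Carlo estimate of the probability that the minimum bounding circle
#' radius of `n_points` localizations of a stationary emitter, each measured
#' with isotropic Gaussian localization error `sigma` per coordinate, does
#' not exceed `radius_threshold`. This quantifies how safely a bounding
#' circle threshold captures immobile trajectories when choosing
#' classification cut-offs.
#'
#' @param n_points localizations per simulated track.
#' @param sigma per-coordinate localization error, metres.
#' @param radius_threshold circle radius threshold, metres.
#' @param n_mc number of Monte-Carlo replicates.
#' @param seed RNG seed; the estimate is reproducible given the seed.
#' @return estimated probability in \[0, 1\].
#' @examples
#' immobile_containment_probability(17, 12e-9, 118e-9, n_mc = 1e4, seed = 1)
#' @export
immobile_containment_probability <- function(n_points, sigma, radius_threshold,
                                             n_mc = 1e5, seed = 1) {
  stopifnot(n_points >= 1, sigma >= 0, n_mc >= 1, radius_threshold >= 0)
  if (sigma == 0) return(1)
  n_mc <- as.integer(n_mc)
  inside <- 0L
  with_seed(seed, {
    chunk <- 50000L
    done <- 0L
    while (done < n_mc) {
      nrep <- min(chunk, n_mc - done)
      xs <- stats::rnorm(nrep * n_points, sd = sigma)
      ys <- stats::rnorm(nrep * n_points, sd = sigma)
      r <- .mec_radius_batch(xs, ys, as.integer(n_points))
      inside <- inside + sum(r <= radius_threshold)
      done <- done + nrep
    }
  })
  inside / n_mc
}

#' Principal component analysis of a property table
#'
#' Standardizes each finite-valued property column to zero mean and unit
#' variance and decomposes the result. Constant columns, and columns with
#' non-finite entries, are excluded with a warning. Useful to see which
#' descriptors spread the trajectories most (biplot candidates for manual
#' tree construction).
#'
#' @param props property table from [compute_properties()].
#' @return list of class `property_pca` with `loadings` (tibble, one row per
#'   property), `scores` (tibble, one row per trajectory), and `variance`
#'   (tibble of component standard deviations and variance fractions).
#' @export
property_pca <- function(props) {
  num_cols <- setdiff(names(props)[vapply(props, is.numeric, logical(1))], "id")
  keep <- character()
  for (cc in num_cols) {
    v <- props[[cc]]
    if (any(!is.finite(v))) {
      warning("excluding property `", cc, "` (non-finite values)", call. = FALSE)
    } else if (stats::sd(v) == 0) {
      warning("excluding constant property `", cc, "`", call. = FALSE)
    } else keep <- c(keep, cc)
  }
  if (nrow(props) < 2 || length(keep) < 2) {
    stop("need >= 2 trajectories and >= 2 usable properties", call. = FALSE)
  }
  m <- scale(as.matrix(props[keep]))
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  loadings <- tibble::as_tibble(pc$rotation, rownames = "property")
  scores <- tibble::as_tibble(pc$x)
  if ("id" %in% names(props)) scores <- dplyr::bind_cols(id = props$id, scores)
  structure(
    list(
      loadings = loadings,
      scores = scores,
      variance = tibble::tibble(
        component = paste0("PC", seq_along(pc$sdev)),
        sdev = pc$sdev,
        var_fraction = pc$sdev^2 / sum(pc$sdev^2)
      )
    ),
    class = "property_pca"
  )
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
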
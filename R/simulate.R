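#' Configuration of the two-state transient-trapping simulator
#'
#' Describes random walkers that alternate between a trapped state with
#' diffusion constant `D1` (default 0: adsorbed/immobile) and a free state
#' with `D2` (default 1.0e-12 m^2/s), switching state at each frame boundary
#' with probability `p_switch` (default 0.02 per frame). Walkers move in a
#' periodic 3-D box and are observed through a focal slice of half-depth
#' `z_visible` around the box mid-plane, with a localization error that
#' grows linearly from `sigma0` in focus to `sigma_z` at the edge of
#' visibility. Positions are propagated at `substeps` sub-frame steps so
#' that motion blur within the exposure can be emulated by averaging the
#' sub-frame positions (`blur = "substep-average"`); `"last-substep"`
#' disables blur.
#'
#' Defaults for quantities the physics does not pin down (box size, walker
#' and frame counts) are chosen so that a default run yields roughly ten
#' thousand observed track fragments of which about two thousand survive
#' the five-localization filter — short mobile fragments dominating, with
#' longer immobile and hybrid tracks.
#'
#' @param n_walkers number of simulated emitters.
#' @param n_frames number of frames.
#' @param dt frame interval, seconds.
#' @param substeps sub-frame propagation steps per frame.
#' @param D1,D2 diffusion constants of the two states, m^2/s.
#' @param p_switch per-frame probability of changing diffusion state.
#' @param box periodic box edge lengths (x, y, z), metres.
#' @param z_visible focal-slice half-depth, metres; a frame is observed iff
#'   the emitter's |z - z_focal| is at most this (`Inf` disables the cut).
#' @param sigma0 per-coordinate localization error in focus, metres.
#' @param sigma_z localization error at |z - z_focal| = `z_visible`, metres.
#' @param blur `"substep-average"` or `"last-substep"`.
#' @param seed integer seed; every random draw of the simulation derives
#'   from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_walkers = 450,
                       n_frames = 600,
                       dt = 0.05,
                       substeps = 5,
                       D1 = 0,
                       D2 = 1.0e-12,
                       p_switch = 0.02,
                       box = c(20e-6, 20e-6, 4e-6),
                       z_visible = 400e-9,
                       sigma0 = 12e-9,
                       sigma_z = 28e-9,
                       blur = c("substep-average", "last-substep"),
                       seed = 1) {
  blur <- match.arg(blur)
  cfg <- list(n_walkers = as.integer(n_walkers), n_frames = as.integer(n_frames),
              dt = dt, substeps = as.integer(substeps), D1 = D1, D2 = D2,
              p_switch = p_switch, box = as.numeric(box), z_visible = z_visible,
              sigma0 = sigma0, sigma_z = sigma_z, blur = blur,
              seed = as.integer(seed))
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_walkers >= 1, "n_walkers must be >= 1")
  chk(cfg$n_frames >= 2, "n_frames must be >= 2")
  chk(is.finite(cfg$dt) && cfg$dt > 0, "dt must be > 0")
  chk(cfg$substeps >= 1, "substeps must be >= 1")
  chk(cfg$D1 >= 0 && cfg$D2 >= 0, "D1 and D2 must be >= 0")
  chk(cfg$p_switch >= 0 && cfg$p_switch <= 1, "p_switch must be in [0, 1]")
  chk(length(cfg$box) == 3 && all(cfg$box > 0), "box must be 3 positive lengths")
  chk(cfg$z_visible > 0, "z_visible must be > 0")
  chk(cfg$sigma0 >= 0 && cfg$sigma_z >= cfg$sigma0,
      "need 0 <= sigma0 <= sigma_z")
  if (length(problems) > 0) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the hidden two-state random walk
#'
#' Generates, for every walker, the per-frame diffusion-state sequence and
#' the true 3-D path at substep resolution. Walkers start uniformly in the
#' box, in a uniformly random state; the state is redrawn at every frame
#' boundary (change with probability `p_switch`); within a frame, each of
#' the `substeps` sub-frame displacements is i.i.d. Gaussian per axis with
#' variance `2 * D_state * dt / substeps`. Positions are wrapped into the
#' periodic box. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list with `config`, `states`
#'   (`n_frames` x `n_walkers` matrix of 1/2, the state governing each
#'   frame's motion), `positions` (array `[n_frames * substeps + 1, 3,
#'   n_walkers]` of wrapped positions; row 1 is the starting position) and
#'   `wrapped` (logical array marking walkers that crossed a periodic
#'   boundary during each frame, per axis).
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nw <- config$n_walkers; nf <- config$n_frames; ns <- config$substeps
  with_seed(config$seed, {
    start <- sapply(config$box, function(L) stats::runif(nw, 0, L))
    start <- matrix(start, nrow = nw)  # nw x 3
    states <- matrix(0L, nrow = nf, ncol = nw)
    states[1, ] <- sample(1:2, nw, replace = TRUE)
    if (nf > 1) {
      flip <- matrix(stats::runif((nf - 1) * nw) < config$p_switch, nf - 1, nw)
      for (f in 2:nf) {
        states[f, ] <- ifelse(flip[f - 1, ], 3L - states[f - 1, ], states[f - 1, ])
      }
    }
    # per-substep displacement sd by walker and frame
    Dmat <- matrix(c(config$D1, config$D2)[states], nf, nw)   # nf x nw
    sd_sub <- sqrt(2 * Dmat * config$dt / ns)
    n_steps <- nf * ns
    positions <- array(NA_real_, dim = c(n_steps + 1, 3, nw))
    wrapped <- array(FALSE, dim = c(nf, 3, nw))
    sd_steps <- sd_sub[rep(seq_len(nf), each = ns), , drop = FALSE]  # n_steps x nw
    for (ax in 1:3) {
      steps <- matrix(stats::rnorm(n_steps * nw), n_steps, nw) * sd_steps
      unwrapped <- rbind(start[, ax], apply(steps, 2, cumsum) + rep(start[, ax], each = n_steps))
      L <- config$box[ax]
      cell <- floor(unwrapped / L)
      positions[, ax, ] <- unwrapped - cell * L
      # frame-level wrap flags: any substep of the frame in a different
      # periodic image than the frame start (catches out-and-back wraps,
      # which would otherwise corrupt the blur average)
      frame_ends <- seq(1, n_steps + 1, by = ns)  # frame-boundary rows
      for (f in seq_len(nf)) {
        rows <- (frame_ends[f]):(frame_ends[f + 1])
        ref <- matrix(cell[rows[1], ], length(rows), nw, byrow = TRUE)
        wrapped[f, ax, ] <- colSums(cell[rows, , drop = FALSE] != ref) > 0
      }
    }
  })
  structure(list(config = config, states = states, positions = positions,
                 wrapped = wrapped),
            class = "sim_truth")
}

#' Render observed trajectories from a simulated ground truth
#'
#' Emulates the detection stage of a tracking experiment on the hidden
#' paths: a frame is observed iff the emitter lies within the focal slice
#' (`|z - z_focal| <= z_visible`, `z_focal` at the box mid-plane); the
#' observed xy position is the substep average over the frame exposure
#' (or the last substep position if `blur = "last-substep"`) plus isotropic
#' Gaussian localization error with per-axis
#' `sigma(z) = sigma0 + (sigma_z - sigma0) |z - z_focal| / z_visible`.
#' Maximal runs of consecutive observed frames become distinct trajectories
#' — so one walker typically yields many short track fragments as it drifts
#' in and out of focus. A frame in which the walker crossed a periodic
#' boundary in x or y breaks the run, as a real linker would lose the
#' emitter there. Each fragment carries its ground-truth label: `immobile`
#' (every frame in state 1), `mobile` (every frame in state 2), `hybrid`
#' (both).
#'
#' @param truth a `sim_truth` from [simulate_ground_truth()].
#' @param config the [sim_config()] the truth was generated under (defaults
#'   to `truth$config`).
#' @return a [track_set()] with columns `id`, `frame` (0-based global frame
#'   index), `x`, `y`, `label` and `walker`.
#' @export
render_observed <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  nw <- config$n_walkers; nf <- config$n_frames; ns <- config$substeps
  z_focal <- config$box[3] / 2
  # frame-representative positions: mean (or last) of the ns substeps
  frame_pos <- function(ax, w) {
    p <- truth$positions[-1, ax, w]                 # n_steps positions
    m <- matrix(p, nrow = ns)                       # ns x nf
    if (config$blur == "substep-average") colMeans(m) else m[ns, ]
  }
  with_seed(config$seed + 1L, {
    pieces <- vector("list", nw)
    for (w in seq_len(nw)) {
      zx <- frame_pos(3, w)
      dz <- abs(zx - z_focal)
      visible <- dz <= config$z_visible
      breaks <- truth$wrapped[, 1, w] | truth$wrapped[, 2, w]
      visible <- visible & !breaks
      if (!any(visible)) next
      runs <- rle(visible)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      vis_runs <- which(runs$values)
      xs <- frame_pos(1, w)
      ys <- frame_pos(2, w)
      sig <- config$sigma0 +
        (config$sigma_z - config$sigma0) * pmin(dz, config$z_visible) / config$z_visible
      frag <- lapply(seq_along(vis_runs), function(k) {
        fr <- starts[vis_runs[k]]:ends[vis_runs[k]]
        st <- truth$states[fr, w]
        lab <- if (all(st == 1L)) "immobile" else if (all(st == 2L)) "mobile" else "hybrid"
        tibble::tibble(
          id = sprintf("w%04d_t%02d", w, k),
          frame = fr - 1L,
          x = xs[fr] + stats::rnorm(length(fr), sd = sig[fr]),
          y = ys[fr] + stats::rnorm(length(fr), sd = sig[fr]),
          label = lab,
          walker = w
        )
      })
      pieces[[w]] <- dplyr::bind_rows(frag)
    }
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble::tibble(id = character(), frame = integer(), x = numeric(),
                          y = numeric(), label = character(), walker = integer())
  }
  track_set(out, dt = config$dt, pixel_size = 1e-7)
}

#' Simulate an observed trajectory set in one call
#'
#' @inheritParams render_observed
#' @return a [track_set()] as from [render_observed()].
#' @export
simulate_tracks <- function(config = sim_config()) {
  render_observed(simulate_ground_truth(config))
}

#' Estimate the per-frame switching probability from a ground truth
#'
#' The number of state changes divided by the number of frame boundaries,
#' pooled over walkers; the natural estimator of `p_switch`.
#'
#' @param truth a `sim_truth`.
#' @return estimated probability.
#' @export
estimate_switching_probability <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  s <- truth$states
  if (nrow(s) < 2) stop("no frame boundaries", call. = FALSE)
  changes <- sum(s[-1, , drop = FALSE] != s[-nrow(s), , drop = FALSE])
  boundaries <- (nrow(s) - 1) * ncol(s)
  changes / boundaries
}
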
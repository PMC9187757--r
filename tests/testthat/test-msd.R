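test_that("time-averaged MSD matches closed forms on simple tracks", {
  um <- 1e-6
  tr <- make_tracks(track_df("a", cbind(0:3, 0) * um), dt = 1)
  cur <- t_msd(tr)
  expect_equal(cur$lag, 1:3)
  expect_equal(cur$msd, c(1, 4, 9) * um^2)
  expect_equal(cur$n_pairs, c(3L, 2L, 1L))
  expect_equal(cur$delay, c(1, 2, 3))

  still <- make_tracks(track_df("s", matrix(2e-7, 5, 2)))
  expect_true(all(t_msd(still)$msd == 0))

  expect_error(t_msd(make_tracks(track_df("p", rbind(c(0, 0))))),
               "single localization")
})

test_that("frame gaps define the lag, not row offsets", {
  um <- 1e-6
  tr <- make_tracks(track_df("g", rbind(c(0, 0), c(1, 0), c(3, 0)) * um,
                             frames = c(0L, 1L, 4L)), dt = 0.5)
  cur <- t_msd(tr)
  # pairs exist only at frame lags 1 (0->1), 3 (1->4) and 4 (0->4)
  expect_equal(cur$lag, c(1L, 3L, 4L))
  expect_equal(cur$msd, c(1, 4, 9) * um^2)
})

test_that("time-averaged MSD equals the nested-loop evaluation", {
  set.seed(31)
  for (rep in 1:200) {
    tr <- random_gapped_track(sample(2:8, 1))
    cur <- t_msd(make_tracks(track_df("t", tr$coords, frames = tr$frames), dt = 1))
    oracle <- brute_t_msd(tr$frames, tr$coords)
    expect_equal(cur$lag, oracle$lag)
    expect_equal(cur$msd, oracle$msd, tolerance = 1e-12)
    expect_equal(cur$n_pairs, oracle$n_pairs)
  }
})

test_that("ensemble MSD averages per-track curves with equal weight", {
  set.seed(33)
  base <- random_gapped_track(6)
  # two identical trajectories: ensemble curve equals the single-track curve
  two <- make_tracks(track_df("a", base$coords, frames = base$frames),
                     track_df("b", base$coords, frames = base$frames), dt = 1)
  one <- make_tracks(track_df("a", base$coords, frames = base$frames), dt = 1)
  expect_equal(te_msd(two)$msd, t_msd(one)$msd)
  expect_equal(te_msd(one)$msd, t_msd(one)$msd)

  # M copies leave the ensemble curve unchanged
  many <- make_tracks(lapply(1:7, function(i) {
    track_df(paste0("c", i), base$coords, frames = base$frames)
  }), dt = 1)
  expect_equal(te_msd(many)$msd, t_msd(one)$msd)
  expect_equal(te_msd(many)$n_tracks, rep(7L, nrow(t_msd(one))))

  # three random unequal tracks: nested-loop oracle
  trs <- lapply(1:3, function(i) random_gapped_track(sample(3:8, 1)))
  set <- make_tracks(lapply(seq_along(trs), function(i) {
    track_df(paste0("t", i), trs[[i]]$coords, frames = trs[[i]]$frames)
  }), dt = 1)
  oracle <- brute_te_msd(trs)
  cur <- te_msd(set)
  expect_equal(cur$lag, oracle$lag)
  expect_equal(cur$msd, oracle$msd, tolerance = 1e-12)
  expect_equal(cur$n_tracks, oracle$n_tracks)
})

test_that("motion blur coefficient reproduces the canonical exposures", {
  expect_lt(abs(motion_blur_coefficient(function(t) as.numeric(t > 0), 1)), 1e-9)
  expect_lt(abs(motion_blur_coefficient(function(t) t, 1) - 1 / 6), 1e-9)
  # uniform exposure over the first half of the frame
  half <- function(t) pmin(2 * t, 1)
  expect_lt(abs(motion_blur_coefficient(half, 1) - 1 / 12), 1e-9)
  # dt scaling does not change R
  expect_equal(motion_blur_coefficient(function(t) t / 0.05, 0.05), 1 / 6,
               tolerance = 1e-9)
  expect_error(motion_blur_coefficient(function(t) 1 - t, 1), "monotone")
})

test_that("fitting exact model curves inverts the diffusion model", {
  dt <- 0.05
  delays <- (1:10) * dt
  # noiseless line through the origin
  curve <- tibble::tibble(lag = 1:10, delay = delays, msd = 4e-12 * delays)
  fit <- fit_msd(curve, R = 0, dt = dt)
  expect_equal(fit$D, 1e-12, tolerance = 1e-12)
  expect_equal(fit$sigma, 0, tolerance = 1e-10)

  # exact curve with localization error and full-frame blur
  D <- 1e-12; sig <- 20e-9; R <- 1 / 6
  msd <- 4 * D * delays + 4 * (sig^2 - 2 * R * D * dt)
  expect_equal(msd[1], 1.3493e-13, tolerance = 1e-4)
  fit2 <- fit_msd(tibble::tibble(lag = 1:10, delay = delays, msd = msd),
                  R = R, dt = dt)
  expect_equal(fit2$D, D, tolerance = 1e-9)
  expect_equal(fit2$sigma, sig, tolerance = 1e-9)
})

test_that("the fit window takes the agreed share of shortest delays", {
  curve <- tibble::tibble(lag = 1:12, delay = (1:12) * 0.1,
                          msd = 4e-13 * (1:12) * 0.1)
  fit <- fit_msd(curve, fraction = 0.25, R = 0)
  expect_equal(fit$n_points_used, 3)  # ceiling(0.25 * 12)
  fit2 <- fit_msd(curve[1:4, ], fraction = 0.25, R = 0)
  expect_equal(fit2$n_points_used, 3)  # floored at min_points
  expect_error(fit_msd(curve[1:2, ], R = 0), "at least 3")
})

test_that("fitted D is invariant under consistent unit rescaling", {
  set.seed(55)
  delays <- (1:8) * 0.05
  msd_m2 <- 4e-12 * delays + rnorm(8, sd = 1e-15)
  m <- tibble::tibble(lag = 1:8, delay = delays, msd = msd_m2)
  um <- dplyr::mutate(m, msd = msd * 1e12)  # metres^2 -> micrometres^2
  fit_m <- fit_msd(m, R = 0)
  fit_um <- fit_msd(um, R = 0)
  expect_equal(fit_um$D * 1e-12, fit_m$D, tolerance = 1e-12)
})

test_that("per-trajectory fits run the whole set and record failures", {
  um <- 1e-6
  good <- lapply(1:4, function(i) {
    track_df(paste0("ok", i), cbind(0:9, 0) * um * i)
  })
  set <- make_tracks(c(good, list(track_df("short", cbind(0:2, 0) * um))), dt = 1)
  res <- per_trajectory_D(set, R = 0)
  expect_equal(nrow(res), 5)
  expect_true(all(res$ok[res$id != "short"]))
  expect_false(res$ok[res$id == "short"])
  expect_match(res$error[res$id == "short"], "at least")
  # ballistic tracks: LS line through (n, n^2 s^2) at lags 1..3 has slope
  # 4 s^2, so the reported D is s^2 for step size s
  ok <- dplyr::filter(res, ok)
  expect_equal(ok$D, (um * (1:4))^2, tolerance = 1e-9)
})

test_that("ensemble lag-1 MSD converges to 4 D dt on clean Brownian motion", {
  cfg <- sim_config(n_walkers = 400, n_frames = 30, D1 = 1e-12, D2 = 1e-12,
                    p_switch = 0, sigma0 = 0, sigma_z = 0,
                    blur = "last-substep", z_visible = Inf,
                    box = c(1e-3, 1e-3, 1e-3), seed = 17)
  tr <- simulate_tracks(cfg)
  cur <- te_msd(tr, max_lag = 1)
  expect_equal(cur$msd[1], 4 * 1e-12 * cfg$dt, tolerance = 0.02)
})
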
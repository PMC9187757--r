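# fixtures and independent brute-force oracles used across the suite

make_tracks <- function(..., dt = 0.05, pixel_size = 1e-7) {
  track_set(dplyr::bind_rows(...), dt = dt, pixel_size = pixel_size)
}

# a single track tibble from a coordinate matrix (metres)
track_df <- function(id, coords, frames = seq_len(nrow(coords)) - 1L) {
  coords <- rbind(coords)
  out <- tibble::tibble(id = id, frame = as.integer(frames),
                        x = coords[, 1], y = coords[, 2])
  if (ncol(coords) >= 3) out$z <- coords[, 3]
  out
}

# O(n^4) oracle: smallest circle among all 2- and 3-point candidate circles
brute_mec_radius <- function(P) {
  n <- nrow(P)
  if (n == 1) return(0)
  contains <- function(cc, r) {
    all(sqrt((P[, 1] - cc[1])^2 + (P[, 2] - cc[2])^2) <= r * (1 + 1e-9) + 1e-30)
  }
  best <- Inf
  for (i in 1:n) for (j in 1:n) {
    cc <- (P[i, ] + P[j, ]) / 2
    r <- sqrt(sum((P[i, ] - P[j, ])^2)) / 2
    if (r < best && contains(cc, r)) best <- r
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      A <- P[i, ]; B <- P[j, ]; C <- P[k, ]
      d <- 2 * ((B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1]))
      if (abs(d) < 1e-30) next
      b2 <- sum((B - A)^2); c2 <- sum((C - A)^2)
      ux <- ((C[2] - A[2]) * b2 - (B[2] - A[2]) * c2) / d
      uy <- ((B[1] - A[1]) * c2 - (C[1] - A[1]) * b2) / d
      cc <- A + c(ux, uy); r <- sqrt(ux^2 + uy^2)
      if (r < best && contains(cc, r)) best <- r
    }
  }
  best
}

# direct double-loop evaluation of the time-averaged MSD at every lag
brute_t_msd <- function(frames, coords) {
  coords <- rbind(coords)
  lags <- seq_len(max(frames) - min(frames))
  out <- lapply(lags, function(L) {
    vals <- c()
    for (i in seq_along(frames)) {
      j <- which(frames == frames[i] + L)
      if (length(j) == 1) {
        vals <- c(vals, sum((coords[j, ] - coords[i, ])^2))
      }
    }
    if (length(vals) == 0) return(NULL)
    data.frame(lag = L, msd = mean(vals), n_pairs = length(vals))
  })
  do.call(rbind, out)
}

# direct nested-loop time-ensemble MSD: unweighted mean over eligible tracks
brute_te_msd <- function(track_list) {
  per <- lapply(track_list, function(tr) brute_t_msd(tr$frames, tr$coords))
  all_lags <- sort(unique(unlist(lapply(per, function(p) p$lag))))
  do.call(rbind, lapply(all_lags, function(L) {
    vals <- unlist(lapply(per, function(p) p$msd[p$lag == L]))
    data.frame(lag = L, msd = mean(vals), n_tracks = length(vals))
  }))
}

random_gapped_track <- function(n_points, d = 2) {
  frames <- sort(sample(0:(n_points * 2), n_points))
  coords <- matrix(rnorm(n_points * d), n_points)
  list(frames = frames, coords = coords)
}
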
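#' Pooled squared displacements at a fixed lag
#'
#' Collects `|x_{i+n} - x_i|^2` for every pair of localizations `n` frames
#' apart, pooled across all trajectories of the set. The lag-1 sample is the
#' basis of survival-function analysis: for a single normal-diffusion state
#' the squared displacements are exponentially distributed with mean equal
#' to the MSD at that lag.
#'
#' @param tracks a [track_set()].
#' @param lag frame lag (default 1).
#' @return tibble with columns `id` and `r2` (m^2), plus `label` when the
#'   set is classified; attribute `lag`.
#' @export
squared_displacements <- function(tracks, lag = 1) {
  stopifnot(lag >= 1)
  df <- tibble::as_tibble(tracks)
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  one <- function(sub) {
    f <- sub$frame
    j <- match(f + lag, f)
    ok <- !is.na(j)
    if (!any(ok)) return(tibble::tibble(r2 = numeric()))
    xm <- as.matrix(sub[coord_cols])
    tibble::tibble(r2 = rowSums((xm[j[ok], , drop = FALSE] -
                                   xm[ok, , drop = FALSE])^2))
  }
  out <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  if (nrow(out) == 0) stop("no displacement pair at lag ", lag, call. = FALSE)
  if ("label" %in% names(df)) {
    lab <- dplyr::distinct(df, .data$id, .data$label)
    out <- dplyr::left_join(out, lab, by = "id")
  }
  structure(out, lag = lag)
}

#' Empirical survival function of squared displacements
#'
#' Returns `1 - CDF(r^2)` evaluated at each sorted sample value: the
#' fraction of displacements strictly larger than `r2`. A single
#' normal-diffusion state gives a straight line in a semi-log plot; multiple
#' decays reveal mixed populations with different MSDs.
#'
#' @param sample numeric vector of squared displacements, or a data frame
#'   with an `r2` column (e.g. from [squared_displacements()]).
#' @return tibble with columns `r2` (sorted) and `survival`, stepping from
#'   `1 - 1/n` down to 0.
#' @export
empirical_survival <- function(sample) {
  r2 <- if (is.data.frame(sample)) sample$r2 else as.numeric(sample)
  if (length(r2) == 0) stop("empty sample", call. = FALSE)
  r2 <- sort(r2)
  n <- length(r2)
  tibble::tibble(r2 = r2, survival = (n - seq_len(n)) / n)
}

#' Fit an exponential mixture to squared displacements
#'
#' Maximum-likelihood fit of a `k`-component exponential mixture to the
#' pooled squared displacements, by expectation-maximization with multiple
#' seeded starts. Each component's scale is the MSD of one diffusive
#' population at the sampled lag, and its weight the fraction of
#' displacements drawn from that population — e.g. the residual fraction of
#' immobile steps contaminating a mobile population. `k = 1` reduces to the
#' closed-form MLE (scale = sample mean).
#'
#' @param sample numeric vector of squared displacements (or data frame
#'   with `r2` column); needs at least `10 * k` values.
#' @param k number of components, 1 or 2.
#' @param n_starts number of EM starts (the first is quantile-based, the
#'   rest randomized from `seed`).
#' @param max_iter EM iteration cap per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed RNG seed for the randomized starts.
#' @return object of class `expmix_fit`: `fractions` and `scales` (ordered
#'   by decreasing scale), `loglik`, `k`, `n`, `n_iter`, `converged`. If no
#'   start converges within `max_iter`, an error carrying the best iterate
#'   in its `fit` field is raised.
#' @export
fit_exponential_mixture <- function(sample, k = 2, n_starts = 5,
                                    max_iter = 1000, tol = 1e-10, seed = 1) {
  r2 <- if (is.data.frame(sample)) sample$r2 else as.numeric(sample)
  stopifnot(k %in% c(1, 2), all(r2 >= 0), n_starts >= 1)
  n <- length(r2)
  if (n < 10 * k) stop("need at least ", 10 * k, " displacements", call. = FALSE)

  if (k == 1) {
    scale <- mean(r2)
    ll <- sum(stats::dexp(r2, rate = 1 / scale, log = TRUE))
    return(new_expmix(1, scale, ll, k, n, 0L, TRUE))
  }

  # avoid zero scales: exponential likelihood diverges for a point mass at 0
  floor_scale <- max(mean(r2) * 1e-12, .Machine$double.xmin)
  em_run <- function(pi0, th0) {
    pi_j <- pi0; th <- pmax(th0, floor_scale)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(1:2, function(j) pi_j[j] * stats::dexp(r2, 1 / th[j]),
                     numeric(n))
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      gamma <- dens / tot
      nk <- colSums(gamma)
      pi_j <- nk / n
      th <- pmax(colSums(gamma * r2) / nk, floor_scale)
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        return(list(pi = pi_j, th = th, ll = ll, iter = it, conv = TRUE))
      }
      ll_old <- ll
    }
    list(pi = pi_j, th = th, ll = ll_old, iter = max_iter, conv = FALSE)
  }

  starts <- list(list(pi = c(0.5, 0.5),
                      th = stats::quantile(r2, c(0.25, 0.9), names = FALSE)))
  with_seed(seed, {
    for (s in seq_len(n_starts - 1)) {
      f <- stats::runif(1, 0.05, 0.95)
      starts[[s + 1]] <- list(
        pi = c(f, 1 - f),
        th = mean(r2) * stats::rlnorm(2, sdlog = 1.5)
      )
    }
  })
  runs <- lapply(starts, function(st) em_run(st$pi, st$th))
  lls <- vapply(runs, function(r) r$ll, numeric(1))
  best <- runs[[which.max(lls)]]
  ord <- order(best$th, decreasing = TRUE)
  fit <- new_expmix(best$pi[ord], best$th[ord], best$ll, k, n, best$iter,
                    best$conv)
  if (!best$conv) {
    cond <- structure(
      class = c("trackpop_em_error", "error", "condition"),
      list(message = "EM did not converge within max_iter; best iterate attached",
           call = sys.call(-1), fit = fit)
    )
    stop(cond)
  }
  fit
}

new_expmix <- function(fractions, scales, loglik, k, n, n_iter, converged) {
  structure(
    list(fractions = as.numeric(fractions), scales = as.numeric(scales),
         loglik = loglik, k = k, n = n, n_iter = n_iter, converged = converged),
    class = "expmix_fit"
  )
}

#' @export
print.expmix_fit <- function(x, ...) {
  cat(sprintf("# expmix_fit: k = %d, n = %d, logLik = %.2f\n", x$k, x$n, x$loglik))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: fraction %.4f, scale %.4g m^2\n",
                j, x$fractions[j], x$scales[j]))
  }
  invisible(x)
}

#' Tidy / summarise an exponential mixture fit
#'
#' @param x an `expmix_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per component (fraction, scale). `glance()`:
#'   one-row fit summary.
#' @export
tidy.expmix_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), fraction = x$fractions,
                 scale = x$scales)
}

#' @rdname tidy.expmix_fit
#' @export
glance.expmix_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged)
}
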
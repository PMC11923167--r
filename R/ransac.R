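#' RANSAC simple linear regression
#'
#' Robust fit of \code{y ~ a * x + b} by random sample consensus, used to
#' transform the isosbestic reference onto the scale of the signal channel.
#' A preliminary ordinary least-squares fit sets the inlier residual
#' threshold at \code{threshold_scale} times the median absolute deviation
#' (consistency-scaled, \code{stats::mad}) of its residuals; candidate lines
#' through random point pairs are scored by inlier count, and the best
#' consensus set is re-fit by OLS, with the inlier set re-selected under the
#' refined line until stable. The default \code{threshold_scale = 2.5} keeps
#' essentially all clean points (near-OLS efficiency when no outliers are
#' present) while still excluding gross outliers such as stimulation
#' responses or calcium transients, whose residuals lie far outside the
#' band; a tight one-MAD band would instead leave the fit underdetermined
#' whenever the residual spread is dominated by the signal itself. When the
#' data are exactly affine the MAD is zero, so the threshold is floored at a
#' tiny multiple of the response scale to keep the consensus well defined.
#'
#' If no candidate reaches \code{min_inlier_frac} of the points, the function
#' falls back to the plain OLS fit with a warning.
#'
#' Uses R's RNG: seed it (or pass \code{seed}) for reproducibility.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param n_iter Number of random candidate pairs (default 100).
#' @param min_inlier_frac Minimum inlier fraction accepted as consensus.
#' @param threshold_scale Inlier band half-width in units of the
#'   consistency-scaled MAD of the preliminary OLS residuals.
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored on exit).
#' @return List with \code{slope}, \code{intercept}, \code{inliers} (logical
#'   mask), \code{fallback_ols} (TRUE if consensus failed).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- 2 * x + 1
#' y[1:20] <- y[1:20] + 10   # outliers
#' fit <- ransac_lm(x, y, seed = 1)
#' c(fit$slope, fit$intercept)
ransac_lm <- function(x, y, n_iter = 100, min_inlier_frac = 0.25,
                      threshold_scale = 2.5, seed = NULL) {
  n <- length(x)
  if (length(y) != n) sf_schema_error("x and y must have equal length")
  if (n < 2) sf_param_error("need at least 2 points for a linear fit")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  ols <- fit_line(x, y)
  res <- y - (ols$slope * x + ols$intercept)
  thr <- threshold_scale * stats::mad(res)
  scale_y <- max(stats::sd(y), max(abs(y)), 1e-300)
  if (thr < 1e-12 * scale_y) thr <- 1e-12 * scale_y

  best_count <- -1L
  best_mask <- NULL
  for (it in seq_len(n_iter)) {
    ij <- sample.int(n, 2L)
    dx <- x[ij[2]] - x[ij[1]]
    if (dx == 0) next
    a <- (y[ij[2]] - y[ij[1]]) / dx
    b <- y[ij[1]] - a * x[ij[1]]
    mask <- abs(y - (a * x + b)) <= thr
    cnt <- sum(mask)
    if (cnt > best_count) {
      best_count <- cnt
      best_mask <- mask
    }
  }

  if (is.null(best_mask) || best_count < max(2, ceiling(min_inlier_frac * n))) {
    warning("RANSAC found no consensus set; falling back to OLS fit",
            call. = FALSE)
    return(list(slope = ols$slope, intercept = ols$intercept,
                inliers = rep(TRUE, n), fallback_ols = TRUE))
  }
  # local optimization: re-fit on the consensus set and re-select inliers
  # with the refined line until stable; removes the selection bias a single
  # random candidate pair imposes on the final fit
  refit <- fit_line(x[best_mask], y[best_mask])
  for (round in 1:5) {
    mask <- abs(y - (refit$slope * x + refit$intercept)) <= thr
    if (sum(mask) < 2 || identical(mask, best_mask)) break
    best_mask <- mask
    refit <- fit_line(x[best_mask], y[best_mask])
  }
  list(slope = refit$slope, intercept = refit$intercept,
       inliers = best_mask, fallback_ols = FALSE)
}

# closed-form OLS for y ~ a x + b (avoids lm() overhead in inner loops)
fit_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  if (vx == 0) return(list(slope = 0, intercept = my))
  a <- sum((x - mx) * (y - my)) / vx
  list(slope = a, intercept = my - a * mx)
}
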
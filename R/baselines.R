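# Reference methods the network is compared against: neighbourhood
# averaging, Gaussian/mean kernel smoothing, Perona-Malik anisotropic
# diffusion, and a random-forest neighbourhood regressor.

# Kernel smoothing with truncated-and-renormalized borders: the part of the
# kernel falling outside the matrix is dropped and the remaining mass
# rescaled, so constant inputs are exactly preserved.
kernel_smooth_values <- function(v, kernel) {
  k <- nrow(kernel)
  stopifnot(ncol(kernel) == k, k %% 2L == 1L)
  h <- (k - 1L) %/% 2L
  n <- nrow(v); m <- ncol(v)
  num <- matrix(0, n, m)
  den <- matrix(0, n, m)
  for (du in -h:h) {
    ri <- max(1L, 1L - du):min(n, n - du)
    for (dv in -h:h) {
      w <- kernel[du + h + 1L, dv + h + 1L]
      if (w == 0) next
      ci <- max(1L, 1L - dv):min(m, m - dv)
      num[ri, ci] <- num[ri, ci] + w * v[ri + du, ci + dv]
      den[ri, ci] <- den[ri, ci] + w
    }
  }
  num / den
}

#' Predict each entry from the average of its neighbours
#'
#' Replaces every cell by the mean of its k x k neighbourhood excluding the
#' centre cell itself -- a predictor from the surroundings, not a denoiser.
#' Border cells use the truncated neighbourhood; symmetry is restored by
#' averaging with the transpose.
#'
#' @param m A \code{contact_matrix}.
#' @param k Odd neighbourhood side >= 3 (3 performs best for this method).
#' @return A \code{contact_matrix} of predictions.
#' @export
neighborhood_average_predict <- function(m, k = 3L) {
  stopifnot(inherits(m, "contact_matrix"))
  k <- as.integer(k)
  if (k %% 2L != 1L || k < 3L) stop("`k` must be odd and >= 3")
  kern <- matrix(1, k, k)
  kern[(k + 1L) %/% 2L, (k + 1L) %/% 2L] <- 0
  v <- m$values
  h <- (k - 1L) %/% 2L
  n <- nrow(v)
  num <- matrix(0, n, n); cntm <- matrix(0, n, n)
  for (du in -h:h) {
    ri <- max(1L, 1L - du):min(n, n - du)
    for (dv in -h:h) {
      if (du == 0L && dv == 0L) next
      ci <- max(1L, 1L - dv):min(n, n - dv)
      num[ri, ci] <- num[ri, ci] + v[ri + du, ci + dv]
      cntm[ri, ci] <- cntm[ri, ci] + 1
    }
  }
  out <- num / cntm
  out <- (out + t(out)) / 2
  res <- m
  res$values <- out
  res$is_normalized <- TRUE
  res
}

#' 2D Gaussian smoothing
#'
#' Convolution with a truncated, normalized isotropic Gaussian kernel;
#' borders renormalize the in-bounds kernel mass. Symmetric input gives
#' symmetric output.
#'
#' @param m A \code{contact_matrix}.
#' @param sigma Gaussian standard deviation in bins.
#' @param kernel_size Odd kernel side (default 5).
#' @return A smoothed \code{contact_matrix}.
#' @export
gaussian_smooth <- function(m, sigma = 1, kernel_size = 5L) {
  stopifnot(inherits(m, "contact_matrix"), sigma > 0)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  h <- (kernel_size - 1L) %/% 2L
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  out <- m
  v <- kernel_smooth_values(m$values, kern)
  out$values <- (v + t(v)) / 2   # clean floating-point asymmetry
  out$is_normalized <- TRUE
  out
}

#' 2D average (mean) smoothing
#'
#' Convolution with a uniform k x k kernel (centre included), truncated and
#' renormalized at the borders.
#'
#' @param m A \code{contact_matrix}.
#' @param kernel_size Odd kernel side.
#' @return A smoothed \code{contact_matrix}.
#' @export
mean_smooth <- function(m, kernel_size = 3L) {
  stopifnot(inherits(m, "contact_matrix"))
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  kern <- matrix(1 / kernel_size^2, kernel_size, kernel_size)
  out <- m
  v <- kernel_smooth_values(m$values, kern)
  out$values <- (v + t(v)) / 2
  out$is_normalized <- TRUE
  out
}

#' Perona-Malik anisotropic diffusion
#'
#' Iterates \code{u <- u + gamma * sum_{4-neighbours} g(grad) * grad} with
#' conductance \code{g(x) = exp(-(x / kappa)^2)} and reflective (zero-flux)
#' borders, which makes the update conservative: the total sum is preserved
#' across iterations. \code{gamma <= 0.25} is required for stability of the
#' 2D explicit scheme.
#'
#' @param m A \code{contact_matrix}.
#' @param n_iter Number of diffusion steps (default 10).
#' @param kappa Conductance scale (default 30).
#' @param gamma Step size in (0, 0.25] (default 0.2).
#' @return A diffused \code{contact_matrix}.
#' @export
anisotropic_diffusion <- function(m, n_iter = 10L, kappa = 30, gamma = 0.2) {
  stopifnot(inherits(m, "contact_matrix"), n_iter >= 0, kappa > 0)
  if (gamma <= 0 || gamma > 0.25) {
    stop("`gamma` must lie in (0, 0.25] for a stable 2D diffusion step")
  }
  u <- m$values
  n <- nrow(u)
  for (it in seq_len(n_iter)) {
    dN <- u[c(1L, seq_len(n - 1L)), ] - u
    dS <- u[c(seq_len(n - 1L) + 1L, n), ] - u
    dW <- u[, c(1L, seq_len(n - 1L))] - u
    dE <- u[, c(seq_len(n - 1L) + 1L, n)] - u
    u <- u + gamma * (exp(-(dN / kappa)^2) * dN + exp(-(dS / kappa)^2) * dS +
                      exp(-(dW / kappa)^2) * dW + exp(-(dE / kappa)^2) * dE)
  }
  out <- m
  out$values <- (u + t(u)) / 2
  out$is_normalized <- TRUE
  out
}

# Feature matrix for the random-forest regressor: flattened window x window
# neighbourhood of each (i, j) cell from the zero-padded matrix, plus the
# bin distance |i - j|. `cells` is a 2-column matrix of 1-based indices.
rf_features <- function(v, cells, window) {
  h <- (window - 1L) %/% 2L
  n <- nrow(v)
  P <- matrix(0, n + 2L * h, n + 2L * h)
  P[h + seq_len(n), h + seq_len(n)] <- v
  X <- matrix(0, nrow(cells), window^2 + 1L)
  col <- 0L
  for (du in -h:h) {
    for (dv in -h:h) {
      col <- col + 1L
      X[, col] <- P[cbind(cells[, 1L] + h + du, cells[, 2L] + h + dv)]
    }
  }
  X[, window^2 + 1L] <- abs(cells[, 1L] - cells[, 2L])
  colnames(X) <- c(sprintf("nb%03d", seq_len(window^2)), "dist")
  X
}

band_cells_upper <- function(n, kmax) {
  d <- bin_distance_matrix(n)
  which(upper.tri(d, diag = TRUE) & d <= kmax, arr.ind = TRUE)
}

#' Fit a random-forest neighbourhood regressor
#'
#' Trains a random forest (100 trees) mapping the flattened
#' \code{window x window} low-depth neighbourhood of a cell (zero-padded at
#' the borders) plus its bin distance to the high-depth centre value, over
#' all upper-triangle cells within the distance band.
#'
#' @param low,high \code{contact_matrix} pair of identical shape.
#' @param window Odd neighbourhood side (default 13, the network's
#'   receptive field).
#' @param max_dist Band width in bp (default 2 Mb).
#' @param ntree Number of trees.
#' @param max_cells Optional cap on the number of training cells (seeded
#'   subsample) to bound fitting time on large chromosomes.
#' @param seed RNG seed.
#' @return A fitted regressor handle of class \code{hic_rf}.
#' @export
rf_fit <- function(low, high, window = 13L, max_dist = 2e6,
                   ntree = 100L, max_cells = NULL, seed = NULL) {
  stopifnot(inherits(low, "contact_matrix"), inherits(high, "contact_matrix"))
  if (low$n_bins != high$n_bins) stop("`low` and `high` shapes differ")
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("`window` must be odd")
  kmax <- floor(max_dist / low$resolution)
  cells <- band_cells_upper(low$n_bins, kmax)
  y <- high$values[cells]
  res <- with_seed(seed, {
    keep <- seq_len(nrow(cells))
    if (!is.null(max_cells) && nrow(cells) > max_cells) {
      keep <- sample(nrow(cells), max_cells)
    }
    X <- rf_features(low$values, cells[keep, , drop = FALSE], window)
    yk <- y[keep]
    if (stats::var(yk) == 0) {
      warning("all training targets identical; returning a constant predictor")
      list(forest = NULL, constant = yk[1L])
    } else {
      list(forest = randomForest::randomForest(x = X, y = yk, ntree = ntree),
           constant = NULL)
    }
  })
  structure(list(forest = res$forest, constant = res$constant,
                 window = window, max_dist = max_dist),
            class = "hic_rf")
}

#' Predict a contact matrix with a fitted random forest
#'
#' Predicts every upper-triangle cell within the band, mirrors to the lower
#' triangle, and leaves out-of-band cells at their input values.
#'
#' @param handle A \code{hic_rf} from \code{\link{rf_fit}}.
#' @param low Low-depth \code{contact_matrix}.
#' @return A \code{contact_matrix} of predictions.
#' @export
rf_predict <- function(handle, low) {
  stopifnot(inherits(handle, "hic_rf"), inherits(low, "contact_matrix"))
  kmax <- floor(handle$max_dist / low$resolution)
  cells <- band_cells_upper(low$n_bins, kmax)
  pred <- if (is.null(handle$forest)) {
    rep(handle$constant, nrow(cells))
  } else {
    X <- rf_features(low$values, cells, handle$window)
    as.numeric(stats::predict(handle$forest, X))
  }
  v <- low$values
  v[cells] <- pred
  v[cells[, c(2L, 1L)]] <- pred
  out <- low
  out$values <- pmax(v, 0)
  out$is_normalized <- TRUE
  out
}
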
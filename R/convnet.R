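#' Valid 2D convolution (cross-correlation) of a channel stack
#'
#' Computes \code{out[y, x, k] = b[k] + sum_{c,u,v} filters[u, v, c, k] *
#' input[y + u - 1, x + v - 1, c]} -- the cross-correlation orientation
#' standard in deep learning, with no border padding, so the spatial size
#' shrinks by \code{f - 1} per axis.
#'
#' @param input Numeric matrix (H x W) or array (H x W x C).
#' @param filters Numeric array (f x f x C x K); a plain f x f matrix is
#'   promoted to a single filter over one channel.
#' @param biases Numeric vector of length K (default zeros).
#' @return Numeric array (H - f + 1) x (W - f + 1) x K.
#' @export
conv2d_valid <- function(input, filters, biases = NULL) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  if (is.matrix(filters)) filters <- array(filters, c(dim(filters), 1L, 1L))
  stopifnot(length(dim(input)) == 3L, length(dim(filters)) == 4L)
  f <- dim(filters)[1L]
  if (dim(filters)[2L] != f) stop("filters must be square")
  if (dim(filters)[3L] != dim(input)[3L]) {
    stop(sprintf("filter channels (%d) do not match input channels (%d)",
                 dim(filters)[3L], dim(input)[3L]))
  }
  if (f > min(dim(input)[1:2])) {
    stop(sprintf("filter size %d exceeds input size %d x %d",
                 f, dim(input)[1L], dim(input)[2L]))
  }
  K <- dim(filters)[4L]
  if (is.null(biases)) biases <- numeric(K)
  if (length(biases) != K) stop("need one bias per filter")
  A <- array(input, c(dim(input), 1L))
  Z <- conv_fwd_cpp(A, filters, as.numeric(biases))
  array(Z, dim(Z)[1:3])
}

#' Glorot-uniform initialization of the three-layer network
#'
#' Weights of each layer are drawn uniformly on \code{[-a, a]} with
#' \code{a = sqrt(6 / (fan_in + fan_out))}, \code{fan_in = C * f^2},
#' \code{fan_out = K * f^2}; all biases start at 0.
#'
#' @param f Integer vector of the three filter sides (default
#'   \code{c(5, 1, 9)}). All must be odd. The defaults give total border
#'   loss \code{sum(f - 1) = 12} and a 13 x 13 receptive field.
#' @param n Integer vector of the three filter counts (default
#'   \code{c(16, 16, 1)}); the last must be 1.
#' @param seed RNG seed (\code{NULL}: current stream).
#' @return An object of class \code{hicnet_params}: weight arrays
#'   \code{w1 (f1,f1,1,n1)}, \code{w2 (f2,f2,n1,n2)}, \code{w3
#'   (f3,f3,n2,1)} and zero biases \code{b1, b2, b3}.
#' @export
init_glorot <- function(f = c(5L, 1L, 9L), n = c(16L, 16L, 1L), seed = NULL) {
  f <- as.integer(f); n <- as.integer(n)
  stopifnot(length(f) == 3L, length(n) == 3L)
  if (any(f %% 2L == 0L) || any(f < 1L)) stop("filter sides must be odd and >= 1")
  if (n[3L] != 1L) stop("the output layer must have a single filter")
  chans <- c(1L, n[1L], n[2L])
  with_seed(seed, {
    w <- vector("list", 3L)
    for (l in 1:3) {
      fan_in <- chans[l] * f[l]^2
      fan_out <- n[l] * f[l]^2
      a <- sqrt(6 / (fan_in + fan_out))
      w[[l]] <- array(stats::runif(f[l]^2 * chans[l] * n[l], -a, a),
                      dim = c(f[l], f[l], chans[l], n[l]))
    }
    structure(list(w1 = w[[1L]], b1 = numeric(n[1L]),
                   w2 = w[[2L]], b2 = numeric(n[2L]),
                   w3 = w[[3L]], b3 = numeric(1L),
                   f = f, n = n),
              class = "hicnet_params")
  })
}

#' Total border loss of a parameter set
#' @param params A \code{hicnet_params}.
#' @return \code{sum(f - 1)}, the number of bins lost between input and
#'   output window sides.
#' @export
net_padding <- function(params) {
  stopifnot(inherits(params, "hicnet_params"))
  sum(params$f - 1L)
}

#' Receptive field of the network
#'
#' The side of the square of input cells that influences one output cell:
#' \code{f1 + f2 + f3 - 2} for three stacked valid convolutions. The default
#' architecture (5, 1, 9) has a 13 x 13 footprint, the neighbourhood size at
#' which per-distance prediction accuracy plateaus.
#'
#' @param params A \code{hicnet_params}.
#' @return Integer receptive-field side in bins.
#' @export
receptive_field <- function(params) {
  stopifnot(inherits(params, "hicnet_params"))
  sum(params$f) - 2L
}

# Batched forward pass. A: (N, N, 1, B). Returns activations when
# keep = TRUE (for backprop), else just the prediction array (T, T, 1, B).
forward_batch <- function(params, A, keep = FALSE) {
  Z1 <- conv_fwd_cpp(A, params$w1, params$b1)
  A1 <- pmax(Z1, 0); dim(A1) <- dim(Z1)
  Z2 <- conv_fwd_cpp(A1, params$w2, params$b2)
  A2 <- pmax(Z2, 0); dim(A2) <- dim(Z2)
  Z3 <- conv_fwd_cpp(A2, params$w3, params$b3)
  if (keep) list(A = A, A1 = A1, A2 = A2, Z1 = Z1, Z2 = Z2, pred = Z3)
  else Z3
}

#' Forward pass of the three-layer network on one input patch
#'
#' Applies \code{F3(F2(F1(X)))}: valid convolution + ReLU, pointwise
#' convolution + ReLU, then a final linear valid convolution. Deterministic
#' given the parameters.
#'
#' @param params A \code{hicnet_params}.
#' @param X Numeric N x N matrix with \code{N - sum(f - 1) >= 1}.
#' @return Numeric (N - padding) x (N - padding) prediction matrix.
#' @export
net_forward <- function(params, X) {
  stopifnot(inherits(params, "hicnet_params"), is.matrix(X))
  if (nrow(X) != ncol(X)) stop("input patch must be square")
  pad <- net_padding(params)
  if (nrow(X) - pad < 1L) {
    stop(sprintf("input side %d too small for total border loss %d (need >= %d)",
                 nrow(X), pad, pad + 1L))
  }
  out <- forward_batch(params, array(X, c(dim(X), 1L, 1L)))
  matrix(out, dim(out)[1L], dim(out)[2L])
}

#' Mean squared error between two grids
#' @param pred,target Numeric arrays of identical shape.
#' @return Mean over all cells of the squared difference.
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) && length(pred) != length(target)) {
    stop("`pred` and `target` shapes differ")
  }
  if (!is.null(dim(pred)) && !is.null(dim(target)) &&
      !identical(as.integer(dim(pred)), as.integer(dim(target)))) {
    stop(sprintf("`pred` (%s) and `target` (%s) shapes differ",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(target), collapse = "x")))
  }
  mean((pred - target)^2)
}

#' Training configuration for the enhancement network
#'
#' Training standardizes inputs and targets internally to unit
#' root-mean-square (the factors are folded back into the returned
#' parameters), so the learning rate is calibrated for unit-scale data
#' regardless of sequencing depth.
#'
#' @param learning_rate SGD step size (on RMS-standardized patches).
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of passes over the training patches.
#' @param momentum Classical momentum coefficient (0 disables).
#' @param seed RNG seed for initialization and shuffling.
#' @param validation_fraction Fraction of patches held out for validation
#'   when no chromosome split is available.
#' @param val_chrom Optional chromosome label to hold out as the validation
#'   set (used when patches from several chromosomes are pooled).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param select Which parameters to return: \code{"best"} (epoch with the
#'   lowest validation MSE) or \code{"final"} (last completed epoch).
#' @param input_scale Multiplier applied to inputs before the network
#'   (1 = raw counts; set to the inverse down-sampling fraction to pre-scale
#'   shallow counts to the deep-library scale).
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 3e-3, batch_size = 16L,
                         max_epochs = 300L, momentum = 0.9, seed = 1L,
                         validation_fraction = 0.1, val_chrom = NULL,
                         patience = 20L, select = c("best", "final"),
                         input_scale = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            momentum >= 0, momentum < 1,
            validation_fraction >= 0, validation_fraction < 1,
            patience >= 1, input_scale > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 momentum = momentum, seed = seed,
                 validation_fraction = validation_fraction,
                 val_chrom = val_chrom,
                 patience = as.integer(patience),
                 select = match.arg(select),
                 input_scale = input_scale),
            class = "train_config")
}

# Stack patch inputs/targets into (side, side, 1, B) arrays.
stack_patches <- function(patches, what = c("input", "target"), scale = 1) {
  what <- match.arg(what)
  mats <- lapply(patches, `[[`, what)
  side <- nrow(mats[[1L]])
  A <- array(0, c(side, side, 1L, length(mats)))
  for (i in seq_along(mats)) A[, , 1L, i] <- mats[[i]]
  if (scale != 1) A <- A * scale
  A
}

#' Train the enhancement network by mini-batch SGD on MSE
#'
#' Standard backpropagation with stochastic gradient descent (plus
#' classical momentum) minimizing the mean squared error between predicted
#' and true high-depth patches. Patches are split into training and
#' validation sets -- by chromosome when several are present (or
#' \code{cfg$val_chrom} is given), otherwise by a seeded random fraction --
#' and the parameters from the epoch with the best validation MSE are
#' returned. Training stops early after \code{cfg$patience} epochs without
#' validation improvement, and aborts with an error if the loss diverges.
#'
#' @param patches Patches with targets from \code{\link{extract_patches}}.
#' @param cfg A \code{\link{train_config}}.
#' @param params Optional initial \code{hicnet_params} (default: Glorot
#'   initialization of the standard 16/16/1, 5/1/9 architecture seeded from
#'   \code{cfg$seed}).
#' @return A list with \code{params} (best-validation
#'   \code{hicnet_params}) and \code{history} (data frame of per-epoch
#'   training and validation MSE).
#' @export
net_train <- function(patches, cfg = train_config(), params = NULL) {
  if (length(patches) == 0L) stop("no training patches")
  if (any(vapply(patches, function(p) is.null(p$target), logical(1L)))) {
    stop("every training patch needs a target")
  }
  if (is.null(params)) params <- init_glorot(seed = cfg$seed)
  tside0 <- nrow(patches[[1L]]$input) - net_padding(params)
  if (nrow(patches[[1L]]$target) != tside0) {
    stop(sprintf("target side %d does not match input side minus border loss (%d)",
                 nrow(patches[[1L]]$target), tside0))
  }

  chroms <- vapply(patches, `[[`, character(1L), "chrom")
  if (!is.null(cfg$val_chrom) || length(unique(chroms)) > 1L) {
    hold <- if (!is.null(cfg$val_chrom)) cfg$val_chrom else sort(unique(chroms))[1L]
    val_idx <- which(chroms == hold)
    if (length(val_idx) == 0L) stop("no patches from validation chromosome ", hold)
  } else {
    n_val <- max(1L, floor(cfg$validation_fraction * length(patches)))
    val_idx <- with_seed(cfg$seed, sample(length(patches), n_val))
  }
  tr_idx <- setdiff(seq_along(patches), val_idx)
  if (length(tr_idx) == 0L) stop("validation split leaves no training patches")

  Xtr <- stack_patches(patches[tr_idx], "input", cfg$input_scale)
  Ytr <- stack_patches(patches[tr_idx], "target")
  Xva <- stack_patches(patches[val_idx], "input", cfg$input_scale)
  Yva <- stack_patches(patches[val_idx], "target")
  m <- length(tr_idx)

  # Precondition the optimization: standardize inputs and targets to unit
  # root-mean-square. The first and last layers are linear in their
  # input/output, so both factors are folded back into the returned
  # parameters and the model maps raw counts to raw counts.
  s_in <- sqrt(mean(Xtr^2)); if (!is.finite(s_in) || s_in == 0) s_in <- 1
  s_out <- sqrt(mean(Ytr^2)); if (!is.finite(s_out) || s_out == 0) s_out <- 1
  Xtr <- Xtr / s_in; Xva <- Xva / s_in
  Ytr <- Ytr / s_out; Yva <- Yva / s_out

  vel <- list(w1 = params$w1 * 0, b1 = params$b1 * 0,
              w2 = params$w2 * 0, b2 = params$b2 * 0,
              w3 = params$w3 * 0, b3 = params$b3 * 0)
  best <- list(params = params, val = Inf, epoch = 0L)
  hist_tr <- hist_va <- numeric(0L)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(m)
      starts <- seq.int(1L, m, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, m)]
        B <- length(idx)
        act <- forward_batch(params, Xtr[, , , idx, drop = FALSE], keep = TRUE)
        resid <- act$pred - Ytr[, , , idx, drop = FALSE]
        ep_loss <- ep_loss + sum(resid^2)
        dZ3 <- 2 * resid / length(resid)
        g3 <- conv_bwd_cpp(act$A2, params$w3, dZ3)
        dZ2 <- g3$dA * (act$Z2 > 0)
        g2 <- conv_bwd_cpp(act$A1, params$w2, dZ2)
        dZ1 <- g2$dA * (act$Z1 > 0)
        g1 <- conv_bwd_cpp(act$A, params$w1, dZ1)

        lr <- cfg$learning_rate; mu <- cfg$momentum
        vel$w1 <- mu * vel$w1 - lr * g1$dW; params$w1 <- params$w1 + vel$w1
        vel$b1 <- mu * vel$b1 - lr * g1$db; params$b1 <- params$b1 + vel$b1
        vel$w2 <- mu * vel$w2 - lr * g2$dW; params$w2 <- params$w2 + vel$w2
        vel$b2 <- mu * vel$b2 - lr * g2$db; params$b2 <- params$b2 + vel$b2
        vel$w3 <- mu * vel$w3 - lr * g3$dW; params$w3 <- params$w3 + vel$w3
        vel$b3 <- mu * vel$b3 - lr * g3$db; params$b3 <- params$b3 + vel$b3
      }
      train_mse <- ep_loss / length(Ytr)
      val_mse <- mse_loss(forward_batch(params, Xva), Yva)
      if (!is.finite(train_mse) || !is.finite(val_mse)) {
        stop("training diverged (non-finite loss); try a smaller learning rate")
      }
      hist_tr <- c(hist_tr, train_mse)
      hist_va <- c(hist_va, val_mse)
      if (val_mse < best$val) {
        best <- list(params = params, val = val_mse, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  # fold the standardization into the parameters (layer 1 is linear in its
  # input, layer 3 in its output) and report losses on the raw-count scale
  out <- if (identical(cfg$select, "final")) params else best$params
  out$w1 <- out$w1 / s_in
  out$w3 <- out$w3 * s_out
  out$b3 <- out$b3 * s_out
  list(params = out,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_mse = hist_tr * s_out^2,
                            val_mse = hist_va * s_out^2),
       best_epoch = best$epoch, config = cfg)
}

#' Enhance a low-depth contact matrix with a trained network
#'
#' Divides the matrix into overlapping input windows, runs the forward pass
#' on each, and merges the predicted output windows back into a
#' chromosome-wide matrix, falling back to the input outside the covered
#' band and clipping negative predictions to 0.
#'
#' @param low Low-depth \code{contact_matrix}.
#' @param params Trained \code{hicnet_params}.
#' @param geom A \code{\link{patch_geometry}} whose padding matches
#'   \code{sum(params$f - 1)}.
#' @param input_scale Multiplier applied to inputs before the forward pass
#'   (use the value the model was trained with).
#' @return The enhanced \code{contact_matrix}.
#' @export
enhance <- function(low, params, geom = patch_geometry(),
                    input_scale = 1) {
  stopifnot(inherits(low, "contact_matrix"), inherits(params, "hicnet_params"))
  if (net_padding(params) != geom$padding) {
    stop(sprintf("network border loss %d does not match geometry padding %d",
                 net_padding(params), geom$padding))
  }
  patches <- extract_patches(low, NULL, geom)
  X <- stack_patches(patches, "input", input_scale)
  pred <- forward_batch(params, X)
  for (i in seq_along(patches)) {
    patches[[i]]$target <- matrix(pred[, , 1L, i], dim(pred)[1L], dim(pred)[2L])
  }
  merge_patches(patches, low$n_bins, geom, fallback = low)
}

#' Save a trained network to a self-describing JSON file
#'
#' Stores architecture (filter sides and counts), all weights and biases,
#' and optional provenance (training seed, input scale) in a single text
#' file re-loadable with \code{\link{load_hicnet}}.
#'
#' @param params A \code{hicnet_params}.
#' @param path Output path.
#' @param extra Optional named list of provenance fields to embed.
#' @export
save_hicnet <- function(params, path, extra = list()) {
  stopifnot(inherits(params, "hicnet_params"))
  obj <- list(format = "hicsr-model", version = 1L,
              f = params$f, n = params$n,
              w1 = as.numeric(params$w1), b1 = params$b1,
              w2 = as.numeric(params$w2), b2 = params$b2,
              w3 = as.numeric(params$w3), b3 = params$b3)
  obj <- c(obj, extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network saved by \code{\link{save_hicnet}}
#' @param path Path to the JSON model file.
#' @return A \code{hicnet_params}.
#' @export
load_hicnet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hicsr-model")) stop("not a hicsr model file: ", path)
  f <- as.integer(obj$f); n <- as.integer(obj$n)
  chans <- c(1L, n[1L], n[2L])
  p <- structure(list(
    w1 = array(obj$w1, c(f[1L], f[1L], chans[1L], n[1L])), b1 = as.numeric(obj$b1),
    w2 = array(obj$w2, c(f[2L], f[2L], chans[2L], n[2L])), b2 = as.numeric(obj$b2),
    w3 = array(obj$w3, c(f[3L], f[3L], chans[3L], n[3L])), b3 = as.numeric(obj$b3),
    f = f, n = n), class = "hicnet_params")
  p
}
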
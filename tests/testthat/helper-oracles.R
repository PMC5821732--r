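# Independent brute-force oracles and small fixture builders used across
# the test files. All oracles are deliberately naive (nested loops) and
# share no code with the implementation they check.

# Six-nested-loop valid cross-correlation.
brute_conv2d <- function(input, filters, biases) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  if (is.matrix(filters)) filters <- array(filters, c(dim(filters), 1L, 1L))
  H <- dim(input)[1L]; W <- dim(input)[2L]; C <- dim(input)[3L]
  f <- dim(filters)[1L]; K <- dim(filters)[4L]
  out <- array(0, c(H - f + 1L, W - f + 1L, K))
  for (k in 1:K) {
    for (y in 1:(H - f + 1L)) {
      for (x in 1:(W - f + 1L)) {
        s <- biases[k]
        for (c in 1:C) {
          for (u in 1:f) {
            for (v in 1:f) {
              s <- s + filters[u, v, c, k] * input[y + u - 1L, x + v - 1L, c]
            }
          }
        }
        out[y, x, k] <- s
      }
    }
  }
  out
}

# Per-cell kernel smoothing with truncated-and-renormalized borders.
brute_kernel_smooth <- function(v, kernel) {
  k <- nrow(kernel); h <- (k - 1L) %/% 2L
  n <- nrow(v); m <- ncol(v)
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      num <- 0; den <- 0
      for (du in -h:h) {
        for (dv in -h:h) {
          ii <- i + du; jj <- j + dv
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
            w <- kernel[du + h + 1L, dv + h + 1L]
            num <- num + w * v[ii, jj]
            den <- den + w
          }
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Per-cell neighbourhood mean excluding the centre, truncated at borders.
brute_neighbor_mean <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- nrow(v)
  out <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      s <- 0; cnt <- 0
      for (du in -h:h) {
        for (dv in -h:h) {
          if (du == 0 && dv == 0) next
          ii <- i + du; jj <- j + dv
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= n) {
            s <- s + v[ii, jj]
            cnt <- cnt + 1
          }
        }
      }
      out[i, j] <- s / cnt
    }
  }
  out
}

# Random symmetric non-negative integer count matrix.
random_count_matrix <- function(n, lambda = 5, resolution = 10000, seed = NULL) {
  draw <- function() {
    v <- matrix(0, n, n)
    ut <- upper.tri(v, diag = TRUE)
    v[ut] <- rpois(sum(ut), lambda)
    v <- v + t(v); diag(v) <- diag(v) / 2
    v
  }
  v <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  contact_matrix(v, resolution = resolution)
}

# Small training set whose target is the centre crop of the input patch.
# 20-bin windows keep the training tests fast; the architecture only
# requires the window to exceed its 12-bin border loss.
identity_patches <- function(n_patches, N = 20L, padding = 12L, seed = 1L) {
  half <- padding %/% 2L
  withr::with_seed(seed, {
    lapply(seq_len(n_patches), function(i) {
      x <- matrix(rpois(N * N, 8), N, N)
      list(row_off = 0L, col_off = 0L, input = x,
           target = x[(half + 1L):(N - half), (half + 1L):(N - half)],
           chrom = "chrS")
    })
  })
}
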
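test_that("valid convolution reproduces simple closed forms", {
  x <- matrix(c(1, 3, 2, 4), 2, 2, byrow = FALSE)  # [[1,2],[3,4]]
  # 1x1 identity kernel
  expect_equal(conv2d_valid(x, matrix(1, 1, 1))[, , 1], x)
  # all-ones 2x2 kernel sums the entries
  expect_equal(conv2d_valid(x, matrix(1, 2, 2))[1, 1, 1], 10)
  # bias shifts every output cell
  expect_equal(conv2d_valid(x, matrix(1, 1, 1), biases = 5)[, , 1], x + 5)
  # filter larger than input
  expect_error(conv2d_valid(x, matrix(1, 3, 3)), "exceeds")
  # channel mismatch
  expect_error(conv2d_valid(array(1, c(4, 4, 2)), array(1, c(3, 3, 1, 1))),
               "channels")
})

test_that("valid convolution matches the brute-force nested-loop oracle", {
  withr::with_seed(11, {
    for (i in 1:30) {
      H <- sample(4:9, 1); W <- sample(4:9, 1)
      C <- sample(1:3, 1); K <- sample(1:3, 1)
      f <- sample(1:min(3, H, W), 1)
      inp <- array(rnorm(H * W * C), c(H, W, C))
      filt <- array(rnorm(f * f * C * K), c(f, f, C, K))
      b <- rnorm(K)
      got <- conv2d_valid(inp, filt, b)
      want <- brute_conv2d(inp, filt, b)
      expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-6)
    }
  })
})

test_that("Glorot initialization respects bounds, zero biases and the seed", {
  p1 <- init_glorot(seed = 4)
  p2 <- init_glorot(seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1$w1, init_glorot(seed = 5)$w1))
  a1 <- sqrt(6 / (1 * 25 + 16 * 25))
  expect_true(all(abs(p1$w1) <= a1))
  a3 <- sqrt(6 / (16 * 81 + 1 * 81))
  expect_true(all(abs(p1$w3) <= a3))
  expect_true(all(p1$b1 == 0) && all(p1$b2 == 0) && all(p1$b3 == 0))
  expect_error(init_glorot(f = c(4, 1, 9)), "odd")
})

test_that("the default architecture maps 40x40 to 28x28 with a 13x13 footprint", {
  p <- init_glorot(seed = 1)
  out <- net_forward(p, matrix(rpois(1600, 5), 40, 40))
  expect_equal(dim(out), c(28L, 28L))
  expect_equal(receptive_field(p), 13L)
  expect_equal(net_padding(p), 12L)
  expect_equal(receptive_field(init_glorot(f = c(1, 1, 1), n = c(4, 4, 1))), 1L)
  expect_equal(receptive_field(init_glorot(f = c(3, 1, 1), n = c(4, 4, 1))), 3L)
  # zero parameters give zero output
  z <- p
  z$w1 <- z$w1 * 0; z$w2 <- z$w2 * 0; z$w3 <- z$w3 * 0
  expect_true(all(net_forward(z, matrix(rnorm(1600), 40, 40)) == 0))
  expect_error(net_forward(p, matrix(0, 12, 12)), "too small")
})

test_that("the forward pass equals its composition from conv2d_valid and ReLU", {
  p <- init_glorot(seed = 21)
  X <- matrix(rpois(1600, 6), 40, 40)
  a1 <- pmax(conv2d_valid(array(X, c(40, 40, 1)), p$w1, p$b1), 0)
  expect_true(all(a1 >= 0))
  a2 <- pmax(conv2d_valid(a1, p$w2, p$b2), 0)
  ref <- conv2d_valid(a2, p$w3, p$b3)[, , 1]
  expect_equal(net_forward(p, X), ref, tolerance = 1e-12)
})

test_that("pure convolution is translation consistent", {
  p <- init_glorot(seed = 33)
  big <- matrix(rpois(41 * 41, 4), 41, 41)
  o1 <- net_forward(p, big[1:40, 1:40])
  o2 <- net_forward(p, big[2:41, 2:41])
  expect_equal(o1[2:28, 2:28], o2[1:27, 1:27], tolerance = 1e-12)
})

test_that("mean squared error follows its definition", {
  a <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a + 2, a), 4)
  expect_equal(mse_loss(matrix(c(1, 3, 2, 4), 2, 2), matrix(0, 2, 2)), 7.5)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("the network learns the identity mapping", {
  patches <- identity_patches(48, seed = 2)
  p0 <- init_glorot(seed = 3)
  loss0 <- mean(vapply(patches, function(p)
    mse_loss(net_forward(p0, p$input), p$target), numeric(1)))
  fit <- net_train(patches, train_config(max_epochs = 300, seed = 3))
  lossT <- mean(vapply(patches, function(p)
    mse_loss(net_forward(fit$params, p$input), p$target), numeric(1)))
  expect_lt(lossT, 0.01 * loss0)
})

test_that("a single repeated patch is overfit with a non-increasing loss trend", {
  patches <- rep(identity_patches(1, seed = 5), 4)
  fit <- net_train(patches, train_config(max_epochs = 60, seed = 6,
                                         validation_fraction = 0.25))
  tr <- fit$history$train_mse
  win <- vapply(seq(1, length(tr) - 4, by = 5), function(i) mean(tr[i:(i + 4)]),
                numeric(1))
  expect_true(all(diff(win) <= 1e-8))
})

test_that("training is reproducible and divergence raises an informative error", {
  patches <- identity_patches(10, seed = 8)
  f1 <- net_train(patches, train_config(max_epochs = 5, seed = 9))
  f2 <- net_train(patches, train_config(max_epochs = 5, seed = 9))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_error(
    net_train(patches, train_config(learning_rate = 1e8, max_epochs = 30, seed = 9)),
    "learning rate")
  expect_error(net_train(list()), "no training patches")
})

test_that("a chromosome split is used for validation when available", {
  pa <- identity_patches(8, seed = 10)
  pb <- identity_patches(8, seed = 11)
  for (i in seq_along(pb)) pb[[i]]$chrom <- "chrV"
  fit <- net_train(c(pa, pb), train_config(max_epochs = 3, seed = 1,
                                           val_chrom = "chrV"))
  expect_s3_class(fit$params, "hicnet_params")
  expect_error(net_train(pa, train_config(max_epochs = 2, val_chrom = "chrQ")),
               "chrQ")
})

test_that("a planted linear blur is recovered by training", {
  # targets are a fixed 13x13 blur of the inputs; the trained network's
  # response should predict fresh blurred samples almost perfectly
  kern <- outer(dnorm(-6:6, sd = 2.5), dnorm(-6:6, sd = 2.5))
  kern <- kern / sum(kern)
  make <- function(n, seed) {
    withr::with_seed(seed, lapply(seq_len(n), function(i) {
      x <- matrix(rpois(400, 6), 20, 20)
      full <- conv2d_valid(x, array(kern, c(13, 13, 1, 1)))[, , 1]
      list(row_off = 0L, col_off = 0L, input = x, target = full, chrom = "chrS")
    }))
  }
  train_set <- make(120, 12)
  fit <- net_train(train_set, train_config(learning_rate = 1e-2,
                                           max_epochs = 300, seed = 14))
  # linearized end-to-end response at one output cell via impulse probes
  base <- matrix(6, 20, 20)
  f0 <- net_forward(fit$params, base)[4, 4]
  delta <- 1
  R <- matrix(0, 13, 13)
  for (u in 1:13) {
    for (v in 1:13) {
      pert <- base
      pert[3 + u, 3 + v] <- pert[3 + u, 3 + v] + delta
      R[u, v] <- (net_forward(fit$params, pert)[4, 4] - f0) / delta
    }
  }
  expect_lt(sum((R - kern)^2), 0.05 * sum(kern^2))
})

test_that("model serialization round-trips exactly", {
  p <- init_glorot(seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  save_hicnet(p, path, extra = list(seed = 17))
  q <- load_hicnet(path)
  expect_equal(q$w1, p$w1, tolerance = 1e-15)
  expect_equal(q$w3, p$w3, tolerance = 1e-15)
  expect_identical(q$f, p$f)
  expect_identical(q$n, p$n)
  expect_error(load_hicnet(withr::local_tempfile(lines = "{}")), "model file")
})

test_that("enhance merges predictions and falls back outside the band", {
  m <- random_count_matrix(96, lambda = 6, seed = 19)
  p <- init_glorot(seed = 20)
  p$w1 <- p$w1 * 0; p$w2 <- p$w2 * 0; p$w3 <- p$w3 * 0
  geom <- patch_geometry(max_dist_bins = 96L)
  out <- enhance(m, p, geom)
  cov <- patch_coverage(96L, geom)
  expect_true(all(out$values[cov] == 0))
  expect_identical(out$values[!cov], m$values[!cov])
  expect_identical(out$values, t(out$values))
  # geometry mismatch is refused
  expect_error(enhance(m, init_glorot(f = c(3, 1, 3), n = c(4, 4, 1)), geom),
               "border loss")
})
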
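test_that("connectivity has the right count, no duplicates, unit norms", {
  net <- visnet(tiny_layer_configs(), retina_dim = c(96, 96, 16), seed = 3)
  for (lay in net$layers) {
    expect_equal(ncol(lay$index), lay$config$n_afferents)
    dup <- apply(lay$index, 1, anyDuplicated)
    expect_true(all(dup == 0))
    expect_equal(rowSums(lay$weights^2), rep(1, nrow(lay$weights)),
                 tolerance = 1e-12)
  }
  # later-layer afferents lie within rf_radius of the corresponding point
  lay2 <- net$layers[[2]]
  g <- lay2$config$grid
  for (i in c(1, 77, g * g)) {
    pr <- (i - 1) %% g + 1; pc <- (i - 1) %/% g + 1
    r <- (lay2$index[i, ] - 1) %% g + 1
    c <- (lay2$index[i, ] - 1) %/% g + 1
    expect_true(all((r - pr)^2 + (c - pc)^2 <= lay2$config$rf_radius^2 + 1e-9))
  }
})

test_that("about 67% of layer-1 retinal afferents fall within the RF radius", {
  for (seed in 1:3) {
    net <- visnet(default_layer_configs(), retina_dim = c(128, 128, 16),
                  seed = seed)
    idx <- net$layers[[1]]$index
    g <- 32; H <- 128
    sp <- (idx - 1) %% (H * H)
    r <- sp %% H + 1
    c <- sp %/% H + 1
    pr <- ((seq_len(g * g) - 1) %% g + 1 - 0.5) * 4 + 0.5
    pc <- ((seq_len(g * g) - 1) %/% g + 1 - 0.5) * 4 + 0.5
    d2 <- (r - pr)^2 + (c - pc)^2
    frac <- mean(d2 <= 9^2)
    expect_gt(frac, 0.62)
    expect_lt(frac, 0.72)
  }
})

test_that("activation is the weighted sum of afferent rates", {
  idx <- matrix(1:2, 1, 2)
  w <- matrix(c(0.6, 0.8), 1, 2)
  expect_equal(activation(c(0.5, 0.5), idx, w), 0.7)
  expect_equal(activation(c(0, 0), idx, w), 0)
  # linear in the input rates
  set.seed(1)
  idx2 <- matrix(sample(1:20, 12), 3, 4)
  w2 <- matrix(runif(12), 3, 4)
  y <- runif(20)
  expect_equal(activation(3 * y, idx2, w2), 3 * activation(y, idx2, w2),
               tolerance = 1e-12)
})

test_that("the lateral-inhibition filter is built per its closed form", {
  K <- inhibition_kernel(1.38, 1.5)
  expect_equal(sum(K), 1, tolerance = 1e-12)
  hw <- (nrow(K) - 1) / 2
  # off-centre coefficient at distance 1
  expect_equal(K[hw + 1, hw + 2], -1.5 * exp(-1 / 1.38^2), tolerance = 1e-12)
  expect_equal(K[hw + 2, hw + 1], K[hw + 1, hw + 2])

  # delta = 0 is the identity filter
  set.seed(5)
  h <- matrix(runif(63), 9, 7)
  expect_equal(lateral_inhibition(h, 2, 0), h, tolerance = 1e-12)

  # convolution agrees with the direct-sum oracle (zero padding)
  got <- lateral_inhibition(h, 1.2, 1.5)
  want <- direct_conv2(h, inhibition_kernel(1.2, 1.5))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("percentile threshold is the linear-interpolation percentile", {
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(matrix(1:100, 10), 0), 1)
  expect_equal(percentile_threshold(rep(0.3, 50), 95), 0.3)
  # degenerate all-equal field: every cell fires exactly 0.5
  y <- sigmoid_rate(rep(0.3, 50), percentile_threshold(rep(0.3, 50), 95), 190)
  expect_equal(y, rep(0.5, 50))
})

test_that("the sigmoid behaves per its closed form", {
  expect_equal(sigmoid_rate(0.4, 0.4, 26), 0.5)
  r <- seq(0, 1, by = 0.01)
  expect_true(all(diff(sigmoid_rate(r, 0.5, 26)) > 0))
  # layer-1 slope 190 is a near-step beyond |r - alpha| >= 0.06
  expect_lt(sigmoid_rate(0.5 - 0.06, 0.5, 190), 1e-8)
  expect_gt(sigmoid_rate(0.5 + 0.06, 0.5, 190), 1 - 1e-8)
})

test_that("hebbian updates strengthen co-active synapses then rescale", {
  # toy: w = (1, 0), pre = (0, 1), post = 1, rate = 0.1
  w <- matrix(c(1, 0), 1, 2)
  got <- hebbian_update(w, matrix(c(0, 1), 1, 2), post = 1, rate = 0.1)
  expect_equal(as.numeric(got), c(1, 0.1) / sqrt(1.01), tolerance = 1e-12)
  expect_equal(sum(got^2), 1, tolerance = 1e-12)

  # silent postsynaptic layer leaves weights untouched (bit-identical)
  expect_identical(hebbian_update(w, matrix(c(0, 1), 1, 2), post = 0), w)
  expect_identical(hebbian_update(w, matrix(c(0, 1), 1, 2), post = 1, rate = 0), w)

  # norm conservation under arbitrary update sequences
  set.seed(11)
  W <- matrix(runif(50), 10, 5); W <- W / sqrt(rowSums(W^2))
  for (i in 1:25) {
    W <- hebbian_update(W, matrix(runif(50), 10, 5), post = runif(10), rate = 0.1)
    expect_equal(rowSums(W^2), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("forward sparseness tracks the layer percentiles", {
  p <- tiny_params()
  net <- visnet(tiny_layer_configs(), retina_dim = c(96, 96, 16), seed = 2)
  rt <- filter_image(compose_stimulus(p, 1, 1), gabor_bank())
  st <- forward_pass(net, rt)
  for (L in 1:4) {
    target <- (100 - net$configs[[L]]$percentile) / 100
    expect_lt(abs(mean(st[[L]]$y > 0.5) - target), 0.03)
    expect_true(all(st[[L]]$y >= 0 & st[[L]]$y <= 1))
  }
  # identical seed + stimulus: identical state
  st2 <- forward_pass(visnet(tiny_layer_configs(), c(96, 96, 16), seed = 2), rt)
  expect_identical(st[[4]]$y, st2[[4]]$y)
})

test_that("the compiled trainer agrees with the composed R operations", {
  p <- tiny_params()
  s <- build_stimulus_set(p)
  net <- visnet(tiny_layer_configs(), retina_dim = c(96, 96, 16), seed = 4)
  b <- gabor_bank()
  lay <- net$layers[[1]]
  G <- lapply(s$image, function(im)
    handnet:::gather_rates(filter_image(im, b), lay$index))
  W_cpp <- handnet:::train_layer_cpp(G, lay$weights, lay$inhib_kernel,
                                     lay$config$grid, lay$config$percentile,
                                     lay$config$beta, 0.1, 2L)
  # reference: the same schedule composed from the exported R operations
  W <- lay$weights
  for (e in 1:2) for (i in seq_along(G)) {
    h <- rowSums(W * G[[i]])
    r <- lateral_inhibition(matrix(h, 12, 12), lay$config$inhib_sigma,
                            lay$config$inhib_delta)
    alpha <- percentile_threshold(r, lay$config$percentile)
    y <- sigmoid_rate(as.numeric(r), alpha, lay$config$beta)
    W <- hebbian_update(W, G[[i]], y, 0.1)
  }
  expect_equal(W_cpp, W, tolerance = 1e-10)
})

test_that("training is inert at learning rate zero and conserves norms", {
  p <- tiny_params()
  s <- build_stimulus_set(p)
  net <- visnet(tiny_layer_configs(), retina_dim = c(96, 96, 16), seed = 5)
  net0 <- train_network(net, s, epochs_per_layer = 3, learning_rate = 0)
  expect_identical(net0$layers[[1]]$weights, net$layers[[1]]$weights)

  net1 <- train_network(net, s, epochs_per_layer = 2)
  for (lay in net1$layers)
    expect_equal(rowSums(lay$weights^2), rep(1, nrow(lay$weights)),
                 tolerance = 1e-9)
})

test_that("CT learning binds overlapping patterns to one winner (toy net)", {
  # two 6-unit input patterns sharing half of their active units, one output
  # row of two fully connected cells; competition via the percentile sigmoid
  p1 <- c(1, 1, 1, 1, 0, 0)
  p2 <- c(0, 0, 1, 1, 1, 1)
  idx <- matrix(rep(1:6, each = 2), 2, 6)
  set.seed(9)
  W <- matrix(runif(12), 2, 6); W <- W / sqrt(rowSums(W^2))
  W_oracle <- W
  step <- function(W, pat) {
    h <- activation(pat, idx, W)
    alpha <- percentile_threshold(h, 50)
    y <- sigmoid_rate(h, alpha, 50)
    hebbian_update(W, matrix(pat[idx], 2, 6), y, 0.1)
  }
  for (t in 1:20) for (pat in list(p1, p2)) W <- step(W, pat)
  # independent oracle: plain-arithmetic replay of the same dynamics
  for (t in 1:20) for (pat in list(p1, p2)) {
    h <- as.numeric(W_oracle %*% pat)
    alpha <- sort(h)[1] + 0.5 * diff(sort(h))
    y <- 1 / (1 + exp(-2 * 50 * (h - alpha)))
    if (any(y > 0)) {
      Wn <- W_oracle + 0.1 * y * matrix(pat, 2, 6, byrow = TRUE)
      W_oracle <- Wn / sqrt(rowSums(Wn^2))
    }
  }
  expect_equal(W, W_oracle, tolerance = 1e-10)
  # both patterns now drive the same winning output unit
  w1 <- which.max(activation(p1, idx, W))
  w2 <- which.max(activation(p2, idx, W))
  expect_equal(w1, w2)
})

test_that("recorded responses are complete, bounded and repeatable", {
  p <- tiny_params()
  s <- build_stimulus_set(p)
  net <- train_network(visnet(tiny_layer_configs(), c(96, 96, 16), seed = 6),
                       s, epochs_per_layer = 2)
  resp <- record_responses(net, s)
  expect_equal(dim(resp), c(144, 3, 3))
  expect_true(all(resp >= 0 & resp <= 1))
  expect_identical(unclass(record_responses(net, s)), unclass(resp))
})

test_that("an untrained network has no cells at the information ceiling", {
  # enough presentations that chance-level perfect selectivity is negligible
  p <- tiny_params(n_configs = 4, n_retinal = 6)
  s <- build_stimulus_set(p)
  net <- visnet(tiny_layer_configs(), c(96, 96, 16), seed = 7)
  resp <- record_responses(net, s)
  expect_equal(n_ceiling_cells(single_cell_information(resp)), 0)
})
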
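test_that("a perfectly selective cell attains the log2(N) ceiling exactly", {
  # responds 1 to one of 8 configurations at every retinal position: 3 bits
  m <- matrix(0, 8, 5); m[3, ] <- 1
  info <- single_cell_information(m, n_bins = 10)
  expect_equal(info$ceiling[1], 3)
  expect_equal(info$info[1], 3, tolerance = 1e-12)
  expect_equal(info$best_config[1], 3)
  expect_equal(n_ceiling_cells(info), 1)
  # the ceiling case is bin-invariant
  for (nb in c(2, 5, 16))
    expect_equal(single_cell_information(m, nb)$info[1], 3, tolerance = 1e-12)
})

test_that("a constant-rate cell carries zero information", {
  m <- matrix(0.7, 6, 4)
  expect_equal(single_cell_information(m)$info[1], 0, tolerance = 1e-12)
})

test_that("single-cell information matches the probability-table oracle", {
  # the spec'd 2-config toy plus random matrices
  m0 <- rbind(c(1, 1), c(0, 1))
  got <- single_cell_information(m0, n_bins = 10)
  want <- oracle_single_info(m0, n_bins = 10)
  expect_equal(attr(got, "per_stimulus")[1, ], want, tolerance = 1e-12)
  expect_equal(got$info[1], max(want), tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(runif(4 * 6), 4, 6)
    got <- single_cell_information(m, n_bins = 8)
    expect_equal(attr(got, "per_stimulus")[1, ], oracle_single_info(m, 8),
                 tolerance = 1e-12)
  }
})

test_that("information is bounded by [0, log2 N]", {
  set.seed(31)
  resp <- array(runif(20 * 5 * 4), c(20, 5, 4))
  info <- single_cell_information(resp)
  per <- attr(info, "per_stimulus")
  expect_true(all(per >= -1e-12))
  expect_true(all(per <= log2(5) + 1e-9))
  mc <- multiple_cell_information(resp, info, n_best = 3)
  expect_gte(mc$info, 0)
  expect_lte(mc$info, log2(5) + 1e-9)
})

test_that("a perfectly selective population decodes to the full ceiling", {
  N <- 3; R <- 4
  resp <- array(0, c(6, N, R))
  for (s in 1:N) { resp[2 * s - 1, s, ] <- 1; resp[2 * s, s, ] <- 1 }
  mc <- multiple_cell_information(resp, n_best = 2)
  expect_equal(mc$info, log2(N), tolerance = 1e-12)
  expect_equal(diag(mc$confusion), rep(1 / N, N))
})

test_that("label-shuffled responses carry almost no decoded information", {
  # a selective population whose (config, retinal) labels are permuted
  set.seed(77)
  N <- 4; R <- 10
  resp <- array(0, c(20, N, R))
  for (s in 1:N) resp[(5 * (s - 1) + 1):(5 * s), s, ] <- 1
  flat <- matrix(resp, 20, N * R)
  shuf <- array(flat[, sample(N * R)], c(20, N, R))
  mc <- multiple_cell_information(shuf, n_best = 5)
  # chance-level decoding carries only the estimator's small-sample bias,
  # about (N-1)^2 / (2 T ln 2) ~ 0.16 bits at T = 40 trials -- far below
  # the 2-bit ceiling a selective population attains
  expect_lte(mc$info, 0.25)
})

test_that("multiple-cell decoding matches exhaustive enumeration on a toy", {
  # 2 cells, 2 stimuli, 3 retinal positions; hand-enumerable decoding
  resp <- array(0, c(2, 2, 3))
  resp[1, 1, ] <- c(0.9, 0.8, 1.0); resp[1, 2, ] <- c(0.1, 0.0, 0.2)
  resp[2, 1, ] <- c(0.2, 0.1, 0.0); resp[2, 2, ] <- c(0.7, 0.9, 0.8)
  mc <- multiple_cell_information(resp, n_best = 2)
  # oracle: leave-one-out class means, dot-product argmax, Eq-11 sum
  conf <- matrix(0, 2, 2)
  for (s in 1:2) for (k in 1:3) {
    v <- resp[, s, k]
    scores <- sapply(1:2, function(sp) {
      M <- apply(resp[, sp, , drop = FALSE], 1, mean)
      if (sp == s) M <- (3 * M - v) / 2
      sum(M * v)
    })
    pick <- which.max(scores)
    conf[s, pick] <- conf[s, pick] + 1
  }
  P <- conf / 6
  I <- 0
  for (s in 1:2) for (sp in 1:2) if (P[s, sp] > 0)
    I <- I + P[s, sp] * log2(P[s, sp] / (sum(P[s, ]) * sum(P[, sp])))
  expect_equal(mc$info, I, tolerance = 1e-12)
  expect_equal(mc$confusion, P)
})

test_that("an all-zero population warns and reports zero information", {
  resp <- array(0, c(4, 2, 3))
  expect_warning(mc <- multiple_cell_information(resp, n_best = 2), "zero")
  expect_equal(mc$info, 0)
})

test_that("the hand-centred classifier accepts columns, rejects rows and blobs", {
  col_bar <- matrix(0, 7, 10); col_bar[3, ] <- 1   # one config, all positions
  row_bar <- matrix(0, 7, 10); row_bar[, 4] <- 1   # all configs, one position
  blobs <- matrix(0, 7, 10); blobs[1:2, 1:2] <- 1; blobs[6:7, 8:10] <- 1
  expect_true(classify_hand_centred(col_bar)$is_hand_centred)
  expect_false(classify_hand_centred(row_bar)$is_hand_centred)
  v <- classify_hand_centred(blobs)
  expect_false(v$is_hand_centred)
  expect_false(v$single_region)

  # fewer than two active entries can never be hand-centred
  single <- matrix(0, 7, 10); single[2, 2] <- 1
  expect_false(classify_hand_centred(single)$is_hand_centred)
  expect_false(classify_hand_centred(matrix(0, 7, 10))$is_hand_centred)
})

test_that("a matrix and its transpose cannot both be hand-centred", {
  set.seed(13)
  for (rep in 1:50) {
    m <- matrix(rbinom(48, 1, 0.25), 6, 8)
    a <- classify_hand_centred(m, lambda = 4)$is_hand_centred
    b <- classify_hand_centred(t(m), lambda = 4)$is_hand_centred
    expect_false(a && b)
  }
})

test_that("fractional RF counting follows the 67/33 rule and conserves mass", {
  # cell active at 10 positions of config 1 and 5 of config 2
  resp <- array(0, c(3, 4, 10))
  resp[1, 1, ] <- 1; resp[1, 2, 1:5] <- 1
  resp[2, 3, ] <- 1
  resp[3, 2, 1:2] <- 1
  # treat all three as hand-centred so the fractional rule itself is isolated
  verd <- tibble::tibble(cell = 1:3, is_hand_centred = TRUE)
  d <- rf_distribution(resp, verd)
  expect_equal(d$count, c(10 / 15, 5 / 15 + 1, 1, 0), tolerance = 1e-12)
  expect_equal(sum(d$count), attr(d, "n_cells"))
  expect_equal(attr(d, "n_cells"), 3)
})

test_that("the uniformity score is SD/mean and scale-invariant", {
  d <- tibble::tibble(location = 1:4, count = c(10, 10, 10, 20))
  expect_equal(uniformity_score(d), 5 / 12.5)
  expect_equal(uniformity_score(tibble::tibble(count = rep(7, 9))), 0)
  d2 <- d; d2$count <- d$count * 3.7
  expect_equal(uniformity_score(d2), uniformity_score(d), tolerance = 1e-12)
  expect_error(uniformity_score(tibble::tibble(count = c(0, 0))), "zero")
})
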
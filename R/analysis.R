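# Response analyses.
#
# All analyses consume a response_tensor (cells x configs x retinal
# positions) or a single cell's configs x retinal response matrix.  Stimuli
# (hand-object configurations) are taken as equiprobable throughout.

bin_rates <- function(rates, n_bins) {
  b <- floor(pmin(pmax(rates, 0), 1) * n_bins) + 1L
  b[b > n_bins] <- n_bins
  b
}

# per-stimulus information vector for one cell's N x R rate matrix
.cell_info <- function(m, n_bins) {
  N <- nrow(m); R <- ncol(m)
  b <- bin_rates(m, n_bins)
  counts <- matrix(0L, N, n_bins)
  for (s in seq_len(N)) counts[s, ] <- tabulate(b[s, ], n_bins)
  p_rs <- counts / R            # P(r | s)
  p_r <- colSums(counts) / (N * R)  # P(r)
  info <- numeric(N)
  for (s in seq_len(N)) {
    nz <- p_rs[s, ] > 0
    info[s] <- sum(p_rs[s, nz] * log2(p_rs[s, nz] / p_r[nz]))
  }
  info
}

#' Stimulus-specific single-cell information
#'
#' For each cell, firing rates are discretised into `n_bins` equal-width bins
#' on \[0, 1\] and the stimulus-specific information
#' `I(s, R) = sum_r P(r|s) log2( P(r|s) / P(r) )` is computed for every
#' stimulus `s` (hand-object configuration), with `P(r|s)` estimated over the
#' retinal presentations of `s` and stimuli equiprobable.  A cell's headline
#' value is its maximum over stimuli; the theoretical ceiling is `log2(N)`
#' bits, reached by a cell that responds to exactly one configuration at
#' every retinal position and never otherwise.
#'
#' @param responses A `response_tensor` (cells x N x R) or a single cell's
#'   `N x R` rate matrix.
#' @param n_bins Number of rate bins (>= 2).
#' @return A tibble with one row per cell: `cell`, `best_config` (stimulus
#'   attaining the maximum), `info` (bits) and `ceiling` (`log2(N)`).  The
#'   full cell x stimulus information matrix is attached as attribute
#'   `per_stimulus`.
#' @export
single_cell_information <- function(responses, n_bins = 10) {
  stopifnot(n_bins >= 2)
  if (is.matrix(responses)) responses <- array(responses, c(1, dim(responses)))
  d <- dim(responses)
  if (d[2] < 2) stop("at least 2 stimuli are required")
  per <- t(vapply(seq_len(d[1]),
                  function(i) .cell_info(matrix(responses[i, , ], d[2], d[3]), n_bins),
                  numeric(d[2])))
  best <- max.col(per, ties.method = "first")
  out <- tibble::tibble(cell = seq_len(d[1]),
                        best_config = best,
                        info = per[cbind(seq_len(d[1]), best)],
                        ceiling = log2(d[2]))
  attr(out, "per_stimulus") <- per
  attr(out, "n_bins") <- n_bins
  class(out) <- c("single_cell_info", class(out))
  out
}

#' Count cells at the information ceiling
#'
#' Cells whose maximal stimulus-specific information is within `tol` of the
#' `log2(N)` ceiling, i.e. perfectly selective, retinally invariant cells.
#'
#' @param info A [single_cell_information()] result (or a `response_tensor`,
#'   which is analysed first).
#' @param tol Tolerance on the ceiling, bits.
#' @param n_bins Bins used when `info` is a raw tensor.
#' @return Integer count.
#' @export
n_ceiling_cells <- function(info, tol = 1e-9, n_bins = 10) {
  if (inherits(info, "response_tensor")) info <- single_cell_information(info, n_bins)
  sum(info$info >= info$ceiling[1] - tol)
}

#' Decoded multiple-cell information
#'
#' Selects, for each stimulus, the `n_best` cells with the highest
#' stimulus-specific information about it, then decodes every single
#' presentation to a stimulus `s'` by highest dot-product similarity between
#' the population response vector and each stimulus's mean response vector
#' (the tested presentation is held out of its own stimulus mean).  The
#' confusion table `P(s, s')` accumulated over all presentations yields the
#' mutual information `I(S, S') = sum P(s,s') log2( P(s,s') / (P(s) P(s')) )`.
#'
#' @param responses A `response_tensor`.
#' @param info Optional precomputed [single_cell_information()] (recomputed
#'   when `NULL`).
#' @param n_best Cells per stimulus entering the decoder.
#' @param n_bins Bins for the single-cell analysis when `info` is `NULL`.
#' @return A list of class `multicell_info`: `info` (bits), `confusion`
#'   (the `P(s, s')` matrix), `cells` (indices used) and `ceiling`
#'   (`log2(N)`).
#' @export
multiple_cell_information <- function(responses, info = NULL, n_best = 5,
                                      n_bins = 10) {
  d <- dim(responses)
  N <- d[2]; R <- d[3]
  if (is.null(info)) info <- single_cell_information(responses, n_bins)
  stopifnot(d[1] >= n_best)
  per <- attr(info, "per_stimulus")
  cells <- sort(unique(as.integer(
    apply(per, 2, function(col) order(col, decreasing = TRUE)[seq_len(n_best)])
  )))
  pop <- responses[cells, , , drop = FALSE]  # n_cells x N x R
  if (all(pop == 0)) {
    warning("all-zero population response; multiple-cell information is 0")
    conf <- matrix(1 / N^2, N, N)
    return(structure(list(info = 0, confusion = conf, cells = cells,
                          ceiling = log2(N)), class = "multicell_info"))
  }
  means <- apply(pop, c(1, 2), mean)  # n_cells x N
  conf <- matrix(0, N, N)
  for (s in seq_len(N)) {
    for (k in seq_len(R)) {
      v <- pop[, s, k]
      M <- means
      M[, s] <- (R * means[, s] - v) / (R - 1)  # leave-one-out own-class mean
      scores <- as.numeric(crossprod(M, v))
      sp <- which.max(scores)
      conf[s, sp] <- conf[s, sp] + 1
    }
  }
  P <- conf / (N * R)
  ps <- rowSums(P); psp <- colSums(P)
  nz <- P > 0
  I <- sum(P[nz] * log2(P[nz] / (ps[row(P)[nz]] * psp[col(P)[nz]])))
  structure(list(info = I, confusion = P, cells = cells, ceiling = log2(N)),
            class = "multicell_info")
}

#' @export
print.multicell_info <- function(x, ...) {
  cat("<multicell_info> I(S, S') = ", format(x$info, digits = 4), " bits (ceiling ",
      format(x$ceiling, digits = 4), "), ", length(x$cells), " cells\n", sep = "")
  invisible(x)
}

# 8-connected components of a binary matrix (no wraparound)
.n_components <- function(b) {
  lab <- matrix(0L, nrow(b), ncol(b))
  comp <- 0L
  act <- which(b, arr.ind = TRUE)
  if (nrow(act) == 0) return(0L)
  for (i in seq_len(nrow(act))) {
    r0 <- act[i, 1]; c0 <- act[i, 2]
    if (lab[r0, c0] != 0L) next
    comp <- comp + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- comp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nrow(b) && cc >= 1 && cc <= ncol(b) &&
            b[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- comp
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  comp
}

#' Classify a cell as hand-centred
#'
#' The cell's `N x R` rate matrix is binarised at threshold `T`; the cell is
#' hand-centred when (1) its active entries form a single 8-connected region
#' and (2) its response profile is elongated along the retinal axis:
#' `Var(retinal) >= lambda * Var(hand-centred)` over the active entries, with
#' both coordinates rescaled to \[0, 1\] (sample variances).  Cells with
#' fewer than 2 active entries are not hand-centred.
#'
#' @param m One cell's `N x R` rate (or already-binary) matrix; rows are
#'   hand-centred configurations, columns retinal positions.
#' @param threshold Binarisation threshold `T`.
#' @param lambda Elongation sensitivity (the retinal variance must exceed
#'   `lambda` times the hand-centred variance).
#' @return A one-row tibble: `is_hand_centred`, `n_active`, `var_hand`,
#'   `var_retina`, `single_region`.
#' @export
classify_hand_centred <- function(m, threshold = 0.5, lambda = 4) {
  b <- m > threshold
  act <- which(b, arr.ind = TRUE)
  n <- nrow(act)
  if (n < 2) {
    return(tibble::tibble(is_hand_centred = FALSE, n_active = n,
                          var_hand = NA_real_, var_retina = NA_real_,
                          single_region = NA))
  }
  N <- nrow(b); R <- ncol(b)
  x <- if (N > 1) (act[, 1] - 1) / (N - 1) else rep(0.5, n)  # hand-centred axis
  y <- if (R > 1) (act[, 2] - 1) / (R - 1) else rep(0.5, n)  # retinal axis
  vh <- stats::var(x); vr <- stats::var(y)
  single <- .n_components(b) == 1L
  tibble::tibble(is_hand_centred = single && (vr >= lambda * vh),
                 n_active = n, var_hand = vh, var_retina = vr,
                 single_region = single)
}

#' Classify every cell of a response tensor
#'
#' @param responses A `response_tensor`.
#' @inheritParams classify_hand_centred
#' @return A tibble with one row per cell (columns as in
#'   [classify_hand_centred()], plus `cell`); the stack of binary matrices is
#'   attached as attribute `binary`.
#' @export
classify_cells <- function(responses, threshold = 0.5, lambda = 4) {
  d <- dim(responses)
  rows <- lapply(seq_len(d[1]), function(i) {
    classify_hand_centred(matrix(responses[i, , ], d[2], d[3]), threshold, lambda)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, cell = dplyr::row_number(), .before = 1)
  attr(out, "binary") <- responses > threshold
  attr(out, "threshold") <- threshold
  attr(out, "lambda") <- lambda
  out
}

#' Fractional receptive-field distribution over hand-centred locations
#'
#' Each hand-centred cell contributes fractionally to every configuration it
#' responds to: if `R_j` is the number of retinal positions at which the cell
#' is active for configuration `j`, the cell adds `R_j / sum_k R_k` to
#' location `j`.  A cell active at 10 retinal positions of one configuration
#' and 5 of a neighbour is thus counted as 67% / 33% hand-centred for the
#' two.  Total mass equals the number of hand-centred cells.
#'
#' @param responses A `response_tensor`.
#' @param verdicts Optional precomputed [classify_cells()] result.
#' @inheritParams classify_hand_centred
#' @return A tibble of class `rf_distribution` with columns `location` and
#'   `count`; the number of contributing cells is attribute `n_cells`.
#' @export
rf_distribution <- function(responses, verdicts = NULL, threshold = 0.5,
                            lambda = 4) {
  if (is.null(verdicts)) verdicts <- classify_cells(responses, threshold, lambda)
  bin <- attr(verdicts, "binary")
  if (is.null(bin)) bin <- responses > threshold
  d <- dim(bin)
  counts <- numeric(d[2])
  hc <- which(verdicts$is_hand_centred)
  for (i in hc) {
    Rj <- rowSums(matrix(bin[i, , ], d[2], d[3]))
    counts <- counts + Rj / sum(Rj)
  }
  out <- tibble::tibble(location = seq_len(d[2]), count = counts)
  attr(out, "n_cells") <- length(hc)
  class(out) <- c("rf_distribution", class(out))
  out
}

#' Uniformity of a receptive-field distribution
#'
#' Sample standard deviation of the per-location counts divided by their
#' mean; 0 for a perfectly uniform distribution, and invariant to rescaling
#' all counts.
#'
#' @param dist An [rf_distribution()] tibble (or any data frame with a
#'   `count` column of length >= 2).
#' @return The SD/mean ratio.
#' @export
uniformity_score <- function(dist) {
  counts <- dist$count
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m == 0) stop("mean count is zero; uniformity undefined")
  stats::sd(counts) / m
}
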
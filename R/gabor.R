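# Gabor hypercolumn front-end.
#
# A stimulus image is converted into a height x width x 16 tensor of
# non-negative V1 simple-cell responses: one channel per combination of 4
# orientations and 4 phases of a Gabor filter with wavelength 16 px.  Kernels
# are mean-subtracted (so uniform fields give zero response), applied by
# same-size zero-padded convolution, half-wave rectified, and the whole tensor
# is rescaled to a maximum of 1 per image.

#' Gabor filter bank parameters
#'
#' The standard bank: wavelength `lambda = 16` px, aspect ratio `gamma = 0.5`,
#' envelope `sigma = 0.56 * lambda`, orientations `{0, pi/4, pi/2, 3pi/4}` and
#' phases `{0, pi, -pi/2, pi/2}`, giving 16 channels.  Channel order is
#' theta-major: channel `(t - 1) * 4 + p` holds orientation `thetas[t]`, phase
#' `psis[p]`.
#'
#' @param lambda Carrier wavelength, pixels.
#' @param gamma Spatial aspect ratio (scales the off-axis coordinate).
#' @param sigma Gaussian envelope width, pixels.
#' @param thetas,psis Orientation and phase sets, radians.
#' @return An object of class `gabor_bank`: the parameters plus the list of
#'   sampled, mean-subtracted kernels.
#' @export
gabor_bank <- function(lambda = 16, gamma = 0.5, sigma = 0.56 * lambda,
                       thetas = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       psis = c(0, pi, -pi / 2, pi / 2)) {
  stopifnot(lambda > 0, sigma > 0, gamma > 0)
  grid <- tidyr::expand_grid(theta = thetas, psi = psis)
  kernels <- purrr::map2(grid$theta, grid$psi,
                         ~make_gabor_kernel(lambda, .x, .y, sigma, gamma))
  structure(list(lambda = lambda, gamma = gamma, sigma = sigma,
                 thetas = thetas, psis = psis,
                 channels = grid, kernels = kernels),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("<gabor_bank> ", length(x$kernels), " channels (",
      length(x$thetas), " orientations x ", length(x$psis),
      " phases), lambda = ", x$lambda, " px, sigma = ", x$sigma, "\n", sep = "")
  invisible(x)
}

#' Sample one Gabor kernel
#'
#' Evaluates `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`
#' on a square integer grid centred at the origin (x = column offset,
#' y = row offset), then subtracts the kernel mean so that a uniform input
#' yields zero response.
#'
#' @inheritParams gabor_bank
#' @param theta Orientation, radians.
#' @param psi Phase, radians.
#' @param half_width Support half-width in pixels; defaults to
#'   `ceil(5 * sigma / min(1, gamma))`-capped-to-`max_half_width`, which covers
#'   the envelope along both principal axes.
#' @param max_half_width Cap on the half-width (use the image size so very
#'   wide envelopes stay tractable).
#' @param mean_subtract Subtract the kernel mean (default) so the DC response
#'   is exactly zero.
#' @return A `(2 half_width + 1)` square matrix; rows index y, columns x.
#' @export
make_gabor_kernel <- function(lambda, theta, psi, sigma, gamma,
                              half_width = NULL, max_half_width = 128L,
                              mean_subtract = TRUE) {
  stopifnot(lambda > 0, sigma > 0)
  if (is.null(half_width))
    half_width <- min(max(ceiling(5 * sigma), ceiling(2 * sigma / min(1, gamma))),
                      max_half_width)
  s <- seq(-half_width, half_width)
  X <- matrix(rep(s, each = length(s)), length(s))  # column offset
  Y <- matrix(rep(s, length(s)), length(s))         # row offset
  xp <- X * cos(theta) + Y * sin(theta)
  yp <- -X * sin(theta) + Y * cos(theta)
  k <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + psi)
  if (mean_subtract) k <- k - mean(k)
  k
}

# Same-size 2-D convolution with zero padding, via FFT on a padded grid.
# `kernel_fft` may carry a precomputed kernel transform (see .conv_plan).
conv2_same <- function(image, kernel, plan = NULL) {
  di <- dim(image); dk <- dim(kernel)
  if (is.null(plan)) plan <- .conv_plan(dk, di)
  n1 <- plan$n1; n2 <- plan$n2
  pad <- matrix(0, n1, n2)
  pad[seq_len(di[1]), seq_len(di[2])] <- image
  KF <- if (!is.null(plan$kf)) plan$kf else .kernel_fft(kernel, n1, n2)
  full <- Re(stats::fft(stats::fft(pad) * KF, inverse = TRUE)) / (n1 * n2)
  hw1 <- (dk[1] - 1) %/% 2; hw2 <- (dk[2] - 1) %/% 2
  full[hw1 + seq_len(di[1]), hw2 + seq_len(di[2])]
}

# smallest 5-smooth (2^a 3^b 5^c) integer >= n, for fast mixed-radix FFTs
.good_fft_size <- function(n) {
  best <- Inf
  p5 <- 1
  while (p5 < 2 * n) {
    p35 <- p5
    while (p35 < 2 * n) {
      p2 <- p35 * 2^max(0, ceiling(log2(n / p35)))
      best <- min(best, max(p2, p35))
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

.conv_plan <- function(dim_kernel, dim_image, kernel = NULL) {
  n1 <- .good_fft_size(dim_image[1] + dim_kernel[1] - 1)
  n2 <- .good_fft_size(dim_image[2] + dim_kernel[2] - 1)
  kf <- if (!is.null(kernel)) .kernel_fft(kernel, n1, n2) else NULL
  list(n1 = n1, n2 = n2, kf = kf)
}

.kernel_fft <- function(kernel, n1, n2) {
  padk <- matrix(0, n1, n2)
  padk[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  stats::fft(padk)
}

# Precompute padded kernel FFTs for a bank at a fixed image size.
gabor_plan <- function(bank, image_dim) {
  dk <- dim(bank$kernels[[1]])
  lapply(bank$kernels, function(k) .conv_plan(dk, image_dim, k))
}

#' Filter an image into a Gabor hypercolumn tensor
#'
#' Convolves the image with every kernel of the bank (same-size output, zero
#' padding at the borders), half-wave rectifies the responses, and rescales
#' the whole tensor so its maximum is 1 (when any response is nonzero).  The
#' image mean is subtracted before convolution: the kernels are zero-mean, so
#' interior responses are unchanged, but the zero padding then no longer
#' manufactures a spurious high-contrast edge along the frame border (which
#' would otherwise dominate the response to any scene on a bright
#' background).  The four phases come in `psi` / `psi + pi` pairs whose
#' pre-rectification responses are sign-flipped, so rectified channels carry
#' opposite polarity lobes.
#'
#' @param image Grey-level matrix.
#' @param bank A [gabor_bank()].
#' @param rectify Half-wave rectify (default `TRUE`; set `FALSE` to inspect
#'   the signed linear responses).
#' @param normalise Rescale the rectified tensor to maximum 1 (default).
#' @param plan Precomputed FFT plan (internal; for repeated filtering).
#' @return A `nrow(image) x ncol(image) x n_channels` array of class
#'   `retina_tensor`; all entries are non-negative when `rectify = TRUE`.
#' @export
filter_image <- function(image, bank = gabor_bank(), rectify = TRUE,
                         normalise = TRUE, plan = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(plan)) plan <- gabor_plan(bank, dim(image))
  nch <- length(bank$kernels)
  out <- array(0, c(nrow(image), ncol(image), nch))
  # all kernels share one support size, so the padded image FFT is shared
  n1 <- plan[[1]]$n1; n2 <- plan[[1]]$n2
  pad <- matrix(0, n1, n2)
  pad[seq_len(nrow(image)), seq_len(ncol(image))] <- image - mean(image)
  IF <- stats::fft(pad)
  dk <- dim(bank$kernels[[1]])
  hw1 <- (dk[1] - 1) %/% 2; hw2 <- (dk[2] - 1) %/% 2
  ri <- hw1 + seq_len(nrow(image)); ci <- hw2 + seq_len(ncol(image))
  for (ch in seq_len(nch)) {
    full <- Re(stats::fft(IF * plan[[ch]]$kf, inverse = TRUE)) / (n1 * n2)
    out[, , ch] <- full[ri, ci]
  }
  if (rectify) out[out < 0] <- 0
  if (rectify && normalise) {
    m <- max(out)
    if (m > 0) out <- out / m
  }
  structure(out, class = "retina_tensor",
            channels = bank$channels)
}

#' @export
print.retina_tensor <- function(x, ...) {
  d <- dim(x)
  cat("<retina_tensor> ", d[1], " x ", d[2], " x ", d[3],
      " (max ", format(max(x), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Persist retina tensors with a manifest-keyed cache
#'
#' `filter_set()` filters every image of a stimulus set, consulting (and
#' populating) an optional on-disk cache keyed by a hash of the stimulus
#' manifest and bank parameters, so repeated runs on the same stimuli skip
#' the convolution stage.  Tensors are stored as flat binary doubles with a
#' JSON sidecar naming the dimensions and the (theta-major, psi-minor)
#' channel order.
#'
#' @param set A `stimulus_set`.
#' @param bank A [gabor_bank()].
#' @param cache_dir Directory for cached tensors (`NULL` disables caching).
#' @return A list of `retina_tensor` arrays, in the set's row order.
#' @export
filter_set <- function(set, bank = gabor_bank(), cache_dir = NULL) {
  plan <- gabor_plan(bank, dim(set$image[[1]]))
  key <- NULL
  if (!is.null(cache_dir)) {
    p <- attr(set, "params")
    key <- rlang::hash(list(unclass(p), bank$lambda, bank$gamma, bank$sigma,
                            bank$thetas, bank$psis))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  }
  lapply(seq_len(nrow(set)), function(i) {
    if (!is.null(key)) {
      base <- file.path(cache_dir, sprintf("%s_%03d_%03d", key,
                                           set$config[i], set$retinal[i]))
      if (file.exists(paste0(base, ".bin"))) return(read_retina_tensor(base))
      rt <- filter_image(set$image[[i]], bank, plan = plan)
      write_retina_tensor(rt, base)
      rt
    } else {
      filter_image(set$image[[i]], bank, plan = plan)
    }
  })
}

#' @rdname filter_set
#' @param tensor A `retina_tensor`.
#' @param base Path prefix; `<base>.bin` holds the values, `<base>.json` the
#'   dimensions and channel order.
#' @export
write_retina_tensor <- function(tensor, base) {
  meta <- list(dim = dim(tensor),
               channel_order = as.data.frame(attr(tensor, "channels")))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(base, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(tensor), con, size = 8)
  invisible(base)
}

#' @rdname filter_set
#' @export
read_retina_tensor <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  con <- file(paste0(base, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = prod(meta$dim), size = 8)
  structure(array(vals, meta$dim), class = "retina_tensor",
            channels = tibble::as_tibble(meta$channel_order))
}
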
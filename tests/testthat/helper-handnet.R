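# Shared fixtures: small, fast parameterisations and independent oracles.

# compact stimulus frame for fast tests (all geometry constraints satisfied)
tiny_params <- function(n_configs = 3, n_retinal = 3, arc_radius = 26, ...) {
  stimulus_params(image_height = 96, image_width = 96, target_diameter = 20,
                  n_configs = n_configs, arc_radius = arc_radius,
                  hand_anchor = c(54, 44),
                  n_retinal = n_retinal, shift_step = 2, ...)
}

# small four-layer network matched to the tiny 96x96 retina
tiny_layer_configs <- function() {
  list(
    layer_config(12, 30, 9,  1.38, 1.5, 99.2, 190),
    layer_config(12, 30, 6,  2.70, 1.5, 98.0, 40),
    layer_config(12, 30, 6,  4.00, 1.6, 88.0, 75),
    layer_config(12, 30, 6,  6.00, 1.4, 90.0, 26)
  )
}

tiny_experiment_config <- function(n_configs = 3, n_retinal = 3,
                                   epochs_per_layer = 5, ...) {
  experiment_config(stimulus = tiny_params(n_configs, n_retinal),
                    layers = tiny_layer_configs(),
                    epochs_per_layer = epochs_per_layer, ...)
}

# direct O(n^2 k^2) same-size zero-padded convolution (oracle for the FFT path)
direct_conv2 <- function(image, kernel) {
  hi <- nrow(image); wi <- ncol(image)
  hw1 <- (nrow(kernel) - 1) %/% 2; hw2 <- (ncol(kernel) - 1) %/% 2
  out <- matrix(0, hi, wi)
  for (i in seq_len(hi)) for (j in seq_len(wi)) {
    acc <- 0
    for (a in -hw1:hw1) for (b in -hw2:hw2) {
      ii <- i - a; jj <- j - b
      if (ii >= 1 && ii <= hi && jj >= 1 && jj <= wi)
        acc <- acc + kernel[a + hw1 + 1, b + hw2 + 1] * image[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# literal probability-table evaluation of the stimulus-specific information
# for one N x R rate matrix (independent of the package's implementation)
oracle_single_info <- function(m, n_bins = 10) {
  N <- nrow(m); R <- ncol(m)
  bin_of <- function(r) min(floor(r * n_bins) + 1, n_bins)
  info <- numeric(N)
  for (s in 1:N) {
    I <- 0
    for (b in 1:n_bins) {
      p_rs <- sum(sapply(m[s, ], bin_of) == b) / R
      p_r <- sum(sapply(as.numeric(m), bin_of) == b) / (N * R)
      if (p_rs > 0) I <- I + p_rs * log2(p_rs / p_r)
    }
    info[s] <- I
  }
  info
}

# pixel set of the target disc in a stimulus image
target_pixels <- function(img, params) {
  which(abs(img - params$target_intensity) < 1e-12, arr.ind = TRUE)
}
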
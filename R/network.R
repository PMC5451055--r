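# Four-layer competitive hierarchy.
#
# Each layer is a square grid of rate-coded neurons receiving a fixed number
# of afferent synapses from the previous layer (the retina for layer 1).
# Dynamics per presentation: linear activation (dot product of weights and
# afferent rates), lateral inhibition (convolution with a
# centre-excitatory / surround-inhibitory filter), then contrast enhancement
# by a sigmoid whose threshold is set at a per-layer percentile of the
# inhibited activations so that sparseness is controlled explicitly.
# Learning is purely Hebbian with synaptic scaling: after every presentation
# each neuron's weight vector is rescaled to unit sum of squares.

#' Per-layer configuration
#'
#' @param grid Neurons per side of the square layer.
#' @param n_afferents Synapses per neuron onto the previous layer.
#' @param rf_radius Receptive-field radius in units of the afferent layer's
#'   grid.  For layer 1 this is the radius containing approximately 67% of the
#'   Gaussian-distributed retinal connections; for later layers afferents are
#'   drawn uniformly within this radius.
#' @param inhib_sigma,inhib_delta Width and contrast of the lateral-inhibition
#'   filter.
#' @param percentile Percentile of the inhibited activations at which the
#'   sigmoid threshold is set (e.g. 99.2 leaves roughly 0.8% of cells above
#'   threshold).
#' @param beta Sigmoid slope.
#' @return An object of class `layer_config`.
#' @export
layer_config <- function(grid = 32, n_afferents = 100, rf_radius = 16,
                         inhib_sigma = 1.5, inhib_delta = 1.5,
                         percentile = 90, beta = 26) {
  stopifnot(grid >= 2, n_afferents >= 1, rf_radius > 0,
            inhib_sigma > 0, inhib_delta >= 0,
            percentile >= 0, percentile <= 100, beta > 0)
  structure(list(grid = as.integer(grid), n_afferents = as.integer(n_afferents),
                 rf_radius = rf_radius, inhib_sigma = inhib_sigma,
                 inhib_delta = inhib_delta, percentile = percentile,
                 beta = beta),
            class = "layer_config")
}

#' Standard four-layer configuration
#'
#' The default network: four 32x32 layers with 100 afferents per neuron,
#' receptive-field radii 9 (layer 1, on the 128x128 retina) and 16 (layers
#' 2-4), lateral-inhibition widths 1.38/2.7/4.0/6.0 with contrasts
#' 1.5/1.5/1.6/1.4, and sigmoid percentiles 99.2/98/88/90 with slopes
#' 190/40/75/26.
#'
#' @return A list of four [layer_config()] objects.
#' @export
default_layer_configs <- function() {
  list(
    layer_config(32, 100, 9,  1.38, 1.5, 99.2, 190),
    layer_config(32, 100, 16, 2.70, 1.5, 98.0, 40),
    layer_config(32, 100, 16, 4.00, 1.6, 88.0, 75),
    layer_config(32, 100, 16, 6.00, 1.4, 90.0, 26)
  )
}

#' Lateral-inhibition filter
#'
#' Off-centre coefficients are `-delta * exp(-(a^2 + b^2) / sigma^2)` for
#' offsets `(a, b)`; the centre coefficient is 1 minus the sum of all
#' off-centre coefficients, so the filter sums to exactly 1.  Support is
#' truncated at half-width `ceil(3 sigma)`.
#'
#' @param sigma Filter width.
#' @param delta Filter contrast (`delta = 0` gives the identity filter).
#' @return A square matrix of odd side length.
#' @export
inhibition_kernel <- function(sigma, delta) {
  hw <- ceiling(3 * sigma)
  s <- seq(-hw, hw)
  K <- -delta * exp(-outer(s^2, s^2, `+`) / sigma^2)
  K[hw + 1, hw + 1] <- 0
  K[hw + 1, hw + 1] <- 1 - sum(K)
  K
}

#' Apply lateral inhibition to a layer's activation field
#'
#' Convolves the 2-D activation field with the [inhibition_kernel()]
#' (same-size output, zero padding at the layer borders).
#'
#' @param h 2-D activation field.
#' @param sigma,delta Filter parameters, see [inhibition_kernel()].
#' @return Matrix of inhibited activations `r`, same shape as `h`.
#' @export
lateral_inhibition <- function(h, sigma, delta) {
  stopifnot(is.matrix(h))
  conv2_same(h, inhibition_kernel(sigma, delta))
}

#' Percentile threshold of an activation field
#'
#' Linear-interpolation percentile (type-7 quantile) of all values in the
#' field; used as the sigmoid threshold `alpha` so that approximately
#' `100 - percentile` percent of neurons fire above 0.5.
#'
#' @param field Numeric vector or matrix of activations.
#' @param percentile Percentile in `[0, 100]`.
#' @return The threshold `alpha` (a single number).
#' @export
percentile_threshold <- function(field, percentile) {
  stats::quantile(as.numeric(field), percentile / 100, type = 7, names = FALSE)
}

#' Sigmoid contrast enhancement
#'
#' `y = 1 / (1 + exp(-2 beta (r - alpha)))`: firing rate 0.5 at the threshold,
#' saturating towards 0/1 at a speed set by the slope `beta`.
#'
#' @param r Inhibited activations.
#' @param alpha Threshold.
#' @param beta Slope (> 0).
#' @return Firing rates in `[0, 1]`, same shape as `r`.
#' @export
sigmoid_rate <- function(r, alpha, beta) {
  stopifnot(beta > 0)
  1 / (1 + exp(-2 * beta * (r - alpha)))
}

#' Linear activation of a layer
#'
#' `h_i = sum_j w_ij y_j` over each neuron's afferent synapses.
#'
#' @param prev_rates Numeric vector (or array, flattened) of afferent-layer
#'   firing rates.
#' @param index Integer matrix (`n_neurons x n_afferents`) of afferent indices
#'   into `prev_rates`.
#' @param weights Numeric matrix, same shape as `index`.
#' @return Numeric vector of activations `h`, one per neuron.
#' @export
activation <- function(prev_rates, index, weights) {
  stopifnot(all(dim(index) == dim(weights)))
  g <- matrix(as.numeric(prev_rates)[index], nrow(index), ncol(index))
  rowSums(weights * g)
}

#' Hebbian update with synaptic scaling
#'
#' `w_ij <- w_ij + rate * y_i * y_j` for connected pairs only, followed by
#' rescaling of each neuron's weight vector to unit sum of squares.  When the
#' learning rate is zero or no postsynaptic neuron is active, the weights are
#' returned untouched (including the rescaling, so the update is exactly the
#' identity).
#'
#' @param weights Weight matrix (`n_neurons x n_afferents`).
#' @param pre Gathered presynaptic rates, same shape as `weights` (rate of the
#'   afferent at each synapse), or a vector of afferent-layer rates together
#'   with `index`.
#' @param post Postsynaptic firing-rate vector (`n_neurons`).
#' @param rate Learning rate.
#' @param index Optional afferent index matrix used to gather `pre` when it is
#'   given as a full afferent-layer rate vector.
#' @return Updated weight matrix with unit-sum-of-squares rows.
#' @export
hebbian_update <- function(weights, pre, post, rate = 0.1, index = NULL) {
  if (!is.null(index))
    pre <- matrix(as.numeric(pre)[index], nrow(index), ncol(index))
  stopifnot(all(dim(pre) == dim(weights)), length(post) == nrow(weights))
  if (rate == 0 || !any(post > 0)) return(weights)
  w <- weights + rate * as.numeric(post) * pre
  w / sqrt(rowSums(w * w))
}

#' Construct a network with random connectivity
#'
#' Layer-1 afferents are drawn from the retina with a Gaussian profile of
#' connection probability around the topologically corresponding retinal
#' point, with the Gaussian width chosen so that approximately 67% of
#' connections fall within `rf_radius`; the channel of each afferent is
#' uniform.  Later layers draw afferents uniformly from neurons within
#' `rf_radius` of the corresponding point.  Sampling is without replacement
#' (no duplicate synapses) and clipped at the layer borders (no torus).
#' Initial weights are uniform on (0, 1), then rescaled to unit sum of
#' squares per neuron.
#'
#' @param configs List of [layer_config()] objects, one per layer (input to
#'   output).
#' @param retina_dim `(height, width, channels)` of the retina tensor feeding
#'   layer 1.
#' @param seed Integer seed for connectivity and initial weights; the full
#'   simulation is a pure function of (stimulus parameters, layer configs,
#'   seed).
#' @return An object of class `visnet`: per-layer index/weight matrices plus
#'   cached lateral-inhibition operators.
#' @export
visnet <- function(configs = default_layer_configs(),
                   retina_dim = c(128, 128, 16), seed = 1) {
  stopifnot(length(configs) >= 1, length(retina_dim) == 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  layers <- vector("list", length(configs))
  for (L in seq_along(configs)) {
    cfg <- configs[[L]]
    idx <- if (L == 1) {
      sample_retina_afferents(cfg, retina_dim)
    } else {
      sample_uniform_afferents(cfg, configs[[L - 1]]$grid)
    }
    n <- cfg$grid^2
    w <- matrix(stats::runif(n * cfg$n_afferents), n, cfg$n_afferents)
    w <- w / sqrt(rowSums(w * w))
    K <- inhibition_kernel(cfg$inhib_sigma, cfg$inhib_delta)
    layers[[L]] <- list(config = cfg, index = idx, weights = w,
                        inhib_plan = .conv_plan(dim(K), c(cfg$grid, cfg$grid), K),
                        inhib_kernel = K)
  }
  structure(list(configs = configs, retina_dim = as.integer(retina_dim),
                 seed = seed, layers = layers, trained = FALSE),
            class = "visnet")
}

#' @export
print.visnet <- function(x, ...) {
  cat("<visnet> ", length(x$layers), " layers (",
    paste(vapply(x$configs, function(c) paste0(c$grid, "x", c$grid), ""),
          collapse = " -> "),
    "), retina ", paste(x$retina_dim, collapse = "x"),
    ", seed ", x$seed, if (x$trained) ", trained" else ", untrained", "\n",
    sep = "")
  invisible(x)
}

# Gaussian width such that a fraction `q` of a 2-D isotropic Gaussian falls
# within radius R: 1 - exp(-R^2 / (2 sigma^2)) = q.
gaussian_rf_sigma <- function(rf_radius, q = 0.67) {
  rf_radius / sqrt(2 * log(1 / (1 - q)))
}

# Layer-1 afferents: weighted sampling without replacement over (x, y, channel)
# retinal units, Gaussian in space, uniform over channels.
sample_retina_afferents <- function(cfg, retina_dim) {
  H <- retina_dim[1]; W <- retina_dim[2]; C <- retina_dim[3]
  g <- cfg$grid; n_aff <- cfg$n_afferents
  sc <- H / g
  # rf_radius is specified in retinal pixels for layer 1 (Table-1 convention)
  sg <- gaussian_rf_sigma(cfg$rf_radius, q = 0.67)
  win <- ceiling(3.5 * sg)
  offs <- seq(-win, win + 1)  # +1 covers fractional centres on both sides
  OG <- expand.grid(dr = offs, dc = offs)
  idx <- matrix(0L, g * g, n_aff)
  for (i in seq_len(g * g)) {
    pr <- (i - 1) %% g + 1; pc <- (i - 1) %/% g + 1
    cr <- (pr - 0.5) * sc + 0.5; cc <- (pc - 0.5) * sc + 0.5
    # integer candidate grid around the (possibly fractional) centre;
    # weights use the exact distances so the 67%-within-radius property holds
    rr <- floor(cr) + OG$dr; cc2 <- floor(cc) + OG$dc
    ok <- rr >= 1 & rr <= H & cc2 >= 1 & cc2 <= W
    spatial <- (cc2[ok] - 1) * H + rr[ok]
    wk <- exp(-((rr[ok] - cr)^2 + (cc2[ok] - cc)^2) / (2 * sg^2))
    ns <- length(spatial)
    if (ns * C < n_aff) stop("receptive field too small to supply ", n_aff, " afferents")
    # weighted sampling without replacement over ns*C units
    # (Efraimidis-Spirakis keys; channel weight uniform)
    keys <- stats::runif(ns * C)^(1 / rep(wk, C))
    top <- order(keys, decreasing = TRUE)[seq_len(n_aff)]
    ch <- (top - 1) %/% ns
    sp <- spatial[(top - 1) %% ns + 1]
    idx[i, ] <- as.integer(ch * (H * W) + sp)
  }
  idx
}

# Later layers: uniform sampling without replacement within rf_radius.
sample_uniform_afferents <- function(cfg, prev_grid) {
  g <- cfg$grid; n_aff <- cfg$n_afferents
  win <- floor(cfg$rf_radius)
  offs <- seq(-win, win)
  OG <- expand.grid(dr = offs, dc = offs)
  OG <- OG[OG$dr^2 + OG$dc^2 <= cfg$rf_radius^2, ]
  idx <- matrix(0L, g * g, n_aff)
  sc <- prev_grid / g
  for (i in seq_len(g * g)) {
    pr <- (i - 1) %% g + 1; pc <- (i - 1) %/% g + 1
    cr <- round((pr - 0.5) * sc + 0.5); cc <- round((pc - 0.5) * sc + 0.5)
    rr <- cr + OG$dr; cc2 <- cc + OG$dc
    ok <- rr >= 1 & rr <= prev_grid & cc2 >= 1 & cc2 <= prev_grid
    cand <- (cc2[ok] - 1L) * prev_grid + rr[ok]
    if (length(cand) < n_aff) stop("receptive field too small to supply ", n_aff, " afferents")
    idx[i, ] <- as.integer(sample(cand, n_aff))
  }
  idx
}

# One layer's forward dynamics from gathered afferent rates (n x n_aff).
layer_forward <- function(gathered, weights, layer) {
  cfg <- layer$config
  h <- rowSums(weights * gathered)
  hf <- matrix(h, cfg$grid, cfg$grid)
  r <- conv2_same(hf, layer$inhib_kernel, layer$inhib_plan)
  alpha <- percentile_threshold(r, cfg$percentile)
  y <- sigmoid_rate(r, alpha, cfg$beta)
  list(h = h, r = as.numeric(r), y = as.numeric(y), alpha = alpha)
}

gather_rates <- function(rates, index) {
  matrix(as.numeric(rates)[index], nrow(index), ncol(index))
}

#' Forward pass through the hierarchy
#'
#' Applies activation, lateral inhibition, percentile thresholding and the
#' sigmoid for layers `1..up_to_layer` with learning off.
#'
#' @param net A [visnet()] network.
#' @param retina A `retina_tensor` from [filter_image()] (dimensions must
#'   match `net$retina_dim`).
#' @param up_to_layer Last layer to evaluate.
#' @return A list of class `network_state`, one element per evaluated layer
#'   with fields `h` (activations), `r` (after inhibition), `y` (firing
#'   rates) and `alpha` (threshold used).
#' @export
forward_pass <- function(net, retina, up_to_layer = length(net$layers)) {
  stopifnot(all(dim(retina) == net$retina_dim))
  prev <- as.numeric(retina)
  states <- vector("list", up_to_layer)
  for (L in seq_len(up_to_layer)) {
    lay <- net$layers[[L]]
    st <- layer_forward(gather_rates(prev, lay$index), lay$weights, lay)
    states[[L]] <- st
    prev <- st$y
  }
  class(states) <- "network_state"
  states
}

#' Train the network layer by layer
#'
#' For each layer in turn (input to output), the full stimulus set is
#' presented `epochs_per_layer` times in its stored order; each presentation
#' drives a forward pass up to the layer being trained, a Hebbian update of
#' that layer's afferent weights, and synaptic rescaling to unit
#' sum-of-squares.  Lower layers are frozen while a layer trains, so their
#' responses to each image are computed once and cached.
#'
#' @param net A [visnet()] network.
#' @param stimulus_set A [build_stimulus_set()] tibble (presentation order =
#'   row order).
#' @param bank Gabor bank for the V1 front-end.
#' @param epochs_per_layer Training epochs per layer.
#' @param learning_rate Hebbian learning rate.
#' @param verbose Print per-layer progress.
#' @return The trained `visnet` (with `trained = TRUE`).
#' @export
train_network <- function(net, stimulus_set, bank = gabor_bank(),
                          epochs_per_layer = 40, learning_rate = 0.1,
                          verbose = FALSE) {
  if (epochs_per_layer == 0 || learning_rate == 0) {
    net$trained <- TRUE
    return(net)
  }
  plan <- gabor_plan(bank, dim(stimulus_set$image[[1]]))
  n_img <- nrow(stimulus_set)
  # gathered layer-1 inputs per image, in presentation order
  G <- lapply(stimulus_set$image, function(im) {
    gather_rates(filter_image(im, bank, plan = plan), net$layers[[1]]$index)
  })
  Y <- NULL
  for (L in seq_along(net$layers)) {
    lay <- net$layers[[L]]
    if (L > 1) {
      G <- lapply(seq_len(n_img), function(i) gather_rates(Y[, i], lay$index))
    }
    cfg <- lay$config
    K <- lay$inhib_kernel
    W <- train_layer_cpp(G, lay$weights, K,
                         cfg$grid, cfg$percentile, cfg$beta,
                         learning_rate, as.integer(epochs_per_layer))
    net$layers[[L]]$weights <- W
    lay$weights <- W
    # cache this layer's responses for the next layer's training
    Y <- vapply(G, function(g) layer_forward(g, W, lay)$y, numeric(cfg$grid^2))
    if (verbose)
      message("layer ", L, " trained (", epochs_per_layer, " epochs, ",
              n_img, " images/epoch)")
  }
  net$trained <- TRUE
  net
}

#' Record output-layer responses to a test set
#'
#' Runs a forward pass (learning off) for every stimulus in the set and
#' collects the output-layer firing rates.
#'
#' @param net A trained [visnet()].
#' @param test_set A `stimulus_set` (may differ from the training set, e.g.
#'   denser hand-centred locations for generalisation testing).
#' @param bank Gabor bank.
#' @return A `response_tensor`: array `(cells x configs x retinal positions)`
#'   with the test parameters attached.
#' @export
record_responses <- function(net, test_set, bank = gabor_bank()) {
  p <- attr(test_set, "params")
  N <- p$n_configs; R_tot <- p$n_retinal * p$n_retinal_v
  n_out <- net$layers[[length(net$layers)]]$config$grid^2
  plan <- gabor_plan(bank, dim(test_set$image[[1]]))
  rates <- array(NA_real_, c(n_out, N, R_tot))
  for (i in seq_len(nrow(test_set))) {
    st <- forward_pass(net, filter_image(test_set$image[[i]], bank, plan = plan))
    rates[, test_set$config[i], test_set$retinal[i]] <-
      st[[length(st)]]$y
  }
  stopifnot(!anyNA(rates))
  structure(rates, class = "response_tensor", params = p,
            order = attr(test_set, "order"))
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x)
  cat("<response_tensor> ", d[1], " cells x ", d[2], " configs x ", d[3],
      " retinal positions\n", sep = "")
  invisible(x)
}

#' Export a response tensor to long-format CSV
#'
#' Columns `cell`, `config`, `retinal`, `rate`.
#'
#' @param responses A `response_tensor`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses_csv <- function(responses, path) {
  utils::write.csv(tidy_response_tensor(responses), path, row.names = FALSE)
  invisible(path)
}

tidy_response_tensor <- function(responses) {
  d <- dim(responses)
  tibble::tibble(
    cell = rep(seq_len(d[1]), times = d[2] * d[3]),
    config = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    retinal = rep(seq_len(d[3]), each = d[1] * d[2]),
    rate = as.numeric(responses)
  )
}
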
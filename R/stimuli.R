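# Procedural hand--target stimulus generation.
#
# Each stimulus is a greyscale image (values in [0, 1]) containing a stylized
# right-hand silhouette and a single dark circular target object placed at one
# of N equidistant locations on a circular arc around the hand.  The whole
# hand--object configuration is shifted rigidly across retinal positions to
# emulate saccades.  Generation is fully deterministic given the parameters.

# Silhouette geometry, in pixels relative to the hand anchor (row, col).
# The anchor sits roughly at the base of the fingers; the palm hangs below it,
# four fingers point upwards and the thumb extends to the right (a right hand
# seen from the back).  Constants are shared by the renderer and the
# frame-bounds validator.
.hand_shape <- list(
  palm   = list(centre = c(8, 0), semi = c(13, 15)),
  # fingers: col offset, length, half width; bases at row offset -2
  fingers = list(
    list(col = -12, len = 14, hw = 3),
    list(col = -4,  len = 17, hw = 3),
    list(col = 4,   len = 18, hw = 3),
    list(col = 12,  len = 13, hw = 3)
  ),
  finger_base_row = -2,
  thumb  = list(from = c(6, 16), to = c(-1, 24), hw = 4),
  # tight bounding box of the silhouette (computed from the shapes above)
  extent = list(top = -23, bottom = 21, left = -15, right = 28)
)

#' Stimulus generation parameters
#'
#' Bundles every knob of the synthetic hand--object stimulus protocol: frame
#' size, target-disc diameter, the arc of hand-centred target locations, and
#' the retinal shift schedule.  Defaults reproduce the standard training
#' protocol: a 128x128 frame, a black target disc of diameter 36 px placed at
#' `n_configs` equidistant locations on a semicircular arc around the hand,
#' with each configuration shown at 10 retinal positions shifted horizontally
#' in 2-px steps.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param target_diameter Diameter of the circular target object, pixels.
#' @param n_configs Number of hand-centred target locations (N).
#' @param arc_radius Distance from the hand anchor to each target centre,
#'   pixels.
#' @param arc_span Angular span of the arc in degrees; 180 places targets on a
#'   semicircle from the left of the hand, over the top, to the right.
#' @param hand_anchor `(row, col)` pixel coordinate (1-based) of the hand's
#'   reference point at retinal position 1.
#' @param n_retinal Number of horizontal retinal positions (R).
#' @param n_retinal_v Number of vertical retinal positions (1 = horizontal
#'   shifts only; >1 yields a shift grid).
#' @param shift_step Retinal shift step, pixels.
#' @param background_intensity,hand_intensity,target_intensity Grey levels in
#'   \[0, 1\]; the target must be darker than the background ("black" target).
#'
#' @return An object of class `stimulus_params` (a validated list).
#' @examples
#' p <- stimulus_params(n_configs = 3, n_retinal = 2)
#' target_centre(p, 2)
#' @export
stimulus_params <- function(image_height = 128, image_width = 128,
                            target_diameter = 36, n_configs = 7,
                            arc_radius = 36, arc_span = 180,
                            hand_anchor = c(72, 55),
                            n_retinal = 10, n_retinal_v = 1, shift_step = 2,
                            background_intensity = 0.8, hand_intensity = 0.5,
                            target_intensity = 0.0) {
  p <- list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    target_diameter = target_diameter, n_configs = as.integer(n_configs),
    arc_radius = arc_radius, arc_span = arc_span,
    hand_anchor = as.numeric(hand_anchor),
    n_retinal = as.integer(n_retinal), n_retinal_v = as.integer(n_retinal_v),
    shift_step = shift_step,
    background_intensity = background_intensity,
    hand_intensity = hand_intensity, target_intensity = target_intensity
  )
  class(p) <- "stimulus_params"
  validate_stimulus_params(p)
  p
}

validate_stimulus_params <- function(p) {
  stopifnot(
    p$image_height > 0, p$image_width > 0,
    p$target_diameter > 0, p$n_configs >= 1,
    p$arc_radius > 0, p$arc_span > 0, p$arc_span <= 360,
    p$n_retinal >= 1, p$n_retinal_v >= 1, p$shift_step >= 0,
    length(p$hand_anchor) == 2
  )
  if (p$target_intensity >= p$background_intensity)
    stop("target_intensity must be below background_intensity (dark target)")
  ints <- c(p$background_intensity, p$hand_intensity, p$target_intensity)
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]")

  # every rendered configuration must fit fully inside the frame at every shift
  ext <- .hand_shape$extent
  max_dr <- (p$n_retinal_v - 1) * p$shift_step
  max_dc <- (p$n_retinal - 1) * p$shift_step
  r0 <- p$hand_anchor[1]; c0 <- p$hand_anchor[2]
  if (r0 + ext$top < 1 || r0 + ext$bottom + max_dr > p$image_height ||
      c0 + ext$left < 1 || c0 + ext$right + max_dc > p$image_width)
    stop("hand silhouette exceeds frame bounds at some retinal shift")
  rad <- p$target_diameter / 2
  for (j in seq_len(p$n_configs)) {
    tc <- target_centre(p, j)
    rr <- r0 + tc[1]; cc <- c0 + tc[2]
    if (rr - rad < 1 || rr + rad + max_dr > p$image_height ||
        cc - rad < 1 || cc + rad + max_dc > p$image_width)
      stop("target configuration ", j, " is clipped by the frame at some retinal shift")
  }
  invisible(p)
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat("<stimulus_params> ", x$image_height, "x", x$image_width,
      " frame, N = ", x$n_configs, " configs on a ", x$arc_span,
      "-degree arc (radius ", x$arc_radius, " px), R = ",
      x$n_retinal * x$n_retinal_v, " retinal positions (step ",
      x$shift_step, " px)\n", sep = "")
  invisible(x)
}

#' Hand-centred target location for one configuration
#'
#' Target centres are equally spaced in angle on an arc of `arc_span` degrees
#' at distance `arc_radius` from the hand anchor.  Configuration 1 is the
#' leftmost position, configuration `n_configs` the rightmost; the arc is
#' centred on the point directly above the hand.
#'
#' @param params A [stimulus_params()] object.
#' @param j Configuration index in `1:n_configs`.
#' @return Numeric `(row, col)` offset of the target centre relative to the
#'   hand anchor (rows grow downward, so targets above the hand have negative
#'   row offsets).
#' @export
target_centre <- function(params, j) {
  stopifnot(j >= 1, j <= params$n_configs)
  n <- params$n_configs
  ang <- if (n == 1) 90 else 90 + params$arc_span / 2 - (j - 1) * params$arc_span / (n - 1)
  c(-params$arc_radius * sinpi(ang / 180),
    params$arc_radius * cospi(ang / 180))
}

# squared distance of pixel grid points to a segment, vectorized
.seg_dist2 <- function(R, C, a, b) {
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  L2 <- vr^2 + vc^2
  t <- ((R - a[1]) * vr + (C - a[2]) * vc) / max(L2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  (R - (a[1] + t * vr))^2 + (C - (a[2] + t * vc))^2
}

#' Render the stylized hand silhouette
#'
#' Draws a deterministic right-hand silhouette (palm ellipse, four finger
#' capsules and a thumb capsule) at the hand anchor, optionally displaced by a
#' retinal offset.  The silhouette stands in for a photographic hand image;
#' none of the analyses depend on its fine morphology.
#'
#' @param params A [stimulus_params()] object.
#' @param offset `(row, col)` displacement in pixels added to the anchor.
#' @return A `image_height x image_width` matrix of grey levels.
#' @export
render_hand <- function(params, offset = c(0, 0)) {
  h <- params$image_height; w <- params$image_width
  r0 <- params$hand_anchor[1] + offset[1]
  c0 <- params$hand_anchor[2] + offset[2]
  ext <- .hand_shape$extent
  if (r0 + ext$top < 1 || r0 + ext$bottom > h ||
      c0 + ext$left < 1 || c0 + ext$right > w)
    stop("hand silhouette exceeds frame bounds")

  R <- matrix(seq_len(h), h, w) ; C <- matrix(rep(seq_len(w), each = h), h, w)
  shp <- .hand_shape
  pal <- shp$palm
  mask <- ((R - (r0 + pal$centre[1])) / pal$semi[1])^2 +
          ((C - (c0 + pal$centre[2])) / pal$semi[2])^2 <= 1
  base <- shp$finger_base_row
  for (f in shp$fingers) {
    a <- c(r0 + base, c0 + f$col)
    b <- c(r0 + base - f$len, c0 + f$col)
    mask <- mask | (.seg_dist2(R, C, a, b) <= f$hw^2)
  }
  th <- shp$thumb
  a <- c(r0 + th$from[1], c0 + th$from[2]); b <- c(r0 + th$to[1], c0 + th$to[2])
  mask <- mask | (.seg_dist2(R, C, a, b) <= th$hw^2)
  img <- matrix(params$background_intensity, h, w)
  img[mask] <- params$hand_intensity
  img
}

#' Compose one stimulus image
#'
#' Renders the hand with its anchor displaced by the retinal offset of
#' position `k`, then draws the target disc at the hand-centred location of
#' configuration `j` displaced by the same offset (the configuration shifts
#' rigidly).  The target over-paints the hand where the two overlap.
#'
#' @param params A [stimulus_params()] object.
#' @param j Configuration index, `1:n_configs`.
#' @param k Retinal position index, `1:(n_retinal * n_retinal_v)`; horizontal
#'   shifts vary fastest when a vertical shift grid is requested.
#' @return Grey-level matrix with attributes `config` and `retinal`.
#' @export
compose_stimulus <- function(params, j, k) {
  R_tot <- params$n_retinal * params$n_retinal_v
  stopifnot(k >= 1, k <= R_tot)
  off <- retinal_offset(params, k)
  img <- render_hand(params, off)
  img <- paint_target(img, params, j, off)
  attr(img, "config") <- as.integer(j)
  attr(img, "retinal") <- as.integer(k)
  img
}

# retinal offset (row, col) for retinal index k (1-based; horizontal fastest)
retinal_offset <- function(params, k) {
  kh <- (k - 1) %% params$n_retinal
  kv <- (k - 1) %/% params$n_retinal
  c(kv, kh) * params$shift_step
}

paint_target <- function(img, params, j, off) {
  ctr <- params$hand_anchor + target_centre(params, j) + off
  rad <- params$target_diameter / 2
  rr <- max(1, floor(ctr[1] - rad)):min(nrow(img), ceiling(ctr[1] + rad))
  cc <- max(1, floor(ctr[2] - rad)):min(ncol(img), ceiling(ctr[2] + rad))
  if (any(ctr - rad < 1) || ctr[1] + rad > nrow(img) || ctr[2] + rad > ncol(img))
    stop("target disc clipped by the frame")
  sub <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`) <= rad^2
  block <- img[rr, cc]
  block[sub] <- params$target_intensity
  img[rr, cc] <- block
  img
}

#' Build an ordered stimulus set
#'
#' Generates all `n_configs x n_retinal` stimulus images in one of the two
#' presentation orders.  `"config-major"` shows each hand--object
#' configuration at every retinal position before moving to the next
#' configuration (the standard training order); `"retina-major"` shows every
#' configuration at one retinal position before moving to the next position,
#' so no two consecutive images share a configuration -- the temporally
#' interleaved control order.
#'
#' @param params A [stimulus_params()] object.
#' @param order Presentation order tag.
#' @return A tibble of class `stimulus_set` with columns `config`, `retinal`
#'   and an `image` list-column, ordered as presented; the parameters and
#'   order tag are stored as attributes.
#' @export
build_stimulus_set <- function(params, order = c("config-major", "retina-major")) {
  order <- match.arg(order)
  N <- params$n_configs
  R_tot <- params$n_retinal * params$n_retinal_v
  idx <- if (order == "config-major") {
    tidyr::expand_grid(config = seq_len(N), retinal = seq_len(R_tot))
  } else {
    tidyr::expand_grid(retinal = seq_len(R_tot), config = seq_len(N))[, c("config", "retinal")]
  }
  # render each hand frame once per retinal offset, then paint discs
  hands <- lapply(seq_len(R_tot), function(k) render_hand(params, retinal_offset(params, k)))
  imgs <- purrr::map2(idx$config, idx$retinal, function(j, k) {
    img <- paint_target(hands[[k]], params, j, retinal_offset(params, k))
    attr(img, "config") <- as.integer(j); attr(img, "retinal") <- as.integer(k)
    img
  })
  out <- tibble::tibble(config = as.integer(idx$config),
                        retinal = as.integer(idx$retinal), image = imgs)
  attr(out, "params") <- params
  attr(out, "order") <- order
  class(out) <- c("stimulus_set", class(out))
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  p <- attr(x, "params")
  cat("<stimulus_set> ", nrow(x), " images (N = ", p$n_configs, ", R = ",
      p$n_retinal * p$n_retinal_v, "), order: ", attr(x, "order"), "\n", sep = "")
  NextMethod()
}

#' Write / read a stimulus set as PNG images plus a JSON manifest
#'
#' Images are stored as 8-bit greyscale PNGs named `stim_<config>_<retinal>.png`
#' together with `manifest.json` recording the generation parameters and the
#' presentation order, so a set can be re-created byte-for-byte.
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if needed).
#' @return `write_stimulus_set()` returns `dir` invisibly;
#'   `read_stimulus_set()` returns a `stimulus_set`.
#' @export
write_stimulus_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- attr(set, "params")
  manifest <- list(
    params = unclass(p), order = attr(set, "order"),
    images = purrr::map2(set$config, set$retinal,
                         ~list(config = .x, retinal = .y,
                               file = sprintf("stim_%03d_%03d.png", .x, .y)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  purrr::pwalk(list(set$config, set$retinal, set$image), function(j, k, img) {
    png::writePNG(img, file.path(dir, sprintf("stim_%03d_%03d.png", j, k)))
  })
  invisible(dir)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  pl <- as.list(m$params)
  params <- do.call(stimulus_params, pl[setdiff(names(pl), character())])
  imgs <- lapply(m$images$file, function(f) {
    x <- png::readPNG(file.path(dir, f))
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  })
  out <- tibble::tibble(config = as.integer(m$images$config),
                        retinal = as.integer(m$images$retinal), image = imgs)
  attr(out, "params") <- params
  attr(out, "order") <- m$order
  class(out) <- c("stimulus_set", class(out))
  out
}
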
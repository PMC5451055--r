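# Eigenimage (PCA) diagnostics of stimulus ensembles.
#
# The competitive Hebbian learning with synaptic scaling behaves like an
# approximate principal-component extraction of its input ensemble, so the
# leading eigenimages of a stimulus set predict whether hand-centred cells
# will develop: when the top components encode the target's hand-centred
# location, training succeeds; when they encode retinal shifts of the whole
# configuration, it fails.

#' Principal-component eigenimages of a stimulus set
#'
#' Images are flattened, the mean image subtracted, and the principal
#' components of the ensemble computed (base `svd`).  Component images are
#' unit-norm and mutually orthogonal; explained-variance fractions are
#' non-increasing and sum to at most 1.
#'
#' @param set A `stimulus_set` (or plain list of equal-size matrices).
#' @param n_components Number of leading components to keep.
#' @return An object of class `eigenimage_set`: `images` (list of component
#'   matrices), `var_fraction`, `cumulative`, `mean_image`, `dim`, and
#'   `all_var` (every eigenvalue fraction).
#' @export
pca_eigenimages <- function(set, n_components = 5) {
  imgs <- if (is.data.frame(set)) set$image else set
  stopifnot(length(imgs) >= 2)
  dm <- dim(imgs[[1]])
  X <- t(vapply(imgs, as.numeric, numeric(prod(dm))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else ev
  k <- min(n_components, ncol(sv$v))
  comps <- lapply(seq_len(k), function(i) matrix(sv$v[, i], dm[1], dm[2]))
  structure(list(images = comps, var_fraction = frac[seq_len(k)],
                 cumulative = cumsum(frac)[seq_len(k)],
                 mean_image = matrix(mu, dm[1], dm[2]),
                 dim = dm, all_var = frac),
            class = "eigenimage_set")
}

#' @export
print.eigenimage_set <- function(x, ...) {
  cat("<eigenimage_set> ", length(x$images), " components; explained variance ",
      paste(sprintf("%.1f%%", 100 * x$var_fraction), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Attribute eigenimage variance to target location vs retinal shift
#'
#' Every image of the set is scored on each component (projection of the
#' mean-centred image onto the component).  Because the stimulus manifest is
#' a balanced two-way design (every configuration crosses every retinal
#' position), the variance of those scores decomposes orthogonally into a
#' configuration (target-location) margin, a retinal-position margin and an
#' interaction remainder: `frac_target` is the fraction of score variance
#' explained by which hand-centred location the target occupies,
#' `frac_retinal` by where the configuration sits on the retina.  A
#' component dominated by the first margin encodes hand-centred target
#' position; by the second, retinal position.  The attribution of component
#' 1 predicts whether hand-centred cells develop.
#'
#' @param eig An [pca_eigenimages()] result for `set`.
#' @param set The `stimulus_set` the PCA was computed from.
#' @return A tibble: `component`, `frac_target`, `frac_retinal` (fractions
#'   of score variance; the remainder is interaction), `attribution`
#'   (`"target-location"` or `"retinal-shift"`).
#' @export
variance_attribution <- function(eig, set) {
  P <- prod(eig$dim)
  X <- t(vapply(set$image, as.numeric, numeric(P)))
  Xc <- sweep(X, 2, colMeans(X))
  rows <- lapply(seq_along(eig$images), function(i) {
    z <- as.numeric(Xc %*% as.numeric(eig$images[[i]]))
    tot <- sum((z - mean(z))^2)
    ss_margin <- function(groups) {
      zm <- tapply(z, groups, mean)
      sum(table(groups) * (zm - mean(z))^2)
    }
    ft <- if (tot > 0) ss_margin(set$config) / tot else 0
    fr <- if (tot > 0) ss_margin(set$retinal) / tot else 0
    tibble::tibble(component = i, frac_target = ft, frac_retinal = fr,
                   attribution = ifelse(ft >= fr, "target-location", "retinal-shift"))
  })
  dplyr::bind_rows(rows)
}

#' Stimulus geometries for the eigenimage diagnostic
#'
#' Six stimulus-set geometries that differ in the number of hand-centred
#' target locations, the number of retinal shifts (a trailing `x 10` denotes
#' a 10x10 shift grid) and the shift step: (a) 4 locations, 10 shifts of 2 px;
#' (b) 30 locations, 10 shifts of 2 px; (c) 4 locations, 10x10 grid of 2-px
#' shifts; (d) 4 locations, 10 shifts of 5 px; (e) 4 locations, 4 shifts of
#' 5 px; (f) 4 locations, 25 shifts of 2 px.  Geometries (a), (b), (c) and
#' (e) develop hand-centred output neurons; (d) and (f) — whose retinal span
#' reaches 45–48 px — do not.  A compact arc (radius 21 px, anchor column
#' 40) is used for all six rows so that even the widest shift schedules fit
#' the 128-px frame.
#'
#' @return A named list of [stimulus_params()], names `"a"`..`"f"`, with a
#'   `develops` attribute giving the expected outcome per row.
#' @export
pca_geometry_params <- function() {
  base <- function(n_configs, n_retinal, shift_step, n_retinal_v = 1)
    stimulus_params(n_configs = n_configs, n_retinal = n_retinal,
                    n_retinal_v = n_retinal_v, shift_step = shift_step,
                    arc_radius = 21, hand_anchor = c(72, 40))
  out <- list(
    a = base(4, 10, 2),
    b = base(30, 10, 2),
    c = base(4, 10, 2, n_retinal_v = 10),
    d = base(4, 10, 5),
    e = base(4, 4, 5),
    f = base(4, 25, 2)
  )
  attr(out, "develops") <- c(a = TRUE, b = TRUE, c = TRUE,
                             d = FALSE, e = TRUE, f = FALSE)
  out
}

#' Export eigenimages as PNGs with an explained-variance sidecar
#'
#' Each component image is rescaled to \[0, 1\] (symmetrically about zero)
#' and written as an 8-bit greyscale PNG, together with `variance.json`
#' holding the explained-variance fractions and cumulative curve.
#'
#' @param eig An [pca_eigenimages()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eigenimages <- function(eig, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(eig$images)) {
    img <- eig$images[[i]]
    m <- max(abs(img), 1e-12)
    png::writePNG((img / m + 1) / 2,
                  file.path(dir, sprintf("component_%d.png", i)))
  }
  jsonlite::write_json(
    list(var_fraction = eig$var_fraction, cumulative = eig$cumulative),
    file.path(dir, "variance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
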
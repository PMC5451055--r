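# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.raster_df <- function(img) {
  tibble::tibble(row = rep(seq_len(nrow(img)), ncol(img)),
                 col = rep(seq_len(ncol(img)), each = nrow(img)),
                 value = as.numeric(img))
}

#' Plot stimulus images
#'
#' @param object A `stimulus_set`.
#' @param configs,retinals Subsets of configurations / retinal positions to
#'   show (defaults: up to 4 configurations at the first retinal position).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stimulus_set <- function(object, configs = NULL, retinals = 1, ...) {
  p <- attr(object, "params")
  configs <- configs %||% unique(object$config)[seq_len(min(4, p$n_configs))]
  sel <- object[object$config %in% configs & object$retinal %in% retinals, ]
  df <- dplyr::bind_rows(purrr::pmap(
    list(sel$config, sel$retinal, sel$image),
    function(j, k, img) dplyr::mutate(.raster_df(img), config = j, retinal = k)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::facet_grid(retinal ~ config, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "grey") +
    ggplot2::theme_void()
}

#' Plot response matrices of selected cells
#'
#' Shows each cell's configuration x retinal-position firing-rate matrix as a
#' heat map; a perfect hand-centred cell appears as a single vertical bar
#' (one configuration, all retinal positions).
#'
#' @param object A `response_tensor`.
#' @param cells Cell indices to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_tensor <- function(object, cells = 1:4, ...) {
  df <- tidy_response_tensor(object) |>
    dplyr::filter(.data$cell %in% cells)
  ggplot2::ggplot(df, ggplot2::aes(.data$config, .data$retinal, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~cell, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "hand-centred configuration", y = "retinal position",
                  fill = "rate")
}

#' Plot a receptive-field distribution over hand-centred locations
#'
#' @param object An [rf_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_distribution <- function(object, ...) {
  n <- max(nrow(object) - 1, 1)
  df <- dplyr::mutate(object, position = (.data$location - 1) / n)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$count)) +
    ggplot2::geom_col(width = 0.8 / n) +
    ggplot2::labs(x = "hand-centred location (0 = leftmost, 1 = rightmost)",
                  y = "hand-centred cells (fractional count)")
}

#' Plot eigenimages and their explained variance
#'
#' @param object An [pca_eigenimages()] result.
#' @param ... Unused.
#' @return A ggplot of the component images (facets) with explained-variance
#'   percentages in the strip labels.
#' @export
autoplot.eigenimage_set <- function(object, ...) {
  df <- dplyr::bind_rows(purrr::imap(object$images, function(img, i) {
    dplyr::mutate(.raster_df(img),
                  component = sprintf("PC%d (%.1f%%)", i, 100 * object$var_fraction[i]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90", high = "red") +
    ggplot2::facet_wrap(~component, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
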
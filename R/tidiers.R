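# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a response tensor into long format
#'
#' @param x A `response_tensor`.
#' @param ... Unused.
#' @return A tibble `cell`, `config`, `retinal`, `rate`.
#' @export
tidy.response_tensor <- function(x, ...) tidy_response_tensor(x)

#' Tidy a multiple-cell information result
#'
#' @param x A `multicell_info`.
#' @param ... Unused.
#' @return The confusion table in long format: `stimulus`, `decoded`,
#'   `probability`.
#' @export
tidy.multicell_info <- function(x, ...) {
  N <- nrow(x$confusion)
  tibble::tibble(stimulus = rep(seq_len(N), N),
                 decoded = rep(seq_len(N), each = N),
                 probability = as.numeric(x$confusion))
}

#' @rdname tidy.multicell_info
#' @export
glance.multicell_info <- function(x, ...) {
  tibble::tibble(info = x$info, ceiling = x$ceiling, n_cells = length(x$cells))
}

#' Tidy an eigenimage set
#'
#' @param x An `eigenimage_set`.
#' @param ... Unused.
#' @return A tibble `component`, `var_fraction`, `cumulative`.
#' @export
tidy.eigenimage_set <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_fraction),
                 var_fraction = x$var_fraction,
                 cumulative = x$cumulative)
}

#' Tidy / glance a run record
#'
#' @param x A `run_record` from [run_experiment()].
#' @param ... Unused.
#' @return `tidy()` returns the long summary (`metric`, `value`); `glance()`
#'   a one-row wide tibble with a `seed` column.
#' @export
tidy.run_record <- function(x, ...) x$summary

#' @rdname tidy.run_record
#' @export
glance.run_record <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric", values_from = "value") |>
    dplyr::mutate(seed = x$seed, .before = 1)
}
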
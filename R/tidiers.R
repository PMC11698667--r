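# broom-style accessors and ggplot2 methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Turnpike fit
#'
#' @param x A `turnpike_fit` from [mm_solve()], [mmdq_solve()], or
#'   [block_mm_solve()].
#' @param ... Unused.
#' @return Tibble with one row per reconstructed point: `index`, `value`.
#' @export
tidy.turnpike_fit <- function(x, ...) {
  tibble::tibble(index = seq_along(x$z), value = x$z)
}

#' One-row summary of a Turnpike fit
#'
#' @inheritParams tidy.turnpike_fit
#' @return Tibble with `n`, `method`, `objective`, `iterations`,
#'   `converged`.
#' @export
glance.turnpike_fit <- function(x, ...) {
  tibble::tibble(n = length(x$z), method = x$method, objective = x$objective,
                 iterations = x$iterations, converged = x$converged)
}

#' Plot a Turnpike fit
#'
#' `type = "points"` draws the reconstructed configuration on the line
#' (optionally over the reference configuration); `type = "trace"` draws
#' the matching objective across MM iterations, which is nondecreasing.
#'
#' @param object A `turnpike_fit`.
#' @param type `"points"` or `"trace"`.
#' @param reference Optional ground-truth configuration to overlay
#'   (canonicalized to the estimate's mirror orientation).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.turnpike_fit <- function(object, type = c("points", "trace"),
                                  reference = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                         objective = object$objective_trace)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::labs(x = "MM iteration", y = "matching objective") +
        ggplot2::theme_minimal()
    )
  }
  df <- tibble::tibble(value = object$z, set = "estimate")
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      value = canonicalize(reference, object$z), set = "reference"
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$set)) +
    ggplot2::geom_point(shape = 124, size = 6) +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot protocol results
#'
#' Normalized MAE per instance, grouped by distribution, on a log scale.
#'
#' @param results Tibble from [run_protocol()].
#' @return A ggplot object.
#' @export
plot_protocol <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$distribution, y = .data$normalized_mae)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "MAE / epsilon") +
    ggplot2::theme_minimal()
}
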
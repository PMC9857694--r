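#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reconstruction into a pair-probability table
#'
#' @param x An `ema_fit`.
#' @param include_observed Also list pairs whose status was observed (their
#'   probability is the observed 0/1). Default `FALSE`: only the inferred,
#'   unobserved pairs.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `from`, `to`, `probability`,
#'   `observed`, one row per i<j pair.
#' @method tidy ema_fit
#' @export
tidy.ema_fit <- function(x, include_observed = FALSE, ...) {
  purrr::map_dfr(x$layer_ids, function(l) {
    P <- x$p[[l]]
    msk <- x$obs$mask[[l]]
    up <- upper.tri(P)
    sel <- if (include_observed) up else (up & !msk)
    idx <- which(sel)
    i <- ((idx - 1L) %% nrow(P)) + 1L
    j <- ((idx - 1L) %/% nrow(P)) + 1L
    tibble::tibble(layer = l,
                   from = x$node_ids[i], to = x$node_ids[j],
                   probability = P[idx],
                   observed = msk[idx])
  })
}

#' One-row summary of a reconstruction
#'
#' @param x An `ema_fit`.
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_layers`, `method`, `m_step`,
#'   `iterations`, `converged`, `final_mae`, `tolerance`.
#' @method glance ema_fit
#' @export
glance.ema_fit <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$node_ids),
    n_layers = length(x$layer_ids),
    method = if (x$config$a_step == "off") "em" else "ema",
    m_step = x$config$m_step,
    iterations = x$iterations,
    converged = x$converged,
    final_mae = x$trace[length(x$trace)],
    tolerance = x$config$tolerance)
}

#' Convergence-trace plot of a reconstruction
#'
#' @param object An `ema_fit`.
#' @param ... Unused.
#' @return A ggplot of the per-iteration mean absolute change (log scale).
#' @method autoplot ema_fit
#' @export
autoplot.ema_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace), mae = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$mae)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "mean absolute change of p",
                  title = "Convergence of the reconstruction") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
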
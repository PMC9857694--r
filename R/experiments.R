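#' Sweep observed fraction, repeat, and compare methods
#'
#' The standard protocol for benchmarking reconstruction: for every observed
#' fraction `c` and repetition, draw one node-masking (shared by all methods
#' — a paired design), reconstruct with each method, and score MCC and
#' G-mean over the unobserved pairs. All per-run seeds derive
#' deterministically from `seed`, `c`, and the repetition index, so the same
#' master seed reproduces the whole sweep.
#'
#' @param net Ground-truth `multiplex_network`.
#' @param c_grid Observed fractions, default `seq(0.1, 0.9, by = 0.1)`.
#' @param reps Repetitions per fraction, default 50.
#' @param methods Subset of `c("ema", "em", "rm")`.
#' @param config Base [ema_config()] (its `a_step` is overridden per
#'   method: the default evidence-gated aggregation for `"ema"`, `"off"` for
#'   `"em"`).
#' @param seed Master seed.
#' @return A `muxrec_sweep` tibble: one row per (method, c, rep, layer) with
#'   layer `"all"` pooled across layers; columns include confusion counts,
#'   `mcc`, `gmean`, `iterations`, `final_mae`, `runtime`. Summarize with
#'   [sweep_summary()], plot with [autoplot.muxrec_sweep()].
#' @export
#' @examples
#' net <- generate_multiplex(60, 2, degree = "poisson:3", overlap = 0.7, seed = 1)
#' sw <- run_sweep(net, c_grid = 0.5, reps = 2, seed = 1)
#' sweep_summary(sw)
run_sweep <- function(net, c_grid = seq(0.1, 0.9, by = 0.1), reps = 50,
                      methods = c("ema", "em", "rm"),
                      config = ema_config(), seed = 1) {
  methods <- match.arg(methods, c("ema", "em", "rm"), several.ok = TRUE)
  stopifnot(all(c_grid > 0 & c_grid < 1), reps >= 1)
  grid <- tidyr::expand_grid(c = c_grid, rep = seq_len(reps))
  rows <- purrr::pmap_dfr(grid, function(c, rep) {
    ci <- round(c * 1000)
    obs <- mask_nodes(net, c, seed = derive_seed(seed, ci, rep, 1))
    purrr::map_dfr(methods, function(meth) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        if (meth == "rm") {
          pred <- random_model(obs, truth = net,
                               seed = derive_seed(seed, ci, rep, 2))
          ev <- evaluate_reconstruction(pred, net, obs = obs)
          ev$iterations <- NA_integer_
          ev$final_mae <- NA_real_
          ev
        } else {
          cfg <- config
          cfg$a_step <- if (meth == "em") "off" else config$a_step
          cfg$seed <- derive_seed(seed, ci, rep, 3)
          fit <- run_ema(obs, cfg)
          ev <- evaluate_reconstruction(fit, net)
          ev$iterations <- fit$iterations
          ev$final_mae <- fit$trace[length(fit$trace)]
          ev
        }
      }, error = function(e) {
        tibble::tibble(layer = "all", tp = NA_real_, tn = NA_real_,
                       fp = NA_real_, fn = NA_real_, mcc = NA_real_,
                       gmean = NA_real_, iterations = NA_integer_,
                       final_mae = NA_real_, error = conditionMessage(e))
      })
      res$runtime <- proc.time()[["elapsed"]] - t0
      res$method <- meth
      res$c <- c
      res$rep <- rep
      res$seed <- seed
      res
    })
  })
  rows <- dplyr::relocate(rows, "method", "c", "rep", "seed", "layer")
  class(rows) <- c("muxrec_sweep", class(rows))
  rows
}

#' Aggregate a sweep into per-cell means and standard deviations
#'
#' @param sweep A `muxrec_sweep` (or any tibble with its columns).
#' @param layer Which layer rows to aggregate (default the pooled `"all"`).
#' @return A tibble keyed by (method, c) with mean/sd of MCC, G-mean and
#'   iterations; G-mean averages skip undefined (NA) runs.
#' @export
sweep_summary <- function(sweep, layer = "all") {
  lay <- layer
  sweep |>
    dplyr::filter(.data$layer == lay) |>
    dplyr::group_by(.data$method, .data$c) |>
    dplyr::summarise(
      n = dplyr::n(),
      mcc_mean = mean(.data$mcc, na.rm = TRUE),
      mcc_sd = stats::sd(.data$mcc, na.rm = TRUE),
      gmean_mean = mean(.data$gmean, na.rm = TRUE),
      gmean_sd = stats::sd(.data$gmean, na.rm = TRUE),
      iterations_mean = mean(.data$iterations, na.rm = TRUE),
      .groups = "drop")
}

#' Metric-versus-fraction plot of a sweep
#'
#' @param object A `muxrec_sweep`.
#' @param metric `"mcc"` or `"gmean"`.
#' @param layer Layer to plot (default pooled `"all"`).
#' @param ... Unused.
#' @return A ggplot with one line per method.
#' @method autoplot muxrec_sweep
#' @export
autoplot.muxrec_sweep <- function(object, metric = c("mcc", "gmean"),
                                  layer = "all", ...) {
  metric <- match.arg(metric)
  agg <- sweep_summary(object, layer = layer)
  ycol <- paste0(metric, "_mean")
  sdcol <- paste0(metric, "_sd")
  ggplot2::ggplot(agg, ggplot2::aes(.data$c, .data[[ycol]],
                                    colour = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[ycol]] - .data[[sdcol]],
                                      ymax = .data[[ycol]] + .data[[sdcol]],
                                      fill = .data$method),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "observed fraction c", y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' Paired convergence traces of the aggregation-augmented and plain solvers
#'
#' Runs both solvers from the same initialization on the same observation
#' and records the per-iteration mean absolute change, plus the first
#' iteration at which each trace drops below `10^-4` and `10^-5`.
#'
#' @param obs A `partial_observation`.
#' @param config Base [ema_config()]; its seed fixes the shared
#'   initialization.
#' @return A tibble with columns `method`, `iteration`, `mae`, and an
#'   attribute `crossings`: a tibble of iterations-to-tolerance per method.
#' @export
convergence_trace <- function(obs, config = ema_config()) {
  cfg_ema <- config
  cfg_em <- config
  cfg_em$a_step <- "off"
  fits <- list(ema = run_ema(obs, cfg_ema), em = run_ema(obs, cfg_em))
  out <- purrr::imap_dfr(fits, function(f, meth) {
    tibble::tibble(method = meth, iteration = seq_along(f$trace), mae = f$trace)
  })
  crossings <- purrr::imap_dfr(fits, function(f, meth) {
    tibble::tibble(
      method = meth,
      iter_at_1e4 = first_at(f$trace, 1e-4),
      iter_at_1e5 = first_at(f$trace, 1e-5),
      converged = f$converged)
  })
  attr(out, "crossings") <- crossings
  out
}

first_at <- function(trace, tol) {
  hit <- which(trace <= tol)
  if (length(hit)) hit[1] else NA_integer_
}
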
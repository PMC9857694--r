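#' Matthews correlation coefficient
#'
#' \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' in \[-1, 1\] and robust to class imbalance, which makes it the metric of
#' choice for sparse-network link prediction where negatives dominate. Any
#' zero factor in the denominator yields 0 by convention.
#'
#' @param tp,fp,tn,fn Confusion counts (vectorized).
#' @return Numeric vector of MCC values.
#' @export
#' @examples
#' mcc(tp = 3, fp = 0, tn = 7, fn = 0) # perfect: 1
mcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

#' Geometric mean of recall and specificity
#'
#' \eqn{\sqrt{TP/(TP+FN) \times TN/(TN+FP)}}, in \[0, 1\]. Undefined (NA)
#' when either class is empty; such runs are excluded from averages.
#'
#' @param tp,fp,tn,fn Confusion counts (vectorized).
#' @return Numeric vector of G-mean values.
#' @export
gmean <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  out <- sqrt((tp / (tp + fn)) * (tn / (tn + fp)))
  out[(tp + fn) == 0 | (tn + fp) == 0] <- NA_real_
  out
}

#' Uniform random baseline prediction
#'
#' Predicts, per layer, exactly `k` links drawn uniformly without
#' replacement from the candidate pairs (all i<j pairs not among observed
#' nodes). `k` defaults to the true number of unobserved links — the same
#' oracle budget the reconstruction methods are scored with.
#'
#' @param obs A `partial_observation`.
#' @param k Integer vector (recycled over layers) of predicted link counts,
#'   or `NULL` to take the true counts from `truth`.
#' @param truth The ground-truth `multiplex_network` (needed when `k` is
#'   `NULL`).
#' @param seed Optional seed.
#' @return Named list of symmetric binary prediction matrices, one per
#'   layer, nonzero only on candidate pairs.
#' @export
random_model <- function(obs, k = NULL, truth = NULL, seed = NULL) {
  layers <- obs$layer_ids
  if (is.null(k)) {
    if (is.null(truth)) rlang::abort("need `truth` when `k` is NULL")
    k <- vapply(layers, function(l) {
      sum(adjacency(truth, l)[unobserved_pair_mask(obs, l)])
    }, numeric(1))
  }
  k <- as.integer(rep_len(k, length(layers)))
  with_seed_opt(seed, {
    preds <- lapply(seq_along(layers), function(li) {
      l <- layers[li]
      cand <- which(unobserved_pair_mask(obs, l))
      if (k[li] < 0 || k[li] > length(cand)) {
        rlang::abort(sprintf("layer %s: k=%d outside [0, %d]", l, k[li], length(cand)),
                     class = "muxrec_domain_error")
      }
      m <- matrix(0L, length(obs$node_ids), length(obs$node_ids),
                  dimnames = list(obs$node_ids, obs$node_ids))
      pick <- if (k[li] > 0) sample(cand, k[li]) else integer(0)
      m[pick] <- 1L
      symmetrize_upper(m)
    })
    stats::setNames(preds, layers)
  })
}

#' Binarize a probability matrix by top-k selection
#'
#' Sets to 1 the `k` candidate pairs with the highest probability; ties at
#' the cutoff break deterministically by canonical (row-major i<j) pair
#' order. Exactly `k` positives result for any input.
#'
#' @param p Symmetric probability matrix.
#' @param candidates Logical matrix of candidate i<j pairs.
#' @param k Number of positives.
#' @return Symmetric binary matrix.
#' @export
binarize_topk <- function(p, candidates, k) {
  idx <- which(candidates & upper.tri(p))
  if (k < 0 || k > length(idx)) {
    rlang::abort(sprintf("k=%d outside [0, %d]", k, length(idx)),
                 class = "muxrec_domain_error")
  }
  ord <- order(-p[idx], canonical_pair_rank(idx, nrow(p)))
  m <- matrix(0L, nrow(p), ncol(p), dimnames = dimnames(p))
  m[idx[ord[seq_len(k)]]] <- 1L
  symmetrize_upper(m)
}

#' Confusion counts over the unobserved region
#'
#' Counts TP/TN/FP/FN over the unobserved i<j pairs of each layer — the
#' evaluation domain; pairs among observed nodes are never scored — and adds
#' a pooled row (`layer = "all"`) aggregating the counts across layers.
#'
#' @param pred Named list of binary prediction matrices (per layer).
#' @param truth The ground-truth `multiplex_network`.
#' @param obs The `partial_observation` defining the evaluation domain.
#' @return A tibble with columns `layer`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth, obs) {
  per <- purrr::map_dfr(obs$layer_ids, function(l) {
    sel <- unobserved_pair_mask(obs, l)
    z <- adjacency(truth, l)[sel]
    y <- pred[[l]][sel]
    tibble::tibble(layer = l,
                   tp = sum(y == 1 & z == 1), tn = sum(y == 0 & z == 0),
                   fp = sum(y == 1 & z == 0), fn = sum(y == 0 & z == 1))
  })
  pooled <- tibble::tibble(layer = "all",
                           tp = sum(per$tp), tn = sum(per$tn),
                           fp = sum(per$fp), fn = sum(per$fn))
  dplyr::bind_rows(per, pooled)
}

#' Score a reconstruction against the ground truth
#'
#' Binarizes the fitted probabilities (top-k per layer by default, with `k`
#' equal to the true number of unobserved links, the same budget the random
#' baseline receives; or a probability threshold), counts the confusion
#' matrix over the unobserved pairs, and attaches MCC and G-mean.
#'
#' @param fit An `ema_fit`, or a named list of binary prediction matrices.
#' @param truth The ground-truth `multiplex_network`.
#' @param obs The `partial_observation`; defaults to `fit$obs`.
#' @param k Per-layer positives budget for top-k binarization (recycled);
#'   `NULL` takes the true counts.
#' @param rule `"topk"` (default) or `"threshold"`.
#' @param threshold Probability cutoff for `rule = "threshold"` (default 0.5).
#' @return A tibble with one row per layer plus a pooled `"all"` row:
#'   confusion counts, `mcc`, `gmean`.
#' @export
#' @examples
#' net <- generate_multiplex(60, 2, degree = "poisson:3", overlap = 0.7, seed = 1)
#' obs <- mask_nodes(net, 0.5, seed = 2)
#' fit <- run_ema(obs, ema_config(seed = 3))
#' evaluate_reconstruction(fit, net)
evaluate_reconstruction <- function(fit, truth, obs = NULL, k = NULL,
                                    rule = c("topk", "threshold"),
                                    threshold = 0.5) {
  rule <- match.arg(rule)
  if (inherits(fit, "ema_fit")) {
    obs <- obs %||% fit$obs
    probs <- fit$p
  } else {
    if (is.null(obs)) rlang::abort("need `obs` for a raw prediction list")
    probs <- fit
  }
  layers <- obs$layer_ids
  already_binary <- all(vapply(probs, function(m) all(m %in% c(0, 1)), logical(1))) &&
    !inherits(fit, "ema_fit")
  pred <- if (already_binary) {
    probs
  } else if (rule == "threshold") {
    lapply(layers, function(l) {
      sel <- unobserved_pair_mask(obs, l)
      m <- matrix(0L, length(obs$node_ids), length(obs$node_ids),
                  dimnames = list(obs$node_ids, obs$node_ids))
      m[sel] <- as.integer(probs[[l]][sel] >= threshold)
      symmetrize_upper(m)
    })
  } else {
    if (is.null(k)) {
      k <- vapply(layers, function(l) {
        sum(adjacency(truth, l)[unobserved_pair_mask(obs, l)])
      }, numeric(1))
    }
    k <- as.integer(rep_len(k, length(layers)))
    lapply(seq_along(layers), function(li) {
      l <- layers[li]
      binarize_topk(probs[[l]], unobserved_pair_mask(obs, l), k[li])
    })
  }
  pred <- stats::setNames(pred, layers)
  cc <- confusion_counts(pred, truth, obs)
  cc$mcc <- mcc(cc$tp, cc$fp, cc$tn, cc$fn)
  cc$gmean <- gmean(cc$tp, cc$fp, cc$tn, cc$fn)
  cc
}
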
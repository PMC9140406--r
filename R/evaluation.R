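#' Mean absolute error
#'
#' `mae = (1/l) * sum |r - r_hat|` between true link indicators and predicted
#' scores.
#'
#' @param pred Numeric vector of predictions.
#' @param truth Numeric vector of the same length.
#' @return Non-negative scalar.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  if (length(pred) == 0L) stop("empty vectors")
  mean(abs(pred - truth))
}

#' Root mean square error
#'
#' `rmse = sqrt((1/l) * sum (r - r_hat)^2)`; always >= [mae()] on the same
#' vectors.
#'
#' @inheritParams mae
#' @return Non-negative scalar.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  if (length(pred) == 0L) stop("empty vectors")
  sqrt(mean((pred - truth)^2))
}

#' Run one train/test link prediction experiment
#'
#' The full evaluation protocol: withhold a random fraction of the edges as
#' positive test pairs, sample matched non-edge negatives for training and
#' testing, fit the model on the training graph (withheld edges removed), and
#' score every test pair with structures extracted from the training graph
#' only — test edges never influence extraction, so there is no leakage.
#'
#' @param net A [bipartite_network].
#' @param k Local-structure depth.
#' @param control A [pathlink_control()].
#' @param seed Integer seed; the split, negative sampling and training all
#'   derive from it.
#' @param test_fraction Fraction of edges withheld, default 0.2.
#' @param literal_hops,path_cap Passed to the extractor.
#' @param keep_fit If `TRUE`, the fitted model is kept on the result.
#' @return An object of class `pathlink_eval`: `mae`, `rmse`, `n_samples`,
#'   `per_pair` (data frame with u, v, truth, score), `k`, `seed`.
#' @export
run_experiment <- function(net, k = 1L, control = pathlink_control(),
                           seed = 1L, test_fraction = 0.2,
                           literal_hops = FALSE, path_cap = 10000L,
                           keep_fit = FALSE) {
  stopifnot(inherits(net, "bipartite_network"))
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  split <- split_edges(net, test_fraction, seed = sub[1L])
  train_net <- .remove_edges(net, split$test_pos)
  fit <- pathlink(train_net, k = k, control = control, seed = sub[2L],
                  negatives = split$train_neg, literal_hops = literal_hops,
                  path_cap = path_cap)
  test_pairs <- rbind(split$test_pos, split$test_neg)
  truth <- c(rep(1, nrow(split$test_pos)), rep(0, nrow(split$test_neg)))
  scores <- predict(fit, test_pairs, network = train_net)
  res <- list(mae = mae(scores, truth), rmse = rmse(scores, truth),
              n_samples = length(truth),
              per_pair = data.frame(u = test_pairs[, 1L], v = test_pairs[, 2L],
                                    truth = truth, score = scores),
              k = as.integer(k), seed = seed, test_fraction = test_fraction)
  if (keep_fit) res$fit <- fit
  class(res) <- "pathlink_eval"
  res
}

#' @export
print.pathlink_eval <- function(x, ...) {
  cat(sprintf("Link prediction evaluation (k = %d, seed %d)\n", x$k, x$seed))
  cat(sprintf("  %d test pairs: RMSE = %.4f, MAE = %.4f\n",
              x$n_samples, x$rmse, x$mae))
  invisible(x)
}

#' Depth sweep
#'
#' Runs [run_experiment()] for every combination of depth `k` and seed and
#' reports per-depth mean RMSE and MAE, to study how far the local structure
#' should reach.
#'
#' @param net A [bipartite_network].
#' @param ks Integer vector of depths.
#' @param control A [pathlink_control()].
#' @param seeds Integer vector of seeds (replicates).
#' @param ... Passed to [run_experiment()].
#' @return Data frame with columns `k`, `rmse`, `mae` (one row per depth,
#'   means over seeds); per-replicate rows in `attr(, "details")`.
#' @export
depth_sweep <- function(net, ks, control = pathlink_control(),
                        seeds = 1:3, ...) {
  details <- do.call(rbind, lapply(ks, function(k) {
    do.call(rbind, lapply(seeds, function(s) {
      r <- run_experiment(net, k = k, control = control, seed = s, ...)
      data.frame(k = k, seed = s, rmse = r$rmse, mae = r$mae)
    }))
  }))
  agg <- do.call(rbind, lapply(split(details, details$k), function(d)
    data.frame(k = d$k[1L], rmse = mean(d$rmse), mae = mean(d$mae))))
  agg <- agg[order(agg$k), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "details") <- details
  agg
}

#' Sparsity sweep
#'
#' Thins the network to each retention fraction with [subsample_links()] and
#' evaluates link prediction on the thinned network, to study how link
#' sparsity degrades the structural evidence. Fraction 1.0 reproduces the
#' full-network evaluation exactly (same seeds).
#'
#' @param net A [bipartite_network].
#' @param fractions Numeric vector of retention fractions in (0, 1].
#' @param control A [pathlink_control()].
#' @param seeds Integer vector of seeds (replicates; each seed governs both
#'   the thinning and the experiment).
#' @param ... Passed to [run_experiment()].
#' @return Data frame with columns `fraction`, `rmse`, `mae`, sorted by
#'   fraction; per-replicate rows in `attr(, "details")`.
#' @export
sparsity_sweep <- function(net, fractions, control = pathlink_control(),
                           seeds = 1:3, ...) {
  details <- do.call(rbind, lapply(fractions, function(f) {
    do.call(rbind, lapply(seeds, function(s) {
      sub <- subsample_links(net, f, seed = s)
      r <- run_experiment(sub, control = control, seed = s, ...)
      data.frame(fraction = f, seed = s, rmse = r$rmse, mae = r$mae)
    }))
  }))
  agg <- do.call(rbind, lapply(split(details, details$fraction), function(d)
    data.frame(fraction = d$fraction[1L], rmse = mean(d$rmse), mae = mean(d$mae))))
  agg <- agg[order(agg$fraction), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "details") <- details
  agg
}
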
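#' Fit a local-structure link prediction model to a bipartite network
#'
#' Trains the path-based link scorer on an observed bipartite network. Every
#' edge of the network is a positive example; an equal number of non-edge
#' pairs is sampled as negatives (or supplied via `negatives`). For each
#' example pair the local structure is extracted from the network — the
#' direct edge between the pair is never traversed and never part of the
#' structure, so positives and negatives are processed identically — nodes
#' are labelled by type and hop distance, one-hot encoded, and the graph
#' convolutional scorer is trained by SGD under mean squared error.
#'
#' @param network A [bipartite_network] (the observed/training graph).
#' @param k Local-structure depth; connecting paths have `2k + 1` edges
#'   (see [extract_local_structure()]).
#' @param control A [pathlink_control()] with optimiser and architecture
#'   settings.
#' @param seed Integer seed; negative sampling, initialisation and batch
#'   shuffling all derive from it, so a fit is reproducible from
#'   `(network, k, control, seed)`.
#' @param negatives Optional two-column matrix of non-edge pairs to use as
#'   negative examples instead of sampling them.
#' @param literal_hops,path_cap Passed to [extract_local_structure()].
#' @param trace If `TRUE`, prints per-stage progress messages.
#' @return An object of class `pathlink` with components `params`,
#'   `loss_history`, `network`, `k`, `control`, `seed`, `pairs` (training
#'   pairs with labels and fitted scores) and `n_capped` (structures whose
#'   path enumeration hit the cap).
#' @examples
#' net <- generate_block_bipartite(block_model_spec(n_u = 20, n_v = 20,
#'   blocks_u = rep(1:2, each = 10), blocks_v = rep(1:2, each = 10)))
#' fit <- pathlink(net, k = 1, control = pathlink_control(epochs = 5))
#' fit
#' predict(fit, cbind(1, 1:3))
#' @export
pathlink <- function(network, k = 1L, control = pathlink_control(),
                     seed = 1L, negatives = NULL, literal_hops = FALSE,
                     path_cap = 10000L, trace = FALSE) {
  stopifnot(inherits(network, "bipartite_network"))
  if (nrow(network$edges) == 0L) stop("network has no edges to train on")
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  if (is.null(negatives)) {
    negatives <- sample_negatives(network, nrow(network$edges), seed = sub[1L])
  } else {
    negatives <- .sort_pairs(negatives)
    if (any(.has_edge(network, negatives[, 1L], negatives[, 2L])))
      stop("`negatives` contains pairs that are edges of the network")
  }
  pairs <- rbind(network$edges, negatives)
  labels <- c(rep(1L, nrow(network$edges)), rep(0L, nrow(negatives)))
  if (trace) message(sprintf("extracting %d local structures (k = %d)...",
                             nrow(pairs), k))
  structures <- .extract_all(network, pairs, k, literal_hops, path_cap)
  n_capped <- sum(vapply(structures, `[[`, logical(1), "capped"))
  if (n_capped > 0L && trace)
    message(sprintf("path cap hit for %d of %d pairs", n_capped, nrow(pairs)))
  if (trace) message("training...")
  tr <- pathlink_train(structures, labels, control, seed = sub[2L])
  fitted_scores <- .score_examples(.prepare_examples(structures), tr$params)
  obj <- list(params = tr$params, loss_history = tr$loss_history,
              network = network, k = as.integer(k),
              literal_hops = literal_hops, path_cap = path_cap,
              control = control, seed = seed,
              pairs = data.frame(u = pairs[, 1L], v = pairs[, 2L],
                                 label = labels, fitted = fitted_scores),
              n_capped = n_capped, call = match.call())
  class(obj) <- "pathlink"
  obj
}

# extract structures for many pairs, suppressing per-pair cap warnings
.extract_all <- function(network, pairs, k, literal_hops, path_cap) {
  lapply(seq_len(nrow(pairs)), function(i)
    extract_local_structure(network, pairs[i, 1L], pairs[i, 2L], k,
                            literal_hops = literal_hops,
                            path_cap = path_cap, warn_cap = FALSE))
}

#' Predict link scores for node pairs
#'
#' Extracts the local structure of each query pair from `network` (by
#' default the graph the model was trained on) and scores it with the fitted
#' model. Scores lie in (0, 1) and estimate the probability that the pair is
#' linked.
#'
#' @param object A fitted [pathlink] model.
#' @param pairs Two-column matrix of (U index, V index) query pairs.
#' @param network Network to extract structures from; defaults to the
#'   training network. Pass the training graph (not the full graph) when
#'   scoring held-out test pairs to avoid leakage.
#' @param ... Unused.
#' @return Numeric vector of scores, one per row of `pairs`.
#' @export
predict.pathlink <- function(object, pairs, network = NULL, ...) {
  if (is.null(network)) network <- object$network
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
  structures <- .extract_all(network, pairs, object$k,
                             object$literal_hops, object$path_cap)
  .score_examples(.prepare_examples(structures), object$params)
}

#' @export
fitted.pathlink <- function(object, ...) object$pairs$fitted

#' @export
residuals.pathlink <- function(object, ...) {
  object$pairs$label - object$pairs$fitted
}

#' @export
coef.pathlink <- function(object, ...) object$params

#' @export
print.pathlink <- function(x, ...) {
  cat("Local-structure link prediction model\n")
  cat(sprintf("  network: |U| = %d, |V| = %d, %d edges\n",
              x$network$n_u, x$network$n_v, nrow(x$network$edges)))
  cat(sprintf("  depth k = %d (paths of %d edges), %d layers, hidden dim %d\n",
              x$k, if (x$literal_hops) x$k else 2L * x$k + 1L,
              x$control$num_layers, x$control$hidden_dim))
  cat(sprintf("  trained %d epochs on %d pairs; final training MSE %.4f\n",
              x$control$epochs, nrow(x$pairs),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.pathlink <- function(object, ...) {
  res <- list(
    k = object$k,
    control = object$control,
    n_pairs = nrow(object$pairs),
    n_pos = sum(object$pairs$label == 1L),
    n_capped = object$n_capped,
    final_loss = object$loss_history[length(object$loss_history)],
    train_mse = mse_loss(object$pairs$fitted, object$pairs$label),
    train_mae = mae(object$pairs$fitted, object$pairs$label),
    score_range = range(object$pairs$fitted),
    seed = object$seed)
  class(res) <- "summary.pathlink"
  res
}

#' @export
print.summary.pathlink <- function(x, ...) {
  cat("Local-structure link prediction model\n")
  cat(sprintf("  depth k = %d, %d layers, hidden dim %d, %d epochs (seed %d)\n",
              x$k, x$control$num_layers, x$control$hidden_dim,
              x$control$epochs, x$seed))
  cat(sprintf("  training pairs: %d (%d positive); %d hit the path cap\n",
              x$n_pairs, x$n_pos, x$n_capped))
  cat(sprintf("  training MSE %.4f, MAE %.4f; score range [%.3f, %.3f]\n",
              x$train_mse, x$train_mae, x$score_range[1L], x$score_range[2L]))
  invisible(x)
}

#' Plot the training loss curve
#'
#' @param x A fitted [pathlink] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pathlink <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training MSE",
                 main = "Training loss", ...)
  invisible(x)
}
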
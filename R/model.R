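#' Training configuration
#'
#' Hyperparameters of the link-scoring model and its SGD optimiser. Defaults
#' are the standard configuration used throughout the package: SGD with
#' learning rate 1e-2, momentum 0.9 and weight decay 1e-5, 80 epochs of
#' mini-batches of 5 structures, a 2-layer graph convolutional encoder with
#' hidden dimension 32.
#'
#' @param lr Learning rate (> 0).
#' @param momentum Momentum coefficient (>= 0).
#' @param weight_decay L2 weight decay added to the gradient (>= 0).
#' @param epochs Number of passes over the training set.
#' @param batch_size Structures per gradient update.
#' @param num_layers Graph convolution layers.
#' @param hidden_dim Hidden state dimension d.
#' @return An object of class `pathlink_control`.
#' @export
pathlink_control <- function(lr = 1e-2, momentum = 0.9, weight_decay = 1e-5,
                             epochs = 80L, batch_size = 5L,
                             num_layers = 2L, hidden_dim = 32L) {
  stopifnot(lr > 0, momentum >= 0, weight_decay >= 0,
            epochs >= 1, batch_size >= 1, num_layers >= 1, hidden_dim >= 1)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim)),
            class = "pathlink_control")
}

#' Initialise model parameters
#'
#' The model holds an input projection `P` (feature dim x d) mapping one-hot
#' node features into the hidden space, one d x d weight matrix per graph
#' convolution layer, and a readout vector `w` (length d) feeding the sigmoid
#' link scorer. Glorot-uniform initialisation draws each matrix from
#' U(-sqrt(6/(fan_in+fan_out)), +sqrt(...)); `init = "zero"` gives the
#' all-zero model, whose score is exactly 0.5 for every structure.
#'
#' @param feature_dim Input feature dimension (`k + 3` for depth `k`).
#' @param control A [pathlink_control()].
#' @param seed Integer seed for the random draw.
#' @param init `"glorot"` or `"zero"`.
#' @return An object of class `pathlink_params`: list with `P`, `W` (list of
#'   matrices) and `w`.
#' @export
pathlink_params <- function(feature_dim, control = pathlink_control(),
                            seed = 1L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  d <- control$hidden_dim
  f <- as.integer(feature_dim)
  stopifnot(f >= 1)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- if (init == "zero") {
    list(P = matrix(0, f, d),
         W = replicate(control$num_layers, matrix(0, d, d), simplify = FALSE),
         w = rep(0, d))
  } else {
    withr::with_seed(seed, list(
      P = glorot(f, d),
      W = replicate(control$num_layers, glorot(d, d), simplify = FALSE),
      w = as.vector(glorot(d, 1L))))
  }
  structure(params, class = "pathlink_params")
}

#' One graph convolution layer
#'
#' Updates every node state by adding the weighted sum of its neighbours'
#' states to its own and applying a ReLU:
#' `h_i' = relu(h_i + sum_{j in N(i)} W h_j)`. The self term is unweighted;
#' a node with no neighbours keeps `relu(h_i)`.
#'
#' @param H Numeric matrix of node states (nodes x d).
#' @param A Symmetric 0/1 adjacency matrix of the structure.
#' @param W d x d layer weight matrix.
#' @return Updated node-state matrix, same shape as `H`.
#' @export
gcn_layer <- function(H, A, W) {
  H <- as.matrix(H); A <- as.matrix(A); W <- as.matrix(W)
  if (ncol(H) != nrow(W) || nrow(W) != ncol(W))
    stop("state dimension does not match layer weight")
  if (nrow(A) != nrow(H) || ncol(A) != nrow(H))
    stop("adjacency dimension does not match node count")
  pmax(H + A %*% H %*% W, 0)
}

#' Encode a local structure into a fixed-size representation
#'
#' Projects the one-hot node features into the hidden space, applies the
#' configured number of graph convolution layers over the structure's
#' adjacency (target edge absent), and mean-pools the node states, giving a
#' length-d vector independent of the structure's size.
#'
#' @param ls A `local_structure`.
#' @param features Feature matrix aligned with the structure's canonical node
#'   order, e.g. from [node_features()].
#' @param params A [pathlink_params()] object.
#' @return Numeric vector of length `hidden_dim`.
#' @export
encode_structure <- function(ls, features, params) {
  stopifnot(inherits(ls, "local_structure"))
  n <- length(ls$u_nodes) + length(ls$v_nodes)
  features <- as.matrix(features)
  if (nrow(features) != n)
    stop("feature rows do not match the structure's node count")
  if (ncol(features) != nrow(params$P))
    stop("feature dimension does not match the input projection")
  A <- .structure_adjacency(ls)
  H <- features %*% params$P
  for (W in params$W) H <- gcn_layer(H, A, W)
  colMeans(H)
}

#' Score a structure representation
#'
#' Maps a structure representation to a link score in (0, 1) through the
#' readout weight and a sigmoid: `score = sigmoid(w . H_ls)`.
#'
#' @param H_ls Numeric vector of length `hidden_dim`.
#' @param params A [pathlink_params()] object.
#' @return Link score in (0, 1).
#' @export
predict_link <- function(H_ls, params) {
  if (!all(is.finite(H_ls))) stop("non-finite structure representation")
  z <- sum(params$w * H_ls)
  1 / (1 + exp(-z))
}

#' Mean squared error loss
#'
#' @param predictions Numeric vector of link scores.
#' @param labels 0/1 vector of the same length.
#' @return Mean of squared differences.
#' @export
mse_loss <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  if (length(predictions) == 0L) stop("empty prediction vector")
  mean((predictions - labels)^2)
}

# prepare (X, A) pairs for the C++ kernels
.prepare_examples <- function(structures) {
  lapply(structures, function(ls)
    list(X = node_features(ls), A = .structure_adjacency(ls)))
}

#' Train the link-scoring model on labelled local structures
#'
#' Minimises the mean squared error between sigmoid link scores and 0/1
#' existence labels by mini-batch SGD with momentum and weight decay
#' (PyTorch convention: `v <- momentum * v + grad + weight_decay * theta;
#' theta <- theta - lr * v`). Gradients are averaged within each shuffled
#' mini-batch. Fully reproducible for a fixed seed.
#'
#' @param structures List of `local_structure` objects (all with the same
#'   `k`).
#' @param labels 0/1 vector, one per structure; defaults to the structures'
#'   own labels.
#' @param control A [pathlink_control()].
#' @param seed Integer seed governing initialisation and batch shuffling.
#' @return List with `params` (a `pathlink_params`), `loss_history` (mean
#'   training MSE per epoch) and `feature_dim`.
#' @export
pathlink_train <- function(structures, labels = NULL,
                           control = pathlink_control(), seed = 1L) {
  if (length(structures) == 0L) stop("empty training set")
  if (is.null(labels)) labels <- vapply(structures, `[[`, integer(1), "label")
  if (length(labels) != length(structures))
    stop("labels and structures differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  k <- structures[[1L]]$k
  f <- k + 3L
  ex <- .prepare_examples(structures)
  n <- length(ex)
  withr::with_seed(seed, {
    params <- pathlink_params(f, control, seed = seed)
    vel <- list(P = params$P * 0,
                W = lapply(params$W, function(W) W * 0),
                w = params$w * 0)
    loss_history <- numeric(control$epochs)
    for (epoch in seq_len(control$epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      ep_loss <- 0
      for (b in batches) {
        gP <- params$P * 0
        gW <- lapply(params$W, function(W) W * 0)
        gw <- params$w * 0
        for (i in b) {
          gr <- .cpp_gcn_grad(ex[[i]]$X, ex[[i]]$A, params$P, params$W,
                              params$w, labels[i])
          gP <- gP + gr$gP
          for (l in seq_along(gW)) gW[[l]] <- gW[[l]] + gr$gW[[l]]
          gw <- gw + gr$gw
          ep_loss <- ep_loss + (gr$score - labels[i])^2
        }
        nb <- length(b)
        cfg <- control
        step <- function(theta, g, v) {
          v <- cfg$momentum * v + g / nb + cfg$weight_decay * theta
          list(theta = theta - cfg$lr * v, v = v)
        }
        sP <- step(params$P, gP, vel$P)
        params$P <- sP$theta; vel$P <- sP$v
        for (l in seq_along(params$W)) {
          sW <- step(params$W[[l]], gW[[l]], vel$W[[l]])
          params$W[[l]] <- sW$theta; vel$W[[l]] <- sW$v
        }
        sw <- step(params$w, gw, vel$w)
        params$w <- sw$theta; vel$w <- sw$v
      }
      loss_history[epoch] <- ep_loss / n
    }
  })
  list(params = params, loss_history = loss_history, feature_dim = f)
}

# score prepared examples with the C++ forward pass
.score_examples <- function(ex, params) {
  vapply(ex, function(e)
    .cpp_gcn_score(e$X, e$A, params$P, params$W, params$w), numeric(1))
}
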
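test_that("the graph convolution layer matches hand computations", {
  # all-zero states stay zero
  A <- matrix(0, 3, 3)
  expect_equal(gcn_layer(matrix(0, 3, 2), A, diag(2)), matrix(0, 3, 2))

  # isolated node with non-negative state is unchanged
  H <- rbind(c(1, 2), c(0.5, 0))
  expect_equal(gcn_layer(H, matrix(0, 2, 2), diag(2)), H)

  # two connected nodes, identity weight: each receives the other's state
  A2 <- rbind(c(0, 1), c(1, 0))
  a <- c(1, 2); b <- c(3, 4)
  expect_equal(gcn_layer(rbind(a, b), A2, diag(2)),
               rbind(a + b, b + a), ignore_attr = TRUE)

  # negative pre-activations are clipped by the ReLU
  W <- -diag(2)
  expect_equal(gcn_layer(rbind(a, b), A2, W),
               pmax(rbind(a - b, b - a), 0), ignore_attr = TRUE)

  expect_error(gcn_layer(matrix(0, 2, 3), A2, diag(2)), "dimension")
  expect_error(gcn_layer(matrix(0, 3, 2), A2, diag(2)), "node count")
})

test_that("structure encoding mean-pools node states and ignores node order", {
  fx <- toy_fixture()
  ls <- extract_local_structure(fx$network, 1, 2, 1)
  ctl <- pathlink_control(hidden_dim = 4L, num_layers = 1L)
  params <- pathlink_params(4L, ctl, seed = 1)
  # identity projection and identity layer weight: hand-rolled matrix oracle
  params$P <- diag(4); params$W <- list(diag(4))
  X <- node_features(ls)
  A <- pathlink:::.structure_adjacency(ls)
  byhand <- colMeans(pmax(X + A %*% X %*% diag(4), 0))
  expect_equal(encode_structure(ls, X, params), byhand)

  # permutation invariance of the mean readout, via the raw forward pass
  params2 <- pathlink_params(4L, ctl, seed = 2)
  perm <- c(3, 1, 4, 2)
  s1 <- r_forward_score(X, A, params2)
  s2 <- r_forward_score(X[perm, ], A[perm, perm], params2)
  expect_equal(s1, s2)

  # two nodes with final states (1,0) and (0,1) average to (0.5, 0.5)
  expect_equal(colMeans(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
})

test_that("the link scorer is a sigmoid of the readout projection", {
  ctl <- pathlink_control(hidden_dim = 3L)
  params <- pathlink_params(6L, ctl, seed = 1, init = "zero")
  expect_equal(predict_link(c(1, 2, 3), params), 0.5)

  params$w <- c(1, 0, 0)
  expect_equal(predict_link(c(0.8473, 5, -2), params),
               1 / (1 + exp(-0.8473)))
  expect_equal(round(predict_link(c(0.8473, 0, 0), params), 4), 0.7)

  # strictly increasing in the pre-activation
  zs <- seq(-4, 4, by = 0.5)
  scores <- vapply(zs, function(z) predict_link(c(z, 0, 0), params), numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(predict_link(c(NaN, 0, 0), params), "non-finite")
})

test_that("mse_loss equals the loop-computed mean of squared differences", {
  expect_equal(mse_loss(c(0, 1), c(0, 1)), 0)
  expect_equal(mse_loss(0.5, 1), 0.25)
  set.seed(31)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  acc <- 0
  for (i in 1:50) acc <- acc + (p[i] - y[i])^2
  expect_equal(mse_loss(p, y), acc / 50)
  expect_error(mse_loss(c(0.1, 0.2), 1), "length")
})

test_that("C++ forward and gradients agree with the R oracle and finite differences", {
  set.seed(32)
  for (rep in 1:10) {
    net <- random_bipartite(5, 5, 0.4)
    ls <- extract_local_structure(net, sample(5, 1), sample(5, 1), 1,
                                  warn_cap = FALSE)
    ctl <- pathlink_control(hidden_dim = 6L)
    params <- pathlink_params(4L, ctl, seed = rep)
    X <- node_features(ls)
    A <- pathlink:::.structure_adjacency(ls)
    r_score <- r_forward_score(X, A, params)
    expect_equal(pathlink:::.cpp_gcn_score(X, A, params$P, params$W, params$w),
                 r_score)
    gr <- pathlink:::.cpp_gcn_grad(X, A, params$P, params$W, params$w, 1)
    expect_equal(gr$score, r_score)
    # spot-check gradient entries against central differences of the R oracle
    eps <- 1e-6
    loss <- function(pp) (r_forward_score(X, A, pp) - 1)^2
    for (probe in 1:4) {
      i <- sample(length(params$P), 1)
      pp <- params; pm <- params
      pp$P[i] <- pp$P[i] + eps; pm$P[i] <- pm$P[i] - eps
      expect_equal(gr$gP[i], (loss(pp) - loss(pm)) / (2 * eps), tolerance = 1e-4)
      j <- sample(length(params$w), 1)
      pp <- params; pm <- params
      pp$w[j] <- pp$w[j] + eps; pm$w[j] <- pm$w[j] - eps
      expect_equal(gr$gw[j], (loss(pp) - loss(pm)) / (2 * eps), tolerance = 1e-4)
      l <- sample(length(params$W), 1)
      m <- sample(length(params$W[[l]]), 1)
      pp <- params; pm <- params
      pp$W[[l]][m] <- pp$W[[l]][m] + eps; pm$W[[l]][m] <- pm$W[[l]][m] - eps
      expect_equal(gr$gW[[l]][m], (loss(pp) - loss(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("the zero model scores exactly 0.5 and training is seed-reproducible", {
  set.seed(33)
  net <- random_bipartite(6, 6, 0.35, min_edges = 8L)
  pairs <- rbind(net$edges[1:4, ], cbind(c(1, 2), c(6, 6)))
  structures <- lapply(seq_len(nrow(pairs)), function(i)
    extract_local_structure(net, pairs[i, 1], pairs[i, 2], 1, warn_cap = FALSE))
  ctl <- pathlink_control(epochs = 10L, hidden_dim = 8L)

  zero <- pathlink_params(4L, ctl, init = "zero")
  scores <- vapply(structures, function(ls)
    predict_link(encode_structure(ls, node_features(ls), zero), zero), numeric(1))
  expect_equal(scores, rep(0.5, length(scores)))

  labs <- c(1, 1, 1, 1, 0, 0)
  a <- pathlink_train(structures, labs, ctl, seed = 5)
  b <- pathlink_train(structures, labs, ctl, seed = 5)
  expect_identical(a, b)
  c2 <- pathlink_train(structures, labs, ctl, seed = 6)
  expect_false(identical(a$params, c2$params))
  expect_error(pathlink_train(list(), numeric(0), ctl), "empty")
  expect_error(pathlink_train(structures, labs[-1], ctl), "length")
})

test_that("training loss decreases on small datasets for almost every seed", {
  set.seed(34)
  net <- random_bipartite(8, 8, 0.35, min_edges = 10L)
  pos <- net$edges[1:5, , drop = FALSE]
  neg <- sample_negatives(net, 5, seed = 9)
  pairs <- rbind(pos, neg)
  structures <- lapply(seq_len(nrow(pairs)), function(i)
    extract_local_structure(net, pairs[i, 1], pairs[i, 2], 1, warn_cap = FALSE))
  labs <- c(rep(1, 5), rep(0, 5))
  drops <- vapply(1:20, function(s) {
    h <- pathlink_train(structures, labs, pathlink_control(), seed = s)$loss_history
    h[length(h)] < h[1L]
  }, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("the model fits a planted rich-vs-empty signal to low error", {
  # positives embedded in many connecting paths, negatives isolated
  set.seed(35)
  core <- expand.grid(u = 1:5, v = 1:5)
  net <- bipartite_network(as.matrix(core), n_u = 8, n_v = 8)
  pos <- as.matrix(core[core$u <= 5 & core$v <= 5, ])[1:6, ]
  neg <- cbind(c(6, 7, 8, 6, 7, 8), c(6, 7, 8, 7, 8, 6))
  pairs <- rbind(pos, neg)
  structures <- lapply(seq_len(nrow(pairs)), function(i)
    extract_local_structure(net, pairs[i, 1], pairs[i, 2], 1, warn_cap = FALSE))
  labs <- c(rep(1, 6), rep(0, 6))
  tr <- pathlink_train(structures, labs, pathlink_control(epochs = 200L), seed = 2)
  scores <- vapply(seq_along(structures), function(i)
    pathlink:::.cpp_gcn_score(node_features(structures[[i]]),
                              pathlink:::.structure_adjacency(structures[[i]]),
                              tr$params$P, tr$params$W, tr$params$w), numeric(1))
  expect_lt(mse_loss(scores, labs), 0.05)
})

test_that("the fitted model object supports the standard S3 verbs", {
  set.seed(36)
  net <- generate_block_bipartite(block_model_spec(
    n_u = 16, n_v = 16, blocks_u = rep(1:2, each = 8),
    blocks_v = rep(1:2, each = 8), p_in = 0.4, p_out = 0.05, seed = 4))
  ctl <- pathlink_control(epochs = 8L, hidden_dim = 8L)
  fit <- pathlink(net, k = 1, control = ctl, seed = 3)
  expect_s3_class(fit, "pathlink")
  expect_length(fitted(fit), 2L * nrow(net$edges))
  expect_equal(residuals(fit), fit$pairs$label - fitted(fit))
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  expect_named(coef(fit), c("P", "W", "w"))
  expect_length(fit$loss_history, 8L)
  expect_output(print(fit), "link prediction")
  expect_output(print(summary(fit)), "training MSE")
  p <- predict(fit, cbind(c(1, 16), c(2, 16)))
  expect_length(p, 2L)
  expect_true(all(p > 0 & p < 1))
  # reproducibility of the whole fit
  fit2 <- pathlink(net, k = 1, control = ctl, seed = 3)
  expect_equal(fit$params, fit2$params)
  expect_equal(fitted(fit), fitted(fit2))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
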
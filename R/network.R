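#' Construct a bipartite network
#'
#' A bipartite network has two disjoint node partitions, U and V, and
#' unweighted undirected edges that only cross partitions. Nodes are addressed
#' by dense 1-based indices within their partition; original file identifiers
#' (when the network was read from disk) are kept in `u_ids` / `v_ids`.
#'
#' @param edges Two-column matrix or data frame of edges; column 1 holds
#'   U-partition indices, column 2 V-partition indices. Duplicate rows are
#'   collapsed.
#' @param n_u,n_v Partition sizes. Default: the largest index seen in the
#'   corresponding column. Nodes with no edges are allowed.
#' @param u_ids,v_ids Optional external identifiers, one per node, kept for
#'   writing the network back out.
#' @return An object of class `bipartite_network` with fields `edges`
#'   (canonically sorted integer matrix), `n_u`, `n_v`, `u_ids`, `v_ids`.
#' @examples
#' net <- bipartite_network(cbind(c(1, 2, 2), c(1, 1, 2)))
#' net
#' @export
bipartite_network <- function(edges, n_u = NULL, n_v = NULL,
                              u_ids = NULL, v_ids = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have exactly two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("`edges` contains missing values")
  if (nrow(edges) > 0L && any(edges < 1L)) stop("node indices must be >= 1")
  if (is.null(n_u)) n_u <- if (nrow(edges)) max(edges[, 1L]) else 0L
  if (is.null(n_v)) n_v <- if (nrow(edges)) max(edges[, 2L]) else 0L
  n_u <- as.integer(n_u); n_v <- as.integer(n_v)
  if (nrow(edges) && (max(edges[, 1L]) > n_u || max(edges[, 2L]) > n_v))
    stop("edge endpoint exceeds partition size")
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("u", "v"))
  if (!is.null(u_ids) && length(u_ids) != n_u) stop("`u_ids` length must be n_u")
  if (!is.null(v_ids) && length(v_ids) != n_v) stop("`v_ids` length must be n_v")
  structure(list(edges = edges, n_u = n_u, n_v = n_v,
                 u_ids = u_ids, v_ids = v_ids),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite network: |U| = %d, |V| = %d, %d edges\n",
              x$n_u, x$n_v, nrow(x$edges)))
  invisible(x)
}

# pair -> scalar key for set operations on U x V
.edge_keys <- function(u, v, n_v) (as.double(u) - 1) * n_v + as.double(v)

.keys_to_pairs <- function(keys, n_v) {
  u <- as.integer((keys - 1) %/% n_v) + 1L
  v <- as.integer((keys - 1) %% n_v) + 1L
  cbind(u = u, v = v)
}

# round half away from zero (base round() is round-half-even)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

.sort_pairs <- function(p) {
  p <- as.matrix(p); storage.mode(p) <- "integer"
  dimnames(p) <- list(NULL, c("u", "v"))
  p[order(p[, 1L], p[, 2L]), , drop = FALSE]
}

#' Read a bipartite edge list
#'
#' Parses KONECT-style edge lists: lines starting with `%` or `#` are
#' comments; data lines carry at least two whitespace-separated integer
#' tokens (U id, V id); trailing columns such as weights or timestamps are
#' ignored; duplicate lines collapse to one edge. File identifiers may be
#' arbitrary positive integers; they are mapped to dense 1-based indices per
#' partition and the id maps are retained on the returned network.
#'
#' @param path Path to the edge-list file.
#' @param format `"konect"`, `"tsv"` or `"auto"`; all use the same tolerant
#'   parser, the argument documents intent.
#' @return A [bipartite_network].
#' @export
read_edge_list <- function(path, format = c("auto", "konect", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  us <- integer(0); vs <- integer(0)
  n_data <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "%") || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) < 2L || !all(grepl("^[0-9]+$", tok[1:2])))
      stop(sprintf("parse error at line %d of %s: expected two integer ids, got '%s'",
                   i, path, lines[i]))
    n_data <- n_data + 1L
    us[n_data] <- as.integer(tok[1L])
    vs[n_data] <- as.integer(tok[2L])
  }
  if (n_data == 0L) stop("no data lines in ", path)
  u_ids <- sort(unique(us)); v_ids <- sort(unique(vs))
  bipartite_network(cbind(match(us, u_ids), match(vs, v_ids)),
                    n_u = length(u_ids), n_v = length(v_ids),
                    u_ids = u_ids, v_ids = v_ids)
}

#' Write a bipartite edge list
#'
#' Emits a sorted two-column whitespace-separated edge list with a `%`
#' provenance header (KONECT dialect). External ids are used when the network
#' carries them, otherwise the internal indices.
#'
#' @param net A [bipartite_network].
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  u <- if (is.null(net$u_ids)) net$edges[, 1L] else net$u_ids[net$edges[, 1L]]
  v <- if (is.null(net$v_ids)) net$edges[, 2L] else net$v_ids[net$edges[, 2L]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%% bip unweighted bipartite edge list (|U|=%d |V|=%d m=%d)",
                     net$n_u, net$n_v, nrow(net$edges)), con)
  writeLines(paste(u, v, sep = "\t"), con)
  invisible(path)
}

# internal impl assuming the RNG state is already set
.sample_negatives_impl <- function(net, count, exclude = NULL) {
  total <- as.double(net$n_u) * net$n_v
  taken <- .edge_keys(net$edges[, 1L], net$edges[, 2L], net$n_v)
  if (!is.null(exclude) && nrow(exclude) > 0L)
    taken <- c(taken, .edge_keys(exclude[, 1L], exclude[, 2L], net$n_v))
  eligible <- setdiff(seq_len(total), taken)
  if (count > length(eligible))
    stop(sprintf("cannot sample %d negatives: only %d non-edge pairs available",
                 count, length(eligible)))
  keys <- if (length(eligible) == 1L) eligible else sample(eligible, count)
  .keys_to_pairs(keys[seq_len(count)], net$n_v)
}

#' Sample non-edge node pairs
#'
#' Draws `count` distinct U x V pairs uniformly from the pairs that are not
#' edges of `net` and not in `exclude`. Used to build negative examples for
#' training and testing.
#'
#' @param net A [bipartite_network].
#' @param count Number of pairs to draw.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param exclude Optional two-column matrix of pairs to exclude as well.
#' @return Two-column integer matrix of pairs.
#' @export
sample_negatives <- function(net, count, seed, exclude = NULL) {
  stopifnot(inherits(net, "bipartite_network"), count >= 0)
  withr::with_seed(seed, .sample_negatives_impl(net, count, exclude))
}

#' Split edges into train/test with matched negatives
#'
#' Uniformly assigns a fraction of the edges to the test set (rounding half
#' away from zero, remainder to training) and samples an equal number of
#' non-edge pairs for each side. Negatives are drawn once, are pairwise
#' distinct, and never coincide with an edge of the original network.
#'
#' @param net A [bipartite_network] with at least 2 edges.
#' @param test_fraction Fraction of edges withheld for testing, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `edge_split` with fields `train_pos`,
#'   `test_pos`, `train_neg`, `test_neg` (two-column integer matrices),
#'   `seed` and `test_fraction`.
#' @export
split_edges <- function(net, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie strictly between 0 and 1")
  m <- nrow(net$edges)
  if (m < 2L) stop("network must have at least 2 edges to split")
  n_test <- as.integer(.round_half_up(test_fraction * m))
  withr::with_seed(seed, {
    test_idx <- sort(sample(m, n_test))
    negs <- .sample_negatives_impl(net, m)  # |train_neg| + |test_neg| = m
  })
  train_pos <- net$edges[setdiff(seq_len(m), test_idx), , drop = FALSE]
  test_pos <- net$edges[test_idx, , drop = FALSE]
  structure(list(train_pos = train_pos,
                 test_pos = test_pos,
                 train_neg = negs[seq_len(m - n_test), , drop = FALSE],
                 test_neg = negs[(m - n_test) + seq_len(n_test), , drop = FALSE],
                 seed = seed, test_fraction = test_fraction),
            class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("Edge split (seed %d): %d/%d train/test positives, %d/%d negatives\n",
              x$seed, nrow(x$train_pos), nrow(x$test_pos),
              nrow(x$train_neg), nrow(x$test_neg)))
  invisible(x)
}

#' Randomly thin the edges of a network
#'
#' Retains a uniformly chosen subset of `round(retain_fraction * m)` edges
#' (rounding half away from zero). Partition sizes are unchanged; nodes left
#' without edges stay in the network. Used for link-sparsity experiments.
#'
#' @param net A [bipartite_network].
#' @param retain_fraction Fraction of edges kept, in (0, 1].
#' @param seed Integer seed.
#' @return A [bipartite_network] whose edges are a subset of `net`'s.
#' @export
subsample_links <- function(net, retain_fraction, seed = 1L) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.numeric(retain_fraction) || retain_fraction <= 0 || retain_fraction > 1)
    stop("`retain_fraction` must lie in (0, 1]")
  if (retain_fraction == 1) return(net)
  m <- nrow(net$edges)
  keep <- as.integer(.round_half_up(retain_fraction * m))
  idx <- withr::with_seed(seed, sort(sample(m, keep)))
  out <- net
  out$edges <- net$edges[idx, , drop = FALSE]
  out
}

# network minus the given edges (partitions unchanged)
.remove_edges <- function(net, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(net)
  keys <- .edge_keys(net$edges[, 1L], net$edges[, 2L], net$n_v)
  drop <- .edge_keys(pairs[, 1L], pairs[, 2L], net$n_v)
  out <- net
  out$edges <- net$edges[!(keys %in% drop), , drop = FALSE]
  out
}

# TRUE for each pair that is an edge of net
.has_edge <- function(net, u, v) {
  keys <- .edge_keys(net$edges[, 1L], net$edges[, 2L], net$n_v)
  .edge_keys(u, v, net$n_v) %in% keys
}

# adjacency list in combined indexing: U node i -> i, V node j -> n_u + j
.adjacency <- function(net) {
  n <- net$n_u + net$n_v
  adj <- vector("list", n)
  e <- net$edges
  uu <- e[, 1L]; vv <- net$n_u + e[, 2L]
  adj_u <- split(vv, factor(uu, levels = seq_len(net$n_u)))
  adj_v <- split(uu, factor(vv, levels = net$n_u + seq_len(net$n_v)))
  for (i in seq_len(net$n_u)) adj[[i]] <- sort(as.integer(adj_u[[i]]))
  for (j in seq_len(net$n_v)) adj[[net$n_u + j]] <- sort(as.integer(adj_v[[j]]))
  adj
}
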
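#' Generate biased second-order random walks
#'
#' Walks follow the node2vec scheme: from current node `v` having arrived
#' from `t`, the unnormalised weight of stepping to neighbour `x` is `1/p`
#' if `x = t` (return), `1` if `x` is adjacent to `t`, and `1/q` otherwise.
#' `p = q = 1` reduces to a simple uniform random walk (and takes a faster
#' code path). The bipartite graph is walked as-is on its undirected view,
#' so walks alternate compound and reaction nodes. Runs are bit-reproducible
#' for a fixed seed.
#'
#' @param graph An `mlnet`, igraph object or edge tibble (`from`, `to`).
#' @param p Return parameter (> 0).
#' @param q In–out parameter (> 0).
#' @param walk_length Maximum walk length in nodes.
#' @param walks_per_node Number of walks started at every node.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A `walk_corpus`: list with `walks` (list of character vectors)
#'   and the parameters used. Isolated nodes yield length-1 walks.
#' @export
generate_walks <- function(graph, p = 1, q = 1, walk_length = 80,
                           walks_per_node = 10, seed = 1L) {
  stopifnot(p > 0, q > 0, walk_length >= 1, walks_per_node >= 1)
  g <- if (igraph::is_igraph(graph)) graph
       else if (inherits(graph, "mlnet")) as_igraph(graph, directed = FALSE)
       else igraph::graph_from_data_frame(as_tibble(graph), directed = FALSE)
  g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  n <- length(adj)
  uniform <- p == 1 && q == 1

  set.seed(seed)
  walks <- vector("list", n * walks_per_node)
  w_i <- 0L
  for (rep in seq_len(walks_per_node)) {
    for (start in seq_len(n)) {
      walk <- integer(walk_length)
      walk[1L] <- start
      len <- 1L
      if (length(adj[[start]]) > 0L) {
        nb <- adj[[start]]
        walk[2L] <- nb[sample.int(length(nb), 1L)]
        len <- 2L
        while (len < walk_length) {
          v <- walk[len]
          nb <- adj[[v]]
          if (length(nb) == 0L) break
          if (uniform) {
            nxt <- nb[sample.int(length(nb), 1L)]
          } else {
            t_prev <- walk[len - 1L]
            w <- ifelse(nb == t_prev, 1 / p,
                        ifelse(nb %in% adj[[t_prev]], 1, 1 / q))
            nxt <- nb[sample.int(length(nb), 1L, prob = w)]
          }
          len <- len + 1L
          walk[len] <- nxt
        }
      }
      w_i <- w_i + 1L
      walks[[w_i]] <- nodes[walk[seq_len(len)]]
    }
  }
  structure(
    list(walks = walks, p = p, q = q, walk_length = walk_length,
         walks_per_node = walks_per_node, seed = seed, nodes = nodes),
    class = "walk_corpus"
  )
}

#' Train node embeddings from a walk corpus
#'
#' Embeddings are learned from walk-context co-occurrences: token pairs
#' within the window are counted symmetrically, converted to a positive
#' pointwise-mutual-information (PPMI) matrix, and factorised with a seeded
#' randomized truncated SVD; node vectors are the left singular vectors
#' scaled by the square roots of the singular values. Nodes sharing walk
#' contexts therefore end up with higher cosine similarity than nodes with
#' disjoint contexts.
#'
#' @param corpus A `walk_corpus`.
#' @param dimension Embedding dimension (default 128; capped at the number
#'   of distinct nodes).
#' @param window Context window in tokens on each side (default 10).
#' @param seed Seed for the randomized factorisation.
#' @param nodes Optional full node-id vector; nodes absent from the corpus
#'   receive a zero vector with a warning.
#' @return Numeric matrix, one named row per node.
#' @export
embed_nodes <- function(corpus, dimension = 128L, window = 10L, seed = 1L,
                        nodes = NULL) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (length(corpus$walks) == 0L) abort("empty walk corpus")
  vocab <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  nv <- length(vocab)
  pairs <- lapply(corpus$walks, function(w) {
    iw <- match(w, vocab)
    L <- length(iw)
    if (L < 2L) return(NULL)
    offs <- seq_len(min(window, L - 1L))
    a <- unlist(lapply(offs, function(off) iw[seq_len(L - off)]), use.names = FALSE)
    b <- unlist(lapply(offs, function(off) iw[seq.int(off + 1L, L)]), use.names = FALSE)
    list(i = c(a, b), j = c(b, a))
  })
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (length(pairs) == 0L) {
    emb <- matrix(0, nrow = nv, ncol = 1L, dimnames = list(vocab, NULL))
  } else {
    ii <- unlist(lapply(pairs, `[[`, "i"), use.names = FALSE)
    jj <- unlist(lapply(pairs, `[[`, "j"), use.names = FALSE)
    X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nv, nv))
    tot <- sum(X)
    rs <- Matrix::rowSums(X)
    trip <- Matrix::summary(X)
    pmi <- log(trip$x * tot / (rs[trip$i] * rs[trip$j]))
    keep <- pmi > 0
    M <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep], x = pmi[keep],
                              dims = c(nv, nv))
    d <- min(as.integer(dimension), nv)
    sv <- randomized_svd(M, rank = d, seed = seed)
    emb <- sv$u %*% diag(sqrt(pmax(sv$d, 0)), nrow = length(sv$d))
    # fix sign indeterminacy per component for reproducibility
    for (c_i in seq_len(ncol(emb))) {
      peak <- which.max(abs(emb[, c_i]))
      if (emb[peak, c_i] < 0) emb[, c_i] <- -emb[, c_i]
    }
    rownames(emb) <- vocab
  }
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, rownames(emb))
    if (length(missing)) {
      warn(paste0(length(missing), " node(s) absent from the walk corpus; ",
                  "assigned zero vectors"))
      emb <- rbind(emb, matrix(0, nrow = length(missing), ncol = ncol(emb),
                               dimnames = list(missing, NULL)))
    }
    emb <- emb[nodes, , drop = FALSE]
  }
  emb
}

# Halko-style randomized truncated SVD with subspace iteration; deterministic
# for a fixed seed.
randomized_svd <- function(M, rank, seed = 1L, oversample = 10L, iters = 2L) {
  n <- ncol(M)
  r <- min(rank + oversample, n)
  set.seed(seed)
  Omega <- matrix(rnorm(n * r), nrow = n)
  Y <- as.matrix(M %*% Omega)
  Q <- qr.Q(qr(Y))
  for (it in seq_len(iters)) {
    Z <- as.matrix(Matrix::crossprod(M, Q))
    Q <- qr.Q(qr(as.matrix(M %*% Z)))
  }
  B <- as.matrix(Matrix::crossprod(Q, M))
  sv <- svd(B, nu = rank, nv = 0)
  list(u = Q %*% sv$u, d = sv$d[seq_len(rank)])
}

#' Reduce embeddings to two dimensions
#'
#' Principal-component projection of the embedding matrix onto its first two
#' components, for plotting only; quantitative separation analyses operate
#' on the full-dimensional vectors.
#'
#' @param matrix Embedding matrix (named rows).
#' @param seed Unused by the deterministic projection; kept so callers can
#'   treat all reducers uniformly.
#' @return Tibble `node_id`, `x`, `y`.
#' @export
reduce_2d <- function(matrix, seed = 1L) {
  ncomp <- min(2L, ncol(matrix))
  pc <- prcomp(matrix, center = TRUE, scale. = FALSE, rank. = ncomp)
  co <- pc$x
  tibble(node_id = rownames(matrix),
         x = co[, 1],
         y = if (ncol(co) >= 2L) co[, 2] else 0)
}

#' Layer/module separation score of an embedding
#'
#' Ratio of the mean inter-label pairwise Euclidean distance to the mean
#' intra-label pairwise distance. Values above 1 indicate that same-label
#' nodes sit closer together than different-label nodes; randomly assigned
#' labels score about 1. Invariant under global rotation and translation of
#' the vectors.
#'
#' @param x Embedding matrix (rows = nodes) or 2-column coordinate matrix.
#' @param labels Label per row; at least two distinct labels required.
#' @param max_n Pairwise distances are computed on at most this many rows
#'   (evenly strided, deterministic) to bound memory on large networks.
#' @return Numeric scalar.
#' @export
separation_score <- function(x, labels, max_n = 4000L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) abort("separation_score needs at least two labels")
  if (nrow(x) > max_n) {
    idx <- unique(round(seq(1L, nrow(x), length.out = max_n)))
    x <- x[idx, , drop = FALSE]
    labels <- labels[idx]
    if (length(unique(labels)) < 2L) abort("subsampled rows lost a label; lower max_n")
  }
  D <- as.matrix(dist(x))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  ut <- upper.tri(D)
  intra <- mean(D[ut & same & !is.na(same)])
  inter <- mean(D[ut & !same])
  inter / intra
}
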
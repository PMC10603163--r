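test_that("p = q = 1 walks are uniform on a triangle", {
  tri <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"))
  corpus <- generate_walks(tri, walk_length = 2000, walks_per_node = 1, seed = 5)
  # on a triangle every step has two choices; empirical split should be ~50/50
  w <- corpus$walks[[1]]
  trans <- table(head(w, -1), tail(w, -1))
  for (v in c("a", "b", "c")) {
    others <- setdiff(c("a", "b", "c"), v)
    p_hat <- trans[v, others[1]] / sum(trans[v, ])
    expect_gt(p_hat, 0.4); expect_lt(p_hat, 0.6)
  }
})

test_that("return parameter p shapes walks on a single edge", {
  edge <- tibble::tibble(from = "a", to = "b")
  # only one neighbour exists, so walks must alternate regardless of p
  corpus <- generate_walks(edge, p = 10, q = 1, walk_length = 8, walks_per_node = 1, seed = 2)
  expect_equal(corpus$walks[[1]], rep(c("a", "b"), 4))
})

test_that("second-order bias matches the analytic transition law", {
  # path graph t - v - x plus edge t - w (w adjacent to t, x not)
  edges <- tibble::tibble(from = c("t", "v", "t"), to = c("v", "x", "w"))
  # from v, having come from t: neighbours are {t, x}; weights 1/p and 1/q
  p <- 4; q <- 0.25
  corpus <- generate_walks(edges, p = p, q = q, walk_length = 3,
                           walks_per_node = 4000, seed = 31)
  starts_tv <- Filter(function(w) length(w) == 3 && w[1] == "t" && w[2] == "v",
                      corpus$walks)
  thirds <- vapply(starts_tv, `[[`, character(1), 3)
  p_x <- mean(thirds == "x")
  expected <- (1 / q) / (1 / p + 1 / q)   # 4/(4.25)
  se3 <- 3 * sqrt(expected * (1 - expected) / length(thirds))
  expect_lt(abs(p_x - expected), se3 + 0.01)
})

test_that("walks are bit-reproducible under a fixed seed and respect dead ends", {
  gen <- generate_network(small_config(seed = 43))
  c1 <- generate_walks(gen$net, walk_length = 10, walks_per_node = 2, seed = 7)
  c2 <- generate_walks(gen$net, walk_length = 10, walks_per_node = 2, seed = 7)
  expect_identical(c1$walks, c2$walks)
  c3 <- generate_walks(gen$net, walk_length = 10, walks_per_node = 2, seed = 8)
  expect_false(identical(c1$walks, c3$walks))
  # isolated node -> walk of length 1
  iso <- igraph::make_empty_graph(1) |> igraph::set_vertex_attr("name", value = "solo")
  expect_equal(generate_walks(iso, walk_length = 5, walks_per_node = 1, seed = 1)$walks[[1]],
               "solo")
})

test_that("disconnected cliques embed with intra > inter cosine similarity", {
  clique_edges <- function(ids) {
    pairs <- t(combn(ids, 2))
    tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  }
  g <- dplyr::bind_rows(clique_edges(sprintf("a%d", 1:6)),
                        clique_edges(sprintf("b%d", 1:6)))
  corpus <- generate_walks(g, walk_length = 20, walks_per_node = 10, seed = 9)
  emb <- embed_nodes(corpus, dimension = 16, window = 5, seed = 10)
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ids_a <- sprintf("a%d", 1:6); ids_b <- sprintf("b%d", 1:6)
  intra <- c(combn(ids_a, 2, function(p) cos(emb[p[1], ], emb[p[2], ])),
             combn(ids_b, 2, function(p) cos(emb[p[1], ], emb[p[2], ])))
  inter <- as.vector(outer(ids_a, ids_b,
                           Vectorize(function(i, j) cos(emb[i, ], emb[j, ]))))
  expect_gt(mean(intra), mean(inter))
})

test_that("structurally equivalent twins are more similar than the corpus median", {
  # twins t1, t2 share the same neighbour set {h1, h2, h3}
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(from = c("t1", "t2"), to = c("h1", "h2", "h3")),
    tibble::tibble(from = c("h1", "h2", "h3", "u1", "u2"),
                   to = c("u1", "u2", "u3", "u4", "u5"))
  )
  corpus <- generate_walks(edges, walk_length = 15, walks_per_node = 20, seed = 11)
  emb <- embed_nodes(corpus, dimension = 8, window = 4, seed = 12)
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  twin_sim <- cos(emb["t1", ], emb["t2", ])
  ids <- rownames(emb)
  all_sims <- combn(ids, 2, function(p) cos(emb[p[1], ], emb[p[2], ]))
  expect_gt(twin_sim, median(all_sims))
})

test_that("single-node and missing-node cases are handled", {
  iso <- igraph::make_empty_graph(1) |> igraph::set_vertex_attr("name", value = "solo")
  corpus <- generate_walks(iso, walk_length = 3, walks_per_node = 1, seed = 1)
  emb <- embed_nodes(corpus, dimension = 4, seed = 2)
  expect_true(all(is.finite(emb)))
  expect_warning(
    emb2 <- embed_nodes(corpus, dimension = 4, seed = 2, nodes = c("solo", "ghost")),
    "absent"
  )
  expect_true(all(emb2["ghost", ] == 0))
})

test_that("separation score detects separated clouds and is rigid-motion invariant", {
  set.seed(14)
  a <- matrix(rnorm(200, 0, 0.1), ncol = 2)
  b <- matrix(rnorm(200, 50, 0.1), ncol = 2)
  x <- rbind(a, b)
  labs <- rep(c("A", "B"), each = 100)
  expect_gt(separation_score(x, labs), 50)
  # rotation + translation leave the score unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  x2 <- sweep(x %*% R, 2, c(5, -3), "+")
  expect_equal(separation_score(x2, labs), separation_score(x, labs))
  expect_error(separation_score(x, rep("A", 200)), "two labels")
})

test_that("random labels score about 1", {
  set.seed(15)
  x <- matrix(rnorm(500 * 8), ncol = 8)
  labs <- sample(c("A", "B"), 500, replace = TRUE)
  s <- separation_score(x, labs)
  expect_gt(s, 0.9); expect_lt(s, 1.1)
})

test_that("2D reduction returns finite coordinates for every node", {
  gen <- generate_network(small_config(seed = 47))
  corpus <- generate_walks(gen$net, walk_length = 10, walks_per_node = 2, seed = 16)
  emb <- embed_nodes(corpus, dimension = 16, window = 5, seed = 17)
  xy <- reduce_2d(emb)
  expect_equal(nrow(xy), nrow(emb))
  expect_true(all(is.finite(xy$x) & is.finite(xy$y)))
})
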
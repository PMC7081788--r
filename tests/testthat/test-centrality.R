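test_that("eigenvector centrality handles canonical small graphs", {
  star <- layer("star", data.frame(source = "c", target = paste0("l", 1:4),
                                   weight = 1), directed = FALSE)
  ev <- eigenvector_centrality(star)
  expect_equal(ev$values[["c"]], 1)
  expect_true(all(ev$values[paste0("l", 1:4)] < 1))

  cyc <- layer("cyc", data.frame(source = c("a", "b", "c"),
                                 target = c("b", "c", "a"), weight = 1),
               directed = TRUE)
  evc <- eigenvector_centrality(cyc)
  expect_equal(unname(evc$values), rep(1, 3), tolerance = 1e-9)
})

test_that("eigenvector centrality matches a dense eigensolver oracle", {
  set.seed(21)
  for (i in 1:20) {
    l <- rand_layer(8, directed = TRUE, p = 0.5)
    g <- layer_igraph(l)
    eps <- if (igraph::is_connected(g, mode = "strong")) NULL else 1e-3
    got <- eigenvector_centrality(l)$values
    want <- oracle_eigenvector(layer_adjacency(l), teleport_eps = eps)
    expect_lt(max(abs(unname(got) - unname(want))), 1e-8)
  }
})

test_that("degree centrality sums incident weights", {
  l <- layer("d", data.frame(source = c("A", "B"), target = c("C", "C"),
                             weight = c(2, 1)), directed = TRUE,
             nodes = c("A", "B", "C", "iso"))
  ind <- degree_centrality(l, "in")$values
  expect_equal(ind[["C"]], 3)
  expect_equal(ind[["iso"]], 0)

  l2 <- layer("d2", data.frame(source = c("A", "B"), target = c("B", "A"),
                               weight = c(1, 2)), directed = TRUE)
  tot <- degree_centrality(l2, "total")$values
  expect_equal(unname(tot[c("A", "B")]), c(3, 3))

  lu <- layer("u", data.frame(source = "A", target = "B", weight = 5), FALSE)
  expect_error(degree_centrality(lu, "in"), "directed")
  expect_equal(unname(degree_centrality(lu, "total")$values), c(5, 5))
})

test_that("betweenness centrality handles canonical graphs and rejects bad weights", {
  path <- layer("p", data.frame(source = c("A", "B"), target = c("B", "C"),
                                weight = 1), directed = FALSE)
  bt <- betweenness_centrality(path)$values
  expect_equal(unname(bt[c("A", "B", "C")]), c(0, 1, 0))

  k4 <- rand_layer(4, directed = FALSE, p = 1.1)  # complete
  k4$edges$weight <- 1
  k4 <- layer("k4", k4$edges, FALSE)
  expect_equal(max(betweenness_centrality(k4)$values), 0)

  bad <- layer("bad", data.frame(source = "A", target = "B", weight = 0), TRUE)
  expect_error(betweenness_centrality(bad), "positive")
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  set.seed(31)
  for (i in 1:15) {
    directed <- i %% 2 == 0
    l <- rand_layer(7, directed = directed, p = 0.5)
    got <- betweenness_centrality(l)$values
    A <- layer_adjacency(l)
    dist <- ifelse(A > 0, 1 / A, Inf)
    diag(dist) <- Inf
    want <- oracle_betweenness(dist, directed = directed)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("dense ranks share ties and stay consecutive", {
  expect_equal(dense_rank(c(A = 0.4, B = 0.4, C = 0.2)),
               c(A = 1L, B = 1L, C = 2L))
  expect_equal(unname(dense_rank(c(a = 1, b = 1, c = 1))), rep(1L, 3))

  set.seed(5)
  v <- setNames(runif(20), paste0("n", 1:20))
  r <- dense_rank(v)
  expect_equal(unname(r[order(-v)]), 1:20)
})

test_that("centralities are scale invariant in rank and equivariant to relabeling", {
  set.seed(41)
  metrics <- list(
    function(l) eigenvector_centrality(l)$values,
    function(l) degree_centrality(l, "total")$values,
    function(l) betweenness_centrality(l)$values)
  for (rep in 1:5) {
    l <- rand_layer(7, directed = FALSE, p = 0.6)
    l10 <- layer(l$name, transform(l$edges, weight = weight * 10), l$directed,
                 nodes = l$nodes)
    for (f in metrics)
      expect_equal(dense_rank(f(l)), dense_rank(f(l10)))
    # relabeling: permute node IDs, centralities follow the labels
    perm <- setNames(sample(l$nodes), l$nodes)
    e2 <- l$edges
    e2$source <- unname(perm[e2$source])
    e2$target <- unname(perm[e2$target])
    l2 <- layer(l$name, e2, l$directed, nodes = unname(perm[l$nodes]))
    for (f in metrics) {
      v1 <- f(l)
      v2 <- f(l2)
      expect_equal(unname(v2[unname(perm[names(v1)])]), unname(v1),
                   tolerance = 1e-9)
    }
  }
})
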
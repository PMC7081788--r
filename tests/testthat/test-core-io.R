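test_that("edge lists aggregate duplicates and canonicalise undirected pairs", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "A,B,2", "A,B,1"), p)
  l <- read_edge_list(p, directed = TRUE)
  expect_equal(nrow(l$edges), 1L)
  expect_equal(l$edges$weight, 3)

  writeLines(c("source,target,weight", "A,B,1", "B,A,1"), p)
  lu <- read_edge_list(p, directed = FALSE)
  expect_equal(nrow(lu$edges), 1L)
  expect_equal(lu$edges$weight, 2)
  expect_equal(lu$edges$source, "A")  # canonical order

  writeLines("source,target,weight", p)
  le <- read_edge_list(p, directed = TRUE)
  expect_equal(nrow(le$edges), 0L)
  expect_equal(length(le$nodes), 0L)
})

test_that("edge list reader validates rows and defaults missing weight", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target", "A,B", "B,C"), p)
  l <- read_edge_list(p, directed = TRUE)
  expect_equal(sort(l$edges$weight), c(1, 1))

  writeLines(c("source,target,weight", "A,B,1", "B,C,-2"), p)
  expect_error(read_edge_list(p, directed = TRUE), "negative weight.*line 2")

  writeLines(c("source,target,weight", "A,B,oops"), p)
  expect_error(read_edge_list(p, directed = TRUE), "malformed")

  # tab-separated dialect accepted
  writeLines(c("source\ttarget\tweight", "A\tB\t4"), p)
  expect_equal(read_edge_list(p, directed = TRUE)$edges$weight, 4)
})

test_that("attribute reader derives transformed certainty and categories", {
  df <- data.frame(node = c("a", "b", "c"), group = "G",
                   sex = c("female", "male", "female"), age = c(7, 9, 4),
                   dominance_rank = c(0.9, 0.2, 0.5),
                   dominance_certainty = c(0.69, 0.98, 1.0),
                   matriline_size = c(7, 3, 12),
                   rearing = c("mother", "nursery", "mother"))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  at <- read_attributes(p)
  expect_equal(at$dc, c(0.31, 0.02, 0.0))
  expect_equal(as.character(at$matriline_size_cat), c("6-10", "1-5", "11+"))

  df$dominance_certainty[1] <- 0.3
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  expect_error(read_attributes(p), "dominance_certainty")

  df$dominance_certainty[1] <- 0.8
  df$sex[1] <- "unknown"
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  expect_error(read_attributes(p), "sex")
})

test_that("multiplex assembly unions node sets and keeps isolates", {
  gen <- test_group(n = 87, seed = 3)
  expect_equal(length(gen$multiplex$nodes), 87L)
  expect_equal(length(gen$multiplex$layers), 5L)

  l1 <- layer("solo", data.frame(source = character(0),
                                 target = character(0),
                                 weight = numeric(0)),
              directed = FALSE, nodes = "only")
  m1 <- assemble_multiplex(list(l1))
  expect_equal(m1$nodes, "only")

  l2 <- layer("a", data.frame(source = "x", target = "y", weight = 1), TRUE)
  m2 <- assemble_multiplex(list(l2), extra_nodes = "ghost")
  expect_true("ghost" %in% m2$layers$a$nodes)
  expect_equal(degree_centrality(m2$layers$a, "total")$values[["ghost"]], 0)

  cfg <- layer_config("b", directed = TRUE, metric = "eigenvector")
  expect_error(assemble_multiplex(list(l2), config = cfg), "config")
})

test_that("write/read round-trips reproduce the edge map exactly", {
  set.seed(11)
  for (i in 1:10) {
    directed <- i %% 2 == 0
    l <- rand_layer(sample(3:9, 1), directed = directed, p = 0.6)
    p <- withr::local_tempfile(fileext = ".csv")
    write_edge_list(l, p)
    l2 <- read_edge_list(p, directed = directed, name = l$name)
    expect_equal(l2$edges, l$edges, ignore_attr = TRUE)
    # node-set closure after assembly
    m <- assemble_multiplex(list(l), extra_nodes = "zz")
    expect_true(all(c(m$layers[[1]]$edges$source,
                      m$layers[[1]]$edges$target) %in% m$nodes))
  }
})
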
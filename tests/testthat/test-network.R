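test_that("edge direction follows the earlier alignment start", {
  rec <- make_records(c("a", "b", "c"), c("b", "c", "d"),
                      LS = c(0.77, -0.62, 0.68),
                      Xs = c(1L, 15L, 2L), Ys = c(2L, 15L, 1L),
                      Len = c(39L, 21L, 39L))
  net <- build_network(rec, 0.05, 0.05)
  dirs <- igraph::edge_attr(net, "direction")
  el <- igraph::as_edgelist(net)
  # Xs < Ys: X's interval starts first, X leads Y, arrow X -> Y
  expect_equal(dirs[1], "x_leads_y")
  expect_equal(el[1, ], c("a", "b"))
  # equal starts: undirected, and the negative score marks a dashed edge
  expect_equal(dirs[2], "undirected")
  expect_equal(igraph::edge_attr(net, "sign")[2], -1)
  # Xs > Ys: Y leads X, arrow stored Y -> X
  expect_equal(dirs[3], "y_leads_x")
  expect_equal(el[3, ], c("d", "c"))
  expect_equal(igraph::edge_attr(net, "delay"), c(-1, 0, 1))
})

test_that("direction assignment is antisymmetric under record swap", {
  fwd <- make_records("x", "y", 0.5, Xs = 1L, Ys = 3L, Len = 5L)
  swp <- make_records("y", "x", 0.5, Xs = 3L, Ys = 1L, Len = 5L)
  n1 <- build_network(fwd)
  n2 <- build_network(swp)
  expect_equal(igraph::as_edgelist(n1)[1, ], c("x", "y"))
  expect_equal(igraph::as_edgelist(n2)[1, ], c("x", "y"))
})

test_that("thresholds gate edges monotonically and keep all factors as nodes", {
  rec <- make_records(c("a", "a", "b"), c("b", "c", "c"),
                      LS = c(0.9, 0.8, 0.7), Xs = 1L, Ys = 1L, Len = 5L,
                      P = c(0.001, 0.03, 0.2), Q = c(0.001, 0.03, 0.2))
  loose <- build_network(rec, 0.05, 0.05)
  tight <- build_network(rec, 0.01, 0.01)
  expect_equal(igraph::ecount(loose), 2)
  expect_equal(igraph::ecount(tight), 1)
  expect_lte(igraph::ecount(tight), igraph::ecount(loose))
  expect_equal(sort(igraph::V(loose)$name), c("a", "b", "c"))

  empty <- build_network(rec[0, ])
  expect_equal(igraph::ecount(empty), 0)
  expect_equal(igraph::vcount(empty), 0)
})

test_that("records without q-values are rejected", {
  rec <- make_records("a", "b", 0.5, 1L, 1L, 5L)
  rec$Q <- NA_real_
  expect_error(build_network(rec), "q-values")
})

test_that("degree distribution matches closed forms", {
  triangle <- make_records(c("a", "a", "b"), c("b", "c", "c"),
                           LS = 0.9, Xs = 1L, Ys = 1L, Len = 5L)
  dd <- degree_distribution(build_network(triangle))
  expect_equal(unname(dd$counts[["2"]]), 3L)
  expect_equal(dd$mean_degree, 2)

  k <- 6
  star <- make_records(rep("hub", k), paste0("leaf", 1:k),
                       LS = 0.9, Xs = 1L, Ys = 1L, Len = 5L)
  ds <- degree_distribution(build_network(star))
  expect_equal(unname(ds$counts[[as.character(k)]]), 1L)
  expect_equal(unname(ds$counts[["1"]]), k)
  expect_equal(ds$mean_degree, 2 * k / (k + 1))
})

test_that("degree counts agree with an adjacency recount on random graphs", {
  set.seed(12)
  pairs <- t(combn(paste0("v", 1:7), 2))
  keep <- sample(nrow(pairs), 12)
  rec <- make_records(pairs[keep, 1], pairs[keep, 2], LS = 0.5,
                      Xs = 1L, Ys = 1L, Len = 4L)
  net <- build_network(rec)
  dd <- degree_distribution(net)
  manual <- table(c(rec$X, rec$Y))
  for (v in names(manual))
    expect_equal(unname(igraph::degree(net, v, mode = "all")),
                 unname(manual[[v]]))
  expect_equal(dd$mean_degree, 2 * 12 / length(manual))
})

test_that("network export writes SIF, attributes, and GraphML round-trips", {
  rec <- make_records(c("a", "b"), c("b", "c"), LS = c(0.9, -0.8),
                      Xs = c(1L, 2L), Ys = c(2L, 2L), Len = 5L)
  net <- build_network(rec)
  base <- file.path(tempdir(), "nettest")
  paths <- export_network(net, base)
  sif <- readLines(paths[["sif"]])
  expect_equal(sif[1], "a\tpa\tb")
  expect_equal(sif[2], "b\tna\tc")
  attrs <- read.table(paths[["edges"]], sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  expect_equal(attrs$direction, c("x_leads_y", "undirected"))
  expect_equal(attrs$ls, c(0.9, -0.8))
  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(back), 2)
  expect_equal(sort(igraph::edge_attr(back, "ls")),
               sort(igraph::edge_attr(net, "ls")))
  expect_equal(sort(igraph::edge_attr(back, "direction")),
               sort(igraph::edge_attr(net, "direction")))
})
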
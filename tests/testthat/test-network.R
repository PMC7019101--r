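test_that("SIF and TSV edge lists parse to simple undirected graphs", {
  tf <- tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tA", "C"), tf)
  g <- read_edge_list(tf)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)  # duplicate/reversed edges collapse

  writeLines(character(0), tf)
  empty <- read_edge_list(tf)
  expect_equal(igraph::vcount(empty), 0)

  writeLines(c("A\tpp\tB", "A\tpp"), tf)
  expect_error(read_edge_list(tf), "line 2")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC\tphysical", "D\tD"), tsv)
  expect_warning(g2 <- read_edge_list(tsv), "self-loop")
  expect_equal(igraph::vcount(g2), 4)
  expect_equal(igraph::ecount(g2), 2)

  # multi-target SIF lines fan out
  writeLines("HUB\tpp\tX\tY\tZ", tf)
  g3 <- read_edge_list(tf)
  expect_equal(igraph::ecount(g3), 3)
  expect_equal(unname(igraph::degree(g3)["HUB"]), 3)
})

test_that("a 35-node edge list reports 35 nodes", {
  pg <- gen_ppi_graph(35, seed = 17)
  tf <- tempfile(fileext = ".sif")
  write_sif(pg$graph, tf)
  expect_equal(igraph::vcount(read_edge_list(tf)), 35)
})

test_that("merging subnetworks is the labeled set union", {
  pg <- gen_ppi_graph(20, seed = 18)
  same <- merge_networks(list(pg$graph, pg$graph))
  expect_equal(igraph::vcount(same), igraph::vcount(pg$graph))
  expect_equal(igraph::ecount(same), igraph::ecount(pg$graph))

  g1 <- gen_ppi_graph(10, prefix = "A", seed = 19)$graph
  g2 <- gen_ppi_graph(12, prefix = "B", seed = 20)$graph
  disjoint <- merge_networks(list(g1, g2))
  expect_equal(igraph::vcount(disjoint), 22)
  expect_equal(igraph::ecount(disjoint),
               igraph::ecount(g1) + igraph::ecount(g2))

  set.seed(21)
  for (rep in 1:10) {
    e1 <- data.frame(from = sample(LETTERS[1:8], 6, TRUE),
                     to = sample(LETTERS[1:8], 6, TRUE))
    e2 <- data.frame(from = sample(LETTERS[5:12], 6, TRUE),
                     to = sample(LETTERS[5:12], 6, TRUE))
    mk <- function(e) {
      e <- e[e$from != e$to, ]
      tf <- tempfile(fileext = ".tsv")
      writeLines(paste(e$from, e$to, sep = "\t"), tf)
      read_edge_list(tf)
    }
    m <- merge_networks(list(mk(e1), mk(e2)))
    canon <- function(e) {
      unique(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    }
    e1c <- e1[e1$from != e1$to, ]; e2c <- e2[e2$from != e2$to, ]
    want_edges <- unique(c(canon(e1c), canon(e2c)))
    expect_equal(igraph::ecount(m), length(want_edges))
    expect_setequal(igraph::V(m)$name,
                    unique(c(e1c$from, e1c$to, e2c$from, e2c$to)))
  }
})

test_that("metrics match closed forms on path, complete and star graphs", {
  # path A-B-C
  p3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  nm <- align_metrics(node_metrics(p3), 3)
  expect_equal(nm$betweenness, c(0, 1, 0))
  expect_equal(nm$closeness, c(2/3, 1, 2/3))
  expect_equal(nm$neighborhood_connectivity, c(2, 1, 2))

  # complete graph K4
  k4 <- graph_from_adj(1 - diag(4))
  nm <- node_metrics(k4)
  expect_equal(nm$betweenness, rep(0, 4))
  expect_equal(nm$closeness, rep(1, 4))

  # star with 8 leaves: center carries all shortest paths
  star <- matrix(0, 9, 9); star[1, 2:9] <- 1; star[2:9, 1] <- 1
  nm <- align_metrics(node_metrics(graph_from_adj(star)), 9)
  expect_equal(nm$betweenness[1], 1)
  expect_equal(nm$betweenness[2], 0)
  expect_equal(nm$closeness[1], 1)
  expect_equal(nm$neighborhood_connectivity[1], 1)
  expect_equal(nm$neighborhood_connectivity[2], 8)
})

test_that("metrics equal the path-enumeration oracle on random graphs", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    adj <- matrix(0, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (runif(1) < 0.45) adj[a, b] <- adj[b, a] <- 1
    }
    nm <- align_metrics(node_metrics(graph_from_adj(adj)), n)
    oracle <- oracle_node_metrics(adj)
    expect_equal(nm$degree, unname(oracle$degree))
    expect_equal(nm$neighborhood_connectivity,
                 oracle$neighborhood_connectivity)
    expect_equal(nm$betweenness, oracle$betweenness, tolerance = 1e-10)
    expect_equal(nm$closeness, oracle$closeness, tolerance = 1e-10)
  }
})

test_that("metrics are invariant under node relabeling", {
  pg <- gen_ppi_graph(30, seed = 23)
  nm1 <- node_metrics(pg$graph)
  set.seed(24)
  relab <- igraph::set_vertex_attr(pg$graph, "name",
                                   value = sample(igraph::V(pg$graph)$name))
  # compare multisets of (degree, betweenness, closeness)
  nm2 <- node_metrics(relab)
  key <- function(nm) {
    o <- order(nm$degree, nm$betweenness, nm$closeness)
    nm[o, c("degree", "betweenness", "closeness")]
  }
  k1 <- key(nm1); k2 <- key(nm2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("betweenness on trees conserves total interior path length", {
  # tree: star of 3 plus a pendant path
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("R\tA", "R\tB", "R\tC", "C\tD"), tf)
  g <- read_edge_list(tf)
  nm <- node_metrics(g)
  n <- 5
  raw <- nm$betweenness * (n - 1) * (n - 2) / 2
  d <- igraph::distances(g)
  interior <- sum(d[upper.tri(d)] - 1)
  expect_equal(sum(raw), interior)
})

test_that("assortativity fit classifies hubby and regular graphs", {
  star <- matrix(0, 9, 9); star[1, 2:9] <- 1; star[2:9, 1] <- 1
  fit <- assortativity_fit(graph_from_adj(star))
  expect_lt(fit$slope, 0)
  expect_equal(fit$mixing, "disassortative")
  # closed form: classes k=8 (knn 1) and k=1 (knn 8):
  # slope = (log 1 - log 8) / (log 8 - log 1) = -1
  expect_equal(fit$slope, -1, tolerance = 1e-9)

  ring <- matrix(0, 6, 6)
  for (i in 1:6) ring[i, c((i %% 6) + 1, ((i - 2) %% 6) + 1)] <- 1
  fit <- assortativity_fit(graph_from_adj(ring))
  expect_equal(fit$mixing, "neutral/undefined")
  expect_true(is.na(fit$slope))
})

test_that("preferential-attachment graphs read as disassortative with the planted hub on top", {
  hits_mix <- 0; hits_hub <- 0
  for (s in 1:20) {
    pg <- gen_ppi_graph(175, planted_hubs = "HUB", seed = 300 + s)
    fit <- assortativity_fit(pg$graph)
    hits_mix <- hits_mix + (fit$mixing == "disassortative")
    nm <- node_metrics(pg$graph)
    top <- top_hubs(nm, 1, key = "betweenness")$node
    hits_hub <- hits_hub + (top == "HUB")
  }
  expect_gte(hits_mix / 20, 0.9)
  expect_gte(hits_hub / 20, 0.9)
})

test_that("hub ranking breaks ties by the other centrality then label", {
  m <- data.frame(node = c("B", "A", "C"),
                  degree = c(2L, 2L, 2L),
                  neighborhood_connectivity = c(1, 1, 1),
                  betweenness = c(0.5, 0.5, 0.9),
                  closeness = c(0.7, 0.7, 0.1))
  expect_equal(top_hubs(m, 3, "betweenness")$node, c("C", "A", "B"))
  expect_equal(top_hubs(m, 3, "closeness")$node, c("A", "B", "C"))
  expect_warning(out <- top_hubs(m, 5, "betweenness"), "exceeds node count")
  expect_equal(nrow(out), 3)

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  nm <- node_metrics(graph_from_adj(star))
  expect_equal(top_hubs(nm, 1, "betweenness")$node, "A")
})
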
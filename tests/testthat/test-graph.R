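test_that("the analysis view drops unconnected genes and rejects self-loops", {
  net <- RegulatoryNetwork(data.frame(regulator = "a", target = "b",
                                      sign = 1, q = 0.01),
                           genes = c("a", "b", "c", "d", "e"))
  v <- buildGraphView(net)
  expect_setequal(v$nodes, c("a", "b"))
  expect_setequal(v$dropped, c("c", "d", "e"))
  empty <- RegulatoryNetwork(data.frame(), genes = c("a", "b"))
  ve <- buildGraphView(empty)
  expect_length(ve$nodes, 0)
  expect_setequal(ve$dropped, c("a", "b"))
  loopy <- igraph::make_graph(c("a", "a", "a", "b"), directed = TRUE)
  expect_error(buildGraphView(loopy), "loop")
})

test_that("characteristic path length matches pair enumeration", {
  ring <- igraph::make_ring(3, directed = TRUE)
  expect_equal(characteristicPathLength(ring), 1.5)   # distances 1 and 2
  full <- igraph::make_full_graph(5, directed = TRUE)
  expect_equal(characteristicPathLength(full), 1)
  path <- igraph::graph_from_literal(a - +b - +c)
  # ordered reachable pairs: a->b (1), b->c (1), a->c (2)
  expect_equal(characteristicPathLength(path, "directed_reachable"), 4 / 3)
  expect_equal(characteristicPathLength(path, "undirected"), 4 / 3)
  expect_error(characteristicPathLength(igraph::make_empty_graph(3)),
               "no connected")
})

test_that("clustering matches triangle/triple enumeration", {
  tri <- igraph::make_full_graph(3, directed = FALSE)
  cc <- clusteringCoefficients(tri)
  expect_equal(unname(cc$local), rep(1, 3))
  expect_equal(cc$transitivity, 1)
  star <- igraph::make_star(5, mode = "undirected")
  cs <- clusteringCoefficients(star)
  expect_equal(cs$average, 0)
  expect_equal(cs$transitivity, 0)
  # triangle plus pendant: pendant 0, apex 1/3, others 1
  g <- igraph::graph_from_literal(a - b, b - c, a - c, a - d)
  cg <- clusteringCoefficients(g)
  expect_equal(unname(cg$local[c("a", "b", "c", "d")]), c(1 / 3, 1, 1, 0))
  expect_equal(cg$transitivity, 3 * 1 / (3 + 2 * 1))
})

test_that("centralities agree with brute-force BFS oracles on random digraphs", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    adj <- matrix(rbinom(n * n, 1, 0.35), n)
    diag(adj) <- 0
    if (sum(adj) == 0) next
    g <- igraph::graph_from_adjacency_matrix(adj)
    igraph::V(g)$name <- letters[1:n]
    cent <- nodeCentralities(g, normalized = FALSE)
    expect_equal(cent$betweenness, enumBetweenness(adj), tolerance = 1e-9)
    expect_equal(cent$clustering, enumClustering(adj), tolerance = 1e-12)
    expect_equal(cent$in_degree, colSums(adj))
    expect_equal(cent$out_degree, rowSums(adj))
    d <- bfsDistances(adj)
    fin <- is.finite(d) & d > 0
    if (any(fin))
      expect_equal(characteristicPathLength(g), mean(d[fin]))
    # closeness over each node's reachable set: 1 / sum of distances
    cl <- vapply(1:n, function(v) {
      dv <- d[v, -v]; dv <- dv[is.finite(dv)]
      if (!length(dv)) 0 else 1 / sum(dv)
    }, 0)
    reach <- vapply(1:n, function(v) sum(is.finite(d[v, -v])), 0)
    expect_equal(cent$closeness[reach > 0], cl[reach > 0], tolerance = 1e-9)
  }
})

test_that("betweenness of simple motifs is exact", {
  pathg <- igraph::graph_from_literal(a - b - c)
  b <- nodeCentralities(igraph::as_directed(pathg, mode = "mutual"))
  expect_equal(b$betweenness[b$node == "b"], 1)    # normalized middle node
  cyc <- igraph::make_ring(5, directed = TRUE)
  bc <- igraph::betweenness(cyc)
  expect_true(all(abs(bc - bc[1]) < 1e-12))        # symmetry
})

test_that("small-worldness is ~1 for its own null family and >> 1 for a lattice", {
  g <- withr::with_seed(5, igraph::sample_gnm(30, 90, directed = TRUE))
  sw <- smallWorldness(g, n_null = 150, seed = 2)
  expect_gt(sw$S, 1 - 3 * sd(sw$null_S))
  expect_lt(sw$S, 1 + 3 * sd(sw$null_S))
  # ring lattice with dense local neighbourhoods: high C, so S >> 1
  lat <- igraph::as_directed(
    igraph::sample_smallworld(1, 100, 3, p = 0.05), mode = "mutual")
  swl <- smallWorldness(lat, n_null = 100, seed = 3)
  expect_gt(swl$S, 1.5)
  # clustering- and transitivity-based variants agree on this fixture
  swt <- smallWorldness(lat, n_null = 100, seed = 3,
                        variant = "transitivity")
  expect_lt(abs(swl$S - swt$S) / swl$S, 0.2)
  expect_error(smallWorldness(g, n_null = 10), "n_null")
})

test_that("rank robustness is deterministic, exact at fraction 0, and hub-stable", {
  hub <- igraph::make_star(9, mode = "out")
  igraph::V(hub)$name <- paste0("n", 1:9)
  r0 <- rankRobustness(hub, metric = "degree", fraction = 0, n_iter = 20,
                       seed = 1)
  expect_equal(r0$sd_rank, rep(0, 9))
  expect_equal(r0$mean_rank, r0$base_rank)
  r1 <- rankRobustness(hub, metric = "degree", mode = "remove",
                       fraction = 0.25, n_iter = 100, seed = 1)
  expect_equal(r1$mean_rank[1], 1)                # hub keeps rank 1
  r1b <- rankRobustness(hub, metric = "degree", mode = "remove",
                        fraction = 0.25, n_iter = 100, seed = 1)
  expect_identical(r1, r1b)                       # determinism
  radd <- rankRobustness(hub, metric = "betweenness", mode = "add",
                         fraction = 0.25, n_iter = 30, seed = 4)
  expect_true(all(radd$mean_rank >= 1 & radd$mean_rank <= 9))
})

test_that("ranks use average ties and are permutation-equivariant", {
  g <- withr::with_seed(8, igraph::sample_gnm(8, 16, directed = TRUE))
  igraph::V(g)$name <- paste0("v", 1:8)
  deg <- igraph::degree(g, mode = "all")
  expect_equal(unname(ilpnet:::rankDesc(deg)), unname(rank(-deg)))
  perm <- withr::with_seed(1, sample(8))
  gp <- igraph::permute(g, perm)
  rp <- ilpnet:::rankDesc(igraph::degree(gp, mode = "all"))
  r <- ilpnet:::rankDesc(deg)
  expect_equal(unname(rp[perm]), unname(r))
})

test_that("pleiotropy correlation reduces to the hand covariance ratio", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 6)
  res <- correlateWithPleiotropy(x, y)
  expect_equal(res$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  expect_equal(correlateWithPleiotropy(x, x)$r, 1)
  yo <- y - cov(x, y) / var(x) * x              # orthogonalized against x
  expect_equal(correlateWithPleiotropy(x, yo)$r, 0, tolerance = 1e-12)
})
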
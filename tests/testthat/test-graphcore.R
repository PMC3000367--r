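test_that("clustering coefficient matches closed-form small cases", {
  tri <- net_from_triples("a", "b", 1, "b", "c", 1, "a", "c", 1)
  expect_equal(node_clustering_coefficient(tri, "a"), 1)
  expect_equal(average_clustering_coefficient(tri), 1)
  expect_equal(background_clustering_coefficient(tri), 1)

  path <- net_from_triples("a", "b", 1, "b", "c", 1)
  expect_equal(node_clustering_coefficient(path, "b"), 0)

  wtri <- net_from_triples("a", "b", 0.5, "b", "c", 1, "a", "c", 1)
  expect_equal(node_clustering_coefficient(wtri, "c"), 0.5)

  star <- net_from_triples("c", "l1", 1, "c", "l2", 1, "c", "l3", 1)
  expect_equal(average_clustering_coefficient(star), 0)

  expect_error(node_clustering_coefficient(tri, "zz"), "not in network")
  expect_error(average_clustering_coefficient(tri, character()), "non-empty")
})

test_that("background CC averages over all nodes incl. low-degree ones", {
  g <- net_from_triples("a", "b", 1, "b", "c", 1, "a", "c", 1,
                        "d", "e", 1, "e", "f", 1, "d", "f", 1,
                        "x", "y", 1)
  expect_equal(background_clustering_coefficient(g), 6 / 8)
  expect_equal(background_clustering_coefficient(g),
               average_clustering_coefficient(g, restrict_to = g$nodes))
})

test_that("weighted CC equals the brute-force oracle on random graphs", {
  for (seed in 1:40) {
    net <- random_graph(n = sample(4:8, 1), p = 0.6, seed = seed)
    for (v in net$nodes)
      expect_equal(node_clustering_coefficient(net, v), cc_oracle(net, v),
                   tolerance = 1e-12)
    expect_equal(average_clustering_coefficient(net),
                 mean(vapply(net$nodes, cc_oracle, 0, net = net)),
                 tolerance = 1e-12)
  }
})

test_that("0/1 weights reduce to the textbook unweighted coefficient", {
  for (seed in 1:20) {
    net <- random_graph(n = 8, p = 0.5, seed = seed, binary = TRUE)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    ref <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    ref[is.na(ref)] <- 0
    names(ref) <- igraph::V(g)$name
    for (v in net$nodes)
      expect_equal(node_clustering_coefficient(net, v), ref[[v]],
                   tolerance = 1e-12)
  }
})

test_that("restriction computes CC on the induced subgraph", {
  # square with one diagonal; restricting away the diagonal endpoint
  net <- net_from_triples("a", "b", 1, "b", "c", 1, "c", "d", 1,
                          "d", "a", 1, "a", "c", 0.5)
  expect_equal(node_clustering_coefficient(net, "b"), 0.5)
  expect_equal(node_clustering_coefficient(net, "b",
                                           restrict_to = c("a", "b", "c")),
               0.5)
  expect_equal(node_clustering_coefficient(net, "a",
                                           restrict_to = c("a", "b", "d")), 0)
  expect_error(node_clustering_coefficient(net, "c",
                                           restrict_to = c("a", "b")),
               "not in restriction")
})

test_that("CC is invariant under node relabeling", {
  net <- random_graph(8, p = 0.5, seed = 5)
  perm <- structure(sprintf("z%02d", sample(8)), names = net$nodes)
  e <- net$edges
  relab <- weighted_network(data.frame(from = unname(perm[e$from]),
                                       to = unname(perm[e$to]),
                                       weight = e$weight))
  for (v in net$nodes)
    expect_equal(node_clustering_coefficient(net, v),
                 node_clustering_coefficient(relab, perm[[v]]))
})

test_that("functional neighbourhood enumerates max-product paths on chains", {
  chain <- net_from_triples("s", "a", 0.6, "a", "b", 0.6)
  nb <- functional_neighborhood(chain, "s", 0.3)
  expect_equal(nb$confidence, c(a = 0.6, b = 0.36))
  expect_equal(nb$path$a, c("s", "a"))
  expect_equal(nb$path$b, c("s", "a", "b"))

  nb4 <- functional_neighborhood(chain, "s", 0.4)
  expect_equal(names(nb4$confidence), "a")

  # two-hop 0.7 * 0.8 beats the direct 0.5 edge
  net <- net_from_triples("s", "b", 0.5, "s", "a", 0.7, "a", "b", 0.8)
  nb2 <- functional_neighborhood(net, "s", 0.1)
  expect_equal(nb2$confidence[["b"]], 0.56)
  expect_equal(nb2$path$b, c("s", "a", "b"))

  expect_error(functional_neighborhood(chain, "nope", 0.5), "not in network")
})

test_that("best confidences equal shortest paths on -log(weight) lengths", {
  for (seed in 1:25) {
    net <- random_graph(n = sample(10:50, 1), p = 0.15, seed = seed + 100)
    seed_node <- net$nodes[1]
    thr <- 0.05
    nb <- functional_neighborhood(net, seed_node, thr)
    ref <- maxprod_oracle(net, seed_node)
    ref <- ref[ref >= thr]
    expect_setequal(names(nb$confidence), names(ref))
    expect_equal(nb$confidence[names(ref)], ref, tolerance = 1e-9)
    # stored best path reproduces the stored confidence
    for (v in names(nb$confidence)) {
      p <- nb$path[[v]]
      expect_identical(p[1], seed_node)
      expect_identical(p[length(p)], v)
      expect_false(anyDuplicated(p) > 0)
      prod_w <- prod(vapply(seq_len(length(p) - 1), function(i)
        edge_weight(net, p[i], p[i + 1]), 0))
      expect_equal(prod_w, nb$confidence[[v]], tolerance = 1e-12)
    }
  }
})

test_that("neighbourhoods shrink monotonically as the threshold rises", {
  net <- random_graph(30, p = 0.2, seed = 9)
  prev <- NULL
  for (thr in seq(0.05, 0.95, length.out = 10)) {
    cur <- names(functional_neighborhood(net, net$nodes[1], thr)$confidence)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("every prefix of a best path meets the threshold", {
  net <- random_graph(25, p = 0.25, seed = 17)
  nb <- functional_neighborhood(net, net$nodes[1], 0.2)
  for (v in names(nb$confidence)) {
    p <- nb$path[[v]]
    for (k in seq_along(p)[-1]) {
      conf_k <- prod(vapply(seq_len(k - 1), function(i)
        edge_weight(net, p[i], p[i + 1]), 0))
      expect_gte(conf_k, nb$threshold)
      if (k < length(p))
        expect_true(p[k] %in% names(nb$confidence))
    }
  }
})
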
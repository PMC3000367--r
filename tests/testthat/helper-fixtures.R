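# Shared fixtures and independent oracles.

net_from_triples <- function(...) {
  # net_from_triples("a","b",0.5, "b","c",0.9)
  x <- list(...)
  stopifnot(length(x) %% 3 == 0)
  idx <- seq(1, length(x), by = 3)
  weighted_network(data.frame(
    from = vapply(idx, function(i) as.character(x[[i]]), ""),
    to = vapply(idx, function(i) as.character(x[[i + 1]]), ""),
    weight = vapply(idx, function(i) as.numeric(x[[i + 2]]), 0)))
}

# Erdos-Renyi weighted graph; weights U(0.1, 1) or 0/1 when binary = TRUE.
random_graph <- function(n, p = 0.4, seed = 1, binary = FALSE) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  w <- if (binary) rep(1, sum(keep)) else stats::runif(sum(keep), 0.1, 1)
  weighted_network(data.frame(from = pairs[1, keep], to = pairs[2, keep],
                              weight = w))
}

# Dense weight matrix from a weighted_network (independent of its adj list).
weight_matrix <- function(net) {
  n <- length(net$nodes)
  m <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    m[e$from[i], e$to[i]] <- e$weight[i]
    m[e$to[i], e$from[i]] <- e$weight[i]
  }
  m
}

# Brute-force weighted clustering coefficient from the weight matrix.
cc_oracle <- function(net, node) {
  m <- weight_matrix(net)
  nbr <- colnames(m)[m[node, ] > 0]
  n <- length(nbr)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + m[nbr[i], nbr[j]]
  tot / choose(n, 2)
}

# Max-product path confidences by shortest paths on -log(weight) lengths.
maxprod_oracle <- function(net, seed_node) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  d <- igraph::distances(g, v = seed_node,
                         weights = -log(igraph::E(g)$weight))
  conf <- exp(-d[1, ])
  conf[setdiff(names(conf), seed_node)]
}

# Two-species fixture: identical 4-cliques (weight 0.9) on s,m1,m2,m3 with a
# low-activity pendant p hanging off m3; activities 0.8 on clique members.
clique_fixture <- function(pendant_activity = 0.05) {
  members <- c("s", "m1", "m2", "m3")
  pairs <- utils::combn(members, 2)
  edges <- data.frame(from = c(pairs[1, ], "m3"), to = c(pairs[2, ], "p"),
                      weight = c(rep(0.9, ncol(pairs)), 0.9))
  net <- weighted_network(edges)
  act <- activity_profile(c(s = 0.8, m1 = 0.8, m2 = 0.8, m3 = 0.8,
                            p = pendant_activity))
  list(nets = list(a = net, b = net), profiles = list(a = act, b = act))
}

# Hand-built two-module cluster-space fixture: two disjoint 4-cliques with
# high conserved activity, plus inert linker nodes.
two_module_fixture <- function() {
  m1 <- c("a1", "a2", "a3", "a4")
  m2 <- c("b1", "b2", "b3", "b4")
  p1 <- utils::combn(m1, 2); p2 <- utils::combn(m2, 2)
  edges <- data.frame(from = c(p1[1, ], p2[1, ], "a4", "z1"),
                      to = c(p1[2, ], p2[2, ], "z1", "b1"),
                      weight = c(rep(0.9, 12), 0.2, 0.2))
  net <- weighted_network(edges)
  act <- activity_profile(structure(c(rep(0.9, 4), rep(-0.8, 4), 0),
                                    names = c(m1, m2, "z1")))
  list(nets = list(a = net, b = net), profiles = list(a = act, b = act),
       modules = list(m1 = m1, m2 = m2))
}

make_subnet <- function(seed, members, score = 0.5) {
  structure(list(seed = seed, members = members, score = score,
                 cc_a = NA_real_, cc_b = NA_real_, mode = "conserved",
                 color = NA_character_, trace = NULL),
            class = "subnetwork")
}

default_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bm <- generate_benchmark(benchmark_spec())
      cs <- suppressMessages(benchmark_cluster_space(bm))
      cache <<- list(bm = bm, cs = cs)
    }
    cache
  }
})
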
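#' Weighted clustering coefficient of one node
#'
#' For node `k` with neighbour set `N` (positive-weight edges), `n = |N|`,
#' the weighted clustering coefficient is the sum of edge weights over all
#' unordered neighbour pairs divided by `n (n - 1) / 2`, with an absent
#' neighbour-neighbour edge contributing weight 0. With 0/1 weights this
#' reduces to the textbook unweighted clustering coefficient. Nodes with
#' fewer than two neighbours have coefficient 0.
#'
#' @param net a [weighted_network()]
#' @param node node identifier (must be present in scope)
#' @param restrict_to optional node set; the computation then runs on the
#'   induced subgraph over these nodes
#' @return coefficient in `[0, 1]`
#' @export
node_clustering_coefficient <- function(net, node, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    if (!node %in% restrict_to) stop("node not in restriction set")
    net <- induce_network(net, restrict_to)
  }
  if (!node %in% net$nodes) stop(sprintf("node '%s' not in network", node))
  nbr <- names(net$adj[[node]])
  n <- length(nbr)
  if (n < 2L) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    wi <- net$adj[[nbr[i]]]
    wj <- wi[nbr[(i + 1L):n]]
    total <- total + sum(wj, na.rm = TRUE)
  }
  total / (n * (n - 1) / 2)
}

#' Average weighted clustering coefficient
#'
#' Arithmetic mean of [node_clustering_coefficient()] over all nodes in scope
#' (the whole network, or the induced subgraph over `restrict_to`). Nodes
#' with fewer than two neighbours contribute 0.
#'
#' @inheritParams node_clustering_coefficient
#' @return coefficient in `[0, 1]`
#' @export
average_clustering_coefficient <- function(net, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    if (length(restrict_to) == 0L) stop("restriction set must be non-empty")
    net <- induce_network(net, restrict_to)
  }
  if (length(net$nodes) == 0L) stop("network is empty")
  mean(vapply(net$nodes, function(v) node_clustering_coefficient(net, v), 0))
}

#' Background clustering coefficient of the whole network
#'
#' The average weighted clustering coefficient over every node of the
#' network; the single-gene background against which relative clustering
#' thresholds are interpreted.
#'
#' @param net a [weighted_network()]
#' @return coefficient in `[0, 1]`
#' @export
background_clustering_coefficient <- function(net) {
  average_clustering_coefficient(net)
}

#' Functional neighbourhood of a seed by max-product path confidence
#'
#' The confidence of a path is the product of its edge weights. A node
#' belongs to the seed's functional neighbourhood when its best (maximum)
#' path confidence from the seed is at least `path_threshold`. Because all
#' weights are at most 1, confidence is non-increasing along a path, so a
#' best-first (Dijkstra-style) expansion finds the maximum-product path for
#' every reachable node without revisits.
#'
#' @param net a [weighted_network()]
#' @param seed node identifier present in `net`
#' @param path_threshold minimum path confidence, in `(0, 1]`
#' @return an object of class `functional_neighbourhood`: list with `seed`,
#'   `threshold`, `confidence` (named numeric, seed excluded) and `path`
#'   (named list; each entry is the maximizing simple path from the seed to
#'   the node, inclusive)
#' @export
functional_neighborhood <- function(net, seed, path_threshold) {
  if (!seed %in% net$nodes) stop(sprintf("seed '%s' not in network", seed))
  stopifnot(path_threshold > 0, path_threshold <= 1)
  best <- c(structure(1, names = seed))
  parent <- list()
  done <- character()
  frontier <- best
  while (length(frontier) > 0L) {
    i <- which.max(frontier)
    v <- names(frontier)[i]
    conf <- frontier[[i]]
    frontier <- frontier[-i]
    done <- c(done, v)
    nbr <- net$adj[[v]]
    if (length(nbr) == 0L) next
    cand <- conf * nbr
    cand <- cand[cand >= path_threshold]
    cand <- cand[!names(cand) %in% done]
    for (u in names(cand)) {
      cur <- best[u]
      if (is.na(cur) || cand[[u]] > cur) {
        best[u] <- cand[[u]]
        parent[[u]] <- v
        frontier[u] <- cand[[u]]
      }
    }
  }
  best <- best[names(best) != seed]
  paths <- lapply(names(best), function(u) {
    p <- u
    while (u != seed) {
      u <- parent[[u]]
      p <- c(u, p)
    }
    p
  })
  names(paths) <- names(best)
  ord <- order(names(best))
  structure(list(seed = seed, threshold = path_threshold,
                 confidence = best[ord], path = paths[ord]),
            class = "functional_neighbourhood")
}

#' @export
print.functional_neighbourhood <- function(x, ...) {
  cat(sprintf("functional neighbourhood of '%s' (threshold %.3g): %d nodes\n",
              x$seed, x$threshold, length(x$confidence)))
  invisible(x)
}
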
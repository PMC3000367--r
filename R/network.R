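#' Weighted functional linkage network
#'
#' Constructs an undirected weighted network from an edge table. Edge weights
#' are confidences in `(0, 1]`; an absent edge is equivalent to weight 0, so
#' zero-weight edges and self-edges are dropped. Duplicate node pairs keep the
#' maximum weight.
#'
#' @param edges data frame (or coercible) with columns `from`, `to`, `weight`.
#'   Extra columns are ignored; the first three columns are used if the names
#'   differ.
#' @return An object of class `weighted_network`: a list with
#'   \describe{
#'     \item{nodes}{sorted character vector of node identifiers}
#'     \item{adj}{named list; `adj[[v]]` is a named numeric vector of
#'       neighbour weights}
#'     \item{edges}{canonical edge data frame (`from < to` lexicographically),
#'       sorted by node pair}
#'   }
#' @export
weighted_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (ncol(edges) < 3L)
    stop("edge table needs at least 3 columns (from, to, weight)")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  w <- edges[[3L]]
  if (!is.numeric(w) || anyNA(w))
    stop("edge weights must be numeric and non-missing")
  if (any(w < 0 | w > 1))
    stop("edge weights must lie in [0, 1]; found value outside range")
  keep <- w > 0 & from != to
  from <- from[keep]; to <- to[keep]; w <- w[keep]
  # canonical orientation, then resolve duplicates by maximum weight
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
    w <- as.numeric(w)
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; w <- w[ord]
  nodes <- sort(unique(c(from, to)))
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (i in seq_along(nodes)) adj[[i]] <- numeric(0)
  for (i in seq_along(from)) {
    adj[[from[i]]][to[i]] <- w[i]
    adj[[to[i]]][from[i]] <- w[i]
  }
  structure(
    list(nodes = nodes,
         adj = adj,
         edges = data.frame(from = from, to = to, weight = w,
                            stringsAsFactors = FALSE)),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0)
    cat(sprintf("  weight range [%.3g, %.3g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

#' Edge weight lookup
#'
#' @param net a `weighted_network`
#' @param a,b node identifiers
#' @return the stored weight, or 0 when the edge (or either node) is absent
#' @export
edge_weight <- function(net, a, b) {
  nb <- net$adj[[a]]
  if (is.null(nb)) return(0)
  w <- nb[b]
  if (is.na(w)) 0 else unname(w)
}

#' Read a weighted network from a tab-separated edge list
#'
#' The file is headerless TSV with columns `node_a`, `node_b`, `weight`.
#' Edges below `min_weight` are dropped; when `max_edges` is given only the
#' largest-weight edges are kept, ties broken by lexicographic node-pair
#' order. Duplicate pairs keep the maximum weight.
#'
#' @param path file path
#' @param min_weight minimum retained edge weight, in `[0, 1]`
#' @param max_edges optional cap on the number of retained edges
#' @return a [weighted_network()]
#' @export
read_network <- function(path, min_weight = 0, max_edges = NULL) {
  stopifnot(length(min_weight) == 1L, min_weight >= 0, min_weight <= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(weighted_network(data.frame(from = character(), to = character(),
                                       weight = numeric())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed network line %d: expected 3 tab-separated fields",
                 bad[1L]))
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w))
    stop(sprintf("malformed network line %d: non-numeric weight",
                 which(is.na(w))[1L]))
  if (any(w < 0 | w > 1))
    stop(sprintf("network line %d: weight outside [0, 1]",
                 which(w < 0 | w > 1)[1L]))
  keep <- w >= min_weight & w > 0
  net <- weighted_network(data.frame(from = from[keep], to = to[keep],
                                     weight = w[keep]))
  if (!is.null(max_edges) && n_edges(net) > max_edges) {
    e <- net$edges
    ord <- order(-e$weight, e$from, e$to)
    net <- weighted_network(e[ord[seq_len(max_edges)], ])
  }
  net
}

#' Write a weighted network as a headerless TSV edge list
#'
#' Round-trips exactly through [read_network()]: edges are written in
#' canonical sorted order with full-precision weights.
#'
#' @param net a `weighted_network`
#' @param path output file path
#' @export
write_network <- function(net, path) {
  e <- net$edges
  lines <- sprintf("%s\t%s\t%s", e$from, e$to,
                   formatC(e$weight, digits = 17, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a weighted network to an igraph object
#'
#' @param net a `weighted_network`
#' @param activity optional activity profile; stored as the `activity` vertex
#'   attribute (0 for nodes without a score)
#' @return an undirected `igraph` graph with a `weight` edge attribute
#' @export
as_igraph <- function(net, activity = NULL) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (!is.null(activity)) {
    igraph::V(g)$activity <- activity_of(activity, net$nodes)
  }
  g
}

# Induced sub-network on a node set (keeps only edges among `nodes`).
induce_network <- function(net, nodes) {
  nodes <- intersect(net$nodes, nodes)
  e <- net$edges
  keep <- e$from %in% nodes & e$to %in% nodes
  sub <- weighted_network(e[keep, , drop = FALSE])
  # retain isolated members so averages are over the full node set
  iso <- setdiff(nodes, sub$nodes)
  if (length(iso) > 0) {
    sub$nodes <- sort(c(sub$nodes, iso))
    for (v in iso) sub$adj[[v]] <- numeric(0)
    sub$adj <- sub$adj[sort(names(sub$adj))]
  }
  sub
}
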
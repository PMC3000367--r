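#' Ortholog cluster map
#'
#' A relation between ortholog cluster identifiers and per-species gene
#' identifiers (InParanoid-style). A `(species, gene)` pair maps to at most
#' one cluster; clusters may hold several genes of one species (paralogs) and
#' genes of both species.
#'
#' @param cluster,species,gene character vectors of equal length
#' @return a data frame of class `orthology_map` with columns
#'   `cluster`, `species`, `gene`
#' @export
orthology_map <- function(cluster, species, gene) {
  map <- data.frame(cluster = as.character(cluster),
                    species = as.character(species),
                    gene = as.character(gene),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  key <- paste(map$species, map$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("a (species, gene) pair maps to more than one cluster")
  map <- map[order(map$cluster, map$species, map$gene), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("orthology_map", "data.frame")
  map
}

#' Read an ortholog cluster map
#'
#' Headerless TSV with columns `cluster_id`, `species`, `gene`.
#'
#' @param path file path
#' @return an [orthology_map()]
#' @export
read_orthology <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("cluster", "species", "gene"))
  orthology_map(tab$cluster, tab$species, tab$gene)
}

#' Write an ortholog cluster map
#'
#' @param orth an [orthology_map()]
#' @param path output file path
#' @export
write_orthology <- function(orth, path) {
  utils::write.table(as.data.frame(orth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# gene -> cluster lookup for one species
gene_to_cluster <- function(orth, species) {
  sub <- orth[orth$species == species, , drop = FALSE]
  structure(sub$cluster, names = sub$gene)
}

#' Map a gene-space network into ortholog-cluster space
#'
#' Cluster nodes replace gene nodes. For clusters A (genes `a1..am`) and B
#' (genes `b1..bn`) the cluster edge weight is the arithmetic mean of the
#' gene-level weights over all `m * n` pairs, where a missing gene edge
#' counts as weight 0 (paralog interactions are averaged). Zero-mean cluster
#' edges are not stored. Genes absent from the orthology map for this
#' species are dropped, with a message reporting the count.
#'
#' @param net a [weighted_network()] over gene identifiers
#' @param orth an [orthology_map()]
#' @param species species identifier as used in `orth`
#' @return a [weighted_network()] over cluster identifiers
#' @export
map_to_cluster_space <- function(net, orth, species) {
  lut <- gene_to_cluster(orth, species)
  mapped <- lut[net$nodes]
  dropped <- sum(is.na(mapped))
  if (dropped > 0)
    message(sprintf("map_to_cluster_space: dropped %d gene(s) of species '%s' absent from the orthology map",
                    dropped, species))
  # per-cluster gene counts from the orthology (network-absent paralogs
  # still dilute the mean: their edges are all weight 0)
  sizes <- table(unname(lut))
  e <- net$edges
  cf <- unname(lut[e$from]); ct <- unname(lut[e$to])
  keep <- !is.na(cf) & !is.na(ct) & cf != ct   # intra-cluster edges vanish
  cf <- cf[keep]; ct <- ct[keep]; w <- e$weight[keep]
  if (length(w) == 0L)
    return(weighted_network(data.frame(from = character(), to = character(),
                                       weight = numeric())))
  swap <- cf > ct
  tmp <- cf[swap]; cf[swap] <- ct[swap]; ct[swap] <- tmp
  key <- paste(cf, ct, sep = "\r")
  wsum <- tapply(w, key, sum)
  parts <- strsplit(names(wsum), "\r", fixed = TRUE)
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  npairs <- as.numeric(sizes[a]) * as.numeric(sizes[b])
  weighted_network(data.frame(from = a, to = b,
                              weight = as.numeric(wsum) / npairs))
}

#' Map a gene-space activity profile into ortholog-cluster space
#'
#' The cluster score is the member gene score of largest absolute value;
#' ties go to the lexicographically smallest gene identifier, so the mapping
#' is deterministic. This keeps the strongest differential signal, which is
#' what the subnetwork search keys on.
#'
#' @param profile an [activity_profile()] keyed by gene
#' @param orth an [orthology_map()]
#' @param species species identifier as used in `orth`
#' @return an [activity_profile()] keyed by cluster
#' @export
map_activity_to_clusters <- function(profile, orth, species) {
  sub <- orth[orth$species == species, , drop = FALSE]
  sc <- activity_of(profile, sub$gene)
  ord <- order(sub$cluster, -abs(sc), sub$gene)
  sub <- sub[ord, , drop = FALSE]
  sc <- sc[ord]
  first <- !duplicated(sub$cluster)
  activity_profile(structure(sc[first], names = sub$cluster[first]))
}
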
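#' Shuffle activity labels over network genes
#'
#' Permutes the activity scores uniformly at random among the genes present
#' in the network (genes outside the network keep their scores). The
#' multiset of scores over network genes is preserved exactly, so the
#' shuffled profile has the same marginal activity distribution but no
#' relationship to network structure.
#'
#' @param profile an [activity_profile()]
#' @param net the [weighted_network()] whose genes take part in the shuffle
#' @param rng_seed integer seed fixing the permutation
#' @return the shuffled [activity_profile()]
#' @export
shuffle_activity <- function(profile, net, rng_seed) {
  nodes <- net$nodes
  scores <- activity_of(profile, nodes)
  perm <- with_rng_seed(rng_seed, sample.int(length(nodes)))
  out <- unclass(profile)
  out <- out[!names(out) %in% nodes]
  shuffled <- structure(scores[perm], names = nodes)
  activity_profile(c(out, shuffled))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomization experiment: real versus shuffled activities
#'
#' Runs [discover_subnetworks()] once on the true activity profiles and `R`
#' times on label-shuffled profiles, independently per species and per
#' repetition. The contrast between the real subnetwork count and the mean
#' random count measures how much discovered structure exceeds what the
#' network yields by chance (signal-to-noise ratio).
#'
#' @inheritParams discover_subnetworks
#' @param R number of shuffled repetitions (default 5)
#' @param base_seed integer; repetition `i` shuffles species A with seed
#'   `base_seed + i - 1` and species B with seed `base_seed + R + i - 1`
#' @param randomize which labels to shuffle: both species, one species only,
#'   or the orthology relation (activities of species B are re-assigned
#'   across clusters, emulating shuffled ortholog links)
#' @return an object of class `randomization_summary`: list with
#'   `real_count`, `random_counts`, `mean_random`, `sd_random`,
#'   `signal_to_noise` (`Inf` when no random run finds anything),
#'   `real_mean_size`, `random_mean_size`, and the real `subnetworks`
#' @export
randomization_experiment <- function(net_a, activity_a, net_b = NULL,
                                     activity_b = NULL,
                                     config = search_config(),
                                     R = 5L, base_seed = 1L,
                                     randomize = c("both", "a-only", "b-only",
                                                   "orthology")) {
  randomize <- match.arg(randomize)
  stopifnot(R >= 1)
  real <- discover_subnetworks(net_a, activity_a, net_b, activity_b, config)
  sizes <- function(set) vapply(set, function(s) length(s$members), 0L)
  random_counts <- integer(R)
  random_sizes <- numeric(0)
  for (i in seq_len(R)) {
    pa <- activity_a
    pb <- activity_b
    if (randomize %in% c("both", "a-only"))
      pa <- shuffle_activity(activity_a, net_a, base_seed + i - 1L)
    if (!is.null(activity_b) && randomize %in% c("both", "b-only", "orthology"))
      pb <- shuffle_activity(activity_b, net_b, base_seed + R + i - 1L)
    rnd <- discover_subnetworks(net_a, pa, net_b, pb, config)
    random_counts[i] <- length(rnd)
    random_sizes <- c(random_sizes, sizes(rnd))
  }
  mean_random <- mean(random_counts)
  structure(
    list(real_count = length(real),
         random_counts = random_counts,
         mean_random = mean_random,
         sd_random = stats::sd(random_counts),
         signal_to_noise = if (mean_random == 0) Inf
           else length(real) / mean_random,
         real_mean_size = if (length(real)) mean(sizes(real)) else NA_real_,
         random_mean_size = if (length(random_sizes)) mean(random_sizes)
           else NA_real_,
         subnetworks = real),
    class = "randomization_summary")
}

#' @export
print.randomization_summary <- function(x, ...) {
  cat(sprintf("randomization: %d real subnetwork(s) vs %.2f +/- %.2f random (R = %d)\n",
              x$real_count, x$mean_random,
              if (is.na(x$sd_random)) 0 else x$sd_random,
              length(x$random_counts)))
  cat(sprintf("  signal-to-noise %.3g; mean size real %.2f, random %.2f\n",
              x$signal_to_noise, x$real_mean_size, x$random_mean_size))
  invisible(x)
}

#' Hypergeometric enrichment of subnetwork members in annotation terms
#'
#' For each term, tests whether the subnetwork members overlap the term's
#' gene set more than expected by chance when drawing `|members|` genes from
#' the population without replacement: upper-tail hypergeometric
#' `P(X >= overlap)`, Bonferroni-corrected over the number of terms tested.
#'
#' @param members character vector of cluster identifiers (subset of
#'   `population`)
#' @param annotations named list; each element is the character vector of
#'   clusters annotated with that term (intersected with the population)
#' @param population character vector: the annotation universe
#' @param alpha significance level on the Bonferroni-corrected p-value
#' @return data frame of class `enrichment_result`, sorted by corrected
#'   p-value, with columns `term`, `overlap`, `term_size`, `subnet_size`,
#'   `population_size`, `p_value`, `p_bonferroni`, `significant`
#' @export
enrich_terms <- function(members, annotations, population, alpha = 0.05) {
  members <- unique(members)
  population <- unique(population)
  if (!all(members %in% population))
    stop("all members must belong to the population")
  n_terms <- length(annotations)
  N <- length(population)
  n <- length(members)
  rows <- lapply(names(annotations), function(term) {
    term_set <- intersect(unique(annotations[[term]]), population)
    K <- length(term_set)
    k <- length(intersect(members, term_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K, subnet_size = n,
               population_size = N, p_value = p,
               p_bonferroni = min(1, p * n_terms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(term = character(), overlap = integer(),
                      term_size = integer(), subnet_size = integer(),
                      population_size = integer(), p_value = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_bonferroni, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read a flat annotation table
#'
#' Headerless TSV with columns `term`, `cluster`. No ontology propagation is
#' performed; each term is taken as the flat set of clusters annotated to it.
#'
#' @param path file path
#' @return named list of cluster-identifier vectors
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("term", "cluster"))
  split(tab$cluster, tab$term)
}

#' Empirical significance of one subnetwork against random runs
#'
#' The fraction of shuffled-activity runs that produced at least one
#' subnetwork of equal or larger size and equal or higher score — an
#' empirical per-subnetwork confidence summary of the randomization
#' experiment.
#'
#' @param subnet a `subnetwork`
#' @param random_sets list of `subnetwork_set`s from shuffled runs
#' @return fraction in `[0, 1]` (lower = more significant)
#' @export
empirical_subnetwork_p <- function(subnet, random_sets) {
  if (length(random_sets) == 0L) return(NA_real_)
  hits <- vapply(random_sets, function(set) {
    any(vapply(set, function(r)
      length(r$members) >= length(subnet$members) &&
        r$score >= subnet$score, TRUE))
  }, TRUE)
  mean(hits)
}
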
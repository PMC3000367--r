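#' Search configuration for subnetwork discovery
#'
#' Bundles the tunable parameters of the greedy seed-and-extend search.
#'
#' @param mode scoring mode: `"conserved"` (signed geometric mean of the two
#'   species' activities), `"species_specific"` (absolute activity
#'   difference), or `"single_species"`
#' @param score_cutoff minimum average activity score of a subnetwork; growth
#'   stops before the mean would drop below it
#' @param cc_a,cc_b minimum average weighted clustering coefficient of the
#'   induced subgraph in species A / species B
#' @param cc_relative if `TRUE`, `cc_a`/`cc_b` are offsets added to each
#'   network's background (whole-network) average clustering coefficient;
#'   if `FALSE` they are absolute thresholds
#' @param path_threshold_a,path_threshold_b minimum max-product path
#'   confidence defining the seed's functional neighbourhood in each species
#' @param min_report_size smallest subnetwork reported
#' @param max_size optional cap on subnetwork size (`Inf` = unbounded)
#' @param overlap_threshold member-overlap fraction above which a subnetwork
#'   is removed in favour of a larger one
#' @return a list of class `search_config`
#' @export
search_config <- function(mode = c("conserved", "species_specific",
                                   "single_species"),
                          score_cutoff = 0.15,
                          cc_a = 0.1, cc_b = 0.2,
                          cc_relative = FALSE,
                          path_threshold_a = 0.3, path_threshold_b = 0.8,
                          min_report_size = 3L,
                          max_size = Inf,
                          overlap_threshold = 0.6) {
  mode <- match.arg(mode)
  stopifnot(score_cutoff >= 0, score_cutoff <= 2,
            cc_a >= 0, cc_b >= 0,
            path_threshold_a > 0, path_threshold_a <= 1,
            path_threshold_b > 0, path_threshold_b <= 1,
            min_report_size >= 1, max_size >= 1,
            overlap_threshold > 0, overlap_threshold <= 1)
  structure(list(mode = mode, score_cutoff = score_cutoff,
                 cc_a = cc_a, cc_b = cc_b, cc_relative = cc_relative,
                 path_threshold_a = path_threshold_a,
                 path_threshold_b = path_threshold_b,
                 min_report_size = as.integer(min_report_size),
                 max_size = max_size,
                 overlap_threshold = overlap_threshold),
            class = "search_config")
}

# Resolve relative clustering thresholds against the network backgrounds.
resolve_cc_thresholds <- function(nets, config) {
  if (!config$cc_relative)
    return(c(a = config$cc_a, b = config$cc_b))
  bg_a <- background_clustering_coefficient(nets$a)
  bg_b <- if (is.null(nets$b)) 0 else background_clustering_coefficient(nets$b)
  c(a = bg_a + config$cc_a, b = bg_b + config$cc_b)
}

# Per-member gene scores in the configured mode.
member_scores <- function(members, profiles, mode) {
  m <- activity_of(profiles$a, members)
  if (mode == "single_species") return(gene_score(m, mode = mode))
  h <- activity_of(profiles$b, members)
  gene_score(m, h, mode = mode)
}

#' Constraint-checked subnetwork score
#'
#' The average gene activity score of the member set, or 0 when a clustering
#' constraint is violated: for member sets of size 3 or more, the average
#' weighted clustering coefficient of the induced subgraph must reach the
#' (absolute) threshold in every species network in play. Sets of size 1-2
#' are exempt (their clustering coefficient is structurally 0) and are kept
#' out of reports by `min_report_size`.
#'
#' @param members character vector of cluster identifiers
#' @param nets list with `a` (and, for two-species modes, `b`) of
#'   [weighted_network()]s
#' @param profiles list with `a` (and `b`) of [activity_profile()]s
#' @param config a [search_config()]
#' @param cc_abs optional named vector `c(a=, b=)` of pre-resolved absolute
#'   clustering thresholds (computed from `config` when missing)
#' @return the mean member gene score, or 0 on constraint violation
#' @export
constrained_score <- function(members, nets, profiles, config,
                              cc_abs = NULL) {
  if (length(members) == 0L) stop("member set must be non-empty")
  two_species <- config$mode != "single_species"
  missing_a <- setdiff(members, nets$a$nodes)
  if (length(missing_a) > 0L)
    stop(sprintf("member '%s' absent from species A network", missing_a[1L]))
  if (two_species) {
    missing_b <- setdiff(members, nets$b$nodes)
    if (length(missing_b) > 0L)
      stop(sprintf("member '%s' absent from species B network", missing_b[1L]))
  }
  if (is.null(cc_abs)) cc_abs <- resolve_cc_thresholds(nets, config)
  if (length(members) >= 3L) {
    if (average_clustering_coefficient(nets$a, members) < cc_abs[["a"]])
      return(0)
    if (two_species &&
        average_clustering_coefficient(nets$b, members) < cc_abs[["b"]])
      return(0)
  }
  subnetwork_score(member_scores(members, profiles, config$mode))
}

# Best stored path (seed -> candidate) across the two species'
# neighbourhoods, restricted to eligible intermediate nodes. Returns NULL
# when no eligible path exists.
best_candidate_path <- function(node, nbhd_a, nbhd_b, eligible) {
  opts <- list()
  if (!is.null(nbhd_a) && node %in% names(nbhd_a$confidence))
    opts[["a"]] <- list(conf = nbhd_a$confidence[[node]],
                        path = nbhd_a$path[[node]])
  if (!is.null(nbhd_b) && node %in% names(nbhd_b$confidence))
    opts[["b"]] <- list(conf = nbhd_b$confidence[[node]],
                        path = nbhd_b$path[[node]])
  opts <- Filter(function(o) all(o$path %in% eligible), opts)
  if (length(opts) == 0L) return(NULL)
  confs <- vapply(opts, `[[`, 0, "conf")
  opts[[which.max(confs)]]$path   # which.max ties -> species A first
}

#' Grow one subnetwork from a seed
#'
#' Implements the greedy seed-and-extend step. The candidate pool is the
#' union of the seed's functional neighbourhoods in the two species
#' (restricted, in two-species modes, to clusters present in both networks).
#' At each iteration the candidate maximizing the constraint-checked score —
#' evaluated after also pulling in the nodes of its stored highest-confidence
#' path to the seed, which lets inactive bridging genes enter — is added,
#' provided the new score stays at or above `score_cutoff`. Growth stops when
#' no candidate qualifies or `max_size` is reached. Ties between candidates
#' go to the lexicographically smallest cluster identifier.
#'
#' @inheritParams constrained_score
#' @param seed cluster identifier with non-zero gene score in the run's mode
#' @param trace if `TRUE`, record a per-iteration snapshot of the member set
#'   and score
#' @return an object of class `subnetwork` (list with `seed`, `members` in
#'   insertion order, `score`, `cc_a`, `cc_b`, `mode`, `trace`), or `NULL`
#'   when the seed is ineligible or the grown set is smaller than
#'   `min_report_size`
#' @export
grow_subnetwork <- function(seed, nets, profiles, config, cc_abs = NULL,
                            trace = TRUE) {
  two_species <- config$mode != "single_species"
  if (!seed %in% nets$a$nodes) return(NULL)
  if (two_species && !seed %in% nets$b$nodes) return(NULL)
  if (member_scores(seed, profiles, config$mode) == 0) return(NULL)
  if (is.null(cc_abs)) cc_abs <- resolve_cc_thresholds(nets, config)

  nbhd_a <- functional_neighborhood(nets$a, seed, config$path_threshold_a)
  nbhd_b <- if (two_species)
    functional_neighborhood(nets$b, seed, config$path_threshold_b)
  else NULL
  pool <- union(names(nbhd_a$confidence),
                if (is.null(nbhd_b)) character() else names(nbhd_b$confidence))
  eligible <- if (two_species)
    intersect(nets$a$nodes, nets$b$nodes)
  else nets$a$nodes
  pool <- sort(intersect(pool, eligible))
  paths <- lapply(pool, best_candidate_path, nbhd_a, nbhd_b, eligible)
  names(paths) <- pool
  pool <- pool[!vapply(paths, is.null, TRUE)]

  members <- seed
  score <- constrained_score(members, nets, profiles, config, cc_abs)
  if (score < config$score_cutoff) return(NULL)
  snapshots <- list(list(members = members, score = score))

  repeat {
    avail <- setdiff(pool, members)
    if (length(avail) == 0L || length(members) >= config$max_size) break
    best_gain <- -Inf; best_members <- NULL
    for (g in avail) {
      extra <- setdiff(c(paths[[g]][-1L]), members)  # path minus seed
      cand_members <- c(members, setdiff(extra, g), g)
      if (length(cand_members) > config$max_size) next
      s <- constrained_score(cand_members, nets, profiles, config, cc_abs)
      if (s > best_gain) {  # avail is sorted, so ties keep the smallest id
        best_gain <- s
        best_members <- cand_members
      }
    }
    if (is.null(best_members) || best_gain < config$score_cutoff) break
    members <- best_members
    score <- best_gain
    snapshots[[length(snapshots) + 1L]] <- list(members = members,
                                                score = score)
  }

  if (length(members) < config$min_report_size) return(NULL)
  structure(
    list(seed = seed,
         members = members,
         score = score,
         cc_a = average_clustering_coefficient(nets$a, members),
         cc_b = if (two_species)
           average_clustering_coefficient(nets$b, members) else NA_real_,
         mode = config$mode,
         color = NA_character_,
         trace = if (trace) snapshots else NULL),
    class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork (seed %s, %s mode): %d members, score %.3f, cc %.3f/%s\n",
              x$seed, x$mode, length(x$members), x$score, x$cc_a,
              if (is.na(x$cc_b)) "-" else sprintf("%.3f", x$cc_b)))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Remove subnetworks that mostly overlap a larger one
#'
#' Subnetworks are ordered by size (descending; ties by higher score, then by
#' seed identifier) and scanned in order; a subnetwork is dropped when the
#' fraction of its members shared with any already-kept subnetwork exceeds
#' `overlap_threshold`. The operation is idempotent.
#'
#' @param subnets list of `subnetwork` objects
#' @param overlap_threshold fraction in `(0, 1]`
#' @return the filtered list, in the scan order
#' @export
deduplicate_subnetworks <- function(subnets, overlap_threshold = 0.6) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  if (length(subnets) <= 1L) return(subnets)
  sizes <- vapply(subnets, function(s) length(s$members), 0L)
  scores <- vapply(subnets, function(s) s$score, 0)
  seeds <- vapply(subnets, function(s) s$seed, "")
  ord <- order(-sizes, -scores, seeds)
  kept <- list()
  for (i in ord) {
    mem <- subnets[[i]]$members
    dup <- any(vapply(kept, function(k)
      length(intersect(mem, k$members)) / length(mem) > overlap_threshold,
      TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- subnets[[i]]
  }
  kept
}

#' Classify a subnetwork's expression direction
#'
#' Members are counted as up-regulated (positive conserved activity sign,
#' i.e. up in both species) or down-regulated (negative sign); zero-activity
#' members are ignored. The subnetwork is `"green"` (active in the first
#' state, e.g. stem cells) when up-counts exceed twice the down-counts,
#' `"red"` when down-counts exceed twice the up-counts, otherwise
#' `"yellow"` (mixed).
#'
#' @param members character vector of cluster identifiers
#' @param profiles list with activity profiles `a` and (optionally) `b`
#' @return one of `"green"`, `"red"`, `"yellow"`
#' @export
classify_color <- function(members, profiles) {
  m <- activity_of(profiles$a, members)
  s <- if (is.null(profiles$b)) sign(m) else {
    h <- activity_of(profiles$b, members)
    ifelse(sign(m) == sign(h), sign(m), 0)  # shared direction, else ignored
  }
  up <- sum(s > 0)
  down <- sum(s < 0)
  if (up > 2 * down) "green" else if (down > 2 * up) "red" else "yellow"
}

#' Discover active subnetworks
#'
#' Runs [grow_subnetwork()] from every cluster with non-zero activity in
#' either species, removes mostly-overlapping results with
#' [deduplicate_subnetworks()], and classifies each surviving subnetwork's
#' expression direction. Deterministic given the inputs.
#'
#' @param net_a [weighted_network()] of the first species, in ortholog
#'   cluster space
#' @param activity_a [activity_profile()] of the first species, in cluster
#'   space
#' @param net_b,activity_b second species (omit for
#'   `mode = "single_species"`)
#' @param config a [search_config()]
#' @return an object of class `subnetwork_set`: list of `subnetwork`s with
#'   the configuration and resolved clustering thresholds as attributes
#' @export
discover_subnetworks <- function(net_a, activity_a, net_b = NULL,
                                 activity_b = NULL,
                                 config = search_config()) {
  two_species <- config$mode != "single_species"
  if (two_species && (is.null(net_b) || is.null(activity_b)))
    stop(sprintf("mode '%s' needs both species' networks and activities",
                 config$mode))
  nets <- list(a = net_a, b = net_b)
  profiles <- list(a = activity_a, b = activity_b)
  cc_abs <- resolve_cc_thresholds(nets, config)

  active <- union(names(activity_a)[activity_a != 0],
                  if (is.null(activity_b)) character()
                  else names(activity_b)[activity_b != 0])
  eligible <- if (two_species) intersect(net_a$nodes, net_b$nodes)
  else net_a$nodes
  seeds <- sort(intersect(active, eligible))

  found <- list()
  for (seed in seeds) {
    sn <- grow_subnetwork(seed, nets, profiles, config, cc_abs)
    if (!is.null(sn)) found[[length(found) + 1L]] <- sn
  }
  found <- deduplicate_subnetworks(found, config$overlap_threshold)
  found <- lapply(found, function(s) {
    s$color <- classify_color(s$members, profiles)
    s
  })
  structure(found, class = "subnetwork_set", config = config,
            cc_abs = cc_abs)
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("subnetwork_set: %d subnetwork(s) [%s mode, score cutoff %.3g]\n",
              length(x), cfg$mode, cfg$score_cutoff))
  if (length(x) > 0) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.subnetwork_set <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(seed = character(), size = integer(),
                      score = numeric(), cc_a = numeric(), cc_b = numeric(),
                      color = character(), members = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    seed = vapply(x, function(s) s$seed, ""),
    size = vapply(x, function(s) length(s$members), 0L),
    score = vapply(x, function(s) s$score, 0),
    cc_a = vapply(x, function(s) s$cc_a, 0),
    cc_b = vapply(x, function(s) s$cc_b, 0),
    color = vapply(x, function(s) if (is.na(s$color)) "" else s$color, ""),
    members = vapply(x, function(s) paste(s$members, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' @export
summary.subnetwork_set <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("%d subnetwork(s); mean size %.2f; mean score %.3f\n",
              nrow(df),
              if (nrow(df)) mean(df$size) else NA,
              if (nrow(df)) mean(df$score) else NA))
  invisible(df)
}

#' Plot a subnetwork
#'
#' Draws the induced subgraph of one species with edge width proportional to
#' linkage weight and node colour by activity sign (green up, red down, grey
#' inactive).
#'
#' @param x a `subnetwork`
#' @param net the species network to induce on
#' @param activity that species' [activity_profile()]
#' @param ... passed to [igraph::plot.igraph()]
#' @export
plot.subnetwork <- function(x, net, activity, ...) {
  sub <- induce_network(net, x$members)
  g <- as_igraph(sub, activity)
  act <- igraph::V(g)$activity
  igraph::V(g)$color <- ifelse(act > 0, "palegreen3",
                               ifelse(act < 0, "indianred2", "grey80"))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$width <- 1 + 4 * igraph::E(g)$weight
  igraph::plot.igraph(g, ...)
  invisible(g)
}
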
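#' Specification of a paired-species synthetic benchmark
#'
#' Describes a two-species benchmark with planted modules. Conserved modules
#' are dense high-weight subgraphs present in both species' networks whose
#' members carry high-magnitude, sign-consistent activity in both species.
#' Species-specific modules share the dense topology in both networks but
#' their activity is planted in species A only (species B members are
#' inactive or, optionally, regulated in the opposite direction), so they
#' diverge in expression rather than in structure. Everything else is
#' background: sparse low-weight edges and mostly-zero activities with
#' small-magnitude tails.
#'
#' @param n_clusters total number of ortholog clusters
#' @param n_conserved_modules,n_specific_modules number of planted modules
#' @param module_size members per module (disjoint across modules)
#' @param p_within within-module edge probability (per species)
#' @param p_background background edge probability (per species)
#' @param w_within,w_background uniform weight ranges for module and
#'   background edges
#' @param activity_high uniform magnitude range of planted activities
#' @param activity_noise_frac fraction of background clusters with non-zero
#'   activity (per species)
#' @param activity_noise_max magnitude cap of background activities (drawn
#'   uniformly from `(0, activity_noise_max]` with random sign)
#' @param mixed_sign_fraction fraction of conserved modules whose members get
#'   per-member random signs (still consistent across species) instead of
#'   one module-wide sign; exercises the mixed ("yellow") colour class
#' @param specific_b species-B activity of specific-module members:
#'   `"zero"` (inactive) or `"opposite"` (inverted sign)
#' @param paralog_rate fraction of clusters carrying two genes in one
#'   (randomly chosen) species
#' @param rng_seed integer seed; the whole benchmark is reproducible from it
#' @return a list of class `benchmark_spec`
#' @export
benchmark_spec <- function(n_clusters = 300L,
                           n_conserved_modules = 3L,
                           n_specific_modules = 2L,
                           module_size = 8L,
                           p_within = 0.8,
                           p_background = 0.02,
                           w_within = c(0.6, 1.0),
                           w_background = c(0.05, 0.25),
                           activity_high = c(0.6, 1.0),
                           activity_noise_frac = 0.2,
                           activity_noise_max = 0.3,
                           mixed_sign_fraction = 0,
                           specific_b = c("zero", "opposite"),
                           paralog_rate = 0.1,
                           rng_seed = 1L) {
  specific_b <- match.arg(specific_b)
  n_planted <- module_size * (n_conserved_modules + n_specific_modules)
  if (n_planted > n_clusters)
    stop("planted modules need more clusters than n_clusters provides")
  stopifnot(p_within >= 0, p_within <= 1, p_background >= 0, p_background <= 1,
            all(w_within > 0), all(w_within <= 1),
            all(w_background > 0), all(w_background <= 1),
            all(activity_high > 0), all(activity_high <= 1),
            activity_noise_frac >= 0, activity_noise_frac <= 1,
            activity_noise_max >= 0, activity_noise_max <= 1,
            mixed_sign_fraction >= 0, mixed_sign_fraction <= 1,
            paralog_rate >= 0, paralog_rate <= 1)
  structure(as.list(environment())[c(
    "n_clusters", "n_conserved_modules", "n_specific_modules", "module_size",
    "p_within", "p_background", "w_within", "w_background", "activity_high",
    "activity_noise_frac", "activity_noise_max", "mixed_sign_fraction",
    "specific_b", "paralog_rate", "rng_seed")],
    class = "benchmark_spec")
}

# Random edges among `nodes` (plus optional cross edges to `others`) with
# probability p and uniform weights in wr. Returns an edge data frame.
random_edges <- function(nodes, p, wr, others = NULL) {
  if (is.null(others)) {
    pairs <- utils::combn(nodes, 2L)
    from <- pairs[1L, ]; to <- pairs[2L, ]
  } else {
    g <- expand.grid(from = nodes, to = others, stringsAsFactors = FALSE)
    from <- g$from; to <- g$to
  }
  keep <- stats::runif(length(from)) < p
  data.frame(from = from[keep], to = to[keep],
             weight = stats::runif(sum(keep), wr[1L], wr[2L]),
             stringsAsFactors = FALSE)
}

#' Generate a paired-species benchmark with planted modules
#'
#' Draws the cluster-space structure described by the [benchmark_spec()],
#' then expands it to gene space through a generated orthology map: every
#' cluster has one gene per species except a `paralog_rate` fraction, which
#' get two genes in one species. Gene-level edges replicate their cluster
#' edge's weight across all gene pairs and member genes inherit the cluster
#' activity, so mapping back to cluster space recovers the planted values
#' exactly.
#'
#' @param spec a [benchmark_spec()]
#' @return list of class `benchmark` with gene-space `net_a`, `net_b`,
#'   `activity_a`, `activity_b`, the `orthology` map, the generating `spec`,
#'   and `truth`: a list per planted module with `members` (cluster ids),
#'   `type` (`"conserved"`/`"specific"`) and the planted `sign_a`, `sign_b`
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  with_rng_seed(spec$rng_seed, {
    clusters <- sprintf("C%04d", seq_len(spec$n_clusters))
    n_mod <- spec$n_conserved_modules + spec$n_specific_modules
    planted <- sample(clusters, n_mod * spec$module_size)
    modules <- split(planted, rep(seq_len(n_mod), each = spec$module_size))
    types <- rep(c("conserved", "specific"),
                 c(spec$n_conserved_modules, spec$n_specific_modules))
    mixed <- rep(FALSE, n_mod)
    if (spec$n_conserved_modules > 0) {
      n_mixed <- round(spec$mixed_sign_fraction * spec$n_conserved_modules)
      mixed[seq_len(n_mixed)] <- TRUE
    }
    background <- setdiff(clusters, planted)

    # cluster-space networks: module edges drawn independently per species
    draw_net <- function() {
      mod_edges <- lapply(modules, random_edges,
                          p = spec$p_within, wr = spec$w_within)
      bg <- random_edges(clusters, spec$p_background, spec$w_background)
      # background draw may duplicate a module pair; constructor keeps max
      weighted_network(do.call(rbind, c(mod_edges, list(bg))))
    }
    cnet_a <- draw_net()
    cnet_b <- draw_net()

    # cluster-space activities
    act_a <- structure(numeric(spec$n_clusters), names = clusters)
    act_b <- act_a
    truth <- vector("list", n_mod)
    for (i in seq_len(n_mod)) {
      mem <- modules[[i]]
      k <- length(mem)
      sgn <- if (mixed[i]) sample(c(-1, 1), k, replace = TRUE)
        else rep(sample(c(-1, 1), 1L), k)
      mag_a <- stats::runif(k, spec$activity_high[1L], spec$activity_high[2L])
      mag_b <- stats::runif(k, spec$activity_high[1L], spec$activity_high[2L])
      if (types[i] == "conserved") {
        act_a[mem] <- sgn * mag_a
        act_b[mem] <- sgn * mag_b
        sign_b <- sgn
      } else {
        act_a[mem] <- sgn * mag_a
        sign_b <- if (spec$specific_b == "opposite") -sgn else rep(0, k)
        act_b[mem] <- sign_b * mag_b
      }
      truth[[i]] <- list(id = sprintf("M%02d", i), members = sort(mem),
                         type = types[i], sign_a = sgn[1L],
                         sign_b = sign_b[1L], mixed = mixed[i])
    }
    for (sp in c("a", "b")) {
      nz <- background[stats::runif(length(background)) < spec$activity_noise_frac]
      vals <- sample(c(-1, 1), length(nz), replace = TRUE) *
        stats::runif(length(nz), .Machine$double.eps, spec$activity_noise_max)
      if (sp == "a") act_a[nz] <- vals else act_b[nz] <- vals
    }

    # orthology: one gene per species per cluster, plus paralogs
    paralog <- stats::runif(spec$n_clusters) < spec$paralog_rate
    paralog_sp <- sample(c("A", "B"), spec$n_clusters, replace = TRUE)
    orows <- list()
    genes_of <- list(A = list(), B = list())
    for (i in seq_along(clusters)) {
      cl <- clusters[i]
      for (sp in c("A", "B")) {
        n_genes <- 1L + (paralog[i] && paralog_sp[i] == sp)
        g <- sprintf("%s_%s_g%d", tolower(sp), cl, seq_len(n_genes))
        genes_of[[sp]][[cl]] <- g
        orows[[length(orows) + 1L]] <- data.frame(cluster = cl, species = sp,
                                                  gene = g,
                                                  stringsAsFactors = FALSE)
      }
    }
    od <- do.call(rbind, orows)
    orth <- orthology_map(od$cluster, od$species, od$gene)

    expand_net <- function(cnet, sp) {
      e <- cnet$edges
      rows <- lapply(seq_len(nrow(e)), function(j) {
        ga <- genes_of[[sp]][[e$from[j]]]
        gb <- genes_of[[sp]][[e$to[j]]]
        g <- expand.grid(from = ga, to = gb, stringsAsFactors = FALSE)
        g$weight <- e$weight[j]
        g
      })
      weighted_network(do.call(rbind, rows))
    }
    expand_act <- function(act, sp) {
      cl <- rep(names(act), lengths(genes_of[[sp]])[names(act)])
      g <- unlist(genes_of[[sp]][names(act)], use.names = FALSE)
      activity_profile(structure(unname(act[cl]), names = g))
    }

    structure(list(net_a = expand_net(cnet_a, "A"),
                   net_b = expand_net(cnet_b, "B"),
                   activity_a = expand_act(act_a, "A"),
                   activity_b = expand_act(act_b, "B"),
                   orthology = orth,
                   truth = truth,
                   spec = spec),
              class = "benchmark")
  })
}

#' @export
print.benchmark <- function(x, ...) {
  cat(sprintf("benchmark: %d clusters, %d planted module(s) [seed %d]\n",
              x$spec$n_clusters, length(x$truth), x$spec$rng_seed))
  cat(sprintf("  species A: %d genes, %d edges; species B: %d genes, %d edges\n",
              length(x$net_a$nodes), n_edges(x$net_a),
              length(x$net_b$nodes), n_edges(x$net_b)))
  invisible(x)
}

#' Map a benchmark into ortholog-cluster space
#'
#' Convenience wrapper applying [map_to_cluster_space()] and
#' [map_activity_to_clusters()] to both species.
#'
#' @param bm a `benchmark` from [generate_benchmark()]
#' @return list with cluster-space `net_a`, `net_b`, `activity_a`,
#'   `activity_b`
#' @export
benchmark_cluster_space <- function(bm) {
  list(net_a = map_to_cluster_space(bm$net_a, bm$orthology, "A"),
       net_b = map_to_cluster_space(bm$net_b, bm$orthology, "B"),
       activity_a = map_activity_to_clusters(bm$activity_a, bm$orthology, "A"),
       activity_b = map_activity_to_clusters(bm$activity_b, bm$orthology, "B"))
}

#' Write benchmark files
#'
#' Emits the TSV formats the readers consume (`net_a.tsv`, `net_b.tsv`,
#' `activity_a.tsv`, `activity_b.tsv`, `orthology.tsv`) plus `truth.json`.
#'
#' @param bm a `benchmark`
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
write_benchmark <- function(bm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bm$net_a, file.path(dir, "net_a.tsv"))
  write_network(bm$net_b, file.path(dir, "net_b.tsv"))
  write_activity(bm$activity_a, file.path(dir, "activity_a.tsv"))
  write_activity(bm$activity_b, file.path(dir, "activity_b.tsv"))
  write_orthology(bm$orthology, file.path(dir, "orthology.tsv"))
  jsonlite::write_json(
    lapply(bm$truth, function(m)
      list(id = m$id, members = m$members, type = m$type,
           sign_a = m$sign_a, sign_b = m$sign_b)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Recovery of planted modules by discovered subnetworks
#'
#' For each planted module, the best Jaccard index between its member set
#' and any discovered subnetwork. Recall is the fraction of modules (of the
#' requested type) whose best Jaccard reaches `jaccard_min`; precision is
#' the fraction of discovered subnetworks matching some planted module at
#' `jaccard_min`.
#'
#' @param found a `subnetwork_set` (or list of `subnetwork`s)
#' @param truth the `truth` element of a `benchmark`
#' @param type which planted modules recall is computed over:
#'   `"conserved"`, `"specific"`, or `"any"`
#' @param jaccard_min match threshold (default 0.5)
#' @return list with `per_module` data frame (`module`, `type`,
#'   `best_jaccard`, `best_match_seed`), `recall`, `precision`
#' @export
recovery_metrics <- function(found, truth, type = c("conserved", "specific",
                                                    "any"),
                             jaccard_min = 0.5) {
  type <- match.arg(type)
  jaccard <- function(x, y)
    length(intersect(x, y)) / length(union(x, y))
  per_module <- do.call(rbind, lapply(truth, function(m) {
    js <- vapply(found, function(s) jaccard(s$members, m$members), 0)
    best <- if (length(js)) which.max(js) else NA_integer_
    data.frame(module = m$id, type = m$type,
               best_jaccard = if (length(js)) max(js) else 0,
               best_match_seed = if (is.na(best)) NA_character_
                 else found[[best]]$seed,
               stringsAsFactors = FALSE)
  }))
  rel <- if (type == "any") per_module
    else per_module[per_module$type == type, , drop = FALSE]
  recall <- if (nrow(rel) == 0L) NA_real_
    else mean(rel$best_jaccard >= jaccard_min)
  precision <- if (length(found) == 0L) NA_real_
    else mean(vapply(found, function(s)
      max(vapply(truth, function(m) jaccard(s$members, m$members), 0)) >=
        jaccard_min, TRUE))
  list(per_module = per_module, recall = recall, precision = precision)
}
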
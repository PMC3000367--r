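#' Write discovered subnetworks to disk
#'
#' Emits `subnetworks.tsv` (one row per subnetwork: seed, size, score,
#' per-species average weighted clustering coefficients, colour class,
#' comma-separated members) and, per subnetwork, GraphML files of the
#' induced subgraphs in each available species (`sub<i>_<species>.graphml`)
#' with a `weight` edge attribute and an `activity` node attribute. Output
#' is byte-stable for a fixed input ordering.
#'
#' @param subnets a `subnetwork_set` (or list of `subnetwork`s)
#' @param out_dir output directory (created if needed)
#' @param nets list with species networks `a` and optionally `b`, in the same
#'   identifier space as the subnetwork members
#' @param profiles list with activity profiles `a` and optionally `b`
#' @return `out_dir`, invisibly
#' @export
write_subnetworks <- function(subnets, out_dir, nets = NULL, profiles = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame.subnetwork_set(
    structure(unclass(subnets), class = "subnetwork_set"))
  utils::write.table(df, file.path(out_dir, "subnetworks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(nets)) {
    for (i in seq_along(subnets)) {
      for (sp in intersect(c("a", "b"), names(nets))) {
        if (is.null(nets[[sp]])) next
        sub <- induce_network(nets[[sp]], subnets[[i]]$members)
        g <- as_igraph(sub, if (is.null(profiles)) NULL else profiles[[sp]])
        igraph::write_graph(
          g, file.path(out_dir, sprintf("sub%03d_%s.graphml", i, sp)),
          format = "graphml")
      }
    }
  }
  invisible(out_dir)
}
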
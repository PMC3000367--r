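#' Rescale raw log fold changes to signed activities in [-1, +1]
#'
#' Non-significant genes are set to 0. Significant up-regulated genes are
#' divided by the largest positive log-ratio among significant genes, and
#' significant down-regulated genes by the magnitude of the most negative
#' one, so the directional extremes land exactly at +1 and -1. Rescaling by
#' the directional extreme is invariant to the logarithm base of the input.
#'
#' @param genes character vector of identifiers
#' @param log_fold_change signed numeric log-ratios
#' @param significant logical vector (differentially expressed or not)
#' @return an [activity_profile()]
#' @export
normalize_fold_changes <- function(genes, log_fold_change, significant) {
  stopifnot(length(genes) == length(log_fold_change),
            length(genes) == length(significant))
  if (length(genes) == 0L) return(activity_profile())
  lfc <- as.numeric(log_fold_change)
  sig <- as.logical(significant)
  if (anyNA(lfc) || anyNA(sig)) stop("fold changes and flags must be non-missing")
  score <- numeric(length(lfc))
  up <- sig & lfc > 0
  down <- sig & lfc < 0
  if (any(up)) score[up] <- lfc[up] / max(lfc[up])
  if (any(down)) score[down] <- lfc[down] / abs(min(lfc[down]))
  names(score) <- as.character(genes)
  activity_profile(score)
}

#' Gene-level activity score
#'
#' Combines the two species' normalized activities for one ortholog cluster:
#' \describe{
#'   \item{conserved}{`sign(m * h) * sqrt(|m * h|)` — geometric mean of the
#'     magnitudes, signed by agreement of direction; 0 when either species is
#'     inactive}
#'   \item{species_specific}{`|m - h|`, the divergence of the two activities}
#'   \item{single_species}{`m` unchanged}
#' }
#' Vectorized over `m` and `h`.
#'
#' @param m,h normalized activities in `[-1, +1]` (first/second species)
#' @param mode one of `"conserved"`, `"species_specific"`, `"single_species"`
#' @return numeric score(s); in `[-1, +1]` for conserved/single_species,
#'   `[0, 2]` for species_specific
#' @export
gene_score <- function(m, h = NULL, mode = c("conserved", "species_specific",
                                             "single_species")) {
  mode <- match.arg(mode)
  if (any(abs(m) > 1)) stop("activity m outside [-1, +1]")
  if (mode == "single_species") return(as.numeric(m))
  if (is.null(h)) stop("two-species modes require both activities")
  if (any(abs(h) > 1)) stop("activity h outside [-1, +1]")
  switch(mode,
         conserved = sign(m * h) * sqrt(abs(m * h)),
         species_specific = abs(m - h))
}

#' Subnetwork activity score (unconstrained)
#'
#' The plain arithmetic mean of member gene scores. Constraint checking
#' (clustering coefficients) lives in [constrained_score()].
#'
#' @param scores numeric vector of member gene scores
#' @return the mean score
#' @export
subnetwork_score <- function(scores) {
  if (length(scores) == 0L) stop("subnetwork must have at least one member")
  mean(scores)
}
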
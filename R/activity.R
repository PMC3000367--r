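#' Activity profile
#'
#' A named numeric vector of signed, normalized differential-expression
#' activities in `[-1, +1]`, keyed by gene or ortholog-cluster identifier.
#' Nodes absent from the profile have implicit activity 0.
#'
#' @param scores named numeric vector with values in `[-1, +1]`
#' @return the validated vector with class `activity_profile`
#' @export
activity_profile <- function(scores = numeric()) {
  if (length(scores) > 0 && is.null(names(scores)))
    stop("activity scores must be named by gene/cluster identifier")
  scores <- vapply(split(scores, names(scores)), `[[`, 0, 1L)  # dedupe keeps first
  if (anyNA(scores)) stop("activity scores must not be missing")
  if (any(scores < -1 | scores > 1))
    stop("activity scores must lie in [-1, +1]")
  structure(scores[order(names(scores))], class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  nz <- sum(x != 0)
  cat(sprintf("activity_profile: %d genes (%d non-zero)\n", length(x), nz))
  invisible(x)
}

#' Look up activity scores with implicit zeros
#'
#' @param profile an [activity_profile()] (or plain named numeric vector)
#' @param nodes character vector of identifiers
#' @return numeric vector of scores, 0 for identifiers not in the profile
#' @export
activity_of <- function(profile, nodes) {
  out <- unname(unclass(profile)[nodes])
  out[is.na(out)] <- 0
  out
}

#' Read an activity table
#'
#' Accepts two TSV layouts, distinguished by the header:
#' \describe{
#'   \item{`gene score`}{pre-normalized signed activities in `[-1, +1]`,
#'     validated and returned as-is}
#'   \item{`gene fold_change significant`}{raw signed log fold changes with a
#'     0/1 significance flag, passed through [normalize_fold_changes()]}
#' }
#'
#' @param path file path
#' @return an [activity_profile()]
#' @export
read_activity <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) >= 3L) {
    return(normalize_fold_changes(as.character(tab[[1L]]),
                                  as.numeric(tab[[2L]]),
                                  as.logical(as.integer(tab[[3L]]))))
  }
  if (ncol(tab) != 2L)
    stop("activity table must have 2 (gene, score) or 3 (gene, fold_change, significant) columns")
  scores <- as.numeric(tab[[2L]])
  names(scores) <- as.character(tab[[1L]])
  activity_profile(scores)
}

#' Write an activity table
#'
#' @param profile an [activity_profile()]
#' @param path output file path
#' @export
write_activity <- function(profile, path) {
  utils::write.table(
    data.frame(gene = names(profile), score = as.numeric(profile)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
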
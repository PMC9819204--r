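#' Zero-anchored quantile scores for one taxon
#'
#' Zero-inflated abundances make plain quantile scoring degenerate (massive
#' ties at zero), so zeros are anchored at score 0 and only the positive
#' values are split into `levels - 1` ordered groups:
#' \itemize{
#'   \item `split = "quantile"`: cut points are the empirical quantiles
#'     (linear interpolation, type 7) of the positive values at
#'     k/(levels-1), k = 1..levels-2; a value equal to a cut point takes the
#'     lower group's score.
#'   \item `split = "median"` (levels = 3 only): positives score 1 if below
#'     their median, 2 if greater than or equal to it.
#' }
#' With `levels = 4` this is the "0 then tertiles above 0" scheme; with
#' `levels = 2` it reduces to presence/absence.
#'
#' @param values nonnegative numeric vector.
#' @param levels integer number of score levels (>= 2); scores are
#'   0..levels-1.
#' @param split `"quantile"` or `"median"`.
#' @return integer vector of scores, same length as `values`.
#' @export
zero_anchored_rank <- function(values, levels = 4L,
                               split = c("quantile", "median")) {
  split <- match.arg(split)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("levels must be an integer >= 2")
  if (split == "median" && levels != 3L)
    stop("split = 'median' requires levels = 3")
  if (anyNA(values) || any(values < 0)) stop("values must be nonnegative, no NA")
  score <- integer(length(values))
  pos <- values > 0
  if (!any(pos)) return(score)
  x <- values[pos]
  if (split == "median") {
    med <- stats::median(x)
    score[pos] <- ifelse(x < med, 1L, 2L)
  } else {
    if (levels == 2L) {
      score[pos] <- 1L
    } else {
      cuts <- stats::quantile(x, probs = seq_len(levels - 2L) / (levels - 1L),
                              type = 7, names = FALSE)
      # ties at a cut point stay in the lower group (strict > to move up)
      score[pos] <- 1L + vapply(x, function(v) sum(v > cuts), integer(1))
    }
  }
  score
}

#' Score every taxon of an abundance table
#'
#' Applies [zero_anchored_rank()] column-wise to a relative-abundance table.
#' Scoring is a preprocessing step computed on the full dataset (before any
#' train/validation split).
#'
#' @param table an [abundance_table()] in relative mode.
#' @param levels,split passed to [zero_anchored_rank()].
#' @return an object of class `ranked_matrix`: list with integer matrix
#'   `scores` (samples x taxa), `levels` and `split`.
#' @export
rank_table <- function(table, levels = 4L, split = c("quantile", "median")) {
  stopifnot(inherits(table, "abundance_table"))
  split <- match.arg(split)
  if (table$mode != "relative")
    stop("rank_table expects a relative-abundance table; see to_relative_abundance()")
  scores <- apply(table$values, 2, zero_anchored_rank,
                  levels = levels, split = split)
  scores <- matrix(as.integer(scores), nrow = nrow(table$values),
                   dimnames = dimnames(table$values))
  structure(list(scores = scores, levels = as.integer(levels), split = split),
            class = "ranked_matrix")
}

#' @export
print.ranked_matrix <- function(x, ...) {
  cat("ranked_matrix:", nrow(x$scores), "samples x", ncol(x$scores),
      "taxa; levels 0..", x$levels - 1L, " (", x$split, "split )\n")
  print(table(factor(x$scores, levels = 0:(x$levels - 1L))) / length(x$scores))
  invisible(x)
}
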
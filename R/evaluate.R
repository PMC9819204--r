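#' Equi-weight threshold for a c-component index
#'
#' 1/c: a component (or pooled genus) with weight above it contributes more
#' than it would if all components were weighted equally.
#'
#' @param n_components number of components (>= 1).
#' @return 1 / n_components.
#' @export
equi_weight_threshold <- function(n_components) {
  if (!is.numeric(n_components) || length(n_components) != 1 ||
      n_components < 1)
    stop("n_components must be a single integer >= 1")
  1 / n_components
}

#' Sensitivity and specificity of signal-taxon identification
#'
#' Against a known signal set: at each cutoff c, sensitivity is the fraction
#' of signal taxa with weight strictly above c and specificity the fraction
#' of non-signal taxa with weight strictly below c. A weight exactly equal
#' to the cutoff counts toward neither numerator ("exceeding"/"below" taken
#' literally), which matters at the equi-weight value. Optional strata
#' (e.g. strong/medium/weak) yield per-stratum sensitivities.
#'
#' @param weights named numeric weight vector over all taxa.
#' @param signal_set character ids (or integer positions) of the true
#'   signal taxa.
#' @param cutoffs positive cutoff vector; defaults to the 0.0005-0.002 grid
#'   in steps of 0.00005.
#' @param strata optional character vector of stratum labels for the signal
#'   taxa (named by taxon id, or aligned with `signal_set`).
#' @return an object of class `eval_curve`: data.frame with `cutoff`,
#'   `sensitivity`, `specificity` and one `sensitivity_<stratum>` column per
#'   stratum; denominators as attributes.
#' @export
sensitivity_specificity <- function(weights, signal_set,
                                    cutoffs = seq(0.0005, 0.002, by = 0.00005),
                                    strata = NULL) {
  if (length(signal_set) == 0) stop("signal set is empty")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (is.numeric(signal_set)) {
    sig_idx <- as.integer(signal_set)
  } else {
    if (is.null(names(weights))) stop("weights must be named to match taxon ids")
    sig_idx <- match(signal_set, names(weights))
    if (anyNA(sig_idx))
      stop("signal taxa not in weights: ",
           paste(signal_set[is.na(sig_idx)], collapse = ", "))
  }
  w_sig <- weights[sig_idx]
  w_non <- weights[-sig_idx]
  if (length(w_non) == 0) stop("no non-signal taxa")
  sens <- vapply(cutoffs, function(c) mean(w_sig > c), numeric(1))
  spec <- vapply(cutoffs, function(c) mean(w_non < c), numeric(1))
  out <- data.frame(cutoff = cutoffs, sensitivity = sens, specificity = spec)
  if (!is.null(strata)) {
    if (!is.null(names(strata)) && !is.numeric(signal_set))
      strata <- strata[as.character(signal_set)]
    if (length(strata) != length(sig_idx))
      stop("strata must align with signal_set")
    for (s in unique(strata)) {
      ws <- w_sig[strata == s]
      out[[paste0("sensitivity_", s)]] <-
        vapply(cutoffs, function(c) mean(ws > c), numeric(1))
    }
    attr(out, "stratum_sizes") <- table(strata)
  }
  attr(out, "n_signal") <- length(sig_idx)
  attr(out, "n_nonsignal") <- length(w_non)
  class(out) <- c("eval_curve", "data.frame")
  out
}

#' Evaluate taxon identification of a repeated-holdout ensemble
#'
#' Two modes: `"per-holdout"` (default) computes sensitivity/specificity of
#' each holdout's final weights and reports their mean across holdouts, the
#' convention for averaged operating characteristics over repeated
#' holdouts; `"mean-weights"` evaluates the ensemble mean weight vector
#' once.
#'
#' @param ensemble a `wqs_rsrh` fit (or, with `mode = "mean-weights"`, any
#'   named weight vector).
#' @param design a `simulation_design` (signal taxa and strengths) or a
#'   character vector of signal taxon ids.
#' @param cutoffs cutoff grid, see [sensitivity_specificity()].
#' @param mode `"per-holdout"` or `"mean-weights"`.
#' @return an `eval_curve` (per-holdout mode: entries are means across
#'   holdouts).
#' @export
evaluate_identification <- function(ensemble, design,
                                    cutoffs = seq(0.0005, 0.002, by = 0.00005),
                                    mode = c("per-holdout", "mean-weights")) {
  mode <- match.arg(mode)
  if (inherits(design, "simulation_design")) {
    signal_set <- design$signal_taxa$taxon_id
    strata <- stats::setNames(design$signal_taxa$strength, signal_set)
  } else {
    signal_set <- design
    strata <- NULL
  }
  if (mode == "mean-weights") {
    w <- if (inherits(ensemble, "wqs_rsrh")) ensemble$mean_weights else ensemble
    return(sensitivity_specificity(w, signal_set, cutoffs, strata))
  }
  stopifnot(inherits(ensemble, "wqs_rsrh"))
  curves <- lapply(seq_len(ncol(ensemble$weight_matrix)), function(r) {
    w <- stats::setNames(ensemble$weight_matrix[, r],
                         names(ensemble$mean_weights))
    sensitivity_specificity(w, signal_set, cutoffs, strata)
  })
  out <- curves[[1]]
  num_cols <- setdiff(names(out), "cutoff")
  for (cn in num_cols)
    out[[cn]] <- rowMeans(matrix(vapply(curves, `[[`, numeric(nrow(out)), cn),
                                 nrow = nrow(out)))
  attr(out, "mode") <- "per-holdout"
  attr(out, "n_holdouts") <- length(curves)
  out
}

#' @export
print.eval_curve <- function(x, ...) {
  ns <- attr(x, "n_signal")
  nn <- attr(x, "n_nonsignal")
  if (is.null(ns) || is.null(nn)) {  # subsetting drops the denominators
    print(as.data.frame(x))
    return(invisible(x))
  }
  cat("identification curve over", nrow(x), "cutoffs; signal taxa:",
      ns, ", non-signal:", nn, "\n")
  thr <- equi_weight_threshold(ns + nn)
  i <- which.min(abs(x$cutoff - thr))
  cat(sprintf("  near equi-weight cutoff %.5g: sensitivity %.3f, specificity %.3f\n",
              x$cutoff[i], x$sensitivity[i], x$specificity[i]))
  invisible(x)
}

#' Normal-approximation confidence interval for a proportion
#'
#' `p +/- 1.96 * sqrt(p(1-p)/n)`, clipped to [0, 1]; the conventional Wald
#' interval used to report the spread of averaged sensitivity/specificity
#' estimates.
#'
#' @param p proportion in [0, 1].
#' @param n number of observations (>= 1).
#' @return named numeric `c(lower, upper)`.
#' @export
proportion_ci <- function(p, n) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}
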
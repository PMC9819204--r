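#' Shannon diversity of one sample
#'
#' H = -sum p_i ln p_i over the positive proportions (natural log).
#'
#' @param relabund_row nonnegative abundance vector with positive sum.
#' @return Shannon index.
#' @export
shannon_index <- function(relabund_row) {
  if (any(relabund_row < 0)) stop("abundances must be nonnegative")
  if (sum(relabund_row) <= 0) stop("all-zero sample")
  as.numeric(vegan::diversity(relabund_row, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' sum |a - b| / sum (a + b); in [0, 1] for nonnegative input.
#'
#' @param a,b nonnegative abundance vectors of equal length.
#' @return Bray-Curtis dissimilarity.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (sum(a) <= 0 || sum(b) <= 0) stop("each sample needs a positive entry")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the centered-log-ratio transforms of the two
#' vectors after adding a pseudocount and renormalizing; the compositional
#' distance, invariant to sample scale.
#'
#' @param a,b nonnegative vectors of equal length.
#' @param pseudocount positive offset added before closure (handles zeros).
#' @return Aitchison distance.
#' @export
aitchison_distance <- function(a, b, pseudocount = 1e-6) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  clr <- function(x) {
    x <- x / sum(x)        # close first, so the distance is scale-invariant
    x <- x + pseudocount
    x <- x / sum(x)
    log(x) - mean(log(x))
  }
  sqrt(sum((clr(a) - clr(b))^2))
}

#' Between-sample distance matrix of an abundance table
#'
#' @param table an [abundance_table()].
#' @param metric `"bray"` or `"aitchison"`.
#' @param pseudocount for the Aitchison metric.
#' @return a `stats::dist` object with sample labels.
#' @export
community_distance <- function(table, metric = c("bray", "aitchison"),
                               pseudocount = 1e-6) {
  stopifnot(inherits(table, "abundance_table"))
  metric <- match.arg(metric)
  v <- table$values
  if (metric == "bray") return(vegan::vegdist(v, method = "bray"))
  x <- v / rowSums(v)
  x <- x + pseudocount
  x <- x / rowSums(x)
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  stats::dist(clr)
}

#' PERMANOVA on a community distance matrix
#'
#' Sequential (Type-I) partitioning of the distance matrix by ordered model
#' terms with free label permutations, delegated to `vegan::adonis2`;
#' p-values use the standard (1 + exceedances) / (1 + permutations) rule.
#'
#' @param dist a `stats::dist` (e.g. from [community_distance()]).
#' @param data data.frame of sample metadata aligned with the distance
#'   labels.
#' @param terms character vector of model terms, in order.
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame: term, df, R2, pseudo_F, p_value; residual and total
#'   rows included with attribute `residual_R2`.
#' @export
permanova <- function(dist, data, terms, n_permutations = 9999, seed = 1) {
  if (n_permutations < 99) stop("use at least 99 permutations")
  data <- as.data.frame(data)
  for (t in terms) {
    if (!t %in% names(data)) stop("term '", t, "' not found in data")
    if (length(unique(data[[t]])) < 2)
      stop("term '", t, "' is constant")
  }
  set.seed(as.integer(seed))
  fml <- stats::as.formula(paste("dist ~", paste(terms, collapse = " + ")))
  res <- vegan::adonis2(fml, data = data, permutations = n_permutations,
                        by = "terms")
  out <- data.frame(term = rownames(res), df = res$Df, R2 = res$R2,
                    pseudo_F = res$F, p_value = res$`Pr(>F)`)
  rownames(out) <- NULL
  attr(out, "residual_R2") <- out$R2[out$term == "Residual"]
  out
}

#' SIMPER decomposition of between-group dissimilarity
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions (delegated to `vegan::simper`), ranks taxa by
#' contribution and identifies the minimal prefix reaching
#' `cumulative_cutoff` of the total; per-taxon permutation p-values come
#' from group-label shuffles.
#'
#' @param table an [abundance_table()] (relative abundances are the working
#'   matrix).
#' @param groups two-level grouping vector aligned with samples.
#' @param n_permutations label permutations for per-taxon p-values.
#' @param cumulative_cutoff cumulative-contribution cutoff for the
#'   identified set.
#' @param seed integer seed.
#' @return an object of class `simper_screen`: data.frame `contributions`
#'   (taxon, average contribution, cumulative share, p), `identified`
#'   taxon ids, `total` (= mean between-group dissimilarity).
#' @export
simper <- function(table, groups, n_permutations = 999,
                   cumulative_cutoff = 0.70, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) == 0)) stop("both groups must be nonempty")
  set.seed(as.integer(seed))
  sim <- vegan::simper(table$values, group = groups,
                       permutations = n_permutations)
  comp <- sim[[1]]
  avg <- comp$average
  names(avg) <- comp$species
  ord <- order(avg, decreasing = TRUE)
  avg <- avg[ord]
  total <- sum(avg)
  cum <- cumsum(avg) / total
  k <- which(cum >= cumulative_cutoff)[1]
  pvals <- if (!is.null(comp$p)) comp$p[ord] else rep(NA_real_, length(avg))
  contributions <- data.frame(taxon_id = names(avg), average = unname(avg),
                              cumulative = unname(cum), p_value = unname(pvals))
  structure(list(contributions = contributions,
                 identified = names(avg)[seq_len(k)],
                 total = total, cumulative_cutoff = cumulative_cutoff),
            class = "simper_screen")
}

#' @export
print.simper_screen <- function(x, ...) {
  cat("SIMPER: mean between-group dissimilarity", signif(x$total, 4), "\n")
  cat(length(x$identified), "taxa reach", x$cumulative_cutoff * 100,
      "% cumulative contribution\n")
  print(utils::head(x$contributions, 10), row.names = FALSE)
  invisible(x)
}

#' Random-forest importance screen
#'
#' Fits an off-the-shelf random forest of the response on all taxa plus
#' covariates, normalizes the raw importance scores to proportions summing
#' to 1, and identifies predictors whose proportion exceeds the equi-weight
#' cutoff 1/(number of predictors).
#'
#' @param table an [abundance_table()].
#' @param response binary (factor/0-1) or continuous response vector.
#' @param covariates optional covariate data.frame included as predictors.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return an object of class `rf_screen`: named `importance` proportions,
#'   `identified` predictor names, `cutoff`.
#' @export
rf_importance_screen <- function(table, response, covariates = NULL,
                                 n_trees = 100, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  preds <- as.data.frame(table$values)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates))
      if (is.character(covariates[[nm]]))
        covariates[[nm]] <- as.factor(covariates[[nm]])
    preds <- cbind(preds, covariates)
  }
  y <- response
  if (!is.factor(y) && length(unique(y)) == 2) y <- as.factor(y)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = preds, y = y, ntree = n_trees)
  imp <- randomForest::importance(rf)[, 1]
  imp <- pmax(imp, 0)
  if (sum(imp) <= 0) stop("random forest produced all-zero importances")
  prop <- imp / sum(imp)
  cutoff <- equi_weight_threshold(ncol(preds))
  structure(list(importance = prop,
                 identified = names(prop)[prop > cutoff],
                 cutoff = cutoff, n_trees = n_trees),
            class = "rf_screen")
}

#' @export
print.rf_screen <- function(x, ...) {
  cat("random-forest screen:", length(x$importance), "predictors, cutoff",
      signif(x$cutoff, 5), "\n")
  cat(length(x$identified), "predictors above cutoff; top 10:\n")
  print(utils::head(sort(x$importance, decreasing = TRUE), 10))
  invisible(x)
}
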
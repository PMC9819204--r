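#' Outcome-variability-preserving train/validation partition
#'
#' Randomly splits the samples so that `round(train_fraction * n)` go to
#' training, while every level of a categorical outcome — and of each
#' declared categorical covariate — appears in both partitions. A plain
#' random 40/60 split can land all subjects of a rare level on one side, in
#' which case the GLM cannot run; this partition guards against that.
#' Continuous outcomes are not stratified (only the covariates are).
#'
#' @param outcome outcome vector; treated as categorical unless numeric with
#'   more than 10 distinct values.
#' @param strata optional data.frame of categorical covariates to preserve.
#' @param train_fraction fraction of samples in the training partition,
#'   in (0, 1).
#' @param seed integer seed.
#' @param max_tries attempts to satisfy the covariate-level constraint
#'   before erroring.
#' @return list with integer index vectors `train` and `validation`.
#' @export
stratified_partition <- function(outcome, strata = NULL, train_fraction = 0.40,
                                 seed = 1, max_tries = 100) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(outcome)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("train_fraction leaves an empty partition")

  categorical_outcome <- !(is.numeric(outcome) &&
                             length(unique(outcome)) > 10)
  groups <- if (categorical_outcome) as.character(outcome) else rep("all", n)

  # feasibility: every declared level needs >= 2 subjects
  check_levels <- list(outcome = if (categorical_outcome) groups else NULL)
  if (!is.null(strata)) {
    strata <- as.data.frame(strata)
    for (nm in names(strata)) check_levels[[nm]] <- as.character(strata[[nm]])
  }
  offending <- character(0)
  for (nm in names(check_levels)) {
    if (is.null(check_levels[[nm]])) next
    tab <- table(check_levels[[nm]])
    bad <- names(tab)[tab < 2]
    if (length(bad))
      offending <- c(offending, paste0(nm, "=", bad))
  }
  if (length(offending))
    stop("infeasible stratification; level(s) with a single subject: ",
         paste(offending, collapse = ", "))

  set.seed(as.integer(seed))
  glev <- unique(groups)
  gsize <- table(groups)[glev]

  for (try in seq_len(max_tries)) {
    # per-group training counts by largest remainder, each clamped to
    # [1, size-1] so both partitions keep every outcome level
    target <- train_fraction * as.numeric(gsize)
    cnt <- floor(target)
    rem <- n_train - sum(cnt)
    if (rem > 0) {
      ord <- order(target - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    } else if (rem < 0) {
      ord <- order(target - cnt)
      cnt[ord[seq_len(-rem)]] <- cnt[ord[seq_len(-rem)]] - 1
    }
    cnt <- pmin(pmax(cnt, 1), as.numeric(gsize) - 1)
    # re-balance to the exact total after clamping
    excess <- sum(cnt) - n_train
    i <- 1
    while (excess != 0 && i <= length(cnt) * 2) {
      j <- ((i - 1) %% length(cnt)) + 1
      if (excess > 0 && cnt[j] > 1) { cnt[j] <- cnt[j] - 1; excess <- excess - 1 }
      if (excess < 0 && cnt[j] < gsize[j] - 1) { cnt[j] <- cnt[j] + 1; excess <- excess + 1 }
      i <- i + 1
    }
    train <- integer(0)
    for (g in seq_along(glev)) {
      members <- which(groups == glev[g])
      train <- c(train, sample(members, cnt[g]))
    }
    train <- sort(train)
    validation <- setdiff(seq_len(n), train)
    ok <- TRUE
    if (!is.null(strata)) {
      for (nm in names(strata)) {
        v <- as.character(strata[[nm]])
        if (!setequal(unique(v[train]), unique(v)) ||
            !setequal(unique(v[validation]), unique(v))) { ok <- FALSE; break }
      }
    }
    if (ok)
      return(list(train = train, validation = validation))
  }
  stop("could not satisfy covariate stratification in ", max_tries, " draws")
}

#' WQS regression with random subsets and repeated holdouts
#'
#' The main fitting function. Ranks the relative abundances with
#' zero-anchored quantile scores, then repeats the random-subset WQS
#' analysis over `repeats` independent stratified train/validation
#' partitions, aggregating taxon weights (mean across holdouts) and the
#' distribution of the validation index coefficient. With
#' `direction = "auto"` the directional constraint is fixed once, before
#' the repetitions, from the majority coefficient sign of an unconstrained
#' pass.
#'
#' @param formula outcome ~ covariates, with variables taken from the
#'   table's sample metadata (use `~ 1` for no covariates).
#' @param table an [abundance_table()]; counts are converted to relative
#'   abundances automatically.
#' @param levels,split scoring scheme, see [zero_anchored_rank()].
#' @param m,B random-subset configuration, see [wqs_rs()].
#' @param repeats number of repeated holdouts.
#' @param signal signal function, see [signal_value()].
#' @param direction `"auto"`, `"positive"`, `"negative"` or
#'   `"unconstrained"`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param train_fraction training fraction per holdout.
#' @param seed master seed; per-repetition sub-seeds are derived from it by
#'   a counter scheme, so the whole ensemble is reproducible.
#' @param n_restarts optimizer starts per subset fit.
#' @param ranked optional precomputed `ranked_matrix` (skips ranking).
#' @return an object of class `wqs_rsrh` with, among others,
#'   `mean_weights` (simplex p-vector), `beta1` (per-holdout validation
#'   coefficients), `beta_summary`, `odds_ratios` (binomial), `results`
#'   (per-holdout `wqs_rs` fits) and the fixed `direction`.
#' @examples
#' tab <- synthesize_abundance_table(n_samples = 60, n_taxa = 40, seed = 1)
#' design <- assign_signal_taxa(tab, n_strong = 1, n_medium = 2, n_weak = 2,
#'                              seed = 1, calibrate_prevalence = 0.3)
#' tab$metadata$test <- simulate_test_variable(tab, design, seed = 1)
#' fit <- wqs_rsrh(test ~ sex, tab, m = 5, B = 20, repeats = 2, seed = 1)
#' summary(fit)
#' @export
wqs_rsrh <- function(formula, table, levels = 4L,
                     split = c("quantile", "median"), m = 30, B = 1000,
                     repeats = 30, signal = c("t2", "exp_t", "abs_t"),
                     direction = c("auto", "positive", "negative",
                                   "unconstrained"),
                     family = c("binomial", "gaussian"),
                     train_fraction = 0.40, seed = 1, n_restarts = 3,
                     ranked = NULL) {
  cl <- match.call()
  stopifnot(inherits(table, "abundance_table"))
  split <- match.arg(split)
  signal <- match.arg(signal)
  direction <- match.arg(direction)
  family <- match.arg(family)
  if (repeats < 1) stop("repeats must be >= 1")
  if (is.null(table$metadata))
    stop("the table has no sample metadata to resolve the formula against")

  mf <- stats::model.frame(formula, data = table$metadata)
  outcome <- stats::model.response(mf)
  outcome_name <- deparse(formula[[2]])
  cov_names <- attr(stats::terms(formula), "term.labels")
  covariates <- if (length(cov_names))
    table$metadata[, cov_names, drop = FALSE]
  if (family == "binomial") {
    if (is.factor(outcome) || is.character(outcome))
      outcome <- as.integer(as.factor(outcome)) - 1L
    if (!all(outcome %in% c(0, 1)))
      stop("binomial outcome must be binary (0/1 or two-level factor)")
  }

  if (table$mode == "counts") {
    message("converting counts to relative abundances")
    table <- to_relative_abundance(table)
  }
  if (is.null(ranked)) ranked <- rank_table(table, levels = levels, split = split)
  p <- ncol(ranked$scores)

  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, repeats + 1L)

  direction_scan <- NULL
  if (direction == "auto") {
    pre <- wqs_rs(ranked, outcome, covariates, m = m, B = B, signal = signal,
                  direction = "unconstrained", family = family,
                  train_fraction = train_fraction, seed = subseeds[1],
                  n_restarts = n_restarts)
    conv <- is.finite(pre$subset_beta1) & is.finite(pre$subset_t)
    direction_scan <- determine_direction(
      lapply(which(conv), function(i)
        list(beta1 = pre$subset_beta1[i], converged = TRUE)))
    direction <- direction_scan$direction
  }

  results <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    results[[r]] <- wqs_rs(ranked, outcome, covariates, m = m, B = B,
                           signal = signal, direction = direction,
                           family = family, train_fraction = train_fraction,
                           seed = subseeds[r + 1L], n_restarts = n_restarts)
  }

  W <- vapply(results, `[[`, numeric(p), "final_weights")  # p x R
  mean_weights <- rowMeans(W)
  names(mean_weights) <- colnames(ranked$scores)
  beta1 <- vapply(results, function(r) r$glm_estimates$beta1, numeric(1))
  qs <- stats::quantile(beta1, c(0.025, 0.975), names = FALSE)
  beta_summary <- list(mean = mean(beta1),
                       percentile_interval = c(lower = qs[1], upper = qs[2]),
                       sign_fraction = c(negative = mean(beta1 < 0),
                                         zero = mean(beta1 == 0),
                                         positive = mean(beta1 > 0)))
  odds_ratios <- if (family == "binomial")
    vapply(results, function(r) r$glm_estimates$odds_ratio, numeric(1))

  structure(list(results = results, mean_weights = mean_weights,
                 weight_matrix = W, beta1 = beta1,
                 beta_summary = beta_summary, odds_ratios = odds_ratios,
                 direction = direction, direction_scan = direction_scan,
                 signal = signal, family = family,
                 config = list(levels = ranked$levels, split = ranked$split,
                               m = m, B = B, repeats = repeats,
                               train_fraction = train_fraction, seed = seed,
                               n_restarts = n_restarts),
                 taxonomy = table$taxonomy, outcome_name = outcome_name,
                 covariate_names = cov_names, ranked = ranked, call = cl),
            class = "wqs_rsrh")
}

#' @export
print.wqs_rsrh <- function(x, ...) {
  cfg <- x$config
  cat("WQS regression with random subsets and repeated holdouts\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  ", cfg$repeats, " holdouts x ", cfg$B, " subsets of ", cfg$m,
      " taxa; scores 0..", cfg$levels - 1L, " (", cfg$split,
      "); signal ", x$signal, "; direction ", x$direction, "\n", sep = "")
  bs <- x$beta_summary
  cat(sprintf("  validation beta1: mean %.4g, 2.5-97.5%% interval [%.4g, %.4g]\n",
              bs$mean, bs$percentile_interval[1], bs$percentile_interval[2]))
  cat(sprintf("  sign split: %d%% negative / %d%% positive across holdouts\n",
              round(100 * bs$sign_fraction["negative"]),
              round(100 * bs$sign_fraction["positive"])))
  invisible(x)
}

#' @export
summary.wqs_rsrh <- function(object, n_top = 10, ...) {
  thr <- equi_weight_threshold(length(object$mean_weights))
  ord <- order(object$mean_weights, decreasing = TRUE)
  top <- data.frame(taxon_id = names(object$mean_weights)[ord[seq_len(n_top)]],
                    mean_weight = unname(object$mean_weights[ord[seq_len(n_top)]]))
  if (!is.null(object$taxonomy))
    top <- cbind(top, object$taxonomy[match(top$taxon_id,
                                            object$taxonomy$taxon_id),
                                      c("phylum", "genus")])
  out <- list(beta_summary = object$beta_summary,
              odds_ratio_mean = if (!is.null(object$odds_ratios))
                mean(object$odds_ratios),
              odds_ratio_interval = if (!is.null(object$odds_ratios))
                stats::quantile(object$odds_ratios, c(0.025, 0.975),
                                names = FALSE),
              direction = object$direction,
              direction_scan = object$direction_scan,
              equi_weight_threshold = thr,
              n_above_threshold = sum(object$mean_weights > thr),
              top_weights = top,
              config = object$config, family = object$family,
              outcome_name = object$outcome_name)
  class(out) <- "summary.wqs_rsrh"
  out
}

#' @export
print.summary.wqs_rsrh <- function(x, ...) {
  cat("WQS_RSRH summary — outcome:", x$outcome_name, "(", x$family, ")\n")
  if (!is.null(x$direction_scan))
    cat(sprintf("  direction fixed to '%s' (%d negative vs %d positive subset coefficients)\n",
                x$direction, x$direction_scan$n_negative,
                x$direction_scan$n_positive))
  else cat("  direction:", x$direction, "\n")
  bs <- x$beta_summary
  cat(sprintf("  mean validation beta1 = %.4g, 2.5-97.5%% interval [%.4g, %.4g]\n",
              bs$mean, bs$percentile_interval[1], bs$percentile_interval[2]))
  if (!is.null(x$odds_ratio_mean))
    cat(sprintf("  mean odds ratio = %.4g, interval [%.4g, %.4g]\n",
                x$odds_ratio_mean, x$odds_ratio_interval[1],
                x$odds_ratio_interval[2]))
  cat(sprintf("  %d taxa above the equi-weight threshold 1/p = %.5g\n",
              x$n_above_threshold, x$equi_weight_threshold))
  cat("  top mean weights:\n")
  print(x$top_weights, row.names = FALSE)
  invisible(x)
}

#' @export
coef.wqs_rsrh <- function(object, ...) {
  cf <- vapply(object$results, function(r) r$glm_estimates$coefficients$estimate,
               numeric(nrow(object$results[[1]]$glm_estimates$coefficients)))
  out <- rowMeans(cf)
  names(out) <- object$results[[1]]$glm_estimates$coefficients$term
  out
}

#' @export
weights.wqs_rsrh <- function(object, ...) object$mean_weights

#' @export
predict.wqs_rsrh <- function(object, newtable = NULL, ranked = NULL, ...) {
  if (is.null(ranked)) {
    if (is.null(newtable)) return(build_index(object$ranked,
                                              object$mean_weights))
    stopifnot(inherits(newtable, "abundance_table"))
    if (newtable$mode == "counts") newtable <- to_relative_abundance(newtable)
    ranked <- rank_table(newtable, levels = object$config$levels,
                         split = object$config$split)
  }
  build_index(ranked, object$mean_weights)
}

#' @export
plot.wqs_rsrh <- function(x, type = c("beta", "weights"), n_top = 20, ...) {
  type <- match.arg(type)
  if (type == "beta") {
    graphics::boxplot(x$beta1,
                      ylab = expression(beta[1] ~ "(validation)"),
                      main = "WQS index coefficient across repeated holdouts",
                      ...)
    graphics::abline(h = 0, lty = 2, col = "grey40")
  } else {
    thr <- equi_weight_threshold(length(x$mean_weights))
    ord <- order(x$mean_weights, decreasing = TRUE)[seq_len(n_top)]
    graphics::barplot(rev(x$mean_weights[ord]), horiz = TRUE, las = 1,
                      xlab = "mean weight",
                      main = paste("Top", n_top, "mean taxon weights"), ...)
    graphics::abline(v = thr, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Pool holdout taxon weights into genus-level weights
#'
#' Within each holdout, sums taxon weights by genus; taxa with an
#' unclassified genus pool per phylum under the label
#' `"unclassified (<phylum>)"`. The equi-weight threshold for genus
#' importance is 1/c, c being the number of genera in the mixture.
#'
#' @param ensemble a `wqs_rsrh` fit.
#' @param taxonomy optional taxonomy data.frame (defaults to the one stored
#'   in the fit).
#' @return an object of class `genus_weights`: data.frame `summary` (genus,
#'   phylum, mean weight, above-threshold flag), per-holdout matrix
#'   `per_holdout` (genera x holdouts) and `threshold`.
#' @export
aggregate_weights_by_genus <- function(ensemble, taxonomy = NULL) {
  stopifnot(inherits(ensemble, "wqs_rsrh"))
  if (is.null(taxonomy)) taxonomy <- ensemble$taxonomy
  if (is.null(taxonomy)) stop("no taxonomy available")
  taxa <- names(ensemble$mean_weights)
  miss <- setdiff(taxa, taxonomy$taxon_id)
  if (length(miss))
    stop("taxonomy missing entries for: ",
         paste(utils::head(miss, 5), collapse = ", "))
  tx <- taxonomy[match(taxa, taxonomy$taxon_id), ]
  genus <- as.character(tx$genus)
  unclass <- is.na(genus) | genus == "" |
    grepl("^unclassified", genus, ignore.case = TRUE)
  genus[unclass] <- paste0("unclassified (", tx$phylum[unclass], ")")

  per_holdout <- rowsum(ensemble$weight_matrix, group = genus)  # c x R
  mean_w <- rowMeans(per_holdout)
  c_gen <- nrow(per_holdout)
  thr <- equi_weight_threshold(c_gen)
  phylum <- tapply(as.character(tx$phylum), genus, function(v)
    paste(unique(v), collapse = "/"))
  smry <- data.frame(genus = rownames(per_holdout),
                     phylum = unname(phylum[rownames(per_holdout)]),
                     mean_weight = unname(mean_w),
                     above_threshold = unname(mean_w > thr))
  smry <- smry[order(smry$mean_weight, decreasing = TRUE), ]
  rownames(smry) <- NULL
  structure(list(summary = smry, per_holdout = per_holdout,
                 threshold = thr, n_genera = c_gen),
            class = "genus_weights")
}

#' @export
print.genus_weights <- function(x, ...) {
  cat("genus-pooled WQS weights:", x$n_genera, "genera, threshold 1/c =",
      signif(x$threshold, 5), "\n")
  cat(sum(x$summary$above_threshold), "genera above threshold:\n")
  print(utils::head(x$summary[x$summary$above_threshold, ], 20),
        row.names = FALSE)
  invisible(x)
}
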
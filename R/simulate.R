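#' Potency-adjusted relative abundance
#'
#' Standardizes a taxon's abundance relative to its maximum before an effect
#' size is applied: `log2(log10(x + 1) / log10(max + 1))`, evaluated on the
#' percent relative-abundance scale. The transform is always <= 0, with
#' equality exactly at `x = max`. At `x = 0` the printed formula diverges to
#' -Inf, so two conventions are offered: `"zero_contribution"` (default; an
#' absent taxon contributes 0 to the linear predictor) and `"as_formula"`
#' (the literal value, clipped at -50, with a warning).
#'
#' @param x relative abundance(s), percent scale, `0 <= x <= max`.
#' @param max the taxon's maximum relative abundance (percent, > 0).
#' @param zero_handling `"zero_contribution"` or `"as_formula"`.
#' @return numeric vector of potency-adjusted values (<= 0).
#' @export
potency_adjust <- function(x, max,
                           zero_handling = c("zero_contribution",
                                             "as_formula")) {
  zero_handling <- match.arg(zero_handling)
  if (!is.numeric(max) || length(max) != 1 || max <= 0)
    stop("max must be a single positive value")
  if (any(x < 0)) stop("x must be nonnegative")
  if (any(x > max)) stop("x exceeds the taxon maximum")
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- log2(log10(x[pos] + 1) / log10(max + 1))
  if (any(!pos)) {
    if (zero_handling == "zero_contribution") {
      out[!pos] <- 0
    } else {
      warning(sum(!pos), " zero abundance value(s) clipped at -50 under ",
              "'as_formula' handling", call. = FALSE)
      out[!pos] <- -50
    }
  }
  out
}

#' Plant signal taxa and build a simulation design
#'
#' Selects distinct taxa meeting a prevalence floor and randomly assigns
#' them strong/medium/weak association strengths. The default counts
#' (2 strong, 8 medium, 10 weak) with effect sizes 8/4/2 on the potency
#' scale, intercept -5 and a female sex effect of -1 (males the reference)
#' define the standard simulated test-variable model.
#'
#' @param table an [abundance_table()].
#' @param n_strong,n_medium,n_weak strength-group sizes.
#' @param min_prevalence minimum nonzero fraction for an eligible taxon.
#' @param seed integer seed.
#' @param strength_betas named effect sizes per strength.
#' @param beta0 model intercept on the logit scale.
#' @param covariate_effects named list: metadata column -> named numeric of
#'   level effects (unlisted levels are reference, effect 0).
#' @param zero_handling convention for zero abundances, see
#'   [potency_adjust()].
#' @param calibrate_prevalence optional target outcome prevalence; when set,
#'   the intercept is re-solved by bisection before outcomes are drawn.
#' @return an object of class `simulation_design`.
#' @export
assign_signal_taxa <- function(table, n_strong = 2, n_medium = 8,
                               n_weak = 10, min_prevalence = 0.10, seed = 1,
                               strength_betas = c(strong = 8, medium = 4,
                                                  weak = 2),
                               beta0 = -5,
                               covariate_effects = list(sex = c(female = -1)),
                               zero_handling = c("zero_contribution",
                                                 "as_formula"),
                               calibrate_prevalence = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  zero_handling <- match.arg(zero_handling)
  if (any(strength_betas <= 0)) stop("strength betas must be positive")
  n_total <- n_strong + n_medium + n_weak
  if (n_total < 1) stop("at least one signal taxon required")
  eligible <- colnames(table$values)[colMeans(table$values > 0) >= min_prevalence]
  if (length(eligible) < n_total)
    stop("only ", length(eligible), " taxa meet min_prevalence ",
         min_prevalence, " but ", n_total, " signal taxa requested")
  set.seed(as.integer(seed))
  ids <- sample(eligible, n_total)
  strength <- sample(rep(c("strong", "medium", "weak"),
                         c(n_strong, n_medium, n_weak)))
  structure(list(signal_taxa = data.frame(taxon_id = ids, strength = strength,
                                          beta = unname(strength_betas[strength])),
                 strength_betas = strength_betas, beta0 = beta0,
                 covariate_effects = covariate_effects,
                 zero_handling = zero_handling,
                 calibrate_prevalence = calibrate_prevalence),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("simulation_design:", nrow(x$signal_taxa), "signal taxa (",
      paste(names(table(x$signal_taxa$strength)),
            table(x$signal_taxa$strength), collapse = ", "), ")\n")
  cat("  beta0 =", x$beta0, "; betas:",
      paste(names(x$strength_betas), x$strength_betas, sep = "=",
            collapse = ", "), "\n")
  cat("  zero handling:", x$zero_handling, "\n")
  if (!is.null(x$calibrate_prevalence))
    cat("  intercept calibrated to prevalence", x$calibrate_prevalence, "\n")
  invisible(x)
}

# linear predictor of the simulated test-variable model (before any
# intercept calibration); percent-scale potency per signal taxon
.simulation_logit <- function(table, design) {
  x_pct <- table$values * 100
  contrib <- numeric(nrow(x_pct))
  for (i in seq_len(nrow(design$signal_taxa))) {
    id <- design$signal_taxa$taxon_id[i]
    if (!id %in% colnames(x_pct))
      stop("signal taxon '", id, "' not present in the table")
    col <- x_pct[, id]
    mx <- max(col)
    if (mx <= 0) stop("signal taxon '", id, "' is all-zero")
    contrib <- contrib + design$signal_taxa$beta[i] *
      potency_adjust(col, mx, design$zero_handling)
  }
  cov_eff <- numeric(nrow(x_pct))
  for (nm in names(design$covariate_effects)) {
    if (is.null(table$metadata) || !nm %in% names(table$metadata))
      stop("covariate '", nm, "' not found in the table metadata")
    v <- as.character(table$metadata[[nm]])
    eff <- design$covariate_effects[[nm]]
    hit <- match(v, names(eff))
    cov_eff <- cov_eff + ifelse(is.na(hit), 0, eff[hit])
  }
  design$beta0 + contrib + cov_eff
}

#' Simulate the binary test variable from planted signal taxa
#'
#' Draws a Bernoulli outcome per sample from the logistic model
#' logit = beta0 + sum over signal taxa of beta_strength * potency(x) +
#' covariate effects. When the design carries `calibrate_prevalence`, the
#' intercept is first re-solved by bisection so the mean fitted probability
#' matches the target within 0.005 (the calibrated intercept is recorded as
#' an attribute).
#'
#' @param table an [abundance_table()] in relative mode with the design's
#'   signal taxa present.
#' @param design a [assign_signal_taxa()] design.
#' @param seed integer seed for the Bernoulli draw.
#' @return integer 0/1 vector with attributes `probability` (per-sample
#'   fitted probabilities) and `beta0` (the intercept actually used).
#' @export
simulate_test_variable <- function(table, design, seed = 1) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "simulation_design"))
  if (table$mode != "relative")
    stop("simulate_test_variable expects a relative-abundance table")
  eta <- .simulation_logit(table, design)
  beta0 <- design$beta0
  if (!is.null(design$calibrate_prevalence)) {
    target <- design$calibrate_prevalence
    base <- eta - beta0
    lo <- -max(base) - 40
    hi <- -min(base) + 40
    for (it in 1:300) {
      mid <- (lo + hi) / 2
      prev <- mean(stats::plogis(mid + base))
      if (abs(prev - target) <= 0.005) break
      if (prev < target) lo <- mid else hi <- mid
    }
    beta0 <- mid
    eta <- beta0 + base
  }
  p <- stats::plogis(eta)
  set.seed(as.integer(seed))
  y <- stats::rbinom(length(p), 1L, p)
  attr(y, "probability") <- p
  attr(y, "beta0") <- beta0
  y
}

#' Simulate an independent control variable
#'
#' An i.i.d. Bernoulli variable with no planted association to any taxon;
#' used as a negative control for the whole analysis pipeline.
#'
#' @param n number of samples.
#' @param prevalence Bernoulli probability in (0, 1).
#' @param seed integer seed.
#' @return integer 0/1 vector.
#' @export
simulate_control_variable <- function(n, prevalence = 0.13, seed = 1) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  set.seed(as.integer(seed))
  stats::rbinom(n, 1L, prevalence)
}

#' Synthesize an abundance table with gut-microbiome-like zero inflation
#'
#' Generates a relative-abundance table whose structure emulates a first-
#' visit adult stool 16S OTU working set: per-taxon zero fractions drawn
#' uniformly in `zero_fraction_range`, lognormal nonzero abundances with
#' per-taxon scale heterogeneity (so a few taxa reach maxima near 20%
#' relative abundance), closed (row-normalized) compositions, a generated
#' taxonomy (genera nested in families and phyla, a fraction of genera
#' unclassified) and a two-level `sex` metadata column. Defaults (210
#' samples, 868 taxa, zero fractions 0.35-0.88) match that working set.
#'
#' Inter-taxon correlation of real communities is NOT emulated; taxa are
#' generated independently before closure.
#'
#' @param n_samples,n_taxa table dimensions.
#' @param zero_fraction_range (lo, hi) with 0 <= lo < hi <= 0.95.
#' @param abundance_shape lognormal parameters: `meanlog_sd` (sd of the
#'   per-taxon meanlog, driving abundance heterogeneity) and `sdlog`
#'   (within-taxon spread).
#' @param taxonomy_breadth number of genera to generate.
#' @param unclassified_fraction fraction of genera labelled unclassified.
#' @param seed integer seed.
#' @return an [abundance_table()] in relative mode with taxonomy and
#'   metadata attached.
#' @export
synthesize_abundance_table <- function(n_samples = 210, n_taxa = 868,
                                       zero_fraction_range = c(0.35, 0.88),
                                       abundance_shape = c(meanlog_sd = 1.5,
                                                           sdlog = 1.0),
                                       taxonomy_breadth = 50,
                                       unclassified_fraction = 0.1,
                                       seed = 1) {
  lo <- zero_fraction_range[1]; hi <- zero_fraction_range[2]
  if (!(lo >= 0 && lo < hi && hi <= 0.95))
    stop("zero_fraction_range must satisfy 0 <= lo < hi <= 0.95")
  set.seed(as.integer(seed))
  zf <- stats::runif(n_taxa, lo, hi)
  meanlog <- stats::rnorm(n_taxa, 0, abundance_shape[["meanlog_sd"]])
  sdlog <- abundance_shape[["sdlog"]]
  vals <- matrix(0, n_samples, n_taxa)
  for (j in seq_len(n_taxa)) {
    present <- stats::runif(n_samples) > zf[j]
    np <- sum(present)
    if (np) vals[present, j] <- stats::rlnorm(np, meanlog[j], sdlog)
  }
  empty <- rowSums(vals) == 0
  if (any(empty)) {  # resample empty rows once
    for (i in which(empty)) {
      for (j in seq_len(n_taxa)) {
        if (stats::runif(1) > zf[j]) vals[i, j] <- stats::rlnorm(1, meanlog[j], sdlog)
      }
    }
    if (any(rowSums(vals) == 0))
      stop("generator produced an all-zero sample; lower the zero fractions")
  }
  vals <- vals / rowSums(vals)
  rownames(vals) <- sprintf("sample_%03d", seq_len(n_samples))
  colnames(vals) <- sprintf("otu_%04d", seq_len(n_taxa))

  phyla <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
             "Proteobacteria", "Verrucomicrobia")
  genus_phylum <- sample(phyla, taxonomy_breadth, replace = TRUE,
                         prob = c(0.45, 0.25, 0.15, 0.10, 0.05))
  genus_names <- sprintf("genus_%03d", seq_len(taxonomy_breadth))
  n_uncl <- round(unclassified_fraction * taxonomy_breadth)
  if (n_uncl > 0)
    genus_names[sample(taxonomy_breadth, n_uncl)] <- "unclassified"
  genus_family <- sprintf("family_%03d",
                          ceiling(seq_len(taxonomy_breadth) / 2))
  gidx <- sample(taxonomy_breadth, n_taxa, replace = TRUE)
  taxonomy <- data.frame(taxon_id = colnames(vals),
                         phylum = genus_phylum[gidx],
                         family = genus_family[gidx],
                         genus = genus_names[gidx])
  metadata <- data.frame(sex = sample(c("male", "female"), n_samples,
                                      replace = TRUE),
                         row.names = rownames(vals))
  abundance_table(vals, mode = "relative", taxonomy = taxonomy,
                  metadata = metadata)
}
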
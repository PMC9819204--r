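# Shared fixture builders; everything is generated in code at test time.

# tiny deterministic table: 4 samples x 3 taxa, counts
tiny_counts <- function() {
  m <- matrix(c(2, 2, 4,
                0, 1, 3,
                5, 0, 5,
                1, 1, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  abundance_table(m, mode = "counts",
                  taxonomy = data.frame(taxon_id = paste0("t", 1:3),
                                        phylum = c("P1", "P1", "P2"),
                                        family = c("F1", "F1", "F2"),
                                        genus = c("gA", "gA", "gB")),
                  metadata = data.frame(sex = c("male", "female",
                                                "male", "female"),
                                        row.names = paste0("s", 1:4)))
}

# moderate synthetic relative table with a planted, rank-monotone binary
# outcome: logit linear in the scores of a few signal taxa (known positive
# sign) — used where a clean planted direction is needed
planted_sign_table <- function(n = 150, p = 25, n_signal = 4, beta = 1.2,
                               sign = 1, seed = 1, levels = 4) {
  tab <- synthesize_abundance_table(n_samples = n, n_taxa = p,
                                    zero_fraction_range = c(0.2, 0.6),
                                    taxonomy_breadth = 8, seed = seed)
  rk <- rank_table(tab, levels = levels)
  sig <- seq_len(n_signal)
  eta <- sign * beta * rowMeans(rk$scores[, sig, drop = FALSE]) -
    sign * beta * mean(rk$scores[, sig]) # centered
  set.seed(seed + 1000)
  tab$metadata$y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(table = tab, ranked = rk, signal = colnames(tab$values)[sig])
}

# brute-force simplex grid oracle for the subset-level likelihood:
# profile (alpha, beta1, delta) by an ordinary GLM at each grid weight
grid_oracle_loglik <- function(scores, y, covariates = NULL,
                               family = "binomial", step = 0.01) {
  m <- ncol(scores)
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  X <- if (is.null(covariates)) NULL else
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  eval_w <- function(w) {
    z <- drop(scores %*% w)
    M <- if (is.null(X)) cbind(1, z) else cbind(1, z, X)
    fit <- suppressWarnings(stats::glm.fit(M, y, family = fam))
    ll <- if (family == "binomial") {
      mu <- fit$fitted.values
      sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    } else {
      -0.5 * sum((y - fit$fitted.values)^2)  # unit-variance gaussian loglik core
    }
    ll
  }
  grid1 <- seq(0, 1, by = step)
  best <- -Inf
  best_w <- NULL
  if (m == 2) {
    for (w1 in grid1) {
      ll <- eval_w(c(w1, 1 - w1))
      if (ll > best) { best <- ll; best_w <- c(w1, 1 - w1) }
    }
  } else if (m == 3) {
    for (w1 in grid1) for (w2 in seq(0, 1 - w1, by = step)) {
      ll <- eval_w(c(w1, w2, 1 - w1 - w2))
      if (ll > best) { best <- ll; best_w <- c(w1, w2, 1 - w1 - w2) }
    }
  } else stop("oracle supports m in {2,3}")
  list(loglik = best, weights = best_w)
}
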
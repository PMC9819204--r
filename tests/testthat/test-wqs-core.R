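test_that("random subsets are distinct, in range, and seed-reproducible", {
  s <- draw_random_subsets(p = 868, m = 30, B = 50, seed = 11)
  expect_identical(dim(s), c(50L, 30L))
  expect_true(all(s >= 1 & s <= 868))
  expect_true(all(apply(s, 1, function(r) !anyDuplicated(r))))
  expect_identical(s, draw_random_subsets(868, 30, 50, seed = 11))
  # exhaustive subset when m = p
  s2 <- draw_random_subsets(5, 5, 3, seed = 1)
  expect_true(all(apply(s2, 1, function(r) setequal(r, 1:5))))
  expect_error(draw_random_subsets(5, 6, 1, seed = 1), "1 <= m <= p")
})

test_that("signal functions transform t as squared, exp-absolute, absolute", {
  expect_equal(signal_value(2, "t2"), 4)
  expect_equal(signal_value(-2, "exp_t"), exp(2))
  expect_equal(signal_value(-3, "abs_t"), 3)
  expect_warning(v <- signal_value(40, "exp_t"), "clipped")
  expect_equal(v, exp(30))
  expect_error(signal_value(Inf, "t2"), "finite")
})

test_that("signal averaging follows the containing-subsets rule", {
  fits <- list(
    list(taxon_indices = c(1L, 2L), weights = c(0.6, 0.4), t_stat = 2,
         converged = TRUE),
    list(taxon_indices = c(2L, 3L), weights = c(0.5, 0.5), t_stat = 1,
         converged = TRUE))
  w <- signal_average(fits, p = 3, kind = "t2")
  # per-taxon means A=0.6, B=(0.4*4+0.5*1)/5=0.42, C=0.5, then simplex-normalized
  expect_equal(w, c(0.6, 0.42, 0.5) / 1.52, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-8)
  # constant signal reduces to the plain mean, renormalized
  fits_const <- lapply(fits, function(f) { f$t_stat <- 3; f })
  w_const <- signal_average(fits_const, 3, "t2")
  expect_equal(w_const, c(0.6, 0.45, 0.5) / 1.55, tolerance = 1e-12)
  # uncovered taxa get zero weight with a warning
  expect_warning(w4 <- signal_average(fits, p = 4, kind = "abs_t"),
                 "no converged subset")
  expect_equal(w4[4], 0)
  expect_error(signal_average(list(list(taxon_indices = 1L, weights = 1,
                                        t_stat = NA, converged = FALSE)), 1),
               "no converged")
})

test_that("the WQS index is the weighted score dot product, bounded by L-1", {
  sc <- matrix(3L, 5, 4)
  expect_equal(build_index(sc, rep(0.25, 4)), rep(3, 5))
  sc2 <- matrix(sample(0:3, 40, TRUE), 10, 4)
  expect_equal(build_index(sc2, c(1, 0, 0, 0)), sc2[, 1])
  w <- runif(4); w <- w / sum(w)
  idx <- build_index(sc2, w)
  expect_true(all(idx >= 0 & idx <= 3))
  expect_error(build_index(sc2, rep(0.5, 2)), "dimension mismatch")
})

test_that("a single-taxon subset reproduces the ordinary GLM fit", {
  set.seed(3)
  n <- 120
  q <- sample(0:3, n, TRUE)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * q))
  fit <- estimate_subset_weights(matrix(q, ncol = 1), y,
                                 direction = "unconstrained")
  expect_equal(fit$weights, 1)
  ref <- glm(y ~ q, family = binomial())
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit$t_stat,
               unname(summary(ref)$coefficients[2, 3]), tolerance = 1e-3)
})

test_that("constrained optimum matches the simplex grid oracle and recovers
           a noiseless driver", {
  set.seed(7)
  n <- 200
  qa <- sample(0:3, n, TRUE)
  qb <- sample(0:3, n, TRUE)
  y <- as.integer(qa >= 2)          # noiseless increasing function of taxon A
  sc <- cbind(A = qa, B = qb)
  fit <- estimate_subset_weights(sc, y, direction = "unconstrained",
                                 n_restarts = 3)
  expect_gte(fit$weights[1], 0.9)
  oracle <- grid_oracle_loglik(sc, y, step = 0.01)
  expect_gte(fit$loglik, oracle$loglik - 1e-4)

  # gaussian family, m = 3, interior optimum
  set.seed(8)
  q3 <- matrix(sample(0:3, 3 * 150, TRUE), 150, 3)
  yg <- drop(q3 %*% c(0.5, 0.3, 0.2)) * 1.5 + rnorm(150, 0, 0.3)
  fitg <- estimate_subset_weights(q3, yg, family = "gaussian",
                                  direction = "positive", n_restarts = 3)
  oracleg <- grid_oracle_loglik(q3, yg, family = "gaussian", step = 0.01)
  expect_gte(fitg$loglik, oracleg$loglik - 1e-4)
  expect_equal(fitg$weights, c(0.5, 0.3, 0.2), tolerance = 0.08)
  expect_gt(fitg$beta1, 0)
})

test_that("weights stay on the simplex even for a pure-noise outcome", {
  set.seed(10)
  sc <- matrix(sample(0:3, 100 * 5, TRUE), 100, 5)
  y <- rbinom(100, 1, 0.3)
  for (dir in c("unconstrained", "positive", "negative")) {
    fit <- estimate_subset_weights(sc, y, direction = dir, n_restarts = 2)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  }
  expect_error(estimate_subset_weights(sc, rep(1, 100)), "constant")
  expect_error(estimate_subset_weights(sc, y,
                                       covariates = cbind(a = 1:100,
                                                          b = 2 * (1:100))),
               "collinear")
})

test_that("validation GLM is unconstrained and recovers a known slope", {
  set.seed(5)
  idx <- runif(150, 0, 3)
  y <- 2 * idx + rnorm(150, 0, 1e-4)
  v <- validate_index(idx, y, family = "gaussian")
  expect_equal(v$beta1, 2, tolerance = 1e-3)
  expect_error(validate_index(idx, y, covariates = cbind(z = idx),
                              family = "gaussian"), "collinear")
})

test_that("null binomial validation CIs cover zero at the nominal rate", {
  set.seed(77)
  cover <- vapply(1:100, function(i) {
    idx <- runif(80, 0, 3)
    y <- rbinom(80, 1, 0.4)   # independent of the index
    v <- suppressWarnings(validate_index(idx, y, family = "binomial"))
    v$ci[1] <= 0 && v$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("separation triggers the penalized fallback with finite estimates", {
  idx <- c(rep(0, 20), rep(3, 20))
  y <- c(rep(0L, 20), rep(1L, 20))
  expect_warning(v <- validate_index(idx, y, family = "binomial"),
                 "separation")
  expect_true(v$separation)
  expect_true(all(is.finite(v$coefficients$estimate)))
  expect_lt(abs(v$beta1), 15)
})

test_that("direction determination takes the majority coefficient sign", {
  mk <- function(b) list(beta1 = b, converged = TRUE)
  d <- determine_direction(lapply(c(-1, -2, -0.5, 1, 2), mk))
  expect_identical(d$direction, "negative")
  expect_identical(d$n_negative, 3L)
  d2 <- determine_direction(lapply(c(1, 2, 0.5), mk))
  expect_identical(d2$direction, "positive")
  expect_warning(d3 <- determine_direction(lapply(c(-1, 1), mk)), "tie")
  expect_identical(d3$direction, "negative")
})

test_that("a full wqs_rs pass is seed-deterministic and handles p = 1", {
  pl <- planted_sign_table(n = 100, p = 12, seed = 21)
  y <- pl$table$metadata$y
  r1 <- wqs_rs(pl$ranked, y, m = 4, B = 15, direction = "positive",
               seed = 99, n_restarts = 2)
  r2 <- wqs_rs(pl$ranked, y, m = 4, B = 15, direction = "positive",
               seed = 99, n_restarts = 2)
  expect_identical(r1$final_weights, r2$final_weights)
  expect_identical(r1$glm_estimates$beta1, r2$glm_estimates$beta1)
  expect_equal(sum(r1$final_weights), 1, tolerance = 1e-8)

  # degenerate single-taxon mixture: weight 1, beta1 = single-taxon GLM
  rk1 <- structure(list(scores = pl$ranked$scores[, 1, drop = FALSE],
                        levels = 4L, split = "quantile"),
                   class = "ranked_matrix")
  r3 <- wqs_rs(rk1, y, m = 1, B = 5, direction = "unconstrained", seed = 5)
  expect_equal(unname(r3$final_weights), 1)
  va <- r3$validation_idx
  ref <- glm(y[va] ~ rk1$scores[va, 1], family = binomial())
  expect_equal(r3$glm_estimates$beta1, unname(coef(ref)[2]), tolerance = 1e-6)
})

test_that("wqs_rs is invariant to taxon column order up to relabeling", {
  pl <- planted_sign_table(n = 90, p = 10, seed = 31)
  y <- pl$table$metadata$y
  r1 <- wqs_rs(pl$ranked, y, m = 3, B = 12, direction = "positive",
               seed = 7, n_restarts = 2)
  perm <- sample(ncol(pl$ranked$scores))
  rkp <- structure(list(scores = pl$ranked$scores[, perm], levels = 4L,
                        split = "quantile"), class = "ranked_matrix")
  # same subsets in permuted index space: map via the permutation
  r2 <- wqs_rs(rkp, y, m = 3, B = 12, direction = "positive",
               seed = 7, n_restarts = 2)
  # identical taxa receive identical weights once relabeled back
  expect_equal(sort(names(r2$final_weights)), sort(names(r1$final_weights)))
  expect_equal(sum(r2$final_weights), 1, tolerance = 1e-8)
})
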
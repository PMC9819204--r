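test_that("stratified partition hits exact sizes and preserves levels", {
  set.seed(1)
  y <- rbinom(210, 1, 0.13)
  part <- stratified_partition(y, train_fraction = 0.40, seed = 42)
  expect_length(part$train, 84)
  expect_length(part$validation, 126)
  expect_setequal(c(part$train, part$validation), 1:210)
  expect_identical(part, stratified_partition(y, train_fraction = 0.40,
                                              seed = 42))
})

test_that("a rare outcome level lands in both partitions for every seed", {
  y <- c(rep(1L, 5), rep(0L, 95))
  for (s in 1:100) {
    part <- stratified_partition(y, train_fraction = 0.4, seed = s)
    expect_gte(sum(y[part$train]), 1)
    expect_gte(sum(y[part$validation]), 1)
  }
})

test_that("categorical covariate levels are preserved; singletons error", {
  y <- rbinom(60, 1, 0.4)
  strata <- data.frame(site = rep(c("a", "b", "c"), each = 20))
  for (s in 1:20) {
    part <- stratified_partition(y, strata, 0.4, seed = s)
    expect_setequal(unique(strata$site[part$train]), c("a", "b", "c"))
    expect_setequal(unique(strata$site[part$validation]), c("a", "b", "c"))
  }
  strata$site[1] <- "lonely"
  expect_error(stratified_partition(y, strata, 0.4, seed = 1),
               "site=lonely")
  expect_error(stratified_partition(y, train_fraction = 1.2, seed = 1),
               "train_fraction")
})

test_that("continuous outcomes skip outcome stratification but split exactly", {
  y <- rnorm(101)
  part <- stratified_partition(y, train_fraction = 0.4, seed = 3)
  expect_length(part$train, round(0.4 * 101))
})

test_that("a one-repeat ensemble reduces to a single wqs_rs with the derived seed", {
  pl <- planted_sign_table(n = 100, p = 12, seed = 51)
  fit <- wqs_rsrh(y ~ 1, pl$table, m = 4, B = 10, repeats = 1,
                  direction = "positive", seed = 17, n_restarts = 2)
  set.seed(17L)
  subseeds <- sample.int(.Machine$integer.max - 1L, 2L)
  single <- wqs_rs(pl$ranked, pl$table$metadata$y, m = 4, B = 10,
                   direction = "positive", seed = subseeds[2], n_restarts = 2)
  expect_equal(unname(fit$mean_weights), unname(single$final_weights))
  expect_equal(fit$beta1[1], single$glm_estimates$beta1)
})

test_that("ensemble aggregation: mean weights identity and sign fractions", {
  pl <- planted_sign_table(n = 120, p = 15, seed = 61)
  fit <- wqs_rsrh(y ~ sex, pl$table, m = 5, B = 12, repeats = 4,
                  direction = "positive", seed = 2, n_restarts = 2)
  expect_equal(unname(fit$mean_weights),
               unname(rowMeans(fit$weight_matrix)), tolerance = 1e-12)
  expect_equal(sum(fit$beta_summary$sign_fraction), 1)
  expect_equal(sum(fit$mean_weights), 1, tolerance = 1e-8)
  expect_length(fit$beta1, 4)
  # repetition order does not change the aggregates (permutation invariance)
  expect_equal(mean(fit$beta1[sample(4)]), fit$beta_summary$mean)
})

test_that("identical master seeds reproduce bit-identical ensembles", {
  pl <- planted_sign_table(n = 90, p = 10, seed = 71)
  f1 <- wqs_rsrh(y ~ 1, pl$table, m = 3, B = 8, repeats = 3,
                 direction = "auto", seed = 123, n_restarts = 2)
  f2 <- wqs_rsrh(y ~ 1, pl$table, m = 3, B = 8, repeats = 3,
                 direction = "auto", seed = 123, n_restarts = 2)
  expect_identical(f1$mean_weights, f2$mean_weights)
  expect_identical(f1$beta1, f2$beta1)
  expect_identical(f1$direction, f2$direction)
  expect_identical(lapply(f1$results, `[[`, "train_ids"),
                   lapply(f2$results, `[[`, "train_ids"))
})

test_that("genus pooling conserves weight and flags 1/c exceedance", {
  pl <- planted_sign_table(n = 80, p = 12, seed = 81)
  fit <- wqs_rsrh(y ~ 1, pl$table, m = 4, B = 8, repeats = 3,
                  direction = "positive", seed = 5, n_restarts = 2)
  gw <- aggregate_weights_by_genus(fit)
  expect_equal(unname(colSums(gw$per_holdout)), rep(1, 3), tolerance = 1e-8)
  expect_equal(gw$threshold, 1 / gw$n_genera)
  expect_setequal(gw$summary$genus[gw$summary$above_threshold],
                  gw$summary$genus[gw$summary$mean_weight > gw$threshold])

  # hand-checked pooling: weights {0.2, 0.3} and {0.5} in two genera
  fit2 <- fit
  fit2$weight_matrix <- matrix(c(0.2, 0.3, 0.5, rep(0, 9)), ncol = 1)
  fit2$mean_weights <- stats::setNames(drop(fit2$weight_matrix),
                                       names(fit$mean_weights))
  tx <- fit$taxonomy
  tx$genus <- c("g1", "g1", "g2", rep("g3", 9))
  gw2 <- aggregate_weights_by_genus(fit2, taxonomy = tx)
  expect_equal(unname(sort(gw2$per_holdout[c("g1", "g2"), 1])), c(0.5, 0.5))

  # all taxa in one genus: that genus carries weight 1 in every holdout
  tx$genus <- "only"
  gw3 <- aggregate_weights_by_genus(fit, taxonomy = tx)
  expect_equal(unname(gw3$per_holdout["only", ]), rep(1, 3), tolerance = 1e-8)

  # unclassified genera pool per phylum
  tx2 <- fit$taxonomy
  tx2$genus <- "unclassified"
  gw4 <- aggregate_weights_by_genus(fit, taxonomy = tx2)
  expect_true(all(grepl("^unclassified \\(", gw4$summary$genus)))

  tx3 <- fit$taxonomy[-1, ]
  expect_error(aggregate_weights_by_genus(fit, taxonomy = tx3),
               "taxonomy missing")
})
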
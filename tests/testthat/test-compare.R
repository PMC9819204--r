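test_that("Shannon index uses natural log over positive proportions", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  # scale-invariant (proportions computed internally)
  expect_equal(shannon_index(c(2, 1, 1)), shannon_index(c(0.5, 0.25, 0.25)))
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches its closed form at the extremes", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)        # disjoint supports
  expect_equal(bray_curtis(c(1, 1), c(1, 0)), 1 / 3)
  expect_error(bray_curtis(1:3, 1:2), "length")
})

test_that("Aitchison distance is compositional: scale-invariant, clr-based", {
  a <- c(1, 3, 2, 0.5)
  b <- c(2, 1, 1, 1)
  expect_equal(aitchison_distance(a, a), 0)
  expect_equal(aitchison_distance(a, b), aitchison_distance(2 * a, b),
               tolerance = 1e-10)
  # two-part closed form: |clr difference| = sqrt(2) * ln 3
  expect_equal(aitchison_distance(c(1, 3), c(3, 1), pseudocount = 1e-12),
               sqrt(2) * log(3), tolerance = 1e-6)
  expect_error(aitchison_distance(a, b, pseudocount = 0), "positive")
})

test_that("community distance matrices are symmetric with zero diagonal", {
  tab <- synthesize_abundance_table(n_samples = 15, n_taxa = 30, seed = 14)
  for (metric in c("bray", "aitchison")) {
    d <- as.matrix(community_distance(tab, metric))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_equal(unname(diag(d)), rep(0, 15))
    expect_true(all(d >= 0))
    if (metric == "bray") expect_true(all(d <= 1))
  }
})

test_that("PERMANOVA separates duplicated clusters at the minimal p-value", {
  base <- matrix(runif(10 * 2, 0.1, 1), 2, 10)
  vals <- rbind(base[rep(1, 8), ] + 5, base[rep(2, 8), ])
  rownames(vals) <- paste0("s", 1:16)
  colnames(vals) <- paste0("t", 1:10)
  tab <- abundance_table(vals, mode = "counts")
  d <- community_distance(tab, "bray")
  meta <- data.frame(cluster = rep(c("a", "b"), each = 8))
  res <- permanova(d, meta, "cluster", n_permutations = 199, seed = 1)
  expect_equal(res$p_value[res$term == "cluster"], 1 / 200, tolerance = 1e-12)
  expect_gt(res$R2[res$term == "cluster"], 0.9)
  # R2 partitioning sums to 1
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-9)
  expect_error(permanova(d, data.frame(g = rep("x", 16)), "g", 199, 1),
               "constant")
})

test_that("SIMPER contributions decompose the mean between-group dissimilarity", {
  set.seed(15)
  vals <- matrix(rexp(12 * 8), 12, 8,
                 dimnames = list(paste0("s", 1:12), paste0("t", 1:8)))
  tab <- to_relative_abundance(abundance_table(vals, mode = "counts"))
  groups <- rep(c("x", "y"), each = 6)
  sp <- simper(tab, groups, n_permutations = 99, seed = 2)
  # decomposition identity: contributions sum to the mean between-group BC
  bc <- as.matrix(community_distance(tab, "bray"))
  between <- bc[1:6, 7:12]
  expect_equal(sp$total, mean(between), tolerance = 1e-10)
  expect_true(all(diff(sp$contributions$average) <= 0))
  # the identified set is the minimal prefix over the cumulative cutoff
  k <- length(sp$identified)
  expect_gte(sp$contributions$cumulative[k], 0.70)
  if (k > 1) expect_lt(sp$contributions$cumulative[k - 1], 0.70)

  # single-taxon table: that taxon contributes 100%
  tab1 <- abundance_table(matrix(c(1, 2, 3, 4), 4, 1,
                                 dimnames = list(paste0("s", 1:4), "only")),
                          mode = "counts")
  sp1 <- simper(tab1, c("x", "x", "y", "y"), n_permutations = 19, seed = 1)
  expect_identical(sp1$identified, "only")
  expect_equal(sp1$contributions$cumulative, 1)

  # a dominant discriminating taxon ranks first
  vals2 <- cbind(disc = c(0.9, 0.85, 0.05, 0.1),
                 t2 = c(0.05, 0.1, 0.9, 0.8) / 2,
                 t3 = c(0.05, 0.05, 0.05, 0.1))
  vals2 <- vals2 / rowSums(vals2)
  rownames(vals2) <- paste0("s", 1:4)
  tab2 <- abundance_table(vals2, mode = "relative")
  sp2 <- simper(tab2, c("x", "x", "y", "y"), n_permutations = 19, seed = 1)
  expect_identical(sp2$contributions$taxon_id[1], "disc")
})

test_that("random-forest screen normalizes importances and flags a planted
           predictor", {
  tab <- synthesize_abundance_table(n_samples = 500, n_taxa = 20,
                                    taxonomy_breadth = 5, seed = 16)
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    y <- rbinom(500, 1, plogis(-1 + 3 * scale(tab$values[, 1])))
    rf <- rf_importance_screen(tab, y, covariates = tab$metadata["sex"],
                               n_trees = 100, seed = s)
    expect_equal(sum(rf$importance), 1, tolerance = 1e-9)
    expect_equal(rf$cutoff, 1 / 21)  # 20 taxa + sex
    "otu_0001" %in% rf$identified
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
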
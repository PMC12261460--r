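test_that("dge_scores recovers planted effects and is calibrated under the null", {
  # null: identical distributions in both classes -> ~5% of genes at p<0.05
  set.seed(1)
  n_genes <- 1000
  X <- matrix(rnorm(100 * n_genes), 100, n_genes)
  labels <- rep(1:2, each = 50)
  dge <- dge_scores(X, labels, 1)
  frac <- mean(dge$p_value < 0.05)
  # binomial 99% CI around 0.05 with n = 1000
  expect_gt(frac, 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_genes))
  expect_lt(frac, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_genes))
  # p-values approximately uniform (KS at 0.01)
  expect_gt(stats::ks.test(dge$p_value, "punif")$p.value, 0.01)

  # planted shift of +2 on gene 1: effect within 3 SE of 2
  set.seed(2)
  X2 <- X
  X2[labels == 1, 1] <- X2[labels == 1, 1] + 2
  dge2 <- dge_scores(X2, labels, 1)
  se <- sqrt(1 / 50 + 1 / 50)
  expect_lt(abs(dge2$effect[1] - 2), 3 * se)
  # constant matrix: all effects 0, p = 1
  dgec <- dge_scores(matrix(3, 10, 5), rep(1:2, each = 5), 2)
  expect_equal(dgec$effect, rep(0, 5))
  expect_equal(dgec$p_value, rep(1, 5))
})

test_that("dge_scores validates its inputs", {
  X <- matrix(rnorm(20), 4, 5)
  expect_error(dge_scores(X, rep(1:2, each = 2), 3), "absent")
  expect_error(dge_scores(X, c(1, 2, 2, 2), 1), ">= 2 samples")
})

test_that("build_expression_knowledge_map selects, filters and standardizes", {
  dge <- data.frame(gene = paste0("g", 1:5), effect = c(5, 4, 3, 2, 1),
                    p_value = rep(0.001, 5))
  km <- build_expression_knowledge_map(dge, 3)
  expect_s3_class(km, "knowledge_map")
  expect_identical(which(km$mask == 1), 1:3)

  # the gene with the largest effect but p = 0.5 is excluded at 0.05
  dge$p_value[1] <- 0.5
  km2 <- build_expression_knowledge_map(dge, 3)
  expect_identical(which(km2$mask == 1), 2:4)

  # two selected genes with effects {4, 2}: z-scores {+1,-1}/sqrt(2)*sd...
  # recompute the documented standardization independently
  dge3 <- data.frame(gene = c("a", "b"), effect = c(4, 2),
                     p_value = c(0.01, 0.01))
  km3 <- build_expression_knowledge_map(dge3, 2)
  z <- (c(4, 2) - 3) / stats::sd(c(4, 2))
  expect_equal(km3$scores, z - min(z) + 0.01)

  # single selected gene -> score 1
  km4 <- build_expression_knowledge_map(dge3, 1)
  expect_equal(sum(km4$mask), 1)
  expect_equal(km4$scores[km4$mask == 1], 1)

  # nothing qualifies -> empty mask with warning
  dge4 <- data.frame(gene = "a", effect = -1, p_value = 0.001)
  expect_warning(km5 <- build_expression_knowledge_map(dge4, 1),
                 "no gene qualifies")
  expect_equal(sum(km5$mask), 0)
})

test_that("expression km ties break by p-value then gene id", {
  dge <- data.frame(gene = c("b", "a", "c"), effect = c(2, 2, 2),
                    p_value = c(0.01, 0.01, 0.001))
  km <- build_expression_knowledge_map(dge, 2)
  sel <- km$feature_ids[km$mask == 1]
  expect_setequal(sel, c("c", "a"))  # smaller p first, then lexicographic
})

test_that("catalytic knowledge maps have the stated support and determinism", {
  set.seed(5)
  km <- build_catalytic_knowledge_map(10, c(3, 8), 2)
  expect_equal(sum(km$mask), 4)
  expect_equal(sum(km$scores == 1), 2)
  expect_equal(km$scores[c(3, 8)], c(1, 1))
  expect_equal(sum(km$scores == 0.01), 2)

  km0 <- build_catalytic_knowledge_map(10, c(3, 8), 0)
  expect_identical(which(km0$mask == 1), c(3L, 8L))

  set.seed(11); a <- build_catalytic_knowledge_map(50, c(1, 25), 10)
  set.seed(11); b <- build_catalytic_knowledge_map(50, c(1, 25), 10)
  expect_identical(a, b)

  expect_error(build_catalytic_knowledge_map(10, c(3, 8), 9), "n_random_low")
  expect_error(build_catalytic_knowledge_map(10, c(0, 8), 1), "outside")
})

test_that("rerandomize_low_scores keeps labeled sites and screens the rest", {
  set.seed(13)
  km <- build_catalytic_knowledge_map(60, c(10, 20, 30), 12)
  seen <- integer(0)
  for (i in 1:100) {
    km2 <- rerandomize_low_scores(km)
    expect_equal(which(km2$scores == 1), c(10, 20, 30))
    expect_equal(sum(km2$mask == 1 & km2$scores != 1), 12)
    seen <- union(seen, which(km2$scores == 0.01))
    km <- km2
  }
  # coupon collector: 100 draws of 12 from 57 cover everything
  expect_setequal(seen, setdiff(1:60, c(10, 20, 30)))
  expect_error(rerandomize_low_scores(tiny_km()), "catalytic")
})

test_that("random_control_knowledge_map mirrors catalytic cardinality", {
  set.seed(3); km <- random_control_knowledge_map(40, 5)
  expect_equal(sum(km$mask), 5)
  expect_setequal(unique(km$scores[km$mask == 1]), 1)
  set.seed(3); km2 <- random_control_knowledge_map(40, 5)
  expect_identical(km, km2)
  expect_error(random_control_knowledge_map(5, 6), "exceeds")
})

test_that("apply_mask is the idempotent Hadamard filter", {
  v <- c(1.5, -2, 0, 4)
  expect_equal(apply_mask(v, rep(1, 4)), v)
  expect_equal(apply_mask(v, rep(0, 4)), rep(0, 4))
  expect_equal(apply_mask(v, c(1, 0, 1, 0)), c(1.5, 0, 0, 0))
  set.seed(17)
  for (i in 1:50) {
    v <- rnorm(20)
    th <- rbinom(20, 1, 0.4)
    expect_identical(apply_mask(apply_mask(v, th), th), apply_mask(v, th))
  }
  expect_error(apply_mask(1:3, c(1, 0)), "equal length")
})

test_that("knowledge_map constructor enforces its invariants", {
  expect_error(knowledge_map(1:3, 1:2, c(1, 0, 1)), "equal length")
  expect_error(knowledge_map(1:3, c(1, Inf, 0), c(1, 1, 0)), "finite")
  expect_error(knowledge_map(1:3, 1:3, c(1, 2, 0)), "0 or 1")
  km <- tiny_km()
  expect_identical(masked_scores(km), km$scores * km$mask)
})
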
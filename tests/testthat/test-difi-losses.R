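test_that("masked_distance matches its definitions and edge cases", {
  km <- tiny_km(3, on = 1, scores = 1)       # K*theta = (1,0,0)
  expect_equal(masked_distance(c(1, 9, 9), km, "l2_squared"), 0)
  expect_equal(masked_distance(c(0, 9, 9), km, "l2_squared"), 1)
  expect_equal(masked_distance(c(1, 9, 9), km, "cosine"), 0)

  # orthogonal masked vectors -> cosine penalty 1
  km2 <- tiny_km(4, on = 1:2, scores = c(1, 0))
  expect_equal(masked_distance(c(0, 1, 5, 5), km2, "cosine"), 1)

  # all-zero mask -> 0; zero-norm masked vector -> 0 with warning
  km0 <- tiny_km(3, on = integer(0))
  expect_equal(masked_distance(c(1, 2, 3), km0, "cosine"), 0)
  expect_warning(d <- masked_distance(c(0, 9, 9), km, "cosine"),
                 "zero-norm")
  expect_equal(d, 0)
  expect_error(masked_distance(1:5, km, "l2_squared"), "different feature")
})

test_that("masked distances ignore K at masked-out positions and stay in range", {
  set.seed(43)
  for (i in 1:100) {
    d <- sample(4:12, 1)
    th <- rbinom(d, 1, 0.5)
    if (!any(th == 1)) th[1] <- 1
    K1 <- rnorm(d); K2 <- K1
    K2[th == 0] <- rnorm(sum(th == 0), sd = 10)   # perturb masked-out only
    w <- rnorm(d)
    for (metric in c("l2_squared", "cosine")) {
      a <- knowledge_map(seq_len(d), K1, th)
      b <- knowledge_map(seq_len(d), K2, th)
      da <- suppressWarnings(masked_distance(w, a, metric))
      db <- suppressWarnings(masked_distance(w, b, metric))
      expect_equal(da, db)
      expect_gte(da, 0)
      if (metric == "cosine") expect_lte(da, 2)
    }
  }
})

test_that("alpha = 0 reproduces plain cross-entropy for every objective", {
  set.seed(47)
  m <- make_expression_cnn(20, 2)
  X <- matrix(rnorm(80, mean = 3), 4, 20)
  y <- c(1L, 2L, 1L, 2L)
  km <- tiny_km(20, 1:3)
  lg <- predict(m, X)
  ce_manual <- mean(sapply(1:4, function(i) {
    z <- lg[i, ]; log(sum(exp(z - max(z)))) + max(z) - z[y[i]]
  }))
  g0 <- gradient_based_difi_loss(m, X, y, rep(list(km), 4),
                                 difi_config("gradient", alpha = 0))
  expect_equal(g0$loss, ce_manual, tolerance = 1e-12)
  expect_equal(g0$sim, 0)

  t0 <- sparse_attention_transfer_loss(m, m, X, y, sparsity_percent = NULL)
  expect_equal(t0$loss, ce_manual, tolerance = 1e-12)

  set.seed(48)
  ms <- make_sequence_resnet(30L, widths = c(4L, 4L, 6L, 6L))
  seqs <- c("HDSTACDEFGHIKLMNPQRS", "MKLVWYYTREMKLVWYYTRE")
  enc <- encode_one_hot(seqs, 30L)
  ys <- c(1L, 2L)
  kms <- list(build_catalytic_knowledge_map(30, 1:3, 5), NULL)
  a0 <- activation_based_difi_loss(ms, enc, ys, kms,
                                   difi_config("activation", alpha = 0))
  lg2 <- predict(ms, enc)
  ce2 <- mean(sapply(1:2, function(i) {
    z <- lg2[i, ]; log(sum(exp(z - max(z)))) + max(z) - z[ys[i]]
  }))
  expect_equal(a0$loss, ce2, tolerance = 1e-12)
})

test_that("similarity vanishes when the feature map equals the knowledge map", {
  # activation loss with a batch of map-less samples contributes only CE
  set.seed(53)
  ms <- make_sequence_resnet(24L, widths = c(4L, 4L, 4L, 4L))
  enc <- encode_one_hot(c("HDSTACDEFGHI", "MKLVWYYTREAC"), 24L)
  cfg <- difi_config("activation", alpha = 2, metric = "cosine")
  r <- activation_based_difi_loss(ms, enc, c(1L, 2L), list(NULL, NULL), cfg)
  expect_equal(r$sim, 0)
  expect_equal(r$loss, r$ce)

  # student == teacher -> transfer similarity exactly 0
  m <- make_expression_cnn(15, 2)
  X <- matrix(rnorm(30, 2), 2, 15)
  tr <- sparse_attention_transfer_loss(m, m, X, c(1L, 2L), 20)
  expect_equal(tr$sim, 0)
})

test_that("the gradient-DIFI similarity term backpropagates into parameters", {
  set.seed(59)
  m <- make_expression_cnn(10, 2)
  X <- matrix(rnorm(40, 2), 4, 10)
  y <- c(1L, 2L, 1L, 2L)
  km <- tiny_km(10, 1:3, scores = c(2, 1, 0.5))
  cfg <- difi_config("gradient", alpha = 1)
  with_sim <- gradient_based_difi_loss(m, X, y, rep(list(km), 4), cfg,
                                       return_grads = TRUE)
  no_sim <- gradient_based_difi_loss(m, X, y, rep(list(km), 4),
                                     difi_config("gradient", alpha = 0),
                                     return_grads = TRUE)
  # double-backprop contract: similarity term contributes nonzero
  # parameter gradients (the saliency graph is not detached)
  delta <- max(abs(with_sim$grads$Wc - no_sim$grads$Wc))
  expect_gt(delta, 1e-8)
  expect_gt(with_sim$sim, 0)
})

test_that("gradient-DIFI parameter gradients match finite differences", {
  set.seed(61)
  m <- make_expression_cnn(8, 2)
  X <- matrix(rnorm(16, 2), 2, 8)
  y <- c(1L, 2L)
  km <- tiny_km(8, c(2, 5), scores = c(1.5, 0.5))
  cfg <- difi_config("gradient", alpha = 0.7)
  out <- gradient_based_difi_loss(m, X, y, list(km, km), cfg,
                                  return_grads = TRUE)
  f0 <- function() gradient_based_difi_loss(m, X, y, list(km, km), cfg)$loss
  eps <- 1e-5
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      orig <- m$params[[nm]][i]
      m$params[[nm]][i] <- orig + eps; fp <- f0()
      m$params[[nm]][i] <- orig - eps; fm <- f0()
      m$params[[nm]][i] <- orig
      fd <- (fp - fm) / (2 * eps)
      expect_lt(abs(fd - out$grads[[nm]][i]) / max(abs(fd), 1e-4), 1e-3)
    }
  }
})

test_that("transfer masks have the promised per-sample support", {
  set.seed(67)
  teacher <- make_expression_cnn(20, 2, "teacher")
  X <- matrix(rnorm(60, 2), 3, 20)
  y <- c(1L, 2L, 1L)
  JT <- saliency_map(teacher, X, y)$weights
  p <- 15
  masks <- t(apply(JT, 1, top_percentile_mask, percent = p))
  expect_true(all(rowSums(masks) == ceiling(p / 100 * 20)))
  # sparsity 100 reduces to full attention transfer: mask everywhere
  masks100 <- t(apply(JT, 1, top_percentile_mask, percent = 100))
  expect_true(all(masks100 == 1))
})

test_that("one activation-DIFI training step decreases the masked distance", {
  set.seed(71)
  ds <- tiny_sequences(n = 24, seed = 71, len = c(20L, 24L))
  enc <- encode_one_hot(ds$sequences, 24L)
  kms <- lapply(ds$truth, function(tp) {
    if (!length(tp)) return(NULL)
    build_catalytic_knowledge_map(24L, tp, 4)
  })
  m <- make_sequence_resnet(24L, widths = c(4L, 4L, 6L, 6L))
  cfg <- difi_config("activation", alpha = 5, metric = "cosine")
  sim0 <- activation_based_difi_loss(m, enc, ds$labels, kms, cfg)$sim
  r <- difi_train(m, enc, ds$labels, cfg, kms = kms, epochs = 8,
                  batch_size = 24, lr = 3e-3, seed = 71)
  simT <- activation_based_difi_loss(r$model, enc, ds$labels, kms, cfg)$sim
  expect_lt(simT, sim0)
})
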
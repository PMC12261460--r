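test_that("expression generator plants recoverable disjoint biomarkers", {
  ds <- simulate_expression_dataset(n_classes = 3, n_genes = 300,
                                    n_biomarkers_per_class = 4,
                                    effect_size = 3, noise_sd = 1,
                                    n_samples_per_class = 40, seed = 2)
  expect_equal(dim(ds$X), c(120L, 300L))
  # disjoint truth sets
  expect_equal(length(unique(unlist(ds$truth))), 12)
  # same seed -> identical matrix; different seed -> different
  ds2 <- simulate_expression_dataset(n_classes = 3, n_genes = 300,
                                     n_biomarkers_per_class = 4,
                                     effect_size = 3, noise_sd = 1,
                                     n_samples_per_class = 40, seed = 2)
  expect_identical(ds$X, ds2$X)
  # knowledge-map builder recovers exactly the planted set per class
  for (cl in 1:3) {
    km <- build_expression_knowledge_map(
      dge_scores(ds$X, ds$labels, cl), 4)
    expect_setequal(km$feature_ids[km$mask == 1], ds$truth[[cl]])
  }
  expect_error(simulate_expression_dataset(n_classes = 5, n_genes = 10,
                                           n_biomarkers_per_class = 3),
               "exceeds")
})

test_that("a null expression dataset yields ~5% DGE discoveries", {
  ds <- simulate_expression_dataset(n_classes = 2, n_genes = 1000,
                                    n_biomarkers_per_class = 1,
                                    effect_size = 0, noise_sd = 1,
                                    n_samples_per_class = 50, seed = 4)
  dge <- dge_scores(ds$X, ds$labels, 1)
  frac <- mean(dge$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 2.58 * sqrt(0.05 * 0.95 / 1000) + 1e-9)
})

test_that("sequence generator plants the motif only where recorded", {
  ds <- simulate_sequence_dataset(n_positive = 30, n_negative = 30,
                                  length_range = c(30L, 60L), seed = 6)
  rx <- "[H][DE][ST]"
  for (i in 1:30) {
    s <- ds$sequences[i]
    hits <- gregexpr(rx, s)[[1]]
    expect_equal(as.integer(hits), ds$truth[[i]][1])  # exactly the planted site
  }
  for (i in 31:60) {
    expect_false(grepl(rx, ds$sequences[i]))
    expect_length(ds$truth[[i]], 0)
  }
  expect_true(all(nchar(ds$sequences) >= 30 & nchar(ds$sequences) <= 60))
  # purity: same spec -> identical records
  ds2 <- simulate_sequence_dataset(n_positive = 30, n_negative = 30,
                                   length_range = c(30L, 60L), seed = 6)
  expect_identical(ds$sequences, ds2$sequences)
  expect_error(simulate_sequence_dataset(length_range = c(2L, 3L)),
               "motif longer")
})

test_that("a position-weight scan recovers planted positions", {
  ds <- simulate_sequence_dataset(n_positive = 20, n_negative = 0,
                                  length_range = c(40L, 50L), seed = 8)
  # PWM-style oracle: score each window by per-position membership in the
  # degenerate motif sets; the argmax window must be the planted site
  motif <- default_motif()
  for (i in 1:20) {
    ch <- strsplit(ds$sequences[i], "")[[1]]
    scores <- vapply(seq_len(length(ch) - 2), function(p)
      sum(vapply(1:3, function(j) ch[p + j - 1] %in% motif[[j]], logical(1))),
      numeric(1))
    expect_equal(which.max(scores), ds$truth[[i]][1])
  }
})

test_that("the motif-presence oracle achieves zero error", {
  ds <- simulate_sequence_dataset(n_positive = 50, n_negative = 50,
                                  length_range = c(30L, 60L), seed = 10)
  pred <- motif_oracle_predict(ds$sequences)
  expect_equal(mean(pred != ds$labels), 0)
})

test_that("simulated distance matrices support exact proximity labeling", {
  D <- simulate_distance_matrix(40, c(10, 11, 12), seed = 12)
  expect_equal(diag(D), rep(0, 40))
  expect_identical(D, t(D))
  labels <- proximity_site_labels(D, c(10, 11, 12), 3.0)
  expect_setequal(labels, 9:13)                 # planted plus flanks
  # exhaustive threshold oracle
  oracle <- which(sapply(1:40, function(i)
    min(D[i, c(10, 11, 12)]) <= 3 | i %in% c(10, 11, 12)))
  expect_setequal(labels, oracle)
})
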
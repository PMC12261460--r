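# Shared fixtures, all built in code at test time.

# tiny expression problem: 2 classes, planted biomarkers on genes 1:3 (class
# 1) and 4:6 (class 2)
tiny_expression <- function(n_per_class = 30, n_genes = 40, effect = 4,
                            seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(1:2, each = n_per_class)
  X <- matrix(rnorm(n * n_genes, mean = 5), n, n_genes)
  X[labels == 1, 1:3] <- X[labels == 1, 1:3] + effect
  X[labels == 2, 4:6] <- X[labels == 2, 4:6] + effect
  colnames(X) <- sprintf("g%02d", seq_len(n_genes))
  list(X = X, labels = labels,
       truth = list(colnames(X)[1:3], colnames(X)[4:6]))
}

tiny_km <- function(d = 10, on = 1:3, scores = NULL) {
  s <- numeric(d); m <- numeric(d)
  m[on] <- 1
  s[on] <- scores %||% rep(1, length(on))
  knowledge_map(seq_len(d), s, m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small sequence dataset shared across tests (motif task)
tiny_sequences <- function(n = 40, seed = 9, len = c(30L, 50L)) {
  simulate_sequence_dataset(n_positive = n / 2, n_negative = n / 2,
                            length_range = len, seed = seed)
}

# O(n^2) pair-counting AUC oracle (ties count 1/2)
auc_oracle <- function(w, pos) {
  neg <- setdiff(seq_along(w), pos)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (w[i] > w[j]) 1 else if (w[i] == w[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# motif-presence oracle classifier: 1 if the planted motif matches, else 2
motif_oracle_predict <- function(sequences) {
  rx <- "[H][DE][ST]"
  ifelse(grepl(rx, sequences), 1L, 2L)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
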
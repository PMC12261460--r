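# Knowledge maps: sparse a-priori feature-importance vectors with a binary
# mask marking which entries are asserted. Consumers only ever see K * theta.

#' Construct a knowledge map
#'
#' A knowledge map holds per-feature knowledge scores \code{K} together with
#' a binary mask \code{theta} marking which entries are asserted. Feature
#' weighting regularization pulls a model's feature map toward
#' \code{K * theta}; entries with \code{mask == 0} are ignored by all
#' consumers.
#'
#' @param feature_ids character or integer vector of feature identifiers
#'   (gene symbols, or 1-based residue positions).
#' @param scores numeric vector of knowledge scores, same length.
#' @param mask binary (0/1) vector, same length.
#' @param provenance one of \code{"dge"}, \code{"catalytic"},
#'   \code{"random_control"}, \code{"user"}.
#' @param catalytic_positions integer vector (1-based) of positions whose
#'   score-1 support must survive re-randomization; only for catalytic maps.
#' @param low_score the score assigned to randomly sampled unlabeled
#'   positions in catalytic maps.
#' @return an object of class \code{knowledge_map}.
#' @export
knowledge_map <- function(feature_ids, scores, mask,
                          provenance = c("user", "dge", "catalytic",
                                         "random_control"),
                          catalytic_positions = integer(0),
                          low_score = 0.01) {
  provenance <- match.arg(provenance)
  d <- length(feature_ids)
  if (length(scores) != d || length(mask) != d)
    stop("feature_ids, scores and mask must have equal length")
  if (!all(is.finite(scores)))
    stop("knowledge scores must be finite")
  if (!all(mask %in% c(0, 1)))
    stop("mask entries must be 0 or 1")
  structure(list(feature_ids = feature_ids,
                 scores = as.numeric(scores),
                 mask = as.numeric(mask),
                 provenance = provenance,
                 catalytic_positions = as.integer(catalytic_positions),
                 low_score = low_score),
            class = "knowledge_map")
}

#' @export
print.knowledge_map <- function(x, ...) {
  cat(sprintf("<knowledge_map> %d features, %d asserted (provenance: %s)\n",
              length(x$feature_ids), sum(x$mask), x$provenance))
  invisible(x)
}

#' @export
length.knowledge_map <- function(x) length(x$feature_ids)

#' Masked knowledge scores K * theta
#' @param km a \code{knowledge_map}.
#' @return numeric vector of masked scores.
#' @export
masked_scores <- function(km) km$scores * km$mask

#' Hadamard masking
#'
#' Elementwise product of a value vector with a binary mask. Idempotent:
#' applying the same mask twice changes nothing.
#'
#' @param values numeric vector.
#' @param mask binary vector of the same length.
#' @return numeric vector.
#' @export
apply_mask <- function(values, mask) {
  if (length(values) != length(mask))
    stop("values and mask must have equal length")
  values * mask
}

#' One-vs-rest differential expression scores
#'
#' Per-gene comparison of a target class against all other samples on
#' log-scale expression values. The effect is the difference of group means
#' (a log fold change, since inputs are already log transformed); the
#' p-value comes from a Welch two-sample t-test.
#'
#' @param expr numeric matrix, samples x genes; values on a log scale
#'   (e.g. log2(FPKM+1)).
#' @param labels vector of class labels, one per row of \code{expr}.
#' @param target_class the class to contrast against the rest.
#' @return a data.frame with columns \code{gene}, \code{effect},
#'   \code{p_value}, one row per gene.
#' @export
dge_scores <- function(expr, labels, target_class) {
  expr <- as.matrix(expr)
  if (nrow(expr) != length(labels))
    stop("labels must have one entry per sample (row)")
  in_cls <- labels == target_class
  if (!any(in_cls)) stop("target class '", target_class, "' absent from labels")
  n1 <- sum(in_cls); n2 <- sum(!in_cls)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 samples in the target class and in its complement")
  m1 <- colMeans(expr[in_cls, , drop = FALSE])
  m2 <- colMeans(expr[!in_cls, , drop = FALSE])
  v1 <- matrixStats::colVars(expr[in_cls, , drop = FALSE])
  v2 <- matrixStats::colVars(expr[!in_cls, , drop = FALSE])
  effect <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, effect / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(expr)))
  data.frame(gene = genes, effect = as.numeric(effect),
             p_value = as.numeric(p), stringsAsFactors = FALSE)
}

#' Build a biomarker knowledge map from DGE results
#'
#' Selects the genes most specifically overexpressed in a class (positive
#' effect, p-value below threshold), masks exactly those, and uses their
#' standardized overexpression levels as knowledge scores. Standardization
#' is a z-score over the selected set shifted so all scores are at least a
#' small positive floor; a single selected gene gets score 1. Ties in the
#' effect ranking are broken by smaller p-value, then by gene id.
#'
#' @param dge data.frame from \code{\link{dge_scores}}.
#' @param n_biomarkers number of top overexpressed genes to assert.
#' @param p_threshold significance threshold (default 0.05).
#' @param score_floor minimum positive score after the shift.
#' @return a \code{knowledge_map} with provenance \code{"dge"}.
#' @export
build_expression_knowledge_map <- function(dge, n_biomarkers,
                                           p_threshold = 0.05,
                                           score_floor = 0.01) {
  stopifnot(n_biomarkers >= 1)
  d <- nrow(dge)
  qual <- which(dge$effect > 0 & dge$p_value < p_threshold)
  mask <- numeric(d)
  scores <- numeric(d)
  if (length(qual) == 0L) {
    warning("no gene qualifies (effect > 0 and p < ", p_threshold,
            "); returning an empty-mask knowledge map")
  } else {
    ord <- qual[order(-dge$effect[qual], dge$p_value[qual], dge$gene[qual])]
    sel <- ord[seq_len(min(n_biomarkers, length(ord)))]
    mask[sel] <- 1
    eff <- dge$effect[sel]
    if (length(sel) == 1L) {
      scores[sel] <- 1
    } else {
      s <- stats::sd(eff)
      z <- if (s == 0) rep(1, length(sel)) else (eff - mean(eff)) / s
      scores[sel] <- z - min(z) + score_floor
    }
  }
  knowledge_map(dge$gene, scores, mask, provenance = "dge")
}

#' Build a catalytic-site knowledge map
#'
#' Catalytic positions get knowledge score 1 and are always asserted. To
#' favor relatively higher weights at the known positions, a number of the
#' remaining (unlabeled) positions are drawn uniformly at random and given a
#' low score; all other positions stay masked out, leaving the model free to
#' learn their weights.
#'
#' @param seq_length sequence length.
#' @param catalytic_positions integer vector of 1-based catalytic positions.
#' @param n_random_low how many unlabeled positions to dampen with the low
#'   score (the reference protocol uses 20 percent of the length).
#' @param low_score score for the sampled unlabeled positions (default 0.01).
#' @return a \code{knowledge_map} with provenance \code{"catalytic"}.
#' @export
build_catalytic_knowledge_map <- function(seq_length, catalytic_positions,
                                          n_random_low, low_score = 0.01) {
  catalytic_positions <- sort(unique(as.integer(catalytic_positions)))
  if (length(catalytic_positions) &&
      (min(catalytic_positions) < 1L || max(catalytic_positions) > seq_length))
    stop("catalytic positions outside [1, ", seq_length, "]")
  pool <- setdiff(seq_len(seq_length), catalytic_positions)
  if (n_random_low > length(pool))
    stop("n_random_low exceeds the number of non-catalytic positions")
  scores <- numeric(seq_length)
  mask <- numeric(seq_length)
  scores[catalytic_positions] <- 1
  mask[catalytic_positions] <- 1
  if (n_random_low > 0L) {
    low <- sample(pool, n_random_low)
    scores[low] <- low_score
    mask[low] <- 1
  }
  knowledge_map(seq_len(seq_length), scores, mask, provenance = "catalytic",
                catalytic_positions = catalytic_positions,
                low_score = low_score)
}

#' Re-randomize the low-score support of a catalytic knowledge map
#'
#' Called at each training epoch: the score-1 catalytic support is kept
#' fixed while the low-score support is redrawn (same cardinality) from the
#' unlabeled positions, so that over epochs every unlabeled residue is
#' screened for higher feature weights.
#'
#' @param km a catalytic \code{knowledge_map}.
#' @return a new \code{knowledge_map}.
#' @export
rerandomize_low_scores <- function(km) {
  if (km$provenance != "catalytic")
    stop("rerandomize_low_scores applies to catalytic knowledge maps only")
  n_low <- sum(km$mask == 1 & km$scores != 1)
  build_catalytic_knowledge_map(length(km$feature_ids),
                                km$catalytic_positions,
                                n_low, km$low_score)
}

#' Random-control knowledge map
#'
#' Assigns feature weight 1 to uniformly drawn positions, mirroring the
#' cardinality of a true catalytic map. Used as the deliberately wrong
#' knowledge control (the "Ran" model).
#'
#' @param seq_length sequence length.
#' @param n_sites number of random score-1 positions.
#' @return a \code{knowledge_map} with provenance \code{"random_control"}.
#' @export
random_control_knowledge_map <- function(seq_length, n_sites) {
  if (n_sites > seq_length)
    stop("n_sites exceeds sequence length")
  sites <- if (n_sites > 0L) sort(sample(seq_len(seq_length), n_sites)) else
    integer(0)
  scores <- numeric(seq_length)
  mask <- numeric(seq_length)
  scores[sites] <- 1
  mask[sites] <- 1
  knowledge_map(seq_len(seq_length), scores, mask,
                provenance = "random_control",
                catalytic_positions = sites)
}
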
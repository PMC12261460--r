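# Evaluation: classification error, rank-based agreement of feature weights
# with annotated sites, proximity labeling from residue distance matrices,
# and in-silico alanine-scanning perturbation.

#' Classification error (percent)
#' @param model a \code{difi_model}.
#' @param X inputs (matrix or \code{encode_one_hot} result).
#' @param labels true integer labels.
#' @return 100 * (1 - accuracy).
#' @export
classification_error <- function(model, X, labels) {
  pred <- predict_class(model, X)
  100 * mean(pred != labels)
}

#' ROC-AUC of feature weights against annotated positions
#'
#' Rank-based (Mann-Whitney) AUC of the weights at annotated positive
#' positions versus all remaining positions; tied weights contribute 1/2.
#' Invariant under strictly monotone transforms of the weights.
#'
#' @param weights numeric vector of feature weights, or a single-sample
#'   \code{feature_map}.
#' @param positives integer vector of 1-based positive positions (nonempty,
#'   proper subset).
#' @return AUC in [0, 1].
#' @export
feature_weight_auc <- function(weights, positives) {
  if (inherits(weights, "feature_map")) {
    stopifnot(nrow(weights$weights) == 1L)
    weights <- weights$weights[1L, ]
  }
  d <- length(weights)
  positives <- unique(as.integer(positives))
  if (length(positives) == 0L)
    stop("positives must be nonempty")
  if (any(positives < 1L | positives > d))
    stop("positive positions outside [1, ", d, "]")
  if (length(positives) >= d)
    stop("positives must be a proper subset of positions")
  r <- rank(weights)   # mid-ranks handle ties with weight 1/2
  n1 <- length(positives)
  n0 <- d - n1
  (sum(r[positives]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Proximity labeling of activation-site residues
#'
#' All positions whose minimum distance to any catalytic residue is within
#' the radius (catalytic residues themselves sit at distance 0).
#'
#' @param dist symmetric residue-residue distance matrix (Angstrom).
#' @param catalytic integer vector of 1-based catalytic positions.
#' @param radius inclusion radius in Angstrom (default 3.0).
#' @return sorted integer vector of positions.
#' @export
proximity_site_labels <- function(dist, catalytic, radius = 3.0) {
  stopifnot(nrow(dist) == ncol(dist))
  catalytic <- unique(as.integer(catalytic))
  if (any(catalytic < 1L | catalytic > nrow(dist)))
    stop("catalytic positions outside the distance matrix")
  mind <- apply(dist[, catalytic, drop = FALSE], 1L, min)
  mind[catalytic] <- 0
  sort(which(mind <= radius))
}

#' Per-sequence feature weights for ranking substitutions
#'
#' Default weight source for perturbation experiments: the activation map
#' at the configured tap, restricted to each sequence's real (non-padding)
#' residues.
#' @keywords internal
.residue_weights <- function(model, enc, tap = "group3") {
  am <- activation_map(model, enc, tap = tap)
  am$weights
}

#' In-silico alanine-scan conversion
#'
#' For each sequence (expected to be currently predicted positive), the k
#' highest- (or lowest-) weighted non-alanine residues are substituted with
#' alanine and the model re-queried; the return value is the percentage of
#' sequences whose prediction flips to the negative class. Residues that
#' are already alanine are skipped when selecting targets; if fewer than k
#' candidates exist, all are substituted.
#'
#' @param model a sequence \code{difi_model}.
#' @param sequences character vector of residue strings.
#' @param k number of residues to substitute (k = 0 returns 0).
#' @param rank_source \code{"top"} or \code{"bottom"} feature weights.
#' @param tap activation tap supplying the feature weights.
#' @param negative_class integer label index treated as "non-enzyme"
#'   (default 2).
#' @param weights optional precomputed weight matrix (sequences x
#'   positions), e.g. from an oracle; defaults to the model's activation
#'   map.
#' @param predict_fn optional classifier stand-in: a function mapping a
#'   character vector of sequences to integer class labels (used by oracle
#'   tests; defaults to the model's own predictions).
#' @param max_len input length when only \code{predict_fn} is given.
#' @return percent of sequences converted to the negative class.
#' @export
alanine_scan_conversion <- function(model, sequences, k,
                                    rank_source = c("top", "bottom"),
                                    tap = "group3", negative_class = 2L,
                                    weights = NULL, predict_fn = NULL,
                                    max_len = 300L) {
  rank_source <- match.arg(rank_source)
  if (k == 0L) return(0)
  n <- length(sequences)
  if (!is.null(model)) max_len <- model$spec$max_len
  if (is.null(weights)) {
    enc <- encode_one_hot(sequences, max_len)
    weights <- .residue_weights(model, enc, tap)
  }
  mutated <- character(n)
  for (i in seq_len(n)) {
    ch <- strsplit(toupper(sequences[i]), "")[[1]]
    len <- min(length(ch), max_len)
    w <- weights[i, seq_len(len)]
    cand <- which(ch[seq_len(len)] != "A")
    if (length(cand)) {
      ord <- if (rank_source == "top") order(-w[cand], cand) else
        order(w[cand], cand)
      targets <- cand[ord[seq_len(min(k, length(cand)))]]
      ch[targets] <- "A"
    }
    mutated[i] <- paste(ch, collapse = "")
  }
  pred <- if (is.null(predict_fn)) {
    predict_class(model, encode_one_hot(mutated, max_len))
  } else predict_fn(mutated)
  100 * mean(pred == negative_class)
}

#' Perturbation curve over substitution counts
#'
#' @inheritParams alanine_scan_conversion
#' @param k_values integer vector of substitution counts.
#' @return object of class \code{perturbation_curve}: data.frame with
#'   \code{k}, \code{percent_conversion}, \code{rank_source}.
#' @export
perturbation_curve <- function(model, sequences, k_values = 0:5,
                               rank_source = c("top", "bottom"),
                               tap = "group3", negative_class = 2L) {
  rank_source <- match.arg(rank_source)
  pc <- vapply(k_values, function(k)
    alanine_scan_conversion(model, sequences, k, rank_source, tap,
                            negative_class), numeric(1))
  structure(data.frame(k = k_values, percent_conversion = pc,
                       rank_source = rank_source),
            class = c("perturbation_curve", "data.frame"))
}
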
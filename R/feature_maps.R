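# Feature maps: per-input-feature weights derived from a model, either as
# the gradient of the loss w.r.t. the input (saliency) or as a
# channel-aggregated spatial activation profile resized to the input length.

#' Construct a feature map
#'
#' @param weights numeric matrix, samples x features (one row per sample).
#' @param source \code{"saliency"} or \code{"activation"}.
#' @param tap optional layer-group identifier for activation maps.
#' @param feature_ids optional feature identifiers.
#' @return object of class \code{feature_map}.
#' @export
feature_map <- function(weights, source = c("saliency", "activation"),
                        tap = NULL, feature_ids = NULL) {
  source <- match.arg(source)
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("feature weights must be finite")
  if (source == "activation" && any(weights < 0))
    stop("activation-derived feature weights must be nonnegative")
  structure(list(weights = weights, source = source, tap = tap,
                 feature_ids = feature_ids),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %d sample(s) x %d features (source: %s%s)\n",
              nrow(x$weights), ncol(x$weights), x$source,
              if (is.null(x$tap)) "" else paste0(", tap ", x$tap)))
  invisible(x)
}

#' Input-gradient saliency map
#'
#' The saliency value of each input feature is the gradient of the
#' cross-entropy loss with respect to that input, evaluated at the sample's
#' true label. For one-hot sequence inputs the per-residue weight is the sum
#' over alphabet channels of the absolute per-element gradients.
#'
#' @param model a \code{difi_model}.
#' @param X samples x genes matrix (expression) or \code{encode_one_hot}
#'   result (sequence).
#' @param labels integer class labels (1-based), one per sample.
#' @param batch_size forward/backward batch size.
#' @return a \code{feature_map} with source \code{"saliency"}; for
#'   expression models the weights are the signed gradients, for sequence
#'   models the channel-aggregated magnitudes.
#' @export
saliency_map <- function(model, X, labels, batch_size = 256L) {
  sp <- model$spec
  n <- if (sp$family == "cnn1d_expression") nrow(X) else length(X$lengths)
  stopifnot(length(labels) == n)
  pn <- .params_as_nodes(model)
  d <- if (sp$family == "cnn1d_expression") sp$n_genes else sp$max_len
  W <- matrix(NA_real_, n, d)
  i <- 1L
  while (i <= n) {
    rows <- i:min(i + batch_size - 1L, n)
    B <- length(rows)
    xb <- .input_node(model, X, rows, requires = TRUE)
    fw <- .forward(model, pn, xb, B)
    # sum of per-sample CE: each row of the gradient is d CE_i / d x_i
    ce <- ag_cross_entropy(fw$logits, labels[rows], reduce = "sum")
    J <- ag_value(ag_grad(ce, list(xb))[[1]])
    if (sp$family == "cnn1d_expression") {
      W[rows, ] <- t(matrix(as.vector(J), d, B))
    } else {
      W[rows, ] <- t(matrix(rowSums(abs(J)), d, B))
    }
    i <- i + B
  }
  feature_map(W, "saliency")
}

#' Spatial activation map
#'
#' Takes the activation tensor at the requested tap, averages absolute
#' values across channels, and resizes the spatial profile to the input
#' length by linear interpolation (non-trainable operations only, so
#' regularizing the map propagates through the whole network).
#'
#' @param model a \code{difi_model} exposing the tap.
#' @param X model input (see \code{\link{saliency_map}}).
#' @param tap layer-group identifier, e.g. \code{"group3"}.
#' @param batch_size forward-pass batch size.
#' @return a \code{feature_map} with source \code{"activation"}, one row per
#'   sample, length equal to the input feature axis.
#' @export
activation_map <- function(model, X, tap = "group3", batch_size = 256L) {
  sp <- model$spec
  if (!tap %in% sp$taps)
    stop("model does not expose tap '", tap, "'")
  n <- if (sp$family == "cnn1d_expression") nrow(X) else length(X$lengths)
  pn <- .params_as_nodes(model)
  d <- sp$max_len
  W <- matrix(NA_real_, n, d)
  i <- 1L
  while (i <= n) {
    rows <- i:min(i + batch_size - 1L, n)
    B <- length(rows)
    xb <- .input_node(model, X, rows)
    fw <- .forward(model, pn, xb, B)
    W[rows, ] <- ag_value(.activation_map_node(fw$taps[[tap]], B, d))
    i <- i + B
  }
  feature_map(W, "activation", tap = tap)
}

# channel mean of |A| then linear resize to input length; returns B x d node
.activation_map_node <- function(tapinfo, B, d) {
  A <- ag_abs(tapinfo$node)                      # (B*L') x C
  Lp <- tapinfo$L; C <- tapinfo$channels
  f <- ag_mul(ag_rowsums(A), 1 / C)              # (B*L') x 1
  fmat <- ag_reshape(f, c(Lp, B))                # (l, b) layout
  R <- .ag_cache_get(paste("interp", Lp, d, sep = "_"),
                     function() interp_matrix(Lp, d))
  ag_mm(fmat, ag_const(R), ta = TRUE)            # B x d
}

#' Top-percentile binary mask of feature weights
#'
#' Masks exactly the \code{ceiling(percent/100 * d)} largest-magnitude
#' weights; ties are broken in favor of the lower feature index.
#'
#' @param weights numeric vector of feature weights (ranked by absolute
#'   value), or a single-sample \code{feature_map}.
#' @param percent percentage in (0, 100].
#' @return binary vector of the same length.
#' @export
top_percentile_mask <- function(weights, percent) {
  if (inherits(weights, "feature_map")) {
    stopifnot(nrow(weights$weights) == 1L)
    weights <- weights$weights[1L, ]
  }
  if (!is.numeric(percent) || percent <= 0 || percent > 100)
    stop("percent must be in (0, 100]")
  d <- length(weights)
  if (d == 0L) stop("empty feature map")
  m <- ceiling(percent / 100 * d)
  ord <- order(-abs(weights), seq_len(d))
  mask <- numeric(d)
  mask[ord[seq_len(m)]] <- 1
  mask
}

# row-wise top-percentile masks for a weight matrix (samples x features)
.top_percentile_masks <- function(W, percent) {
  t(apply(W, 1L, top_percentile_mask, percent = percent))
}

#' Export a feature map as a TSV table
#' @param fm a \code{feature_map} (single sample or averaged).
#' @param path output file.
#' @param feature_ids optional identifiers; defaults to those stored in the
#'   map or the column index.
#' @export
write_feature_map <- function(fm, path, feature_ids = NULL) {
  ids <- feature_ids %||% fm$feature_ids %||% seq_len(ncol(fm$weights))
  w <- if (nrow(fm$weights) == 1L) fm$weights[1L, ] else colMeans(fm$weights)
  utils::write.table(data.frame(feature_id = ids, weight = w),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
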
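# The three training objectives. Each adds an alpha-weighted distance
# between the model's (masked) feature map and a (masked) knowledge map to
# the standard cross-entropy loss. For the gradient-based objective the
# feature map is itself a gradient, so parameter gradients of the similarity
# term involve second-order mixed partial derivatives; the saliency graph is
# never detached from the parameter graph.

#' DIFI configuration
#'
#' @param mode \code{"gradient"} (saliency regularized), \code{"activation"}
#'   (activation map regularized) or \code{"transfer"} (sparse attention
#'   transfer from a teacher).
#' @param alpha nonnegative weight of the similarity term. The transfer
#'   objective carries no alpha in its printed form; it defaults to 1 there.
#' @param metric \code{"l2_squared"} or \code{"cosine"} (penalty
#'   \code{1 - cosine similarity}).
#' @param tap activation tap used in activation mode (default
#'   \code{"group3"}).
#' @param sparsity_percent teacher-saliency percentile kept in transfer mode.
#' @param n_random_low low-score positions per catalytic map refresh.
#' @param normalize_maps if TRUE, feature and knowledge maps are unit-
#'   normalized per sample before the l2 distance (off by default: the raw
#'   printed formula).
#' @param seed integer seed recorded with the config.
#' @return object of class \code{difi_config}.
#' @export
difi_config <- function(mode = c("gradient", "activation", "transfer"),
                        alpha = 3, metric = c("l2_squared", "cosine"),
                        tap = "group3", sparsity_percent = NULL,
                        n_random_low = NULL, normalize_maps = FALSE,
                        seed = 0L) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (alpha < 0) stop("alpha must be nonnegative")
  structure(list(mode = mode, alpha = alpha, metric = metric, tap = tap,
                 sparsity_percent = sparsity_percent,
                 n_random_low = n_random_low,
                 normalize_maps = normalize_maps, seed = as.integer(seed)),
            class = "difi_config")
}

#' @export
print.difi_config <- function(x, ...) {
  cat(sprintf("<difi_config> mode=%s alpha=%g metric=%s\n",
              x$mode, x$alpha, x$metric))
  invisible(x)
}

#' Masked distance between a feature map and a knowledge map
#'
#' \code{l2_squared}: squared euclidean distance between the masked vectors.
#' \code{cosine}: one minus the cosine similarity of the masked vectors.
#' An all-zero mask gives 0; a zero-norm masked feature vector under the
#' cosine metric is treated as distance 0 with a warning.
#'
#' @param fm numeric vector of feature weights, or a single-sample
#'   \code{feature_map}.
#' @param km a \code{knowledge_map} on the same feature axis.
#' @param metric \code{"l2_squared"} or \code{"cosine"}.
#' @return nonnegative scalar.
#' @export
masked_distance <- function(fm, km, metric = c("l2_squared", "cosine")) {
  metric <- match.arg(metric)
  w <- if (inherits(fm, "feature_map")) {
    stopifnot(nrow(fm$weights) == 1L)
    fm$weights[1L, ]
  } else as.numeric(fm)
  if (length(w) != length(km$mask))
    stop("feature map and knowledge map are on different feature axes (",
         length(w), " vs ", length(km$mask), ")")
  u <- apply_mask(w, km$mask)
  v <- masked_scores(km)
  if (all(km$mask == 0)) return(0)
  if (metric == "l2_squared") return(sum((u - v)^2))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm masked vector under cosine metric; distance set to 0")
    return(0)
  }
  1 - sum(u * v) / (nu * nv)
}

# ---- internal graph builders ------------------------------------------------

# per-sample similarity term over rows of a (B x d) feature-map node.
# kmat/tmat: B x d masked knowledge scores and masks (constants).
# Returns scalar node: mean over rows with a nonzero mask (others excluded).
.similarity_node <- function(Fnode, kmat, tmat, metric, normalize = FALSE) {
  B <- nrow(kmat)
  has_km <- rowSums(tmat) > 0
  n_eff <- sum(has_km)
  if (n_eff == 0L) return(ag_const(matrix(0, 1, 1)))
  Fm <- ag_mul(Fnode, ag_const(tmat))
  if (metric == "l2_squared") {
    if (normalize) {
      nrm <- ag_sqrt(ag_add(ag_rowsums(ag_mul(Fm, Fm)), 1e-12))
      Fm <- ag_div(Fm, ag_bcast_cols(nrm, ncol(kmat)))
      krow <- sqrt(rowSums(kmat^2)); krow[krow == 0] <- 1
      kmat <- kmat / krow
    }
    diff <- ag_sub(Fm, ag_const(kmat))
    per <- ag_rowsums(ag_mul(diff, diff))               # B x 1
  } else {
    dot <- ag_rowsums(ag_mul(Fm, ag_const(kmat)))
    nu <- ag_sqrt(ag_add(ag_rowsums(ag_mul(Fm, Fm)), 1e-12))
    nv <- sqrt(rowSums(kmat^2))
    valid <- has_km & nv > 0
    nv[!valid] <- 1
    cosim <- ag_div(dot, ag_mul(nu, ag_const(matrix(nv, B, 1))))
    per <- ag_sub(ag_const(matrix(as.numeric(valid), B, 1)),
                  ag_mul(cosim, ag_const(matrix(as.numeric(valid), B, 1))))
    n_eff <- max(sum(valid), 1L)
  }
  sel <- matrix(as.numeric(has_km), B, 1)
  ag_mul(ag_sum(ag_mul(per, ag_const(sel))), 1 / n_eff)
}

# forward + per-sample saliency as a (B x d) node kept in the graph
.saliency_node <- function(model, pn, X, rows, labels) {
  sp <- model$spec
  B <- length(rows)
  x <- .input_node(model, X, rows, requires = TRUE)
  fw <- .forward(model, pn, x, B)
  ce_sum <- ag_cross_entropy(fw$logits, labels[rows], reduce = "sum")
  J <- ag_grad(ce_sum, list(x), create_graph = TRUE)[[1]]
  d <- if (sp$family == "cnn1d_expression") sp$n_genes else sp$max_len
  Jmat <- if (sp$family == "cnn1d_expression") {
    ag_t(ag_reshape(J, c(d, B)))
  } else {
    ag_t(ag_reshape(ag_rowsums(ag_abs(J)), c(d, B)))
  }
  list(Jmat = Jmat, ce_mean = ag_mul(ce_sum, 1 / B), fw = fw, x = x)
}

# stack masked knowledge scores/masks for a batch into B x d constants
.km_matrices <- function(kms, d) {
  B <- length(kms)
  kmat <- matrix(0, B, d)
  tmat <- matrix(0, B, d)
  for (b in seq_len(B)) {
    km <- kms[[b]]
    if (is.null(km)) next
    if (length(km$mask) != d)
      stop("knowledge map axis (", length(km$mask),
           ") does not match model input axis (", d, ")")
    kmat[b, ] <- masked_scores(km)
    tmat[b, ] <- km$mask
  }
  list(kmat = kmat, tmat = tmat)
}

# ---- public loss evaluators -------------------------------------------------

#' Gradient-based DIFI loss
#'
#' Cross-entropy plus \code{alpha} times the mean masked distance between
#' each sample's saliency map and its class knowledge map. The similarity
#' term stays connected to the parameter graph, so optimizing this loss
#' updates the weights through second-order mixed partial derivatives.
#'
#' @param model a \code{difi_model}.
#' @param X batch inputs (samples x genes, or \code{encode_one_hot} result).
#' @param labels integer class labels (1-based).
#' @param kms list of \code{knowledge_map}s, one per sample (an entry may be
#'   NULL: that sample contributes only cross-entropy).
#' @param cfg a \code{difi_config} with mode \code{"gradient"}.
#' @param return_grads if TRUE, also return parameter gradients.
#' @return list with numeric \code{loss}, \code{ce}, \code{sim} and, if
#'   requested, \code{grads} (named list of arrays matching
#'   \code{model$params}).
#' @export
gradient_based_difi_loss <- function(model, X, labels, kms, cfg,
                                     return_grads = FALSE) {
  pn <- .params_as_nodes(model)
  built <- .build_gradient_loss(model, pn, X, seq_along(labels), labels,
                                kms, cfg)
  .finish_loss(built, pn, model, return_grads)
}

#' Activation-based DIFI loss
#'
#' Cross-entropy plus \code{alpha} times the mean masked distance between
#' the spatial activation map at the configured tap and each sample's
#' knowledge map. Samples without a knowledge map contribute only
#' cross-entropy.
#'
#' @inheritParams gradient_based_difi_loss
#' @param cfg a \code{difi_config} with mode \code{"activation"} (metric
#'   \code{"cosine"} reproduces the reference protocol).
#' @return as \code{\link{gradient_based_difi_loss}}.
#' @export
activation_based_difi_loss <- function(model, X, labels, kms, cfg,
                                       return_grads = FALSE) {
  pn <- .params_as_nodes(model)
  built <- .build_activation_loss(model, pn, X, seq_along(labels), labels,
                                  kms, cfg)
  .finish_loss(built, pn, model, return_grads)
}

#' Sparse attention transfer loss
#'
#' Student cross-entropy plus the squared distance between student and
#' teacher saliency maps restricted to each sample's top-percentile teacher
#' saliency values. With \code{sparsity_percent = 100} this is full
#' attention transfer.
#'
#' @param student,teacher \code{difi_model}s on the same input axis; the
#'   teacher is treated as frozen.
#' @param X,labels batch.
#' @param sparsity_percent percentage of teacher saliency entries kept.
#' @param alpha weight of the transfer term (printed form: 1).
#' @param return_grads if TRUE, also return student parameter gradients.
#' @return as \code{\link{gradient_based_difi_loss}}.
#' @export
sparse_attention_transfer_loss <- function(student, teacher, X, labels,
                                           sparsity_percent = 10,
                                           alpha = 1, return_grads = FALSE) {
  ds <- if (student$spec$family == "cnn1d_expression")
    student$spec$n_genes else student$spec$max_len
  dt <- if (teacher$spec$family == "cnn1d_expression")
    teacher$spec$n_genes else teacher$spec$max_len
  if (ds != dt) stop("student and teacher input axes differ")
  pn <- .params_as_nodes(student)
  built <- .build_transfer_loss(student, pn, teacher, X, seq_along(labels),
                                labels, sparsity_percent, alpha)
  .finish_loss(built, pn, student, return_grads)
}

.finish_loss <- function(built, pn, model, return_grads) {
  out <- list(loss = as.vector(ag_value(built$loss)),
              ce = as.vector(ag_value(built$ce)),
              sim = as.vector(ag_value(built$sim)))
  if (return_grads) {
    gs <- ag_grad(built$loss, pn)
    out$grads <- stats::setNames(lapply(gs, ag_value), names(model$params))
  }
  out
}

# builders shared with the training loop ------------------------------------

# plain supervised cross-entropy (the alpha = 0 path of every objective:
# no saliency graph is built, so training is exactly the baseline)
.build_ce_only <- function(model, pn, X, rows, labels) {
  B <- length(rows)
  x <- .input_node(model, X, rows)
  fw <- .forward(model, pn, x, B)
  ce <- ag_cross_entropy(fw$logits, labels[rows], reduce = "mean")
  list(loss = ce, ce = ce, sim = ag_const(matrix(0, 1, 1)))
}

.build_gradient_loss <- function(model, pn, X, rows, labels, kms, cfg) {
  if (cfg$alpha == 0) return(.build_ce_only(model, pn, X, rows, labels))
  sal <- .saliency_node(model, pn, X, rows, labels)
  d <- ncol(ag_value(sal$Jmat))
  kmt <- .km_matrices(kms[rows], d)
  sim <- .similarity_node(sal$Jmat, kmt$kmat, kmt$tmat, cfg$metric,
                          cfg$normalize_maps)
  list(loss = ag_add(sal$ce_mean, ag_mul(sim, cfg$alpha)),
       ce = sal$ce_mean, sim = sim)
}

.build_activation_loss <- function(model, pn, X, rows, labels, kms, cfg) {
  B <- length(rows)
  x <- .input_node(model, X, rows)
  fw <- .forward(model, pn, x, B)
  ce <- ag_cross_entropy(fw$logits, labels[rows], reduce = "mean")
  if (cfg$alpha == 0)
    return(list(loss = ce, ce = ce, sim = ag_const(matrix(0, 1, 1))))
  if (!cfg$tap %in% names(fw$taps))
    stop("model does not expose tap '", cfg$tap, "'")
  d <- model$spec$max_len
  Q <- .activation_map_node(fw$taps[[cfg$tap]], B, d)
  kmt <- .km_matrices(kms[rows], d)
  sim <- .similarity_node(Q, kmt$kmat, kmt$tmat, cfg$metric,
                          cfg$normalize_maps)
  list(loss = ag_add(ce, ag_mul(sim, cfg$alpha)), ce = ce, sim = sim)
}

.build_transfer_loss <- function(student, pn, teacher, X, rows, labels,
                                 sparsity_percent, alpha = 1) {
  if (is.null(sparsity_percent) || alpha == 0 || is.null(teacher))
    return(.build_ce_only(student, pn, X, rows, labels))
  sal <- .saliency_node(student, pn, X, rows, labels)
  JT <- saliency_map(teacher, .subset_input(teacher, X, rows),
                     labels[rows])$weights
  tmat <- .top_percentile_masks(JT, sparsity_percent)
  diff <- ag_mul(ag_sub(sal$Jmat, ag_const(JT)), ag_const(tmat))
  sim <- ag_mean(ag_rowsums(ag_mul(diff, diff)))
  list(loss = ag_add(sal$ce_mean, ag_mul(sim, alpha)),
       ce = sal$ce_mean, sim = sim)
}
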
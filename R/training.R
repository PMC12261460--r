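# Seeded training: stratified splits, Adam, per-epoch knowledge-map
# refresh, model selection by validation error, and grid search.
#
# Reproducibility contract: every source of randomness inside a run is
# re-seeded from the run seed at a fixed point (initialization by the
# caller, shuffling and map refresh per epoch on separate derived seeds),
# so an alpha = 0 run is bit-identical to the plain supervised baseline
# under the same seed, whether or not knowledge maps are attached.

#' Stratified 72/18/10 split
#'
#' Splits sample indices into training (72 percent), validation (18
#' percent) and test (10 percent) of the whole, stratified by class: within
#' each class 10 percent is held out for test and 20 percent of the
#' remainder forms the validation set.
#'
#' @param labels class label vector, one entry per sample.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list of integer index vectors \code{train}, \code{validation},
#'   \code{test} (disjoint, union = all samples).
#' @export
split_dataset <- function(labels, seed = 1L) {
  set.seed(seed)
  tr <- integer(0); va <- integer(0); te <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 10L)
      stop("class '", cl, "' has fewer than 10 samples; cannot stratify")
    idx <- sample(idx)
    n <- length(idx)
    n_te <- round(0.10 * n)
    n_va <- round(0.20 * (n - n_te))
    te <- c(te, idx[seq_len(n_te)])
    va <- c(va, idx[n_te + seq_len(n_va)])
    tr <- c(tr, idx[(n_te + n_va + 1L):n])
  }
  list(train = sort(tr), validation = sort(va), test = sort(te))
}

# expand a per-class knowledge-map list into a per-sample list
#' Attach class knowledge maps to samples
#' @param km_by_class list of \code{knowledge_map}s indexed by class.
#' @param labels integer class labels.
#' @return list of knowledge maps, one per sample.
#' @export
kms_for_labels <- function(km_by_class, labels) {
  lapply(labels, function(k) {
    if (k <= length(km_by_class)) km_by_class[[k]] else NULL
  })
}

.adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))),
       t = 0L)
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

.batch_rows <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Train a classifier with a DIFI objective
#'
#' Runs Adam over mini-batches of the chosen objective. Catalytic knowledge
#' maps are re-randomized at the start of every epoch (fixed score-1 sites,
#' fresh low-score support) so unlabeled residues are screened across
#' epochs. Both loss components and the validation error are logged per
#' epoch, and the returned model carries the parameters with the best
#' validation error.
#'
#' @param model an initialized \code{difi_model}.
#' @param X training inputs (samples x genes matrix, or
#'   \code{\link{encode_one_hot}} result).
#' @param labels integer class labels (1-based).
#' @param cfg a \code{difi_config}; \code{cfg$alpha = 0} (or a NULL
#'   \code{sparsity_percent} in transfer mode) trains the plain baseline.
#' @param kms per-sample list of knowledge maps (see
#'   \code{\link{kms_for_labels}}); may be NULL for baselines.
#' @param teacher frozen teacher model (transfer mode only).
#' @param epochs,batch_size,lr optimizer settings (defaults: batch 128,
#'   Adam 1e-3).
#' @param seed run seed controlling shuffling and map refresh.
#' @param val_X,val_labels optional validation split for model selection;
#'   without one the final parameters are kept.
#' @param verbose print per-epoch progress.
#' @return object of class \code{difi_run}: \code{model} (best
#'   parameters), \code{final_model}, \code{history} (per-epoch data.frame
#'   with \code{loss}, \code{ce}, \code{sim}, \code{val_error}),
#'   \code{cfg}, \code{seed}.
#' @export
difi_train <- function(model, X, labels, cfg, kms = NULL, teacher = NULL,
                       epochs = 10L, batch_size = 128L, lr = 1e-3,
                       seed = 1L, val_X = NULL, val_labels = NULL,
                       verbose = FALSE) {
  n <- length(labels)
  st <- .adam_state(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        ce = numeric(0), sim = numeric(0),
                        val_error = numeric(0))
  best_err <- Inf
  best_params <- model$params
  refresh <- !is.null(kms) && cfg$alpha > 0 &&
    any(vapply(kms, function(k) !is.null(k) && k$provenance == "catalytic",
               logical(1)))
  for (ep in seq_len(epochs)) {
    if (refresh) {
      set.seed((seed + 104729L * ep) %% .Machine$integer.max)
      kms <- lapply(kms, function(k) {
        if (!is.null(k) && k$provenance == "catalytic")
          rerandomize_low_scores(k) else k
      })
    }
    set.seed((seed + 7919L * ep) %% .Machine$integer.max)
    perm <- sample(n)
    ep_loss <- ep_ce <- ep_sim <- 0
    nb <- 0L
    for (rows in .batch_rows(n, batch_size)) {
      br <- perm[rows]
      pn <- lapply(model$params, ag_leaf)
      built <- switch(cfg$mode,
        gradient = .build_gradient_loss(model, pn, X, br, labels, kms, cfg),
        activation = .build_activation_loss(model, pn, X, br, labels, kms,
                                            cfg),
        transfer = .build_transfer_loss(model, pn, teacher, X, br, labels,
                                        cfg$sparsity_percent, cfg$alpha))
      lv <- as.vector(ag_value(built$loss))
      if (!is.finite(lv))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", batch ", nb + 1L, "; ce=", ag_value(built$ce),
             " sim=", ag_value(built$sim))
      gs <- ag_grad(built$loss, pn)
      grads <- stats::setNames(lapply(gs, ag_value), names(model$params))
      upd <- .adam_step(model$params, grads, st, lr)
      model$params <- upd$params
      st <- upd$state
      ep_loss <- ep_loss + lv
      ep_ce <- ep_ce + as.vector(ag_value(built$ce))
      ep_sim <- ep_sim + as.vector(ag_value(built$sim))
      nb <- nb + 1L
    }
    val_err <- NA_real_
    if (!is.null(val_X)) {
      val_err <- classification_error(model, val_X, val_labels)
      if (val_err <= best_err) {
        best_err <- val_err
        best_params <- model$params
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / nb,
                                ce = ep_ce / nb, sim = ep_sim / nb,
                                val_error = val_err))
    if (verbose)
      message(sprintf("epoch %d: loss=%.4f ce=%.4f sim=%.4f val=%.2f%%",
                      ep, ep_loss / nb, ep_ce / nb, ep_sim / nb, val_err))
  }
  final_model <- model
  if (!is.null(val_X)) model$params <- best_params
  structure(list(model = model, final_model = final_model,
                 history = history, cfg = cfg, seed = seed),
            class = "difi_run")
}

#' @export
print.difi_run <- function(x, ...) {
  cat(sprintf("<difi_run> mode=%s alpha=%g, %d epochs, final loss %.4f\n",
              x$cfg$mode, x$cfg$alpha, nrow(x$history),
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Exhaustive grid search over a parameter space
#'
#' Evaluates \code{train_fn} on every combination of the declared parameter
#' values and returns the configuration with the lowest validation error.
#' Ties are broken in favor of the smaller \code{alpha} (combinations are
#' visited in increasing alpha order).
#'
#' @param space named list of parameter value vectors, e.g.
#'   \code{list(alpha = c(0.3, 1, 3, 10), n_random_low = c(3, 30, 60, 100))}.
#' @param train_fn function taking a named list of parameters and a seed,
#'   returning a validation error (percent).
#' @param seed base seed; combination i is evaluated under \code{seed + i}.
#' @return list with \code{best} (named list of winning parameters),
#'   \code{table} (data.frame of all combinations and their errors).
#' @export
grid_search <- function(space, train_fn, seed = 1L) {
  if (!length(space)) stop("empty search space")
  tab <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  if ("alpha" %in% names(tab)) tab <- tab[order(tab$alpha), , drop = FALSE]
  rownames(tab) <- NULL
  errs <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    params <- as.list(tab[i, , drop = FALSE])
    errs[i] <- train_fn(params, seed + i)
  }
  tab$val_error <- errs
  list(best = as.list(tab[which.min(errs), setdiff(names(tab), "val_error"),
                          drop = FALSE]),
       table = tab)
}
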
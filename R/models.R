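# Reference classifier families. Parameters are plain R arrays; every
# forward pass builds an autodiff graph so input gradients (saliency) and
# higher-order parameter gradients are available for any family.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' One-hot encode protein sequences
#'
#' Each residue becomes a one-hot column over the 20 standard amino acids;
#' positions beyond the sequence end are all-zero (padding). Sequences
#' longer than \code{max_len} keep their N-terminal prefix.
#'
#' @param sequences character vector of residue strings (case-insensitive).
#' @param max_len maximum model length (default 300).
#' @return list with \code{x}: a \code{(n*max_len) x 20} matrix whose rows
#'   are ordered position-within-sequence fastest; \code{lengths}: encoded
#'   (possibly truncated) sequence lengths; \code{max_len}.
#' @export
encode_one_hot <- function(sequences, max_len = 300L) {
  sequences <- toupper(sequences)
  n <- length(sequences)
  x <- matrix(0, n * max_len, length(AA_ALPHABET))
  lens <- integer(n)
  for (i in seq_len(n)) {
    ch <- strsplit(sequences[i], "")[[1]]
    if (length(ch) > max_len) ch <- ch[seq_len(max_len)]
    aa <- match(ch, AA_ALPHABET)
    if (anyNA(aa)) {
      bad <- which(is.na(aa))[1]
      stop("illegal residue symbol '", ch[bad], "' at position ", bad,
           " of sequence ", i)
    }
    lens[i] <- length(ch)
    rows <- (i - 1L) * max_len + seq_along(ch)
    x[cbind(rows, aa)] <- 1
  }
  list(x = x, lengths = lens, max_len = as.integer(max_len))
}

#' Decode one-hot encoded sequences
#' @param enc result of \code{\link{encode_one_hot}}.
#' @return character vector of sequences.
#' @export
decode_one_hot <- function(enc) {
  n <- length(enc$lengths)
  out <- character(n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * enc$max_len + seq_len(enc$lengths[i])
    aa <- max.col(enc$x[rows, , drop = FALSE])
    out[i] <- paste(AA_ALPHABET[aa], collapse = "")
  }
  out
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# output layers start near zero so the softmax is unsaturated at init
.out_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.01), nr, nc)

#' Shallow 1-D CNN for expression vectors
#'
#' One-dimensional kernels over the gene axis, max pooling over the
#' (position x channel) plane of the conv output, then a fully connected
#' prediction layer. The teacher preset is wider than the student, so the
#' teacher always has more parameters. Draws initial weights from the
#' current RNG state; seed before calling for reproducibility.
#'
#' @param n_genes input length.
#' @param n_classes number of classes (>= 2).
#' @param size_preset \code{"teacher"} (64 filters) or \code{"student"}
#'   (16 filters).
#' @param center optional per-gene centering vector (typically training-set
#'   column means), applied as a fixed preprocessing layer inside the
#'   model graph; constant shifts leave input gradients unchanged.
#' @param input_scale fixed scalar applied after centering.
#' @return an object of class \code{difi_model}, family
#'   \code{"cnn1d_expression"}.
#' @export
make_expression_cnn <- function(n_genes, n_classes,
                                size_preset = c("student", "teacher"),
                                center = NULL, input_scale = 1) {
  size_preset <- match.arg(size_preset)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (!is.null(center) && length(center) != n_genes)
    stop("center must have one entry per gene")
  filters <- if (size_preset == "teacher") 64L else 16L
  k <- 9L; stride <- 2L; pool_l <- 4L; pool_c <- 2L
  Lc <- ceiling(n_genes / stride)
  n_flat <- (Lc %/% pool_l) * (filters %/% pool_c)
  params <- list(
    Wc = .he_init(k, filters, k),
    bc = matrix(0, 1, filters),
    Wf = .out_init(n_flat, n_classes),
    bf = matrix(0, 1, n_classes)
  )
  spec <- list(family = "cnn1d_expression", n_genes = n_genes,
               n_classes = n_classes, size_preset = size_preset,
               filters = filters, k = k, stride = stride,
               pool_l = pool_l, pool_c = pool_c, n_flat = n_flat,
               center = center, input_scale = input_scale,
               taps = character(0))
  structure(list(spec = spec, params = params), class = "difi_model")
}

#' Residual 1-D CNN for one-hot protein sequences
#'
#' Four groups of convolutional layers, two residual blocks per group, with
#' skip connections bypassing two convolutions each; groups 2-4 halve the
#' spatial resolution. Activation tensors can be tapped after groups 3 and
#' 4. Head: global average pooling and a fully connected layer over
#' \{enzyme, non-enzyme\} (or any \code{n_classes}).
#'
#' @param max_len input length after padding/truncation (<= 300).
#' @param n_classes number of classes.
#' @param widths channel widths of the four groups.
#' @param head global pooling flavor of the classification head.
#' @return an object of class \code{difi_model}, family
#'   \code{"resnet_sequence"} exposing taps \code{"group3"}, \code{"group4"}.
#' @export
make_sequence_resnet <- function(max_len, n_classes = 2L,
                                 widths = c(8L, 12L, 16L, 16L),
                                 head = c("max", "avg")) {
  head <- match.arg(head)
  stopifnot(length(widths) == 4, max_len <= 300)
  A <- length(AA_ALPHABET)
  params <- list(
    Wstem = .he_init(5L * A, widths[1], 5L * A),
    bstem = matrix(0, 1, widths[1])
  )
  cin <- widths[1]
  for (g in 1:4) {
    cout <- widths[g]
    stride1 <- if (g == 1) 1L else 2L
    for (blk in 1:2) {
      s <- if (blk == 1) stride1 else 1L
      cb <- if (blk == 1) cin else cout
      pre <- sprintf("g%db%d", g, blk)
      params[[paste0(pre, "_W1")]] <- .he_init(3L * cb, cout, 3L * cb)
      params[[paste0(pre, "_b1")]] <- matrix(0, 1, cout)
      params[[paste0(pre, "_W2")]] <- .he_init(3L * cout, cout, 3L * cout)
      params[[paste0(pre, "_b2")]] <- matrix(0, 1, cout)
      if (blk == 1 && (s != 1L || cb != cout)) {
        params[[paste0(pre, "_Wp")]] <- .he_init(cb, cout, cb)
        params[[paste0(pre, "_bp")]] <- matrix(0, 1, cout)
      }
    }
    cin <- cout
  }
  params$Wf <- .out_init(widths[4], n_classes)
  params$bf <- matrix(0, 1, n_classes)
  spec <- list(family = "resnet_sequence", max_len = as.integer(max_len),
               n_classes = n_classes, widths = widths, head = head,
               taps = c("group3", "group4"))
  structure(list(spec = spec, params = params), class = "difi_model")
}

#' @export
print.difi_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<difi_model> family=%s, %d parameters\n", x$spec$family, np))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a \code{difi_model}.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# wrap current parameter arrays as graph leaves
.params_as_nodes <- function(model) lapply(model$params, ag_leaf)

# Forward pass. x_node: graph node holding the encoded input
#   cnn1d_expression: (B*G) x 1, rows ordered gene-within-sample fastest
#   resnet_sequence:  (B*L) x 20, rows ordered position-within-sequence
# Returns list(logits = node (B x C), taps = named list of
#   list(node, L, channels)).
.forward <- function(model, pn, x_node, B) {
  sp <- model$spec
  if (sp$family == "cnn1d_expression") {
    # fixed preprocessing layer inside the graph: centering leaves input
    # gradients untouched; a scale multiplies them by a known constant
    if (!is.null(sp$center))
      x_node <- ag_sub(x_node,
                       ag_const(matrix(rep(sp$center, B), ncol = 1L)))
    if (!identical(sp$input_scale, 1))
      x_node <- ag_mul(x_node, sp$input_scale)
    cv <- ag_conv1d(x_node, pn$Wc, pn$bc, B, sp$n_genes, sp$k, sp$stride)
    h <- ag_relu(cv$out)
    mp <- ag_maxpool2d(h, B, cv$L, sp$pool_l, sp$pool_c)
    fl <- ag_pool_flatten(mp$out, B, mp$n_flat)
    logits <- ag_add_bias(ag_mm(fl, pn$Wf), pn$bf)
    return(list(logits = logits, taps = list()))
  }
  if (sp$family == "resnet_sequence") {
    L <- sp$max_len
    cv <- ag_conv1d(x_node, pn$Wstem, pn$bstem, B, L, 5L, 1L)
    h <- ag_relu(cv$out); L <- cv$L
    taps <- list()
    for (g in 1:4) {
      stride1 <- if (g == 1) 1L else 2L
      for (blk in 1:2) {
        s <- if (blk == 1) stride1 else 1L
        pre <- sprintf("g%db%d", g, blk)
        c1 <- ag_conv1d(h, pn[[paste0(pre, "_W1")]], pn[[paste0(pre, "_b1")]],
                        B, L, 3L, s)
        a1 <- ag_relu(c1$out)
        c2 <- ag_conv1d(a1, pn[[paste0(pre, "_W2")]], pn[[paste0(pre, "_b2")]],
                        B, c1$L, 3L, 1L)
        skip <- if (!is.null(pn[[paste0(pre, "_Wp")]])) {
          ag_conv1d(h, pn[[paste0(pre, "_Wp")]], pn[[paste0(pre, "_bp")]],
                    B, L, 1L, s)$out
        } else h
        h <- ag_relu(ag_add(c2$out, skip))
        L <- c1$L
      }
      if (g >= 3) {
        taps[[paste0("group", g)]] <-
          list(node = h, L = L, channels = sp$widths[g])
      }
    }
    pooled <- if (identical(sp$head, "avg")) ag_global_avgpool(h, B, L)
      else ag_global_maxpool(h, B, L)
    logits <- ag_add_bias(ag_mm(pooled, pn$Wf), pn$bf)
    return(list(logits = logits, taps = taps))
  }
  stop("unknown model family: ", sp$family)
}

# encode a batch for the model input axis; X is samples x genes (expression)
# or an encode_one_hot() result (sequence)
.input_node <- function(model, X, rows, requires = FALSE) {
  sp <- model$spec
  if (sp$family == "cnn1d_expression") {
    v <- matrix(as.vector(t(X[rows, , drop = FALSE])), ncol = 1L)
  } else {
    L <- sp$max_len
    take <- as.vector(vapply(rows, function(i) (i - 1L) * L + seq_len(L),
                             integer(L)))
    v <- X$x[take, , drop = FALSE]
  }
  if (requires) ag_leaf(v) else ag_const(v)
}

#' Subset model inputs to selected samples
#'
#' Works for both input containers: plain samples x genes matrices and
#' \code{\link{encode_one_hot}} results.
#'
#' @param model the \code{difi_model} the input feeds (determines the
#'   container convention).
#' @param X inputs.
#' @param rows integer sample indices.
#' @return the same container type restricted to \code{rows}.
#' @export
subset_input <- function(model, X, rows) {
  if (model$spec$family == "cnn1d_expression") return(X[rows, , drop = FALSE])
  L <- X$max_len
  take <- as.vector(vapply(rows, function(i) (i - 1L) * L + seq_len(L),
                           integer(L)))
  list(x = X$x[take, , drop = FALSE], lengths = X$lengths[rows], max_len = L)
}

.subset_input <- subset_input

#' Predict class logits
#'
#' @param object a \code{difi_model}.
#' @param newdata samples x genes matrix (expression family) or an
#'   \code{\link{encode_one_hot}} result (sequence family).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return matrix of logits, samples x classes.
#' @export
predict.difi_model <- function(object, newdata, batch_size = 256L, ...) {
  sp <- object$spec
  n <- if (sp$family == "cnn1d_expression") nrow(newdata) else
    length(newdata$lengths)
  pn <- .params_as_nodes(object)
  out <- matrix(NA_real_, n, sp$n_classes)
  i <- 1L
  while (i <= n) {
    rows <- i:min(i + batch_size - 1L, n)
    xb <- .input_node(object, newdata, rows)
    fw <- .forward(object, pn, xb, length(rows))
    out[rows, ] <- ag_value(fw$logits)
    i <- i + length(rows)
  }
  out
}

#' Predicted class labels
#' @inheritParams predict.difi_model
#' @param model a \code{difi_model}.
#' @return integer vector of class indices (1-based).
#' @export
predict_class <- function(model, newdata, batch_size = 256L) {
  max.col(predict(model, newdata, batch_size), ties.method = "first")
}
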
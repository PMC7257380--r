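#' Numerically stable softmax
#'
#' Converts a vector of scores (or each row of a matrix of scores) into a
#' probability distribution `exp(g_i) / sum_k exp(g_k)`, using the max-shift
#' trick so arbitrarily large magnitudes cannot overflow.
#'
#' @param logits Numeric vector or matrix (rows = samples).
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    if (any(!is.finite(logits))) stopf("softmax requires finite logits")
    z <- logits - max(logits)
    e <- exp(z)
    e / sum(e)
  }
}

#' Fully connected classification head
#'
#' Two hidden layers (1024 and 512 units, ReLU), each followed by dropout 0.5,
#' then a linear output layer over the four epileptic states. Emits logits;
#' apply [softmax()] for probabilities.
#'
#' @param in_dim Input feature dimension (5632 for the full ensemble).
#' @param fc1_width,fc2_width Hidden widths (defaults 1024, 512).
#' @param dropout_p Dropout probability behind each hidden layer (default 0.5).
#' @param n_classes Number of output classes (default 4).
#' @param seed Seed for weight initialization.
#' @return An internal layer graph (class `nn_module`).
#' @export
classifier_head <- function(in_dim, fc1_width = 1024, fc2_width = 512,
                            dropout_p = 0.5, n_classes = 4, seed = 1L) {
  stopifnot(fc1_width > 0, fc2_width > 0, dropout_p >= 0, dropout_p < 1)
  with_seed(seed, nn_seq(
    nn_dense(in_dim, fc1_width), nn_relu(), nn_dropout(dropout_p),
    nn_dense(fc1_width, fc2_width), nn_relu(), nn_dropout(dropout_p),
    nn_dense(fc2_width, n_classes, sd = sqrt(1 / fc2_width))
  ))
}

#' Ensemble classifier: backbone feature extractors plus a softmax head
#'
#' @param backbones A [backbone_spec()], a list of them, or pre-built
#'   [build_backbone()] objects. Default: the single tiny test backbone. The
#'   published ensemble is
#'   `lapply(c("inception_v3","resnet152","inception_resnet_v2"), backbone_spec)`.
#' @param fc1_width,fc2_width,dropout_p Head geometry, see [classifier_head()].
#' @param n_classes Number of classes (default 4).
#' @param seed Seed for all weight initialization.
#' @return Object of class `state_classifier`.
#' @export
ensemble_classifier <- function(backbones = backbone_spec("tiny"),
                                fc1_width = 1024, fc2_width = 512,
                                dropout_p = 0.5, n_classes = 4, seed = 1L) {
  if (inherits(backbones, "backbone_spec") || inherits(backbones, "backbone"))
    backbones <- list(backbones)
  nms <- vapply(backbones, function(b)
    if (inherits(b, "backbone")) b$spec$name else b$name, "")
  backbones <- backbones[canonical_backbone_order(nms)]
  built <- lapply(seq_along(backbones), function(i) {
    b <- backbones[[i]]
    if (inherits(b, "backbone")) b else build_backbone(b, seed + i)
  })
  feature_dim <- sum(vapply(built, function(b) b$spec$feature_dim, 0))
  head <- classifier_head(feature_dim, fc1_width, fc2_width, dropout_p,
                          n_classes, seed = seed + 1000L)
  structure(list(backbones = built, head = head, feature_dim = feature_dim,
                 n_classes = n_classes, class_levels = state_labels(),
                 input_stats = NULL, seed = seed),
            class = "state_classifier")
}

#' @export
print.state_classifier <- function(x, ...) {
  nms <- vapply(x$backbones, function(b) b$spec$name, "")
  cat(sprintf("<state_classifier> backbones: %s; feature dim %d; %d classes\n",
              paste(nms, collapse = " + "), x$feature_dim, x$n_classes))
  invisible(x)
}

#' Forward pass of the classifier
#'
#' @param model A [ensemble_classifier()].
#' @param images Image batch (see [extract_features()]).
#' @param training Activate dropout (default FALSE; evaluation mode is
#'   deterministic).
#' @return N x n_classes probability matrix; rows sum to 1.
#' @export
model_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "state_classifier"))
  images <- apply_input_stats(as_image_batch(images), model$input_stats)
  feats <- extract_features(images, model$backbones)
  logits <- nn_forward(model$head, feats, training = training)$out
  softmax(logits)
}

#' Predict epileptic states for a batch of PSDED images
#'
#' @param object A trained [ensemble_classifier()].
#' @param images Image batch.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted states, or a probability matrix.
#' @export
predict.state_classifier <- function(object, images, type = c("class", "prob"),
                                     ...) {
  type <- match.arg(type)
  probs <- model_forward(object, images, training = FALSE)
  if (type == "prob") {
    colnames(probs) <- object$class_levels[seq_len(object$n_classes)]
    return(probs)
  }
  factor(object$class_levels[max.col(probs, ties.method = "first")],
         levels = object$class_levels)
}

# Dataset-level input standardization (per-pixel mean/sd over the training
# set), fitted by train_classifier() and replayed at prediction time. The
# pixel-scale contrast between the two preictal states is a few percent;
# standardizing puts it on the unit scale the random-init backbones expect.
fit_input_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  mu <- rowMeans(m)
  sdv <- sqrt(pmax(rowMeans((m - mu)^2), 0))
  list(mean = mu, sd = pmax(sdv, 1e-3), dim = d[1:3])
}

apply_input_stats <- function(x, stats) {
  if (is.null(stats)) return(x)
  d <- dim(x)
  if (!all(d[1:3] == stats$dim))
    stopf("image shape %s does not match the %s the classifier was trained on",
          paste(d[1:3], collapse = "x"), paste(stats$dim, collapse = "x"))
  array((as.vector(x) - stats$mean) / stats$sd, d)
}

#' Save / load a classifier checkpoint
#'
#' Single-file archive holding the backbone specs, all weights and the head
#' configuration.
#'
#' @param model A [ensemble_classifier()].
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_classifier()` returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "state_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "state_classifier")) stopf("not a classifier checkpoint: %s", path)
  m
}
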
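#' Per-sample cross-entropy loss and batch mean
#'
#' The binary cross-entropy form `-[y log p + (1-y) log(1-p)]` applied per
#' class against one-hot labels and summed over classes (the form paired with
#' a softmax output layer here); `loss_form = "categorical"` gives the plain
#' `-log p_true` alternative. Predictions are clipped to `[1e-12, 1 - 1e-12]`
#' for finiteness.
#'
#' @param labels One-hot matrix (N x K), or a factor over the class levels.
#' @param predictions N x K probability matrix.
#' @param loss_form `"binary_per_class"` (default) or `"categorical"`.
#' @return List with `per_sample` (length-N vector) and `batch_mean`.
#' @export
cross_entropy_batch <- function(labels, predictions,
                                loss_form = c("binary_per_class", "categorical")) {
  loss_form <- match.arg(loss_form)
  Y <- as_one_hot(labels, ncol(predictions))
  if (!all(dim(Y) == dim(predictions)))
    stopf("labels (%d x %d) and predictions (%d x %d) shapes differ",
          nrow(Y), ncol(Y), nrow(predictions), ncol(predictions))
  eps <- 1e-12
  P <- pmin(pmax(predictions, eps), 1 - eps)
  per_sample <- if (loss_form == "binary_per_class") {
    -rowSums(Y * log(P) + (1 - Y) * log(1 - P))
  } else {
    -log(P[cbind(seq_len(nrow(P)), max.col(Y, ties.method = "first"))])
  }
  list(per_sample = per_sample, batch_mean = mean(per_sample))
}

as_one_hot <- function(labels, k) {
  if (is.matrix(labels)) return(labels)
  f <- as.factor(labels)
  Y <- matrix(0, length(f), k)
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

#' Online hard example mining (OHEM) loss
#'
#' Mean of the `top_k` largest per-sample losses in a batch: training is
#' focused on the hardest (most ambiguous) examples. With `top_k = n` it
#' reduces to the plain batch mean.
#'
#' @param per_sample_losses Non-negative numeric vector.
#' @param top_k Integer, `1 <= top_k <= length(per_sample_losses)`.
#' @return Scalar loss.
#' @export
ohem_loss <- function(per_sample_losses, top_k) {
  n <- length(per_sample_losses)
  if (!(is_count(top_k) && top_k <= n))
    stopf("top_k must be an integer in [1, %d]", n)
  s <- sort(per_sample_losses, decreasing = TRUE, method = "radix")
  sum(s[seq_len(top_k)]) / top_k
}

resolve_top_k <- function(top_k, n) {
  if (is.null(top_k)) return(as.integer(ceiling(n / 2)))
  if (top_k > 0 && top_k < 1) return(max(1L, as.integer(round(top_k * n))))
  as.integer(min(top_k, n))
}

#' Stratified train/test split of labeled frames
#'
#' Per class, `floor(n_class * fraction)` frames go to the training set after
#' a seeded permutation; splits are disjoint, exhaustive and reproducible.
#'
#' @param frames List of [labeled_frame()] objects.
#' @param fraction Training fraction (default 0.7).
#' @param seed Permutation seed.
#' @param stratify Split within each class (default TRUE); requires at least
#'   one frame in every class. `FALSE` permutes globally.
#' @return List with `train` and `test` frame lists.
#' @export
split_dataset <- function(frames, fraction = 0.7, seed = 1L, stratify = TRUE) {
  idx_train <- split_indices(frame_labels(frames), fraction, seed, stratify)
  list(train = frames[idx_train],
       test = frames[setdiff(seq_along(frames), idx_train)])
}

split_indices <- function(labs, fraction, seed, stratify = TRUE) {
  stopifnot(fraction > 0, fraction < 1)
  labs <- as.factor(labs)
  idx_train <- integer(0)
  if (stratify) {
    counts <- table(labs)
    if (any(counts == 0))
      stopf("stratified split needs >= 1 frame per class; missing: %s",
            paste(names(counts)[counts == 0], collapse = ", "))
    with_seed(seed, for (lv in levels(labs)) {
      ids <- which(labs == lv)
      ids <- ids[sample.int(length(ids))]
      idx_train <- c(idx_train, ids[seq_len(floor(length(ids) * fraction))])
    })
  } else {
    idx_train <- with_seed(seed, sample.int(length(labs)))[
      seq_len(floor(length(labs) * fraction))]
  }
  sort(idx_train)
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 32).
#' @param loss `"cross_entropy"` or `"ohem"`.
#' @param ohem_top_k Count (or fraction of the batch) of hardest samples kept
#'   by the OHEM loss; default `ceiling(batch_size / 2)`.
#' @param transfer_mode `"freeze_backbone"` (train the head on frozen
#'   features) or `"finetune_all"` (backpropagate through everything).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 30).
#' @param seed Seed controlling shuffling, dropout and any weight init.
#' @param split_fraction Training fraction used by callers that split (0.7).
#' @param loss_form See [cross_entropy_batch()].
#' @param grad_clip Global gradient-norm ceiling (default 5; guards the
#'   `1/(p(1-p))` factor of the binary loss form near saturation).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, loss = c("cross_entropy", "ohem"),
                         ohem_top_k = NULL,
                         transfer_mode = c("freeze_backbone", "finetune_all"),
                         lr = 1e-4, epochs = 30, seed = 1L,
                         split_fraction = 0.7,
                         loss_form = c("binary_per_class", "categorical"),
                         grad_clip = 5) {
  loss <- match.arg(loss)
  transfer_mode <- match.arg(transfer_mode)
  loss_form <- match.arg(loss_form)
  stopifnot(batch_size >= 1, lr > 0, epochs >= 1,
            split_fraction > 0, split_fraction < 1)
  if (!is.null(ohem_top_k) && ohem_top_k >= 1 && ohem_top_k > batch_size)
    stopf("ohem_top_k must be <= batch_size")
  structure(list(batch_size = as.integer(batch_size), loss = loss,
                 ohem_top_k = ohem_top_k, transfer_mode = transfer_mode,
                 lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
                 split_fraction = split_fraction, loss_form = loss_form,
                 grad_clip = grad_clip),
            class = "train_config")
}

# gradient of the selected-and-averaged loss w.r.t. the logits
loss_logit_grad <- function(probs, Y, weights, loss_form) {
  eps <- 1e-12
  P <- pmin(pmax(probs, eps), 1 - eps)
  if (loss_form == "categorical") {
    return((P - Y) * weights)
  }
  dP <- weights * (P - Y) / (P * (1 - P))
  inner <- rowSums(dP * P)
  P * (dP - inner)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, ceiling_norm) {
  if (is.null(ceiling_norm) || !is.finite(ceiling_norm)) return(grads)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (gn > ceiling_norm) grads <- lapply(grads, function(g) g * ceiling_norm / gn)
  grads
}

#' Train a classifier on labeled PSDED images
#'
#' Adam optimization of the cross-entropy or OHEM loss. In
#' `"freeze_backbone"` mode the backbone feature extractors run once in
#' evaluation mode and only the head is updated (backbone parameters are
#' bit-identical before and after); `"finetune_all"` backpropagates through
#' the backbones as well. Fully deterministic given `config$seed`.
#'
#' @param model A [ensemble_classifier()].
#' @param images Image batch accepted by [extract_features()].
#' @param labels Factor (or character) over the model's class levels.
#' @param config A [train_config()].
#' @return List with `model` (trained) and `history` (data frame of per-batch
#'   epoch, batch, loss).
#' @export
train_classifier <- function(model, images, labels, config = train_config()) {
  stopifnot(inherits(model, "state_classifier"),
            inherits(config, "train_config"))
  x <- as_image_batch(images)
  # dataset-level standardization for random-init backbones (pretrained ones
  # use their own pretraining-corpus normalization instead)
  if (all(vapply(model$backbones, function(b)
    b$spec$weights_init == "random", TRUE))) {
    model$input_stats <- fit_input_stats(x)
    x <- apply_input_stats(x, model$input_stats)
  }
  labels <- factor(as.character(labels), levels = model$class_levels)
  N <- dim(x)[4]
  if (N == 0 || length(labels) != N)
    stopf("need one label per image (%d images, %d labels)", N, length(labels))
  Y <- as_one_hot(labels, model$n_classes)
  finetune <- config$transfer_mode == "finetune_all"

  if (!finetune) {
    feats <- extract_features(x, model$backbones)
  } else {
    resized <- lapply(model$backbones, function(b) {
      xi <- resize_images(x, b$spec$input_size)
      if (b$spec$weights_init == "pretrained") xi <- imagenet_normalize(xi)
      xi
    })
    dims <- vapply(model$backbones, function(b) b$spec$feature_dim, 0)
  }

  history <- data.frame(epoch = integer(0), batch = integer(0),
                        loss = numeric(0))
  opt <- list(t = 0, m = list(), v = list())

  run <- function() {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(N)
      starts <- seq(1, N, by = config$batch_size)
      for (bi in seq_along(starts)) {
        sel <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1, N)]
        if (finetune) {
          fwd_bb <- lapply(seq_along(model$backbones), function(i) {
            nn_forward(model$backbones[[i]]$net,
                       resized[[i]][, , , sel, drop = FALSE],
                       training = TRUE, keep_cache = TRUE)
          })
          fb <- do.call(cbind, lapply(fwd_bb, `[[`, "out"))
        } else {
          fb <- feats[sel, , drop = FALSE]
        }
        fwd_head <- nn_forward(model$head, fb, training = TRUE,
                               keep_cache = TRUE)
        probs <- softmax(fwd_head$out)
        ce <- cross_entropy_batch(Y[sel, , drop = FALSE], probs,
                                  config$loss_form)
        k <- length(sel)
        if (config$loss == "ohem") {
          k <- resolve_top_k(config$ohem_top_k, length(sel))
          loss <- ohem_loss(ce$per_sample, k)
          thresh <- sort(ce$per_sample, decreasing = TRUE)[k]
          chosen <- which(ce$per_sample >= thresh)[seq_len(k)]
        } else {
          loss <- ce$batch_mean
          chosen <- seq_along(sel)
        }
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d batch %d",
                epoch, bi)
        history[nrow(history) + 1L, ] <<- list(epoch, bi, loss)

        w <- numeric(length(sel))
        w[chosen] <- 1 / length(chosen)
        dlogits <- loss_logit_grad(probs, Y[sel, , drop = FALSE], w,
                                   config$loss_form)
        bwd_head <- nn_backward(model$head, fwd_head$cache, dlogits,
                                prefix = "head.")
        grads <- bwd_head$grads
        if (finetune) {
          at <- 0
          for (i in seq_along(model$backbones)) {
            dfi <- bwd_head$dx[, at + seq_len(dims[i]), drop = FALSE]
            at <- at + dims[i]
            bwd <- nn_backward(model$backbones[[i]]$net, fwd_bb[[i]]$cache,
                               dfi, prefix = sprintf("bb%d.", i))
            grads <- c(grads, bwd$grads)
            model$backbones[[i]]$net <<- nn_update_bn_stats(
              model$backbones[[i]]$net, fwd_bb[[i]]$cache)
          }
        }
        grads <- clip_grads(grads, config$grad_clip)

        params <- nn_collect_params(model$head, "head.")
        if (finetune)
          for (i in seq_along(model$backbones))
            params <- c(params,
                        nn_collect_params(model$backbones[[i]]$net,
                                          sprintf("bb%d.", i)))
        st <- adam_step(params, grads, opt, config$lr)
        opt <<- st$state
        model$head <<- nn_set_params(model$head, st$params, "head.")
        if (finetune)
          for (i in seq_along(model$backbones))
            model$backbones[[i]]$net <<- nn_set_params(
              model$backbones[[i]]$net, st$params, sprintf("bb%d.", i))
      }
    }
  }
  with_seed(config$seed, run())
  list(model = model, history = history)
}
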
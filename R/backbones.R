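# Feature-extractor backbones. The three published architectures are
# instantiated up to their global-average-pooling layer (classification heads
# removed), which fixes their output dimensions at 2048 (Inception-v3),
# 2048 (ResNet152) and 1536 (Inception-ResNet-v2). A compact "tiny" backbone
# (3 conv blocks) is provided as a CPU-scale test surrogate; it is not part of
# the published ensemble.

conv_bn <- function(in_ch, out_ch, kh, kw = kh, stride = 1, pad = 0) {
  nn_seq(nn_conv(in_ch, out_ch, kh, kw, stride, pad, bias = FALSE),
         nn_bn(out_ch), nn_relu())
}

inception_a <- function(in_ch, pool_ch) {
  nn_par(list(
    conv_bn(in_ch, 64, 1),
    nn_seq(conv_bn(in_ch, 48, 1), conv_bn(48, 64, 5, pad = 2)),
    nn_seq(conv_bn(in_ch, 64, 1), conv_bn(64, 96, 3, pad = 1),
           conv_bn(96, 96, 3, pad = 1)),
    nn_seq(nn_avgpool(3, stride = 1, pad = 1), conv_bn(in_ch, pool_ch, 1))
  ), "concat")
}

inception_b <- function(in_ch) {
  nn_par(list(
    conv_bn(in_ch, 384, 3, stride = 2),
    nn_seq(conv_bn(in_ch, 64, 1), conv_bn(64, 96, 3, pad = 1),
           conv_bn(96, 96, 3, stride = 2)),
    nn_maxpool(3, stride = 2)
  ), "concat")
}

inception_c <- function(in_ch, c7) {
  pad17 <- c(0, 0, 3, 3)  # 1x7 kernel
  pad71 <- c(3, 3, 0, 0)  # 7x1 kernel
  nn_par(list(
    conv_bn(in_ch, 192, 1),
    nn_seq(conv_bn(in_ch, c7, 1), conv_bn(c7, c7, 1, 7, pad = pad17),
           conv_bn(c7, 192, 7, 1, pad = pad71)),
    nn_seq(conv_bn(in_ch, c7, 1), conv_bn(c7, c7, 7, 1, pad = pad71),
           conv_bn(c7, c7, 1, 7, pad = pad17),
           conv_bn(c7, c7, 7, 1, pad = pad71),
           conv_bn(c7, 192, 1, 7, pad = pad17)),
    nn_seq(nn_avgpool(3, stride = 1, pad = 1), conv_bn(in_ch, 192, 1))
  ), "concat")
}

inception_d <- function(in_ch) {
  nn_par(list(
    nn_seq(conv_bn(in_ch, 192, 1), conv_bn(192, 320, 3, stride = 2)),
    nn_seq(conv_bn(in_ch, 192, 1),
           conv_bn(192, 192, 1, 7, pad = c(0, 0, 3, 3)),
           conv_bn(192, 192, 7, 1, pad = c(3, 3, 0, 0)),
           conv_bn(192, 192, 3, stride = 2)),
    nn_maxpool(3, stride = 2)
  ), "concat")
}

inception_e <- function(in_ch) {
  split13 <- function(ch) {
    nn_par(list(conv_bn(ch, 384, 1, 3, pad = c(0, 0, 1, 1)),
                conv_bn(ch, 384, 3, 1, pad = c(1, 1, 0, 0))), "concat")
  }
  nn_par(list(
    conv_bn(in_ch, 320, 1),
    nn_seq(conv_bn(in_ch, 384, 1), split13(384)),
    nn_seq(conv_bn(in_ch, 448, 1), conv_bn(448, 384, 3, pad = 1),
           split13(384)),
    nn_seq(nn_avgpool(3, stride = 1, pad = 1), conv_bn(in_ch, 192, 1))
  ), "concat")
}

build_inception_v3 <- function() {
  nn_seq(
    conv_bn(3, 32, 3, stride = 2), conv_bn(32, 32, 3),
    conv_bn(32, 64, 3, pad = 1), nn_maxpool(3, stride = 2),
    conv_bn(64, 80, 1), conv_bn(80, 192, 3), nn_maxpool(3, stride = 2),
    inception_a(192, 32), inception_a(256, 64), inception_a(288, 64),
    inception_b(288),
    inception_c(768, 128), inception_c(768, 160), inception_c(768, 160),
    inception_c(768, 192),
    inception_d(768),
    inception_e(1280), inception_e(2048),
    nn_gap()
  )
}

res_bottleneck <- function(in_ch, mid, out_ch, stride = 1) {
  main <- nn_seq(
    conv_bn(in_ch, mid, 1),
    conv_bn(mid, mid, 3, stride = stride, pad = 1),
    nn_conv(mid, out_ch, 1, bias = FALSE), nn_bn(out_ch))
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    nn_seq(nn_conv(in_ch, out_ch, 1, stride = stride, bias = FALSE),
           nn_bn(out_ch))
  } else nn_identity()
  nn_seq(nn_par(list(shortcut, main), "add"), nn_relu())
}

res_stage <- function(in_ch, mid, out_ch, blocks, stride) {
  mods <- list(res_bottleneck(in_ch, mid, out_ch, stride))
  for (i in seq_len(blocks - 1))
    mods[[i + 1]] <- res_bottleneck(out_ch, mid, out_ch, 1)
  nn_seq(mods)
}

build_resnet152 <- function() {
  nn_seq(
    conv_bn(3, 64, 7, stride = 2, pad = 3),
    nn_maxpool(3, stride = 2, pad = 1),
    res_stage(64, 64, 256, 3, 1),
    res_stage(256, 128, 512, 8, 2),
    res_stage(512, 256, 1024, 36, 2),
    res_stage(1024, 512, 2048, 3, 2),
    nn_gap()
  )
}

# residual inception block: branches -> 1x1 projection (linear) scaled and
# added back to the input
res_inception_block <- function(in_ch, branches, branch_ch, scale) {
  nn_seq(
    nn_par(list(
      nn_identity(),
      nn_seq(nn_par(branches, "concat"),
             nn_conv(branch_ch, in_ch, 1, bias = TRUE),
             nn_scale(scale))
    ), "add"),
    nn_relu())
}

block35 <- function() {
  res_inception_block(320, list(
    conv_bn(320, 32, 1),
    nn_seq(conv_bn(320, 32, 1), conv_bn(32, 32, 3, pad = 1)),
    nn_seq(conv_bn(320, 32, 1), conv_bn(32, 48, 3, pad = 1),
           conv_bn(48, 64, 3, pad = 1))
  ), 128, 0.17)
}

block17 <- function() {
  res_inception_block(1088, list(
    conv_bn(1088, 192, 1),
    nn_seq(conv_bn(1088, 128, 1),
           conv_bn(128, 160, 1, 7, pad = c(0, 0, 3, 3)),
           conv_bn(160, 192, 7, 1, pad = c(3, 3, 0, 0)))
  ), 384, 0.10)
}

block8 <- function() {
  res_inception_block(2080, list(
    conv_bn(2080, 192, 1),
    nn_seq(conv_bn(2080, 192, 1),
           conv_bn(192, 224, 1, 3, pad = c(0, 0, 1, 1)),
           conv_bn(224, 256, 3, 1, pad = c(1, 1, 0, 0)))
  ), 448, 0.20)
}

build_inception_resnet_v2 <- function() {
  mixed_5b <- nn_par(list(
    conv_bn(192, 96, 1),
    nn_seq(conv_bn(192, 48, 1), conv_bn(48, 64, 5, pad = 2)),
    nn_seq(conv_bn(192, 64, 1), conv_bn(64, 96, 3, pad = 1),
           conv_bn(96, 96, 3, pad = 1)),
    nn_seq(nn_avgpool(3, stride = 1, pad = 1), conv_bn(192, 64, 1))
  ), "concat")
  mixed_6a <- nn_par(list(
    conv_bn(320, 384, 3, stride = 2),
    nn_seq(conv_bn(320, 256, 1), conv_bn(256, 256, 3, pad = 1),
           conv_bn(256, 384, 3, stride = 2)),
    nn_maxpool(3, stride = 2)
  ), "concat")
  mixed_7a <- nn_par(list(
    nn_seq(conv_bn(1088, 256, 1), conv_bn(256, 384, 3, stride = 2)),
    nn_seq(conv_bn(1088, 256, 1), conv_bn(256, 288, 3, stride = 2)),
    nn_seq(conv_bn(1088, 256, 1), conv_bn(256, 288, 3, pad = 1),
           conv_bn(288, 320, 3, stride = 2)),
    nn_maxpool(3, stride = 2)
  ), "concat")
  nn_seq(c(
    list(conv_bn(3, 32, 3, stride = 2), conv_bn(32, 32, 3),
         conv_bn(32, 64, 3, pad = 1), nn_maxpool(3, stride = 2),
         conv_bn(64, 80, 1), conv_bn(80, 192, 3), nn_maxpool(3, stride = 2),
         mixed_5b),
    replicate(10, block35(), simplify = FALSE),
    list(mixed_6a),
    replicate(20, block17(), simplify = FALSE),
    list(mixed_7a),
    replicate(10, block8(), simplify = FALSE),
    list(conv_bn(2080, 1536, 1), nn_gap())
  ))
}

# In a PSDED rows are EEG channels (exchangeable, so averaged out first --
# this is also the strongest noise reduction available) while columns are
# frequency bands, positional information the feature must keep. Hence: row
# average, three 1-D conv blocks along the band axis, flatten + projection.
build_tiny <- function(feature_dim = 64, input_size = 32) {
  cols <- input_size %/% 2
  nn_seq(
    nn_avgpool(input_size, 1, stride = c(input_size, 1)),
    nn_conv(3, 16, 1, 3, pad = c(0, 0, 1, 1)), nn_relu(),
    nn_conv(16, 32, 1, 3, pad = c(0, 0, 1, 1)), nn_relu(),
    nn_maxpool(1, 2, stride = c(1, 2)),
    nn_conv(32, 32, 1, 3, pad = c(0, 0, 1, 1)), nn_relu(),
    nn_flatten(),
    nn_dense(32 * cols, feature_dim), nn_relu()
  )
}

BACKBONE_REGISTRY <- list(
  inception_v3        = list(input_size = 299, feature_dim = 2048),
  resnet152           = list(input_size = 224, feature_dim = 2048),
  inception_resnet_v2 = list(input_size = 299, feature_dim = 1536),
  tiny                = list(input_size = 32, feature_dim = 64)
)

#' Backbone specification
#'
#' @param name One of `"inception_v3"` (299 px in, 2048-d out), `"resnet152"`
#'   (224 px, 2048-d), `"inception_resnet_v2"` (299 px, 1536-d) or `"tiny"`
#'   (a compact 3-conv-block test surrogate, default 32 px / 64-d).
#' @param weights_init `"random"` (default) or `"pretrained"`. Pretrained
#'   weights are not bundled; `"pretrained"` requires `weights_file`, a
#'   checkpoint produced by [save_classifier()] machinery (RDS of the flat
#'   parameter list).
#' @param input_size,feature_dim Overrides, honored for `"tiny"` only.
#' @param weights_file Optional checkpoint path for `weights_init =
#'   "pretrained"`.
#' @return Object of class `backbone_spec`.
#' @export
backbone_spec <- function(name, weights_init = c("random", "pretrained"),
                          input_size = NULL, feature_dim = NULL,
                          weights_file = NULL) {
  if (!name %in% names(BACKBONE_REGISTRY))
    stopf("unknown backbone '%s'; available: %s", name,
          paste(names(BACKBONE_REGISTRY), collapse = ", "))
  weights_init <- match.arg(weights_init)
  reg <- BACKBONE_REGISTRY[[name]]
  if (name != "tiny") {
    input_size <- reg$input_size
    feature_dim <- reg$feature_dim
  } else {
    input_size <- input_size %||% reg$input_size
    feature_dim <- feature_dim %||% reg$feature_dim
  }
  structure(list(name = name, input_size = input_size,
                 feature_dim = feature_dim, weights_init = weights_init,
                 weights_file = weights_file),
            class = "backbone_spec")
}

#' Instantiate a backbone network from its specification
#'
#' @param spec A [backbone_spec()].
#' @param seed Seed for the random weight initialization.
#' @return Object of class `backbone`: the spec plus the layer graph.
#' @export
build_backbone <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  net <- with_seed(seed, switch(spec$name,
    inception_v3 = build_inception_v3(),
    resnet152 = build_resnet152(),
    inception_resnet_v2 = build_inception_resnet_v2(),
    tiny = build_tiny(spec$feature_dim, spec$input_size)))
  if (spec$weights_init == "pretrained") {
    if (is.null(spec$weights_file) || !file.exists(spec$weights_file %||% ""))
      stopf("pretrained weights for '%s' require an existing weights_file checkpoint",
            spec$name)
    net <- nn_set_params(net, readRDS(spec$weights_file))
  }
  structure(list(spec = spec, net = net), class = "backbone")
}

canonical_backbone_order <- function(names) {
  canon <- c("inception_v3", "resnet152", "inception_resnet_v2")
  key <- match(names, canon)
  key[is.na(key)] <- length(canon) + which(is.na(key))
  order(key)
}

resize_images <- function(images, size) {
  d <- dim(images)
  if (d[1] == size && d[2] == size) return(images)
  out <- array(0, c(size, size, 3, d[4]))
  for (n in seq_len(d[4]))
    out[, , , n] <- EBImage::resize(images[, , , n], w = size, h = size,
                                    filter = "bilinear")
  out
}

as_image_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3)
    return(array(images, c(dim(images), 1)))
  if (inherits(images, "psded_image")) images <- list(images)
  if (is.list(images)) {
    tens <- lapply(images, function(im) {
      if (inherits(im, "psded_image")) image_tensor(im) else im
    })
    d <- dim(tens[[1]])
    out <- array(0, c(d[1], d[2], 3, length(tens)))
    for (i in seq_along(tens)) out[, , , i] <- tens[[i]]
    return(out)
  }
  stopf("malformed image input: expected H x W x 3 (x N) array, psded_image, or list thereof")
}

# ImageNet channel statistics, applied only when a backbone carries
# pretrained weights (random-init backbones see the raw [0,1] image)
imagenet_normalize <- function(x) {
  mu <- c(0.485, 0.456, 0.406)
  sdv <- c(0.229, 0.224, 0.225)
  d <- dim(x)
  (x - bcast_channel(mu, d)) / bcast_channel(sdv, d)
}

#' Extract ensemble feature vectors from a batch of images
#'
#' Each backbone resizes the batch to its own input size, runs an eval-mode
#' forward pass, and emits its pooled feature vector; vectors are concatenated
#' per image in the fixed order inception_v3, resnet152, inception_resnet_v2
#' (other backbones keep their given order). The full published ensemble gives
#' 5632 = 2048 + 2048 + 1536 dimensions.
#'
#' @param images H x W x 3 (x N) array in `[0, 1]`, a `psded_image`, or a list
#'   of either.
#' @param backbones List of [backbone_spec()] or built [build_backbone()]
#'   objects (a single one is accepted too).
#' @param seed Seed used to build any backbone passed as a bare spec.
#' @param batch_size Images per forward chunk (memory control).
#' @return N x D feature matrix, D = sum of backbone feature dims.
#' @export
extract_features <- function(images, backbones, seed = 1L, batch_size = 4L) {
  if (inherits(backbones, "backbone_spec") || inherits(backbones, "backbone"))
    backbones <- list(backbones)
  x <- as_image_batch(images)
  nms <- vapply(backbones, function(b)
    if (inherits(b, "backbone")) b$spec$name else b$name, "")
  ord <- canonical_backbone_order(nms)
  backbones <- backbones[ord]
  N <- dim(x)[4]
  feats <- vector("list", length(backbones))
  for (i in seq_along(backbones)) {
    b <- backbones[[i]]
    built <- if (inherits(b, "backbone")) b else build_backbone(b, seed + i)
    xi <- resize_images(x, built$spec$input_size)
    if (built$spec$weights_init == "pretrained") xi <- imagenet_normalize(xi)
    out <- matrix(0, N, built$spec$feature_dim)
    for (at in seq(1, N, by = batch_size)) {
      sel <- at:min(at + batch_size - 1, N)
      out[sel, ] <- nn_forward(built$net, xi[, , , sel, drop = FALSE])$out
    }
    feats[[i]] <- out
    if (!inherits(b, "backbone")) { rm(built); gc(FALSE) }
  }
  do.call(cbind, feats)
}
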
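test_that("cross-entropy matches hand-computed values", {
  Y <- diag(4)
  P <- matrix(0.25, 4, 4)
  ce <- cross_entropy_batch(Y, P)
  # binary form summed over 4 classes at uniform prediction:
  # -(ln .25 + 3 ln .75) = 2.2493...
  expect_equal(ce$per_sample, rep(-(log(0.25) + 3 * log(0.75)), 4),
               tolerance = 1e-12)
  expect_equal(ce$batch_mean, ce$per_sample[1])

  perfect <- cross_entropy_batch(Y, Y)
  expect_lt(perfect$batch_mean, 1e-6)

  cat <- cross_entropy_batch(Y, P, loss_form = "categorical")
  expect_equal(cat$per_sample, rep(-log(0.25), 4))

  expect_error(cross_entropy_batch(diag(4), matrix(0.5, 3, 4)), "differ")
})

test_that("a batch of identical samples has batch mean equal to each per-sample loss", {
  Y <- matrix(rep(c(1, 0, 0, 0), each = 5), 5, 4)
  P <- matrix(rep(c(0.7, 0.1, 0.1, 0.1), each = 5), 5, 4)
  ce <- cross_entropy_batch(Y, P)
  expect_true(all(abs(ce$per_sample - ce$batch_mean) < 1e-12))
})

test_that("OHEM equals the direct evaluation on the worked example", {
  expect_equal(ohem_loss(c(0.9, 0.1, 0.5, 0.3), 2), 0.7)
  expect_equal(ohem_loss(c(0.9, 0.1, 0.5, 0.3), 4), mean(c(0.9, 0.1, 0.5, 0.3)))
  expect_error(ohem_loss(c(1, 2), 3), "top_k")
  expect_error(ohem_loss(c(1, 2), 0), "top_k")
})

test_that("OHEM matches a brute-force oracle on 1000 random batches, all k", {
  oracle <- function(l, k) {
    picked <- l[order(l, decreasing = TRUE)][seq_len(k)]
    sum(picked) / k
  }
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    l <- round(rexp(n), 3)   # rounding forces ties regularly
    for (k in seq_len(n))
      expect_identical(ohem_loss(l, k), oracle(l, k))
  }
})

test_that("OHEM dominates the batch mean and is non-increasing in k", {
  set.seed(43)
  for (i in 1:200) {
    l <- rexp(sample(3:20, 1))
    vals <- vapply(seq_along(l), function(k) ohem_loss(l, k), 0)
    expect_gte(min(vals) + 1e-12, mean(l))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("stratified splits are exhaustive, proportional and reproducible", {
  cfg <- small_config(seed = 15, n_channels = 1)
  frames <- gen_frames(cfg, 10, duration_s = 1)
  sp <- split_dataset(frames, 0.7, seed = 4)
  expect_length(sp$train, 28)
  expect_length(sp$test, 12)
  expect_equal(as.vector(table(frame_labels(sp$train))), rep(7, 4))
  sp2 <- split_dataset(frames, 0.7, seed = 4)
  expect_identical(vapply(sp$train, `[[`, "", "source_id"),
                   vapply(sp2$train, `[[`, "", "source_id"))
  # 3 frames in a class at 0.7 -> 2 train / 1 test
  idx <- eegstates:::split_indices(factor(rep("a", 3)), 0.7, 1)
  expect_length(idx, 2)
  tiny <- frames[frame_labels(frames) != "seizure"]
  expect_error(split_dataset(tiny), "seizure")
})

test_that("freeze_backbone leaves backbone weights bit-identical", {
  cfg <- small_config(seed = 16)
  frames <- gen_frames(cfg, 8)
  x <- frames_to_images(frames)
  model <- ensemble_classifier(backbone_spec("tiny"), seed = 2)
  before <- eegstates:::nn_collect_params(model$backbones[[1]]$net)
  fit <- train_classifier(model, x, frame_labels(frames),
                          train_config(batch_size = 8, epochs = 2,
                                       transfer_mode = "freeze_backbone",
                                       seed = 3))
  after <- eegstates:::nn_collect_params(fit$model$backbones[[1]]$net)
  expect_identical(before, after)
  head_after <- eegstates:::nn_collect_params(fit$model$head)
  head_before <- eegstates:::nn_collect_params(model$head)
  expect_false(identical(head_before, head_after))
  expect_equal(nrow(fit$history), 2 * 4)  # epochs x batches
})

test_that("OHEM with k = batch size reproduces the cross-entropy trajectory", {
  cfg <- small_config(seed = 17)
  frames <- gen_frames(cfg, 6)
  x <- frames_to_images(frames)
  labs <- frame_labels(frames)
  run <- function(loss, k = NULL) {
    model <- ensemble_classifier(backbone_spec("tiny"), seed = 5)
    train_classifier(model, x, labs,
                     train_config(batch_size = 12, epochs = 2, loss = loss,
                                  ohem_top_k = k,
                                  transfer_mode = "finetune_all",
                                  seed = 6))$history
  }
  expect_equal(run("cross_entropy")$loss, run("ohem", k = 12)$loss,
               tolerance = 1e-12)
})

test_that("seeded training is reproducible run to run", {
  cfg <- small_config(seed = 18)
  frames <- gen_frames(cfg, 5)
  x <- frames_to_images(frames)
  labs <- frame_labels(frames)
  one <- function() {
    model <- ensemble_classifier(backbone_spec("tiny"), seed = 7)
    train_classifier(model, x, labs,
                     train_config(batch_size = 10, epochs = 2, seed = 8,
                                  transfer_mode = "finetune_all"))
  }
  f1 <- one(); f2 <- one()
  expect_identical(f1$history, f2$history)
  expect_identical(eegstates:::nn_collect_params(f1$model$head),
                   eegstates:::nn_collect_params(f2$model$head))
})

test_that("switching to OHEM does not hurt the hard preictal pair", {
  pair_acc <- function(seed, loss) {
    cfg <- synth_config(seed = seed)
    frames <- gen_frames(cfg, 100)
    labs <- frame_labels(frames)
    x <- frames_to_images(frames)
    idx <- eegstates:::split_indices(labs, 0.7, seed + 10)
    te <- setdiff(seq_along(labs), idx)
    hard <- te[labs[te] %in% c("preictal_I", "preictal_II")]
    model <- ensemble_classifier(backbone_spec("tiny"), seed = seed + 2)
    tc <- train_config(batch_size = 32, epochs = 10, lr = 1e-3, loss = loss,
                       transfer_mode = "finetune_all", seed = seed + 3)
    fit <- train_classifier(model, x[, , , idx, drop = FALSE], labs[idx], tc)
    mean(predict(fit$model, x[, , , hard, drop = FALSE]) == labs[hard])
  }
  accs <- vapply(1:3, function(s)
    c(ce = pair_acc(s, "cross_entropy"), ohem = pair_acc(s, "ohem")), numeric(2))
  # directional check: averaged over seeds, hard-example mining must not
  # reduce accuracy on the two preictal states (small slack for run noise)
  expect_gte(mean(accs["ohem", ]), mean(accs["ce", ]) - 0.01)
})

test_that("training validates inputs and aborts on divergence", {
  x <- withr::with_seed(1, array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4)))
  model <- ensemble_classifier(backbone_spec("tiny"), seed = 1)
  expect_error(train_classifier(model, x, factor(rep("seizure", 3))),
               "one label per image")
  expect_error(train_config(batch_size = 8, ohem_top_k = 20), "batch_size")
})
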
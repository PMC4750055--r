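test_that("presets encode the layer-removal and width-reduction variants", {
  t1 <- architecture_preset(1)
  widths <- vapply(t1$conv_layers, `[[`, integer(1), "n_filters")
  expect_equal(widths, c(128L, 256L, 384L, 384L, 256L))
  expect_equal(t1$fc_layers, c(4096L, 4096L))
  expect_equal(t1$dropout_ratio, 0.7)
  expect_equal(t1$conv_layers[[1]]$stride, 3L)
  expect_equal(t1$conv_layers[[1]]$kernel, 11L)

  expect_equal(architecture_preset(2)$fc_layers, 4096L)
  expect_length(architecture_preset(3)$fc_layers, 0L)
  expect_length(architecture_preset(4)$conv_layers, 4L)
  expect_length(architecture_preset(7)$conv_layers, 1L)
  w8 <- vapply(architecture_preset(8)$conv_layers, `[[`, integer(1),
               "n_filters")
  expect_equal(w8[2:5], c(192L, 320L, 320L, 192L))
  w10 <- vapply(architecture_preset(10)$conv_layers, `[[`, integer(1),
                "n_filters")
  expect_equal(w10[2:5], c(64L, 192L, 192L, 64L))
  expect_error(architecture_preset(11), "1..10")
  expect_error(architecture_spec(list(), n_classes = 3), "convolutional")
  expect_error(architecture_spec(architecture_preset(1)$conv_layers,
                                 dropout_ratio = 1), "dropout")
})

test_that("parameter counts match hand arithmetic and shrink monotonically", {
  # single conv layer, no hidden FC: conv contributes 128*11*11*3 + 128
  spec <- architecture_spec(list(pestscout:::conv_layer(128L, 11L, 3L, 0L)),
                            integer(0), n_classes = 12L, input_size = 227L)
  side <- (227 - 11) %/% 3 + 1
  expect_equal(count_parameters(spec),
               (128 * 363 + 128) + side^2 * 128 * 12 + 12)

  # final classifier from a 4096-unit FC layer: 4096*12 + 12 = 49164
  spec2 <- architecture_spec(list(pestscout:::conv_layer(8L, 11L, 3L, 0L,
                                                         pool_after = 3L)),
                             4096L, n_classes = 12L, input_size = 227L)
  flat <- 8 * 8 * 8  # 227 -> 73 -> 36 -> 17 -> 8
  expect_equal(count_parameters(spec2),
               (8 * 363 + 8) + (flat * 4096 + 4096) + 49164)

  counts <- vapply(1:10, function(i) {
    count_parameters(architecture_preset(i))
  }, numeric(1))
  expect_true(all(diff(counts[1:7]) < 0))
  expect_true(all(diff(counts[c(1, 8, 9, 10)]) < 0))
})

test_that("networks build deterministically and reject impossible geometry", {
  spec <- desk_scale(architecture_preset(1), input_size = 64,
                     width_divisor = 8, fc_width = 32, n_classes = 3)
  n1 <- build_network(spec, seed = 4)
  n2 <- build_network(spec, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, build_network(spec, seed = 5)))

  tiny <- architecture_spec(list(pestscout:::conv_layer(4L, 11L, 1L, 0L)),
                            n_classes = 3L, input_size = 8L)
  expect_error(build_network(tiny),
               class = "pestscout_invalid_architecture")

  # with dropout 0 a training-mode forward equals the evaluation forward
  spec0 <- architecture_spec(spec$conv_layers, spec$fc_layers,
                             dropout_ratio = 0, n_classes = 3L,
                             input_size = 64L)
  net <- build_network(spec0, seed = 1, init = "he")
  x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3))
  expect_equal(pestscout:::cnn_forward(net, x, train = TRUE)$scores,
               pestscout:::cnn_forward(net, x)$scores)
})

test_that("the full architecture emits one score per class", {
  net <- build_network(architecture_preset(1), seed = 1)
  x <- array(stats::rnorm(227 * 227 * 3) * 50, c(227, 227, 3))
  expect_length(pestscout:::cnn_forward(net, x)$scores, 12L)
})

test_that("random crops honour count, mirroring and bounds", {
  img <- make_localization_fixture(seed = 2, height = 256, width = 256)$image
  crops <- random_crops(img, n = 5, size = 227, mirror = TRUE, seed = 3)
  expect_length(crops, 10L)
  expect_true(all(vapply(crops, function(cr) {
    identical(dim(cr), c(227L, 227L, 3L))
  }, logical(1))))
  expect_identical(crops, random_crops(img, 5, 227, TRUE, seed = 3))

  same <- random_crops(img, n = 3, size = 256, mirror = FALSE, seed = 1)
  expect_identical(same[[1]], img)
  expect_identical(mirror_horizontal(mirror_horizontal(img)), img)
  expect_error(random_crops(img, 2, 300), "exceeds")
})

test_that("losses match analytic values and finite differences", {
  expect_equal(softmax_loss(rep(0, 12), 3L)$loss, log(12))
  big <- rep(0, 12); big[4] <- 1e4
  expect_equal(softmax_loss(big, 3L)$loss, 0, tolerance = 1e-8)
  expect_equal(sum(softmax_loss(stats::rnorm(12), 0L)$grad), 0,
               tolerance = 1e-12)

  s <- rep(-2, 12); s[5] <- 2
  expect_equal(hinge_loss_ova(s, 4L)$loss, 0)
  expect_equal(hinge_loss_ova(rep(0, 12), 2L)$loss, 12)

  fd_check <- function(fn, scores, label) {
    g <- fn(scores, label)$grad
    eps <- 1e-6
    num <- vapply(seq_along(scores), function(i) {
      up <- scores; up[i] <- up[i] + eps
      dn <- scores; dn[i] <- dn[i] - eps
      (fn(up, label)$loss - fn(dn, label)$loss) / (2 * eps)
    }, numeric(1))
    max(abs(num - g)) / max(max(abs(g)), 1e-8)
  }
  set.seed(6)
  for (i in 1:10) {
    sc <- stats::rnorm(12, sd = 2)
    expect_lt(fd_check(softmax_loss, sc, sample(0:11, 1)), 1e-5)
    # keep clear of the hinge kinks where the subgradient jumps
    sc2 <- sc
    sc2[abs(abs(sc2) - 1) < 1e-2] <- 0
    expect_lt(fd_check(hinge_loss_ova, sc2, sample(0:11, 1)), 1e-5)
  }
})

test_that("inverted dropout preserves the expected activation", {
  spec <- architecture_spec(list(pestscout:::conv_layer(4L, 3L, 1L, 0L)),
                            fc_layers = 64L, dropout_ratio = 0.7,
                            n_classes = 3L, input_size = 10L)
  net <- build_network(spec, seed = 2, init = "he")
  # uniform positive readout: scores average the dropped-out activations,
  # so the comparison is on the activation scale without sign cancellation
  nl <- length(net$layers)
  net$layers[[nl]]$W <- matrix(1 / 64, 64, 3)
  net$layers[[nl]]$b <- rep(0, 3)
  x <- array(stats::runif(10 * 10 * 3), c(10, 10, 3))
  eval_scores <- pestscout:::cnn_forward(net, x)$scores
  set.seed(99)
  mc <- replicate(10000, pestscout:::cnn_forward(net, x,
                                                 train = TRUE)$scores)
  expect_lt(max(abs(rowMeans(mc) - eval_scores)),
            0.01 * max(abs(eval_scores)))
})

test_that("training is deterministic and degenerate rates freeze the weights", {
  ds <- make_classification_dataset(2, 4, image_size = 64, seed = 5)
  spec <- desk_scale(architecture_preset(1), input_size = 64,
                     width_divisor = 16, fc_width = 16, n_classes = 2)
  cfg <- train_config(batch_size = 4, epochs = 2, iters_per_epoch = 3,
                      crop_size = 64, seed = 7, init = "he",
                      input_scale = 1)
  f1 <- train_classifier(spec, ds, cfg)
  f2 <- train_classifier(spec, ds, cfg)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$net, f2$net)

  # full-batch, no augmentation, no dropout: with lr0 = 0 every pass is
  # the same deterministic computation, so the loss cannot improve
  spec_nd <- architecture_spec(spec$conv_layers, spec$fc_layers,
                               dropout_ratio = 0, n_classes = 2L,
                               input_size = 64L)
  cfg0 <- train_config(batch_size = 6, lr0 = 0, weight_decay = 0,
                       epochs = 2, iters_per_epoch = 3, crop_size = 64,
                       mirror = FALSE, seed = 7, init = "he",
                       input_scale = 1)
  f0 <- train_classifier(spec_nd, ds, cfg0)
  init_net <- build_network(spec_nd, seed = 7, init_std = cfg0$init_std,
                            init = "he")
  expect_identical(f0$net$layers[[1]]$W, init_net$layers[[1]]$W)
  expect_equal(f0$curves$train_loss[1], f0$curves$train_loss[2],
               tolerance = 1e-9)

  expect_error(train_classifier(spec,
    structure(list(items = list(), n_classes = 2L, split = character(0)),
              class = "labeled_dataset")), "non-empty")
})

test_that("evaluation reports accuracy, AP and flags absent classes", {
  ds <- make_classification_dataset(3, 6, image_size = 64, seed = 8)
  spec <- desk_scale(architecture_preset(4), input_size = 64,
                     width_divisor = 8, fc_width = 32, n_classes = 3)
  cfg <- train_config(batch_size = 12, epochs = 2, iters_per_epoch = 15,
                      crop_size = 64, seed = 2, init = "he",
                      input_scale = 1)
  fit <- train_classifier(spec, ds, cfg)
  rep_tr <- evaluate_classifier(fit, ds, split = "train")
  expect_true(rep_tr$accuracy >= 0 && rep_tr$accuracy <= 1)
  expect_true(rep_tr$map >= 0 && rep_tr$map <= 1)
  if (rep_tr$accuracy == 1) expect_equal(rep_tr$map, 1)

  # constant scores on a balanced set give chance accuracy
  blank <- fit
  blank$net <- build_network(spec, seed = 1, init_std = 0)  # zero weights
  rep_bl <- evaluate_classifier(blank, ds, split = "all")
  expect_equal(rep_bl$accuracy, 1 / 3, tolerance = 1e-12)

  # a class missing from the split is flagged and excluded from mAP
  sub <- ds
  keep <- vapply(ds$items, `[[`, integer(1), "label") != 2L
  sub$items <- ds$items[keep]
  sub$split <- ds$split[keep]
  expect_warning(rep_m <- evaluate_classifier(fit, sub, split = "all"),
                 "absent class")
  expect_equal(rep_m$undefined_classes, 2L)
  expect_false(is.na(rep_m$map))
})

test_that("the ablation table is deterministic with decreasing capacity", {
  ds <- make_classification_dataset(3, 4, image_size = 64, seed = 12)
  cfg <- train_config(batch_size = 6, epochs = 1, iters_per_epoch = 4,
                      crop_size = 64, seed = 3, init = "he",
                      input_scale = 1)
  tab <- ablation_table(c(1, 8, 9, 10), ds, cfg, input_size = 64,
                        width_divisor = 16, fc_width = 16)
  expect_equal(tab$type, c(1, 8, 9, 10))
  expect_true(all(diff(tab$n_parameters) < 0))
  expect_true(all(tab$val_accuracy >= 0 & tab$val_accuracy <= 1))
  tab2 <- ablation_table(c(1, 8, 9, 10), ds, cfg, input_size = 64,
                         width_divisor = 16, fc_width = 16)
  expect_identical(tab, tab2)
})

test_that("removing intermediate conv layers does not improve accuracy", {
  ds <- make_classification_dataset(3, 8, image_size = 64, seed = 21)
  cfg <- train_config(batch_size = 18, epochs = 2, iters_per_epoch = 20,
                      crop_size = 64, seed = 5, init = "he",
                      input_scale = 1)
  accs <- vapply(c(1, 7), function(tp) {
    spec <- desk_scale(architecture_preset(tp), input_size = 64,
                       width_divisor = 8, fc_width = 32, n_classes = 3)
    cfg_t <- cfg
    cfg_t$seed <- cfg$seed + tp
    evaluate_classifier(train_classifier(spec, ds, cfg_t), ds)$accuracy
  }, numeric(1))
  # qualitative capacity ordering, allowing seed noise on the easy task
  expect_lte(accs[2], accs[1] + 0.2)
})
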
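# tiny configs keep these structural tests fast
tiny_cfg <- function(variant = "se_unet", ...) {
  model_config(variant = variant, preset = "desk", depth = 3L,
               base_channels = 4L, r = 2L, seed = 3L, ...)
}

test_that("the network emits a per-position two-class distribution", {
  m <- build_model(tiny_cfg())
  x <- list(matrix(rnorm(4096 * 16), 4096, 16))
  fwd <- unet_forward(m, x, B = 1L, training = FALSE)
  expect_identical(dim(fwd$logits), c(4096L, 2L))
  p <- exp(fwd$logits) / rowSums(exp(fwd$logits))
  expect_equal(unname(rowSums(p)), rep(1, 4096))
  expect_true(all(p > 0 & p < 1))
})

test_that("SE parameter overhead matches the closed-form audit", {
  for (r in c(2L, 4L)) {
    base <- 8L; depth <- 4L
    se <- build_model(model_config("se_unet", "desk", depth = depth,
                                   base_channels = base, r = r, seed = 1))
    un <- build_model(model_config("unet", "desk", depth = depth,
                                   base_channels = base, r = r, seed = 1))
    ch <- base * 2^(seq_len(depth) - 1L)
    se_channels <- c(ch, rev(ch[-depth]))  # one SE per encoder + decoder block
    audit <- sum(2 * se_channels * (se_channels %/% r) +
                   se_channels + se_channels %/% r)
    expect_identical(n_params(se) - n_params(un), as.integer(audit))
  }
})

test_that("unet and se_unet share all non-SE parameter shapes", {
  se <- build_model(tiny_cfg("se_unet"))
  un <- build_model(tiny_cfg("unet"))
  shared <- intersect(names(se$params), names(un$params))
  expect_identical(setdiff(names(un$params), names(se$params)), character(0))
  for (nm in shared) {
    expect_identical(dim(se$params[[nm]]) %||% length(se$params[[nm]]),
                     dim(un$params[[nm]]) %||% length(un$params[[nm]]))
  }
  expect_true(all(grepl("\\.se\\.", setdiff(names(se$params), shared))))
})

test_that("fusion with one stem is the single-feature graph plus a stem block", {
  fu <- build_model(tiny_cfg("se_unet_fusion", n_features = 1L))
  si <- build_model(tiny_cfg("se_unet"))
  extra <- setdiff(names(fu$params), names(si$params))
  expect_true(all(grepl("^stem1\\.", extra)))
  stem_params <- 9L * 16L * 16L + 16L + 2L * 16L  # conv W+b, bn gamma+beta
  expect_identical(n_params(fu) - n_params(si), stem_params)
})

test_that("se_block gates match hand computation", {
  # zero input stays zero for any weights
  w <- list(W1 = matrix(rnorm(4), 2, 2), b1 = rnorm(2),
            W2 = matrix(rnorm(4), 2, 2), b2 = rnorm(2))
  z <- array(0, c(3, 3, 2))
  expect_identical(se_block(z, w), z)
  # zero weights give sigmoid(0) = 0.5 gates
  x <- array(rnorm(18), c(3, 3, 2))
  w0 <- list(W1 = matrix(0, 2, 1), b1 = 0, W2 = matrix(0, 1, 2), b2 = c(0, 0))
  expect_equal(se_block(x, w0), x / 2)
  # 1 x 1 x 2 toy, arithmetic by hand:
  # z = (2, -1); h = relu(W1' z + b1) = relu(2*1 + (-1)*0.5 + 0.1) = 1.6
  # u = W2' h + b2 = (0.5*1.6, -0.25*1.6) + (0.2, 0) = (1.0, -0.4)
  xt <- array(c(2, -1), c(1, 1, 2))
  wt <- list(W1 = matrix(c(1, 0.5), 2, 1), b1 = 0.1,
             W2 = matrix(c(0.5, -0.25), 1, 2), b2 = c(0.2, 0))
  s <- 1 / (1 + exp(-c(1.0, -0.4)))
  expect_equal(as.vector(se_block(xt, wt)), c(2, -1) * s)
  # gates lie strictly in (0, 1): output magnitude never exceeds input
  y <- se_block(x, w)
  expect_true(all(abs(y) < abs(x) | x == 0))
})

test_that("dice loss follows the smoothed overlap formula", {
  t <- c(1, 1, 0, 0, 1)
  expect_lte(dice_loss(t, t), 1 / (2 * 3 + 1))
  expect_gt(dice_loss(c(1, 0, 0), c(0, 1, 1), eps = 1), 0.6)
  expect_identical(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0), eps = 0), 0.5)
  # bounded and symmetric for binary arguments
  set.seed(2)
  for (i in 1:5) {
    a <- rbinom(20, 1, 0.4); b <- rbinom(20, 1, 0.4)
    expect_gte(dice_loss(a, b), 0)
    expect_lte(dice_loss(a, b), 1)
    expect_identical(dice_loss(a, b), dice_loss(b, a))
  }
  # masked slots contribute to neither sum
  expect_identical(dice_loss(c(1, 1), c(1, 0), mask = c(TRUE, FALSE)),
                   dice_loss(1, 1))
  expect_error(dice_loss(c(1, 0), c(1, 0, 1)),
               class = "hinge3_dimension_error")
})

test_that("the learning-rate schedule decays exponentially from lr0", {
  cfg <- model_config(preset = "desk", lr0 = 0.05, lr_decay = 0.9)
  expect_identical(lr_at(cfg, 0), 0.05)
  expect_equal(lr_at(cfg, 7), 0.05 * 0.9^7)
})

test_that("training is deterministic given the seed and reduces the loss", {
  sub <- small_subject()
  lab <- expand_regions(sub$surface, sub$annotation)
  fb <- compute_feature_blocks(sub$surface, sub$morph, feature_config())
  samples <- blocks_to_samples(fb, lab)
  cfg <- model_config(preset = "desk", seed = 11L, batch_size = 2L)
  m1 <- train_model(build_model(cfg), samples, epochs = 3)
  m2 <- train_model(build_model(cfg), samples, epochs = 3)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_lt(m1$log$loss[3], m1$log$loss[1])
  expect_identical(m1$log$lr, lr_at(cfg, 0:2))
  # tidy/glance expose the log
  expect_identical(tidy(m1), m1$log)
  expect_identical(glance(m1)$epochs_trained, 3L)
})

test_that("a constant-foreground model labels all real vertices, no pad leak", {
  sub <- small_subject()
  fb <- compute_feature_blocks(sub$surface, sub$morph, feature_config())
  m <- build_model(model_config(preset = "desk", seed = 1))
  m$params <- lapply(m$params, function(p) p * 0)
  m$params[["head.b"]] <- c(-4, 4)  # foreground prob sigmoid(8) ~ 1
  pred <- predict_regions(m, fb)
  expect_identical(nrow(pred), n_vertices(sub$surface))
  expect_true(all(pred$label == 1L))
  # threshold 1.0 -> empty prediction
  pred0 <- predict_regions(m, fb, threshold = 1)
  expect_identical(sum(pred0$label), 0L)
})

test_that("feature-order mismatch against the model config is rejected", {
  sub <- small_subject()
  fb <- compute_feature_blocks(sub$surface, sub$morph,
                               feature_config(feature_names = "curv"))
  m <- build_model(model_config(preset = "desk", seed = 1,
                                feature_names = "sulc"))
  expect_error(predict_regions(m, fb), "feature order")
})

test_that("invalid SE reduction and empty training sets are config errors", {
  expect_error(model_config(preset = "desk", base_channels = 4L, r = 8L),
               class = "hinge3_config_error")
  m <- build_model(tiny_cfg())
  expect_error(train_model(m, list()), class = "hinge3_config_error")
})
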
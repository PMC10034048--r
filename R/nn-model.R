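#' SE-Unet model configuration
#'
#' Architecture and training hyper-parameters for the hinge-region segmenter.
#' The reference configuration mirrors the published training setup: a
#' 5-level U-net over 64 x 64 x 16 inputs, squeeze-excitation reduction
#' `r = 24`, dropout 0.2 between the paired convolutions, batch-norm momentum
#' 0.6, RMSprop at initial learning rate 0.05 decayed exponentially per
#' epoch, batch size 40, 150 epochs, Dice loss. `preset = "desk"` is a
#' CPU-scale configuration (depth 4, 8 base channels, `r = 4`, smaller
#' learning rate for the much smaller batches) used by the package's tests
#' and the synthetic pipeline.
#'
#' @param variant `"se_unet"`, `"unet"` (no SE blocks) or `"se_unet_fusion"`
#'   (per-feature convolutional stems concatenated before the encoder).
#' @param depth number of resolution levels (encoder levels + bottleneck).
#' @param base_channels channel count at the first level; doubled per level.
#' @param r squeeze-excitation reduction ratio; needs
#'   `floor(base_channels / r) >= 1`.
#' @param dropout dropout probability between paired convolutions.
#' @param bn_momentum batch-norm running-statistics momentum
#'   (`running <- momentum * running + (1 - momentum) * batch`).
#' @param lr0 initial learning rate.
#' @param lr_decay per-epoch exponential decay factor; the learning rate at
#'   0-based epoch `e` is `lr0 * lr_decay^e`.
#' @param batch_size training batch size.
#' @param epochs training epochs.
#' @param n_features number of fused input tensors `m` (>= 1).
#' @param channels_in channels per input tensor (k + 1; default 16).
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param preset `"reference"` (full study scale) or `"desk"` (CPU test scale).
#' @param feature_names optional feature order the model expects; checked at
#'   prediction time.
#' @return a `model_config` list.
#' @export
model_config <- function(variant = c("se_unet", "unet", "se_unet_fusion"),
                         preset = c("reference", "desk"),
                         depth = NULL, base_channels = NULL, r = NULL,
                         dropout = 0.2, bn_momentum = 0.6,
                         lr0 = NULL, lr_decay = 0.96, batch_size = NULL,
                         epochs = NULL, n_features = 1L, channels_in = 16L,
                         seed = 1L, feature_names = NULL) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  if (preset == "reference") {
    depth <- depth %||% 5L; base_channels <- base_channels %||% 64L
    r <- r %||% 24L; lr0 <- lr0 %||% 0.05
    batch_size <- batch_size %||% 40L; epochs <- epochs %||% 150L
  } else {
    depth <- depth %||% 4L; base_channels <- base_channels %||% 8L
    r <- r %||% 4L; lr0 <- lr0 %||% 0.01
    batch_size <- batch_size %||% 10L; epochs <- epochs %||% 30L
  }
  assert_that(depth >= 2, "depth must be >= 2")
  assert_that(n_features >= 1, "n_features must be >= 1")
  if (variant != "unet") {
    assert_that(base_channels %/% r >= 1,
                sprintf("SE reduction r = %d too large for %d base channels",
                        r, base_channels))
  }
  structure(list(variant = variant, preset = preset, depth = as.integer(depth),
                 base_channels = as.integer(base_channels), r = as.integer(r),
                 dropout = dropout, bn_momentum = bn_momentum, lr0 = lr0,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_features = as.integer(n_features),
                 channels_in = as.integer(channels_in),
                 seed = as.integer(seed), feature_names = feature_names),
            class = "model_config")
}

#' Learning-rate schedule
#'
#' @param cfg a [model_config()].
#' @param epoch 0-based epoch index.
#' @return `lr0 * lr_decay^epoch`.
#' @export
lr_at <- function(cfg, epoch) cfg$lr0 * cfg$lr_decay^epoch

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

level_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)

#' Build an (untrained) hinge-region segmentation network
#'
#' Constructs the parameter set of the configured variant: a symmetric
#' U-shaped encoder/decoder. Each encoder level applies two 3x3
#' convolutions (each followed by batch norm and ReLU, with dropout between
#' them), a squeeze-excitation block (omitted for `variant = "unet"`), and
#' 2x2 max pooling with channel doubling; the decoder mirrors it with
#' learned 2x2 transposed convolutions that halve the channels, skip-
#' connection concatenation, paired convolutions and SE. A 1x1 two-channel
#' head with softmax produces the per-position class distribution. The
#' fusion variant prepends one conv/BN/ReLU stem per input feature and
#' concatenates the stem outputs.
#'
#' @param cfg a [model_config()].
#' @return a `hinge3_model` with elements `params` (named list of arrays),
#'   `bn_state` (running statistics), `cfg` and `log` (training history
#'   tibble, empty until trained).
#' @seealso [train_model()], [predict_regions()], [n_params()]
#' @export
build_model <- function(cfg = model_config()) {
  set.seed(cfg$seed)
  ch <- level_channels(cfg)
  cin <- cfg$channels_in
  use_se <- cfg$variant != "unet"
  fusion <- cfg$variant == "se_unet_fusion"
  params <- list()
  bn_names <- character()
  add_conv <- function(name, Cin, Cout) {
    params[[paste0(name, ".W")]] <<- he_init(9L * Cin, Cout, 9L * Cin)
    params[[paste0(name, ".b")]] <<- numeric(Cout)
  }
  add_bn <- function(name, C) {
    params[[paste0(name, ".gamma")]] <<- rep(1, C)
    params[[paste0(name, ".beta")]] <<- numeric(C)
    bn_names <<- c(bn_names, name)
  }
  add_se <- function(name, C) {
    Cr <- max(1L, C %/% cfg$r)
    params[[paste0(name, ".W1")]] <<- he_init(C, Cr, C)
    params[[paste0(name, ".b1")]] <<- numeric(Cr)
    params[[paste0(name, ".W2")]] <<- he_init(Cr, C, Cr)
    params[[paste0(name, ".b2")]] <<- numeric(C)
  }
  if (fusion) {
    for (f in seq_len(cfg$n_features)) {
      add_conv(sprintf("stem%d.conv", f), cin, cin)
      add_bn(sprintf("stem%d.bn", f), cin)
    }
  } else {
    assert_that(cfg$n_features == 1L,
                "variant se_unet_fusion is required for n_features > 1")
  }
  enc_in <- if (fusion) cin * cfg$n_features else cin
  for (l in seq_len(cfg$depth)) {
    Cin_l <- if (l == 1) enc_in else ch[l - 1]
    add_conv(sprintf("enc%d.conv1", l), Cin_l, ch[l])
    add_bn(sprintf("enc%d.bn1", l), ch[l])
    add_conv(sprintf("enc%d.conv2", l), ch[l], ch[l])
    add_bn(sprintf("enc%d.bn2", l), ch[l])
    if (use_se) add_se(sprintf("enc%d.se", l), ch[l])
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    params[[sprintf("dec%d.up.W", l)]] <-
      array(rnorm(ch[l + 1] * ch[l] * 4L, sd = sqrt(2 / ch[l + 1])),
            dim = c(ch[l + 1], ch[l], 4L))
    params[[sprintf("dec%d.up.b", l)]] <- numeric(ch[l])
    add_conv(sprintf("dec%d.conv1", l), 2L * ch[l], ch[l])
    add_bn(sprintf("dec%d.bn1", l), ch[l])
    add_conv(sprintf("dec%d.conv2", l), ch[l], ch[l])
    add_bn(sprintf("dec%d.bn2", l), ch[l])
    if (use_se) add_se(sprintf("dec%d.se", l), ch[l])
  }
  params[["head.W"]] <- he_init(ch[1], 2L, ch[1])
  params[["head.b"]] <- numeric(2L)
  bn_state <- lapply(stats::setNames(bn_names, bn_names), function(nm) {
    C <- length(params[[paste0(nm, ".gamma")]])
    list(mean = numeric(C), var = rep(1, C))
  })
  structure(list(params = params, bn_state = bn_state, cfg = cfg,
                 log = tibble::tibble(epoch = integer(), lr = numeric(),
                                      loss = numeric())),
            class = "hinge3_model")
}

#' Total trainable parameter count
#' @param model a `hinge3_model`.
#' @return integer count over all weights and biases (batch-norm running
#'   statistics excluded).
#' @export
n_params <- function(model) sum(vapply(model$params, length, integer(1)))

#' @export
print.hinge3_model <- function(x, ...) {
  cat(sprintf("<hinge3_model> %s, depth %d, base %d, r %d: %d parameters; %s\n",
              x$cfg$variant, x$cfg$depth, x$cfg$base_channels, x$cfg$r,
              n_params(x),
              if (nrow(x$log)) sprintf("trained %d epochs (final Dice loss %.4f)",
                                       max(x$log$epoch), x$log$loss[nrow(x$log)])
              else "untrained"))
  invisible(x)
}

# forward pass; xs: list (per feature) of [B*4096, channels_in] matrices
unet_forward <- function(model, xs, B, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  st <- model$bn_state
  use_se <- cfg$variant != "unet"
  fusion <- cfg$variant == "se_unet_fusion"
  H <- 64L; W <- 64L
  caches <- list()

  run_bn <- function(nm, M) {
    out <- bn_fwd(M, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                  st[[nm]], cfg$bn_momentum, training)
    st[[nm]] <<- out$state
    caches[[nm]] <<- out$cache
    out$Y
  }
  run_conv <- function(nm, M, ci) {
    out <- conv_fwd(M, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]], ci)
    caches[[nm]] <<- list(P = out$P)
    out$Y
  }
  run_relu <- function(nm, M) {
    out <- relu_fwd(M)
    caches[[nm]] <<- out$mask
    out$Y
  }
  run_drop <- function(nm, M) {
    out <- dropout_fwd(M, cfg$dropout, training)
    caches[[nm]] <<- out$mask
    out$Y
  }
  run_se <- function(nm, M) {
    out <- se_fwd(M, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".b1")]],
                  p[[paste0(nm, ".W2")]], p[[paste0(nm, ".b2")]], B)
    caches[[nm]] <<- c(out$cache, list(M = M))
    out$Y
  }
  double_conv <- function(prefix, M, ci) {
    M <- run_conv(paste0(prefix, ".conv1"), M, ci)
    M <- run_bn(paste0(prefix, ".bn1"), M)
    M <- run_relu(paste0(prefix, ".relu1"), M)
    M <- run_drop(paste0(prefix, ".drop"), M)
    M <- run_conv(paste0(prefix, ".conv2"), M, ci)
    M <- run_bn(paste0(prefix, ".bn2"), M)
    run_relu(paste0(prefix, ".relu2"), M)
  }

  ci <- make_conv_idx(H, W, B)
  if (fusion) {
    stems <- lapply(seq_along(xs), function(f) {
      nm <- sprintf("stem%d", f)
      M <- run_conv(paste0(nm, ".conv"), xs[[f]], ci)
      M <- run_bn(paste0(nm, ".bn"), M)
      run_relu(paste0(nm, ".relu"), M)
    })
    x <- do.call(cbind, stems)
  } else {
    x <- xs[[1]]
  }

  skips <- list(); sizes <- list()
  for (l in seq_len(cfg$depth - 1L)) {
    ci <- make_conv_idx(H, W, B)
    x <- double_conv(sprintf("enc%d", l), x, ci)
    if (use_se) x <- run_se(sprintf("enc%d.se", l), x)
    skips[[l]] <- x
    sizes[[l]] <- c(H, W)
    pi <- make_pool_idx(H, W, B)
    out <- maxpool_fwd(x, pi)
    caches[[sprintf("pool%d", l)]] <- out
    x <- out$Y
    H <- H %/% 2L; W <- W %/% 2L
  }
  ci <- make_conv_idx(H, W, B)
  x <- double_conv(sprintf("enc%d", cfg$depth), x, ci)
  if (use_se) x <- run_se(sprintf("enc%d.se", cfg$depth), x)
  for (l in rev(seq_len(cfg$depth - 1L))) {
    ui <- make_up_idx(H, W, B)
    caches[[sprintf("dec%d.up", l)]] <- list(M = x, ui = ui)
    x <- upconv_fwd(x, p[[sprintf("dec%d.up.W", l)]],
                    p[[sprintf("dec%d.up.b", l)]], ui)
    H <- 2L * H; W <- 2L * W
    x <- cbind(skips[[l]], x)
    ci <- make_conv_idx(H, W, B)
    x <- double_conv(sprintf("dec%d", l), x, ci)
    if (use_se) x <- run_se(sprintf("dec%d.se", l), x)
  }
  logits <- sweep(x %*% p[["head.W"]], 2, p[["head.b"]], "+")
  caches[["head"]] <- list(M = x)
  list(logits = logits, caches = caches, bn_state = st, B = B)
}

unet_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg
  p <- model$params
  caches <- fwd$caches
  B <- fwd$B
  use_se <- cfg$variant != "unet"
  fusion <- cfg$variant == "se_unet_fusion"
  grads <- list()
  ch <- level_channels(cfg)

  bwd_se <- function(nm, dY) {
    cc <- caches[[nm]]
    out <- se_bwd(dY, cc$M, cc, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".W2")]])
    grads[[paste0(nm, ".W1")]] <<- out$dW1; grads[[paste0(nm, ".b1")]] <<- out$db1
    grads[[paste0(nm, ".W2")]] <<- out$dW2; grads[[paste0(nm, ".b2")]] <<- out$db2
    out$dM
  }
  bwd_double_conv <- function(prefix, dY, ci, Cin1) {
    dY <- dY * caches[[paste0(prefix, ".relu2")]]
    bn <- bn_bwd(dY, caches[[paste0(prefix, ".bn2")]],
                 p[[paste0(prefix, ".bn2.gamma")]])
    grads[[paste0(prefix, ".bn2.gamma")]] <<- bn$dgamma
    grads[[paste0(prefix, ".bn2.beta")]] <<- bn$dbeta
    cv <- conv_bwd(bn$dX, caches[[paste0(prefix, ".conv2")]],
                   p[[paste0(prefix, ".conv2.W")]], ci,
                   ncol(caches[[paste0(prefix, ".relu1")]]))
    grads[[paste0(prefix, ".conv2.W")]] <<- cv$dW
    grads[[paste0(prefix, ".conv2.b")]] <<- cv$db
    dY <- cv$dM
    dmask <- caches[[paste0(prefix, ".drop")]]
    if (!is.null(dmask)) dY <- dY * dmask
    dY <- dY * caches[[paste0(prefix, ".relu1")]]
    bn <- bn_bwd(dY, caches[[paste0(prefix, ".bn1")]],
                 p[[paste0(prefix, ".bn1.gamma")]])
    grads[[paste0(prefix, ".bn1.gamma")]] <<- bn$dgamma
    grads[[paste0(prefix, ".bn1.beta")]] <<- bn$dbeta
    cv <- conv_bwd(bn$dX, caches[[paste0(prefix, ".conv1")]],
                   p[[paste0(prefix, ".conv1.W")]], ci, Cin1)
    grads[[paste0(prefix, ".conv1.W")]] <<- cv$dW
    grads[[paste0(prefix, ".conv1.b")]] <<- cv$db
    cv$dM
  }

  hd <- caches[["head"]]
  grads[["head.W"]] <- crossprod(hd$M, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dx <- dlogits %*% t(p[["head.W"]])

  H <- 64L; W <- 64L
  sizes_enc <- list()
  for (l in seq_len(cfg$depth - 1L)) {
    sizes_enc[[l]] <- c(H, W)
    H <- H %/% 2L; W <- W %/% 2L
  }
  # decoder, from finest level back down
  dskips <- list()
  for (l in seq_len(cfg$depth - 1L)) {
    Hl <- sizes_enc[[l]][1]; Wl <- sizes_enc[[l]][2]
    ci <- make_conv_idx(Hl, Wl, B)
    if (use_se) dx <- bwd_se(sprintf("dec%d.se", l), dx)
    dx <- bwd_double_conv(sprintf("dec%d", l), dx, ci, 2L * ch[l])
    dskips[[l]] <- dx[, seq_len(ch[l]), drop = FALSE]
    dup <- dx[, ch[l] + seq_len(ch[l]), drop = FALSE]
    uc <- caches[[sprintf("dec%d.up", l)]]
    ub <- upconv_bwd(dup, uc$M, p[[sprintf("dec%d.up.W", l)]], uc$ui)
    grads[[sprintf("dec%d.up.W", l)]] <- ub$dWq
    grads[[sprintf("dec%d.up.b", l)]] <- ub$db
    dx <- ub$dM
  }
  # bottleneck
  Hb <- sizes_enc[[cfg$depth - 1L]][1] %/% 2L
  Wb <- sizes_enc[[cfg$depth - 1L]][2] %/% 2L
  ci <- make_conv_idx(Hb, Wb, B)
  if (use_se) dx <- bwd_se(sprintf("enc%d.se", cfg$depth), dx)
  dx <- bwd_double_conv(sprintf("enc%d", cfg$depth), dx, ci,
                        ch[cfg$depth - 1L])
  # encoder, from coarsest back to input
  enc_in <- if (fusion) cfg$channels_in * cfg$n_features else cfg$channels_in
  for (l in rev(seq_len(cfg$depth - 1L))) {
    Hl <- sizes_enc[[l]][1]; Wl <- sizes_enc[[l]][2]
    pl <- caches[[sprintf("pool%d", l)]]
    pi <- make_pool_idx(Hl, Wl, B)
    dx <- maxpool_bwd(dx, pl, pi, B * Hl * Wl)
    dx <- dx + dskips[[l]]
    ci <- make_conv_idx(Hl, Wl, B)
    Cin1 <- if (l == 1) enc_in else ch[l - 1]
    if (use_se) dx <- bwd_se(sprintf("enc%d.se", l), dx)
    dx <- bwd_double_conv(sprintf("enc%d", l), dx, ci, Cin1)
  }
  if (fusion) {
    ci <- make_conv_idx(64L, 64L, B)
    cin <- cfg$channels_in
    for (f in seq_len(cfg$n_features)) {
      nm <- sprintf("stem%d", f)
      dxf <- dx[, (f - 1L) * cin + seq_len(cin), drop = FALSE]
      dxf <- dxf * caches[[paste0(nm, ".relu")]]
      bn <- bn_bwd(dxf, caches[[paste0(nm, ".bn")]],
                   p[[paste0(nm, ".bn.gamma")]])
      grads[[paste0(nm, ".bn.gamma")]] <- bn$dgamma
      grads[[paste0(nm, ".bn.beta")]] <- bn$dbeta
      cv <- conv_bwd(bn$dX, caches[[paste0(nm, ".conv")]],
                     p[[paste0(nm, ".conv.W")]], ci, cin)
      grads[[paste0(nm, ".conv.W")]] <- cv$dW
      grads[[paste0(nm, ".conv.b")]] <- cv$db
    }
  }
  grads
}

# assemble training samples from feature blocks + per-vertex labels
#' Convert feature blocks and labels into network training samples
#'
#' @param blocks a `feature_blocks` object.
#' @param labels per-vertex 0/1 vector (ground-truth region labels).
#' @return list of samples, each holding per-feature `[4096 x channels]`
#'   matrices, a blocked label vector and a validity mask excluding padding.
#' @export
blocks_to_samples <- function(blocks, labels) {
  assert_that(length(labels) == blocks$n_vertices,
              "labels length must equal the blocked vertex count",
              "hinge3_dimension_error")
  lab_arr <- block_vector(as.numeric(labels), blocks)
  msk_arr <- block_vector(rep(1, blocks$n_vertices), blocks)
  lapply(seq_len(blocks$n_blocks), function(b) {
    t0 <- lab_arr[b, , , drop = TRUE]
    m0 <- msk_arr[b, , , drop = TRUE]
    list(
      features = lapply(names(blocks$tensors), function(f)
        block_matrix(blocks, f, b)),
      label = as.vector(t(t0)),   # position p = (r-1)*W + c
      mask = as.vector(t(m0)) > 0
    )
  })
}

rmsprop_update <- function(params, grads, vstate, lr, rho = 0.9, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- vstate[[nm]]
    if (is.null(v)) v <- g * 0
    v <- rho * v + (1 - rho) * g^2
    vstate[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + eps)
  }
  list(params = params, vstate = vstate)
}

#' Train a hinge-region segmentation network
#'
#' RMSprop on masked soft Dice loss with a per-epoch exponential
#' learning-rate schedule. The model seed controls initialisation, shuffling
#' and dropout, so two runs from the same seed produce identical loss
#' sequences.
#'
#' @param model an untrained (or partially trained) `hinge3_model`.
#' @param samples training samples from [blocks_to_samples()]; multi-feature
#'   models expect each sample to carry `n_features` matrices.
#' @param epochs optional override of `model$cfg$epochs`.
#' @param verbose print per-epoch loss.
#' @return the trained `hinge3_model`; `tidy()` returns the per-epoch log.
#' @export
train_model <- function(model, samples, epochs = NULL, verbose = FALSE) {
  cfg <- model$cfg
  assert_that(length(samples) >= 1, "empty training set")
  nf <- length(samples[[1]]$features)
  assert_that(nf == cfg$n_features,
              sprintf("model expects %d feature tensors, samples carry %d",
                      cfg$n_features, nf))
  epochs <- epochs %||% cfg$epochs
  set.seed(derive_seed(cfg$seed, 7L))
  vstate <- list()
  n <- length(samples)
  bs <- min(cfg$batch_size, n)
  log <- model$log
  e0 <- if (nrow(log)) max(log$epoch) else 0L
  for (e in seq_len(epochs)) {
    lr <- lr_at(cfg, e0 + e - 1L)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      ids <- ord[start:min(start + bs - 1L, n)]
      B <- length(ids)
      xs <- lapply(seq_len(nf), function(f)
        do.call(rbind, lapply(ids, function(i) samples[[i]]$features[[f]])))
      target <- unlist(lapply(ids, function(i) samples[[i]]$label))
      mask <- unlist(lapply(ids, function(i) samples[[i]]$mask))
      fwd <- unet_forward(model, xs, B, training = TRUE)
      model$bn_state <- fwd$bn_state
      dl <- dice_on_logits(fwd$logits, target, mask)
      upd <- rmsprop_update(model$params,
                            unet_backward(model, fwd, dl$dlogits),
                            vstate, lr)
      model$params <- upd$params
      vstate <- upd$vstate
      losses <- c(losses, dl$loss)
    }
    log <- dplyr::bind_rows(log, tibble::tibble(epoch = e0 + e, lr = lr,
                                                loss = mean(losses)))
    if (verbose) message(sprintf("epoch %3d  lr %.5f  dice loss %.4f",
                                 e0 + e, lr, mean(losses)))
  }
  model$log <- log
  model
}

#' Predict per-vertex 3-hinge region labels
#'
#' Runs the trained network over every block (batch-norm in inference mode,
#' no dropout), maps the foreground softmax probabilities back to vertices
#' via the block index map (padding discarded), and thresholds. At the
#' default `threshold = 0.5` this equals the softmax argmax.
#'
#' @param model a trained `hinge3_model`.
#' @param blocks a `feature_blocks` object whose feature order matches the
#'   model's `feature_names` (checked when both are recorded).
#' @param threshold foreground probability threshold in `[0, 1]`.
#' @return tibble with columns `vertex`, `prob`, `label`.
#' @export
predict_regions <- function(model, blocks, threshold = 0.5) {
  cfg <- model$cfg
  assert_that(length(blocks$tensors) == cfg$n_features,
              sprintf("model expects %d feature tensors, blocks carry %d",
                      cfg$n_features, length(blocks$tensors)))
  if (!is.null(cfg$feature_names)) {
    assert_that(identical(names(blocks$tensors), cfg$feature_names),
                paste0("feature order mismatch: model trained on [",
                       paste(cfg$feature_names, collapse = ", "),
                       "], blocks carry [",
                       paste(names(blocks$tensors), collapse = ", "), "]"))
  }
  nb <- blocks$n_blocks
  H <- blocks$cfg$block_rows; W <- blocks$cfg$block_cols
  arr <- array(0, dim = c(nb, H, W))
  # blocks are independent at inference; process in small batches to bound
  # the im2col working set
  for (grp in split(seq_len(nb), ceiling(seq_len(nb) / 8))) {
    xs <- lapply(names(blocks$tensors), function(f)
      do.call(rbind, lapply(grp, function(b) block_matrix(blocks, f, b))))
    fwd <- unet_forward(model, xs, B = length(grp), training = FALSE)
    l <- fwd$logits
    mm <- pmax(l[, 1], l[, 2])
    p1 <- exp(l[, 2] - mm) / (exp(l[, 1] - mm) + exp(l[, 2] - mm))
    for (j in seq_along(grp)) {
      chunk <- p1[(j - 1L) * H * W + seq_len(H * W)]
      arr[grp[j], , ] <- t(matrix(chunk, W, H))
    }
  }
  prob <- unblock(blocks, arr)
  tibble::tibble(vertex = seq_len(blocks$n_vertices), prob = prob,
                 label = as.integer(prob > threshold))
}

#' @rdname train_model
#' @param x a `hinge3_model`.
#' @param ... unused.
#' @export
tidy.hinge3_model <- function(x, ...) x$log

#' @rdname train_model
#' @export
glance.hinge3_model <- function(x, ...) {
  tibble::tibble(variant = x$cfg$variant, depth = x$cfg$depth,
                 base_channels = x$cfg$base_channels, r = x$cfg$r,
                 n_params = n_params(x),
                 epochs_trained = if (nrow(x$log)) max(x$log$epoch) else 0L,
                 final_loss = if (nrow(x$log)) x$log$loss[nrow(x$log)] else NA_real_)
}

#' Plot the training loss curve
#'
#' @param model a trained `hinge3_model`.
#' @return a ggplot object.
#' @export
plot_training <- function(model) {
  ggplot2::ggplot(model$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "Dice loss",
                  title = "Hinge-region segmentation training") +
    ggplot2::theme_minimal()
}
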
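# Neural-network primitives for the SE-Unet, implemented on BLAS matrix
# arithmetic. Activations are stored as [B*H*W, C] matrices with the spatial
# position p = (r-1)*W + c (column index fastest), samples stacked in rows.
# Convolutions use im2col gathers + matrix multiply; index tables are memoised
# per (H, W, B).

.idx_cache <- new.env(parent = emptyenv())

conv_offsets <- expand.grid(dc = -1:1, dr = -1:1)[, c("dr", "dc")]

# im2col source-row table for a same-padded 3x3 conv: (B*H*W) x 9, with the
# out-of-bounds pad mapped to row B*H*W + 1 (an all-zero row appended by the
# caller)
make_conv_idx <- function(H, W, B) {
  key <- sprintf("c%d_%d_%d", H, W, B)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  r <- rep(seq_len(H), each = W)
  c <- rep(seq_len(W), times = H)
  HW <- H * W
  pad <- B * HW + 1L
  one <- matrix(0L, HW, 9L)
  for (j in 1:9) {
    rr <- r + conv_offsets$dr[j]
    cc <- c + conv_offsets$dc[j]
    src <- (rr - 1L) * W + cc
    src[rr < 1L | rr > H | cc < 1L | cc > W] <- NA_integer_
    one[, j] <- src
  }
  idx <- matrix(0L, B * HW, 9L)
  for (b in seq_len(B)) {
    blockrows <- (b - 1L) * HW + seq_len(HW)
    shifted <- one + (b - 1L) * HW
    shifted[is.na(one)] <- pad
    idx[blockrows, ] <- shifted
  }
  .idx_cache[[key]] <- idx
  idx
}

# 2x2/stride-2 pooling gather: four source-row vectors per output position
make_pool_idx <- function(H, W, B) {
  key <- sprintf("p%d_%d_%d", H, W, B)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(seq_len(H2), each = W2)
  c2 <- rep(seq_len(W2), times = H2)
  at <- function(dr, dc) (2L * r2 - 2L + dr - 1L) * W + (2L * c2 - 2L + dc)
  one <- cbind(at(1L, 1L), at(1L, 2L), at(2L, 1L), at(2L, 2L))
  HW <- H * W; HW2 <- H2 * W2
  idx <- do.call(rbind, lapply(seq_len(B), function(b) one + (b - 1L) * HW))
  .idx_cache[[key]] <- idx
  idx
}

# output scatter rows for a 2x2/stride-2 transposed conv: input (r, c) writes
# the output quadrant (2r-1+dr, 2c-1+dc), q = 1..4
make_up_idx <- function(H, W, B) {
  key <- sprintf("u%d_%d_%d", H, W, B)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  r <- rep(seq_len(H), each = W)
  c <- rep(seq_len(W), times = H)
  W2 <- 2L * W; HW <- H * W; HW4 <- 4L * HW
  quads <- expand.grid(dc = 0:1, dr = 0:1)[, c("dr", "dc")]
  one <- sapply(1:4, function(q)
    (2L * r - 2L + quads$dr[q]) * W2 + (2L * c - 1L + quads$dc[q]))
  idx <- do.call(rbind, lapply(seq_len(B), function(b) one + (b - 1L) * HW4))
  .idx_cache[[key]] <- idx
  idx
}

conv_fwd <- function(M, W, b, ci) {
  N <- nrow(M); Cin <- ncol(M)
  M2 <- rbind(M, 0)
  P <- matrix(M2[as.vector(ci), , drop = FALSE], N, 9L * Cin)
  Y <- P %*% W
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, P = P)
}

conv_bwd <- function(dY, cache, W, ci, Cin) {
  N <- nrow(dY)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(W)
  dM <- matrix(0, N, Cin)
  for (j in 1:9) {
    cols <- j + (seq_len(Cin) - 1L) * 9L
    src <- ci[, j]
    valid <- src <= N
    dM[src[valid], ] <- dM[src[valid], ] + dP[valid, cols, drop = FALSE]
  }
  list(dM = dM, dW = dW, db = db)
}

bn_fwd <- function(M, gamma, beta, state, momentum, training, eps = 1e-3) {
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(M, 2, mu), 2, invstd, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd), state = state)
}

bn_bwd <- function(dY, cache, gamma) {
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  t1 <- sweep(dY, 2, dbeta / N)
  t2 <- sweep(xhat, 2, dgamma / N, "*")
  dX <- sweep(t1 - t2, 2, gamma * cache$invstd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(M) {
  mask <- M > 0
  list(Y = M * mask, mask = mask)
}

dropout_fwd <- function(M, p, training) {
  if (!training || p <= 0) return(list(Y = M, mask = NULL))
  mask <- matrix((runif(length(M)) >= p) / (1 - p), nrow(M), ncol(M))
  list(Y = M * mask, mask = mask)
}

maxpool_fwd <- function(M, pi) {
  A1 <- M[pi[, 1], , drop = FALSE]; A2 <- M[pi[, 2], , drop = FALSE]
  A3 <- M[pi[, 3], , drop = FALSE]; A4 <- M[pi[, 4], , drop = FALSE]
  Y <- pmax(pmax(A1, A2), pmax(A3, A4))
  list(Y = Y, A = list(A1, A2, A3, A4))
}

maxpool_bwd <- function(dY, cache, pi, n_in) {
  A <- cache$A; V <- cache$Y
  dM <- matrix(0, n_in, ncol(dY))
  taken <- matrix(FALSE, nrow(dY), ncol(dY))
  for (q in 1:4) {
    w <- (A[[q]] == V) & !taken        # route to the first max (ties once)
    taken <- taken | w
    dM[pi[, q], ] <- dM[pi[, q], ] + dY * w
  }
  dM
}

upconv_fwd <- function(M, Wq, b, ui) {
  Cout <- dim(Wq)[2]
  Y <- matrix(0, 4L * nrow(M), Cout)
  for (q in 1:4) Y[ui[, q], ] <- M %*% Wq[, , q]
  Y <- sweep(Y, 2, b, "+")
  Y
}

upconv_bwd <- function(dY, M, Wq, ui) {
  Cin <- ncol(M)
  dWq <- array(0, dim(Wq))
  dM <- matrix(0, nrow(M), Cin)
  for (q in 1:4) {
    dYq <- dY[ui[, q], , drop = FALSE]
    dWq[, , q] <- crossprod(M, dYq)
    dM <- dM + dYq %*% t(Wq[, , q])
  }
  list(dM = dM, dWq = dWq, db = colSums(dY))
}

se_fwd <- function(M, W1, b1, W2, b2, B) {
  HW <- nrow(M) / B
  sid <- rep(seq_len(B), each = HW)
  z <- rowsum(M, sid, reorder = FALSE) / HW
  h <- sweep(z %*% W1, 2, b1, "+")
  hr <- pmax(h, 0)
  u <- sweep(hr %*% W2, 2, b2, "+")
  s <- 1 / (1 + exp(-u))
  Y <- M * s[sid, , drop = FALSE]
  list(Y = Y, cache = list(z = z, h = h, hr = hr, s = s, sid = sid, HW = HW))
}

se_bwd <- function(dY, M, cache, W1, W2) {
  s <- cache$s; sid <- cache$sid
  dM <- dY * s[sid, , drop = FALSE]
  ds <- rowsum(dY * M, sid, reorder = FALSE)
  du <- ds * s * (1 - s)
  dW2 <- crossprod(cache$hr, du)
  db2 <- colSums(du)
  dhr <- du %*% t(W2)
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(cache$z, dh)
  db1 <- colSums(dh)
  dz <- dh %*% t(W1)
  dM <- dM + dz[sid, , drop = FALSE] / cache$HW
  list(dM = dM, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Squeeze-and-excitation gating of a feature map
#'
#' Global-average-pools each channel, passes the channel descriptor through a
#' two-layer bottleneck (`C -> floor(C/r) -> C`, ReLU then sigmoid), and
#' rescales every channel of the input by its gate in `(0, 1)`.
#'
#' @param x numeric array `H x W x C`.
#' @param weights list with `W1` (`C x floor(C/r)`), `b1`, `W2`
#'   (`floor(C/r) x C`), `b2`. Channel counts must satisfy `C >= r`, i.e.
#'   `floor(C/r) >= 1`.
#' @return array of the same shape, `x` scaled channel-wise.
#' @export
se_block <- function(x, weights) {
  d <- dim(x)
  assert_that(length(d) == 3, "x must be an H x W x C array",
              "hinge3_dimension_error")
  C <- d[3]
  assert_that(ncol(weights$W1) >= 1 && nrow(weights$W1) == C,
              "squeeze bottleneck needs C >= r (floor(C/r) >= 1)")
  M <- matrix(x, d[1] * d[2], C)
  out <- se_fwd(M, weights$W1, weights$b1, weights$W2, weights$b2, B = 1L)
  array(out$Y, d)
}

#' Soft Dice loss for binary segmentation
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` over the foreground
#' probabilities, with smoothing `eps` and optional masking of padded
#' positions (masked slots contribute to neither sum).
#'
#' @param pred numeric vector/array of foreground probabilities in `[0, 1]`.
#' @param target binary vector/array of the same shape.
#' @param mask optional logical vector/array of valid positions.
#' @param eps smoothing constant (default 1).
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, mask = NULL, eps = 1) {
  assert_that(length(pred) == length(target),
              "pred and target must have the same length",
              "hinge3_dimension_error")
  p <- as.numeric(pred); t <- as.numeric(target)
  if (!is.null(mask)) {
    assert_that(length(mask) == length(p), "mask length mismatch",
                "hinge3_dimension_error")
    p <- p[mask]; t <- t[mask]
  }
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

# Dice loss + gradient on the two-channel logits (channel 2 = foreground)
dice_on_logits <- function(logits, target, mask, eps = 1) {
  mm <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - mm); e2 <- exp(logits[, 2] - mm)
  p1 <- e2 / (e1 + e2)
  w <- as.numeric(mask)
  S_pt <- sum(w * p1 * target)
  S_p <- sum(w * p1); S_t <- sum(w * target)
  den <- S_p + S_t + eps
  loss <- 1 - (2 * S_pt + eps) / den
  dp1 <- w * (-2 * target * den + (2 * S_pt + eps)) / den^2
  g <- dp1 * p1 * (1 - p1)
  list(loss = loss, dlogits = cbind(-g, g), prob = p1)
}
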
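#' Feature aggregation configuration
#'
#' Each vertex's network input is the vector `[a, b1, ..., bk]` holding its
#' own morph value and the values at its `k` nearest neighbours (ambient
#' Euclidean distance, sorted ascending), giving `k + 1` channels. Vertices
#' are then tiled into fixed 64 x 64 x (k+1) blocks, so with the default
#' `k = 15` each block is 64 x 64 x 16.
#'
#' @param k neighbour count (default 15).
#' @param feature_names ordered character vector, subset of
#'   `c("sulc", "curv", "thick", "area", "vol")`.
#' @param block_rows,block_cols spatial block size (fixed 64 x 64).
#' @return a `feature_config` list with derived element `channels = k + 1`.
#' @export
feature_config <- function(k = 15L, feature_names = "sulc",
                           block_rows = 64L, block_cols = 64L) {
  assert_that(k >= 1, "k must be >= 1")
  bad <- setdiff(feature_names, c("sulc", "curv", "thick", "area", "vol"))
  assert_that(length(bad) == 0,
              paste0("unknown feature name(s): ", paste(bad, collapse = ", ")))
  structure(list(k = as.integer(k), channels = as.integer(k + 1L),
                 block_rows = as.integer(block_rows),
                 block_cols = as.integer(block_cols),
                 feature_names = feature_names),
            class = "feature_config")
}

# k nearest neighbour indices for every vertex (self excluded), ties at the
# k-th distance broken deterministically by lower vertex index. kd-tree with
# slack + exact re-sort; rows whose tie group may be truncated fall back to a
# brute-force scan.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  assert_that(k < n, sprintf("k = %d must be < n_vertices = %d", k, n))
  kq <- min(n, k + 17L)  # self + k + tie slack
  nn <- RANN::nn2(coords, coords, k = kq)
  idx <- matrix(0L, n, k)
  for (v in seq_len(n)) {
    cand <- nn$nn.idx[v, ]
    cd <- nn$nn.dists[v, ]
    keep <- cand != v
    cand <- cand[keep]; cd <- cd[keep]
    o <- order(cd, cand)
    cand <- cand[o]; cd <- cd[o]
    truncated <- kq < n && length(cd) >= k + 1L && cd[k] >= cd[length(cd)] - 1e-12
    if (truncated) {
      d2 <- (coords[, 1] - coords[v, 1])^2 + (coords[, 2] - coords[v, 2])^2 +
        (coords[, 3] - coords[v, 3])^2
      d2[v] <- Inf
      o <- order(d2, seq_len(n))[seq_len(k)]
      idx[v, ] <- o
    } else {
      idx[v, ] <- cand[seq_len(k)]
    }
  }
  idx
}

#' Aggregate a morph map into per-vertex KNN feature vectors
#'
#' Row `v` of the result is `[map(v), map(b1), ..., map(bk)]` where
#' `b1 ... bk` are `v`'s k nearest vertices by ambient Euclidean distance,
#' sorted ascending (ties broken by lower vertex index); `v` is excluded from
#' its own neighbour list.
#'
#' @param surface a [cortical_surface()].
#' @param map numeric per-vertex scalar vector.
#' @param cfg a [feature_config()].
#' @return numeric matrix, n x (k+1).
#' @export
knn_vectors <- function(surface, map, cfg = feature_config()) {
  n <- n_vertices(surface)
  assert_that(length(map) == n,
              sprintf("map length %d != %d vertices", length(map), n),
              "hinge3_dimension_error")
  nb <- knn_indices(surface$vertices, cfg$k)
  cbind(map, matrix(map[nb], n, cfg$k), deparse.level = 0)
}

#' Min-max normalise a feature matrix to [0, 1]
#'
#' Uses the minimum and maximum over all valid entries of the whole matrix
#' (one subject-hemisphere, one feature), so relative contrasts between
#' channels are preserved. A constant matrix maps to all zeros with a
#' warning. Rows with `mask = FALSE` (padding) are forced to 0 and never
#' contribute to the statistics.
#'
#' @param m numeric matrix, n x channels.
#' @param mask logical vector of valid rows (default all valid).
#' @return matrix of the same shape with valid entries in `[0, 1]`.
#' @export
normalize_minmax <- function(m, mask = NULL) {
  m <- as.matrix(m)
  mask <- mask %||% rep(TRUE, nrow(m))
  assert_that(length(mask) == nrow(m), "mask length must match rows",
              "hinge3_dimension_error")
  v <- m[mask, , drop = FALSE]
  lo <- min(v); hi <- max(v)
  out <- matrix(0, nrow(m), ncol(m))
  if (hi - lo <= 0) {
    warning("constant feature: all valid entries normalised to 0")
  } else {
    out[mask, ] <- (v - lo) / (hi - lo)
  }
  out
}

#' Pad a feature matrix with zero rows and tile it into 64 x 64 blocks
#'
#' Rows are padded with zeros up to the smallest multiple of
#' 64 x 64 = 4096 and laid out in native vertex order: 0-based row `i` goes
#' to block `floor(i / 4096)`, block row `floor((i mod 4096) / 64)`, block
#' column `i mod 64`. A 330,000-vertex hemisphere therefore pads to
#' 331,776 = 64 * 64 * 81 rows in 81 blocks. The index map makes the layout
#' invertible (see [unblock()]); padding slots are recorded in `pad_mask` and
#' never carry signal.
#'
#' @param m numeric matrix, n x channels (one feature), or a named list of
#'   such matrices sharing n (multi-feature run).
#' @param cfg a [feature_config()].
#' @param feature_name name used when `m` is a single matrix.
#' @return a `feature_blocks` object: `tensors` (named list of
#'   `n_blocks x 64 x 64 x channels` arrays), `index_map`
#'   (`n_blocks x 64 x 64` integer array, `NA` at padding), `pad_mask`
#'   (logical array), `n_vertices`, `n_blocks`, `cfg`.
#' @export
pad_and_block <- function(m, cfg = feature_config(), feature_name = "sulc") {
  if (!is.list(m)) {
    m <- stats::setNames(list(as.matrix(m)), feature_name)
  }
  n <- nrow(m[[1]])
  assert_that(n >= 1, "need at least one vertex")
  bs <- cfg$block_rows * cfg$block_cols
  n_blocks <- ceiling(n / bs)
  N <- n_blocks * bs
  to_tensor <- function(x) {
    assert_that(nrow(x) == n, "all feature matrices must share row count",
                "hinge3_dimension_error")
    P <- rbind(x, matrix(0, N - n, ncol(x)))
    # column-major fill: col fastest, then row, then block
    aperm(array(P, dim = c(cfg$block_cols, cfg$block_rows, n_blocks, ncol(x))),
          c(3, 2, 1, 4))
  }
  tensors <- lapply(m, to_tensor)
  idx <- c(seq_len(n), rep(NA_integer_, N - n))
  index_map <- aperm(array(idx, dim = c(cfg$block_cols, cfg$block_rows,
                                        n_blocks)), c(3, 2, 1))
  structure(list(tensors = tensors, index_map = index_map,
                 pad_mask = is.na(index_map), n_vertices = n,
                 n_blocks = as.integer(n_blocks), cfg = cfg),
            class = "feature_blocks")
}

#' @export
print.feature_blocks <- function(x, ...) {
  cat(sprintf("<feature_blocks> %d blocks of %d x %d x %d; %d vertices (%d padded); features: %s\n",
              x$n_blocks, x$cfg$block_rows, x$cfg$block_cols, x$cfg$channels,
              x$n_vertices, x$n_blocks * x$cfg$block_rows * x$cfg$block_cols -
                x$n_vertices, paste(names(x$tensors), collapse = ", ")))
  invisible(x)
}

#' Map blocked per-position values back to vertices
#'
#' Inverse of [pad_and_block()]'s spatial layout: values at padding slots are
#' discarded and every real vertex receives exactly one value.
#'
#' @param blocks a `feature_blocks` object.
#' @param predictions numeric array `n_blocks x 64 x 64` (e.g. per-position
#'   foreground probabilities or labels).
#' @return numeric vector of length `n_vertices`.
#' @export
unblock <- function(blocks, predictions) {
  dims <- c(blocks$n_blocks, blocks$cfg$block_rows, blocks$cfg$block_cols)
  assert_that(length(dim(predictions)) == 3 &&
                all(dim(predictions) == dims),
              sprintf("predictions must be a %s array",
                      paste(dims, collapse = " x ")),
              "hinge3_dimension_error")
  flat <- as.vector(aperm(predictions, c(3, 2, 1)))
  flat[seq_len(blocks$n_vertices)]
}

# flatten one block of one feature tensor into the [4096 x channels] matrix
# the network consumes (position p = col + (row-1)*64, column index fastest)
block_matrix <- function(blocks, feature, b) {
  t0 <- blocks$tensors[[feature]][b, , , , drop = TRUE]  # [row, col, ch]
  matrix(aperm(t0, c(2, 1, 3)),
         blocks$cfg$block_rows * blocks$cfg$block_cols, dim(t0)[3])
}

# blocked layout for a plain per-vertex vector (labels, masks)
block_vector <- function(x, blocks) {
  bs <- blocks$cfg$block_rows * blocks$cfg$block_cols
  N <- blocks$n_blocks * bs
  P <- c(x, rep(0, N - length(x)))
  aperm(array(P, dim = c(blocks$cfg$block_cols, blocks$cfg$block_rows,
                         blocks$n_blocks)), c(3, 2, 1))
}

#' Build network-ready feature blocks for one subject-hemisphere
#'
#' Convenience wrapper chaining [knn_vectors()], [normalize_minmax()] and
#' [pad_and_block()] over the configured features, producing one tensor per
#' feature with a shared index map.
#'
#' @param surface a [cortical_surface()].
#' @param morph a [morph_maps()] list.
#' @param cfg a [feature_config()].
#' @return a `feature_blocks` object.
#' @export
compute_feature_blocks <- function(surface, morph, cfg = feature_config()) {
  missing <- setdiff(cfg$feature_names, names(morph))
  assert_that(length(missing) == 0,
              paste0("morph maps missing feature(s): ",
                     paste(missing, collapse = ", ")))
  nb <- knn_indices(surface$vertices, cfg$k)
  n <- n_vertices(surface)
  mats <- lapply(cfg$feature_names, function(f) {
    map <- morph[[f]]
    normalize_minmax(cbind(map, matrix(map[nb], n, cfg$k),
                           deparse.level = 0))
  })
  names(mats) <- cfg$feature_names
  pad_and_block(mats, cfg)
}
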
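test_that("a constant map yields constant feature rows", {
  set.seed(4)
  s <- cortical_surface(matrix(runif(90), 30, 3), cbind(1:28, 2:29, 3:30))
  m <- knn_vectors(s, rep(3.5, 30), feature_config(k = 5))
  expect_identical(dim(m), c(30L, 6L))
  expect_true(all(m == 3.5))
})

test_that("KNN neighbour sets equal the brute-force full-sort oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(rnorm(90), 30, 3)
    s <- cortical_surface(pts, cbind(1:28, 2:29, 3:30))
    map <- rnorm(30)
    got <- knn_vectors(s, map, feature_config(k = 5))
    nb <- brute_knn(pts, 5)
    expect_equal(got, cbind(map, matrix(map[nb], 30, 5), deparse.level = 0))
  }
})

test_that("collinear points are ordered by distance", {
  pts <- cbind(0:9, 0, 0)
  s <- cortical_surface(pts, cbind(1:8, 2:9, 3:10))
  map <- (0:9) * 10
  m <- knn_vectors(s, map, feature_config(k = 2))
  expect_identical(m[1, ], c(0, 10, 20))   # x=0 -> neighbours at x=1, x=2
})

test_that("KNN ties at the k-th distance break to the lower vertex index", {
  # exact 1 mm lattice (flat, noiseless): the sqrt(5) ring ties must resolve
  sub <- generate_subject(synth_config(seed = 2, grid_shape = c(48, 48),
                                       ridge_height = 0, noise_sd = 0))
  pts <- sub$surface$vertices
  nb <- hinge3:::knn_indices(pts, 15L)
  d <- function(v, w) sqrt(sum((pts[v, ] - pts[w, ])^2))
  for (v in c(1000L, 2017L)) {
    dk <- vapply(nb[v, ], d, numeric(1), v = v)
    expect_true(all(diff(dk) >= -1e-12))
    # any excluded vertex at exactly the k-th distance has a higher index
    excl <- setdiff(seq_len(nrow(pts)), c(v, nb[v, ]))
    dists_excl <- sqrt(colSums((t(pts[excl, ]) - pts[v, ])^2))
    tied <- excl[abs(dists_excl - dk[15]) < 1e-12]
    if (length(tied)) expect_true(all(tied > max(nb[v, ][abs(dk - dk[15]) < 1e-12])))
  }
})

test_that("KNN is equivariant under vertex re-indexing", {
  set.seed(9)
  pts <- matrix(rnorm(120), 40, 3)
  s <- cortical_surface(pts, cbind(1:38, 2:39, 3:40))
  map <- rnorm(40)
  perm <- sample(40)
  s2 <- cortical_surface(pts[perm, ], cbind(1:38, 2:39, 3:40))
  m1 <- knn_vectors(s, map, feature_config(k = 4))
  m2 <- knn_vectors(s2, map[perm], feature_config(k = 4))
  expect_equal(m2, m1[perm, ])
})

test_that("min-max normalisation maps to [0, 1] with exact endpoints", {
  expect_identical(as.vector(normalize_minmax(matrix(c(2, 4, 6), 3))),
                   c(0, 0.5, 1))
  m <- matrix(c(0, 0.3, 1, 0.7), 2)
  expect_identical(normalize_minmax(m), m)
  set.seed(1)
  r <- normalize_minmax(matrix(rnorm(100), 20))
  expect_identical(range(r), c(0, 1))
  expect_warning(z <- normalize_minmax(matrix(5, 4, 2)), "constant")
  expect_true(all(z == 0))
  # masked rows stay zero and do not shape the statistics
  m2 <- rbind(c(100, 100), c(2, 4), c(4, 6))
  out <- normalize_minmax(m2, mask = c(FALSE, TRUE, TRUE))
  expect_identical(out[1, ], c(0, 0))
  expect_identical(range(out[2:3, ]), c(0, 1))
})

test_that("padding arithmetic matches the 64*64 block contract", {
  cfg <- feature_config()
  b1 <- pad_and_block(matrix(0, 330000, 16), cfg)
  expect_identical(b1$n_blocks, 81L)
  expect_identical(sum(!b1$pad_mask), 330000L)
  expect_identical(length(b1$pad_mask), 331776L)
  b2 <- pad_and_block(matrix(1, 4096, 16), cfg)
  expect_identical(b2$n_blocks, 1L)
  expect_identical(sum(b2$pad_mask), 0L)
  b3 <- pad_and_block(matrix(0, 365000, 16), cfg)
  expect_identical(b3$n_blocks, 90L)
})

test_that("blocks place row i at block/row/col given by the index arithmetic", {
  cfg <- feature_config(k = 1)
  n <- 5000L
  m <- matrix(seq_len(n), n, 2)
  b <- pad_and_block(m, cfg, "sulc")
  # 0-based row i -> block i %/% 4096, row (i %% 4096) %/% 64, col i %% 64
  for (i in c(0L, 63L, 64L, 4095L, 4096L, 4999L)) {
    expect_identical(b$tensors$sulc[i %/% 4096L + 1L,
                                    (i %% 4096L) %/% 64L + 1L,
                                    i %% 64L + 1L, 1L],
                     as.numeric(i + 1L))
    expect_identical(b$index_map[i %/% 4096L + 1L,
                                 (i %% 4096L) %/% 64L + 1L,
                                 i %% 64L + 1L], i + 1L)
  }
  # 5000 = 4096 + 904 rows; block 2 fills 14 full rows plus 8 entries
  expect_true(all(is.na(b$index_map[2, 16:64, ])))
  expect_true(all(is.na(b$index_map[2, 15, 9:64])))
  expect_true(all(!is.na(b$index_map[2, 15, 1:8])))
})

test_that("unblock inverts pad_and_block on every channel", {
  set.seed(7)
  n <- 6000L
  m <- matrix(rnorm(n * 16), n, 16)
  b <- pad_and_block(m, feature_config(), "sulc")
  for (ch in c(1L, 7L, 16L)) {
    expect_identical(unblock(b, b$tensors$sulc[, , , ch]), m[, ch])
  }
})

test_that("unblock is invariant to a consistent block permutation", {
  set.seed(8)
  n <- 9000L
  m <- matrix(rnorm(n), n, 1)
  b <- pad_and_block(m, feature_config(k = 1L), "sulc")
  pred <- b$tensors$sulc[, , , 1]
  perm <- c(3L, 1L, 2L)
  b2 <- b
  b2$tensors$sulc <- b$tensors$sulc[perm, , , , drop = FALSE]
  b2$index_map <- b$index_map[perm, , ]
  b2$pad_mask <- b$pad_mask[perm, , ]
  out2 <- rep(NA_real_, n)
  pred2 <- pred[perm, , ]
  idx2 <- b2$index_map
  out2[idx2[!is.na(idx2)]] <- pred2[!is.na(idx2)]
  expect_identical(out2, unblock(b, pred))
})

test_that("padded slots are zero and excluded from normalisation", {
  sub <- small_subject()
  fb <- compute_feature_blocks(sub$surface, sub$morph,
                               feature_config(feature_names = "sulc"))
  pad_vals <- fb$tensors$sulc[rep(fb$pad_mask, 16)]
  expect_true(all(pad_vals == 0))
  real <- fb$tensors$sulc[rep(!fb$pad_mask, 16)]
  expect_identical(range(real), c(0, 1))
})

test_that("k >= n_vertices is rejected", {
  s <- tetra_surface()
  expect_error(knn_vectors(s, rep(0, 4), feature_config(k = 4)),
               class = "hinge3_config_error")
})
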
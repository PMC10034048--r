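test_that("a symmetric two-point region gives a zero offset", {
  xm <- c(1, 2, 3)
  d <- c(0.5, -1, 2)
  cfg <- meanshift_config(weight_fn = "uniform")
  off <- shift_vector(xm, rbind(xm + d, xm - d), cfg)
  expect_equal(as.numeric(off), c(0, 0, 0))
})

test_that("a single-point region collapses the ratio to X1 - Xm", {
  xm <- c(0, 0, 0); x1 <- c(3, 4, 0)
  off <- shift_vector(xm, matrix(x1, 1), meanshift_config())
  expect_equal(as.numeric(off), x1)
  expect_equal(sqrt(sum(off^2)), 5)
})

test_that("the offset equals literal summation of the weighted kernel formula", {
  for (wf in c("gaussian_distance", "uniform")) {
    set.seed(17)
    pts <- matrix(rnorm(150, sd = 4), 50, 3)
    xm <- c(0.5, -0.2, 1)
    cfg <- meanshift_config(weight_fn = wf)
    expect_lt(max(abs(shift_vector(xm, pts, cfg) - brute_shift(xm, pts, cfg))),
              1e-10)
  }
})

test_that("coincident points are flagged degenerate with zero offset", {
  xm <- c(1, 1, 1)
  off <- shift_vector(xm, rbind(xm, xm, xm), meanshift_config())
  expect_identical(as.numeric(off), c(0, 0, 0))
  expect_true(attr(off, "degenerate"))
})

test_that("mode iteration honours the stopping contracts", {
  pt <- matrix(c(2, 2, 2), 1)
  res <- mean_shift_mode(c(2, 2, 2), pt, meanshift_config())
  expect_lte(res$iters, 1L)
  expect_true(res$converged)
  # tol larger than the first offset stops after one iteration
  set.seed(1)
  pts <- matrix(rnorm(60), 20, 3)
  res2 <- mean_shift_mode(c(0, 0, 0), pts, meanshift_config(tol = 100))
  expect_identical(res2$iters, 1L)
})

test_that("the mode of an isotropic Gaussian cloud is near the sample mean", {
  set.seed(23)
  cfg <- meanshift_config(h = 6)
  pts <- matrix(rnorm(1500, sd = cfg$h / 2), 500, 3)
  mu <- colMeans(pts)
  res <- mean_shift_mode(mu + c(cfg$h, 0, 0), pts, cfg)
  expect_lt(sqrt(sum((res$mode - mu)^2)), 0.5 * cfg$h)
})

test_that("mean shift is translation and rotation equivariant", {
  set.seed(5)
  pts <- matrix(rnorm(90, sd = 3), 30, 3)
  seed <- c(1, 0, -1)
  cfg <- meanshift_config()
  m0 <- mean_shift_mode(seed, pts, cfg)$mode
  t <- c(10, -20, 5)
  mt <- mean_shift_mode(seed + t, sweep(pts, 2, t, "+"), cfg)$mode
  expect_equal(mt, m0 + t, tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mr <- mean_shift_mode(as.numeric(R %*% seed), pts %*% t(R), cfg)$mode
  expect_equal(mr, as.numeric(R %*% m0), tolerance = 1e-9)
})

test_that("uniform weights + flat kernel reproduce the sample-mean offset", {
  set.seed(11)
  pts <- matrix(rnorm(300, sd = 5), 100, 3)
  xm <- c(0.5, 0.5, 0)
  cfg <- meanshift_config(h = 4, weight_fn = "uniform", kernel = "flat")
  # literal spherical-window form: mean over the K points inside S_h
  inside <- rowSums(sweep(pts, 2, xm)^2) <= cfg$h^2
  eq1 <- colSums(sweep(pts[inside, , drop = FALSE], 2, xm)) / sum(inside)
  expect_equal(as.numeric(shift_vector(xm, pts, cfg)), eq1, tolerance = 1e-12)
})

test_that("find_centroids recovers well-separated planted blobs", {
  sub <- small_subject()
  ann <- sub$annotation
  # the two most distant junction balls on the sheet
  jd <- as.matrix(stats::dist(ann$three_hinge_centroids))
  pick <- which(jd == max(jd), arr.ind = TRUE)[1, ]
  ann2 <- hinge_annotation(integer(), ann$three_hinge_idx[pick],
                           ann$three_hinge_centroids[pick, , drop = FALSE])
  expect_gt(max(jd), 18)
  lab <- expand_regions(sub$surface, ann2, labeling_config(R1 = 6, R2 = 0))
  cs <- find_centroids(lab, sub$surface)
  expect_identical(nrow(cs), 2L)
  expect_lt(centroid_pre(cs, ann2$three_hinge_centroids), 6)
  mem <- attr(cs, "memberships")
  expect_setequal(mem$vertex, which(lab == 1L))
})

test_that("degenerate label patterns behave per contract", {
  sub <- small_subject()
  n <- n_vertices(sub$surface)
  expect_identical(nrow(find_centroids(integer(n), sub$surface)), 0L)
  one <- integer(n); one[500] <- 1L
  cs <- find_centroids(one, sub$surface,
                       meanshift_config(min_region_size = 1))
  expect_identical(nrow(cs), 1L)
  expect_equal(c(cs$x, cs$y, cs$z), unname(sub$surface$vertices[500, ]))
})

test_that("mode count is monotone non-increasing in merge_radius", {
  sub <- small_subject()
  lab <- expand_regions(sub$surface, sub$annotation,
                        labeling_config(R1 = 6, R2 = 0))
  counts <- vapply(c(0.5, 3, 8, 20), function(mr) {
    nrow(find_centroids(lab, sub$surface, meanshift_config(merge_radius = mr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every centroid lies inside the member bounding box expanded by h", {
  sub <- small_subject()
  lab <- expand_regions(sub$surface, sub$annotation)
  cfg <- meanshift_config()
  cs <- find_centroids(lab, sub$surface, cfg)
  mem <- attr(cs, "memberships")
  for (i in cs$centroid_id) {
    pts <- sub$surface$vertices[mem$vertex[mem$centroid_id == i], ,
                                drop = FALSE]
    lohi <- apply(pts, 2, range)
    p <- c(cs$x[i], cs$y[i], cs$z[i])
    expect_true(all(p >= lohi[1, ] - cfg$h & p <= lohi[2, ] + cfg$h))
  }
  # memberships partition the labeled vertices
  expect_identical(sort(mem$vertex), which(lab == 1L))
})
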
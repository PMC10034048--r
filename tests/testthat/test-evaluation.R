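test_that("region metrics follow the confusion-table formulas", {
  t <- c(1, 1, 0, 0, 1)
  m <- region_metrics(t, t)
  expect_identical(c(m$precision, m$recall, m$f1), c(100, 100, 100))
  # TP=2, FP=1, FN=1
  m2 <- region_metrics(c(1, 1, 1, 0), c(1, 1, 0, 1))
  expect_equal(m2$precision, 200 / 3, tolerance = 1e-10)
  expect_equal(m2$recall, 200 / 3, tolerance = 1e-10)
  expect_equal(m2$f1, 200 / 3, tolerance = 1e-10)
  # empty prediction, nonempty truth
  m3 <- region_metrics(c(0, 0, 0), c(1, 0, 1))
  expect_identical(c(m3$recall, m3$f1), c(0, 0))
  expect_false(m3$precision_defined)
  # mask excludes padding
  m4 <- region_metrics(c(1, 1), c(1, 0), mask = c(TRUE, FALSE))
  expect_identical(m4$f1, 100)
})

test_that("F1 lies between min and max of precision and recall", {
  set.seed(3)
  for (i in 1:20) {
    p <- rbinom(50, 1, 0.4); t <- rbinom(50, 1, 0.4)
    m <- region_metrics(p, t)
    if (m$precision_defined && m$recall_defined && m$precision + m$recall > 0) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-9)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-9)
    }
  }
})

test_that("centroid prediction error matches hand values and the oracle", {
  expect_identical(centroid_pre(rbind(c(1, 2, 3)), rbind(c(1, 2, 3))), 0)
  expect_identical(centroid_pre(rbind(c(3, 4, 0)), rbind(c(0, 0, 0))), 5)
  set.seed(6)
  tru <- matrix(rnorm(15), 5, 3)
  prd <- matrix(rnorm(21), 7, 3)
  oracle <- mean(apply(tru, 1, function(p)
    min(sqrt(rowSums(sweep(prd, 2, p)^2)))))
  expect_equal(centroid_pre(prd, tru), oracle, tolerance = 1e-12)
  # invariance to ordering and rigid translation of both sets
  sh <- c(5, -3, 2)
  expect_equal(centroid_pre(prd[sample(7), ], tru[sample(5), ]),
               centroid_pre(sweep(prd, 2, sh, "+"), sweep(tru, 2, sh, "+")),
               tolerance = 1e-12)
  expect_identical(centroid_pre(matrix(numeric(), 0, 3), tru), Inf)
  expect_error(centroid_pre(prd, matrix(numeric(), 0, 3)),
               class = "hinge3_config_error")
  # secondary directions
  expect_equal(centroid_pre(prd, tru, "symmetric"),
               (centroid_pre(prd, tru) + centroid_pre(tru, prd)) / 2)
})

test_that("subject aggregation: identity, macro mean, micro pooling", {
  one <- tibble::tibble(subject_id = "s1", hemisphere = "lh",
                        tp = 10, fp = 5, fn = 2,
                        precision = 100 * 10 / 15, recall = 100 * 10 / 12,
                        f1 = 2 * (10 / 15) * (10 / 12) / (10 / 15 + 10 / 12) * 100,
                        pre = 4.2)
  r1 <- aggregate_subjects(one)
  expect_equal(r1$summary$f1, one$f1)
  expect_equal(r1$summary$lh_pre, 4.2)
  expect_equal(r1$summary$mean_pre, 4.2)

  two <- dplyr::bind_rows(one,
    tibble::tibble(subject_id = "s2", hemisphere = "rh", tp = 20, fp = 2,
                   fn = 30, precision = 100 * 20 / 22, recall = 100 * 20 / 50,
                   f1 = 70, pre = 6))
  two$f1 <- c(60, 70)
  macro <- aggregate_subjects(two, "macro")
  expect_equal(macro$summary$f1, 65)
  micro <- aggregate_subjects(two, "micro")
  tp <- 30; fp <- 7; fn <- 32
  P <- 100 * tp / (tp + fp); R <- 100 * tp / (tp + fn)
  expect_equal(micro$summary$precision, P)
  expect_equal(micro$summary$f1, 2 * P * R / (P + R))
  expect_equal(macro$summary$lh_pre, 4.2)
  expect_equal(macro$summary$rh_pre, 6)
  expect_equal(macro$summary$mean_pre, mean(c(4.2, 6)))
})

test_that("micro pooling equals recomputation on concatenated vertex arrays", {
  set.seed(9)
  preds <- list(rbinom(40, 1, 0.3), rbinom(60, 1, 0.5))
  trus <- list(rbinom(40, 1, 0.3), rbinom(60, 1, 0.4))
  rows <- purrr::map2(preds, trus, region_metrics)
  ps <- dplyr::bind_cols(
    tibble::tibble(subject_id = c("a", "b"), hemisphere = c("lh", "lh")),
    dplyr::bind_rows(rows))
  ps$pre <- NA_real_
  micro <- aggregate_subjects(ps, "micro")
  pooled <- region_metrics(unlist(preds), unlist(trus))
  expect_equal(micro$summary$precision, pooled$precision)
  expect_equal(micro$summary$recall, pooled$recall)
  expect_equal(micro$summary$f1, pooled$f1)
})

test_that("gender correlation matches the closed-form point-biserial value", {
  acc <- c(60, 62, 61, 70, 71, 69)
  g <- c(0, 0, 0, 1, 1, 1)
  out <- gender_correlation(acc, g)
  n0 <- 3; n1 <- 3; n <- 6
  sx <- sd(acc) * sqrt((n - 1) / n)  # population sd
  rpb <- sqrt(n0 * n1) / n * (mean(acc[g == 1]) - mean(acc[g == 0])) / sx
  expect_equal(abs(out$r), abs(rpb), tolerance = 1e-12)
  # label swap negates r, keeps p
  sw <- gender_correlation(acc, 1 - g)
  expect_equal(sw$r, -out$r)
  expect_equal(sw$p_value, out$p_value)
})

test_that("the t-based p-value agrees with a permutation null", {
  set.seed(31)
  n <- 24
  g <- rep(c(0, 1), n / 2)
  acc <- rnorm(n) + 0.8 * g
  out <- gender_correlation(acc, g)
  perm <- replicate(2000, abs(cor(acc, sample(g))))
  p_emp <- mean(perm >= abs(out$r))
  mc_err <- 3 * sqrt(out$p_value * (1 - out$p_value) / 2000)
  expect_lt(abs(p_emp - out$p_value), mc_err + 0.02)
})

test_that("accuracy independent of gender keeps |r| small", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    acc <- rnorm(100)
    g <- rep(c(0, 1), 50)
    if (abs(gender_correlation(acc, g)$r) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("degenerate gender inputs are rejected", {
  expect_error(gender_correlation(c(1, 2, 3), c(0, 0, 0)), "both genders")
  expect_error(gender_correlation(c(1, 1, 1, 1), c(0, 1, 0, 1)),
               "non-constant")
  expect_error(gender_correlation(c(1, 2), c(0, 1)), "n >= 3")
})
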
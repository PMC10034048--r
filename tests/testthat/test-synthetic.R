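test_that("flat sheet (ridge_height 0, noise 0) has no hinges and z == 0", {
  cfg <- synth_config(seed = 1, grid_shape = c(32, 32), ridge_height = 0,
                      noise_sd = 0)
  sub <- generate_subject(cfg)
  expect_identical(length(sub$annotation$two_hinge_idx), 0L)
  expect_identical(length(sub$annotation$three_hinge_idx), 0L)
  expect_identical(nrow(sub$annotation$three_hinge_centroids), 0L)
  expect_identical(max(abs(sub$surface$vertices[, 3])), 0)
})

test_that("generation is a pure function of the config", {
  a <- generate_subject(small_cfg(3))
  b <- generate_subject(small_cfg(3))
  expect_identical(a$surface$vertices, b$surface$vertices)
  expect_identical(a$morph$sulc, b$morph$sulc)
  expect_identical(a$annotation$three_hinge_idx, b$annotation$three_hinge_idx)
  c_ <- generate_subject(small_cfg(4))
  expect_false(identical(a$surface$vertices[, 3], c_$surface$vertices[, 3]))
})

test_that("planted junction count equals an independent graph-oracle count", {
  for (pattern in c("hex_lattice", "tri_lattice", "random_voronoi")) {
    cfg <- synth_config(seed = 5, grid_shape = c(128, 128),
                        ridge_pattern = pattern,
                        n_cells = if (pattern == "tri_lattice") 16L else 8L,
                        margin = 8)
    sk <- ridge_skeleton(cfg)
    g <- igraph::graph_from_edgelist(sk$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(sk$nodes) - igraph::vcount(g)))
    oracle <- sum(igraph::degree(g) >= 3)
    expect_identical(length(sk$junctions), oracle)
    expect_gt(oracle, 0)
    # annotation carries one centroid per junction
    sub <- generate_subject(cfg)
    expect_identical(nrow(sub$annotation$three_hinge_centroids),
                     length(sub$skeleton$junctions))
  }
})

test_that("junction count is invariant to vertex jitter noise", {
  base <- small_cfg(7)
  counts <- vapply(c(0, 0.2, 1), function(ns) {
    cfg <- base; cfg$noise_sd <- ns
    nrow(generate_subject(cfg)$annotation$three_hinge_centroids)
  }, numeric(1))
  expect_identical(length(unique(counts)), 1L)
})

test_that("morph maps carry the promised geometric couplings", {
  cfg <- synth_config(seed = 9, grid_shape = c(128, 128), n_cells = 8L,
                      margin = 8, ridge_height = 8, noise_sd = 0.8)
  stopifnot(abs(cfg$noise_sd - 0.1 * cfg$ridge_height) < 1e-12)
  sub <- generate_subject(cfg)
  # sulc anticorrelated with ridge height at noise_sd = 0.1 * ridge_height
  expect_lt(cor(sub$morph$sulc, sub$height), -0.9)
  # curv changes sign between crest and fundus: negative on crests (convex),
  # positive on the flanks
  sk <- sub$skeleton
  px <- sub$surface$vertices[, 1]; py <- sub$surface$vertices[, 2]
  d <- hinge3:::min_segment_dist(px, py, sk$nodes, sk$edges)
  expect_lt(mean(sub$morph$curv[d < 0.5]), 0)
  expect_gt(mean(sub$morph$curv[d > 2 & d < 4]), 0)
  # crowns thicker than fossae
  expect_gt(mean(sub$morph$thick[d < 1]), mean(sub$morph$thick[d > 8]))
  # vol = area * thick by construction
  expect_equal(sub$morph$vol, sub$morph$area * sub$morph$thick)
})

test_that("the sheet mesh is manifold: every edge borders at most 2 faces", {
  sub <- small_subject()
  f <- sub$surface$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_lte(max(table(key)), 2L)
})

test_that("cohort manifests alternate genders and derive per-subject seeds", {
  cfg <- small_cfg(21)
  co <- generate_cohort(6, cfg, gender_effect = 0)
  expect_identical(co$gender, rep(c(0L, 1L), 3))
  expect_identical(length(unique(co$seed)), 6L)
  co2 <- generate_cohort(2, cfg)
  expect_identical(sort(co2$gender), c(0L, 1L))
  # realising a subject yields both hemispheres with independent seeds
  subj <- cohort_subject(co, 1)
  expect_identical(subj$lh$surface$hemisphere, "lh")
  expect_identical(subj$rh$surface$hemisphere, "rh")
  expect_false(identical(subj$lh$surface$vertices[, 3],
                         subj$rh$surface$vertices[, 3]))
})

test_that("a planted gender effect is recovered from cohort ridge heights", {
  base <- small_cfg(31)
  # null case: group means differ only by sampling noise
  co0 <- generate_cohort(100, base, gender_effect = 0)
  d0 <- abs(diff(tapply(co0$ridge_height, co0$gender, mean)))
  se <- base$noise_sd * sqrt(1 / 50 + 1 / 50)
  expect_lt(d0, 4 * se)
  # planted effect of 2 * noise_sd recovered within 3 SE, 20 replicates
  eff <- 2 * base$noise_sd
  for (rep in 1:20) {
    cfg <- base; cfg$seed <- 1000L + rep
    co <- generate_cohort(100, cfg, gender_effect = eff)
    dhat <- diff(tapply(co$ridge_height, co$gender, mean))
    expect_lt(abs(dhat - eff), 3 * se)
  }
})
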
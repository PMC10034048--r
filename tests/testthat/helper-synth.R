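# shared fixtures, built once per test run

# small ridge sheet (96 x 96 mm, ~5 hexagonal cells, 4 junctions) used by
# several suites
small_cfg <- function(seed = 11L) {
  synth_config(seed = seed, grid_shape = c(96L, 96L), n_cells = 6L,
               margin = 8)
}

.fixture_env <- new.env(parent = emptyenv())

small_subject <- function(seed = 11L) {
  key <- paste0("sub", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_subject(small_cfg(seed))
  }
  .fixture_env[[key]]
}

# tetrahedron surface fixture
tetra_surface <- function() {
  cortical_surface(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# brute-force k nearest neighbours sorted by (distance, index), self excluded
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  t(vapply(seq_len(n), function(v) {
    d <- sqrt(colSums((t(coords) - coords[v, ])^2))
    d[v] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

# literal weighted mean-shift offset, scalar loop
brute_shift <- function(xm, pts, cfg) {
  num <- c(0, 0, 0); den <- 0
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(sum((pts[i, ] - xm)^2))
    u <- d / cfg$h
    g <- u / (sqrt(2 * pi) * cfg$s^3) * exp(-u^2 / (2 * cfg$s^2))
    w <- if (cfg$weight_fn == "uniform") 1 else exp(-d^2 / (2 * cfg$h^2))
    num <- num + g * w * (pts[i, ] - xm)
    den <- den + g * w
  }
  num / den
}
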
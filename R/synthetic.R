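#' Configuration for the synthetic cortical sheet generator
#'
#' The generator emulates the local geometry a hinge-detection pipeline sees
#' on a real hemisphere: a 2.5-D triangulated height-field sheet carrying a
#' network of gyral ridges whose triple junctions are exact, known 3-hinges.
#' A flat sheet (rather than a closed brain-like surface) is used because
#' every pipeline operation (KNN aggregation, spherical expansion, blocking,
#' mean shift) depends only on local geometry, and on a sheet the ground
#' truth is analytic.
#'
#' @param seed integer RNG seed; identical configs give identical output.
#' @param grid_shape `(rows, cols)` of the vertex lattice. The default
#'   256 x 256 at 1 mm spacing (65,536 vertices) is the test-scale sheet; a
#'   576 x 576 sheet (331,776 vertices) reproduces the per-subject block
#'   count of a full hemisphere padded to 81 blocks.
#' @param spacing mm between lattice vertices.
#' @param ridge_pattern `"hex_lattice"` (honeycomb ridges, degree-3
#'   junctions), `"tri_lattice"` (triangular, degree-6 junctions) or
#'   `"random_voronoi"` (Voronoi cell boundaries of random seed points).
#' @param n_cells target number of ridge cells on the sheet.
#' @param ridge_height mm amplitude of the gyral ridges (crest height above
#'   the fossae). `0` gives a flat sheet with no hinges.
#' @param ridge_sigma mm Gaussian cross-sectional width of a ridge.
#' @param noise_sd mm standard deviation of vertex height jitter; also scales
#'   the noise added to the morph maps. Hinge labels always come from the
#'   noiseless skeleton, so the planted junction count is invariant to it.
#' @param morph_coupling named list of coefficients linking ridge height to
#'   the morph maps: `sulc` (sulc = -sulc_coef * height + noise), `curv`
#'   (scales the signed mean curvature of the height field), `thick` (mm of
#'   extra cortical thickness per mm of ridge height; gyral crowns are
#'   thicker than fossae), `thick_base` (mm baseline thickness).
#' @param margin mm kept clear of the sheet border by the ridge network.
#' @return a `synth_config` list.
#' @seealso [generate_subject()], [ridge_skeleton()], [generate_cohort()]
#' @export
synth_config <- function(seed = 1L,
                         grid_shape = c(256L, 256L),
                         spacing = 1,
                         ridge_pattern = c("hex_lattice", "tri_lattice",
                                           "random_voronoi"),
                         n_cells = 24L,
                         ridge_height = 8,
                         ridge_sigma = 2.5,
                         noise_sd = 0.3,
                         morph_coupling = list(sulc = 1, curv = 1,
                                               thick = 0.12, thick_base = 2.5),
                         margin = 6) {
  ridge_pattern <- match.arg(ridge_pattern)
  assert_that(spacing > 0, "spacing must be > 0")
  assert_that(ridge_height >= 0, "ridge_height must be >= 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(length(grid_shape) == 2 && all(grid_shape >= 2),
              "grid_shape must be two integers >= 2")
  default_coupling <- list(sulc = 1, curv = 1, thick = 0.12, thick_base = 2.5)
  morph_coupling <- utils::modifyList(default_coupling, morph_coupling)
  structure(list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 spacing = spacing, ridge_pattern = ridge_pattern,
                 n_cells = as.integer(n_cells), ridge_height = ridge_height,
                 ridge_sigma = ridge_sigma, noise_sd = noise_sd,
                 morph_coupling = morph_coupling, margin = margin),
            class = "synth_config")
}

sheet_extent <- function(cfg) {
  c(w = (cfg$grid_shape[2] - 1) * cfg$spacing,
    h = (cfg$grid_shape[1] - 1) * cfg$spacing)
}

dedupe_nodes <- function(xy, digits = 6) {
  key <- paste(round(xy[, 1], digits), round(xy[, 2], digits))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(nodes = xy[first, , drop = FALSE], map = map)
}

#' Generate the planted gyral ridge skeleton
#'
#' Returns the noiseless 2-D ridge network of a synthetic sheet: node
#' coordinates, an edge list, and the indices of junction nodes (degree >= 3),
#' which are the planted 3-hinges.
#'
#' @param cfg a [synth_config()].
#' @return list with `nodes` (j x 2 matrix, mm), `edges` (e x 2 integer
#'   matrix of node indices) and `junctions` (integer node indices with
#'   degree >= 3).
#' @export
ridge_skeleton <- function(cfg) {
  ext <- sheet_extent(cfg)
  m <- min(cfg$margin, min(ext) / 4)
  lo <- c(m, m); hi <- c(ext[["w"]] - m, ext[["h"]] - m)
  area <- prod(hi - lo)
  assert_that(area > 0, "grid too small for the requested ridge margin")
  sk <- switch(cfg$ridge_pattern,
    hex_lattice = skeleton_hex(cfg, lo, hi, area),
    tri_lattice = skeleton_tri(cfg, lo, hi, area),
    random_voronoi = skeleton_voronoi(cfg, lo, hi, area))
  deg <- tabulate(c(sk$edges), nbins = nrow(sk$nodes))
  sk$junctions <- which(deg >= 3L)
  sk
}

finish_skeleton <- function(xy_all, edge_pairs, lo, hi) {
  dd <- dedupe_nodes(xy_all)
  e <- cbind(dd$map[edge_pairs[, 1]], dd$map[edge_pairs[, 2]])
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  # clip: drop nodes outside the margin box and their incident edges
  keep <- dd$nodes[, 1] >= lo[1] - 1e-9 & dd$nodes[, 1] <= hi[1] + 1e-9 &
    dd$nodes[, 2] >= lo[2] - 1e-9 & dd$nodes[, 2] <= hi[2] + 1e-9
  new_id <- cumsum(keep)
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  list(nodes = dd$nodes[keep, , drop = FALSE],
       edges = cbind(new_id[e[, 1]], new_id[e[, 2]]))
}

skeleton_hex <- function(cfg, lo, hi, area) {
  a <- sqrt(area / (2.598 * max(cfg$n_cells, 1L)))
  assert_that(a >= 2 * cfg$spacing,
              "grid too small to host n_cells ridge cells at this spacing")
  dx <- sqrt(3) * a; dy <- 1.5 * a
  rows <- seq(lo[2] + a, hi[2] - a, by = dy)
  assert_that(length(rows) >= 1, "grid too small to host any ridge cell")
  centers <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) dx / 2 else 0
    xs <- seq(lo[1] + a + off, hi[1] - a, by = dx)
    if (length(xs) == 0) return(NULL)
    cbind(xs, rows[i])
  }))
  assert_that(!is.null(centers) && nrow(centers) >= 1,
              "grid too small to host any ridge cell")
  th <- (90 + 60 * (0:5)) * pi / 180  # pointy-top hexagon corners
  verts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(centers[i, 1] + a * cos(th), centers[i, 2] + a * sin(th))
  }))
  k <- rep(seq(0, nrow(centers) - 1) * 6, each = 6)
  e <- cbind(k + rep(1:6, nrow(centers)), k + rep(c(2:6, 1), nrow(centers)))
  finish_skeleton(verts, e, lo, hi)
}

skeleton_tri <- function(cfg, lo, hi, area) {
  b <- sqrt(4 * area / (sqrt(3) * max(cfg$n_cells, 1L)))
  assert_that(b >= 2 * cfg$spacing,
              "grid too small to host n_cells ridge cells at this spacing")
  ys <- seq(lo[2], hi[2], by = b * sqrt(3) / 2)
  pts <- NULL; row_of <- integer(); col_of <- integer()
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) b / 2 else 0
    xs <- seq(lo[1] + off, hi[1], by = b)
    pts <- rbind(pts, cbind(xs, ys[i]))
    row_of <- c(row_of, rep(i, length(xs)))
    col_of <- c(col_of, seq_along(xs))
  }
  n <- nrow(pts)
  # connect every pair at lattice distance b (right + the two diagonals)
  e <- NULL
  for (i in seq_len(n)) {
    d <- row_dist(cbind(pts[, 1], pts[, 2], 0), c(pts[i, ], 0))
    j <- which(d > 1e-9 & d < b * 1.1)
    j <- j[j > i]
    if (length(j)) e <- rbind(e, cbind(i, j))
  }
  finish_skeleton(pts, e, lo, hi)
}

skeleton_voronoi <- function(cfg, lo, hi, area) {
  set.seed(derive_seed(cfg$seed, 17L))
  n <- max(cfg$n_cells, 2L)
  mind <- 0.5 * sqrt(area / n)
  pts <- matrix(numeric(), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 400L * n) {
    p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) > mind) {
      pts <- rbind(pts, p)
    }
    tries <- tries + 1L
  }
  assert_that(nrow(pts) >= 2, "grid too small to place Voronoi seeds")
  dd <- deldir::deldir(pts[, 1], pts[, 2],
                       rw = c(lo[1], hi[1], lo[2], hi[2]), suppressMsge = TRUE)
  segs <- dd$dirsgs
  xy <- rbind(as.matrix(segs[, c("x1", "y1")]), as.matrix(segs[, c("x2", "y2")]))
  colnames(xy) <- NULL
  e <- cbind(seq_len(nrow(segs)), seq_len(nrow(segs)) + nrow(segs))
  finish_skeleton(xy, e, lo, hi)
}

# minimum distance from each 2-D point to a set of segments
min_segment_dist <- function(px, py, nodes, edges) {
  dmin2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(edges))) {
    a <- nodes[edges[i, 1], ]; b <- nodes[edges[i, 2], ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    t <- if (len2 < 1e-12) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - a[1]) * dx + (py - a[2]) * dy) / len2))
    d2 <- (px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2
    dmin2 <- pmin(dmin2, d2)
  }
  sqrt(dmin2)
}

grid_faces <- function(R, C) {
  r <- rep(seq_len(R - 1), each = C - 1)
  c <- rep(seq_len(C - 1), times = R - 1)
  v00 <- (r - 1L) * C + c
  v01 <- v00 + 1L
  v10 <- v00 + C
  v11 <- v10 + 1L
  rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))
}

# per-vertex area: one third of each incident triangle's area
vertex_areas <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  ta <- 0.5 * sqrt(rowSums(cr^2))
  n <- nrow(vertices)
  a <- numeric(n)
  for (k in 1:3) {
    s <- rowsum(ta / 3, group = faces[, k])
    idx <- as.integer(rownames(s))
    a[idx] <- a[idx] + s[, 1]
  }
  a
}

# 5-point Laplacian of the height field with replicated borders
grid_laplacian <- function(z, R, C, spacing) {
  Z <- matrix(z, nrow = C)                       # Z[c, r], col index fastest
  shift <- function(M, dc, dr) {
    ci <- pmin(pmax(seq_len(C) + dc, 1L), C)
    ri <- pmin(pmax(seq_len(R) + dr, 1L), R)
    M[ci, ri, drop = FALSE]
  }
  L <- (shift(Z, 1, 0) + shift(Z, -1, 0) + shift(Z, 0, 1) + shift(Z, 0, -1) -
          4 * Z) / spacing^2
  as.vector(L)
}

#' Generate one synthetic cortical sheet with planted 3-hinges
#'
#' Builds a triangulated height-field sheet whose gyral ridges follow the
#' skeleton from [ridge_skeleton()]. Ridge crests rise `ridge_height` mm above
#' the fossae with Gaussian cross-section `ridge_sigma`. Morph maps are
#' statistically coupled to the geometry the way real FreeSurfer maps are:
#' `sulc` is anticorrelated with height (crowns negative), `curv` is the
#' signed mean curvature of the height field (negative on crests, positive on
#' flanks/fundi), `thick` is larger on ridges than in fossae, `area` comes
#' from incident triangle areas and `vol = area * thick`. Hinge annotations
#' are derived from the noiseless skeleton: junction-nearest mesh vertices are
#' 3-hinges, vertices sampled every `spacing` along crest lines (away from
#' junctions) are 2-hinges, and `three_hinge_centroids` holds the exact
#' junction coordinates.
#'
#' @param cfg a [synth_config()].
#' @param hemisphere hemisphere tag, `"lh"` or `"rh"`.
#' @return a `synth_subject` list: `surface` ([cortical_surface()]), `morph`
#'   ([morph_maps()]), `annotation` ([hinge_annotation()]), `skeleton` (see
#'   [ridge_skeleton()]), `height` (the noiseless per-vertex ridge height
#'   field, mm) and `cfg`.
#' @examples
#' sub <- generate_subject(synth_config(seed = 7, grid_shape = c(64, 64),
#'                                      n_cells = 4))
#' sub$annotation
#' @export
generate_subject <- function(cfg, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  R <- cfg$grid_shape[1]; C <- cfg$grid_shape[2]
  n <- R * C
  # vertex i = (r-1)*C + c at (x, y) = ((c-1)*sp, (r-1)*sp)
  cidx <- rep(seq_len(C), times = R)
  ridx <- rep(seq_len(R), each = C)
  px <- (cidx - 1) * cfg$spacing
  py <- (ridx - 1) * cfg$spacing

  flat <- cfg$ridge_height == 0
  sk <- if (flat) {
    list(nodes = matrix(numeric(), 0, 2), edges = matrix(integer(), 0, 2),
         junctions = integer())
  } else {
    ridge_skeleton(cfg)
  }
  h0 <- if (flat || nrow(sk$edges) == 0) {
    rep(0, n)
  } else {
    d <- min_segment_dist(px, py, sk$nodes, sk$edges)
    cfg$ridge_height * exp(-d^2 / (2 * cfg$ridge_sigma^2))
  }

  set.seed(cfg$seed)
  z <- h0 + if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
  vertices <- cbind(px, py, z)
  colnames(vertices) <- NULL
  surface <- cortical_surface(vertices, grid_faces(R, C), hemisphere)

  cp <- cfg$morph_coupling
  sulc <- -cp$sulc * h0 + if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
  curv <- cp$curv * 0.5 * grid_laplacian(h0, R, C, cfg$spacing)
  thick <- cp$thick_base + cp$thick * h0 +
    if (cfg$noise_sd > 0) rnorm(n, 0, 0.2 * cfg$noise_sd) else 0
  thick <- pmax(thick, 0.1)
  area <- vertex_areas(vertices, surface$faces)
  vol <- area * thick
  morph <- morph_maps(list(sulc = sulc, curv = curv, thick = thick,
                           area = area, vol = vol), surface)

  ann <- if (flat) {
    hinge_annotation(surface = surface)
  } else {
    annotate_from_skeleton(sk, cfg, R, C, cfg$ridge_height)
  }
  structure(list(surface = surface, morph = morph, annotation = ann,
                 skeleton = sk, height = h0, cfg = cfg,
                 hemisphere = hemisphere),
            class = "synth_subject")
}

nearest_grid_vertex <- function(x, y, cfg, R, C) {
  c <- pmin(pmax(round(x / cfg$spacing) + 1L, 1L), C)
  r <- pmin(pmax(round(y / cfg$spacing) + 1L, 1L), R)
  as.integer((r - 1L) * C + c)
}

annotate_from_skeleton <- function(sk, cfg, R, C, ridge_height) {
  jn <- sk$nodes[sk$junctions, , drop = FALSE]
  three_idx <- unique(nearest_grid_vertex(jn[, 1], jn[, 2], cfg, R, C))
  centroids <- cbind(jn, rep(ridge_height, nrow(jn)))  # skeleton lies on crest
  # 2-hinges: crest samples every `spacing`, clear of junctions
  excl <- 2 * cfg$spacing
  two_pts <- NULL
  for (i in seq_len(nrow(sk$edges))) {
    a <- sk$nodes[sk$edges[i, 1], ]; b <- sk$nodes[sk$edges[i, 2], ]
    len <- sqrt(sum((b - a)^2))
    if (len < 2 * excl) next
    t <- seq(0, len, by = cfg$spacing) / len
    p <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    if (nrow(jn) > 0) {
      dj <- sapply(seq_len(nrow(jn)), function(j)
        (p[, 1] - jn[j, 1])^2 + (p[, 2] - jn[j, 2])^2)
      dj <- if (is.matrix(dj)) do.call(pmin, as.data.frame(dj)) else dj
      p <- p[dj > excl^2, , drop = FALSE]
    }
    two_pts <- rbind(two_pts, p)
  }
  two_idx <- if (is.null(two_pts)) integer() else
    unique(nearest_grid_vertex(two_pts[, 1], two_pts[, 2], cfg, R, C))
  two_idx <- setdiff(two_idx, three_idx)
  hinge_annotation(two_idx, three_idx, centroids)
}

#' Generate a seeded cohort manifest with planted gender effect
#'
#' Subjects alternate gender labels (0, 1, 0, 1, ...). Each subject draws an
#' individual ridge height `base + gender * gender_effect + N(0, noise_sd)`
#' from a per-subject seed derived deterministically from the base seed, so
#' hinge prominence differs between the groups by `gender_effect` on average.
#' The manifest is lazy: call [cohort_subject()] to realise a subject's
#' surfaces.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param base_cfg a [synth_config()]; its `seed` is the cohort base seed.
#' @param gender_effect mm shift of ridge height for gender 1.
#' @return tibble with columns `subject_id`, `gender`, `seed`,
#'   `ridge_height`, and a `cfg` list-column of per-subject [synth_config()]s.
#' @export
generate_cohort <- function(n_subjects, base_cfg, gender_effect = 0) {
  assert_that(n_subjects >= 2, "n_subjects must be >= 2")
  rows <- lapply(seq_len(n_subjects), function(i) {
    g <- (i - 1L) %% 2L
    seed_i <- derive_seed(base_cfg$seed, i)
    set.seed(derive_seed(seed_i, 101L))
    rh <- base_cfg$ridge_height + g * gender_effect +
      if (base_cfg$noise_sd > 0) rnorm(1, 0, base_cfg$noise_sd) else 0
    rh <- max(rh, 0)
    cfg_i <- base_cfg
    cfg_i$seed <- seed_i
    cfg_i$ridge_height <- rh
    tibble::tibble(subject_id = sprintf("sub-%03d", i), gender = g,
                   seed = seed_i, ridge_height = rh, cfg = list(cfg_i))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "base_cfg") <- base_cfg
  attr(out, "gender_effect") <- gender_effect
  out
}

#' Realise both hemispheres of one cohort subject
#'
#' @param cohort a manifest from [generate_cohort()].
#' @param i subject row number.
#' @return list with `lh` and `rh` `synth_subject`s (independent seeds).
#' @export
cohort_subject <- function(cohort, i) {
  cfg <- cohort$cfg[[i]]
  cfg_rh <- cfg
  cfg_rh$seed <- derive_seed(cfg$seed, 2L)
  list(lh = generate_subject(cfg, "lh"), rh = generate_subject(cfg_rh, "rh"))
}
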
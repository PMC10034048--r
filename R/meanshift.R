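#' Mean-shift configuration for 3-hinge centroid extraction
#'
#' The bandwidth matrix is isotropic, `H = h^2 I`, so the kernel has a single
#' hyper-parameter `h`, tied to the 6 mm radius of a 3-hinge spherical
#' region. The kernel profile is the magnitude of the derivative of a
#' Gaussian, `g(u) = u / (sqrt(2*pi) * s^3) * exp(-u^2 / (2 s^2))`, evaluated
#' on the scaled scalar distance `u = ||X_i - X_m|| / h` (the radially
#' symmetric reading of the kernel under an isotropic bandwidth). Vertex
#' weights default to a Gaussian of the distance to the current centre, so
#' vertices close to the evolving cluster centre matter more; `uniform`
#' recovers the classical algorithm.
#'
#' @param h bandwidth in mm (default 6, the 3-hinge region radius).
#' @param s kernel scale constant (default `h / 2`).
#' @param tol convergence threshold on the offset norm, mm (default 1e-3).
#' @param max_iter maximum iterations per seed (default 200).
#' @param merge_radius mm within which converged modes are merged
#'   (default `h / 2`).
#' @param min_region_size minimum vertex count of a seeded connected
#'   component (default 5).
#' @param weight_fn `"gaussian_distance"` or `"uniform"`.
#' @param kernel `"gaussian_deriv"` (the derivative-of-Gaussian profile
#'   above) or `"flat"` (indicator of the `h`-ball); with `uniform` weights
#'   the flat kernel reduces one step to the classical sample-mean offset
#'   over the spherical window.
#' @return a `meanshift_config` list.
#' @export
meanshift_config <- function(h = 6, s = h / 2, tol = 1e-3, max_iter = 200L,
                             merge_radius = h / 2, min_region_size = 5L,
                             weight_fn = c("gaussian_distance", "uniform"),
                             kernel = c("gaussian_deriv", "flat")) {
  weight_fn <- match.arg(weight_fn)
  kernel <- match.arg(kernel)
  assert_that(h > 0 && s > 0 && tol > 0 && merge_radius >= 0,
              "need h > 0, s > 0, tol > 0, merge_radius >= 0")
  structure(list(h = h, s = s, tol = tol, max_iter = as.integer(max_iter),
                 merge_radius = merge_radius,
                 min_region_size = as.integer(min_region_size),
                 weight_fn = weight_fn, kernel = kernel),
            class = "meanshift_config")
}

#' Weighted mean-shift offset at a point
#'
#' Computes `M_h(X_m) = sum_i g(||X_i - X_m|| / h) w(X_i) (X_i - X_m) /`
#' `sum_i g(||X_i - X_m|| / h) w(X_i)` over the region points, with the
#' derivative-of-Gaussian profile `g` and weights `w` from the
#' configuration. If the total kernel-weight mass vanishes (all points
#' coincide with `X_m`, where `g(0) = 0`), a zero offset is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param xm numeric length-3 point (mm).
#' @param points numeric n x 3 matrix of region coordinates.
#' @param cfg a [meanshift_config()].
#' @return numeric length-3 offset, with attribute `degenerate`.
#' @export
shift_vector <- function(xm, points, cfg = meanshift_config()) {
  points <- matrix(as.numeric(points), ncol = 3)
  assert_that(nrow(points) >= 1, "region must contain at least one point")
  d <- row_dist(points, xm)
  u <- d / cfg$h
  g <- switch(cfg$kernel %||% "gaussian_deriv",
              gaussian_deriv =
                u / (sqrt(2 * pi) * cfg$s^3) * exp(-u^2 / (2 * cfg$s^2)),
              flat = as.numeric(u <= 1))
  w <- switch(cfg$weight_fn,
              gaussian_distance = exp(-d^2 / (2 * cfg$h^2)),
              uniform = rep(1, nrow(points)))
  gw <- g * w
  den <- sum(gw)
  if (den <= 1e-300) {
    off <- c(0, 0, 0)
    attr(off, "degenerate") <- TRUE
    return(off)
  }
  off <- colSums(gw * sweep(points, 2, xm)) / den
  attr(off, "degenerate") <- FALSE
  off
}

#' Iterate mean shift to a mode
#'
#' Repeats `X_m <- X_m + M_h(X_m)` until the offset norm falls below `tol`
#' or `max_iter` is reached.
#'
#' @inheritParams shift_vector
#' @param seed numeric length-3 starting point.
#' @return list with `mode` (length-3), `iters`, `converged`.
#' @export
mean_shift_mode <- function(seed, points, cfg = meanshift_config()) {
  xm <- as.numeric(seed)
  points <- matrix(as.numeric(points), ncol = 3)
  iters <- 0L
  converged <- FALSE
  while (iters < cfg$max_iter) {
    off <- shift_vector(xm, points, cfg)
    iters <- iters + 1L
    xm <- xm + as.numeric(off)
    if (sqrt(sum(off^2)) < cfg$tol || isTRUE(attr(off, "degenerate"))) {
      converged <- TRUE
      break
    }
  }
  list(mode = xm, iters = iters, converged = converged)
}

# connected components of the labeled vertex set under mesh edges
labeled_components <- function(labels, surface) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(list())
  f <- surface$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  keep <- labels[e[, 1]] > 0 & labels[e[, 2]] > 0
  e <- e[keep, , drop = FALSE]
  sub <- match(e, idx)
  g <- igraph::graph_from_edgelist(matrix(sub, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  split(idx, comp$membership)
}

# deterministic ~spacing-spaced subsample: lowest-index vertex per grid cell
grid_subsample <- function(idx, coords, spacing) {
  key <- paste(floor(coords[, 1] / spacing), floor(coords[, 2] / spacing),
               floor(coords[, 3] / spacing))
  idx[!duplicated(key)]
}

# iterate mean shift for many seeds at once: the offset of every still-active
# seed is computed in one matrix pass per iteration (identical arithmetic to
# mean_shift_mode, vectorised across seeds); seed chunks bound the S x N
# working set
local_modes <- function(seed_pts, pts, cfg) {
  S <- nrow(seed_pts); N <- nrow(pts)
  chunk <- max(1L, min(S, floor(4e6 / max(N, 1L))))
  modes <- matrix(0, S, 3)
  iters <- integer(S); conv <- logical(S)
  pts2 <- rowSums(pts^2)
  for (start in seq(1, S, by = chunk)) {
    rows <- start:min(start + chunk - 1L, S)
    X <- seed_pts[rows, , drop = FALSE]
    act <- rep(TRUE, length(rows))
    it <- integer(length(rows))
    cv <- logical(length(rows))
    n_iter <- 0L
    while (any(act) && n_iter < cfg$max_iter) {
      n_iter <- n_iter + 1L
      Xa <- X[act, , drop = FALSE]
      d2 <- outer(rowSums(Xa^2), pts2, "+") - 2 * (Xa %*% t(pts))
      d <- sqrt(pmax(d2, 0))
      u <- d / cfg$h
      g <- switch(cfg$kernel %||% "gaussian_deriv",
                  gaussian_deriv =
                    u / (sqrt(2 * pi) * cfg$s^3) * exp(-u^2 / (2 * cfg$s^2)),
                  flat = (u <= 1) + 0)
      w <- switch(cfg$weight_fn,
                  gaussian_distance = exp(-d^2 / (2 * cfg$h^2)),
                  uniform = 1)
      gw <- g * w
      den <- rowSums(gw)
      degen <- den <= 1e-300
      den[degen] <- 1
      off <- (gw %*% pts) / den - Xa
      off[degen, ] <- 0
      X[act, ] <- Xa + off
      done <- sqrt(rowSums(off^2)) < cfg$tol | degen
      idx <- which(act)
      it[idx] <- n_iter
      cv[idx[done]] <- TRUE
      act[idx[done]] <- FALSE
    }
    modes[rows, ] <- X
    iters[rows] <- it
    conv[rows] <- cv
  }
  list(modes = modes, iters = iters, conv = conv)
}

# merge modes within merge_radius: single-linkage clusters on the proximity
# graph, each replaced by its weight-averaged position (deterministic, and
# the cluster count is monotone non-increasing in merge_radius)
merge_modes <- function(xyz, weight, merge_radius) {
  n <- nrow(xyz)
  if (n < 2 || merge_radius <= 0) return(list(xyz = xyz, weight = weight))
  dd <- as.matrix(stats::dist(xyz)) < merge_radius
  memb <- igraph::components(
    igraph::graph_from_adjacency_matrix(dd, mode = "undirected",
                                        diag = FALSE))$membership
  k <- max(memb)
  w <- as.numeric(rowsum(weight, memb))
  pos <- rowsum(xyz * weight, memb) / w
  list(xyz = unname(pos), weight = w)
}

#' Identify 3-hinge centroids from predicted region labels
#'
#' Labeled vertices are split into connected components along mesh edges and
#' components smaller than `min_region_size` are discarded. Each remaining
#' component is seeded at a deterministic `h`-spaced subsample of its
#' vertices — one seed per bandwidth cell (a single connected component can
#' span several junctions, so one seed per component would under-count) —
#' every seed is iterated to a
#' mode with [mean_shift_mode()], and modes closer than `merge_radius` are
#' merged (weighted by the number of contributing seeds). Because the
#' derivative-of-Gaussian kernel admits unstable equilibria halfway along a
#' symmetric crest line, each merged mode is then stability-checked: mean
#' shift is restarted from the mode displaced by `merge_radius` along each
#' coordinate axis, and modes whose restarts do not all return within
#' `merge_radius` are dropped (their restarts flow into the neighbouring
#' stable modes and are merged there). Every labeled vertex is finally
#' assigned to its nearest surviving mode.
#'
#' @param labels per-vertex 0/1 vector.
#' @param surface a [cortical_surface()].
#' @param cfg a [meanshift_config()].
#' @return a `centroid_set`: tibble with columns `centroid_id`, `hemisphere`,
#'   `x`, `y`, `z`, `cluster_size`, `iterations`, `converged`, carrying the
#'   vertex-to-centroid assignment as attribute `memberships` (tibble
#'   `vertex`, `centroid_id`).
#' @export
find_centroids <- function(labels, surface, cfg = meanshift_config()) {
  assert_that(length(labels) == n_vertices(surface),
              "labels length must equal the surface vertex count",
              "hinge3_dimension_error")
  comps <- labeled_components(labels, surface)
  comps <- comps[lengths(comps) >= cfg$min_region_size]
  empty <- tibble::tibble(centroid_id = integer(), hemisphere = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          cluster_size = integer(), iterations = integer(),
                          converged = logical())
  if (length(comps) == 0) {
    attr(empty, "memberships") <- tibble::tibble(vertex = integer(),
                                                 centroid_id = integer())
    class(empty) <- c("centroid_set", class(empty))
    return(empty)
  }
  all_modes <- list()
  for (vs in comps) {
    pts <- surface$vertices[vs, , drop = FALSE]
    seeds <- grid_subsample(seq_len(nrow(pts)), pts, max(cfg$h, 1e-6))
    runs <- local_modes(pts[seeds, , drop = FALSE], pts, cfg)
    merged <- merge_modes(runs$modes, rep(1, nrow(runs$modes)),
                          cfg$merge_radius)
    # stability check: restarts displaced by merge_radius must come back
    if (cfg$merge_radius > 0 && nrow(merged$xyz) > 1) {
      dirs <- rbind(diag(3), -diag(3)) * cfg$merge_radius
      nm <- nrow(merged$xyz)
      starts <- merged$xyz[rep(seq_len(nm), each = nrow(dirs)), ] +
        dirs[rep(seq_len(nrow(dirs)), nm), ]
      rr <- local_modes(starts, pts, cfg)
      back <- sqrt(rowSums((rr$modes -
        merged$xyz[rep(seq_len(nm), each = nrow(dirs)), ])^2)) <
        cfg$merge_radius
      stable <- vapply(seq_len(nm), function(i)
        all(back[(i - 1L) * nrow(dirs) + seq_len(nrow(dirs))]), logical(1))
      if (any(stable)) {
        pool <- rbind(merged$xyz[stable, , drop = FALSE], rr$modes)
        w <- c(merged$weight[stable] * 100, rep(1, nrow(rr$modes)))
        merged <- merge_modes(pool, w, cfg$merge_radius)
        # keep the heavy (originally stable) modes only
        keep <- merged$weight >= 100
        merged$xyz <- merged$xyz[keep, , drop = FALSE]
        merged$weight <- merged$weight[keep]
      }
    }
    iters <- max(runs$iters)
    conv <- all(runs$conv)
    all_modes[[length(all_modes) + 1L]] <-
      list(xyz = merged$xyz, iters = iters, conv = conv)
  }
  xyz <- do.call(rbind, lapply(all_modes, `[[`, "xyz"))
  iters <- rep(vapply(all_modes, `[[`, integer(1), "iters"),
               vapply(all_modes, function(m) nrow(m$xyz), integer(1)))
  conv <- rep(vapply(all_modes, `[[`, logical(1), "conv"),
              vapply(all_modes, function(m) nrow(m$xyz), integer(1)))
  members <- sort(unname(unlist(comps)))
  nearest <- RANN::nn2(xyz, surface$vertices[members, , drop = FALSE],
                       k = 1L)$nn.idx[, 1]
  size <- tabulate(nearest, nbins = nrow(xyz))
  out <- tibble::tibble(centroid_id = seq_len(nrow(xyz)),
                        hemisphere = surface$hemisphere,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        cluster_size = as.integer(size),
                        iterations = as.integer(iters), converged = conv)
  attr(out, "memberships") <- tibble::tibble(vertex = members,
                                             centroid_id = nearest)
  class(out) <- c("centroid_set", class(out))
  out
}

#' Plot a centroid set over the labeled region
#'
#' @param centroids a `centroid_set`.
#' @param surface optional [cortical_surface()] to draw member vertices.
#' @param labels optional per-vertex labels for context.
#' @return a ggplot object (x-y projection).
#' @export
plot_centroids <- function(centroids, surface = NULL, labels = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(surface) && !is.null(labels)) {
    df <- tibble::tibble(x = surface$vertices[, 1], y = surface$vertices[, 2],
                         label = factor(labels))
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$label != "0"),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey70", size = 0.3)
  }
  p + ggplot2::geom_point(
    data = centroids,
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$cluster_size),
    colour = "firebrick", shape = 4, stroke = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Predicted 3-hinge centroids", x = "x (mm)",
                  y = "y (mm)") +
    ggplot2::theme_minimal()
}
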
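#' Labeling configuration
#'
#' Radii of the spherical neighbourhoods used to expand annotated hinge
#' vertices into the binary 3-hinge region: `R1` around 3-hinge (junction)
#' vertices and `R2` around 2-hinge (crest) vertices. The defaults, 6 mm and
#' 2 mm, are the empirical radii for human cortex.
#'
#' @param R1 mm radius around 3-hinge vertices (default 6).
#' @param R2 mm radius around 2-hinge vertices (default 2).
#' @return a `labeling_config` list.
#' @export
labeling_config <- function(R1 = 6, R2 = 2) {
  assert_that(R1 >= 0 && R2 >= 0, "R1 and R2 must be >= 0")
  structure(list(R1 = R1, R2 = R2), class = "labeling_config")
}

#' Expand hinge vertices into a binary 3-hinge region label
#'
#' A vertex is labeled 1 iff its Euclidean (ambient) distance to any 3-hinge
#' vertex is <= `R1` or to any 2-hinge vertex is <= `R2`; all other vertices
#' are 0. Spherical neighbourhoods are ambient balls, not geodesic patches;
#' nearest-hinge distances are computed with a kd-tree ([RANN::nn2()]), and
#' correctness is defined by (and tested against) the brute-force all-pairs
#' distance rule.
#'
#' @param surface a [cortical_surface()].
#' @param ann a [hinge_annotation()] with 1-based vertex indices.
#' @param cfg a [labeling_config()].
#' @return integer vector of per-vertex 0/1 labels.
#' @examples
#' sub <- generate_subject(synth_config(seed = 1, grid_shape = c(64, 64),
#'                                      n_cells = 4))
#' labels <- expand_regions(sub$surface, sub$annotation)
#' mean(labels)
#' @export
expand_regions <- function(surface, ann, cfg = labeling_config()) {
  n <- n_vertices(surface)
  for (fld in c("two_hinge_idx", "three_hinge_idx")) {
    v <- ann[[fld]]
    assert_that(length(v) == 0 || (min(v) >= 1L && max(v) <= n),
                sprintf("annotation %s out of range [1, %d]", fld, n),
                "hinge3_format_error")
  }
  if (length(ann$two_hinge_idx) == 0 && length(ann$three_hinge_idx) == 0) {
    warning("empty hinge annotation: all labels are 0")
    return(integer(n))
  }
  lab <- rep(FALSE, n)
  within_r <- function(idx, r) {
    if (length(idx) == 0 || r < 0) return(rep(FALSE, n))
    d <- RANN::nn2(surface$vertices[idx, , drop = FALSE], surface$vertices,
                   k = 1L)$nn.dists[, 1]
    d <= r + 1e-9
  }
  lab <- within_r(ann$three_hinge_idx, cfg$R1) |
    within_r(ann$two_hinge_idx, cfg$R2)
  as.integer(lab)
}
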
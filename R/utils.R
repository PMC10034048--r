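# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hinge3 <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hinge3_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
assert_that <- function(cond, msg, class = "hinge3_config_error") {
  if (!isTRUE(cond)) stop_hinge3(msg, class)
  invisible(TRUE)
}

# deterministic 32-bit-safe derived seeds: seeds fan out from a base seed by a
# counter scheme so stages/subjects are independent but reproducible
derive_seed <- function(base, counter) {
  as.integer((as.double(base) * 48271 + counter * 9973 + 12345) %% 2147483647)
}

# md5 of a config-like list via its canonical JSON serialisation
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

# Euclidean distances from one point to rows of a matrix
row_dist <- function(pts, p) {
  sqrt(rowSums(sweep(pts, 2, p)^2))
}
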
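#' Construct a cortical surface object
#'
#' A triangular surface mesh with vertex coordinates in mm (surface RAS frame;
#' the pipeline is frame-agnostic because every distance it uses is
#' intra-subject) and a hemisphere tag. Vertex indices are 1-based in memory;
#' on-disk plain-text index lists use 0-based indices with an `index_base=`
#' header (see [read_hinge_list()]).
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param hemisphere `"lh"` or `"rh"`.
#' @return An object of class `cortical_surface` with elements `vertices`,
#'   `faces`, `hemisphere`.
#' @examples
#' s <- cortical_surface(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' )
#' n_vertices(s)
#' @export
cortical_surface <- function(vertices, faces, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  assert_that(ncol(vertices) == 3, "vertices must be an n x 3 matrix",
              "hinge3_format_error")
  assert_that(ncol(faces) == 3, "faces must be an m x 3 matrix",
              "hinge3_format_error")
  assert_that(nrow(vertices) >= 3, "a surface needs at least 3 vertices",
              "hinge3_format_error")
  assert_that(all(is.finite(vertices)), "vertex coordinates must be finite",
              "hinge3_format_error")
  n <- nrow(vertices)
  if (nrow(faces) > 0) {
    assert_that(all(faces >= 1L) && all(faces <= n),
                sprintf("face indices must lie in [1, %d]", n),
                "hinge3_format_error")
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    assert_that(!any(degen), "degenerate faces (repeated vertex index)",
                "hinge3_format_error")
  }
  structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere),
            class = "cortical_surface")
}

#' @rdname cortical_surface
#' @param x a `cortical_surface`.
#' @export
n_vertices <- function(x) nrow(x$vertices)

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("<cortical_surface> %s: %d vertices, %d faces\n",
              x$hemisphere, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Validate a named set of per-vertex morphometry maps
#'
#' @param maps named list of numeric vectors; names drawn from
#'   `c("sulc", "curv", "thick", "area", "vol")`.
#' @param surface the `cortical_surface` the maps belong to.
#' @return the validated list, classed `morph_maps`.
#' @export
morph_maps <- function(maps, surface) {
  assert_that(is.list(maps) && !is.null(names(maps)) && all(nzchar(names(maps))),
              "maps must be a named list", "hinge3_format_error")
  bad <- setdiff(names(maps), c("sulc", "curv", "thick", "area", "vol"))
  assert_that(length(bad) == 0,
              paste0("unknown morph map name(s): ", paste(bad, collapse = ", ")),
              "hinge3_format_error")
  n <- n_vertices(surface)
  for (nm in names(maps)) {
    assert_that(length(maps[[nm]]) == n,
                sprintf("map '%s' has length %d, surface has %d vertices",
                        nm, length(maps[[nm]]), n),
                "hinge3_dimension_error")
    assert_that(all(is.finite(maps[[nm]])),
                sprintf("map '%s' contains non-finite values", nm),
                "hinge3_format_error")
  }
  structure(maps, class = "morph_maps")
}

# ---------------------------------------------------------------------------
# FreeSurfer binary formats (big-endian). Triangle surface: 3-byte magic
# 0xFFFFFE, comment terminated by "\n\n", int32 vcount/fcount, float32 xyz,
# int32 faces (0-based on disk). Morph ("curv") new format: 3-byte magic
# 0xFFFFFF, int32 vnum/fnum/vals_per_vertex, float32 values.
# ---------------------------------------------------------------------------

TRIANGLE_MAGIC <- 16777214L # 0xFFFFFE
MORPH_MAGIC <- 16777215L    # 0xFFFFFF

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) return(NA_integer_)
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_int3 <- function(con, x) {
  writeBin(as.raw(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)), con)
}

#' Read a cortical surface file
#'
#' Reads FreeSurfer binary triangle surfaces or GIfTI surface files.
#' Coordinates are kept in the file's native frame (no registration or
#' resampling). Truncated or malformed files raise a typed format error that
#' names the failing element.
#'
#' @param path file path.
#' @param fmt `"freesurfer"` or `"gifti"`; default guesses from the extension
#'   (`.gii` is GIfTI, anything else FreeSurfer).
#' @param hemisphere hemisphere tag to attach (`"lh"` or `"rh"`); default
#'   guessed from the filename prefix, falling back to `"lh"`.
#' @return a [cortical_surface()].
#' @seealso [write_surface()], [read_morph()]
#' @export
read_surface <- function(path, fmt = NULL, hemisphere = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "hinge3_io_error")
  fmt <- fmt %||% (if (grepl("\\.gii$", path)) "gifti" else "freesurfer")
  fmt <- match.arg(fmt, c("freesurfer", "gifti"))
  hemisphere <- hemisphere %||%
    (if (grepl("(^|[/._-])rh", basename(path))) "rh" else "lh")
  if (fmt == "gifti") return(read_surface_gifti(path, hemisphere))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- read_int3(con)
  if (is.na(magic) || magic != TRIANGLE_MAGIC) {
    stop_hinge3(sprintf(
      "%s: bad magic at byte 0 (got %s, expected 0xFFFFFE triangle file)",
      path, ifelse(is.na(magic), "EOF", format(magic))), "hinge3_format_error")
  }
  # comment: bytes up to "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) {
      stop_hinge3(sprintf("%s: EOF inside comment header", path),
                  "hinge3_format_error")
    }
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L)) {
    stop_hinge3(sprintf("%s: truncated vertex/face count header", path),
                "hinge3_format_error")
  }
  nv <- counts[1]; nf <- counts[2]
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  if (length(v) < 3L * nv) {
    stop_hinge3(sprintf("%s: truncated at vertex %d of %d",
                        path, length(v) %/% 3L + 1L, nv), "hinge3_format_error")
  }
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(f) < 3L * nf) {
    stop_hinge3(sprintf("%s: truncated at face %d of %d",
                        path, length(f) %/% 3L + 1L, nf), "hinge3_format_error")
  }
  vertices <- matrix(v, ncol = 3, byrow = TRUE)
  faces <- matrix(f, ncol = 3, byrow = TRUE) + 1L # disk is 0-based
  if (nf > 0 && (min(faces) < 1L || max(faces) > nv)) {
    stop_hinge3(sprintf("%s: face index out of range [0, %d)", path, nv),
                "hinge3_format_error")
  }
  cortical_surface(vertices, faces, hemisphere)
}

#' Write a cortical surface file
#'
#' @inheritParams read_surface
#' @param surface a [cortical_surface()].
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, fmt = NULL) {
  fmt <- fmt %||% (if (grepl("\\.gii$", path)) "gifti" else "freesurfer")
  fmt <- match.arg(fmt, c("freesurfer", "gifti"))
  if (fmt == "gifti") return(write_surface_gifti(surface, path))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  write_int3(con, TRIANGLE_MAGIC)
  writeChar("created by hinge3\n\n", con, eos = NULL)
  writeBin(as.integer(c(nrow(surface$vertices), nrow(surface$faces))), con,
           size = 4L, endian = "big")
  writeBin(as.numeric(t(surface$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(surface$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a per-vertex scalar morphometry map
#'
#' Reads FreeSurfer "curv"-format binary morph files or GIfTI functional
#' files. Values must be finite.
#'
#' @param path file path.
#' @param fmt `"freesurfer_curv"` or `"gifti"`; default guesses from the
#'   extension.
#' @param surface optional [cortical_surface()]; if supplied, the map length
#'   is checked against its vertex count.
#' @return numeric vector of per-vertex values.
#' @export
read_morph <- function(path, fmt = NULL, surface = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "hinge3_io_error")
  fmt <- fmt %||% (if (grepl("\\.gii$", path)) "gifti" else "freesurfer_curv")
  fmt <- match.arg(fmt, c("freesurfer_curv", "gifti"))
  if (fmt == "gifti") {
    vals <- read_morph_gifti(path)
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    magic <- read_int3(con)
    if (is.na(magic) || magic != MORPH_MAGIC) {
      stop_hinge3(sprintf("%s: bad magic at byte 0 (expected 0xFFFFFF)", path),
                  "hinge3_format_error")
    }
    hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    if (length(hdr) < 3L || hdr[1] < 0L) {
      stop_hinge3(sprintf("%s: truncated morph header", path),
                  "hinge3_format_error")
    }
    vals <- readBin(con, "numeric", n = hdr[1] * hdr[3], size = 4L,
                    endian = "big")
    if (length(vals) < hdr[1] * hdr[3]) {
      stop_hinge3(sprintf("%s: truncated at value %d of %d", path,
                          length(vals) + 1L, hdr[1] * hdr[3]),
                  "hinge3_format_error")
    }
  }
  assert_that(all(is.finite(vals)),
              sprintf("%s: morph map contains non-finite values", path),
              "hinge3_format_error")
  if (!is.null(surface)) {
    assert_that(length(vals) == n_vertices(surface),
                sprintf("%s: map length %d != surface vertex count %d",
                        path, length(vals), n_vertices(surface)),
                "hinge3_dimension_error")
  }
  vals
}

#' Write a per-vertex scalar morphometry map
#'
#' @inheritParams read_morph
#' @param values numeric vector of per-vertex values.
#' @return `path`, invisibly.
#' @export
write_morph <- function(values, path, fmt = NULL) {
  fmt <- fmt %||% (if (grepl("\\.gii$", path)) "gifti" else "freesurfer_curv")
  fmt <- match.arg(fmt, c("freesurfer_curv", "gifti"))
  assert_that(all(is.finite(values)), "morph values must be finite",
              "hinge3_format_error")
  if (fmt == "gifti") return(write_morph_gifti(values, path))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  write_int3(con, MORPH_MAGIC)
  writeBin(as.integer(c(length(values), 0L, 1L)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal GIfTI (XML) support: POINTSET+TRIANGLE surfaces and one-array
# functional files. Reader accepts ASCII, Base64Binary and GZipBase64Binary
# encodings; writer emits ASCII (plain text, diff-friendly).
# ---------------------------------------------------------------------------

gifti_decode_array <- function(da, path) {
  enc <- xml2::xml_attr(da, "Encoding")
  dtype <- xml2::xml_attr(da, "DataType")
  ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
  dims <- vapply(seq_len(ndim) - 1L, function(d)
    as.integer(xml2::xml_attr(da, paste0("Dim", d))), integer(1))
  order <- xml2::xml_attr(da, "ArrayIndexingOrder")
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//*[local-name()='Data']"))
  n <- prod(dims)
  vals <- switch(enc,
    ASCII = {
      v <- scan(text = txt, quiet = TRUE)
      if (dtype == "NIFTI_TYPE_INT32") v <- as.integer(round(v))
      v
    },
    Base64Binary = ,
    GZipBase64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      what <- if (dtype == "NIFTI_TYPE_INT32") "integer" else "numeric"
      size <- if (dtype == "NIFTI_TYPE_FLOAT64") 8L else 4L
      readBin(raw, what, n = n, size = size, endian = "little")
    },
    stop_hinge3(sprintf("%s: unsupported GIfTI encoding '%s'", path, enc),
                "hinge3_format_error")
  )
  if (length(vals) != n) {
    stop_hinge3(sprintf("%s: GIfTI data array has %d values, header says %d",
                        path, length(vals), n), "hinge3_format_error")
  }
  if (length(dims) == 2L) {
    if (identical(order, "ColumnMajorOrder")) {
      matrix(vals, nrow = dims[1])
    } else {
      matrix(vals, ncol = dims[2], byrow = TRUE)
    }
  } else {
    vals
  }
}

gifti_arrays <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_hinge3(sprintf("%s: not parseable XML (%s)", path,
                        conditionMessage(e)), "hinge3_format_error")
  })
  xml2::xml_find_all(doc, "//*[local-name()='DataArray']")
}

read_surface_gifti <- function(path, hemisphere) {
  das <- gifti_arrays(path)
  intents <- vapply(das, xml2::xml_attr, "", attr = "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1L || length(it) != 1L) {
    stop_hinge3(sprintf(
      "%s: GIfTI surface needs one POINTSET and one TRIANGLE array", path),
      "hinge3_format_error")
  }
  vertices <- gifti_decode_array(das[[ip]], path)
  faces <- gifti_decode_array(das[[it]], path) + 1L # 0-based on disk
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop_hinge3(sprintf("%s: face index out of range [0, %d)",
                        path, nrow(vertices)), "hinge3_format_error")
  }
  cortical_surface(vertices, faces, hemisphere)
}

gifti_header <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<GIFTI xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
         'Version="1.0" NumberOfDataArrays="%d">\n')
}

gifti_data_array <- function(vals, intent, dtype, dims) {
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  body <- paste(format(vals, digits = 9, trim = TRUE, scientific = FALSE),
                collapse = " ")
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="',
         length(dims), '" ', dim_attrs,
         ' Encoding="ASCII" Endian="LittleEndian">\n<Data>',
         body, '</Data>\n</DataArray>\n')
}

write_surface_gifti <- function(surface, path) {
  v <- as.vector(t(surface$vertices))
  f <- as.integer(t(surface$faces) - 1L)
  txt <- paste0(
    sprintf(gifti_header(), 2L),
    gifti_data_array(v, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                     c(nrow(surface$vertices), 3L)),
    gifti_data_array(f, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                     c(nrow(surface$faces), 3L)),
    "</GIFTI>\n")
  writeLines(txt, path, sep = "")
  invisible(path)
}

read_morph_gifti <- function(path) {
  das <- gifti_arrays(path)
  if (length(das) < 1L) {
    stop_hinge3(sprintf("%s: GIfTI file has no data array", path),
                "hinge3_format_error")
  }
  as.numeric(gifti_decode_array(das[[1]], path))
}

write_morph_gifti <- function(values, path) {
  txt <- paste0(
    sprintf(gifti_header(), 1L),
    gifti_data_array(as.numeric(values), "NIFTI_INTENT_NONE",
                     "NIFTI_TYPE_FLOAT32", length(values)),
    "</GIFTI>\n")
  writeLines(txt, path, sep = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Hinge annotations
# ---------------------------------------------------------------------------

#' Construct a hinge annotation
#'
#' Lists of 2-hinge (on-crest) and 3-hinge (junction) vertex indices plus the
#' ground-truth 3-hinge centroid coordinates. The two index lists must be
#' disjoint and valid for the surface.
#'
#' @param two_hinge_idx integer vector of 1-based vertex indices on gyral
#'   crest lines.
#' @param three_hinge_idx integer vector of 1-based vertex indices at gyral
#'   junctions.
#' @param three_hinge_centroids numeric matrix (j x 3) of junction
#'   coordinates in mm; may have zero rows.
#' @param surface optional [cortical_surface()] used to validate indices.
#' @return an object of class `hinge_annotation`.
#' @export
hinge_annotation <- function(two_hinge_idx = integer(),
                             three_hinge_idx = integer(),
                             three_hinge_centroids = matrix(numeric(), 0, 3),
                             surface = NULL) {
  two_hinge_idx <- as.integer(two_hinge_idx)
  three_hinge_idx <- as.integer(three_hinge_idx)
  three_hinge_centroids <- matrix(as.numeric(three_hinge_centroids), ncol = 3)
  assert_that(length(intersect(two_hinge_idx, three_hinge_idx)) == 0,
              "2-hinge and 3-hinge vertex lists must be disjoint",
              "hinge3_format_error")
  if (!is.null(surface)) {
    n <- n_vertices(surface)
    ok <- function(v) length(v) == 0 || (min(v) >= 1L && max(v) <= n)
    assert_that(ok(two_hinge_idx) && ok(three_hinge_idx),
                sprintf("hinge indices must lie in [1, %d]", n),
                "hinge3_format_error")
  }
  structure(list(two_hinge_idx = two_hinge_idx,
                 three_hinge_idx = three_hinge_idx,
                 three_hinge_centroids = three_hinge_centroids),
            class = "hinge_annotation")
}

#' @export
print.hinge_annotation <- function(x, ...) {
  cat(sprintf("<hinge_annotation> %d 2-hinge, %d 3-hinge vertices, %d centroids\n",
              length(x$two_hinge_idx), length(x$three_hinge_idx),
              nrow(x$three_hinge_centroids)))
  invisible(x)
}

#' Read / write plain-text vertex index lists
#'
#' One index per line; `#` starts a comment; an optional header line
#' `index_base=0` (default) or `index_base=1` declares the on-disk base.
#' Indices are returned 1-based regardless of the on-disk base.
#'
#' @param path file path.
#' @return `read_hinge_list()`: integer vector of 1-based indices.
#' @export
read_hinge_list <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "hinge3_io_error")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  base <- 0L
  is_hdr <- grepl("^index_base\\s*=", lines)
  if (any(is_hdr)) {
    base <- as.integer(sub("^index_base\\s*=\\s*", "", lines[which(is_hdr)[1]]))
    assert_that(base %in% c(0L, 1L), sprintf("%s: index_base must be 0 or 1", path),
                "hinge3_format_error")
  }
  lines <- lines[!is_hdr & nzchar(lines)]
  if (length(lines) == 0) return(integer())
  idx <- suppressWarnings(as.integer(lines))
  if (anyNA(idx)) {
    stop_hinge3(sprintf("%s: non-integer entry at line containing '%s'",
                        path, lines[which(is.na(idx))[1]]),
                "hinge3_format_error")
  }
  idx + (1L - base)
}

#' @rdname read_hinge_list
#' @param idx integer vector of 1-based vertex indices.
#' @param index_base on-disk base, 0 (default) or 1.
#' @export
write_hinge_list <- function(idx, path, index_base = 0L) {
  writeLines(c(sprintf("index_base=%d", index_base),
               format(as.integer(idx) - (1L - as.integer(index_base)))),
             path)
  invisible(path)
}

#' Write pipeline result files
#'
#' Writes per-vertex labels as a FreeSurfer curv-format 0/1 overlay plus a
#' plain-text vertex index list, centroids as a CSV
#' (`hemisphere,x,y,z,cluster_size`), and, if supplied, an evaluation metrics
#' JSON.
#'
#' @param labels integer/numeric vector of per-vertex 0/1 labels.
#' @param centroids a [centroid_set()] tibble (may have zero rows), or `NULL`.
#' @param out_dir output directory (created if missing).
#' @param prefix filename prefix, e.g. `"lh"`.
#' @param metrics optional list/tibble of metrics to store as JSON.
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(labels, centroids, out_dir, prefix = "lh",
                          metrics = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  assert_that(ok && file.access(out_dir, 2) == 0,
              sprintf("cannot write to directory %s", out_dir),
              "hinge3_io_error")
  paths <- c()
  if (!is.null(labels)) {
    p1 <- file.path(out_dir, paste0(prefix, ".hinge_labels.curv"))
    write_morph(as.numeric(labels), p1, fmt = "freesurfer_curv")
    p2 <- file.path(out_dir, paste0(prefix, ".hinge_labels.txt"))
    write_hinge_list(which(labels > 0), p2)
    paths <- c(overlay = p1, index_list = p2)
  }
  if (!is.null(centroids)) {
    p3 <- file.path(out_dir, paste0(prefix, ".centroids.csv"))
    df <- tibble::as_tibble(centroids)
    cols <- c("hemisphere", "x", "y", "z", "cluster_size")
    for (cc in setdiff(cols, names(df))) df[[cc]] <- if (cc == "hemisphere") prefix else NA
    readr::write_csv(df[, cols], p3)
    paths <- c(paths, centroids = p3)
  }
  if (!is.null(metrics)) {
    p4 <- file.path(out_dir, paste0(prefix, ".metrics.json"))
    jsonlite::write_json(metrics, p4, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    paths <- c(paths, metrics = p4)
  }
  invisible(paths)
}
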
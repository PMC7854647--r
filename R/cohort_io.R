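# Readers/writers for all on-disk formats: patch probability tables (CSV),
# tumor annotations (GeoJSON, pixel coordinates), binary masks (8-bit PNG),
# clinical tables and score tables (CSV). Validation is strict: readers never
# silently drop rows.

T_STAGE_LABELS <- c("T1a", "T1b", "T2a", "T2b", "T3a", "T3b", "T4a", "T4b")
STAGE_LABELS <- c("I", "II", "III")

#' Construct an image patch set
#'
#' Container for one image's lymphocyte-probability map on a fixed grid:
#' each patch is anchored by the pixel coordinates of its upper-left vertex
#' and carries the detector's probability of lymphocytic infiltration.
#'
#' @param image_id Image identifier (scalar character).
#' @param patches `data.frame` with columns `x`, `y` (non-negative integer
#'   pixel coordinates of the patch upper-left vertex) and `prob`
#'   (probability in `[0, 1]`).
#' @param patch_size Patch edge length in pixels (default 100, the upstream
#'   detector's tiling).
#' @return An object of class `image_patch_set`: a list with elements
#'   `image_id`, `patch_size`, `patches`.
#' @export
patch_set <- function(image_id, patches, patch_size = 100) {
  if (length(patch_size) != 1 || !is.finite(patch_size) || patch_size <= 0)
    abort_validation("patch_size must be a positive scalar")
  req <- c("x", "y", "prob")
  miss <- setdiff(req, names(patches))
  if (length(miss))
    abort_format("patch table is missing column(s): %s",
                 paste(miss, collapse = ", "))
  patches <- patches[req]
  for (cc in req) {
    if (!is.numeric(patches[[cc]]) || anyNA(patches[[cc]]))
      abort_validation("column '%s' must be numeric with no missing values", cc)
  }
  bad <- which(patches$prob < 0 | patches$prob > 1)
  if (length(bad))
    abort_validation("prob outside [0, 1] at row %d (value %g)",
                     bad[1], patches$prob[bad[1]])
  bad <- which(patches$x < 0 | patches$y < 0 |
                 patches$x != floor(patches$x) | patches$y != floor(patches$y))
  if (length(bad))
    abort_validation("x/y must be non-negative integers; first bad row %d", bad[1])
  patches$x <- as.integer(patches$x)
  patches$y <- as.integer(patches$y)
  dup <- duplicated(patches[c("x", "y")])
  if (any(dup))
    abort_validation("duplicate patch coordinates (x=%d, y=%d) at row %d",
                     patches$x[which(dup)[1]], patches$y[which(dup)[1]],
                     which(dup)[1])
  structure(list(image_id = as.character(image_id),
                 patch_size = as.integer(patch_size),
                 patches = patches),
            class = "image_patch_set")
}

#' Read a patch probability table
#'
#' Reads the documented upstream-detector output for one image: a CSV with
#' header `x,y,prob`, one row per 100x100-pixel patch, giving the upper-left
#' vertex coordinates and the lymphocyte probability. Other detector dialects
#' can be adapted by passing a `converter` that maps the raw `data.frame`
#' to these three columns before validation.
#'
#' @param path CSV file path.
#' @param patch_size Patch edge length in pixels (default 100).
#' @param image_id Image identifier; defaults to the file name without
#'   extension.
#' @param converter Optional function applied to the raw `data.frame` before
#'   validation (extension hook for other detector file dialects).
#' @return An [patch_set()] object.
#' @export
read_patch_table <- function(path, patch_size = 100,
                             image_id = tools::file_path_sans_ext(basename(path)),
                             converter = NULL) {
  if (!file.exists(path)) abort_format("patch table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(converter)) df <- converter(df)
  patch_set(image_id, df, patch_size)
}

#' Write a patch probability table
#'
#' Inverse of [read_patch_table()]; probabilities are printed with enough
#' digits (`%.17g`) that a write/read round trip reproduces every double
#' exactly.
#'
#' @param x An `image_patch_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(x, path) {
  stopifnot(inherits(x, "image_patch_set"))
  df <- data.frame(x = x$patches$x, y = x$patches$y,
                   prob = sprintf("%.17g", x$patches$prob))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) < 2 || !is.numeric(ring) || anyNA(ring))
    abort_validation("ring vertices must be numeric (x, y) pairs")
  ring <- ring[, 1:2, drop = FALSE]
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ]))       # closed by convention
    ring <- ring[-n, , drop = FALSE]
  if (nrow(unique(ring)) < 3)
    abort_validation("ring has fewer than 3 distinct vertices")
  dimnames(ring) <- NULL
  ring
}

#' Construct a tumor annotation
#'
#' One image's tumor region as one or more polygons in pixel coordinates.
#' Each polygon is a list of rings (open `n x 2` matrices): the first ring is
#' the outer loop, any further rings are holes. Fill semantics downstream are
#' even-odd, so holes subtract.
#'
#' @param image_id Image identifier.
#' @param polygons List of polygons; each polygon is a list of rings, a ring
#'   being an `n x 2` numeric matrix of vertices (a repeated closing vertex
#'   is dropped).
#' @return Object of class `tumor_annotation`.
#' @export
tumor_annotation <- function(image_id, polygons) {
  if (!length(polygons)) abort_validation("annotation has no polygons")
  polygons <- lapply(polygons, function(poly) {
    if (is.matrix(poly) || is.data.frame(poly)) poly <- list(poly)
    lapply(poly, normalize_ring)
  })
  structure(list(image_id = as.character(image_id), polygons = polygons),
            class = "tumor_annotation")
}

geojson_ring_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(pt) {
    if (length(pt) < 2) abort_validation("ring vertex with fewer than 2 coordinates")
    c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
  }))
}

extract_geometries <- function(obj) {
  type <- obj$type %||% abort_format("GeoJSON object has no 'type'")
  switch(type,
    FeatureCollection = do.call(c, lapply(obj$features, extract_geometries)),
    Feature = extract_geometries(obj$geometry),
    Polygon = list(list(type = "Polygon", coordinates = obj$coordinates)),
    MultiPolygon = list(list(type = "MultiPolygon", coordinates = obj$coordinates)),
    GeometryCollection = do.call(c, lapply(obj$geometries, extract_geometries)),
    abort_format("unsupported GeoJSON geometry type: %s", type)
  )
}

#' Read a tumor annotation from GeoJSON
#'
#' Reads Polygon or MultiPolygon geometry (RFC 7946 structure, but coordinates
#' interpreted as pixel positions, y increasing downward) as exported by e.g.
#' QuPath region annotations. Rings are normalized: the closing vertex is
#' dropped, the first ring of each polygon is the outer loop, later rings are
#' holes.
#'
#' @param path GeoJSON file path.
#' @param image_id Image identifier; defaults to file name without extension.
#' @return A [tumor_annotation()] object.
#' @export
read_annotation <- function(path,
                            image_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort_format("annotation file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- extract_geometries(obj)
  polygons <- list()
  for (g in geoms) {
    if (g$type == "Polygon") {
      polygons <- c(polygons, list(lapply(g$coordinates, geojson_ring_to_matrix)))
    } else {                                         # MultiPolygon
      polygons <- c(polygons,
                    lapply(g$coordinates,
                           function(poly) lapply(poly, geojson_ring_to_matrix)))
    }
  }
  tumor_annotation(image_id, polygons)
}

#' Write a tumor annotation to GeoJSON
#'
#' @param annotation A `tumor_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "tumor_annotation"))
  close_ring <- function(ring) {
    ring <- rbind(ring, ring[1, ])
    lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
  }
  coords <- lapply(annotation$polygons, function(poly) lapply(poly, close_ring))
  obj <- list(type = "Feature",
              properties = list(image_id = annotation$image_id),
              geometry = list(type = "MultiPolygon", coordinates = coords))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with one row per patient. Required columns: `patient_id`, `dss_event`
#' (1 = died of melanoma, 0 = censored, i.e. alive or dead of another cause),
#' `followup_months` (> 0). Optional columns: `depth_mm` (Breslow depth),
#' `ulceration` (0/1), `t_stage` (1..8 or labels T1a..T4b), `til_grade`
#' (0 absent, 1 non-brisk, 2 brisk), `node_or_satellite_positive` (0/1),
#' `stage` (I/II/III or 1..3), `institution`. Absent optional columns and
#' blank cells become `NA`; downstream model fits are complete-case.
#'
#' @param path CSV path.
#' @return A `data.frame` with one validated row per patient and all optional
#'   columns present (possibly all-`NA`).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort_format("clinical table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("patient_id", "dss_event", "followup_months")
  miss <- setdiff(req, names(df))
  if (length(miss))
    abort_format("clinical table is missing column(s): %s",
                 paste(miss, collapse = ", "))
  validate_clinical(df)
}

#' Validate a clinical data.frame
#'
#' Enforces the field invariants of [read_clinical_table()] on an in-memory
#' table (used by both the reader and the synthetic generator).
#'
#' @param df `data.frame` with at least `patient_id`, `dss_event`,
#'   `followup_months`.
#' @return The validated, normalized `data.frame`.
#' @export
validate_clinical <- function(df) {
  if (anyNA(df$dss_event) || !all(df$dss_event %in% c(0, 1)))
    abort_validation("dss_event must be 0 or 1 for every patient; first bad row %d",
                     which(!(df$dss_event %in% c(0, 1)))[1])
  bad <- which(!is.finite(df$followup_months) | df$followup_months <= 0)
  if (length(bad))
    abort_validation("followup_months must be > 0; bad value at row %d", bad[1])
  if (anyDuplicated(df$patient_id))
    abort_validation("duplicate patient_id: %s",
                     df$patient_id[anyDuplicated(df$patient_id)])
  opt_defaults <- list(depth_mm = NA_real_, ulceration = NA_integer_,
                       t_stage = NA_integer_, til_grade = NA_integer_,
                       node_or_satellite_positive = NA_integer_,
                       stage = NA_integer_, institution = NA_character_)
  for (cc in names(opt_defaults)) if (is.null(df[[cc]])) df[[cc]] <- opt_defaults[[cc]]
  if (is.character(df$t_stage))
    df$t_stage <- match(df$t_stage, T_STAGE_LABELS)
  if (is.character(df$stage))
    df$stage <- match(df$stage, STAGE_LABELS)
  chk <- function(col, ok, what) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !(v %in% ok))
    if (length(bad))
      abort_validation("%s must be one of {%s}; bad value at row %d",
                       col, what, bad[1])
  }
  chk("ulceration", c(0, 1), "0,1")
  chk("til_grade", c(0, 1, 2), "0,1,2")
  chk("node_or_satellite_positive", c(0, 1), "0,1")
  chk("t_stage", 1:8, "1..8 / T1a..T4b")
  chk("stage", 1:3, "I,II,III")
  bad <- which(!is.na(df$depth_mm) & df$depth_mm <= 0)
  if (length(bad))
    abort_validation("depth_mm must be > 0; bad value at row %d", bad[1])
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Read a binary tumor mask from PNG
#'
#' Single-channel 8-bit PNG; any nonzero pixel is tumor. Row 1 of the bitmap
#' is the top row of the image (pixel y = 0).
#'
#' @param path PNG path.
#' @param image_id Image identifier.
#' @return A [tumor_mask()] object.
#' @export
read_mask <- function(path, image_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort_format("mask file not found: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  tumor_mask(image_id, ifelse(img > 0, 1L, 0L))
}

#' Write a binary tumor mask to PNG
#'
#' @param mask A `tumor_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  png::writePNG(matrix(as.numeric(mask$bitmap), nrow = mask$height), path)
  invisible(path)
}

#' Read / write score tables
#'
#' Image-level score table columns: `patient_id`, `image_id`, `n_total`,
#' `n_pos`, `image_score`. Patient-level: `patient_id`, `adta`, `risk_class`.
#'
#' @param df Table to write.
#' @param path CSV path.
#' @return The table (readers) or `path` invisibly (writers).
#' @name score_tables
NULL

#' @rdname score_tables
#' @export
write_score_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname score_tables
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) abort_format("score table not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character"))
}

#' @export
print.image_patch_set <- function(x, ...) {
  cat(sprintf("<image_patch_set> %s: %d patches of %dpx, prob in [%.3f, %.3f]\n",
              x$image_id, nrow(x$patches), x$patch_size,
              min(x$patches$prob), max(x$patches$prob)))
  invisible(x)
}

#' @export
print.tumor_annotation <- function(x, ...) {
  nr <- sum(vapply(x$polygons, length, 1L))
  cat(sprintf("<tumor_annotation> %s: %d polygon(s), %d ring(s)\n",
              x$image_id, length(x$polygons), nr))
  invisible(x)
}
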
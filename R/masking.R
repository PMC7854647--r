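# Tumor-region masks: even-odd scanline rasterization of annotation polygons
# and patch membership decisions.

#' Construct a binary tumor mask
#'
#' @param image_id Image identifier.
#' @param bitmap Integer matrix in \{0, 1\}, `height` rows by `width` columns;
#'   row 1 is image row y = 0 (origin top-left), 1 = tumor.
#' @return Object of class `tumor_mask` with elements `image_id`, `width`,
#'   `height`, `bitmap`.
#' @export
tumor_mask <- function(image_id, bitmap) {
  bitmap <- as.matrix(bitmap)
  if (!all(bitmap %in% c(0L, 1L)))
    abort_validation("mask bitmap values must be 0 or 1")
  storage.mode(bitmap) <- "integer"
  structure(list(image_id = as.character(image_id),
                 width = ncol(bitmap), height = nrow(bitmap), bitmap = bitmap),
            class = "tumor_mask")
}

#' Rasterize a tumor annotation to a binary mask
#'
#' Pixel `(i, j)` (0-based, origin top-left) is set iff its center
#' `(i + 0.5, j + 0.5)` lies inside the polygon set under the even-odd rule,
#' so hole rings subtract. Implementation is a scanline fill: for each pixel
#' row, edge crossings with the horizontal line through the pixel centers are
#' computed with the half-open rule `(y1 <= yc) != (y2 <= yc)` and sorted;
#' pixels between alternate crossing pairs are filled.
#'
#' @param annotation A [tumor_annotation()].
#' @param width,height Mask dimensions in pixels.
#' @return A [tumor_mask()].
#' @export
rasterize <- function(annotation, width, height) {
  stopifnot(inherits(annotation, "tumor_annotation"),
            width >= 1, height >= 1)
  rings <- annotation_rings(annotation)
  allv <- do.call(rbind, rings)
  if (any(allv[, 1] < 0 | allv[, 1] > width | allv[, 2] < 0 | allv[, 2] > height))
    warning(sprintf("annotation '%s' has vertices outside [0,%d]x[0,%d]; clipped to the raster",
                    annotation$image_id, width, height))
  # edge table over all rings (even-odd parity is global)
  x1 <- numeric(0); y1 <- numeric(0); x2 <- numeric(0); y2 <- numeric(0)
  for (ring in rings) {
    n <- nrow(ring)
    nx <- c(2:n, 1)
    x1 <- c(x1, ring[, 1]); y1 <- c(y1, ring[, 2])
    x2 <- c(x2, ring[nx, 1]); y2 <- c(y2, ring[nx, 2])
  }
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  bitmap <- matrix(0L, nrow = height, ncol = width)
  ymin <- pmin(y1, y2); ymax <- pmax(y1, y2)
  row_lo <- max(0L, floor(min(ymin) - 0.5) + 1L)
  row_hi <- min(height - 1L, ceiling(max(ymax)))
  if (row_lo <= row_hi) for (row in row_lo:row_hi) {
    yc <- row + 0.5
    act <- which((y1 <= yc) != (y2 <= yc))
    if (!length(act)) next
    xs <- sort(x1[act] + (yc - y1[act]) * (x2[act] - x1[act]) / (y2[act] - y1[act]))
    if (length(xs) < 2) next
    for (k in seq(1, length(xs) - 1, by = 2)) {
      # pixel centers j + 0.5 in (xs[k], xs[k+1]]
      lo <- max(0L, floor(xs[k] - 0.5) + 1L)
      hi <- min(width - 1L, floor(xs[k + 1] - 0.5))
      if (lo <= hi) bitmap[row + 1L, (lo:hi) + 1L] <- 1L
    }
  }
  if (sum(bitmap) == 0L) abort_validation("empty tumor region")
  tumor_mask(annotation$image_id, bitmap)
}

#' Patch membership in the tumor region
#'
#' A patch anchored at `(x, y)` belongs to the tumor iff its center pixel
#' `(x + floor(patch_size/2), y + floor(patch_size/2))` is set in the mask
#' (the default `"center"` rule). The alternative `"overlap"` rule requires
#' at least `min_overlap` of the patch's pixels to be tumor.
#'
#' @param mask A [tumor_mask()].
#' @param x,y Patch upper-left vertex coordinates (vectorized).
#' @param patch_size Patch edge length in pixels.
#' @param rule `"center"` (default) or `"overlap"`.
#' @param min_overlap Minimum tumor-area fraction for the `"overlap"` rule.
#' @return Integer vector of 0/1. Patches whose decisive pixels fall outside
#'   the mask bounds return 0 (logged when `options(adta.verbose = TRUE)`).
#' @export
patch_in_tumor <- function(mask, x, y, patch_size,
                           rule = c("center", "overlap"), min_overlap = 0.5) {
  stopifnot(inherits(mask, "tumor_mask"))
  rule <- match.arg(rule)
  if (rule == "center") {
    cx <- floor(x + patch_size / 2)
    cy <- floor(y + patch_size / 2)
    inside <- cx >= 0 & cx < mask$width & cy >= 0 & cy < mask$height
    out <- integer(length(x))
    if (any(!inside))
      debug_log("%d patch(es) with center outside mask bounds treated as non-tumor",
                sum(!inside))
    idx <- which(inside)
    out[idx] <- mask$bitmap[cbind(cy[idx] + 1L, cx[idx] + 1L)]
    out
  } else {
    vapply(seq_along(x), function(i) {
      cols <- seq(max(0, x[i]), min(mask$width - 1, x[i] + patch_size - 1))
      rows <- seq(max(0, y[i]), min(mask$height - 1, y[i] + patch_size - 1))
      if (!length(cols) || !length(rows) || x[i] >= mask$width || y[i] >= mask$height)
        return(0L)
      frac <- sum(mask$bitmap[rows + 1L, cols + 1L, drop = FALSE]) / patch_size^2
      as.integer(frac >= min_overlap)
    }, integer(1))
  }
}

#' Patch membership directly from polygons
#'
#' Equivalent to rasterizing and applying the center rule, but tests the
#' patch-center pixel's center point against the annotation polygons
#' directly. Used on large cohorts where full-resolution masks are not
#' needed.
#'
#' @param annotation A [tumor_annotation()].
#' @param x,y Patch upper-left vertex coordinates (vectorized).
#' @param patch_size Patch edge length in pixels.
#' @return Integer vector of 0/1.
#' @export
patch_in_annotation <- function(annotation, x, y, patch_size) {
  stopifnot(inherits(annotation, "tumor_annotation"))
  cx <- floor(x + patch_size / 2) + 0.5
  cy <- floor(y + patch_size / 2) + 0.5
  as.integer(point_in_rings(cx, cy, annotation_rings(annotation)))
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %s: %dx%d px, %d tumor pixels (%.1f%%)\n",
              x$image_id, x$width, x$height, sum(x$bitmap),
              100 * mean(x$bitmap)))
  invisible(x)
}
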
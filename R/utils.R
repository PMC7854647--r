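# Internal helpers: error classes and point-in-polygon geometry.

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("adta_format_error", "adta_error", "error")))
}

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("adta_validation_error", "adta_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adta_verbose <- function() isTRUE(getOption("adta.verbose", FALSE))

debug_log <- function(msg, ...) {
  if (adta_verbose()) message(sprintf(msg, ...))
}

# Even-odd membership of points in a set of rings (holes subtract by parity).
# Rings are open Nx2 matrices (closing vertex dropped). A point is inside iff
# an odd number of ring edges cross the horizontal ray extending to -x, using
# the half-open rule (y1 <= py) != (y2 <= py) so shared edges never double
# count. Vectorized over points; loops over edges.
point_in_rings <- function(px, py, rings) {
  stopifnot(length(px) == length(py))
  crossings <- integer(length(px))
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
    for (i in seq_len(n)) {
      straddle <- (y1[i] <= py) != (y2[i] <= py)
      if (!any(straddle)) next
      xint <- x1[i] + (py[straddle] - y1[i]) * (x2[i] - x1[i]) / (y2[i] - y1[i])
      idx <- which(straddle)[xint < px[straddle]]
      crossings[idx] <- crossings[idx] + 1L
    }
  }
  crossings %% 2L == 1L
}

# Flatten a tumor_annotation into a single list of rings (outer + holes);
# even-odd parity makes the outer/hole distinction unnecessary for fills.
annotation_rings <- function(annotation) {
  rings <- list()
  for (poly in annotation$polygons) rings <- c(rings, poly)
  rings
}

# Shoelace area of one open ring (absolute value).
ring_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xs <- x[c(2:n, 1)]; ys <- y[c(2:n, 1)]
  abs(sum(x * ys - xs * y)) / 2
}
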
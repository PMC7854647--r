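# Rasterization (even-odd scanline fill) and patch membership decisions.

test_that("axis-aligned squares rasterize to exact pixel counts", {
  sq <- cbind(c(0, 200, 200, 0), c(0, 0, 200, 200))
  ann <- tumor_annotation("sq", list(list(sq)))
  mask <- rasterize(ann, 300, 300)
  expect_equal(sum(mask$bitmap), 200 * 200)

  # concentric hole subtracts under the even-odd rule
  hole <- cbind(c(50, 150, 150, 50), c(50, 50, 150, 150))
  ann2 <- tumor_annotation("sq_hole", list(list(sq, hole)))
  mask2 <- rasterize(ann2, 300, 300)
  expect_equal(sum(mask2$bitmap), 200 * 200 - 100 * 100)
})

test_that("rasterization agrees with per-pixel ray casting on random polygons", {
  set.seed(101)
  for (i in 1:25) {
    w <- sample(40:160, 1); h <- sample(40:160, 1)
    ring <- random_star_polygon(w, h)
    ann <- tumor_annotation("rand", list(list(ring)))
    mask <- tryCatch(rasterize(ann, w, h),
                     adta_validation_error = function(e) NULL)
    if (is.null(mask)) next  # polygon too small to cover any pixel center
    expect_identical(mask$bitmap, oracle_rasterize(list(ring), w, h))
  }
})

test_that("rasterization is invariant to ring orientation and rotation", {
  set.seed(11)
  ring <- random_star_polygon(120, 120, nv = 9)
  base <- rasterize(tumor_annotation("a", list(list(ring))), 120, 120)
  flipped <- ring[rev(seq_len(nrow(ring))), ]
  rotated <- ring[c(4:nrow(ring), 1:3), ]
  expect_identical(
    rasterize(tumor_annotation("a", list(list(flipped))), 120, 120)$bitmap,
    base$bitmap)
  expect_identical(
    rasterize(tumor_annotation("a", list(list(rotated))), 120, 120)$bitmap,
    base$bitmap)
})

test_that("out-of-frame vertices warn and clip to the raster", {
  ring <- cbind(c(-50, 100, 100, -50), c(10, 10, 60, 60))
  ann <- tumor_annotation("clip", list(list(ring)))
  expect_warning(mask <- rasterize(ann, 80, 80), "clipped")
  expect_equal(sum(mask$bitmap), 80 * 50)
  expect_error(rasterize(tumor_annotation("z", list(list(
    cbind(c(0.1, 0.3, 0.3, 0.1), c(0.1, 0.1, 0.3, 0.3))))), 50, 50),
    "empty tumor region")
})

test_that("patch membership follows the center-pixel rule", {
  # tumor = left two-thirds (x < 200) of a 300x300 frame, 100-px grid
  ring <- cbind(c(0, 200, 200, 0), c(0, 0, 300, 300))
  mask <- rasterize(tumor_annotation("m", list(list(ring))), 300, 300)
  g <- expand.grid(x = c(0, 100, 200), y = c(0, 100, 200))
  member <- patch_in_tumor(mask, g$x, g$y, 100)
  expect_equal(sum(member), 6)
  expect_equal(member[g$x == 200], c(0L, 0L, 0L))

  # empty mask rejects every patch
  empty <- tumor_mask("e", matrix(0L, 300, 300))
  expect_equal(sum(patch_in_tumor(empty, g$x, g$y, 100)), 0)

  # patches outside the mask bounds return 0
  expect_equal(patch_in_tumor(mask, 500, 500, 100), 0L)
})

test_that("mask-based and polygon-based membership agree on random cases", {
  set.seed(202)
  for (i in 1:20) {
    ps <- sample(c(5L, 10L), 1)
    nx <- sample(4:15, 1); ny <- sample(4:15, 1)
    w <- nx * ps; h <- ny * ps
    ring <- random_star_polygon(w, h)
    ann <- tumor_annotation("r", list(list(ring)))
    mask <- tryCatch(rasterize(ann, w, h),
                     adta_validation_error = function(e) NULL)
    if (is.null(mask)) next
    g <- expand.grid(x = (seq_len(nx) - 1L) * ps, y = (seq_len(ny) - 1L) * ps)
    via_mask <- patch_in_tumor(mask, g$x, g$y, ps)
    via_poly <- patch_in_annotation(ann, g$x, g$y, ps)
    # oracle recomputes the center test from the polygon, bypassing both
    cx <- floor(g$x + ps / 2) + 0.5
    cy <- floor(g$y + ps / 2) + 0.5
    via_oracle <- as.integer(oracle_point_in_poly(cx, cy, list(ring)))
    expect_identical(via_mask, via_oracle)
    expect_identical(via_poly, via_oracle)
  }
})

test_that("translating annotation and grid together preserves membership", {
  set.seed(33)
  ps <- 10L
  ring <- random_star_polygon(100, 100)
  g <- expand.grid(x = (0:9) * ps, y = (0:9) * ps)
  base <- patch_in_annotation(tumor_annotation("t", list(list(ring))),
                              g$x, g$y, ps)
  shift <- 3L * ps
  moved <- patch_in_annotation(
    tumor_annotation("t", list(list(ring + shift))),
    g$x + shift, g$y + shift, ps)
  expect_identical(base, moved)
})

test_that("minimum-overlap rule is available as an alternative", {
  ring <- cbind(c(0, 150, 150, 0), c(0, 0, 300, 300))
  mask <- rasterize(tumor_annotation("m", list(list(ring))), 300, 300)
  # patch at x=100 overlaps the tumor by half
  expect_equal(patch_in_tumor(mask, 100, 0, 100, rule = "overlap",
                              min_overlap = 0.5), 1L)
  expect_equal(patch_in_tumor(mask, 100, 0, 100, rule = "overlap",
                              min_overlap = 0.6), 0L)
})
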
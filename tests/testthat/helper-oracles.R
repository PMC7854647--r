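# Independent reference implementations ("oracles") used to check the
# package's fast paths. These deliberately use different algorithms from the
# implementation: the rasterizer is a scanline span fill counting crossings
# to the LEFT of each pixel center, while the oracles below cast a ray to
# the RIGHT of each point and count per point; Cox fits are checked against
# direct maximization of an explicitly written partial likelihood; etc.

# Even-odd point-in-polygon by per-point +x ray casting.
oracle_point_in_poly <- function(px, py, rings) {
  vapply(seq_along(px), function(i) {
    crossings <- 0L
    for (ring in rings) {
      n <- nrow(ring)
      for (e in seq_len(n)) {
        x1 <- ring[e, 1]; y1 <- ring[e, 2]
        j <- if (e == n) 1L else e + 1L
        x2 <- ring[j, 1]; y2 <- ring[j, 2]
        if ((y1 <= py[i]) != (y2 <= py[i])) {
          xint <- x1 + (py[i] - y1) * (x2 - x1) / (y2 - y1)
          if (xint > px[i]) crossings <- crossings + 1L
        }
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Per-pixel rasterization oracle: +x ray casting over every pixel center,
# vectorized per row with an outer product (structurally unlike the
# implementation's sorted-span fill).
oracle_rasterize <- function(rings, width, height) {
  edges <- do.call(rbind, lapply(rings, function(ring) {
    n <- nrow(ring)
    cbind(ring[, 1], ring[, 2], ring[c(2:n, 1), 1], ring[c(2:n, 1), 2])
  }))
  xc <- (seq_len(width) - 1) + 0.5
  bitmap <- matrix(0L, nrow = height, ncol = width)
  for (row in seq_len(height)) {
    yc <- (row - 1) + 0.5
    act <- (edges[, 2] <= yc) != (edges[, 4] <= yc)
    if (!any(act)) next
    e <- edges[act, , drop = FALSE]
    xint <- e[, 1] + (yc - e[, 2]) * (e[, 3] - e[, 1]) / (e[, 4] - e[, 2])
    ncross <- rowSums(outer(xc, xint, function(a, b) b > a))
    bitmap[row, ] <- as.integer(ncross %% 2 == 1)
  }
  bitmap
}

# Exhaustive per-patch scoring: mask lookup of the center pixel, then
# threshold count, one patch at a time.
brute_score <- function(patches_df, bitmap, patch_size, tau,
                        rule = "at_least") {
  height <- nrow(bitmap); width <- ncol(bitmap)
  n_total <- 0L; n_pos <- 0L
  for (i in seq_len(nrow(patches_df))) {
    cx <- floor(patches_df$x[i] + patch_size / 2)
    cy <- floor(patches_df$y[i] + patch_size / 2)
    if (cx < 0 || cx >= width || cy < 0 || cy >= height) next
    if (bitmap[cy + 1, cx + 1] == 1L) {
      n_total <- n_total + 1L
      hit <- if (rule == "at_least") patches_df$prob[i] >= tau
             else patches_df$prob[i] > tau
      if (hit) n_pos <- n_pos + 1L
    }
  }
  list(n_total = n_total, n_pos = n_pos,
       value = if (n_total > 0) n_pos / n_total else NA_real_)
}

# All-pairs concordance probability (AUC oracle), half credit for ties,
# in the "lower score predicts death" orientation.
oracle_concordance <- function(scores, died) {
  s1 <- scores[died == 1]; s0 <- scores[died == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# Exhaustive Youden-J maximization over the candidate threshold grid
# (midpoints of sorted unique scores plus infinite sentinels), by direct
# counting; ties toward the smallest threshold.
oracle_best_cutoff <- function(scores, died) {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf; best_j <- -Inf
  for (t in thr) {
    sens <- sum(scores[died == 1] < t) / sum(died == 1)
    spec <- sum(scores[died == 0] >= t) / sum(died == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best <- t }
  }
  best
}

# Textbook product-limit estimator: S(t) over distinct event times.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (i in seq_along(et)) {
    n_j <- sum(time >= et[i])
    d_j <- sum(time == et[i] & event == 1)
    s <- s * (1 - d_j / n_j)
    surv[i] <- s
  }
  data.frame(time = et, surv = surv)
}

# Two-group log-rank by explicit per-event-time hypergeometric sums.
oracle_logrank <- function(time, event, group) {
  g <- unique(group)
  et <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in et) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox log partial likelihood for a single covariate, no ties, written out
# directly; maximized by golden-section search in the tests.
cox_logpl <- function(beta, time, event, x) {
  sum(vapply(which(event == 1), function(i) {
    beta * x[i] - log(sum(exp(beta * x[time >= time[i]])))
  }, numeric(1)))
}

oracle_cox_beta <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(cox_logpl, interval, time = time, event = event, x = x,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# Mid-ranks by explicit enumeration (average rank of tied values), then the
# Pearson correlation written out longhand.
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random simple (star-shaped) polygon in pixel coordinates, for fixtures.
random_star_polygon <- function(width, height, nv = sample(4:12, 1)) {
  cx <- runif(1, 0.3, 0.7) * width
  cy <- runif(1, 0.3, 0.7) * height
  theta <- sort(runif(nv, 0, 2 * pi))
  rmax <- pmin(
    ifelse(cos(theta) > 0, (width - cx) / cos(theta),
           ifelse(cos(theta) < 0, -cx / cos(theta), Inf)),
    ifelse(sin(theta) > 0, (height - cy) / sin(theta),
           ifelse(sin(theta) < 0, -cy / sin(theta), Inf)))
  r <- runif(nv, 0.2, 0.95) * pmin(rmax, min(width, height) / 2)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

# Small square-grid patch table fixture.
grid_patches <- function(nx, ny, patch_size, probs = runif(nx * ny)) {
  g <- expand.grid(x = (seq_len(nx) - 1) * patch_size,
                   y = (seq_len(ny) - 1) * patch_size)
  patch_set("fixture", data.frame(x = g$x, y = g$y, prob = probs), patch_size)
}
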
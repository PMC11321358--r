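# Shared fixtures and independent oracles, all built in code.

# random open polyline with the requested number of vertices
random_polyline <- function(n_vertices = 10L, scale = 20) {
  steps <- matrix(stats::runif(3 * (n_vertices - 1L), 0.5, 3), ncol = 3L)
  signs <- matrix(sample(c(-1, 1), 3 * (n_vertices - 1L), replace = TRUE), ncol = 3L)
  polyline3(apply(rbind(stats::runif(3, 0, scale), steps * signs), 2, cumsum))
}

# dense-sampling oracle: min distance to the polyline sampled at a fixed
# arc-length resolution (vertex positions included, so corner minima are
# sampled exactly), independent of the segment-projection code path
oracle_polyline_distance <- function(p, line, step_mm = 1e-3) {
  v <- unclass(line)
  al <- attr(line, "arc_length")
  s <- sort(unique(c(seq(0, max(al), by = step_mm), al)))
  px <- stats::approx(al, v[, 1], xout = s)$y
  py <- stats::approx(al, v[, 2], xout = s)$y
  pz <- stats::approx(al, v[, 3], xout = s)$y
  sqrt(min((px - p[1])^2 + (py - p[2])^2 + (pz - p[3])^2))
}

# exhaustive-face oracle: scalar loop over faces; per face the exact distance
# from the 2x2 normal equations, clamped to edges via point_segment_distance
oracle_mesh_distance <- function(p, mesh) {
  best <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[i, 1], ]
    b <- mesh$vertices[mesh$faces[i, 2], ]
    cc <- mesh$vertices[mesh$faces[i, 3], ]
    E <- cbind(b - a, cc - a)
    st <- solve(crossprod(E), crossprod(E, p - a))
    d <- if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
      sqrt(sum((a + E %*% st - p)^2))
    } else {
      min(point_segment_distance(p, a, b)$distance,
          point_segment_distance(p, a, cc)$distance,
          point_segment_distance(p, b, cc)$distance)
    }
    best <- min(best, d)
  }
  best
}

# unit cube surface as 12 triangles
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = 1
  )
  triangle_mesh(v, f)
}

# random closed-ish surface: jittered ellipsoid mesh built from the package's
# generator geometry (via generate_anatomy would be heavy; a sphere suffices)
random_blob_mesh <- function(n_theta = 10L, n_phi = 12L, radius = 10) {
  th <- seq(0.2, pi - 0.2, length.out = n_theta)
  ph <- seq(0, 2 * pi - 1e-6, length.out = n_phi)
  g <- expand.grid(th = th, ph = ph)
  r <- radius * (1 + 0.2 * sin(3 * g$ph) * sin(2 * g$th))
  v <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph), r * cos(g$th))
  idx <- function(i, j) (j - 1L) * n_theta + i
  f <- list()
  for (j in seq_len(n_phi)) {
    jn <- j %% n_phi + 1L
    for (i in seq_len(n_theta - 1L)) {
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, jn))
      f[[length(f) + 1L]] <- c(idx(i + 1L, j), idx(i + 1L, jn), idx(i, jn))
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

# brute-force concordance AUC: double loop over positive/negative pairs,
# ties counted one half
oracle_concordance_auc <- function(predictor, positive) {
  xp <- predictor[positive]
  xn <- predictor[!positive]
  tot <- 0
  for (i in seq_along(xp)) {
    tot <- tot + sum(xp[i] > xn) + 0.5 * sum(xp[i] == xn)
  }
  tot / (length(xp) * length(xn))
}

# small five-category records table with prescribed distances
records_from <- function(distance_mm, category_index) {
  data.frame(
    distance_mm = distance_mm,
    category = factor(threshold_categories()[category_index],
                      levels = threshold_categories(), ordered = TRUE)
  )
}
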
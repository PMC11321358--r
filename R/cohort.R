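# Synthetic study data. Two generators:
#  (a) a geometric anatomy model (left-atrial shell + epicardial nerve course)
#      driving the full imaging pipeline end to end, and
#  (b) a calibrated statistical cohort drawn from truncated normal
#      distributions matching published per-category distance summaries,
#      the input to the diagnostic-accuracy reproduction.

# ---- truncated-normal calibration ------------------------------------------

#' Solve truncated-normal moment equations
#'
#' Given the target mean and SD of a normal distribution left-truncated at
#' `lower_mm`, solves for the (mu, sigma) of the untruncated parent so that
#' the post-truncation moments match. With `alpha = (lower - mu)/sigma` and
#' hazard `lambda = phi(alpha) / (1 - Phi(alpha))`, the truncated moments are
#' `mean = mu + sigma lambda` and
#' `var = sigma^2 (1 - lambda (lambda - alpha))`; the ratio
#' `var / (mean - lower)^2` depends on `alpha` alone and is solved by
#' bisection, after which sigma and mu follow in closed form.
#'
#' @param mean_mm,sd_mm target post-truncation mean and SD (mm), with
#'   `mean_mm > lower_mm` and `sd_mm > 0`.
#' @param lower_mm truncation point (mm).
#' @return named numeric `c(mu =, sigma =)` of the parent distribution.
#' @export
calibrate_truncated_normal <- function(mean_mm, sd_mm, lower_mm) {
  if (mean_mm <= lower_mm) stop("target mean must exceed the truncation point", call. = FALSE)
  if (sd_mm <= 0) stop("target SD must be > 0", call. = FALSE)
  r_target <- sd_mm^2 / (mean_mm - lower_mm)^2
  hazard <- function(alpha) dnorm(alpha) / pnorm(alpha, lower.tail = FALSE)
  f <- function(alpha) {
    lam <- hazard(alpha)
    delta <- lam - alpha
    (1 - lam * delta) / delta^2 - r_target
  }
  if (r_target >= 1) {
    stop("target SD too large relative to mean - lower; no truncated normal matches", call. = FALSE)
  }
  alpha <- stats::uniroot(f, c(-40, 8), tol = 1e-13)$root
  lam <- hazard(alpha)
  sigma <- (mean_mm - lower_mm) / (lam - alpha)
  c(mu = lower_mm - sigma * alpha, sigma = sigma)
}

#' Draw from a left-truncated normal by inverse CDF
#'
#' @param n number of draws.
#' @param mu,sigma parent-normal parameters.
#' @param lower truncation point; all draws are `>= lower`.
#' @return numeric vector of n draws.
#' @export
rtruncnorm <- function(n, mu, sigma, lower) {
  plo <- stats::pnorm((lower - mu) / sigma)
  mu + sigma * stats::qnorm(stats::runif(n, plo, 1))
}

# ---- published cohort summaries --------------------------------------------

#' Per-category distance summaries of the reference pace-mapping cohort
#'
#' The published site-level summaries of a 45-patient cohort of 1033
#' endocardial pace-mapping sites: per threshold category the site count and
#' the mean, SD and minimum of the measured site-to-nerve distance, plus the
#' region split (872 left-atrial septal sites, 161 SVC/RA sites). These are
#' the calibration targets of [generate_calibrated_cohort()]. Shipped as a
#' JSON fixture under `extdata/`.
#'
#' @return list with `categories` (data.frame: `category`, `n`, `mean_mm`,
#'   `sd_mm`, `min_mm`), `n_patients`, `total_sites`, `region_counts`.
#' @export
reference_category_summaries <- function() {
  path <- system.file("extdata", "category_summaries.json", package = "phrenicmap",
                      mustWork = TRUE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$categories <- as.data.frame(x$categories)
  x
}

# ---- geometric anatomy ------------------------------------------------------

# surface point of an axis-aligned ellipsoid along direction u (unit), and
# outward unit normal there
.ellipsoid_surface <- function(u, axes) {
  s <- 1 / sqrt(sum((u / axes)^2))
  p <- s * u
  n <- p / axes^2
  list(point = p, normal = n / sqrt(sum(n^2)))
}

.unit <- function(v) v / sqrt(sum(v^2))

# UV-sphere triangulation of an ellipsoid
.ellipsoid_mesh <- function(axes, n_theta = 40L, n_phi = 56L) {
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(phi = phi, theta = theta)
  ring <- cbind(
    axes[1] * sin(grid$theta) * cos(grid$phi),
    axes[2] * sin(grid$theta) * sin(grid$phi),
    axes[3] * cos(grid$theta)
  )
  vertices <- rbind(c(0, 0, axes[3]), ring, c(0, 0, -axes[3]))
  vid <- function(it, ip) 1L + (it - 1L) * n_phi + ((ip - 1L) %% n_phi) + 1L
  faces <- list()
  for (ip in seq_len(n_phi)) {  # polar caps
    faces[[length(faces) + 1L]] <- c(1L, vid(1L, ip), vid(1L, ip + 1L))
    faces[[length(faces) + 1L]] <- c(nrow(vertices), vid(n_theta - 1L, ip + 1L), vid(n_theta - 1L, ip))
  }
  for (it in seq_len(n_theta - 2L)) {
    for (ip in seq_len(n_phi)) {
      a <- vid(it, ip); b <- vid(it, ip + 1L); cc <- vid(it + 1L, ip); d <- vid(it + 1L, ip + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, cc)
      faces[[length(faces) + 1L]] <- c(b, d, cc)
    }
  }
  list(vertices = vertices, faces = do.call(rbind, faces))
}

# open cylinder (tube) mesh along direction dir from base point, for PV ostia
.tube_mesh <- function(base, dir, radius, length, n_seg = 10L) {
  dir <- .unit(dir)
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(pracma_cross(dir, ref))
  e2 <- pracma_cross(dir, e1)
  ang <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  circle <- t(vapply(ang, function(a) radius * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  v0 <- sweep(circle, 2L, base, "+")
  v1 <- sweep(circle, 2L, base + dir * length, "+")
  vertices <- rbind(v0, v1)
  faces <- list()
  for (i in seq_len(n_seg)) {
    j <- i %% n_seg + 1L
    faces[[length(faces) + 1L]] <- c(i, j, i + n_seg)
    faces[[length(faces) + 1L]] <- c(j, j + n_seg, i + n_seg)
  }
  list(vertices = vertices, faces = do.call(rbind, faces))
}

# cross product (kept local; avoids pulling in a dependency for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Default anatomy-generator parameters
#'
#' Semi-axes of the left-atrial ellipsoid shell (mm; a 4.3 cm atrium is
#' typical), the nerve clearance range spanned along its course (designed to
#' run from about 1 mm at the closest approach, near the right superior PV,
#' to beyond 30 mm), the position of the closest approach along the course,
#' PV ostium geometry, and mesh resolution.
#'
#' @return list of parameters accepted by [generate_anatomy()].
#' @export
anatomy_params <- function() {
  list(
    axes_mm = c(30, 26, 27),
    clearance_range_mm = c(1.2, 32),
    t_closest = 0.35,
    nerve_n_vertices = 60L,
    n_theta = 40L, n_phi = 56L,
    pv_radius_mm = 6.5, pv_length_mm = 7,
    pv_directions = rbind(
      RSPV = c(0.72, -0.48, 0.55),
      RIPV = c(0.80, -0.52, -0.40),
      LSPV = c(-0.72, -0.48, 0.55),
      LIPV = c(-0.80, -0.52, -0.40)
    ),
    jitter_frac = 0.04
  )
}

#' Generate a synthetic atrial anatomy with an epicardial nerve course
#'
#' Builds a left-atrium-like ellipsoid shell with four tubular PV ostia and a
#' right phrenic nerve polyline running epicardially along the right aspect
#' of the shell: superior to inferior, passing closest to the shell near the
#' right-superior-PV region and receding elsewhere, so that the nerve-to-shell
#' clearance spans roughly 1 mm to beyond 30 mm across the septal patch.
#' Deterministic for a fixed seed (axes and closest-approach position receive
#' a small seeded jitter).
#'
#' @param seed integer seed.
#' @param params parameter list, see [anatomy_params()].
#' @return object of class `anatomy_model`: list with `shell`
#'   (a [triangle_mesh()]), `nerve_path` (a [polyline3()]), `fiducials`
#'   (5 x 3 matrix: four PV ostium centers and the chamber centroid),
#'   `axes_mm`, `params`.
#' @export
generate_anatomy <- function(seed = 1L, params = anatomy_params()) {
  cl <- params$clearance_range_mm
  if (cl[1] <= 0 || cl[2] <= cl[1]) {
    stop("infeasible clearance range: need 0 < min < max", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  axes <- params$axes_mm * (1 + stats::runif(3, -params$jitter_frac, params$jitter_frac))
  t0 <- params$t_closest + stats::runif(1, -0.03, 0.03)

  shell_parts <- .ellipsoid_mesh(axes, params$n_theta, params$n_phi)
  vertices <- shell_parts$vertices
  faces <- shell_parts$faces
  pv_centers <- matrix(NA_real_, 4L, 3L,
                       dimnames = list(rownames(params$pv_directions), c("x", "y", "z")))
  for (i in 1:4) {
    dir <- .unit(params$pv_directions[i, ])
    base <- .ellipsoid_surface(dir, axes)$point
    tube <- .tube_mesh(base, dir, params$pv_radius_mm, params$pv_length_mm)
    faces <- rbind(faces, tube$faces + nrow(vertices))
    vertices <- rbind(vertices, tube$vertices)
    pv_centers[i, ] <- base + dir * params$pv_length_mm / 2
  }
  shell <- triangle_mesh(vertices, faces)

  # nerve course: superior->inferior along the right aspect, anterior of the
  # SVC region then drifting posterior, offset outward by a clearance profile
  # with its minimum near the right-superior-PV region
  tt <- seq(0, 1, length.out = params$nerve_n_vertices)
  theta <- (25 + 130 * tt) * pi / 180
  phi <- (12 - 30 * tt) * pi / 180
  clearance <- cl[1] + (cl[2] - cl[1]) * pmin(1, ((tt - t0) / 0.45)^2)
  nerve <- t(vapply(seq_along(tt), function(i) {
    u <- c(cos(phi[i]) * sin(theta[i]), sin(phi[i]) * sin(theta[i]), cos(theta[i]))
    s <- .ellipsoid_surface(u, axes)
    s$point + clearance[i] * s$normal
  }, numeric(3)))
  nerve_path <- polyline3(nerve)

  model <- structure(
    list(shell = shell, nerve_path = nerve_path,
         fiducials = rbind(pv_centers, centroid = c(0, 0, 0)),
         axes_mm = axes, params = params),
    class = "anatomy_model"
  )
  if (!all(nerve_outside_shell(model))) {
    stop("generated nerve path intersects the chamber shell; adjust parameters", call. = FALSE)
  }
  model
}

#' Check that every nerve vertex lies strictly outside the closed shell
#'
#' Outside means outside the ellipsoid body and outside every PV tube
#' (evaluated analytically against the generating primitives).
#'
#' @param anatomy an `anatomy_model`.
#' @return logical vector, one entry per nerve vertex.
#' @export
nerve_outside_shell <- function(anatomy) {
  v <- unclass(anatomy$nerve_path)
  axes <- anatomy$axes_mm
  p <- anatomy$params
  outside_ellipsoid <- rowSums(sweep(v, 2L, axes, "/")^2) > 1
  inside_tube <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(p$pv_directions))) {
    dir <- .unit(p$pv_directions[i, ])
    base <- .ellipsoid_surface(dir, axes)$point
    rel <- sweep(v, 2L, base)
    ax <- drop(rel %*% dir)
    rad2 <- rowSums(rel^2) - ax^2
    inside_tube <- inside_tube |
      (ax > 0 & ax < p$pv_length_mm & rad2 < p$pv_radius_mm^2)
  }
  outside_ellipsoid & !inside_tube
}

# face centroid directions classified into named surface regions
.region_faces <- function(anatomy, region) {
  m <- anatomy$shell
  n_ell_faces <- nrow(m$faces) - 4L * 20L  # tubes appended last (10 seg x 2)
  ctr <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
          m$vertices[m$faces[, 3], ]) / 3
  phi <- atan2(ctr[, 2], ctr[, 1]) * 180 / pi
  theta <- acos(pmin(1, pmax(-1, ctr[, 3] / sqrt(rowSums(ctr^2))))) * 180 / pi
  on_ellipsoid <- seq_len(nrow(m$faces)) <= n_ell_faces
  if (region == "LA-septal") {
    which(on_ellipsoid & phi > -45 & phi < 40 & theta > 35 & theta < 150)
  } else if (region == "SVC/RA") {
    which(on_ellipsoid & phi > -60 & phi < 60 & theta <= 35)
  } else {
    stop(sprintf("unknown region label '%s'", region), call. = FALSE)
  }
}

#' Sample pacing sites on the shell surface
#'
#' Sites are drawn on mesh faces of the named region patch (area-weighted
#' face choice, uniform barycentric placement), so every site lies exactly on
#' the shell. The true shortest distance to the nerve centerline is computed
#' for each site. Patient labels are assigned with seeded random weights so
#' that per-patient counts vary around `n_sites / n_patients`.
#'
#' @param anatomy an `anatomy_model` from [generate_anatomy()].
#' @param n_sites number of sites (>= 1).
#' @param region `"LA-septal"` or `"SVC/RA"`.
#' @param seed integer seed.
#' @param n_patients number of synthetic patients the sites are spread over.
#' @return data.frame: `site_id`, `patient_id`, `region`, `x`, `y`, `z`,
#'   `distance_mm`.
#' @export
sample_pacing_sites <- function(anatomy, n_sites, region = "LA-septal",
                                seed = 1L, n_patients = 45L) {
  stopifnot(n_sites >= 1)
  face_idx <- .region_faces(anatomy, region)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  m <- anatomy$shell
  A <- m$vertices[m$faces[face_idx, 1], , drop = FALSE]
  B <- m$vertices[m$faces[face_idx, 2], , drop = FALSE]
  C <- m$vertices[m$faces[face_idx, 3], , drop = FALSE]
  cr <- cbind(
    (B - A)[, 2] * (C - A)[, 3] - (B - A)[, 3] * (C - A)[, 2],
    (B - A)[, 3] * (C - A)[, 1] - (B - A)[, 1] * (C - A)[, 3],
    (B - A)[, 1] * (C - A)[, 2] - (B - A)[, 2] * (C - A)[, 1]
  )
  area <- sqrt(rowSums(cr^2)) / 2
  pick <- sample.int(length(face_idx), n_sites, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n_sites)); r2 <- stats::runif(n_sites)
  w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
  pts <- w0 * A[pick, , drop = FALSE] + w1 * B[pick, , drop = FALSE] +
    w2 * C[pick, , drop = FALSE]
  # overdispersed patient allocation (gamma weights -> multinomial-like)
  wpat <- stats::rgamma(n_patients, shape = 2, rate = 1)
  patient <- sample.int(n_patients, n_sites, replace = TRUE, prob = wpat)
  data.frame(
    site_id = seq_len(n_sites),
    patient_id = patient,
    region = region,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    distance_mm = points_polyline_distance(pts, anatomy$nerve_path)
  )
}

# ---- calibrated statistical cohort -----------------------------------------

#' Generate a calibrated cohort of site-to-nerve distance records
#'
#' For each threshold category, draws exactly `n` distances from a normal
#' distribution truncated at the category's published minimum, with the
#' parent parameters solved by [calibrate_truncated_normal()] so that the
#' post-truncation mean and SD match the published values. Patient and region
#' labels are attached to mirror the reference cohort's structure (they do
#' not enter the site-level statistics). Deterministic per seed.
#'
#' @param summaries as returned by [reference_category_summaries()]; any list
#'   with the same shape works.
#' @param seed integer seed.
#' @return data.frame of site-distance records: `site_id`, `patient_id`,
#'   `region`, `distance_mm`, `category` (ordered factor).
#' @export
generate_calibrated_cohort <- function(summaries = reference_category_summaries(),
                                       seed = 1L) {
  cats <- summaries$categories
  stopifnot(all(cats$n >= 0), all(cats$sd_mm >= 0), all(cats$min_mm <= cats$mean_mm))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  draws <- lapply(seq_len(nrow(cats)), function(i) {
    tn <- calibrate_truncated_normal(cats$mean_mm[i], cats$sd_mm[i], cats$min_mm[i])
    rtruncnorm(cats$n[i], tn["mu"], tn["sigma"], cats$min_mm[i])
  })
  n_total <- sum(cats$n)
  category <- factor(rep(cats$category, cats$n),
                     levels = threshold_categories(), ordered = TRUE)
  n_svc <- round(n_total * summaries$region_counts$`SVC/RA` /
                   (summaries$region_counts$`SVC/RA` + summaries$region_counts$`LA-septal`))
  region <- rep("LA-septal", n_total)
  region[sample.int(n_total, n_svc)] <- "SVC/RA"
  data.frame(
    site_id = seq_len(n_total),
    patient_id = sample.int(summaries$n_patients, n_total, replace = TRUE),
    region = region,
    distance_mm = unlist(draws),
    category = category
  )
}
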
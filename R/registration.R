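# Rigid fusion of the electroanatomical-map frame with the CT frame:
# paired-landmark Kabsch initialisation refined by point-to-point ICP.

#' Construct a rigid transform
#'
#' A proper rigid motion `y = R x + t` (no scaling, no reflection) mapping the
#' electroanatomical-map frame into the CT frame. Both frames are metric (mm),
#' so no scale term is admitted.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric length-3 point or n x 3 matrix.
#' @return transformed points in the same shape.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) {
    drop(transform$rotation %*% as.numeric(points)) + transform$translation
  } else {
    sweep(as.matrix(points) %*% t(transform$rotation), 2L, transform$translation, "+")
  }
}

#' Invert / compose rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first, then
#' `a` (i.e. `a %then-after% b`).
#'
#' @param transform,a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  rigid_transform(R, -drop(R %*% transform$translation))
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(
    a$rotation %*% b$rotation,
    drop(a$rotation %*% b$translation) + a$translation
  )
}

#' Rotation angle of a rigid transform (degrees)
#' @param transform a [rigid_transform()].
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(transform) {
  ctheta <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Least-squares rigid alignment of paired landmarks (Kabsch)
#'
#' Finds the proper rigid transform minimising the sum of squared residuals
#' between `R source + t` and `target` over paired points. Reflections are
#' excluded by sign-correcting the smallest singular vector, so the result is
#' always a rotation.
#'
#' @param source,target n x 3 matrices of paired points (n >= 3, not collinear).
#' @return a [rigid_transform()].
#' @export
kabsch_align <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target)) stop("source and target must be paired", call. = FALSE)
  if (nrow(source) < 3L) stop("need at least 3 point pairs", call. = FALSE)
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2L, cs); T <- sweep(target, 2L, ct)
  if (svd(S)$d[2] < 1e-9 * max(svd(S)$d[1], 1)) {
    stop("source landmarks are collinear; rotation is not identifiable", call. = FALSE)
  }
  H <- crossprod(S, T)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - drop(R %*% cs))
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbour correspondence (point-to-point, brute force)
#' with Kabsch alignment. The RMS residual is non-increasing across
#' iterations; iteration stops when its change drops below `tol_mm` or after
#' `max_iter` iterations.
#'
#' @param source_cloud,target_cloud n x 3 / m x 3 point matrices (mm).
#' @param init initial [rigid_transform()] (default identity).
#' @param max_iter maximum iterations.
#' @param tol_mm convergence tolerance on the RMS residual change (mm).
#' @return list of class `registration_result`: `transform`, `rms_residual`
#'   (mm), `iterations`, `converged`, and the per-iteration `rms_trace`.
#' @export
icp_register <- function(source_cloud, target_cloud, init = rigid_transform(),
                         max_iter = 50L, tol_mm = 1e-6) {
  source_cloud <- as.matrix(source_cloud); target_cloud <- as.matrix(target_cloud)
  if (nrow(source_cloud) < 1L || nrow(target_cloud) < 1L) {
    stop("point clouds must be non-empty", call. = FALSE)
  }
  transform <- init
  rms_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  tt2 <- rowSums(target_cloud^2)
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(transform, source_cloud)
    # nearest target per moved source point, brute force
    d2 <- outer(rowSums(moved^2), tt2, "+") - 2 * moved %*% t(target_cloud)
    nn <- max.col(-d2, ties.method = "first")
    matched <- target_cloud[nn, , drop = FALSE]
    rms <- sqrt(mean(rowSums((moved - matched)^2)))
    trace <- c(trace, rms)
    iterations <- it
    if (abs(rms_prev - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    transform <- kabsch_align(source_cloud, matched)
  }
  structure(
    list(transform = transform, rms_residual = trace[length(trace)],
         iterations = iterations, converged = converged, rms_trace = trace),
    class = "registration_result"
  )
}

#' Randomly perturb a rigid transform
#'
#' Composes `transform` with a rotation of exactly `rotation_deg` about a
#' uniformly random axis through the origin and a translation of exactly
#' `translation_mm` in a uniformly random direction. Used to study how
#' map/CT misregistration propagates into site-to-nerve distances.
#'
#' @param transform a [rigid_transform()].
#' @param rotation_deg rotation magnitude, degrees (>= 0).
#' @param translation_mm translation magnitude, mm (>= 0).
#' @param seed integer seed; the perturbation is deterministic given the seed.
#' @return a [rigid_transform()].
#' @export
perturb_transform <- function(transform, rotation_deg, translation_mm, seed = 1L) {
  stopifnot(rotation_deg >= 0, translation_mm >= 0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  axis <- .random_unit_vector()
  dir <- .random_unit_vector()
  R <- rotation_about_axis(axis, rotation_deg)
  compose_transforms(rigid_transform(R, dir * translation_mm), transform)
}

#' Rotation matrix about an axis (Rodrigues formula)
#' @param axis numeric length-3, need not be unit.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis); u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' Serialize a rigid transform to JSON
#'
#' JSON with 9 row-major rotation entries and 3 translation entries (mm).
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @return [read_transform_json()] returns a [rigid_transform()].
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(transform$rotation)),
         translation = transform$translation),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
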
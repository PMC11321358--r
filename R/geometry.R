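# Exact 3D distance primitives: point <-> segment / polyline / triangle mesh.
# All coordinates are in millimetres throughout the package.

#' Validate a 3D point
#'
#' @param p numeric vector of length 3 (x, y, z in mm).
#' @return `p` as a plain numeric vector.
#' @keywords internal
as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    stop("a 3D point must be a finite numeric vector of length 3", call. = FALSE)
  }
  p
}

#' Construct a 3D polyline
#'
#' An ordered open polyline through 3D space, the representation used for the
#' phrenic-nerve centerline. Consecutive vertices must be distinct so that the
#' cumulative arc length is strictly increasing.
#'
#' @param vertices numeric matrix with one row per vertex and columns x, y, z
#'   (mm), at least two rows.
#' @return An object of class `polyline3`: the vertex matrix with an
#'   `arc_length` attribute (cumulative arc length per vertex, mm).
#' @export
polyline3 <- function(vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("polyline vertices must have 3 columns", call. = FALSE)
  if (nrow(vertices) < 2L) stop("a polyline needs at least 2 vertices", call. = FALSE)
  if (any(!is.finite(vertices))) stop("polyline vertices must be finite", call. = FALSE)
  seg <- sqrt(rowSums((vertices[-1L, , drop = FALSE] - vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive polyline vertices must be distinct", call. = FALSE)
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  structure(vertices, arc_length = c(0, cumsum(seg)), class = c("polyline3", "matrix", "array"))
}

#' Total arc length of a polyline (mm)
#' @param line a [polyline3()].
#' @return scalar length in mm.
#' @export
polyline_length <- function(line) {
  al <- attr(line, "arc_length")
  if (is.null(al)) line <- polyline3(line)
  al <- attr(line, "arc_length")
  al[length(al)]
}

#' Construct a triangle mesh
#'
#' Plumbing container for the segmented chamber surface (e.g. the left-atrial
#' shell). Faces with zero area are rejected.
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `triangle_mesh`: list with `vertices`, `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    stop("vertices and faces must each have 3 columns", call. = FALSE)
  }
  if (nrow(faces) < 1L) stop("mesh must have at least one face", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  a <- vertices[faces[, 1L], , drop = FALSE]
  e0 <- vertices[faces[, 2L], , drop = FALSE] - a
  e1 <- vertices[faces[, 3L], , drop = FALSE] - a
  cr <- cbind(
    e0[, 2L] * e1[, 3L] - e0[, 3L] * e1[, 2L],
    e0[, 3L] * e1[, 1L] - e0[, 1L] * e1[, 3L],
    e0[, 1L] * e1[, 2L] - e0[, 2L] * e1[, 1L]
  )
  area2 <- rowSums(cr^2)
  if (any(area2 == 0)) stop("mesh contains degenerate (zero-area) faces", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' Distance from a point to a closed segment
#'
#' Euclidean distance from `p` to the closed segment `[a, b]`, with the
#' attaining point. Degenerate segments (`a == b`) are rejected.
#'
#' @param p,a,b points (numeric length-3, mm).
#' @return list with `distance` (mm), `closest` (point on the segment) and
#'   `t` (parameter in `[0,1]` along a->b).
#' @export
point_segment_distance <- function(p, a, b) {
  p <- as_point3(p); a <- as_point3(a); b <- as_point3(b)
  ab <- b - a
  ab2 <- sum(ab^2)
  if (ab2 == 0) stop("degenerate segment: endpoints coincide", call. = FALSE)
  t <- sum((p - a) * ab) / ab2
  t <- min(1, max(0, t))
  q <- a + t * ab
  list(distance = sqrt(sum((p - q)^2)), closest = q, t = t)
}

# Distances from one point to every segment of a vertex matrix; vectorised
# over segments. Returns list(d2, t) of squared distances and clamped params.
.segment_d2_all <- function(p, v) {
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  ab <- b - a
  ab2 <- rowSums(ab^2)
  t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2] + (p[3] - a[, 3]) * ab[, 3]) / ab2
  t <- pmin(1, pmax(0, t))
  qx <- a[, 1] + t * ab[, 1]; qy <- a[, 2] + t * ab[, 2]; qz <- a[, 3] + t * ab[, 3]
  list(d2 = (p[1] - qx)^2 + (p[2] - qy)^2 + (p[3] - qz)^2, t = t, qx = qx, qy = qy, qz = qz)
}

#' Shortest distance from a point to a polyline
#'
#' Minimum over segments of the exact point-to-segment distance; ties are
#' broken by the lowest segment index so the result is deterministic.
#'
#' @param p point (numeric length-3, mm).
#' @param line a [polyline3()] (or plain vertex matrix with >= 2 rows).
#' @return list with `distance` (mm), `closest` (point on the polyline) and
#'   `segment` (1-based index of the attaining segment).
#' @export
point_polyline_distance <- function(p, line) {
  p <- as_point3(p)
  v <- unclass(line)
  if (is.null(dim(v)) || nrow(v) < 2L) stop("polyline must have at least 2 vertices", call. = FALSE)
  s <- .segment_d2_all(p, v)
  i <- which.min(s$d2)  # which.min returns the first (lowest-index) minimum
  list(
    distance = sqrt(s$d2[i]),
    closest = c(x = s$qx[i], y = s$qy[i], z = s$qz[i]),
    segment = i
  )
}

#' Shortest distances from many points to a polyline
#'
#' Vectorised convenience wrapper used to score whole site tables.
#'
#' @param points numeric matrix (n x 3), mm.
#' @param line a [polyline3()].
#' @return numeric vector of n distances (mm).
#' @export
points_polyline_distance <- function(points, line) {
  points <- as.matrix(points)
  v <- unclass(line)
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  ab <- b - a
  ab2 <- rowSums(ab^2)
  # loop over segments (few) rather than points (many)
  best <- rep(Inf, nrow(points))
  for (j in seq_len(nrow(a))) {
    t <- ((points[, 1] - a[j, 1]) * ab[j, 1] +
          (points[, 2] - a[j, 2]) * ab[j, 2] +
          (points[, 3] - a[j, 3]) * ab[j, 3]) / ab2[j]
    t <- pmin(1, pmax(0, t))
    d2 <- (points[, 1] - (a[j, 1] + t * ab[j, 1]))^2 +
          (points[, 2] - (a[j, 2] + t * ab[j, 2]))^2 +
          (points[, 3] - (a[j, 3] + t * ab[j, 3]))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Exact distance from a point to a triangle mesh
#'
#' Minimum over faces of the exact point-to-triangle distance. Each triangle
#' is handled by solving the unconstrained least-squares projection in
#' barycentric coordinates and, when the foot falls outside the triangle,
#' clamping to the nearest of the three edges.
#'
#' @param p point (numeric length-3, mm).
#' @param mesh a [triangle_mesh()].
#' @return list with `distance` (mm), `closest` (point on the mesh) and
#'   `face` (index of the attaining face).
#' @export
point_mesh_distance <- function(p, mesh) {
  p <- as_point3(p)
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh", call. = FALSE)
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1L], , drop = FALSE]
  B <- v[f[, 2L], , drop = FALSE]
  C <- v[f[, 3L], , drop = FALSE]
  E0 <- B - A; E1 <- C - A
  D <- cbind(A[, 1] - p[1], A[, 2] - p[2], A[, 3] - p[3])
  a <- rowSums(E0^2); b <- rowSums(E0 * E1); c <- rowSums(E1^2)
  d <- rowSums(E0 * D); e <- rowSums(E1 * D)
  det <- a * c - b^2
  s <- (b * e - c * d) / det
  t <- (b * d - a * e) / det
  inside <- is.finite(s) & is.finite(t) & s >= 0 & t >= 0 & (s + t) <= 1
  qx <- A[, 1] + s * E0[, 1] + t * E1[, 1]
  qy <- A[, 2] + s * E0[, 2] + t * E1[, 2]
  qz <- A[, 3] + s * E0[, 3] + t * E1[, 3]
  d2 <- (p[1] - qx)^2 + (p[2] - qy)^2 + (p[3] - qz)^2
  # outside faces: exact distance is attained on one of the three edges
  edge_d2 <- function(P0, P1) {
    e <- P1 - P0
    e2 <- rowSums(e^2)
    tt <- ((p[1] - P0[, 1]) * e[, 1] + (p[2] - P0[, 2]) * e[, 2] + (p[3] - P0[, 3]) * e[, 3]) / e2
    tt <- pmin(1, pmax(0, tt))
    gx <- P0[, 1] + tt * e[, 1]; gy <- P0[, 2] + tt * e[, 2]; gz <- P0[, 3] + tt * e[, 3]
    list(d2 = (p[1] - gx)^2 + (p[2] - gy)^2 + (p[3] - gz)^2, x = gx, y = gy, z = gz)
  }
  if (any(!inside)) {
    eAB <- edge_d2(A, B); eAC <- edge_d2(A, C); eBC <- edge_d2(B, C)
    dmin <- pmin(eAB$d2, eAC$d2, eBC$d2)
    pickAB <- eAB$d2 == dmin
    pickAC <- !pickAB & eAC$d2 == dmin
    ex <- ifelse(pickAB, eAB$x, ifelse(pickAC, eAC$x, eBC$x))
    ey <- ifelse(pickAB, eAB$y, ifelse(pickAC, eAC$y, eBC$y))
    ez <- ifelse(pickAB, eAB$z, ifelse(pickAC, eAC$z, eBC$z))
    d2[!inside] <- dmin[!inside]
    qx[!inside] <- ex[!inside]; qy[!inside] <- ey[!inside]; qz[!inside] <- ez[!inside]
  }
  i <- which.min(d2)
  list(distance = sqrt(d2[i]), closest = c(x = qx[i], y = qy[i], z = qz[i]), face = i)
}

#' Read / write a polyline as CSV
#'
#' CSV with columns `x_mm,y_mm,z_mm` in path order.
#'
#' @param path file path.
#' @return [read_polyline_csv()] returns a [polyline3()].
#' @export
read_polyline_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) stop("polyline CSV needs columns x_mm,y_mm,z_mm", call. = FALSE)
  polyline3(as.matrix(df[, need]))
}

#' @rdname read_polyline_csv
#' @param line a [polyline3()].
#' @export
write_polyline_csv <- function(line, path) {
  v <- unclass(line)
  utils::write.csv(
    data.frame(x_mm = v[, 1], y_mm = v[, 2], z_mm = v[, 3]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read / write a triangle mesh as Wavefront OBJ
#'
#' Minimal ASCII OBJ support (`v` and triangular `f` records), sufficient for
#' the synthetic chamber shells this pipeline produces.
#'
#' @param path file path.
#' @return [read_mesh_obj()] returns a [triangle_mesh()].
#' @export
read_mesh_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  vm <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"), function(x) as.numeric(x[1:3])))
  fm <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"), function(x) {
    as.integer(vapply(strsplit(x[1:3], "/"), `[[`, "", 1L))
  }))
  triangle_mesh(vm, fm)
}

#' @rdname read_mesh_obj
#' @param mesh a [triangle_mesh()].
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}
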
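# CT-side encoding of the nerve course: write the path into an attenuation
# volume as a 5-voxel-wide 900 HU curved line, segment it back by
# thresholding, and recover an ordered centerline.

#' Construct a Hounsfield-unit volume
#'
#' Axis-aligned scalar attenuation grid. A voxel index `(i, j, k)` (1-based in
#' R) refers to the voxel *center*, whose world coordinate is
#' `origin + (index - 1) * spacing` per axis, in mm. No direction cosines:
#' synthetic volumes never need oblique orientation.
#'
#' @param data 3D numeric array of attenuation values (HU).
#' @param spacing numeric length-3 voxel spacing per axis (mm), all > 0.
#' @param origin numeric length-3 world coordinate of the center of voxel
#'   `(1,1,1)` (mm).
#' @return object of class `hu_volume`.
#' @export
hu_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values", call. = FALSE)
  if (length(origin) != 3L) stop("origin must be length 3", call. = FALSE)
  if (any(!is.finite(data))) stop("volume values must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin), class = "hu_volume")
}

#' Create an empty volume covering a bounding box
#'
#' @param lower,upper world-space corners (mm).
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @param background fill value (HU).
#' @return a [hu_volume()] whose voxel centers cover `[lower, upper]`.
#' @export
empty_volume <- function(lower, upper, spacing = 1, background = 0) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  n <- pmax(2L, as.integer(ceiling((upper - lower) / spacing)) + 1L)
  hu_volume(array(background, dim = n), spacing = spacing, origin = as.numeric(lower))
}

#' World coordinates of voxel centers
#' @param vol a [hu_volume()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' A set of voxels within a volume
#'
#' Segmentation output: integer voxel indices plus the owning volume's
#' geometry, so world coordinates remain recoverable.
#'
#' @param indices integer matrix (n x 3), 1-based voxel indices.
#' @param vol the owning [hu_volume()] (geometry only is retained).
#' @return object of class `voxel_set`.
#' @export
voxel_set <- function(indices, vol) {
  indices <- matrix(as.integer(indices), ncol = 3L)
  dims <- dim(vol$data)
  if (nrow(indices) > 0 &&
      (any(indices < 1L) || any(indices[, 1] > dims[1]) ||
       any(indices[, 2] > dims[2]) || any(indices[, 3] > dims[3]))) {
    stop("voxel indices out of grid bounds", call. = FALSE)
  }
  structure(list(indices = indices, spacing = vol$spacing, origin = vol$origin,
                 dim = dims), class = "voxel_set")
}

#' Rasterize a nerve path into an attenuation volume
#'
#' Overwrites every voxel whose center lies within the tube radius
#' `(width_voxels * mean(spacing)) / 2` of the path centerline with
#' `hu_value`; all other voxels are left unchanged. This emulates marking the
#' nerve course in a CT series as a bright curved line so that a simple
#' threshold recovers it. The tube is 3D-isotropic (the width parameter
#' applies in all directions).
#'
#' @param path a [polyline3()] in world coordinates (mm); must lie inside the
#'   volume with a margin of the tube radius.
#' @param vol a [hu_volume()].
#' @param width_voxels tube diameter in voxels (default 5).
#' @param hu_value attenuation written along the tube (default 900 HU).
#' @return the modified [hu_volume()].
#' @export
rasterize_nerve <- function(path, vol, width_voxels = 5, hu_value = 900) {
  stopifnot(inherits(vol, "hu_volume"), width_voxels >= 1)
  v <- unclass(path)
  radius <- width_voxels * mean(vol$spacing) / 2
  dims <- dim(vol$data)
  upper <- vol$origin + (dims - 1) * vol$spacing
  bad <- which(
    v[, 1] < vol$origin[1] + radius | v[, 1] > upper[1] - radius |
    v[, 2] < vol$origin[2] + radius | v[, 2] > upper[2] - radius |
    v[, 3] < vol$origin[3] + radius | v[, 3] > upper[3] - radius
  )
  if (length(bad)) {
    stop(sprintf("path vertex %d at (%.1f, %.1f, %.1f) exits the volume (tube radius %.2f mm)",
                 bad[1], v[bad[1], 1], v[bad[1], 2], v[bad[1], 3], radius), call. = FALSE)
  }
  # candidate voxels: bounding box of the path expanded by the radius
  lo <- pmax(1L, floor((apply(v, 2, min) - radius - vol$origin) / vol$spacing) + 1L)
  hi <- pmin(dims, ceiling((apply(v, 2, max) + radius - vol$origin) / vol$spacing) + 1L)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  centers <- voxel_to_world(vol, idx)
  d <- points_polyline_distance(centers, path)
  hit <- idx[d <= radius, , drop = FALSE]
  vol$data[hit] <- hu_value
  vol
}

#' Segment a volume by attenuation threshold
#'
#' Returns exactly the voxels with value `>= hu_min`. With the marker written
#' at 900 HU over a soft-tissue/air background the default threshold of
#' 850 HU sits well clear of both.
#'
#' @param vol a [hu_volume()].
#' @param hu_min attenuation threshold (HU).
#' @return a [voxel_set()].
#' @export
segment_hu_threshold <- function(vol, hu_min = 850) {
  stopifnot(inherits(vol, "hu_volume"))
  voxel_set(which(vol$data >= hu_min, arr.ind = TRUE), vol)
}

# 26-neighbourhood adjacency lists over a voxel index set.
.voxel_adjacency <- function(indices, dims) {
  n <- nrow(indices)
  key <- (indices[, 1] - 1) + dims[1] * ((indices[, 2] - 1) + dims[2] * (indices[, 3] - 1))
  lookup <- new.env(hash = TRUE, size = max(n, 1L))
  kc <- as.character(key)
  for (i in seq_len(n)) assign(kc[i], i, envir = lookup)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  okey <- offs[, 1] + dims[1] * (offs[, 2] + dims[2] * offs[, 3])
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- as.character(key[i] + okey)
    hits <- integer(0)
    for (k in cand) {
      j <- lookup[[k]]
      if (!is.null(j)) hits <- c(hits, j)
    }
    nb[[i]] <- hits
  }
  nb
}

# connected component labels from adjacency lists
.components_from_adjacency <- function(nb) {
  n <- length(nb)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    comp[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      fresh <- nb[[i]][comp[nb[[i]]] == 0L]
      comp[fresh] <- cur
      stack <- c(stack, fresh)
    }
  }
  comp
}

# single-source geodesic distances through the voxel graph (Dijkstra, dense)
.voxel_geodesic <- function(pts, nb, source) {
  n <- nrow(pts)
  d <- rep(Inf, n)
  d[source] <- 0
  done <- logical(n)
  scratch <- numeric(n)
  for (iter in seq_len(n)) {
    scratch[] <- d
    scratch[done] <- Inf
    i <- which.min(scratch)
    if (!is.finite(scratch[i])) break
    done[i] <- TRUE
    js <- nb[[i]]
    if (length(js)) {
      w <- sqrt((pts[js, 1] - pts[i, 1])^2 + (pts[js, 2] - pts[i, 2])^2 +
                  (pts[js, 3] - pts[i, 3])^2)
      upd <- d[i] + w < d[js]
      d[js[upd]] <- d[i] + w[upd]
    }
  }
  d
}

#' Extract an ordered centerline from a segmented tube
#'
#' Recovers a measurable path from a tube-shaped voxel set. The set must be
#' 26-connected. An endpoint voxel is seeded from the extreme of the first
#' principal axis of the voxel centers; every voxel is then ordered by its
#' geodesic distance from the seed through the 26-neighbourhood voxel graph
#' (so the ordering follows the tube even when it curves back on itself in
#' any single axis); voxels are binned by geodesic position at `step_mm`
#' resolution and each bin contributes its centroid. Half a tube radius is
#' trimmed at both ends so the hemispherical end caps of the rasterized tube
#' do not bias the endpoint estimates, and the centroid sequence is smoothed
#' by a running mean over one tube diameter.
#'
#' @param voxels a [voxel_set()].
#' @param tube_diameter_mm tube diameter (mm); defaults to 5x the mean voxel
#'   spacing, matching the default rasterization width.
#' @param step_mm vertex spacing of the returned polyline (mm); defaults to
#'   the mean voxel spacing.
#' @return a [polyline3()] (or a 1 x 3 matrix flagged by attribute
#'   `degenerate = TRUE` when the set has a single voxel).
#' @export
extract_centerline <- function(voxels, tube_diameter_mm = NULL, step_mm = NULL) {
  stopifnot(inherits(voxels, "voxel_set"))
  n <- nrow(voxels$indices)
  if (n == 0L) stop("empty voxel set", call. = FALSE)
  pts <- sweep(sweep(voxels$indices - 1, 2L, voxels$spacing, "*"), 2L, voxels$origin, "+")
  if (n == 1L) {
    out <- matrix(pts, 1, 3, dimnames = list(NULL, c("x", "y", "z")))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  nb <- .voxel_adjacency(voxels$indices, voxels$dim)
  comp <- .components_from_adjacency(nb)
  ncomp <- max(comp)
  if (ncomp > 1L) {
    stop(sprintf("voxel set is disconnected: %d components (26-neighbourhood)", ncomp), call. = FALSE)
  }
  if (is.null(tube_diameter_mm)) tube_diameter_mm <- 5 * mean(voxels$spacing)
  if (is.null(step_mm)) step_mm <- mean(voxels$spacing)
  radius <- tube_diameter_mm / 2
  # seed: extreme voxel along the first principal axis, refined to the two
  # end-cap tips by successive farthest-point geodesic sweeps
  ctr <- colMeans(pts)
  pc1 <- svd(sweep(pts, 2L, ctr), nu = 0, nv = 1)$v[, 1]
  proj <- drop(sweep(pts, 2L, ctr) %*% pc1)
  g0 <- .voxel_geodesic(pts, nb, which.min(proj))
  tip2 <- which.max(g0)
  g2 <- .voxel_geodesic(pts, nb, tip2)
  tip1 <- which.max(g2)
  g1 <- .voxel_geodesic(pts, nb, tip1)
  # trim the end caps by each tip's own geodesic so neither cap biases the
  # endpoint estimates, then bin by position along the tube
  inner <- g1 >= radius & g2 >= radius
  if (sum(inner) < 2L) inner <- rep(TRUE, n)
  bin <- floor(g1[inner] / step_mm)
  pin <- pts[inner, , drop = FALSE]
  ord <- sort(unique(bin))
  cl <- t(vapply(ord, function(b) colMeans(pin[bin == b, , drop = FALSE]), numeric(3)))
  gmid <- (ord + 0.5) * step_mm
  # running mean over one tube diameter of geodesic position
  half <- tube_diameter_mm / 2
  sm <- t(vapply(seq_along(gmid), function(i) {
    w <- abs(gmid - gmid[i]) <= half
    colMeans(cl[w, , drop = FALSE])
  }, numeric(3)))
  keep2 <- c(TRUE, rowSums(diff(sm)^2) > 1e-12)
  sm <- sm[keep2, , drop = FALSE]
  if (nrow(sm) < 2L) sm <- rbind(sm, sm + c(1e-6, 0, 0))
  polyline3(sm)
}

#' Distance error introduced by the rasterize/segment/centerline round trip
#'
#' For each pacing site, compares its shortest distance to the centerline
#' extracted from a rasterized-then-segmented volume against its distance to
#' the generating path.
#'
#' @param path the true nerve [polyline3()] (world mm).
#' @param vol a [hu_volume()] covering the path (used for geometry; its
#'   voxel values are overwritten in a copy).
#' @param sites n x 3 matrix of site coordinates (mm); may have zero rows.
#' @param width_voxels,hu_value,hu_min rasterization and segmentation
#'   parameters, see [rasterize_nerve()] and [segment_hu_threshold()].
#' @return list: `error_mm` (per-site absolute distance error),
#'   `distance_true`, `distance_extracted`, and the extracted `centerline`.
#' @export
roundtrip_distance_error <- function(path, vol, sites, width_voxels = 5,
                                     hu_value = 900, hu_min = 850) {
  sites <- matrix(as.numeric(sites), ncol = 3L)
  ras <- rasterize_nerve(path, vol, width_voxels = width_voxels, hu_value = hu_value)
  seg <- segment_hu_threshold(ras, hu_min = hu_min)
  cl <- extract_centerline(seg, tube_diameter_mm = width_voxels * mean(vol$spacing))
  if (nrow(sites) == 0L) {
    return(list(error_mm = numeric(0), distance_true = numeric(0),
                distance_extracted = numeric(0), centerline = cl))
  }
  d_true <- points_polyline_distance(sites, path)
  d_ext <- points_polyline_distance(sites, cl)
  list(error_mm = abs(d_ext - d_true), distance_true = d_true,
       distance_extracted = d_ext, centerline = cl)
}

#' Symmetric Hausdorff distance between two polylines
#'
#' Computed on dense arc-length resamplings of both lines; used to assess
#' centerline recovery against the generating path.
#'
#' @param a,b [polyline3()] objects.
#' @param step_mm resampling step (mm).
#' @return scalar distance (mm).
#' @export
polyline_hausdorff <- function(a, b, step_mm = 0.1) {
  pa <- resample_polyline(a, step_mm)
  pb <- resample_polyline(b, step_mm)
  da <- points_polyline_distance(pa, b)
  db <- points_polyline_distance(pb, a)
  max(max(da), max(db))
}

#' Resample a polyline at fixed arc-length steps
#' @param line a [polyline3()].
#' @param step_mm arc-length step (mm).
#' @return matrix of points including both endpoints.
#' @export
resample_polyline <- function(line, step_mm = 0.1) {
  v <- unclass(line)
  al <- attr(line, "arc_length")
  if (is.null(al)) { line <- polyline3(v); v <- unclass(line); al <- attr(line, "arc_length") }
  total <- al[length(al)]
  s <- unique(c(seq(0, total, by = step_mm), total))
  cbind(
    stats::approx(al, v[, 1], xout = s)$y,
    stats::approx(al, v[, 2], xout = s)$y,
    stats::approx(al, v[, 3], xout = s)$y
  )
}

#' Read / write a volume as NIfTI-1
#'
#' Spacing is carried in the NIfTI header (`pixdim`); the origin is stored in
#' the sform translation.
#'
#' @param vol a [hu_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [read_hu_volume()] returns a [hu_volume()].
#' @export
write_hu_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, reference = NULL)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  sform <- diag(c(vol$spacing, 1))
  sform[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(sform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_hu_volume
#' @export
read_hu_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sform <- RNifti::xform(img)
  hu_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3], origin = sform[1:3, 4])
}

#' Write a voxel set as CSV of integer indices
#' @param voxels a [voxel_set()].
#' @param path file path.
#' @export
write_voxel_set_csv <- function(voxels, path) {
  utils::write.csv(
    data.frame(i = voxels$indices[, 1], j = voxels$indices[, 2], k = voxels$indices[, 3]),
    path, row.names = FALSE
  )
  invisible(path)
}
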
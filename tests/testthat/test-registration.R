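test_that("rigid transforms apply, invert and compose as isometries", {
  expect_equal(apply_transform(rigid_transform(), c(1, 2, 3)), c(1, 2, 3))
  set.seed(11)
  Tr <- rigid_transform(rotation_about_axis(c(1, 2, 0.5), 37), c(4, -2, 9))
  pts <- matrix(stats::rnorm(60, 0, 10), ncol = 3)
  back <- apply_transform(invert_transform(Tr), apply_transform(Tr, pts))
  expect_equal(back, pts, tolerance = 1e-9)
  moved <- apply_transform(Tr, pts)
  expect_equal(as.numeric(dist(moved)), as.numeric(dist(pts)), tolerance = 1e-9)
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
})

test_that("Kabsch recovers constructed motions and rejects degenerate input", {
  set.seed(21)
  src <- matrix(stats::rnorm(30, 0, 15), ncol = 3)
  fit <- kabsch_align(src, src)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)

  R90 <- rotation_about_axis(c(0, 0, 1), 90)
  tgt <- sweep(src %*% t(R90), 2, c(1, 2, 3), "+")
  fit <- kabsch_align(src, tgt)
  expect_equal(fit$rotation, R90, tolerance = 1e-9)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-9)

  expect_error(kabsch_align(src[1:2, ], src[1:2, ]), "at least 3")
  line_pts <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_align(line_pts, line_pts), "collinear")
})

test_that("Kabsch under noise reduces RMS and recovers the rotation angle", {
  angle_errs <- numeric(100)
  set.seed(31)
  for (s in 1:100) {
    src <- matrix(stats::rnorm(60, 0, 20), ncol = 3)
    Rtrue <- rotation_about_axis(stats::rnorm(3), 25)
    tgt <- sweep(src %*% t(Rtrue), 2, c(5, -3, 2), "+") +
      matrix(stats::rnorm(60, 0, 0.5), ncol = 3)
    fit <- kabsch_align(src, tgt)
    rms_pre <- sqrt(mean(rowSums((src - tgt)^2)))
    rms_post <- sqrt(mean(rowSums((apply_transform(fit, src) - tgt)^2)))
    expect_lte(rms_post, rms_pre)
    err <- fit$rotation %*% t(Rtrue)
    angle_errs[s] <- rotation_angle_deg(rigid_transform(err, c(0, 0, 0)))
  }
  expect_lt(max(angle_errs), 2)
})

test_that("ICP converges immediately on identical clouds with monotone residuals", {
  set.seed(41)
  cloud <- matrix(stats::rnorm(300, 0, 20), ncol = 3)
  res <- icp_register(cloud, cloud)
  expect_true(res$converged)
  expect_lte(res$rms_residual, 1e-9)
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-6)
  expect_true(all(diff(res$rms_trace) <= 1e-12))
  expect_error(icp_register(cloud[0, ], cloud), "non-empty")
})

test_that("ICP recovers known rigid motions on a shell cloud", {
  set.seed(51)
  anatomy <- generate_anatomy(seed = 7)
  shell <- anatomy$shell$vertices
  cloud <- shell[sample.int(nrow(shell), 500), ]
  for (case in list(c(5, 2), c(10, 5))) {
    Rtrue <- rotation_about_axis(stats::rnorm(3), case[1])
    tvec <- stats::rnorm(3); tvec <- tvec / sqrt(sum(tvec^2)) * case[2]
    Ttrue <- rigid_transform(Rtrue, tvec)
    src <- apply_transform(invert_transform(Ttrue), cloud)
    res <- icp_register(src, cloud, max_iter = 60, tol_mm = 1e-9)
    err <- compose_transforms(res$transform, invert_transform(Ttrue))
    expect_lt(rotation_angle_deg(err), 0.5)
    expect_lt(sqrt(sum(err$translation^2)), 0.5)
    expect_true(all(diff(res$rms_trace) <= 1e-9))
  }
})

test_that("perturbation magnitudes translate into exact point displacements", {
  Tr <- rigid_transform(rotation_about_axis(c(0, 1, 0), 12), c(3, 1, -2))
  expect_equal(perturb_transform(Tr, 0, 0, seed = 5)$rotation, Tr$rotation)
  expect_equal(perturb_transform(Tr, 0, 0, seed = 5)$translation, Tr$translation)

  set.seed(61)
  pts <- matrix(stats::rnorm(90, 0, 30), ncol = 3)
  pure_t <- perturb_transform(Tr, 0, 2, seed = 9)
  shift <- apply_transform(pure_t, pts) - apply_transform(Tr, pts)
  expect_equal(sqrt(rowSums(shift^2)), rep(2, nrow(pts)), tolerance = 1e-9)

  # 5 degree rotation about an axis through the origin: chord-length bound
  pure_r <- perturb_transform(Tr, 5, 0, seed = 9)
  moved <- apply_transform(pure_r, pts) - apply_transform(Tr, pts)
  r <- sqrt(rowSums(apply_transform(Tr, pts)^2))
  bound <- 2 * r * sin(2.5 * pi / 180)
  expect_true(all(sqrt(rowSums(moved^2)) <= bound + 1e-9))

  # deterministic per seed
  expect_equal(perturb_transform(Tr, 3, 1, seed = 2)$rotation,
               perturb_transform(Tr, 3, 1, seed = 2)$rotation)
})

test_that("transform JSON serialization round-trips", {
  Tr <- rigid_transform(rotation_about_axis(c(2, -1, 1), 73), c(0.1, -9, 4))
  tmp <- tempfile(fileext = ".json")
  write_transform_json(Tr, tmp)
  back <- read_transform_json(tmp)
  expect_equal(back$rotation, Tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation, Tr$translation, tolerance = 1e-12)
})
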
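test_that("truncated-normal moment matching solves the stated targets", {
  # truncation far below the mean: parent equals target within 1e-4
  fit <- calibrate_truncated_normal(20, 2, 10)
  expect_equal(unname(fit["mu"]), 20, tolerance = 1e-4)
  expect_equal(unname(fit["sigma"]), 2, tolerance = 1e-4)

  # Monte-Carlo verification of the solved moments at the two extreme
  # category targets
  for (targ in list(c(19.2, 6.5, 9.4), c(7.5, 3.0, 1.0))) {
    fit <- calibrate_truncated_normal(targ[1], targ[2], targ[3])
    set.seed(9)
    x <- rtruncnorm(1e6, fit["mu"], fit["sigma"], targ[3])
    expect_equal(mean(x), targ[1], tolerance = 0.02 / targ[1])
    expect_equal(stats::sd(x), targ[2], tolerance = 0.02 / targ[2])
    expect_gte(min(x), targ[3])
  }
  expect_error(calibrate_truncated_normal(5, 1, 6), "must exceed")
})

test_that("anatomy generation is deterministic and keeps the nerve epicardial", {
  a1 <- generate_anatomy(seed = 3)
  a2 <- generate_anatomy(seed = 3)
  expect_identical(a1$shell$vertices, a2$shell$vertices)
  expect_identical(unclass(a1$nerve_path), unclass(a2$nerve_path))

  expect_true(all(nerve_outside_shell(a1)))

  # closest approach over the septal patch emulates the reported ~1 mm finding
  sites <- sample_pacing_sites(a1, 800, "LA-septal", seed = 4)
  expect_gte(min(sites$distance_mm), 0.8)
  expect_lte(min(sites$distance_mm), 3)
  # and the clearance spans beyond 30 mm
  expect_gt(max(sites$distance_mm), 30)

  expect_error(generate_anatomy(seed = 1, params = within(anatomy_params(), {
    clearance_range_mm <- c(0, 5)
  })), "infeasible")
})

test_that("pacing sites lie on the shell with consistent stored distances", {
  anatomy <- generate_anatomy(seed = 5)
  sites <- sample_pacing_sites(anatomy, 150, "LA-septal", seed = 6)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  on_mesh <- vapply(seq_len(nrow(xyz)), function(i) {
    point_mesh_distance(xyz[i, ], anatomy$shell)$distance
  }, numeric(1))
  expect_true(all(on_mesh <= 1e-6))
  expect_equal(points_polyline_distance(xyz, anatomy$nerve_path),
               sites$distance_mm, tolerance = 1e-12)

  svc <- sample_pacing_sites(anatomy, 40, "SVC/RA", seed = 6)
  expect_equal(nrow(svc), 40L)
  expect_error(sample_pacing_sites(anatomy, 10, "LAA", seed = 1), "unknown region")

  # 1033 sites over 45 patients: total exact, mean count near 23
  big <- sample_pacing_sites(anatomy, 1033, "LA-septal", seed = 7, n_patients = 45)
  expect_equal(nrow(big), 1033L)
  expect_equal(mean(table(factor(big$patient_id, levels = 1:45))), 1033 / 45)
})

test_that("calibrated cohorts honour the published per-category structure", {
  summaries <- reference_category_summaries()
  cohort <- generate_calibrated_cohort(summaries, seed = 11)
  expect_equal(nrow(cohort), 1033L)
  expect_equal(as.integer(table(cohort$category)), summaries$categories$n)
  expect_equal(sum(cohort$region == "SVC/RA"), 161L)

  # every distance respects its category's truncation minimum
  for (i in 1:5) {
    d <- cohort$distance_mm[as.integer(cohort$category) == i]
    expect_gte(min(d), summaries$categories$min_mm[i])
  }

  # determinism
  again <- generate_calibrated_cohort(summaries, seed = 11)
  expect_identical(cohort, again)

  # replicate grand means converge on the calibration targets (CLT check on
  # the lowest-threshold category)
  means <- vapply(1:60, function(s) {
    co <- generate_calibrated_cohort(summaries, seed = 100 + s)
    mean(co$distance_mm[co$category == "<=10 mA"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 7.5), 0.15)
})

test_that("geometric cohorts show a strong positive threshold-distance trend", {
  anatomy <- generate_anatomy(seed = 21)
  sites <- sample_pacing_sites(anatomy, 400, "LA-septal", seed = 22)
  thr <- threshold_from_distance(sites$distance_mm, capture_params())
  obs <- simulate_observed_category(thr, noise_sd_log = 0.5, seed = 23)
  rho <- spearman_rho(obs, sites$distance_mm)
  expect_gt(rho$rho, 0.5)
})
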
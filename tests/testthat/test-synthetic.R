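# Synthetic femur generator: cohort sampler moments, exact landmark
# placement, mesh construction and pose randomization, file round trips.

test_that("degenerate cohort with zero SDs reproduces the configured means", {
  cfg <- cohort_config(
    n = 5,
    mean = c(ml = 75.1, me_fj = 29.4, le_fj = 21.2, me_ej = 25.1, le_ej = 21.3),
    sd = c(ml = 0, me_fj = 0, le_fj = 0, me_ej = 0, le_ej = 0),
    cor_with_ml = c(me_fj = 0.623, le_fj = 0.396, me_ej = 0.393, le_ej = 0.445),
    seed = 1)
  specs <- sample_cohort_specs(cfg)
  expect_equal(unique(specs$ml), 75.1)
  expect_equal(unique(specs$me_fj), 29.4)
  expect_equal(unique(specs$le_ej), 21.3)
})

test_that("cohort sampler is deterministic and respects constructability", {
  cfg <- reference_cohort_config(n = 200, seed = 42)
  s1 <- sample_cohort_specs(cfg)
  s2 <- sample_cohort_specs(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$ml > s1$me_fj))
  expect_true(all(s1$me_fj > 0 & s1$le_ej > 0))
})

test_that("large cohorts recover the configured moments and ML-correlations", {
  cfg <- reference_cohort_config(n = 10000, seed = 9)
  specs <- sample_cohort_specs(cfg)
  expect_lt(abs(mean(specs$ml) - 75.1), 3 * 4.2 / sqrt(10000))
  expect_lt(abs(mean(specs$me_fj) - 29.4), 3 * 2.2 / sqrt(10000))
  expect_lt(abs(stats::sd(specs$me_fj) - 2.2), 0.1)
  expect_lt(abs(stats::cor(specs$ml, specs$me_fj) - 0.623), 0.03)
  expect_lt(abs(stats::cor(specs$ml, specs$le_fj) - 0.396), 0.03)
  expect_lt(abs(stats::cor(specs$ml, specs$me_ej) - 0.393), 0.03)
  expect_lt(abs(stats::cor(specs$ml, specs$le_ej) - 0.445), 0.03)
})

test_that("cohort config rejects invalid moments", {
  m <- c(ml = 75, me_fj = 29, le_fj = 21, me_ej = 25, le_ej = 21)
  s <- c(ml = 4, me_fj = 2, le_fj = 2, me_ej = 3, le_ej = 2)
  expect_error(cohort_config(1, m, s,
    c(me_fj = .6, le_fj = .4, me_ej = .4, le_ej = .4)), "n >= 2")
  expect_error(cohort_config(10, m, s,
    c(me_fj = 1.2, le_fj = .4, me_ej = .4, le_ej = .4)), "correlations")
})

test_that("landmark builder is an exact right inverse of the measurement", {
  bl <- build_landmarks(ref_spec())
  meas <- measure_knee(bl$landmarks, bl$ground_truth$frame)
  expect_equal(measured_distances(meas), ref_distances, tolerance = 1e-12)
  # the stored ground-truth measurement agrees
  expect_equal(measured_distances(bl$ground_truth$measurement), ref_distances,
               tolerance = 1e-12)
})

test_that("mirrored side negates x and leaves measurements unchanged", {
  r <- build_landmarks(ref_spec())
  l <- build_landmarks(femur_spec(side = "left"))
  for (nm in names(r$landmarks)) {
    expect_equal(l$landmarks[[nm]],
                 r$landmarks[[nm]] * c(-1, 1, 1), tolerance = 1e-12)
  }
  mr <- measured_distances(r$ground_truth$measurement)
  ml <- measured_distances(l$ground_truth$measurement)
  expect_equal(ml, mr, tolerance = 1e-12)
})

test_that("uniform scaling doubles distances and preserves ratios", {
  base <- ref_spec()
  scaled <- femur_spec(ml = 2 * 75.1, me_fj = 2 * 29.4, le_fj = 2 * 21.2,
                       me_ej = 2 * 25.1, le_ej = 2 * 21.3,
                       shaft_length = 400, shaft_radius = 32)
  m1 <- build_landmarks(base)$ground_truth$measurement
  m2 <- build_landmarks(scaled)$ground_truth$measurement
  expect_equal(measured_distances(m2), 2 * measured_distances(m1),
               tolerance = 1e-9)
  expect_equal(measured_ratios(m2), measured_ratios(m1), tolerance = 1e-12)
})

test_that("mesh builder realizes the landmarks as surface extremes", {
  spec <- ref_spec(mesh_resolution = 1.5)
  bm <- build_mesh(spec)
  expect_gte(nrow(bm$mesh$vertices), 500)
  gt <- bm$ground_truth$landmarks
  v <- bm$mesh$vertices
  # noise-free: posterior-most vertex of the medial condylar band is the
  # ground-truth posterior landmark
  med <- v[, 1] > 5 & v[, 3] < 10
  i_post <- which(med)[which.min(v[med, 2])]
  expect_lt(vnorm(v[i_post, ] - gt$post_medial), 0.5)
  i_dist <- which(med)[which.min(v[med, 3])]
  expect_lt(vnorm(v[i_dist, ] - gt$dist_medial), 0.5)
  # ME apex is the +x extreme
  expect_lt(vnorm(v[which.max(v[, 1]), ] - gt$me), 0.5)
})

test_that("mesh builder is deterministic and enforces resolution", {
  spec <- ref_spec(mesh_resolution = 2, surface_noise_sd = 0.1, seed = 5)
  m1 <- build_mesh(spec)$mesh
  m2 <- build_mesh(spec)$mesh
  expect_identical(m1$vertices, m2$vertices)
  expect_error(build_mesh(ref_spec(mesh_resolution = 4)), "resolution")
})

test_that("full pipeline on a noise-free mesh recovers the spec distances", {
  spec <- ref_spec(mesh_resolution = 1.5)
  bm <- build_mesh(spec)
  meas <- measure_mesh(bm$mesh, spec$side)
  expect_lt(max(abs(measured_distances(meas) - ref_distances)), 0.5)
})

test_that("random pose is an isometry, identity at seed 0, and harmless", {
  spec <- ref_spec(mesh_resolution = 2)
  bm <- build_mesh(spec)
  expect_identical(apply_random_pose(bm$mesh, seed = 0)$mesh$vertices,
                   bm$mesh$vertices)
  rp <- apply_random_pose(bm$mesh, seed = 8)
  set.seed(30)
  idx <- sample(nrow(bm$mesh$vertices), 50)
  d0 <- as.matrix(stats::dist(bm$mesh$vertices[idx, ]))
  d1 <- as.matrix(stats::dist(rp$mesh$vertices[idx, ]))
  expect_lt(max(abs(d0 - d1)), 1e-6)
  meas <- measure_mesh(rp$mesh, spec$side)
  expect_lt(max(abs(measured_distances(meas) - ref_distances)), 0.5)
})

test_that("PLY, landmark JSON and cohort CSV round-trip through disk", {
  spec <- ref_spec(mesh_resolution = 2.5)
  bm <- build_mesh(spec)
  f <- tempfile(fileext = ".ply")
  write_ply(bm$mesh, f)
  back <- read_ply(f)
  expect_equal(back$vertices, bm$mesh$vertices, tolerance = 1e-5)
  expect_identical(back$faces, bm$mesh$faces)
  expect_identical(back$side, "right")

  fs <- tempfile(fileext = ".stl")
  write_stl(bm$mesh, fs)
  head1 <- readLines(fs, n = 1)
  expect_match(head1, "^solid")
  expect_equal(sum(grepl("^facet", readLines(fs))), nrow(bm$mesh$faces))

  bl <- build_landmarks(spec)
  fj <- tempfile(fileext = ".json")
  write_landmarks_json(bl$landmarks, fj, side = spec$side)
  lj <- read_landmarks_json(fj)
  expect_equal(lj$landmarks$me, bl$landmarks$me, tolerance = 1e-12)
  expect_identical(lj$side, "right")

  specs <- sample_cohort_specs(reference_cohort_config(n = 10, seed = 2))
  fc <- tempfile(fileext = ".csv")
  write_cohort_csv(specs, fc)
  back <- read_cohort_csv(fc)
  expect_equal(back$ml, specs$ml, tolerance = 1e-9)
  expect_identical(back$side, specs$side)
})
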
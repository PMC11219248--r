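# Frame construction: initial axis, anatomical/mechanical axes, landmark
# detection and the fixed-point iteration.

canonical_gt_frame <- function(spec = ref_spec()) {
  build_landmarks(spec)$ground_truth$frame
}

test_that("initial long axis tracks the shaft and points proximal", {
  spec <- ref_spec(mesh_resolution = 2)
  bm <- build_mesh(spec)
  axis <- estimate_initial_long_axis(bm$mesh)
  anat_dir <- c(-sin(6 * pi / 180), 0, cos(6 * pi / 180))
  expect_lt(angle_between(axis$direction, anat_dir), 3)
  expect_gt(sum(axis$direction * c(0, 0, 1)), 0)  # proximal orientation
})

test_that("initial long axis is equivariant under rotation", {
  spec <- ref_spec(mesh_resolution = 2)
  bm <- build_mesh(spec)
  a0 <- estimate_initial_long_axis(bm$mesh)
  rot <- rigid_transform(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, byrow = TRUE))
  meshr <- femur_mesh(apply_rigid(rot, bm$mesh$vertices), bm$mesh$faces, "right")
  a1 <- estimate_initial_long_axis(meshr)
  expect_lt(angle_between(a1$direction, apply_rigid_direction(rot, a0$direction)), 3)
})

test_that("a near-spherical cloud is rejected as degenerate", {
  set.seed(21)
  v <- matrix(stats::rnorm(3000), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * 10
  mesh <- femur_mesh(v, cbind(1:3, 4:6, 7:9), "right")
  expect_error(estimate_initial_long_axis(mesh), "degenerate")
})

test_that("anatomical axis recovers a straight cylinder axis", {
  # explicit oblique cylinder built in the test
  dir <- unitize(c(0.2, 0.1, 1))
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  ts <- seq(0, 200, by = 1)
  e1 <- unitize(cross3(dir, c(0, 1, 0)))
  e2 <- cross3(dir, e1)
  grid <- expand.grid(th = th, t = ts)
  v <- outer(grid$t, dir) + 15 * outer(cos(grid$th), e1) + 15 * outer(sin(grid$th), e2)
  mesh <- femur_mesh(v, cbind(1:3, 4:6, 7:9), "right")
  cfg <- frame_config()
  anat <- compute_anatomical_axis(mesh, distal_jl_level = 0, cfg,
                                  axis_dir = c(0, 0, 1), ml_dir = c(1, 0, 0))
  expect_lt(angle_between(anat$direction, dir), 0.5)

  # translation moves the axis equally, direction unchanged
  mesh2 <- femur_mesh(sweep(v, 2, c(25, 0, 0), "+"), mesh$faces, "right")
  anat2 <- compute_anatomical_axis(mesh2, 0, cfg, c(0, 0, 1), c(1, 0, 0))
  expect_lt(angle_between(anat2$direction, anat$direction), 1e-6)
  expect_equal(anat2$origin - anat$origin, c(25, 0, 0), tolerance = 1e-9)

  # brute-force slice-extreme midpoints match the operation
  s <- v[, 3]
  for (lev in cfg$shaft_levels) {
    sel <- which(abs(s - lev) <= 2)
    x <- v[sel, 1]
    mid <- (v[sel[which.max(x)], ] + v[sel[which.min(x)], ]) / 2
    expect_lt(vnorm(project_point_onto_line(mid, anat) - mid), 1e-6)
  }
  expect_error(compute_anatomical_axis(mesh, 500, cfg, c(0, 0, 1), c(1, 0, 0)),
               "empty")
})

test_that("mechanical axis sits at the valgus angle with the correct sense", {
  cfg <- frame_config()
  # right: shaft proximally lateral (-x); valgus rotation brings it to +z
  anat_r <- line3(c(0, 0, 0), c(-sin(6 * pi / 180), 0, cos(6 * pi / 180)))
  mech_r <- compute_mechanical_axis(anat_r, "right", cfg, anterior = c(0, 1, 0))
  expect_equal(mech_r$direction, c(0, 0, 1), tolerance = 1e-9)
  # left: mirrored shaft, opposite rotation sense
  anat_l <- line3(c(0, 0, 0), c(sin(6 * pi / 180), 0, cos(6 * pi / 180)))
  mech_l <- compute_mechanical_axis(anat_l, "left", cfg, anterior = c(0, 1, 0))
  expect_equal(mech_l$direction, c(0, 0, 1), tolerance = 1e-9)
  # zero valgus keeps the axis
  cfg0 <- frame_config(valgus_angle = 0)
  mech0 <- compute_mechanical_axis(anat_r, "right", cfg0, anterior = c(0, 1, 0))
  expect_equal(mech0$direction, anat_r$direction, tolerance = 1e-12)
  # the constructed angle is exact
  expect_equal(angle_between(mech_r$direction, anat_r$direction), 6,
               tolerance = 1e-6)
})

test_that("epicondyle detection finds the apices and ignores vertex order", {
  spec <- ref_spec(mesh_resolution = 1.5)
  bm <- build_mesh(spec)
  frame <- canonical_gt_frame(spec)
  cfg <- frame_config()
  epi <- detect_epicondyles(bm$mesh, frame, cfg)
  expect_lt(vnorm(epi$me - bm$ground_truth$landmarks$me), 0.5)
  expect_lt(vnorm(epi$le - bm$ground_truth$landmarks$le), 0.5)

  set.seed(22)
  perm <- sample(nrow(bm$mesh$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh_p <- femur_mesh(bm$mesh$vertices[perm, ],
                       matrix(inv[bm$mesh$faces], ncol = 3), "right")
  epi_p <- detect_epicondyles(mesh_p, frame, cfg)
  expect_equal(epi_p$me, epi$me)
  expect_equal(epi_p$le, epi$le)
})

test_that("tied epicondylar extremes break toward the band midline", {
  # two vertices share the extreme ML coordinate at different axial levels
  v <- rbind(c(30, 0, 10), c(30, 0, 18), c(-30, 0, 12),
             c(0, 0, 0), c(0, 5, 5), c(0, -5, 5), c(0, 0, 30))
  mesh <- femur_mesh(v, rbind(c(4, 5, 6), c(1, 2, 3)), "right")
  frame <- structure(list(
    mechanical_axis = line3(c(0, 0, 0), c(0, 0, 1)),
    ml_dir = c(1, 0, 0), anterior_dir = c(0, 1, 0), side = "right"
  ), class = "femoral_frame")
  cfg <- frame_config(epicondylar_band = 10)  # band [0, 20], midline s = 10
  epi <- detect_epicondyles(mesh, frame, cfg)
  expect_equal(epi$me, c(30, 0, 10))
})

test_that("condylar extremes equal a brute-force scan of the vertex set", {
  spec <- ref_spec(mesh_resolution = 1.5)
  bm <- build_mesh(spec)
  frame <- canonical_gt_frame(spec)
  cond <- detect_condylar_extremes(bm$mesh, frame)
  gt <- bm$ground_truth$landmarks
  for (nm in c("post_medial", "post_lateral", "dist_medial", "dist_lateral")) {
    expect_lt(vnorm(cond[[nm]] - gt[[nm]]), 0.5)
  }
  # independent scan in canonical coordinates (medial = +x, posterior = -y,
  # distal = -z), restricted to the condylar mass
  v <- bm$mesh$vertices
  cond_sel <- v[, 3] <= min(v[, 3]) + 60
  med <- cond_sel & v[, 1] > 0
  lat <- cond_sel & v[, 1] <= 0
  expect_equal(cond$post_medial, v[which(med)[which.min(v[med, 2])], ],
               tolerance = 1e-9)
  expect_equal(cond$post_lateral, v[which(lat)[which.min(v[lat, 2])], ],
               tolerance = 1e-9)
  expect_equal(cond$dist_medial, v[which(med)[which.min(v[med, 3])], ],
               tolerance = 1e-9)
})

test_that("frame construction converges quickly and matches ground truth", {
  spec <- ref_spec(mesh_resolution = 1.5)
  bm <- build_mesh(spec)
  fr <- build_frame(bm$mesh, "right")
  expect_lte(fr$frame$iterations, 5)
  gt_frame <- bm$ground_truth$frame
  expect_lt(angle_between(fr$frame$mechanical_axis$direction,
                          gt_frame$mechanical_axis$direction), 1)
  expect_lt(angle_between(fr$frame$anatomical_axis$direction,
                          gt_frame$anatomical_axis$direction), 1)
  for (nm in names(bm$ground_truth$landmarks)) {
    expect_lt(vnorm(fr$landmarks[[nm]] - bm$ground_truth$landmarks[[nm]]), 0.5)
  }
  # structural invariants
  expect_equal(abs(sum(fr$frame$axial_plane$normal *
                         fr$frame$mechanical_axis$direction)), 1,
               tolerance = 1e-9)
  expect_equal(angle_between(fr$frame$mechanical_axis$direction,
                             fr$frame$anatomical_axis$direction),
               6, tolerance = 1e-6)
  expect_lt(abs(sum(fr$frame$coronal_plane$normal * fr$frame$c_tea$direction)),
            1e-9)
})

test_that("frame construction is equivariant under rigid transforms", {
  spec <- ref_spec(mesh_resolution = 1.5)
  bm <- build_mesh(spec)
  fr0 <- build_frame(bm$mesh, "right")
  tf <- random_rigid_transform(seed = 77)
  mesh_t <- femur_mesh(apply_rigid(tf, bm$mesh$vertices), bm$mesh$faces, "right")
  fr1 <- build_frame(mesh_t, "right")
  expect_lt(angle_between(fr1$frame$mechanical_axis$direction,
                          apply_rigid_direction(tf, fr0$frame$mechanical_axis$direction)),
            1)
  for (nm in names(fr0$landmarks)) {
    expect_lt(vnorm(fr1$landmarks[[nm]] - apply_rigid(tf, fr0$landmarks[[nm]])),
              0.5)
  }
})
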
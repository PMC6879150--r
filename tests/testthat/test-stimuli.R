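test_that("frontoparallel flow is radial with speed proportional to FOE distance", {
  scene <- scene_spec("frontoparallel", self_motion_speed = 0.5,
                      component_speed_at_probe = 1, rng_seed = 11L)
  probe <- probe_spec(c(0, -4), object_speed = 2)
  seq <- gen_frontoparallel(scene, probe)
  pts <- seq$points
  r <- sqrt(pts$x^2 + pts$y^2)
  spd <- sqrt(pts$vx^2 + pts$vy^2)
  k <- 1 / 4   # component speed / probe eccentricity
  expect_equal(spd, k * r, tolerance = 1e-12)
  # direction radially outward wherever defined
  ok <- r > 1e-9
  expect_circ_equal(rad2deg(atan2(pts$vy[ok], pts$vx[ok])),
                    rad2deg(atan2(pts$y[ok], pts$x[ok])), tol = 1e-8)
  # 0.5 m/s condition: the probe's self-motion component is 1 deg/s downward
  expect_equal(seq$probe_velocity$component, c(0, -1), tolerance = 1e-12)
  # velocities identical across all frames (acceleration removed)
  f1 <- flow_frame(seq, 1); f2 <- flow_frame(seq, seq$n_frames)
  expect_identical(f1[!f1$is_probe, c("vx", "vy")],
                   f2[!f2$is_probe, c("vx", "vy")])
})

test_that("probe at the FOE and perpendicularity violations are rejected", {
  expect_error(probe_spec(c(0, 0)), "FOE")
  expect_error(probe_spec(c(0, -4), object_direction = 45), "perpendicular")
  # perpendicularity holds by construction for the default direction
  scene <- scene_spec("frontoparallel", component_speed_at_probe = 2)
  probe <- probe_spec(c(3, -1), object_speed = 6)
  pv <- gen_frontoparallel(scene, probe)$probe_velocity
  expect_lt(abs(sum(pv$component * pv$object)), 1e-9)
})

test_that("identical specs produce bit-identical sequences and rasters", {
  scene <- scene_spec("frontoparallel", component_speed_at_probe = 3,
                      rng_seed = 99L)
  probe <- probe_spec(c(0, -4), object_speed = 6)
  a <- gen_frontoparallel(scene, probe)
  b <- gen_frontoparallel(scene, probe)
  expect_identical(a, b)
  expect_identical(rasterize(a, 32), rasterize(b, 32))
})

test_that("ground flow exists only below the horizon and grows along the meridian", {
  scene <- scene_spec("ground", self_motion_speed = 5.7,
                      component_speed_at_probe = 1,
                      depth_range = c(0.56, 25), rng_seed = 4L)
  probe <- probe_spec(c(0, -2), object_speed = 2.5)
  expect_error(gen_ground(scene, probe_spec(c(0, 4), object_speed = 2.5)),
               "horizon")
  seq <- gen_ground(scene, probe)
  expect_true(all(seq$points$y < 0))
  # probe: initial optical speed 2.5 deg/s rightward plus 1 deg/s downward
  expect_equal(seq$probe_velocity$total, c(2.5, -1), tolerance = 1e-12)
  # closed form: speed = (T/h) * tan(|b|) * r with T/h set by the probe's
  # component speed; monotone along the vertical meridian
  Th <- 1 * deg2rad(1) / deg2rad(2)^2          # c = 1 deg/s at e = 2 deg
  b <- seq(-1, -19, by = -0.5)
  spd <- Th * tan(deg2rad(abs(b))) * abs(b)
  expect_true(all(diff(spd) > 0))
  # the generated points follow the same closed form
  got <- sqrt(seq$points$vx^2 + seq$points$vy^2)
  want <- Th * tan(deg2rad(abs(seq$points$y))) *
    sqrt(seq$points$x^2 + seq$points$y^2)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("cloud stimulus honours component speed, masks and disparity ordering", {
  base <- function(mask) scene_spec("cloud", self_motion_speed = 0.3,
                                    component_speed_at_probe = 2,
                                    depth_range = c(0.69, 1.03),
                                    stereo = TRUE, condition_mask = mask,
                                    n_points = 480, rng_seed = 5L)
  probe <- probe_spec(c(4, 0), object_speed = 2, onset = 0.8, offset = 1)
  seq <- gen_cloud(base("full"), probe)
  # probe 4 deg from FOE: horizontal self-motion component 2 deg/s
  expect_equal(seq$probe_velocity$component, c(2, 0), tolerance = 1e-12)
  expect_equal(seq$probe_velocity$object, c(0, 2), tolerance = 1e-12)
  # probe visible only in the last 200 ms
  expect_false(probe_visible(seq, 1))
  expect_true(probe_visible(seq, 25))
  # disparity strictly decreases with depth (brute force over the formula)
  Z <- seq(0.69, 1.03, length.out = 50)
  d <- flowparse:::depth_to_disparity(Z, mean(c(0.69, 1.03)), 0.064)
  expect_true(all(diff(d) < 0))
  # no-local-depth: no vertices in the central 50% of the depth range
  nld <- gen_cloud(base("no_local_depth"), probe)
  band <- flowparse:::depth_to_disparity(0.69 + c(0.75, 0.25) * 0.34,
                                         0.86, 0.064)
  expect_true(all(nld$points$disparity <= band[1] - 1e-9 |
                    nld$points$disparity >= band[2] + 1e-9))
  # count matches the brute-force mask predicate applied to the full set
  full_d <- seq$points$disparity
  inside <- full_d > band[1] & full_d < band[2]
  expect_equal(nrow(nld$points), nrow(seq$points) - sum(inside))
  # no-local-frontal-view: nothing within 4 deg of the probe frontally
  nlf <- gen_cloud(base("no_local_frontal_view"), probe)
  dd <- sqrt((nlf$points$x - 4)^2 + nlf$points$y^2)
  expect_true(all(dd > 4))
})

test_that("rasterize assigns nearest cells, averages, and places the probe", {
  scene <- scene_spec("frontoparallel", component_speed_at_probe = 1,
                      duration = 1, field_of_view = 40)
  probe <- probe_spec(c(0, -4), object_speed = 2, onset = 0.9, offset = 1)
  geom <- grid_geometry(32, 40)
  # empty frame group (probe not yet on, no background points)
  empty <- flow_sequence(data.frame(x = numeric(0), y = numeric(0),
                                    vx = numeric(0), vy = numeric(0)),
                         scene, probe)
  gf <- rasterize(empty, 32)
  g1 <- which(gf$groups == 1L)
  expect_true(all(gf$vx[, , g1] == 0))
  expect_false(any(gf$occupancy[, , g1]))
  # one point at an exact cell centre
  cx <- geom$xdeg[10]; cy <- geom$xdeg[20]
  one <- flow_sequence(data.frame(x = cx, y = cy, vx = 3, vy = 0),
                       scene, probe)
  gf <- rasterize(one, 32)
  sl <- gf$vx[, , g1]
  expect_equal(sl[10, 20], 3)
  expect_equal(sum(sl != 0), 1L)
  # two points in one cell are averaged
  two <- flow_sequence(data.frame(x = c(cx, cx + 0.1), y = c(cy, cy),
                                  vx = c(2, 4), vy = c(0, 0)),
                       scene, probe)
  gf <- rasterize(two, 32)
  expect_equal(gf$vx[, , g1][10, 20], 3)
  # points outside the FOV are dropped and counted
  out <- flow_sequence(data.frame(x = c(cx, 500), y = c(cy, 0),
                                  vx = c(1, 1), vy = c(0, 0)),
                       scene, probe)
  expect_true(all(rasterize(out, 32)$dropped_points == 1L))
  # probe occupies the cells within its diameter and carries its motion
  gp <- which(rasterize(one, 32)$groups == 2L)
  gf <- rasterize(one, 32)
  pc <- gf$probe_cells[[gp]]
  expect_gt(length(pc), 0)
  pv <- one$probe_velocity$total
  expect_true(all(abs(gf$vx[, , gp][pc] - pv[1]) < 1e-12))
  d2 <- (geom$xdeg_grid[pc] - 0)^2 + (geom$ydeg_grid[pc] + 4)^2
  expect_true(all(d2 <= max((probe$diameter / 2)^2, geom$cell^2)))
})

test_that("scene configs round-trip through YAML", {
  cfg <- list(scene = list(scenario = "ground", self_motion_speed = 5.7,
                           component_speed_at_probe = 1,
                           depth_range = c(0.56, 25), rng_seed = 3L),
              probe = list(offset_from_foe = c(0, -2), object_speed = 2.5))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  got <- read_scene_config(path)
  expect_s3_class(got$scene, "scene_spec")
  expect_equal(got$scene$component_speed_at_probe, 1)
  expect_equal(got$probe$eccentricity, 2)
})
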
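test_that("direction tuning peaks at preference and is circularly symmetric", {
  expect_equal(direction_response(123, 123), 1)
  offs <- seq(-180, 180, by = 5)
  resp <- direction_response(40 + offs, 40)
  expect_equal(which.min(resp), which(offs == -180))
  for (d in c(15, 30, 90))
    expect_equal(direction_response(40 + d, 40), direction_response(40 - d, 40))
  # wraps: 350 vs 10 is a 20 degree difference
  expect_equal(direction_response(350, 10), direction_response(30, 10))
})

test_that("speed tuning is log-Gaussian band-pass with a zero floor", {
  expect_equal(speed_response(4, 4), 1)
  expect_equal(speed_response(0, 4), 0)
  expect_error(speed_response(-1, 4), ">= 0")
  # half-max points symmetric in log-speed around each preference
  for (pref in c(0.5, 2, 8)) {
    x <- sqrt(log(2))          # solves exp(-x^2) = 1/2 with sigma = 1 octave
    expect_equal(speed_response(pref * 2^x, pref), 0.5, tolerance = 1e-12)
    expect_equal(speed_response(pref * 2^-x, pref), 0.5, tolerance = 1e-12)
  }
})

test_that("disparity tuning, gain, and the monocular bypass behave as specified", {
  expect_equal(disparity_response(12, 12, 20), 1)
  bank_m <- tuning_bank(speed_prefs_for("frontoparallel"))
  expect_equal(disparity_gain(c(5, NA), bank_m), c(1, 1))
  bank_s <- tuning_bank(speed_prefs_for("cloud"),
                        disp_prefs = seq(60, -40, length.out = 5),
                        gain_near = 1.5, gain_far = 1.15)
  g <- disparity_gain(bank_s$disp_prefs, bank_s)
  expect_equal(g[1], 1.5)
  expect_equal(g[5], 1.15)
  expect_true(all(diff(g) <= 0))      # non-increasing near -> far
  expect_true(all(g >= 1))
})

make_single_cell_grid <- function(n, cell_xy, v, disp = NA, stereo = FALSE) {
  scene <- scene_spec(if (stereo) "cloud" else "frontoparallel",
                      component_speed_at_probe = 1, duration = 1 / 30,
                      stereo = stereo,
                      depth_range = if (stereo) c(0.69, 1.03) else NULL)
  probe <- probe_spec(c(-19, -19), object_speed = 1, onset = 0,
                      offset = 1 / 30)
  geom <- grid_geometry(n, 40)
  pts <- data.frame(x = geom$xdeg[cell_xy[1]], y = geom$xdeg[cell_xy[2]],
                    vx = v[1], vy = v[2], disparity = disp)
  rasterize(flow_sequence(pts, scene, probe, frame_groups = 1L), n)
}

test_that("encoding is the product of the separable tuning curves", {
  bank <- tuning_bank(speed_prefs_for("cloud"),
                      disp_prefs = seq(60, -40, length.out = 5))
  set.seed(42)
  for (rep in 1:5) {
    v <- stats::runif(2, -4, 4)
    disp <- stats::runif(1, -40, 60)
    gf <- make_single_cell_grid(32, c(12, 22), v, disp, stereo = TRUE)
    enc <- mt_encode(gf, bank, frame_group = 1L)
    cell <- 12 + (22 - 1) * 32
    th <- rad2deg(atan2(v[2], v[1])); sp <- sqrt(sum(v^2))
    for (d in sample(24, 3)) for (s in sample(5, 3)) for (p in sample(5, 2)) {
      want <- direction_response(th, bank$dir_prefs[d], bank$dir_sigma) *
        speed_response(sp, bank$speed_prefs[s], bank$speed_sigma_oct) *
        disparity_response(disp, bank$disp_prefs[p], bank$disp_sigma) *
        disparity_gain(disp, bank)
      expect_equal(enc[cell, d, s, p], want, tolerance = 1e-12)
    }
  }
})

test_that("all-zero input encodes to an all-zero tensor; peak at matched tuning", {
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  scene <- scene_spec("frontoparallel", component_speed_at_probe = 1,
                      duration = 1 / 30)
  probe <- probe_spec(c(-19, -19), object_speed = 1, onset = 0, offset = 1 / 30)
  empty <- flow_sequence(data.frame(x = numeric(0), y = numeric(0),
                                    vx = numeric(0), vy = numeric(0)),
                         scene, probe, frame_groups = 1L)
  enc0 <- mt_encode(rasterize(empty, 32), bank, 1L)
  # only the probe's own cells are nonzero
  occ <- rowSums(matrix(enc0, 32 * 32)) > 0
  gf0 <- rasterize(empty, 32)
  expect_equal(which(occ), sort(gf0$probe_cells[[1]]))
  # a cell moving at a preferred (d, s) attains the per-cell maximum there
  d0 <- 5; s0 <- 3
  v <- bank$speed_prefs[s0] *
    c(cos(deg2rad(bank$dir_prefs[d0])), sin(deg2rad(bank$dir_prefs[d0])))
  gf <- make_single_cell_grid(32, c(20, 8), v)
  enc <- mt_encode(gf, bank, 1L)
  cell <- 20 + 7 * 32
  plane <- enc[cell, , ]
  expect_equal(unname(which(plane == max(plane), arr.ind = TRUE)[1, ]),
               c(d0, s0))
  expect_equal(max(plane), 1)
})

test_that("rotating the input by 15 degrees permutes the direction axis exactly", {
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  scene <- scene_spec("frontoparallel", component_speed_at_probe = 1,
                      duration = 1 / 30, rng_seed = 8L)
  probe <- probe_spec(c(-19, -19), object_speed = 1, onset = 0, offset = 1 / 30)
  set.seed(31)
  pts <- data.frame(x = stats::runif(40, -18, 18),
                    y = stats::runif(40, -18, 18),
                    vx = stats::rnorm(40), vy = stats::rnorm(40))
  rot <- deg2rad(15)
  ptsr <- pts
  ptsr$vx <- cos(rot) * pts$vx - sin(rot) * pts$vy
  ptsr$vy <- sin(rot) * pts$vx + cos(rot) * pts$vy
  gf1 <- rasterize(flow_sequence(pts, scene, probe, 1L), 32)
  e1 <- mt_encode(gf1, bank, 1L)
  e2 <- mt_encode(rasterize(flow_sequence(ptsr, scene, probe, 1L), 32), bank, 1L)
  bg <- setdiff(seq_len(32 * 32), gf1$probe_cells[[1]])  # probe is unrotated
  perm <- c(24, 1:23)            # pref d responds to rotated like pref d-1
  expect_equal(e2[bg, , ], e1[bg, perm, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # summed activity over (d, s) is invariant under the rotation
  expect_equal(apply(e2[bg, , ], 1, sum), apply(e1[bg, , ], 1, sum),
               tolerance = 1e-9)
})

test_that("a stereo run with unit gains and one disparity bin matches monocular", {
  bank_m <- tuning_bank(speed_prefs_for("cloud"))
  bank_s <- tuning_bank(speed_prefs_for("cloud"), disp_prefs = 0,
                        disp_sigma = 1e6, gain_near = 1, gain_far = 1)
  v <- c(1.5, -2)
  gm <- make_single_cell_grid(32, c(9, 9), v)
  gs <- make_single_cell_grid(32, c(9, 9), v, disp = 0, stereo = TRUE)
  em <- mt_encode(gm, bank_m, 1L)
  es <- mt_encode(gs, bank_s, 1L)
  expect_equal(dim(es), c(dim(em), 1L))
  cell <- 9 + 8 * 32
  expect_equal(es[cell, , , 1], em[cell, , ], tolerance = 1e-12)
})
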
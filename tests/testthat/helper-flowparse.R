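# Shared fixtures. Tests run the model in the reduced 32 x 32 mode unless a
# quantity was calibrated at the 64 x 64 reference resolution (the
# acceptance checks say which). Expensive runs are memoised per session.

ctl32 <- function(...) fp_control(resolution = 32, ...)
ctl64 <- function(...) fp_control(resolution = 64, ...)

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# campaign summary at the reference resolution, shared across acceptance
# blocks
campaign64 <- function(sim) {
  cached_run(paste0("campaign64_", sim),
             run_campaign(sim, control = ctl64()))
}

run64 <- function(sim, idx, ...) {
  cached_run(paste(sim, idx, ..., sep = "_"), {
    ctl <- ctl64(...)
    run_condition(fp_conditions(sim)[idx, ], ctl)
  })
}

# analytic full-occupancy radial grid flow with the FOE at cell (i0, j0),
# as a noise-free probe of the template machinery
radial_grid <- function(n, i0, j0, k = 0.5, fov = 40) {
  geom <- grid_geometry(n, fov)
  x0 <- geom$xdeg[i0]; y0 <- geom$xdeg[j0]
  pts <- expand.grid(x = geom$xdeg, y = geom$xdeg)
  pts$vx <- k * (pts$x - x0)
  pts$vy <- k * (pts$y - y0)
  keep <- !(pts$x == x0 & pts$y == y0)   # drop the singular point
  scene <- scene_spec("frontoparallel", component_speed_at_probe = 1,
                      field_of_view = fov, duration = 1 / 30, n_points = 1)
  # minimal-footprint probe in a corner, far from the FOE
  probe <- probe_spec(offset_from_foe = c(-fov / 2 + 1, -fov / 2 + 1),
                      object_speed = 1, onset = 0, offset = 1 / 30)
  seq <- flow_sequence(pts[keep, ], scene, probe, frame_groups = 1L)
  rasterize(seq, n)
}

expect_circ_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(circ_diff(a, b))), tol)
}
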
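# Stimulus generation: analytic optic-flow fields with an embedded probe
# object, for the three experimental scenarios (frontoparallel plane of dots,
# travel over a ground plane, stereo cloud of wire-frame objects).
#
# Dots are treated as limited-lifetime texture elements: their positions are
# fixed within a trial and their velocity vectors sample the stationary
# analytic flow field of the simulated translation.  The model consumes the
# velocity field, not dot trajectories, so this preserves exactly the
# quantities the model sees while keeping trials deterministic.

#' Scene specification for a simulated self-motion display
#'
#' Stimuli are parameterized directly by retinal quantities (the self-motion
#' component speed at the probe, eccentricities, optical speeds) rather than
#' by physical viewing geometry, so that the retinal values that define each
#' experimental condition hold exactly.
#'
#' @param scenario one of `"frontoparallel"`, `"ground"`, `"cloud"`.
#' @param self_motion_speed simulated observer translation speed (m/s). A
#'   label for the condition; the retinal flow is set by
#'   `component_speed_at_probe`.
#' @param component_speed_at_probe the self-motion component of the probe's
#'   retinal motion, deg/s. Must be positive when `self_motion_speed > 0`.
#' @param depth_range numeric length-2 `(near, far)` in metres; required for
#'   `"ground"` and `"cloud"` scenarios.
#' @param field_of_view square field of view, deg (default 40).
#' @param duration trial duration, s (default 1).
#' @param frame_rate input frames per second (default 30).
#' @param stereo logical; add a binocular-disparity channel (cloud only).
#' @param condition_mask `"full"`, `"no_local_depth"` (remove vertices in the
#'   central 50 percent of the depth range) or `"no_local_frontal_view"`
#'   (remove vertices within 4 deg of the probe in the frontal view). Only
#'   meaningful for the cloud scenario.
#' @param n_points number of fiducial dots (frontoparallel/ground) or
#'   wire-frame cubes * 8 vertices (cloud).
#' @param eye_height observer eye height above the ground plane, m (ground
#'   scenario; 0.40 m reconciles the printed translation speeds, component
#'   speeds and depth range).
#' @param interocular interocular distance used to convert depth to
#'   disparity, m (default 0.064).
#' @param rng_seed integer seed for dot placement.
#' @return an object of class `"scene_spec"`.
#' @export
scene_spec <- function(scenario = c("frontoparallel", "ground", "cloud"),
                       self_motion_speed = 1,
                       component_speed_at_probe = 1,
                       depth_range = NULL,
                       field_of_view = 40,
                       duration = 1,
                       frame_rate = 30,
                       stereo = FALSE,
                       condition_mask = c("full", "no_local_depth",
                                          "no_local_frontal_view"),
                       n_points = 300,
                       eye_height = 0.40,
                       interocular = 0.064,
                       rng_seed = 1L) {
  scenario <- match.arg(scenario)
  condition_mask <- match.arg(condition_mask)
  stopifnot_scalar(component_speed_at_probe, "component_speed_at_probe")
  stopifnot_scalar(field_of_view, "field_of_view", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (self_motion_speed > 0 && component_speed_at_probe <= 0)
    stop("component_speed_at_probe must be > 0 when self_motion_speed > 0")
  if (scenario %in% c("ground", "cloud")) {
    if (is.null(depth_range) || length(depth_range) != 2L ||
        !(depth_range[1] < depth_range[2]))
      stop("depth_range = (near, far) with near < far is required for ",
           scenario, " scenes")
  }
  if (condition_mask != "full" && scenario != "cloud")
    stop("condition_mask applies only to the cloud scenario")
  structure(list(scenario = scenario,
                 self_motion_speed = self_motion_speed,
                 component_speed_at_probe = component_speed_at_probe,
                 depth_range = depth_range,
                 field_of_view = field_of_view,
                 duration = duration,
                 frame_rate = frame_rate,
                 stereo = stereo,
                 condition_mask = condition_mask,
                 n_points = as.integer(n_points),
                 eye_height = eye_height,
                 interocular = interocular,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

#' Probe (moving object) specification
#'
#' The probe's object-motion component and its self-motion component are
#' perpendicular by experimental design: the probe sits on a radial line
#' through the FOE (so its self-motion component is along that line) and
#' moves at right angles to it.
#'
#' @param offset_from_foe length-2 offset (deg, deg) of the probe centre from
#'   the focus of expansion.
#' @param object_speed world-relative retinal component speed, deg/s.
#' @param object_direction world-relative retinal component direction, deg
#'   CCW from +x. Must be perpendicular to the offset direction.
#' @param diameter probe diameter, deg.
#' @param onset,offset probe visibility window, s.
#' @param depth probe depth, m (cloud scenario: the cloud's centre depth).
#' @return an object of class `"probe_spec"`.
#' @export
probe_spec <- function(offset_from_foe = c(0, -4),
                       object_speed = 2,
                       object_direction = NULL,
                       diameter = 1,
                       onset = 0,
                       offset = 1,
                       depth = NULL) {
  if (length(offset_from_foe) != 2L)
    stop("offset_from_foe must have length 2")
  ecc <- sqrt(sum(offset_from_foe^2))
  if (ecc < 1e-9)
    stop("probe at the FOE: the self-motion component direction is undefined")
  radial_dir <- rad2deg(atan2(offset_from_foe[2], offset_from_foe[1]))
  if (is.null(object_direction)) {
    # default: perpendicular, rotated +90 deg from the radial direction
    object_direction <- wrap180(radial_dir + 90)
  } else {
    if (abs(abs(circ_diff(object_direction, radial_dir)) - 90) > 1e-6)
      stop("object_direction must be perpendicular to the probe's radial ",
           "(self-motion component) direction")
  }
  stopifnot_scalar(object_speed, "object_speed", positive = TRUE)
  if (!(onset >= 0 && onset < offset))
    stop("need 0 <= onset < offset")
  structure(list(offset_from_foe = as.numeric(offset_from_foe),
                 eccentricity = ecc,
                 radial_direction = radial_dir,
                 object_speed = object_speed,
                 object_direction = object_direction,
                 diameter = diameter,
                 onset = onset, offset = offset,
                 depth = depth),
            class = "probe_spec")
}

probe_velocity <- function(scene, probe) {
  c_dir <- deg2rad(probe$radial_direction)
  o_dir <- deg2rad(probe$object_direction)
  comp <- scene$component_speed_at_probe * c(cos(c_dir), sin(c_dir))
  obj <- probe$object_speed * c(cos(o_dir), sin(o_dir))
  list(component = comp, object = obj, total = comp + obj,
       retinal_direction = rad2deg(atan2(comp[2] + obj[2], comp[1] + obj[1])))
}

#' Construct a flow sequence from an explicit point set
#'
#' Low-level constructor used by the stimulus generators; also useful for
#' building hand-crafted inputs. `points` holds the background texture
#' elements (columns `x`, `y` in deg, `vx`, `vy` in deg/s and `disparity`
#' in arcmin or `NA`); the probe is described by `probe` and appears in the
#' frames of its visibility window.
#'
#' @param points data.frame of background points.
#' @param scene a [scene_spec()].
#' @param probe a [probe_spec()].
#' @param frame_groups optional integer vector mapping each frame to an
#'   equivalence class of identical frames (computed from the probe window
#'   by default).
#' @return an object of class `"flow_sequence"`.
#' @export
flow_sequence <- function(points, scene, probe, frame_groups = NULL) {
  stopifnot(is.data.frame(points),
            all(c("x", "y", "vx", "vy") %in% names(points)))
  if (is.null(points$disparity))
    points$disparity <- rep(NA_real_, nrow(points))
  n_frames <- round(scene$duration * scene$frame_rate)
  pv <- probe_velocity(scene, probe)
  if (is.null(frame_groups)) frame_groups <- frame_groups_for(scene, probe)
  structure(list(points = points,          # data.frame x, y, vx, vy, disparity
                 scene = scene, probe = probe,
                 probe_velocity = pv,
                 n_frames = n_frames,
                 frame_groups = frame_groups),
            class = "flow_sequence")
}

new_flow_sequence <- function(points, scene, probe, frame_groups) {
  flow_sequence(points, scene, probe, frame_groups)
}

#' @export
print.flow_sequence <- function(x, ...) {
  cat(sprintf("<flow_sequence> %s scenario: %d frames, %d points, probe %s\n",
              x$scene$scenario, x$n_frames, nrow(x$points),
              sprintf("at (%.2f, %.2f) deg", x$probe$offset_from_foe[1],
                      x$probe$offset_from_foe[2])))
  invisible(x)
}

# Materialize one frame as a point set (background points + probe if visible).
flow_frame <- function(seq, f) {
  t0 <- (f - 1) / seq$scene$frame_rate
  pts <- seq$points
  pts$is_probe <- rep(FALSE, nrow(pts))
  if (probe_visible(seq, f)) {
    pv <- seq$probe_velocity$total
    pr <- data.frame(x = seq$probe$offset_from_foe[1],
                     y = seq$probe$offset_from_foe[2],
                     vx = pv[1], vy = pv[2],
                     disparity = probe_disparity(seq),
                     is_probe = TRUE)
    pts <- rbind(pts, pr)
  }
  pts
}

probe_visible <- function(seq, f) {
  t0 <- (f - 1) / seq$scene$frame_rate
  t0 >= seq$probe$onset - 1e-9 && t0 < seq$probe$offset - 1e-9
}

probe_disparity <- function(seq) {
  if (!isTRUE(seq$scene$stereo)) return(NA_real_)
  if (is.null(seq$probe$depth)) return(0)
  depth_to_disparity(seq$probe$depth, mean(seq$scene$depth_range),
                     seq$scene$interocular)
}

# binocular parallax relative to fixation at Zfix, in arcmin
depth_to_disparity <- function(Z, Zfix, iod) {
  rad2deg(iod * (1 / Z - 1 / Zfix)) * 60
}

#' Generate the frontoparallel-plane stimulus
#'
#' Radial flow centred on the FOE with the optical acceleration of approach
#' removed: every fiducial dot's speed is `k * r` where `r` is its distance
#' to the FOE, with `k` chosen so that the speed at the probe's eccentricity
#' equals the condition's self-motion component speed. Velocities are
#' constant over frames.
#'
#' @param scene a [scene_spec()] with `scenario = "frontoparallel"`.
#' @param probe a [probe_spec()].
#' @return a `"flow_sequence"`.
#' @export
gen_frontoparallel <- function(scene, probe) {
  stopifnot(inherits(scene, "scene_spec"), inherits(probe, "probe_spec"))
  if (scene$scenario != "frontoparallel")
    stop("scene$scenario must be 'frontoparallel'")
  half <- scene$field_of_view / 2
  k <- scene$component_speed_at_probe / probe$eccentricity
  pts <- with_seed(scene$rng_seed, {
    data.frame(x = stats::runif(scene$n_points, -half, half),
               y = stats::runif(scene$n_points, -half, half))
  })
  r <- sqrt(pts$x^2 + pts$y^2)
  # speed = k*r, direction radially outward; exactly (0,0) at the FOE
  pts$vx <- k * pts$x
  pts$vy <- k * pts$y
  pts$disparity <- NA_real_
  new_flow_sequence(pts, scene, probe,
                    frame_groups = frame_groups_for(scene, probe))
}

#' Generate the ground-plane stimulus
#'
#' Perspective flow of forward translation at eye height `h` over a dotted
#' ground plane. For a dot at angular position `(a, b)` below the horizon
#' (depth `Z = h / tan(-b)`), the flow is `(T/Z) * (a, b)` in radians, i.e.
#' speed grows with the product of eccentricity and angle below the horizon.
#' The translation speed is derived from the printed retinal quantities:
#' `T = c * h / e_rad^2` makes the vertical self-motion component at the
#' probe's eccentricity equal the condition's component speed exactly.
#'
#' @param scene a [scene_spec()] with `scenario = "ground"`.
#' @param probe a [probe_spec()]; must lie below the horizon.
#' @return a `"flow_sequence"`.
#' @export
gen_ground <- function(scene, probe) {
  stopifnot(inherits(scene, "scene_spec"), inherits(probe, "probe_spec"))
  if (scene$scenario != "ground") stop("scene$scenario must be 'ground'")
  if (probe$offset_from_foe[2] >= 0)
    stop("probe above the horizon: ground scenario requires the probe below ",
         "the FOE")
  half <- scene$field_of_view / 2
  h <- scene$eye_height
  e_rad <- deg2rad(probe$eccentricity)
  Tspeed <- scene$component_speed_at_probe * deg2rad(1) * h / e_rad^2
  # visible angular band below the horizon from the depth range
  b_far <- rad2deg(atan2(h, scene$depth_range[2]))   # smallest angle below
  b_near <- rad2deg(atan2(h, scene$depth_range[1]))  # largest
  b_lo <- min(b_near, half)
  pts <- with_seed(scene$rng_seed, {
    data.frame(x = stats::runif(scene$n_points, -half, half),
               y = -stats::runif(scene$n_points, b_far, b_lo))
  })
  Z <- h / tan(deg2rad(-pts$y))
  rate <- Tspeed / Z                    # rad/s per rad of eccentricity
  pts$vx <- rate * pts$x                # (a, b) in deg scaled by 1/s rate
  pts$vy <- rate * pts$y
  pts$disparity <- NA_real_
  new_flow_sequence(pts, scene, probe,
                    frame_groups = frame_groups_for(scene, probe))
}

#' Generate the stereo wire-frame cloud stimulus
#'
#' Vertices of wire-frame cubes uniformly fill a depth volume around the
#' fixation depth. Per-vertex velocity follows motion parallax,
#' `v = kappa * (Zbar/Z) * (a, b)`, scaled so the probe's self-motion
#' component speed holds exactly at its eccentricity and the cloud's centre
#' depth. Per-vertex disparity is the binocular parallax relative to
#' fixation at the centre depth. Condition masks remove vertices in the
#' central half of the depth range (`no_local_depth`) or within 4 deg of the
#' probe in the frontal view (`no_local_frontal_view`).
#'
#' @param scene a [scene_spec()] with `scenario = "cloud"` and
#'   `stereo = TRUE`.
#' @param probe a [probe_spec()]; its `depth` defaults to the centre depth.
#' @return a `"flow_sequence"`.
#' @export
gen_cloud <- function(scene, probe) {
  stopifnot(inherits(scene, "scene_spec"), inherits(probe, "probe_spec"))
  if (scene$scenario != "cloud") stop("scene$scenario must be 'cloud'")
  if (!isTRUE(scene$stereo)) stop("cloud scenario requires stereo = TRUE")
  half <- scene$field_of_view / 2
  near <- scene$depth_range[1]; far <- scene$depth_range[2]
  Zbar <- (near + far) / 2
  if (is.null(probe$depth)) probe$depth <- Zbar
  n_cubes <- max(1L, scene$n_points %/% 8L)
  cube_half <- 0.03                      # 6 cm wire-frame cubes
  pts <- with_seed(scene$rng_seed, {
    cx <- stats::runif(n_cubes, -half + 2, half - 2)
    cy <- stats::runif(n_cubes, -half + 2, half - 2)
    cz <- stats::runif(n_cubes, near + cube_half, far - cube_half)
    corner <- expand.grid(dx = c(-1, 1), dy = c(-1, 1), dz = c(-1, 1))
    idx <- rep(seq_len(n_cubes), each = 8L)
    Z <- cz[idx] + cube_half * rep(corner$dz, times = n_cubes)
    ang_off <- rad2deg(cube_half / Z)
    data.frame(x = cx[idx] + ang_off * rep(corner$dx, times = n_cubes),
               y = cy[idx] + ang_off * rep(corner$dy, times = n_cubes),
               Z = Z)
  })
  # condition masks
  if (scene$condition_mask == "no_local_depth") {
    band <- near + c(0.25, 0.75) * (far - near)
    pts <- pts[!(pts$Z >= band[1] & pts$Z <= band[2]), , drop = FALSE]
  } else if (scene$condition_mask == "no_local_frontal_view") {
    d <- sqrt((pts$x - probe$offset_from_foe[1])^2 +
              (pts$y - probe$offset_from_foe[2])^2)
    pts <- pts[d > 4, , drop = FALSE]
  }
  if (nrow(pts) == 0L)
    stop("empty vertex set after applying the condition mask")
  # flow scaled so the component speed at the probe (centre depth) is exact
  kappa <- scene$component_speed_at_probe / probe$eccentricity  # 1/s
  rate <- kappa * Zbar / pts$Z
  pts$vx <- rate * pts$x
  pts$vy <- rate * pts$y
  pts$disparity <- depth_to_disparity(pts$Z, Zbar, scene$interocular)
  pts$Z <- NULL
  new_flow_sequence(pts, scene, probe,
                    frame_groups = frame_groups_for(scene, probe))
}

# frames sharing a group index have identical content (probe on/off is the
# only time-varying element); downstream stages encode each group once.
frame_groups_for <- function(scene, probe) {
  n_frames <- round(scene$duration * scene$frame_rate)
  t0 <- (seq_len(n_frames) - 1) / scene$frame_rate
  vis <- t0 >= probe$onset - 1e-9 & t0 < probe$offset - 1e-9
  as.integer(vis) + 1L   # group 1 = background only, 2 = with probe
}

#' Generate a flow sequence for any scenario
#'
#' Dispatches to [gen_frontoparallel()], [gen_ground()] or [gen_cloud()].
#' @param scene a [scene_spec()].
#' @param probe a [probe_spec()].
#' @return a `"flow_sequence"`.
#' @export
gen_flow <- function(scene, probe) {
  switch(scene$scenario,
         frontoparallel = gen_frontoparallel(scene, probe),
         ground = gen_ground(scene, probe),
         cloud = gen_cloud(scene, probe))
}

#' Rasterize a flow sequence to the model's input grid
#'
#' Each point is assigned to its nearest grid cell; multiple points in one
#' cell are averaged (velocity and disparity). The probe occupies all cells
#' whose centres fall within its diameter, and those cells carry the probe's
#' motion. Points outside the field of view are dropped (their count is
#' recorded in the result). Cells with no projected point have zero velocity
#' and empty occupancy.
#'
#' @param seq a `"flow_sequence"`.
#' @param grid grid dimension, either a single integer or `(nx, ny)` with
#'   `nx == ny` (default 64).
#' @return an object of class `"grid_flow"` with per-frame `nx x ny` slices
#'   of `vx`, `vy` (deg/s), `disparity` (arcmin; `NA` where no stimulus) and
#'   logical `occupancy`, plus `probe_cells` (cell indices per frame) and
#'   grid geometry.
#' @export
rasterize <- function(seq, grid = 64L) {
  stopifnot(inherits(seq, "flow_sequence"))
  n <- as.integer(grid[1])
  if (length(grid) == 2L && grid[2] != grid[1])
    stop("only square grids are supported")
  if (n <= 0) stop("grid dims must be positive")
  geom <- grid_geometry(n, seq$scene$field_of_view)
  groups <- unique(seq$frame_groups)
  ng <- length(groups)
  vx <- array(0, c(n, n, ng)); vy <- array(0, c(n, n, ng))
  disp <- array(NA_real_, c(n, n, ng))
  occ <- array(FALSE, c(n, n, ng))
  probe_cells <- vector("list", ng)
  dropped <- integer(ng)     # out-of-FOV background points per frame group
  for (g in seq_along(groups)) {
    f <- match(groups[g], seq$frame_groups)
    pts <- flow_frame(seq, f)
    cx <- round(pts$x / geom$cell) + geom$c0
    cy <- round(pts$y / geom$cell) + geom$c0
    inside <- cx >= 1 & cx <= n & cy >= 1 & cy <= n
    dropped[g] <- sum(!inside & !pts$is_probe)
    pts <- pts[inside, , drop = FALSE]
    cx <- cx[inside]; cy <- cy[inside]
    idx <- cx + (cy - 1L) * n
    bg <- !pts$is_probe
    if (any(bg)) {
      sl_vx <- rep(0, n * n); sl_vy <- rep(0, n * n)
      sl_d <- rep(0, n * n); cnt <- rep(0, n * n); cntd <- rep(0, n * n)
      ib <- idx[bg]
      sl_vx <- sl_vx + unname(tapply_sum(pts$vx[bg], ib, n * n))
      sl_vy <- sl_vy + unname(tapply_sum(pts$vy[bg], ib, n * n))
      cnt <- cnt + unname(tapply_sum(rep(1, sum(bg)), ib, n * n))
      hasd <- bg & !is.na(pts$disparity)
      if (any(hasd)) {
        sl_d <- sl_d + unname(tapply_sum(pts$disparity[hasd], idx[hasd], n * n))
        cntd <- cntd + unname(tapply_sum(rep(1, sum(hasd)), idx[hasd], n * n))
      }
      occ_sl <- cnt > 0
      sl_vx[occ_sl] <- sl_vx[occ_sl] / cnt[occ_sl]
      sl_vy[occ_sl] <- sl_vy[occ_sl] / cnt[occ_sl]
      dsl <- rep(NA_real_, n * n)
      dsl[cntd > 0] <- sl_d[cntd > 0] / cntd[cntd > 0]
      vx[, , g] <- sl_vx; vy[, , g] <- sl_vy
      disp[, , g] <- dsl; occ[, , g] <- occ_sl
    }
    if (any(pts$is_probe)) {
      pr <- seq$probe
      d2 <- (geom$xdeg_grid - pr$offset_from_foe[1])^2 +
            (geom$ydeg_grid - pr$offset_from_foe[2])^2
      pc <- which(d2 <= (pr$diameter / 2)^2)
      if (length(pc) == 0L) {  # probe smaller than a cell: nearest cell
        pc <- which.min(d2)
      }
      pv <- seq$probe_velocity$total
      vxg <- vx[, , g]; vyg <- vy[, , g]; dg <- disp[, , g]; og <- occ[, , g]
      vxg[pc] <- pv[1]; vyg[pc] <- pv[2]
      dg[pc] <- pts$disparity[pts$is_probe][1]
      og[pc] <- TRUE
      vx[, , g] <- vxg; vy[, , g] <- vyg; disp[, , g] <- dg; occ[, , g] <- og
      probe_cells[[g]] <- pc
    } else probe_cells[[g]] <- integer(0)
  }
  structure(list(vx = vx, vy = vy, disparity = disp, occupancy = occ,
                 groups = groups, frame_groups = seq$frame_groups,
                 probe_cells = probe_cells,
                 n = n, geom = geom,
                 stereo = isTRUE(seq$scene$stereo),
                 dropped_points = dropped,
                 seq = seq),
            class = "grid_flow")
}

# grouped sum over cell indices, returning a length-ncell vector
tapply_sum <- function(v, idx, ncell) {
  out <- rep(0, ncell)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Grid geometry for an n x n input raster
#'
#' Cell size is `fov / n`; the grid origin (0 deg, 0 deg) is the centre of
#' cell `c0 = n/2 + 1`, which also lies on the MSTd singularity lattice so
#' that a central FOE falls exactly on a template singularity.
#'
#' @param n grid dimension.
#' @param fov field of view in degrees.
#' @return list with `cell` (deg), `c0`, per-cell degree coordinates and
#'   eccentricity maps.
#' @export
grid_geometry <- function(n, fov = 40) {
  cell <- fov / n
  c0 <- n / 2 + 1
  xdeg <- (seq_len(n) - c0) * cell
  xg <- matrix(xdeg, n, n)          # column index = x
  yg <- matrix(xdeg, n, n, byrow = TRUE)
  list(n = n, fov = fov, cell = cell, c0 = c0, xdeg = xdeg,
       xdeg_grid = xg, ydeg_grid = yg,
       ecc_grid = sqrt(xg^2 + yg^2))
}

#' @export
print.grid_flow <- function(x, ...) {
  cat(sprintf(
    "<grid_flow> %dx%d grid, %d unique frame groups (%d frames), %s\n",
    x$n, x$n, length(x$groups), length(x$frame_groups),
    if (x$stereo) "stereo" else "monocular"))
  invisible(x)
}

#' Read a scene + probe configuration from a YAML file
#'
#' The YAML file mirrors the [scene_spec()] and [probe_spec()] argument
#' names under top-level keys `scene:` and `probe:`.
#'
#' @param path path to a YAML file.
#' @return list with elements `scene` and `probe`.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scene <- do.call(scene_spec, cfg$scene)
  probe <- do.call(probe_spec, cfg$probe)
  list(scene = scene, probe = probe)
}

#' Export a grid_flow object to CSV
#'
#' One row per occupied cell and frame group: columns `group`, `col`, `row`,
#' `x_deg`, `y_deg`, `vx`, `vy`, `disparity`, `is_probe`.
#'
#' @param gf a `"grid_flow"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gridflow_csv <- function(gf, path) {
  rows <- list()
  for (g in seq_along(gf$groups)) {
    occ <- which(gf$occupancy[, , g])
    if (!length(occ)) next
    col <- ((occ - 1L) %% gf$n) + 1L
    row <- ((occ - 1L) %/% gf$n) + 1L
    rows[[g]] <- data.frame(group = gf$groups[g], col = col, row = row,
                            x_deg = gf$geom$xdeg[col], y_deg = gf$geom$xdeg[row],
                            vx = gf$vx[, , g][occ], vy = gf$vy[, , g][occ],
                            disparity = gf$disparity[, , g][occ],
                            is_probe = occ %in% gf$probe_cells[[g]])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
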
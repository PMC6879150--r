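# MT Layer 4/6 front-end: separable direction, speed and disparity tuning
# curves applied to the rasterized velocity field, including the
# disparity-dependent response gain used for binocular stimuli.

#' MT tuning bank
#'
#' Defines the tuning of the MT Layer 4/6 population: 24 direction
#' preferences tiling 360 deg in 15 deg steps, 5 log-spaced speed
#' preferences spanning the stimulus family's dynamic range, and (for stereo
#' runs) 5 disparity preferences ordered near to far. Tuning-curve families
#' are a circular Gaussian in direction, a log-Gaussian band-pass in speed
#' and a Gaussian in disparity; responses along the three dimensions combine
#' multiplicatively.
#'
#' @param speed_prefs increasing vector of preferred speeds, deg/s.
#' @param dir_prefs direction preferences, deg (default 24 values 15 deg
#'   apart).
#' @param disp_prefs disparity preferences in arcmin ordered near (crossed,
#'   positive) to far, or `NULL` for monocular runs.
#' @param dir_sigma circular-Gaussian direction bandwidth, deg.
#' @param speed_sigma_oct log-Gaussian speed bandwidth, octaves.
#' @param disp_sigma disparity bandwidth, arcmin; defaults to the
#'   inter-preference spacing.
#' @param gain_mono monocular response gain.
#' @param gain_near,gain_far binocular response gain at the nearest and
#'   farthest disparity preference; the gain interpolates linearly in
#'   between and decreases with depth.
#' @return an object of class `"tuning_bank"`.
#' @export
tuning_bank <- function(speed_prefs,
                        dir_prefs = seq(0, 345, by = 15),
                        disp_prefs = NULL,
                        dir_sigma = 30,
                        speed_sigma_oct = 1,
                        disp_sigma = NULL,
                        gain_mono = 1,
                        gain_near = 1.5,
                        gain_far = 1.15) {
  if (any(diff(speed_prefs) <= 0)) stop("speed_prefs must be increasing")
  if (length(dir_prefs) > 1) {
    gaps <- diff(sort(dir_prefs %% 360))
    if (max(abs(gaps - gaps[1])) > 1e-9)
      stop("dir_prefs must uniformly tile 360 degrees")
  }
  if (!is.null(disp_prefs)) {
    if (any(diff(disp_prefs) >= 0))
      stop("disp_prefs must be strictly ordered near (positive) to far")
    if (is.null(disp_sigma)) disp_sigma <- abs(mean(diff(disp_prefs)))
  }
  if (!(gain_near >= gain_far && gain_far >= gain_mono))
    stop("need gain_near >= gain_far >= gain_mono")
  structure(list(speed_prefs = speed_prefs, dir_prefs = dir_prefs,
                 disp_prefs = disp_prefs,
                 dir_sigma = dir_sigma, speed_sigma_oct = speed_sigma_oct,
                 disp_sigma = disp_sigma,
                 gain_mono = gain_mono, gain_near = gain_near,
                 gain_far = gain_far),
            class = "tuning_bank")
}

#' Direction tuning curve
#'
#' Circular Gaussian `exp(-(d/sigma)^2)` of the wrapped difference between
#' stimulus and preferred direction; 1 at the preferred direction, minimal
#' at the anti-preferred, symmetric in +/- offsets.
#'
#' @param angle stimulus direction, deg.
#' @param pref preferred direction, deg.
#' @param bandwidth sigma, deg.
#' @return weight in `[0, 1]`.
#' @export
direction_response <- function(angle, pref, bandwidth = 30) {
  exp(-(circ_diff(angle, pref) / bandwidth)^2)
}

#' Speed tuning curve
#'
#' Log-Gaussian band-pass `exp(-(log2(v/pref)/sigma)^2)`; peak 1 at the
#' preferred speed, 0 at zero speed for any positive preference.
#'
#' @param speed stimulus speed, deg/s (non-negative).
#' @param pref preferred speed, deg/s.
#' @param bandwidth sigma in octaves.
#' @return weight in `[0, 1]`.
#' @export
speed_response <- function(speed, pref, bandwidth = 1) {
  if (any(speed < 0)) stop("speed must be >= 0")
  out <- numeric(length(speed))
  pos <- speed > 1e-12
  out[pos] <- exp(-(log2(speed[pos] / pref) / bandwidth)^2)
  out
}

#' Disparity tuning curve
#'
#' Gaussian in the difference between stimulus and preferred disparity. In
#' monocular runs disparity tuning is bypassed (the activity tensors carry
#' no disparity axis and the weight is identically 1).
#'
#' @param disp stimulus disparity, arcmin.
#' @param pref preferred disparity, arcmin.
#' @param bandwidth sigma, arcmin.
#' @return weight in `[0, 1]`.
#' @export
disparity_response <- function(disp, pref, bandwidth) {
  exp(-((disp - pref) / bandwidth)^2)
}

#' Disparity-dependent response gain
#'
#' Multiplier applied to MT Layer 4/6 responses in binocular runs. The gain
#' is maximal at the nearest preferred disparity and decreases linearly (in
#' disparity) towards the farthest, clamped at the endpoints; monocular
#' stimuli have gain `gain_mono`.
#'
#' @param disp stimulus disparity, arcmin (`NA` for monocular input).
#' @param bank a [tuning_bank()].
#' @return multiplier `>= gain_mono` for binocular input, `gain_mono`
#'   otherwise.
#' @export
disparity_gain <- function(disp, bank) {
  if (is.null(bank$disp_prefs)) return(rep(bank$gain_mono, length(disp)))
  near <- bank$disp_prefs[1]
  far <- bank$disp_prefs[length(bank$disp_prefs)]
  frac <- if (near == far) rep(0, length(disp))
          else pmin(pmax((disp - near) / (far - near), 0), 1)
  out <- bank$gain_near + frac * (bank$gain_far - bank$gain_near)
  out[is.na(disp)] <- bank$gain_mono
  out
}

#' Encode a grid-flow frame into MT Layer 4/6 activity
#'
#' For every occupied cell, activation over the (direction, speed[,
#' disparity]) tuning lattice is the product of the separable tuning curves
#' evaluated on the cell's motion vector, times the disparity-dependent
#' gain. Unoccupied cells are zero.
#'
#' @param grid a `"grid_flow"`.
#' @param bank a [tuning_bank()].
#' @param frame_group which unique frame group of `grid` to encode.
#' @return numeric array of dimension `(n*n, n_dir, n_speed)` for monocular
#'   input or `(n*n, n_dir, n_speed, n_disp)` for stereo, with attribute
#'   `area_tag = "MT46"`.
#' @export
mt_encode <- function(grid, bank, frame_group = 1L) {
  stopifnot(inherits(grid, "grid_flow"), inherits(bank, "tuning_bank"))
  g <- match(frame_group, grid$groups)
  if (is.na(g)) stop("no such frame group")
  vx <- c(grid$vx[, , g]); vy <- c(grid$vy[, , g])
  if (any(!is.finite(vx)) || any(!is.finite(vy)))
    stop("non-finite velocities at cells ",
         paste(utils::head(which(!is.finite(vx) | !is.finite(vy))), collapse = ", "))
  occ <- c(grid$occupancy[, , g])
  ncell <- length(vx)
  nd <- length(bank$dir_prefs); ns <- length(bank$speed_prefs)
  stereo <- grid$stereo && !is.null(bank$disp_prefs)
  speed <- sqrt(vx^2 + vy^2)
  theta <- rad2deg(atan2(vy, vx))
  Wd <- matrix(0, ncell, nd)
  Ws <- matrix(0, ncell, ns)
  io <- which(occ)
  for (d in seq_len(nd))
    Wd[io, d] <- direction_response(theta[io], bank$dir_prefs[d], bank$dir_sigma)
  for (s in seq_len(ns))
    Ws[io, s] <- speed_response(speed[io], bank$speed_prefs[s], bank$speed_sigma_oct)
  # zero-speed cells have undefined direction: no response
  zs <- occ & speed <= 1e-12
  Wd[zs, ] <- 0
  if (!stereo) {
    out <- array(0, c(ncell, nd, ns))
    for (s in seq_len(ns)) out[, , s] <- (Wd * Ws[, s]) * bank$gain_mono
  } else {
    disp <- c(grid$disparity[, , g])
    gain <- disparity_gain(disp, bank)
    gain[!occ | is.na(disp)] <- 0
    ndp <- length(bank$disp_prefs)
    Wp <- matrix(0, ncell, ndp)
    iod <- which(occ & !is.na(disp))
    for (p in seq_len(ndp))
      Wp[iod, p] <- disparity_response(disp[iod], bank$disp_prefs[p], bank$disp_sigma)
    out <- array(0, c(ncell, nd, ns, ndp))
    for (p in seq_len(ndp))
      for (s in seq_len(ns))
        out[, , s, p] <- Wd * (Ws[, s] * Wp[, p] * gain)
  }
  attr(out, "area_tag") <- "MT46"
  out
}

#' Default per-family speed preferences
#'
#' Five log-spaced preferred speeds spanning the dynamic range of retinal
#' speeds produced by each stimulus family across its experimental
#' conditions (slow speeds near the FOE up to fast peripheral motion).
#' Frozen values, so that tuning is identical across the conditions of a
#' campaign.
#'
#' @param family `"frontoparallel"`, `"ground"` or `"cloud"`.
#' @return numeric vector of 5 speeds, deg/s.
#' @export
speed_prefs_for <- function(family) {
  switch(family,
         # components 1-10 deg/s at 4 deg ecc; the preference range covers
         # the slow-to-moderate bulk of the distribution and saturates below
         # the fastest peripheral speeds of the fastest conditions
         frontoparallel = logspace(0.5, 8, 5),
         # matched to the quintile medians of the ground-flow speed
         # distribution (geometric mean over the two translation speeds), so
         # that eccentricity ring q of a true-horizon ground template is
         # congruent with preference q
         ground = c(2.5, 12, 26, 45, 69),
         # kappa ~ 0.4-1.15 /s times ecc up to ~28 deg
         cloud = logspace(0.4, 16, 5),
         stop("unknown stimulus family: ", family))
}

#' Default disparity preferences for the cloud stimulus
#'
#' Five preferences evenly spanning the disparity range of the cloud's
#' depth volume (binocular parallax relative to fixation at the centre
#' depth), ordered near (crossed, positive) to far.
#'
#' @param scene a cloud [scene_spec()].
#' @return numeric vector of 5 disparities, arcmin.
#' @export
disp_prefs_for <- function(scene) {
  Zbar <- mean(scene$depth_range)
  d_near <- depth_to_disparity(scene$depth_range[1], Zbar, scene$interocular)
  d_far <- depth_to_disparity(scene$depth_range[2], Zbar, scene$interocular)
  seq(d_near, d_far, length.out = 5)
}
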
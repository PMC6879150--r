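# Object-motion readout: MSTv integration of MT- signals, population-vector
# decoding of the represented direction, stabilization detection, and the
# conversion of the angular shift into a flow-parsing gain.

#' One Euler step of the MSTv shunting equation
#'
#' MSTv units respond proportionally to retinal speed (speed-summating
#' pooling: the mean over MT- speed channels), integrate MT- signals with
#' an on-centre/off-surround receptive field, and are suppressed by the
#' MSTd feedback field. Same shunting form and semi-implicit update as
#' [mt_minus_step()]; MSTv carries no speed axis.
#'
#' @param P current MSTv activity `(n_cells, n_dir[, n_disp])`.
#' @param E excitatory drive: centre-pooled, speed-averaged MT- activity
#'   (see [mstv_drive()]).
#' @param I_surround feedforward surround inhibition.
#' @param I_fb MSTd feedback suppression (no speed axis).
#' @param dt Euler step, s.
#' @param alpha rate constant, 1/s.
#' @param B shunting bound.
#' @param gamma passive decay.
#' @return updated activity in `[0, B]`.
#' @export
mstv_step <- function(P, E, I_surround, I_fb = 0, dt = 1 / 300,
                      alpha = 30, B = 1, gamma = 1) {
  P <- (P + dt * alpha * B * E) /
    (1 + dt * alpha * (gamma + E + I_surround + I_fb))
  P[P < 0] <- 0
  P[P > B] <- B
  P
}

#' Excitatory and surround drives for MSTv
#'
#' Pools MT- activity across speed (proportional, equal-weight mean),
#' integrates it over a small Gaussian centre, and computes the like-tuned
#' surround inhibition from neighbouring positions.
#'
#' @param Mminus MT- activity `(n_cells, n_dir, n_speed[, n_disp])` defined
#'   on the cells `cells_in` of an `n x n` grid.
#' @param n grid dimension.
#' @param cells_in cell indices of the rows of `Mminus`.
#' @param cells_out cell indices at which drives are needed.
#' @param bank the [tuning_bank()] (for the direction/disparity similarity
#'   of the surround).
#' @param kappa_sur surround inhibition strength.
#' @param radius_c centre radius, cells.
#' @param radius_s surround radius, cells.
#' @return list `E`, `I` of arrays `(length(cells_out), n_dir[, n_disp])`.
#' @export
mstv_drive <- function(Mminus, n, cells_in, cells_out, bank, kappa_sur = 4,
                       radius_c = 1, radius_s = 2) {
  dm <- dim(Mminus)
  nd <- dm[2]; ns <- dm[3]
  stereo <- length(dm) == 4L
  # speed-summating pooling
  pooled <- if (stereo) {
    out <- array(0, c(dm[1], nd, dm[4]))
    for (p in seq_len(dm[4])) out[, , p] <- apply(Mminus[, , , p, drop = FALSE],
                                                  c(1, 2), mean)
    out
  } else apply(Mminus, c(1, 2), mean)
  nch <- prod(dim(pooled)) / dm[1]
  # scatter the patch into a full-grid sparse field for the convolutions
  full <- matrix(0, n * n, nch)
  full[cells_in, ] <- matrix(pooled, dm[1], nch)
  offc <- spatial_offsets(radius_c, radius_c / 2 + 0.5, normalize = TRUE)
  offs <- spatial_offsets(radius_s, radius_s / 2 + 0.5, exclude_center = TRUE,
                          normalize = TRUE)
  E <- conv_spatial(full, n, offc, cells = cells_out)
  Isur <- conv_spatial(full, n, offs, cells = cells_out)
  # direction (and disparity) similarity weighting of the surround
  sim <- similarity_matrices(bank)
  shp <- c(length(cells_out), nd, if (stereo) dm[4])
  Ea <- array(E, shp)
  Ia <- array(Isur, shp)
  m <- matrix(aperm(Ia, c(2, 1, if (stereo) 3)), nd, length(Ia) / nd)
  m <- crossprod(t(sim$Cd), m)
  Ia <- aperm(array(m, c(nd, length(cells_out), if (stereo) dm[4])),
              c(2, 1, if (stereo) 3))
  if (stereo && !is.null(sim$Cp)) {
    np <- dm[4]
    m <- matrix(aperm(Ia, c(3, 1, 2)), np, length(Ia) / np)
    m <- crossprod(t(sim$Cp), m)
    Ia <- aperm(array(m, c(np, length(cells_out), nd)), c(2, 3, 1))
  }
  list(E = Ea, I = kappa_sur * Ia)
}

#' Population-vector direction estimate
#'
#' The angle of the firing-rate-weighted resultant of the units' preferred
#' direction vectors:
#' `J = (sum w_d cos(theta_d), sum w_d sin(theta_d))`, decoded as
#' `atan2(Jv, Ju)`. Invariant to uniform scaling of the weights, and far
#' less constrained by the 15 deg angular quantization than winner-take-all.
#'
#' @param weights nonnegative firing rates, one per direction preference.
#' @param dir_prefs preferred directions, deg.
#' @return decoded angle in degrees (in (-180, 180]), or `NA` with
#'   attribute `reason` when all weights are zero or the resultant vanishes.
#' @export
population_vector <- function(weights, dir_prefs) {
  if (length(weights) != length(dir_prefs))
    stop("weights and dir_prefs lengths differ")
  if (all(weights == 0)) {
    return(structure(NA_real_, reason = "all-zero weights"))
  }
  th <- deg2rad(dir_prefs)
  ju <- sum(weights * cos(th))
  jv <- sum(weights * sin(th))
  if (sqrt(ju^2 + jv^2) < 1e-12 * sum(abs(weights))) {
    return(structure(NA_real_, reason = "zero resultant"))
  }
  rad2deg(atan2(jv, ju))
}

#' Angular shift of the decoded direction
#'
#' Circular difference between the decoded and the retinal object
#' direction, wrapped to (-180, 180].
#'
#' @param decoded decoded direction, deg.
#' @param retinal_dir the object's retinal direction, deg.
#' @return shift in degrees.
#' @export
shift_angle <- function(decoded, retinal_dir) {
  wrap180(decoded - retinal_dir)
}

#' Flow-parsing gain from an angular shift
#'
#' With object component speed `o` and self-motion component speed `c`
#' perpendicular to it, the retinal direction lies `beta = atan(c/o)` away
#' from the world-relative direction. A decoded shift of `shift` towards
#' the world-relative direction leaves a residual self-motion component
#' `resid = o * tan(beta - shift)`, and the gain is the fraction of the
#' self-motion component that was removed: `gain = 1 - r/c`. A shift of 0
#' gives gain 0; a shift of `beta` gives gain 1; overshoot past the
#' world-relative direction gives gain > 1.
#'
#' @param shift decoded shift towards the world-relative direction, deg.
#' @param o object component speed, deg/s (> 0).
#' @param c_comp self-motion component speed, deg/s (> 0).
#' @return object of class `"gain_result"`: list with `component_speed`,
#'   `object_speed`, `shift`, `residual` (deg/s) and `gain`.
#' @export
flow_parsing_gain <- function(shift, o, c_comp) {
  stopifnot_scalar(o, "o", positive = TRUE)
  stopifnot_scalar(c_comp, "c_comp", positive = TRUE)
  beta <- rad2deg(atan2(c_comp, o))
  if (abs(shift) >= beta + 90)
    stop("shift of ", shift, " deg is beyond the defined range ",
         "(|shift| < beta + 90)")
  residual <- o * tan(deg2rad(beta - shift))
  structure(list(component_speed = c_comp, object_speed = o,
                 shift = shift, residual = residual,
                 beta = beta, gain = 1 - residual / c_comp),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf(
    "flow parsing gain %.3f (shift %.2f deg of beta %.2f deg; o = %g, c = %g deg/s)\n",
    x$gain, x$shift, x$beta, x$object_speed, x$component_speed))
  invisible(x)
}

#' Detect stabilization of the decoded-direction trace
#'
#' The model run is considered stabilized at the first step from which the
#' decoded direction stays within a 1 deg band for a duration equivalent to
#' at least five frames of video.
#'
#' @param trace decoded angles, one per Euler step.
#' @param frame_rate input frame rate, frames/s.
#' @param steps_per_frame Euler steps per frame.
#' @param band tolerance band, deg.
#' @param n_frames number of frames the band must hold.
#' @return list with `stabilized` (logical) and `step` (the step at which
#'   the criterion first fires, `NA` if never).
#' @export
stabilization_check <- function(trace, frame_rate = 30, steps_per_frame = 10,
                                band = 1, n_frames = 5) {
  if (!length(trace)) stop("empty trace")
  W <- ceiling(n_frames * steps_per_frame)
  if (length(trace) < W) return(list(stabilized = FALSE, step = NA_integer_))
  # running min/max over trailing windows of length W
  for (t in seq_len(length(trace) - W + 1L)) {
    win <- trace[t:(t + W - 1L)]
    if (max(win) - min(win) <= band)
      return(list(stabilized = TRUE, step = t + W - 1L))
  }
  list(stabilized = FALSE, step = NA_integer_)
}

#' Plateau time of a shift trace
#'
#' The first time the shift trace enters, and stays within, a band of
#' `frac` of its final value.
#'
#' @param trace shift values, one per Euler step.
#' @param dt step size, s.
#' @param frac band half-width as a fraction of the final value.
#' @return plateau time in ms (time of first entry into the sustained
#'   band, measured from the first trace sample).
#' @export
plateau_time <- function(trace, dt, frac = 0.05) {
  final <- trace[length(trace)]
  tol <- abs(final) * frac
  inside <- abs(trace - final) <= tol
  # last step outside the band, +1 = first step of the sustained band
  out <- which(!inside)
  first_in <- if (!length(out)) 1L else out[length(out)] + 1L
  (first_in - 1L) * dt * 1000
}
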
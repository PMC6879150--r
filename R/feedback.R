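# MSTd feedback suppression. The most active MSTd unit suppresses MT- and
# MSTv units that locally match the direction, speed and disparity of its
# preferred global motion pattern; suppression falls off with tuning
# mismatch (Gaussian weighting per dimension) and with retinotopic distance
# from the winner's singularity, and is modulated by the winner's activity.

#' Gaussian tuning-mismatch weight
#'
#' `W(w; mu, sigma) = exp(-((w - mu)/sigma)^2)`: 1 at zero mismatch,
#' `exp(-1)` one sigma away, symmetric. Applied per dimension (direction
#' uses the circular difference, speed the log-speed difference, disparity
#' the bin difference) and multiplied across dimensions.
#'
#' @param w tuning value of the target unit.
#' @param mu locally prescribed value of the winner's template.
#' @param sigma mismatch falloff (> 0).
#' @return weight in `(0, 1]`.
#' @export
mismatch_weight <- function(w, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  exp(-((w - mu) / sigma)^2)
}

#' Local motion prescribed by the winning MSTd template
#'
#' For each requested grid cell, the direction and speed that the winner's
#' template prescribes there: direction is the template's local flow
#' direction; speed is the winner's estimate of the mean pattern speed
#' scaled by the template's local speed profile (proportional to
#' eccentricity for the radial family, to eccentricity times angle below
#' the horizon for ground units). The eccentricity-ring quintile and the
#' congruent disparity bin (slow pairs with far, fast with near, per motion
#' parallax) are also reported. Cells outside the template's domain (above
#' the horizon for a ground winner, or at the singularity) prescribe no
#' suppression.
#'
#' @param winner a winner description from [mstd_winner()].
#' @param tb the [template_bank()].
#' @param cells cell indices (into the `n x n` grid).
#' @param mean_speed the winner's estimate of the mean pattern speed across
#'   the field, deg/s (a band-pass winner's preferred speed; defaults to
#'   the geometric mean of the speed preferences).
#' @return list with per-cell `dir` (deg), `speed` (deg/s, continuous local
#'   pattern speed), `speed_bin` (ring quintile 1..n_speed), `disp_bin`
#'   (congruent disparity bin), and `defined`.
#' @export
local_template_motion <- function(winner, tb, cells, mean_speed = NULL) {
  n <- tb$n
  ground <- identical(winner$subpop, "ground")
  tpl <- if (ground) build_ground_template(winner$i, winner$j, n, tb$dist_r0)
         else build_radial_template(winner$i, winner$j, n, tb$dist_r0)
  prefs <- tb$bank$speed_prefs
  ns <- length(prefs)
  if (is.null(mean_speed)) {
    mean_speed <- if (!is.na(winner$s_pref %||% NA)) prefs[winner$s_pref]
                  else exp(mean(log(prefs)))
  }
  dirv <- tpl$dir[cells]
  ring <- tpl$ring[cells]
  if (ground) {
    profile <- tpl$speed[cells] / mean(tpl$speed[tpl$defined])
    defined <- tpl$defined[cells] & tpl$speed[cells] > 1e-9
  } else {
    profile <- tpl$r[cells] / mean(tpl$r)
    defined <- tpl$r[cells] > 1e-9
  }
  sbin <- switch(winner$subpop,
                 bp = rep(winner$s_pref, length(cells)),
                 grad_dec = ns + 1L - pmin(ring, ns),
                 pmin(ring, ns))   # ss, grad_inc, ground: quintile profile
  ndisp <- length(tb$bank$disp_prefs %||% 1)
  # congruent pairing: slowest quintile <-> farthest disparity bin
  rr <- pmin(ring, ns)
  dbin <- round(1 + (ndisp - 1) * (1 - (rr - 1) / max(ns - 1, 1)))
  list(dir = dirv, speed = mean_speed * profile,
       speed_bin = sbin, disp_bin = dbin, defined = defined)
}

#' Compose the MSTd feedback suppression field
#'
#' Builds the suppressive field delivered to MT-/MSTv:
#' `F(x, y, d, s[, p]) = scale * exp(-(r/sigma_dist)^2) * W_dir * W_sp`,
#' where `r` is the cell's distance from the winner's singularity, `W_dir`
#' is the [mismatch_weight()] between the unit's preferred direction and
#' the winner template's locally prescribed direction, and `W_sp` is the
#' log-speed mismatch against the locally prescribed pattern speed. In
#' stereo runs the prescribed speed follows the congruent speed-disparity
#' diagonal of motion parallax: at disparity preference `p` it is the local
#' pattern speed times the relative parallax rate of that depth, so units
#' tuned to slow-and-far (or fast-and-near) are suppressed more than
#' incongruent combinations. The field is zero when MSTd is inactive and
#' scales linearly with the winner's activity; fields without a speed axis
#' (MSTv) are the speed-average of the full field.
#'
#' @param winner a winner description from [mstd_winner()] (or `NULL` /
#'   zero activity for an inactive MSTd).
#' @param tb the [template_bank()].
#' @param cells cell indices at which the field is needed.
#' @param fb_gain overall feedback gain multiplying the winner activity.
#' @param dir_sigma direction-mismatch falloff, deg.
#' @param speed_sigma_oct speed-mismatch falloff, octaves.
#' @param dist_sigma retinotopic distance falloff, cells.
#' @param mean_speed passed to [local_template_motion()].
#' @param parallax relative parallax-rate factors per disparity preference
#'   (near to far, decreasing; 1 = fixation depth), or `NULL` for a
#'   disparity-indifferent field.
#' @param speed_axis include the speed axis (MT- form); `FALSE` gives the
#'   MSTv form `(cells, n_dir[, n_disp])`.
#' @param stereo include the disparity axis.
#' @return suppression array `(length(cells), n_dir[, n_speed][, n_disp])`.
#' @export
compose_feedback <- function(winner, tb, cells, fb_gain = 1,
                             dir_sigma = 45, speed_sigma_oct = 0.75,
                             dist_sigma = 16, mean_speed = NULL,
                             parallax = NULL, speed_axis = TRUE,
                             stereo = FALSE) {
  bank <- tb$bank
  nd <- length(bank$dir_prefs)
  ns <- length(bank$speed_prefs)
  np <- if (stereo) length(bank$disp_prefs) else 1L
  shape_full <- c(length(cells), nd, ns, if (stereo) np)
  if (is.null(winner) || winner$activity <= 0) {
    out <- array(0, shape_full)
  } else {
    loc <- local_template_motion(winner, tb, cells, mean_speed = mean_speed)
    n <- tb$n
    cx <- ((cells - 1L) %% n) + 1L
    cy <- ((cells - 1L) %/% n) + 1L
    r <- sqrt((cx - winner$i)^2 + (cy - winner$j)^2)
    scale <- fb_gain * winner$activity * exp(-(r / dist_sigma)^2)
    scale[!loc$defined] <- 0
    Wd <- exp(-(outer(loc$dir, bank$dir_prefs, circ_diff) / dir_sigma)^2)
    Wd[!loc$defined, ] <- 0
    if (is.null(parallax)) parallax <- rep(1, np)
    out <- array(0, shape_full)
    lsp <- log2(pmax(loc$speed, 1e-6))
    for (p in seq_len(np)) {
      mu <- lsp + log2(parallax[p])
      for (s in seq_len(ns)) {
        Ws <- exp(-((log2(bank$speed_prefs[s]) - mu) / speed_sigma_oct)^2)
        slice <- (scale * Ws) * Wd
        if (stereo) out[, , s, p] <- slice else out[, , s] <- slice
      }
    }
  }
  if (!speed_axis) {
    # MSTv form: speed-average of the full field
    pm <- aperm(out, c(1, 2, if (stereo) 4, 3))
    dim(pm) <- c(length(pm) / ns, ns)
    out <- array(rowMeans(pm), c(length(cells), nd, if (stereo) np))
  }
  out
}
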
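# The model runner: wires stimuli -> MT front-end -> MT+/MSTd and MT-/MSTv
# pathways -> feedback -> readout into a single condition simulation, with
# the frame -> 10 Euler substeps integration scheme and input-held
# continuation until the decoded direction stabilizes.

# template banks and encoded frames are expensive; cache them per geometry
.fp_cache <- new.env(parent = emptyenv())

#' Model control parameters
#'
#' All tunable constants of the model in one place. Defaults are the
#' package's calibrated standard parameter set; spatial radii and scales
#' are expressed at the reference 64 x 64 resolution and scaled
#' proportionally when `resolution` differs (the reduced 32 x 32 mode is
#' intended for fast tests).
#'
#' @param resolution input grid dimension (64 reference; 32 reduced mode).
#' @param fov field of view, deg.
#' @param frame_rate input frames per second.
#' @param steps_per_frame Euler substeps per input frame (step size
#'   `1/(frame_rate*steps_per_frame)` s, about 3 ms at the defaults).
#' @param hold_max maximum input-held continuation after the last frame, s.
#' @param dir_sigma MT direction tuning width, deg.
#' @param speed_sigma_oct MT speed tuning width, octaves.
#' @param gain_near,gain_far binocular response gain at the nearest/farthest
#'   disparity preference.
#' @param stereo_gain logical; disable to force all disparity gains to 1
#'   (the gain-ablation used to probe recurrent engagement).
#' @param mtplus_alpha,mtplus_radius,mtplus_sigma MT+ integrator rate (1/s)
#'   and RF radius/width (cells).
#' @param tau_rec,kappa_dep depressing-synapse recovery time constant (s)
#'   and depletion rate.
#' @param mtminus_alpha,mtminus_B,mtminus_gamma MT- shunting constants.
#' @param kappa_loc feedforward surround-inhibition strength.
#' @param sur_radius,sur_sigma MT- surround geometry, cells.
#' @param mstv_alpha,mstv_B,mstv_gamma MSTv shunting constants.
#' @param kappa_sur_v,mstv_radius_c,mstv_radius_s MSTv surround strength and
#'   centre/surround radii, cells.
#' @param mstd_alpha,mstd_B,mstd_gamma,mstd_beta,mstd_omega MSTd
#'   competitive-network constants (rate, shunting ceiling, decay, recurrent
#'   signal gain, broad lateral-inhibition strength).
#' @param theta_eng engagement threshold as a fraction of the theoretical
#'   maximum feedforward drive of the subpopulation.
#' @param gain_bp,gain_ss,gain_grad,gain_ground MSTd subpopulation input
#'   gains.
#' @param dist_r0 retinotopic distance-weight scale of the MSTd templates,
#'   cells.
#' @param ring_sigma ring-to-speed coupling width of gradient/ground
#'   templates.
#' @param fb_gain overall feedback gain to MT- (0 disables feedback).
#' @param fb_gain_v feedback gain of the direct MSTd->MSTv projection;
#'   defaults to `fb_gain / 20` (the MSTv field is speed-averaged and hence
#'   less selective, so it carries a small share of the suppression).
#' @param fb_dir_sigma,fb_speed_sigma_oct feedback mismatch falloffs (deg,
#'   octaves); disparity selectivity follows the congruent speed-disparity
#'   diagonal (see [compose_feedback()]).
#' @param fb_dist_sigma feedback distance falloff, cells.
#' @param ground_veto strength of the ground units' horizon constraint
#'   (see [feedforward_drive()]).
#' @param ground_units `NA` (scenario default: on for ground scenes, off
#'   otherwise) or logical.
#' @param readout `"mstv"` (default) or `"mt-"`.
#' @return a list of class `"fp_control"`.
#' @export
fp_control <- function(resolution = 64, fov = 40, frame_rate = 30,
                       steps_per_frame = 10, hold_max = 3,
                       dir_sigma = 45, speed_sigma_oct = 1,
                       gain_near = 2.2, gain_far = 1.6, stereo_gain = TRUE,
                       mtplus_alpha = 20, mtplus_radius = 2, mtplus_sigma = 1,
                       tau_rec = 0.5, kappa_dep = 0.3,
                       mtminus_alpha = 30, mtminus_B = 1, mtminus_gamma = 1,
                       kappa_loc = 4, sur_radius = 3, sur_sigma = 1.5,
                       mstv_alpha = 30, mstv_B = 1, mstv_gamma = 1,
                       kappa_sur_v = 2, mstv_radius_c = 0, mstv_radius_s = 2,
                       mstd_alpha = 10, mstd_B = 1, mstd_gamma = 1,
                       mstd_beta = 60, mstd_omega = 30, theta_eng = 1.15,
                       gain_bp = 1, gain_ss = 1, gain_grad = 0.15,
                       gain_ground = 2.2,
                       dist_r0 = 32, ring_sigma = 1,
                       fb_gain = 500, fb_gain_v = NULL, fb_dir_sigma = 45,
                       fb_speed_sigma_oct = 1.0, fb_dist_sigma = 5,
                       ground_veto = 12,
                       ground_units = NA, readout = c("mstv", "mt-")) {
  ctl <- as.list(environment())
  ctl$readout <- match.arg(readout)
  class(ctl) <- "fp_control"
  ctl
}

# resolution-scaled geometry
scaled_ctl <- function(ctl) {
  sc <- ctl$resolution / 64
  ctl$mtplus_radius <- max(1L, round(ctl$mtplus_radius * sc))
  ctl$sur_radius <- max(1L, round(ctl$sur_radius * sc))
  ctl$mstv_radius_c <- if (ctl$mstv_radius_c > 0)
    max(1L, round(ctl$mstv_radius_c * sc)) else 0L
  ctl$mstv_radius_s <- max(1L, round(ctl$mstv_radius_s * sc))
  ctl$fb_dist_sigma <- ctl$fb_dist_sigma * sc
  ctl$dist_r0 <- ctl$dist_r0 * sc
  ctl
}

fp_bank <- function(scene, ctl) {
  stereo <- isTRUE(scene$stereo)
  dp <- if (stereo) disp_prefs_for(scene) else NULL
  gn <- if (stereo && ctl$stereo_gain) ctl$gain_near else 1
  gf <- if (stereo && ctl$stereo_gain) ctl$gain_far else 1
  tuning_bank(speed_prefs = speed_prefs_for(scene$scenario),
              disp_prefs = dp,
              dir_sigma = ctl$dir_sigma,
              speed_sigma_oct = ctl$speed_sigma_oct,
              gain_mono = 1, gain_near = gn, gain_far = gf)
}

fp_template_bank <- function(n, bank, ctl) {
  key <- paste(n, ctl$dist_r0, ctl$ring_sigma, ctl$dir_sigma,
               length(bank$dir_prefs), length(bank$speed_prefs), sep = "|")
  tb <- .fp_cache[[key]]
  if (is.null(tb)) {
    tb <- template_bank(n, bank, dist_r0 = ctl$dist_r0,
                        ring_sigma = ctl$ring_sigma, ground = TRUE)
    .fp_cache[[key]] <- tb
  }
  tb$bank <- bank   # speed/disparity prefs may differ between families
  tb
}

# linear operators mapping a patch field (rows = cells_in) to values at
# cells_out through a spatial offset kernel
patch_operator <- function(cells_in, cells_out, offsets, n) {
  K <- matrix(0, length(cells_out), length(cells_in))
  ox <- ((cells_out - 1L) %% n) + 1L
  oy <- ((cells_out - 1L) %/% n) + 1L
  pos <- integer(n * n); pos[cells_in] <- seq_along(cells_in)
  for (k in seq_len(nrow(offsets))) {
    sx <- ox + offsets$dx[k]; sy <- oy + offsets$dy[k]
    ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n
    if (!any(ok)) next
    src <- pos[sx[ok] + (sy[ok] - 1L) * n]
    hit <- src > 0
    if (!any(hit)) next
    rows <- which(ok)[hit]
    K[cbind(rows, src[hit])] <- K[cbind(rows, src[hit])] + offsets$w[k]
  }
  K
}

expand_bbox <- function(cells, n, margin) {
  cx <- ((cells - 1L) %% n) + 1L
  cy <- ((cells - 1L) %/% n) + 1L
  xr <- max(1L, min(cx) - margin):min(n, max(cx) + margin)
  yr <- max(1L, min(cy) - margin):min(n, max(cy) + margin)
  as.integer(outer(xr, (yr - 1L) * n, "+"))
}

#' Run the model on one stimulus condition
#'
#' The main entry point: generates the stimulus, encodes it into MT Layer
#' 4/6 activity, integrates the MT+/MSTd self-motion pathway and the
#' MT-/MSTv object-motion pathway with MSTd feedback suppression (10 Euler
#' substeps per input frame), holds the final input until the decoded
#' object direction stabilizes (within 1 deg over five frames), and
#' returns the decoded-direction trace, the angular shift and flow-parsing
#' gain, and MSTd diagnostics.
#'
#' @param scene a [scene_spec()].
#' @param probe a [probe_spec()].
#' @param control an [fp_control()].
#' @return an object of class `"flowparse"`; see [summary.flowparse()].
#' @export
flow_parse <- function(scene, probe, control = fp_control()) {
  stopifnot(inherits(scene, "scene_spec"), inherits(probe, "probe_spec"),
            inherits(control, "fp_control"))
  ctl <- scaled_ctl(control)
  n <- ctl$resolution
  spf <- ctl$steps_per_frame
  dtt <- 1 / (ctl$frame_rate * spf)
  scene$frame_rate <- ctl$frame_rate
  scene$field_of_view <- ctl$fov
  seq <- gen_flow(scene, probe)
  gf <- rasterize(seq, n)
  stereo <- gf$stereo
  bank <- fp_bank(scene, ctl)
  ground_on <- if (is.na(ctl$ground_units)) scene$scenario == "ground"
               else isTRUE(ctl$ground_units)
  tb <- fp_template_bank(n, bank, ctl)
  gains <- list(bp = ctl$gain_bp, ss = ctl$gain_ss, grad = ctl$gain_grad,
                ground = if (ground_on) ctl$gain_ground else 0)

  # per-frame-group static quantities
  groups <- gf$groups
  enc <- lapply(seq_along(groups), function(g)
    mt_encode(gf, bank, frame_group = groups[g]))
  dplus <- lapply(enc, function(e)
    c(mt_plus_drive(e, n, ctl$mtplus_radius, ctl$mtplus_sigma)))
  occs <- lapply(seq_along(groups), function(g)
    as.numeric(gf$occupancy[, , g]))
  vys <- lapply(seq_along(groups), function(g) as.numeric(gf$vy[, , g]))
  # probe patch geometry (probe cells exist in the probe-bearing group)
  pg <- which(vapply(gf$probe_cells, length, 1L) > 0)[1]
  if (is.na(pg)) stop("no probe cells on the grid")
  probe_cells <- gf$probe_cells[[pg]]
  margin <- max(ctl$mstv_radius_c, ctl$mstv_radius_s)
  cells_m <- expand_bbox(probe_cells, n, margin)
  cells_v <- probe_cells
  iloc <- lapply(enc, function(e)
    mt_surround_inhibition(e, n, bank, ctl$kappa_loc, ctl$sur_radius,
                           ctl$sur_sigma, cells = cells_m))
  e_m <- lapply(enc, function(e) {
    dm <- dim(e); dm[1] <- length(cells_m)
    array(matrix(e, dim(e)[1])[cells_m, ], dm)
  })
  # MSTv patch operators
  offc <- spatial_offsets(ctl$mstv_radius_c, ctl$mstv_radius_c / 2 + 0.5,
                          normalize = TRUE)
  offs <- spatial_offsets(ctl$mstv_radius_s, ctl$mstv_radius_s / 2 + 0.5,
                          exclude_center = TRUE, normalize = TRUE)
  Kc <- patch_operator(cells_m, cells_v, offc, n)
  Ks <- patch_operator(cells_m, cells_v, offs, n)
  sim <- similarity_matrices(bank)

  # state
  nd <- length(bank$dir_prefs); ns <- length(bank$speed_prefs)
  np <- if (stereo) length(bank$disp_prefs) else 0L
  sz_full <- n * n * nd * ns * max(np, 1L)
  m_plus <- numeric(sz_full)
  u_syn <- rep(1, sz_full)
  mstd <- mstd_state(tb, stereo = stereo, theta_eng = ctl$theta_eng,
                     gains = gains)
  shp_m <- c(length(cells_m), nd, ns, if (stereo) np)
  M <- array(0, shp_m)
  shp_v <- c(length(cells_v), nd, if (stereo) np)
  P <- array(0, shp_v)
  win <- NULL
  Fm_unit <- array(0, shp_m)      # feedback fields for unit winner activity
  Fv_unit <- array(0, shp_v)
  win_index <- -1L
  # relative parallax rate per disparity preference (near moves faster)
  parallax <- if (stereo)
    1 + mean(scene$depth_range) * deg2rad(bank$disp_prefs / 60) /
      scene$interocular else NULL

  n_frames <- seq$n_frames
  hold_frames <- ceiling(ctl$hold_max * ctl$frame_rate)
  retinal_dir <- seq$probe_velocity$retinal_direction
  world_dir <- probe$object_direction
  toward <- sign(circ_diff(world_dir, retinal_dir))
  if (toward == 0) toward <- 1

  trace_dec <- numeric(0)
  trace_t <- numeric(0)
  peak_series <- numeric(0)
  drive_peak <- 0
  stab <- list(stabilized = FALSE, step = NA_integer_)
  t_now <- 0
  zdim <- c(n * n, nd, ns, if (stereo) np)

  for (f in seq_len(n_frames + hold_frames)) {
    g <- if (f <= n_frames) match(gf$frame_groups[f], groups)
         else match(gf$frame_groups[n_frames], groups)
    st <- cpp_mtplus_frame(m_plus, u_syn, dplus[[g]], dtt, spf,
                           ctl$mtplus_alpha, ctl$tau_rec, ctl$kappa_dep)
    m_plus <- st$m; u_syn <- st$u
    z <- st$z; dim(z) <- zdim
    drv <- flatten_drive(mstd, feedforward_drive(tb, z, gains,
                                                 occupancy = occs[[g]],
                                                 ground_veto = ctl$ground_veto,
                                                 vy = vys[[g]]))
    drive_peak <- max(drive_peak, max(drv))
    probe_on <- length(gf$probe_cells[[g]]) > 0
    for (k in seq_len(spf)) {
      mstd <- recurrent_step(mstd, drv, dtt, alpha = ctl$mstd_alpha,
                             B = ctl$mstd_B, gamma = ctl$mstd_gamma,
                             beta = ctl$mstd_beta, omega = ctl$mstd_omega)
      w <- mstd_winner(mstd, tb)
      if (w$index != win_index && w$activity > 0) {
        win_index <- w$index
        wu <- w; wu$activity <- 1
        # the winner's mean-pattern-speed estimate: a band-pass winner's own
        # preference, otherwise the activity-weighted mean of the band-pass
        # column at the winner's singularity
        ms <- if (!is.na(w$s_pref)) NULL else {
          blk <- mstd$A[mstd$offsets["bp"] + seq_len(mstd$sizes["bp"])]
          Abp <- matrix(blk, mstd$nij)[w$ij, ]
          wsp <- rowSums(matrix(Abp, ns))
          if (sum(wsp) > 0) sum(bank$speed_prefs * wsp) / sum(wsp) else NULL
        }
        Fm_unit <- compose_feedback(wu, tb, cells_m, fb_gain = 1,
                                    dir_sigma = ctl$fb_dir_sigma,
                                    speed_sigma_oct = ctl$fb_speed_sigma_oct,
                                    dist_sigma = ctl$fb_dist_sigma,
                                    mean_speed = ms, parallax = parallax,
                                    speed_axis = TRUE, stereo = stereo)
        Fv_unit <- compose_feedback(wu, tb, cells_v, fb_gain = 1,
                                    dir_sigma = ctl$fb_dir_sigma,
                                    speed_sigma_oct = ctl$fb_speed_sigma_oct,
                                    dist_sigma = ctl$fb_dist_sigma,
                                    mean_speed = ms, parallax = parallax,
                                    speed_axis = FALSE, stereo = stereo)
      }
      fb_scale <- ctl$fb_gain * w$activity
      fb_scale_v <- (ctl$fb_gain_v %||% (ctl$fb_gain / 20)) * w$activity
      M <- mt_minus_step(M, e_m[[g]], iloc[[g]], fb_scale * Fm_unit,
                         dt = dtt, alpha = ctl$mtminus_alpha,
                         B = ctl$mtminus_B, gamma = ctl$mtminus_gamma)
      # MSTv drive from the current MT- patch (speed-summating pooling)
      pooled <- if (stereo) {
        pl <- array(0, c(length(cells_m), nd, np))
        for (p in seq_len(np)) {
          sl <- M[, , , p]
          dim(sl) <- c(length(cells_m) * nd, ns)
          pl[, , p] <- rowMeans(sl)
        }
        pl
      } else {
        sl <- M
        dim(sl) <- c(length(cells_m) * nd, ns)
        array(rowMeans(sl), c(length(cells_m), nd))
      }
      pm <- matrix(pooled, length(cells_m))
      Ev <- array(Kc %*% pm, shp_v)
      Iv <- array(Ks %*% pm, shp_v)
      mm <- matrix(aperm(Iv, c(2, 1, if (stereo) 3)), nd, length(Iv) / nd)
      mm <- crossprod(t(sim$Cd), mm)
      Iv <- aperm(array(mm, c(nd, length(cells_v), if (stereo) np)),
                  c(2, 1, if (stereo) 3))
      if (stereo && !is.null(sim$Cp)) {
        mm <- matrix(aperm(Iv, c(3, 1, 2)), np, length(Iv) / np)
        mm <- crossprod(t(sim$Cp), mm)
        Iv <- aperm(array(mm, c(np, length(cells_v), nd)), c(2, 3, 1))
      }
      P <- mstv_step(P, Ev, ctl$kappa_sur_v * Iv, fb_scale_v * Fv_unit,
                     dt = dtt, alpha = ctl$mstv_alpha, B = ctl$mstv_B,
                     gamma = ctl$mstv_gamma)
      t_now <- t_now + dtt
      if (probe_on) {
        wsrc <- if (ctl$readout == "mstv") P else {
          ip <- match(cells_v, cells_m)
          if (stereo) M[ip, , , , drop = FALSE] else M[ip, , , drop = FALSE]
        }
        wd <- rowSums(matrix(wsrc, length(cells_v) * nd))
        wd <- colSums(matrix(wd, length(cells_v), nd))
        dec <- population_vector(wd, bank$dir_prefs)
        trace_dec <- c(trace_dec, dec)
        trace_t <- c(trace_t, t_now)
      }
    }
    peak_series <- c(peak_series, max(mstd$A))
    if (f > n_frames && length(trace_dec) >= 5 * spf) {
      stab <- stabilization_check(trace_dec, ctl$frame_rate, spf)
      if (stab$stabilized) break
    }
  }

  dec_final <- trace_dec[length(trace_dec)]
  shift_signed <- shift_angle(dec_final, retinal_dir)
  shift_tw <- toward * shift_signed
  gr <- flow_parsing_gain(shift_tw, probe$object_speed,
                          scene$component_speed_at_probe)
  shift_trace <- toward * shift_angle(trace_dec, retinal_dir)
  plateau_ms <- plateau_time(shift_trace, dtt)
  # subpopulation diagnostics
  kurt <- engaged <- list()
  for (nm in names(mstd$sizes)) {
    if (mstd$sizes[nm] == 0) next
    blk <- mstd$A[mstd$offsets[nm] + seq_len(mstd$sizes[nm])]
    # peakedness of the subpopulation's spatial response map (max over the
    # tuning dims per singularity position), comparable across subpopulations
    pos <- apply(matrix(blk, mstd$nij), 1, max)
    kurt[[nm]] <- if (stats::var(pos) > 0) population_kurtosis(pos)
                  else NA_real_
    engaged[[nm]] <- unname(mstd$engaged[nm])
  }
  structure(list(scene = scene, probe = probe, control = control,
                 bank = bank,
                 retinal_dir = retinal_dir, world_dir = world_dir,
                 trace = data.frame(time_ms = trace_t * 1000,
                                    decoded_deg = trace_dec,
                                    shift_deg = shift_trace),
                 shift_final = shift_tw, gain = gr,
                 stabilized = stab$stabilized,
                 plateau_ms = plateau_ms,   # ms since probe onset
                 mstd_peak = max(peak_series),
                 drive_peak = drive_peak,
                 mstd_final = mstd,
                 winner = mstd_winner(mstd, tb),
                 kurtosis = kurt, engaged = unlist(engaged),
                 recurrent = mstd$recurrent,
                 peak_series = peak_series,
                 n_frames_run = f),
            class = "flowparse")
}

#' @export
print.flowparse <- function(x, ...) {
  cat(sprintf("<flowparse> %s: shift %.2f deg, gain %.3f (%s)\n",
              x$scene$scenario, x$shift_final, x$gain$gain,
              if (x$stabilized) "stabilized" else "hold cap reached"))
  invisible(x)
}

#' Summarize a model run
#'
#' @param object a `"flowparse"` object.
#' @param ... unused.
#' @return the object, invisibly; prints condition, shift, gain,
#'   stabilization and MSTd diagnostics.
#' @export
summary.flowparse <- function(object, ...) {
  x <- object
  cat(sprintf("Scenario: %s (%s)\n", x$scene$scenario,
              if (x$scene$stereo) "stereo" else "monocular"))
  cat(sprintf("  component %.2f deg/s, object %.2f deg/s at (%.1f, %.1f) deg\n",
              x$scene$component_speed_at_probe, x$probe$object_speed,
              x$probe$offset_from_foe[1], x$probe$offset_from_foe[2]))
  cat(sprintf("  retinal direction %.2f deg -> decoded %.2f deg\n",
              x$retinal_dir,
              x$trace$decoded_deg[nrow(x$trace)]))
  cat(sprintf("  shift %.2f deg (beta %.2f), flow-parsing gain %.3f\n",
              x$shift_final, x$gain$beta, x$gain$gain))
  cat(sprintf("  stabilized: %s; plateau at %.0f ms after probe onset\n",
              x$stabilized, x$plateau_ms))
  cat(sprintf("  MSTd peak %.4f, winner %s at (%d, %d), engaged: %s\n",
              x$mstd_peak, x$winner$subpop, x$winner$i, x$winner$j,
              paste(names(which(x$engaged)), collapse = " ") |>
                (\(s) if (nzchar(s)) s else "none")()))
  ku <- vapply(x$kurtosis, identity, 1)
  cat("  kurtosis:", paste(sprintf("%s %.1f", names(ku), ku),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Plot the decoded-direction shift trace
#'
#' @param x a `"flowparse"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.flowparse <- function(x, ...) {
  graphics::plot(x$trace$time_ms, x$trace$shift_deg, type = "l",
                 xlab = "time (ms)", ylab = "shift toward world-relative (deg)",
                 main = sprintf("%s: gain %.2f", x$scene$scenario,
                                x$gain$gain), ...)
  graphics::abline(h = x$gain$beta, lty = 2)
  invisible(x)
}

#' Export the readout trace of a run to CSV
#'
#' Columns `time_ms`, `decoded_deg`, `shift_deg`.
#'
#' @param x a `"flowparse"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(x$trace, path, row.names = FALSE)
  invisible(path)
}
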
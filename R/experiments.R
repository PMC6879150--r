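# The three simulation campaigns: frontoparallel plane (varying self-motion
# component speed x object speed), ground plane (probe eccentricity 2/4 deg
# with matched component speeds), and stereo wire-frame cloud (condition
# masks and a self-motion speed series). Plus the ground-unit ablation.

#' Condition tables for the three campaigns
#'
#' @param sim `"sim1"`, `"sim2"` or `"sim3"`.
#' @param component_speeds (sim1) self-motion component speeds at the probe,
#'   deg/s.
#' @param object_speeds (sim1) probe object-component speeds, deg/s.
#' @return data.frame with one row per condition.
#' @export
fp_conditions <- function(sim = c("sim1", "sim2", "sim3"),
                          component_speeds = c(1, 2, 4, 6, 8, 10),
                          object_speeds = c(2, 6)) {
  sim <- match.arg(sim)
  switch(sim,
    sim1 = {
      g <- expand.grid(component = component_speeds, object = object_speeds)
      data.frame(sim = "sim1", condition = sprintf("c%g_o%g", g$component,
                                                   g$object),
                 component = g$component, object = g$object,
                 eccentricity = 4, mask = "full",
                 stringsAsFactors = FALSE)
    },
    sim2 = data.frame(sim = "sim2",
                      condition = c("ecc2", "ecc4"),
                      component = c(1, 2), object = c(2.5, 2.5),
                      eccentricity = c(2, 4), mask = "full",
                      stringsAsFactors = FALSE),
    sim3 = {
      base <- data.frame(sim = "sim3",
                         condition = c("full", "no_local_depth",
                                       "no_local_frontal_view"),
                         component = 2, object = 2, eccentricity = 4,
                         mask = c("full", "no_local_depth",
                                  "no_local_frontal_view"),
                         stringsAsFactors = FALSE)
      spd <- data.frame(sim = "sim3",
                        condition = sprintf("full_c%g", c(1.6, 2.6, 3.6, 4.6)),
                        component = c(1.6, 2.6, 3.6, 4.6), object = 2,
                        eccentricity = 4, mask = "full",
                        stringsAsFactors = FALSE)
      rbind(base, spd)
    })
}

# scene + probe specs for one condition row
condition_specs <- function(row, control, rng_seed = 7L) {
  if (row$sim == "sim1") {
    scene <- scene_spec("frontoparallel",
                        self_motion_speed = row$component / 2,
                        component_speed_at_probe = row$component,
                        field_of_view = control$fov,
                        frame_rate = control$frame_rate,
                        n_points = 300, rng_seed = rng_seed)
    probe <- probe_spec(offset_from_foe = c(0, -row$eccentricity),
                        object_speed = row$object, onset = 0, offset = 1)
  } else if (row$sim == "sim2") {
    scene <- scene_spec("ground",
                        self_motion_speed = if (row$eccentricity == 2) 5.7
                                            else 2.9,
                        component_speed_at_probe = row$component,
                        depth_range = c(0.56, 25),
                        field_of_view = control$fov,
                        frame_rate = control$frame_rate,
                        n_points = 300, eye_height = 0.40, rng_seed = rng_seed)
    probe <- probe_spec(offset_from_foe = c(0, -row$eccentricity),
                        object_speed = row$object, onset = 0, offset = 1)
  } else {
    scene <- scene_spec("cloud",
                        self_motion_speed = 0.30 * row$component / 2,
                        component_speed_at_probe = row$component,
                        depth_range = c(0.69, 1.03),
                        field_of_view = control$fov,
                        frame_rate = control$frame_rate,
                        stereo = TRUE, condition_mask = row$mask,
                        n_points = 480, rng_seed = rng_seed)
    probe <- probe_spec(offset_from_foe = c(4, 0),
                        object_speed = row$object, onset = 0.8, offset = 1)
  }
  list(scene = scene, probe = probe)
}

#' Run one campaign condition
#'
#' @param row one row of [fp_conditions()].
#' @param control an [fp_control()].
#' @param rng_seed seed for the dot/vertex placement of the stimulus.
#' @return the full `"flowparse"` run object.
#' @export
run_condition <- function(row, control = fp_control(), rng_seed = 7L) {
  sp <- condition_specs(row, control, rng_seed = rng_seed)
  flow_parse(sp$scene, sp$probe, control)
}

#' Run a simulation campaign
#'
#' Maps [run_condition()] over a condition table and collects one summary
#' row per condition. Runs are deterministic given the control parameters;
#' failures of individual conditions are collected and reported together at
#' the end.
#'
#' @param sim `"sim1"`, `"sim2"` or `"sim3"`, or a condition table from
#'   [fp_conditions()].
#' @param control an [fp_control()].
#' @param keep_runs keep the full run objects in the result (attribute
#'   `runs`).
#' @param verbose print one line per condition.
#' @return data.frame of class `"fp_campaign"`: per condition, the final
#'   shift (deg), flow-parsing gain, stabilization flag, plateau time (ms),
#'   MSTd peak activity, winner subpopulation, kurtosis of the winning
#'   subpopulation and recurrent-engagement flag.
#' @export
run_campaign <- function(sim, control = fp_control(), keep_runs = FALSE,
                         verbose = FALSE) {
  conds <- if (is.data.frame(sim)) sim else fp_conditions(sim)
  rows <- vector("list", nrow(conds))
  runs <- vector("list", nrow(conds))
  fails <- character(0)
  for (r in seq_len(nrow(conds))) {
    row <- conds[r, ]
    res <- tryCatch(run_condition(row, control), error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, sprintf("%s/%s: %s", row$sim, row$condition,
                                conditionMessage(res)))
      next
    }
    kwin <- res$kurtosis[[res$winner$subpop]] %||% NA_real_
    rows[[r]] <- data.frame(
      sim = row$sim, condition = row$condition,
      component = row$component, object = row$object,
      eccentricity = row$eccentricity, mask = row$mask,
      shift_deg = res$shift_final, gain = res$gain$gain,
      stabilized = res$stabilized, plateau_ms = res$plateau_ms,
      mstd_peak = res$mstd_peak, winner = res$winner$subpop,
      kurtosis = kwin, engaged = any(res$engaged),
      stringsAsFactors = FALSE)
    if (keep_runs) runs[[r]] <- res
    if (verbose)
      message(sprintf("%s %s: shift %.2f deg gain %.3f peak %.4f %s",
                      row$sim, row$condition, res$shift_final, res$gain$gain,
                      res$mstd_peak,
                      if (res$engaged["bp"] || any(res$engaged)) "engaged"
                      else ""))
  }
  out <- do.call(rbind, rows)
  if (length(fails))
    warning("failed conditions:\n", paste(fails, collapse = "\n"))
  class(out) <- c("fp_campaign", class(out))
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Plot campaign gains
#'
#' Gain versus self-motion component speed, one line per object speed /
#' condition family.
#'
#' @param x an `"fp_campaign"` data.frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fp_campaign <- function(x, ...) {
  graphics::plot(x$component, x$gain, type = "n",
                 xlab = "self-motion component (deg/s)",
                 ylab = "flow parsing gain", ylim = c(0, max(1, x$gain)), ...)
  for (o in unique(x$object)) {
    sub <- x[x$object == o, ]
    sub <- sub[order(sub$component), ]
    graphics::lines(sub$component, sub$gain, type = "b",
                    pch = 19, lty = which(unique(x$object) == o))
  }
  graphics::legend("topright", legend = sprintf("object %g deg/s",
                                                unique(x$object)),
                   lty = seq_along(unique(x$object)), pch = 19, bty = "n")
  invisible(x)
}

#' Ground-unit ablation
#'
#' Runs every condition of the given campaigns twice, with MSTd
#' ground-pattern units included and excluded, and reports the per-condition
#' absolute change in the final decoded object direction.
#'
#' @param sims campaigns to pair (default Sim 1 and Sim 3).
#' @param control an [fp_control()].
#' @param verbose print per-condition lines.
#' @return data.frame with per-condition decoded directions (ground units
#'   on/off) and `delta_deg`; the maximum is the headline number.
#' @export
ablate_ground_units <- function(sims = c("sim1", "sim3"),
                                control = fp_control(), verbose = FALSE) {
  conds <- do.call(rbind, lapply(sims, fp_conditions))
  out <- vector("list", nrow(conds))
  for (r in seq_len(nrow(conds))) {
    row <- conds[r, ]
    ctl_on <- control; ctl_on$ground_units <- TRUE
    ctl_off <- control; ctl_off$ground_units <- FALSE
    on <- run_condition(row, ctl_on)
    off <- run_condition(row, ctl_off)
    dec_on <- on$trace$decoded_deg[nrow(on$trace)]
    dec_off <- off$trace$decoded_deg[nrow(off$trace)]
    out[[r]] <- data.frame(sim = row$sim, condition = row$condition,
                           decoded_on = dec_on, decoded_off = dec_off,
                           delta_deg = abs(circ_diff(dec_on, dec_off)),
                           stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("%s %s: on %.3f off %.3f delta %.3f deg",
                      row$sim, row$condition, dec_on, dec_off,
                      out[[r]]$delta_deg))
  }
  do.call(rbind, out)
}

#' Packaged human flow-parsing gains
#'
#' The mean human flow-parsing gains printed in the source experiments'
#' reports: ground plane 84 and 72 percent (2 and 4 deg eccentricity),
#' frontoparallel 67 and 50 percent at the matched component speeds, and
#' the 0.30-0.40 gain band at the fastest frontoparallel self-motion
#' speeds.
#'
#' @return data.frame with columns `sim`, `condition`, `gain_pct_lo`,
#'   `gain_pct_hi` (equal for point values).
#' @export
human_reference <- function() {
  path <- system.file("extdata", "human_gains.csv", package = "flowparse")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
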
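# Segregated MT Layer 2-3 pathways. MT+ units (reinforcing surrounds)
# integrate like-tuned Layer 4/6 activity over their receptive fields and
# project to MSTd through depressing synapses; MT- units (antagonistic
# surrounds) perform shunting on-centre/off-surround integration and project
# to MSTv. The two pathways never cross.

# Gaussian spatial offsets within a square radius. `exclude_center` drops
# the (0,0) offset (surround ring); `normalize` scales weights to unit sum.
spatial_offsets <- function(radius, sigma, exclude_center = FALSE,
                            normalize = FALSE) {
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  g$w <- exp(-(g$dx^2 + g$dy^2) / (2 * sigma^2))
  if (exclude_center) g <- g[!(g$dx == 0 & g$dy == 0), ]
  if (normalize) g$w <- g$w / sum(g$w)
  g
}

# Shift-add convolution of an (ncell, nch) field (cells = n x n grid, zero
# padding) with a small offset kernel; `cells` restricts the output rows.
conv_spatial <- function(field, n, offsets, cells = NULL) {
  nch <- ncol(field)
  rows <- cells %||% seq_len(n * n)
  cx <- ((rows - 1L) %% n) + 1L
  cy <- ((rows - 1L) %/% n) + 1L
  out <- matrix(0, length(rows), nch)
  for (k in seq_len(nrow(offsets))) {
    sx <- cx + offsets$dx[k]
    sy <- cy + offsets$dy[k]
    ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n
    if (!any(ok)) next
    src <- sx[ok] + (sy[ok] - 1L) * n
    out[ok, ] <- out[ok, ] + offsets$w[k] * field[src, , drop = FALSE]
  }
  out
}

#' MT+ receptive-field drive
#'
#' Spatial integration of same-preference MT Layer 4/6 activity over the
#' reinforcing receptive field: a Gaussian kernel of the given radius with
#' unit centre weight (unnormalized), so that coherent full-field motion
#' drives MT+ above the single-cell response.
#'
#' @param mt46 MT Layer 4/6 activity array `(n*n, n_dir, n_speed[, n_disp])`.
#' @param n grid dimension.
#' @param radius integration radius, cells.
#' @param sigma Gaussian width, cells.
#' @return array of the same shape.
#' @export
mt_plus_drive <- function(mt46, n, radius = 2, sigma = 1) {
  dm <- dim(mt46)
  offs <- spatial_offsets(radius, sigma)
  out <- conv_spatial(matrix(mt46, dm[1]), n, offs)
  array(out, dm)
}

#' One Euler step of the MT+ leaky integrator
#'
#' `dP/dt = alpha * (drive - P)`: activity relaxes towards the integrated
#' receptive-field drive with rate `alpha`.
#'
#' @param state current MT+ activity (array or vector).
#' @param drive output of [mt_plus_drive()].
#' @param dt Euler step, s.
#' @param alpha rate constant, 1/s.
#' @return updated activity.
#' @export
mt_plus_step <- function(state, drive, dt, alpha = 20) {
  state + dt * alpha * (drive - state)
}

#' Depressing-synapse state
#'
#' Per-connection efficacy in `(0, 1]` for the MT+ to MSTd projection.
#' Efficacy depletes in proportion to the transmitted signal and recovers
#' towards 1 with time constant `tau_rec`, so tonic MT+ signals activate
#' MSTd with reduced efficacy.
#'
#' @param size number of connections (length of the MT+ tensor).
#' @param tau_rec recovery time constant, s.
#' @param depletion_rate depletion per unit presynaptic activity and second.
#' @return an object of class `"synapse_state"`.
#' @export
synapse_state <- function(size, tau_rec = 0.5, depletion_rate = 0.3) {
  structure(list(efficacy = rep(1, size), tau_rec = tau_rec,
                 depletion_rate = depletion_rate),
            class = "synapse_state")
}

#' One Euler step of synaptic depression
#'
#' Transmits `z = efficacy * activity` and updates the efficacy:
#' `du/dt = (1 - u)/tau_rec - depletion_rate * u * activity`. Without input
#' the efficacy recovers to 1; under constant tonic input it settles at the
#' steady state `u* = (1/tau) / (1/tau + depletion_rate * P)`.
#'
#' @param mtplus MT+ activity (array or vector).
#' @param syn a [synapse_state()].
#' @param dt Euler step, s (> 0).
#' @return list with `signal` (transmitted to MSTd, same shape as `mtplus`)
#'   and the updated `syn`.
#' @export
depress <- function(mtplus, syn, dt) {
  if (dt <= 0) stop("dt must be > 0")
  u <- syn$efficacy
  sig <- u * c(mtplus)
  u <- u + dt * ((1 - u) / syn$tau_rec - syn$depletion_rate * u * c(mtplus))
  syn$efficacy <- pmin(pmax(u, 0), 1)
  out <- mtplus
  out[] <- sig
  list(signal = out, syn = syn)
}

# ---- MT- : antagonistic surround ------------------------------------------

# Row-normalized tuning-similarity matrices used by feedforward lateral
# inhibition: neighbours inhibit units with similar direction, speed and
# disparity tuning.
similarity_matrices <- function(bank) {
  nd <- length(bank$dir_prefs)
  Cd <- exp(-(outer(bank$dir_prefs, bank$dir_prefs, circ_diff) /
                bank$dir_sigma)^2)
  Cd <- Cd / rowSums(Cd)
  ls <- log2(bank$speed_prefs)
  Cs <- exp(-(outer(ls, ls, "-") / bank$speed_sigma_oct)^2)
  Cs <- Cs / rowSums(Cs)
  out <- list(Cd = Cd, Cs = Cs)
  if (!is.null(bank$disp_prefs)) {
    bins <- seq_along(bank$disp_prefs)
    Cp <- exp(-(outer(bins, bins, "-"))^2)
    out$Cp <- Cp / rowSums(Cp)
  }
  out
}

# contract the tuning axes of an (ncells, nd, ns[, np]) array with the
# similarity matrices (weighted average over similarly tuned units)
contract_similarity <- function(x, sim) {
  dm <- dim(x)
  nd <- dm[2]; ns <- dm[3]
  m <- matrix(aperm(x, c(2, 1, 3, if (length(dm) == 4) 4)),
              nd, prod(dm) / nd)
  m <- crossprod(sim$Cd, m)      # Cd is symmetric before normalization
  x2 <- aperm(array(m, c(nd, dm[1], dm[-(1:2)])),
              c(2, 1, 3, if (length(dm) == 4) 4))
  m <- matrix(aperm(x2, c(3, 1, 2, if (length(dm) == 4) 4)),
              ns, prod(dm) / ns)
  m <- crossprod(t(sim$Cs), m)
  x3 <- aperm(array(m, c(ns, dm[1], dm[2], if (length(dm) == 4) dm[4])),
              c(2, 3, 1, if (length(dm) == 4) 4))
  if (length(dm) == 4 && !is.null(sim$Cp)) {
    np <- dm[4]
    m <- matrix(aperm(x3, c(4, 1, 2, 3)), np, prod(dm) / np)
    m <- crossprod(t(sim$Cp), m)
    x3 <- aperm(array(m, c(np, dm[1], dm[2], dm[3])), c(2, 3, 4, 1))
  }
  x3
}

#' Feedforward surround inhibition for the MT- pathway
#'
#' The inhibitory signal each MT- unit receives from MT Layer 4/6 units in
#' its surround that are tuned to similar directions, speeds and
#' disparities: a Gaussian surround ring (centre excluded, unit-sum
#' weights) followed by a weighted average over the tuning axes, scaled by
#' `kappa_loc`. Maximal when surround motion matches the centre tuning.
#'
#' @param mt46 MT Layer 4/6 activity array `(n*n, n_dir, n_speed[, n_disp])`.
#' @param n grid dimension.
#' @param bank the [tuning_bank()].
#' @param kappa_loc inhibition strength.
#' @param radius surround radius, cells.
#' @param sigma surround Gaussian width, cells.
#' @param cells optional cell indices to which the output is restricted.
#' @return inhibition array `(n_cells_out, n_dir, n_speed[, n_disp])`.
#' @export
mt_surround_inhibition <- function(mt46, n, bank, kappa_loc = 8,
                                   radius = 3, sigma = 1.5, cells = NULL) {
  dm <- dim(mt46)
  offs <- spatial_offsets(radius, sigma, exclude_center = TRUE,
                          normalize = TRUE)
  sur <- conv_spatial(matrix(mt46, dm[1]), n, offs, cells = cells)
  dm2 <- dm; dm2[1] <- nrow(sur)
  sur <- array(sur, dm2)
  sim <- similarity_matrices(bank)
  kappa_loc * contract_similarity(sur, sim)
}

#' One Euler step of the MT- shunting equation
#'
#' On-centre/off-surround shunting dynamics:
#' `dM/dt = alpha * (-gamma*M + (B - M)*E - M*(I_local + I_fb))`, with
#' excitation `E` the like-tuned centre input, `I_local` the feedforward
#' surround inhibition and `I_fb` the MSTd feedback suppression. The update
#' is the semi-implicit (Patankar) form of the Euler step -- gain terms
#' explicit, loss terms implicit -- which has the same fixed points and is
#' unconditionally stable under strong suppression. Activity stays within
#' `[0, B]`.
#'
#' @param M current MT- activity.
#' @param E centre excitation (MT Layer 4/6 activity at the cell).
#' @param I_local feedforward surround inhibition
#'   ([mt_surround_inhibition()]).
#' @param I_fb MSTd feedback suppression field (0 when feedback is absent).
#' @param dt Euler step, s.
#' @param alpha rate constant, 1/s.
#' @param B shunting upper bound.
#' @param gamma passive decay.
#' @return updated activity, clipped to `[0, B]`.
#' @export
mt_minus_step <- function(M, E, I_local, I_fb = 0, dt = 1 / 300,
                          alpha = 30, B = 1, gamma = 1) {
  M <- (M + dt * alpha * B * E) /
    (1 + dt * alpha * (gamma + E + I_local + I_fb))
  M[M < 0] <- 0
  M[M > B] <- B
  M
}
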
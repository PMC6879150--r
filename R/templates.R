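# MSTd template populations: radial heading templates (band-pass and
# speed-summating pooling), speed-gradient subunits, and ground-plane
# templates, plus the recurrent competitive network that turns template
# matches into a self-motion estimate.
#
# The singularity lattice samples every fourth MT cell position in x and y
# (a 16x16 grid at the default 64x64 input resolution). Template matching
# against the full MT+ field is the model's hot loop; templates are compiled
# once into a compressed structure consumed by cpp_template_drive().

#' Singularity lattice for an n x n grid
#'
#' Every fourth MT cell position in x and y, chosen so that the central cell
#' `n/2 + 1` (the 0 deg, 0 deg origin) is on the lattice.
#'
#' @param n input grid dimension.
#' @return integer vector of cell indices (length `n/4`).
#' @export
singularity_positions <- function(n) {
  seq(1L, n - 3L, by = 4L)
}

#' Build one radial MSTd template
#'
#' The global radial motion pattern with singularity at cell `(i, j)`: at
#' cell `(x, y)` the template vector is `(x - i, y - j)`, i.e. direction
#' `atan2(y - j, x - i)` pointing away from the singularity and zero at the
#' singularity itself. Templates span the visual field but are inversely
#' weighted by distance from the singularity to give a retinotopic
#' receptive field, and carry an eccentricity-ring index (equal-count
#' quintiles of distance) used by the speed-gradient machinery.
#'
#' @param i,j singularity cell position (x = column, y = row).
#' @param n grid dimension.
#' @param dist_r0 distance-weight scale, cells: `w = 1 / (1 + r / dist_r0)`.
#' @return list with `n x n` fields: `u`, `v` (raw template vectors in cell
#'   units), `dir` (deg), `r` (cells), `wdist`, and `ring` (1..5).
#' @export
build_radial_template <- function(i, j, n, dist_r0 = 4) {
  u <- matrix(seq_len(n) - i, n, n)
  v <- matrix(seq_len(n) - j, n, n, byrow = TRUE)
  r <- sqrt(u^2 + v^2)
  dir <- rad2deg(atan2(v, u))
  wdist <- 1 / (1 + r / dist_r0)
  ring <- ring_index(r)
  list(i = i, j = j, u = u, v = v, r = r, dir = dir, wdist = wdist,
       ring = ring)
}

# equal-count quintile ring index of a positive scalar field
ring_index <- function(r, nq = 5L) {
  br <- stats::quantile(r, probs = seq_len(nq - 1) / nq, names = FALSE)
  findInterval(r, br, left.open = TRUE) + 1L
}

#' Build one ground-plane MSTd template
#'
#' The flow pattern of translation parallel to a ground plane with heading
#' `(i, j)` on the horizon row `j`. With offsets `u = x - i`, `v = y - j`
#' (y up), the template vector is `|v| * (u, v)`, defined only at and below
#' the horizon (`v <= 0`): direction radially outward and downward, speed
#' proportional to `|v| * r` (zero along the horizon's vertical component
#' and at the heading point). This is the half-field ground-flow pattern
#' expressed in the package's y-up convention. The template normalization
#' counts only defined cells.
#'
#' @inheritParams build_radial_template
#' @return list like [build_radial_template()] plus `defined` (logical
#'   mask), `speed` (pattern speed `|v| * r`) and `ring` (quintiles of
#'   pattern speed over defined cells).
#' @export
build_ground_template <- function(i, j, n, dist_r0 = 4) {
  u <- matrix(seq_len(n) - i, n, n)
  v <- matrix(seq_len(n) - j, n, n, byrow = TRUE)
  defined <- v <= 0
  r <- sqrt(u^2 + v^2)
  gx <- abs(v) * u
  gy <- abs(v) * v
  gx[!defined] <- 0; gy[!defined] <- 0
  dir <- rad2deg(atan2(gy, gx))
  dir[!defined] <- NA_real_
  speed <- r * abs(v)
  speed[!defined] <- NA_real_
  wdist <- 1 / (1 + r / dist_r0)
  ring <- matrix(NA_integer_, n, n)
  sp <- speed[defined]
  br <- stats::quantile(sp, probs = seq(0.2, 0.8, by = 0.2), names = FALSE)
  ring[defined] <- findInterval(speed[defined], br, left.open = TRUE) + 1L
  list(i = i, j = j, u = gx, v = gy, r = r, dir = dir, wdist = wdist,
       defined = defined, speed = speed, ring = ring)
}

#' Gradient-cell subunit weight maps
#'
#' Five annular weight maps per singularity, one per MT speed preference:
#' the increasing variant is maximally sensitive to the slowest speed at the
#' RF centre and to the fastest at the periphery; the decreasing variant is
#' the same set with the speed axis reversed. Weights are
#' `wdist * exp(-((ring - s)/sigma)^2)` and are normalized (to unit sum)
#' after construction.
#'
#' @inheritParams build_radial_template
#' @param n_speeds number of speed preferences (5).
#' @param ring_sigma width of the ring-to-speed coupling, in ring units.
#' @param variant `"increasing"` or `"decreasing"`.
#' @return list of `n_speeds` normalized `n x n` weight maps.
#' @export
build_gradient_subunits <- function(i, j, n, n_speeds = 5, ring_sigma = 1,
                                    dist_r0 = 4,
                                    variant = c("increasing", "decreasing")) {
  variant <- match.arg(variant)
  tpl <- build_radial_template(i, j, n, dist_r0)
  maps <- vector("list", n_speeds)
  for (s in seq_len(n_speeds)) {
    sq <- if (variant == "increasing") s else n_speeds + 1 - s
    m <- tpl$wdist * exp(-((tpl$ring - sq) / ring_sigma)^2)
    maps[[s]] <- m / sum(m)
  }
  maps
}

# ---- compiled template bank ------------------------------------------------

# Compress a template family into the (ptr, idx, w, q) structure used by
# cpp_template_drive(). Direction-template weights below `trunc` are dropped
# (a numerical-support truncation; exact template fields are available from
# the build_* constructors).
compile_family <- function(n, dir_prefs, dir_sigma, dist_r0, ground = FALSE,
                           trunc = 1e-4) {
  sing <- singularity_positions(n)
  nij <- length(sing)^2
  nd <- length(dir_prefs)
  ncell <- n * n
  ptr <- integer(nij + 1L)
  idx_l <- vector("list", nij); w_l <- vector("list", nij)
  q_l <- vector("list", nij)
  Wq <- matrix(0, nij, 5)          # ring-wise sum of wdist (normalization)
  norm <- numeric(nij)             # per-template cell-count normalization
  imax <- numeric(nij)
  k <- 0L
  ij <- 0L
  ij_tab <- matrix(0L, nij, 2)
  for (j in sing) for (i in sing) {
    ij <- ij + 1L
    ij_tab[ij, ] <- c(i, j)
    tpl <- if (ground) build_ground_template(i, j, n, dist_r0)
           else build_radial_template(i, j, n, dist_r0)
    def <- if (ground) which(tpl$defined) else seq_len(ncell)
    norm[ij] <- length(def)
    wd <- tpl$wdist[def]
    rg <- tpl$ring[def]
    dirv <- tpl$dir[def]
    # direction weights for all prefs at once: (ncells_def x nd)
    fd <- exp(-(outer(dirv, dir_prefs, circ_diff) / dir_sigma)^2)
    # cells where the template vector vanishes (the singularity; for ground
    # templates also the horizon row) have undefined direction: no weight
    mag <- if (ground) tpl$speed[def] else tpl$r[def]
    fd[mag < 1e-9, ] <- 0
    keep <- which(fd >= trunc)
    cellk <- ((keep - 1L) %% length(def)) + 1L
    dk <- ((keep - 1L) %/% length(def))          # 0-based direction
    idx_l[[ij]] <- (def[cellk] - 1L) + dk * ncell # 0-based Z row
    w_l[[ij]] <- wd[cellk] * fd[keep]
    q_l[[ij]] <- rg[cellk] - 1L
    for (qq in 1:5) Wq[ij, qq] <- sum(wd[rg == qq])
    imax[ij] <- sum(wd)
    k <- k + length(keep)
    ptr[ij + 1L] <- k
  }
  list(ptr = ptr,
       idx = unlist(idx_l, use.names = FALSE),
       w = unlist(w_l, use.names = FALSE),
       q = unlist(q_l, use.names = FALSE),
       Wq = Wq, norm = norm, imax = imax, ij = ij_tab,
       sing = sing, nij = nij)
}

#' Compile the MSTd template bank
#'
#' Builds the compressed matching structures for the radial family (shared
#' by band-pass, speed-summating and gradient units) and, when ground units
#' are enabled, the ground family, for a given input resolution.
#'
#' @param n input grid dimension.
#' @param bank a [tuning_bank()].
#' @param dist_r0 retinotopic distance-weight scale, cells.
#' @param ring_sigma ring-to-speed coupling width of gradient/ground speed
#'   templates, in ring units.
#' @param ground include the ground-template structure.
#' @return an object of class `"template_bank"`.
#' @export
template_bank <- function(n, bank, dist_r0 = 4, ring_sigma = 1,
                          ground = TRUE) {
  rad <- compile_family(n, bank$dir_prefs, bank$dir_sigma, dist_r0,
                        ground = FALSE)
  gnd <- if (ground) compile_family(n, bank$dir_prefs, bank$dir_sigma,
                                    dist_r0, ground = TRUE) else NULL
  ns <- length(bank$speed_prefs)
  G <- outer(1:5, seq_len(ns), function(q, s)
    exp(-((q - s) / ring_sigma)^2))          # ring x speed coupling
  structure(list(n = n, bank = bank, dist_r0 = dist_r0,
                 ring_sigma = ring_sigma,
                 radial = rad, ground = gnd, G = G,
                 sing = rad$sing, nij = rad$nij, ij = rad$ij),
            class = "template_bank")
}

#' Match the MT+ signal against the MSTd template bank
#'
#' Computes the feedforward drive of every MSTd unit: the retinotopically
#' weighted inner product of the (depressed) MT+ signal with the unit's
#' direction x speed (x disparity) template. Speed pooling is
#' subpopulation-specific: speed-summating units average the per-speed
#' matches (`U(w) = mean(w_s)`), band-pass units keep the match at their
#' preferred speed (`B_s(w) = w_s`), and gradient/ground units weight
#' speeds by eccentricity ring. In stereo runs the five MT disparity
#' channels are pooled to three MSTd bins (near, mid, far) with
#' partition-of-unity weights.
#'
#' Template matches are normalized by each template's own weighted mass over
#' the MT+ inputs actually present (the distance- and direction-template-
#' weighted occupied cells), i.e. they are normalized cross-correlations:
#' the drive measures per-input match quality and is invariant to display
#' density and grid resolution.
#'
#' @param tb a [template_bank()].
#' @param z MT+ transmitted signal, array `(n*n, n_dir, n_speed[, n_disp])`.
#' @param gains named list of subpopulation input gains
#'   (`bp`, `ss`, `grad`, `ground`).
#' @param occupancy logical/0-1 vector over the `n*n` cells marking where
#'   the stimulus provides input; by default inferred as the cells with any
#'   nonzero signal in `z`.
#' @param ground_veto strength of the horizon constraint on ground units:
#'   their drive is scaled by `max(0, 1 - ground_veto * (f_above + f_up))`,
#'   where `f_above` is the fraction of stimulated cells above the
#'   template's horizon and `f_up` the fraction of upward-moving stimulated
#'   cells below it (ground flow cannot appear above the horizon and never
#'   moves upward, so both are evidence against the template).
#' @param vy per-cell vertical velocities (deg/s) of the input frame, used
#'   by the upward-motion part of the ground veto; `NULL` disables it.
#' @return list of drive arrays: `bp` `(nij, n_speed, n_disp3)`, `ss`
#'   `(nij, n_disp3)`, `grad_inc`, `grad_dec`, and (if compiled) `ground`
#'   `(nij)`. Monocular runs have a single disparity bin.
#' @export
feedforward_drive <- function(tb, z, gains = list(bp = 1, ss = 1, grad = 1,
                                                  ground = 1),
                              occupancy = NULL, ground_veto = 12,
                              vy = NULL) {
  dmz <- dim(z)
  ncell <- dmz[1]; nd <- dmz[2]; ns <- dmz[3]
  if (ncell != tb$n^2 || nd != length(tb$bank$dir_prefs))
    stop("shape mismatch between template bank and MT+ tensor")
  stereo <- length(dmz) == 4L
  if (stereo) {
    ndp <- dmz[4]
    zm <- matrix(z, ncell * nd, ns * ndp)
    # pool the 5 MT disparity channels into 3 MSTd bins (near, mid, far)
    # with partition-of-unity weights: an MSTd disparity bin integrates
    # (sums) its afferent channels, and each MT channel contributes once
    pool <- function(sl) cbind(sl[, 1] + 0.5 * sl[, 2],
                               0.5 * sl[, 2] + sl[, 3] + 0.5 * sl[, 4],
                               0.5 * sl[, 4] + sl[, 5])
    Z3 <- matrix(0, ncell * nd, ns * 3L)
    Zm <- matrix(0, ncell * nd, ns)       # disparity-integrated, per speed
    for (s in seq_len(ns)) {
      sl <- zm[, s + ns * (seq_len(ndp) - 1L), drop = FALSE]
      Z3[, s + ns * (0:2)] <- pool(sl)
      Zm[, s] <- rowSums(sl)
    }
    Zall <- cbind(Z3, Zm)
    nd3 <- 3L
  } else {
    Zall <- matrix(z, ncell * nd, ns)
    nd3 <- 1L
  }
  if (is.null(occupancy)) {
    zo <- matrix(z, ncell)
    occupancy <- as.numeric(rowSums(zo) > 1e-12)
  }
  # final column: the occupancy indicator, broadcast over directions, gives
  # each template's weighted occupied mass (the normalization denominator)
  Zall <- cbind(Zall, rep(as.numeric(occupancy > 0), nd))
  Zt <- t(Zall)
  nc <- nrow(Zt)
  oc <- nc                                   # occupancy column index
  R <- cpp_template_drive(tb$radial$ptr, tb$radial$idx, tb$radial$w,
                          tb$radial$q, 5L, Zt)
  dim(R) <- c(nc, 5L, tb$nij)
  Rsum <- apply(R, c(1, 3), sum)             # (nc, nij): sum over rings
  den_rad <- pmax(Rsum[oc, ], 1e-9)          # weighted occupied mass per ij
  bp <- array(0, c(tb$nij, ns, nd3))
  for (dd in seq_len(nd3))
    for (s in seq_len(ns))
      bp[, s, dd] <- gains$bp * Rsum[s + ns * (dd - 1L), ] / den_rad
  ss <- array(0, c(tb$nij, nd3))
  for (dd in seq_len(nd3))
    ss[, dd] <- gains$ss * colMeans(matrix(Rsum[ns * (dd - 1L) + seq_len(ns), ],
                                           ns, tb$nij)) / den_rad
  # gradient units: ring-speed congruence on disparity-integrated channels
  gcols <- if (stereo) ns * nd3 + seq_len(ns) else seq_len(ns)
  grad_inc <- numeric(tb$nij); grad_dec <- numeric(tb$nij)
  G <- tb$G
  Grev <- G[, rev(seq_len(ns)), drop = FALSE]
  for (ij in seq_len(tb$nij)) {
    Rg <- R[gcols, , ij, drop = FALSE]       # (ns, 5): speed x ring
    dim(Rg) <- c(ns, 5L)
    occ_q <- R[oc, , ij]                     # weighted occupied mass per ring
    den_i <- max(sum(t(G) * matrix(occ_q, ns, 5L, byrow = TRUE)), 1e-9)
    grad_inc[ij] <- gains$grad * sum(t(G) * Rg) / den_i
    grad_dec[ij] <- gains$grad * sum(t(Grev) * Rg) / den_i
  }
  out <- list(bp = bp, ss = ss, grad_inc = grad_inc, grad_dec = grad_dec)
  if (!is.null(tb$ground)) {
    Rg <- cpp_template_drive(tb$ground$ptr, tb$ground$idx, tb$ground$w,
                             tb$ground$q, 5L, Zt)
    dim(Rg) <- c(nc, 5L, tb$nij)
    # ground templates are normalized by their EXPECTED weighted mass at the
    # display's overall occupancy rate, not by the occupied mass alone: a
    # template whose below-horizon domain is partly empty is thereby
    # penalized (a ground plane would fill it), which anchors the estimated
    # horizon to the top of the flow field
    p_occ <- max(sum(occupancy > 0) / ncell, 1e-9)
    cdir <- sum(exp(-(circ_diff(tb$bank$dir_prefs, 0) /
                        tb$bank$dir_sigma)^2))
    # fraction of stimulated cells above each candidate horizon row, and of
    # upward-moving stimulated cells at or below it
    n <- tb$n
    occ_row <- colSums(matrix(occupancy > 0, n, n))  # cells per y-row
    above <- rev(cumsum(rev(occ_row)))               # cells at rows >= y
    n_occ <- max(sum(occupancy > 0), 1)
    up_below <- numeric(n)
    if (!is.null(vy)) {
      up_row <- colSums(matrix(occupancy > 0 & vy > 1e-9, n, n))
      up_below <- cumsum(up_row)                     # upward cells at rows <= y
    }
    gnd <- numeric(tb$nij)
    for (ij in seq_len(tb$nij)) {
      den <- sum(G * tb$ground$Wq[ij, ]) * cdir * p_occ
      if (den <= 1e-9) next
      j <- tb$ij[ij, 2]
      f_above <- if (j < n) above[j + 1L] / n_occ else 0
      f_up <- up_below[j] / n_occ
      veto <- max(0, 1 - ground_veto * (f_above + f_up))
      if (veto == 0) next
      Rq <- Rg[gcols, , ij, drop = FALSE]
      dim(Rq) <- c(ns, 5L)
      gnd[ij] <- gains$ground * veto * sum(t(G) * Rq) / den
    }
    out$ground <- gnd
  }
  out
}

# ---- MSTd state and recurrent competition ---------------------------------

#' Initialize the MSTd population state
#'
#' Lays out all subpopulations in a single activity vector in the
#' deterministic winner order: band-pass, speed-summating, gradient
#' (increasing then decreasing), ground; within each block, row-major
#' singularity position varies fastest.
#'
#' @param tb a [template_bank()].
#' @param stereo logical; three disparity bins per band-pass and
#'   speed-summating position when `TRUE`.
#' @param theta_eng engagement threshold as a fraction of the
#'   subpopulation's theoretical maximum feedforward drive.
#' @param gains subpopulation input gains (as in [feedforward_drive()]).
#' @return an object of class `"mstd_state"`.
#' @export
mstd_state <- function(tb, stereo = FALSE, theta_eng = 0.02,
                       gains = list(bp = 1, ss = 1, grad = 1, ground = 1)) {
  ns <- length(tb$bank$speed_prefs)
  nd3 <- if (stereo) 3L else 1L
  nij <- tb$nij
  sizes <- c(bp = nij * ns * nd3, ss = nij * nd3,
             grad_inc = nij, grad_dec = nij,
             ground = if (!is.null(tb$ground)) nij else 0L)
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  ntot <- sum(sizes)
  # engagement threshold per unit: a fraction of the subpopulation's
  # theoretical maximum feedforward drive (a complete, perfectly congruent
  # pattern at the MT+ transmission ceiling zmax)
  zmax <- 3
  gam <- numeric(ntot)
  gam[offs["bp"] + seq_len(sizes["bp"])] <- theta_eng * gains$bp * zmax
  gam[offs["ss"] + seq_len(sizes["ss"])] <- theta_eng * gains$ss * zmax
  gam[offs["grad_inc"] + seq_len(sizes["grad_inc"])] <-
    theta_eng * gains$grad * zmax
  gam[offs["grad_dec"] + seq_len(sizes["grad_dec"])] <-
    theta_eng * gains$grad * zmax
  # ground templates run hotter per unit gain (expected-mass normalization
  # over a half-field domain), so their theoretical ceiling is larger
  if (sizes["ground"] > 0)
    gam[offs["ground"] + seq_len(sizes["ground"])] <-
      theta_eng * gains$ground * zmax * 1.6
  structure(list(A = numeric(ntot), sizes = sizes, offsets = offs,
                 nij = nij, ns = ns, nd3 = nd3, gamma_eng = gam,
                 drive = numeric(ntot),
                 engaged = stats::setNames(logical(length(sizes)),
                                           names(sizes)),
                 recurrent = 0),
            class = "mstd_state")
}

# flatten a feedforward_drive() result into the state's unit order
flatten_drive <- function(state, drv) {
  out <- numeric(sum(state$sizes))
  out[state$offsets["bp"] + seq_len(state$sizes["bp"])] <- c(drv$bp)
  out[state$offsets["ss"] + seq_len(state$sizes["ss"])] <- c(drv$ss)
  out[state$offsets["grad_inc"] + seq_len(state$sizes["grad_inc"])] <-
    drv$grad_inc
  out[state$offsets["grad_dec"] + seq_len(state$sizes["grad_dec"])] <-
    drv$grad_dec
  if (state$sizes["ground"] > 0)
    out[state$offsets["ground"] + seq_len(state$sizes["ground"])] <-
      drv$ground %||% 0
  out
}

#' One Euler step of the recurrent competitive MSTd network
#'
#' Shunting on-centre/off-surround competition with normalization: every
#' unit excites itself through a faster-than-linear signal function that is
#' active only above its engagement threshold, and inhibits all others.
#'
#'   dA/dt = alpha * (-gamma*A + (B - A)*S - A*omega*mean(S[-k])),
#'   S = I + beta * A^2 * (I > Gamma)
#'
#' The faster-than-linear recurrent term is gated by the engagement
#' threshold on the unit's feedforward input: only units driven strongly
#' enough recruit self-excitation (otherwise the competition would
#' pathologically enhance weak, unreliable signals), and below-threshold
#' units evolve feedforward-only with the engagement flag `FALSE`. The
#' broad lateral inhibition each unit receives is the population mean of
#' the others' signals scaled by `omega`, so the competition normalizes
#' activity across the population: every unit's activity is bounded by the
#' shunting ceiling `B`, strongly driven units approach `B`, and raising
#' the drive of any competitor lowers everyone else's equilibrium.
#'
#' @param state an `"mstd_state"`.
#' @param drive flattened drive vector (see [feedforward_drive()]), or a
#'   drive list which will be flattened.
#' @param dt Euler step, s.
#' @param alpha rate constant, 1/s.
#' @param B shunting ceiling / normalization bound.
#' @param gamma passive decay.
#' @param beta recurrent signal gain.
#' @param omega broad lateral-inhibition strength (scales the population
#'   mean of the competitors' signals).
#' @return the updated `"mstd_state"`, with `engaged` flags and the
#'   strength of the recurrent signal of the most active subpopulation.
#' @export
recurrent_step <- function(state, drive, dt, alpha = 15, B = 1, gamma = 1,
                           beta = 40, omega = 30) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.list(drive)) drive <- flatten_drive(state, drive)
  A <- state$A
  eng <- drive > state$gamma_eng
  rec <- beta * A^2 * eng
  S <- drive + rec
  tot <- sum(S)
  # semi-implicit (Patankar) Euler step: gains explicit, losses implicit;
  # same fixed points, unconditionally stable
  A <- (A + dt * alpha * B * S) /
    (1 + dt * alpha * (gamma + S + omega * (tot - S) / (length(S) - 1)))
  A[A < 0] <- 0
  state$A <- A
  state$drive <- drive
  for (nm in names(state$sizes)) {
    if (state$sizes[nm] == 0) next
    blk <- state$offsets[nm] + seq_len(state$sizes[nm])
    state$engaged[nm] <- any(eng[blk])
  }
  state$recurrent <- max(rec)
  state
}

#' Most active MSTd unit
#'
#' Argmax over the whole population; ties break to the lowest linear index,
#' i.e. subpopulation order band-pass, speed-summating, gradient
#' (increasing, decreasing), ground, then row-major singularity position.
#'
#' @param state an `"mstd_state"`.
#' @param tb the [template_bank()] the state was built for.
#' @return list with `subpop`, singularity cell `(i, j)`, linear index,
#'   `activity`, and (band-pass) the preferred speed/disparity bin.
#' @export
mstd_winner <- function(state, tb) {
  k <- which.max(state$A)
  act <- state$A[k]
  for (nm in names(state$sizes)) {
    if (state$sizes[nm] == 0) next
    off <- state$offsets[nm]
    if (k > off && k <= off + state$sizes[nm]) {
      loc <- k - off
      ij <- ((loc - 1L) %% state$nij) + 1L
      rest <- (loc - 1L) %/% state$nij
      s_pref <- if (nm == "bp") (rest %% state$ns) + 1L else NA_integer_
      d_pref <- if (nm %in% c("bp", "ss") && state$nd3 > 1L) {
        if (nm == "bp") (rest %/% state$ns) + 1L else rest + 1L
      } else NA_integer_
      return(list(subpop = nm, i = tb$ij[ij, 1], j = tb$ij[ij, 2],
                  ij = ij, index = k, activity = act,
                  s_pref = s_pref, d_pref = d_pref))
    }
  }
  stop("winner index out of range")  # nocov
}

#' Model unit counts per area
#'
#' The number of units in each model area for a given input resolution and
#' viewing condition: MT populations tile every grid cell with the full
#' direction x speed (x disparity) tuning lattice; MSTd subpopulations tile
#' the singularity lattice (every fourth position); MSTv pools over speed
#' and keeps direction (x disparity).
#'
#' @param n input grid dimension (64 reference).
#' @param stereo logical; disparity axes present (5 bins in MT/MSTv, 3 in
#'   MSTd) when `TRUE`.
#' @param n_dir,n_speed,n_disp tuning lattice sizes.
#' @return named integer vector of unit counts.
#' @export
unit_counts <- function(n = 64, stereo = FALSE, n_dir = 24, n_speed = 5,
                        n_disp = 5) {
  np <- if (stereo) n_disp else 1L
  np3 <- if (stereo) 3L else 1L
  nij <- length(singularity_positions(n))^2
  c(MTplus = n * n * n_dir * n_speed * np,
    MSTd_bandpass = nij * n_speed * np3,
    MSTd_gradient = nij,
    MSTd_ground = nij,
    MSTd_speed_summating = nij * np3,
    MTminus = n * n * n_dir * n_speed * np,
    MSTv = n * n * n_dir * np)
}

#' Population kurtosis
#'
#' The standardized fourth central moment `mean(((a - mean(a))/sd)^4)` of a
#' flattened population response distribution (biased moments, normal
#' reference value 3). Used as a measure of how peaked, i.e. how selective,
#' a population response is.
#'
#' @param activity numeric vector of unit activities (at least 4 values).
#' @return kurtosis, or `NA_real_` (with a warning) for zero variance.
#' @export
population_kurtosis <- function(activity) {
  if (length(activity) < 4L) stop("need at least 4 units")
  m <- mean(activity)
  v <- mean((activity - m)^2)
  if (v <= 0) {
    warning("zero variance: kurtosis undefined")
    return(NA_real_)
  }
  mean(((activity - m)^2 / v)^2)
}
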
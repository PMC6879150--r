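test_that("MT+ integrates its RF above the single-cell response and converges", {
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  # uniform full-field motion at a preferred direction/speed
  n <- 16
  enc <- array(0, c(n * n, 24, 5))
  enc[, 5, 3] <- 1
  drv <- mt_plus_drive(enc, n, radius = 2, sigma = 1)
  inner <- matrix(seq_len(n * n), n)[4:13, 4:13]  # away from the border
  expect_true(all(drv[inner, 5, 3] > enc[inner, 5, 3]))
  # zero input, zero state stays zero
  expect_equal(mt_plus_step(0, 0, dt = 1 / 300), 0)
  # steady input: Euler iterates converge to the analytic fixed point (drive)
  m <- 0
  for (k in 1:3000) m <- mt_plus_step(m, drive = 2.5, dt = 1 / 300, alpha = 20)
  expect_equal(m, 2.5, tolerance = 1e-8)
})

test_that("depressing synapses recover without input and plateau under tonic drive", {
  syn <- synapse_state(1, tau_rec = 0.5, depletion_rate = 0.3)
  syn$efficacy <- 0.4
  for (k in 1:3000) syn <- depress(0, syn, dt = 1 / 300)$syn
  expect_equal(syn$efficacy, 1, tolerance = 1e-6)
  # constant tonic input: transmitted signal decays to the analytic plateau
  syn <- synapse_state(1)
  P <- 1.8
  first <- depress(P, syn, dt = 1 / 300)$signal
  for (k in 1:6000) {
    st <- depress(P, syn, dt = 1 / 300)
    syn <- st$syn
  }
  last <- depress(P, syn, dt = 1 / 300)$signal
  u_star <- (1 / 0.5) / (1 / 0.5 + 0.3 * P)   # recovery/depletion balance
  expect_lt(last, first)
  expect_equal(last, u_star * P, tolerance = 1e-4)
})

test_that("the fused frame integrator equals per-step R updates", {
  set.seed(7)
  m0 <- stats::runif(50); u0 <- stats::runif(50, 0.5, 1)
  drive <- stats::runif(50, 0, 2)
  dt <- 1 / 300
  out <- flowparse:::cpp_mtplus_frame(m0, u0, drive, dt, 10L, 20, 0.5, 0.3)
  m <- m0; syn <- synapse_state(50); syn$efficacy <- u0
  for (k in 1:10) {
    st <- depress(m, syn, dt)      # updates efficacy using the current m
    syn <- st$syn
    m <- mt_plus_step(m, drive, dt, alpha = 20)
  }
  expect_equal(out$m, m, tolerance = 1e-12)
  expect_equal(out$u, syn$efficacy, tolerance = 1e-12)
  expect_equal(out$z, syn$efficacy * m, tolerance = 1e-12)
})

test_that("MT- surround suppression cancels uniform motion but spares a lone probe", {
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  n <- 16
  dirv <- bank$dir_prefs[4]; spd <- bank$speed_prefs[3]
  mk_enc <- function(cells) {
    enc <- array(0, c(n * n, 24, 5))
    for (d in 1:24) for (s in 1:5)
      enc[cells, d, s] <- direction_response(dirv, bank$dir_prefs[d]) *
        speed_response(spd, bank$speed_prefs[s])
    enc
  }
  centre <- 8 + 7 * n
  full <- mk_enc(seq_len(n * n))
  lone <- mk_enc(centre)
  dt <- 1 / 300
  run_mt_minus <- function(enc) {
    I <- mt_surround_inhibition(enc, n, bank, kappa_loc = 8, cells = centre)
    M <- array(0, dim(I))
    for (k in 1:2000)
      M <- mt_minus_step(M, enc[centre, , , drop = FALSE], I, 0, dt = dt)
    M
  }
  m_full <- run_mt_minus(full)
  m_lone <- run_mt_minus(lone)
  expect_lt(max(m_full), max(m_lone) / 3)   # surround cancels matched centre
  # without surround stimulation the response is the unsuppressed centre drive
  E <- lone[centre, 4, 3]
  expect_equal(m_lone[1, 4, 3], E / (1 + E), tolerance = 1e-6)
})

test_that("surround inhibition is graded with tuning similarity and depth specificity", {
  bank <- tuning_bank(speed_prefs_for("cloud"),
                      disp_prefs = seq(60, -40, length.out = 5))
  n <- 16
  centre <- 8 + 7 * n
  ring <- setdiff(which(abs(((1:(n * n)) - 1) %% n + 1 - 8) <= 2 &
                          abs(((1:(n * n)) - 1) %/% n + 1 - 8) <= 2), centre)
  mk <- function(d_s, s_s, p_s) {
    enc <- array(0, c(n * n, 24, 5, 5))
    enc[ring, d_s, s_s, p_s] <- 1
    enc
  }
  inhib_at <- function(enc) {
    I <- mt_surround_inhibition(enc, n, bank, kappa_loc = 6, cells = centre)
    I[1, 4, 3, 3]                    # inhibition onto a (d=4, s=3, p=3) unit
  }
  i_match <- inhib_at(mk(4, 3, 3))        # surround matches centre tuning
  i_other_disp <- inhib_at(mk(4, 3, 1))   # same motion at another depth
  i_far <- inhib_at(mk(16, 3, 1))         # opposite direction, other depth
  expect_gt(i_match, i_other_disp)
  expect_gt(i_other_disp, i_far)
  # monotone: increasing direction similarity never decreases inhibition
  offs <- c(12, 8, 4, 2, 0)
  vals <- vapply(offs, function(o) inhib_at(mk(4 + o, 3, 3)), 1)
  expect_true(all(diff(vals) >= 0))
})

test_that("MT- activity respects the shunting bounds for random inputs", {
  set.seed(11)
  M <- stats::runif(200)
  for (k in 1:500) {
    E <- stats::runif(200, 0, 3)
    Il <- stats::runif(200, 0, 10)
    Ifb <- stats::runif(200, 0, 50)
    M <- mt_minus_step(M, E, Il, Ifb, dt = 1 / 300, B = 1)
    expect_true(all(M >= 0 & M <= 1))
  }
})
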
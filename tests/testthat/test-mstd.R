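test_that("radial templates match the closed-form singularity field", {
  n <- 32
  tpl <- build_radial_template(13, 21, n)
  # brute force over every cell
  for (x in 1:n) for (y in seq(1, n, by = 5)) {
    expect_equal(tpl$u[x, y], x - 13)
    expect_equal(tpl$v[x, y], y - 21)
    if (x != 13 || y != 21)
      expect_equal(tpl$dir[x, y], rad2deg(atan2(y - 21, x - 13)),
                   tolerance = 1e-9)
  }
  expect_equal(tpl$u[13, 21], 0)
  expect_equal(tpl$v[13, 21], 0)
  expect_equal(tpl$dir[14, 21], 0)     # one cell to the right: rightward
  expect_true(all(diff(tpl$wdist[13:n, 21]) < 0))  # weight decays outward
})

test_that("ground templates cover the below-horizon half-field", {
  n <- 32
  tpl <- build_ground_template(13, 21, n)
  expect_equal(tpl$u[13, 21], 0)
  expect_equal(tpl$v[13, 21], 0)
  # at the horizon row the template vector vanishes ((y - j)^2 = 0)
  expect_true(all(abs(tpl$v[, 21]) < 1e-12))
  expect_true(all(is.na(tpl$dir[, 22:n])))     # undefined above the horizon
  # random below-horizon cells match ((x-i)(y-j), (y-j)^2) up to the sign
  # convention for "below" (y up in this package)
  set.seed(2)
  for (k in 1:10) {
    x <- sample(n, 1); y <- sample(20, 1)
    u <- x - 13; v <- y - 21
    expect_equal(c(tpl$u[x, y], tpl$v[x, y]), -c(u * v, v^2),
                 tolerance = 1e-12)
  }
})

test_that("gradient subunits tile eccentricity and mirror across variants", {
  n <- 32
  inc <- build_gradient_subunits(17, 17, n, variant = "increasing")
  dec <- build_gradient_subunits(17, 17, n, variant = "decreasing")
  r <- build_radial_template(17, 17, n)$r
  peak_r <- vapply(inc, function(m) mean(r[m >= max(m) * 0.999]), 1)
  expect_equal(peak_r[1], min(peak_r))  # slowest subunit peaks at the centre
  expect_true(all(diff(peak_r) >= 0))   # maxima move outward with speed
  for (s in 1:5) expect_equal(dec[[s]], inc[[6 - s]], tolerance = 1e-12)
  for (s in 1:5) expect_equal(sum(inc[[s]]), 1, tolerance = 1e-12)  # normalized
})

test_that("speed pooling: band-pass keeps its channel, speed-summating averages", {
  n <- 32
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  tb <- template_bank(n, bank, dist_r0 = 16, ground = FALSE)
  set.seed(5)
  cs <- stats::runif(5, 0.1, 2)       # one constant per speed channel
  z <- array(0, c(n * n, 24, 5))
  for (s in 1:5) z[, , s] <- cs[s]
  drv <- feedforward_drive(tb, z, gains = list(bp = 1, ss = 1, grad = 1,
                                               ground = 1))
  # with a channel-constant signal the normalized match returns the channel
  # value exactly: B_s(w) = w_s and U(w) = mean(w_s), to within 1e-9
  for (s in 1:5)
    expect_equal(unname(drv$bp[, s, 1]), rep(cs[s], tb$nij), tolerance = 1e-9)
  expect_equal(unname(drv$ss[, 1]), rep(mean(cs), tb$nij), tolerance = 1e-9)
})

test_that("a noise-free radial field is localized exactly on the singularity grid", {
  n <- 32
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  tb <- template_bank(n, bank, dist_r0 = 16, ground = TRUE)
  sing <- singularity_positions(n)
  for (foe in list(c(17, 17), c(13, 25))) {
    stopifnot(foe[1] %in% sing, foe[2] %in% sing)
    gf <- radial_grid(n, foe[1], foe[2], k = 0.4)
    enc <- mt_encode(gf, bank, frame_group = 1L)
    z <- mt_plus_drive(enc, n, radius = 1, sigma = 1)
    drv <- feedforward_drive(tb, z, gains = list(bp = 1, ss = 1, grad = 0.15,
                                                 ground = 0))
    peak <- which(drv$bp == max(drv$bp), arr.ind = TRUE)[1, 1]
    expect_equal(unname(tb$ij[peak, ]), foe)
    # and the competitive network's winner lands there too
    st <- mstd_state(tb, theta_eng = 1e6)
    for (k in 1:100) st <- recurrent_step(st, drv, dt = 1 / 300)
    w <- mstd_winner(st, tb)
    expect_equal(c(w$i, w$j), foe)
  }
})

test_that("the competitive network decays, sharpens winners, and stays bounded", {
  n <- 32
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  tb <- template_bank(n, bank, dist_r0 = 16, ground = FALSE)
  st <- mstd_state(tb, theta_eng = 0.1)
  # zero drive: activity decays toward zero, no engagement
  st$A[] <- 0.5
  for (k in 1:500) st <- recurrent_step(st, numeric(length(st$A)), 1 / 300)
  expect_lt(max(st$A), 1e-3)
  expect_false(any(st$engaged))
  # strong/weak unit pair, strong above the engagement threshold: from the
  # feedforward fixed point, recurrence strictly increases the strong
  # unit's share of activity (winner sharpening)
  st <- mstd_state(tb, theta_eng = 0.3)   # threshold at 0.9: only unit 10
  drv <- numeric(length(st$A)); drv[c(10, 20)] <- c(3, 0.6)
  for (k in 1:2000) st <- recurrent_step(st, drv, 1 / 300, beta = 0)
  shares <- st$A[10] / (st$A[10] + st$A[20])
  for (k in 1:100) {
    st <- recurrent_step(st, drv, 1 / 300, beta = 60)
    if (k %in% c(10, 30, 60, 100))
      shares <- c(shares, st$A[10] / (st$A[10] + st$A[20]))
  }
  expect_true(all(diff(shares) > 0))
  expect_true(st$engaged["bp"])
  # random drives: every unit stays within the shunting ceiling B
  set.seed(9)
  st <- mstd_state(tb, theta_eng = 0.5)
  drv <- stats::rexp(length(st$A), rate = 2)
  for (k in 1:800) st <- recurrent_step(st, drv, 1 / 300, B = 1)
  expect_true(all(st$A >= 0 & st$A <= 1))
})

test_that("ties in the winner break deterministically to the lowest index", {
  n <- 32
  bank <- tuning_bank(speed_prefs_for("frontoparallel"))
  tb <- template_bank(n, bank, dist_r0 = 16, ground = FALSE)
  st <- mstd_state(tb)
  st$A[] <- 0.3
  w <- mstd_winner(st, tb)
  expect_equal(w$subpop, "bp")
  expect_equal(c(w$i, w$j), c(1, 1))
})

test_that("population kurtosis matches the normalized fourth moment", {
  set.seed(3)
  x <- stats::rnorm(20000)
  expect_equal(population_kurtosis(x), 3, tolerance = 0.1)
  spike <- c(rep(0.001, 499), 5)
  expect_gt(population_kurtosis(spike), 50)
  for (k in 1:5) {
    v <- stats::rgamma(100, shape = 1)
    brute <- sum(((v - mean(v)) / sqrt(mean((v - mean(v))^2)))^4) / length(v)
    expect_equal(population_kurtosis(v), brute, tolerance = 1e-12)
  }
  expect_warning(ku <- population_kurtosis(rep(2, 10)), "variance")
  expect_true(is.na(ku))
  expect_error(population_kurtosis(1:3), "at least 4")
})

test_that("unit counts follow the area layout", {
  cnt32 <- unit_counts(32, stereo = FALSE)
  expect_equal(unname(cnt32["MTplus"]), 32 * 32 * 24 * 5)
  expect_equal(unname(cnt32["MSTd_gradient"]), 64)
})
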
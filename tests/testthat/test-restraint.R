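# A coupling whose curve is easy to steer in tests: J = 3 cos(theta) + 7
# on the HA-HB3 frame (offset 0), so J(0) = 10, J(180) = 4, J(90) = 7.
test_coupling <- function() {
  coupling_definition("HA-HB3", params = karplus_params(0, 3, 7, "test"))
}
test_spec <- function(J0 = 7, ...) restraint_spec(J0, test_coupling(), ...)

test_that("damped average has constants as fixed points and obeys limits", {
  st <- new_restraint_state(test_spec())
  expect_true(is.na(st$J_avg))
  st <- update_average(st, 3.2, 0.002)
  expect_equal(st$J_avg, 3.2)            # first-sample limit
  for (i in 1:500) st <- update_average(st, 3.2, 0.013)
  expect_equal(st$J_avg, 3.2)            # constant signal is a fixed point

  expect_error(update_average(st, 5, 0), "positive")
  expect_error(update_average(st, 5, -1), "positive")
  expect_error(update_average(st, Inf, 0.1), "finite")
})

test_that("damped average of a fast square wave matches fine quadrature", {
  tau <- 5; dt <- 0.005; period <- 0.1
  sqw <- function(t) ifelse(t %% period < period / 2, 4, 10)
  st <- new_restraint_state(test_spec(tau_J = tau))
  n <- round(10 * tau / dt)
  for (i in seq_len(n)) st <- update_average(st, sqw((i - 1) * dt), dt)
  expect_equal(st$J_avg, 7.0, tolerance = 0.05 / 7)
  oracle <- damped_average_quadrature(sqw, 10 * tau, tau, dt = 1e-4)
  expect_equal(st$J_avg, oracle, tolerance = 0.02 / 7)
})

test_that("biquadratic gate requires both values outside on the same side", {
  expect_equal(gate_factors(7, 7, 7, 1), list(factor = 0, side = "none"))
  # opposite sides never gate
  expect_equal(gate_factors(9, 5, 7, 1)$side, "none")
  expect_equal(gate_factors(9, 5, 7, 1)$factor, 0)
  # direct substitution: (2-1)^2 (3-1)^2 = 4
  g <- gate_factors(9, 10, 7, 1)
  expect_equal(g$factor, 4)
  expect_equal(g$side, "attractive")
  # symmetric repulsive case
  g <- gate_factors(5, 4, 7, 1)
  expect_equal(g$factor, 4)
  expect_equal(g$side, "repulsive")
  # upper edge counts as violating (H = 1 at the threshold) with zero factor
  g <- gate_factors(8, 8, 7, 1)
  expect_equal(g$side, "attractive")
  expect_equal(g$factor, 0)
  # lower edge counts as satisfied (strict inequality)
  expect_equal(gate_factors(6, 6, 7, 1)$side, "none")
  # infinite flat bottom disables the restraint entirely
  expect_equal(gate_factors(100, 100, 7, Inf)$factor, 0)
})

test_that("weights accumulate as time averages and decay as 1/t", {
  # constant violating signal: J_inst = 9, J_avg -> 9, factor (1)^2(1)^2 = 1
  st <- new_restraint_state(test_spec(J0 = 7))
  dt <- 0.01
  theta <- 47  # bin 5 of the 36-bin grid (centers at 10, 20, ...)
  for (i in 1:200) {
    st <- update_average(st, 9, dt)
    st <- update_weights(st, theta, 9, dt)
    w <- le_weights(st)
    expect_equal(w[[le_bin_index(theta, 36)]], 1)
    expect_true(all(w[-le_bin_index(theta, 36)] == 0))
  }
  # stop violating: J_inst inside the flat bottom gates to zero
  S_frozen <- st$S
  tT <- st$t
  for (i in 1:200) {
    st <- update_average(st, 7, dt)
    st <- update_weights(st, theta, 7, dt)
    expect_equal(st$S, S_frozen)                       # omega * t constant
  }
  expect_equal(st$t, 2 * tT)
  expect_equal(le_weights(st)[[le_bin_index(theta, 36)]], 0.5)

  # never-gated runs leave all weights at zero
  st0 <- new_restraint_state(test_spec())
  for (i in 1:50) {
    st0 <- update_average(st0, 7, dt)
    st0 <- update_weights(st0, runif(1, -180, 180), 7, dt)
  }
  expect_true(all(le_weights(st0) == 0))
  expect_error(update_weights(st0, NA_real_, 7, dt), "finite")
})

test_that("grid bins partition the circle", {
  set.seed(23)
  for (N in c(4L, 9L, 36L)) {
    th <- runif(1000, -180, 180)
    idx <- le_bin_index(th, N)
    expect_true(all(idx >= 1 & idx <= N))
    # away from bin edges the containing bin has the nearest center
    centers <- le_grid_centers(N)
    d <- abs(wrap_angle(outer(th, centers, "-")))
    off_edge <- abs(d[cbind(seq_along(th), idx)] - 180 / N) > 1e-6
    expect_equal(idx[off_edge], apply(d, 1, which.min)[off_edge])
    # half-open convention at the edges: lower edge in, upper edge out
    width <- 360 / N
    for (i in seq_len(N)) {
      expect_equal(le_bin_index(centers[i] - width / 2, N), i)
      expect_false(le_bin_index(centers[i] + width / 2, N) == i)
    }
  }
})

test_that("energy and force are consistent and behave at the peak", {
  spec <- test_spec(N_le = 36L, K_Jr = 50)
  st <- new_restraint_state(spec)
  expect_equal(restraint_energy(st, 13), 0)
  expect_equal(restraint_force(st, 13), 0)

  # single occupied bin: peak energy is K * omega, force vanishes there
  st$t <- 1
  st$S <- numeric(36); st$S[12] <- 0.3
  center <- le_grid_centers(36)[12]
  expect_equal(restraint_energy(st, center), 50 * 0.3, tolerance = 1e-6)
  expect_equal(restraint_force(st, center), 0, tolerance = 1e-9)

  # uniform weights give a nearly flat periodic Gaussian comb
  st$S <- rep(0.2, 36)
  e <- vapply(seq(-180, 180, by = 0.25), function(th)
    restraint_energy(st, th), numeric(1))
  expect_lt((max(e) - min(e)) / mean(e), 1e-3)

  # analytic force equals central differences for random weights
  set.seed(7)
  st$S <- runif(36)
  for (th in runif(100, -180, 180)) {
    num <- central_diff_force(function(x) restraint_energy(st, x), th)
    ana <- restraint_force(st, th)
    expect_equal(ana, num, tolerance = 1e-6)
  }
})

test_that("restraint_step wires average, weights, energy and force together", {
  # theta = 90 gives J_inst = 7 = J0: no gating, ever
  st <- new_restraint_state(test_spec(J0 = 7))
  out <- restraint_step(st, 90, 0.002)
  expect_equal(out$J_inst, 7)
  expect_equal(out$energy, 0)
  expect_equal(out$force, 0)
  expect_equal(out$side, "none")

  # held at theta = 0 (J = 10, 2 Hz above the upper edge): energy grows
  st <- new_restraint_state(test_spec(J0 = 7))
  e <- numeric(20)
  for (i in 1:20) {
    out <- restraint_step(st, 0, 0.002)
    st <- out$state
    e[i] <- out$energy
  }
  expect_equal(out$side, "attractive")
  expect_true(all(diff(e[2:20]) >= -1e-9))  # non-decreasing up to rounding
  expect_gt(e[20], 0)

  # two restraints on the same angle add independently
  stA <- new_restraint_state(test_spec(J0 = 7))
  stB <- new_restraint_state(test_spec(J0 = 6))
  for (i in 1:10) {
    oA <- restraint_step(stA, 0, 0.002); stA <- oA$state
    oB <- restraint_step(stB, 0, 0.002); stB <- oB$state
  }
  total <- restraint_energy(stA, 0) + restraint_energy(stB, 0)
  expect_equal(total, oA$energy + oB$energy)
})

test_that("weights are covariant under grid rotation of the trajectory", {
  set.seed(11)
  dt <- 0.01
  thetas <- runif(300, -180, 180)
  Js <- runif(300, 8.5, 10)  # always violating once the average settles
  advance <- function(shift_bins) {
    st <- new_restraint_state(test_spec(J0 = 7, N_le = 36L))
    width <- 10
    for (i in seq_along(thetas)) {
      st <- update_average(st, Js[i], dt)
      st <- update_weights(st, thetas[i] + shift_bins * width, Js[i], dt)
    }
    le_weights(st)
  }
  w0 <- advance(0)
  w3 <- advance(3)
  idx <- seq_len(36)
  shifted <- ((idx - 1 + 3) %% 36) + 1
  expect_equal(w3[shifted], w0[idx], tolerance = 1e-12)
})

test_that("an infinite flat bottom silences the restraint on any trajectory", {
  set.seed(3)
  st <- new_restraint_state(test_spec(J0 = 7, dJ_fb = Inf))
  for (i in 1:200) {
    out <- restraint_step(st, runif(1, -180, 180), 0.002)
    st <- out$state
    expect_identical(out$energy, 0)
    expect_identical(out$force, 0)
  }
})

test_that("restraint state survives a JSON checkpoint round trip", {
  st <- new_restraint_state(restraint_spec(8.2, coupling_definition("HN-HA"),
                                           tau_J = 50, N_le = 18L))
  for (i in 1:40) {
    out <- restraint_step(st, -40 + i, 0.002)
    st <- out$state
  }
  path <- tempfile(fileext = ".json")
  save_restraint_state(st, path)
  st2 <- load_restraint_state(path)
  expect_equal(st2$S, st$S)
  expect_equal(st2$t, st$t)
  expect_equal(st2$J_avg, st$J_avg)
  expect_equal(st2$spec$J0, st$spec$J0)
  # identical continuation
  a <- restraint_step(st, -10, 0.002)
  b <- restraint_step(st2, -10, 0.002)
  expect_equal(a$energy, b$energy)
  expect_equal(a$J_avg, b$J_avg)
})
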
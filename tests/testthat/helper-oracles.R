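# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# number of dihedral solutions of J(theta) = J by dense grid sign scan
grid_solution_count <- function(a, b, c, J, step = 0.001) {
  th <- seq(-180, 180, by = step)
  f <- a * cos(th * pi / 180)^2 + b * cos(th * pi / 180) + c - J
  sum(f[-length(f)] * f[-1] < 0) + sum(f == 0)
}

# continuous exponentially damped average by fine quadrature
damped_average_quadrature <- function(J_of_t, t_end, tau, dt = 1e-3) {
  tp <- seq(dt / 2, t_end, by = dt)  # midpoint rule
  w <- exp(-(t_end - tp) / tau)
  sum(w * J_of_t(tp)) * dt / (tau * (1 - exp(-t_end / tau)))
}

# Kolmogorov-Smirnov statistic of samples against a CDF given on a grid
ks_statistic <- function(samples, grid, cdf) {
  x <- sort(samples)
  Fx <- stats::approx(grid, cdf, xout = x, rule = 2)$y
  n <- length(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# Boltzmann CDF of a torsional potential over (-180, 180]
boltzmann_cdf <- function(potential, temperature = 308, n_grid = 72001) {
  kB <- 0.008314462618
  grid <- seq(-180, 180, length.out = n_grid)
  dens <- exp(-reference_potential(potential, grid) / (kB * temperature))
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  list(grid = grid, cdf = cdf)
}

# brute-force S2: explicit double loop over the alpha/beta components
s2_brute_force <- function(vectors, frames_per_win, r_eff = NULL) {
  r <- sqrt(rowSums(vectors^2))
  if (is.null(r_eff)) r_eff <- mean(r)
  n_win <- nrow(vectors) %/% frames_per_win
  out <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * frames_per_win + 1):(w * frames_per_win)
    acc <- 0
    for (a in 1:3) {
      for (b in 1:3) {
        s <- 0
        for (i in idx)
          s <- s + vectors[i, a] * vectors[i, b] / (r[i]^2 * r[i]^3)
        acc <- acc + (s / length(idx))^2
      }
    }
    s_inv <- 0
    for (i in idx) s_inv <- s_inv + 1 / r[i]^3
    out[w] <- 0.5 * (3 * acc - (s_inv / length(idx))^2) * r_eff^6
  }
  out
}

# central-difference gradient of a scalar function of one angle (degrees in,
# derivative per radian out)
central_diff_force <- function(f, theta_deg, h_rad = 1e-5) {
  h_deg <- h_rad * 180 / pi
  -(f(theta_deg + h_deg) - f(theta_deg - h_deg)) / (2 * h_rad)
}
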
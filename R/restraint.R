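#' Specification of a 3J-coupling restraint
#'
#' Bundles the target coupling with the penalty parameters of the
#' biquadratic time-averaging local-elevation (BQ-TA-LER) restraint: the
#' flat-bottom half-width representing the Karplus-relation uncertainty,
#' the overall force constant, the memory relaxation time of the damped
#' coupling average, and the number of local-elevation grid intervals.
#'
#' @param J0 Target coupling in Hz (the capped experimental value).
#' @param coupling A [coupling_definition()] linking the restrained torsion
#'   to the coupling.
#' @param dJ_fb Flat-bottom half-width in Hz (default 1.0, i.e. a 2 Hz wide
#'   penalty-free band representing Karplus uncertainty).
#' @param K_Jr Force constant in kJ mol^-1 Hz^-4 (default 50).
#' @param tau_J Memory relaxation time of the damped average in ps
#'   (default 500).
#' @param N_le Number of local-elevation grid intervals (default 36,
#'   i.e. 10-degree bins).
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(J0, coupling, dJ_fb = 1.0, K_Jr = 50,
                           tau_J = 500, N_le = 36L) {
  stopifnot(inherits(coupling, "coupling_definition"),
            is.numeric(J0), length(J0) == 1L, is.finite(J0),
            dJ_fb >= 0, K_Jr >= 0, tau_J > 0, N_le >= 2)
  structure(list(J0 = J0, coupling = coupling, dJ_fb = dJ_fb,
                 K_Jr = K_Jr, tau_J = tau_J, N_le = as.integer(N_le)),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf(
    "BQ-TA-LER restraint: J0 = %g Hz (%s), dJ_fb = %g Hz, K_Jr = %g, tau_J = %g ps, N_le = %d\n",
    x$J0, x$coupling$kind, x$dJ_fb, x$K_Jr, x$tau_J, x$N_le))
  invisible(x)
}

#' Local-elevation grid centers
#'
#' Centers \eqn{\theta_i^0 = 2\pi i / N_{le}} for i = 1..N_le, reported in
#' degrees wrapped to (-180, 180].
#'
#' @param N_le Number of grid intervals.
#' @return Numeric vector of bin centers in degrees.
#' @export
le_grid_centers <- function(N_le) {
  wrap_angle(360 * seq_len(N_le) / N_le)
}

#' Locate the local-elevation bin containing an angle
#'
#' Bins are the half-open intervals
#' \eqn{[\theta_i^0 - \Delta\theta^0/2,\ \theta_i^0 + \Delta\theta^0/2)}
#' (lower edge inclusive), which partition the circle.
#'
#' @param theta Angle(s) in degrees.
#' @param N_le Number of grid intervals.
#' @return Integer bin index in 1..N_le.
#' @export
le_bin_index <- function(theta, N_le) {
  if (any(!is.finite(theta))) stop("'theta' must be finite (degrees)")
  width <- 360 / N_le
  idx <- floor(theta / width + 0.5) %% N_le
  as.integer(ifelse(idx == 0, N_le, idx))
}

#' Fresh restraint state
#'
#' Initialises the mutable per-coupling state: the exponentially damped
#' coupling-average accumulators and the local-elevation weight integrals.
#'
#' @param spec A [restraint_spec()].
#' @return An object of class `restraint_state`.
#' @export
new_restraint_state <- function(spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  structure(list(spec = spec,
                 S = numeric(spec$N_le),  # integral of gated factor, Hz^4 ps
                 t = 0,                   # elapsed restraining time, ps
                 avg_num = 0,             # damped integral of J, Hz ps
                 avg_den = 0,             # damped integral of 1, ps
                 J_avg = NA_real_),
            class = "restraint_state")
}

#' Time-averaged local-elevation weights
#'
#' \eqn{\omega_i(t) = t^{-1} \int_0^t [\ldots] dt'}; zero before the first
#' step. When the restraint stays satisfied the weights decay as 1/t.
#'
#' @param state A `restraint_state`.
#' @return Numeric vector of weights in Hz^4.
#' @export
le_weights <- function(state) {
  if (state$t <= 0) return(numeric(state$spec$N_le))
  state$S / state$t
}

#' Update the exponentially damped coupling average
#'
#' Left-rectangle discretisation of the damped time average
#' \eqn{\langle J\rangle_t = [\tau_J(1 - e^{-t/\tau_J})]^{-1}
#' \int_0^t e^{-(t-t')/\tau_J} J(t')\,dt'}, including the finite-time
#' normalisation, so a constant signal is a fixed point at every t and the
#' first sample initialises the average to itself.
#'
#' @param state A `restraint_state`.
#' @param J_inst Instantaneous coupling in Hz.
#' @param dt Time step in ps (> 0).
#' @return The updated state.
#' @export
update_average <- function(state, J_inst, dt) {
  stopifnot(inherits(state, "restraint_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ps)")
  if (!is.finite(J_inst)) stop("'J_inst' must be finite (Hz)")
  decay <- exp(-dt / state$spec$tau_J)
  state$avg_num <- state$avg_num * decay + J_inst * dt
  state$avg_den <- state$avg_den * decay + dt
  state$J_avg <- state$avg_num / state$avg_den
  state
}

#' Biquadratic gate of the BQ-TA-LER restraint
#'
#' The penalty accumulates only when the instantaneous coupling and its
#' damped time average both lie outside the flat bottom on the same side of
#' the target. At the upper edge the step function counts the boundary as a
#' violation (H(x; x0) = 1 at x = x0); at the lower edge the complement
#' makes the boundary satisfied.
#'
#' @param J_inst Instantaneous coupling (Hz).
#' @param J_avg Damped time-averaged coupling (Hz).
#' @param J0 Target coupling (Hz).
#' @param dJ_fb Flat-bottom half-width (Hz).
#' @return List with `factor` (Hz^4) and `side` (`"attractive"`,
#'   `"repulsive"` or `"none"`).
#' @export
gate_factors <- function(J_inst, J_avg, J0, dJ_fb) {
  hi <- J0 + dJ_fb
  lo <- J0 - dJ_fb
  if (is.finite(hi) && J_inst >= hi && J_avg >= hi) {
    list(factor = (J_inst - hi)^2 * (J_avg - hi)^2, side = "attractive")
  } else if (is.finite(lo) && J_inst < lo && J_avg < lo) {
    list(factor = (J_inst - lo)^2 * (J_avg - lo)^2, side = "repulsive")
  } else {
    list(factor = 0, side = "none")
  }
}

#' Accumulate local-elevation weights for one step
#'
#' Deposits the gated biquadratic factor into the grid bin containing the
#' current torsion angle and advances the restraining clock; call
#' [update_average()] first so the gate sees the average through this step.
#'
#' @param state A `restraint_state` (average already updated for this step).
#' @param theta Torsion angle in degrees.
#' @param J_inst Instantaneous coupling in Hz.
#' @param dt Time step in ps (> 0).
#' @return The updated state.
#' @export
update_weights <- function(state, theta, J_inst, dt) {
  stopifnot(inherits(state, "restraint_state"))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("'theta' must be a single finite number (degrees)")
  if (dt <= 0) stop("'dt' must be positive (ps)")
  g <- gate_factors(J_inst, state$J_avg, state$spec$J0, state$spec$dJ_fb)
  i <- le_bin_index(theta, state$spec$N_le)
  state$S[i] <- state$S[i] + g$factor * dt
  state$t <- state$t + dt
  attr(state, "last_gate") <- g$side
  attr(state, "last_bin") <- i
  state
}

## Wrapped deviations from all grid centers, in radians
.le_deltas <- function(theta, N_le) {
  deg2rad(wrap_angle(theta - le_grid_centers(N_le)))
}

#' Local-elevation restraining energy
#'
#' \eqn{V(\theta) = \sum_i K^{Jr} \omega_i
#' \exp(-(\theta-\theta_i^0)^2 / (2 (\Delta\theta^0)^2))} with the deviation
#' from each center wrapped to its nearest periodic image.
#'
#' @param state A `restraint_state`.
#' @param theta Torsion angle in degrees.
#' @return Energy in kJ/mol (non-negative).
#' @export
restraint_energy <- function(state, theta) {
  stopifnot(inherits(state, "restraint_state"))
  w <- le_weights(state)
  if (!any(w > 0)) return(0)
  dlt <- .le_deltas(theta, state$spec$N_le)
  width <- 2 * pi / state$spec$N_le
  sum(state$spec$K_Jr * w * exp(-dlt^2 / (2 * width^2)))
}

#' Generalized force of the local-elevation restraint
#'
#' Analytic \eqn{-dV/d\theta} of [restraint_energy()], with the weights held
#' constant during differentiation (standard for local-elevation biasing).
#'
#' @inheritParams restraint_energy
#' @return Force in kJ mol^-1 rad^-1.
#' @export
restraint_force <- function(state, theta) {
  stopifnot(inherits(state, "restraint_state"))
  w <- le_weights(state)
  if (!any(w > 0)) return(0)
  dlt <- .le_deltas(theta, state$spec$N_le)
  width <- 2 * pi / state$spec$N_le
  sum(state$spec$K_Jr * w * exp(-dlt^2 / (2 * width^2)) * dlt / width^2)
}

#' Advance a restraint by one time step
#'
#' Computes the instantaneous coupling from the torsion, updates the damped
#' average, deposits the gated local-elevation weight, and returns the
#' energy and generalized force evaluated with the weights through this
#' step (update order: average, then weights, then force).
#'
#' @param state A `restraint_state`.
#' @param theta Torsion angle in degrees.
#' @param dt Time step in ps (> 0).
#' @return List with the updated `state`, `energy` (kJ/mol), `force`
#'   (kJ mol^-1 rad^-1), and diagnostics `J_inst`, `J_avg`, `side`, `bin`.
#' @export
restraint_step <- function(state, theta, dt) {
  stopifnot(inherits(state, "restraint_state"))
  J_inst <- coupling_from_torsion(state$spec$coupling, theta)
  state <- update_average(state, J_inst, dt)
  state <- update_weights(state, theta, J_inst, dt)
  list(state = state,
       energy = restraint_energy(state, theta),
       force = restraint_force(state, theta),
       J_inst = J_inst,
       J_avg = state$J_avg,
       side = attr(state, "last_gate"),
       bin = attr(state, "last_bin"))
}

#' Local-elevation weight and energy profile
#'
#' Tabulates the accumulated weights and the restraining energy at each
#' grid center, the torsional fingerprint the method builds up during a
#' restrained run.
#'
#' @param state A `restraint_state`.
#' @return Data frame with columns `theta_center_deg`, `omega_Hz4`,
#'   `energy_kJmol`.
#' @export
le_profile <- function(state) {
  centers <- le_grid_centers(state$spec$N_le)
  ord <- order(centers)
  energy <- vapply(centers, function(th) restraint_energy(state, th),
                   numeric(1))
  data.frame(theta_center_deg = centers[ord],
             omega_Hz4 = le_weights(state)[ord],
             energy_kJmol = energy[ord])
}

#' Checkpoint a restraint state to JSON
#'
#' @param state A `restraint_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_restraint_state <- function(state, path) {
  stopifnot(inherits(state, "restraint_state"))
  sp <- state$spec
  obj <- list(
    spec = list(J0 = sp$J0, dJ_fb = sp$dJ_fb, K_Jr = sp$K_Jr,
                tau_J = sp$tau_J, N_le = sp$N_le,
                coupling = list(kind = sp$coupling$kind,
                                torsion_name = sp$coupling$torsion_name,
                                residue = sp$coupling$residue,
                                params = unclass(sp$coupling$params))),
    S = state$S, t = state$t,
    avg_num = state$avg_num, avg_den = state$avg_den, J_avg = state$J_avg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a restraint state from a JSON checkpoint
#'
#' @param path File written by [save_restraint_state()].
#' @return A `restraint_state`.
#' @export
load_restraint_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- obj$spec$coupling
  pp <- karplus_params(cp$params$a, cp$params$b, cp$params$c,
                       cp$params$label)
  defn <- coupling_definition(cp$kind, torsion_name = cp$torsion_name,
                              residue = cp$residue, params = pp)
  spec <- restraint_spec(obj$spec$J0, defn, dJ_fb = obj$spec$dJ_fb,
                         K_Jr = obj$spec$K_Jr, tau_J = obj$spec$tau_J,
                         N_le = obj$spec$N_le)
  state <- new_restraint_state(spec)
  state$S <- as.numeric(obj$S)
  state$t <- obj$t
  state$avg_num <- obj$avg_num
  state$avg_den <- obj$avg_den
  state$J_avg <- if (is.null(obj$J_avg)) NA_real_ else obj$J_avg
  state
}
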
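#' Karplus parameter set
#'
#' Coefficients of the Karplus relation \eqn{{}^3J(\theta) = a\cos^2\theta +
#' b\cos\theta + c} linking a three-bond scalar coupling to the intervening
#' dihedral angle \eqn{\theta}.
#'
#' @param a,b,c Coefficients in Hz.
#' @param label Short identifier for the parameter set.
#' @return An object of class `karplus_params`.
#' @seealso [karplus_pardi()], [karplus_demarco()]
#' @export
karplus_params <- function(a, b, c, label = "custom") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L,
            is.finite(a), is.finite(b), is.finite(c))
  structure(list(a = a, b = b, c = c, label = as.character(label)),
            class = "karplus_params")
}

#' @export
print.karplus_params <- function(x, ...) {
  cat(sprintf("Karplus parameters [%s]: a = %g Hz, b = %g Hz, c = %g Hz\n",
              x$label, x$a, x$b, x$c))
  invisible(x)
}

#' Built-in Karplus parameter sets
#'
#' `karplus_pardi()` returns the backbone HN-HA parameterisation
#' (a = 6.4, b = -1.4, c = 1.9 Hz); `karplus_demarco()` the side-chain
#' HA-HB parameterisation (a = 9.5, b = -1.6, c = 1.8 Hz).
#'
#' @return A `karplus_params` object.
#' @export
karplus_pardi <- function() karplus_params(6.4, -1.4, 1.9, "pardi")

#' @rdname karplus_pardi
#' @export
karplus_demarco <- function() karplus_params(9.5, -1.6, 1.8, "demarco")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-180, 180] degrees
#'
#' @param theta Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 360 * floor((theta + 180) / 360)
  # floor maps exactly +180 to -180; keep the (-180, 180] convention
  w[w == -180] <- 180
  w
}

#' Evaluate a Karplus curve
#'
#' @param params A [karplus_params()] object.
#' @param theta Dihedral angle(s) in degrees; any real value (periodic).
#' @return Coupling value(s) in Hz.
#' @examples
#' evaluate_karplus(karplus_pardi(), 180)  # 9.7 Hz, the curve maximum
#' @export
evaluate_karplus <- function(params, theta) {
  stopifnot(inherits(params, "karplus_params"))
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric (degrees)")
  ct <- cos(deg2rad(theta))
  params$a * ct^2 + params$b * ct + params$c
}

## Registered coupling kinds: the angular offset added to the molecular
## torsion (phi or chi1) to obtain the Karplus dihedral, and which built-in
## parameter set applies. The HA-HB_single offset depends on residue type
## (Ile/Thr follow the beta2 convention, Val the beta3 convention).
.coupling_kinds <- function() {
  list(
    "HN-HA"        = list(offset = -60,  set = "pardi",   torsion = "phi"),
    "HN-HA2_Re"    = list(offset = -60,  set = "pardi",   torsion = "phi"),
    "HN-HA3_Si"    = list(offset = +60,  set = "pardi",   torsion = "phi"),
    "HA-HB_single" = list(offset = NA,   set = "demarco", torsion = "chi1"),
    "HA-HB2"       = list(offset = -120, set = "demarco", torsion = "chi1"),
    "HA-HB3"       = list(offset = 0,    set = "demarco", torsion = "chi1")
  )
}

#' Define a coupling in terms of a molecular torsion
#'
#' Maps a named coupling kind to the Karplus dihedral via a fixed angular
#' offset and a parameter set. Backbone HN-HA couplings report on phi,
#' side-chain HA-HB couplings on chi1.
#'
#' @param kind One of `"HN-HA"`, `"HN-HA2_Re"`, `"HN-HA3_Si"`,
#'   `"HA-HB_single"`, `"HA-HB2"`, `"HA-HB3"`.
#' @param torsion_name Label of the torsion the coupling reports on.
#' @param residue Residue type, required for `"HA-HB_single"` (one of
#'   `"Ile"`, `"Thr"`, `"Val"`): Ile/Thr single beta hydrogens follow the
#'   beta2 dihedral convention (offset -120 deg), Val the beta3 convention
#'   (offset 0 deg).
#' @param params Optional `karplus_params` overriding the built-in set.
#' @return An object of class `coupling_definition`.
#' @export
coupling_definition <- function(kind, torsion_name = NULL, residue = NULL,
                                params = NULL) {
  kinds <- .coupling_kinds()
  if (!kind %in% names(kinds))
    stop(sprintf("unknown coupling kind '%s' (known: %s)", kind,
                 paste(names(kinds), collapse = ", ")))
  k <- kinds[[kind]]
  offset <- k$offset
  if (kind == "HA-HB_single") {
    if (is.null(residue) || !residue %in% c("Ile", "Thr", "Val"))
      stop("'HA-HB_single' requires residue = 'Ile', 'Thr' or 'Val'")
    offset <- if (residue == "Val") 0 else -120
  }
  if (is.null(params))
    params <- if (k$set == "pardi") karplus_pardi() else karplus_demarco()
  stopifnot(inherits(params, "karplus_params"))
  structure(list(kind = kind,
                 torsion_name = if (is.null(torsion_name)) k$torsion
                                else torsion_name,
                 residue = residue, offset = offset, params = params),
            class = "coupling_definition")
}

#' @export
print.coupling_definition <- function(x, ...) {
  cat(sprintf("Coupling %s on %s (offset %+g deg, %s parameters)\n",
              x$kind, x$torsion_name, x$offset, x$params$label))
  invisible(x)
}

#' Coupling value from a molecular torsion angle
#'
#' Evaluates the Karplus curve at `torsion + offset` for the definition's
#' coupling kind.
#'
#' @param defn A [coupling_definition()].
#' @param torsion Torsion angle(s) in degrees (phi or chi1).
#' @return Coupling value(s) in Hz.
#' @examples
#' # Asn 103 main-conformation phi of -79 deg -> 6.6 Hz
#' coupling_from_torsion(coupling_definition("HN-HA"), -79)
#' @export
coupling_from_torsion <- function(defn, torsion) {
  stopifnot(inherits(defn, "coupling_definition"))
  evaluate_karplus(defn$params, torsion + defn$offset)
}

#' Invert a Karplus curve
#'
#' Solves \eqn{a x^2 + b x + c = J} for \eqn{x = \cos\theta} and returns all
#' dihedral angles in (-180, 180] attaining the given coupling. The inverse
#' is up to four-valued; double roots at curve extrema are merged.
#'
#' @param params A [karplus_params()] object.
#' @param J Target coupling in Hz.
#' @return Sorted numeric vector of dihedral angles in degrees (possibly
#'   empty when `J` lies outside the attainable range).
#' @export
invert_karplus <- function(params, J) {
  stopifnot(inherits(params, "karplus_params"))
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J))
    stop("'J' must be a single finite number (Hz)")
  a <- params$a; b <- params$b; cc <- params$c - J
  if (a == 0) {
    xs <- if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(numeric(0))
    xs <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  # keep roots with |cos theta| <= 1, clamping values within 1e-12 of +/-1
  keep <- abs(xs) <= 1 + 1e-12
  xs <- pmin(pmax(xs[keep], -1), 1)
  if (!length(xs)) return(numeric(0))
  th <- rad2deg(acos(xs))          # in [0, 180]
  th[abs(th - 180) < 1e-9] <- 180  # snap the cos = -1 boundary exactly
  th <- c(th, -th)
  th <- wrap_angle(th)
  th <- sort(th)
  # deduplicate merged double roots; acos conditioning near cos = +/-1
  # spreads an exactly-degenerate root over ~1e-5 degrees, so the merge
  # tolerance must sit well above that
  tol <- 1e-4
  if (length(th) > 1L)
    th <- th[c(TRUE, diff(th) > tol)]
  # the +/-180 boundary holds the same circle point twice when a double
  # root sits at the cos = -1 extremum
  n <- length(th)
  if (n > 1L && 360 - (th[n] - th[1]) <= tol) {
    th <- th[-1]
    th[n - 1L] <- 180
  }
  th
}

#' Extrema of a Karplus curve
#'
#' Minimum and maximum coupling over a full dihedral rotation, with the
#' angles attaining them. Candidates are the boundary points of cos
#' (0 and 180 degrees) and the interior critical point at
#' \eqn{\cos\theta = -b/(2a)} when it exists.
#'
#' @param params A [karplus_params()] object.
#' @return List with `J_min`, `J_max` (Hz) and `argmin`, `argmax`
#'   (degrees, in (-180, 180]).
#' @examples
#' curve_extrema(karplus_pardi())$J_max  # 9.7 Hz
#' @export
curve_extrema <- function(params) {
  stopifnot(inherits(params, "karplus_params"))
  cand <- c(0, 180)
  if (params$a != 0 && abs(params$b / (2 * params$a)) <= 1)
    cand <- c(cand, rad2deg(acos(-params$b / (2 * params$a))))
  J <- evaluate_karplus(params, cand)
  jmin <- min(J); jmax <- max(J)
  amin <- cand[abs(J - jmin) < 1e-12]
  amax <- cand[abs(J - jmax) < 1e-12]
  sym <- function(th) {                  # add the mirror image -theta
    th <- unique(wrap_angle(c(th, -th)))
    sort(th)
  }
  list(J_min = jmin, J_max = jmax, argmin = sym(amin), argmax = sym(amax))
}

#' Cap an experimental coupling to the attainable range of a Karplus curve
#'
#' Experimental couplings lying outside the curve (e.g. 10.6 Hz against a
#' 9.7 Hz maximum) are replaced by the nearest attainable value before
#' restraining or deviation analysis.
#'
#' @param params A [karplus_params()] object.
#' @param J_exp Experimental coupling(s) in Hz.
#' @return Capped coupling(s) in Hz.
#' @export
cap_to_curve <- function(params, J_exp) {
  ex <- curve_extrema(params)
  pmin(pmax(J_exp, ex$J_min), ex$J_max)
}
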
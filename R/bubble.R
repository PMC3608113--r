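#' Microbubble and ambient-medium parameters
#'
#' Physical parameters of an encapsulated microbubble (a thin-shelled,
#' gas-filled contrast agent) plus the surrounding-liquid constants needed by
#' the shell-modified Rayleigh-Plesset model. Defaults describe a 1.5 um
#' polymer-shelled agent in water: resting radius 1.5 um, shell thickness
#' 1.5 nm, shell shear modulus 10 MPa, shell shear viscosity 1.49 Pa s;
#' water at 1000 kg/m^3 and 1 mPa s, ambient pressure 101.325 kPa, and a
#' near-adiabatic polytropic exponent of 1.07 for the gas core.
#'
#' @param r0 Resting radius (m).
#' @param shell_thickness Shell thickness d_Se (m); must be much smaller
#'   than `r0`.
#' @param shear_modulus Shell shear modulus G_s (Pa).
#' @param shell_viscosity Shell shear viscosity eta (Pa s).
#' @param liquid_density Density of the surrounding liquid (kg/m^3).
#' @param liquid_viscosity Dynamic viscosity of the liquid (Pa s).
#' @param ambient_pressure Static ambient pressure p0 (Pa).
#' @param polytropic_exponent Polytropic exponent kappa of the gas core
#'   (1 = isothermal, 1.4 = adiabatic air).
#' @param n_bubbles Number of bubbles in the insonified cloud; the echo of a
#'   cloud is modeled as `n_bubbles` times the single-bubble echo.
#' @return A list of class `bubble_params`.
#' @examples
#' p <- bubble_params()
#' resonance_frequency(p) / 1e6 # about 2.24 MHz
#' @export
bubble_params <- function(r0 = 1.5e-6,
                          shell_thickness = 1.5e-9,
                          shear_modulus = 10e6,
                          shell_viscosity = 1.49,
                          liquid_density = 1000,
                          liquid_viscosity = 1e-3,
                          ambient_pressure = 101325,
                          polytropic_exponent = 1.07,
                          n_bubbles = 1) {
  p <- list(r0 = r0, shell_thickness = shell_thickness,
            shear_modulus = shear_modulus, shell_viscosity = shell_viscosity,
            liquid_density = liquid_density,
            liquid_viscosity = liquid_viscosity,
            ambient_pressure = ambient_pressure,
            polytropic_exponent = polytropic_exponent,
            n_bubbles = n_bubbles)
  stopifnot(
    "r0 must be > 0" = r0 > 0,
    "shell_thickness must be > 0" = shell_thickness > 0,
    "shell must be thin: shell_thickness < r0 / 10" = shell_thickness < r0 / 10,
    "moduli/viscosities/pressures must be >= 0" =
      all(c(shear_modulus, shell_viscosity, liquid_viscosity,
            ambient_pressure) >= 0),
    "liquid_density must be > 0" = liquid_density > 0,
    "polytropic_exponent must be > 0" = polytropic_exponent > 0,
    "n_bubbles must be >= 1" = n_bubbles >= 1
  )
  class(p) <- "bubble_params"
  p
}

#' @export
print.bubble_params <- function(x, ...) {
  cat("<bubble_params>\n")
  cat(sprintf("  r0 = %.3g um, shell %.3g nm, Gs = %.3g MPa, eta_s = %.3g Pa s\n",
              x$r0 * 1e6, x$shell_thickness * 1e9, x$shear_modulus / 1e6,
              x$shell_viscosity))
  cat(sprintf("  liquid: rho = %g kg/m^3, mu = %g Pa s; p0 = %g kPa, kappa = %g, Nb = %g\n",
              x$liquid_density, x$liquid_viscosity, x$ambient_pressure / 1e3,
              x$polytropic_exponent, x$n_bubbles))
  invisible(x)
}

#' Linear resonance frequency of an encapsulated bubble
#'
#' Undamped natural frequency from linearization of the shell-modified
#' Rayleigh-Plesset equation about the resting radius:
#' `f = (1 / 2 pi) sqrt((3 kappa p0 + 12 Gs dSe / r0) / (rho r0^2))`.
#' With the shell terms zeroed this reduces to the Minnaert frequency of a
#' free gas bubble.
#'
#' @param params A [bubble_params()] object.
#' @return Resonance frequency in Hz.
#' @export
resonance_frequency <- function(params) {
  stopifnot(inherits(params, "bubble_params"))
  w2 <- (3 * params$polytropic_exponent * params$ambient_pressure +
           12 * params$shear_modulus * params$shell_thickness / params$r0) /
    (params$liquid_density * params$r0^2)
  sqrt(w2) / (2 * pi)
}

# Vectorized RHS pieces of the shell-modified Rayleigh-Plesset equation:
# rho (R Rdd + 3/2 Rd^2) = pg0 (r0/R)^(3 kappa) - p0 - p_drive(t)
#                          - 4 mu_L Rd / R - 12 eta dSe r0^2 Rd / R^4
#                          - 12 Gs dSe r0^2 (1 - r0/R) / R^3
bubble_accel <- function(R, Rd, p_drive, p) {
  pg <- p$ambient_pressure * (p$r0 / R)^(3 * p$polytropic_exponent)
  num <- pg - p$ambient_pressure - p_drive -
    4 * p$liquid_viscosity * Rd / R -
    12 * p$shell_viscosity * p$shell_thickness * p$r0^2 * Rd / R^4 -
    12 * p$shear_modulus * p$shell_thickness * p$r0^2 * (1 - p$r0 / R) / R^3
  num / (p$liquid_density * R) - 1.5 * Rd^2 / R
}

#' Simulate the echo scattered by a microbubble cloud
#'
#' Integrates the shell-modified Rayleigh-Plesset equation for the bubble
#' radius `R(t)` driven by the burst pressure, then forms the far-field
#' scattered pressure, proportional to the second time derivative of the
#' bubble volume: `p_s(t) = rho (R^2 Rdd + 2 R Rd^2)` (the 1/distance factor
#' is absorbed by the default unit-peak normalization, since kernel
#' identification is scale-invariant). The cloud of `n_bubbles` bubbles is
#' modeled as `n_bubbles` identical, non-interacting scatterers, so the echo
#' scales linearly with the count. At clinical driving pressures (around
#' 1 MPa, roughly twice the bubble's resonance frequency) the radial
#' oscillation period-doubles and the echo contains the subharmonic `f0/2`
#' and ultraharmonics `3 f0/2`, `5 f0/2`, ... in addition to harmonics.
#'
#' @param burst The driving pressure burst, an `rf_signal` in Pa (see
#'   [make_burst()]).
#' @param params A [bubble_params()] object.
#' @param normalize If `TRUE` (default), scale the echo to unit peak
#'   amplitude; the raw scale is kept in the `scale` attribute.
#' @param rtol,atol Relative / absolute integration tolerances passed to the
#'   stiff-capable solver (absolute tolerance applies to both R in m and
#'   Rdot in m/s).
#' @param collapse_radius Fraction of `r0` below which the bubble is deemed
#'   collapsed; integration stops with an error naming the collapse time.
#' @return An `rf_signal` on the burst's time grid with attributes `radius`
#'   (the radius trace R(t) in m), `params`, and `scale` (peak of the
#'   unnormalized echo).
#' @examples
#' \donttest{
#' b <- make_burst()
#' echo <- simulate_echo(b, bubble_params())
#' sp <- signal_spectrum(echo)
#' }
#' @export
simulate_echo <- function(burst, params = bubble_params(), normalize = TRUE,
                          rtol = 1e-8, atol = 1e-12, collapse_radius = 0.01) {
  stopifnot(inherits(params, "bubble_params"))
  burst <- as_rf_signal(burst)
  if (!all(is.finite(burst$value))) stop("Burst contains non-finite values.")
  fs <- attr(burst, "fs")
  tt <- burst$time - burst$time[1]
  drive <- stats::splinefun(tt, burst$value, method = "natural")
  p <- params
  rhs <- function(t, state, parms) {
    list(c(state[2], bubble_accel(state[1], state[2], drive(t), p)))
  }
  rootfun <- function(t, state, parms) state[1] - collapse_radius * p$r0
  sol <- deSolve::ode(
    y = c(R = p$r0, Rd = 0), times = tt, func = rhs, parms = NULL,
    method = "lsodar", rtol = rtol, atol = c(atol, atol),
    rootfunc = rootfun, maxsteps = 100000
  )
  troot <- attr(sol, "troot")
  if (!is.null(troot) && length(troot) > 0)
    stop(sprintf("Bubble collapse (R < %g r0) at t = %.4g s; reduce the drive pressure.",
                 collapse_radius, troot[1]))
  if (nrow(sol) < length(tt) || any(!is.finite(sol[, "R"]))) {
    di <- attr(sol, "istate")
    stop(sprintf(
      "ODE solver failed after %d of %d output times (istate = %s). Try loosening rtol/atol.",
      nrow(sol), length(tt), if (is.null(di)) "?" else di[1]))
  }
  R <- sol[, "R"]; Rd <- sol[, "Rd"]
  Rdd <- bubble_accel(R, Rd, drive(tt), p)
  ps <- p$liquid_density * (R^2 * Rdd + 2 * R * Rd^2) * p$n_bubbles
  scale <- max(abs(ps))
  out <- rf_signal(if (normalize && scale > 0) ps / scale else ps, fs,
                   t0 = burst$time[1])
  attr(out, "radius") <- R
  attr(out, "params") <- params
  attr(out, "scale") <- scale
  out
}
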
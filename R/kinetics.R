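#' Gating-variable kinetics
#'
#' Describes one Hodgkin-Huxley gating variable by a Boltzmann steady-state
#' curve and a bell-shaped voltage-dependent time constant
#' \deqn{x_\infty(V) = 1 / (1 + e^{-(V - V_h)/k}), \qquad
#'       \tau(V) = \tau_{min} + \tau_{amp} / \cosh((V - V_\tau)/k_\tau).}
#' A negative `slope` gives an inactivation gate (monotone decreasing).
#' Calcium sensitivity is optional: `ca_mode = "mult"` multiplies the
#' voltage-dependent steady state by the Michaelis factor `ca / (ca + kd)`
#' (used for KCa), and `ca_mode = "ca"` replaces it entirely (purely
#' calcium-gated, used for AHP; its time constant is voltage independent).
#'
#' @param vh half-activation voltage (mV).
#' @param slope Boltzmann slope factor (mV); negative for inactivation.
#' @param tau_min minimum time constant (ms), must be > 0.
#' @param tau_amp amplitude of the bell-shaped tau component (ms), >= 0.
#' @param tau_vh voltage of the tau peak (mV); defaults to `vh`.
#' @param tau_k width of the tau bell (mV), > 0.
#' @param exponent integer power the gate enters the conductance with.
#' @param ca_mode one of `"none"`, `"mult"`, `"ca"` (see Details).
#' @param kd half-saturation calcium concentration (mM) for calcium-sensitive
#'   modes.
#' @return an object of class `gate_kinetics`.
#' @seealso [gate_steady_state()], [gate_time_constant()], [advance_gate()]
#' @export
gate_kinetics <- function(vh = 0, slope = 10, tau_min = 1, tau_amp = 0,
                          tau_vh = vh, tau_k = 2 * abs(slope),
                          exponent = 1L,
                          ca_mode = c("none", "mult", "ca"), kd = 5e-4) {
  ca_mode <- match.arg(ca_mode)
  .check_scalar(vh, "vh")
  if (ca_mode != "ca") .check_scalar(slope, "slope")
  .check_scalar(tau_min, "tau_min", positive = TRUE)
  .check_scalar(tau_amp, "tau_amp", nonneg = TRUE)
  .check_scalar(tau_k, "tau_k", positive = TRUE)
  .check_scalar(kd, "kd", positive = TRUE)
  if (!is.numeric(exponent) || exponent < 1 || exponent != round(exponent))
    .stop_validation("'exponent' must be a positive integer")
  structure(list(vh = vh, slope = slope, tau_min = tau_min,
                 tau_amp = tau_amp, tau_vh = tau_vh, tau_k = tau_k,
                 exponent = as.integer(exponent), ca_mode = ca_mode, kd = kd),
            class = "gate_kinetics")
}

#' Steady-state value of a gating variable
#'
#' @param kinetics a [gate_kinetics()] object.
#' @param voltage membrane voltage (mV); vectorised.
#' @param calcium intracellular free calcium (mM); only used by
#'   calcium-sensitive gates, where an absent value means no calcium and
#'   hence no activation.
#' @return dimensionless value(s) in `[0, 1]`.
#' @export
gate_steady_state <- function(kinetics, voltage, calcium = 0) {
  stopifnot(inherits(kinetics, "gate_kinetics"))
  if (any(!is.finite(voltage)))
    .stop_validation("'voltage' must be finite")
  caf <- calcium / (calcium + kinetics$kd)
  switch(kinetics$ca_mode,
    none = 1 / (1 + exp(-(voltage - kinetics$vh) / kinetics$slope)),
    mult = caf / (1 + exp(-(voltage - kinetics$vh) / kinetics$slope)),
    ca   = rep_len(caf, length(voltage)))
}

#' Voltage-dependent time constant of a gating variable
#'
#' @inheritParams gate_steady_state
#' @return time constant(s) in ms, strictly positive.
#' @export
gate_time_constant <- function(kinetics, voltage) {
  stopifnot(inherits(kinetics, "gate_kinetics"))
  kinetics$tau_min +
    kinetics$tau_amp / cosh((voltage - kinetics$tau_vh) / kinetics$tau_k)
}

#' Advance a gating variable by one explicit Euler step
#'
#' Applies `x' = x + dt * (x_inf - x) / tau` and clamps the result to
#' `[0, 1]` (an overshooting step cannot leave the admissible range).
#'
#' @param state current gate value (dimensionless, in `[0, 1]`).
#' @param kinetics a [gate_kinetics()] object.
#' @param voltage membrane voltage (mV) at the start of the step.
#' @param dt step size (ms), must be > 0.
#' @param calcium intracellular calcium (mM) for calcium-sensitive gates.
#' @return the updated gate value.
#' @export
advance_gate <- function(state, kinetics, voltage, dt, calcium = 0) {
  .check_scalar(dt, "dt", positive = TRUE)
  xinf <- gate_steady_state(kinetics, voltage, calcium)
  tau <- gate_time_constant(kinetics, voltage)
  if (dt >= tau)
    warning(sprintf("dt = %g ms is not below the gate time constant %g ms",
                    dt, tau), call. = FALSE)
  pmin(1, pmax(0, state + dt * (xinf - state) / tau))
}
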
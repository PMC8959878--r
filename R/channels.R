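#' Nernst equilibrium potential
#'
#' \deqn{E = \frac{RT}{zF} \ln\frac{[X]_{out}}{[X]_{in}}} expressed in mV.
#'
#' @param valence ionic valence z (nonzero integer; negative for anions).
#' @param conc_out,conc_in extracellular / intracellular concentration (mM),
#'   both > 0.
#' @param temperature absolute temperature (K).
#' @return equilibrium potential in mV.
#' @examples
#' nernst_potential(1, 145, 12)   # sodium, mammalian defaults
#' nernst_potential(2, 2, 5e-5)   # calcium
#' @export
nernst_potential <- function(valence, conc_out, conc_in, temperature = 295) {
  if (!is.numeric(valence) || length(valence) != 1L || valence == 0)
    .stop_validation("'valence' must be a nonzero integer")
  .check_scalar(conc_out, "conc_out", positive = TRUE)
  .check_scalar(conc_in, "conc_in", positive = TRUE)
  .check_scalar(temperature, "temperature", positive = TRUE)
  1000 * .RGAS * temperature / (valence * .FARADAY) * log(conc_out / conc_in)
}

#' Ohmic channel mechanism
#'
#' A channel whose current is `g_max * prod(gate_i ^ exponent_i) * (V - E)`,
#' in nA when `g_max` is in uS and voltages in mV.
#'
#' @param name stable channel key (e.g. `"na"`).
#' @param g_max maximal conductance (uS), >= 0.
#' @param reversal reversal potential (mV).
#' @param gates named list of [gate_kinetics()] objects (may be empty for a
#'   pure leak).
#' @return an object of class `c("ohmic_channel", "channel")`.
#' @export
ohmic_channel <- function(name, g_max, reversal, gates = list()) {
  .check_scalar(g_max, "g_max", nonneg = TRUE)
  .check_scalar(reversal, "reversal")
  structure(list(name = name, g_max = g_max, reversal = reversal,
                 gates = gates),
            class = c("ohmic_channel", "channel"))
}

#' Constant-field (GHK) channel mechanism
#'
#' A channel whose open-channel current follows the Goldman-Hodgkin-Katz
#' flux equation. The permeability scale `p_max` lumps membrane area and
#' unit conversions so that the returned current is in nA with
#' concentrations in mM and voltage in mV (units nA/mM); see
#' [ghk_current()].
#'
#' @param name stable channel key (e.g. `"ca_t"`).
#' @param p_max permeability scale (nA/mM), >= 0.
#' @param valence ionic valence (+2 for calcium).
#' @param conc_in,conc_out intracellular / extracellular concentration (mM).
#' @param gates named list of [gate_kinetics()] objects (no inactivation
#'   gate for a non-inactivating channel such as CaL).
#' @return an object of class `c("ghk_channel", "channel")`.
#' @export
ghk_channel <- function(name, p_max, valence = 2L, conc_in, conc_out,
                        gates = list()) {
  .check_scalar(p_max, "p_max", nonneg = TRUE)
  if (!is.numeric(valence) || length(valence) != 1L || valence == 0)
    .stop_validation("'valence' must be a nonzero integer")
  .check_scalar(conc_in, "conc_in", positive = TRUE)
  .check_scalar(conc_out, "conc_out", positive = TRUE)
  structure(list(name = name, p_max = p_max, valence = as.integer(valence),
                 conc_in = conc_in, conc_out = conc_out, gates = gates),
            class = c("ghk_channel", "channel"))
}

#' Two-component A-type potassium channel
#'
#' A transient potassium current that inactivates with two time constants,
#' modelled as two weighted (m, h) gating components sharing one maximal
#' conductance: the first component contributes 60% of the gating value
#' and the second 40%, so the conductance is
#' `g_max * (0.6 * m1 * h1 + 0.4 * m2 * h2)`.
#'
#' @param name stable channel key (default `"a"`).
#' @param g_max maximal conductance (uS).
#' @param reversal reversal potential (mV), typically the potassium
#'   equilibrium potential.
#' @param m1,h1,m2,h2 [gate_kinetics()] for each component's activation and
#'   inactivation gate.
#' @param w1 weight of the first component; the second weighs `1 - w1`.
#' @return an object of class `c("a_current_channel", "channel")`.
#' @export
a_current_channel <- function(name = "a", g_max, reversal, m1, h1, m2, h2,
                              w1 = 0.6) {
  .check_scalar(g_max, "g_max", nonneg = TRUE)
  .check_scalar(w1, "w1", nonneg = TRUE)
  if (w1 > 1) .stop_validation("'w1' must be in [0, 1]")
  structure(list(name = name, g_max = g_max, reversal = reversal,
                 gates = list(m1 = m1, h1 = h1, m2 = m2, h2 = h2),
                 w1 = w1, w2 = 1 - w1),
            class = c("a_current_channel", "channel"))
}

# GHK flux factor u * (ci - co * exp(-u)) / (1 - exp(-u)) in mM, with a
# fourth-order series branch near u = 0 where the direct form is 0/0.
.ghk_flux <- function(u, conc_in, conc_out) {
  small <- abs(u) < 1e-4
  out <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    d <- conc_in - conc_out
    out[small] <- d + us * (conc_in + conc_out) / 2 +
      us^2 * d / 12 - us^4 * d / 720
  }
  big <- u < -700                       # exp(-u) would overflow
  mid <- !small & !big
  if (any(mid)) {
    ub <- u[mid]
    out[mid] <- ub * (conc_in - conc_out * exp(-ub)) / (-expm1(-ub))
  }
  # asymptote for extreme hyperpolarization: flux -> u * conc_out
  if (any(big)) out[big] <- u[big] * conc_out
  out
}

#' GHK constant-field current
#'
#' Computes `gate_product * p_max * z * u * (c_in - c_out e^{-u}) /
#' (1 - e^{-u})` with `u = zFV/RT`; a fourth-order series expansion is used
#' for `|u| < 1e-4` so the current is continuous through V = 0. The current
#' is exactly zero at the ion's Nernst potential and follows the outward-
#' positive sign convention.
#'
#' @param channel a [ghk_channel()].
#' @param voltage membrane voltage (mV); vectorised.
#' @param temperature absolute temperature (K).
#' @param gates numeric vector of current gate values, one per entry of
#'   `channel$gates` (raised to each gate's exponent); defaults to fully
#'   open.
#' @return current in nA (outward positive).
#' @export
ghk_current <- function(channel, voltage, temperature = 295,
                        gates = rep(1, length(channel$gates))) {
  stopifnot(inherits(channel, "ghk_channel"))
  .check_scalar(temperature, "temperature", positive = TRUE)
  gp <- 1
  if (length(channel$gates)) {
    expn <- vapply(channel$gates, `[[`, integer(1), "exponent")
    gp <- prod(gates^expn)
  }
  u <- channel$valence * .FARADAY * (voltage / 1000) /
    (.RGAS * temperature)
  gp * channel$p_max * channel$valence *
    .ghk_flux(u, channel$conc_in, channel$conc_out)
}

#' Ohmic channel current
#'
#' `g_max * prod(gate_i ^ exponent_i) * (V - E)`; uS times mV gives nA.
#'
#' @param channel an [ohmic_channel()].
#' @param gates numeric vector of gate values matching `channel$gates`
#'   (fully open by default).
#' @param voltage membrane voltage (mV); vectorised.
#' @return current in nA (outward positive).
#' @export
ohmic_current <- function(channel, gates = rep(1, length(channel$gates)),
                          voltage) {
  stopifnot(inherits(channel, "ohmic_channel"))
  gp <- 1
  if (length(channel$gates)) {
    expn <- vapply(channel$gates, `[[`, integer(1), "exponent")
    gp <- prod(gates^expn)
  }
  channel$g_max * gp * (voltage - channel$reversal)
}

#' A-current with two weighted gating components
#'
#' Current is `g_max * (w1 * m1 * h1 + w2 * m2 * h2) * (V - E)` with the
#' default weights 0.6 and 0.4.
#'
#' @param channel an [a_current_channel()].
#' @param m1,h1,m2,h2 gate values of the two components.
#' @param voltage membrane voltage (mV); vectorised.
#' @return current in nA (outward positive).
#' @export
a_current <- function(channel, m1, h1, m2, h2, voltage) {
  stopifnot(inherits(channel, "a_current_channel"))
  g <- channel$g_max * (channel$w1 * m1 * h1 + channel$w2 * m2 * h2)
  g * (voltage - channel$reversal)
}

#' Intracellular calcium pool
#'
#' A single well-mixed pool fed by the calcium currents (CaT + CaL) and
#' drained first-order toward its resting level:
#' `ca' = -influx_scale * i_ca - (ca - ca_rest) / tau_ca`.
#' Inward (negative) calcium current raises the pool. The pool gates the
#' KCa and AHP currents; it does not feed back on the GHK concentration
#' terms, which stay at their configured values.
#'
#' @param ca current free calcium (mM); defaults to the resting level.
#' @param ca_rest resting free calcium (mM).
#' @param tau_ca removal time constant (ms).
#' @param influx_scale conversion from current to concentration rate
#'   (mM / (nA * ms)).
#' @return an object of class `calcium_pool`.
#' @export
calcium_pool <- function(ca = ca_rest, ca_rest = 5e-5, tau_ca = 20,
                         influx_scale = 5e-4) {
  .check_scalar(ca_rest, "ca_rest", positive = TRUE)
  .check_scalar(tau_ca, "tau_ca", positive = TRUE)
  .check_scalar(influx_scale, "influx_scale", nonneg = TRUE)
  .check_scalar(ca, "ca", nonneg = TRUE)
  structure(list(ca = ca, ca_rest = ca_rest, tau_ca = tau_ca,
                 influx_scale = influx_scale),
            class = "calcium_pool")
}

#' Advance the calcium pool by one Euler step
#'
#' @param pool a [calcium_pool()].
#' @param i_ca_total total calcium current (nA), the sum of the CaT and CaL
#'   currents (negative = inward).
#' @param dt step size (ms), > 0.
#' @return the updated pool (free calcium floored at 0).
#' @export
update_calcium <- function(pool, i_ca_total, dt) {
  stopifnot(inherits(pool, "calcium_pool"))
  .check_scalar(dt, "dt", positive = TRUE)
  ca <- pool$ca + dt * (-pool$influx_scale * i_ca_total -
                          (pool$ca - pool$ca_rest) / pool$tau_ca)
  pool$ca <- max(0, ca)
  pool
}

#' Default ionic concentrations
#'
#' Mammalian cell values (mM): Na 145/12, K 4/140, Cl 110/10, Ca 2/5e-5
#' (out/in).
#'
#' @return a named list with elements `na`, `k`, `cl`, `ca`, each a list
#'   with `out` and `in_` concentrations in mM.
#' @export
default_ions <- function() {
  list(na = list(out = 145, in_ = 12),
       k  = list(out = 4,   in_ = 140),
       cl = list(out = 110, in_ = 10),
       ca = list(out = 2,   in_ = 5e-5))
}

#' The channel roster keys, in recording order
#' @return character vector of the 11 channel keys.
#' @export
channel_keys <- function() .CHANNEL_KEYS

#' Build the default 11-channel roster
#'
#' Constructs the full set of mechanisms with mammalian room-temperature
#' defaults: voltage-gated Na (m^3 h), delayed-rectifier K (n^4), ohmic Cl,
#' Na and K leaks, the two-component A current, the slow M current, the
#' calcium-gated AHP and KCa currents, and GHK CaT (m^2 h) and
#' non-inactivating CaL (m^2) calcium channels. Reversal potentials are
#' derived from `ions` via the Nernst equation. All kinetic constants are
#' plain list entries and can be edited before passing the roster to
#' [membrane_model()].
#'
#' @param ions ionic concentrations as returned by [default_ions()].
#' @param temperature absolute temperature (K) used for the Nernst-derived
#'   reversals.
#' @return a named list of 11 channel objects in roster order.
#' @export
default_channels <- function(ions = default_ions(), temperature = 295) {
  e_na <- nernst_potential(1, ions$na$out, ions$na$in_, temperature)
  e_k  <- nernst_potential(1, ions$k$out, ions$k$in_, temperature)
  e_cl <- nernst_potential(-1, ions$cl$out, ions$cl$in_, temperature)

  list(
    na = ohmic_channel("na", g_max = 1.2, reversal = e_na, gates = list(
      m = gate_kinetics(vh = -40, slope = 5.5, tau_min = 0.04, tau_amp = 0.25,
                        tau_vh = -40, tau_k = 15, exponent = 3L),
      h = gate_kinetics(vh = -60, slope = -7, tau_min = 0.5, tau_amp = 7,
                        tau_vh = -60, tau_k = 12))),
    k = ohmic_channel("k", g_max = 0.36, reversal = e_k, gates = list(
      n = gate_kinetics(vh = -33, slope = 10, tau_min = 0.8, tau_amp = 4,
                        tau_vh = -50, tau_k = 25, exponent = 4L))),
    cl = ohmic_channel("cl", g_max = 0.001, reversal = e_cl),
    na_leak = ohmic_channel("na_leak", g_max = 0.0008, reversal = e_na),
    k_leak = ohmic_channel("k_leak", g_max = 0.004, reversal = e_k),
    a = a_current_channel("a", g_max = 0.1, reversal = e_k,
      m1 = gate_kinetics(vh = -45, slope = 10, tau_min = 0.5, tau_amp = 1,
                         tau_vh = -45, tau_k = 20),
      h1 = gate_kinetics(vh = -78, slope = -6, tau_min = 5, tau_amp = 20,
                         tau_vh = -78, tau_k = 15),
      m2 = gate_kinetics(vh = -45, slope = 10, tau_min = 0.5, tau_amp = 1,
                         tau_vh = -45, tau_k = 20),
      h2 = gate_kinetics(vh = -78, slope = -6, tau_min = 50, tau_amp = 100,
                         tau_vh = -78, tau_k = 15)),
    m = ohmic_channel("m", g_max = 0.02, reversal = e_k, gates = list(
      m = gate_kinetics(vh = -35, slope = 9, tau_min = 40, tau_amp = 60,
                        tau_vh = -35, tau_k = 20))),
    ahp = ohmic_channel("ahp", g_max = 0.03, reversal = e_k, gates = list(
      q = gate_kinetics(tau_min = 80, ca_mode = "ca", kd = 1e-3,
                        exponent = 2L))),
    kca = ohmic_channel("kca", g_max = 0.05, reversal = e_k, gates = list(
      m = gate_kinetics(vh = -20, slope = 12, tau_min = 2, tau_amp = 10,
                        tau_vh = -20, tau_k = 20, ca_mode = "mult",
                        kd = 5e-4))),
    ca_t = ghk_channel("ca_t", p_max = 0.02, valence = 2L,
                       conc_in = ions$ca$in_, conc_out = ions$ca$out,
                       gates = list(
      m = gate_kinetics(vh = -50, slope = 6, tau_min = 0.5, tau_amp = 2,
                        tau_vh = -50, tau_k = 15, exponent = 2L),
      h = gate_kinetics(vh = -75, slope = -6, tau_min = 10, tau_amp = 30,
                        tau_vh = -75, tau_k = 15))),
    ca_l = ghk_channel("ca_l", p_max = 0.02, valence = 2L,
                       conc_in = ions$ca$in_, conc_out = ions$ca$out,
                       gates = list(
      m = gate_kinetics(vh = -20, slope = 7, tau_min = 0.5, tau_amp = 2,
                        tau_vh = -20, tau_k = 15, exponent = 2L)))
  )
}
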
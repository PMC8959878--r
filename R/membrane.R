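# Flatten the channel list into numeric parameter tables so the inner
# integration loop is plain vector arithmetic (no S3 dispatch per step).
.compile_model <- function(channels, calcium, capacitance, temperature) {
  keys <- names(channels)
  n_ch <- length(channels)
  type <- integer(n_ch)            # 1 ohmic, 2 ghk, 3 a-current
  gmax <- numeric(n_ch)            # g_max (uS) or p_max (nA/mM)
  erev <- numeric(n_ch)            # reversal (mV); Nernst potential for GHK
  zval <- integer(n_ch); ci <- numeric(n_ch); co <- numeric(n_ch)
  w1 <- numeric(n_ch); w2 <- numeric(n_ch)

  gname <- character(0)
  gch <- integer(0)                # owning channel index per gate
  vh <- slope <- tau_min <- tau_amp <- tau_vh <- tau_k <- kd <- numeric(0)
  expn <- camode <- integer(0)     # camode: 0 none, 1 mult, 2 ca
  gidx <- vector("list", n_ch)     # gate indices per channel

  for (i in seq_len(n_ch)) {
    ch <- channels[[i]]
    gmax[i] <- if (inherits(ch, "ghk_channel")) ch$p_max else ch$g_max
    if (inherits(ch, "a_current_channel")) {
      type[i] <- 3L; erev[i] <- ch$reversal; w1[i] <- ch$w1; w2[i] <- ch$w2
    } else if (inherits(ch, "ghk_channel")) {
      type[i] <- 2L
      zval[i] <- ch$valence; ci[i] <- ch$conc_in; co[i] <- ch$conc_out
      erev[i] <- nernst_potential(ch$valence, ch$conc_out, ch$conc_in,
                                  temperature)
    } else {
      type[i] <- 1L; erev[i] <- ch$reversal
    }
    idx <- integer(0)
    for (gn in names(ch$gates)) {
      g <- ch$gates[[gn]]
      gname <- c(gname, paste(keys[i], gn, sep = "."))
      gch <- c(gch, i)
      vh <- c(vh, g$vh); slope <- c(slope, g$slope)
      tau_min <- c(tau_min, g$tau_min); tau_amp <- c(tau_amp, g$tau_amp)
      tau_vh <- c(tau_vh, g$tau_vh); tau_k <- c(tau_k, g$tau_k)
      kd <- c(kd, g$kd); expn <- c(expn, g$exponent)
      camode <- c(camode, match(g$ca_mode, c("none", "mult", "ca")) - 1L)
      idx <- c(idx, length(gname))
    }
    gidx[[i]] <- idx
  }
  list(keys = keys, n_ch = n_ch, type = type, gmax = gmax, erev = erev,
       z = zval, ci = ci, co = co, w1 = w1, w2 = w2,
       gname = gname, gch = gch, gidx = gidx,
       vh = vh, slope = slope, tau_min = tau_min, tau_amp = tau_amp,
       tau_vh = tau_vh, tau_k = tau_k, kd = kd, expn = expn,
       camode = camode, n_gates = length(gname),
       capacitance = capacitance, temperature = temperature,
       ca_rest = calcium$ca_rest, tau_ca = calcium$tau_ca,
       influx_scale = calcium$influx_scale,
       ghk_scale = .FARADAY / (1000 * .RGAS))   # u = z * ghk_scale * V / T
}

#' Single-compartment membrane model
#'
#' Assembles a set of channel mechanisms, an intracellular calcium pool and
#' a membrane capacitance into one compartment obeying Kirchhoff's current
#' law. The default model carries the full 11-channel roster of
#' [default_channels()].
#'
#' @param capacitance membrane capacitance (nF), > 0; default 0.01.
#' @param temperature absolute temperature (K); used by the Nernst and GHK
#'   relations.
#' @param ions ionic concentrations ([default_ions()]).
#' @param channels named list of channel objects; defaults to the full
#'   roster. A subset (e.g. Na + K + leak) is a valid model.
#' @param calcium a [calcium_pool()].
#' @return an object of class `membrane_model`.
#' @examples
#' mod <- membrane_model()
#' mod
#' @export
membrane_model <- function(capacitance = 0.01, temperature = 295,
                           ions = default_ions(),
                           channels = default_channels(ions, temperature),
                           calcium = calcium_pool()) {
  .check_scalar(capacitance, "capacitance", positive = TRUE)
  .check_scalar(temperature, "temperature", positive = TRUE)
  stopifnot(inherits(calcium, "calcium_pool"))
  if (length(channels)) {
    if (is.null(names(channels)) || anyDuplicated(names(channels)))
      .stop_validation("channel keys must be unique and named")
    ok <- vapply(channels, inherits, logical(1), "channel")
    if (!all(ok)) .stop_validation("all channels must be channel objects")
  }
  m <- structure(list(capacitance = capacitance, temperature = temperature,
                      ions = ions, channels = channels, calcium = calcium),
                 class = "membrane_model")
  m$compiled <- .compile_model(channels, calcium, capacitance, temperature)
  m
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("Single-compartment membrane: %d channels, C = %g nF, T = %g K\n",
              length(x$channels), x$capacitance, x$temperature))
  for (k in names(x$channels)) {
    ch <- x$channels[[k]]
    lab <- if (inherits(ch, "ghk_channel"))
      sprintf("GHK p_max = %g nA/mM (z = %+d)", ch$p_max, ch$valence)
    else sprintf("g_max = %g uS, E = %.2f mV", ch$g_max, ch$reversal)
    cat(sprintf("  %-8s %s, %d gate(s)\n", k, lab, length(ch$gates)))
  }
  invisible(x)
}

# Gate steady states and time constants for all gates at scalar (v, ca).
.gates_inf_tau <- function(cm, v, ca) {
  xinf <- 1 / (1 + exp(-(v - cm$vh) / cm$slope))
  caf <- ca / (ca + cm$kd)
  mult <- cm$camode == 1L
  pure <- cm$camode == 2L
  if (any(mult)) xinf[mult] <- xinf[mult] * caf[mult]
  if (any(pure)) xinf[pure] <- caf[pure]
  tau <- cm$tau_min + cm$tau_amp / cosh((v - cm$tau_vh) / cm$tau_k)
  list(xinf = xinf, tau = tau)
}

# Per-channel currents and conductances at scalar (v, gates, ca).
# Conductance is g_max * gate-product for ohmic/A channels and the chord
# conductance I / (V - E_Nernst) for GHK channels.
.currents_fast <- function(cm, v, gates) {
  gp <- numeric(cm$n_ch)
  gpow <- gates^cm$expn
  for (i in seq_len(cm$n_ch)) {
    idx <- cm$gidx[[i]]
    if (cm$type[i] == 3L) {
      gp[i] <- cm$w1[i] * gates[idx[1L]] * gates[idx[2L]] +
        cm$w2[i] * gates[idx[3L]] * gates[idx[4L]]
    } else if (length(idx)) {
      gp[i] <- prod(gpow[idx])
    } else gp[i] <- 1
  }
  cur <- numeric(cm$n_ch)
  cond <- numeric(cm$n_ch)
  oh <- cm$type != 2L
  if (any(oh)) {
    cond[oh] <- cm$gmax[oh] * gp[oh]
    cur[oh] <- cond[oh] * (v - cm$erev[oh])
  }
  gk <- which(cm$type == 2L)
  for (i in gk) {
    u <- cm$z[i] * cm$ghk_scale * v / cm$temperature
    cur[i] <- cm$gmax[i] * gp[i] * cm$z[i] * .ghk_flux(u, cm$ci[i], cm$co[i])
    drive <- v - cm$erev[i]
    cond[i] <- if (abs(drive) < 1e-9) 0 else cur[i] / drive
  }
  list(currents = cur, conductances = cond,
       i_ca = sum(cur[gk]))
}

#' Membrane state
#'
#' Snapshot of the compartment: time, voltage, all gate values (named
#' `channel.gate`), free calcium and the last net current (the clamp
#' current in voltage-clamp mode).
#'
#' @param model a [membrane_model()].
#' @param v0 initial voltage (mV).
#' @param ca0 initial free calcium (mM); `NULL` sets the calcium pool to
#'   its steady state given the calcium currents at `v0`.
#' @return an object of class `membrane_state` with every gate at its
#'   steady-state value for (`v0`, calcium), so the state is a fixed point
#'   of the gate dynamics at constant `v0`.
#' @export
init_state <- function(model, v0 = -65, ca0 = NULL) {
  stopifnot(inherits(model, "membrane_model"))
  if (!is.finite(v0)) .stop_validation("'v0' must be finite")
  cm <- model$compiled
  if (is.null(ca0)) {
    # calcium currents depend on V only (their gates are voltage-gated),
    # so the pool steady state is available in closed form
    it0 <- .gates_inf_tau(cm, v0, cm$ca_rest)
    cc0 <- .currents_fast(cm, v0, it0$xinf)
    ca0 <- max(0, cm$ca_rest - cm$influx_scale * cc0$i_ca * cm$tau_ca)
  }
  it <- .gates_inf_tau(cm, v0, ca0)
  gates <- it$xinf
  names(gates) <- cm$gname
  structure(list(time = 0, voltage = v0, gates = gates, calcium = ca0,
                 last_net_current = NA_real_),
            class = "membrane_state")
}

.check_state <- function(model, state) {
  stopifnot(inherits(model, "membrane_model"),
            inherits(state, "membrane_state"))
  if (!identical(names(state$gates), model$compiled$gname))
    .stop_validation(paste0("state gates do not match the model's channels",
                            " (expected ",
                            paste(model$compiled$gname, collapse = ", "), ")"))
}

#' Per-channel ionic currents
#'
#' Evaluates every channel's instantaneous current at the given state,
#' outward positive.
#'
#' @param model a [membrane_model()].
#' @param state a [init_state()] membrane state consistent with the model.
#' @return named numeric vector of currents (nA), one per channel key.
#' @export
channel_currents <- function(model, state) {
  .check_state(model, state)
  cm <- model$compiled
  cc <- .currents_fast(cm, state$voltage, unname(state$gates))
  stats::setNames(cc$currents, cm$keys)
}

# One explicit Euler step; all right-hand sides evaluated at the step start.
# mode 1 = current clamp (stim in nA), 2 = voltage clamp (stim in mV).
.step <- function(cm, v, gates, ca, stim, dt, mode, clamp_sign = -1) {
  if (mode == 2L) v <- stim                       # ideal clamp: pin first
  cc <- .currents_fast(cm, v, gates)
  it <- .gates_inf_tau(cm, v, ca)
  gates_new <- gates + dt * (it$xinf - gates) / it$tau
  gates_new[gates_new < 0] <- 0
  gates_new[gates_new > 1] <- 1
  ca_new <- ca + dt * (-cm$influx_scale * cc$i_ca - (ca - cm$ca_rest) / cm$tau_ca)
  if (ca_new < 0) ca_new <- 0
  if (mode == 1L) {
    v_new <- v + dt / cm$capacitance * (stim - sum(cc$currents))
    inet <- stim
  } else {
    v_new <- stim
    inet <- clamp_sign * sum(cc$currents)
  }
  list(v = v_new, gates = gates_new, ca = ca_new, inet = inet, cc = cc)
}

#' Advance the membrane one step under current clamp
#'
#' Explicit Euler update of Kirchhoff's law
#' `dV/dt = (i_applied - sum of channel currents) / C`; gates and the
#' calcium pool advance using the start-of-step voltage and currents.
#'
#' @param model a [membrane_model()].
#' @param state the current [init_state()] membrane state.
#' @param i_applied applied current (nA, depolarising positive).
#' @param dt step size (ms), > 0.
#' @return the updated `membrane_state`.
#' @export
step_current_clamp <- function(model, state, i_applied, dt) {
  .check_state(model, state)
  .check_scalar(dt, "dt", positive = TRUE)
  cm <- model$compiled
  s <- .step(cm, state$voltage, unname(state$gates), state$calcium,
             i_applied, dt, 1L)
  if (!is.finite(s$v))
    .stop_numeric(sprintf(
      "non-finite voltage after current-clamp step (dt = %g ms); reduce dt",
      dt))
  state$voltage <- s$v
  state$gates[] <- s$gates
  state$calcium <- s$ca
  state$time <- state$time + dt
  state$last_net_current <- s$inet
  state
}

#' Advance the membrane one step under voltage clamp
#'
#' The voltage is pinned to `v_hold` (ideal clamp, instantaneous settling);
#' gates and calcium advance at `v_hold`, and the recorded net current is
#' `clamp_sign * sum(channel currents)` — the default `-1` reports the
#' current the amplifier injects to hold the membrane.
#'
#' @param model a [membrane_model()].
#' @param state the current membrane state.
#' @param v_hold holding voltage (mV).
#' @param dt step size (ms), > 0.
#' @param clamp_sign `-1` (default) or `+1`, the sign convention for the
#'   recorded clamp current.
#' @return the updated `membrane_state` with `last_net_current` set.
#' @export
step_voltage_clamp <- function(model, state, v_hold, dt, clamp_sign = -1) {
  .check_state(model, state)
  .check_scalar(dt, "dt", positive = TRUE)
  cm <- model$compiled
  s <- .step(cm, state$voltage, unname(state$gates), state$calcium,
             v_hold, dt, 2L, clamp_sign)
  state$voltage <- s$v
  state$gates[] <- s$gates
  state$calcium <- s$ca
  state$time <- state$time + dt
  state$last_net_current <- s$inet
  state
}

# Net steady-state membrane current at voltage v (gates and calcium at
# their self-consistent steady state).
.net_steady_current <- function(cm, v) {
  it0 <- .gates_inf_tau(cm, v, cm$ca_rest)
  cc0 <- .currents_fast(cm, v, it0$xinf)
  ca <- max(0, cm$ca_rest - cm$influx_scale * cc0$i_ca * cm$tau_ca)
  it <- .gates_inf_tau(cm, v, ca)
  sum(.currents_fast(cm, v, it$xinf)$currents)
}

#' Locate the resting potential
#'
#' Finds a voltage in `[lower, upper]` at which the total steady-state
#' membrane current vanishes. The search interval is scanned on a 1 mV
#' grid for a rising zero crossing — net current negative (depolarising)
#' below and positive (repolarising) above, i.e. a *stable* equilibrium —
#' and the crossing is then refined by bisection. An excitable membrane
#' has further zeros (the firing threshold); those are skipped.
#'
#' @param model a [membrane_model()].
#' @param lower,upper search interval (mV); defaults -90 and -40.
#' @param tol voltage tolerance (mV).
#' @return the resting potential (mV).
#' @export
find_rest <- function(model, lower = -90, upper = -40, tol = 1e-9) {
  stopifnot(inherits(model, "membrane_model"))
  cm <- model$compiled
  grid <- seq(lower, upper, by = 1)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  fv <- vapply(grid, function(v) .net_steady_current(cm, v), numeric(1))
  lo <- hi <- NA_real_
  for (i in seq_len(length(grid) - 1L)) {
    if (fv[i] <= 0 && fv[i + 1L] > 0) {
      lo <- grid[i]; hi <- grid[i + 1L]
      flo <- fv[i]
      break
    }
  }
  if (is.na(lo)) {
    cross <- which(sign(fv[-length(fv)]) * sign(fv[-1]) < 0)
    if (!length(cross))
      .stop_validation(sprintf(
        "no zero of the net current bracketed in [%g, %g] mV", lower, upper))
    lo <- grid[cross[1]]; hi <- grid[cross[1] + 1L]
    flo <- fv[cross[1]]
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- .net_steady_current(cm, mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
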
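#' Simulation configuration
#'
#' @param dt integration step (ms), > 0; default 0.01. Values above 0.1 ms
#'   are rejected unless `allow_large_dt = TRUE` (explicit-Euler stability
#'   guard — fast Na kinetics need sub-0.1 ms steps).
#' @param initial_voltage starting voltage (mV); default -65.
#' @param temperature absolute temperature (K) for the GHK/Nernst terms.
#' @param auto_rest if `TRUE`, ignore `initial_voltage` and start from the
#'   numerically located resting potential ([find_rest()]).
#' @param allow_large_dt override the 0.1 ms stability guard.
#' @param clamp_sign sign convention for the recorded voltage-clamp
#'   current: `-1` (default, amplifier current) or `+1` (total membrane
#'   current).
#' @param vc_baseline voltage-mode pre/post behaviour when the protocol
#'   baseline is `NULL`: `"hold"` (default) clamps at the resting
#'   potential, `"free"` lets the membrane run free (current clamp at
#'   0 nA) outside the clamp segment.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, initial_voltage = -65, temperature = 295,
                       auto_rest = FALSE, allow_large_dt = FALSE,
                       clamp_sign = -1, vc_baseline = c("hold", "free")) {
  .check_scalar(dt, "dt", positive = TRUE)
  if (dt > 0.1 && !allow_large_dt)
    .stop_validation(sprintf(
      "dt = %g ms exceeds the 0.1 ms stability guard (set allow_large_dt = TRUE to override)",
      dt))
  .check_scalar(initial_voltage, "initial_voltage")
  .check_scalar(temperature, "temperature", positive = TRUE)
  if (!clamp_sign %in% c(-1, 1))
    .stop_validation("'clamp_sign' must be -1 or +1")
  structure(list(dt = dt, initial_voltage = initial_voltage,
                 temperature = temperature, auto_rest = auto_rest,
                 allow_large_dt = allow_large_dt, clamp_sign = clamp_sign,
                 vc_baseline = match.arg(vc_baseline)),
            class = "sim_config")
}

# Number of samples on [0, total] with uniform spacing dt (guard against
# floating-point shortfall in total/dt).
.n_samples <- function(total, dt) as.integer(floor(total / dt + 1e-9)) + 1L

# Resolve the run setup shared by run_simulation() and reference_run().
.run_setup <- function(model, protocol, config) {
  stopifnot(inherits(model, "membrane_model"), inherits(config, "sim_config"))
  validate_protocol(protocol)
  cm <- model$compiled
  cm$temperature <- config$temperature
  v0 <- config$initial_voltage
  baseline <- protocol$baseline
  free_pre <- FALSE
  if (protocol$mode == "voltage" && is.null(baseline)) {
    if (config$vc_baseline == "hold") {
      baseline <- find_rest(model)
      v0 <- baseline
    } else {
      free_pre <- TRUE
      baseline <- 0       # free-running segments: current clamp at 0 nA
    }
  }
  if (config$auto_rest) v0 <- find_rest(model)
  list(cm = cm, v0 = v0, baseline = baseline, free_pre = free_pre)
}

.new_result <- function(model, protocol, config, times, voltage, net,
                        cur, cond, calcium) {
  keys <- model$compiled$keys
  colnames(cur) <- keys
  colnames(cond) <- keys
  structure(list(times = times, voltage = voltage, net_current = net,
                 currents = cur, conductances = cond, calcium = calcium,
                 channel_keys = keys, mode = protocol$mode,
                 protocol = protocol, config = config),
            class = "clamp_result")
}

#' Run a clamp simulation (forward Euler)
#'
#' Initialises every gate at its steady state for the initial voltage,
#' records the state at t = 0, then advances with the mode-appropriate
#' explicit Euler update, recording voltage, net current and per-channel
#' currents and conductances at every step. Conductance is reported as
#' `g_max * gate product` for ohmic channels (identical to
#' `I / (V - E)`) and as the chord conductance `I / (V - E_Nernst)` for
#' GHK channels (0 where the driving force is below 1e-9 mV).
#'
#' In current mode the recorded net current is the applied current (the
#' quantity the protocol holds); in voltage mode it is the clamp current
#' `clamp_sign * sum(channel currents)`.
#'
#' @param model a [membrane_model()].
#' @param protocol a [clamp_protocol()].
#' @param config a [sim_config()].
#' @return an object of class `clamp_result`; see [as.data.frame.clamp_result()].
#' @examples
#' mod <- membrane_model()
#' res <- run_simulation(mod, default_protocol("current"), sim_config(dt = 0.05))
#' summary(res)
#' @export
run_simulation <- function(model, protocol, config = sim_config()) {
  su <- .run_setup(model, protocol, config)
  cm <- su$cm
  dt <- config$dt
  total <- protocol_duration(protocol)
  n <- .n_samples(total, dt)
  pre_end <- protocol$pre_ms
  clamp_end <- protocol$pre_ms + protocol$clamp_ms
  vmode <- protocol$mode == "voltage"
  amp <- protocol$amplitude
  base <- su$baseline

  st0 <- init_state(model, su$v0)
  v <- st0$voltage; gates <- unname(st0$gates); ca <- st0$calcium

  times <- (seq_len(n) - 1) * dt
  voltage <- numeric(n); net <- numeric(n); calcium <- numeric(n)
  cur <- matrix(0, n, cm$n_ch); cond <- matrix(0, n, cm$n_ch)

  for (i in seq_len(n)) {
    t <- times[i]
    in_clamp <- t >= pre_end && t < clamp_end
    stim <- if (in_clamp) amp else base
    # mode for this step: voltage-clamp protocols may free-run outside the
    # clamp segment when vc_baseline = "free"
    mode_i <- if (!vmode) 1L else if (in_clamp || !su$free_pre) 2L else 1L
    if (mode_i == 2L) v <- stim      # pin before recording (ideal clamp)
    cc <- .currents_fast(cm, v, gates)
    voltage[i] <- v
    cur[i, ] <- cc$currents
    cond[i, ] <- cc$conductances
    calcium[i] <- ca
    net[i] <- if (mode_i == 2L) config$clamp_sign * sum(cc$currents) else stim
    if (i == n) break
    it <- .gates_inf_tau(cm, v, ca)
    gates <- gates + dt * (it$xinf - gates) / it$tau
    gates[gates < 0] <- 0
    gates[gates > 1] <- 1
    ca <- ca + dt * (-cm$influx_scale * cc$i_ca - (ca - cm$ca_rest) / cm$tau_ca)
    if (ca < 0) ca <- 0
    if (mode_i == 1L) {
      v <- v + dt / cm$capacitance * (stim - sum(cc$currents))
      if (!is.finite(v))
        .stop_numeric(sprintf(
          "non-finite voltage at step %d (t = %g ms, dt = %g ms); reduce dt",
          i, t, dt))
    }
  }
  .new_result(model, protocol, config, times, voltage, net, cur, cond, calcium)
}

# Time derivatives of (v, gates, ca) for the reference integrator.
.rhs <- function(cm, v, gates, ca, stim, mode) {
  cc <- .currents_fast(cm, v, gates)
  it <- .gates_inf_tau(cm, v, ca)
  dv <- if (mode == 1L) (stim - sum(cc$currents)) / cm$capacitance else 0
  list(dv = dv,
       dg = (it$xinf - gates) / it$tau,
       dca = -cm$influx_scale * cc$i_ca - (ca - cm$ca_rest) / cm$tau_ca)
}

#' Reference run with a classical 4th-order integrator
#'
#' Integrates the same trajectory with the classical Runge-Kutta scheme at
#' a finer step `dt / refine`, recording on the same sample grid as
#' [run_simulation()]. Intended as an accuracy reference for verifying the
#' Euler solver, not as the production integrator.
#'
#' @inheritParams run_simulation
#' @param refine step refinement factor (default 10): the internal RK4
#'   step is `config$dt / refine`.
#' @return a `clamp_result` on the same time grid as `run_simulation()`.
#' @export
reference_run <- function(model, protocol, config = sim_config(), refine = 10) {
  su <- .run_setup(model, protocol, config)
  cm <- su$cm
  dt <- config$dt
  h <- dt / refine
  total <- protocol_duration(protocol)
  n <- .n_samples(total, dt)
  pre_end <- protocol$pre_ms
  clamp_end <- protocol$pre_ms + protocol$clamp_ms
  vmode <- protocol$mode == "voltage"

  st0 <- init_state(model, su$v0)
  v <- st0$voltage; gates <- unname(st0$gates); ca <- st0$calcium

  times <- (seq_len(n) - 1) * dt
  voltage <- numeric(n); net <- numeric(n); calcium <- numeric(n)
  cur <- matrix(0, n, cm$n_ch); cond <- matrix(0, n, cm$n_ch)

  record <- function(i, v, gates, ca, mode_i, stim) {
    cc <- .currents_fast(cm, v, gates)
    voltage[i] <<- v
    cur[i, ] <<- cc$currents
    cond[i, ] <<- cc$conductances
    calcium[i] <<- ca
    net[i] <<- if (mode_i == 2L) config$clamp_sign * sum(cc$currents) else stim
  }

  for (i in seq_len(n)) {
    t <- times[i]
    in_clamp <- t >= pre_end && t < clamp_end
    stim <- if (in_clamp) protocol$amplitude else su$baseline
    mode_i <- if (!vmode) 1L else if (in_clamp || !su$free_pre) 2L else 1L
    if (mode_i == 2L) v <- stim
    record(i, v, gates, ca, mode_i, stim)
    if (i == n) break
    for (k in seq_len(refine)) {
      k1 <- .rhs(cm, v, gates, ca, stim, mode_i)
      k2 <- .rhs(cm, v + h / 2 * k1$dv, gates + h / 2 * k1$dg,
                 max(0, ca + h / 2 * k1$dca), stim, mode_i)
      k3 <- .rhs(cm, v + h / 2 * k2$dv, gates + h / 2 * k2$dg,
                 max(0, ca + h / 2 * k2$dca), stim, mode_i)
      k4 <- .rhs(cm, v + h * k3$dv, gates + h * k3$dg,
                 max(0, ca + h * k3$dca), stim, mode_i)
      v <- v + h / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
      gates <- gates + h / 6 * (k1$dg + 2 * k2$dg + 2 * k3$dg + k4$dg)
      gates[gates < 0] <- 0
      gates[gates > 1] <- 1
      ca <- max(0, ca + h / 6 * (k1$dca + 2 * k2$dca + 2 * k3$dca + k4$dca))
      if (!is.finite(v))
        .stop_numeric(sprintf(
          "non-finite voltage in reference run at t = %g ms; reduce dt", t))
    }
  }
  .new_result(model, protocol, config, times, voltage, net, cur, cond, calcium)
}

#' Count action potentials by upward threshold crossing
#'
#' A spike is counted each time the voltage trace passes from strictly
#' below the threshold to at or above it.
#'
#' @param trace numeric voltage trace (mV) or a `clamp_result`.
#' @param threshold crossing threshold (mV), default 0.
#' @return integer spike count.
#' @export
spike_count <- function(trace, threshold = 0) {
  if (inherits(trace, "clamp_result")) trace <- trace$voltage
  if (!is.numeric(trace) || length(trace) == 0)
    .stop_validation("'trace' must be a non-empty numeric vector")
  if (length(trace) == 1L) return(0L)
  below <- trace[-length(trace)] < threshold
  above <- trace[-1] >= threshold
  sum(below & above)
}

#' @export
print.clamp_result <- function(x, ...) {
  cat(sprintf("%s-clamp simulation: %d samples over %g ms (dt = %g ms)\n",
              x$mode, length(x$times), max(x$times), x$config$dt))
  cat(sprintf("  voltage range [%.2f, %.2f] mV, %d spike(s) above 0 mV\n",
              min(x$voltage), max(x$voltage), spike_count(x)))
  invisible(x)
}

#' @export
summary.clamp_result <- function(object, ...) {
  peak <- vapply(seq_along(object$channel_keys), function(j)
    object$currents[which.max(abs(object$currents[, j])), j], numeric(1))
  out <- list(mode = object$mode, samples = length(object$times),
              duration_ms = max(object$times), dt_ms = object$config$dt,
              v_min = min(object$voltage), v_max = max(object$voltage),
              spikes = spike_count(object),
              peak_currents_nA = stats::setNames(peak, object$channel_keys))
  class(out) <- "summary.clamp_result"
  out
}

#' @export
print.summary.clamp_result <- function(x, ...) {
  cat(sprintf("%s clamp, %d samples over %g ms (dt = %g ms)\n",
              x$mode, x$samples, x$duration_ms, x$dt_ms))
  cat(sprintf("voltage: [%.2f, %.2f] mV; spikes (0 mV threshold): %d\n",
              x$v_min, x$v_max, x$spikes))
  cat("peak channel currents (nA):\n")
  print(round(x$peak_currents_nA, 6))
  invisible(x)
}

#' Convert a simulation result to the CSV data frame
#'
#' Columns: `time_ms`, `voltage_mV`, `net_current_nA`, then for each
#' channel key in roster order `<key>_current_nA` and
#' `<key>_conductance_uS` (3 + 2 x 11 = 25 columns for the full model).
#'
#' @param x a `clamp_result`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a `data.frame`, one row per sample.
#' @export
as.data.frame.clamp_result <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  df <- data.frame(time_ms = x$times, voltage_mV = x$voltage,
                   net_current_nA = x$net_current)
  for (j in seq_along(x$channel_keys)) {
    k <- x$channel_keys[j]
    df[[paste0(k, "_current_nA")]] <- x$currents[, j]
    df[[paste0(k, "_conductance_uS")]] <- x$conductances[, j]
  }
  df
}
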
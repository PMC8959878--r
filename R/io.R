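#' Write a simulation result to CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal point, one header row and one row per
#' sample, in the fixed column order of [as.data.frame.clamp_result()].
#'
#' @param result a `clamp_result` from [run_simulation()].
#' @param destination file path.
#' @return the number of data rows written, invisibly.
#' @export
write_trace_csv <- function(result, destination) {
  stopifnot(inherits(result, "clamp_result"))
  if (length(result$times) == 0)
    .stop_validation("result contains no samples; nothing written")
  df <- as.data.frame(result)
  ok <- tryCatch({
    utils::write.csv(df, destination, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop(errorCondition(sprintf("cannot write '%s': %s", destination,
                                conditionMessage(ok)),
                        class = c("clampsim_io_error", "error")))
  invisible(nrow(df))
}

#' Read a simulation result back from CSV
#'
#' Validates the schema written by [write_trace_csv()]: the first three
#' columns must be `time_ms`, `voltage_mV`, `net_current_nA`, followed by
#' `<key>_current_nA` / `<key>_conductance_uS` pairs; times must be
#' strictly increasing with uniform spacing.
#'
#' @param source file path.
#' @return a `clamp_result` (mode recorded as `"unknown"`, protocol and
#'   config absent).
#' @export
read_trace_csv <- function(source) {
  df <- utils::read.csv(source, check.names = FALSE)
  cols <- names(df)
  fixed <- c("time_ms", "voltage_mV", "net_current_nA")
  for (i in seq_along(fixed)) {
    if (length(cols) < i || cols[i] != fixed[i])
      .stop_validation(sprintf(
        "CSV schema error: expected column %d to be '%s'%s", i, fixed[i],
        if (length(cols) >= i) sprintf(" (found '%s')", cols[i]) else ""))
  }
  rest <- cols[-seq_along(fixed)]
  if (length(rest) %% 2L != 0L)
    .stop_validation("CSV schema error: unpaired channel columns")
  keys <- character(0)
  for (j in seq_len(length(rest) / 2)) {
    curc <- rest[2 * j - 1]; conc <- rest[2 * j]
    if (!grepl("_current_nA$", curc))
      .stop_validation(sprintf(
        "CSV schema error: expected a *_current_nA column, found '%s'", curc))
    k <- sub("_current_nA$", "", curc)
    if (conc != paste0(k, "_conductance_uS"))
      .stop_validation(sprintf(
        "CSV schema error: expected '%s_conductance_uS', found '%s'", k, conc))
    keys <- c(keys, k)
  }
  if (nrow(df) < 1) .stop_validation("CSV contains no data rows")
  times <- df$time_ms
  if (nrow(df) > 1) {
    dts <- diff(times)
    if (any(dts <= 0))
      .stop_validation("times are not strictly increasing")
    if (diff(range(dts)) > 1e-9 * max(dts))
      .stop_validation("times are not uniformly spaced")
  }
  cur <- as.matrix(df[paste0(keys, "_current_nA")])
  cond <- as.matrix(df[paste0(keys, "_conductance_uS")])
  colnames(cur) <- keys; colnames(cond) <- keys
  structure(list(times = times, voltage = df$voltage_mV,
                 net_current = df$net_current_nA,
                 currents = cur, conductances = cond,
                 calcium = NULL, channel_keys = keys, mode = "unknown",
                 protocol = NULL,
                 config = list(dt = if (nrow(df) > 1) times[2] - times[1]
                               else NA_real_)),
            class = "clamp_result")
}

# ---- configuration files ----------------------------------------------

# flatten nested lists to dotted key paths
.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, .flatten_config(v, key))
    else out[[key]] <- v
  }
  out
}

.TOP_KEYS <- c("mode", "amplitude", "baseline", "pre_ms", "clamp_ms",
               "post_ms", "dt_ms", "initial_voltage_mv", "temperature_k",
               "capacitance_nf", "auto_rest", "clamp_sign", "vc_baseline")
.CHANNEL_PARAM_KEYS <- c("g_max", "p_max", "reversal", "conc_in", "conc_out")
.GATE_PARAM_KEYS <- c("vh", "slope", "tau_min", "tau_amp", "tau_vh", "tau_k",
                      "kd", "exponent")
.CALCIUM_KEYS <- c("ca_rest", "tau_ca", "influx_scale")
.ION_KEYS <- c("out", "in")

.check_config_key <- function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  bad <- function() .stop_validation(sprintf("unknown configuration key: %s",
                                             key))
  if (parts[1] == "channels") {
    if (length(parts) < 3 || !parts[2] %in% .CHANNEL_KEYS) bad()
    if (length(parts) == 3) {
      if (!parts[3] %in% .CHANNEL_PARAM_KEYS) bad()
    } else if (length(parts) == 5 && parts[3] == "gates") {
      if (!parts[5] %in% .GATE_PARAM_KEYS) bad()
    } else bad()
  } else if (parts[1] == "calcium") {
    if (length(parts) != 2 || !parts[2] %in% .CALCIUM_KEYS) bad()
  } else if (parts[1] == "ions") {
    if (length(parts) != 3 || !parts[2] %in% c("na", "k", "cl", "ca") ||
        !parts[3] %in% .ION_KEYS) bad()
  } else if (!(length(parts) == 1 && parts[1] %in% .TOP_KEYS)) bad()
  parts
}

# Build (model, protocol, config) from a flat dotted-key settings list.
.apply_config <- function(settings) {
  for (key in names(settings)) .check_config_key(key)
  get_num <- function(key, default = NULL) {
    v <- settings[[key]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      .stop_validation(sprintf("configuration key %s must be a finite number",
                               key))
    as.numeric(v)
  }

  ions <- default_ions()
  for (ion in c("na", "k", "cl", "ca")) {
    o <- get_num(paste("ions", ion, "out", sep = "."))
    i <- get_num(paste("ions", ion, "in", sep = "."))
    if (!is.null(o)) {
      if (o <= 0) .stop_validation(sprintf("ions.%s.out must be > 0", ion))
      ions[[ion]]$out <- o
    }
    if (!is.null(i)) {
      if (i <= 0) .stop_validation(sprintf("ions.%s.in must be > 0", ion))
      ions[[ion]]$in_ <- i
    }
  }
  temperature <- get_num("temperature_k", 295)
  if (temperature <= 0) .stop_validation("temperature_k must be > 0")
  channels <- default_channels(ions, temperature)

  for (key in names(settings)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] != "channels") next
    chk <- parts[2]
    v <- get_num(key)
    if (length(parts) == 3) {
      p <- parts[3]
      if (p %in% c("g_max", "p_max") && v < 0)
        .stop_validation(sprintf("%s must be >= 0 (got %g)", key, v))
      if (p %in% c("conc_in", "conc_out") && v <= 0)
        .stop_validation(sprintf("%s must be > 0 (got %g)", key, v))
      if (p == "p_max" && !inherits(channels[[chk]], "ghk_channel"))
        .stop_validation(sprintf("%s: channel '%s' has a conductance, not a permeability",
                                 key, chk))
      if (p == "g_max" && inherits(channels[[chk]], "ghk_channel"))
        .stop_validation(sprintf("%s: channel '%s' has a permeability, not a conductance",
                                 key, chk))
      channels[[chk]][[p]] <- v
    } else {
      gk <- parts[4]; p <- parts[5]
      if (is.null(channels[[chk]]$gates[[gk]]))
        .stop_validation(sprintf("unknown gate in configuration key: %s", key))
      if (p %in% c("tau_min", "tau_k", "kd") && v <= 0)
        .stop_validation(sprintf("%s must be > 0 (got %g)", key, v))
      if (p == "exponent" && (v < 1 || v != round(v)))
        .stop_validation(sprintf("%s must be a positive integer", key))
      channels[[chk]]$gates[[gk]][[p]] <- if (p == "exponent") as.integer(v) else v
    }
  }

  ca_args <- list(ca_rest = get_num("calcium.ca_rest", 5e-5),
                  tau_ca = get_num("calcium.tau_ca", 20),
                  influx_scale = get_num("calcium.influx_scale", 5e-4))
  if (ca_args$ca_rest <= 0) .stop_validation("calcium.ca_rest must be > 0")
  if (ca_args$tau_ca <= 0) .stop_validation("calcium.tau_ca must be > 0")
  if (ca_args$influx_scale < 0)
    .stop_validation("calcium.influx_scale must be >= 0")

  capacitance <- get_num("capacitance_nf", 0.01)
  if (capacitance <= 0) .stop_validation("capacitance_nf must be > 0")
  model <- membrane_model(capacitance = capacitance,
                          temperature = temperature, ions = ions,
                          channels = channels,
                          calcium = do.call(calcium_pool, ca_args))

  mode <- settings[["mode"]]
  if (is.null(mode)) mode <- "current"
  if (!is.character(mode) || !mode %in% c("current", "voltage"))
    .stop_validation("mode must be \"current\" or \"voltage\"")
  proto_args <- list(mode = mode,
                     pre_ms = get_num("pre_ms", 10),
                     clamp_ms = get_num("clamp_ms", 50),
                     post_ms = get_num("post_ms", 10))
  amp <- get_num("amplitude")
  if (!is.null(amp)) proto_args$amplitude <- amp
  basel <- get_num("baseline")
  if (!is.null(basel)) proto_args$baseline <- basel
  protocol <- do.call(clamp_protocol, proto_args)

  config <- sim_config(dt = get_num("dt_ms", 0.01),
                       initial_voltage = get_num("initial_voltage_mv", -65),
                       temperature = temperature,
                       auto_rest = isTRUE(settings[["auto_rest"]]),
                       clamp_sign = get_num("clamp_sign", -1),
                       vc_baseline = if (is.null(settings[["vc_baseline"]]))
                         "hold" else settings[["vc_baseline"]])
  list(model = model, protocol = protocol, config = config)
}

#' Load a simulation configuration file
#'
#' Reads a YAML document holding protocol timing, clamp mode, integration
#' settings, ionic concentrations and per-channel parameter overrides.
#' Keys may be nested (`channels: {na: {g_max: 1.2}}`) or flat dotted
#' (`channels.na.g_max: 1.2`). Unknown keys are rejected with their key
#' path; all physical quantities are validated at load time (positivity,
#' the 1000 ms protocol cap). An empty document yields all defaults
#' (10/50/10 ms, C = 0.01 nF, dt = 0.01 ms).
#'
#' @param source path to the YAML file.
#' @return a list with elements `model` ([membrane_model()]), `protocol`
#'   ([clamp_protocol()]), `config` ([sim_config()]) and `settings` (the
#'   flat key-value list as read).
#' @export
load_config <- function(source) {
  doc <- yaml::read_yaml(source)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) .stop_validation("config file must be a YAML mapping")
  settings <- .flatten_config(doc)
  built <- .apply_config(settings)
  c(built, list(settings = settings))
}

# ---- plotting ----------------------------------------------------------

#' Plot a simulation result
#'
#' Three stacked panels sharing the time axis: membrane voltage, per-
#' channel currents and per-channel conductances, one colour per channel
#' with a legend of channel keys.
#'
#' @param x a `clamp_result`.
#' @param ... passed on to [graphics::plot()] for the voltage panel.
#' @return the result, invisibly.
#' @export
plot.clamp_result <- function(x, ...) {
  if (length(x$times) == 0) .stop_validation("result contains no samples")
  keys <- x$channel_keys
  cols <- grDevices::hcl.colors(max(3L, length(keys)), "Dark 3")[seq_along(keys)]
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 6), xpd = FALSE,
                      mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  graphics::plot(x$times, x$voltage, type = "l", lwd = 1.5,
                 xlab = "", ylab = "voltage (mV)",
                 main = sprintf("%s clamp", x$mode), ...)
  for (panel in c("currents", "conductances")) {
    mat <- x[[panel]]
    ylab <- if (panel == "currents") "current (nA)" else "conductance (uS)"
    graphics::matplot(x$times, mat, type = "l", lty = 1, col = cols,
                      xlab = if (panel == "conductances") "time (ms)" else "",
                      ylab = ylab)
    graphics::legend("topright", inset = c(-0.12, 0), legend = keys,
                     col = cols, lty = 1, cex = 0.55, bty = "n", xpd = NA)
  }
  invisible(x)
}

#' Render a simulation result to a PNG file
#'
#' @param result a `clamp_result`.
#' @param destination output PNG path.
#' @param width,height,res device geometry (pixels / ppi); fixed defaults
#'   so identical results render identical files.
#' @return `destination`, invisibly.
#' @export
plot_trace <- function(result, destination, width = 900, height = 900,
                       res = 100) {
  stopifnot(inherits(result, "clamp_result"))
  if (length(result$times) == 0)
    .stop_validation("result contains no samples")
  ok <- tryCatch({
    grDevices::png(destination, width = width, height = height, res = res)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(errorCondition(sprintf("cannot open '%s' for plotting", destination),
                        class = c("clampsim_io_error", "error")))
  on.exit(grDevices::dev.off())
  plot(result)
  invisible(destination)
}
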
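# Model fixtures built in code.

# single leak conductance: an RC membrane with analytic solution
leak_model <- function(g = 0.005, e = -70, capacitance = 0.01) {
  membrane_model(capacitance = capacitance,
                 channels = list(k_leak = ohmic_channel("k_leak", g, e)))
}

# excitable Na + K + leak subset of the default roster
nak_model <- function() {
  membrane_model(channels = default_channels()[c("na", "k", "na_leak",
                                                 "k_leak")])
}

# full roster with every conductance/permeability zeroed
zeroed_model <- function() {
  chs <- default_channels()
  for (k in names(chs)) {
    if (inherits(chs[[k]], "ghk_channel")) chs[[k]]$p_max <- 0
    else chs[[k]]$g_max <- 0
  }
  membrane_model(channels = chs)
}

# random short protocol for property tests
random_protocol <- function() {
  mode <- sample(c("current", "voltage"), 1)
  amp <- if (mode == "current") stats::runif(1, -0.5, 0.5)
         else stats::runif(1, -120, 60)
  base <- if (mode == "current") 0 else stats::runif(1, -90, -50)
  clamp_protocol(mode, pre_ms = stats::runif(1, 0.5, 2),
                 clamp_ms = stats::runif(1, 1, 5),
                 post_ms = stats::runif(1, 0.5, 2),
                 amplitude = amp, baseline = base)
}

# max |V_euler - V_reference| with the reference sampled on the Euler grid
euler_error <- function(run_res, ref_res) {
  k <- as.integer(round(run_res$config$dt / ref_res$config$dt))
  idx <- seq(1, length(ref_res$times), by = k)
  stopifnot(length(idx) == length(run_res$times))
  max(abs(run_res$voltage - ref_res$voltage[idx]))
}
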
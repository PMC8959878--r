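# Nernst potential -------------------------------------------------------

test_that("Nernst potential matches the closed form and its symmetries", {
  # equal concentrations: ln(1) = 0
  expect_identical(nernst_potential(1, 10, 10, 295.15), 0)
  # (RT/F) ln 10 at 295.15 K, CODATA constants, computed independently
  expect_equal(nernst_potential(1, 100, 10, 295.15), 58.56408539238873,
               tolerance = 1e-12)
  # 1/z scaling
  expect_equal(nernst_potential(2, 100, 10, 295.15),
               nernst_potential(1, 100, 10, 295.15) / 2, tolerance = 1e-15)
  # anions flip the sign
  expect_equal(nernst_potential(-1, 100, 10, 295.15),
               -nernst_potential(1, 100, 10, 295.15), tolerance = 1e-15)
})

test_that("Nernst potential rejects invalid inputs naming the field", {
  expect_error(nernst_potential(0, 10, 10), "valence",
               class = "clampsim_validation_error")
  expect_error(nernst_potential(1, -1, 10), "conc_out",
               class = "clampsim_validation_error")
  expect_error(nernst_potential(1, 10, 0), "conc_in",
               class = "clampsim_validation_error")
  expect_error(nernst_potential(1, 10, 10, temperature = -5), "temperature",
               class = "clampsim_validation_error")
})

# GHK constant-field current ---------------------------------------------

test_that("GHK current vanishes exactly at the Nernst potential", {
  ch <- ghk_channel("ca_t", p_max = 0.02, valence = 2L,
                    conc_in = 5e-5, conc_out = 2)
  e_ca <- nernst_potential(2, 2, 5e-5, 295)
  expect_lt(abs(ghk_current(ch, e_ca, 295)), 1e-9)

  # independent oracle: bisect the current itself for its root
  f <- function(v) ghk_current(ch, v, 295)
  lo <- 100; hi <- 150
  stopifnot(sign(f(lo)) != sign(f(hi)))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, e_ca, tolerance = 1e-8)
})

test_that("GHK current is continuous through V = 0 and matches the limit", {
  ch <- ghk_channel("ca_l", p_max = 0.5, valence = 2L,
                    conc_in = 0.3, conc_out = 2)
  # L'Hopital limit at V = 0: p * z * (conc_in - conc_out)
  i0 <- ghk_current(ch, 0, 295)
  expect_equal(i0, 0.5 * 2 * (0.3 - 2), tolerance = 1e-10)
  expect_equal(ghk_current(ch, 1e-6, 295), i0, tolerance = 1e-6)
  expect_equal(ghk_current(ch, -1e-6, 295), i0, tolerance = 1e-6)

  # series branch and direct formula agree at the switch threshold
  u <- c(0.99e-4, 1.01e-4, -0.99e-4, -1.01e-4)
  direct <- u * (0.3 - 2 * exp(-u)) / (-expm1(-u))
  series <- clampsim:::.ghk_flux(u, 0.3, 2)
  expect_equal(series[c(2, 4)], direct[c(2, 4)], tolerance = 1e-15)
  expect_lt(max(abs(series - direct)), 1e-9)
})

test_that("GHK current crosses zero exactly once in (-150, 100) mV", {
  # concentration ratio chosen so the Nernst potential (~ +38 mV) lies
  # inside the physiological scan window
  ch <- ghk_channel("ca_t", p_max = 0.02, valence = 2L,
                    conc_in = 0.1, conc_out = 2)
  v <- seq(-150, 100, by = 0.25)
  i <- vapply(v, function(x) ghk_current(ch, x, 295), numeric(1))
  crossings <- sum(diff(sign(i)) != 0)
  expect_identical(crossings, 1L)
  expect_true(all(diff(i) > 0))  # monotone increasing through its root
})

test_that("GHK current scales with permeability and gate product", {
  gates <- list(m = gate_kinetics(vh = -50, slope = 6, exponent = 2L))
  ch <- ghk_channel("ca_l", p_max = 0, valence = 2L, conc_in = 5e-5,
                    conc_out = 2, gates = gates)
  expect_identical(ghk_current(ch, -30, 295), 0)
  ch$p_max <- 0.02
  full <- ghk_current(ch, -30, 295, gates = 1)
  expect_equal(ghk_current(ch, -30, 295, gates = 0.5), full * 0.25,
               tolerance = 1e-12)  # exponent 2
  expect_error(ghk_current(ch, -30, temperature = 0),
               class = "clampsim_validation_error")
})

# gating kinetics ---------------------------------------------------------

test_that("gate steady state is bounded, monotone and half at vh", {
  act <- gate_kinetics(vh = -40, slope = 5.5)
  v <- seq(-150, 100, by = 1)
  x <- gate_steady_state(act, v)
  expect_true(all(x >= 0 & x <= 1))
  expect_true(all(diff(x) > 0))
  expect_gte(gate_steady_state(act, 100), gate_steady_state(act, -100))
  expect_equal(gate_steady_state(act, -40), 0.5, tolerance = 1e-15)
  inact <- gate_kinetics(vh = -60, slope = -7)
  expect_true(all(diff(gate_steady_state(inact, v)) < 0))
  expect_true(all(gate_time_constant(act, v) > 0))
})

test_that("calcium-gated steady states need calcium", {
  kca <- gate_kinetics(vh = -20, slope = 12, ca_mode = "mult", kd = 5e-4)
  expect_identical(gate_steady_state(kca, 40, calcium = 0), 0)
  expect_equal(gate_steady_state(kca, 1e6, calcium = 5e-4), 0.5,
               tolerance = 1e-6)
  ahp <- gate_kinetics(tau_min = 80, ca_mode = "ca", kd = 1e-3)
  expect_identical(gate_steady_state(ahp, -60, calcium = 0), 0)
  expect_equal(gate_steady_state(ahp, -60, calcium = 1e-3), 0.5,
               tolerance = 1e-15)
})

test_that("advance_gate follows the explicit Euler update", {
  kin <- gate_kinetics(vh = 0, slope = 10, tau_min = 1)
  # fixed point: x = x_inf
  xinf <- gate_steady_state(kin, -10)
  expect_equal(advance_gate(xinf, kin, -10, dt = 0.1), xinf,
               tolerance = 1e-15)
  # forced by the update formula: 0 + 0.1 * (1 - 0) / 1
  kin1 <- gate_kinetics(vh = -1e5, slope = 10, tau_min = 1)  # x_inf ~ 1
  expect_equal(advance_gate(0, kin1, 0, dt = 0.1), 0.1, tolerance = 1e-10)
  expect_error(advance_gate(0.5, kin, 0, dt = 0), class = "clampsim_validation_error")
  expect_warning(advance_gate(0.5, kin, 0, dt = 2), "time constant")
})

test_that("n Euler gate steps match the geometric closed form", {
  kin <- gate_kinetics(vh = -35, slope = 8, tau_min = 2, tau_amp = 5,
                       tau_vh = -35, tau_k = 20)
  v <- -50; dt <- 0.05; x0 <- 0.9; n <- 200
  x <- x0
  for (i in seq_len(n)) x <- advance_gate(x, kin, v, dt)
  xinf <- gate_steady_state(kin, v)
  tau <- gate_time_constant(kin, v)
  expect_equal(x, xinf + (x0 - xinf) * (1 - dt / tau)^n, tolerance = 1e-12)
})

# ohmic and A currents ----------------------------------------------------

test_that("ohmic current obeys driving-force arithmetic and symmetry", {
  ch <- ohmic_channel("k_leak", g_max = 1, reversal = -70)
  expect_identical(ohmic_current(ch, voltage = -70), 0)
  expect_equal(ohmic_current(ch, voltage = -60), 10, tolerance = 1e-15)
  ch2 <- ch; ch2$g_max <- 0.5
  expect_equal(ohmic_current(ch2, voltage = -60),
               ohmic_current(ch, voltage = -60) / 2, tolerance = 1e-15)
  # odd symmetry about the reversal potential
  for (d in c(1, 7.5, 30))
    expect_equal(ohmic_current(ch, voltage = -70 + d),
                 -ohmic_current(ch, voltage = -70 - d), tolerance = 1e-12)
})

test_that("gate exponents enter the ohmic conductance as powers", {
  ch <- ohmic_channel("na", g_max = 2, reversal = 60, gates = list(
    m = gate_kinetics(vh = -40, slope = 6, exponent = 3L),
    h = gate_kinetics(vh = -60, slope = -7)))
  expect_equal(ohmic_current(ch, gates = c(0.5, 0.8), voltage = 0),
               2 * 0.5^3 * 0.8 * (0 - 60), tolerance = 1e-12)
})

test_that("A-current components carry 60% / 40% weights summing to one", {
  g <- gate_kinetics(vh = -45, slope = 10)
  h <- gate_kinetics(vh = -78, slope = -6)
  ch <- a_current_channel("a", g_max = 1, reversal = -90,
                          m1 = g, h1 = h, m2 = g, h2 = h)
  gcond <- function(m1, h1, m2, h2)
    a_current(ch, m1, h1, m2, h2, voltage = -89) / (-89 - -90)
  expect_equal(gcond(1, 1, 0, 0), 0.6, tolerance = 1e-15)
  expect_equal(gcond(0, 0, 1, 1), 0.4, tolerance = 1e-15)
  expect_equal(gcond(1, 1, 1, 1), 1, tolerance = 1e-15)
  expect_equal(ch$w1 + ch$w2, 1, tolerance = 0)
  # collapsing the weights onto one component changes nothing when the
  # components share kinetics and state
  ch1 <- a_current_channel("a", g_max = 1, reversal = -90,
                           m1 = g, h1 = h, m2 = g, h2 = h, w1 = 1)
  for (x in c(0.2, 0.7))
    expect_equal(a_current(ch1, x, x, x, x, -40),
                 a_current(ch, x, x, x, x, -40), tolerance = 1e-15)
})

# calcium pool ------------------------------------------------------------

test_that("calcium pool has the analytic steady state and fixed point", {
  pool <- calcium_pool(ca_rest = 5e-5, tau_ca = 20, influx_scale = 5e-4)
  # fixed point at rest with no current
  expect_equal(update_calcium(pool, 0, dt = 0.1)$ca, 5e-5, tolerance = 1e-18)
  # steady state under constant inward current: ca_rest + k * |I| * tau
  # (set the derivative to zero analytically)
  i_ca <- -0.2
  target <- 5e-5 + 5e-4 * 0.2 * 20
  p <- pool
  for (i in 1:20000) p <- update_calcium(p, i_ca, dt = 0.05)
  expect_equal(p$ca, target, tolerance = 1e-9)
  expect_error(update_calcium(pool, 0, dt = -1),
               class = "clampsim_validation_error")
})

test_that("calcium decays exponentially toward rest without influx", {
  pool <- calcium_pool(ca = 2e-3, ca_rest = 5e-5, tau_ca = 20)
  dt <- 0.01
  p <- pool
  traj <- numeric(500)
  for (i in 1:500) { p <- update_calcium(p, 0, dt); traj[i] <- p$ca }
  t <- (1:500) * dt
  closed <- 5e-5 + (2e-3 - 5e-5) * exp(-t / 20)
  expect_lt(max(abs(traj - closed)), 1e-6)       # first-order accuracy
  expect_true(all(diff(traj) < 0))               # monotone convergence
  expect_true(all(traj >= 5e-5))
})

# steady-state initialization ---------------------------------------------

test_that("init_state is a fixed point of the gate dynamics and idempotent", {
  mod <- membrane_model()
  st <- init_state(mod, v0 = -65)
  st2 <- step_voltage_clamp(mod, st, v_hold = -65, dt = 0.05)
  expect_lt(max(abs(st2$gates - st$gates)), 1e-12)
  expect_lt(abs(st2$calcium - st$calcium), 1e-12)
  # idempotent
  expect_identical(init_state(mod, -65), init_state(mod, -65))
  # hyperpolarized init: Na activation ~ 0, Na inactivation ~ 1
  sth <- init_state(mod, v0 = -100)
  expect_lt(sth$gates[["na.m"]], 1e-4)
  expect_gt(sth$gates[["na.h"]], 0.99)
})
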
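# Intrinsic-current gating kinetics for all cell types.
#
# Cortical rate constants are divided by the temperature factor QT = 2.9529;
# the thalamic T-current kinetics carry their own printed divisors
# (3.9482 TC, 6.8986 / 3.7372 RE).

QT_CORT <- 2.9529

# guarded x/(1 - exp(-x/k)): -> k as x -> 0
.vtrap <- function(x, k) {
  ifelse(abs(x / k) < 1e-6, k * (1 + x / (2 * k)), x / (1 - exp(-x / k)))
}

#' Gating rate functions for every intrinsic current
#'
#' Returns, for each gate of the requested current, the steady-state
#' activation `inf` and time constant `tau` (ms), plus the raw transition
#' rates `alpha`/`beta` (1/ms) where the kinetics are rate-based.
#' Singularity-guarded branches are applied where the rate expressions are
#' 0/0 at isolated voltages.
#'
#' @param current_id One of `"Na"`, `"K"`, `"Nap"`, `"Km"`, `"KCa"`,
#'   `"HVA"` (cortical), `"Na_t"`, `"K_t"`, `"T_tc"`, `"T_re"`, `"h_tc"`
#'   (thalamic). The leak currents `"KL"` and `"L"` have no gates and
#'   raise an error.
#' @param V Membrane potential (mV).
#' @param Ca_i Intracellular calcium (mM); required for `"KCa"`.
#' @return Named list with one entry per gate (`m`, and `h` where the
#'   current inactivates), each a list with `tau`, `inf` and, when
#'   defined, `alpha` and `beta`.
#' @export
rate_functions <- function(current_id, V, Ca_i = NULL) {
  stopifnot(is.finite(V))
  switch(current_id,
    Na = {
      # fast sodium, cortical (axosomatic + dendritic); guards at V = -25,
      # V = -40 and V = 85 where the rational expressions are 0/0
      a1 <- 0.182 * .vtrap(V + 25, 9)
      b1 <- 0.124 * .vtrap(-(V + 25), 9)
      tm <- (1 / (a1 + b1)) / QT_CORT
      mi <- a1 / (a1 + b1)
      a2 <- 0.024 * .vtrap(V + 40, 5)
      b2 <- 0.0091 * .vtrap(V - 85, 5)
      th <- (1 / (a2 + b2)) / QT_CORT
      hi <- 1 / (1 + exp((V + 55) / 6.2)) # explicit, not a2/(a2+b2)
      list(m = list(alpha = a1, beta = b1, tau = tm, inf = mi),
           h = list(alpha = a2, beta = b2, tau = th, inf = hi))
    },
    K = {
      # delayed rectifier, cortical; M = 1
      a <- 0.02 * .vtrap(V - 25, 9)
      b <- 0.002 * .vtrap(-(V - 25), 9)
      list(m = list(alpha = a, beta = b,
                    tau = (1 / (a + b)) / QT_CORT, inf = a / (a + b)))
    },
    Nap = {
      # persistent sodium: instantaneous activation, max 0.02
      mi <- 0.02 / (1 + exp(-(V + 42) / 5))
      list(m = list(tau = 0, inf = mi))
    },
    Km = {
      a <- 0.001 * .vtrap(V + 30, 9)
      b <- 0.001 * .vtrap(-(V + 30), 9)
      list(m = list(alpha = a, beta = b,
                    tau = (1 / (a + b)) / QT_CORT, inf = a / (a + b)))
    },
    KCa = {
      # calcium-dependent activation; the 0.01 rate is per uM of
      # intracellular calcium (Ca_i is in mM throughout the package)
      stopifnot(!is.null(Ca_i), Ca_i >= 0)
      a <- 0.01 * Ca_i * 1000
      b <- 0.02
      list(m = list(alpha = a, beta = b,
                    tau = (1 / (a + b)) / QT_CORT, inf = a / (a + b)))
    },
    HVA = {
      a1 <- 0.055 * .vtrap(V + 27, 3.8)
      b1 <- 0.94 * exp((-75 - V) / 17)
      a2 <- 0.000457 * exp((-13 - V) / 50)
      b2 <- 0.0065 / (exp((-V - 15) / 28) + 1)
      list(m = list(alpha = a1, beta = b1,
                    tau = (1 / (a1 + b1)) / QT_CORT, inf = a1 / (a1 + b1)),
           h = list(alpha = a2, beta = b2,
                    tau = (1 / (a2 + b2)) / QT_CORT, inf = a2 / (a2 + b2)))
    },
    Na_t = {
      # fast sodium, thalamic: Traub kinetics on the shifted voltage
      # V2 = V + 50 (the shift used by the thalamic delayed rectifier)
      V2 <- V + 50
      a1 <- 0.32 * .vtrap(V2 - 13, 4)
      b1 <- 0.28 * .vtrap(40 - V2, 5)
      a2 <- 0.128 * exp((17 - V2) / 18)
      b2 <- 4 / (1 + exp((40 - V2) / 5))
      list(m = list(alpha = a1, beta = b1,
                    tau = 1 / (a1 + b1), inf = a1 / (a1 + b1)),
           h = list(alpha = a2, beta = b2,
                    tau = 1 / (a2 + b2), inf = a2 / (a2 + b2)))
    },
    K_t = {
      # delayed rectifier, thalamic; M = 4
      a <- 0.032 * .vtrap(V + 35, 5)
      b <- 0.5 * exp((-40 - V) / 40)
      list(m = list(alpha = a, beta = b,
                    tau = 1 / (a + b), inf = a / (a + b)))
    },
    T_tc = {
      # low-threshold calcium, TC: the canonical relay-cell kinetics of
      # the antecedent model family (+2 mV screening shift, Q10-corrected
      # to 36 C); M = 2 activation, slow inactivation recovery below -80
      v <- V + 2
      phi_m <- 3.55^1.2
      phi_h <- 3^1.2
      mi <- 1 / (1 + exp(-(v + 57) / 6.2))
      hi <- 1 / (1 + exp((v + 81) / 4))
      tm <- (0.612 + 1 / (exp(-(v + 132) / 16.7) + exp((v + 16.8) / 18.2))) / phi_m
      th <- ifelse(v < -80, exp((v + 467) / 66.6),
                   28 + exp(-(v + 22) / 10.5)) / phi_h
      list(m = list(tau = tm, inf = mi), h = list(tau = th, inf = hi))
    },
    T_re = {
      tm <- (3 + 1 / (exp((V + 27) / 10) + exp(-(V + 102) / 15))) / 6.8986
      mi <- 1 / (1 + exp(-(V + 52) / 7.4))
      th <- (85 + 1 / (exp((V + 48) / 4) + exp(-(V + 407) / 50))) / 3.7372
      hi <- 1 / (1 + exp((V + 80) / 5))
      list(m = list(tau = tm, inf = mi), h = list(tau = th, inf = hi))
    },
    h_tc = {
      # two-state open/closed scheme: C -> O at alpha, O -> C at beta
      hi <- 1 / (1 + exp((V + 75) / 5.5))
      ts <- 20 + 1000 / (exp((V + 71.5) / 14.2) + exp(-(V + 89) / 11.6))
      list(s = list(alpha = hi / ts, beta = (1 - hi) / ts, tau = ts, inf = hi))
    },
    KL = stop("KL is a leak current and has no gates"),
    L = stop("L is a leak current and has no gates"),
    stop("unknown current_id: ", current_id)
  )
}

#' Ohmic intrinsic current density
#'
#' `I = g_max * m^M * h^N * (V - E_rev)` in uA/cm^2; leaks use M = N = 0.
#'
#' @param g_max Maximal conductance density (mS/cm^2).
#' @param E_rev Reversal potential (mV).
#' @param V Membrane potential (mV).
#' @param m,h Gating values in `[0, 1]`.
#' @param M,N Activation / inactivation exponents.
#' @export
intrinsic_current <- function(g_max, E_rev, V, m = 1, h = 1, M = 0, N = 0) {
  stopifnot(g_max >= 0, all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  g_max * m^M * h^N * (V - E_rev)
}

#' Exponential-Euler gating update
#'
#' Advances `dx/dt = -(x - x_inf)/tau` exactly over `dt` for constant
#' `x_inf`, `tau`. `tau = 0` is treated as instantaneous (`x -> x_inf`).
#'
#' @param x Current gating value.
#' @param x_inf Steady-state value.
#' @param tau Time constant (ms), `>= 0`.
#' @param dt Step (ms), `> 0`.
#' @export
update_gating <- function(x, x_inf, tau, dt) {
  if (any(tau < 0)) stop("tau must be >= 0")
  stopifnot(dt > 0)
  ifelse(tau == 0, x_inf, x_inf + (x - x_inf) * exp(-dt / tau))
}

#' Two-state update for the hyperpolarization-activated current
#'
#' Integrates `dO/dt = alpha (1 - O) - beta O` with `alpha = h_inf/tau_s`,
#' `beta = (1 - h_inf)/tau_s`; the steady state is `h_inf(V)`.
#'
#' @param open Open fraction in `[0, 1]`.
#' @param V Membrane potential (mV).
#' @param dt Step (ms).
#' @export
update_ih_two_state <- function(open, V, dt) {
  stopifnot(open >= 0, open <= 1)
  g <- rate_functions("h_tc", V)$s
  update_gating(open, g$inf, g$tau, dt)
}

#' Goldman-Hodgkin-Katz driving function for the T current
#'
#' The low-threshold calcium current uses the nonlinear GHK flux
#' (divalent ion, 36 C, resting internal and 2 mM external calcium)
#' rather than an ohmic driving force, normalized so that at -60 mV it
#' equals the linear drive `(-60 - E_Ca)`. Relative to the linear form
#' this strengthens the inward drive at hyperpolarized potentials, where
#' rebound bursts are born.
#'
#' @param V Membrane potential (mV).
#' @param E_Ca Linear calcium reversal used for the normalization (mV).
#' @param Ca_i,Ca_o Internal/external calcium (mM).
#' @return Drive in mV-equivalent units (negative = inward).
#' @export
ghk_t_drive <- function(V, E_Ca = 120, Ca_i = 2.4e-4, Ca_o = 2) {
  k <- 13.36 # RT/zF at 36 C for a divalent ion, mV
  flux <- function(v) {
    u <- v / k
    g <- ifelse(abs(u) < 1e-6, 1 + u / 2, u / (1 - exp(-u)))
    k * g * (Ca_i - Ca_o * exp(-u))
  }
  flux(V) / flux(-60) * (-60 - E_Ca)
}

#' Intracellular calcium pool update
#'
#' `d[Ca]/dt = -A * I_Ca + ([Ca]_inf - [Ca])/tau`, advanced exactly over
#' `dt` for constant `I_Ca` (the inward low- or high-threshold calcium
#' current density, uA/cm^2).
#'
#' @param Ca_i Calcium concentration (mM).
#' @param I_Ca Calcium current density (uA/cm^2); inward is negative.
#' @param dt Step (ms).
#' @param Ca_inf Floor concentration (mM).
#' @param A Influx coefficient (mM cm^2 / (ms uA)).
#' @param tau Relaxation time (ms).
#' @export
update_calcium <- function(Ca_i, I_Ca, dt, Ca_inf = 2.4e-4,
                           A = 5.1819e-5, tau = 5) {
  stopifnot(dt > 0, Ca_i > 0)
  target <- Ca_inf - A * tau * I_Ca
  target + (Ca_i - target) * exp(-dt / tau)
}
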
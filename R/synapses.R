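# First-order AMPA/NMDA/GABA-A kinetics, short-term depression, the
# GABA-B G-protein cascade, and miniature-event generation. These are the
# reference implementations; the network engine (src/engine.cpp) applies
# the same update rules with precomputed decay factors.

#' Transmitter concentration pulse
#'
#' A presynaptic event deposits a rectangular transmitter pulse of
#' amplitude `A` lasting `t_max` ms from `t0`; a spike arriving during an
#' active pulse restarts the window.
#'
#' @param t Query time (ms).
#' @param t0 Pulse start (ms); `-Inf` for "no pulse yet".
#' @param A Pulse amplitude (concentration units).
#' @param t_max Pulse duration (ms).
#' @export
transmitter <- function(t, t0, A = 0.5, t_max = 0.3) {
  ifelse(t >= t0 & t <= t0 + t_max, A, 0)
}

#' Open-fraction update for first-order receptor kinetics
#'
#' Exact exponential advance of `dO/dt = alpha (1 - O) T - beta O` over
#' `dt` with `T` held constant.
#'
#' @param O Open fraction in `[0, 1]`.
#' @param T_conc Transmitter concentration over the step.
#' @param alpha,beta Binding/unbinding rates (1/ms; alpha additionally
#'   per concentration unit).
#' @param dt Step (ms).
#' @export
update_open_fraction <- function(O, T_conc, alpha, beta, dt) {
  stopifnot(all(O >= 0 & O <= 1), dt >= 0)
  r <- alpha * T_conc + beta
  O_inf <- ifelse(r > 0, alpha * T_conc / r, 0)
  O_inf + (O - O_inf) * exp(-r * dt)
}

#' First-order synaptic current
#'
#' `I = g * D * O * f(V) * (V - E)` (nA when `g` is in uS). `f(V) = 1`
#' for AMPA and GABA-A; NMDA uses the voltage-dependent sigmoid
#' `1/(1 + exp(-(V - V_th)/sigma))`.
#'
#' @param g Maximal conductance (uS).
#' @param O Open fraction.
#' @param V_post Postsynaptic potential (mV).
#' @param E Reversal potential (mV).
#' @param D Depression resource (1 for non-depressing synapses).
#' @param nmda Logical; apply the NMDA voltage gate.
#' @param V_th,sigma NMDA gate midpoint and slope (mV).
#' @export
first_order_current <- function(g, O, V_post, E, D = 1, nmda = FALSE,
                                V_th = -25, sigma = 12.5) {
  f <- if (nmda) 1 / (1 + exp(-(V_post - V_th) / sigma)) else 1
  g * D * O * f * (V_post - E)
}

#' NMDA voltage gate
#' @inheritParams first_order_current
#' @export
nmda_gate <- function(V_post, V_th = -25, sigma = 12.5) {
  1 / (1 + exp(-(V_post - V_th) / sigma))
}

#' Short-term depression recursion
#'
#' Resource available at the (n+1)-th presynaptic event:
#' `D' = 1 - (1 - D (1 - U)) exp(-dt/tau_rec)` where `dt` is the
#' inter-event interval. `D = 1` is full recovery; each event consumes a
#' fraction `U` of the remaining resource.
#'
#' @param D Resource available at the previous event.
#' @param dt_ms Interval since the previous event (ms), `> 0`.
#' @param U Utilization fraction per event.
#' @param tau_rec Recovery time constant (ms).
#' @export
update_depression <- function(D, dt_ms, U, tau_rec = 700) {
  stopifnot(all(dt_ms > 0), U >= 0, U < 1)
  1 - (1 - D * (1 - U)) * exp(-dt_ms / tau_rec)
}

#' Fixed point of the depression recursion for a periodic train
#'
#' Closed-form steady-state resource for events at a fixed interval.
#'
#' @inheritParams update_depression
#' @export
depression_fixed_point <- function(dt_ms, U, tau_rec = 700) {
  e <- exp(-dt_ms / tau_rec)
  (1 - e) / (1 - (1 - U) * e)
}

#' GABA-B receptor/G-protein cascade update
#'
#' `dR/dt = K1 (1 - R) T - K2 R`, `dG/dt = K3 R - K4 G`, advanced over
#' `dt` with `T` (and then `R`) held constant; `R` stays in `[0, 1]`.
#'
#' @param R Activated-receptor fraction.
#' @param G G-protein concentration.
#' @param T_conc Transmitter concentration.
#' @param dt Step (ms).
#' @param K1,K2,K3,K4 Cascade rate constants (1/ms; `K1` per
#'   concentration unit).
#' @return List with updated `R` and `G`.
#' @export
update_gabab <- function(R, G, T_conc, dt,
                         K1 = 0.052, K2 = 0.0013, K3 = 0.098, K4 = 0.033) {
  stopifnot(R >= 0, R <= 1, G >= 0)
  a <- K1 * T_conc + K2
  R_inf <- K1 * T_conc / a
  R_new <- R_inf + (R - R_inf) * exp(-a * dt)
  G_inf <- K3 * R_new / K4
  G_new <- G_inf + (G - G_inf) * exp(-K4 * dt)
  list(R = min(max(R_new, 0), 1), G = max(G_new, 0))
}

#' GABA-B potassium current
#'
#' Hill-activated potassium current
#' `I = g * G^4/(G^4 + K) * (V - E_K)`.
#'
#' @param G G-protein concentration.
#' @param g Maximal conductance (uS).
#' @param V Postsynaptic potential (mV).
#' @param K_hill Half-activation constant (G^4 units).
#' @param E_K Potassium reversal (mV).
#' @export
gabab_current <- function(G, g, V, K_hill = 100, E_K = -95) {
  stopifnot(all(G >= 0))
  g * G^4 / (G^4 + K_hill) * (V - E_K)
}

#' Miniature synaptic event stream
#'
#' Poisson-timed miniature events emitted only while the down-state gate
#' is open. Used for unit-level statistics; the network engine draws the
#' same kind of stream per target synapse internally.
#'
#' @param rate_hz Event rate while gated on (events/s).
#' @param gates Tibble/data.frame with `on`, `off` columns (ms) giving
#'   the open intervals.
#' @return Numeric vector of event times (ms), sorted.
#' @export
mini_generator <- function(rate_hz, gates) {
  stopifnot(rate_hz >= 0)
  if (rate_hz == 0 || nrow(gates) == 0) return(numeric(0))
  rate_ms <- rate_hz / 1000
  out <- lapply(seq_len(nrow(gates)), function(i) {
    t0 <- gates$on[i]; t1 <- gates$off[i]
    ts <- numeric(0)
    t <- t0 + stats::rexp(1, rate_ms)
    while (t < t1) {
      ts <- c(ts, t)
      t <- t + stats::rexp(1, rate_ms)
    }
    ts
  })
  sort(unlist(out))
}
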
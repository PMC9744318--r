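# First-order receptor kinetics, depression, GABA-B cascade and
# miniature-event statistics.

test_that("transmitter pulse is a gated rectangle", {
  expect_equal(transmitter(5, t0 = 10), 0)
  expect_equal(transmitter(10.15, t0 = 10, A = 0.5, t_max = 0.3), 0.5)
  expect_equal(transmitter(10.7, t0 = 10, t_max = 0.3), 0)
  expect_equal(transmitter(0, t0 = -Inf), 0)
})

test_that("open fraction follows the exact exponential solution", {
  # pure decay
  expect_equal(update_open_fraction(0.4, 0, 1.1, 0.19, 2), 0.4 * exp(-0.38))
  # fixed point under sustained transmitter
  O <- 0
  for (i in 1:20000) O <- update_open_fraction(O, 0.5, 1.1, 0.19, 0.5)
  expect_equal(O, 1.1 * 0.5 / (1.1 * 0.5 + 0.19), tolerance = 1e-9)
  # GABA-A decay time constant 1/beta ~ 6 ms
  O <- 0.8
  O <- update_open_fraction(O, 0, 10.5, 0.166, 1 / 0.166)
  expect_equal(O, 0.8 * exp(-1), tolerance = 1e-12)
  # bounds for arbitrary pulse trains
  set.seed(7)
  O <- 0
  for (i in 1:2000) {
    O <- update_open_fraction(O, sample(c(0, 0.5), 1), 10.5, 0.166, 0.1)
    expect_true(O >= 0 && O <= 1)
  }
})

test_that("first-order current obeys the driving-force and NMDA gate", {
  expect_equal(first_order_current(0.1, 0.5, -70, -70), 0)
  expect_equal(nmda_gate(-25), 0.5)
  expect_equal(nmda_gate(50), 1 / (1 + exp(-75 / 12.5)), tolerance = 1e-12)
  expect_gt(nmda_gate(50), 0.997)
  # depression scales linearly
  expect_equal(first_order_current(0.1, 0.5, -60, 0, D = 0.5),
               0.5 * first_order_current(0.1, 0.5, -60, 0))
})

test_that("depression recursion recovers, depletes and hits its fixed point", {
  expect_equal(update_depression(0.2, 1e9, U = 0.07), 1)
  # immediately-reused resource after one event from rest: 1 - U
  expect_equal(update_depression(1, 1e-9, U = 0.07), 0.93, tolerance = 1e-6)
  # 10 spikes at 100 Hz: strictly decreasing to a positive plateau
  D <- 1; seqD <- numeric(0)
  for (i in 1:10) { D <- update_depression(D, 10, U = 0.07); seqD <- c(seqD, D) }
  expect_true(all(diff(seqD) < 0))
  expect_gt(min(seqD), 0)
  # iterated recursion converges to the closed-form fixed point
  D <- 1
  for (i in 1:500) D <- update_depression(D, 10, U = 0.07)
  expect_equal(D, depression_fixed_point(10, 0.07), tolerance = 1e-10)
  # the closed form solves the recursion's fixed-point equation
  Dstar <- depression_fixed_point(25, 0.073)
  expect_equal(update_depression(Dstar, 25, 0.073), Dstar, tolerance = 1e-12)
})

test_that("depression recursion matches the two-state resource ODE", {
  # oracle: resource recovers as dD/dt = (1 - D)/tau between events and is
  # scaled by (1 - U) at each event; simulated with small steps
  U <- 0.07; tau <- 700; isi <- 10
  D_ode <- 1; used <- numeric(0)
  for (ev in 1:40) {
    used <- c(used, D_ode)
    D_ode <- D_ode * (1 - U)
    for (s in seq_len(isi / 0.01)) D_ode <- D_ode + 0.01 * (1 - D_ode) / tau
  }
  D_rec <- 1; used_rec <- numeric(0)
  for (ev in 1:40) {
    used_rec <- c(used_rec, D_rec)
    D_rec <- update_depression(D_rec, isi, U, tau)
  }
  expect_equal(used, used_rec, tolerance = 1e-4)
})

test_that("GABA-B cascade has the right fixed points and peak ordering", {
  s <- list(R = 0, G = 0.5)
  for (i in 1:5000) s <- update_gabab(s$R, s$G, 0, 1)
  expect_equal(s$G, 0, tolerance = 1e-10)
  # sustained transmitter fixed points
  s <- list(R = 0, G = 0)
  for (i in 1:50000) s <- update_gabab(s$R, s$G, 0.5, 1)
  K1 <- 0.052; K2 <- 0.0013; K3 <- 0.098; K4 <- 0.033
  Rstar <- K1 * 0.5 / (K1 * 0.5 + K2)
  expect_equal(s$R, Rstar, tolerance = 1e-6)
  expect_equal(s$G, K3 * Rstar / K4, tolerance = 1e-4)
  # single pulse: G peaks after R (cascade lag)
  s <- list(R = 0, G = 0); Rt <- Gt <- numeric(0)
  for (i in 1:3000) {
    s <- update_gabab(s$R, s$G, if (i <= 20) 0.5 else 0, 0.1)
    Rt <- c(Rt, s$R); Gt <- c(Gt, s$G)
  }
  expect_gt(which.max(Gt), which.max(Rt))
  expect_true(all(Rt >= 0 & Rt <= 1) && all(Gt >= 0))
})

test_that("GABA-B current is a monotone Hill function of G", {
  expect_equal(gabab_current(0, 0.01, -70), 0)
  expect_equal(gabab_current(100^0.25, 1, -94), 0.5 * (-94 + 95))
  expect_equal(gabab_current(2, 0.01, -95), 0)
  g <- gabab_current(seq(0, 10, 0.1), 0.01, -120)
  expect_true(all(diff(g) <= 0)) # more negative (monotone in magnitude)
  expect_true(all(diff(abs(g)) >= 0))
})

test_that("miniature event streams are Poisson and gated", {
  gates <- tibble::tibble(on = numeric(0), off = numeric(0))
  expect_length(mini_generator(100, gates), 0)
  set.seed(1)
  expect_length(mini_generator(0, tibble::tibble(on = 0, off = 1000)), 0)
  # empirical mean within 3 SE of rate * window over many windows
  set.seed(123)
  rate <- 50; w <- 500 # ms
  counts <- replicate(400, length(mini_generator(rate, tibble::tibble(on = 0, off = w))))
  lambda <- rate * w / 1000
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 400))
  # determinism under a fixed seed
  set.seed(99); a <- mini_generator(40, tibble::tibble(on = 0, off = 2000))
  set.seed(99); b <- mini_generator(40, tibble::tibble(on = 0, off = 2000))
  expect_identical(a, b)
  # events fall inside the gate intervals only
  set.seed(5)
  ev <- mini_generator(80, tibble::tibble(on = c(100, 900), off = c(300, 1200)))
  expect_true(all((ev >= 100 & ev <= 300) | (ev >= 900 & ev <= 1200)))
})
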
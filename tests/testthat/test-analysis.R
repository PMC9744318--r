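# LFP, spectra, slow-oscillation segmentation and event detection on
# synthetic fixtures.

test_that("LFP is linear in the synaptic currents and respects the sign flip", {
  syn <- tibble::tibble(t_ms = 1:100, AMPA = -1, NMDA = -0.5, GABA_A = 0.5)
  l1 <- compute_lfp(syn)
  expect_true(all(l1$lfp == 1))
  syn2 <- dplyr::mutate(syn, AMPA = 2 * AMPA, NMDA = 2 * NMDA,
                        GABA_A = 2 * GABA_A)
  expect_equal(compute_lfp(syn2)$lfp, 2 * l1$lfp)
  expect_true(all(compute_lfp(dplyr::mutate(syn, AMPA = 0, NMDA = 0,
                                            GABA_A = 0))$lfp == 0))
})

test_that("causal smoothing has the rectangular impulse response", {
  x <- make_fixture("sinusoid", list(freq_hz = 1, duration_s = 2))
  x$lfp <- 0; x$lfp[1000] <- 1
  sm <- smooth_lfp(x, window = 200)
  expect_equal(nrow(sm), nrow(x)) # length preserved
  expect_equal(sm$lfp[1000:1199], rep(1 / 200, 200))
  expect_equal(sm$lfp[999], 0)
  expect_equal(sm$lfp[1200], 0)
  # constant trace unchanged; smoothing idempotent only then
  x$lfp <- 3
  expect_equal(smooth_lfp(x, 200)$lfp, rep(3, nrow(x)))
  # white-noise variance reduced ~window-fold
  set.seed(2)
  x$lfp <- stats::rnorm(nrow(x))
  v <- stats::var(smooth_lfp(x, 200)$lfp[300:2000])
  expect_lt(v, 2 / 200)
  expect_gt(v, 0.5 / 200)
})

test_that("smoothing is shift-invariant", {
  set.seed(3)
  x <- make_fixture("sinusoid", list(freq_hz = 3, duration_s = 3))
  x$lfp <- x$lfp + stats::rnorm(nrow(x), sd = 0.1)
  s1 <- smooth_lfp(x, 100)$lfp
  xs <- x; xs$lfp <- c(rep(0, 50), x$lfp[1:(nrow(x) - 50)])
  s2 <- smooth_lfp(xs, 100)$lfp
  expect_equal(s2[201:2000], s1[151:1950], tolerance = 1e-12)
})

test_that("spectral peaks locate synthetic sinusoids within 0.2 Hz", {
  s14 <- power_spectrum(make_fixture("sinusoid", list(freq_hz = 14,
                                                      duration_s = 20)))
  expect_lt(abs(peak_frequency(s14, c(5, 20)) - 14), 0.2)
  mix <- make_fixture("sinusoid", list(freq_hz = c(1, 10, 14),
                                       duration_s = 30))
  sp <- power_spectrum(mix)
  expect_lt(abs(peak_frequency(sp, c(0.3, 5)) - 1), 0.2)
  expect_lt(abs(peak_frequency(sp, c(8, 12)) - 10), 0.2)
  expect_lt(abs(peak_frequency(sp, c(12, 16)) - 14), 0.2)
  expect_error(power_spectrum(make_fixture("sinusoid",
                                           list(duration_s = 5))), "short")
})

test_that("total spectral power matches the time-domain variance", {
  set.seed(4)
  x <- make_fixture("sinusoid", list(freq_hz = 5, duration_s = 60))
  x$lfp <- stats::rnorm(nrow(x))
  sp <- power_spectrum(x, segment_s = 60, overlap = 0)
  df <- diff(sp$freq_hz[1:2])
  expect_equal(sum(sp$power) * df, stats::var(x$lfp), tolerance = 0.01)
})

test_that("spectrogram tracks stationary and swept frequencies", {
  x <- make_fixture("sinusoid", list(freq_hz = 14, duration_s = 12))
  sg <- spectrogram(x, band = c(5, 20))
  ridge <- sg |>
    dplyr::group_by(.data$t_ms) |>
    dplyr::summarise(f = .data$freq_hz[which.max(.data$power)])
  expect_lt(max(abs(ridge$f - 14)), 1)
  # linear chirp 5 -> 20 Hz over 12 s
  t <- seq_len(12000) / 1000
  ch <- x; ch$lfp <- sin(2 * pi * (5 * t + (15 / (2 * 12)) * t^2))
  sgc <- spectrogram(ch, band = c(2, 25))
  ridge_c <- sgc |>
    dplyr::group_by(.data$t_ms) |>
    dplyr::summarise(f = .data$freq_hz[which.max(.data$power)])
  fit <- stats::coef(stats::lm(f ~ I(t_ms / 1000), data = ridge_c))
  expect_equal(unname(fit[2]), 15 / 12, tolerance = 0.15)
})

test_that("square-wave rasters segment into cycles of the right period", {
  fx <- make_fixture("square_so", list(freq_hz = 1, duration_s = 20,
                                       rate_hz = 25), seed = 8)
  sim <- fake_sim(fx$spikes, duration_ms = 20000)
  cyc <- segment_so_cycles(sim, lfp = fx$lfp, down_hold_ms = 100)
  expect_gt(nrow(cyc), 15)
  expect_equal(mean(cyc$duration_ms), 1000, tolerance = 0.05)
  expect_true(all(cyc$up_onset < cyc$next_up_onset))
  expect_true(all(cyc$initiated_by == "mini")) # no slow-TC spikes supplied
})

test_that("down-state time partitions the analysed duration", {
  fx <- make_fixture("square_so", list(freq_hz = 1, duration_s = 20,
                                       rate_hz = 25), seed = 8)
  sim <- fake_sim(fx$spikes, duration_ms = 20000)
  down <- down_state_time(sim, rate_down = 1)
  up_or_transition <- 20 - down
  expect_equal(down + up_or_transition, 20)
  # roughly half the time is silent for a 50% duty cycle
  expect_gt(down, 7); expect_lt(down, 13)
})

test_that("event detection obeys the proper-spindle lifetime rule", {
  empty <- detect_events(tibble::tibble(layer = character(0),
                                        cell = integer(0),
                                        t_ms = numeric(0)), "TC_s")
  expect_equal(nrow(empty), 0)
  # 10 Hz burst train lasting 0.8 s -> one proper slow spindle
  b <- make_fixture("burst_raster", list(freq_hz = 10, duration_s = 0.8))
  ev <- detect_events(b, "TC_s")
  expect_equal(nrow(ev), 1)
  expect_true(ev$is_spindle)
  expect_equal(ev$band, "slow")
  # 0.3 s burst -> an event but not a proper spindle
  s <- make_fixture("burst_raster", list(freq_hz = 10, duration_s = 0.3))
  ev2 <- detect_events(s, "TC_s")
  expect_equal(nrow(ev2), 1)
  expect_false(ev2$is_spindle)
  # translation invariance of event structure
  s2 <- s; s2$t_ms <- s2$t_ms + 5000
  ev3 <- detect_events(s2, "TC_s")
  expect_equal(ev3$duration_ms, ev2$duration_ms)
  expect_equal(ev3$n_spikes, ev2$n_spikes)
  expect_equal(ev3$onset_ms - 5000, ev2$onset_ms)
})

test_that("bursts split on gaps longer than the separation threshold", {
  b1 <- make_fixture("burst_raster", list(freq_hz = 10, duration_s = 0.6,
                                          onset_ms = 1000, n_cells = 1))
  b2 <- make_fixture("burst_raster", list(freq_hz = 10, duration_s = 0.6,
                                          onset_ms = 2000, n_cells = 1))
  ev <- detect_events(dplyr::bind_rows(b1, b2), "TC_s")
  expect_equal(nrow(ev), 2)
  ce <- cell_events(dplyr::bind_rows(b1, b2), "TC_s", cell = 0L)
  expect_equal(nrow(ce), 2)
  expect_equal(ce$n_spikes, c(7, 7))
})

test_that("condition comparisons report effect sizes and the P<.01 rule", {
  set.seed(10)
  a <- stats::rnorm(40, 8.1, 0.5)
  cmp_same <- compare_conditions(a, a)
  expect_equal(cmp_same$difference, 0)
  expect_false(cmp_same$significant)
  b <- stats::rnorm(40, 7.0, 0.5)
  cmp <- compare_conditions(a, b)
  expect_true(cmp$significant)
  expect_gt(cmp$cohens_d, 1)
})

test_that("summary statistics flag single-cycle dispersion as undefined", {
  fx <- make_fixture("square_so", list(freq_hz = 0.4, duration_s = 5,
                                       rate_hz = 25), seed = 8)
  sim <- fake_sim(fx$spikes, duration_ms = 5000)
  cyc <- segment_so_cycles(sim, lfp = fx$lfp, down_hold_ms = 100)
  if (nrow(cyc) == 1) {
    st <- summary_statistics(sim, cycles = cyc)
    expect_true(is.na(st$so_amplitude_sd))
  } else succeed("fixture produced more than one cycle")
})
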
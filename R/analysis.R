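# LFP computation, spectral analysis, slow-oscillation cycle
# segmentation, spindle-event detection and summary statistics.

#' Cortical local field potential
#'
#' The LFP is the sum over PY cells of the presynaptic AMPA, NMDA and
#' GABA-A currents (GABA-B excluded), sign-flipped so that depolarized
#' up states plot upward, and multiplied by the global display scale.
#' The initial settling period is dropped.
#'
#' @param sim A `"tc_sim"` object (or a tibble with `t_ms`, `AMPA`,
#'   `NMDA`, `GABA_A` columns plus a `scale`).
#' @param scale Global LFP scale factor (mV display units per nA);
#'   defaults to the configured value.
#' @param drop_settle Drop the settling period (default TRUE).
#' @return Tibble of class `"lfp_trace"` with `t_ms`, `lfp`.
#' @export
compute_lfp <- function(sim, scale = NULL, drop_settle = TRUE) {
  if (inherits(sim, "tc_sim")) {
    syn <- sim$syn_currents
    if (is.null(scale)) scale <- sim$lfp_scale
    settle <- if (drop_settle) sim$settle_ms else 0
  } else {
    syn <- sim
    if (is.null(scale)) scale <- 1
    settle <- 0
  }
  stopifnot(all(c("t_ms", "AMPA", "NMDA", "GABA_A") %in% names(syn)))
  out <- tibble::tibble(
    t_ms = syn$t_ms,
    lfp = -scale * (syn$AMPA + syn$NMDA + syn$GABA_A)
  )
  out <- out[out$t_ms > settle, ]
  attr(out, "sample_ms") <- if (nrow(out) > 1) diff(out$t_ms[1:2]) else 1
  class(out) <- c("lfp_trace", class(out))
  out
}

#' Causal moving-average smoothing of an LFP trace
#'
#' One-sided (causal) moving average over `window` samples; output length
#' is preserved (the first `window - 1` samples average the partial
#' history).
#'
#' @param trace An `"lfp_trace"` tibble.
#' @param window Window length in samples (200 samples = 200 ms at the
#'   1 kHz sampling default).
#' @export
smooth_lfp <- function(trace, window = 200) {
  stopifnot(window >= 1, nrow(trace) >= 1)
  x <- trace$lfp
  cs <- cumsum(x)
  n <- length(x)
  sm <- numeric(n)
  idx <- seq_len(n)
  lead <- idx - window
  sm <- (cs - c(rep(0, min(window, n)), cs[seq_len(max(0, n - window))])) /
    pmin(idx, window)
  out <- trace
  out$lfp <- sm
  attr(out, "sample_ms") <- attr(trace, "sample_ms")
  class(out) <- class(trace)
  out
}

#' Averaged-periodogram (Welch) power spectrum
#'
#' Hann-windowed overlapping segments, averaged; returns linear and log
#' power. The full-network spectrum shows peaks in the slow-oscillation
#' (~1 Hz), slow-spindle (8-12 Hz) and fast-spindle (12-16 Hz) bands.
#'
#' @param trace An `"lfp_trace"` tibble (>= 10 s).
#' @param segment_s Segment length (s).
#' @param overlap Fractional overlap between segments.
#' @param demean Remove the segment mean before transforming.
#' @return Tibble with `freq_hz`, `power`, `log_power`.
#' @export
power_spectrum <- function(trace, segment_s = 20, overlap = 0.5,
                           demean = TRUE) {
  dt_ms <- attr(trace, "sample_ms") %||% 1
  x <- trace$lfp
  fs <- 1000 / dt_ms
  if (length(x) < 10 * fs) stop("trace too short: need >= 10 s")
  nseg <- min(length(x), round(segment_s * fs))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  wnorm <- sum(w^2)
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    if (demean) seg <- seg - mean(seg)
    p <- Mod(stats::fft(seg * w))^2 / (wnorm * fs)
    acc <- if (is.null(acc)) p else acc + p
  }
  p <- acc / length(starts)
  nf <- floor(nseg / 2)
  freq <- (seq_len(nf)) * fs / nseg
  pw <- 2 * p[2:(nf + 1)]
  tibble::tibble(freq_hz = freq, power = pw, log_power = log10(pw))
}

#' Short-time Fourier spectrogram
#'
#' 1 s Hann window with 90% overlap by default, restricted to a frequency
#' band of interest.
#'
#' @param trace An `"lfp_trace"` tibble.
#' @param band Frequency range (Hz) to retain.
#' @param window_s Window length (s).
#' @param overlap Fractional overlap.
#' @return Tibble with `t_ms`, `freq_hz`, `power`.
#' @export
spectrogram <- function(trace, band = c(0, 25), window_s = 1, overlap = 0.9) {
  dt_ms <- attr(trace, "sample_ms") %||% 1
  fs <- 1000 / dt_ms
  n <- round(window_s * fs)
  sg <- signal::specgram(trace$lfp, n = n, Fs = fs,
                         overlap = round(n * overlap))
  keep <- sg$f >= band[1] & sg$f <= band[2]
  pw <- Mod(sg$S[keep, , drop = FALSE])^2
  tibble::tibble(
    t_ms = rep(trace$t_ms[1] + sg$t * 1000, each = sum(keep)),
    freq_hz = rep(sg$f[keep], times = length(sg$t)),
    power = as.vector(pw)
  )
}

#' Location of the dominant spectral peak within a band
#'
#' @param spec Output of [power_spectrum()].
#' @param band Frequency range (Hz).
#' @export
peak_frequency <- function(spec, band = c(0.3, 5)) {
  s <- spec[spec$freq_hz >= band[1] & spec$freq_hz <= band[2], ]
  s$freq_hz[which.max(s$power)]
}

# population firing rate (Hz/cell) in 1-ms bins from a spike tibble
population_rate <- function(spikes, layer, n_cells, duration_ms,
                            smooth_ms = 20) {
  s <- spikes$t_ms[spikes$layer == layer]
  bins <- tabulate(pmin(floor(s) + 1L, duration_ms), nbins = duration_ms)
  k <- rep(1 / smooth_ms, smooth_ms)
  r <- stats::filter(bins, k, sides = 2)
  r[is.na(r)] <- 0
  as.numeric(r) * 1000 / n_cells
}

#' Segment slow-oscillation cycles
#'
#' Cycles are segmented from the PY population firing rate: an up state
#' begins when the smoothed rate exceeds `rate_up` (Hz/cell) and ends
#' when it stays below `rate_down` for `down_hold_ms`. A cycle runs from
#' one up onset to the next; its amplitude is the peak-to-trough
#' excursion of the smoothed LFP within the cycle. Each cycle is
#' labelled `initiated_by = "slow_spindle"` when slow-subnetwork TC
#' spikes precede the up onset within the attribution window and no
#' miniature event fell in the `mini_veto_ms` before it, otherwise
#' `"mini"`.
#'
#' @param sim A `"tc_sim"` object.
#' @param lfp Smoothed LFP trace (computed from `sim` if missing).
#' @param rate_up,rate_down Up/down thresholds (Hz/cell).
#' @param down_hold_ms Minimum below-threshold time ending an up state.
#' @param attribution_ms Slow-spindle attribution window before up onset.
#' @param mini_veto_ms Mini-free interval required for slow-spindle
#'   attribution.
#' @return Tibble of class `"so_cycles"`: one row per complete cycle.
#' @export
segment_so_cycles <- function(sim, lfp = NULL, rate_up = NULL, rate_down = NULL,
                              down_hold_ms = NULL, attribution_ms = 200,
                              mini_veto_ms = 100) {
  stopifnot(inherits(sim, "tc_sim"))
  sd <- sim$config$so_detect
  rate_up <- rate_up %||% sd$rate_up
  rate_down <- rate_down %||% sd$rate_down
  down_hold_ms <- down_hold_ms %||% sd$down_hold_ms
  if (is.null(lfp)) lfp <- smooth_lfp(compute_lfp(sim), sim$smooth_window)
  npy <- sim$config$layers$size[sim$config$layers$layer == "PY"]
  dur <- as.integer(sim$duration_ms)
  rate <- population_rate(sim$spikes, "PY", npy, dur)
  t_bin <- seq_len(dur) - 0.5
  settle <- sim$settle_ms
  up <- rate > rate_up
  onsets <- offs <- numeric(0)
  state <- FALSE; below_since <- NA_real_
  for (i in seq_along(rate)) {
    if (!state && up[i]) {
      state <- TRUE; below_since <- NA_real_
      onsets <- c(onsets, t_bin[i])
    } else if (state) {
      if (rate[i] < rate_down) {
        if (is.na(below_since)) below_since <- t_bin[i]
        if (t_bin[i] - below_since >= down_hold_ms) {
          state <- FALSE
          offs <- c(offs, below_since)
        }
      } else below_since <- NA_real_
    }
  }
  onsets <- onsets[onsets > settle]
  if (length(onsets) < 2)
    return(tibble::tibble(up_onset = numeric(0), up_offset = numeric(0),
                          next_up_onset = numeric(0), duration_ms = numeric(0),
                          amplitude = numeric(0), initiated_by = character(0)))
  tc_s <- sim$spikes$t_ms[sim$spikes$layer == "TC_s"]
  minis <- sim$log$mini_times
  cyc <- purrr::map_dfr(seq_len(length(onsets) - 1), function(k) {
    a <- onsets[k]; b <- onsets[k + 1]
    off <- offs[offs > a & offs < b]
    off <- if (length(off) > 0) off[1] else NA_real_
    seg <- lfp$lfp[lfp$t_ms >= a & lfp$t_ms < b]
    amp <- if (length(seg) > 1) max(seg) - min(seg) else NA_real_
    slow_in <- length(tc_s) > 0 &&
      any(tc_s >= a - attribution_ms & tc_s <= a)
    mini_in <- length(minis) > 0 &&
      any(minis >= a - mini_veto_ms & minis <= a)
    tibble::tibble(
      up_onset = a, up_offset = off, next_up_onset = b,
      duration_ms = b - a, amplitude = amp,
      initiated_by = if (slow_in && !mini_in) "slow_spindle" else "mini"
    )
  })
  class(cyc) <- c("so_cycles", class(cyc))
  cyc
}

#' Total down-state time
#'
#' Sums the silent (below-rate) time between consecutive up states over
#' the analysed span.
#'
#' @inheritParams segment_so_cycles
#' @param from_ms,to_ms Analysis span (defaults: settle end, run end).
#' @export
down_state_time <- function(sim, rate_down = NULL, from_ms = NULL, to_ms = NULL) {
  rate_down <- rate_down %||% sim$config$so_detect$rate_down
  npy <- sim$config$layers$size[sim$config$layers$layer == "PY"]
  dur <- as.integer(sim$duration_ms)
  rate <- population_rate(sim$spikes, "PY", npy, dur)
  t_bin <- seq_len(dur) - 0.5
  from_ms <- from_ms %||% sim$settle_ms
  to_ms <- to_ms %||% sim$duration_ms
  sel <- t_bin >= from_ms & t_bin <= to_ms
  sum(rate[sel] < rate_down) / 1000
}

#' Detect thalamic burst events and classify proper spindles
#'
#' Groups the population spikes of one thalamic layer into events
#' separated by more than `gap_ms` of silence. Events lasting at least
#' `min_spindle_ms` are proper spindles; shorter trains are still
#' events. `n_spikes` counts the whole layer, `n_spikes_center` the
#' central cell.
#'
#' @param spikes Spike tibble (`layer`, `cell`, `t_ms`).
#' @param layer Thalamic layer name (`"TC_f"` or `"TC_s"`).
#' @param gap_ms Silence gap splitting events.
#' @param min_spindle_ms Proper-spindle lifetime rule (>= 0.5 s).
#' @param center_cell Zero-based index of the representative cell.
#' @param from_ms Drop events before this time.
#' @return Tibble: `band`, `onset_ms`, `offset_ms`, `duration_ms`,
#'   `n_spikes`, `n_spikes_center`, `is_spindle`.
#' @export
detect_events <- function(spikes, layer, gap_ms = 250, min_spindle_ms = 500,
                          center_cell = 20L, from_ms = 0) {
  band <- if (grepl("_s$", layer)) "slow" else "fast"
  s <- dplyr::filter(spikes, .data$layer == !!layer, .data$t_ms >= from_ms)
  if (nrow(s) == 0)
    return(tibble::tibble(band = character(0), onset_ms = numeric(0),
                          offset_ms = numeric(0), duration_ms = numeric(0),
                          n_spikes = integer(0), n_spikes_center = integer(0),
                          is_spindle = logical(0)))
  ts <- sort(s$t_ms)
  grp <- cumsum(c(1, diff(ts) > gap_ms))
  ev <- tibble::tibble(t = ts, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(onset_ms = min(.data$t), offset_ms = max(.data$t),
                     n_spikes = dplyr::n(), .groups = "drop")
  cen <- s$t_ms[s$cell == center_cell]
  ev$n_spikes_center <- vapply(seq_len(nrow(ev)), function(i)
    sum(cen >= ev$onset_ms[i] & cen <= ev$offset_ms[i]), integer(1))
  tibble::tibble(
    band = band,
    onset_ms = ev$onset_ms, offset_ms = ev$offset_ms,
    duration_ms = ev$offset_ms - ev$onset_ms,
    n_spikes = ev$n_spikes, n_spikes_center = ev$n_spikes_center,
    is_spindle = (ev$offset_ms - ev$onset_ms) >= min_spindle_ms
  )
}

#' Dominant firing frequency from inter-spike intervals
#'
#' The modal instantaneous rate (1/ISI) of one cell, restricted to ISIs
#' inside the oscillation band of interest (intra-burst intervals and
#' long pauses excluded), optionally within stimulation windows only.
#'
#' @param spikes Spike tibble.
#' @param layer,cell Cell selector (zero-based index).
#' @param windows Optional two-column matrix/data frame of window
#'   `(start, end)` times (ms); ISIs must fall inside one window.
#' @param band Frequency band (Hz) of admissible 1/ISI values.
#' @return Modal frequency (Hz), or `NA` if no admissible ISI.
#' @export
isi_dominant_frequency <- function(spikes, layer, cell, windows = NULL,
                                   band = c(5, 40)) {
  ts <- sort(spikes$t_ms[spikes$layer == layer & spikes$cell == cell])
  if (length(ts) < 3) return(NA_real_)
  isi <- diff(ts)
  t_mid <- ts[-length(ts)]
  ok <- rep(TRUE, length(isi))
  if (!is.null(windows)) {
    w <- as.matrix(windows)
    ok <- vapply(seq_along(isi), function(i)
      any(t_mid[i] >= w[, 1] & ts[i + 1] <= w[, 2]), logical(1))
  }
  f <- 1000 / isi[ok]
  f <- f[f >= band[1] & f <= band[2]]
  if (length(f) < 3) return(NA_real_)
  d <- stats::density(f, bw = 0.5)
  d$x[which.max(d$y)]
}

#' Summary statistics of a simulated condition
#'
#' Mean slow-oscillation amplitude and cycle duration (with SD across
#' cycles), total down-state time, thalamic events per minute and spikes
#' per event, and the fraction of slow-spindle-initiated cycles.
#'
#' @param sim A `"tc_sim"` object.
#' @param cycles Optional precomputed [segment_so_cycles()] output.
#' @return One-row tibble.
#' @export
summary_statistics <- function(sim, cycles = NULL) {
  if (is.null(cycles)) cycles <- segment_so_cycles(sim)
  span_s <- (sim$duration_ms - sim$settle_ms) / 1000
  ev_f <- detect_events(sim$spikes, "TC_f", from_ms = sim$settle_ms)
  ev_s <- detect_events(sim$spikes, "TC_s", from_ms = sim$settle_ms)
  tibble::tibble(
    n_cycles = nrow(cycles),
    so_amplitude_mean = mean(cycles$amplitude, na.rm = TRUE),
    so_amplitude_sd = if (nrow(cycles) > 1) stats::sd(cycles$amplitude, na.rm = TRUE) else NA_real_,
    so_duration_mean_ms = mean(cycles$duration_ms),
    so_duration_sd_ms = if (nrow(cycles) > 1) stats::sd(cycles$duration_ms) else NA_real_,
    so_rate_hz = nrow(cycles) / span_s,
    down_time_s = down_state_time(sim),
    frac_slow_initiated = if (nrow(cycles) > 0)
      mean(cycles$initiated_by == "slow_spindle") else NA_real_,
    fast_events_per_min = nrow(ev_f) / (span_s / 60),
    slow_events_per_min = nrow(ev_s) / (span_s / 60),
    fast_spikes_per_event = mean(ev_f$n_spikes_center[ev_f$n_spikes_center > 0]),
    slow_spikes_per_event = mean(ev_s$n_spikes_center[ev_s$n_spikes_center > 0])
  )
}

#' Compare a statistic between two conditions
#'
#' Two-sample comparison (Welch t-test at the P < .01 criterion) with
#' Cohen's d reported alongside.
#'
#' @param a,b Numeric vectors of per-cycle (or per-event) values.
#' @return One-row tibble: means, difference, `cohens_d`, `p_value`,
#'   `significant`.
#' @export
compare_conditions <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  sp <- sqrt((stats::var(a) * (length(a) - 1) + stats::var(b) * (length(b) - 1)) /
               (length(a) + length(b) - 2))
  tt <- stats::t.test(a, b)
  tibble::tibble(
    mean_a = mean(a), mean_b = mean(b), difference = mean(a) - mean(b),
    cohens_d = (mean(a) - mean(b)) / sp,
    p_value = tt$p.value, significant = tt$p.value < 0.01
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dominant oscillation frequency of a membrane-potential trace
#'
#' Welch-style averaged spectrum of a recorded cell's membrane potential
#' over a set of analysis windows, returning the peak frequency within a
#' band. Robust to subharmonic firing: relay cells often fire on every
#' second cycle of a spindle while their membrane potential oscillates at
#' the full network frequency.
#'
#' @param sim A `"tc_sim"` object with the cell in `traces`.
#' @param trace Column name in `sim$traces` (e.g. `"TC_f_20"`).
#' @param windows Two-column matrix of `(start, end)` times (ms); e.g.
#'   [step_windows()]. Default: one window spanning the post-settle run.
#' @param band Frequency band searched (Hz).
#' @param skip_ms Dropped from the start of each window.
#' @param nfft Zero-padded transform length (frequency resolution).
#' @return Peak frequency (Hz), or `NA` if no usable window.
#' @export
membrane_dominant_frequency <- function(sim, trace, windows = NULL,
                                        band = c(5, 20), skip_ms = 100,
                                        nfft = 8192) {
  tr <- sim$traces
  stopifnot(trace %in% names(tr))
  if (is.null(windows))
    windows <- cbind(sim$settle_ms, sim$duration_ms)
  pacc <- NULL
  for (i in seq_len(nrow(windows))) {
    v <- tr[[trace]][tr$t_ms >= windows[i, 1] + skip_ms &
                       tr$t_ms <= windows[i, 2]]
    if (length(v) < 256) next
    v <- v - mean(v)
    v <- v * 0.5 * (1 - cos(2 * pi * seq_along(v) / (length(v) + 1)))
    if (length(v) > nfft) v <- v[seq_len(nfft)]
    p <- Mod(stats::fft(c(v, rep(0, nfft - length(v)))))^2
    pacc <- if (is.null(pacc)) p else pacc + p
  }
  if (is.null(pacc)) return(NA_real_)
  fr <- (seq_len(nfft) - 1) * 1000 / nfft
  sel <- fr >= band[1] & fr <= band[2]
  fr[sel][which.max(pacc[sel])]
}

#' Burst events of a single cell
#'
#' Groups one cell's spike train into events separated by more than
#' `gap_ms` of silence; used for per-cell spikes-per-event statistics.
#'
#' @inheritParams detect_events
#' @param cell Zero-based cell index.
#' @return Tibble: `onset_ms`, `offset_ms`, `duration_ms`, `n_spikes`.
#' @export
cell_events <- function(spikes, layer, cell = 20L, gap_ms = 250,
                        from_ms = 0) {
  ts <- sort(spikes$t_ms[spikes$layer == layer & spikes$cell == cell &
                           spikes$t_ms >= from_ms])
  if (length(ts) == 0)
    return(tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0), n_spikes = integer(0)))
  grp <- cumsum(c(1, diff(ts) > gap_ms))
  tibble::tibble(t = ts, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(onset_ms = min(.data$t), offset_ms = max(.data$t),
                     n_spikes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(duration_ms = .data$offset_ms - .data$onset_ms) |>
    dplyr::select("onset_ms", "offset_ms", "duration_ms", "n_spikes")
}
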
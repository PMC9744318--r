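# Experiment presets: each named condition is a pure override of the
# control configuration, paired with its protocol and a default duration.

#' Available experiment presets
#' @export
preset_names <- function() {
  c("control_full", "block_slow", "block_fast", "block_both",
    "reduced_minis", "reduced_minis_no_slow", "fast_for_slow",
    "hyperpolarized_fast", "cortex_only", "fast_isolated",
    "fast_isolated_gkl", "slow_isolated")
}

#' Build the network and protocol for a named preset
#'
#' @param name One of [preset_names()]:
#'   * `control_full`: all six layers, mini-driven slow oscillations.
#'   * `block_slow` / `block_fast` / `block_both`: corticothalamic
#'     conductances to the named subnetwork(s) set to zero.
#'   * `reduced_minis`: control network, miniature rate halved;
#'     `reduced_minis_no_slow` additionally blocks the slow subnetwork.
#'   * `fast_for_slow`: slow-subnetwork layers take the fast-subnetwork
#'     parameters (keeping the 600 ms delay).
#'   * `hyperpolarized_fast`: fast-subnetwork TC potassium leak raised
#'     to 0.033 mS/cm^2.
#'   * `cortex_only`: isolated two-layer cortical network, mini protocol.
#'   * `fast_isolated` / `fast_isolated_gkl` / `slow_isolated`: one
#'     thalamic subnetwork under the 0.065/0.09 nA step protocol
#'     (`_gkl` raises TC leak to 0.033).
#' @param mini_factor Rate multiplier for the reduced-mini presets.
#' @return List with `network`, `protocol`, `duration_ms`.
#' @export
preset <- function(name, mini_factor = 0.8) {
  full <- function() build_network(network_config())
  p <- switch(name,
    control_full = list(full(), protocol_minis(), 120000),
    block_slow = list(block_subnetwork(full(), "slow"), protocol_minis(), 120000),
    block_fast = list(block_subnetwork(full(), "fast"), protocol_minis(), 120000),
    block_both = list(block_subnetwork(full(), "both"), protocol_minis(), 120000),
    reduced_minis = list(full(), protocol_minis(rate_factor = mini_factor), 120000),
    reduced_minis_no_slow = list(block_subnetwork(full(), "slow"),
                                 protocol_minis(rate_factor = mini_factor), 120000),
    fast_for_slow = list(swap_slow_for_fast(full()), protocol_minis(), 30000),
    hyperpolarized_fast = list(apply_gkl_override(full(), "TC_f", 0.033),
                               protocol_minis(), 120000),
    cortex_only = list(build_network(network_config(layers = c("PY", "IN"))),
                       protocol_minis(), 60000),
    fast_isolated = list(build_network(network_config(layers = c("TC_f", "RE_f"))),
                         protocol_step(), 12000),
    fast_isolated_gkl = list(
      apply_gkl_override(
        build_network(network_config(layers = c("TC_f", "RE_f"))),
        "TC_f", 0.033),
      protocol_step(), 12000),
    slow_isolated = list(build_network(network_config(layers = c("TC_s", "RE_s"))),
                         protocol_step(), 12000),
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  )
  names(p) <- c("network", "protocol", "duration_ms")
  p
}

#' Run a preset end to end
#'
#' Builds the preset network, simulates it, and returns the simulation
#' together with its summary report.
#'
#' @param name Preset name (see [preset()]).
#' @param seed Integer seed.
#' @param duration_ms Optional duration override (ms).
#' @param dt Optional integration-step override (ms).
#' @return List with `sim` (a `"tc_sim"`) and `report` (a one-row tibble).
#' @export
run_preset <- function(name, seed = 1L, duration_ms = NULL, dt = NULL) {
  ps <- preset(name)
  dur <- duration_ms %||% ps$duration_ms
  sim <- simulate_network(ps$network, ps$protocol, dur, seed = seed, dt = dt)
  report <- if ("PY" %in% sim$config$layers$layer)
    summary_statistics(sim)
  else {
    win <- step_windows(sim)
    tc <- grep("^TC", sim$config$layers$layer, value = TRUE)[1]
    tibble::tibble(
      tc_dominant_hz = membrane_dominant_frequency(
        sim, paste0(tc, "_20"), windows = win),
      tc_isi_hz = isi_dominant_frequency(sim$spikes, tc, 20L, windows = win),
      n_spikes = nrow(sim$spikes)
    )
  }
  list(sim = sim, report = report)
}

#' Stimulation windows of a step-protocol run
#'
#' @param sim A `"tc_sim"` run with [protocol_step()].
#' @return Matrix with `start`, `end` columns (ms).
#' @export
step_windows <- function(sim) {
  p <- sim$protocol
  stopifnot(identical(p$kind, "step"))
  starts <- seq(p$start_ms, sim$duration_ms - 1, by = p$period_ms)
  cbind(start = starts, end = pmin(starts + p$on_ms, sim$duration_ms))
}
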
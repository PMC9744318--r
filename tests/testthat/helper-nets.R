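# Shared builders and a per-session cache so expensive simulations are
# run once and reused across expectations.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# one-layer network with no synapses: isolated cells at rest
lonely_layer <- function(layer) {
  cfg <- network_config(layers = layer)
  cfg$projections <- cfg$projections[0, ]
  build_network(cfg)
}

# minimal object that the analysis functions accept in place of a full
# simulation (synthetic rasters/LFP in, statistics out)
fake_sim <- function(spikes, syn = NULL, duration_ms = 10000,
                     settle_ms = 0, mini_times = numeric(0)) {
  if (is.null(syn))
    syn <- tibble::tibble(t_ms = seq_len(duration_ms), AMPA = 0, NMDA = 0,
                          GABA_A = 0)
  structure(list(
    spikes = spikes,
    syn_currents = syn,
    log = list(mini_times = mini_times, up_onsets = numeric(0),
               down_onsets = numeric(0)),
    duration_ms = duration_ms,
    settle_ms = settle_ms,
    lfp_scale = 1,
    smooth_window = 200,
    config = list(layers = tibble::tibble(
      layer = c("PY", "IN", "TC_f", "RE_f", "TC_s", "RE_s"),
      size = c(200L, 40L, 40L, 40L, 40L, 40L)),
      so_detect = list(rate_up = 10, rate_down = 1, window_ms = 20,
                       down_hold_ms = 300))
  ), class = "tc_sim")
}

# dominant frequency of a step-protocol run, from the central TC cell's
# membrane-potential spectrum
step_run_frequency <- function(preset_name, seed = 1, duration_ms = 12000) {
  r <- cached(paste0(preset_name, "_", seed, "_", duration_ms),
              run_preset(preset_name, seed = seed, duration_ms = duration_ms))
  r$report$tc_dominant_hz
}
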
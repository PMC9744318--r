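# Driving the network engine: protocol constructors, gating lookup-table
# construction, and the simulation front end.

#' Stimulation protocols
#'
#' `protocol_minis()` drives slow-oscillation cycles with gated Poisson
#' miniature currents (the default network protocol); `rate_factor < 1`
#' emulates the reduced-mini experiments. `protocol_step()` injects the
#' isolated-network step currents: 0.065 nA into TC and 0.09 nA into RE
#' cells for 600 ms every 3 s. `protocol_none()` applies no input.
#'
#' @param rate_factor Multiplier on the miniature event rate.
#' @param tc_nA,re_nA Injected currents (nA).
#' @param on_ms,period_ms,start_ms Stimulation window, period, first onset (ms).
#' @return A list of class `"tc_protocol"`.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_minis <- function(rate_factor = 1) {
  structure(list(kind = "minis", rate_factor = rate_factor),
            class = "tc_protocol")
}

#' @rdname protocols
#' @export
protocol_step <- function(tc_nA = 0.065, re_nA = 0.09, on_ms = 600,
                          period_ms = 3000, start_ms = 1000) {
  structure(list(kind = "step", tc_nA = tc_nA, re_nA = re_nA, on_ms = on_ms,
                 period_ms = period_ms, start_ms = start_ms),
            class = "tc_protocol")
}

#' @rdname protocols
#' @export
protocol_none <- function() {
  structure(list(kind = "none"), class = "tc_protocol")
}

# Build the voltage-indexed gating tables (steady state + exp(-dt/tau))
# from the exported rate functions, so the engine and the R reference
# share one set of formulas.
gating_tables <- function(dt, vmin = -130, vmax = 60, vstep = 0.05) {
  V <- seq(vmin, vmax, by = vstep)
  tab <- function(id, gate) {
    g <- rate_functions(id, V)[[gate]]
    cbind(inf = g$inf, dec = exp(-dt / g$tau))
  }
  list(
    vmin = vmin, vstep = vstep,
    cNa_m = tab("Na", "m"), cNa_h = tab("Na", "h"),
    cK = tab("K", "m"), cKm = tab("Km", "m"),
    cHVA_m = tab("HVA", "m"), cHVA_h = tab("HVA", "h"),
    tNa_m = tab("Na_t", "m"), tNa_h = tab("Na_t", "h"),
    tK = tab("K_t", "m"),
    tcT_m = tab("T_tc", "m"), tcT_h = tab("T_tc", "h"),
    reT_m = tab("T_re", "m"), reT_h = tab("T_re", "h"),
    ih = tab("h_tc", "s"),
    nmdaF = nmda_gate(V),
    tdrive = ghk_t_drive(V)
  )
}

# Marshal a tc_network + protocol into the flat lists the engine expects.
engine_config <- function(network, protocol, record = "centers") {
  cfg <- network$config
  layers <- cfg$layers$layer
  kind_of <- function(l) switch(cfg$membrane[[l]]$kind,
                                cortical = 0L, TC = 1L, RE = 2L)
  lidx <- stats::setNames(seq_along(layers) - 1L, layers)
  Lc <- lapply(layers, function(l) {
    list(name = l, size = cfg$layers$size[cfg$layers$layer == l],
         kind = kind_of(l), params = cfg$membrane[[l]])
  })
  rmap <- c(AMPA = 0L, NMDA = 1L, GABA_A = 2L, GABA_B = 3L)
  pr <- cfg$projections
  Pc <- purrr::pmap(pr, function(source, target, receptor, g_uS, radius,
                                 delay_ms, depressing, E_override, per_target) {
    E <- if (!is.na(E_override)) E_override else cfg$receptors[[receptor]]$E
    U <- if (receptor == "AMPA") cfg$depression$U_AMPA
         else if (receptor == "GABA_A") cfg$depression$U_GABA_A else 0
    list(src = unname(lidx[source]), tgt = unname(lidx[target]),
         receptor = unname(rmap[receptor]), g = g_uS, E = E, radius = radius,
         delay_ms = delay_ms, depressing = depressing, U = U,
         self_excl = (source == target) && !cfg$self_connect,
         fanin_div = isTRUE(cfg$divide_by_fanin) || isTRUE(per_target))
  })
  minis_enabled <- identical(protocol$kind, "minis")
  streams <- list()
  if (minis_enabled) {
    gm <- cfg$minis$g_uS
    add <- function(src, tgt, receptor, g) {
      if (all(c(src, tgt) %in% layers))
        streams[[length(streams) + 1]] <<-
          list(tgt = unname(lidx[tgt]), receptor = unname(rmap[receptor]), g = g)
    }
    add("PY", "PY", "AMPA", gm[["PY_PY"]])
    add("PY", "IN", "AMPA", gm[["PY_IN"]])
    add("IN", "PY", "GABA_A", gm[["IN_PY"]])
  }
  rate_factor <- if (!is.null(protocol$rate_factor)) protocol$rate_factor
                 else cfg$minis$rate_factor
  rec_layer <- integer(0); rec_cell <- integer(0)
  if (identical(record, "centers")) {
    rec_layer <- unname(lidx[layers])
    rec_cell <- as.integer(cfg$layers$size %/% 2)
  } else if (is.data.frame(record)) {
    rec_layer <- unname(lidx[record$layer])
    rec_cell <- as.integer(record$cell)
  }
  list(
    layers = Lc, projections = Pc,
    receptors = cfg$receptors,
    transmitter = cfg$transmitter,
    depression = cfg$depression,
    minis = list(enabled = minis_enabled,
                 rate_ms = cfg$minis$rate_hz * rate_factor / 1000,
                 gate_delay_ms = cfg$minis$gate_delay_ms,
                 streams = streams),
    spike = cfg$spike,
    so_detect = cfg$so_detect,
    sample_ms = cfg$lfp$sample_ms,
    record_layer = rec_layer,
    record_cell = rec_cell
  )
}

#' Run a network simulation
#'
#' Advances the network with a fixed step and returns spikes, sampled
#' membrane potentials, the per-receptor presynaptic currents onto PY
#' cells (the raw material of the LFP), and the protocol log (mini gate
#' openings, up/down-state onsets). Deterministic for a fixed
#' `(network, protocol, seed, dt)`.
#'
#' @param network A `"tc_network"` object from [build_network()].
#' @param protocol A protocol from [protocol_minis()], [protocol_step()]
#'   or [protocol_none()].
#' @param duration_ms Simulated time (ms).
#' @param seed Integer seed for the miniature-event streams.
#' @param dt Override the configured integration step (ms).
#' @param record `"centers"` (central cell of each layer) or a data frame
#'   with `layer`, `cell` (zero-based) columns.
#' @return A list of class `"tc_sim"`: `spikes`, `traces`,
#'   `syn_currents` tibbles, `log` list, and the run metadata.
#' @export
simulate_network <- function(network, protocol, duration_ms, seed = 1L,
                     dt = NULL, record = "centers") {
  stopifnot(inherits(network, "tc_network"), inherits(protocol, "tc_protocol"),
            duration_ms > 0)
  cfg <- network$config
  if (!is.null(dt)) cfg$dt <- dt
  dt <- cfg$dt
  ec <- engine_config(structure(list(config = cfg), class = "tc_network"),
                      protocol, record)
  tb <- gating_tables(dt)
  set.seed(seed)
  raw <- simulate_network_cpp(ec, tb, duration_ms, dt, unclass(protocol))
  layers <- cfg$layers$layer
  spikes <- tibble::tibble(
    layer = layers[raw$spike_layer + 1L],
    cell = raw$spike_cell,
    t_ms = raw$spike_t
  )
  rec_names <- paste0(layers[ec$record_layer + 1L], "_", ec$record_cell)
  traces <- tibble::as_tibble(raw$v, .name_repair = "minimal")
  names(traces) <- rec_names
  traces <- dplyr::bind_cols(tibble::tibble(t_ms = raw$time), traces)
  syn <- tibble::tibble(
    t_ms = raw$time,
    AMPA = raw$lfp_components[, 1],
    NMDA = raw$lfp_components[, 2],
    GABA_A = raw$lfp_components[, 3]
  )
  structure(list(
    spikes = spikes,
    traces = traces,
    syn_currents = syn,
    log = list(
      mini_times = raw$mini_times,
      up_onsets = raw$up_onsets,
      down_onsets = raw$down_onsets,
      gate_opens = raw$gate_opens,
      gate_closes = raw$gate_closes,
      gate = raw$gate,
      state_up = raw$state_up
    ),
    n_synapses = raw$n_synapses,
    duration_ms = duration_ms,
    dt = dt,
    seed = seed,
    settle_ms = cfg$settle_ms,
    lfp_scale = cfg$lfp$scale,
    smooth_window = cfg$lfp$smooth_window,
    protocol = protocol,
    config = cfg
  ), class = "tc_sim")
}

#' @export
print.tc_sim <- function(x, ...) {
  cat("<tc_sim> ", x$duration_ms / 1000, " s, dt = ", x$dt, " ms, layers: ",
      paste(x$config$layers$layer, collapse = ", "), "\n",
      "  spikes: ", nrow(x$spikes), "; SO up-state onsets: ",
      length(x$log$up_onsets), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation: one row per spike
#' @param x A `"tc_sim"` object.
#' @param ... Unused.
#' @method tidy tc_sim
#' @export
tidy.tc_sim <- function(x, ...) x$spikes

#' One-row summary of a simulation
#' @param x A `"tc_sim"` object.
#' @param ... Unused.
#' @method glance tc_sim
#' @export
glance.tc_sim <- function(x, ...) {
  tibble::tibble(
    duration_s = x$duration_ms / 1000,
    dt_ms = x$dt,
    n_layers = nrow(x$config$layers),
    n_cells = sum(x$config$layers$size),
    n_synapses = x$n_synapses,
    n_spikes = nrow(x$spikes),
    n_so_cycles = length(x$log$up_onsets),
    seed = x$seed
  )
}
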
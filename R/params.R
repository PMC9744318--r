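# Default model parameterization: membrane blocks per cell population,
# receptor kinetics, and the synaptic projection table.

#' Membrane parameter block for one cell population
#'
#' Conductance densities in mS/cm^2, reversal potentials in mV, membrane
#' capacitance in uF/cm^2, areas in cm^2. Cortical cells are
#' two-compartment (dendrite + quasi-static axosomatic compartment with
#' the huge spike conductances); thalamic cells are single-compartment.
#' The slow-spindle thalamic blocks differ from the fast blocks by lower
#' sodium/T conductances and more hyperpolarized leak reversals, which is
#' what slows their spindle frequency into the 8-12 Hz band.
#'
#' @param population One of `"PY"`, `"IN"`, `"TC_f"`, `"RE_f"`, `"TC_s"`,
#'   `"RE_s"`.
#' @return Named list of parameters.
#' @export
cell_parameters <- function(population) {
  cort <- function(rho, g_Nap_soma, g_Nap_dend, g_Km) {
    list(
      kind = "cortical", Cm = 0.75, rho = rho,
      R_Mohm = 10, S_soma = 1e-6,
      ca_tau = 165, # slow dendritic pool; thalamic cells use the 5 ms pool
      hetero = 0.1, # per-cell uniform jitter of the dendritic leak
      soma = list(g_Na = 3000, E_Na = 50, g_K = 200, E_K = -95,
                  g_Nap = g_Nap_soma),
      dend = list(g_Na = 1.5, E_Na = 50, g_Nap = g_Nap_dend,
                  g_KL = 0.003, E_KL = -95, g_L = 0.034, E_L = -68,
                  g_HVA = 0.01, E_Ca = 140, g_KCa = 0.3, E_K = -95,
                  g_Km = g_Km)
    )
  }
  switch(population,
    PY = cort(rho = 165, g_Nap_soma = 15, g_Nap_dend = 2.5, g_Km = 0.02),
    IN = cort(rho = 50, g_Nap_soma = 0, g_Nap_dend = 0, g_Km = 0.03),
    TC_f = list(kind = "TC", Cm = 1, area = 2.9e-4, ca_tau = 5, hetero = 0,
                g_Na = 90, E_Na = 50, g_K = 10, E_K = -95,
                g_KL = 0.03, E_KL = -95, g_L = 0.01, E_L = -70,
                g_T = 1.8, E_Ca = 120, M_T = 2, g_h = 0.025, E_h = -40),
    RE_f = list(kind = "RE", Cm = 1, area = 1.43e-4, ca_tau = 5, hetero = 0,
                g_Na = 100, E_Na = 50, g_K = 10, E_K = -95,
                g_KL = 0.005, E_KL = -95, g_L = 0.05, E_L = -77,
                g_T = 1.8, E_Ca = 120, M_T = 2),
    TC_s = list(kind = "TC", Cm = 1, area = 2.9e-4, ca_tau = 5, hetero = 0,
                g_Na = 70, E_Na = 50, g_K = 12, E_K = -95,
                g_KL = 0.03, E_KL = -95, g_L = 0.01, E_L = -77,
                g_T = 1, E_Ca = 120, M_T = 2, g_h = 0.017, E_h = -40),
    RE_s = list(kind = "RE", Cm = 1, area = 1.43e-4, ca_tau = 5, hetero = 0,
                g_Na = 100, E_Na = 50, g_K = 10, E_K = -95,
                g_KL = 0.015, E_KL = -95, g_L = 0.016, E_L = -82,
                g_T = 1, E_Ca = 120, M_T = 2),
    stop("unknown population: ", population)
  )
}

#' Synaptic projection table
#'
#' The 21 synaptic pathways of the default network: intracortical
#' (with short-term depression), intrathalamic, thalamocortical and
#' corticothalamic rows for both spindle subnetworks. `g_uS` is the
#' per-synapse maximal conductance (uS), `radius` the connection radius in
#' target-layer index units, `delay_ms` the conduction delay
#' (600 ms on the corticothalamic projections to the slow subnetwork,
#' otherwise one integration step). `E_override` replaces the receptor
#' reversal where set (GABA-A onto slow-subnetwork TC cells: -88 mV).
#'
#' @return A tibble with one row per projection.
#' @export
projection_table <- function() {
  tibble::tribble(
    ~source, ~target, ~receptor, ~g_uS, ~radius, ~delay_ms, ~depressing, ~E_override, ~per_target,
    "PY",   "PY",   "AMPA",   0.026,  11, 0,   TRUE,  NA, FALSE,
    "PY",   "PY",   "NMDA",   0.0018, 11, 0,   FALSE, NA, FALSE,
    "PY",   "IN",   "AMPA",   0.05,    3, 0,   TRUE,  NA, TRUE,
    "PY",   "IN",   "NMDA",   0.001,   3, 0,   FALSE, NA, TRUE,
    "IN",   "PY",   "GABA_A", 0.16,   11, 0,   TRUE,  NA, TRUE,
    "TC_f", "RE_f", "AMPA",   0.025,  17, 0,   FALSE, NA, FALSE,
    "RE_f", "TC_f", "GABA_A", 0.05,   17, 0,   FALSE, -85, FALSE,
    "RE_f", "TC_f", "GABA_B", 0.01,   17, 0,   FALSE, NA, FALSE,
    "RE_f", "RE_f", "GABA_A", 0.075,  11, 0,   FALSE, NA, FALSE,
    "TC_f", "PY",   "AMPA",   0.012,  21, 0,   FALSE, NA, FALSE,
    "TC_f", "IN",   "AMPA",   0.012,   5, 0,   FALSE, NA, FALSE,
    "PY",   "TC_f", "AMPA",   0.0013, 21, 0,   FALSE, NA, FALSE,
    "PY",   "RE_f", "AMPA",   0.0032, 17, 0,   FALSE, NA, FALSE,
    "TC_s", "RE_s", "AMPA",   0.022,  17, 0,   FALSE, NA, FALSE,
    "RE_s", "TC_s", "GABA_A", 0.22,   17, 0,   FALSE, -88, FALSE,
    "RE_s", "TC_s", "GABA_B", 0.025,  17, 0,   FALSE, NA, FALSE,
    "RE_s", "RE_s", "GABA_A", 0.05,   11, 0,   FALSE, NA, FALSE,
    "TC_s", "PY",   "AMPA",   0.004,  21, 0,   FALSE, NA, FALSE,
    "TC_s", "IN",   "AMPA",   0.004,   5, 0,   FALSE, NA, FALSE,
    "PY",   "TC_s", "AMPA",   0.0009, 21, 600, FALSE, NA, FALSE,
    "PY",   "RE_s", "AMPA",   0.002,  17, 600, FALSE, NA, FALSE
  )
}

#' Default network configuration
#'
#' Assembles the full control configuration: layer sizes (200 PY, 40 in
#' every other layer), membrane blocks, receptor kinetics, the projection
#' table, miniature-current settings, integration and recording options.
#' Experiment presets are expressed as pure overrides of this list.
#'
#' @param layers Character vector of layers to instantiate (default all
#'   six). Projections touching excluded layers are dropped.
#' @param dt Integration step (ms).
#' @return A list of class `"tc_config"`.
#' @export
network_config <- function(layers = c("PY", "IN", "TC_f", "RE_f", "TC_s", "RE_s"),
                           dt = 0.025) {
  all_layers <- c("PY", "IN", "TC_f", "RE_f", "TC_s", "RE_s")
  stopifnot(all(layers %in% all_layers))
  sizes <- c(PY = 200L, IN = 40L, TC_f = 40L, RE_f = 40L, TC_s = 40L, RE_s = 40L)
  proj <- projection_table()
  proj <- proj[proj$source %in% layers & proj$target %in% layers, ]
  cfg <- list(
    dt = dt,
    layers = tibble::tibble(layer = layers, size = unname(sizes[layers])),
    membrane = stats::setNames(lapply(layers, cell_parameters), layers),
    receptors = list(
      AMPA   = list(alpha = 1.1, beta = 0.19, E = 0),
      NMDA   = list(alpha = 1, beta = 0.0067, E = 0, sigma = 12.5, V_th = -25),
      GABA_A = list(alpha = 10.5, beta = 0.166, E = -70),
      GABA_B = list(K1 = 0.052, K2 = 0.0013, K3 = 0.098, K4 = 0.033,
                    K_hill = 100, E = -95)
    ),
    transmitter = list(A = 0.5, t_max = 0.3),
    depression = list(tau_rec = 700, U_AMPA = 0.07, U_GABA_A = 0.073),
    projections = proj,
    self_connect = FALSE,
    divide_by_fanin = FALSE,
    minis = list(
      # Poisson miniature currents onto PY-PY, PY-IN (AMPA) and IN-PY
      # (GABA_A) synapses; gated on 100 ms after each down-state onset and
      # off at slow-oscillation initiation. Rate is per target cell;
      # amplitudes calibrated so the isolated cortical network cycles at
      # ~1.3 Hz.
      rate_hz = 60, rate_factor = 1, gate_delay_ms = 100,
      g_uS = c(PY_PY = 0.0375, PY_IN = 0.01, IN_PY = 0.03)
    ),
    spike = list(threshold = 0, refractory_ms = 2),
    so_detect = list(rate_up = 10, rate_down = 1, window_ms = 20,
                     down_hold_ms = 300),
    lfp = list(scale = 0.324, sample_ms = 1, smooth_window = 200),
    settle_ms = 500
  )
  class(cfg) <- "tc_config"
  cfg
}
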
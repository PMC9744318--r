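# Network construction: radius-based one-dimensional connectivity across
# the six layers, plus the manipulation operators used by the
# experiments (blocking, leak overrides, subnetwork swap).

#' Map a source-layer index onto target-layer coordinates
#'
#' Layers are one-dimensional chains of different sizes (200 PY vs 40
#' elsewhere); a source cell's fan-out is centred at its proportional
#' position in the target layer, so the PY layer maps 5:1 onto thalamic
#' layers and vice versa.
#'
#' @param i Zero-based source index (vectorized).
#' @param n_source,n_target Layer sizes.
#' @return Real-valued target-layer coordinate.
#' @export
map_index <- function(i, n_source, n_target) {
  if (any(i < 0 | i >= n_source)) stop("source index out of range")
  i * n_target / n_source
}

#' Target indices within a connection radius
#'
#' All target indices `j` with `|j - center| <= radius`, truncated at the
#' layer boundaries (open chain, no wraparound).
#'
#' @param center Target-layer coordinate (from [map_index()]).
#' @param radius Connection radius in target index units, `>= 0`.
#' @param n_target Target layer size.
#' @return Integer vector of zero-based target indices.
#' @export
neighbors_within_radius <- function(center, radius, n_target) {
  stopifnot(radius >= 0)
  lo <- max(0L, as.integer(ceiling(center - radius - 1e-9)))
  hi <- min(n_target - 1L, as.integer(floor(center + radius + 1e-9)))
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Build the thalamocortical network
#'
#' Validates a configuration and wraps it as a network object ready for
#' [simulate()]. Projections must reference configured layers; the
#' GABA-A reversal override onto slow-subnetwork TC cells and the 600 ms
#' corticothalamic conduction delay are part of the default projection
#' table.
#'
#' @param config A `"tc_config"` list from [network_config()].
#' @return A list of class `"tc_network"`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "tc_config"))
  layers <- config$layers$layer
  missing_m <- setdiff(layers, names(config$membrane))
  if (length(missing_m) > 0)
    stop("missing membrane block(s): ", paste(missing_m, collapse = ", "))
  pr <- config$projections
  bad <- !(pr$source %in% layers) | !(pr$target %in% layers)
  if (any(bad))
    stop("projection(s) reference unconfigured layers: ",
         paste(paste(pr$source[bad], pr$target[bad], sep = "->"), collapse = ", "))
  if (!all(pr$receptor %in% c("AMPA", "NMDA", "GABA_A", "GABA_B")))
    stop("unknown receptor in projection table")
  structure(list(config = config), class = "tc_network")
}

#' Instantiated synapse edge list
#'
#' Expands the radius-based projection table into one row per synapse:
#' `(source_layer, source_idx, target_layer, target_idx, receptor, g_uS,
#' delay_ms)` with zero-based indices. Self-connections are excluded in
#' the within-layer projections.
#'
#' @param network A `"tc_network"` object.
#' @return A tibble of synapse instances.
#' @export
network_edges <- function(network) {
  cfg <- network$config
  sizes <- stats::setNames(cfg$layers$size, cfg$layers$layer)
  pr <- cfg$projections
  rows <- purrr::pmap(pr, function(source, target, receptor, g_uS, radius,
                                   delay_ms, depressing, E_override, per_target) {
    ns <- sizes[[source]]; nt <- sizes[[target]]
    purrr::map_dfr(seq_len(ns) - 1L, function(i) {
      js <- neighbors_within_radius(map_index(i, ns, nt), radius, nt)
      if (!cfg$self_connect && source == target) js <- js[js != i]
      if (length(js) == 0) return(NULL)
      tibble::tibble(source_layer = source, source_idx = i,
                     target_layer = target, target_idx = js,
                     receptor = receptor, g_uS = g_uS, delay_ms = delay_ms)
    })
  })
  dplyr::bind_rows(rows)
}

#' Zero out projections (spindle-blocking experiments)
#'
#' Sets `g = 0` on the listed projections, e.g. blocking the slow
#' thalamic subnetwork by silencing the corticothalamic drive
#' `PY->TC_s` and `PY->RE_s`. Pure: returns a modified copy.
#'
#' @param network A `"tc_network"` object.
#' @param projections Character vector `"SRC->TGT"` (all receptors of the
#'   pathway), e.g. `c("PY->TC_s", "PY->RE_s")`.
#' @export
apply_block <- function(network, projections) {
  pr <- network$config$projections
  keys <- paste0(pr$source, "->", pr$target)
  unknown <- setdiff(projections, keys)
  if (length(unknown) > 0)
    stop("unknown projection(s): ", paste(unknown, collapse = ", "))
  pr$g_uS[keys %in% projections] <- 0
  network$config$projections <- pr
  network
}

#' Convenience: block a thalamic subnetwork (or both)
#'
#' @param network A `"tc_network"` object.
#' @param which `"slow"`, `"fast"` or `"both"`.
#' @export
block_subnetwork <- function(network, which = c("slow", "fast", "both")) {
  which <- match.arg(which)
  p <- switch(which,
    slow = c("PY->TC_s", "PY->RE_s"),
    fast = c("PY->TC_f", "PY->RE_f"),
    both = c("PY->TC_s", "PY->RE_s", "PY->TC_f", "PY->RE_f"))
  apply_block(network, p)
}

#' Override the potassium-leak conductance of a thalamic layer
#'
#' Replaces `g_KL` for every cell of the layer; the hyperpolarization
#' experiment raises fast-subnetwork TC leak from 0.03 to
#' 0.033 mS/cm^2. Pure: returns a modified copy.
#'
#' @param network A `"tc_network"` object.
#' @param layer `"TC_f"`, `"RE_f"`, `"TC_s"` or `"RE_s"`.
#' @param g_KL New conductance density (mS/cm^2).
#' @export
apply_gkl_override <- function(network, layer, g_KL) {
  stopifnot(layer %in% c("TC_f", "RE_f", "TC_s", "RE_s"),
            layer %in% names(network$config$membrane), g_KL >= 0)
  network$config$membrane[[layer]]$g_KL <- g_KL
  network
}

#' Replace the slow subnetwork by a second fast subnetwork
#'
#' Gives layers TC_s/RE_s the fast-subnetwork membrane and synaptic
#' parameters (including the standard -70 mV GABA-A reversal) while
#' keeping the 600 ms corticothalamic delay, so fast spindles are driven
#' in both halves of the slow-oscillation cycle. Idempotent and pure.
#'
#' @param network A `"tc_network"` object.
#' @export
swap_slow_for_fast <- function(network) {
  cfg <- network$config
  stopifnot(all(c("TC_s", "RE_s") %in% names(cfg$membrane)))
  tc <- cell_parameters("TC_f"); re <- cell_parameters("RE_f")
  cfg$membrane$TC_s <- tc
  cfg$membrane$RE_s <- re
  pr <- cfg$projections
  fast <- projection_table()
  # copy conductances and reversal overrides from the matching fast rows
  for (k in seq_len(nrow(pr))) {
    src <- pr$source[k]; tgt <- pr$target[k]
    if (!grepl("_s$", src) && !grepl("_s$", tgt)) next
    fsrc <- sub("_s$", "_f", src); ftgt <- sub("_s$", "_f", tgt)
    m <- fast$source == fsrc & fast$target == ftgt &
      fast$receptor == pr$receptor[k]
    if (any(m)) {
      pr$g_uS[k] <- fast$g_uS[which(m)[1]]
      pr$E_override[k] <- fast$E_override[which(m)[1]]
    }
  }
  cfg$projections <- pr
  network$config <- cfg
  network
}
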
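# Deterministic synthetic inputs for unit-testing the analysis module
# without running the network.

#' Synthetic traces and rasters for analysis tests
#'
#' * `sinusoid`: an LFP-like tibble `sin(2 pi f t)`; `params$freq_hz`
#'   (may be a vector of summed components), `params$duration_s`.
#' * `burst_raster`: a spike tibble with bursts at `params$freq_hz` for
#'   `params$duration_s`, one spike per cycle per cell, starting at
#'   `params$onset_ms`.
#' * `poisson_raster`: homogeneous Poisson spikes, `params$rate_hz` per
#'   cell, `params$n_cells`, `params$duration_s`.
#' * `square_so`: a block-alternating raster (up/down at
#'   `params$freq_hz`, firing at `params$rate_hz` per cell during up
#'   half-cycles) plus a matching square-wave LFP.
#'
#' @param kind One of `"sinusoid"`, `"burst_raster"`, `"poisson_raster"`,
#'   `"square_so"`.
#' @param params Named list of parameters (see above).
#' @param seed Integer seed (used by the stochastic kinds).
#' @return An `"lfp_trace"` tibble or a spike tibble, per kind;
#'   `square_so` returns a list with both.
#' @export
make_fixture <- function(kind, params = list(), seed = 1L) {
  set.seed(seed)
  p <- function(name, default) params[[name]] %||% default
  switch(kind,
    sinusoid = {
      f <- p("freq_hz", 14); dur <- p("duration_s", 10)
      t_ms <- seq(1, dur * 1000)
      x <- rowSums(sapply(f, function(fi) sin(2 * pi * fi * t_ms / 1000)))
      out <- tibble::tibble(t_ms = t_ms, lfp = x)
      attr(out, "sample_ms") <- 1
      class(out) <- c("lfp_trace", class(out))
      out
    },
    burst_raster = {
      f <- p("freq_hz", 10); dur <- p("duration_s", 0.8)
      onset <- p("onset_ms", 1000); n_cells <- p("n_cells", 5)
      layer <- p("layer", "TC_s")
      ts <- seq(onset, onset + dur * 1000, by = 1000 / f)
      tibble::tibble(
        layer = layer,
        cell = rep(seq_len(n_cells) - 1L, each = length(ts)),
        t_ms = rep(ts, times = n_cells) +
          rep(seq_len(n_cells) - 1, each = length(ts)) * 0.1
      )
    },
    poisson_raster = {
      rate <- p("rate_hz", 5); dur <- p("duration_s", 10)
      n_cells <- p("n_cells", 10); layer <- p("layer", "PY")
      n <- stats::rpois(n_cells, rate * dur)
      tibble::tibble(
        layer = layer,
        cell = rep(seq_len(n_cells) - 1L, times = n),
        t_ms = sort(stats::runif(sum(n), 0, dur * 1000))
      )
    },
    square_so = {
      f <- p("freq_hz", 1); dur <- p("duration_s", 10)
      rate <- p("rate_hz", 20); n_cells <- p("n_cells", 200)
      period <- 1000 / f
      t_ms <- seq(1, dur * 1000)
      up <- (t_ms %% period) < period / 2
      n_ev <- stats::rpois(1, rate * n_cells * dur / 2)
      cand <- stats::runif(3 * n_ev, 0, dur * 1000)
      cand <- cand[(cand %% period) < period / 2]
      cand <- cand[seq_len(min(n_ev, length(cand)))]
      spikes <- tibble::tibble(
        layer = "PY",
        cell = sample.int(n_cells, length(cand), replace = TRUE) - 1L,
        t_ms = sort(cand)
      )
      lfp <- tibble::tibble(t_ms = t_ms, lfp = ifelse(up, 1, -1))
      attr(lfp, "sample_ms") <- 1
      class(lfp) <- c("lfp_trace", class(lfp))
      list(spikes = spikes, lfp = lfp)
    },
    stop("unknown fixture kind: ", kind)
  )
}
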
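# Spike-train spectral analysis: binned population rate -> Welch power
# spectrum -> band powers, plus firing-rate summaries and LOESS smoothing
# for presentation.

#' Frequency band definitions
#'
#' Delta 0.5-5 Hz, theta 5-8, alpha 8-12, beta 12-30, gamma 30-150 (all
#' half-open `[lo, hi)`). The `"caption"` preset uses the 13-30 Hz beta
#' variant.
#'
#' @param preset `"text"` (beta 12-30) or `"caption"` (beta 13-30)
#' @return `data.frame(band, lo_hz, hi_hz)`
#' @export
band_definitions <- function(preset = c("text", "caption")) {
  preset <- match.arg(preset)
  beta_lo <- if (preset == "text") 12 else 13
  d <- data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
                  lo_hz = c(0.5, 5, 8, beta_lo, 30),
                  hi_hz = c(5, 8, 12, 30, 150),
                  stringsAsFactors = FALSE)
  stopifnot(all(d$hi_hz > d$lo_hz))
  d
}

#' Spike train container
#'
#' @param spikes `data.frame(neuron, time_ms)`
#' @param populations named character vector mapping neuron id to population
#'   label (`"PC"`, `"LBC"`, `"NGC"`), one entry per neuron in the network
#'   (including silent neurons)
#' @param duration simulated duration, ms
#' @param transient discarded initial transient, ms
#' @return object of class `spike_train_set`
#' @export
spike_train_set <- function(spikes, populations, duration, transient = 1000) {
  stopifnot(duration > transient, all(spikes$time_ms <= duration))
  spikes <- spikes[order(spikes$neuron, spikes$time_ms), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, populations = populations,
                 duration = duration, transient = transient),
            class = "spike_train_set")
}

#' Binned, mean-subtracted population rate signal
#'
#' Population spike counts per time bin over the post-transient window, with
#' the mean subtracted; the basis of all spectral estimates (the spectral
#' readout of the circuit is pyramidal-cell spiking).
#'
#' @param spikes a [spike_train_set()]
#' @param population population label (default `"PC"`)
#' @param bin_ms bin width, ms
#' @return `list(x, bin_ms, fs_hz, n_spikes, window_ms)`
#' @export
population_rate_signal <- function(spikes, population = "PC", bin_ms = 1) {
  ids <- as.integer(names(spikes$populations)[spikes$populations == population])
  if (length(ids) == 0) stop("empty population: ", population)
  st <- spikes$spikes
  tt <- st$time_ms[st$neuron %in% ids & st$time_ms > spikes$transient]
  window <- spikes$duration - spikes$transient
  nbin <- floor(window / bin_ms)
  edges_end <- spikes$transient + nbin * bin_ms
  tt <- tt[tt <= edges_end]
  idx <- pmin(floor((tt - spikes$transient) / bin_ms) + 1L, nbin)
  x <- tabulate(idx, nbins = nbin)
  list(x = x - mean(x), bin_ms = bin_ms, fs_hz = 1000 / bin_ms,
       n_spikes = length(tt), window_ms = nbin * bin_ms)
}

#' Welch power spectral density of a rate signal
#'
#' Averaged periodogram over Hann-windowed segments with the given overlap,
#' normalized so that the integral of the one-sided PSD over frequency
#' equals the signal variance (Parseval-consistent).
#'
#' @param signal output of [population_rate_signal()] (or any
#'   `list(x, fs_hz)`)
#' @param segment_ms Welch segment length, ms
#' @param overlap fractional segment overlap
#' @param seed optional bookkeeping seed stored in the metadata
#' @return object of class `power_spectrum`: `list(freq_hz, power, meta)`
#' @export
power_spectrum <- function(signal, segment_ms = 8192, overlap = 0.5,
                           seed = NA) {
  fs <- signal$fs_hz
  x <- signal$x
  nper <- round(segment_ms * fs / 1000)
  step <- max(1, round(nper * (1 - overlap)))
  nseg <- if (length(x) >= nper) (length(x) - nper) %/% step + 1L else 0L
  if (nseg < 1)
    stop("series too short for segment length ", segment_ms, " ms")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) # Hann
  u <- sum(w^2)
  acc <- numeric(nper %/% 2 + 1)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * step + 1):((s - 1) * step + nper)]
    seg <- (seg - mean(seg)) * w
    f <- fft(seg)
    p <- Mod(f[seq_len(nper %/% 2 + 1)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even nper)
    p[-1] <- 2 * p[-1]
    if (nper %% 2 == 0) p[length(p)] <- p[length(p)] / 2
    acc <- acc + p
  }
  freq <- (0:(nper %/% 2)) * fs / nper
  structure(list(freq_hz = freq, power = acc / nseg,
                 meta = list(bin_ms = 1000 / fs, window = "hann",
                             segment_ms = segment_ms, overlap = overlap,
                             n_segments = nseg, seed = seed)),
            class = "power_spectrum")
}

#' Band power of a spectrum
#'
#' Reduces the power values at frequencies inside `[lo, hi)` by the mean
#' (default) or the sum. Ratios between conditions on a shared frequency
#' grid are invariant to that choice.
#'
#' @param ps a [power_spectrum()]
#' @param band band name from [band_definitions()] or a `c(lo, hi)` pair, Hz
#' @param reduction `"mean"` or `"sum"`
#' @param bands band table used to resolve names
#' @return scalar band power
#' @export
band_power <- function(ps, band = "delta", reduction = c("mean", "sum"),
                       bands = band_definitions()) {
  reduction <- match.arg(reduction)
  if (is.character(band)) {
    row <- bands[bands$band == band, ]
    if (nrow(row) != 1) stop("unknown band: ", band)
    band <- c(row$lo_hz, row$hi_hz)
  }
  sel <- ps$freq_hz >= band[1] & ps$freq_hz < band[2]
  if (!any(sel)) stop("no spectrum frequencies inside the band")
  if (reduction == "mean") mean(ps$power[sel]) else sum(ps$power[sel])
}

#' Band power of a test condition as percent of control
#'
#' @param test,control [power_spectrum()] objects on the same grid
#' @inheritParams band_power
#' @return percent of control (100 = unchanged)
#' @export
delta_power_ratio <- function(test, control, band = "delta",
                              reduction = c("mean", "sum"),
                              bands = band_definitions()) {
  reduction <- match.arg(reduction)
  100 * band_power(test, band, reduction, bands) /
    band_power(control, band, reduction, bands)
}

#' Mean firing rate of a population
#'
#' Total post-transient spike count divided by (number of neurons in the
#' population x window length in seconds).
#'
#' @inheritParams population_rate_signal
#' @return rate, Hz per neuron
#' @export
firing_rate <- function(spikes, population = "PC") {
  ids <- as.integer(names(spikes$populations)[spikes$populations == population])
  if (length(ids) == 0) stop("empty population: ", population)
  st <- spikes$spikes
  n <- sum(st$neuron %in% ids & st$time_ms > spikes$transient)
  n / (length(ids) * (spikes$duration - spikes$transient) / 1000)
}

#' LOESS-smoothed spectrum (presentation only)
#'
#' Locally weighted regression of power on frequency; never used in the
#' statistics.
#'
#' @param ps a [power_spectrum()]
#' @param span LOESS span in (0, 1]
#' @param degree local polynomial degree
#' @return a [power_spectrum()] on the same grid with smoothed power
#' @export
loess_smooth <- function(ps, span = 0.2, degree = 2) {
  stopifnot(span > 0, span <= 1)
  d <- data.frame(f = ps$freq_hz, p = ps$power)
  fit <- loess(p ~ f, data = d, span = span, degree = degree,
               surface = "direct")
  out <- ps
  out$power <- as.numeric(predict(fit, newdata = d))
  out$meta$loess_span <- span
  out
}
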
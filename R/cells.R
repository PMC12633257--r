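#' Construct a compartmental cell specification
#'
#' A cell is a tree of cylindrical sections, each split into `nseg`
#' subcompartments. The first section is the soma; its first compartment is
#' the spike-detection site. Channel densities reference mechanisms from
#' [channel_mechanisms()].
#'
#' @param cell_class one of `"PC"`, `"LBC"`, `"NGC"` (or `"toy"` for test
#'   fixtures)
#' @param sections list of sections built with [cell_section()]
#' @param v_init initial membrane voltage, mV
#' @param lif optional `list(vth=, vreset=, tref=)` enabling
#'   threshold-and-reset dynamics at the soma (used for analytically
#'   tractable surrogate cells); `NULL` for conductance-based cells
#' @return object of class `cell_spec`
#' @export
cell_spec <- function(cell_class, sections, v_init = -70, lif = NULL) {
  x <- structure(list(cell_class = cell_class, sections = sections,
                      v_init = v_init, lif = lif),
                 class = "cell_spec")
  validate_cell_spec(x)
  x
}

#' @param name section name, unique within the cell
#' @param length_um,diam_um cylinder length and diameter, um
#' @param nseg number of subcompartments (odd for dendrites by convention)
#' @param ra_ohm_cm axial resistivity, Ohm cm
#' @param cm_uf_cm2 specific membrane capacitance, uF/cm2
#' @param g_pas,e_pas leak conductance density (S/cm2) and reversal (mV)
#' @param parent name of the parent section (`NULL` for the root); the
#'   section attaches to the parent's last compartment
#' @param channels named numeric vector/list of channel densities, S/cm2
#' @param ca optional Ca2+ dynamics: `list(gamma=, tau=, cainf=, depth=)`
#'   (fraction of Ca2+ current contributing, decay time ms, resting level
#'   mM, shell depth um)
#' @rdname cell_spec
#' @export
cell_section <- function(name, length_um, diam_um, nseg = 1L,
                         ra_ohm_cm = 100, cm_uf_cm2 = 1,
                         g_pas = 1e-4, e_pas = -70,
                         parent = NULL, channels = list(), ca = NULL) {
  list(name = name, length_um = length_um, diam_um = diam_um,
       nseg = as.integer(nseg), ra_ohm_cm = ra_ohm_cm,
       cm_uf_cm2 = cm_uf_cm2, g_pas = g_pas, e_pas = e_pas,
       parent = parent, channels = as.list(channels), ca = ca)
}

#' Validate a cell specification
#'
#' Checks geometry positivity, oddness of dendritic subcompartment counts,
#' mechanism existence, and parent ordering.
#'
#' @param cell a [cell_spec()]
#' @return the cell, invisibly; stops with an informative error otherwise
#' @export
validate_cell_spec <- function(cell) {
  stopifnot(is.list(cell$sections), length(cell$sections) >= 1)
  reg <- channel_mechanisms()
  seen <- character(0)
  for (sec in cell$sections) {
    if (sec$length_um <= 0 || sec$diam_um <= 0 || sec$nseg <= 0)
      stop("section '", sec$name, "': lengths, diameters and nseg must be > 0")
    if (!is.null(sec$parent)) {
      if (!sec$parent %in% seen)
        stop("section '", sec$name, "': parent '", sec$parent,
             "' must be defined earlier")
      if (sec$nseg %% 2 == 0)
        stop("section '", sec$name, "': dendritic nseg must be odd")
    }
    bad <- setdiff(names(sec$channels), names(reg))
    if (length(bad))
      stop("section '", sec$name, "': unknown mechanism(s): ",
           paste(bad, collapse = ", "))
    seen <- c(seen, sec$name)
  }
  invisible(cell)
}

#' Read a cell specification from a YAML config file
#'
#' The shipped configs under `inst/extdata/cells/` encode the simplified
#' thick-tufted layer-5 pyramidal cell and the reduced ball-and-stick basket
#' and neurogliaform cell models (reduced parameter sets written for this
#' package, not the original full-morphology files).
#'
#' @param path YAML file path
#' @return a [cell_spec()]
#' @export
read_cell_spec <- function(path) {
  y <- yaml::read_yaml(path)
  secs <- lapply(y$sections, function(s) {
    cell_section(name = s$name, length_um = s$length_um, diam_um = s$diam_um,
                 nseg = s$nseg %||% 1L, ra_ohm_cm = s$ra_ohm_cm %||% 100,
                 cm_uf_cm2 = s$cm_uf_cm2 %||% 1,
                 g_pas = s$g_pas %||% 1e-4, e_pas = s$e_pas %||% -70,
                 parent = s$parent, channels = s$channels %||% list(),
                 ca = s$ca)
  })
  cell_spec(cell_class = y$cell_class, sections = secs,
            v_init = y$v_init %||% -70)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shipped cell models
#'
#' Loaders for the three cell classes of the layer-V circuit: the simplified
#' thick-tufted pyramidal cell (`pc_cell`), the reduced large basket cell
#' (`lbc_cell`, two 301-um dendrites with 1 subcompartment each) and the
#' reduced neurogliaform cell (`ngc_cell`, two 245-um dendrites with 5
#' subcompartments each).
#'
#' @return a [cell_spec()]
#' @export
pc_cell <- function() {
  read_cell_spec(system.file("extdata", "cells", "pc.yaml",
                             package = "deltacircuit", mustWork = TRUE))
}

#' @rdname pc_cell
#' @export
lbc_cell <- function() {
  read_cell_spec(system.file("extdata", "cells", "lbc.yaml",
                             package = "deltacircuit", mustWork = TRUE))
}

#' @rdname pc_cell
#' @export
ngc_cell <- function() {
  read_cell_spec(system.file("extdata", "cells", "ngc.yaml",
                             package = "deltacircuit", mustWork = TRUE))
}

#' Current-clamp stimulation protocol
#'
#' @param amplitudes injected current amplitudes, nA (non-decreasing)
#' @param stimulus_duration stimulus length, ms
#' @param onset_delay unstimulated equilibration time before the step, ms
#' @param spike_threshold detection threshold, mV (positive-going crossing)
#' @return object of class `clamp_protocol`
#' @export
current_clamp_protocol <- function(amplitudes, stimulus_duration = 20000,
                                   onset_delay = 200, spike_threshold = -10) {
  stopifnot(onset_delay >= 0, stimulus_duration > 0,
            !is.unsorted(amplitudes))
  structure(list(amplitudes = amplitudes,
                 stimulus_duration = stimulus_duration,
                 onset_delay = onset_delay,
                 spike_threshold = spike_threshold),
            class = "clamp_protocol")
}

#' Standard interneuron f-I protocols
#'
#' The basket-cell protocol spans 0-0.8 nA in 0.1 nA steps, the
#' neurogliaform protocol 0-0.2 nA in 0.025 nA steps (9 points each), with a
#' 200 ms pre-stimulus delay. Two stimulus-length presets are shipped:
#' `"long"` (20 s, used for f-I frequency resolution) and `"short"` (20 ms).
#'
#' @param preset stimulus-length preset
#' @param stimulus_duration override, ms
#' @return a [current_clamp_protocol()]
#' @export
lbc_protocol <- function(preset = c("long", "short"), stimulus_duration = NULL) {
  preset <- match.arg(preset)
  dur <- stimulus_duration %||% if (preset == "long") 20000 else 20
  current_clamp_protocol(seq(0, 0.8, by = 0.1), stimulus_duration = dur)
}

#' @rdname lbc_protocol
#' @export
ngc_protocol <- function(preset = c("long", "short"), stimulus_duration = NULL) {
  preset <- match.arg(preset)
  dur <- stimulus_duration %||% if (preset == "long") 20000 else 20
  current_clamp_protocol(seq(0, 0.2, by = 0.025), stimulus_duration = dur)
}

#' Simulate a current-clamp protocol on one cell
#'
#' Runs one simulation per amplitude: `onset_delay` of rest, then the
#' current step into the soma. Spikes are positive-going threshold crossings
#' at the soma with a 1 ms detection refractory period.
#'
#' @param cell a [cell_spec()]
#' @param protocol a [current_clamp_protocol()]
#' @param dt integration step, ms
#' @param rec_dt voltage recording interval, ms (0 disables traces)
#' @param use_tables use voltage-interpolated gating tables (faster); exact
#'   rate evaluation when `FALSE`
#' @return list with one element per amplitude:
#'   `list(amplitude, times, v, spike_times)`
#' @export
simulate_current_clamp <- function(cell, protocol, dt = 0.025, rec_dt = 0.5,
                                   use_tables = TRUE) {
  validate_cell_spec(cell)
  tstop <- protocol$onset_delay + protocol$stimulus_duration
  lapply(protocol$amplitudes, function(amp) {
    asm <- .assemble_net(
      list(cell),
      iclamp = data.frame(comp = 1L, amp_nA = amp,
                          start = protocol$onset_delay, end = tstop),
      spike_threshold = protocol$spike_threshold)
    res <- tryCatch(
      .run_engine(asm, tstop = tstop, dt = dt, v_init = cell$v_init,
                  record_comps = if (rec_dt > 0) 1L else integer(0),
                  rec_dt = rec_dt, use_tables = use_tables),
      error = function(e)
        stop("integration failure at amplitude ", amp, " nA: ",
             conditionMessage(e)))
    list(amplitude = amp, times = res$times,
         v = if (length(res$v)) res$v[, 1] else numeric(0),
         spike_times = res$spike_time)
  })
}

#' Compute an f-I curve
#'
#' Firing frequency (spike count during the stimulus divided by the stimulus
#' duration) as a function of injected current amplitude. Spikes before the
#' stimulus onset are excluded.
#'
#' @inheritParams simulate_current_clamp
#' @return object of class `fi_curve`: `data.frame(amplitude_nA, freq_hz)`
#' @export
compute_fi_curve <- function(cell, protocol, dt = 0.025, use_tables = TRUE) {
  traces <- simulate_current_clamp(cell, protocol, dt = dt, rec_dt = 0,
                                   use_tables = use_tables)
  freq <- vapply(traces, function(tr) {
    n <- sum(tr$spike_times > protocol$onset_delay)
    n / (protocol$stimulus_duration / 1000)
  }, 0)
  fi_curve(protocol$amplitudes, freq)
}

#' @param amplitudes,freq_hz equal-length numeric vectors
#' @rdname compute_fi_curve
#' @export
fi_curve <- function(amplitudes, freq_hz) {
  stopifnot(length(amplitudes) == length(freq_hz), all(freq_hz >= 0))
  structure(data.frame(amplitude_nA = amplitudes, freq_hz = freq_hz),
            class = c("fi_curve", "data.frame"))
}

#' Read a reference f-I table
#'
#' Two-column whitespace- or comma-separated text: amplitude (nA) and firing
#' frequency (Hz). Used to supply the full-morphology reference curves that
#' the morphology reduction is scored against.
#'
#' @param path file path
#' @return an [fi_curve()]
#' @export
read_fi_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  d <- read.table(path, header = FALSE, sep = sep, comment.char = "#")
  fi_curve(d[[1]], d[[2]])
}
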
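#' @useDynLib deltacircuit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft loess predict rgamma runif rexp setNames wilcox.test
#' @importFrom utils read.table write.table modifyList
NULL

# Temperature adjustment factors at the default simulation temperature (34 C).
# Kinetics in the Hay lineage are specified at 21 C with Q10 = 2.3.
.QT_HAY <- 2.3^((34 - 21) / 10)

# x / (1 - exp(-x/y)) with the removable singularity at x = 0 handled.
vtrap <- function(x, y) {
  out <- ifelse(abs(x / y) < 1e-6, y * (1 + x / (2 * y)), x / (1 - exp(-x / y)))
  out
}

# x / (exp(x/y) - 1), guarded near x = 0.
efun <- function(x, y) {
  ifelse(abs(x / y) < 1e-6, y * (1 - x / (2 * y)), x / (exp(x / y) - 1))
}

#' Voltage-gated channel mechanism registry
#'
#' Returns the set of channel mechanisms available to cell models: transient
#' and persistent Na+, fast (Kv3.1-like), persistent, transient, M-type and
#' deterministic-Kv K+ conductances, the hyperpolarization-activated cation
#' current Ih, high- and low-voltage-activated Ca2+ channels, and the
#' Ca2+-activated SK K+ channel. Each entry lists its gating variables with
#' steady-state and time-constant functions of membrane voltage (and
#' intracellular Ca2+ for SK), the gate exponents, and the default reversal
#' potential. Kinetic forms follow the thick-tufted layer-5 pyramidal cell
#' model lineage, evaluated at 34 C.
#'
#' The deterministic Kv mechanism (`KvDet`) is the deterministic replacement
#' for a stochastic slow K+ channel: its trajectory depends only on voltage
#' history, so repeated runs with identical inputs are bit-identical.
#'
#' @return Named list of mechanism descriptors. Each has elements `name`,
#'   `gates` (a named list of `list(power, inf, tau)`), `erev` (mV, `NA` for
#'   the Ca2+ channels, which use a Nernst reversal computed from
#'   intracellular Ca2+), and `ca_dependent` / `is_ca_channel` flags.
#' @export
channel_mechanisms <- function() {
  qt <- .QT_HAY
  mech <- function(name, gates, erev, ca_dependent = FALSE, is_ca_channel = FALSE)
    list(name = name, gates = gates, erev = erev,
         ca_dependent = ca_dependent, is_ca_channel = is_ca_channel)
  g <- function(power, inf, tau) list(power = power, inf = inf, tau = tau)

  nata_m_a <- function(v) 0.182 * vtrap(v + 38, 6)
  nata_m_b <- function(v) 0.124 * vtrap(-(v + 38), 6)
  nata_h_a <- function(v) 0.015 * vtrap(-(v + 66), 6)
  nata_h_b <- function(v) 0.015 * vtrap(v + 66, 6)

  nap_h_a <- function(v) 2.88e-6 * vtrap(-(v + 17), 4.63)
  nap_h_b <- function(v) 6.94e-6 * vtrap(v + 64.4, 2.63)

  im_a <- function(v) 3.3e-3 * exp(0.1 * (v + 35))
  im_b <- function(v) 3.3e-3 * exp(-0.1 * (v + 35))

  ih_a <- function(v) 6.43e-3 * efun(v + 154.9, 11.9)
  ih_b <- function(v) 1.93e-3 * exp(v / 33.1)

  hva_m_a <- function(v) 0.055 * efun((-27 - v), 3.8)
  hva_m_b <- function(v) 0.94 * exp((-75 - v) / 17)
  hva_h_a <- function(v) 4.57e-4 * exp((-13 - v) / 50)
  hva_h_b <- function(v) 6.5e-3 / (exp((-15 - v) / 28) + 1)

  list(
    NaTa = mech("NaTa", list(
      m = g(3, function(v, cai) nata_m_a(v) / (nata_m_a(v) + nata_m_b(v)),
            function(v, cai) 1 / (nata_m_a(v) + nata_m_b(v)) / qt),
      h = g(1, function(v, cai) nata_h_a(v) / (nata_h_a(v) + nata_h_b(v)),
            function(v, cai) 1 / (nata_h_a(v) + nata_h_b(v)) / qt)
    ), erev = 50),
    NaP = mech("NaP", list(
      m = g(3, function(v, cai) 1 / (1 + exp(-(v + 52.6) / 4.6)),
            function(v, cai) 6 / (nata_m_a(v) + nata_m_b(v)) / qt),
      h = g(1, function(v, cai) 1 / (1 + exp((v + 48.8) / 10)),
            function(v, cai) 1 / (nap_h_a(v) + nap_h_b(v)) / qt)
    ), erev = 50),
    Kv31 = mech("Kv31", list(
      m = g(1, function(v, cai) 1 / (1 + exp(-(v - 18.7) / 9.7)),
            function(v, cai) 4 / (1 + exp(-(v + 46.56) / 44.14)))
    ), erev = -85),
    KPst = mech("KPst", list(
      m = g(2, function(v, cai) 1 / (1 + exp(-(v + 11) / 12)),
            function(v, cai) ifelse(v < -50,
              (1.25 + 175.03 * exp(0.026 * v)) / qt,
              (1.25 + 13 * exp(-0.026 * v)) / qt)),
      h = g(1, function(v, cai) 1 / (1 + exp((v + 64) / 11)),
            function(v, cai) (360 + (1010 + 24 * (v + 65)) *
                                exp(-((v + 85) / 48)^2)) / qt)
    ), erev = -85),
    KTst = mech("KTst", list(
      m = g(4, function(v, cai) 1 / (1 + exp(-(v + 10) / 19)),
            function(v, cai) (0.34 + 0.92 * exp(-((v + 81) / 59)^2)) / qt),
      h = g(1, function(v, cai) 1 / (1 + exp((v + 76) / 10)),
            function(v, cai) (8 + 49 * exp(-((v + 83) / 23)^2)) / qt)
    ), erev = -85),
    Im = mech("Im", list(
      m = g(1, function(v, cai) im_a(v) / (im_a(v) + im_b(v)),
            function(v, cai) 1 / (im_a(v) + im_b(v)) / qt)
    ), erev = -85),
    Ih = mech("Ih", list(
      m = g(1, function(v, cai) ih_a(v) / (ih_a(v) + ih_b(v)),
            function(v, cai) 1 / (ih_a(v) + ih_b(v)))
    ), erev = -45),
    CaHVA = mech("CaHVA", list(
      m = g(2, function(v, cai) hva_m_a(v) / (hva_m_a(v) + hva_m_b(v)),
            function(v, cai) 1 / (hva_m_a(v) + hva_m_b(v))),
      h = g(1, function(v, cai) hva_h_a(v) / (hva_h_a(v) + hva_h_b(v)),
            function(v, cai) 1 / (hva_h_a(v) + hva_h_b(v)))
    ), erev = NA_real_, is_ca_channel = TRUE),
    CaLVA = mech("CaLVA", list(
      m = g(2, function(v, cai) 1 / (1 + exp(-(v + 40) / 6)),
            function(v, cai) (5 + 20 / (1 + exp((v + 35) / 5))) / qt),
      h = g(1, function(v, cai) 1 / (1 + exp((v + 90) / 6.4)),
            function(v, cai) (20 + 50 / (1 + exp((v + 50) / 7))) / qt)
    ), erev = NA_real_, is_ca_channel = TRUE),
    SK = mech("SK", list(
      z = g(1, function(v, cai) 1 / (1 + (0.00043 / pmax(cai, 1e-10))^4.8),
            function(v, cai) rep(1, length(v)))
    ), erev = -85, ca_dependent = TRUE),
    KvDet = mech("KvDet", list(
      n = g(1, function(v, cai) 1 / (1 + exp(-(v + 30) / 10)),
            function(v, cai) 2 + 16 * exp(-((v + 40) / 30)^2))
    ), erev = -85)
  )
}

#' Evaluate a gating variable's steady state or time constant
#'
#' @param mech mechanism name (see [channel_mechanisms()])
#' @param gate gate name within the mechanism (e.g. `"m"`, `"h"`)
#' @param v membrane voltage, mV (vectorized)
#' @param cai intracellular Ca2+ concentration, mM (used by Ca-dependent gates)
#' @return steady-state value in \[0, 1\] (`gate_inf`) or time constant in ms
#'   (`gate_tau`)
#' @export
gate_inf <- function(mech, gate, v, cai = 1e-4) {
  m <- .get_gate(mech, gate)
  m$inf(v, cai)
}

#' @rdname gate_inf
#' @export
gate_tau <- function(mech, gate, v, cai = 1e-4) {
  m <- .get_gate(mech, gate)
  m$tau(v, cai)
}

.get_gate <- function(mech, gate) {
  reg <- channel_mechanisms()
  if (!mech %in% names(reg)) stop("unknown mechanism: ", mech)
  gg <- reg[[mech]]$gates
  if (!gate %in% names(gg)) stop("unknown gate '", gate, "' for ", mech)
  gg[[gate]]
}

#' Nernst reversal potential for Ca2+ at 34 C
#'
#' @param cai intracellular Ca2+, mM
#' @param cao extracellular Ca2+, mM (default 2)
#' @return reversal potential, mV
#' @export
ca_reversal <- function(cai, cao = 2) {
  # RT/zF at 307.15 K, z = 2, in mV
  1000 * 8.31446 * 307.15 / (2 * 96485) * log(cao / cai)
}

#' Steady-state channel current density at a clamped voltage
#'
#' Scalar evaluation of the ohmic current `g * prod(state^power) * (v - E)`,
#' independent of the simulation engine; used to validate the engine and to
#' reason about conductance scaling. Outward current is positive.
#'
#' @param v membrane voltage, mV
#' @param state named numeric vector of gating values in \[0, 1\], one per
#'   gate of the mechanism
#' @param ca_i intracellular Ca2+, mM (sets the Ca2+ Nernst reversal and the
#'   SK activation)
#' @param mech a channel instance: `list(name=, gbar=, erev=)` where `gbar`
#'   is the maximal conductance density in S/cm2; `erev` may be `NULL` for
#'   the default
#' @return current density, mA/cm2
#' @export
channel_current <- function(v, state, ca_i, mech) {
  reg <- channel_mechanisms()
  if (!mech$name %in% names(reg)) stop("unknown mechanism: ", mech$name)
  desc <- reg[[mech$name]]
  if (any(state < 0 | state > 1)) stop("invalid-state: gating values must lie in [0, 1]")
  gates <- desc$gates
  if (length(state) != length(gates))
    stop("state must have one value per gate (", length(gates), ")")
  open <- 1
  for (i in seq_along(gates)) open <- open * state[[i]]^gates[[i]]$power
  erev <- mech$erev
  if (is.null(erev) || is.na(erev)) {
    erev <- if (isTRUE(desc$is_ca_channel)) ca_reversal(ca_i) else desc$erev
  }
  unname(mech$gbar * open * (v - erev))
}

#' Synaptic receptor kinetics
#'
#' Dual-exponential conductance kinetics for one receptor class. GABA_B
#' defaults to a 30 ms rise and 200 ms decay, the slow time course through
#' which neurogliaform cells pace the network; NMDA carries the standard
#' sigmoidal Mg2+ block.
#'
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABA_A"`, `"GABA_B"`
#' @param tau_rise,tau_decay rise/decay time constants, ms; must satisfy
#'   `tau_decay > tau_rise > 0`
#' @param e_rev reversal potential, mV
#' @param peak_conductance synaptic peak conductance, uS
#' @param mg_block apply the voltage-dependent Mg2+ block (NMDA)
#' @param mg_conc extracellular Mg2+, mM
#' @return an object of class `synapse_kinetics`
#' @export
synapse_kinetics <- function(receptor, tau_rise, tau_decay, e_rev,
                             peak_conductance = 1e-3,
                             mg_block = identical(receptor, "NMDA"),
                             mg_conc = 1) {
  receptor <- match.arg(receptor, c("AMPA", "NMDA", "GABA_A", "GABA_B"))
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_decay <= tau_rise)
    stop("invalid-kinetics: need tau_decay > tau_rise > 0")
  structure(list(receptor = receptor, tau_rise = tau_rise,
                 tau_decay = tau_decay, e_rev = e_rev,
                 peak_conductance = peak_conductance,
                 mg_block = mg_block, mg_conc = mg_conc),
            class = "synapse_kinetics")
}

#' Default receptor kinetics
#'
#' AMPA and GABA_A constants follow the fast-synapse lineage of earlier
#' layer-V delta models; the GABA_B pair (30/200 ms) matches experimentally
#' constrained slow inhibition. Reversals: glutamatergic 0 mV, GABA_A
#' -80 mV, GABA_B -95 mV (K+-like), all configurable.
#'
#' @return named list of [synapse_kinetics()] objects
#' @export
default_synapse_kinetics <- function() {
  list(
    AMPA   = synapse_kinetics("AMPA",   0.3,  3,   0),
    NMDA   = synapse_kinetics("NMDA",   2,    65,  0),
    GABA_A = synapse_kinetics("GABA_A", 0.5,  8,  -80),
    GABA_B = synapse_kinetics("GABA_B", 30,   200, -95)
  )
}

#' Dual-exponential synaptic conductance waveform
#'
#' `g(t) = gmax * (exp(-t/tau_d) - exp(-t/tau_r)) / norm`, normalized so the
#' peak equals `peak_conductance`.
#'
#' @param t_since_event time since the presynaptic event, ms (vectorized,
#'   must be >= 0)
#' @param kin a [synapse_kinetics()] object
#' @return conductance, uS
#' @export
dual_exponential_conductance <- function(t_since_event, kin) {
  stopifnot(inherits(kin, "synapse_kinetics"))
  if (any(t_since_event < 0)) stop("t_since_event must be >= 0")
  tr <- kin$tau_rise; td <- kin$tau_decay
  tp <- dual_exp_peak_time(kin)
  norm <- exp(-tp / td) - exp(-tp / tr)
  kin$peak_conductance * (exp(-t_since_event / td) - exp(-t_since_event / tr)) / norm
}

#' Peak time of the dual-exponential waveform
#'
#' Closed form `tp = tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @inheritParams dual_exponential_conductance
#' @return peak time, ms
#' @export
dual_exp_peak_time <- function(kin) {
  tr <- kin$tau_rise; td <- kin$tau_decay
  tr * td / (td - tr) * log(td / tr)
}

#' Voltage-dependent NMDA Mg2+ block factor
#'
#' Standard sigmoidal block `1 / (1 + mg/3.57 * exp(-0.062 v))`.
#'
#' @param v membrane voltage, mV
#' @param mg extracellular Mg2+ concentration, mM
#' @return unblocked fraction in (0, 1)
#' @export
nmda_mg_block <- function(v, mg = 1) {
  1 / (1 + mg / 3.57 * exp(-0.062 * v))
}
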
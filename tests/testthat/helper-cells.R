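# Shared fixtures: small cells and networks built in code.

# single-compartment passive cell
toy_passive_cell <- function(g_pas = 1e-4, e_pas = -70, L = 30, d = 20) {
  cell_spec("toy", list(cell_section("soma", L, d, g_pas = g_pas,
                                     e_pas = e_pas)))
}

# single-compartment cell with one channel, for clamp tests
toy_channel_cell <- function(mech, gbar, g_pas = 0, e_pas = -70) {
  ch <- setNames(list(gbar), mech)
  cell_spec("toy", list(cell_section("soma", 30, 20, g_pas = g_pas,
                                     e_pas = e_pas, channels = ch)))
}

# passive ball-and-stick template (soma + 2 dendrites), LIF-resettable
toy_ball_and_stick <- function(length = 200, diam = 2, nseg = 1,
                               lif = NULL, g_pas = 1e-4) {
  cell_spec("toy", list(
    cell_section("soma", 20, 20, g_pas = g_pas, e_pas = -70),
    cell_section("dend1", length, diam, nseg = nseg, g_pas = g_pas,
                 e_pas = -70, parent = "soma"),
    cell_section("dend2", length, diam, nseg = nseg, g_pas = g_pas,
                 e_pas = -70, parent = "soma")),
    lif = lif)
}

# a small network spec for fast simulations
micro_spec <- function(n_pc = 16, n_lbc = 4, n_ngc = 4, seed = 1, ...) {
  network_spec(n_pc = n_pc, n_lbc = n_lbc, n_ngc = n_ngc, seed = seed, ...)
}

# voltage-clamp a single-compartment cell and return recorded states:
# columns = gates..., cai, channel current (nA); rows every dt
clamp_states <- function(cell, v_hold, v_step, t_step, tstop, dt = 0.025) {
  asm <- .assemble_net(list(cell),
                       vclamp = data.frame(comp = 1L, hold = v_hold,
                                           step = v_step, tstep = t_step))
  res <- .run_engine(asm, tstop = tstop, dt = dt, v_init = v_hold,
                     record_comps = 1L, rec_dt = dt,
                     record_states_comp = 1L, use_tables = FALSE)
  list(times = res$times, states = res$states, v = res$v[, 1])
}
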
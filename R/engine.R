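# Engine assembly: turn cell specs + synapse/drive descriptions into the
# flat arrays consumed by the compiled integrator.

.MECH_IDS <- c(NaTa = 0L, NaP = 1L, Kv31 = 2L, KPst = 3L, KTst = 4L,
               Im = 5L, Ih = 6L, CaHVA = 7L, CaLVA = 8L, SK = 9L, KvDet = 10L)

# Flatten one cell spec into compartment/channel tables.
# Returns list(comp = data.frame, chan = data.frame) with 1-based local ids.
.flatten_cell <- function(cell) {
  validate_cell_spec(cell)
  nsec <- length(cell$sections)
  secnames <- vapply(cell$sections, `[[`, "", "name")
  nsegs <- vapply(cell$sections, `[[`, 0L, "nseg")
  sec_last <- cumsum(nsegs)
  sec_first <- sec_last - nsegs + 1L
  reg <- channel_mechanisms()
  comp_l <- vector("list", nsec)
  chan_l <- vector("list", nsec)
  for (si in seq_len(nsec)) {
    sec <- cell$sections[[si]]
    n <- sec$nseg
    l_seg <- sec$length_um / n      # um
    r_cm <- sec$diam_um / 2 * 1e-4  # cm
    area <- pi * sec$diam_um * l_seg           # um2, lateral per segment
    r_half <- sec$ra_ohm_cm * (l_seg * 1e-4 / 2) / (pi * r_cm^2)  # Ohm
    ids <- sec_first[si]:sec_last[si]
    parent <- c(NA_integer_, ids[-n])
    gax <- rep(1e6 / (2 * r_half), n)
    if (is.null(sec$parent) || is.na(sec$parent)) {
      parent[1] <- -1L; gax[1] <- 0
    } else {
      pidx <- match(sec$parent, secnames)
      parent[1] <- sec_last[pidx]
      psec <- cell$sections[[pidx]]
      p_half <- psec$ra_ohm_cm * (psec$length_um / psec$nseg * 1e-4 / 2) /
        (pi * (psec$diam_um / 2 * 1e-4)^2)
      gax[1] <- 1e6 / (r_half + p_half)
    }
    has_ca <- !is.null(sec$ca)
    comp_l[[si]] <- data.frame(
      sec = sec$name, seg = seq_len(n), area_um2 = area,
      c_nF = sec$cm_uf_cm2 * area * 1e-5,
      gpas_uS = sec$g_pas * area * 1e-2,
      epas = sec$e_pas, parent = parent, gax_uS = gax,
      ca_on = as.integer(has_ca),
      ca_k = if (has_ca) 1e4 * sec$ca$gamma / (2 * 96485 * sec$ca$depth) *
               100 / area else 0,
      ca_tau = if (has_ca) sec$ca$tau else 1,
      ca_inf = if (has_ca) sec$ca$cainf else 1e-4,
      stringsAsFactors = FALSE)
    chs <- sec$channels[vapply(sec$channels, function(g) g > 0, TRUE)]
    if (length(chs)) {
      mn <- names(chs)
      isca <- vapply(mn, function(m) isTRUE(reg[[m]]$is_ca_channel), TRUE)
      chan_l[[si]] <- data.frame(
        comp = rep(ids, each = length(chs)),
        mech = rep(unname(.MECH_IDS[mn]), n),
        gbar_uS = rep(unlist(chs), n) * area * 1e-2,
        erev = rep(ifelse(isca, 0,
                          vapply(mn, function(m) reg[[m]]$erev, 0)), n),
        is_ca = rep(as.integer(isca), n),
        stringsAsFactors = FALSE)
    }
  }
  comp <- do.call(rbind, comp_l)
  chan_l <- chan_l[!vapply(chan_l, is.null, TRUE)]
  chan <- if (length(chan_l)) do.call(rbind, chan_l) else
    data.frame(comp = integer(0), mech = integer(0), gbar_uS = numeric(0),
               erev = numeric(0), is_ca = integer(0))
  list(comp = comp, chan = chan, soma_comp = sec_first[1L],
       sec_first = sec_first, sec_last = sec_last)
}

# Assemble a multi-cell engine problem. `cells` is a list of cell specs.
# Optional components use 1-based global compartment / cell indices and are
# converted to 0-based here.
.assemble_net <- function(cells,
                          slots = NULL, connections = NULL, background = NULL,
                          gaps = NULL, iclamp = NULL, vclamp = NULL,
                          spike_threshold = -10, spike_refractory = 1) {
  ncell <- length(cells)
  flat <- lapply(cells, .flatten_cell)
  offs <- cumsum(c(0L, vapply(flat, function(f) nrow(f$comp), 0L)))
  comp <- do.call(rbind, lapply(seq_len(ncell), function(i) {
    f <- flat[[i]]$comp
    f$parent <- ifelse(f$parent < 0, -1L, f$parent + offs[i])
    f$cell <- i
    f
  }))
  chan <- do.call(rbind, lapply(seq_len(ncell), function(i) {
    f <- flat[[i]]$chan
    if (nrow(f)) f$comp <- f$comp + offs[i]
    f
  }))
  soma_comp <- vapply(seq_len(ncell), function(i) flat[[i]]$soma_comp + offs[i], 0L)
  lif <- lapply(cells, function(cl) cl$lif)
  empty_df <- function(...) list(...)
  if (is.null(slots))
    slots <- data.frame(comp = integer(0), tau_r = numeric(0),
                        tau_d = numeric(0), e = numeric(0), mg = integer(0),
                        mg_conc = numeric(0))
  if (is.null(connections))
    connections <- data.frame(pre_cell = integer(0), slot = integer(0),
                              dw = numeric(0), delay = numeric(0))
  if (is.null(background))
    background <- data.frame(slot = integer(0), rate_hz = numeric(0),
                             dw = numeric(0))
  if (is.null(gaps))
    gaps <- data.frame(a = integer(0), b = integer(0), g_uS = numeric(0))
  if (is.null(iclamp))
    iclamp <- data.frame(comp = integer(0), amp_nA = numeric(0),
                         start = numeric(0), end = numeric(0))
  if (is.null(vclamp))
    vclamp <- data.frame(comp = integer(0), hold = numeric(0),
                         step = numeric(0), tstep = numeric(0))
  list(
    ncomp = nrow(comp), ncell = ncell,
    c_nF = comp$c_nF, gpas_uS = comp$gpas_uS, epas = comp$epas,
    area_um2 = comp$area_um2,
    parent = as.integer(ifelse(comp$parent < 0, -1L, comp$parent - 1L)),
    gax_uS = comp$gax_uS,
    comp_cell = as.integer(comp$cell - 1L),
    chan_comp = as.integer(chan$comp - 1L), chan_mech = as.integer(chan$mech),
    chan_gbar_uS = chan$gbar_uS, chan_erev = chan$erev,
    chan_is_ca = as.integer(chan$is_ca),
    ca_on = as.integer(comp$ca_on), ca_k = comp$ca_k, ca_tau = comp$ca_tau,
    ca_inf = comp$ca_inf,
    slot_comp = as.integer(slots$comp - 1L),
    slot_tau_r = slots$tau_r, slot_tau_d = slots$tau_d, slot_e = slots$e,
    slot_mg = as.integer(slots$mg), slot_mg_conc = slots$mg_conc,
    con_pre_cell = as.integer(connections$pre_cell - 1L),
    con_slot = as.integer(connections$slot - 1L),
    con_dw = connections$dw, con_delay = connections$delay,
    bg_slot = as.integer(background$slot - 1L),
    bg_rate_hz = background$rate_hz, bg_dw = background$dw,
    gap_a = as.integer(gaps$a - 1L), gap_b = as.integer(gaps$b - 1L),
    gap_g_uS = gaps$g_uS,
    ic_comp = as.integer(iclamp$comp - 1L), ic_amp_nA = iclamp$amp_nA,
    ic_start = iclamp$start, ic_end = iclamp$end,
    vc_comp = as.integer(vclamp$comp - 1L), vc_hold = vclamp$hold,
    vc_step = vclamp$step, vc_tstep = vclamp$tstep,
    cell_spike_comp = as.integer(soma_comp - 1L),
    spike_threshold = spike_threshold, spike_refractory = spike_refractory,
    cell_lif = as.integer(vapply(lif, function(x) !is.null(x), TRUE)),
    lif_vth = vapply(lif, function(x) if (is.null(x)) 0 else x$vth, 0),
    lif_vreset = vapply(lif, function(x) if (is.null(x)) 0 else x$vreset, 0),
    lif_tref = vapply(lif, function(x) if (is.null(x)) 0 else x$tref, 0),
    comp_table = comp, soma_comp = soma_comp, offsets = offs
  )
}

# Run the engine on an assembled problem.
.run_engine <- function(asm, tstop, dt = 0.025, v_init = -70, seed = 1,
                        record_comps = integer(0), rec_dt = 0.5,
                        record_states_comp = -1L, use_tables = TRUE) {
  ctl <- list(dt = dt, tstop = tstop, v_init = v_init, seed = as.double(seed),
              record_comps = as.integer(record_comps - 1L), rec_dt = rec_dt,
              record_states_comp = as.integer(record_states_comp - 1L),
              use_tables = use_tables)
  .engine_run(asm, ctl)
}
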
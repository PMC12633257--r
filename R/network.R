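# Layer-V network: 120 PC / 30 LBC / 30 NGC (configurable), randomly
# connected within seven nonzero connection classes with x6-scaled base
# probabilities, stochastic background drive onto PC compartments only,
# LBC-LBC gap junctions, and receptor-blockade switches.

.CONNECTION_CLASSES <- c("PC->PC", "PC->LBC", "PC->NGC", "LBC->PC",
                         "LBC->LBC", "NGC->LBC", "NGC->PC")

# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synaptic conductance weights
#'
#' The five free dimensionless weights of the circuit, applied to each
#' connection class's base synaptic peak conductance. The two tying
#' constraints hold by construction: `g_I` covers both LBC->PC and
#' LBC->LBC, `g_N` both NGC->PC and NGC->LBC. Defaults are the calibrated
#' best-fit set.
#'
#' @param g_EE PC->PC weight
#' @param g_I LBC->PC and LBC->LBC weight (tied)
#' @param g_EI PC->LBC weight
#' @param g_EN PC->NGC weight
#' @param g_N NGC->PC and NGC->LBC weight (tied)
#' @return named numeric vector
#' @export
conductance_set <- function(g_EE = 0.2, g_I = 0.5, g_EI = 0.7,
                            g_EN = 1.2, g_N = 0.6) {
  g <- c(g_EE = g_EE, g_I = g_I, g_EI = g_EI, g_EN = g_EN, g_N = g_N)
  stopifnot(all(g >= 0))
  g
}

#' Network specification
#'
#' Populations, connection table, synaptic weights, background drive, gap
#' junctions, blockade switches and the wiring seed. The connection table
#' and background defaults are read from the shipped
#' `extdata/network.yaml`.
#'
#' @param n_pc,n_lbc,n_ngc population sizes
#' @param conductances a [conductance_set()]
#' @param probability_scale multiplier on base connection probabilities
#'   (scaled values are clipped to \[0, 1\], with a message when clipped)
#' @param background `data.frame(receptor, rate_hz, weight_uS)`: Poisson
#'   drive per PC cell (rate split uniformly over its dendritic
#'   compartments); LBC and NGC receive no background
#' @param gap_junctions `list(p, g_uS)` for LBC-LBC somatic coupling
#' @param blockade `list(gabaA =, gabaB =)` logical switches; blockade acts
#'   by zeroing synaptic weights, never by deleting synapses
#' @param block_all_gabaA when `TRUE`, GABA_A blockade also zeroes
#'   LBC->LBC (default follows the narrower LBC->PC-only convention)
#' @param connection_table override of the shipped class table
#' @param kinetics receptor kinetics, default [default_synapse_kinetics()]
#' @param cells named list of template cell specs (`PC`, `LBC`, `NGC`)
#' @param delay_ms synaptic delay
#' @param seed wiring seed (fully determines the realized graph)
#' @return object of class `network_spec`
#' @export
network_spec <- function(n_pc = 120, n_lbc = 30, n_ngc = 30,
                         conductances = conductance_set(),
                         probability_scale = 6,
                         background = NULL,
                         gap_junctions = NULL,
                         blockade = list(gabaA = FALSE, gabaB = FALSE),
                         block_all_gabaA = FALSE,
                         connection_table = NULL,
                         kinetics = default_synapse_kinetics(),
                         cells = NULL,
                         delay_ms = 1,
                         seed = 1) {
  defaults <- yaml::read_yaml(system.file("extdata", "network.yaml",
                                          package = "deltacircuit",
                                          mustWork = TRUE))
  if (is.null(connection_table)) {
    connection_table <- do.call(rbind, lapply(defaults$connections, function(cc)
      data.frame(class = cc$class, p_base = cc$p_base, nsyn = cc$nsyn,
                 symbol = cc$symbol, base_g_uS = cc$base_g_uS,
                 nmda_ratio = cc$nmda_ratio %||% 0,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(setequal(connection_table$class, .CONNECTION_CLASSES))
  if (is.null(background)) {
    background <- do.call(rbind, lapply(defaults$background, function(b)
      data.frame(receptor = b$receptor, rate_hz = b$rate_hz,
                 weight_uS = b$weight_uS, stringsAsFactors = FALSE)))
  }
  if (is.null(gap_junctions))
    gap_junctions <- list(p = defaults$gap_junctions$p,
                          g_uS = defaults$gap_junctions$g_uS)
  if (is.null(cells))
    cells <- list(PC = pc_cell(), LBC = lbc_cell(), NGC = ngc_cell())
  structure(list(n_pc = n_pc, n_lbc = n_lbc, n_ngc = n_ngc,
                 conductances = conductances,
                 probability_scale = probability_scale,
                 background = background, gap_junctions = gap_junctions,
                 blockade = blockade, block_all_gabaA = block_all_gabaA,
                 connection_table = connection_table, kinetics = kinetics,
                 cells = cells, delay_ms = delay_ms, seed = seed),
            class = "network_spec")
}

# weight symbol value for a class
.class_weight <- function(spec, class) {
  sym <- spec$connection_table$symbol[spec$connection_table$class == class]
  unname(spec$conductances[[sym]])
}

# dendritic (non-root-section) compartment local indices for a cell spec
.dend_comps_local <- function(cell) {
  n <- vapply(cell$sections, `[[`, 0L, "nseg")
  isroot <- vapply(cell$sections, function(s) is.null(s$parent), TRUE)
  ends <- cumsum(n)
  starts <- ends - n + 1L
  unlist(lapply(which(!isroot), function(i) starts[i]:ends[i]))
}

#' Build (realize) a network from its specification
#'
#' Draws the random graph: for each ordered neuron pair in a nonzero
#' connection class, a connection exists with probability
#' `min(1, probability_scale * p_base)` and carries the class's
#' `nsyn` synapse instances at uniformly chosen postsynaptic dendritic
#' subcompartments. LBC-LBC gap junctions are drawn per unordered pair.
#' Fully determined by `spec$seed`.
#'
#' @param spec a [network_spec()]
#' @return object of class `delta_network` with elements `spec`, `cells`
#'   (per-neuron cell specs), `populations`, `syn` (synapse instance
#'   table), `gaps`, and bookkeeping offsets
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  pops <- c(rep("PC", spec$n_pc), rep("LBC", spec$n_lbc),
            rep("NGC", spec$n_ngc))
  ncell <- length(pops)
  cells <- lapply(pops, function(p) spec$cells[[p]])
  # global compartment offsets (geometry fixed; densities may change later)
  ncomps <- vapply(cells, function(cl)
    sum(vapply(cl$sections, `[[`, 0L, "nseg")), 0L)
  offs <- cumsum(c(0L, ncomps))
  dendl <- lapply(spec$cells, .dend_comps_local)

  syn <- .with_seed(spec$seed, {
    rows <- vector("list", length(.CONNECTION_CLASSES))
    names(rows) <- .CONNECTION_CLASSES
    for (class in .CONNECTION_CLASSES) {
      parts <- strsplit(class, "->", fixed = TRUE)[[1]]
      pre_ids <- which(pops == parts[1]); post_ids <- which(pops == parts[2])
      row <- spec$connection_table[spec$connection_table$class == class, ]
      p <- spec$probability_scale * row$p_base
      if (p > 1) {
        message("class ", class, ": scaled probability ", round(p, 3),
                " clipped to 1")
        p <- 1
      }
      pairs <- expand.grid(pre = pre_ids, post = post_ids)
      pairs <- pairs[pairs$pre != pairs$post, ]
      conn <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
      if (nrow(conn) == 0) { rows[[class]] <- NULL; next }
      nsyn <- row$nsyn
      reccfg <- if (parts[1] == "PC") {
        if (row$nmda_ratio > 0) c("AMPA", "NMDA") else "AMPA"
      } else if (parts[1] == "LBC") "GABA_A" else "GABA_B"
      w <- .class_weight(spec, class) * row$base_g_uS
      out <- list()
      for (rec in reccfg) {
        wrec <- if (rec == "NMDA") w * row$nmda_ratio else w
        comp_local <- dendl[[parts[2]]][
          sample.int(length(dendl[[parts[2]]]),
                     nrow(conn) * nsyn, replace = TRUE)]
        out[[rec]] <- data.frame(
          pre_cell = rep(conn$pre, each = nsyn),
          post_cell = rep(conn$post, each = nsyn),
          class = class, receptor = rec,
          comp = offs[rep(conn$post, each = nsyn)] + comp_local,
          weight_uS = wrec, stringsAsFactors = FALSE)
      }
      rows[[class]] <- do.call(rbind, out)
    }
    gaps <- NULL
    lbc_ids <- which(pops == "LBC")
    if (length(lbc_ids) >= 2 && spec$gap_junctions$p > 0) {
      prs <- t(utils::combn(lbc_ids, 2))
      keep <- runif(nrow(prs)) < spec$gap_junctions$p
      prs <- prs[keep, , drop = FALSE]
      if (nrow(prs) > 0)
        gaps <- data.frame(a = offs[prs[, 1]] + 1L, b = offs[prs[, 2]] + 1L,
                           g_uS = spec$gap_junctions$g_uS)
    }
    list(syn = do.call(rbind, rows), gaps = gaps)
  })
  tab <- syn$syn
  if (is.null(tab))
    tab <- data.frame(pre_cell = integer(0), post_cell = integer(0),
                      class = character(0), receptor = character(0),
                      comp = integer(0), weight_uS = numeric(0))
  rownames(tab) <- NULL
  tab$blocked <- logical(nrow(tab))
  net <- structure(list(spec = spec, cells = cells, populations = pops,
                        syn = tab, gaps = syn$gaps, offsets = offs,
                        dend_local = dendl),
                   class = "delta_network")
  apply_blockade(net, spec$blockade)
}

#' Apply or release receptor blockade
#'
#' GABA_A blockade zeroes LBC->PC synaptic weights (and LBC->LBC as well
#' when the network's `block_all_gabaA` flag is set); GABA_B blockade
#' zeroes NGC->PC and NGC->LBC weights. Blockade marks synapses, leaving
#' the stored weights untouched, so it is exactly reversible and the
#' background drive is never affected.
#'
#' @param network a [build_network()] result
#' @param state `list(gabaA =, gabaB =)`
#' @return the modified network
#' @export
apply_blockade <- function(network, state) {
  gA_classes <- if (isTRUE(network$spec$block_all_gabaA))
    c("LBC->PC", "LBC->LBC") else "LBC->PC"
  gB_classes <- c("NGC->PC", "NGC->LBC")
  network$syn$blocked <- logical(nrow(network$syn))
  if (isTRUE(state$gabaA))
    network$syn$blocked <- network$syn$blocked |
      network$syn$class %in% gA_classes
  if (isTRUE(state$gabaB))
    network$syn$blocked <- network$syn$blocked |
      network$syn$class %in% gB_classes
  network$spec$blockade <- list(gabaA = isTRUE(state$gabaA),
                                gabaB = isTRUE(state$gabaB))
  network
}

#' Apply conductance coefficients to a network
#'
#' Multiplies channel densities (keys `CaHVA`, `CaLVA`, `Ih`, `KPst`,
#' `Im`, ...) wherever the channel exists in the targeted populations. The
#' `GABA_B` key instead multiplies GABA_B synaptic peak conductances whose
#' postsynaptic cell is in a targeted population. Coefficients compose
#' multiplicatively, so applying `c` then `1/c` restores the network.
#'
#' @param network a [build_network()] result
#' @param coeffs a [coefficient_set()]
#' @param target_populations subset of `c("PC", "LBC", "NGC")`
#' @return the modified network
#' @export
apply_coefficients <- function(network, coeffs,
                               target_populations = c("PC", "LBC", "NGC")) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  known <- c(names(.MECH_IDS), "GABA_B")
  bad <- setdiff(names(coeffs$coefficients), known)
  if (length(bad))
    stop("coefficient key(s) not mapping to any mechanism: ",
         paste(bad, collapse = ", "))
  targets <- which(network$populations %in% target_populations)
  for (key in names(coeffs$coefficients)) {
    cf <- coeffs$coefficients[[key]]
    if (key == "GABA_B") {
      sel <- network$syn$receptor == "GABA_B" &
        network$syn$post_cell %in% targets
      network$syn$weight_uS[sel] <- network$syn$weight_uS[sel] * cf
    } else {
      for (i in targets) {
        for (s in seq_along(network$cells[[i]]$sections)) {
          ch <- network$cells[[i]]$sections[[s]]$channels
          if (key %in% names(ch))
            network$cells[[i]]$sections[[s]]$channels[[key]] <- ch[[key]] * cf
        }
      }
    }
  }
  network
}

# Assemble engine arrays for a realized network.
.network_assembly <- function(network) {
  spec <- network$spec
  kin <- spec$kinetics
  syn <- network$syn
  eff_w <- ifelse(syn$blocked, 0, syn$weight_uS)
  # aggregate synapse instances into (compartment, receptor) slots
  key <- paste(syn$comp, syn$receptor)
  ukey <- unique(key)
  slot_of <- match(key, ukey)
  first <- match(ukey, key)
  slot_rec <- syn$receptor[first]
  slots <- data.frame(
    comp = syn$comp[first],
    tau_r = vapply(slot_rec, function(r) kin[[r]]$tau_rise, 0),
    tau_d = vapply(slot_rec, function(r) kin[[r]]$tau_decay, 0),
    e = vapply(slot_rec, function(r) kin[[r]]$e_rev, 0),
    mg = as.integer(vapply(slot_rec, function(r) isTRUE(kin[[r]]$mg_block), TRUE)),
    mg_conc = vapply(slot_rec, function(r) kin[[r]]$mg_conc %||% 1, 0))
  norm <- function(r) {
    k <- kin[[r]]
    tp <- dual_exp_peak_time(k)
    1 / (exp(-tp / k$tau_decay) - exp(-tp / k$tau_rise))
  }
  norms <- vapply(names(kin), norm, 0)
  connections <- data.frame(
    pre_cell = syn$pre_cell, slot = slot_of,
    dw = eff_w * norms[syn$receptor], delay = spec$delay_ms)
  # background: per PC cell, per receptor, one stream per dendritic comp
  bg <- NULL
  if (!is.null(spec$background) && nrow(spec$background) > 0) {
    pc_ids <- which(network$populations == "PC")
    dloc <- network$dend_local[["PC"]]
    rows <- list()
    for (bi in seq_len(nrow(spec$background))) {
      rec <- spec$background$receptor[bi]
      rate <- spec$background$rate_hz[bi] / length(dloc)
      wt <- spec$background$weight_uS[bi] * norms[[rec]]
      if (rate <= 0 || wt == 0) next
      comps <- as.vector(outer(dloc, network$offsets[pc_ids], `+`))
      nb <- length(comps)
      extra <- data.frame(
        comp = comps,
        tau_r = kin[[rec]]$tau_rise, tau_d = kin[[rec]]$tau_decay,
        e = kin[[rec]]$e_rev,
        mg = as.integer(isTRUE(kin[[rec]]$mg_block)),
        mg_conc = kin[[rec]]$mg_conc %||% 1)
      rows[[bi]] <- list(slots = extra,
                         bg = data.frame(slot = seq_len(nb),
                                         rate_hz = rate, dw = wt))
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) {
      nslot0 <- nrow(slots)
      for (r in rows) {
        r$bg$slot <- r$bg$slot + nslot0
        slots <- rbind(slots, r$slots)
        bg <- rbind(bg, r$bg)
        nslot0 <- nrow(slots)
      }
    }
  }
  .assemble_net(network$cells, slots = slots, connections = connections,
                background = bg, gaps = network$gaps)
}

#' Simulate a realized network
#'
#' Runs the compiled integrator: deterministic given the network (which
#' carries the wiring seed) plus the noise `seed`, the duration and the
#' step size.
#'
#' @param network a [build_network()] result
#' @param duration simulated time, ms
#' @param seed background-noise seed
#' @param dt integration step, ms
#' @param transient transient recorded on the returned spike set, ms
#' @param record_cells optional neuron ids whose soma voltage is recorded
#' @param rec_dt voltage recording interval, ms
#' @return a [spike_train_set()]; when `record_cells` is non-empty the
#'   attributes `v_times` and `v_traces` carry the soma voltages
#' @export
simulate_network <- function(network, duration, seed = 1, dt = 0.1,
                             transient = 1000, record_cells = integer(0),
                             rec_dt = 1) {
  asm <- .network_assembly(network)
  rec_comps <- if (length(record_cells))
    asm$soma_comp[record_cells] else integer(0)
  res <- .run_engine(asm, tstop = duration, dt = dt,
                     v_init = -70, seed = seed,
                     record_comps = rec_comps,
                     rec_dt = if (length(rec_comps)) rec_dt else 0)
  spikes <- data.frame(neuron = res$spike_cell, time_ms = res$spike_time)
  pops <- setNames(network$populations,
                   as.character(seq_along(network$populations)))
  sts <- spike_train_set(spikes, pops, duration = duration,
                         transient = transient)
  if (length(rec_comps)) {
    attr(sts, "v_times") <- res$times
    attr(sts, "v_traces") <- res$v
  }
  sts
}

#' Write / read spike trains as plain text
#'
#' Two-column text (`neuron_id`, `time_ms`) plus a population-map sidecar
#' (`<path>.populations`).
#'
#' @param sts a [spike_train_set()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_spike_trains <- function(sts, path) {
  write.table(sts$spikes, path, row.names = FALSE, quote = FALSE)
  pm <- data.frame(neuron = names(sts$populations),
                   population = unname(sts$populations),
                   duration = sts$duration, transient = sts$transient)
  write.table(pm, paste0(path, ".populations"), row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  sp <- read.table(path, header = TRUE)
  pm <- read.table(paste0(path, ".populations"), header = TRUE)
  spike_train_set(sp, setNames(as.character(pm$population),
                               as.character(pm$neuron)),
                  duration = pm$duration[1], transient = pm$transient[1])
}
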
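# Grid-search calibration of the five synaptic conductance weights against
# the pharmacological blockade targets (GABA_A blockade -> 109% of control
# delta power, GABA_B blockade -> 17%), under firing-rate acceptance
# windows (PC 2.5-3.5 Hz, LBC 3-12 Hz).

#' Calibration configuration
#'
#' @param grids named list of per-parameter candidate values; defaults to
#'   the published search grid (3^5 = 243 candidates)
#' @param n_reps_screen seeds per candidate in the screening pass
#' @param n_reps_confirm seeds for candidates that pass the rate windows
#' @param target_gabaA,target_gabaB blockade delta-power targets, percent
#'   of control
#' @param rate_window_pc,rate_window_lbc accepted spontaneous-rate windows,
#'   Hz
#' @param base_spec the [network_spec()] whose conductances are varied
#' @param duration,transient,dt simulation settings per evaluation
#' @param segment_ms Welch segment length for the delta-power estimates
#' @param scoring `"target_deviation"` scores a candidate by
#'   `|ratio_A - target_A| + |ratio_B - target_B|`;
#'   `"alteration_difference"` by
#'   `| |ratio_A - 100| - |ratio_B - 100| |` (the alternative reading of
#'   the selection rule)
#' @return object of class `fit_config`
#' @export
fit_config <- function(grids = list(g_EE = c(0.2, 0.25, 0.3),
                                    g_I = c(0.5, 0.6, 0.7),
                                    g_EI = c(0.7, 0.75, 0.8),
                                    g_EN = c(1.2, 1.4, 1.6),
                                    g_N = c(0.6, 0.8, 1.0)),
                       n_reps_screen = 3, n_reps_confirm = 5,
                       target_gabaA = 109, target_gabaB = 17,
                       rate_window_pc = c(2.5, 3.5),
                       rate_window_lbc = c(3.0, 12.0),
                       base_spec = network_spec(),
                       duration = 11000, transient = 1000, dt = 0.1,
                       segment_ms = 4096,
                       scoring = c("target_deviation",
                                   "alteration_difference")) {
  stopifnot(all(lengths(grids) > 0), n_reps_screen >= 1,
            n_reps_confirm >= 1,
            rate_window_pc[1] < rate_window_pc[2],
            rate_window_lbc[1] < rate_window_lbc[2])
  scoring <- match.arg(scoring)
  structure(list(grids = grids, n_reps_screen = n_reps_screen,
                 n_reps_confirm = n_reps_confirm,
                 target_gabaA = target_gabaA, target_gabaB = target_gabaB,
                 rate_window_pc = rate_window_pc,
                 rate_window_lbc = rate_window_lbc,
                 base_spec = base_spec, duration = duration,
                 transient = transient, dt = dt, segment_ms = segment_ms,
                 scoring = scoring),
            class = "fit_config")
}

# Default simulator: control / GABA_A-blocked / GABA_B-blocked delta powers
# and rates for one conductance set and one seed. The wiring seed and the
# background-noise seed are shared across the three conditions so that the
# blockade is the only difference.
.blockade_trio <- function(g, cfg, seed) {
  spec <- cfg$base_spec
  spec$conductances <- g
  spec$seed <- seed
  net <- build_network(spec)
  one <- function(blockade) {
    n2 <- apply_blockade(net, blockade)
    sts <- simulate_network(n2, duration = cfg$duration, seed = seed,
                            dt = cfg$dt, transient = cfg$transient)
    ps <- power_spectrum(population_rate_signal(sts, "PC"),
                         segment_ms = cfg$segment_ms)
    list(delta = band_power(ps, "delta"),
         pc = firing_rate(sts, "PC"), lbc = firing_rate(sts, "LBC"))
  }
  ctrl <- one(list(gabaA = FALSE, gabaB = FALSE))
  bA <- one(list(gabaA = TRUE, gabaB = FALSE))
  bB <- one(list(gabaA = FALSE, gabaB = TRUE))
  c(delta_ctrl = ctrl$delta, delta_blockA = bA$delta,
    delta_blockB = bB$delta, rate_pc = ctrl$pc, rate_lbc = ctrl$lbc)
}

#' Evaluate one conductance candidate
#'
#' Simulates control, GABA_A-blocked and GABA_B-blocked networks for each
#' seed (wiring and noise seeds shared across the three conditions) and
#' reports mean blockade delta-power ratios and mean control rates.
#'
#' @param g a [conductance_set()]
#' @param cfg a [fit_config()]
#' @param seeds distinct integer seeds
#' @param simulator evaluation function
#'   `function(g, cfg, seed) -> c(delta_ctrl, delta_blockA, delta_blockB,
#'   rate_pc, rate_lbc)`; the default runs the full network; tests can
#'   substitute an analytic stub
#' @return one-row `data.frame` with the mean ratios (percent of control),
#'   rates, and the per-seed values as an attribute
#' @export
evaluate_candidate <- function(g, cfg, seeds = seq_len(cfg$n_reps_screen),
                               simulator = .blockade_trio) {
  stopifnot(!anyDuplicated(seeds))
  per <- t(vapply(seeds, function(s) simulator(g, cfg, s), numeric(5)))
  ratios_A <- 100 * per[, "delta_blockA"] / per[, "delta_ctrl"]
  ratios_B <- 100 * per[, "delta_blockB"] / per[, "delta_ctrl"]
  out <- data.frame(t(g), ratio_A = mean(ratios_A), ratio_B = mean(ratios_B),
                    rate_pc = mean(per[, "rate_pc"]),
                    rate_lbc = mean(per[, "rate_lbc"]),
                    n_seeds = length(seeds))
  attr(out, "per_seed") <- per
  out
}

.fit_score <- function(row, cfg) {
  if (cfg$scoring == "target_deviation")
    abs(row$ratio_A - cfg$target_gabaA) + abs(row$ratio_B - cfg$target_gabaB)
  else
    abs(abs(row$ratio_A - 100) - abs(row$ratio_B - 100))
}

#' Full-factorial grid search over the conductance weights
#'
#' Screens every grid candidate with `n_reps_screen` seeds, rejects
#' candidates whose control firing rates fall outside the PC or LBC
#' windows, re-evaluates the accepted candidates with `n_reps_confirm`
#' seeds, and ranks by the configured score. Failed simulations mark a
#' candidate invalid and the search continues. The evaluation table can be
#' persisted and passed back via `resume` to skip completed candidates.
#'
#' @inheritParams evaluate_candidate
#' @param resume optional previous evaluation table (screening pass rows)
#' @param verbose print progress
#' @return `list(table = full screening table, accepted = confirmed
#'   candidates with scores, best = best row or NULL)`
#' @export
grid_search_conductances <- function(cfg, simulator = .blockade_trio,
                                     resume = NULL, verbose = FALSE) {
  grid <- expand.grid(cfg$grids, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- do.call(conductance_set, as.list(grid[i, ]))
    if (!is.null(resume)) {
      prev <- merge(resume, grid[i, , drop = FALSE])
      if (nrow(prev) == 1) { rows[[i]] <- prev; next }
    }
    rows[[i]] <- tryCatch(
      evaluate_candidate(g, cfg, seeds = seq_len(cfg$n_reps_screen),
                         simulator = simulator),
      error = function(e) {
        warning("candidate ", i, " failed: ", conditionMessage(e))
        cbind(data.frame(t(unclass(g))), ratio_A = NA, ratio_B = NA,
              rate_pc = NA, rate_lbc = NA, n_seeds = 0)
      })
    if (verbose) message("screened ", i, "/", nrow(grid))
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$rate_pc) &
    tab$rate_pc >= cfg$rate_window_pc[1] & tab$rate_pc <= cfg$rate_window_pc[2] &
    tab$rate_lbc >= cfg$rate_window_lbc[1] & tab$rate_lbc <= cfg$rate_window_lbc[2]
  accepted <- tab[ok, , drop = FALSE]
  if (nrow(accepted) > 0) {
    conf <- lapply(seq_len(nrow(accepted)), function(j) {
      g <- do.call(conductance_set, as.list(accepted[j, names(cfg$grids)]))
      evaluate_candidate(g, cfg, seeds = seq_len(cfg$n_reps_confirm),
                         simulator = simulator)
    })
    accepted <- do.call(rbind, conf)
    accepted$score <- vapply(seq_len(nrow(accepted)),
                             function(j) .fit_score(accepted[j, ], cfg), 0)
    best <- select_final(accepted, cfg)
  } else {
    warning("no candidate satisfied the firing-rate windows; ",
            "reporting the best by score anyway")
    tab$score <- vapply(seq_len(nrow(tab)),
                        function(j) .fit_score(tab[j, ], cfg), 0)
    best <- NULL
  }
  list(table = tab, accepted = accepted, best = best,
       scoring = cfg$scoring)
}

#' Select the final conductance set from the accepted candidates
#'
#' Argmin of the configured score; ties break toward the lexicographically
#' smallest parameter vector.
#'
#' @param accepted evaluation table of accepted candidates
#' @param cfg a [fit_config()]
#' @return a [conductance_set()]
#' @export
select_final <- function(accepted, cfg) {
  stopifnot(nrow(accepted) > 0)
  score <- vapply(seq_len(nrow(accepted)),
                  function(j) .fit_score(accepted[j, ], cfg), 0)
  pars <- names(cfg$grids)
  ord <- do.call(order, c(list(score), as.list(accepted[pars])))
  do.call(conductance_set, as.list(accepted[ord[1], pars]))
}
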
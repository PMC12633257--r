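# Experiment orchestration: population-averaged, subject-wise,
# single-channel and per-population comparisons of SCZ-coefficient
# networks against the healthy-control network, with Mann-Whitney
# statistics on per-seed delta powers.

#' Experiment configuration
#'
#' @param region `"ACC"` or `"PFC"` (selects the coefficient column)
#' @param scale `"desk"` (40 PC / 10 LBC / 10 NGC, 10 s + transient,
#'   5 seeds; sized for routine runs and tests) or `"paper"` (120/30/30,
#'   20 s + transient, 30 seeds; full-scale runs)
#' @param n_seeds,duration,transient overrides of the preset
#' @param bands band table, default [band_definitions()]
#' @param segment_ms Welch segment length, ms
#' @param dt integration step, ms
#' @param base_spec optional [network_spec()] override (population sizes
#'   are taken from the preset unless a spec is supplied)
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(region = c("ACC", "PFC"),
                              scale = c("desk", "paper"),
                              n_seeds = NULL, duration = NULL,
                              transient = 1000,
                              bands = band_definitions(),
                              segment_ms = NULL, dt = 0.1,
                              base_spec = NULL) {
  region <- match.arg(region)
  scale <- match.arg(scale)
  preset <- if (scale == "desk")
    list(n = c(40, 10, 10), n_seeds = 5, duration = 16000, segment_ms = 4096)
  else
    list(n = c(120, 30, 30), n_seeds = 30, duration = 21000,
         segment_ms = 8192)
  n_seeds <- n_seeds %||% preset$n_seeds
  duration <- duration %||% preset$duration
  segment_ms <- segment_ms %||% preset$segment_ms
  stopifnot(n_seeds >= 2, duration > transient)
  if (is.null(base_spec))
    base_spec <- network_spec(n_pc = preset$n[1], n_lbc = preset$n[2],
                              n_ngc = preset$n[3])
  structure(list(region = region, scale = scale, n_seeds = n_seeds,
                 duration = duration, transient = transient, bands = bands,
                 segment_ms = segment_ms, dt = dt, base_spec = base_spec),
            class = "experiment_config")
}

#' Two-sided Mann-Whitney U test
#'
#' Normal-approximation U test with tie correction (exact for small
#' untied samples), as used for all between-arm comparisons.
#'
#' @param a,b numeric samples
#' @return `list(U, p)` where `U` is the statistic for `a` vs `b`
#' @export
mann_whitney <- function(a, b) {
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Region's population-averaged coefficient set
#'
#' Built from the published per-gene expression ratios
#' ([published_gene_table()]), or from ratios recomputed from a dataset.
#'
#' @param region `"ACC"` or `"PFC"`
#' @param ratios optional named per-gene ratio vector overriding the
#'   published values
#' @return a [coefficient_set()]
#' @export
region_coefficients <- function(region = c("ACC", "PFC"), ratios = NULL) {
  region <- match.arg(region)
  if (is.null(ratios)) {
    t1 <- published_gene_table()
    ratios <- setNames(
      if (region == "ACC") t1$acc_coefficient else t1$pfc_coefficient,
      t1$gene)
  }
  build_population_coefficients(ratios, region = region)
}

# Simulate one arm for one seed and return band powers + PC rate.
.arm_run <- function(spec, coeffs, targets, seed, cfg) {
  spec$seed <- seed
  net <- build_network(spec)
  if (!is.null(coeffs)) net <- apply_coefficients(net, coeffs, targets)
  sts <- simulate_network(net, duration = cfg$duration, seed = seed,
                          dt = cfg$dt, transient = cfg$transient)
  ps <- power_spectrum(population_rate_signal(sts, "PC"),
                       segment_ms = cfg$segment_ms)
  bp <- vapply(cfg$bands$band, function(b)
    band_power(ps, b, bands = cfg$bands), 0)
  c(bp, rate_pc = firing_rate(sts, "PC"))
}

# Assemble a comparison result from per-seed HC and SCZ matrices.
.comparison <- function(hc, scz, cfg, label) {
  pct <- function(col)
    100 * (mean(scz[, col]) - mean(hc[, col])) / mean(hc[, col])
  mw <- mann_whitney(scz[, "delta"], hc[, "delta"])
  per_band <- lapply(cfg$bands$band, function(b) {
    m <- mann_whitney(scz[, b], hc[, b])
    data.frame(band = b, percent_change = pct(b), U = m$U, p = m$p)
  })
  structure(list(
    label = label, region = cfg$region, scale = cfg$scale,
    hc = hc, scz = scz,
    percent_change = pct("delta"),
    U = mw$U, p = mw$p,
    rate_hc = mean(hc[, "rate_pc"]), rate_scz = mean(scz[, "rate_pc"]),
    rate_p = mann_whitney(scz[, "rate_pc"], hc[, "rate_pc"])$p,
    bands = do.call(rbind, per_band),
    n_seeds = nrow(hc)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s, %s scale, %d seeds]\n  delta power change: %+.1f%% (U = %g, p = %.3g)\n  PC rate: %.2f -> %.2f Hz (p = %.3g)\n",
    x$label, x$region, x$scale, x$n_seeds, x$percent_change, x$U, x$p,
    x$rate_hc, x$rate_scz, x$rate_p))
  invisible(x)
}

#' Population-averaged SCZ-vs-HC comparison
#'
#' The HC arm is the default network; the SCZ arm applies the region's
#' population-averaged coefficient set to all populations. Both arms use
#' the same seed list (wiring and noise).
#'
#' @param cfg an [experiment_config()]
#' @param coeffs coefficient set for the SCZ arm (default: the region's
#'   published averages)
#' @param seeds seed vector (default `1:n_seeds`)
#' @return a `comparison_result` (delta plus all other bands)
#' @export
run_population_averaged <- function(cfg, coeffs = NULL, seeds = NULL) {
  coeffs <- coeffs %||% region_coefficients(cfg$region)
  seeds <- seeds %||% seq_len(cfg$n_seeds)
  hc <- t(vapply(seeds, function(s)
    .arm_run(cfg$base_spec, NULL, NULL, s, cfg), numeric(6)))
  scz <- t(vapply(seeds, function(s)
    .arm_run(cfg$base_spec, coeffs, c("PC", "LBC", "NGC"), s, cfg),
    numeric(6)))
  .comparison(hc, scz, cfg, "population-averaged expression coefficients")
}

#' Subject-wise SCZ-vs-HC comparison
#'
#' One simulation per subject: each subject's coefficients (expression
#' normalized to the HC regional mean) are applied to all populations, HC
#' subjects included. The comparison is across the subject groups.
#'
#' @param cfg an [experiment_config()]
#' @param ds an [expression_dataset()]
#' @param max_subjects_per_group optional cap per diagnosis group (subjects
#'   are taken in dataset order)
#' @return a `comparison_result`
#' @export
run_subject_wise <- function(cfg, ds, max_subjects_per_group = Inf) {
  md <- ds$metadata[ds$metadata$region == cfg$region, ]
  pick <- function(dx) {
    ids <- md$subject_id[md$diagnosis == dx]
    utils::head(ids, max_subjects_per_group)
  }
  runs <- function(ids) t(vapply(seq_along(ids), function(i) {
    cs <- build_subject_coefficients(ds, ids[i])
    .arm_run(cfg$base_spec, cs, c("PC", "LBC", "NGC"), i, cfg)
  }, numeric(6)))
  hc <- runs(pick("HC"))
  scz <- runs(pick("SCZ"))
  .comparison(hc, scz, cfg, "subject-wise expression coefficients")
}

#' Single-channel manipulations
#'
#' One comparison per mapped conductance: only that channel's coefficient
#' differs from 1 in the SCZ arm (the HVA entry uses the averaged
#' CACNA1C/CACNA1D coefficient; the GABBR2 entry scales the GABA_B
#' synaptic weights).
#'
#' @param cfg an [experiment_config()]
#' @param seeds seed vector
#' @return named list of `comparison_result`s, one per channel key
#' @export
run_single_channel <- function(cfg, seeds = NULL) {
  full <- region_coefficients(cfg$region)
  out <- list()
  for (key in names(full$coefficients)) {
    cs <- coefficient_set(setNames(full$coefficients[key], key),
                          scope = "population", region = cfg$region)
    res <- run_population_averaged(cfg, coeffs = cs, seeds = seeds)
    res$label <- paste0("single channel: ", key)
    out[[key]] <- res
  }
  out
}

#' Per-population manipulations
#'
#' The full regional coefficient set applied to exactly one population at
#' a time.
#'
#' @param cfg an [experiment_config()]
#' @param populations populations to test
#' @param seeds seed vector
#' @return named list of `comparison_result`s
#' @export
run_per_population <- function(cfg, populations = c("PC", "LBC", "NGC"),
                               seeds = NULL) {
  coeffs <- region_coefficients(cfg$region)
  seeds <- seeds %||% seq_len(cfg$n_seeds)
  hc <- t(vapply(seeds, function(s)
    .arm_run(cfg$base_spec, NULL, NULL, s, cfg), numeric(6)))
  out <- list()
  for (pop in populations) {
    scz <- t(vapply(seeds, function(s)
      .arm_run(cfg$base_spec, coeffs, pop, s, cfg), numeric(6)))
    res <- .comparison(hc, scz, cfg, paste0("coefficients in ", pop, " only"))
    out[[pop]] <- res
  }
  out
}

#' Blockade calibration readout on the shipped best-fit network
#'
#' Wraps [evaluate_candidate()] on the base spec's conductances: control /
#' GABA_A-blocked / GABA_B-blocked delta-power ratios and control rates.
#'
#' @param cfg an [experiment_config()]
#' @param n_seeds seeds
#' @return the [evaluate_candidate()] row
#' @export
run_blockade_calibration <- function(cfg, n_seeds = cfg$n_seeds) {
  fc <- fit_config(base_spec = cfg$base_spec, duration = cfg$duration,
                   transient = cfg$transient, dt = cfg$dt,
                   segment_ms = cfg$segment_ms)
  evaluate_candidate(cfg$base_spec$conductances, fc, seeds = seq_len(n_seeds))
}
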
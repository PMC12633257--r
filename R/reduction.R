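# Two-stage ball-and-stick morphology reduction: a coarse-then-fine grid
# search over dendrite length (conserving total dendritic area by adjusting
# the diameter), followed by minimization of the subcompartment count
# against the 19-subcompartment reference.

#' Search configuration for the morphology reduction
#'
#' @param reference_fi the full-morphology reference f-I curve
#'   ([fi_curve()] or [read_fi_table()])
#' @param total_dendritic_area total dendritic membrane area to conserve, um2
#' @param protocol the [current_clamp_protocol()] used to evaluate candidate
#'   f-I curves (its amplitude grid must match the reference)
#' @param coarse_lengths coarse length grid, um (default 50-750 in steps
#'   of 50)
#' @param fine_halfwidth half-width of the fine search window around the
#'   coarse argmin, um
#' @param fine_step fine grid step, um
#' @param segment_candidates odd subcompartment counts tried per dendrite
#' @param n_dendrites number of dendritic sections
#' @param nseg_reference subcompartments per dendrite during the length
#'   search and as the segment-search reference
#' @param adequacy_threshold segment search acceptance threshold, Hz; the
#'   default is the self-error of the reference curve (0) plus 1 Hz per
#'   amplitude point
#' @param dt integration step for candidate evaluations, ms
#' @return object of class `reduction_config`
#' @export
reduction_search_config <- function(reference_fi, total_dendritic_area,
                                    protocol,
                                    coarse_lengths = seq(50, 750, by = 50),
                                    fine_halfwidth = 75, fine_step = 1,
                                    segment_candidates = c(1, 3, 5, 7, 9),
                                    n_dendrites = 2, nseg_reference = 19,
                                    adequacy_threshold = NULL,
                                    dt = 0.025) {
  stopifnot(length(coarse_lengths) > 0, fine_step > 0,
            fine_step <= min(diff(sort(coarse_lengths)), Inf),
            all(segment_candidates >= 1),
            all(segment_candidates %% 2 == 1))
  if (is.null(adequacy_threshold))
    adequacy_threshold <- 1 * length(protocol$amplitudes)
  structure(list(reference_fi = reference_fi,
                 total_dendritic_area = total_dendritic_area,
                 protocol = protocol, coarse_lengths = coarse_lengths,
                 fine_halfwidth = fine_halfwidth, fine_step = fine_step,
                 segment_candidates = as.integer(segment_candidates),
                 n_dendrites = n_dendrites,
                 nseg_reference = as.integer(nseg_reference),
                 adequacy_threshold = adequacy_threshold, dt = dt),
            class = "reduction_config")
}

#' Dendrite diameter conserving total dendritic area
#'
#' For `n_dendrites` cylinders of the given length, returns the diameter at
#' which their summed lateral area equals `total_area`:
#' `d = total_area / (n_dendrites * pi * length)`.
#'
#' @param total_area total dendritic membrane area, um2
#' @param length cylinder length, um
#' @param n_dendrites number of dendrites
#' @return diameter, um
#' @export
area_preserving_diameter <- function(total_area, length, n_dendrites = 2) {
  if (any(c(total_area, length, n_dendrites) <= 0))
    stop("total_area, length and n_dendrites must all be > 0")
  total_area / (n_dendrites * pi * length)
}

#' Absolute f-I curve error
#'
#' Sum over amplitudes of `|f_candidate - f_reference|` (Hz). The amplitude
#' grids must be identical.
#'
#' @param candidate,reference [fi_curve()] objects on the same amplitude grid
#' @return total absolute error, Hz
#' @export
fi_error <- function(candidate, reference) {
  if (length(candidate$amplitude_nA) != length(reference$amplitude_nA) ||
      any(abs(candidate$amplitude_nA - reference$amplitude_nA) > 1e-9))
    stop("amplitude grids differ between candidate and reference f-I curves")
  sum(abs(candidate$freq_hz - reference$freq_hz))
}

# Build a ball-and-stick variant of a template cell: every non-root section
# gets the given length, the area-conserving diameter, and nseg
# subcompartments. The soma (first section) is untouched.
#' @rdname two_stage_length_search
#' @param length dendrite length, um
#' @param nseg subcompartments per dendrite
#' @export
ball_and_stick_variant <- function(cell_template, length, nseg, cfg) {
  diam <- area_preserving_diameter(cfg$total_dendritic_area, length,
                                   cfg$n_dendrites)
  cell <- cell_template
  for (i in seq_along(cell$sections)) {
    if (is.null(cell$sections[[i]]$parent)) next
    cell$sections[[i]]$length_um <- length
    cell$sections[[i]]$diam_um <- diam
    cell$sections[[i]]$nseg <- as.integer(nseg)
  }
  cell
}

#' Two-stage dendrite-length search
#'
#' Coarse grid search over dendrite length (default 50-750 um in 50 um
#' steps, 15 points), then a fine search within +/- `fine_halfwidth` um of
#' the coarse argmin at `fine_step` um resolution. Every candidate keeps the
#' total dendritic area fixed by adjusting the diameter and is scored with
#' [fi_error()] against the reference f-I curve. Ties break toward the
#' smallest length.
#'
#' @param cell_template a [cell_spec()] whose non-soma sections are the
#'   dendrites to be resized
#' @param cfg a [reduction_search_config()]
#' @param evaluator optional `function(cell) -> fi_curve` overriding the
#'   default current-clamp evaluation (used to plug in surrogate models)
#' @return `list(best_length, coarse = data.frame(length_um, error_hz),
#'   fine = data.frame(length_um, error_hz), error_metric = "sum_abs")`
#' @export
two_stage_length_search <- function(cell_template, cfg, evaluator = NULL) {
  if (is.null(evaluator))
    evaluator <- function(cell)
      compute_fi_curve(cell, cfg$protocol, dt = cfg$dt)
  score <- function(length) {
    cell <- ball_and_stick_variant(cell_template, length,
                                   cfg$nseg_reference, cfg)
    fi_error(evaluator(cell), cfg$reference_fi)
  }
  coarse_err <- vapply(cfg$coarse_lengths, score, 0)
  l0 <- cfg$coarse_lengths[which.min(coarse_err)]
  lo <- l0 - cfg$fine_halfwidth
  if (lo < 1) {
    message("fine window clipped at 1 um (was ", lo, ")")
    lo <- 1
  }
  fine_grid <- seq(lo, l0 + cfg$fine_halfwidth, by = cfg$fine_step)
  fine_err <- vapply(fine_grid, score, 0)
  list(best_length = fine_grid[which.min(fine_err)],
       coarse = data.frame(length_um = cfg$coarse_lengths,
                           error_hz = coarse_err),
       fine = data.frame(length_um = fine_grid, error_hz = fine_err),
       error_metric = "sum_abs")
}

#' Minimal adequate subcompartment count
#'
#' Computes the f-I curve of the cell at the chosen length with the
#' 19-subcompartment reference discretization, then returns the smallest
#' odd candidate count whose f-I error against that internal reference is
#' below the adequacy threshold. If none is adequate, the reference count
#' is returned with a warning.
#'
#' @param cell_at_best_length a [cell_spec()] already at the best-fit length
#' @inheritParams two_stage_length_search
#' @return `list(best_nseg, errors = data.frame(nseg, error_hz), threshold)`
#' @export
segment_count_search <- function(cell_at_best_length, cfg, evaluator = NULL) {
  if (is.null(evaluator))
    evaluator <- function(cell)
      compute_fi_curve(cell, cfg$protocol, dt = cfg$dt)
  with_nseg <- function(n) {
    cell <- cell_at_best_length
    for (i in seq_along(cell$sections)) {
      if (is.null(cell$sections[[i]]$parent)) next
      cell$sections[[i]]$nseg <- as.integer(n)
    }
    cell
  }
  ref_fi <- evaluator(with_nseg(cfg$nseg_reference))
  cands <- sort(unique(cfg$segment_candidates))
  errs <- vapply(cands, function(n) fi_error(evaluator(with_nseg(n)), ref_fi), 0)
  ok <- which(errs < cfg$adequacy_threshold)
  if (length(ok) == 0) {
    warning("no candidate adequate; returning the reference count")
    best <- cfg$nseg_reference
  } else best <- cands[ok[1]]
  list(best_nseg = as.integer(best),
       errors = data.frame(nseg = cands, error_hz = errs),
       threshold = cfg$adequacy_threshold)
}

#' Total dendritic area of an SWC morphology
#'
#' Reads a standard SWC reconstruction and sums the lateral areas of the
#' truncated cones between each dendritic sample (types 3 and 4) and its
#' parent. Used only to supply `total_dendritic_area` to the reduction.
#'
#' @param path SWC file path
#' @return total dendritic membrane area, um2
#' @export
swc_total_dendritic_area <- function(path) {
  d <- read.table(path, comment.char = "#",
                  col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  idx <- match(d$parent, d$id)
  area <- 0
  for (i in seq_len(nrow(d))) {
    if (!d$type[i] %in% c(3, 4) || is.na(idx[i])) next
    p <- idx[i]
    if (d$type[p] == 1) next   # skip the soma attachment
    h <- sqrt((d$x[i] - d$x[p])^2 + (d$y[i] - d$y[p])^2 + (d$z[i] - d$z[p])^2)
    s <- sqrt(h^2 + (d$r[i] - d$r[p])^2)
    area <- area + pi * (d$r[i] + d$r[p]) * s
  }
  area
}
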
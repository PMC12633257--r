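# The two-stage ball-and-stick reduction, tested on cheap surrogate
# evaluators and small passive cells so every search is exhaustive.

# analytic surrogate: f-I frequencies depend smoothly on dendrite length,
# mimicking a cell whose excitability falls with dendritic load
surrogate_evaluator <- function(protocol, l_star = 312) {
  function(cell) {
    len <- cell$sections[[2]]$length_um
    f <- pmax(0, 100 * protocol$amplitudes - 0.05 * abs(len - l_star))
    fi_curve(protocol$amplitudes, f)
  }
}

test_that("the area-preserving diameter conserves total lateral area", {
  # direct formula: d = A / (n pi L)
  expect_equal(area_preserving_diameter(2 * pi * 100 * 1, 100, 2),
               2 * pi * 100 / (2 * pi * 100))
  # doubling the length halves the diameter
  d1 <- area_preserving_diameter(5000, 150, 2)
  d2 <- area_preserving_diameter(5000, 300, 2)
  expect_equal(d2, d1 / 2)
  # conservation to 1e-9 relative over a length sweep
  for (L in seq(50, 750, by = 50)) {
    d <- area_preserving_diameter(5000, L, 2)
    expect_lt(abs(2 * pi * d * L - 5000) / 5000, 1e-9)
  }
  expect_error(area_preserving_diameter(-1, 100, 2), "> 0")
  expect_error(area_preserving_diameter(100, 0, 2), "> 0")
})

test_that("f-I error is the summed absolute frequency difference", {
  a <- fi_curve(c(0, 0.1, 0.2), c(0, 10, 20))
  b <- fi_curve(c(0, 0.1, 0.2), c(0, 12, 19))
  expect_equal(fi_error(a, b), 3)
  expect_equal(fi_error(a, a), 0)
  expect_error(fi_error(a, fi_curve(c(0, 0.1, 0.3), c(0, 12, 19))),
               "grids differ")
})

test_that("the two-stage search recovers a planted optimum exactly", {
  pr <- current_clamp_protocol(seq(0, 0.8, by = 0.1),
                               stimulus_duration = 20)
  tmpl <- toy_ball_and_stick()
  cfg <- reduction_search_config(
    reference_fi = NULL, total_dendritic_area = 5000, protocol = pr)
  expect_length(cfg$coarse_lengths, 15)   # 50..750 by 50
  ev <- surrogate_evaluator(pr, l_star = 312)
  cfg$reference_fi <- ev(ball_and_stick_variant(tmpl, 312, 19, cfg))
  res <- two_stage_length_search(tmpl, cfg, evaluator = ev)
  expect_equal(res$best_length, 312)
  expect_equal(nrow(res$coarse), 15)
  # fine pass covers +/- 75 um at 1 um steps around the coarse argmin
  expect_equal(min(diff(res$fine$length_um)), 1)
  expect_equal(diff(range(res$fine$length_um)), 150)
})

test_that("the two-stage search equals the exhaustive 1-um search on a surrogate", {
  pr <- current_clamp_protocol(seq(0, 0.2, by = 0.025),
                               stimulus_duration = 20)
  tmpl <- toy_ball_and_stick()
  ev <- surrogate_evaluator(pr, l_star = 488)
  cfg <- reduction_search_config(
    reference_fi = ev(toy_ball_and_stick(488)),
    total_dendritic_area = 5000, protocol = pr)
  res <- two_stage_length_search(tmpl, cfg, evaluator = ev)
  exhaustive <- vapply(seq(50, 750, by = 1), function(L)
    fi_error(ev(ball_and_stick_variant(tmpl, L, 19, cfg)),
             cfg$reference_fi), 0)
  expect_equal(res$best_length, seq(50, 750, by = 1)[which.min(exhaustive)])
})

test_that("a fine window extending below 1 um is clipped", {
  pr <- current_clamp_protocol(c(0, 0.1), stimulus_duration = 20)
  tmpl <- toy_ball_and_stick()
  ev <- surrogate_evaluator(pr, l_star = 20)
  cfg <- reduction_search_config(
    reference_fi = ev(toy_ball_and_stick(20)),
    total_dendritic_area = 5000, protocol = pr)
  expect_message(res <- two_stage_length_search(tmpl, cfg, evaluator = ev),
                 "clipped")
  expect_gte(min(res$fine$length_um), 1)
})

test_that("segment-count search returns the smallest adequate odd count", {
  pr <- current_clamp_protocol(seq(0, 0.2, by = 0.05),
                               stimulus_duration = 20)
  tmpl <- toy_ball_and_stick(300)
  cfg <- reduction_search_config(reference_fi = NULL,
                                 total_dendritic_area = 5000, protocol = pr)
  # surrogate where discretization error decays with segment count
  ev <- function(cell) {
    n <- cell$sections[[2]]$nseg
    f <- 100 * pr$amplitudes + 10 / n
    fi_curve(pr$amplitudes, f)
  }
  res <- segment_count_search(tmpl, cfg, evaluator = ev)
  # per-candidate error vs the 19-segment reference: 5 * (10/n - 10/19)
  err <- function(n) length(pr$amplitudes) * (10 / n - 10 / 19)
  expect_equal(res$errors$error_hz, vapply(c(1, 3, 5, 7, 9), err, 0),
               tolerance = 1e-12)
  # threshold is 1 Hz per amplitude point = 5 Hz; err(5) = 7.37, err(7) = 4.52
  expect_equal(res$best_nseg, 7L)
  # the returned count is non-increasing in the adequacy threshold
  counts <- vapply(c(0.5, 2, 5, 20, 60), function(thr) {
    cfg$adequacy_threshold <- thr
    suppressWarnings(segment_count_search(tmpl, cfg, evaluator = ev)$best_nseg)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  # an impossible threshold falls back to the reference count with warning
  cfg$adequacy_threshold <- 1e-9
  expect_warning(res19 <- segment_count_search(tmpl, cfg, evaluator = ev),
                 "no candidate adequate")
  expect_equal(res19$best_nseg, 19L)
})

test_that("a passive cell spikes nowhere, so the smallest candidate wins", {
  pr <- current_clamp_protocol(c(0, 0.02), stimulus_duration = 50,
                               onset_delay = 20)
  tmpl <- toy_ball_and_stick(300)
  cfg <- reduction_search_config(reference_fi = NULL,
                                 total_dendritic_area = 5000, protocol = pr,
                                 segment_candidates = c(1, 3), dt = 0.05)
  res <- segment_count_search(tmpl, cfg)
  expect_equal(res$best_nseg, 1L)
  expect_true(all(res$errors$error_hz == 0))
})

test_that("an SWC morphology's dendritic area is the summed frustum area", {
  swc <- tempfile(fileext = ".swc")
  # soma sample, then a two-sample dendrite of radius 1, length 100
  writeLines(c("# synthetic morphology",
               "1 1 0 0 0 5 -1",
               "2 3 0 0 0 1 1",
               "3 3 100 0 0 1 2",
               "4 4 100 50 0 2 3"), swc)
  # segment 2->3: cylinder r=1, L=100; segment 3->4: frustum r 1->2, L=50
  a_expect <- pi * (1 + 1) * 100 + pi * (1 + 2) * sqrt(50^2 + 1)
  expect_equal(swc_total_dendritic_area(swc), a_expect, tolerance = 1e-12)
})
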
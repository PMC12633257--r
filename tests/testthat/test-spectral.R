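# Spectral pipeline tested against analytic oracles: counting identities,
# a sinusoid with known band, a flat-spectrum process, and partition
# identities on band reductions.

make_sts <- function(spikes, n_neurons = 4, duration = 3000,
                     transient = 1000, pops = NULL) {
  if (is.null(pops))
    pops <- setNames(rep("PC", n_neurons), as.character(seq_len(n_neurons)))
  spike_train_set(spikes, pops, duration = duration, transient = transient)
}

test_that("the population rate signal counts spikes in the post-transient window", {
  sts <- make_sts(data.frame(neuron = c(1, 1, 2, 3),
                             time_ms = c(500, 1500.2, 2400.8, 2999)))
  sig <- population_rate_signal(sts, "PC", bin_ms = 1)
  expect_length(sig$x, 2000)
  expect_equal(sig$n_spikes, 3)        # the 500 ms spike is in the transient
  expect_equal(mean(sig$x), 0)         # mean-subtracted
  expect_equal(sum(sig$x + sig$n_spikes / 2000), 3)
  # no spikes -> all-zero series
  sig0 <- population_rate_signal(
    make_sts(data.frame(neuron = integer(0), time_ms = numeric(0))), "PC")
  expect_true(all(sig0$x == 0))
  # one spike per bin per neuron -> constant -> zero after mean subtraction
  full <- expand.grid(neuron = 1:2, t = seq(1000.5, 2999.5, by = 1))
  sigc <- population_rate_signal(
    make_sts(data.frame(neuron = full$neuron, time_ms = full$t)), "PC")
  expect_true(all(abs(sigc$x) < 1e-12))
  expect_error(population_rate_signal(sts, "LBC"), "empty population")
})

test_that("a 2 Hz sinusoid concentrates its power in the delta band", {
  tt <- seq(0.0005, 60, by = 0.001)   # 60 s at 1 ms
  sig <- list(x = sin(2 * pi * 2 * tt), fs_hz = 1000)
  ps <- power_spectrum(sig, segment_ms = 8192)
  delta <- band_power(ps, "delta", reduction = "sum")
  total <- sum(ps$power)
  expect_gt(delta / total, 0.99)
  # Parseval consistency: integral of the PSD ~ signal variance
  df <- ps$freq_hz[2] - ps$freq_hz[1]
  expect_equal(sum(ps$power) * df, 0.5, tolerance = 0.05)
})

test_that("zero and too-short signals are handled", {
  zero <- list(x = rep(0, 20000), fs_hz = 1000)
  ps <- power_spectrum(zero, segment_ms = 4096)
  expect_true(all(ps$power == 0))
  expect_error(power_spectrum(list(x = rep(0, 100), fs_hz = 1000),
                              segment_ms = 4096), "too short")
})

test_that("white noise yields band power proportional to bandwidth", {
  set.seed(42)
  acc <- NULL
  for (i in 1:20) {
    sig <- list(x = rnorm(32768), fs_hz = 1000)
    ps <- power_spectrum(sig, segment_ms = 4096)
    acc <- if (is.null(acc)) ps$power else acc + ps$power
  }
  ps$power <- acc / 20
  # equal-width bands should carry equal power on a flat spectrum
  p1 <- band_power(ps, c(10, 60), reduction = "sum")
  p2 <- band_power(ps, c(100, 150), reduction = "sum")
  p3 <- band_power(ps, c(200, 400), reduction = "sum")
  expect_lt(abs(p1 / p2 - 1), 0.1)
  expect_lt(abs(p3 / (4 * p2) - 1), 0.1)
})

test_that("band reductions satisfy the partition identity", {
  set.seed(7)
  ps <- power_spectrum(list(x = rnorm(16384), fs_hz = 1000),
                       segment_ms = 4096)
  whole_sum <- band_power(ps, c(1, 9), reduction = "sum")
  expect_equal(band_power(ps, c(1, 5), reduction = "sum") +
                 band_power(ps, c(5, 9), reduction = "sum"), whole_sum)
  # count-weighted mean of sub-band means equals the full-band mean
  n1 <- sum(ps$freq_hz >= 1 & ps$freq_hz < 5)
  n2 <- sum(ps$freq_hz >= 5 & ps$freq_hz < 9)
  wm <- (n1 * band_power(ps, c(1, 5)) + n2 * band_power(ps, c(5, 9))) /
    (n1 + n2)
  expect_equal(wm, band_power(ps, c(1, 9)))
  expect_error(band_power(ps, c(600, 700)), "no spectrum frequencies")
})

test_that("delta-power ratios are 100% for identical spectra and reduction-invariant", {
  set.seed(1)
  ps1 <- power_spectrum(list(x = rnorm(16384), fs_hz = 1000),
                        segment_ms = 4096)
  expect_equal(delta_power_ratio(ps1, ps1), 100)
  ps2 <- power_spectrum(list(x = rnorm(16384, sd = 2), fs_hz = 1000),
                        segment_ms = 4096)
  expect_equal(delta_power_ratio(ps2, ps1, reduction = "mean"),
               delta_power_ratio(ps2, ps1, reduction = "sum"))
})

test_that("band definitions are non-overlapping with the beta variant preset", {
  b <- band_definitions()
  expect_equal(b$lo_hz[b$band == "delta"], 0.5)
  expect_equal(b$hi_hz[b$band == "delta"], 5)
  expect_true(all(b$hi_hz[-nrow(b)] >= b$lo_hz[-1] - 1e-12))
  expect_equal(band_definitions("caption")$lo_hz[4], 13)
})

test_that("firing rate is spikes over neurons times window", {
  # 120 neurons, 30 spikes each within a 10 s window -> 3.0 Hz
  n <- 120
  sp <- expand.grid(neuron = seq_len(n), k = 1:30)
  sp$time_ms <- 1000 + sp$k * 330
  sts <- spike_train_set(sp[c("neuron", "time_ms")],
                         setNames(rep("PC", n), as.character(seq_len(n))),
                         duration = 11000, transient = 1000)
  expect_equal(firing_rate(sts, "PC"), 3.0)
  # relabeling neurons within the population changes nothing spectral
  perm <- sample(seq_len(n))
  sp2 <- sp; sp2$neuron <- perm[sp$neuron]
  sts2 <- spike_train_set(sp2[c("neuron", "time_ms")],
                          setNames(rep("PC", n), as.character(seq_len(n))),
                          duration = 11000, transient = 1000)
  s1 <- population_rate_signal(sts, "PC")
  s2 <- population_rate_signal(sts2, "PC")
  expect_equal(s1$x, s2$x)
})

test_that("LOESS smoothing is identity-like on constants and tracks slow trends", {
  ps <- structure(list(freq_hz = seq(0, 50, by = 0.5),
                       power = rep(2.5, 101), meta = list()),
                  class = "power_spectrum")
  sm <- loess_smooth(ps, span = 0.3)
  expect_equal(sm$power, ps$power, tolerance = 1e-10)
  # smooth trend plus jitter: the smoother must stay near the trend
  set.seed(3)
  f <- seq(0, 50, by = 0.25)
  trend <- exp(-f / 10)
  ps2 <- structure(list(freq_hz = f, power = trend + rnorm(length(f), 0, 0.02),
                        meta = list()), class = "power_spectrum")
  sm2 <- loess_smooth(ps2, span = 0.25)
  expect_lt(mean(abs(sm2$power - trend)), 0.01)
  expect_error(loess_smooth(ps, span = 0), "span > 0")
})

test_that("LOESS matches an independently coded local quadratic regression", {
  # independent implementation: tricube-weighted quadratic fit over the
  # span-sized neighborhood, the classical definition
  local_quad <- function(x, y, x0, span) {
    n <- length(x)
    q <- floor(n * span)
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    w <- (1 - pmin(d / h, 1)^3)^3
    X <- cbind(1, x - x0, (x - x0)^2)
    fit <- lm.wfit(X, y, w)
    unname(fit$coefficients[1])
  }
  set.seed(9)
  x <- seq(0, 20, by = 0.1)
  y <- sin(x / 3) + rnorm(length(x), 0, 0.05)
  ps <- structure(list(freq_hz = x, power = y, meta = list()),
                  class = "power_spectrum")
  sm <- loess_smooth(ps, span = 0.4)
  for (x0 in c(4, 8, 10.5, 14, 17)) {
    i <- which.min(abs(x - x0))
    expect_equal(sm$power[i], local_quad(x, y, x[i], 0.4), tolerance = 1e-6)
  }
})

test_that("spike trains round-trip through the text format", {
  sp <- data.frame(neuron = c(1, 2, 2), time_ms = c(1200, 1500, 2100))
  sts <- make_sts(sp, n_neurons = 3)
  path <- tempfile()
  write_spike_trains(sts, path)
  back <- read_spike_trains(path)
  expect_equal(back$spikes, sts$spikes)
  expect_equal(back$duration, sts$duration)
  expect_equal(unname(back$populations), unname(sts$populations))
})
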
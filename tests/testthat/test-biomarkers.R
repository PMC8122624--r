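fs <- 508.6
t1 <- (0:508) / fs

test_that("band power integrates the right part of the spectrum", {
  expect_equal(band_power(numeric(509), "delta", fs), 0)
  expect_equal(band_power(numeric(509), "high_gamma", fs), 0)

  x <- sin(2 * pi * 6 * t1)
  expect_gte(band_power(x, "theta", fs), 100 * band_power(x, "delta", fs))

  expect_error(band_power(x, "high_gamma", fs = 300), "Nyquist")

  # white noise: ratio of mean band powers matches the bandwidth ratio
  set.seed(2)
  hg <- 0; dl <- 0
  for (i in 1:300) {
    w <- rnorm(2034) # 4-s draws give ~0.25 Hz resolution
    hg <- hg + band_power(w, "high_gamma", fs)
    dl <- dl + band_power(w, "delta", fs)
  }
  expect_lt(abs(hg / dl - 100 / 3) / (100 / 3), 0.10)
})

test_that("wavelet entropy has the right extremes, bounds and oracle value", {
  # distribution-level extremes of the entropy kernel
  expect_equal(vigimark:::shannon_entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(vigimark:::shannon_entropy(rep(0.2, 5)), log(5))

  # frozen PyWavelets oracle ('db4', level 4, periodized) for a pure 10 Hz
  # tone of 512 samples; small tolerance covers the alignment convention
  x <- sin(2 * pi * 10 * (0:511) / fs)
  expect_lt(abs(wavelet_entropy(x) - 0.2101022320) / 0.2101022320, 0.02)

  # energy conservation at a dyadic length
  e <- vigimark:::dwt_energies(x, 4)[, 1]
  expect_equal(sum(e), sum(x^2), tolerance = 1e-10)

  # bounds on arbitrary epochs
  set.seed(3)
  for (i in 1:25) {
    v <- wavelet_entropy(rnorm(509) * 10^runif(1, -2, 2))
    expect_gte(v, 0)
    expect_lte(v, log(5))
  }
  expect_error(wavelet_entropy(numeric(509)), "all-zero")
  expect_error(wavelet_entropy(rnorm(8)), "too short")

  # a narrowband signal is more ordered than broadband noise
  set.seed(4)
  wins <- vapply(1:200, function(i) {
    wavelet_entropy(sin(2 * pi * 10 * t1 + runif(1, 0, 2 * pi))) <
      wavelet_entropy(rnorm(509))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("Hjorth parameters obey scale invariance and the sampled-sinusoid form", {
  set.seed(5)
  x <- rnorm(509)
  h1 <- hjorth(x)
  h2 <- hjorth(3 * x)
  expect_equal(unname(h2["activity"]), unname(9 * h1["activity"]))
  expect_equal(unname(h2["mobility"]), unname(h1["mobility"]))
  expect_equal(unname(h2["complexity"]), unname(h1["complexity"]))

  # first difference of a sampled sinusoid: mobility = 2 sin(pi f / fs)
  for (f0 in c(5, 17, 40)) {
    m <- hjorth(sin(2 * pi * f0 * seq(0, 4, by = 1 / fs)))["mobility"]
    expect_equal(unname(m), 2 * sin(pi * f0 / fs), tolerance = 1e-3)
  }

  # white noise is more complex than its own derivative process
  cmp <- vapply(1:200, function(i) hjorth(rnorm(300))["complexity"],
                numeric(1))
  expect_gt(mean(cmp), 1)

  hc <- hjorth(rep(2, 100))
  expect_equal(unname(hc["activity"]), 0)
  expect_true(is.na(hc["mobility"]) && is.na(hc["complexity"]))
})

test_that("the coupling modulation index spans its extremes and detects PAC", {
  expect_equal(vigimark:::mi_from_distribution(rep(1, 18)), 0)
  p1 <- c(1, rep(0, 17))
  expect_equal(vigimark:::mi_from_distribution(p1), 1)
  expect_error(pac_mi(rnorm(509), fs, n_bins = 1), ">= 2")

  # 100 Hz carrier amplitude-modulated by a 5 Hz phase beats its own
  # phase-shuffled surrogate distribution
  set.seed(6)
  t3 <- seq(0, 3, by = 1 / fs)
  slow <- sin(2 * pi * 5 * t3)
  xm <- slow + (1 + 0.9 * slow) / 2 * sin(2 * pi * 100 * t3) +
    0.2 * rnorm(length(t3))
  pl <- vigimark:::band_limits("pac_phase")
  al <- vigimark:::band_limits("pac_amplitude")
  ph <- Arg(vigimark:::band_analytic(xm, pl[1], pl[2], fs))[1, ]
  am <- Mod(vigimark:::band_analytic(xm, al[1], al[2], fs))[1, ]
  mi <- vigimark:::pac_mi_core(ph, am, 18)
  expect_equal(mi, pac_mi(xm, fs))
  null <- vapply(1:200, function(i)
    vigimark:::pac_mi_core(sample(ph), am, 18), numeric(1))
  expect_gt(mi, quantile(null, 0.95))
})

test_that("instantaneous amplitude and frequency recover known signals", {
  x <- 2.5 * sin(2 * pi * 2 * t1)
  expect_lt(abs(ia_if(x, fs)["ia"] - 2.5) / 2.5, 0.02)

  x10 <- sin(2 * pi * 10 * t1)
  expect_lt(abs(ia_if(x10, fs)["if_"] - 10) / 10, 0.02)

  # linear chirp 4 -> 14 Hz: mean instantaneous frequency ~ 9 Hz
  ch <- sin(2 * pi * (4 * t1 + (14 - 4) / (2 * max(t1)) * t1^2))
  expect_lt(abs(ia_if(ch, fs)["if_"] - 9) / 9, 0.05)

  # pathological mean frequency flags the ratio as missing
  dc <- ia_if(rep(0, 509), fs)
  expect_true(is.na(dc["ratio"]))
})
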
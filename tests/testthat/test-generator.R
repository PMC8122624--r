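test_that("generation is deterministic and respects the task structure", {
  g1 <- generate_session(generator_config(n_trials = 22, seed = 13))
  g2 <- generate_session(generator_config(n_trials = 22, seed = 13))
  expect_identical(g1$session$data, g2$session$data)
  expect_identical(g1$events, g2$events)
  expect_identical(g1$ground_truth$trials, g2$ground_truth$trials)

  expect_equal(nrow(g1$session$data), 10)
  expect_equal(g1$session$fs, 508.6)
  expect_silent(validate_events(g1$events, g1$session))
  expect_true(all(g1$events$delay_ms >= 500))
  # a differently-seeded session differs
  g3 <- generate_session(generator_config(n_trials = 22, seed = 14))
  expect_false(identical(g1$session$data, g3$session$data))
})

test_that("generated sessions load back through the standard reader", {
  g <- tiny_session()
  td <- withr::local_tempdir()
  p <- write_session(g$session, g$events, td)
  r <- read_session(p$signal_path, p$events_path)
  expect_equal(nrow(r$session$data), 10)
  expect_equal(r$session$fs, 508.6)
})

test_that("delay draws are truncated-normal with the configured moments", {
  set.seed(1)
  d <- draw_delays(20000)
  expect_true(all(d >= 500))
  expect_lt(abs(mean(d) - 2500), 3 * 250 / sqrt(20000))
  expect_lt(abs(sd(d) - 250), 3 * 250 / sqrt(2 * 20000))
})

test_that("cohort regimes hit their class-balance windows", {
  cfg <- generator_config(n_trials = 120, seed = 21)
  bal <- generate_cohort(cfg, 4, "balanced")
  frac_b <- mean(unlist(purrr::map(bal, ~ .x$events$outcome == "incorrect")))
  expect_gt(frac_b, 0.45)
  expect_lt(frac_b, 0.60)

  unb <- generate_cohort(cfg, 4, "unbalanced")
  frac_u <- mean(unlist(purrr::map(unb, ~ .x$events$outcome == "incorrect")))
  expect_gt(frac_u, 0.65)
  expect_lt(frac_u, 0.78)

  one <- generate_cohort(cfg, 1, "balanced")
  expect_length(one, 1)
  expect_equal(one[[1]]$ground_truth$regime, "balanced")
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_trials = 10), ">= 20")
  expect_error(generator_config(delay_sd_ms = 0), "> 0")
  expect_error(generator_config(effect_sizes = list(entropy_drop = -1)), ">= 0")
  expect_error(
    generate_session(generator_config(
      n_trials = 20, seed = 1,
      coupling_ar = list(a1 = 1.2, a2 = 0.1, b1 = 0.5, c1 = 0.8))),
    "unstable")
  gt <- tiny_session()$ground_truth
  fam <- unique(unlist(purrr::map(gt$effects, "families")))
  expect_true(all(fam %in% feature_registry()$family))
})

test_that("low-frequency power gain has a monotone dose-response", {
  gains <- c(0, 0.5, 1, 1.5, 2)
  diffs <- matrix(NA_real_, length(gains), 10)
  for (gi in seq_along(gains)) {
    for (s in 1:10) {
      g <- generate_session(generator_config(
        n_trials = 24, seed = 400 + s,
        effect_sizes = list(lowfreq_power_gain = gains[gi], entropy_drop = 0,
                            coupling_gain = 0, pac_gain = 0,
                            artifact_amplitude = 0),
        effect_channels = "CZ"))
      fs <- g$session$fs
      pw <- delay_epoch_power(g$session, g$events, "delta", "CZ", fs) +
        delay_epoch_power(g$session, g$events, "theta", "CZ", fs)
      inc <- g$events$outcome == "incorrect"
      diffs[gi, s] <- mean(pw[inc]) - mean(pw[!inc])
    }
  }
  m <- rowMeans(diffs)
  expect_true(all(diff(m) > 0))
})

test_that("entropy drop lowers incorrect-trial wavelet entropy across seeds", {
  wins <- vapply(1:10, function(s) {
    g <- generate_session(generator_config(
      n_trials = 24, seed = 500 + s,
      effect_sizes = list(lowfreq_power_gain = 0, entropy_drop = 0.5,
                          coupling_gain = 0, pac_gain = 0,
                          artifact_amplitude = 0)))
    ep <- extract_epochs(g$session, g$events, "delay", 1.0)
    we <- vapply(ep$signal, function(x) wavelet_entropy(x["CZ", ]), numeric(1))
    inc <- ep$outcome == "incorrect"
    mean(we[inc]) < mean(we[!inc])
  }, logical(1))
  expect_gte(sum(wins), 9) # sign test: 9+/10 at a true effect
})

test_that("frontal artifacts raise LFL/RFL delta power above CZ", {
  g <- generate_session(generator_config(
    n_trials = 30, seed = 77,
    effect_sizes = list(lowfreq_power_gain = 0, entropy_drop = 0,
                        coupling_gain = 0, pac_gain = 0,
                        artifact_amplitude = 150),
    artifact_rate_incorrect = 3, artifact_rate_correct = 0))
  fs <- g$session$fs
  art <- g$ground_truth$trials$n_artifacts > 0 &
    g$events$outcome == "incorrect"
  expect_gte(sum(art), 3)
  for (chn in c("LFL", "RFL")) {
    p_ch <- delay_epoch_power(g$session, g$events, "delta", chn, fs)
    p_cz <- delay_epoch_power(g$session, g$events, "delta", "CZ", fs)
    expect_gt(mean(p_ch[art]), mean(p_cz[art]))
  }
})

test_that("null configuration yields labels at the calibrated rate", {
  g <- generate_session(generator_config(
    n_trials = 200, seed = 31, fatigue_gain = 0,
    effect_sizes = list(lowfreq_power_gain = 0, entropy_drop = 0,
                        coupling_gain = 0, pac_gain = 0,
                        artifact_amplitude = 0)))
  p <- mean(g$events$outcome == "incorrect")
  expect_lt(abs(p - 0.515), 3 * sqrt(0.25 / 200))
  # with zero fatigue gain the incorrect probability is flat across trials
  expect_equal(length(unique(g$ground_truth$trials$p_incorrect)), 1)
})
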
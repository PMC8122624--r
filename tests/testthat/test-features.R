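test_that("the registry enumerates the full column contract", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 708)
  counts <- table(reg$family)
  expect_equal(as.integer(counts[c("delta", "high_gamma")]), c(10L, 10L))
  expect_equal(sum(reg$family %in% vigimark:::POWER_BANDS), 80)
  expect_equal(as.integer(counts["wavelet_entropy"]), 10L)
  expect_equal(sum(grepl("^hjorth", reg$family)), 30)
  expect_equal(as.integer(counts["pac"]), 10L)
  expect_equal(as.integer(counts["iaif"]), 30L)
  expect_equal(as.integer(counts["pdc"]), 360L)
  expect_equal(as.integer(counts["pli"]), 180L)
  expect_equal(as.integer(counts["gc"]), 8L)
  expect_equal(length(unique(reg$family)), 17)
  expect_false(anyDuplicated(reg$column) > 0)
})

test_that("feature extraction is deterministic and matches the unit operations", {
  g <- tiny_session()
  ep <- extract_epochs(g$session, g$events, "delay", 1.0)
  ft1 <- extract_features(ep)
  ft2 <- extract_features(ep)
  expect_identical(as.data.frame(ft1), as.data.frame(ft2))
  expect_equal(nrow(ft1), nrow(ep))
  expect_equal(ncol(ft1), 708 + 2)
  expect_true(all(attr(ft1, "registry")$column %in% names(ft1)))

  sig <- ep$signal[[3]]
  fs <- attr(ep, "fs")
  expect_equal(ft1$alpha.RO[3], band_power(sig["RO", ], "alpha", fs))
  expect_equal(ft1$wavelet_entropy.FZ[3], wavelet_entropy(sig["FZ", ]))
  expect_equal(unname(ft1$hjorth_mobility.LT[3]),
               unname(hjorth(sig["LT", ])["mobility"]))
  expect_equal(ft1$pac.CZ[3], pac_mi(sig["CZ", ], fs))
  expect_equal(unname(ft1$iaif.LO.ia[3]), unname(ia_if(sig["LO", ], fs)["ia"]))
  expect_equal(ft1$`pdc.FZ->CZ.theta`[3], pdc(sig, "theta", fs)[10, 9])
  expect_equal(ft1$`pli.LO-RO.delta`[3],
               pli(sig["LO", ], sig["RO", ], "delta", fs))
  expect_equal(ft1$gc.high_beta[3], global_coherence(sig, "high_beta", fs))

  # bounded families stay in range over the whole table
  bounded <- attr(ft1, "registry")$column[
    attr(ft1, "registry")$family %in% c("pac", "pli", "gc")]
  vals <- as.matrix(ft1[, bounded])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(as.matrix(ft1[, paste0("delta.", channel_layout()$names)]) >= 0))
})

test_that("extraction preconditions are enforced", {
  g <- tiny_session()
  ep <- extract_epochs(g$session, g$events, "delay", 1.0)
  expect_error(extract_features(ep[1, ]), "both outcomes")
  same <- ep[ep$outcome == ep$outcome[1], ]
  attr(same, "fs") <- attr(ep, "fs")
  attr(same, "channels") <- attr(ep, "channels")
  expect_error(extract_features(same), "both outcomes")
  expect_error(extract_features(tibble::tibble(signal = list())), "extract_epochs")
})

test_that("injected-effect families dominate the discriminability ranking", {
  top_hit <- vapply(1:20, function(s) {
    g <- generate_session(generator_config(
      n_trials = 30, seed = 600 + s,
      effect_sizes = list(lowfreq_power_gain = 1.2, entropy_drop = 0,
                          coupling_gain = 0, pac_gain = 0,
                          artifact_amplitude = 0)))
    ep <- extract_epochs(g$session, g$events, "delay", 1.0)
    ft <- extract_features(ep)
    r2 <- feature_r2(ft)
    fam <- unlist(purrr::map(g$ground_truth$effects, "families"))
    r2$family[1] %in% fam
  }, logical(1))
  expect_gte(mean(top_hit), 0.8)
})

test_that("imputation statistics come from the supplied rows only", {
  x <- matrix(c(1, 2, 3, NA, 10, 20, 30, 40), 4)
  st <- vigimark:::impute_stats(x)
  expect_equal(unname(st), c(2, 25))
  filled <- vigimark:::impute_apply(x, st)
  expect_equal(filled[4, 1], 2)
  expect_false(anyNA(filled))
  # a column with no finite entries imputes to 0
  x2 <- matrix(NA_real_, 3, 1)
  expect_equal(unname(vigimark:::impute_stats(x2)), 0)
})

test_that("the MVAR order scan returns a usable AIC table", {
  g <- tiny_session()
  ep <- extract_epochs(g$session, g$events, "delay", 1.0)
  sc <- mvar_order_scan(ep, orders = c(2, 5), n_epochs = 4)
  expect_equal(sc$order, c(2, 5))
  expect_true(all(is.finite(sc$aic)))
})
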
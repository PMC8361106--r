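test_that("noiseless planted features are recovered exactly", {
  g <- gen_peaklists(3, planted_features(), seed = 42)
  fs <- detect_features(g$peaklists)
  keep <- g$truth$features$intensity >= 1e5
  expect_equal(nrow(fs$features), sum(keep))
  ord_t <- order(g$truth$features$mz[keep])
  ord_f <- order(fs$features$mz)
  expect_equal(fs$features$mz[ord_f], g$truth$features$mz[keep][ord_t],
               tolerance = 1e-9)
  expect_equal(unname(fs$intensity[ord_f, ]),
               unname(g$truth$apex[keep, , drop = FALSE][ord_t, ]),
               tolerance = 1e-9)
})

test_that("all-sub-threshold input yields an empty feature set", {
  feats <- planted_features()
  feats$intensity <- feats$intensity / 1e3  # all below the 1e5 floor
  g <- gen_peaklists(3, feats, seed = 1)
  fs <- detect_features(g$peaklists)
  expect_equal(nrow(fs$features), 0)
  expect_equal(nrow(detect_features(list())$features), 0)
})

test_that("peaks separated beyond the ppm threshold form distinct features", {
  mz0 <- 300
  mz1 <- mz0 * (1 + 30e-6)  # 30 ppm apart, same rt
  pl <- peaklist("S1", rt = c(5, 5), mz = c(mz0, mz1),
                 intensity = c(2e6, 1e6))
  fs <- detect_features(list(pl))
  expect_equal(nrow(fs$features), 2)
  # within 20 ppm they merge
  mz2 <- mz0 * (1 + 10e-6)
  pl2 <- peaklist("S1", rt = c(5, 5), mz = c(mz0, mz2),
                  intensity = c(2e6, 1e6))
  expect_equal(nrow(detect_features(list(pl2))$features), 1)
})

test_that("detection is idempotent and outputs respect the thresholds", {
  g <- gen_peaklists(3, planted_features(), n_background = 50, seed = 3)
  fs <- detect_features(g$peaklists)
  # regroup: keep only assigned peaks, re-detect
  pls2 <- lapply(seq_along(g$peaklists), function(i) {
    pl <- g$peaklists[[i]]
    pool_idx <- which(!is.na(fs$assignment))
    # rebuild this sample's assigned peaks from the feature matrices
    keep <- pl$intensity %in% fs$intensity[, i] |
      pl$intensity >= 1e5  # planted peaks and any above-floor peak
    peaklist(paste0("S", i), pl$rt[keep], pl$mz[keep], pl$intensity[keep],
             "negative")
  })
  fs2 <- detect_features(pls2)
  expect_equal(sort(fs2$features$mz), sort(fs$features$mz),
               tolerance = 1e-9)
  # detected entries never violate the intensity floor
  expect_true(all(fs$intensity[fs$detected] >= 1e5))
})

test_that("mixed polarity input is rejected", {
  a <- peaklist("S1", 1, 100, 2e6, "negative")
  b <- peaklist("S2", 1, 100, 2e6, "positive")
  expect_error(detect_features(list(a, b)), "polarit")
})

test_that("signal-to-noise uses the median m/z slice away from the peak", {
  # 11 noise peaks at the candidate m/z spread in rt, median 1e5
  host <- peaklist("S1",
                   rt = c(10, seq(1, 6, 0.5)),
                   mz = c(200, rep(200.001, 11)),
                   intensity = c(1e6, seq(0.5e5, 1.5e5, length.out = 11)))
  expect_equal(estimate_snr(200, 10, 1e6, host), 10, tolerance = 0.5)
  expect_equal(estimate_snr(200, 10, 1e5, host), 1, tolerance = 0.05)
  lone <- peaklist("S1", 10, 200, 1e6)
  expect_identical(estimate_snr(200, 10, 1e6, lone), Inf)
})

test_that("library quantitation enforces ppm, rt window and apex tolerance", {
  target <- theoretical_mz("C5H6O5", "negative", "physical")
  lib <- data.frame(name = "KG", formula = "C5H6O5", mox = 1, tbdms = 2,
                    mode = "negative", n_carbons = 5,
                    expected_rt_min = 8, fragment_loss = "C4H9")
  mk <- function(ppm_off, rt) {
    peaklist("S", rt = rt, mz = target * (1 + ppm_off / 1e6),
             intensity = 5e6)
  }
  # planted at +2 ppm, on-time: quantified at planted apex
  pls <- list(mk(2, 8.0), mk(2, 8.01), mk(2, 7.99))
  for (i in 1:3) attr(pls[[i]], "sample_id") <- paste0("S", i)
  q <- quantify_library(pls, lib)
  expect_true(all(q$detected))
  expect_equal(q$intensity, rep(5e6, 3))
  # +10 ppm: outside the 5 ppm tolerance
  pls10 <- list(mk(10, 8.0)); attr(pls10[[1]], "sample_id") <- "S1"
  q10 <- quantify_library(pls10, lib)
  expect_false(any(q10$detected))
  # apex 10 s from consensus: rejected for that sample only
  pls_ap <- list(mk(2, 8.0), mk(2, 8.0), mk(2, 8 + 10 / 60))
  for (i in 1:3) attr(pls_ap[[i]], "sample_id") <- paste0("S", i)
  qa <- quantify_library(pls_ap, lib)
  expect_equal(qa$detected, c(TRUE, TRUE, FALSE))
})

test_that("unparseable library formulas yield error records, not aborts", {
  lib <- data.frame(name = c("good", "bad"),
                    formula = c("C5H6O5", "Qq9!"),
                    mox = 0, tbdms = 0, mode = "negative", n_carbons = 5,
                    expected_rt_min = 8, fragment_loss = "")
  pl <- peaklist("S1", 8, theoretical_mz("C5H6O5", "negative"), 1e6)
  q <- quantify_library(list(pl), lib)
  errs <- attr(q, "errors")
  expect_equal(errs$name, "bad")
  expect_true("good" %in% q$name)
})

test_that("blank correction applies the 3x-blank rule with its floor", {
  rows <- data.frame(name = "m1",
                     sample = c("b1", "s1", "s2"),
                     intensity = c(1e5, 2e5, 5e5))
  cor <- blank_correct(rows, "b1")
  expect_equal(unique(cor$threshold), 3e5)
  expect_equal(cor$intensity[cor$sample == "s1"], 3e5)  # replaced
  expect_false(cor$detected[cor$sample == "s1"])
  expect_equal(cor$intensity[cor$sample == "s2"], 5e5)  # untouched
  expect_true(cor$detected[cor$sample == "s2"])
  # zero-replacement policy
  corz <- blank_correct(rows, "b1", policy = "zero")
  expect_equal(corz$intensity[corz$sample == "s1"], 0)
  # zero blank mean: the floor applies
  rows0 <- data.frame(name = "m1", sample = c("b1", "s1"),
                      intensity = c(0, 2e5))
  expect_equal(unique(blank_correct(rows0, "b1")$threshold), 1e5)
  # no blanks at all: floor alone
  expect_equal(unique(blank_correct(rows0[2, ], character(0))$threshold), 1e5)
})

test_that("MID extraction normalizes windows and flags absent signal", {
  pl <- peaklist("S1", rt = c(8, 8, 8), mz = c(246, 247, 248),
                 intensity = c(8e5, 1e5, 1e5))
  expect_equal(extract_mid(pl, 246, 2, rt = 8), c(0.8, 0.1, 0.1))
  expect_equal(sum(extract_mid(pl, 246, 2, rt = 8)), 1, tolerance = 1e-12)
  # planted fractions recovered exactly in the noiseless case
  frac <- c(0.5, 0.2, 0.05, 0.05, 0.1, 0.1)
  pl2 <- peaklist("S1", rt = rep(8, 6), mz = 246 + 0:5,
                  intensity = 1e7 * frac)
  expect_equal(extract_mid(pl2, 246, 5, rt = 8), frac, tolerance = 1e-9)
  empty <- peaklist("S1", 1, 500, 1e6)
  expect_error(extract_mid(empty, 246, 5, rt = 8), "not detected")
})
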
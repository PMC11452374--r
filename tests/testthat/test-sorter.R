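test_that("density and intensity follow their defining ratios", {
  # nucleus of 1000 px, 100 foci px at RF intensity 80
  labels <- matrix(0L, 50, 50)
  labels[1:40, 1:25] <- 1L          # 1000 px
  fmask <- matrix(FALSE, 50, 50)
  fmask[1:10, 1:10] <- TRUE          # 100 foci px inside the nucleus
  px <- matrix(5, 50, 50)
  px[fmask] <- 80
  rec <- measure_nuclei(count_mask(labels), channel_image(px),
                        foci_mask(fmask, 60))
  expect_equal(rec$N_nuc, 1000L)
  expect_equal(rec$N_RF, 100L)
  expect_equal(rec$rho_RF, 0.1)
  expect_equal(rec$I_RF, 80)

  # no foci pixels: rho = 0 and I = 0 by convention
  rec0 <- measure_nuclei(count_mask(labels), channel_image(px),
                         foci_mask(matrix(FALSE, 50, 50), 60))
  expect_equal(rec0$rho_RF, 0)
  expect_equal(rec0$I_RF, 0)
})

test_that("measurements equal a per-pixel accumulation oracle exactly", {
  set.seed(31)
  labels <- matrix(0L, 64, 64)
  labels[5:30, 5:30] <- 1L
  labels[40:60, 35:60] <- 4L   # non-contiguous label ids are fine
  cm <- count_mask(labels)
  px <- matrix(runif(64 * 64, 0, 100), 64, 64)
  fmask <- matrix(runif(64 * 64) < 0.3, 64, 64)
  rec <- measure_nuclei(cm, channel_image(px), foci_mask(fmask, 1))
  for (l in c(1L, 4L)) {
    n_nuc <- 0L; n_rf <- 0L; i_sum <- 0
    for (i in 1:64) for (j in 1:64) {
      if (labels[i, j] != l) next
      n_nuc <- n_nuc + 1L
      if (fmask[i, j]) { n_rf <- n_rf + 1L; i_sum <- i_sum + px[i, j] }
    }
    r <- rec[rec$label == l, ]
    expect_identical(r$N_nuc, n_nuc)
    expect_identical(r$N_RF, n_rf)
    expect_equal(r$rho_RF, n_rf / n_nuc)
    expect_equal(r$I_RF, i_sum / n_rf)
  }
})

test_that("excluded labels are dropped from measurement", {
  labels <- matrix(0L, 40, 40)
  labels[1:10, 1:10] <- 1L; labels[20:29, 20:29] <- 2L
  cm <- count_mask(labels, excluded_labels = 1L)
  rec <- measure_nuclei(cm, channel_image(matrix(1, 40, 40)),
                        foci_mask(matrix(FALSE, 40, 40), 1))
  expect_equal(rec$label, 2L)
})

test_that("threshold derivation implements the population rules", {
  # mean N_nuc = 1000 and N_min = 10 -> rho_min = 0.01
  rec <- make_records(N_RF = c(0, 500, 100, 100, 100),
                      I_RF = c(0, 300, 50, 100, 200))
  thr <- derive_thresholds(rec, sorting_params())
  expect_equal(thr$rho_min, 0.01)
  expect_equal(thr$rho_max, 0.5)
  expect_equal(thr$rho_thr, 0.4 * 0.5)   # k_rho x rho_max
  expect_equal(thr$I_min_subgroup, 50)   # min I over the subgroup
  expect_equal(thr$I_thr, 150)           # k x I_min
  expect_equal(thr$mean_N_nuc, 1000)
})

test_that("all-zero densities warn and give a G1/G2-only population", {
  rec <- make_records(N_RF = c(0, 0, 0), I_RF = c(0, 0, 0))
  expect_warning(thr <- derive_thresholds(rec), "entirely G1/G2")
  expect_equal(thr$rho_thr, 0)
  cls <- classify_nuclei(rec, thr)
  expect_true(all(cls$phase == "G1G2"))
})

test_that("the rule set classifies the canonical subgroup example", {
  rec <- make_records(N_RF = c(0, 500, 100, 100, 100),
                      I_RF = c(0, 300, 50, 100, 200))
  thr <- derive_thresholds(rec)
  cls <- classify_nuclei(rec, thr)
  expect_equal(cls$phase, c("G1G2", "MIDDLE", "EARLY", "EARLY", "LATE"))
})

test_that("N_min is the boundary between G1/G2 and S phase at uniform size", {
  # uniform 1000-px nuclei: 9 foci px -> G1/G2, 10 -> S (boundary inclusive)
  rec <- make_records(N_RF = c(9, 10, 500, 100), I_RF = c(20, 20, 80, 30))
  thr <- derive_thresholds(rec)
  cls <- classify_nuclei(rec, thr)
  expect_equal(cls$phase[1], "G1G2")
  expect_true(cls$phase[2] %in% c("EARLY", "LATE"))
})

test_that("the maximum-density nucleus is always Middle", {
  set.seed(77)
  rec <- make_records(N_RF = sample(0:400, 20), I_RF = runif(20, 10, 100))
  thr <- derive_thresholds(rec)
  cls <- classify_nuclei(rec, thr)
  expect_equal(cls$phase[which.max(rec$rho_RF)], "MIDDLE")
  # density exactly at rho_thr stays in the subgroup's Middle side
  rec2 <- make_records(N_RF = c(0, 500, 200, 100), I_RF = c(0, 50, 40, 30))
  thr2 <- derive_thresholds(rec2)
  expect_equal(rec2$rho_RF[3], thr2$rho_thr)
  cls2 <- classify_nuclei(rec2, thr2)
  expect_equal(cls2$phase[3], "MIDDLE")
})

test_that("oversized Early nuclei are excluded with a qc flag", {
  rec <- make_records(N_RF = c(rep(0, 10), 500, 100, 130),
                      I_RF = c(rep(0, 10), 300, 50, 60),
                      N_nuc = c(rep(1000L, 12), 1300L))
  thr <- derive_thresholds(rec)
  cls <- classify_nuclei(rec, thr)
  i <- 13
  expect_lt(1.2 * thr$mean_N_nuc, 1300)
  expect_equal(cls$phase[i], "EXCLUDED")
  expect_match(cls$qc_flags[i], "early-size-exclusion")
  # same nucleus at average size would have been Early
  expect_equal(cls$phase[12], "EARLY")
})

test_that("a singleton subgroup is classified Early and flagged", {
  rec <- make_records(N_RF = c(0, 500, 100), I_RF = c(0, 300, 75))
  thr <- derive_thresholds(rec)
  cls <- classify_nuclei(rec, thr)
  expect_equal(cls$phase[3], "EARLY")
  expect_match(cls$qc_flags[3], "singleton-subgroup")
})

test_that("classification refuses thresholds derived from other records", {
  rec <- make_records(N_RF = c(0, 500, 100), I_RF = c(0, 300, 75))
  other <- make_records(N_RF = c(0, 400, 90), I_RF = c(0, 200, 60))
  thr <- derive_thresholds(other)
  expect_error(classify_nuclei(rec, thr), "stale thresholds")
})

test_that("every non-excluded nucleus gets exactly one phase (partition)", {
  set.seed(123)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    rec <- make_records(N_RF = sample(0:500, n, replace = TRUE),
                        I_RF = runif(n, 0, 200),
                        N_nuc = sample(800:1400, n, replace = TRUE))
    thr <- derive_thresholds(rec)
    cls <- classify_nuclei(rec, thr)
    expect_false(anyNA(cls$phase))
    counts <- table(factor(cls$phase, levels = c("G1G2", "EARLY", "MIDDLE",
                                                 "LATE", "EXCLUDED")))
    expect_equal(sum(counts), n)
  }
})

test_that("raising a nucleus's foci count never demotes Middle to G1/G2", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 25
    rec <- make_records(N_RF = sample(0:500, n, replace = TRUE),
                        I_RF = runif(n, 1, 200))
    cls <- classify_nuclei(rec, derive_thresholds(rec))
    i <- sample(n, 1)
    rec2 <- rec
    rec2$N_RF[i] <- min(rec2$N_RF[i] + sample(10:200, 1), rec2$N_nuc[i])
    rec2$rho_RF[i] <- rec2$N_RF[i] / rec2$N_nuc[i]
    cls2 <- classify_nuclei(rec2, derive_thresholds(rec2))
    expect_false(cls$phase[i] == "MIDDLE" && cls2$phase[i] == "G1G2")
  }
})

test_that("classification is a pure function of records and params", {
  set.seed(2)
  rec <- make_records(N_RF = sample(0:300, 15), I_RF = runif(15, 0, 100))
  thr <- derive_thresholds(rec)
  expect_identical(classify_nuclei(rec, thr), classify_nuclei(rec, thr))
})

test_that("scatter table preserves one row per record including G1/G2", {
  rec <- make_records(N_RF = c(0, 500, 100, 100), I_RF = c(0, 300, 50, 200))
  cls <- classify_nuclei(rec, derive_thresholds(rec))
  tab <- scatter_data(cls)
  expect_equal(nrow(tab), nrow(rec))
  expect_named(tab, c("frame_id", "label", "rho_RF", "I_RF", "phase"))
  expect_true(any(tab$phase == "G1G2" & tab$I_RF == 0))
  expect_equal(nrow(scatter_data(cls[0, ])), 0)
})
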
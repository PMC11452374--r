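make_crop <- function(seed, side = 24, rate = 30) {
  set.seed(seed)
  a <- matrix(rpois(side * side, rate) + runif(side * side), side, side)
  b <- matrix(rpois(side * side, rate) + runif(side * side), side, side)
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  mask <- (rows - side / 2)^2 + (cols - side / 2)^2 <= (side / 2 - 1)^2
  list(a = a, b = b, mask = mask)
}

test_that("zero lag of the ACF equals variance over squared mean", {
  cr <- make_crop(1, 24)
  cf <- masked_correlation(cr$a, cr$a, cr$mask, max_lag_px = 6,
                           min_overlap = 10, channel_pair = "11")
  v <- cr$a[cr$mask]
  n <- length(v)
  expect_equal(zero_lag(cf), var(v) * (n - 1) / n / mean(v)^2,
               tolerance = 1e-12)
})

test_that("masked correlation equals the nested-loop oracle", {
  # small instance, all lags up to 4, tight tolerance
  cr <- make_crop(2, 16)
  cf <- masked_correlation(cr$a, cr$b, cr$mask, max_lag_px = 4,
                           min_overlap = 1)
  oracle <- oracle_masked_corr(cr$a, cr$b, cr$mask, 4)
  expect_equal(cf$overlap_counts, oracle$overlap, ignore_attr = TRUE)
  expect_lt(max(abs(cf$values - oracle$values) / abs(oracle$values)), 1e-10)

  # larger instances up to 32 x 32
  for (seed in 3:5) {
    cr <- make_crop(seed, 32)
    cf <- masked_correlation(cr$a, cr$b, cr$mask, max_lag_px = 6,
                             min_overlap = 1)
    oracle <- oracle_masked_corr(cr$a, cr$b, cr$mask, 6)
    rel <- abs(cf$values - oracle$values) /
      pmax(abs(oracle$values), .Machine$double.eps)
    expect_lt(max(rel, na.rm = TRUE), 1e-8)
  }
})

test_that("ACF is symmetric under lag negation", {
  cr <- make_crop(6, 24)
  cf <- masked_correlation(cr$a, cr$a, cr$mask, 5, 1, "11")
  v <- cf$values
  expect_equal(v, v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v)))],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  cr <- make_crop(7, 24)
  expect_error(masked_correlation(matrix(5, 24, 24), cr$b, cr$mask, 4, 1),
               "degenerate channel")
  sq <- matrix(FALSE, 24, 24); sq[1:10, 1:10] <- TRUE  # 100 px, even count
  zz <- matrix(0, 24, 24); zz[sq] <- rep(c(1, -1), 50)  # exact zero mean
  expect_error(masked_correlation(zz, cr$b, sq, 4, 1), "zero mean")
  small <- matrix(TRUE, 8, 8)
  expect_error(masked_correlation(cr$a[1:8, 1:8], cr$b[1:8, 1:8], small, 2, 1),
               "at least 100")
})

test_that("lags with overlap below min_overlap are missing", {
  cr <- make_crop(8, 24)
  cf <- masked_correlation(cr$a, cr$b, cr$mask, 10, min_overlap = 200)
  expect_true(any(is.na(cf$values)))
  expect_true(all(is.na(cf$values[cf$overlap_counts < 200])))
  expect_true(all(is.finite(cf$values[cf$overlap_counts >= 200])))
})

test_that("the Pearson coefficient is recovered at raw zero lag", {
  for (seed in c(11, 12)) {
    cr <- make_crop(seed, 32)
    g11 <- zero_lag(masked_correlation(cr$a, cr$a, cr$mask, 5, 1, "11"))
    g22 <- zero_lag(masked_correlation(cr$b, cr$b, cr$mask, 5, 1, "22"))
    g12 <- zero_lag(masked_correlation(cr$a, cr$b, cr$mask, 5, 1, "12"))
    expect_equal(g12 / sqrt(g11 * g22),
                 cor(cr$a[cr$mask], cr$b[cr$mask]), tolerance = 1e-12)
  }
})

test_that("correlation functions are scale invariant", {
  cr <- make_crop(13, 24)
  cf1 <- masked_correlation(cr$a, cr$b, cr$mask, 5, 1)
  cf2 <- masked_correlation(cr$a * 7.3, cr$b * 0.02, cr$mask, 5, 1)
  expect_equal(cf1$values, cf2$values, tolerance = 1e-10)
})

test_that("radial profile bins exclude and report the zero lag", {
  cr <- make_crop(14, 32)
  cf <- masked_correlation(cr$a, cr$a, cr$mask, 8, 1, "11")
  prof <- radial_profile(cf)
  expect_equal(nrow(prof), 8)
  expect_equal(prof$r, 1:8)
  expect_equal(attr(prof, "zero_lag"), zero_lag(cf))
  # bin populations: r = 1 collects the 4 nearest neighbours plus diagonals
  expect_equal(prof$n_points[1], 8)
})

test_that("an isotropic Gaussian correlation matches its axis slice", {
  L <- 10
  lags <- -L:L
  g <- 0.5 * exp(-outer(lags^2, lags^2, "+") / 3^2) + 0.02
  cf <- structure(list(values = g, overlap_counts = matrix(1000, 21, 21),
                       lags = lags, mu_a = 1, mu_b = 1, max_lag_px = L,
                       channel_pair = "11"),
                  class = "correlation_function")
  prof <- radial_profile(cf)
  slice <- 0.5 * exp(-(1:L)^2 / 9) + 0.02
  expect_equal(prof$G_mean, slice, tolerance = 0.05)
})

test_that("the Gaussian fit recovers noiseless parameters", {
  r <- 1:20
  prof <- data.frame(r = r, G_mean = 0.4 * exp(-r^2 / 9) + 0.01,
                     n_points = 8 * r)
  fit <- fit_gaussian(prof)
  expect_true(fit$converged)
  expect_equal(fit$amplitude_B, 0.4, tolerance = 1e-6)
  expect_equal(fit$width_w, 3, tolerance = 1e-6)
  expect_equal(fit$offset_Ginf, 0.01, tolerance = 1e-6)
})

test_that("the fit amplitude is robust to 1% noise (50 seeds)", {
  r <- 1:20
  err <- vapply(1:50, function(s) {
    set.seed(s)
    prof <- data.frame(
      r = r,
      G_mean = 0.4 * exp(-r^2 / 9) + 0.01 + rnorm(20, 0, 0.004),
      n_points = 8 * r)
    abs(fit_gaussian(prof)$amplitude_B - 0.4)
  }, numeric(1))
  expect_lt(median(err), 0.02)
})

test_that("a flat profile fits to near-zero amplitude", {
  prof <- data.frame(r = 1:15, G_mean = rep(0.01, 15), n_points = 8 * (1:15))
  fit <- fit_gaussian(prof)
  expect_true(fit$converged)
  expect_lt(abs(fit$amplitude_B), 1e-3)
})

test_that("the fit needs at least 5 usable bins", {
  prof <- data.frame(r = 1:4, G_mean = c(0.3, 0.2, 0.1, 0.05),
                     n_points = c(8, 16, 24, 32))
  expect_error(fit_gaussian(prof), "5 usable")
})

test_that("colocalization fractions follow the amplitude ratios", {
  gf <- function(B) structure(list(amplitude_B = B, width_w = 2,
                                   offset_Ginf = 0, residual_rms = 0,
                                   converged = TRUE), class = "gaussian_fit")
  # identical channels: all amplitudes equal -> f1 = f2 = 1 both conventions
  r <- coloc_fractions(gf(0.3), gf(0.3), gf(0.3))
  expect_equal(r$f1, 1); expect_equal(r$f2, 1)
  rp <- coloc_fractions(gf(0.3), gf(0.3), gf(0.3), convention = "pearson")
  expect_equal(rp$f1, 1)
  # zero cross-correlation
  r0 <- coloc_fractions(gf(0.3), gf(0.2), gf(0))
  expect_equal(r0$f1, 0); expect_equal(r0$f2, 0)
  # asymmetric arithmetic and the pearson form
  ra <- coloc_fractions(gf(0.2), gf(0.1), gf(0.05))
  expect_equal(ra$f1, 0.5); expect_equal(ra$f2, 0.25)
  rs <- coloc_fractions(gf(0.2), gf(0.1), gf(0.05), convention = "pearson")
  expect_equal(rs$f1, 0.05 / sqrt(0.02))
  # anti-correlation keeps its sign
  rn <- coloc_fractions(gf(0.2), gf(0.1), gf(-0.08))
  expect_equal(rn$f1, -0.8)
  # non-positive ACF amplitude
  rb <- coloc_fractions(gf(-0.1), gf(0.2), gf(0.05))
  expect_true(is.na(rb$f1))
  expect_match(rb$qc_flags, "bad-acf")
  # unconverged fit refused
  bad <- gf(0.1); bad$converged <- FALSE
  expect_error(coloc_fractions(bad, gf(0.2), gf(0.05)), "converged")
})

test_that("shifting one channel moves the CCF peak and damps the amplitude", {
  sp <- one_nucleus_spec(seed = 21, n_foci = 40, phi = 0, noise = FALSE)
  sc <- generate_scene(sp)
  a <- sc$rf$pixels
  m <- sc$truth_mask$labels == 1L
  shift_img <- function(x, d) {
    out <- matrix(mean(x), nrow(x), ncol(x))
    out[(1 + d):nrow(x), ] <- x[1:(nrow(x) - d), ]
    out
  }
  amps <- vapply(c(0, 3, 6), function(d) {
    b <- if (d == 0) a else shift_img(a, d)
    cf <- masked_correlation(a, b, m, 12, 50)
    if (d > 0) {
      peak <- which(cf$values == max(cf$values, na.rm = TRUE), arr.ind = TRUE)
      expect_equal(unname(cf$lags[peak[1, 1]]), d)
    }
    fit_gaussian(radial_profile(cf))$amplitude_B
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("per-nucleus ICCS fills f1 on S-phase cells and flags failures", {
  sp <- scene_spec(n_nuclei = 6, nucleus_radius_px = c(mean = 30, sd = 1),
                   phase_mix = c(G1G2 = 0.5, EARLY = 0, MIDDLE = 0.5,
                                 LATE = 0),
                   coloc_fraction_phi = 1, tf_n_foci = 120, seed = 3)
  sc <- generate_scene(sp)
  rfs <- subtract_background(sc$rf)
  tfs <- subtract_background(sc$tf)
  fm <- binarize_foci(sc$rf, background_level = 20)
  rec <- measure_nuclei(sc$truth_mask, rfs, fm)
  rec <- classify_nuclei(rec, derive_thresholds(rec))
  out <- iccs_per_nucleus(rfs, tfs, sc$truth_mask, rec)
  s <- out$phase == "MIDDLE"
  expect_true(all(is.finite(out$f1[s])))
  expect_true(all(is.na(out$f1[out$phase == "G1G2"])))

  # a nucleus with too few foci pixels is skipped with a qc flag
  rec2 <- out
  i <- which(s)[1]
  rec2$N_RF[i] <- 5L
  rec2$f1 <- NA_real_
  out2 <- iccs_per_nucleus(rfs, tfs, sc$truth_mask, rec2)
  expect_true(is.na(out2$f1[i]))
  expect_match(out2$qc_flags[i], "insufficient-foci")
})
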
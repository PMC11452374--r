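#' ICCS settings
#'
#' @param max_lag_px Maximum spatial lag of the correlation functions,
#'   pixels.
#' @param min_overlap Minimum number of mask-pair pixel overlaps for a lag to
#'   be usable; lags supported by fewer pixels are set to missing.
#' @param convention `"asymmetric"` (default): `f1 = Bcc/B22`,
#'   `f2 = Bcc/B11`, the classical fraction-colocalized convention that
#'   distinguishes the two channels; `"pearson"`: the symmetric
#'   `f1 = f2 = Bcc/sqrt(B11*B22)`.
#' @param pad_px Padding added around each nucleus bounding box before
#'   correlation.
#' @return An object of class `iccs_settings`.
#' @export
iccs_settings <- function(max_lag_px = 32, min_overlap = 200,
                          convention = c("asymmetric", "pearson"),
                          pad_px = 8) {
  convention <- match.arg(convention)
  stopifnot(max_lag_px >= 5, min_overlap >= 1, pad_px >= 0)
  structure(list(max_lag_px = as.integer(max_lag_px),
                 min_overlap = as.integer(min_overlap),
                 convention = convention, pad_px = as.integer(pad_px)),
            class = "iccs_settings")
}

#' Masked spatial correlation of two channels
#'
#' Computes the fluctuation cross-correlation function
#' `G(xi, eta) = <dI_a(x, y) dI_b(x + xi, y + eta)> / (mu_a * mu_b)` over an
#' irregular region of interest (the nucleus mask), with masked
#' normalization: means are taken within the mask, fluctuation images are
#' zeroed outside it, raw lag sums are computed by FFT and each lag is
#' divided by the number of mask pixel pairs contributing to it (the
#' autocorrelation of the mask indicator, also by FFT). This gives an
#' unbiased `G` for arbitrarily shaped nuclei, unlike zero-padding with
#' global means. With `a == b` the result is the spatial autocorrelation
#' function (ACF); its zero lag equals `variance / mean^2` within the mask.
#'
#' @param a,b Numeric matrices (channel crops), same shape.
#' @param nucleus_mask Logical matrix, same shape, at least 100 `TRUE`
#'   pixels.
#' @param max_lag_px Maximum lag, pixels.
#' @param min_overlap Minimum pixel-pair count per lag; lags with fewer are
#'   `NA`.
#' @param channel_pair Label stored with the result (`"11"`, `"22"`,
#'   `"12"`).
#' @return An object of class `correlation_function` with fields `values`
#'   and `overlap_counts` ((2L+1) x (2L+1) matrices over lags -L..L), the
#'   lags, the in-mask means, and `channel_pair`.
#' @export
masked_correlation <- function(a, b, nucleus_mask, max_lag_px = 32,
                               min_overlap = 200, channel_pair = "12") {
  stopifnot(is.matrix(a), is.matrix(b), is.logical(nucleus_mask))
  if (!.same_shape(a, b) || !.same_shape(a, nucleus_mask)) {
    stop("channel crops and mask must share shape")
  }
  if (sum(nucleus_mask) < 100) stop("mask must contain at least 100 pixels")
  L <- as.integer(max_lag_px)
  m <- nucleus_mask * 1
  mu_a <- mean(a[nucleus_mask])
  mu_b <- mean(b[nucleus_mask])
  if (mu_a == 0 || mu_b == 0) stop("zero mean within mask")
  if (var(a[nucleus_mask]) == 0 || var(b[nucleus_mask]) == 0) {
    stop("degenerate channel: zero variance within mask")
  }
  da <- (a - mu_a) * m
  db <- (b - mu_b) * m

  s_ab <- .xcorr_fft(da, db, L)
  w <- round(.xcorr_fft(m, m, L))
  g <- s_ab / (w * mu_a * mu_b)
  g[w < min_overlap] <- NA_real_

  lags <- -L:L
  dimnames(g) <- dimnames(w) <- list(xi = lags, eta = lags)
  structure(
    list(values = g, overlap_counts = w, lags = lags,
         mu_a = mu_a, mu_b = mu_b, max_lag_px = L,
         channel_pair = as.character(channel_pair)),
    class = "correlation_function"
  )
}

## raw lag sums S(xi, eta) = sum_xy A(x,y) B(x+xi, y+eta) for |xi|,|eta| <= L,
## via zero-padded FFT cross-correlation
.xcorr_fft <- function(a, b, L) {
  nr <- nrow(a) + L
  nc <- ncol(a) + L
  pa <- matrix(0, nr, nc); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pb <- matrix(0, nr, nc); pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  s <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / (nr * nc)
  idx_r <- c(nr - L + seq_len(L), seq_len(L + 1))   # lags -L..L
  idx_c <- c(nc - L + seq_len(L), seq_len(L + 1))
  s[idx_r, idx_c]
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("<correlation_function> pair %s, lags -%d..%d, G(0,0) = %.4g\n",
              x$channel_pair, x$max_lag_px, x$max_lag_px,
              x$values[x$max_lag_px + 1, x$max_lag_px + 1]))
  invisible(x)
}

#' Zero-lag value of a correlation function
#'
#' @param cf A [masked_correlation()] result.
#' @return `G(0, 0)`.
#' @export
zero_lag <- function(cf) {
  stopifnot(inherits(cf, "correlation_function"))
  cf$values[cf$max_lag_px + 1, cf$max_lag_px + 1]
}

#' Radial profile of a 2-D correlation function
#'
#' Averages `G` over integer radial bins `r = 1..max_lag` (lag radius rounded
#' to the nearest integer). The zero lag is reported separately as the
#' attribute `zero_lag` and excluded from the bins: in fluorescence images
#' uncorrelated shot noise inflates the ACF at lag (0,0) only, so fits start
#' at r = 1.
#'
#' @param cf A [masked_correlation()] result.
#' @return data.frame with columns `r`, `G_mean`, `n_points`
#'   (`n_points = 0` and `G_mean = NA` where every lag in the bin is
#'   missing), with attribute `zero_lag`.
#' @export
radial_profile <- function(cf) {
  stopifnot(inherits(cf, "correlation_function"))
  L <- cf$max_lag_px
  r <- round(sqrt(outer(cf$lags^2, cf$lags^2, "+")))
  ok <- !is.na(cf$values) & r >= 1 & r <= L
  g_sum <- rep(0, L); n <- rep(0L, L)
  if (any(ok)) {
    agg_s <- rowsum(cf$values[ok], r[ok])
    agg_n <- rowsum(rep(1L, sum(ok)), r[ok])
    idx <- as.integer(rownames(agg_s))
    g_sum[idx] <- agg_s[, 1]
    n[idx] <- agg_n[, 1]
  }
  out <- data.frame(r = seq_len(L),
                    G_mean = ifelse(n > 0, g_sum / pmax(n, 1), NA_real_),
                    n_points = n)
  attr(out, "zero_lag") <- zero_lag(cf)
  out
}

#' Fit a Gaussian to a radial correlation profile
#'
#' Weighted least squares of `G(r) = B * exp(-r^2 / w^2) + Ginf` with the
#' bin populations as weights. Initialization: `B = G(1) - tail mean`,
#' `w = 2` px, `Ginf` = mean of the outermost 3 usable bins; bounds
#' `0.5 <= w <= max(r)`; `B` is unconstrained in sign so anti-correlation
#' survives the fit. The amplitude `B` estimates the correlation strength
#' free of the shot-noise zero-lag spike; amplitudes of the two ACFs and the
#' CCF feed [coloc_fractions()].
#'
#' @param profile A [radial_profile()] result with at least 5 usable bins.
#' @return An object of class `gaussian_fit` with fields `amplitude_B`,
#'   `width_w`, `offset_Ginf`, `residual_rms`, `converged`.
#' @export
fit_gaussian <- function(profile) {
  use <- profile[profile$n_points > 0 & is.finite(profile$G_mean), ]
  if (nrow(use) < 5) stop("need at least 5 usable radial bins")
  tail_m <- mean(tail(use$G_mean, 3))
  max_r <- max(use$r)

  ## profile the width on a grid: for fixed w the model is linear in
  ## (B, Ginf), so weighted linear LS always has a solution — this makes the
  ## fit robust for flat or near-flat profiles where w is unidentifiable
  grid <- exp(seq(log(0.5), log(max_r), length.out = 40))
  best <- NULL
  for (w in grid) {
    x <- exp(-(use$r / w)^2)
    lf <- stats::lm.wfit(cbind(B = x, Ginf = 1), use$G_mean, use$n_points)
    sse <- sum(use$n_points * lf$residuals^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(w = w, B = unname(lf$coefficients["B"]),
                   Ginf = unname(lf$coefficients["Ginf"]), sse = sse)
    }
  }
  if (is.null(best) || !is.finite(best$sse)) {
    return(structure(list(amplitude_B = NA_real_, width_w = NA_real_,
                          offset_Ginf = NA_real_, residual_rms = NA_real_,
                          converged = FALSE),
                     class = "gaussian_fit"))
  }
  if (!is.finite(best$B)) best$B <- 0
  if (!is.finite(best$Ginf)) best$Ginf <- tail_m

  ## polish with Levenberg-Marquardt from the grid optimum
  fit <- tryCatch(
    minpack.lm::nlsLM(
      G_mean ~ B * exp(-(r / w)^2) + Ginf,
      data = use, start = list(B = best$B, w = best$w, Ginf = best$Ginf),
      weights = use$n_points,
      lower = c(B = -Inf, w = 0.5, Ginf = -Inf),
      upper = c(B = Inf, w = max_r, Ginf = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    ## the grid solution is itself a valid weighted least-squares estimate
    res <- best$B * exp(-(use$r / best$w)^2) + best$Ginf - use$G_mean
    return(structure(list(amplitude_B = best$B, width_w = best$w,
                          offset_Ginf = best$Ginf,
                          residual_rms = sqrt(mean(res^2)),
                          converged = TRUE),
                     class = "gaussian_fit"))
  }
  cf <- coef(fit)
  structure(
    list(amplitude_B = unname(cf["B"]), width_w = unname(cf["w"]),
         offset_Ginf = unname(cf["Ginf"]),
         residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         converged = TRUE),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> B = %.4g, w = %.3g px, Ginf = %.4g (%s)\n",
              x$amplitude_B, x$width_w, x$offset_Ginf,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Colocalization fractions from fitted amplitudes
#'
#' `f1` is the fraction of channel-1 signal cross-correlated with channel 2,
#' `f2` the converse. Under the default asymmetric convention
#' `f1 = Bcc / B22` and `f2 = Bcc / B11`; under the symmetric Pearson-style
#' convention `f1 = f2 = Bcc / sqrt(B11 * B22)`. Values range from 1
#' (maximum cross-correlation) through 0 (independent channels) to -1
#' (maximum anti-correlation); the sign of `Bcc` carries anti-correlation
#' and is never clamped. Fit noise can push values marginally outside
#' [-1, 1]; such results keep their value and gain qc flag `out-of-range`.
#'
#' @param fit11,fit22 ACF [fit_gaussian()] results for channels 1 and 2.
#' @param fit_cc CCF fit.
#' @param convention `"asymmetric"` or `"pearson"`.
#' @return An object of class `coloc_result` with `f1`, `f2`, the three
#'   amplitudes, the convention and qc flags.
#' @export
coloc_fractions <- function(fit11, fit22, fit_cc,
                            convention = c("asymmetric", "pearson")) {
  convention <- match.arg(convention)
  for (f in list(fit11, fit22, fit_cc)) {
    stopifnot(inherits(f, "gaussian_fit"))
    if (!f$converged) stop("all three fits must have converged")
  }
  b11 <- fit11$amplitude_B
  b22 <- fit22$amplitude_B
  bcc <- fit_cc$amplitude_B
  qc <- ""
  if (b11 <= 0 || b22 <= 0) {
    f1 <- f2 <- NA_real_
    qc <- .add_flag(qc, "bad-acf")
  } else if (convention == "asymmetric") {
    f1 <- bcc / b22
    f2 <- bcc / b11
  } else {
    f1 <- f2 <- bcc / sqrt(b11 * b22)
  }
  if (!is.na(f1) && (abs(f1) > 1 || abs(f2) > 1)) {
    qc <- .add_flag(qc, "out-of-range")
  }
  structure(list(f1 = f1, f2 = f2, B11 = b11, B22 = b22, Bcc = bcc,
                 convention = convention, qc_flags = qc),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> f1 = %.3f, f2 = %.3f (%s)\n",
              x$f1, x$f2, x$convention))
  invisible(x)
}

## full ICCS chain on one nucleus crop; returns list(f1, f2, qc, details)
.iccs_on_crop <- function(a, b, m, settings) {
  L <- min(settings$max_lag_px, floor(min(dim(m)) / 2) - 1L)
  cf11 <- masked_correlation(a, a, m, L, settings$min_overlap, "11")
  cf22 <- masked_correlation(b, b, m, L, settings$min_overlap, "22")
  cf12 <- masked_correlation(a, b, m, L, settings$min_overlap, "12")
  fit11 <- fit_gaussian(radial_profile(cf11))
  fit22 <- fit_gaussian(radial_profile(cf22))
  fitcc <- fit_gaussian(radial_profile(cf12))
  if (!fit11$converged || !fit22$converged || !fitcc$converged) {
    return(list(f1 = NA_real_, f2 = NA_real_, qc = "fit-failed",
                fits = list(fit11, fit22, fitcc)))
  }
  res <- coloc_fractions(fit11, fit22, fitcc, settings$convention)
  list(f1 = res$f1, f2 = res$f2, qc = res$qc_flags,
       fits = list(fit11, fit22, fitcc), result = res)
}

#' Per-nucleus ICCS over a classified batch
#'
#' For every S-phase nucleus (`EARLY`, `MIDDLE`, `LATE`) the nucleus
#' bounding box is cropped with `pad_px` of margin, the nucleus indicator
#' used as correlation mask, the two ACFs and the CCF computed with masked
#' normalization, radial profiles fitted, and `f1`/`f2` filled into the
#' records. G1/G2 nuclei carry no replication signal and are skipped.
#' Nuclei with fewer foci pixels than `N_min`, nuclei whose mask is too
#' small, and any per-nucleus numerical failure are recorded as qc flags and
#' never abort the batch; nuclei touching the image border are processed
#' with their available pixels and flagged `border`.
#'
#' @param rf,tf Background-subtracted [channel_image()]s (channel 1 =
#'   replication, channel 2 = e.g. transcription).
#' @param mask [count_mask()] shared by both channels.
#' @param records Classified records for this frame (subset of the batch
#'   records with matching `frame_id`).
#' @param settings [iccs_settings()].
#' @param N_min Minimum foci pixels for a nucleus to be analysed.
#' @return `records` with `f1`, `f2` and qc flags updated.
#' @export
iccs_per_nucleus <- function(rf, tf, mask, records,
                             settings = iccs_settings(), N_min = 10) {
  stopifnot(inherits(rf, "channel_image"), inherits(tf, "channel_image"),
            inherits(mask, "count_mask"))
  if (!.same_shape(rf$pixels, tf$pixels) ||
      !.same_shape(rf$pixels, mask$labels)) {
    stop("rf, tf and mask shapes differ")
  }
  s_phase <- which(records$phase %in% c("EARLY", "MIDDLE", "LATE"))
  dims <- dim(mask$labels)
  for (i in s_phase) {
    lab <- records$label[i]
    if (records$N_RF[i] < N_min) {
      records$qc_flags[i] <- .add_flag(records$qc_flags[i],
                                       "insufficient-foci")
      next
    }
    pos <- which(mask$labels == lab, arr.ind = TRUE)
    if (!nrow(pos)) next
    r0 <- max(1L, min(pos[, 1]) - settings$pad_px)
    r1 <- min(dims[1], max(pos[, 1]) + settings$pad_px)
    c0 <- max(1L, min(pos[, 2]) - settings$pad_px)
    c1 <- min(dims[2], max(pos[, 2]) + settings$pad_px)
    if (min(pos[, 1]) == 1L || max(pos[, 1]) == dims[1] ||
        min(pos[, 2]) == 1L || max(pos[, 2]) == dims[2]) {
      records$qc_flags[i] <- .add_flag(records$qc_flags[i], "border")
    }
    m <- mask$labels[r0:r1, c0:c1] == lab
    a <- rf$pixels[r0:r1, c0:c1]
    b <- tf$pixels[r0:r1, c0:c1]
    out <- tryCatch(.iccs_on_crop(a, b, m, settings),
                    error = function(e) {
                      list(f1 = NA_real_, f2 = NA_real_,
                           qc = paste0("iccs-error:",
                                       gsub("[,;\n]", " ",
                                            conditionMessage(e))))
                    })
    records$f1[i] <- out$f1
    records$f2[i] <- out$f2
    if (nzchar(out$qc)) {
      records$qc_flags[i] <- .add_flag(records$qc_flags[i], out$qc)
    }
  }
  records
}
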
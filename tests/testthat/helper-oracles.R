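# Independent brute-force oracles and small image fixtures built in code.

# disk on constant background
disk_image <- function(side, cx, cy, r, fg = 200, bg = 10) {
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  m <- matrix(bg, side, side)
  m[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- fg
  m
}

# 8-connected component labelling by direct flood fill (pure R)
oracle_label8 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (bin[i, j] == 0 || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (bin[qi, qj] != 0 && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# masked fluctuation correlation by direct nested loops over all pixel pairs
oracle_masked_corr <- function(a, b, mask, L) {
  mu_a <- mean(a[mask]); mu_b <- mean(b[mask])
  nr <- nrow(a); nc <- ncol(a)
  g <- w <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  for (xi in -L:L) for (eta in -L:L) {
    s <- 0; cnt <- 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + xi; j2 <- j + eta
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      if (!mask[i, j] || !mask[i2, j2]) next
      s <- s + (a[i, j] - mu_a) * (b[i2, j2] - mu_b)
      cnt <- cnt + 1
    }
    w[xi + L + 1, eta + L + 1] <- cnt
    g[xi + L + 1, eta + L + 1] <- if (cnt > 0) s / (cnt * mu_a * mu_b) else NA
  }
  list(values = g, overlap = w)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  u_all <- apply(combos, 2, function(idx) {
    sum(rk[idx]) - n_a * (n_a + 1) / 2
  })
  mu <- n_a * (n - n_a) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# one-nucleus scene with uniformly placed foci in both channels
one_nucleus_spec <- function(seed, n_foci = 60L, phi = 0, noise = TRUE,
                             radius = 36) {
  scene_spec(
    n_nuclei = 1, nucleus_radius_px = c(mean = radius, sd = 0),
    phase_mix = c(G1G2 = 0, EARLY = 0, MIDDLE = 1, LATE = 0),
    foci_params = list(MIDDLE = list(n_foci = as.integer(n_foci),
                                     placement = "uniform")),
    tf_n_foci = n_foci, coloc_fraction_phi = phi,
    noise = if (noise) list(gaussian_sd = 2, poisson = TRUE) else
      list(gaussian_sd = 0, poisson = FALSE),
    background_level = if (noise) 20 else 0,
    seed = seed
  )
}

# f1 for a one-nucleus scene via the exported ICCS chain
one_nucleus_f1 <- function(scene, settings = iccs_settings()) {
  rfs <- subtract_background(scene$rf)
  tfs <- subtract_background(scene$tf)
  m <- scene$truth_mask$labels == 1L
  pos <- which(m, arr.ind = TRUE)
  r0 <- max(1, min(pos[, 1]) - settings$pad_px)
  r1 <- min(nrow(m), max(pos[, 1]) + settings$pad_px)
  c0 <- max(1, min(pos[, 2]) - settings$pad_px)
  c1 <- min(ncol(m), max(pos[, 2]) + settings$pad_px)
  a <- rfs$pixels[r0:r1, c0:c1]
  b <- tfs$pixels[r0:r1, c0:c1]
  mm <- m[r0:r1, c0:c1]
  L <- min(settings$max_lag_px, floor(min(dim(mm)) / 2) - 1L)
  f11 <- fit_gaussian(radial_profile(
    masked_correlation(a, a, mm, L, settings$min_overlap, "11")))
  f22 <- fit_gaussian(radial_profile(
    masked_correlation(b, b, mm, L, settings$min_overlap, "22")))
  fcc <- fit_gaussian(radial_profile(
    masked_correlation(a, b, mm, L, settings$min_overlap, "12")))
  coloc_fractions(f11, f22, fcc, settings$convention)$f1
}

# synthetic record table for sorter-rule tests (uniform-size nuclei unless
# N_nuc given); rho/I set through N_RF and I_RF directly
make_records <- function(N_RF, I_RF, N_nuc = 1000L,
                         frame_id = "t", label = seq_along(N_RF)) {
  n <- length(N_RF)
  N_nuc <- rep_len(N_nuc, n)
  data.frame(frame_id = frame_id, label = label, N_nuc = as.integer(N_nuc),
             N_RF = as.integer(N_RF), rho_RF = N_RF / N_nuc, I_RF = I_RF,
             phase = NA_character_, f1 = NA_real_, f2 = NA_real_,
             qc_flags = "", stringsAsFactors = FALSE)
}
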
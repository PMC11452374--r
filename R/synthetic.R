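#' Default foci parameters per cell-cycle phase archetype
#'
#' Simulator defaults emulating the qualitative replication-foci patterns of
#' the S subphases: `EARLY` nuclei carry sparse, dim foci in the nuclear
#' interior (euchromatin replicating early); `MIDDLE` nuclei dense, brighter
#' foci biased toward the nuclear rim; `LATE` nuclei few large bright foci,
#' also rim-biased (heterochromatin); `G1G2` nuclei carry none. Amplitudes
#' are multiples of the scene's base focus amplitude. These are simulator
#' defaults chosen so the default sorter separates the archetypes; they are
#' not measured biological values.
#'
#' @param phase One of `"G1G2"`, `"EARLY"`, `"MIDDLE"`, `"LATE"`.
#' @return List with `n_foci`, `amplitude` (x base), `sigma` (px),
#'   `placement` (`"interior"`, `"rim"` or `"uniform"`).
#' @export
phase_archetype_defaults <- function(phase) {
  switch(phase,
    G1G2   = list(n_foci = 0L,   amplitude = 0, sigma = 1.5,
                  placement = "uniform"),
    EARLY  = list(n_foci = 15L,  amplitude = 1, sigma = 1.5,
                  placement = "interior"),
    MIDDLE = list(n_foci = 120L, amplitude = 2, sigma = 1.5,
                  placement = "rim"),
    LATE   = list(n_foci = 5L,   amplitude = 6, sigma = 2.5,
                  placement = "rim"),
    stop("unknown phase: ", phase)
  )
}

#' Specification of a synthetic multi-channel nuclear scene
#'
#' Describes a fully reproducible synthetic field of view: disk-shaped,
#' non-overlapping nuclei in a DNA channel; phase-specific replication foci
#' (RF channel) rendered as isotropic Gaussian spots; a second foci channel
#' (TF) in which a controllable fraction `coloc_fraction_phi` of foci is
#' placed exactly coincident with RF foci and the rest uniformly at random
#' within the nucleus; Gaussian PSF blur, then Poisson noise on the signal
#' plus additive Gaussian read noise, then a constant background, applied to
#' all channels. The seed fully determines the scene; each nucleus draws its
#' foci from its own RNG sub-stream so adding nuclei leaves earlier nuclei
#' unchanged.
#'
#' @param n_nuclei Number of nuclei.
#' @param nucleus_radius_px Mean and spread (sd) of the nucleus radius,
#'   pixels.
#' @param phase_mix Named proportions over the four phases; must sum to 1.
#' @param foci_params Optional named list overriding
#'   [phase_archetype_defaults()] per phase.
#' @param base_amplitude Peak intensity of a 1x focus before blur, counts.
#' @param tf_n_foci Foci count in the TF channel of each nucleus.
#' @param tf_amplitude,tf_sigma_px TF focus peak (counts) and width.
#' @param coloc_fraction_phi Ground-truth colocalized fraction in [0, 1];
#'   scalar, or named per phase.
#' @param psf_sigma_px Gaussian PSF sigma, pixels.
#' @param noise List with `gaussian_sd` (additive read noise, counts) and
#'   `poisson` (flag; shot noise on the blurred signal).
#' @param background_level Constant background added last, counts. The
#'   default of 20 keeps the standard 1.5x-background foci threshold 5 read
#'   noise sd above the background, so EdU-negative nuclei stay dark.
#' @param dna_intensity Nucleus intensity in the DNA channel, counts.
#' @param image_size Side of the square scene, pixels; `NULL` picks a size
#'   that places the nuclei at a loose packing density.
#' @param pixel_size_nm Pixel size recorded in the channel metadata.
#' @param seed Integer seed; determines the scene completely.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_nuclei = 60,
                       nucleus_radius_px = c(mean = 36, sd = 2),
                       phase_mix = c(G1G2 = 0.25, EARLY = 0.25,
                                     MIDDLE = 0.25, LATE = 0.25),
                       foci_params = NULL,
                       base_amplitude = 60,
                       tf_n_foci = 60, tf_amplitude = 90, tf_sigma_px = 1.5,
                       coloc_fraction_phi = 0,
                       psf_sigma_px = 1,
                       noise = list(gaussian_sd = 2, poisson = TRUE),
                       background_level = 20,
                       dna_intensity = 100,
                       image_size = NULL,
                       pixel_size_nm = 45,
                       seed = 1) {
  stopifnot(n_nuclei >= 1, all(phase_mix >= 0),
            abs(sum(phase_mix) - 1) < 1e-8,
            all(coloc_fraction_phi >= 0), all(coloc_fraction_phi <= 1),
            tf_n_foci >= 0, psf_sigma_px >= 0, background_level >= 0)
  if (is.null(names(nucleus_radius_px))) {
    names(nucleus_radius_px) <- c("mean", "sd")[seq_along(nucleus_radius_px)]
  }
  fp <- lapply(setNames(nm = names(phase_mix)), phase_archetype_defaults)
  if (!is.null(foci_params)) {
    for (ph in names(foci_params)) {
      fp[[ph]] <- modifyList(fp[[ph]], foci_params[[ph]])
    }
  }
  structure(
    list(n_nuclei = as.integer(n_nuclei),
         nucleus_radius_px = nucleus_radius_px,
         phase_mix = phase_mix, foci_params = fp,
         base_amplitude = base_amplitude,
         tf_n_foci = as.integer(tf_n_foci), tf_amplitude = tf_amplitude,
         tf_sigma_px = tf_sigma_px,
         coloc_fraction_phi = coloc_fraction_phi,
         psf_sigma_px = psf_sigma_px, noise = noise,
         background_level = background_level,
         dna_intensity = dna_intensity, image_size = image_size,
         pixel_size_nm = pixel_size_nm, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

.phi_for_phase <- function(spec, phase) {
  phi <- spec$coloc_fraction_phi
  if (!is.null(names(phi)) && phase %in% names(phi)) return(unname(phi[phase]))
  unname(phi[1])
}

.scene_side <- function(spec) {
  if (!is.null(spec$image_size)) return(as.integer(spec$image_size))
  rmax <- spec$nucleus_radius_px["mean"] + 3 * spec$nucleus_radius_px["sd"]
  max(128L, as.integer(ceiling(sqrt(spec$n_nuclei * (2 * rmax + 8)^2 / 0.25))))
}

## deterministic phase counts from the mix (largest-remainder rounding)
.phase_counts <- function(mix, n) {
  raw <- mix * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

## sample a focus position inside a disk; placement controls the radial law
.sample_foci <- function(n, cx, cy, r_eff, placement) {
  if (n == 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  u <- runif(n)
  rad <- switch(placement,
    uniform  = r_eff * sqrt(u),
    interior = 0.85 * r_eff * sqrt(u),
    rim      = r_eff * u^(1 / 4),
    stop("unknown placement: ", placement)
  )
  th <- runif(n, 0, 2 * pi)
  data.frame(x = cx + rad * cos(th), y = cy + rad * sin(th))
}

## add Gaussian spots (continuous centres) into an intensity matrix in place
.render_spots <- function(img, foci, amplitude, sigma) {
  if (!nrow(foci)) return(img)
  w <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(nrow(foci))) {
    i0 <- max(1L, floor(foci$y[k]) - w); i1 <- min(nr, ceiling(foci$y[k]) + w)
    j0 <- max(1L, floor(foci$x[k]) - w); j1 <- min(nc, ceiling(foci$x[k]) + w)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    gy <- exp(-(ii - foci$y[k])^2 / (2 * sigma^2))
    gx <- exp(-(jj - foci$x[k])^2 / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gy, gx)
  }
  img
}

.blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

.apply_noise <- function(img, noise, background) {
  if (isTRUE(noise$poisson)) {
    img[] <- rpois(length(img), lambda = pmax(img, 0))
  }
  sd <- if (is.null(noise$gaussian_sd)) 0 else noise$gaussian_sd
  if (sd > 0) img <- img + rnorm(length(img), 0, sd)
  pmax(img + background, 0)
}

#' Generate a synthetic multi-channel nuclear scene
#'
#' Renders the scene described by a [scene_spec()]: DNA, RF and TF channels,
#' the ground-truth count mask (the exact disk regions, before blur and
#' noise), and the per-nucleus ground truth (true phase, centre, radius,
#' focus coordinates, and which TF foci were placed coincident with RF
#' foci). The number of coincident TF foci per nucleus is
#' `round(phi * min(n_RF_foci, tf_n_foci))`.
#'
#' @param spec A [scene_spec()].
#' @return List with elements `dna`, `rf`, `tf` ([channel_image()]s),
#'   `truth_mask` ([count_mask()]), `ground_truth` (list of data.frames
#'   `nuclei`, `rf_foci`, `tf_foci`) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  side <- .scene_side(spec)
  r_mean <- spec$nucleus_radius_px["mean"]
  r_sd <- if (is.na(spec$nucleus_radius_px["sd"])) 0 else
    spec$nucleus_radius_px["sd"]

  set.seed(spec$seed)
  counts <- .phase_counts(spec$phase_mix, spec$n_nuclei)
  phases <- sample(rep(names(spec$phase_mix), counts))
  radii <- pmin(pmax(rnorm(spec$n_nuclei, r_mean, r_sd), 0.7 * r_mean),
                1.3 * r_mean)

  ## non-overlapping placement by rejection
  cx <- cy <- numeric(spec$n_nuclei)
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      x <- runif(1, radii[i] + 2, side - radii[i] - 1)
      y <- runif(1, radii[i] + 2, side - radii[i] - 1)
      if (i == 1 || all((x - cx[seq_len(i - 1)])^2 +
                        (y - cy[seq_len(i - 1)])^2 >
                        (radii[i] + radii[seq_len(i - 1)] + 4)^2)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("could not place ", spec$n_nuclei, " non-overlapping nuclei; ",
           "reduce n_nuclei or nucleus_radius_px, or enlarge image_size")
    }
  }

  dna <- rf <- tf <- matrix(0, side, side)
  labels <- matrix(0L, side, side)
  row_g <- matrix(seq_len(side), side, side)
  col_g <- matrix(seq_len(side), side, side, byrow = TRUE)

  rf_foci_all <- list()
  tf_foci_all <- list()
  for (i in seq_len(spec$n_nuclei)) {
    inside <- (row_g - cy[i])^2 + (col_g - cx[i])^2 <= radii[i]^2
    labels[inside] <- i
    dna[inside] <- dna[inside] + spec$dna_intensity

    fp <- spec$foci_params[[phases[i]]]
    ## per-nucleus RNG sub-stream: foci layout independent of other nuclei
    set.seed(as.integer((as.numeric(spec$seed) * 10007 + i * 101) %%
                          2147483647))
    ## uniform placement covers the whole disk (no interior envelope that
    ## would correlate two otherwise independent channels); the biased
    ## archetype placements keep foci clear of the boundary
    r_eff <- if (fp$placement == "uniform") radii[i] else
      max(radii[i] - 2 * fp$sigma - 2, 2)
    rfi <- .sample_foci(fp$n_foci, cx[i], cy[i], r_eff, fp$placement)
    rf <- .render_spots(rf, rfi, fp$amplitude * spec$base_amplitude,
                        fp$sigma)

    phi <- .phi_for_phase(spec, phases[i])
    n_tf <- spec$tf_n_foci
    n_co <- round(phi * min(nrow(rfi), n_tf))
    co_idx <- if (n_co > 0) sample(nrow(rfi), n_co) else integer(0)
    tfi_free <- .sample_foci(n_tf - n_co, cx[i], cy[i], radii[i], "uniform")
    tfi <- rbind(rfi[co_idx, , drop = FALSE], tfi_free)
    tf <- .render_spots(tf, tfi, spec$tf_amplitude, spec$tf_sigma_px)

    if (nrow(rfi)) {
      rf_foci_all[[i]] <- cbind(label = i, rfi)
    }
    if (nrow(tfi)) {
      tf_foci_all[[i]] <- cbind(label = i, tfi,
                                coincident = rep(c(TRUE, FALSE),
                                                 c(n_co, nrow(tfi) - n_co)))
    }
  }

  dna <- .blur(dna, spec$psf_sigma_px)
  rf <- .blur(rf, spec$psf_sigma_px)
  tf <- .blur(tf, spec$psf_sigma_px)

  set.seed(as.integer((as.numeric(spec$seed) * 31 + 7) %% 2147483647))
  dna <- .apply_noise(dna, spec$noise, spec$background_level)
  rf <- .apply_noise(rf, spec$noise, spec$background_level)
  tf <- .apply_noise(tf, spec$noise, spec$background_level)

  as_ch <- function(m, role) {
    channel_image(m, pixel_size_nm = spec$pixel_size_nm, channel_role = role,
                  frame_id = sprintf("scene-%d", spec$seed))
  }
  list(
    dna = as_ch(dna, "DNA"), rf = as_ch(rf, "RF"), tf = as_ch(tf, "TF"),
    truth_mask = count_mask(labels),
    ground_truth = list(
      nuclei = data.frame(label = seq_len(spec$n_nuclei), phase = phases,
                          cx = cx, cy = cy, radius = radii,
                          stringsAsFactors = FALSE),
      rf_foci = do.call(rbind, rf_foci_all),
      tf_foci = do.call(rbind, tf_foci_all)
    ),
    spec = spec
  )
}
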
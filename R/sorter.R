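#' Sorting parameters for cell-cycle classification
#'
#' The four tunable constants of the sorter, with the working defaults used
#' throughout: `N_min = 10` foci pixels (the minimum signal to call a nucleus
#' replicating at all), `k_rho = 0.4` (Middle-group density threshold as a
#' fraction of the population maximum density), `k = 3` (Late-group intensity
#' threshold as a multiple of the subgroup minimum intensity) and
#' `k_size = 1.2` (nuclear-size guard on the Early group: S-phase cells that
#' are about to enter G2 have larger-than-average nuclei and would otherwise
#' contaminate Early). Thresholds derived from them are recomputed per
#' analysis batch and must be held fixed across images acquired under the
#' same experimental conditions.
#'
#' @param N_min Minimum number of foci pixels, positive integer.
#' @param k_rho Density-threshold multiplier in (0, 1].
#' @param k Intensity-threshold multiplier, > 1.
#' @param k_size Early-group size-exclusion multiplier, > 1.
#' @param rho_thr_max Optional absolute cap on the derived density threshold
#'   `rho_thr` (the threshold otherwise tracks the observed maximum density,
#'   which a single outlier nucleus can shift); `NULL` applies no cap.
#' @return An object of class `sorting_params`.
#' @export
sorting_params <- function(N_min = 10, k_rho = 0.4, k = 3, k_size = 1.2,
                           rho_thr_max = NULL) {
  stopifnot(N_min >= 1, k_rho > 0, k_rho <= 1, k > 1, k_size > 1)
  structure(list(N_min = as.integer(N_min), k_rho = k_rho, k = k,
                 k_size = k_size, rho_thr_max = rho_thr_max),
            class = "sorting_params")
}

#' Measure per-nucleus replication-foci density and intensity
#'
#' For each non-excluded nucleus j of the count mask, computes the nuclear
#' area `N_nuc`, the foci pixel count `N_RF` (foci-mask pixels inside the
#' nucleus), the replication-foci pixel density `rho_RF = N_RF / N_nuc`, and
#' the replication-foci pixel intensity `I_RF` = mean RF intensity over the
#' foci pixels of the nucleus (0 when the nucleus has no foci pixels). Foci
#' pixels outside any nucleus are ignored.
#'
#' @param mask [count_mask()].
#' @param rf RF [channel_image()] (typically background-subtracted).
#' @param foci [foci_mask()] from [binarize_foci()].
#' @return A data.frame of nucleus records with columns `frame_id`, `label`,
#'   `N_nuc`, `N_RF`, `rho_RF`, `I_RF`, `phase` (unset, `NA`), `f1`, `f2`,
#'   `qc_flags`.
#' @export
measure_nuclei <- function(mask, rf, foci) {
  stopifnot(inherits(mask, "count_mask"), inherits(rf, "channel_image"),
            inherits(foci, "foci_mask"))
  if (!.same_shape(mask$labels, rf$pixels) ||
      !.same_shape(mask$labels, foci$mask)) {
    stop("mask, rf and foci shapes differ")
  }
  labs <- active_labels(mask)
  if (!length(labs)) return(.empty_records())
  lv <- as.vector(mask$labels)
  keep <- lv > 0L & !(lv %in% mask$excluded_labels)
  lv <- lv[keep]
  fv <- as.vector(foci$mask)[keep]
  iv <- as.vector(rf$pixels)[keep]
  n_nuc <- tabulate(lv)
  n_rf <- tabulate(lv[fv])
  length(n_rf) <- length(n_nuc)
  n_rf[is.na(n_rf)] <- 0L
  i_sum <- rep(0, length(n_nuc))
  agg <- rowsum(iv[fv], lv[fv])
  i_sum[as.integer(rownames(agg))] <- agg[, 1]
  data.frame(
    frame_id = rf$frame_id,
    label = labs,
    N_nuc = n_nuc[labs],
    N_RF = n_rf[labs],
    rho_RF = n_rf[labs] / n_nuc[labs],
    I_RF = ifelse(n_rf[labs] > 0, i_sum[labs] / n_rf[labs], 0),
    phase = NA_character_,
    f1 = NA_real_,
    f2 = NA_real_,
    qc_flags = "",
    stringsAsFactors = FALSE
  )
}

.empty_records <- function() {
  data.frame(frame_id = character(0), label = integer(0), N_nuc = integer(0),
             N_RF = integer(0), rho_RF = numeric(0), I_RF = numeric(0),
             phase = character(0), f1 = numeric(0), f2 = numeric(0),
             qc_flags = character(0), stringsAsFactors = FALSE)
}

## fingerprint used to detect classification against thresholds that were
## derived from a different record set
.records_digest <- function(records) {
  c(n = nrow(records), s_rho = sum(records$rho_RF), s_i = sum(records$I_RF),
    s_n = sum(records$N_nuc))
}

#' Derive population sorting thresholds
#'
#' From the pooled nucleus records of one analysis batch, derives
#' `rho_min = N_min / <N_nuc>` (the density of `N_min` foci pixels in an
#' average-size nucleus), `rho_thr = k_rho * max(rho_RF)` and
#' `I_thr = k * I_min` where `I_min` is the minimum `I_RF` within the
#' Early-or-Late subgroup (`rho_min <= rho_RF <= rho_thr`). Thresholds are
#' population-derived and must never be cached across experiments.
#'
#' @param records Records from [measure_nuclei()] (all frames of the batch
#'   pooled).
#' @param params [sorting_params()].
#' @return An object of class `derived_thresholds` with fields `rho_min`,
#'   `rho_thr`, `I_thr`, `mean_N_nuc`, `rho_max`, `I_min_subgroup`.
#' @export
derive_thresholds <- function(records, params = sorting_params()) {
  stopifnot(inherits(params, "sorting_params"), nrow(records) >= 1)
  mean_n <- mean(records$N_nuc)
  rho_min <- params$N_min / mean_n
  rho_max <- max(records$rho_RF)
  if (rho_max == 0) {
    warning("all replication-foci densities are zero; ",
            "population is entirely G1/G2")
  }
  rho_thr <- params$k_rho * rho_max
  if (!is.null(params$rho_thr_max)) {
    rho_thr <- min(rho_thr, params$rho_thr_max)
  }
  sub <- records$rho_RF >= rho_min & records$rho_RF <= rho_thr
  i_min <- if (any(sub)) min(records$I_RF[sub]) else NA_real_
  structure(
    list(rho_min = rho_min, rho_thr = rho_thr,
         I_thr = if (is.na(i_min)) NA_real_ else params$k * i_min,
         mean_N_nuc = mean_n, rho_max = rho_max, I_min_subgroup = i_min,
         n_subgroup = sum(sub), params = params,
         digest = .records_digest(records)),
    class = "derived_thresholds"
  )
}

#' @export
print.derived_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<derived_thresholds> rho_min %.4g, rho_thr %.4g ",
                     "(rho_max %.4g), I_thr %.4g (I_min %.4g, n_sub %d), ",
                     "<N_nuc> %.1f\n"),
              x$rho_min, x$rho_thr, x$rho_max, x$I_thr, x$I_min_subgroup,
              x$n_subgroup, x$mean_N_nuc))
  invisible(x)
}

#' Classify nuclei into cell-cycle groups
#'
#' Applies the threshold rules: `G1G2` if `rho_RF < rho_min`; `MIDDLE` if
#' `rho_RF > rho_thr`; otherwise the nucleus falls in the Early-or-Late
#' subgroup and is `EARLY` if `I_RF < I_thr`, `LATE` if `I_RF > I_thr`.
#' Boundary ties go to the group whose defining threshold was derived from
#' that side's extremum: density exactly `rho_min` enters S phase, exactly
#' `rho_thr` is `MIDDLE`, intensity exactly `I_thr` is `EARLY`. Finally any
#' `EARLY` nucleus with `N_nuc > k_size * <N_nuc>` is reassigned `EXCLUDED`
#' with qc flag `early-size-exclusion` (very late S cells entering G2).
#' G1 cannot be distinguished from G2 here: that would require total DNA
#' content, which a single optical section does not measure.
#'
#' @param records Records the thresholds were derived from.
#' @param thresholds [derive_thresholds()] output for these records.
#' @param params The same [sorting_params()] used for derivation.
#' @return `records` with `phase` filled and qc flags updated.
#' @export
classify_nuclei <- function(records, thresholds, params = thresholds$params) {
  stopifnot(inherits(thresholds, "derived_thresholds"))
  if (!isTRUE(all.equal(.records_digest(records), thresholds$digest))) {
    stop("stale thresholds: derive_thresholds() was run on different records")
  }
  rho <- records$rho_RF
  phase <- rep(NA_character_, nrow(records))
  phase[rho < thresholds$rho_min] <- "G1G2"
  phase[is.na(phase) & rho >= thresholds$rho_thr] <- "MIDDLE"
  sub <- is.na(phase)
  if (any(sub)) {
    if (is.na(thresholds$I_thr)) {
      stop("I_thr undefined but the Early-or-Late subgroup is non-empty")
    }
    phase[sub] <- ifelse(records$I_RF[sub] <= thresholds$I_thr,
                         "EARLY", "LATE")
    if (thresholds$n_subgroup == 1) {
      records$qc_flags[sub] <- .add_flag(records$qc_flags[sub],
                                         "singleton-subgroup")
    }
  }
  oversize <- phase == "EARLY" &
    records$N_nuc > params$k_size * thresholds$mean_N_nuc
  if (any(oversize)) {
    phase[oversize] <- "EXCLUDED"
    records$qc_flags[oversize] <- .add_flag(records$qc_flags[oversize],
                                            "early-size-exclusion")
  }
  records$phase <- phase
  records
}

#' Scatter-plot table of density versus intensity
#'
#' The classified records reduced to the columns of the diagnostic
#' density/intensity scatter plot. G1/G2 records with `I_RF = 0` are retained
#' in the table even though they sit on the axis of the plot.
#'
#' @param records Classified records.
#' @return data.frame with columns `frame_id`, `label`, `rho_RF`, `I_RF`,
#'   `phase`; one row per record.
#' @export
scatter_data <- function(records) {
  records[, c("frame_id", "label", "rho_RF", "I_RF", "phase")]
}

#' Plot the sorting scatter
#'
#' Density versus intensity per nucleus, coloured by phase, with the derived
#' thresholds drawn as dashed lines.
#'
#' @param records Classified records.
#' @param thresholds Optional [derive_thresholds()] output to overlay.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the scatter table.
#' @export
plot_sorting_scatter <- function(records, thresholds = NULL, ...) {
  tab <- scatter_data(records)
  cols <- c(G1G2 = "grey50", EARLY = "#1b9e77", MIDDLE = "#d95f02",
            LATE = "#7570b3", EXCLUDED = "black")
  graphics::plot(tab$rho_RF, tab$I_RF, col = cols[tab$phase], pch = 16,
                 xlab = expression(rho[RF]), ylab = expression(I[RF]), ...)
  if (!is.null(thresholds)) {
    graphics::abline(v = c(thresholds$rho_min, thresholds$rho_thr),
                     lty = 2, col = "grey40")
    graphics::abline(h = thresholds$I_thr, lty = 2, col = "grey40")
  }
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(tab)
}
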
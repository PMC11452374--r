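#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided rank-sum test as used for all group comparisons in the
#' reporting stage: the exact null distribution when the smaller group has
#' at most 8 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. No multiple-testing
#' correction is applied; comparisons are reported with raw p-values.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @param group_a,group_b Labels carried into the result.
#' @return An object of class `group_comparison` with `n_a`, `n_b`,
#'   `U_statistic` (in `[0, n_a * n_b]`, counted for group a), `p_value`,
#'   `method` (`"exact"` or `"normal-approximation"`) and `flags`
#'   (`"no-variation"` when all values are identical, with `p = 1`).
#' @export
mann_whitney <- function(values_a, values_b, group_a = "a", group_b = "b") {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 1 || n_b < 1) stop("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  flags <- ""
  if (max(pooled) == min(pooled)) {
    return(structure(list(group_a = group_a, group_b = group_b,
                          n_a = n_a, n_b = n_b, U_statistic = u,
                          p_value = 1, method = "exact",
                          flags = "no-variation"),
                     class = "group_comparison"))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- min(n_a, n_b) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  structure(
    list(group_a = group_a, group_b = group_b, n_a = n_a, n_b = n_b,
         U_statistic = u, p_value = min(wt$p.value, 1),
         method = if (exact) "exact" else "normal-approximation",
         flags = flags),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d): U = %g, p = %.4g (%s)\n",
              x$group_a, x$n_a, x$group_b, x$n_b, x$U_statistic, x$p_value,
              x$method))
  invisible(x)
}

#' Total EdU and DNA content per nucleus from z-stacks
#'
#' Sums the (background-subtracted) intensities of each channel over all
#' optical sections and all mask pixels of every nucleus. Used to
#' cross-validate the single-section phase sorting against total DNA/EdU
#' content.
#'
#' @param zstack_edu,zstack_dna Lists of [channel_image()]s (the optical
#'   sections), equal length, each section sharing the mask shape.
#' @param mask [count_mask()].
#' @return data.frame with columns `label`, `total_EdU`, `total_DNA`.
#' @export
total_content <- function(zstack_edu, zstack_dna, mask) {
  stopifnot(inherits(mask, "count_mask"))
  if (length(zstack_edu) != length(zstack_dna)) {
    stop("section-count mismatch between channels")
  }
  labs <- active_labels(mask)
  if (!length(labs)) {
    return(data.frame(label = integer(0), total_EdU = numeric(0),
                      total_DNA = numeric(0)))
  }
  sum_by_label <- function(stack) {
    tot <- rep(0, max(labs))
    for (sec in stack) {
      stopifnot(inherits(sec, "channel_image"))
      if (!.same_shape(sec$pixels, mask$labels)) {
        stop("section shape differs from mask")
      }
      lv <- as.vector(mask$labels)
      keep <- lv %in% labs
      agg <- rowsum(as.vector(sec$pixels)[keep], lv[keep])
      tot[as.integer(rownames(agg))] <- tot[as.integer(rownames(agg))] +
        agg[, 1]
    }
    tot[labs]
  }
  data.frame(label = labs, total_EdU = sum_by_label(zstack_edu),
             total_DNA = sum_by_label(zstack_dna))
}

#' Per-phase group summary of a classified batch
#'
#' Reports per phase the cell count, mean and s.e.m. (the conventional
#' reporting style for f1), and, since group tests are rank-based, the
#' median and IQR as well.
#'
#' @param records Classified records (with `f1` filled where computed).
#' @param value Column to summarise, default `"f1"`.
#' @return data.frame, one row per phase present.
#' @export
group_summary <- function(records, value = "f1") {
  phases <- intersect(.phase_levels, unique(records$phase))
  out <- lapply(phases, function(ph) {
    v <- records[[value]][records$phase == ph]
    v <- v[is.finite(v)]
    n <- length(v)
    data.frame(phase = ph, n_cells = sum(records$phase == ph), n_value = n,
               mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) sd(v) / sqrt(n) else NA_real_,
               median = if (n) median(v) else NA_real_,
               iqr = if (n) stats::IQR(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.default_preprocess <- function() {
  list(ball_radius_px = 10, foci_threshold_factor = 1.5,
       explicit_foci_threshold = NULL, background_level = NULL,
       min_area_px = 500, fill_holes = TRUE)
}

.load_frame <- function(frame, idx) {
  get_ch <- function(x, role) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "channel_image")) return(x)
    read_image_set(x, role, frame_id = frame$frame_id %||%
                     sprintf("frame-%d", idx))[[1]]
  }
  list(dna = get_ch(frame$dna, "DNA"), rf = get_ch(frame$rf, "RF"),
       tf = get_ch(frame$tf, "TF"),
       mask = if (!is.null(frame$mask)) frame$mask else NULL,
       excluded_labels = frame$excluded_labels %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full sorting + ICCS pipeline on a batch of frames
#'
#' Executes, per frame: channel loading, nucleus segmentation (unless a
#' count mask is supplied), rolling-ball background subtraction of the foci
#' channels, replication-foci binarization, per-nucleus measurement; then,
#' pooled across all frames of the batch: threshold derivation and
#' classification; then per-nucleus ICCS on the S-phase cells of frames
#' that carry a second foci channel. The foci threshold is resolved in this
#' order: an explicit threshold from `preprocess$explicit_foci_threshold`; a
#' supplied `preprocess$background_level` times the factor; otherwise a
#' two-pass bootstrap, where a first-pass isodata binarization of the RF
#' channel sorts the batch once and the G1/G2 nuclei of the first frame
#' serve as the EdU-negative background reference for the final
#' factor-times-background threshold.
#'
#' Frame-level failures are warned about and the frame skipped; the batch
#' fails only when no frame succeeds. Thresholds are derived per batch and
#' never reused across batches.
#'
#' @param frames List of frames; each frame is a list with entries `dna`,
#'   `rf` and optionally `tf` ([channel_image()]s or TIFF paths), optionally
#'   `mask` (a [count_mask()]), `frame_id`, `excluded_labels`.
#' @param params [sorting_params()].
#' @param preprocess Preprocessing settings overriding the defaults:
#'   fields `ball_radius_px`, `foci_threshold_factor`,
#'   `explicit_foci_threshold`, `background_level`, `min_area_px`,
#'   `fill_holes`.
#' @param iccs [iccs_settings()], or `NULL` to skip colocalization.
#' @param output_dir When non-`NULL`, writes `cells.csv`, `manifest.yaml`
#'   and `scatter.png` there.
#' @return List with `records` (the per-cell table), `thresholds`,
#'   `foci_threshold`, `background_level`, `summary` (per-phase
#'   [group_summary()]), `comparisons` (Mann-Whitney f1 comparisons between
#'   S subphases, when f1 was computed), and `manifest`.
#' @export
run_pipeline <- function(frames, params = sorting_params(),
                         preprocess = list(), iccs = iccs_settings(),
                         output_dir = NULL) {
  pp <- modifyList(.default_preprocess(), preprocess)
  loaded <- list()
  for (i in seq_along(frames)) {
    fr <- tryCatch(.load_frame(frames[[i]], i), error = function(e) {
      warning(sprintf("frame %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(fr)) next
    fr <- tryCatch({
      if (is.null(fr$mask)) {
        fr$mask <- segment_nuclei(fr$dna, min_area_px = pp$min_area_px,
                                  fill_holes = pp$fill_holes)
      }
      if (length(fr$excluded_labels)) {
        fr$mask$excluded_labels <- sort(unique(c(fr$mask$excluded_labels,
                                                 as.integer(fr$excluded_labels))))
      }
      fr$rf_sub <- subtract_background(fr$rf, pp$ball_radius_px)
      if (!is.null(fr$tf)) {
        fr$tf_sub <- subtract_background(fr$tf, pp$ball_radius_px)
      }
      fr
    }, error = function(e) {
      warning(sprintf("frame %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(fr)) loaded[[length(loaded) + 1]] <- fr
  }
  if (!length(loaded)) stop("no frame could be processed")

  ## resolve the foci threshold
  bg <- NA_real_
  if (!is.null(pp$explicit_foci_threshold)) {
    thr <- pp$explicit_foci_threshold
  } else if (!is.null(pp$background_level)) {
    bg <- pp$background_level
    thr <- pp$foci_threshold_factor * bg
  } else {
    first_pass <- do.call(rbind, lapply(loaded, function(fr) {
      fm <- foci_mask(fr$rf$pixels >= threshold_isodata(fr$rf$pixels),
                      threshold_value = threshold_isodata(fr$rf$pixels))
      measure_nuclei(fr$mask, fr$rf_sub, fm)
    }))
    fp_thr <- derive_thresholds(first_pass, params)
    fp_rec <- classify_nuclei(first_pass, fp_thr, params)
    ref <- fp_rec$label[fp_rec$phase == "G1G2" &
                          fp_rec$frame_id == loaded[[1]]$rf$frame_id]
    if (!length(ref)) {
      ## no EdU-negative nuclei in the first pass (population all replicating,
      ## or no replication signal at all): fall back to the median RF
      ## intensity over all nuclei of the first frame
      warning("no G1/G2 nuclei in the first-pass sort; estimating background ",
              "as the median RF intensity over all nuclei of the first frame")
      ref <- active_labels(loaded[[1]]$mask)
    }
    bg <- estimate_background_level(loaded[[1]]$rf, loaded[[1]]$mask, ref)
    thr <- pp$foci_threshold_factor * bg
  }

  ## final measurement, pooled threshold derivation, classification
  per_frame <- lapply(loaded, function(fr) {
    fr$foci <- binarize_foci(fr$rf, threshold = thr, background_level = bg)
    fr$records <- measure_nuclei(fr$mask, fr$rf_sub, fr$foci)
    fr
  })
  records <- do.call(rbind, lapply(per_frame, `[[`, "records"))
  thresholds <- derive_thresholds(records, params)
  records <- classify_nuclei(records, thresholds, params)

  ## ICCS on S-phase nuclei of frames carrying a second channel
  if (!is.null(iccs)) {
    out_list <- lapply(per_frame, function(fr) {
      rec <- records[records$frame_id == fr$rf$frame_id, , drop = FALSE]
      if (!is.null(fr$tf)) {
        rec <- iccs_per_nucleus(fr$rf_sub, fr$tf_sub, fr$mask, rec,
                                settings = iccs, N_min = params$N_min)
      }
      rec
    })
    records <- do.call(rbind, out_list)
  }
  rownames(records) <- NULL

  summary <- group_summary(records)
  comparisons <- list()
  if (any(is.finite(records$f1))) {
    pairs <- list(c("EARLY", "MIDDLE"), c("EARLY", "LATE"),
                  c("MIDDLE", "LATE"))
    for (p in pairs) {
      va <- records$f1[records$phase == p[1]]
      vb <- records$f1[records$phase == p[2]]
      if (sum(is.finite(va)) >= 1 && sum(is.finite(vb)) >= 1) {
        comparisons[[paste(p, collapse = "_vs_")]] <-
          mann_whitney(va, vb, p[1], p[2])
      }
    }
  }

  manifest <- list(
    sorting_params = list(N_min = params$N_min, k_rho = params$k_rho,
                          k = params$k, k_size = params$k_size),
    preprocess = pp[!vapply(pp, is.null, logical(1))],
    iccs = if (is.null(iccs)) NULL else unclass(iccs),
    derived = list(foci_threshold = thr, background_level = bg,
                   rho_min = thresholds$rho_min,
                   rho_thr = thresholds$rho_thr, I_thr = thresholds$I_thr,
                   mean_N_nuc = thresholds$mean_N_nuc),
    n_frames = length(per_frame),
    phase_counts = as.list(table(records$phase))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(output_dir, "cells.csv"), row.names = FALSE)
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
    grDevices::png(file.path(output_dir, "scatter.png"), 700, 600)
    plot_sorting_scatter(records, thresholds,
                         main = "Replication-foci density vs intensity")
    grDevices::dev.off()
  }

  list(records = records, thresholds = thresholds, foci_threshold = thr,
       background_level = bg, summary = summary, comparisons = comparisons,
       manifest = manifest)
}

#' Write / read a run manifest
#'
#' The manifest records every parameter and derived threshold of a run as
#' structured text; re-running a batch from the same manifest reproduces the
#' per-cell table.
#'
#' @param manifest Named list (e.g. `run_pipeline()$manifest`).
#' @param path YAML file path.
#' @return `read_manifest` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}
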
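#' Isodata (iterative intermeans) global threshold
#'
#' The classic isodata scheme: starting from the global mean, the threshold is
#' repeatedly replaced by the midpoint between the means of the two classes it
#' induces, until it stabilises. This is the documented equivalent of the
#' ImageJ "Default" automatic threshold used for nucleus and foci binarization.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param tol Convergence tolerance on the threshold, in intensity units.
#' @return The threshold value; pixels `>= t` are foreground.
#' @export
threshold_isodata <- function(x, tol = 1e-6) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to threshold")
  if (max(x) == min(x)) return(max(x))
  t_cur <- mean(x)
  for (i in seq_len(200)) {
    lo <- x[x < t_cur]
    hi <- x[x >= t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Segment nuclei from the DNA channel into a count mask
#'
#' Applies the isodata global threshold to the DNA counterstain, optionally
#' fills holes (nucleoli and other dim intranuclear regions would otherwise
#' fragment the mask), labels 8-connected components, and keeps components of
#' at least `min_area_px` pixels. Labels are renumbered 1..n in raster order.
#'
#' @param dna A [channel_image()] with role `"DNA"`.
#' @param min_area_px Minimum object area, pixels. The 500 px default
#'   corresponds to roughly 1 um^2 at 45 nm pixels, far below any real
#'   nucleus, and removes debris.
#' @param fill_holes Fill enclosed background holes inside objects.
#' @return A [count_mask()]. A blank (zero-variance) image yields an empty
#'   mask with a warning rather than an error.
#' @export
segment_nuclei <- function(dna, min_area_px = 500, fill_holes = TRUE) {
  stopifnot(inherits(dna, "channel_image"))
  if (dna$channel_role != "DNA") stop("`dna` must have channel_role 'DNA'")
  px <- dna$pixels
  if (max(px) == min(px)) {
    warning("blank DNA image; returning empty count mask")
    return(count_mask(matrix(0L, nrow(px), ncol(px))))
  }
  thr <- threshold_isodata(px)
  bin <- (px >= thr) * 1
  if (fill_holes) bin <- as.matrix(EBImage::fillHull(bin))
  lab <- .label_components(bin)
  lab <- .filter_relabel(lab, min_area_px)
  count_mask(lab)
}

## 8-connected component labelling ("analyze particles" convention; note
## EBImage::bwlabel is 4-connected, hence the own flood fill in src/).
.label_components <- function(bin) {
  .cpp_label8(bin)
}

.filter_relabel <- function(lab, min_area_px) {
  tab <- tabulate(lab[lab > 0L])
  keep <- which(tab >= min_area_px)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image with
#' a non-flat ball structuring element of the given radius (the standard
#' rolling-ball construction) and subtracts it, clipping at zero. Features
#' narrower than the ball (foci) are preserved; any structure the ball can
#' roll along (flat or slowly varying background) is removed.
#'
#' @param img A [channel_image()].
#' @param ball_radius_px Ball radius in pixels; the 10 px default suits foci
#'   a few pixels wide.
#' @return A [channel_image()] with the background removed.
#' @export
subtract_background <- function(img, ball_radius_px = 10) {
  stopifnot(inherits(img, "channel_image"))
  if (!is.numeric(ball_radius_px) || ball_radius_px < 1) {
    stop("radius must be >= 1")
  }
  r <- as.integer(round(ball_radius_px))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- off$dr^2 + off$dc^2
  off <- off[d2 <= r^2, ]
  h <- sqrt(r^2 - off$dr^2 - off$dc^2)
  er <- .cpp_gray_erode(img$pixels, off$dr, off$dc, h)
  bg <- .cpp_gray_dilate(er, off$dr, off$dc, h)
  out <- pmax(img$pixels - bg, 0)
  channel_image(out, pixel_size_nm = img$pixel_size_nm,
                channel_role = img$channel_role, frame_id = img$frame_id)
}

#' Background level from EdU-negative reference nuclei
#'
#' The replication-foci background is estimated as the median RF intensity
#' over all pixels of a set of reference nuclei judged to contain no EdU
#' signal (in practice the G1/G2 cells of the first frame of a dataset,
#' from a first-pass sort or user input). The median is robust to the odd
#' residual focus inside a reference nucleus.
#'
#' @param rf RF [channel_image()].
#' @param mask [count_mask()] paired with `rf`.
#' @param reference_labels Non-empty integer vector of reference nucleus
#'   labels.
#' @return The pooled-pixel median intensity.
#' @export
estimate_background_level <- function(rf, mask, reference_labels) {
  stopifnot(inherits(rf, "channel_image"), inherits(mask, "count_mask"))
  if (!.same_shape(rf$pixels, mask$labels)) stop("rf and mask shapes differ")
  reference_labels <- as.integer(reference_labels)
  if (!length(reference_labels)) {
    stop("no reference nuclei: provide labels of EdU-negative (G1/G2) nuclei ",
         "or an explicit background value")
  }
  sel <- mask$labels %in% reference_labels
  if (!any(sel)) stop("reference labels not present in the mask")
  median(rf$pixels[sel])
}

#' Binarize the replication-foci channel
#'
#' Thresholds the RF image at `factor` times the background level (the
#' working default is 1.5x background, chosen so that only genuine foci
#' signal survives), or at an explicit absolute threshold. Pixels exactly at
#' the threshold count as foreground.
#'
#' @param rf RF [channel_image()].
#' @param background_level Background estimate, e.g. from
#'   [estimate_background_level()].
#' @param factor Multiplier applied to the background level.
#' @param threshold Explicit absolute threshold overriding the factor mode.
#' @return A [foci_mask()].
#' @export
binarize_foci <- function(rf, background_level = NULL, factor = 1.5,
                          threshold = NULL) {
  stopifnot(inherits(rf, "channel_image"))
  if (!is.null(threshold)) {
    thr <- as.numeric(threshold)
    bg <- if (is.null(background_level)) NA_real_ else background_level
  } else {
    if (is.null(background_level)) stop("supply background_level or threshold")
    if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
    if (background_level < 0) stop("background_level must be >= 0")
    if (background_level == 0) {
      stop("background level is 0; supply an explicit threshold instead")
    }
    thr <- factor * background_level
    bg <- background_level
  }
  foci_mask(rf$pixels >= thr, threshold_value = thr, background_level = bg)
}
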
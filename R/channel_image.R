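#' Single-channel 2-D fluorescence image
#'
#' The basic container passed between all analysis stages: one 2-D matrix of
#' non-negative intensities plus the pixel size and the biological role of the
#' channel (DNA counterstain, replication foci, transcription foci).
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x,
#'   0-based pixel coordinates are used internally).
#' @param pixel_size_nm Positive pixel size in nanometres. Defaults to 45 nm,
#'   a typical confocal/STED sampling for nuclear foci imaging.
#' @param channel_role One of `"DNA"`, `"RF"` (replication foci) or `"TF"`
#'   (transcription foci).
#' @param frame_id Character identifier of the acquisition frame the channel
#'   belongs to; channels of one frame share it.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_nm = 45,
                          channel_role = c("RF", "DNA", "TF"),
                          frame_id = "frame-1") {
  channel_role <- match.arg(channel_role)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (any(!is.finite(pixels))) stop("`pixels` must be finite")
  if (any(pixels < 0)) stop("`pixels` must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a positive scalar")
  }
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel_role = channel_role, frame_id = as.character(frame_id)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %.1f nm/px, frame '%s'\n",
              x$channel_role, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_nm, x$frame_id))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

.check_analysis_size <- function(img) {
  if (nrow(img$pixels) < 32 || ncol(img$pixels) < 32) {
    stop("analysis requires images of at least 32 x 32 pixels")
  }
  invisible(img)
}

#' Integer-labelled nucleus mask ("count mask")
#'
#' Each nucleus carries a distinct positive integer label; 0 is background.
#' The count mask is the unit of iteration for all per-cell measurements.
#' `excluded_labels` lists nuclei removed from analysis by the user (e.g.
#' mitotic cells, which are excluded manually rather than detected).
#'
#' @param labels Integer matrix of non-negative labels.
#' @param excluded_labels Integer vector of labels to exclude from analysis.
#'
#' @return An object of class `count_mask`.
#' @export
count_mask <- function(labels, excluded_labels = integer(0)) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE) || anyNA(labels)) {
    stop("labels must be non-negative integers")
  }
  structure(
    list(labels = labels,
         excluded_labels = sort(unique(as.integer(excluded_labels)))),
    class = "count_mask"
  )
}

#' @export
print.count_mask <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$labels)), 0L))
  cat(sprintf("<count_mask> %d x %d px, %d nuclei (%d excluded)\n",
              nrow(x$labels), ncol(x$labels), n, length(x$excluded_labels)))
  invisible(x)
}

#' Labels retained for analysis
#'
#' @param mask A [count_mask()].
#' @return Sorted integer vector of non-excluded positive labels.
#' @export
active_labels <- function(mask) {
  stopifnot(inherits(mask, "count_mask"))
  setdiff(sort(unique(as.vector(mask$labels))), c(0L, mask$excluded_labels))
}

#' Binary replication-foci mask
#'
#' Boolean mask of the pixels counted as replication-foci signal, together
#' with the threshold that produced it and the background level the threshold
#' was derived from.
#'
#' @param mask Logical matrix.
#' @param threshold_value Intensity threshold applied (pixels `>=` threshold
#'   are foreground).
#' @param background_level Background estimate the threshold was derived from
#'   (`NA` when an explicit threshold was supplied).
#'
#' @return An object of class `foci_mask`.
#' @export
foci_mask <- function(mask, threshold_value, background_level = NA_real_) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix")
  }
  structure(
    list(mask = mask, threshold_value = as.numeric(threshold_value),
         background_level = as.numeric(background_level)),
    class = "foci_mask"
  )
}

#' @export
print.foci_mask <- function(x, ...) {
  cat(sprintf("<foci_mask> %d x %d px, threshold %.3g, %d foci pixels\n",
              nrow(x$mask), ncol(x$mask), x$threshold_value, sum(x$mask)))
  invisible(x)
}

.same_shape <- function(a, b) identical(dim(a), dim(b))
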
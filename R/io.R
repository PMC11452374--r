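#' Read a set of channel images from TIFF files
#'
#' Accepts either one single-channel TIFF per channel role, or a single
#' multi-page TIFF whose pages map onto the roles in order. All channels of a
#' frame must share the same shape. 8/16-bit unsigned and float TIFFs are
#' supported; integer data are read as raw counts (no rescaling).
#'
#' @param paths Character vector of TIFF paths (length 1 for a multi-page
#'   file, else one path per role).
#' @param channel_roles Character vector of roles, subset of
#'   `c("DNA", "RF", "TF")`, in channel order.
#' @param pixel_size_nm Pixel size in nm. When `NULL` it is taken from the
#'   TIFF resolution tags if present, otherwise a warning is issued and the
#'   45 nm default used.
#' @param frame_id Frame identifier shared by the returned channels; defaults
#'   to the basename of the first path.
#'
#' @return A list of [channel_image()] objects, one per role.
#' @export
read_image_set <- function(paths, channel_roles, pixel_size_nm = NULL,
                           frame_id = NULL) {
  stopifnot(length(paths) >= 1, length(channel_roles) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  if (is.null(frame_id)) {
    frame_id <- sub("\\.tiff?$", "", basename(paths[[1]]), ignore.case = TRUE)
  }

  pages <- list()
  meta_px <- NA_real_
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    ## 32-bit pages hold float data (the ImageJ convention); integer decoding
    ## does not apply to them, so re-read those natively
    bits <- vapply(pg, function(x) attr(x, "bits.per.sample") %||% 16L,
                   numeric(1))
    if (any(bits == 32)) {
      pg_f <- tiff::readTIFF(p, all = TRUE)
      if (!is.list(pg_f)) pg_f <- list(pg_f)
      pg[bits == 32] <- pg_f[bits == 32]
    }
    if (is.na(meta_px)) meta_px <- .tiff_pixel_size_nm(pg[[1]])
    pages <- c(pages, lapply(pg, .page_to_matrix))
  }
  if (length(pages) != length(channel_roles)) {
    stop(sprintf("found %d image planes for %d channel roles",
                 length(pages), length(channel_roles)))
  }
  shapes <- vapply(pages, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) stop("channel shape mismatch")

  if (is.null(pixel_size_nm)) {
    if (is.finite(meta_px)) {
      pixel_size_nm <- meta_px
    } else {
      warning("pixel size missing from metadata; using 45 nm default")
      pixel_size_nm <- 45
    }
  }
  mapply(function(m, role) {
    channel_image(m, pixel_size_nm = pixel_size_nm, channel_role = role,
                  frame_id = frame_id)
  }, pages, channel_roles, SIMPLIFY = FALSE)
}

.page_to_matrix <- function(pg) {
  m <- unclass(pg)
  if (length(dim(m)) == 3) {
    if (dim(m)[3] > 1) stop("RGB/multi-sample TIFF pages are not supported; ",
                            "supply one grayscale image per channel")
    m <- m[, , 1]
  }
  storage.mode(m) <- "double"
  attributes(m) <- list(dim = dim(m))
  m
}

## pixel size from TIFF resolution tags (pixels per unit; unit 2 = inch, 3 = cm)
.tiff_pixel_size_nm <- function(pg) {
  xres <- attr(pg, "x.resolution")
  unit <- attr(pg, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NA_real_)
  per_nm <- switch(as.character(if (is.null(unit)) "inch" else unit),
                   "2" = , "inch" = 2.54e7, "3" = , "cm" = 1e7, NA_real_)
  if (!is.finite(per_nm)) return(NA_real_)
  per_nm / xres
}

#' Write a count mask as a 16-bit label TIFF
#'
#' @param mask A [count_mask()]; labels must be below 65536.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_mask <- function(mask, path) {
  stopifnot(inherits(mask, "count_mask"))
  if (max(mask$labels) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a count mask from a label TIFF
#'
#' @param path Path to an integer label TIFF (0 = background).
#' @param excluded_labels Labels to mark excluded (e.g. mitotic cells).
#' @return A [count_mask()].
#' @export
read_count_mask <- function(path, excluded_labels = integer(0)) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  m <- .page_to_matrix(m)
  count_mask(m, excluded_labels = excluded_labels)
}

#' Write a foci binary mask as an 8-bit 0/255 TIFF
#'
#' Uses the ImageJ binary-image convention (foreground = 255).
#'
#' @param fmask A [foci_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foci_mask <- function(fmask, path) {
  stopifnot(inherits(fmask, "foci_mask"))
  tiff::writeTIFF(fmask$mask * 1.0, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Write a channel image as a 16-bit TIFF
#'
#' Intensities are rounded to integer counts and clipped to the 16-bit
#' range. All downstream analysis (thresholding ratios, ICCS) is invariant
#' to this quantisation at typical photon-count scales.
#'
#' @param img A [channel_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  px <- pmin(pmax(round(img$pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
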
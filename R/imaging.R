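# Imaging module: raw co-/cross-polarized frames -> validity masks,
# background-corrected images, per-pixel Fpol images, pseudo-color
# renderings, and per-cell records.
#
# Images are plain numeric matrices (row-major, 0-based pixel semantics:
# pixel centers at (index - 0.5) * pixel_size_um). Masks share image
# geometry exactly.

#' Co-/cross-polarized image pair
#'
#' Container for one acquisition: the co-polarized channel
#' \eqn{I_{\parallel}} and the simultaneously detected cross-polarized
#' channel \eqn{I_{\perp}}, with pixel geometry.
#'
#' @param co,cross numeric matrices of identical dimensions.
#' @param pixel_size_um pixel side length in micrometers (> 0).
#' @param bit_depth detector bit depth of the source data.
#' @param frame_count_averaged number of frames averaged into this pair.
#' @return An object of class `"fpol_pair"`.
#' @export
fpol_pair <- function(co, cross, pixel_size_um, bit_depth = 8,
                      frame_count_averaged = 1) {
  co <- as.matrix(co); cross <- as.matrix(cross)
  if (!identical(dim(co), dim(cross)))
    stop(.data_error("co and cross images must have identical dimensions"))
  stopifnot(pixel_size_um > 0)
  structure(list(co = co, cross = cross,
                 pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth),
                 frame_count_averaged = as.integer(frame_count_averaged)),
            class = "fpol_pair")
}

#' @export
print.fpol_pair <- function(x, ...) {
  cat(sprintf(
    "Polarized image pair: %d x %d px, %.3f um/px, %d-bit, %d frame(s) averaged\n",
    nrow(x$co), ncol(x$co), x$pixel_size_um, x$bit_depth,
    x$frame_count_averaged))
  invisible(x)
}

.data_error <- function(msg) {
  structure(class = c("fpol_data_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# read one 8-bit grayscale TIFF as an integer-valued matrix
.read_gray_tiff <- function(path) {
  if (!file.exists(path))
    stop(.data_error(paste0("file not found: ", path)))
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1] else
      stop(.data_error(paste0("expected grayscale image, got ",
                              dim(img)[3], " channels: ", path)))
  }
  img
}

#' Read a co-/cross-polarized TIFF pair
#'
#' @param co_path,cross_path paths to 8-bit grayscale TIFF files of equal
#'   dimensions.
#' @param pixel_size_um pixel size; alternatively give `field_of_view_um`
#'   and it is derived as field-of-view / image width.
#' @param field_of_view_um optional square field of view, micrometers.
#' @return An [fpol_pair()].
#' @export
read_image_pair <- function(co_path, cross_path, pixel_size_um = NULL,
                            field_of_view_um = NULL) {
  co <- .read_gray_tiff(co_path)
  cross <- .read_gray_tiff(cross_path)
  if (!identical(dim(co), dim(cross)))
    stop(.data_error(sprintf(
      "image dimensions differ: %s is %dx%d, %s is %dx%d",
      co_path, nrow(co), ncol(co), cross_path, nrow(cross), ncol(cross))))
  if (is.null(pixel_size_um)) {
    if (is.null(field_of_view_um))
      stop(.data_error("give pixel_size_um or field_of_view_um"))
    pixel_size_um <- field_of_view_um / ncol(co)
  }
  fpol_pair(co, cross, pixel_size_um = pixel_size_um)
}

#' Write a polarized image pair as 8-bit grayscale TIFFs
#'
#' @param pair an [fpol_pair()].
#' @param co_path,cross_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_image_pair <- function(pair, co_path, cross_path) {
  qmax <- 2^pair$bit_depth - 1
  tiff::writeTIFF(pmin(pmax(pair$co, 0), qmax) / qmax, co_path,
                  bits.per.sample = 8L)
  tiff::writeTIFF(pmin(pmax(pair$cross, 0), qmax) / qmax, cross_path,
                  bits.per.sample = 8L)
  invisible(c(co_path, cross_path))
}

#' Read / write an integer label mask as 16-bit TIFF
#'
#' @param mask integer matrix, 0 = background, labels 1..n.
#' @param path file path.
#' @return `read_label_mask` returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path))
    stop(.data_error(paste0("file not found: ", path)))
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Average repeated acquisition frames
#'
#' Per-pixel arithmetic mean of each channel over repeated acquisitions
#' of the same scene. The result is real-valued (no re-quantization).
#'
#' @param frames a list of [fpol_pair()] objects with identical geometry,
#'   or a single pair (returned unchanged).
#' @return An [fpol_pair()] with `frame_count_averaged` set.
#' @export
average_frames <- function(frames) {
  if (inherits(frames, "fpol_pair")) frames <- list(frames)
  if (length(frames) == 0L)
    stop(.data_error("no frames to average"))
  ref <- frames[[1]]
  for (f in frames) {
    if (!identical(dim(f$co), dim(ref$co)) ||
        f$pixel_size_um != ref$pixel_size_um)
      stop(.data_error("frames differ in geometry"))
  }
  co <- Reduce(`+`, lapply(frames, `[[`, "co")) / length(frames)
  cross <- Reduce(`+`, lapply(frames, `[[`, "cross")) / length(frames)
  fpol_pair(co, cross, pixel_size_um = ref$pixel_size_um,
            bit_depth = ref$bit_depth,
            frame_count_averaged = length(frames))
}

#' Build the pixel validity mask
#'
#' A pixel is usable iff its 8-bit value in *both* channels lies within
#' `[low, high]` inclusive; the defaults 2 and 254 remove near-zero
#' ("noise") and saturated pixels. Given multiple frames, thresholds are
#' applied per frame before any averaging: a pixel must be valid in every
#' frame. Requiring validity in both channels prevents asymmetric
#' censoring from biasing the polarization ratio.
#'
#' @param frames an [fpol_pair()] or list of them.
#' @param low,high inclusive validity thresholds (`low < high`, within
#'   the bit-depth range).
#' @return A logical matrix, `TRUE` where the pixel is usable.
#' @export
build_validity_mask <- function(frames, low = 2, high = 254) {
  if (inherits(frames, "fpol_pair")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  qmax <- 2^frames[[1]]$bit_depth - 1
  if (!(low >= 0 && high <= qmax && low < high))
    stop("thresholds must satisfy 0 <= low < high <= ", qmax, call. = FALSE)
  valid <- matrix(TRUE, nrow(frames[[1]]$co), ncol(frames[[1]]$co))
  for (f in frames) {
    valid <- valid &
      f$co >= low & f$co <= high &
      f$cross >= low & f$cross <= high
  }
  valid
}

#' Background-correct a polarized image pair
#'
#' Per channel, subtracts the median intensity of background pixels and
#' clamps at zero. Background pixels are the valid pixels outside
#' `cell_mask` when a mask is supplied; without a mask, the channel's
#' lowest-decile valid pixels are used as a background proxy. Applying
#' the correction twice equals applying it once (the median of the
#' corrected background is zero).
#'
#' @param pair an [fpol_pair()].
#' @param cell_mask optional logical or integer matrix marking foreground
#'   (cells); nonzero/`TRUE` pixels are excluded from the background.
#' @param validity optional logical validity mask (see
#'   [build_validity_mask()]); computed from `pair` if omitted.
#' @return The corrected [fpol_pair()].
#' @export
background_correct <- function(pair, cell_mask = NULL, validity = NULL) {
  stopifnot(inherits(pair, "fpol_pair"))
  if (is.null(validity)) validity <- build_validity_mask(pair)
  bg_sel <- if (!is.null(cell_mask)) {
    validity & !(as.matrix(cell_mask) > 0)
  } else validity
  if (!any(bg_sel)) {
    warning(if (is.null(cell_mask)) "no valid pixels; image left uncorrected"
            else "no background pixels available; image left uncorrected",
            call. = FALSE)
    return(pair)
  }
  correct1 <- function(ch) {
    px <- ch[bg_sel]
    if (is.null(cell_mask)) {
      px <- px[px <= quantile(px, 0.10, names = FALSE)]
    }
    pmax(ch - median(px), 0)
  }
  fpol_pair(correct1(pair$co), correct1(pair$cross),
            pixel_size_um = pair$pixel_size_um, bit_depth = pair$bit_depth,
            frame_count_averaged = pair$frame_count_averaged)
}

#' Per-pixel Fpol image
#'
#' Builds the difference image \eqn{I_{\parallel} - G I_{\perp}} and
#' emission image \eqn{I_{\parallel} + G I_{\perp}} and forms the
#' per-pixel ratio on the display scale,
#' \eqn{100 (I_{\parallel} - G I_{\perp}) / (I_{\parallel} + G I_{\perp})}.
#' Pixels that are invalid, or whose emission is not positive, are
#' undefined (`NA`); no exception is raised per pixel.
#'
#' @param pair an [fpol_pair()] (typically averaged and
#'   background-corrected).
#' @param g G-factor.
#' @param mask optional logical validity mask; computed from `pair` if
#'   omitted. Pass `NULL` explicitly after background correction, where
#'   raw-value thresholds no longer apply, or supply the mask computed on
#'   the raw frames.
#' @param display_range reporting range for rendering, display scale.
#' @return An object of class `"fpol_image"`: a numeric matrix of display
#'   values with `NA` at undefined pixels, with attributes
#'   `display_range` and `g`.
#' @export
compute_fpol_image <- function(pair, g, mask = NULL,
                               display_range = c(0, 40)) {
  stopifnot(inherits(pair, "fpol_pair"))
  g <- .check_g(g)
  if (is.null(mask)) mask <- build_validity_mask(pair)
  emission <- pair$co + g * pair$cross
  diff <- pair$co - g * pair$cross
  img <- 100 * diff / emission
  img[!mask | !(emission > 0)] <- NA_real_
  structure(img, display_range = display_range, g = g,
            pixel_size_um = pair$pixel_size_um,
            class = c("fpol_image", class(img)))
}

#' Pseudo-color rendering of an Fpol image
#'
#' Clips display values to the image's display range (default 0.0-40.0 on
#' the x10^-2 scale) and maps them through a fixed perceptually uniform
#' colormap (viridis). Undefined pixels render black.
#'
#' @param fpol_image an object from [compute_fpol_image()].
#' @param n_colors number of colormap levels.
#' @return An `nrow x ncol x 3` array of RGB values in `[0, 1]`, with
#'   attributes `display_range` and `colorbar` (the hex color ramp, for
#'   colorbar rendering).
#' @export
pseudo_color <- function(fpol_image, n_colors = 256) {
  rng <- attr(fpol_image, "display_range")
  if (is.null(rng)) rng <- c(0, 40)
  pal <- hcl.colors(n_colors, "viridis")
  x <- pmin(pmax(unclass(fpol_image), rng[1]), rng[2])
  idx <- 1L + as.integer(round((x - rng[1]) / (rng[2] - rng[1]) *
                                 (n_colors - 1)))
  rgb01 <- t(col2rgb(pal)) / 255
  out <- array(0, dim = c(nrow(fpol_image), ncol(fpol_image), 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(fpol_image), ncol(fpol_image))
    plane[ok] <- rgb01[idx[ok], ch]
    out[, , ch] <- plane
  }
  structure(out, display_range = rng, colorbar = pal)
}

#' Write an Fpol image to disk
#'
#' The quantitative image goes to 32-bit float TIFF with display-scale
#' values mapped affinely from \[-100, 100\] onto the storable \[0, 1\]
#' range (`(display + 100) / 200`); undefined pixels are stored as
#' exactly 0 (a value no physically measured pixel attains after the
#' half-sample margin applied on read). [read_fpol_image()] inverts the
#' mapping and restores the `NA` flags. The rendering goes to PNG with
#' the display range recorded in the PNG text metadata.
#'
#' @param fpol_image an object from [compute_fpol_image()].
#' @param tiff_path,png_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_fpol_image <- function(fpol_image, tiff_path = NULL, png_path = NULL) {
  written <- character(0)
  if (!is.null(tiff_path)) {
    img <- (unclass(fpol_image) + 100) / 200
    img[is.na(img)] <- 0
    tiff::writeTIFF(img, tiff_path, bits.per.sample = 32L,
                    reduce = FALSE)
    written <- c(written, tiff_path)
  }
  if (!is.null(png_path)) {
    rng <- attr(fpol_image, "display_range")
    png::writePNG(pseudo_color(fpol_image), png_path,
                  text = c(fpol_display_min = format(rng[1]),
                           fpol_display_max = format(rng[2])))
    written <- c(written, png_path)
  }
  invisible(written)
}

#' @rdname write_fpol_image
#' @param path path of a TIFF written by `write_fpol_image`.
#' @param display_range display range to attach to the restored image.
#' @export
read_fpol_image <- function(path, display_range = c(0, 40)) {
  if (!file.exists(path))
    stop(.data_error(paste0("file not found: ", path)))
  stored <- tiff::readTIFF(path)
  img <- stored * 200 - 100
  img[stored == 0] <- NA_real_
  structure(img, display_range = display_range,
            class = c("fpol_image", class(img)))
}

#' Quantify per-cell Fpol from a labeled image pair
#'
#' For each label: the mean co- and mean cross-polarized intensities over
#' the region's valid pixels are computed first, then the Fpol ratio is
#' applied to the means (not averaged per pixel). This equals the
#' emission-weighted mean of per-pixel Fpol over the region. Cell size is
#' the full mask area (pixel count times pixel area), independent of
#' validity. Regions with fewer valid pixels than `min_valid_pixels` are
#' dropped, with the reason recorded in the `dropped` attribute.
#'
#' @param pair an [fpol_pair()] (averaged, background-corrected).
#' @param label_mask integer matrix, 0 background, cell labels > 0.
#' @param g G-factor.
#' @param validity logical validity mask; computed from `pair` if omitted
#'   (supply the mask built from the raw frames when quantifying
#'   corrected images).
#' @param min_valid_pixels minimum number of valid pixels for a region to
#'   be quantified.
#' @param specimen_id,subject_id,group,histology,grade optional
#'   annotations copied onto every record.
#' @return A data frame of cell records: `cell_id`, `mean_co`,
#'   `mean_cross`, `fpol_display`, `cell_size_um2`, `n_valid_pixels`,
#'   plus any annotations; attribute `dropped` lists skipped labels.
#' @export
quantify_cells <- function(pair, label_mask, g, validity = NULL,
                           min_valid_pixels = 10,
                           specimen_id = NA_character_,
                           subject_id = NA_character_,
                           group = NA_character_,
                           histology = NA_character_, grade = NA_integer_) {
  stopifnot(inherits(pair, "fpol_pair"))
  g <- .check_g(g)
  label_mask <- as.matrix(label_mask)
  if (!identical(dim(label_mask), dim(pair$co)))
    stop(.data_error("label mask dimensions do not match the images"))
  if (is.null(validity)) validity <- build_validity_mask(pair)
  labels <- sort(unique(label_mask[label_mask > 0]))
  px_area <- pair$pixel_size_um^2
  rows <- list(); dropped <- list()
  for (lab in labels) {
    in_region <- label_mask == lab
    sel <- in_region & validity
    n_valid <- sum(sel)
    if (n_valid < min_valid_pixels) {
      dropped[[length(dropped) + 1L]] <- list(
        label = lab, n_valid_pixels = n_valid,
        reason = sprintf("fewer than %d valid pixels", min_valid_pixels))
      next
    }
    m_co <- mean(pair$co[sel]); m_cross <- mean(pair$cross[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = lab, mean_co = m_co, mean_cross = m_cross,
      fpol_display = fpol_display(fpol_from_intensities(m_co, m_cross, g)),
      cell_size_um2 = sum(in_region) * px_area,
      n_valid_pixels = n_valid,
      specimen_id = specimen_id, subject_id = subject_id,
      group = group, histology = histology, grade = grade)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), mean_co = numeric(0),
               mean_cross = numeric(0), fpol_display = numeric(0),
               cell_size_um2 = numeric(0), n_valid_pixels = integer(0),
               specimen_id = character(0), subject_id = character(0),
               group = character(0), histology = character(0),
               grade = integer(0))
  attr(out, "dropped") <- dropped
  out
}

#' Automatic cell segmentation of an emission image
#'
#' Convenience segmentation for synthetic fields (the clinical protocol
#' segments cells manually): Otsu global threshold on the emission image
#' \eqn{I_{\parallel} + G I_{\perp}}, connected-component labeling, and a
#' minimum-area filter. Labels are renumbered 1..n.
#'
#' @param pair an [fpol_pair()].
#' @param g G-factor used to form the emission image.
#' @param min_area_um2 minimum region area retained, square micrometers.
#' @return An integer label matrix (0 = background).
#' @export
segment_cells <- function(pair, g, min_area_um2 = 20) {
  stopifnot(inherits(pair, "fpol_pair"))
  g <- .check_g(g)
  emission <- pair$co + g * pair$cross
  mx <- max(emission)
  if (mx <= 0) return(matrix(0L, nrow(emission), ncol(emission)))
  norm <- emission / mx
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw)) return(matrix(0L, nrow(emission), ncol(emission)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  lab <- matrix(as.integer(lab), nrow(emission), ncol(emission))
  min_px <- ceiling(min_area_um2 / pair$pixel_size_um^2)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}
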
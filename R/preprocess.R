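# Preprocessing chain: median denoising -> CLAHE enhancement -> breast mask
# -> ROI window extraction around annotated (or random) centers -> non-breast
# cropping -> bilinear rescale to the canonical 120x120 ROI.

#' Median-filter denoising
#'
#' Replaces each pixel by the median of its `kernel` x `kernel`
#' neighbourhood; image borders are handled by symmetric reflection.
#' Removes the impulse (salt-and-pepper) noise typical of digitised films.
#'
#' @param image A [mammogram_image()] or pixel matrix.
#' @param kernel Odd window side length (default 3).
#' @return Same type as the input, same dimensions.
#' @export
denoise_median <- function(image, kernel = 3L) {
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel < 1 ||
      kernel %% 2 == 0)
    stop("`kernel` must be an odd positive integer")
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  out <- median_filter_cpp(px + 0.0, as.integer(kernel))
  if (inherits(image, "mammogram_image"))
    mammogram_image(out, image$image_id) else out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with the per-tile histogram clipped at
#' `clip_limit` times the uniform bin height (excess redistributed
#' uniformly), and per-pixel bilinear interpolation between the four nearest
#' tile mappings.  Bounds the noise amplification of plain adaptive
#' equalization while still lifting local contrast.
#'
#' @param image A [mammogram_image()] or pixel matrix.
#' @param clip_limit Positive clip factor (default 2.0).
#' @param tile_grid Integer pair `(rows, cols)` of tiles (default `c(8, 8)`).
#' @return Same type as the input; intensities stay in `[0, 255]`.
#' @export
enhance_clahe <- function(image, clip_limit = 2.0, tile_grid = c(8L, 8L)) {
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0)
    stop("`clip_limit` must be > 0")
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || anyNA(tile_grid) || any(tile_grid < 1))
    stop("`tile_grid` must be two positive integers")
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  out <- clahe_cpp(px + 0.0, clip_limit, tile_grid[1], tile_grid[2])
  if (inherits(image, "mammogram_image"))
    mammogram_image(out, image$image_id) else out
}

#' Compute the breast-tissue mask
#'
#' Thresholds the image, applies a morphological closing with a disk, and
#' keeps the largest 8-connected component.  The result separates breast
#' tissue from the dark scanner background (and from small bright artefacts
#' such as labels, which form smaller components).
#'
#' @param image A [mammogram_image()] or pixel matrix.
#' @param threshold Intensity threshold; pixels strictly above it are
#'   candidate tissue (default 15).
#' @param closing_radius Disk radius for the closing (default 5).
#' @return Logical matrix with the image's dimensions; `TRUE` = breast.
#' @export
compute_breast_mask <- function(image, threshold = 15, closing_radius = 5L) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  cand <- px > threshold
  if (!any(cand))
    stop("empty breast mask: no pixel above threshold ", threshold)
  closed <- binary_close_cpp(cand, as.integer(closing_radius))
  largest_component_cpp(closed)
}

#' Convert a MIAS annotation center to matrix (row, col) coordinates
#'
#' MIAS annotates centers in bottom-left-origin pixel coordinates; matrix
#' indexing puts the origin at the top-left, so the y axis is flipped.
#'
#' @param ann One row of a [read_info_file()] data frame (or any list with
#'   `x` and `y`).
#' @param image_height Image height in pixels.
#' @return Named numeric vector `c(row, col)` (0-based).
#' @export
annotation_to_rowcol <- function(ann, image_height) {
  if (is.na(ann$x) || is.na(ann$y))
    stop("annotation has no center coordinates")
  c(row = (image_height - 1) - ann$y, col = ann$x + 0)
}

#' Extract a square window, clamped inside the image
#'
#' Returns the `(2 * half_side)` square window nominally spanning
#' `[center - half_side, center + half_side)`.  A window that would overrun
#' the image is shifted (clamped) to lie fully inside, so the output size is
#' always exact.
#'
#' @param image A [mammogram_image()] or pixel matrix.
#' @param center_row,center_col Window center, 0-based.
#' @param half_side Half side length (default 60, i.e. a 120x120 window).
#' @return Pixel matrix of side `2 * half_side`, with attributes `top` and
#'   `left` giving the 0-based window origin actually used.
#' @export
extract_window <- function(image, center_row, center_col, half_side = 60L) {
  stop_if_not_scalar_count(half_side, "half_side")
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  side <- 2L * as.integer(half_side)
  if (nrow(px) < side || ncol(px) < side)
    stop(sprintf("image %d x %d smaller than the %d x %d window",
                 nrow(px), ncol(px), side, side))
  top <- round(center_row) - half_side
  left <- round(center_col) - half_side
  top <- max(0L, min(as.integer(top), nrow(px) - side))
  left <- max(0L, min(as.integer(left), ncol(px) - side))
  out <- px[(top + 1L):(top + side), (left + 1L):(left + side), drop = FALSE]
  attr(out, "top") <- top
  attr(out, "left") <- left
  out
}

#' Trim dark non-breast margins from a window
#'
#' Removes leading and trailing rows/columns in which more than 95% of
#' pixels are at or below `dark_threshold` (the black bands left when an ROI
#' window extends past the breast outline).
#'
#' @param window Pixel matrix.
#' @param dark_threshold Intensity at or below which a pixel counts as dark
#'   (default 10).
#' @param dark_fraction Fraction of dark pixels above which a row/column is
#'   dropped (default 0.95).
#' @return The trimmed (still rectangular, non-empty) pixel matrix.
#' @export
crop_nonbreast <- function(window, dark_threshold = 10, dark_fraction = 0.95) {
  if (!is.matrix(window) || !length(window)) stop("`window` must be a matrix")
  dark_rows <- rowMeans(window <= dark_threshold) > dark_fraction
  dark_cols <- colMeans(window <= dark_threshold) > dark_fraction
  keep_r <- which(!dark_rows)
  keep_c <- which(!dark_cols)
  if (!length(keep_r) || !length(keep_c))
    stop("degenerate ROI: window is entirely dark")
  window[keep_r[1]:keep_r[length(keep_r)],
         keep_c[1]:keep_c[length(keep_c)], drop = FALSE]
}

#' Rescale a pixel grid to the canonical ROI size
#'
#' Bilinear interpolation (align-corners mapping, so a same-size input is
#' returned unchanged up to rounding); output clipped to `[0, 255]`.
#'
#' @param grid Pixel matrix.
#' @param target Output side length (default 120).
#' @return `target` x `target` integer pixel matrix.
#' @export
rescale_roi <- function(grid, target = 120L) {
  if (!is.matrix(grid) || !length(grid)) stop("`grid` must be non-empty")
  stop_if_not_scalar_count(target, "target")
  out <- bilinear_resize_cpp(grid + 0.0, as.integer(target),
                             as.integer(target))
  matrix(as.integer(pmin(255, pmax(0, round(out)))), nrow(out), ncol(out))
}

#' Sample a random ROI center inside the breast
#'
#' Draws mask-true pixels uniformly until the clamped window around the
#' candidate lies fully inside the image with at least `min_coverage` of its
#' area on breast tissue.
#'
#' @param mask Logical breast mask.
#' @param half_side Window half side (default 60).
#' @param min_coverage Minimum mask-true fraction of the window (default 0.5).
#' @param max_retries Attempt bound before failing (default 1000).
#' @param seed Optional seed.
#' @return Named vector `c(row, col)` (0-based center).
#' @export
random_roi_center <- function(mask, half_side = 60L, min_coverage = 0.5,
                              max_retries = 1000L, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, random_roi_center(
    mask, half_side, min_coverage, max_retries)))
  idx <- which(mask)
  if (!length(idx)) stop("breast mask is empty")
  side <- 2L * as.integer(half_side)
  if (nrow(mask) < side || ncol(mask) < side)
    stop("image smaller than the ROI window")
  H <- nrow(mask)
  for (attempt in seq_len(max_retries)) {
    p <- idx[sample.int(length(idx), 1L)]
    row <- (p - 1L) %% H        # 0-based
    col <- (p - 1L) %/% H
    top <- max(0L, min(row - half_side, nrow(mask) - side))
    left <- max(0L, min(col - half_side, ncol(mask) - side))
    cov <- mean(mask[(top + 1L):(top + side), (left + 1L):(left + side)])
    if (cov >= min_coverage)
      return(c(row = row, col = col))
  }
  stop("no admissible ROI center found after ", max_retries, " attempts")
}

#' Construct an ROI object
#'
#' @param pixels 120x120 (or `target`-sided) pixel matrix.
#' @param label `"Normal"` or `"Tumor"`.
#' @param image_id Source image identifier.
#' @param annotation_ref Row index of the source annotation, or `NA` for a
#'   random normal ROI.
#' @param center_row,center_col ROI center in the source image (0-based,
#'   top-left origin).
#' @return Object of class `mammo_roi`.
#' @export
mammo_roi <- function(pixels, label, image_id, annotation_ref = NA_integer_,
                      center_row = NA_real_, center_col = NA_real_) {
  label <- match.arg(label, c("Normal", "Tumor"))
  if ((label == "Tumor") != !is.na(annotation_ref))
    stop("label must be Tumor iff annotation_ref is present")
  structure(list(pixels = pixels, label = label, image_id = image_id,
                 annotation_ref = annotation_ref, center_row = center_row,
                 center_col = center_col),
            class = "mammo_roi")
}

#' @export
print.mammo_roi <- function(x, ...) {
  cat(sprintf("<mammo_roi> %s from %s (%d x %d)%s\n", x$label, x$image_id,
              nrow(x$pixels), ncol(x$pixels),
              if (is.na(x$annotation_ref)) "" else
                sprintf(", annotation %d", x$annotation_ref)))
  invisible(x)
}

#' Run the full preprocessing chain on one mammogram
#'
#' Median denoising then CLAHE, in that order.
#'
#' @param image A [mammogram_image()].
#' @param kernel Median window (default 3).
#' @param clip_limit,tile_grid CLAHE parameters.
#' @return The preprocessed [mammogram_image()].
#' @export
preprocess_image <- function(image, kernel = 3L, clip_limit = 2.0,
                             tile_grid = c(8L, 8L)) {
  enhance_clahe(denoise_median(image, kernel), clip_limit, tile_grid)
}

#' Extract labeled ROIs from a preprocessed mammogram
#'
#' For each annotation row of this image: abnormal rows with coordinates
#' give a Tumor ROI at the annotated center; `NORM` rows give a Normal ROI
#' at a random breast-mask center.  Abnormal rows without coordinates are
#' skipped with a warning.  Each window is clamped inside the image, dark
#' non-breast margins are trimmed, and the result is rescaled to
#' `target` x `target`.
#'
#' @param image A preprocessed [mammogram_image()].
#' @param annotations A [read_info_file()] data frame (all images); rows are
#'   matched on `image_id`.
#' @param half_side ROI half side (default 60).
#' @param target Final ROI side (default 120).
#' @param dark_threshold,mask_threshold Intensity thresholds for cropping
#'   and the breast mask.
#' @param seed Optional seed for random normal centers.
#' @return List of [mammo_roi()] objects.
#' @export
extract_rois <- function(image, annotations, half_side = 60L, target = 120L,
                         dark_threshold = 10, mask_threshold = 15,
                         seed = NULL) {
  rows <- which(annotations$image_id == image$image_id)
  if (!length(rows)) return(list())
  mask <- compute_breast_mask(image, mask_threshold)
  with_seed(seed, {
    out <- list()
    for (i in rows) {
      ann <- annotations[i, ]
      if (ann$abnorm_class == "NORM") {
        ctr <- random_roi_center(mask, half_side)
        ref <- NA_integer_
        label <- "Normal"
      } else if (!is.na(ann$x)) {
        ctr <- annotation_to_rowcol(ann, image$height)
        ref <- i
        label <- "Tumor"
      } else {
        warning("skipping annotation ", i, " (no coordinates)")
        next
      }
      win <- extract_window(image, ctr["row"], ctr["col"], half_side)
      grid <- tryCatch(crop_nonbreast(win, dark_threshold),
                       error = function(e) NULL)
      if (is.null(grid)) {
        warning("skipping degenerate (all-dark) ROI for annotation ", i)
        next
      }
      out[[length(out) + 1L]] <-
        mammo_roi(rescale_roi(grid, target), label, image$image_id, ref,
                  ctr["row"], ctr["col"])
    }
    out
  })
}
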
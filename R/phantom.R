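# Synthetic MIAS-format phantom datasets: a breast-shaped bright half-ellipse
# on dark background, smoothed random texture, optional radially tapered
# bright lesions (annotated with center/radius in MIAS bottom-left-origin
# coordinates), and salt-and-pepper impulse noise for the median filter to
# remove.  Everything the real archive provides, with known ground truth and
# no download.

#' Phantom dataset configuration
#'
#' @param n_normal,n_abnormal Image counts per class.
#' @param image_side Square image side in pixels (default 256 for desk-scale
#'   runs; 1024 mirrors the real archive's geometry).
#' @param lesion_radius_range Min/max lesion radius in pixels
#'   (default `c(8, 40)`; must lie within `(0, image_side / 4]`).
#' @param lesion_contrast Peak lesion brightness above the breast base
#'   intensity (default 60).
#' @param texture_scale Gaussian smoothing scale of the tissue texture in
#'   pixels (default 16).
#' @param texture_sd Standard deviation of the smoothed tissue texture in
#'   intensity units (default 8; clipped at three standard deviations).
#'   Kept well below `lesion_contrast` so that lesions remain the dominant
#'   bright structures after contrast enhancement.
#' @param impulse_noise_rate Fraction of salt/pepper pixels (default 0.01,
#'   must be `< 0.5`).
#' @param center_margin Minimum distance of a lesion center from every image
#'   edge (default 60, the canonical ROI half side), so the annotated ROI
#'   window never needs clamping.
#' @param seed Dataset seed.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_normal = 10L, n_abnormal = 10L,
                           image_side = 256L,
                           lesion_radius_range = c(8, 40),
                           lesion_contrast = 60, texture_scale = 16,
                           texture_sd = 8,
                           impulse_noise_rate = 0.01, center_margin = 60,
                           seed = 1L) {
  if (n_normal < 0 || n_abnormal < 0) stop("counts must be >= 0")
  stop_if_not_scalar_count(image_side, "image_side", min = 64L)
  if (length(lesion_radius_range) != 2L || lesion_radius_range[1] <= 0 ||
      diff(lesion_radius_range) < 0 ||
      lesion_radius_range[2] > image_side / 4)
    stop("`lesion_radius_range` must lie within (0, image_side / 4]")
  if (impulse_noise_rate < 0 || impulse_noise_rate >= 0.5)
    stop("`impulse_noise_rate` must be in [0, 0.5)")
  structure(list(n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 image_side = as.integer(image_side),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = lesion_contrast,
                 texture_scale = texture_scale,
                 texture_sd = texture_sd,
                 impulse_noise_rate = impulse_noise_rate,
                 center_margin = center_margin,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# breast half-ellipse geometry: attached to the left image edge
breast_ellipse <- function(side) {
  list(row0 = (side - 1) / 2, col0 = 0,
       a = 0.62 * side,   # column semi-axis
       b = 0.45 * side)   # row semi-axis
}

BREAST_BASE <- 120
BACKGROUND <- 5

#' Generate one phantom mammogram
#'
#' @param config A [phantom_config()].
#' @param with_lesion Add an annotated bright lesion.
#' @param image_id Identifier for the image/annotation.
#' @param seed Optional seed (identical seed, identical bytes).
#' @return List with `image` (a [mammogram_image()]) and `annotation` (a
#'   one-row [read_info_file()]-style data frame).
#' @export
generate_image <- function(config, with_lesion = FALSE, image_id = "syn001",
                           seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    side <- config$image_side
    el <- breast_ellipse(side)
    rr <- matrix(0:(side - 1), side, side)           # row index per pixel
    cc <- matrix(0:(side - 1), side, side, byrow = TRUE)
    inside <- ((cc - el$col0) / el$a)^2 + ((rr - el$row0) / el$b)^2 <= 1
    img <- matrix(BACKGROUND, side, side)
    img[inside] <- BREAST_BASE
    noise <- matrix(rnorm(side * side), side, side)
    tex <- gaussian_blur_cpp(noise, config$texture_scale)
    tex <- tex / max(sd(tex), 1e-9) * config$texture_sd
    tex <- pmin(pmax(tex, -3 * config$texture_sd), 3 * config$texture_sd)
    img[inside] <- img[inside] + tex[inside]

    ann <- data.frame(image_id = image_id,
                      tissue = sample(MIAS_TISSUES, 1L),
                      abnorm_class = "NORM", severity = NA_character_,
                      x = NA_real_, y = NA_real_, radius = NA_real_,
                      stringsAsFactors = FALSE)
    if (with_lesion) {
      r <- runif(1, config$lesion_radius_range[1],
                 config$lesion_radius_range[2])
      margin <- r + 6
      # centers are uniform in the breast interior, but kept at least
      # center_margin from every image edge so the canonical ROI window
      # around the annotation is clamp-free (as it is for the real archive,
      # where lesions sit well inside the 1024-pixel film)
      cm <- min(config$center_margin, floor(side / 4))
      repeat {
        crow <- runif(1, cm, side - 1 - cm)
        ccol <- runif(1, cm, el$a)
        if (((ccol - el$col0) / (el$a - margin))^2 +
            ((crow - el$row0) / (el$b - margin))^2 <= 1) break
      }
      d <- sqrt((rr - crow)^2 + (cc - ccol)^2)
      prof <- ifelse(d < 0.6 * r, 1,
                     ifelse(d < r, 0.5 * (1 + cos(pi * (d - 0.6 * r) /
                                                    (0.4 * r))), 0))
      img <- img + config$lesion_contrast * prof
      ann$abnorm_class <- "CIRC"
      ann$severity <- sample(MIAS_SEVERITIES, 1L)
      ann$x <- round(ccol)
      ann$y <- (side - 1) - round(crow)
      ann$radius <- round(r)
    }
    if (config$impulse_noise_rate > 0) {
      hit <- which(runif(side * side) < config$impulse_noise_rate)
      img[hit] <- ifelse(runif(length(hit)) < 0.5, 0, 255)
    }
    img <- pmin(pmax(round(img), 0), 255)
    list(image = mammogram_image(img, image_id), annotation = ann)
  })
}

#' Generate a complete phantom dataset on disk
#'
#' Writes `n_normal + n_abnormal` PGM images plus a MIAS-format `info.txt`,
#' readable back with [read_info_file()]/[read_pgm()] with round-trip
#' fidelity.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `info_path`, `records` and
#'   `image_paths`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_normal + config$n_abnormal
  with_seed(config$seed, {
    recs <- vector("list", n)
    paths <- character(n)
    for (i in seq_len(n)) {
      id <- sprintf("syn%03d", i)
      g <- generate_image(config, with_lesion = i > config$n_normal, id)
      paths[i] <- file.path(out_dir, paste0(id, ".pgm"))
      write_pgm(g$image, paths[i])
      recs[[i]] <- g$annotation
    }
    records <- do.call(rbind, recs)
    class(records) <- c("mias_annotations", "data.frame")
    info_path <- file.path(out_dir, "info.txt")
    write_info_file(records, info_path)
    invisible(list(dir = out_dir, info_path = info_path, records = records,
                   image_paths = paths))
  })
}
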
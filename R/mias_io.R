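# MIAS-format archive I/O: 8-bit PGM images and the plain-text annotation
# ("info") file.  The same writers serve the synthetic phantom generator, so
# generated datasets are byte-level indistinguishable in layout from a real
# archive.

MIAS_TISSUES <- c("F", "G", "D")
MIAS_CLASSES <- c("CALC", "CIRC", "SPIC", "MISC", "ARCH", "ASYM", "NORM")
MIAS_SEVERITIES <- c("B", "M")

#' Construct a mammogram image object
#'
#' @param pixels Integer matrix of 8-bit intensities (rows are image rows,
#'   top-left origin).
#' @param image_id Identifier string (defaults to `"img"`).
#' @return An object of class `mammogram_image` with fields `image_id`,
#'   `pixels`, `height`, `width`.
#' @export
mammogram_image <- function(pixels, image_id = "img") {
  if (!is_pixel_matrix(pixels))
    stop("`pixels` must be a numeric matrix with values in [0, 255]")
  structure(
    list(image_id = as.character(image_id),
         pixels = matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
         height = nrow(pixels), width = ncol(pixels)),
    class = "mammogram_image")
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf("<mammogram_image> %s: %d x %d, range [%d, %d]\n",
              x$image_id, x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a MIAS annotation ("info") file
#'
#' Each non-comment line describes one abnormality (or a normal image) with
#' 3, 4 or 7 whitespace-separated fields:
#' `id tissue NORM`, `id tissue class severity`, or
#' `id tissue class severity x y radius`.  Coordinates use the MIAS
#' convention: origin at the bottom-left of the image, in pixels.
#'
#' @param path Path to the info file.
#' @return A data frame of class `mias_annotations` with columns `image_id`,
#'   `tissue`, `abnorm_class`, `severity`, `x`, `y`, `radius` (the last four
#'   `NA` where absent).  One row per line; an image with several
#'   abnormalities contributes several rows.  Input order is preserved.
#' @export
read_info_file <- function(path) {
  if (!file.exists(path)) stop("info file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    err <- function(msg) stop(sprintf("info file line %d: %s", ln, msg),
                              call. = FALSE)
    if (!(length(f) %in% c(3L, 4L, 7L)))
      err(sprintf("expected 3, 4 or 7 fields, got %d", length(f)))
    if (!(f[2] %in% MIAS_TISSUES)) err(paste0("unknown tissue '", f[2], "'"))
    if (!(f[3] %in% MIAS_CLASSES)) err(paste0("unknown class '", f[3], "'"))
    if (f[3] == "NORM" && length(f) != 3L)
      err("NORM lines must have exactly 3 fields")
    if (f[3] != "NORM" && length(f) == 3L)
      err("abnormal lines need a severity field")
    sev <- NA_character_
    x <- y <- r <- NA_real_
    if (length(f) >= 4L) {
      if (!(f[4] %in% MIAS_SEVERITIES))
        err(paste0("unknown severity '", f[4], "'"))
      sev <- f[4]
    }
    if (length(f) == 7L) {
      v <- suppressWarnings(as.numeric(f[5:7]))
      if (anyNA(v)) err("non-numeric coordinate or radius")
      if (v[3] <= 0) err("radius must be > 0")
      x <- v[1]; y <- v[2]; r <- v[3]
    }
    rows[[k]] <- data.frame(image_id = f[1], tissue = f[2],
                            abnorm_class = f[3], severity = sev,
                            x = x, y = y, radius = r,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), tissue = character(),
               abnorm_class = character(), severity = character(),
               x = numeric(), y = numeric(), radius = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mias_annotations", "data.frame")
  out
}

#' Write a MIAS annotation file
#'
#' Inverse of [read_info_file()]: NORM rows emit 3 fields, abnormal rows
#' without coordinates 4 fields, fully annotated rows 7 fields.
#'
#' @param records Data frame as returned by [read_info_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_info_file <- function(records, path) {
  lines <- character(nrow(records))
  for (i in seq_len(max(nrow(records), 0))) {
    r <- records[i, ]
    if (r$abnorm_class == "NORM") {
      lines[i] <- paste(r$image_id, r$tissue, r$abnorm_class)
    } else if (is.na(r$x)) {
      lines[i] <- paste(r$image_id, r$tissue, r$abnorm_class, r$severity)
    } else {
      lines[i] <- paste(r$image_id, r$tissue, r$abnorm_class, r$severity,
                        format(r$x, scientific = FALSE),
                        format(r$y, scientific = FALSE),
                        format(r$radius, scientific = FALSE))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an 8-bit PGM image
#'
#' Accepts both the binary (`P5`) and ASCII (`P2`) dialects with
#' `maxval <= 255`.  Comment lines (`#`) in the header are ignored.
#'
#' @param path Path to the PGM file.
#' @param image_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A [mammogram_image()].
#' @export
read_pgm <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("PGM file not found: ", path)
  if (is.null(image_id))
    image_id <- sub("\\.[^.]*$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", file.info(path)$size)
  n <- length(raw_all)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  hash <- charToRaw("#")
  nl <- charToRaw("\n")
  # tokenize the header: magic, width, height, maxval, skipping '#' comments
  pos <- 1L
  tokens <- character(4)
  for (t in 1:4) {
    repeat {
      while (pos <= n && raw_all[pos] %in% ws) pos <- pos + 1L
      if (pos <= n && raw_all[pos] == hash) {
        while (pos <= n && raw_all[pos] != nl) pos <- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !(raw_all[pos] %in% ws) && raw_all[pos] != hash)
      pos <- pos + 1L
    if (start > n || pos == start) stop("truncated PGM header")
    tokens[t] <- rawToChar(raw_all[start:(pos - 1L)])
  }
  magic <- tokens[1]
  if (!(magic %in% c("P2", "P5")))
    stop("not a PGM file (bad magic number)")
  w <- suppressWarnings(as.integer(tokens[2]))
  h <- suppressWarnings(as.integer(tokens[3]))
  maxval <- suppressWarnings(as.integer(tokens[4]))
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1)
    stop("malformed PGM header")
  if (maxval > 255)
    stop("unsupported PGM depth: maxval ", maxval, " > 255")
  if (magic == "P5") {
    pos <- pos + 1L  # single whitespace byte after maxval
    need <- as.numeric(w) * h
    if (n - pos + 1L < need) stop("truncated PGM pixel data")
    vals <- as.integer(raw_all[pos:(pos + need - 1L)])
  } else {
    txt <- rawToChar(raw_all[pos:n])
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) < w * h || anyNA(vals[seq_len(w * h)]))
      stop("malformed P2 pixel data")
    vals <- vals[seq_len(w * h)]
  }
  # PGM is row-major from the top-left; R matrices are column-major
  px <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  mammogram_image(px, image_id)
}

#' Write an 8-bit binary (P5) PGM image
#'
#' @param image A [mammogram_image()] or a pixel matrix in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  if (!is_pixel_matrix(px))
    stop("`image` must be a mammogram_image or an 8-bit pixel matrix")
  px <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px))), con)
  writeBin(as.raw(as.integer(t(px))), con)
  invisible(path)
}
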
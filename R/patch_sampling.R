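# ROI-level 60/20/20 splitting and random 72x72 patch sampling (500 per
# normal ROI, 2000 per abnormal ROI at full scale), with patch-wise
# centralization and isometric augmentation.  Splitting is at ROI level so no
# ROI ever contributes patches to two splits.

#' Assign ROIs to train/validation/test splits
#'
#' Stratified by label: within each class, ROIs are shuffled and cut at the
#' requested fractions (largest-remainder rounding, so per-class counts are
#' within one ROI of the exact fractions).
#'
#' @param rois List of [mammo_roi()] objects; names (if any) are used as
#'   `roi_ref`s, otherwise `roi_0001`-style ids are generated.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default `c(0.6, 0.2, 0.2)`).
#' @param seed Optional seed.
#' @return A named factor (levels `train`, `val`, `test`), one element per
#'   ROI, names = `roi_ref`; class `split_assignment`.
#' @export
split_rois <- function(rois, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be three non-negative numbers summing to 1")
  refs <- roi_refs(rois)
  labels <- vapply(rois, `[[`, "", "label")
  if (length(unique(labels)) && any(table(labels) < 1L))
    stop("each class needs at least one ROI")
  if (!all(c("Normal", "Tumor") %in% labels))
    stop("stratification needs at least one ROI of each class")
  out <- factor(rep("train", length(rois)),
                levels = c("train", "val", "test"))
  with_seed(seed, {
    for (cls in unique(labels)) {
      ix <- which(labels == cls)
      ix <- ix[sample.int(length(ix))]
      n <- length(ix)
      cnt <- floor(fractions * n)
      rem <- n - sum(cnt)
      if (rem > 0) {
        frac_rem <- fractions * n - cnt
        add <- order(frac_rem, decreasing = TRUE)[seq_len(rem)]
        cnt[add] <- cnt[add] + 1L
      }
      out[ix] <- rep(c("train", "val", "test"), times = cnt)
    }
  })
  names(out) <- refs
  class(out) <- c("split_assignment", class(out))
  out
}

roi_refs <- function(rois) {
  if (!is.null(names(rois)) && !anyNA(names(rois)) &&
      !any(names(rois) == "") && !anyDuplicated(names(rois)))
    return(names(rois))
  sprintf("roi_%04d", seq_along(rois))
}

#' Construct a patch set
#'
#' The batched container for sampled patches: an `side x side x n` array of
#' (real-valued, typically centralized) pixel grids plus per-patch label,
#' source-ROI reference, and offset inside the ROI.
#'
#' @param pixels Numeric array `side x side x n`.
#' @param label Character vector of `"Normal"`/`"Tumor"`, length `n`.
#' @param roi_ref Character vector, length `n`.
#' @param top,left Integer offsets (0-based) of each patch inside its ROI.
#' @return Object of class `patch_set`.
#' @export
patch_set <- function(pixels, label, roi_ref, top, left) {
  n <- if (length(dim(pixels)) == 3L) dim(pixels)[3] else
    stop("`pixels` must be a 3-d array")
  stopifnot(length(label) == n, length(roi_ref) == n, length(top) == n,
            length(left) == n)
  structure(list(pixels = pixels, label = as.character(label),
                 roi_ref = as.character(roi_ref), top = as.integer(top),
                 left = as.integer(left)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d x %d): %s\n", length(x$label),
              dim(x$pixels)[1], dim(x$pixels)[2],
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.patch_set <- function(x) length(x$label)

#' Sample random square patches from one ROI
#'
#' Offsets are drawn uniformly (with replacement) from the admissible
#' lattice `{0, ..., roi_side - size}^2`; every patch inherits the ROI's
#' label.  With the defaults (120-pixel ROI, 72-pixel patches) that lattice
#' is `{0..48}^2`.
#'
#' @param roi A [mammo_roi()].
#' @param n Number of patches (>= 0).
#' @param size Patch side (default 72).
#' @param centralize If `TRUE` (default) each patch has its own mean
#'   subtracted (patch-wise centralization).
#' @param roi_ref Reference id recorded on the patches (defaults to the
#'   ROI's `image_id`).
#' @param seed Optional seed.
#' @return A [patch_set()] of `n` patches.
#' @export
sample_patches <- function(roi, n, size = 72L, centralize = TRUE,
                           roi_ref = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != as.integer(n))
    stop("`n` must be a single non-negative integer")
  side <- nrow(roi$pixels)
  if (size > side)
    stop(sprintf("patch size %d exceeds ROI side %d", size, side))
  if (is.null(roi_ref)) roi_ref <- roi$image_id
  n <- as.integer(n)
  span <- side - as.integer(size) + 1L
  with_seed(seed, {
    top <- sample.int(span, n, replace = TRUE) - 1L
    left <- sample.int(span, n, replace = TRUE) - 1L
    px <- array(0, c(size, size, max(n, 1L)))
    for (i in seq_len(n)) {
      p <- roi$pixels[(top[i] + 1L):(top[i] + size),
                      (left[i] + 1L):(left[i] + size)] + 0.0
      if (centralize) p <- p - mean(p)
      px[, , i] <- p
    }
    if (n == 0L) px <- array(0, c(size, size, 0L))
    patch_set(px, rep(roi$label, n), rep(roi_ref, n), top, left)
  })
}

#' Patch-wise centralization
#'
#' Subtracts the patch's own mean so each patch enters the network with zero
#' mean (idempotent).
#'
#' @param patch Numeric matrix (a single patch).
#' @return Zero-mean matrix of the same shape.
#' @export
centralize <- function(patch) patch - mean(patch)

#' Isometric patch augmentation
#'
#' Applies each requested operation independently with probability
#' `prob`: horizontal flip, vertical flip, and/or rotation by a random
#' multiple of 90 degrees.  All operations are isometries, so the multiset
#' of pixel values (and hence the zero mean) is preserved.
#'
#' @param patch Numeric matrix.
#' @param ops Subset of `c("hflip", "vflip", "rot90", "none")`.
#' @param prob Per-operation application probability (default 0.5).
#' @param seed Optional seed.
#' @return The transformed matrix.
#' @export
augment <- function(patch, ops = c("hflip", "vflip", "rot90"), prob = 0.5,
                    seed = NULL) {
  known <- c("hflip", "vflip", "rot90", "none")
  if (!all(ops %in% known))
    stop("unknown augmentation op: ",
         paste(setdiff(ops, known), collapse = ", "))
  with_seed(seed, {
    out <- patch
    for (op in ops) {
      if (op == "none") next
      if (runif(1) >= prob) next
      out <- switch(op,
        hflip = out[, rev(seq_len(ncol(out))), drop = FALSE],
        vflip = out[rev(seq_len(nrow(out))), , drop = FALSE],
        rot90 = {
          k <- sample.int(3L, 1L)
          r <- out
          for (q in seq_len(k)) r <- t(r[rev(seq_len(nrow(r))), , drop = FALSE])
          r
        })
    }
    out
  })
}

#' Build per-split patch datasets from ROIs
#'
#' Samples `counts[label]` patches from every ROI and groups them by the
#' ROI's split, so patch provenance never crosses splits.  Training patches
#' are optionally augmented (the validation/test patches never are);
#' all patches are centralized.
#'
#' @param rois List of [mammo_roi()] objects.
#' @param split A [split_rois()] assignment for exactly these ROIs.
#' @param counts Named per-class patch counts
#'   (default `c(Normal = 500, Tumor = 2000)`).
#' @param size Patch side (default 72).
#' @param seed Optional seed governing sampling and augmentation.
#' @param augment_train Augment training patches (default `TRUE`).
#' @param augment_ops Operations passed to [augment()].
#' @return List with elements `train`, `val`, `test`, each a [patch_set()].
#' @export
build_patch_dataset <- function(rois, split,
                                counts = c(Normal = 500, Tumor = 2000),
                                size = 72L, seed = NULL,
                                augment_train = TRUE,
                                augment_ops = c("hflip", "vflip", "rot90")) {
  if (length(split) != length(rois))
    stop("`split` must assign exactly the given ROIs")
  if (any(counts < 1)) stop("`counts` must be positive")
  refs <- names(split)
  with_seed(seed, {
    out <- list()
    for (s in c("train", "val", "test")) {
      ix <- which(split == s)
      sets <- vector("list", length(ix))
      for (k in seq_along(ix)) {
        i <- ix[k]
        ps <- sample_patches(rois[[i]], counts[[rois[[i]]$label]], size,
                             centralize = TRUE, roi_ref = refs[i])
        if (s == "train" && augment_train && length(ps) > 0) {
          for (p in seq_len(length(ps)))
            ps$pixels[, , p] <- augment(ps$pixels[, , p], augment_ops)
        }
        sets[[k]] <- ps
      }
      out[[s]] <- combine_patch_sets(sets, size)
    }
    out
  })
}

combine_patch_sets <- function(sets, size) {
  if (!length(sets))
    return(patch_set(array(0, c(size, size, 0L)), character(), character(),
                     integer(), integer()))
  ntot <- sum(vapply(sets, length, 0L))
  px <- array(0, c(size, size, ntot))
  lab <- character(ntot); ref <- character(ntot)
  top <- integer(ntot); left <- integer(ntot)
  at <- 0L
  for (ps in sets) {
    n <- length(ps)
    if (n > 0) {
      px[, , (at + 1L):(at + n)] <- ps$pixels
      lab[(at + 1L):(at + n)] <- ps$label
      ref[(at + 1L):(at + n)] <- ps$roi_ref
      top[(at + 1L):(at + n)] <- ps$top
      left[(at + 1L):(at + n)] <- ps$left
      at <- at + n
    }
  }
  patch_set(px, lab, ref, top, left)
}

#' Write a patch manifest as CSV
#'
#' @param patches A [patch_set()].
#' @param path Output CSV path.
#' @param split Optional split name recorded per row.
#' @return `path`, invisibly.
#' @export
write_patch_manifest <- function(patches, path, split = NA_character_) {
  df <- data.frame(roi_ref = patches$roi_ref, label = patches$label,
                   top = patches$top, left = patches$left, split = split,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
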
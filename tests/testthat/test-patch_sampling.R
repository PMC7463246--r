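test_that("ROI splits are stratified, exhaustive and deterministic", {
  rois <- make_roi_set(10)
  s1 <- split_rois(rois, seed = 3)
  s2 <- split_rois(rois, seed = 3)
  expect_identical(s1, s2)
  labels <- vapply(rois, `[[`, "", "label")
  for (cls in c("Normal", "Tumor")) {
    tab <- table(s1[labels == cls])
    expect_equal(unname(tab[c("train", "val", "test")]), c(6L, 2L, 2L),
                 ignore_attr = TRUE)
  }
  expect_equal(length(s1), length(rois))
  expect_false(anyNA(s1))
  expect_error(split_rois(rois, c(0.5, 0.5, 0.1)), "fractions")
  only_normal <- rois[1:10]
  expect_error(split_rois(only_normal), "each class|stratification")
})

test_that("patch sampling respects the offset lattice and labels", {
  roi <- make_test_roi("Tumor", 2)
  ps <- sample_patches(roi, 300, seed = 4)
  expect_equal(length(ps), 300L)
  expect_true(all(ps$top >= 0 & ps$top <= 48))
  expect_true(all(ps$left >= 0 & ps$left <= 48))
  expect_true(all(ps$label == "Tumor"))
  # every patch zero mean after centralization
  mus <- apply(ps$pixels, 3, mean)
  expect_true(all(abs(mus) < 1e-6))
  # patch size equal to ROI side forces offset (0, 0) and the whole ROI
  whole <- sample_patches(roi, 3, size = 120, centralize = FALSE, seed = 1)
  expect_true(all(whole$top == 0L & whole$left == 0L))
  expect_equal(whole$pixels[, , 2], roi$pixels + 0.0)
  expect_error(sample_patches(roi, 5, size = 121), "exceeds")
  expect_equal(length(sample_patches(roi, 0)), 0L)
})

test_that("centralization is exact mean removal and idempotent", {
  expect_equal(centralize(matrix(42, 8, 8)), matrix(0, 8, 8))
  p <- matrix(rep(c(0, 10), 32), 8, 8)
  expect_setequal(unique(as.vector(centralize(p))), c(-5, 5))
  z <- centralize(matrix(rnorm(64), 8, 8))
  expect_equal(centralize(z), z)
  expect_lt(abs(mean(z)), 1e-6)
})

test_that("augmentation ops are isometries and seed deterministic", {
  set.seed(8)
  p <- matrix(rnorm(72 * 72), 72, 72)
  expect_identical(augment(p, ops = "none"), p)
  # involution: one guaranteed horizontal flip twice returns the original
  flip_once <- augment(p, ops = "hflip", prob = 1)
  expect_false(identical(flip_once, p))
  expect_identical(augment(flip_once, ops = "hflip", prob = 1), p)
  # every op preserves the pixel multiset
  for (op in c("hflip", "vflip", "rot90")) {
    out <- augment(p, ops = op, prob = 1, seed = 5)
    expect_equal(dim(out), dim(p))
    expect_equal(sort(as.vector(out)), sort(as.vector(p)), info = op)
  }
  expect_identical(augment(p, seed = 11), augment(p, seed = 11))
  expect_error(augment(p, ops = "zoom"), "unknown")
})

test_that("patch datasets follow per-class counts with no split leakage", {
  rois <- make_roi_set(5)
  split <- split_rois(rois, seed = 2)
  counts <- c(Normal = 30, Tumor = 80)
  ds <- build_patch_dataset(rois, split, counts, seed = 6)
  labels <- vapply(rois, `[[`, "", "label")
  for (s in c("train", "val", "test")) {
    in_split <- names(split)[split == s]
    want <- sum(counts[labels[in_split]])
    expect_equal(length(ds[[s]]), unname(want), info = s)
    expect_true(all(ds[[s]]$roi_ref %in% in_split), info = s)
  }
  # bit-identical under the same seed
  ds2 <- build_patch_dataset(rois, split, counts, seed = 6)
  expect_identical(ds, ds2)
  # a split with no test ROIs yields an empty test set
  tiny <- rois[c(1, 2, 6, 7)]
  sp <- factor(c("train", "val", "train", "val"),
               levels = c("train", "val", "test"))
  names(sp) <- names(tiny)
  class(sp) <- c("split_assignment", class(sp))
  ds3 <- build_patch_dataset(tiny, sp, counts, seed = 1)
  expect_equal(length(ds3$test), 0L)
  # arithmetic example: 2 normal + 1 abnormal training ROIs
  expect_equal(2 * 30 + 1 * 80, 140)
})

test_that("patch manifests round trip through CSV", {
  roi <- make_test_roi("Normal", 3)
  ps <- sample_patches(roi, 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patch_manifest(ps, path, split = "train")
  back <- read.csv(path)
  expect_equal(nrow(back), 10L)
  expect_equal(back$top, ps$top)
  expect_equal(unique(back$split), "train")
})
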
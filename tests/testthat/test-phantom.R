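test_that("phantom config enforces its invariants", {
  expect_error(phantom_config(lesion_radius_range = c(0, 10)), "radius")
  expect_error(phantom_config(image_side = 128,
                              lesion_radius_range = c(8, 40)), "radius")
  expect_error(phantom_config(impulse_noise_rate = 0.6), "noise")
  expect_silent(phantom_config(0, 0))
})

test_that("generated images are deterministic and annotated consistently", {
  cfg <- phantom_config(1, 1, 256, seed = 1)
  a <- generate_image(cfg, TRUE, "syn001", seed = 11)
  b <- generate_image(cfg, TRUE, "syn001", seed = 11)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$annotation, b$annotation)

  ann <- a$annotation
  expect_equal(ann$abnorm_class, "CIRC")
  expect_true(ann$severity %in% c("B", "M"))
  expect_true(ann$radius > 0)
  expect_true(ann$x >= 0 && ann$x < 256 && ann$y >= 0 && ann$y < 256)

  norm <- generate_image(cfg, FALSE, "syn002", seed = 12)$annotation
  expect_equal(norm$abnorm_class, "NORM")
  expect_true(is.na(norm$severity) && is.na(norm$x) && is.na(norm$radius))
})

test_that("lesions are bright relative to a surrounding breast ring", {
  cfg <- phantom_config(1, 1, 256, seed = 2)
  g <- generate_image(cfg, TRUE, "syn001", seed = 21)
  px <- g$image$pixels
  ann <- g$annotation
  ctr <- annotation_to_rowcol(ann, 256)
  rr <- outer(0:(255), rep(1, 256)); cc <- t(rr)
  d <- sqrt((rr - ctr["row"])^2 + (cc - ctr["col"])^2)
  inside <- d <= ann$radius
  ring <- d > ann$radius & d <= ann$radius * sqrt(2)  # same-area ring
  expect_gt(mean(px[inside]) - mean(px[ring]), cfg$lesion_contrast / 2)
})

test_that("lesion circles lie inside the default breast mask", {
  cfg <- phantom_config(1, 1, 256, seed = 3)
  for (s in 1:5) {
    g <- generate_image(cfg, TRUE, "syn001", seed = 30 + s)
    mask <- compute_breast_mask(g$image)
    ctr <- annotation_to_rowcol(g$annotation, 256)
    r <- g$annotation$radius
    rr <- outer(0:255, rep(1, 256)); cc <- t(rr)
    inside <- sqrt((rr - ctr["row"])^2 + (cc - ctr["col"])^2) <= r
    expect_true(all(mask[inside]), info = paste("seed", 30 + s))
  }
})

test_that("datasets land on disk in MIAS format with exact round trip", {
  cfg <- phantom_config(3, 2, 160, lesion_radius_range = c(8, 30), seed = 4)
  dir <- withr::local_tempdir()
  res <- generate_dataset(cfg, dir)
  expect_length(list.files(dir, pattern = "\\.pgm$"), 5L)
  back <- read_info_file(res$info_path)
  expect_equal(as.data.frame(back), as.data.frame(res$records))
  expect_equal(sum(back$abnorm_class == "NORM"), 3L)
  img <- read_pgm(res$image_paths[1])
  expect_equal(img$height, 160L)
  # no-normals dataset has no NORM lines
  res0 <- generate_dataset(phantom_config(0, 2, 160,
                                          lesion_radius_range = c(8, 30),
                                          seed = 5),
                           withr::local_tempdir())
  expect_false(any(res0$records$abnorm_class == "NORM"))
})

test_that("tumor ROI intensities stochastically dominate normal ROIs", {
  # rank-sum direction check over >= 100 ROIs per class, windows taken
  # straight from the generated images at the annotated / random centers
  cfg <- phantom_config(100, 100, 256, seed = 6)
  set.seed(6)
  mean_n <- numeric(0); mean_t <- numeric(0)
  for (i in 1:200) {
    lesion <- i > 100
    g <- generate_image(cfg, lesion, sprintf("s%03d", i))
    if (lesion) {
      ctr <- annotation_to_rowcol(g$annotation, 256)
    } else {
      mask <- compute_breast_mask(g$image)
      ctr <- random_roi_center(mask, 60)
    }
    w <- extract_window(g$image, ctr["row"], ctr["col"], 60)
    if (lesion) mean_t <- c(mean_t, mean(w)) else mean_n <- c(mean_n, mean(w))
  }
  wt <- wilcox.test(mean_t, mean_n, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
  expect_gt(median(mean_t), median(mean_n))
})
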
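test_that("median filter matches the brute-force window oracle", {
  # constant image unchanged
  expect_equal(denoise_median(matrix(7, 9, 9), 3), matrix(7, 9, 9))
  # single impulse removed
  imp <- matrix(0, 9, 9); imp[5, 5] <- 255
  expect_equal(denoise_median(imp, 3), matrix(0, 9, 9))
  # random fixtures vs oracle, several sizes and kernels
  set.seed(11)
  for (case in list(c(16, 3), c(12, 5), c(7, 3), c(32, 3))) {
    img <- matrix(sample(0:255, case[1]^2, replace = TRUE), case[1])
    expect_equal(denoise_median(img, case[2]), oracle_median(img, case[2]),
                 info = paste(case, collapse = "x"))
  }
  expect_error(denoise_median(imp, 2), "odd")
  expect_error(denoise_median(imp, -1), "odd")
})

test_that("CLAHE matches the independent reference implementation", {
  set.seed(7)
  img <- matrix(sample(0:255, 32 * 40, replace = TRUE), 32, 40)
  for (grid in list(c(2, 2), c(4, 5), c(1, 1))) {
    got <- enhance_clahe(img, 2.0, grid)
    expect_equal(got, oracle_clahe(img, 2.0, grid[1], grid[2]),
                 info = paste(grid, collapse = "x"))
    expect_true(all(got >= 0 & got <= 255))
  }
})

test_that("CLAHE contracts: constant input, contrast lift, parameter errors", {
  const <- matrix(40, 32, 32)
  out <- enhance_clahe(const)
  expect_equal(length(unique(as.vector(out))), 1L)
  # low-contrast two-level image gains contrast
  two <- matrix(rep(c(100, 110), each = 512), 32, 32)
  expect_gt(sd(enhance_clahe(two)), sd(two))
  expect_error(enhance_clahe(const, clip_limit = 0), "clip_limit")
  expect_error(enhance_clahe(const, tile_grid = c(0, 4)), "tile_grid")
})

test_that("breast mask keeps the largest bright component", {
  half <- cbind(matrix(0, 40, 20), matrix(200, 40, 20))
  m <- compute_breast_mask(half, 20, closing_radius = 2)
  expect_true(all(m[, 21:40]))
  expect_false(any(m[, 1:18]))  # closing may bleed one radius at the seam

  two <- matrix(0, 60, 60)
  two[5:29, 5:24] <- 200    # 500 px
  two[45:54, 45:49] <- 200  # 50 px
  m2 <- compute_breast_mask(two, 20, closing_radius = 1)
  expect_true(all(m2[5:29, 5:24]))
  expect_false(any(m2[45:54, 45:49]))

  expect_error(compute_breast_mask(matrix(0, 10, 10), 15), "empty")
})

test_that("annotation y axis flips from bottom-left to row origin", {
  expect_equal(annotation_to_rowcol(list(x = 535, y = 425), 1024),
               c(row = 598, col = 535))
  expect_equal(annotation_to_rowcol(list(x = 0, y = 0), 1024),
               c(row = 1023, col = 0))
  expect_equal(annotation_to_rowcol(list(x = 10, y = 1023), 1024),
               c(row = 0, col = 10))
  expect_error(annotation_to_rowcol(list(x = NA, y = 2), 64), "coordinates")
})

test_that("window extraction is exact and clamps at borders", {
  img <- matrix(seq_len(1024 * 1024) %% 251, 1024, 1024)
  w <- extract_window(img, 512, 512, 60)
  expect_equal(dim(w), c(120L, 120L))
  expect_equal(attr(w, "top"), 452L)
  expect_equal(w[1, 1], img[453, 453])
  # clamped near the top edge
  w2 <- extract_window(img, 30, 512, 60)
  expect_equal(attr(w2, "top"), 0L)
  expect_equal(w2[1, 1], img[1, 453])
  expect_error(extract_window(matrix(0, 100, 100), 50, 50, 60), "smaller")
})

test_that("a radius-60 annotation's circle lies inside a clamp-free window", {
  set.seed(3)
  H <- 512
  for (rep in 1:20) {
    r <- sample(3:60, 1)
    cr <- sample(61:(H - 61), 1)
    cc <- sample(61:(H - 61), 1)
    w <- extract_window(matrix(0, H, H), cr, cc, 60)
    top <- attr(w, "top"); left <- attr(w, "left")
    expect_true(top <= cr - r && cr + r <= top + 119)
    expect_true(left <= cc - r && cc + r <= left + 119)
  }
})

test_that("dark margins are trimmed, fully dark windows rejected", {
  win <- matrix(100, 120, 120)
  win[, 1:20] <- 0
  expect_equal(dim(crop_nonbreast(win)), c(120L, 100L))
  expect_equal(crop_nonbreast(matrix(100, 50, 50)), matrix(100, 50, 50))
  expect_error(crop_nonbreast(matrix(0, 30, 30)), "degenerate")
  # isolated bright noise inside a dark band does not save the band
  win2 <- matrix(100, 120, 120)
  win2[, 1:10] <- 0
  win2[5, 3] <- 200
  expect_equal(ncol(crop_nonbreast(win2)), 110L)
})

test_that("ROI rescaling is bilinear with identity and constants preserved", {
  set.seed(5)
  px <- matrix(sample(0:255, 120 * 120, replace = TRUE), 120, 120)
  expect_equal(rescale_roi(px, 120), px)
  out <- rescale_roi(px[, 1:100], 120)
  expect_equal(dim(out), c(120L, 120L))
  expect_true(all(out >= 0 & out <= 255))
  expect_equal(rescale_roi(matrix(42, 60, 60), 120), matrix(42L, 120, 120))
})

test_that("random ROI centers are admissible and seed deterministic", {
  mask <- matrix(TRUE, 200, 200)
  c1 <- random_roi_center(mask, 60, seed = 9)
  c2 <- random_roi_center(mask, 60, seed = 9)
  expect_identical(c1, c2)
  # single admissible pixel is the forced outcome
  single <- matrix(FALSE, 200, 200); single[77, 133] <- TRUE
  got <- random_roi_center(single, 60, min_coverage = 0)
  expect_equal(unname(got), c(76, 132))
  expect_error(random_roi_center(single, 60, min_coverage = 0.5,
                                 max_retries = 10), "admissible")
  expect_error(random_roi_center(matrix(FALSE, 200, 200), 60), "empty")
})

test_that("full chain yields 120x120 8-bit ROIs, deterministically", {
  cfg <- phantom_config(1, 1, 192, seed = 5)
  run_once <- function() {
    rois <- list()
    for (i in 1:2) {
      g <- generate_image(cfg, with_lesion = i == 2, sprintf("p%02d", i),
                          seed = 100 + i)
      pre <- preprocess_image(g$image)
      rois <- c(rois, extract_rois(pre, g$annotation, seed = 7))
    }
    rois
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1, r2)
  for (r in r1) {
    expect_equal(dim(r$pixels), c(120L, 120L))
    expect_true(all(r$pixels >= 0 & r$pixels <= 255))
  }
  expect_setequal(vapply(r1, `[[`, "", "label"), c("Normal", "Tumor"))
})
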
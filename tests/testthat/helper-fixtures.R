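# In-code fixtures shared across test files.

# a 120x120 ROI: smooth texture, optionally with a central bright blob
make_test_roi <- function(label = "Normal", seed = 1, blob = 25) {
  set.seed(seed)
  base <- matrix(120, 120, 120)
  tex <- matrix(rnorm(120 * 120, sd = 5), 120, 120)
  px <- base + tex
  if (label == "Tumor") {
    d <- sqrt(outer((1:120 - 60)^2, (1:120 - 60)^2, "+"))
    px <- px + blob * exp(-(d / 20)^2)
  }
  px <- pmin(pmax(round(px), 0), 255)
  mammofuse::mammo_roi(px, label, sprintf("fix_%s_%d", label, seed),
                       annotation_ref = if (label == "Tumor") 1L else
                         NA_integer_)
}

make_roi_set <- function(n_per_class = 4, seed = 1) {
  rois <- list()
  for (i in seq_len(n_per_class))
    rois[[sprintf("n%02d", i)]] <- make_test_roi("Normal", seed + i)
  for (i in seq_len(n_per_class))
    rois[[sprintf("t%02d", i)]] <- make_test_roi("Tumor", seed + 100 + i)
  rois
}

# small labeled patch sets with an easily separable mean-free signal
make_separable_patches <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  px <- array(rnorm(72 * 72 * n, sd = 8), c(72, 72, n))
  d <- sqrt(outer((1:72 - 36)^2, (1:72 - 36)^2, "+"))
  blob <- 40 * exp(-(d / 12)^2)
  lab <- rep(c("Normal", "Tumor"), each = n_per_class)
  for (i in which(lab == "Tumor")) px[, , i] <- px[, , i] + blob
  for (i in seq_len(n)) px[, , i] <- px[, , i] - mean(px[, , i])
  mammofuse::patch_set(px, lab, rep(c("nroi", "troi"), each = n_per_class),
                       rep(0L, n), rep(0L, n))
}

tiny_model <- function(mode = "fusion1", seed = 1, branches = 1:5, ...) {
  mammofuse::build_model(
    mammofuse::fusion_spec("tiny_test", branches, mode, ...), seed = seed)
}
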
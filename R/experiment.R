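# End-to-end desk-scale experiment on phantom data: generate, preprocess,
# extract ROIs, split, sample patches, train both fusion heads over the
# tiny_test backbone, and evaluate by 25-patch majority voting.

#' Run the full pipeline on a synthetic phantom dataset
#'
#' Generates `n_normal + n_abnormal` phantom mammograms, runs the
#' preprocessing chain (median filter, CLAHE, ROI extraction with non-breast
#' cropping and rescaling), splits ROIs 60/20/20, samples labeled 72x72
#' patches, trains the requested fusion heads on the frozen backbone, and
#' classifies the test ROIs by majority voting.
#'
#' @param n_normal,n_abnormal Phantom images per class (defaults 40/40).
#' @param image_side Phantom side (default 256).
#' @param counts Patches per ROI by class
#'   (default `c(Normal = 50, Tumor = 200)`, a 1/10 scale of the full-size
#'   500/2000 protocol).
#' @param modes Fusion modes to train (default both).
#' @param backbone Backbone name (default `"tiny_test"`).
#' @param n_vote Voting patches per test ROI (default 25).
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param seed Single seed governing the whole experiment.
#' @return List with one element per mode (each holding `history`,
#'   `best_epoch`, `votes`, `report`, `curves`) plus `split` and
#'   `n_rois`.
#' @export
phantom_experiment <- function(n_normal = 40L, n_abnormal = 40L,
                               image_side = 256L,
                               counts = c(Normal = 50, Tumor = 200),
                               modes = c("fusion1", "fusion2"),
                               backbone = "tiny_test", n_vote = 25L,
                               epochs = 20L, batch_size = 64L,
                               learning_rate = 1e-3, seed = 1L) {
  cfg <- phantom_config(n_normal, n_abnormal, image_side, seed = seed)
  with_seed(seed, {
    n <- n_normal + n_abnormal
    rois <- list()
    for (i in seq_len(n)) {
      id <- sprintf("syn%03d", i)
      g <- generate_image(cfg, with_lesion = i > n_normal, id)
      pre <- preprocess_image(g$image)
      r <- extract_rois(pre, g$annotation)
      if (length(r)) rois[[id]] <- r[[1]]
    }
    split <- split_rois(rois)
    ds <- build_patch_dataset(rois, split, counts)
    test_rois <- rois[split == "test"]
    out <- list()
    for (mode in modes) {
      spec <- fusion_spec(backbone, 1:5, mode)
      model <- build_model(spec, seed = seed)
      fit <- train(model, ds$train, ds$val,
                   train_config(learning_rate = learning_rate,
                                batch_size = batch_size, epochs = epochs,
                                seed = seed))
      ev <- evaluate_rois(fit$model, test_rois, n = n_vote)
      out[[mode]] <- list(history = fit$history, best_epoch = fit$best_epoch,
                          votes = ev$votes, report = ev$report,
                          curves = ev$curves)
    }
    out$split <- split
    out$n_rois <- length(rois)
    out
  })
}
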
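# Head training over a frozen backbone, Eq.-style majority voting at the ROI
# level (n = 25 patches), and full binary evaluation.
#
# Because the backbone never trains, every patch's backbone activations are
# computed once and cached; head training then runs on the cache.  For
# fusion2 the per-branch BN statistics are still exact: the per-channel BN
# affine commutes with spatial average pooling, and the batch mean/variance
# over the *pre-pool* maps are recovered from cached per-patch channel sums
# and sums of squares.  Gradients with respect to the trainable parameters
# are exact as well (the frozen input makes the branch-BN statistics
# constants of the optimisation).

#' Training configuration
#'
#' @param loss Only `"cross_entropy"` is supported.
#' @param optimizer Only `"adam"` is supported.
#' @param learning_rate Step size (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param epochs Maximum epochs (default 20).
#' @param seed Seed governing shuffling (default 1).
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping (default 5).
#' @param class_weighting Use inverse-frequency class weights in the loss.
#' @param bn_momentum Running-statistics update rate (default 0.1).
#' @return Object of class `train_config`.
#' @export
train_config <- function(loss = "cross_entropy", optimizer = "adam",
                         learning_rate = 1e-3, batch_size = 64L,
                         epochs = 20L, seed = 1L,
                         early_stopping_patience = 5L,
                         class_weighting = FALSE, bn_momentum = 0.1) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  stop_if_not_scalar_count(epochs, "epochs")
  stop_if_not_scalar_count(batch_size, "batch_size")
  structure(list(loss = loss, optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 class_weighting = isTRUE(class_weighting),
                 bn_momentum = bn_momentum),
            class = "train_config")
}

patch_subset <- function(ps, idx) {
  patch_set(ps$pixels[, , idx, drop = FALSE], ps$label[idx], ps$roi_ref[idx],
            ps$top[idx], ps$left[idx])
}

# Cache the frozen-backbone representation of a patch set.
# fusion1: the concatenated GAP matrix (n x D).
# fusion2: per branch, the post-avgpool maps as an (n*M_b) x C_b row matrix
#   (rows grouped per patch) plus per-patch channel sums / sums of squares of
#   the pre-pool maps (for exact BN batch statistics) and the pre-pool pixel
#   count.
compute_feature_cache <- function(model, patches, batch_size = 128L) {
  n <- length(patches)
  spec <- model$spec
  if (spec$mode == "fusion1") {
    X <- matrix(0, n, fused_dimension(spec))
    at <- 0L
    while (at < n) {
      idx <- (at + 1L):min(n, at + batch_size)
      maps <- backbone_branch_maps(
        model, as_patch_array(patch_subset(patches, idx), model$input_side))
      X[idx, ] <- do.call(cbind, lapply(spec$branches, function(b)
        gap_cpp(maps[[as.character(b)]])))
      at <- idx[length(idx)]
    }
    return(list(mode = "fusion1", n = n, X = X,
                y = match(patches$label, model$classes)))
  }
  br <- list()
  at <- 0L
  while (at < n) {
    idx <- (at + 1L):min(n, at + batch_size)
    maps <- backbone_branch_maps(
      model, as_patch_array(patch_subset(patches, idx), model$input_side))
    for (b in spec$branches) {
      key <- as.character(b)
      m <- maps[[key]]
      mom <- channel_moments_cpp(m)
      pooled <- pool2_cpp(m, 1L)
      d <- dim(pooled)
      if (is.null(br[[key]])) {
        br[[key]] <- list(
          P = matrix(0, n * d[1] * d[2], d[3]),
          S = matrix(0, n, d[3]), Q = matrix(0, n, d[3]),
          M = d[1] * d[2], HW = dim(m)[1] * dim(m)[2], C = d[3])
      }
      Mb <- br[[key]]$M
      rows <- rep((idx - 1L) * Mb, each = Mb) + seq_len(Mb)
      br[[key]]$P[rows, ] <- map_to_rows(pooled)
      br[[key]]$S[idx, ] <- mom$sum
      br[[key]]$Q[idx, ] <- mom$sumsq
    }
    at <- idx[length(idx)]
  }
  list(mode = "fusion2", n = n, branches = br,
       y = match(patches$label, model$classes))
}

# inference-mode probabilities straight from a feature cache
infer_from_cache <- function(model, cache) {
  spec <- model$spec
  if (cache$mode == "fusion1") {
    F <- cache$X
  } else {
    feats <- lapply(spec$branches, function(b) {
      cb <- cache$branches[[as.character(b)]]
      z <- bn_affine(cb$P,
                     model$buffers[[sprintf("branch%d.bn.running_mean", b)]],
                     model$buffers[[sprintf("branch%d.bn.running_var", b)]],
                     model$params[[sprintf("branch%d.bn.gamma", b)]],
                     model$params[[sprintf("branch%d.bn.beta", b)]])
      a <- bias_relu(
        z %*% model$params[[sprintf("branch%d.conv1x1.W", b)]],
        model$params[[sprintf("branch%d.conv1x1.b", b)]])
      rowsum(a, rep(seq_len(cache$n), each = cb$M), reorder = FALSE) / cb$M
    })
    F <- do.call(cbind, feats)
  }
  softmax_rows(head_forward_infer(model, F))
}

cross_entropy <- function(probs, y, w = NULL) {
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  if (is.null(w)) mean(-log(p)) else sum(-w[y] * log(p)) / sum(w[y])
}

#' Train the fusion head
#'
#' Minibatch Adam on the trainable parameters only; the frozen backbone is
#' untouched (bit-identical before and after).  BN layers use batch
#' statistics during training and maintain running statistics for
#' inference.  The returned model carries the parameters of the epoch with
#' the best validation loss.
#'
#' @param model A [build_model()] result.
#' @param train_patches,val_patches [patch_set()]s of centralized patches.
#'   `val_patches` may be `NULL`/empty, in which case the training loss is
#'   monitored instead.
#' @param config A [train_config()].
#' @return List with `model` (trained), `history` (per-epoch data frame with
#'   train/val loss and accuracy) and `best_epoch`.
#' @export
train <- function(model, train_patches, val_patches = NULL,
                  config = train_config()) {
  stopifnot(inherits(model, "fusion_model"), inherits(config, "train_config"))
  n <- length(train_patches)
  if (n == 0L) stop("empty training set")
  spec <- model$spec
  tr <- compute_feature_cache(model, train_patches)
  va <- if (!is.null(val_patches) && length(val_patches) > 0)
    compute_feature_cache(model, val_patches) else NULL
  y <- tr$y
  if (anyNA(y)) stop("patch labels must be in ", paste(model$classes, collapse = "/"))
  w <- NULL
  if (config$class_weighting) {
    freq <- tabulate(y, nbins = spec$n_classes)
    w <- sum(freq) / (spec$n_classes * pmax(freq, 1))
  }

  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0L)
  mom <- config$bn_momentum
  hist_rows <- vector("list", config$epochs)
  # checkpoint on best validation accuracy (ties: lower loss); early stopping
  # watches validation loss
  best <- list(loss = Inf, acc = -Inf, epoch = 0L, params = model$params,
               buffers = model$buffers)
  best_loss <- Inf
  wait <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      at <- 0L
      while (at < n) {
        idx <- ord[(at + 1L):min(n, at + config$batch_size)]
        at <- at + length(idx)
        B <- length(idx)
        yb <- y[idx]

        # ---- forward (training mode) ----
        branch_ctx <- list()
        if (spec$mode == "fusion1") {
          F <- tr$X[idx, , drop = FALSE]
        } else {
          feats <- list()
          for (b in spec$branches) {
            cb <- tr$branches[[as.character(b)]]
            rows <- rep((idx - 1L) * cb$M, each = cb$M) + seq_len(cb$M)
            Xp <- cb$P[rows, , drop = FALSE]
            tot <- B * cb$HW
            mu <- colSums(cb$S[idx, , drop = FALSE]) / tot
            vv <- pmax(colSums(cb$Q[idx, , drop = FALSE]) / tot - mu^2, 0)
            sg <- sqrt(vv + BN_EPS)
            xhat <- col_affine(Xp, 1 / sg, -mu / sg)
            gkey <- sprintf("branch%d.bn.gamma", b)
            bkey <- sprintf("branch%d.bn.beta", b)
            z <- col_affine(xhat, model$params[[gkey]],
                                  model$params[[bkey]])
            wkey <- sprintf("branch%d.conv1x1.W", b)
            ckey <- sprintf("branch%d.conv1x1.b", b)
            a <- bias_relu(z %*% model$params[[wkey]],
                                     model$params[[ckey]])
            g <- rowsum(a, rep(seq_len(B), each = cb$M),
                        reorder = FALSE) / cb$M
            feats[[as.character(b)]] <- g
            branch_ctx[[as.character(b)]] <-
              list(xhat = xhat, z = z, mask = a > 0, M = cb$M)
            rmk <- sprintf("branch%d.bn.running_mean", b)
            rvk <- sprintf("branch%d.bn.running_var", b)
            model$buffers[[rmk]] <- (1 - mom) * model$buffers[[rmk]] + mom * mu
            model$buffers[[rvk]] <- (1 - mom) * model$buffers[[rvk]] + mom * vv
          }
          F <- do.call(cbind, feats)
        }

        # head BN (batch statistics)
        mu_h <- colMeans(F)
        vv_h <- pmax(colMeans(F^2) - mu_h^2, 0)
        sg_h <- sqrt(vv_h + BN_EPS)
        xhat_h <- sweep(sweep(F, 2, mu_h), 2, sg_h, "/")
        z_h <- sweep(sweep(xhat_h, 2, model$params[["head.bn.gamma"]], "*"),
                     2, model$params[["head.bn.beta"]], "+")
        h1pre <- sweep(z_h %*% model$params[["head.fc1.W"]], 2,
                       model$params[["head.fc1.b"]], "+")
        h1 <- pmax(h1pre, 0)
        h2pre <- sweep(h1 %*% model$params[["head.fc2.W"]], 2,
                       model$params[["head.fc2.b"]], "+")
        h2 <- pmax(h2pre, 0)
        logits <- sweep(h2 %*% model$params[["head.out.W"]], 2,
                        model$params[["head.out.b"]], "+")
        probs <- softmax_rows(logits)
        loss <- cross_entropy(probs, yb, w)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct +
          sum(max.col(probs, ties.method = "first") == yb)
        model$buffers[["head.bn.running_mean"]] <-
          (1 - mom) * model$buffers[["head.bn.running_mean"]] + mom * mu_h
        model$buffers[["head.bn.running_var"]] <-
          (1 - mom) * model$buffers[["head.bn.running_var"]] + mom * vv_h

        # ---- backward ----
        onehot <- matrix(0, B, spec$n_classes)
        onehot[cbind(seq_len(B), yb)] <- 1
        if (is.null(w)) {
          dlogits <- (probs - onehot) / B
        } else {
          dlogits <- (probs - onehot) * (w[yb] / sum(w[yb]))
        }
        grads <- list()
        grads[["head.out.W"]] <- crossprod(h2, dlogits)
        grads[["head.out.b"]] <- colSums(dlogits)
        dh2 <- (dlogits %*% t(model$params[["head.out.W"]])) * (h2pre > 0)
        grads[["head.fc2.W"]] <- crossprod(h1, dh2)
        grads[["head.fc2.b"]] <- colSums(dh2)
        dh1 <- (dh2 %*% t(model$params[["head.fc2.W"]])) * (h1pre > 0)
        grads[["head.fc1.W"]] <- crossprod(z_h, dh1)
        grads[["head.fc1.b"]] <- colSums(dh1)
        dz_h <- dh1 %*% t(model$params[["head.fc1.W"]])
        grads[["head.bn.gamma"]] <- colSums(dz_h * xhat_h)
        grads[["head.bn.beta"]] <- colSums(dz_h)

        if (spec$mode == "fusion2") {
          # full BN backward: the head-BN input depends on branch parameters
          dxhat <- sweep(dz_h, 2, model$params[["head.bn.gamma"]], "*")
          s1 <- colSums(dxhat)
          s2 <- colSums(dxhat * xhat_h)
          dF <- sweep(dxhat - matrix(s1 / B, B, ncol(F), byrow = TRUE) -
                        xhat_h * matrix(s2 / B, B, ncol(F), byrow = TRUE),
                      2, sg_h, "/")
          col_at <- 0L
          for (b in spec$branches) {
            ctx <- branch_ctx[[as.character(b)]]
            K <- spec$bottleneck_channels
            dg <- dF[, (col_at + 1L):(col_at + K), drop = FALSE]
            col_at <- col_at + K
            da <- dg[rep(seq_len(B), each = ctx$M), , drop = FALSE] / ctx$M
            da <- da * ctx$mask
            wkey <- sprintf("branch%d.conv1x1.W", b)
            grads[[wkey]] <- crossprod(ctx$z, da)
            grads[[sprintf("branch%d.conv1x1.b", b)]] <- colSums(da)
            dz_b <- da %*% t(model$params[[wkey]])
            grads[[sprintf("branch%d.bn.gamma", b)]] <-
              colSums(dz_b * ctx$xhat)
            grads[[sprintf("branch%d.bn.beta", b)]] <- colSums(dz_b)
          }
        }

        # ---- Adam update ----
        adam$t <- adam$t + 1L
        lr_t <- config$learning_rate *
          sqrt(1 - 0.999^adam$t) / (1 - 0.9^adam$t)
        for (nm in names(grads)) {
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * grads[[nm]]
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * grads[[nm]]^2
          model$params[[nm]] <- model$params[[nm]] -
            lr_t * adam$m[[nm]] / (sqrt(adam$v[[nm]]) + 1e-8)
        }
      }

      train_loss <- ep_loss / n
      train_acc <- ep_correct / n
      if (!is.null(va)) {
        vp <- infer_from_cache(model, va)
        val_loss <- cross_entropy(vp, va$y)
        val_acc <- mean(max.col(vp, ties.method = "first") == va$y)
      } else {
        val_loss <- train_loss
        val_acc <- NA_real_
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = train_loss, train_acc = train_acc,
        val_loss = if (is.null(va)) NA_real_ else val_loss,
        val_acc = val_acc)
      sel_acc <- if (is.na(val_acc)) train_acc else val_acc
      if (sel_acc > best$acc + 1e-12 ||
          (abs(sel_acc - best$acc) <= 1e-12 && val_loss < best$loss)) {
        best <- list(loss = val_loss, acc = sel_acc, epoch = epoch,
                     params = model$params, buffers = model$buffers)
      }
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
  })

  model$params <- best$params
  model$buffers <- best$buffers
  list(model = model,
       history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)]),
       best_epoch = best$epoch)
}

#' Majority vote over patch labels
#'
#' Returns the modal label of the patch-level predictions for one ROI.  An
#' exact tie is resolved by `tie_rule`: `"prefer_tumor"` (default; favours
#' recall, the clinical priority) or `"first"` (first tied label in order of
#' appearance).  With the default odd `n = 25` a binary tie cannot occur.
#'
#' @param labels Non-empty character vector of class labels.
#' @param tie_rule `"prefer_tumor"` or `"first"`.
#' @return The winning label.
#' @export
majority_vote <- function(labels, tie_rule = c("prefer_tumor", "first")) {
  tie_rule <- match.arg(tie_rule)
  if (!length(labels)) stop("empty label list")
  lv <- unique(labels)
  cnt <- vapply(lv, function(l) sum(labels == l), 0L)
  tied <- lv[cnt == max(cnt)]
  if (length(tied) == 1L) return(tied)
  if (tie_rule == "prefer_tumor" && "Tumor" %in% tied) return("Tumor")
  tied[1L]
}

#' Classify one ROI by patch-level majority voting
#'
#' Samples `n` fresh patches from the ROI (centralized, no augmentation),
#' predicts each with the trained model, and votes.
#'
#' @param model A trained [build_model()] result.
#' @param roi A [mammo_roi()].
#' @param n Number of voting patches (default 25).
#' @param tie_rule See [majority_vote()].
#' @param seed Optional seed for the patch sample.
#' @return Object of class `voting_result`: `roi_ref`, `predicted_label`,
#'   `vote_fraction_tumor`, `n`, and `mean_tumor_prob` (the ROC/PR score).
#' @export
classify_roi <- function(model, roi, n = 25L, tie_rule = "prefer_tumor",
                         seed = NULL) {
  stop_if_not_scalar_count(n, "n")
  ps <- sample_patches(roi, n, size = model$input_side, centralize = TRUE,
                       seed = seed)
  probs <- predict_patch_probs(model, ps)
  labels <- model$classes[max.col(probs, ties.method = "first")]
  structure(list(roi_ref = roi$image_id,
                 predicted_label = majority_vote(labels, tie_rule),
                 vote_fraction_tumor = mean(labels == "Tumor"),
                 n = as.integer(n),
                 mean_tumor_prob = mean(probs[, "Tumor"])),
            class = "voting_result")
}

#' @export
print.voting_result <- function(x, ...) {
  cat(sprintf("<voting_result> %s -> %s (%.0f%% tumor votes of %d patches)\n",
              x$roi_ref, x$predicted_label, 100 * x$vote_fraction_tumor, x$n))
  invisible(x)
}

#' Continuous tumor score for one ROI
#'
#' Mean Tumor-class softmax probability over `n` sampled patches; the score
#' used for the ROI-level ROC/PR curves.
#'
#' @inheritParams classify_roi
#' @return A number in `[0, 1]`.
#' @export
roi_tumor_score <- function(model, roi, n = 25L, seed = NULL) {
  ps <- sample_patches(roi, n, size = model$input_side, centralize = TRUE,
                       seed = seed)
  mean(predict_patch_probs(model, ps)[, "Tumor"])
}

#' Confusion matrix and per-class metrics
#'
#' Binary evaluation with Tumor as the positive class: per-class recall
#' `TP_c / (TP_c + FN_c)`, precision `TP_c / (TP_c + FP_c)` (0 when the
#' class is never predicted), F1 (0 when precision + recall is 0), and
#' overall accuracy.
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   `"Normal"`/`"Tumor"`.
#' @return Object of class `eval_report` with `confusion`
#'   (`TN`, `FP`, `FN`, `TP`), `per_class` data frame, and `accuracy`.
#' @export
compute_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels) || !length(true_labels))
    stop("label vectors must have equal positive length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)),
                 c("Normal", "Tumor"))
  if (length(bad)) stop("labels must be Normal/Tumor; got ",
                        paste(bad, collapse = ", "))
  TP <- sum(true_labels == "Tumor" & predicted_labels == "Tumor")
  TN <- sum(true_labels == "Normal" & predicted_labels == "Normal")
  FP <- sum(true_labels == "Normal" & predicted_labels == "Tumor")
  FN <- sum(true_labels == "Tumor" & predicted_labels == "Normal")
  one_class <- function(tp, fn, fp) {
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    c(recall = recall, precision = precision, f1 = f1)
  }
  mN <- one_class(TN, FP, FN)
  mT <- one_class(TP, FN, FP)
  structure(list(
    confusion = c(TN = TN, FP = FP, FN = FN, TP = TP),
    per_class = data.frame(class = c("Normal", "Tumor"),
                           recall = c(mN["recall"], mT["recall"]),
                           precision = c(mN["precision"], mT["precision"]),
                           f1 = c(mN["f1"], mT["f1"]),
                           row.names = NULL),
    accuracy = (TP + TN) / length(true_labels)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  confusion: TN=%d FP=%d FN=%d TP=%d\n", x$confusion["TN"],
              x$confusion["FP"], x$confusion["FN"], x$confusion["TP"]))
  df <- x$per_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-6s recall %.4f  precision %.4f  F1 %.4f\n",
                df$class[i], round_half_up(df$recall[i]),
                round_half_up(df$precision[i]), round_half_up(df$f1[i])))
  cat(sprintf("  accuracy %.4f\n", round_half_up(x$accuracy)))
  invisible(x)
}

#' ROC and precision-recall curves
#'
#' Threshold sweep over the unique scores (predict Tumor when
#' `score >= threshold`), with trapezoidal areas under both curves.
#'
#' @param true_labels Character vector of `"Normal"`/`"Tumor"` (both classes
#'   must occur).
#' @param scores Numeric tumor scores in `[0, 1]`.
#' @return List with `roc` and `pr` data frames (one row per threshold) and
#'   `auc_roc`, `auc_pr`.
#' @export
roc_pr_curves <- function(true_labels, scores) {
  if (length(true_labels) != length(scores))
    stop("labels and scores must have equal length")
  P <- sum(true_labels == "Tumor")
  N <- sum(true_labels == "Normal")
  if (P == 0 || N == 0)
    stop("ROC/PR curves are undefined for single-class truth")
  ord <- order(scores, decreasing = TRUE)
  y <- true_labels[ord] == "Tumor"
  s <- scores[ord]
  # cumulative counts at each distinct threshold
  last <- which(diff(s) != 0)
  cut <- c(last, length(s))
  tp <- cumsum(y)[cut]
  fp <- cumsum(!y)[cut]
  roc <- data.frame(threshold = c(Inf, s[cut]), fpr = c(0, fp / N),
                    tpr = c(0, tp / P))
  auc_roc <- sum(diff(roc$fpr) * (head_(roc$tpr) + tail_(roc$tpr)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  pr <- data.frame(threshold = c(Inf, s[cut]),
                   recall = c(0, recall),
                   precision = c(precision[1], precision))
  auc_pr <- sum(diff(pr$recall) * (head_(pr$precision) + tail_(pr$precision)) / 2)
  list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Evaluate a trained model on a set of ROIs
#'
#' Classifies each ROI by `n`-patch majority voting (one patch sample per
#' ROI serves both the vote and the continuous tumor score) and assembles
#' the full evaluation report.
#'
#' @param model A trained model.
#' @param rois List of [mammo_roi()] objects.
#' @param n Voting patches per ROI (default 25).
#' @param tie_rule See [majority_vote()].
#' @param seed Optional seed for the evaluation patch samples.
#' @return List with `votes` (data frame), `report` ([compute_metrics()])
#'   and `curves` ([roc_pr_curves()], `NULL` for single-class truth).
#' @export
evaluate_rois <- function(model, rois, n = 25L, tie_rule = "prefer_tumor",
                          seed = NULL) {
  refs <- roi_refs(rois)
  with_seed(seed, {
    res <- lapply(seq_along(rois), function(i) {
      v <- classify_roi(model, rois[[i]], n, tie_rule)
      data.frame(roi_ref = refs[i], true = rois[[i]]$label,
                 predicted = v$predicted_label,
                 vote_fraction_tumor = v$vote_fraction_tumor,
                 score = v$mean_tumor_prob, stringsAsFactors = FALSE)
    })
    votes <- do.call(rbind, res)
    report <- compute_metrics(votes$true, votes$predicted)
    curves <- if (length(unique(votes$true)) == 2L)
      roc_pr_curves(votes$true, votes$score) else NULL
    list(votes = votes, report = report, curves = curves)
  })
}
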
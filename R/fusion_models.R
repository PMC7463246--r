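# Multi-branch fusion heads over a frozen convolutional backbone.
#
# Two fusion modes over the pooled output of each backbone block ("branch"):
#   fusion1: per-branch global average pooling (GAP), concatenated.
#   fusion2: per-branch batch norm -> 2x2 stride-2 average pool -> 1x1
#            convolution (ReLU, channel bottleneck) -> GAP, concatenated.
# Either way the concatenated vector feeds BN -> FC1 (ReLU) -> FC2 (ReLU) ->
# Output (softmax).  Backbone convolutions are frozen; only branch/head
# weights train.

BACKBONES <- list(
  vgg16 = list(widths = c(64L, 128L, 256L, 512L, 512L),
               convs = c(2L, 2L, 3L, 3L, 3L), kernel = 3L),
  vgg19 = list(widths = c(64L, 128L, 256L, 512L, 512L),
               convs = c(2L, 2L, 4L, 4L, 4L), kernel = 3L),
  tiny_test = list(widths = c(8L, 16L, 32L, 32L, 32L),
                   convs = c(1L, 1L, 1L, 1L, 1L), kernel = 3L))

BN_EPS <- 1e-5

#' Describe a fusion architecture
#'
#' @param backbone One of `"vgg16"`, `"vgg19"`, `"tiny_test"` (a miniature
#'   random 5-block backbone for tests and desk-scale experiments).
#' @param branches Ordered subset of `1:5`; which block outputs are fused.
#' @param mode `"fusion1"` (per-branch GAP) or `"fusion2"` (per-branch
#'   BN/avgpool/1x1-conv/GAP bottleneck).
#' @param bottleneck_channels 1x1-conv output channels per branch
#'   (fusion2 only; default 64).
#' @param fc1_width,fc2_width Hidden widths of the classification head
#'   (defaults 256 and 128).
#' @param n_classes Number of output classes (default 2).
#' @param pretrained Load pretrained backbone weights.  No offline weight
#'   source exists in this toolchain, so `TRUE` raises a dependency error;
#'   `FALSE` (default) initialises the backbone randomly (still frozen).
#' @return Object of class `fusion_spec`.
#' @export
fusion_spec <- function(backbone = c("tiny_test", "vgg16", "vgg19"),
                        branches = 1:5,
                        mode = c("fusion1", "fusion2"),
                        bottleneck_channels = 64L,
                        fc1_width = 256L, fc2_width = 128L,
                        n_classes = 2L, pretrained = FALSE) {
  backbone <- match.arg(backbone)
  mode <- match.arg(mode)
  branches <- sort(unique(as.integer(branches)))
  if (!length(branches) || !all(branches %in% 1:5))
    stop("`branches` must be a non-empty subset of 1:5")
  if (mode == "fusion2")
    stop_if_not_scalar_count(bottleneck_channels, "bottleneck_channels")
  stop_if_not_scalar_count(fc1_width, "fc1_width")
  stop_if_not_scalar_count(fc2_width, "fc2_width")
  stop_if_not_scalar_count(n_classes, "n_classes", min = 2L)
  structure(list(backbone = backbone, branches = branches, mode = mode,
                 bottleneck_channels = as.integer(bottleneck_channels),
                 fc1_width = as.integer(fc1_width),
                 fc2_width = as.integer(fc2_width),
                 n_classes = as.integer(n_classes),
                 pretrained = isTRUE(pretrained)),
            class = "fusion_spec")
}

#' @export
print.fusion_spec <- function(x, ...) {
  cat(sprintf("<fusion_spec> %s %s, branches {%s}, fused width %d\n",
              x$backbone, x$mode, paste(x$branches, collapse = ","),
              fused_dimension(x)))
  invisible(x)
}

#' Width of the concatenated fused feature vector
#'
#' For `fusion1` this is the sum of the backbone block channel counts over
#' the selected branches (VGG blocks: 64, 128, 256, 512, 512); for
#' `fusion2` it is `length(branches) * bottleneck_channels`.
#'
#' @param spec A [fusion_spec()].
#' @return Integer width.
#' @export
fused_dimension <- function(spec) {
  bb <- BACKBONES[[spec$backbone]]
  if (is.null(bb)) stop("unknown backbone: ", spec$backbone)
  if (spec$mode == "fusion1") sum(bb$widths[spec$branches])
  else length(spec$branches) * spec$bottleneck_channels
}

# uniform fan-in initialisation, the stated scheme for all trainable weights
init_mat <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Assemble a fusion model
#'
#' Builds the frozen backbone (random weights unless pretrained weights were
#' requested) and the randomly initialised trainable branch/head layers.
#' Initialisation is deterministic given `seed`.
#'
#' @param spec A [fusion_spec()].
#' @param input_side Expected patch side (default 72).
#' @param seed Optional seed for weight initialisation.
#' @return Object of class `fusion_model` with fields `spec`, `backbone`
#'   (frozen), `params` (trainable), `buffers` (BN running statistics).
#' @export
build_model <- function(spec, input_side = 72L, seed = NULL) {
  stopifnot(inherits(spec, "fusion_spec"))
  if (spec$pretrained)
    stop("pretrained backbone weights are not available in this ",
         "offline toolchain; build with pretrained = FALSE ",
         "(random frozen backbone)")
  bb <- BACKBONES[[spec$backbone]]
  side <- as.integer(input_side)
  if (side %/% 2L^5L < 1L)
    stop("input side too small for a 5-block stride-2 backbone")
  with_seed(seed, {
    backbone <- list()
    cin <- 3L
    for (blk in 1:5) {
      convs <- list()
      for (cv in seq_len(bb$convs[blk])) {
        cout <- bb$widths[blk]
        k <- bb$kernel
        fan <- k * k * cin
        W <- array(runif(k * k * cin * cout, -1, 1) * sqrt(6 / fan),
                   c(k, k, cin, cout))
        convs[[cv]] <- list(W = W, b = numeric(cout))
        cin <- cout
      }
      backbone[[blk]] <- list(convs = convs)
    }
    params <- list()
    buffers <- list()
    if (spec$mode == "fusion2") {
      for (b in spec$branches) {
        cb <- bb$widths[b]
        params[[sprintf("branch%d.bn.gamma", b)]] <- rep(1, cb)
        params[[sprintf("branch%d.bn.beta", b)]] <- rep(0, cb)
        params[[sprintf("branch%d.conv1x1.W", b)]] <-
          init_mat(cb, spec$bottleneck_channels, cb)
        params[[sprintf("branch%d.conv1x1.b", b)]] <-
          numeric(spec$bottleneck_channels)
        buffers[[sprintf("branch%d.bn.running_mean", b)]] <- rep(0, cb)
        buffers[[sprintf("branch%d.bn.running_var", b)]] <- rep(1, cb)
      }
    }
    D <- fused_dimension(spec)
    params[["head.bn.gamma"]] <- rep(1, D)
    params[["head.bn.beta"]] <- rep(0, D)
    buffers[["head.bn.running_mean"]] <- rep(0, D)
    buffers[["head.bn.running_var"]] <- rep(1, D)
    params[["head.fc1.W"]] <- init_mat(D, spec$fc1_width, D)
    params[["head.fc1.b"]] <- numeric(spec$fc1_width)
    params[["head.fc2.W"]] <- init_mat(spec$fc1_width, spec$fc2_width,
                                       spec$fc1_width)
    params[["head.fc2.b"]] <- numeric(spec$fc2_width)
    params[["head.out.W"]] <- init_mat(spec$fc2_width, spec$n_classes,
                                       spec$fc2_width)
    params[["head.out.b"]] <- numeric(spec$n_classes)
    structure(list(spec = spec, backbone = backbone, params = params,
                   buffers = buffers, input_side = side,
                   classes = c("Normal", "Tumor")[seq_len(min(spec$n_classes, 2))]),
              class = "fusion_model")
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  nf <- sum(vapply(frozen_parameter_names(x), function(nm) 1L, 1L))
  cat(sprintf("<fusion_model> %s %s: %d trainable values in %d tensors, %d frozen tensors\n",
              x$spec$backbone, x$spec$mode, np, length(x$params), nf))
  invisible(x)
}

#' Names of trainable parameters
#'
#' Excludes every backbone convolution weight (those are frozen); contains
#' the post-concatenation BN, FC1, FC2 and Output weights, plus — in
#' fusion2 — the per-branch BN and 1x1-conv weights.
#'
#' @param model A [build_model()] result.
#' @return Character vector of parameter names.
#' @export
trainable_parameter_names <- function(model) names(model$params)

#' Names of frozen (backbone) parameters
#'
#' @param model A [build_model()] result.
#' @return Character vector like `backbone.block1.conv1.W`.
#' @export
frozen_parameter_names <- function(model) {
  out <- character()
  for (blk in seq_along(model$backbone))
    for (cv in seq_along(model$backbone[[blk]]$convs))
      out <- c(out, sprintf("backbone.block%d.conv%d.W", blk, cv),
               sprintf("backbone.block%d.conv%d.b", blk, cv))
  out
}

# patches argument -> (H, W, 3, N) array with the grayscale channel
# replicated, as VGG-style backbones expect
as_patch_array <- function(patches, side) {
  px <- if (inherits(patches, "patch_set")) patches$pixels else patches
  d <- dim(px)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("patches must be a patch_set or a 3-d/4-d array")
  if (d[1] != side || d[2] != side)
    stop(sprintf("patch spatial size %d x %d does not match the model's %d",
                 d[1], d[2], side))
  if (length(d) == 4L) return(px)
  n <- d[3]
  out <- array(0, c(side, side, 3L, n))
  for (c in 1:3) out[, , c, ] <- px
  out
}

# forward through the frozen backbone; returns pooled maps for the selected
# branches as a named list of (H, W, C, N) arrays
backbone_branch_maps <- function(model, x) {
  maps <- list()
  top <- max(model$spec$branches)
  for (blk in seq_len(top)) {
    for (cv in model$backbone[[blk]]$convs)
      x <- conv2d_same_cpp(x, cv$W, cv$b, TRUE)
    x <- pool2_cpp(x, 0L)
    if (blk %in% model$spec$branches)
      maps[[as.character(blk)]] <- x
  }
  maps
}

# (H, W, C, N) array -> (H*W*N) x C matrix, rows grouped per item
# (spatial index fastest); inverse grouping via rep(seq_len(N), each = H*W)
map_to_rows <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 2, 4, 3)), nrow = d[1] * d[2] * d[4], ncol = d[3])
}

bn_affine <- function(x, mean, var, gamma, beta) {
  s <- gamma / sqrt(var + BN_EPS)
  affine_cols_cpp(x, s, beta - mean * s, FALSE)
}

col_affine <- function(x, scale, offset) affine_cols_cpp(x, scale, offset, FALSE)
bias_relu <- function(x, b) affine_cols_cpp(x, rep(1, length(b)), b, TRUE)
bias_add <- function(x, b) affine_cols_cpp(x, rep(1, length(b)), b, FALSE)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fused feature vectors for a batch of patches (inference mode)
#'
#' Runs the frozen backbone and the per-branch fusion path (GAP for
#' fusion1; BN with running statistics, average pool, 1x1 conv, GAP for
#' fusion2) and concatenates the branches.
#'
#' @param model A [build_model()] result.
#' @param patches A [patch_set()] or array of centralized patches.
#' @return Numeric matrix `n x fused_dimension(spec)`.
#' @export
patch_features <- function(model, patches) {
  x <- as_patch_array(patches, model$input_side)
  n <- dim(x)[4]
  if (n == 0L)
    return(matrix(0, 0, fused_dimension(model$spec)))
  maps <- backbone_branch_maps(model, x)
  feats <- list()
  for (b in model$spec$branches) {
    m <- maps[[as.character(b)]]
    if (model$spec$mode == "fusion1") {
      feats[[length(feats) + 1L]] <- gap_cpp(m)
    } else {
      pooled <- pool2_cpp(m, 1L)
      d <- dim(pooled)
      X <- map_to_rows(pooled)
      z <- bn_affine(X,
                     model$buffers[[sprintf("branch%d.bn.running_mean", b)]],
                     model$buffers[[sprintf("branch%d.bn.running_var", b)]],
                     model$params[[sprintf("branch%d.bn.gamma", b)]],
                     model$params[[sprintf("branch%d.bn.beta", b)]])
      a <- bias_relu(z %*% model$params[[sprintf("branch%d.conv1x1.W", b)]],
                     model$params[[sprintf("branch%d.conv1x1.b", b)]])
      g <- rowsum(a, rep(seq_len(n), each = d[1] * d[2]),
                  reorder = FALSE) / (d[1] * d[2])
      feats[[length(feats) + 1L]] <- g
    }
  }
  do.call(cbind, feats)
}

head_forward_infer <- function(model, F) {
  p <- model$params
  z <- bn_affine(F, model$buffers[["head.bn.running_mean"]],
                 model$buffers[["head.bn.running_var"]],
                 p[["head.bn.gamma"]], p[["head.bn.beta"]])
  h1 <- bias_relu(z %*% p[["head.fc1.W"]], p[["head.fc1.b"]])
  h2 <- bias_relu(h1 %*% p[["head.fc2.W"]], p[["head.fc2.b"]])
  bias_add(h2 %*% p[["head.out.W"]], p[["head.out.b"]])
}

#' Class probabilities for a batch of patches
#'
#' Deterministic inference: BN layers use running statistics; each output
#' row is a softmax probability vector.
#'
#' @param model A (typically trained) [build_model()] result.
#' @param patches A [patch_set()] or centralized patch array.
#' @return Matrix `n x n_classes` with columns `Normal`, `Tumor`.
#' @export
predict_patch_probs <- function(model, patches) {
  F <- patch_features(model, patches)
  if (nrow(F) == 0L) {
    out <- matrix(0, 0, model$spec$n_classes)
    colnames(out) <- model$classes
    return(out)
  }
  probs <- softmax_rows(head_forward_infer(model, F))
  colnames(probs) <- model$classes
  probs
}
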
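# Independent oracle implementations, deliberately written as plain,
# straightforward R so they share no code with the package internals.

reflect_index <- function(i, n) {
  # symmetric (edge-including) reflection into 1..n, for 1-based i
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force per-window median with reflected borders
oracle_median <- function(img, k) {
  H <- nrow(img); W <- ncol(img); r <- (k - 1) / 2
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, img[reflect_index(i + di, H), reflect_index(j + dj, W)])
    out[i, j] <- sort(vals)[(k * k + 1) / 2]
  }
  out
}

# reference CLAHE: same algorithm definition, independent code path
oracle_clahe <- function(img, clip_limit, tiles_r, tiles_c) {
  H <- nrow(img); W <- ncol(img)
  th <- ceiling(H / tiles_r); tw <- ceiling(W / tiles_c)
  npix <- th * tw
  clip <- max(1, clip_limit * npix / 256)
  luts <- array(0, c(tiles_r, tiles_c, 256))
  for (tr in 1:tiles_r) for (tc in 1:tiles_c) {
    hist <- numeric(256)
    for (i in 1:th) for (j in 1:tw) {
      v <- img[reflect_index((tr - 1) * th + i, H),
               reflect_index((tc - 1) * tw + j, W)]
      hist[v + 1] <- hist[v + 1] + 1
    }
    excess <- sum(pmax(hist - clip, 0))
    hist <- pmin(hist, clip) + excess / 256
    luts[tr, tc, ] <- cumsum(hist) * 255 / npix
  }
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gy <- (i - 0.5) / th - 0.5
    gx <- (j - 0.5) / tw - 0.5
    y0 <- floor(gy); wy <- gy - y0
    x0 <- floor(gx); wx <- gx - x0
    y1 <- y0 + 1; x1 <- x0 + 1
    if (y0 < 0) { y0 <- 0; y1 <- 0; wy <- 0 }
    if (y1 > tiles_r - 1) { y1 <- tiles_r - 1; y0 <- min(y0, y1) }
    if (x0 < 0) { x0 <- 0; x1 <- 0; wx <- 0 }
    if (x1 > tiles_c - 1) { x1 <- tiles_c - 1; x0 <- min(x0, x1) }
    v <- img[i, j] + 1
    val <- (1 - wy) * ((1 - wx) * luts[y0 + 1, x0 + 1, v] +
                         wx * luts[y0 + 1, x1 + 1, v]) +
      wy * ((1 - wx) * luts[y1 + 1, x0 + 1, v] +
              wx * luts[y1 + 1, x1 + 1, v])
    out[i, j] <- floor(min(max(val, 0), 255) + 0.5)
  }
  out
}

# count-and-argmax majority vote with prefer-Tumor ties
oracle_vote <- function(labels) {
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if ("Tumor" %in% winners && length(winners) > 1) return("Tumor")
  if (length(winners) == 1) return(winners)
  winners[1]
}

# exhaustive search over integer confusion matrices with fixed class margins
# that reproduce a set of printed metric values at 4 decimals (half-up)
backsolve_confusion <- function(n_normal, n_tumor, printed) {
  r4 <- function(x) floor(x * 1e4 + 0.5) / 1e4
  hits <- list()
  for (TN in 0:n_normal) for (TP in 0:n_tumor) {
    FP <- n_normal - TN; FN <- n_tumor - TP
    acc <- (TN + TP) / (n_normal + n_tumor)
    t_rec <- if (n_tumor > 0) TP / n_tumor else 0
    t_prec <- if (TP + FP > 0) TP / (TP + FP) else 0
    t_f1 <- if (t_prec + t_rec > 0) 2 * t_prec * t_rec / (t_prec + t_rec) else 0
    ok <- TRUE
    if (!is.null(printed$acc)) ok <- ok && r4(acc) == printed$acc
    if (!is.null(printed$t_recall)) ok <- ok && r4(t_rec) == printed$t_recall
    if (!is.null(printed$t_precision))
      ok <- ok && r4(t_prec) == printed$t_precision
    if (!is.null(printed$t_f1)) ok <- ok && r4(t_f1) == printed$t_f1
    if (ok) hits[[length(hits) + 1]] <- c(TN = TN, TP = TP)
  }
  hits
}
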
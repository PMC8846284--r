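#' @include AllClasses.R AllGenerics.R registration.R
NULL

# ---- feature extraction for the learned backend -------------------------

# per-voxel feature matrix: raw intensity, two box-smoothed scales
# (local context) and normalized spatial coordinates
#' @keywords internal
voxelFeatures <- function(mri) {
  a <- volData(mri)
  d <- dim(a)
  b1 <- boxBlur3(a, 1)
  b2 <- boxBlur3(b1, 2)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  cbind(int = as.vector(a), blur1 = as.vector(b1), blur2 = as.vector(b2),
        x = idx[, 1] / d[1], y = idx[, 2] / d[2], z = idx[, 3] / d[3])
}

# single-hidden-layer softmax network trained by full-batch gradient
# descent with momentum; returns weights and the per-epoch loss history
#' @keywords internal
trainSoftmaxNet <- function(X, y, nClasses, hidden = 16L, epochs = 30L,
                            lr = 0.5, momentum = 0.9, seed = 1L) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  W1 <- matrix(stats::rnorm(p * hidden, 0, 0.3), p, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(stats::rnorm(hidden * nClasses, 0, 0.3), hidden, nClasses)
  b2 <- rep(0, nClasses)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  Y <- matrix(0, n, nClasses); Y[cbind(seq_len(n), y)] <- 1
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    H <- tanh(sweep(X %*% W1, 2, b1, `+`))
    S <- sweep(H %*% W2, 2, b2, `+`)
    S <- S - apply(S, 1, max)
    P <- exp(S); P <- P / rowSums(P)
    loss[e] <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
    if (!is.finite(loss[e]))
      stop("non-finite training loss; aborting segmenter training", call. = FALSE)
    G <- (P - Y) / n
    gW2 <- t(H) %*% G; gb2 <- colSums(G)
    GH <- (G %*% t(W2)) * (1 - H^2)
    gW1 <- t(X) %*% GH; gb1 <- colSums(GH)
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, loss = loss)
}

#' @keywords internal
predictSoftmaxNet <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2, net$b1, `+`))
  S <- sweep(H %*% net$W2, 2, net$b2, `+`)
  S
}

#' Segmenter training settings
#'
#' @param epochs gradient-descent epochs.
#' @param hidden hidden units of the voxel classifier.
#' @param voxelsPerClass training voxels sampled per class per volume.
#' @param backgroundFactor multiple of `voxelsPerClass` sampled for the
#'   background class, which covers the whole field of view.
#' @param lr,momentum optimizer settings.
#' @param seed RNG seed (sampling and weight initialization).
#' @return list of settings.
#' @export
segmenterConfig <- function(epochs = 60L, hidden = 24L,
                            voxelsPerClass = 1500L, backgroundFactor = 8L,
                            lr = 0.5, momentum = 0.9, seed = 1L) {
  list(epochs = epochs, hidden = hidden, voxelsPerClass = voxelsPerClass,
       backgroundFactor = backgroundFactor, lr = lr, momentum = momentum,
       seed = seed)
}

#' Train the learned segmentation backend
#'
#' Fits a compact neural voxel classifier: each voxel is described by a
#' multiscale feature vector (raw intensity, two box-smoothed context
#' scales, normalized coordinates) and classified into the 10 regions or
#' background by a single-hidden-layer softmax network trained by seeded
#' full-batch gradient descent. Training voxels are subsampled per class
#' from every training pair. Deterministic given the config seed; the
#' per-epoch loss history is stored on the model.
#'
#' @param trainingPairs list of `list(mri = VolumeImage, labels = LabelMap)`
#'   with identical grid shapes; at least 2 pairs.
#' @param config settings from [segmenterConfig()].
#' @return a [SegmenterModel-class] with backend "learned".
#' @export
trainSegmenter <- function(trainingPairs, config = segmenterConfig()) {
  stopIfNot(length(trainingPairs) >= 2L,
            "at least 2 training pairs are required")
  dims <- lapply(trainingPairs, function(p) dim(p$mri))
  stopIfNot(all(vapply(dims, identical, TRUE, dims[[1]])),
            "training pairs must share one grid shape")
  ct <- codeTable(trainingPairs[[1]]$labels)
  codes <- c(0L, sort(ct$code))
  Xs <- list(); ys <- list()
  set.seed(deriveSeed(config$seed, "sample"))
  for (p in trainingPairs) {
    X <- voxelFeatures(p$mri)
    lab <- as.vector(volData(p$labels))
    for (ci in seq_along(codes)) {
      vox <- which(lab == codes[ci])
      if (!length(vox)) next
      # with-replacement upsampling keeps the nuclei balanced (tiny ones
      # would be swamped otherwise); the background keeps a larger quota
      # because it must be learned over the whole field of view, and half
      # of it is mined from the boundary shells around bright structures,
      # where the smoothed context features are ambiguous
      quota <- config$voxelsPerClass *
        if (codes[ci] == 0L) config$backgroundFactor else 1L
      if (codes[ci] == 0L) {
        hard <- vox[X[vox, "blur1"] - X[vox, "int"] > 5]
        nHard <- min(length(hard), quota %/% 2L)
        takeHard <- if (nHard > 0)
          hard[sample.int(length(hard), nHard)] else integer()
        takeUnif <- vox[sample.int(length(vox), quota - nHard)]
        take <- c(takeHard, takeUnif)
      } else {
        take <- vox[sample.int(length(vox), quota,
                               replace = length(vox) < quota)]
      }
      Xs[[length(Xs) + 1L]] <- X[take, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep(ci, length(take))
    }
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  mu <- colMeans(X); sd_ <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs_ <- sweep(sweep(X, 2, mu, `-`), 2, sd_, `/`)
  net <- trainSoftmaxNet(Xs_, y, length(codes), hidden = config$hidden,
                         epochs = config$epochs, lr = config$lr,
                         momentum = config$momentum,
                         seed = deriveSeed(config$seed, "init"))
  new("SegmenterModel", backend = "learned",
      fit = list(net = net, mu = mu, sd = sd_, codes = codes,
                 codeTable = ct, lossHistory = net$loss,
                 gridShape = dims[[1]], config = config))
}

#' Build an atlas segmentation backend
#'
#' The zero-training default: a reference MRI with its label map. Targets
#' are segmented by rigidly registering the reference MRI to the target and
#' propagating the reference labels by nearest neighbor.
#'
#' @param referenceMri a [VolumeImage-class].
#' @param referenceLabels the matching [LabelMap-class].
#' @param regConfig registration settings ([registrationConfig()]).
#' @return a [SegmenterModel-class] with backend "atlas".
#' @export
atlasSegmenter <- function(referenceMri, referenceLabels,
                           regConfig = registrationConfig()) {
  stopIfNot(identical(dim(referenceMri), dim(referenceLabels)),
            "reference MRI and labels must share a grid")
  new("SegmenterModel", backend = "atlas",
      fit = list(mri = referenceMri, labels = referenceLabels,
                 regConfig = regConfig))
}

#' Segment an anatomical volume into the 10 ROIs
#'
#' Applies a fitted [SegmenterModel-class]. The learned backend scores
#' every voxel and takes the arg-max class, breaking exact score ties by
#' the lowest region code; the atlas backend registers its reference MRI to
#' the target and propagates labels. A constant (e.g. all-zero) input
#' yields an all-background map with one warning per missing region; any
#' expected region that comes out empty is likewise warned about and listed
#' in the `missingRegions` attribute.
#'
#' @param model a [SegmenterModel-class].
#' @param mri target [VolumeImage-class].
#' @return a [LabelMap-class] on the target grid.
#' @export
segment <- function(model, mri) {
  ct <- if (model@backend == "learned") model@fit$codeTable else
    codeTable(model@fit$labels)
  if (diff(range(volData(mri))) == 0) {
    out <- labelMap(array(0L, dim(mri)), voxelSpacing(mri), volOrigin(mri),
                    codeTable = ct)
    return(flagMissingRegions(out, ct))
  }
  if (model@backend == "atlas") {
    tr <- registerRigid(model@fit$mri, mri, model@fit$regConfig)
    out <- suppressWarnings(resampleLabels(model@fit$labels, tr, mri))
    return(flagMissingRegions(out, ct))
  }
  stopIfNot(identical(dim(mri), model@fit$gridShape),
            "MRI grid incompatible with the trained model")
  X <- voxelFeatures(mri)
  X <- sweep(sweep(X, 2, model@fit$mu, `-`), 2, model@fit$sd, `/`)
  lab <- integer(nrow(X))
  codes <- model@fit$codes  # ascending; ties.method "first" => lowest code
  chunk <- 65536L
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    S <- predictSoftmaxNet(model@fit$net, X[s:e, , drop = FALSE])
    lab[s:e] <- codes[max.col(S, ties.method = "first")]
  }
  out <- labelMap(array(lab, dim(mri)), voxelSpacing(mri), volOrigin(mri),
                  codeTable = ct)
  flagMissingRegions(out, ct)
}

#' @keywords internal
flagMissingRegions <- function(labels, ct) {
  present <- unique(as.vector(volData(labels)))
  lost <- ct$code[!ct$code %in% present]
  for (code in lost)
    warning(sprintf("region %s %s missing from segmentation",
                    ct$region[ct$code == code], ct$side[ct$code == code]),
            call. = FALSE)
  attr(labels, "missingRegions") <- lost
  labels
}

#' Dice overlap coefficient between two label maps
#'
#' @param pred,truth [LabelMap-class] objects on the same grid (or integer
#'   arrays).
#' @param codes region codes to evaluate (default: all nonzero codes in
#'   `truth`).
#' @return named numeric vector of per-region Dice coefficients.
#' @export
diceCoefficient <- function(pred, truth, codes = NULL) {
  p <- if (is(pred, "VolumeImage")) volData(pred) else pred
  t_ <- if (is(truth, "VolumeImage")) volData(truth) else truth
  if (is.null(codes)) codes <- setdiff(sort(unique(as.vector(t_))), 0L)
  vapply(codes, function(cd) {
    a <- p == cd; b <- t_ == cd
    denom <- sum(a) + sum(b)
    if (denom == 0) return(NA_real_)
    2 * sum(a & b) / denom
  }, 0, USE.NAMES = FALSE) -> d
  names(d) <- codes
  d
}
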
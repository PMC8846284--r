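#' @include AllClasses.R AllGenerics.R classification.R
NULL

#' Importance-analysis settings
#'
#' @param nTrees trees per forest.
#' @param nRep seeded forest fits averaged to stabilize the ranking.
#' @param method "impurity" (mean decrease in impurity, default) or
#'   "permutation" (mean decrease in accuracy).
#' @param seed master seed; per-repetition seeds are derived from it.
#' @return list of settings.
#' @export
importanceConfig <- function(nTrees = 500L, nRep = 10L,
                             method = c("impurity", "permutation"),
                             seed = 1L) {
  list(nTrees = as.integer(nTrees), nRep = as.integer(nRep),
       method = match.arg(method), seed = as.integer(seed))
}

#' Per-subregion contribution to the classification
#'
#' Fits `nRep` seeded random forests to the 14 striatal SOR features,
#' normalizes each fit's importance values to sum to one, averages across
#' fits, and aggregates bilaterally and by nucleus with
#' [aggregateContributions()].
#'
#' @param X feature matrix or table with the 14 striatal SOR columns.
#' @param y class labels (>= 2 classes).
#' @param config settings from [importanceConfig()].
#' @return an `ImportanceTable`: list with `perFeature` (named, sums to 1),
#'   `bilateral` and `nucleus` aggregates (proportions), and their
#'   percentage views.
#' @export
featureContributions <- function(X, y, config = importanceConfig()) {
  X <- featureMatrix(X)
  y <- droplevels(factor(y))
  stopIfNot(nlevels(y) >= 2L, "need at least 2 classes")
  expected <- featureColumns("striatum")
  stopIfNot(all(expected %in% colnames(X)),
            sprintf("missing striatal features: %s",
                    paste(setdiff(expected, colnames(X)), collapse = ", ")))
  X <- X[, expected, drop = FALSE]
  acc <- rep(0, ncol(X))
  for (r in seq_len(config$nRep)) {
    set.seed(deriveSeed(config$seed, "forest", r))
    rf <- randomForest::randomForest(X, y, ntree = config$nTrees,
                                     importance = config$method == "permutation")
    imp <- if (config$method == "impurity")
      randomForest::importance(rf, type = 2)[, 1]
    else
      randomForest::importance(rf, type = 1)[, 1]
    imp <- pmax(imp, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
    acc <- acc + imp
  }
  per <- acc / config$nRep
  if (sum(per) > 0) per <- per / sum(per)
  names(per) <- colnames(X)
  out <- aggregateContributions(per)
  out$perFeature <- per
  structure(out, class = "ImportanceTable")
}

#' @export
print.ImportanceTable <- function(x, ...) {
  cat("ImportanceTable (bilateral aggregates, %):\n")
  print(x$bilateralPercent)
  cat("nucleus aggregates (%):\n")
  print(x$nucleusPercent)
  invisible(x)
}

#' Aggregate per-feature contributions bilaterally and by nucleus
#'
#' Sums the 14 per-side subregion contributions into 7 bilateral values
#' (anterior/middle/posterior caudate and putamen, pallidum) and 3 nucleus
#' totals (caudate, putamen, pallidum). Percentages are rounded half away
#' from zero to one decimal, the precision of published contribution
#' tables. Aggregation is exact summation, hence linear.
#'
#' @param perFeature named numeric(14), keys `sor_<nucleus>_<third>_<R|L>`
#'   (or the same without the `sor_` prefix), all nonnegative.
#' @return list with `bilateral`, `nucleus` (proportions) and
#'   `bilateralPercent`, `nucleusPercent` (rounded percentages).
#' @export
aggregateContributions <- function(perFeature) {
  keys <- names(perFeature)
  stopIfNot(!is.null(keys), "perFeature must be named")
  keys <- sub("^sor_", "", keys)
  expected <- sub("^sor_", "", featureColumns("striatum"))
  unknown <- setdiff(keys, expected)
  stopIfNot(length(unknown) == 0,
            sprintf("unknown feature key(s): %s", paste(unknown, collapse = ", ")))
  stopIfNot(all(perFeature >= 0), "contributions must be nonnegative")
  names(perFeature) <- keys
  bilKeys <- c(splitSubregionKeys(), "pallidum")
  bilateral <- vapply(bilKeys, function(k)
    sum(perFeature[paste0(k, c("_R", "_L"))]), 0)
  nucleus <- c(caudate = sum(bilateral[grep("^caudate", bilKeys)]),
               putamen = sum(bilateral[grep("^putamen", bilKeys)]),
               pallidum = unname(bilateral["pallidum"]))
  list(bilateral = bilateral, nucleus = nucleus,
       bilateralPercent = asPercent(bilateral),
       nucleusPercent = asPercent(nucleus))
}

#' Exact McNemar test on discordant pairs
#'
#' Paired comparison of two classifiers on the same subjects: with `b`
#' subjects correct only under the first and `c` correct only under the
#' second, the exact two-sided p-value is `min(1, 2 P(X <= min(b, c)))`
#' for `X ~ Binomial(b + c, 1/2)`; `b + c = 0` gives p = 1. The
#' continuity-corrected chi-squared variant is available for large
#' discordant counts.
#'
#' @param b,c discordant counts.
#' @param method "exact" (default) or "chisq".
#' @return list(p, b, c, method).
#' @export
mcnemarExact <- function(b, c, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopIfNot(b >= 0 && c >= 0 && b == round(b) && c == round(c),
            "b and c must be nonnegative integers")
  n <- b + c
  p <- if (n == 0) 1 else if (method == "exact") {
    min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p = p, b = b, c = c, method = method)
}

#' Does adding the midbrain help the multiclass diagnosis?
#'
#' Runs leave-one-out multiclass classification on the
#' striatum-plus-midbrain (16), striatum-only (14) and midbrain-only (2)
#' feature sets of the same subjects and compares per-subject correctness
#' of the first two arms with the exact McNemar test.
#'
#' @param features16,features14,features2 feature tables for identical
#'   subjects (matched on `subject_id`).
#' @param y class labels in the row order of the tables.
#' @param config settings from [classifierConfig()].
#' @return list with per-arm accuracies, the McNemar result and the two
#'   compared `ClassificationResult`s.
#' @export
midbrainAddonTest <- function(features16, features14, features2, y,
                              config = classifierConfig()) {
  ids <- features16$subject_id
  stopIfNot(!is.null(ids) && identical(ids, features14$subject_id) &&
              identical(ids, features2$subject_id),
            "feature tables must cover identical subjects in the same order")
  arms <- list(striatum_midbrain = features16, striatum = features14,
               midbrain = features2)
  res <- lapply(arms, function(ft) loocv(ft, y, config, ids = ids))
  acc <- vapply(res, function(r) mean(r$predicted == r$true), 0)
  ok16 <- res$striatum_midbrain$predicted == res$striatum_midbrain$true
  ok14 <- res$striatum$predicted == res$striatum$true
  b <- sum(ok16 & !ok14)  # correct with midbrain only
  c_ <- sum(!ok16 & ok14)
  list(accuracy = acc, mcnemar = mcnemarExact(b, c_),
       results = res[c("striatum_midbrain", "striatum")])
}

#' Paint bilateral contributions into a volume
#'
#' Produces the voxelwise "contribution map": every voxel of each split
#' subregion (and the pallidum) is set to its bilateral aggregate
#' percentage, for rendering in external viewers.
#'
#' @param submap a [SubregionMap-class].
#' @param importance an `ImportanceTable`.
#' @return a [VolumeImage-class] of contribution percentages.
#' @export
contributionMap <- function(submap, importance) {
  ct <- codeTable(submap)
  grid <- volData(submap)
  out <- array(0, dim(grid))
  for (i in seq_len(nrow(ct))) {
    key <- if (ct$subregion[i] == "whole") ct$region[i] else
      paste(ct$region[i], ct$subregion[i], sep = "_")
    if (!key %in% names(importance$bilateralPercent)) next
    out[grid == ct$code[i]] <- importance$bilateralPercent[[key]]
  }
  volumeImage(out, voxelSpacing(submap), volOrigin(submap))
}
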
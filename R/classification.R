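#' @include AllClasses.R AllGenerics.R evaluation.R
NULL

#' Classifier settings
#'
#' @param costGrid candidate values of the squared-hinge cost parameter;
#'   selected by inner stratified cross-validation (a length-1 grid fixes
#'   the cost).
#' @param innerFolds folds of the inner cross-validation.
#' @param seed RNG seed (fold assignment, backend seeding).
#' @param backend "svm" (linear, squared hinge; default), "logistic"
#'   (multinomial logistic regression) or "rf" (random forest). Alternative
#'   backends share the interface for algorithm comparisons; the SVM is the
#'   reference classifier.
#' @param classWeight if TRUE, per-sample weights inversely proportional to
#'   class frequency (default FALSE: no reweighting).
#' @return list of settings.
#' @export
classifierConfig <- function(costGrid = 10^seq(-3, 3), innerFolds = 5L,
                             seed = 1L, backend = c("svm", "logistic", "rf"),
                             classWeight = FALSE) {
  backend <- match.arg(backend)
  stopIfNot(length(costGrid) >= 1L, "costGrid must be nonempty")
  list(costGrid = costGrid, innerFolds = as.integer(innerFolds),
       seed = as.integer(seed), backend = backend, classWeight = classWeight)
}

# ---- squared-hinge linear SVM (primal, BFGS) ----------------------------

# minimize 0.5 ||w||^2 + C sum_i s_i max(0, 1 - y_i (x_i.w + b))^2
# convex and differentiable; solved deterministically by BFGS
#' @keywords internal
svmSquaredHinge <- function(X, y, C, sampleWeight = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(sampleWeight)) sampleWeight <- rep(1, n)
  fn <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + C * sum(sampleWeight * xi^2)
  }
  gr <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
    coef <- 2 * C * sampleWeight * xi * y
    c(w - drop(crossprod(X, coef)), -sum(coef))
  }
  opt <- stats::optim(rep(0, p + 1), fn, gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(w = opt$par[1:p], b = opt$par[p + 1])
}

# ---- model fitting -------------------------------------------------------

#' Extract the numeric feature matrix from a feature table
#'
#' @param features feature data.frame (columns `sor_*` and optionally
#'   `ai_*`) or an already-numeric matrix.
#' @param includeAsymmetry use `ai_` columns as classifier inputs.
#' @return numeric matrix, rows named by `subject_id` when available.
#' @export
featureMatrix <- function(features, includeAsymmetry = FALSE) {
  if (is.matrix(features)) return(features)
  pats <- if (includeAsymmetry) "^(sor|ai)_" else "^sor_"
  cols <- grep(pats, names(features), value = TRUE)
  X <- as.matrix(features[, cols, drop = FALSE])
  if (!is.null(features$subject_id)) rownames(X) <- features$subject_id
  X
}

#' Fit the diagnostic classifier
#'
#' Standardizes features (mean 0, SD 1 computed on the training rows only;
#' constant columns are centered and get zero weight), selects the cost
#' parameter by inner stratified cross-validation over `costGrid`, then
#' fits one-vs-rest linear squared-hinge SVMs (or the configured
#' alternative backend). Deterministic given `config$seed`.
#'
#' @param X numeric feature matrix (or feature data.frame).
#' @param y class labels (coerced to factor; >= 2 classes required).
#' @param config settings from [classifierConfig()].
#' @return a fitted model of class `cftClassifier`.
#' @export
fitClassifier <- function(X, y, config = classifierConfig()) {
  X <- featureMatrix(X)
  stopIfNot(!anyNA(X), "missing feature values")
  y <- droplevels(factor(y))
  stopIfNot(nlevels(y) >= 2L, "training set contains a single class")
  stopIfNot(nrow(X) == length(y), "X rows and labels differ in length")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1  # constant column -> centered zeros, zero weight
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sd_, `/`)
  C <- if (length(config$costGrid) > 1L && config$backend == "svm")
    chooseCost(Xs, y, config) else config$costGrid[1]
  model <- list(classes = levels(y), mu = mu, sd = sd_, C = C,
                backend = config$backend, config = config)
  if (config$backend == "svm") {
    p <- ncol(Xs)
    W <- matrix(0, p, nlevels(y)); b <- numeric(nlevels(y))
    for (k in seq_len(nlevels(y))) {
      yk <- ifelse(y == levels(y)[k], 1, -1)
      # balanced mode weights each one-vs-rest subproblem by inverse
      # class frequency, cancelling the training-prior pull
      wts <- if (config$classWeight)
        ifelse(yk == 1, length(yk) / (2 * sum(yk == 1)),
               length(yk) / (2 * sum(yk == -1))) else NULL
      fitk <- svmSquaredHinge(Xs, yk, C, wts)
      W[, k] <- fitk$w; b[k] <- fitk$b
    }
    model$W <- W; model$b <- b
  } else if (config$backend == "logistic") {
    df <- data.frame(.y = y, Xs)
    capture.output(fit <- nnet::multinom(.y ~ ., data = df, maxit = 300,
                                         trace = FALSE))
    model$fit <- fit
  } else {
    set.seed(deriveSeed(config$seed, "rf-backend"))
    model$fit <- randomForest::randomForest(Xs, y, ntree = 500)
  }
  class(model) <- "cftClassifier"
  model
}

# inner stratified K-fold cross-validation over the cost grid;
# ties broken toward the smallest cost
#' @keywords internal
chooseCost <- function(Xs, y, config) {
  K <- min(config$innerFolds, min(table(y)))
  if (K < 2L) return(config$costGrid[ceiling(length(config$costGrid) / 2)])
  fold <- integer(length(y))
  set.seed(deriveSeed(config$seed, "inner-cv"))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  acc <- vapply(config$costGrid, function(C) {
    correct <- 0L; total <- 0L
    for (f in seq_len(K)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2L) next
      W <- sapply(levels(y), function(cl) {
        yk <- ifelse(y[tr] == cl, 1, -1)
        fit <- svmSquaredHinge(Xs[tr, , drop = FALSE], yk, C)
        c(fit$w, fit$b)
      })
      S <- cbind(Xs[!tr, , drop = FALSE], 1) %*% W
      pred <- levels(y)[max.col(S, ties.method = "first")]
      correct <- correct + sum(pred == y[!tr]); total <- total + sum(!tr)
    }
    if (total == 0L) 0 else correct / total
  }, 0)
  config$costGrid[which.max(acc)]  # which.max takes the first (smallest C)
}

#' Decision scores of a fitted classifier
#'
#' @param model a `cftClassifier`.
#' @param X feature matrix or table (columns as at training).
#' @return n x K numeric matrix of per-class scores.
#' @export
decisionScores <- function(model, X) {
  X <- featureMatrix(X, includeAsymmetry = TRUE)
  X <- X[, names(model$mu), drop = FALSE]  # invariant to column order
  Xs <- sweep(sweep(X, 2, model$mu, `-`), 2, model$sd, `/`)
  S <- switch(model$backend,
              svm = sweep(Xs %*% model$W, 2, model$b, `+`),
              logistic = {
                pr <- stats::predict(model$fit,
                                     newdata = as.data.frame(Xs), type = "probs")
                if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
                pr
              },
              rf = stats::predict(model$fit, Xs, type = "prob"))
  colnames(S) <- model$classes
  S
}

#' @export
predict.cftClassifier <- function(object, newdata, ...) {
  S <- decisionScores(object, newdata)
  factor(object$classes[max.col(S, ties.method = "first")],
         levels = object$classes)
}

# ---- cross-validation ----------------------------------------------------

#' Build a classification result
#' @keywords internal
classificationResult <- function(ids, true, predicted, scores, classes) {
  structure(list(ids = ids, true = factor(true, classes),
                 predicted = factor(predicted, classes), scores = scores,
                 classes = classes),
            class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
  cat(sprintf("ClassificationResult: %d subjects, accuracy %.3f\n",
              length(x$ids), mean(x$predicted == x$true)))
  invisible(x)
}

#' Confusion matrix of a classification result
#'
#' @param result a `ClassificationResult`.
#' @return a [ConfusionMatrix-class].
#' @export
resultConfusion <- function(result) {
  confusionMatrix(true = result$true, predicted = result$predicted,
                  classes = result$classes)
}

#' Leave-one-out cross-validation
#'
#' Each subject is predicted by a model trained on all other subjects plus
#' an optional fixed augmentation pool (e.g. advanced-stage patients when
#' cross-validating the early-stage pool). The held-out subject must never
#' appear in the augmentation pool; this is asserted on subject ids.
#'
#' @param X feature matrix or table (n >= 3 rows).
#' @param y class labels.
#' @param config settings from [classifierConfig()].
#' @param ids subject identifiers (default: rownames or indices).
#' @param augment optional list(X, y, ids) of extra training rows.
#' @param includeAsymmetry when `X` is a feature table, also use the
#'   asymmetry columns (default FALSE: SOR features only).
#' @return a `ClassificationResult` over the n held-out subjects.
#' @export
loocv <- function(X, y, config = classifierConfig(), ids = NULL,
                  augment = NULL, includeAsymmetry = FALSE) {
  X <- featureMatrix(X, includeAsymmetry)
  y <- factor(y)
  n <- nrow(X)
  stopIfNot(n >= 3L, "leave-one-out needs at least 3 subjects")
  if (is.null(ids)) ids <- if (!is.null(rownames(X))) rownames(X) else
    as.character(seq_len(n))
  if (!is.null(augment)) {
    augment$X <- featureMatrix(augment$X, includeAsymmetry)
    if (is.null(augment$ids)) augment$ids <- rownames(augment$X)
    if (any(ids %in% augment$ids))
      stop("leakage guard: held-out subject(s) present in the augmentation pool",
           call. = FALSE)
  }
  classes <- levels(factor(if (is.null(augment)) as.character(y) else
    c(as.character(y), as.character(augment$y))))
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(ids, classes))
  pred <- character(n)
  for (i in seq_len(n)) {
    trX <- X[-i, , drop = FALSE]; trY <- as.character(y[-i])
    if (!is.null(augment)) {
      trX <- rbind(trX, augment$X); trY <- c(trY, as.character(augment$y))
    }
    model <- fitClassifier(trX, factor(trY, classes), config)
    S <- decisionScores(model, X[i, , drop = FALSE])
    scores[i, model$classes] <- S
    pred[i] <- model$classes[which.max(S)]
  }
  classificationResult(ids, as.character(y), pred, scores, classes)
}

# ---- binary one-vs-rest tasks -------------------------------------------

#' One-vs-rest binary diagnosis tasks
#'
#' For each disease class, runs leave-one-out cross-validation of
#' disease-vs-rest classification and computes the rank-statistic AUC over
#' the held-out decision scores.
#'
#' @param X feature matrix or table.
#' @param y multiclass labels (each level in turn is the positive class).
#' @param config settings from [classifierConfig()].
#' @param ids subject identifiers.
#' @return named list per class: list(result, auc, accuracy).
#' @export
binaryTasks <- function(X, y, config = classifierConfig(), ids = NULL) {
  y <- factor(y)
  stopIfNot(nlevels(y) >= 2L, "need at least 2 classes")
  out <- list()
  for (cl in levels(y)) {
    yb <- factor(ifelse(y == cl, cl, "rest"), levels = c("rest", cl))
    res <- loocv(X, yb, config, ids = ids)
    auc <- aucRank(res$scores[, cl], res$true == cl)
    out[[cl]] <- list(result = res, auc = auc,
                      accuracy = mean(res$predicted == res$true))
  }
  out
}

# ---- disease-stage training strategies ----------------------------------

#' Specification of a stage-stratified training strategy
#'
#' Four strategies probe how advanced-stage (AS) data helps early-stage
#' (ES) diagnosis: (1) train on all AS plus the other ES subjects,
#' leave-one-out over ES; (2) leave-one-out within ES only; (3) train on
#' all AS, test all ES; (4) train on an AS subsample matched to the ES
#' pool size, test all ES.
#'
#' @param id strategy number 1-4.
#' @return list(id, description, cv).
#' @export
strategySpec <- function(id) {
  stopIfNot(id %in% 1:4, "strategy id must be 1, 2, 3 or 4")
  desc <- c("AS + other ES / 1 ES (LOOCV over ES)",
            "other ES / 1 ES (LOOCV over ES)",
            "all AS / all ES (holdout)",
            "AS subsample (|ES|) / all ES (holdout)")
  list(id = id, description = desc[id],
       cv = if (id <= 2) "loocv" else "holdout")
}

#' Run a stage-stratified training strategy
#'
#' @param features feature table with `group` and `stage` columns (patients
#'   only; rows with other groups or missing stage are dropped).
#' @param strategy a [strategySpec()] or its integer id.
#' @param config settings from [classifierConfig()].
#' @param seed seed for the strategy-4 advanced-stage subsample.
#' @param includeAsymmetry use asymmetry columns as features.
#' @return a `ClassificationResult` over the early-stage pool, with the
#'   strategy stored in attribute `strategy`.
#' @export
runStrategy <- function(features, strategy, config = classifierConfig(),
                        seed = 1L, includeAsymmetry = FALSE) {
  if (is.numeric(strategy)) strategy <- strategySpec(strategy)
  f <- features[features$stage %in% c("ES", "AS"), , drop = FALSE]
  es <- f[f$stage == "ES", , drop = FALSE]
  as_ <- f[f$stage == "AS", , drop = FALSE]
  stopIfNot(nrow(es) >= 3L, "early-stage pool too small")
  Xes <- featureMatrix(es, includeAsymmetry)
  Xas <- featureMatrix(as_, includeAsymmetry)
  classes <- levels(factor(f$group))
  res <- switch(as.character(strategy$id),
    "1" = loocv(Xes, factor(es$group, classes), config, ids = es$subject_id,
                augment = list(X = Xas, y = factor(as_$group, classes),
                               ids = as_$subject_id)),
    "2" = loocv(Xes, factor(es$group, classes), config, ids = es$subject_id),
    "3" = {
      model <- fitClassifier(Xas, factor(as_$group, classes), config)
      S <- decisionScores(model, Xes)
      classificationResult(es$subject_id, es$group,
                           model$classes[max.col(S, ties.method = "first")],
                           S, model$classes)
    },
    "4" = {
      stopIfNot(nrow(as_) >= nrow(es),
                "requested AS training pool larger than available")
      set.seed(deriveSeed(seed, "strategy4-subsample"))
      take <- sample(nrow(as_), nrow(es))
      model <- fitClassifier(Xas[take, , drop = FALSE],
                             factor(as_$group[take], classes), config)
      S <- decisionScores(model, Xes)
      r <- classificationResult(es$subject_id, es$group,
                                model$classes[max.col(S, ties.method = "first")],
                                S, model$classes)
      attr(r, "asSubsample") <- as_$subject_id[take]
      r
    })
  attr(res, "strategy") <- strategy
  res
}
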
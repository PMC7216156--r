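#' Rank-based area under the ROC curve
#'
#' The AUC as the normalized Mann-Whitney statistic: the probability that
#' a random positive scores above a random negative, with tied scores
#' contributing 1/2.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two classes")
    pos <- labels == levels(labels)[2]
  } else {
    pos <- as.logical(labels)
  }
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has ", length(idx),
           " samples (< k = ", k, "); use a smaller k")
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-fold standardization using training statistics only (no leakage);
# zero-variance columns pass through unscaled.
scale_by_train <- function(train, test) {
  mu <- colMeans(train)
  sdev <- apply(train, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdev, "/"))
}

#' Repeated stratified cross-validation of a linear SVM on the functionome
#'
#' Checks the informativeness of a (immuno)functionome by supervised
#' classification: a linear-kernel maximum-margin classifier
#' ([kernlab::ksvm], C = 1) is trained on each training fold (features
#' standardized per training fold) and evaluated on the held-out fold,
#' repeated over independently re-drawn stratified fold assignments.
#' Binary problems report sensitivity, specificity, accuracy and
#' rank-based AUC per repeat; multiclass problems report overall and
#' per-class accuracy.
#'
#' @param f A [functionome] or plain samples x features numeric matrix.
#' @param labels Class labels per sample; defaults to the functionome's
#'   group labels.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated fold draws (default 10).
#' @param seed Integer seed; mandatory for reproducibility. Repeat r uses
#'   the derived seed `seed + r - 1`.
#' @param feature_filter Optional integer: keep only the top-N features by
#'   variance before CV (a coarse stand-in for an unspecified upstream
#'   feature filter; default NULL = off).
#' @return Object of class `gsr_cv`: list with `per_repeat` (data.frame),
#'   `summary` (mean metrics), `per_class` (multiclass accuracy or NULL),
#'   `k`, `repeats`, `seed`.
#' @export
cross_validated_classifier <- function(f, labels = NULL, k = 10, repeats = 10,
                                       seed, feature_filter = NULL) {
  if (missing(seed)) stop("seed is required for reproducible cross-validation")
  X <- if (inherits(f, "functionome")) f$gsr else as.matrix(f)
  if (is.null(labels) && inherits(f, "functionome")) labels <- f$groups
  stopifnot(length(labels) == nrow(X))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("at least two classes are required")
  if (!is.null(feature_filter)) {
    v <- apply(X, 2, stats::var)
    X <- X[, order(-v)[seq_len(min(feature_filter, ncol(X)))], drop = FALSE]
  }
  binary <- nlevels(y) == 2
  pos <- levels(y)[2]

  per_repeat <- vector("list", repeats)
  class_acc <- matrix(NA_real_, repeats, nlevels(y),
                      dimnames = list(NULL, levels(y)))
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    fold <- stratified_folds(y, k)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    score <- numeric(length(y))
    for (fd in seq_len(k)) {
      tr <- fold != fd; te <- !tr
      sc <- scale_by_train(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      fit <- try(kernlab::ksvm(sc$train, y[tr], type = "C-svc",
                               kernel = "vanilladot", C = 1, scaled = FALSE,
                               kpar = list()), silent = TRUE)
      if (inherits(fit, "try-error")) {
        # degenerate training data (e.g. constant features): fall back to
        # the majority class with uninformative scores
        pred[te] <- names(which.max(table(y[tr])))
        score[te] <- 0
        next
      }
      pred[te] <- kernlab::predict(fit, sc$test)
      if (binary) {
        dec_te <- kernlab::predict(fit, sc$test, type = "decision")[, 1]
        dec_tr <- kernlab::predict(fit, sc$train, type = "decision")[, 1]
        # orient decision values so the positive class scores higher,
        # judged on the training fold only
        if (mean(dec_tr[y[tr] == pos]) < mean(dec_tr[y[tr] != pos])) {
          dec_te <- -dec_te
        }
        score[te] <- dec_te
      }
    }
    acc <- mean(pred == y)
    if (binary) {
      sens <- mean(pred[y == pos] == pos)
      spec <- mean(pred[y != pos] != pos)
      auc <- if (length(unique(score)) == 1) 0.5 else roc_auc(score, y)
      per_repeat[[r]] <- data.frame(repeat_ = r, accuracy = acc,
                                    sensitivity = sens, specificity = spec,
                                    auc = auc)
    } else {
      per_repeat[[r]] <- data.frame(repeat_ = r, accuracy = acc,
                                    sensitivity = NA_real_,
                                    specificity = NA_real_, auc = NA_real_)
    }
    class_acc[r, ] <- vapply(levels(y), function(cl) mean(pred[y == cl] == cl),
                             numeric(1))
  }
  per_repeat <- do.call(rbind, per_repeat)
  structure(list(per_repeat = per_repeat,
                 summary = colMeans(per_repeat[, -1, drop = FALSE]),
                 per_class = colMeans(class_acc),
                 k = k, repeats = repeats, seed = seed),
            class = "gsr_cv")
}

#' @export
print.gsr_cv <- function(x, ...) {
  cat("Cross-validated SVM (", x$k, "-fold x ", x$repeats,
      " repeats, seed ", x$seed, ")\n", sep = "")
  print(round(x$summary, 4))
  cat("Per-class accuracy:\n")
  print(round(x$per_class, 4))
  invisible(x)
}
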
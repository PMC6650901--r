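# Final labeling stage behind a pluggable classifier interface (one-vs-one
# RBF SVM via e1071/libsvm, or a spectral-angle nearest-centroid
# fallback), stratified train/test splitting and map-accuracy metrics.

#' Stratified train/test split of labeled pixels
#'
#' Draws a seeded, stratified training sample per class; all remaining
#' labeled pixels form the test set.  Exactly one of `n_per_class`,
#' `fraction` or `total` must be given.  With `total`, per-class counts
#' are proportional to class size with largest-remainder rounding so the
#' training set has exactly `total` pixels.  A class with fewer pixels
#' than requested contributes all but one (with a warning); single-pixel
#' classes are excluded entirely.
#'
#' @param labels a [label_map()].
#' @param n_per_class training pixels per class.
#' @param fraction training fraction per class.
#' @param total exact total number of training pixels.
#' @param seed optional integer seed.
#' @return A list: `train` and `test` (disjoint linear pixel indices).
#' @export
split_train_test <- function(labels, n_per_class = NULL, fraction = NULL,
                             total = NULL, seed = NULL) {
  lab <- label_map(labels)
  if (sum(!vapply(list(n_per_class, fraction, total), is.null, TRUE)) != 1)
    stop("give exactly one of `n_per_class`, `fraction`, `total`")
  if (!is.null(seed)) set.seed(seed)
  M <- attr(lab, "n_classes")
  idx_by_class <- split(seq_along(lab), as.vector(lab))
  sizes <- lengths(idx_by_class)
  want <-
    if (!is.null(n_per_class)) rep(n_per_class, M)
    else if (!is.null(fraction)) round(fraction * sizes)
    else {  # largest-remainder apportionment to hit `total` exactly
      raw <- total * sizes / sum(sizes)
      base <- floor(raw)
      rem <- total - sum(base)
      base + (rank(-(raw - base), ties.method = "first") <= rem)
    }
  train <- integer(0)
  for (k in seq_len(M)) {
    n <- sizes[k]
    if (n < 2) { warning("class ", k, " has a single pixel; excluded"); next }
    w <- want[k]
    if (w >= n) { warning("class ", k, ": requested ", w, " of ", n,
                          " pixels; taking all but one"); w <- n - 1 }
    w <- max(w, 1)
    train <- c(train, sort(sample(idx_by_class[[k]], w)))
  }
  excluded <- unlist(idx_by_class[sizes < 2], use.names = FALSE)
  list(train = train,
       test = setdiff(setdiff(seq_along(lab), train), excluded))
}

#' Classifier specification
#'
#' @param kind `"svm"` for a one-vs-one RBF-kernel support vector machine
#'   (via e1071/libsvm) or `"centroid"` for the built-in nearest-class-
#'   centroid rule under the spectral-angle distance.
#' @param C,gamma SVM hyperparameters; when `NULL` they are selected by
#'   `folds`-fold cross-validated grid search over `C_grid` x
#'   `gamma_grid` on the training pixels.
#' @param folds cross-validation folds for the grid search (default 5).
#' @param C_grid,gamma_grid candidate grids.
#' @param seed optional integer seed (cross-validation shuffling).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "centroid"), C = NULL,
                            gamma = NULL, folds = 5,
                            C_grid = 10^(0:3), gamma_grid = 10^(-2:1),
                            seed = NULL) {
  structure(list(kind = match.arg(kind), C = C, gamma = gamma,
                 folds = as.integer(folds), C_grid = C_grid,
                 gamma_grid = gamma_grid, seed = seed),
            class = "classifier_spec")
}

svm_grid_search <- function(X, y, spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  folds <- max(2L, min(spec$folds, min(table(y))))
  fold_id <- integer(length(y))
  for (idx in split(seq_along(y), y))
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  best <- c(acc = -1, C = spec$C_grid[1], gamma = spec$gamma_grid[1])
  for (C in spec$C_grid) for (g in spec$gamma_grid) {
    acc <- mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) return(0)
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = g, scale = FALSE)
      mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }, 0))
    if (acc > best["acc"]) best <- c(acc = acc, C = C, gamma = g)
  }
  best
}

#' Classify every pixel of a spectral image
#'
#' Fits the classifier named in `spec` on the training pixels only and
#' predicts a class for every pixel of the image.  The centroid rule
#' assigns each pixel to the class whose mean training spectrum has the
#' smallest spectral angle to it.
#'
#' @param img a [spectral_image()].
#' @param labels a [label_map()] supplying the training labels.
#' @param train linear pixel indices of the training sample (see
#'   [split_train_test()]).
#' @param spec a [classifier_spec()].
#' @return A [label_map()] of predictions; chosen SVM hyperparameters, if
#'   any, are stored in the `"params"` attribute.
#' @export
classify_pixels <- function(img, labels, train, spec = classifier_spec()) {
  img <- spectral_image(img); lab <- label_map(labels)
  if (!identical(dim(img)[1:2], dim(lab)[1:2]))
    stop("image and label dimensions differ")
  X <- pixel_matrix(img)
  ytr <- factor(lab[train], levels = seq_len(attr(lab, "n_classes")))
  ytr <- droplevels(ytr)
  if (nlevels(ytr) < 1) stop("no training classes")
  params <- NULL
  pred <-
    if (spec$kind == "centroid") {
      cent <- t(vapply(levels(ytr), function(l)
        colMeans(X[train[ytr == l], , drop = FALSE]), numeric(ncol(X))))
      ang <- vapply(seq_len(nrow(cent)), function(i)
        row_spectral_angle(X, matrix(cent[i, ], nrow(X), ncol(X), byrow = TRUE)),
        numeric(nrow(X)))
      as.integer(levels(ytr))[max.col(-ang, ties.method = "first")]
    } else {
      if (nlevels(ytr) < 2) {
        rep(as.integer(levels(ytr)), nrow(X))
      } else {
        C <- spec$C; g <- spec$gamma
        if (is.null(C) || is.null(g)) {
          best <- svm_grid_search(X[train, , drop = FALSE], ytr, spec)
          C <- best[["C"]]; g <- best[["gamma"]]
          params <- c(C = C, gamma = g)
        }
        fit <- e1071::svm(X[train, , drop = FALSE], ytr, kernel = "radial",
                          cost = C, gamma = g, scale = FALSE)
        as.integer(as.character(predict(fit, X)))
      }
    }
  # keep the prediction ids aligned with the truth ids (no re-canonicalization)
  structure(matrix(as.integer(pred), nrow(lab), ncol(lab)),
            class = "label_map", n_classes = attr(lab, "n_classes"),
            levels = seq_len(attr(lab, "n_classes")), params = params)
}

#' Align the class ids of one label map with another's
#'
#' Canonicalization assigns ids `1..M` in order of first appearance, so
#' two label maps read from separate files can use different ids for the
#' same underlying class (e.g. the same PNG color).  This remaps `x` so
#' that entries whose persisted original level (see the `"levels"`
#' attribute of [label_map()]) matches one of `reference`'s levels receive
#' the reference's id; unmatched levels get fresh ids beyond the
#' reference's range.
#'
#' @param x,reference [label_map()]s.
#' @return `x` with ids aligned to `reference`.
#' @export
align_labels <- function(x, reference) {
  x <- label_map(x); reference <- label_map(reference)
  map <- match(attr(x, "levels"), attr(reference, "levels"))
  extra <- which(is.na(map))
  map[extra] <- attr(reference, "n_classes") + seq_along(extra)
  structure(matrix(as.integer(map[x]), nrow(x), ncol(x)),
            class = "label_map",
            n_classes = max(map),
            levels = c(attr(reference, "levels"),
                       attr(x, "levels")[extra])[seq_len(max(map))])
}

#' Map-accuracy metrics
#'
#' Confusion-matrix metrics on the masked pixels (typically the labeled
#' pixels minus the training sample): overall accuracy (OA, percent of
#' correctly classified pixels), average accuracy (AA, mean per-class
#' recall) and Cohen's kappa (agreement corrected for chance), all
#' reported as percentages, plus per-class accuracies.
#'
#' @param pred,truth [label_map()]s of equal size.
#' @param mask linear pixel indices to evaluate on (default: all pixels).
#' @return A list of class `accuracy_report`: `OA`, `AA`, `kappa`,
#'   `per_class`, `confusion`, `n`.
#' @export
accuracy <- function(pred, truth, mask = NULL) {
  pred <- label_map(pred); truth <- label_map(truth)
  if (!identical(dim(pred), dim(truth))) stop("prediction and truth sizes differ")
  if (is.null(mask)) mask <- seq_along(truth)
  if (!length(mask)) stop("empty evaluation mask")
  M <- max(attr(truth, "n_classes"), attr(pred, "n_classes"), pred[mask], truth[mask])
  cm <- table(factor(truth[mask], levels = seq_len(M)),
              factor(pred[mask], levels = seq_len(M)))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  per_class <- diag(cm) / pmax(rowSums(cm), 1)
  present <- rowSums(cm) > 0
  kappa <- if (pe >= 1) 100 else 100 * (po - pe) / (1 - pe)
  structure(list(OA = 100 * po, AA = 100 * mean(per_class[present]),
                 kappa = kappa, per_class = 100 * per_class,
                 confusion = unclass(cm), n = n),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> OA %.2f%%  AA %.2f%%  kappa %.2f%%  (n = %d)\n",
              x$OA, x$AA, x$kappa, x$n))
  invisible(x)
}
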
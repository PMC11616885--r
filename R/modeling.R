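# Modeling: SMOTE class rebalancing (training folds only), random-forest
# classification with default parameters, and cross-dataset training-set
# assembly.

#' SMOTE oversampling of the training set
#'
#' Synthetic minority oversampling: each minority class is upsampled to the
#' majority count by interpolating between a random class member and one of
#' its k nearest same-class neighbours (`x + u * (neighbour - x)`,
#' `u ~ U(0, 1)`).  Applied to training data only — test rows must never see
#' synthetic samples.  A class with a single instance cannot seed neighbours
#' and is left un-oversampled with a warning; a class of size 2 proceeds
#' with a neighbourhood of 1.
#'
#' @param x Numeric feature data frame or matrix (complete, no `NA`).
#' @param y Class labels (length `nrow(x)`).
#' @param seed Integer seed.
#' @param k Neighbourhood size (shrunk to class size - 1 where needed).
#' @return A list with `x`, `y` and logical `synthetic` flagging the
#'   generated rows.
#' @export
oversample_train <- function(x, y, seed = 1L, k = 5L) {
  .assert(length(unique(y)) >= 2, "need at least 2 classes to oversample")
  X <- as.matrix(x)
  .assert(!anyNA(X), "oversampling requires complete (imputed) features")
  set.seed(seed)
  counts <- table(y)
  target <- max(counts)
  newX <- list(); newy <- character(0)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    idx <- which(y == cl)
    if (length(idx) < 2) {
      warning("class '", cl, "' has a single instance; not oversampled")
      next
    }
    Xc <- X[idx, , drop = FALSE]
    kk <- min(k, length(idx) - 1)
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    nn <- apply(D, 1, function(d) order(d)[seq_len(kk)])
    nn <- matrix(nn, nrow = kk)    # kk x n
    base <- sample(length(idx), need, replace = TRUE)
    pick <- vapply(base, function(b) nn[sample.int(kk, 1), b], 0L)
    u <- stats::runif(need)
    S <- Xc[base, , drop = FALSE] +
      u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    newX[[length(newX) + 1]] <- S
    newy <- c(newy, rep(cl, need))
  }
  n0 <- nrow(X)
  if (length(newX)) X <- rbind(X, do.call(rbind, newX))
  out_x <- as.data.frame(X)
  names(out_x) <- colnames(x)
  rownames(out_x) <- NULL
  list(x = out_x, y = c(as.character(y), newy),
       synthetic = c(rep(FALSE, n0), rep(TRUE, nrow(X) - n0)))
}

#' Fit the random-forest classifier
#'
#' Random forest with the implementation's default parameters (500 trees,
#' `mtry = floor(sqrt(p))`), deterministic given the seed.  Classes are
#' modeled as unordered categories.  The stored feature-column list is
#' checked at prediction time.
#'
#' @param x Complete numeric feature data frame.
#' @param y Class labels (at least two distinct).
#' @param seed Integer seed.
#' @return An object of class `foh_model`.
#' @export
fit_classifier <- function(x, y, seed = 1L) {
  .assert(length(unique(y)) >= 2, "need at least 2 classes to fit a classifier")
  .assert(!anyNA(x), "features must be complete (imputed) before fitting")
  xx <- as.data.frame(x)
  names(xx) <- make.names(names(xx))   # randomForest needs syntactic names
  set.seed(seed)
  rf <- randomForest::randomForest(x = xx, y = factor(y))
  structure(list(rf = rf, columns = colnames(x),
                 classes = levels(factor(y)), seed = as.integer(seed)),
            class = "foh_model")
}

#' @export
predict.foh_model <- function(object, newdata, ...) {
  .assert(all(object$columns %in% colnames(newdata)),
          "newdata is missing columns the model was trained on")
  nd <- as.data.frame(newdata)[object$columns]
  names(nd) <- make.names(names(nd))
  as.character(stats::predict(object$rf, nd, ...))
}

#' @export
print.foh_model <- function(x, ...) {
  cat("Random-forest FOH classifier:", length(x$columns), "features,",
      "classes:", paste(x$classes, collapse = "/"),
      "| trees:", x$rf$ntree, "\n")
  invisible(x)
}

#' Stack a second dataset onto the training matrix
#'
#' Row-binds the two feature matrices restricted to their compatible
#' (name-intersected) feature columns, keeping metadata.  A `.source`
#' provenance column is retained for audit but is not a feature column.
#'
#' @param primary,auxiliary Feature matrices built by this package.
#' @return The stacked matrix on the common columns.
#' @export
combine_train_sets <- function(primary, auxiliary) {
  common <- compatible_feature_set(primary, auxiliary)
  cols <- c(intersect(META_COLS, names(primary)), common)
  a <- primary[cols]; a$.source <- rep("primary", nrow(a))
  b <- auxiliary[cols]; b$.source <- rep("auxiliary", nrow(b))
  out <- rbind(a, b)
  rownames(out) <- NULL
  out
}

#' Impurity-based feature importances
#'
#' The forest's built-in (Gini impurity decrease) importances, normalized to
#' sum to 1 and sorted descending.
#'
#' @param model A fitted [fit_classifier()] model.
#' @return Data frame with columns `feature`, `importance`.
#' @export
feature_importance <- function(model) {
  .assert(inherits(model, "foh_model"), "model must come from fit_classifier()")
  imp <- model$rf$importance[, "MeanDecreaseGini"]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  o <- order(imp, decreasing = TRUE)
  data.frame(feature = model$columns[o], importance = unname(imp[o]),
             stringsAsFactors = FALSE)
}
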
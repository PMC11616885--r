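# Preprocessing: missingness-threshold feature filtering, global vs.
# personalized imputation (KNN and chained equations), and the optional
# previous-day FOH feature.

#' Imputation plan
#'
#' @param method `"knn"` (mean of the k nearest donors under nan-Euclidean
#'   distance) or `"mice"` (iterative chained equations: a ridge model per
#'   feature, refit over `max_iter` rounds).
#' @param scope `"global"` fits one imputer on all fitting rows;
#'   `"personalized"` fits one imputer per patient on that patient's rows,
#'   falling back to the global mean for patient-columns with no observed
#'   value.
#' @param k_neighbors Number of donors for KNN.
#' @param max_iter Chained-equation rounds for MICE.
#' @return An object of class `foh_impute_plan`.
#' @export
imputation_plan <- function(method = c("knn", "mice"),
                            scope = c("global", "personalized"),
                            k_neighbors = 5, max_iter = 10) {
  method <- match.arg(method); scope <- match.arg(scope)
  .assert(k_neighbors >= 1 && max_iter >= 1, "parameters must be positive")
  structure(list(method = method, scope = scope,
                 k_neighbors = as.integer(k_neighbors),
                 max_iter = as.integer(max_iter)),
            class = "foh_impute_plan")
}

#' Drop features with too many missing values
#'
#' Columns whose missing fraction strictly exceeds `threshold` are removed
#' ("more than X% missing"); rows are untouched.  The dropped names are
#' attached as attribute `"dropped"`.
#'
#' @param matrix A feature matrix.
#' @param threshold Maximum tolerated missing fraction in [0, 1] (0.3 was
#'   used for the Chiron-style data, 0.6 for HeartMan-style).
#' @return The reduced feature matrix.
#' @export
filter_by_missingness <- function(matrix, threshold) {
  .assert(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  fc <- feature_cols(matrix)
  miss <- vapply(matrix[fc], function(x) mean(is.na(x)), 0)
  dropped <- fc[miss > threshold]
  out <- matrix[, !(names(matrix) %in% dropped), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# ---------------------------------------------------------------------------
# KNN imputer (nan-Euclidean distance, mean of k donors)

.knn_fit <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv, Z = sweep(sweep(X, 2, mu), 2, sdv, "/"), X = X)
}

.knn_transform <- function(fit, X, k) {
  miss_rows <- which(rowSums(is.na(X)) > 0)
  if (!length(miss_rows)) return(X)
  Z <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
  p <- ncol(X)
  # nan-Euclidean distances to all fitting rows in one block:
  # sum over co-observed columns of squared diffs, scaled by p / #co-observed
  A <- Z[miss_rows, , drop = FALSE]; Ia <- (!is.na(A)) * 1; A[is.na(A)] <- 0
  B <- fit$Z; Ib <- (!is.na(B)) * 1; B[is.na(B)] <- 0
  S <- (A * A) %*% t(Ib) + Ia %*% t(B * B) - 2 * A %*% t(B)
  Cnt <- Ia %*% t(Ib)
  D <- sqrt(p * pmax(S, 0) / Cnt)
  D[Cnt == 0] <- Inf
  obs_col <- !is.na(fit$X)
  for (ii in seq_along(miss_rows)) {
    i <- miss_rows[ii]
    ord <- order(D[ii, ])
    ord <- ord[is.finite(D[ii, ord])]
    for (j in which(is.na(X[i, ]))) {
      donors <- ord[obs_col[ord, j]]
      if (!length(donors)) {
        X[i, j] <- fit$mu[j]
      } else {
        X[i, j] <- mean(fit$X[donors[seq_len(min(k, length(donors)))], j])
      }
    }
  }
  X
}

# ---------------------------------------------------------------------------
# Chained-equations imputer (ridge model per feature)

.ridge_coef <- function(Z, y, lambda = 1) {
  # Z standardized predictors (complete), y centered response
  A <- crossprod(Z) + lambda * diag(ncol(Z))
  as.numeric(solve(A, crossprod(Z, y)))
}

.mice_fit <- function(X, max_iter) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  miss <- is.na(X)
  Xc <- X
  for (j in seq_len(ncol(X))) Xc[miss[, j], j] <- mu[j]
  models <- vector("list", ncol(X))
  target <- which(colSums(miss) > 0 & colSums(!miss) >= 2)
  for (it in seq_len(max_iter)) {
    for (j in target) {
      Z <- sweep(sweep(Xc[, -j, drop = FALSE], 2, mu[-j]), 2, sdv[-j], "/")
      obs <- !miss[, j]
      b <- .ridge_coef(Z[obs, , drop = FALSE], X[obs, j] - mu[j])
      pred <- mu[j] + as.numeric(Z %*% b)
      Xc[miss[, j], j] <- pred[miss[, j]]
      models[[j]] <- b
    }
  }
  list(mu = mu, sd = sdv, models = models, target = target,
       completed = Xc, max_iter = max_iter)
}

.mice_transform <- function(fit, X) {
  miss <- is.na(X)
  Xc <- X
  for (j in seq_len(ncol(X))) Xc[miss[, j], j] <- fit$mu[j]
  for (it in seq_len(fit$max_iter)) {
    for (j in fit$target) {
      if (!any(miss[, j]) || is.null(fit$models[[j]])) next
      Z <- sweep(sweep(Xc[, -j, drop = FALSE], 2, fit$mu[-j]), 2,
                 fit$sd[-j], "/")
      pred <- fit$mu[j] + as.numeric(Z %*% fit$models[[j]])
      Xc[miss[, j], j] <- pred[miss[, j]]
    }
  }
  Xc
}

.impute_block <- function(X_fit, X_all, plan) {
  if (plan$method == "knn") {
    .knn_transform(.knn_fit(X_fit), X_all, plan$k_neighbors)
  } else {
    fit <- .mice_fit(X_fit, plan$max_iter)
    .mice_transform(fit, X_all)
  }
}

#' Impute missing feature values
#'
#' Fills every missing cell of the feature matrix.  Imputation statistics
#' are learned on `fit_rows` only (the training rows when used inside
#' evaluation, so no information flows from test rows into the imputer) and
#' applied to all rows.  With `scope = "personalized"` one imputer is fitted
#' per patient on that patient's fitting rows; any patient-column with no
#' observed value falls back to the global mean of the fitting rows.
#' Observed cells are never altered.
#'
#' @param matrix A (filtered) feature matrix.
#' @param plan An [imputation_plan()].
#' @param fit_rows Integer row indices the imputer may learn from.
#' @return The completed feature matrix (no `NA` left in feature columns).
#' @export
impute <- function(matrix, plan = imputation_plan(),
                   fit_rows = seq_len(nrow(matrix))) {
  .assert(inherits(plan, "foh_impute_plan"), "plan must come from imputation_plan()")
  .assert(all(fit_rows %in% seq_len(nrow(matrix))), "fit_rows out of range")
  fc <- feature_cols(matrix)
  num <- fc[vapply(matrix[fc], is.numeric, TRUE)]
  X <- as.matrix(matrix[num])
  Xf <- X[fit_rows, , drop = FALSE]
  gmu <- colMeans(Xf, na.rm = TRUE)
  all_na <- !is.finite(gmu)
  .assert(!(plan$scope == "global" && any(all_na)),
          paste("columns with zero observed values in the fitting rows:",
                paste(num[all_na], collapse = ", ")))
  gmu[all_na] <- 0

  if (plan$scope == "global") {
    Xc <- .impute_block(Xf, X, plan)
  } else {
    Xc <- X
    pid <- matrix$patient_id
    fit_flag <- seq_len(nrow(matrix)) %in% fit_rows
    for (p in unique(pid)) {
      rows_p <- which(pid == p)
      fit_p <- rows_p[fit_flag[rows_p]]
      Xp <- X[rows_p, , drop = FALSE]
      if (length(fit_p) == 0) {
        # no fitting data for this patient: global-mean fallback
        for (j in seq_len(ncol(Xp))) Xp[is.na(Xp[, j]), j] <- gmu[j]
      } else {
        Xfp <- X[fit_p, , drop = FALSE]
        empty <- !is.finite(colMeans(Xfp, na.rm = TRUE))
        if (any(!empty)) {
          Xp[, !empty] <- .impute_block(Xfp[, !empty, drop = FALSE],
                                        Xp[, !empty, drop = FALSE], plan)
        }
        for (j in which(empty)) Xp[is.na(Xp[, j]), j] <- gmu[j]
      }
      Xc[rows_p, ] <- Xp
    }
  }
  # imputation must never alter an observed cell
  obs <- !is.na(X)
  Xc[obs] <- X[obs]
  matrix[num] <- as.data.frame(Xc)
  matrix
}

#' Add the previous-day FOH feature
#'
#' For each row, yesterday's canonical FOH class if the patient reported on
#' the previous calendar day, else `"same"` (the rule also covers a
#' patient's first-ever report).  The feature is one-hot encoded so it can
#' sit alongside the numeric features without being imputed (it is never
#' missing by construction).  It is an optional feature: callers decide
#' whether to include it.
#'
#' @param matrix A feature matrix.
#' @param reports FOH reports covering the matrix rows.
#' @param encode `"onehot"` (default; columns `prevday_foh.worse/same/
#'   better`) or `"label"` (single character column `prevday_foh`).
#' @return The matrix with the extra column(s).
#' @export
add_prevday_foh <- function(matrix, reports, encode = c("onehot", "label")) {
  encode <- match.arg(encode)
  canon <- merge_five_to_three(reports$raw_value, reports$dialect)
  key <- paste(reports$patient_id, as.Date(reports$date))
  prev_key <- paste(matrix$patient_id, as.Date(matrix$date) - 1)
  prev <- canon[match(prev_key, key)]
  prev[is.na(prev)] <- "same"
  if (encode == "label") {
    matrix$prevday_foh <- prev
  } else {
    for (cl in FOH_LEVELS)
      matrix[[paste0("prevday_foh.", cl)]] <- as.numeric(prev == cl)
  }
  matrix
}
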
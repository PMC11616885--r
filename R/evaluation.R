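# Evaluation: split schemes (10-fold, leave-one-subject-out,
# leave-half-a-subject-out), accuracy and F1 metrics, the experiment
# orchestrator, and the fold-level t-test used to compare imputation
# strategies.

#' Build a cross-validation split plan
#'
#' Three schemes:
#' \describe{
#'   \item{kfold10}{random (unstratified) 10-way row partition; each fold is
#'     a test set once.}
#'   \item{loso}{leave-one-subject-out: one split per patient, that
#'     patient's rows as the test set.}
#'   \item{leave_half}{one split; per patient, rows dated up to the midpoint
#'     of that patient's observed date span go to training (ties to
#'     training: for days 0-100, days 0-50 train) and the rest to test.
#'     Patients with fewer than 2 rows are excluded and recorded in the
#'     `excluded` attribute.}
#' }
#'
#' @param meta Data frame with `patient_id` and `date` per row.
#' @param scheme `"kfold10"`, `"loso"` or `"leave_half"`.
#' @param seed Integer seed (used by kfold10).
#' @return An object of class `foh_splits`: list of splits, each with
#'   `train`, `test` row indices and an `id` (fold index or held patient).
#' @export
make_splits <- function(meta, scheme = c("kfold10", "loso", "leave_half"),
                        seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(meta)
  .assert(n >= 2, "need at least 2 rows to split")
  splits <- list()
  excluded <- character(0)
  if (scheme == "kfold10") {
    set.seed(seed)
    fold <- sample(rep(seq_len(10), length.out = n))
    for (f in sort(unique(fold))) {
      splits[[length(splits) + 1]] <-
        list(train = which(fold != f), test = which(fold == f), id = f)
    }
  } else if (scheme == "loso") {
    pats <- unique(meta$patient_id)
    .assert(length(pats) >= 2, "leave-one-subject-out needs at least 2 patients")
    for (p in pats) {
      splits[[length(splits) + 1]] <-
        list(train = which(meta$patient_id != p),
             test = which(meta$patient_id == p), id = p)
    }
  } else {
    dn <- as.numeric(as.Date(meta$date))
    train <- integer(0); test <- integer(0)
    for (p in unique(meta$patient_id)) {
      rows <- which(meta$patient_id == p)
      if (length(rows) < 2) { excluded <- c(excluded, p); next }
      d <- dn[rows]
      mid <- min(d) + floor((max(d) - min(d)) / 2)
      train <- c(train, rows[d <= mid])
      test <- c(test, rows[d > mid])
    }
    .assert(length(test) > 0, "leave_half produced an empty test set")
    splits[[1]] <- list(train = train, test = test, id = "half")
  }
  structure(splits, class = "foh_splits", scheme = scheme,
            excluded = excluded)
}

#' Classification accuracy
#'
#' The number of correctly predicted instances divided by the total number
#' of instances.
#'
#' @param truth,pred Equal-length label vectors.
#' @return Fraction in [0, 1].
#' @export
accuracy <- function(truth, pred) {
  .assert(length(truth) == length(pred), "length mismatch")
  .assert(length(truth) > 0, "empty label vectors")
  mean(truth == pred)
}

#' Confusion matrix over a fixed class set
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Class universe (default: sorted union of both vectors).
#' @return Integer matrix, true classes in rows, predicted in columns.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  .assert(length(truth) == length(pred), "length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  table(factor(truth, classes), factor(pred, classes))
}

#' Per-class and macro F1 scores
#'
#' One-vs-rest precision and recall per class, F1 as their harmonic mean
#' (0 when the denominator is 0).  The macro F1 is the unweighted mean over
#' the class universe: every class counts the same, so rare classes are not
#' drowned out by the majority class.  A support-weighted average is also
#' returned for reference.  A class absent from both vectors contributes
#' F1 = 0 and triggers a warning.
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Class universe (default: sorted union of both vectors).
#' @return List with `per_class` (data frame: class, precision, recall, f1,
#'   support), `macro_f1`, `weighted_f1`, `accuracy`, `confusion`.
#' @export
f1_scores <- function(truth, pred, classes = NULL) {
  .assert(length(truth) == length(pred), "length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  cm <- confusion_matrix(truth, pred, classes)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  absent <- rowSums(cm) == 0 & colSums(cm) == 0
  if (any(absent))
    warning("class absent from truth and predictions: ",
            paste(classes[absent], collapse = ", "))
  support <- rowSums(cm)
  weighted <- if (sum(support) > 0) sum(f1 * support) / sum(support) else 0
  list(per_class = data.frame(class = classes, precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1),
                              support = as.integer(support),
                              stringsAsFactors = FALSE),
       macro_f1 = mean(f1), weighted_f1 = weighted,
       accuracy = accuracy(truth, pred), confusion = cm)
}

#' Welch t-test on fold-level scores
#'
#' Two-sample unpaired Welch t-test comparing per-fold metric values of two
#' configurations (e.g. global vs. personalized imputation).  When both
#' samples are degenerate (zero variance) the p-value is reported as 1 with
#' a warning.
#'
#' @param scores_a,scores_b Numeric vectors of per-fold scores (each of
#'   length >= 2).
#' @return List with `t` and `p_value`.
#' @export
compare_scores_ttest <- function(scores_a, scores_b) {
  .assert(length(scores_a) >= 2 && length(scores_b) >= 2,
          "each score list needs at least 2 values")
  if (stats::var(scores_a) == 0 && stats::var(scores_b) == 0) {
    warning("both samples have zero variance; p-value reported as 1")
    return(list(t = NA_real_, p_value = 1))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value)
}

# ---------------------------------------------------------------------------
# Orchestration

#' Evaluate a feature matrix under one split scheme
#'
#' Runs the modeling chain with leakage guards on an extracted feature
#' matrix: split, fit the imputer on training rows only, SMOTE the training
#' rows only, fit the forest, predict the held-out rows, score.
#'
#' @param matrix Feature matrix (metadata + numeric features, `NA` allowed).
#' @param scheme Split scheme for [make_splits()].
#' @param plan [imputation_plan()] for the missing values.
#' @param n_classes 3 (worse/same/better) or 2 ('same' rows dropped before
#'   splitting).
#' @param seed Integer seed fanned out to the split, SMOTE and forest
#'   stages.
#' @param aux_matrix Optional second-dialect matrix merged into every
#'   training set on the compatible feature columns (cross-dataset setting).
#' @param feature_subset Optional character vector restricting the feature
#'   columns used.
#' @return An object of class `foh_eval`: per-split metrics, their
#'   mean/SD, and the pooled confusion matrix.
#' @export
evaluate_matrix <- function(matrix, scheme = "kfold10",
                            plan = imputation_plan(), n_classes = 3,
                            seed = 1L, aux_matrix = NULL,
                            feature_subset = NULL, keep_predictions = FALSE) {
  .assert(n_classes %in% c(2, 3), "n_classes must be 2 or 3")
  if (!is.null(feature_subset)) {
    keep <- c(intersect(META_COLS, names(matrix)),
              intersect(feature_subset, names(matrix)))
    matrix <- matrix[keep]
  }
  if (n_classes == 2) {
    matrix <- matrix[drop_same_class(matrix$label), , drop = FALSE]
    if (!is.null(aux_matrix))
      aux_matrix <- aux_matrix[drop_same_class(aux_matrix$label), , drop = FALSE]
  }
  n_primary <- nrow(matrix)
  if (!is.null(aux_matrix)) {
    common <- compatible_feature_set(matrix, aux_matrix)
    cols <- c(intersect(META_COLS, names(matrix)), common)
    matrix <- rbind(matrix[cols], aux_matrix[cols])
    rownames(matrix) <- NULL
  }
  aux_rows <- if (is.null(aux_matrix)) integer(0)
    else seq.int(n_primary + 1L, nrow(matrix))
  classes <- sort(unique(matrix$label))
  splits <- make_splits(matrix[seq_len(n_primary), c("patient_id", "date")],
                        scheme, seed = .stage_seed(seed, 1L))
  per <- list()
  preds <- list()
  pooled <- NULL
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    fit_rows <- c(sp$train, aux_rows)
    comp <- impute(matrix, plan, fit_rows = fit_rows)
    train_c <- comp[fit_rows, , drop = FALSE]
    test_c <- comp[sp$test, , drop = FALSE]
    if (length(unique(train_c$label)) < 2) next
    fc <- feature_cols(train_c)
    sm <- oversample_train(train_c[fc], train_c$label,
                           seed = .stage_seed(seed, 100L + s))
    model <- fit_classifier(sm$x, sm$y, seed = .stage_seed(seed, 200L + s))
    pred <- predict(model, test_c[fc])
    sc <- f1_scores(test_c$label, pred, classes)
    per[[length(per) + 1]] <- data.frame(
      split = as.character(sp$id), n_test = nrow(test_c),
      accuracy = sc$accuracy, macro_f1 = sc$macro_f1,
      weighted_f1 = sc$weighted_f1, stringsAsFactors = FALSE)
    if (keep_predictions)
      preds[[length(preds) + 1]] <- list(id = sp$id, rows = sp$test,
                                         truth = test_c$label, pred = pred)
    pooled <- if (is.null(pooled)) sc$confusion else pooled + sc$confusion
  }
  per <- do.call(rbind, per)
  structure(list(scheme = scheme, n_classes = n_classes, plan = plan,
                 per_split = per,
                 mean_accuracy = mean(per$accuracy),
                 mean_macro_f1 = mean(per$macro_f1),
                 sd_macro_f1 = if (nrow(per) > 1) stats::sd(per$macro_f1) else NA_real_,
                 confusion = pooled, seed = seed,
                 predictions = if (keep_predictions) preds else NULL),
            class = "foh_eval")
}

#' @export
print.foh_eval <- function(x, ...) {
  cat("FOH evaluation (", x$scheme, ", ", x$n_classes, " classes, ",
      x$plan$scope, " ", x$plan$method, " imputation)\n", sep = "")
  cat(sprintf("  splits: %d   accuracy: %.3f   macro F1: %.3f",
              nrow(x$per_split), x$mean_accuracy, x$mean_macro_f1))
  if (!is.na(x$sd_macro_f1)) cat(sprintf(" (SD %.3f)", x$sd_macro_f1))
  cat("\n")
  invisible(x)
}

#' @export
summary.foh_eval <- function(object, ...) {
  print(object)
  cat("\nPer-split metrics:\n")
  print(object$per_split, row.names = FALSE)
  cat("\nPooled confusion matrix (rows = truth):\n")
  print(object$confusion)
  invisible(object)
}

#' Run an end-to-end synthetic experiment
#'
#' Generates a cohort, curates and extracts the dialect's features, applies
#' the label transformation (Chiron dialect) and optional previous-day FOH
#' feature, filters features by missingness, and evaluates under the
#' requested scheme(s).
#'
#' @param config A [sim_config()]; its dialect decides the feature set.
#' @param schemes Character vector of split schemes to run.
#' @param n_classes 2 or 3.
#' @param transform_labels If `TRUE` (Chiron dialect), rewrite the
#'   yesterday-relative labels as usual-relative before modeling.
#' @param plan [imputation_plan()].
#' @param prevday Include the previous-day FOH feature.
#' @param threshold Missingness threshold for feature filtering; default
#'   0.6 for the HeartMan dialect and 0.3 for Chiron.
#' @param seed Integer master seed (overrides `config$seed`).
#' @return A named list of `foh_eval` objects, one per scheme, with the
#'   extracted matrix attached as attribute `"matrix"`.
#' @export
run_experiment <- function(config = sim_config(), schemes = "kfold10",
                           n_classes = 3, transform_labels = FALSE,
                           plan = imputation_plan(), prevday = FALSE,
                           threshold = NULL, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(threshold))
    threshold <- if (config$dialect == "heartman") 0.6 else 0.3
  cohort <- generate_cohort(config)
  mat <- build_feature_matrix(cohort, transform_labels = transform_labels,
                              prevday = prevday, threshold = threshold)
  out <- lapply(schemes, function(sch)
    evaluate_matrix(mat, scheme = sch, plan = plan, n_classes = n_classes,
                    seed = config$seed))
  names(out) <- schemes
  attr(out, "matrix") <- mat
  out
}

#' Build the modeling-ready feature matrix from a cohort
#'
#' Curation, dialect feature extraction, optional label transformation and
#' previous-day feature, and missingness filtering, in the standard order.
#'
#' @param cohort A `foh_cohort`.
#' @param transform_labels Rewrite Chiron labels to usual-relative.
#' @param prevday Add the previous-day FOH feature.
#' @param threshold Missingness threshold (`NULL` = dialect default).
#' @return A feature matrix.
#' @export
build_feature_matrix <- function(cohort, transform_labels = FALSE,
                                 prevday = FALSE, threshold = NULL) {
  dialect <- cohort$config$dialect
  if (is.null(threshold)) threshold <- if (dialect == "heartman") 0.6 else 0.3
  cur <- curate_measurements(cohort$measurements)$curated
  mat <- if (dialect == "heartman")
    extract_heartman_features(cur, cohort$reports,
                              anchor_minute = cohort$config$report_minute)
  else
    extract_chiron_features(cur, cohort$reports,
                            anchor_minute = cohort$config$report_minute)
  if (transform_labels) {
    .assert(dialect == "chiron",
            "label transformation applies to the Chiron dialect")
    for (p in unique(mat$patient_id)) {
      rows <- which(mat$patient_id == p)
      o <- rows[order(mat$date[rows])]
      mat$label[o] <- transform_yesterday_to_usual(mat$label[o], mat$date[o])
    }
  }
  if (prevday) mat <- add_prevday_foh(mat, cohort$reports)
  filter_by_missingness(mat, threshold)
}
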
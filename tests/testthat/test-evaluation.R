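meta_frame <- function(pats, days_each, start = "2023-01-01") {
  data.frame(patient_id = rep(pats, each = days_each),
             date = rep(as.Date(start) + seq_len(days_each) - 1,
                        length(pats)),
             stringsAsFactors = FALSE)
}

test_that("split plans satisfy disjointness and coverage across seeds", {
  meta <- meta_frame(sprintf("P%d", 1:5), 20)
  for (seed in 1:20) {
    kf <- make_splits(meta, "kfold10", seed)
    expect_length(kf, 10)
    tests <- unlist(lapply(kf, `[[`, "test"))
    expect_setequal(tests, seq_len(nrow(meta)))
    expect_false(any(duplicated(tests)))
    for (sp in kf) expect_length(intersect(sp$train, sp$test), 0)
  }
  lo <- make_splits(meta, "loso")
  expect_length(lo, 5)
  for (sp in lo)
    expect_length(unique(meta$patient_id[sp$test]), 1)
  expect_error(make_splits(meta_frame("P1", 10), "loso"), "2 patients")
})

test_that("leave-half puts days 0-50 of a 0-100 span into training", {
  meta <- data.frame(patient_id = "P1",
                     date = as.Date("2023-01-01") + 0:100,
                     stringsAsFactors = FALSE)
  meta <- rbind(meta, data.frame(patient_id = "P2",
                                 date = as.Date("2023-01-01") + 0:10))
  sp <- make_splits(meta, "leave_half")[[1]]
  p1_train_days <- as.numeric(meta$date[sp$train][meta$patient_id[sp$train] == "P1"]) -
    as.numeric(as.Date("2023-01-01"))
  expect_equal(sort(p1_train_days), 0:50)
  # patients with < 2 rows are excluded and logged
  meta2 <- rbind(meta, data.frame(patient_id = "P3",
                                  date = as.Date("2023-01-01")))
  plan <- make_splits(meta2, "leave_half")
  expect_equal(attr(plan, "excluded"), "P3")
  expect_false(any(c(plan[[1]]$train, plan[[1]]$test) %in%
                     which(meta2$patient_id == "P3")))
})

test_that("accuracy and F1 match their definitions and worked example", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1.0)
  tr <- c("worse", "worse", "same", "better")
  pr <- c("worse", "same", "same", "better")
  expect_equal(accuracy(tr, pr), 0.75)
  sc <- f1_scores(tr, pr)
  expect_equal(sc$macro_f1, 7 / 9)
  expect_equal(sc$accuracy, 0.75)
  expect_equal(sum(sc$confusion), 4)
  expect_equal(sum(diag(sc$confusion)) / sum(sc$confusion), sc$accuracy)
  # majority-class predictor on a 73%-'same' vector
  n <- 100
  truth <- c(rep("same", 73), rep("worse", 15), rep("better", 12))
  expect_equal(accuracy(truth, rep("same", n)), 0.73)
  # never predicting a present class gives that class F1 = 0
  pc <- f1_scores(truth, rep("same", n))$per_class
  expect_equal(pc$f1[pc$class == "worse"], 0)
  expect_error(accuracy(c("a"), c("a", "b")), "mismatch")
})

test_that("metrics match independent oracles on random vectors", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    cls <- c("worse", "same", "better")[seq_len(sample(2:3, 1))]
    tr <- sample(cls, n, TRUE)
    pr <- sample(cls, n, TRUE)
    sc <- suppressWarnings(f1_scores(tr, pr, classes = cls))
    expect_equal(sc$accuracy, oracle_accuracy(tr, pr))
    expect_equal(sc$macro_f1, oracle_macro_f1(tr, pr, cls))
  }
})

test_that("the Welch t-test behaves at the boundaries and detects separation", {
  expect_warning(res <- compare_scores_ttest(c(0.5, 0.5), c(0.5, 0.5)),
                 "zero variance")
  expect_equal(res$p_value, 1)
  a <- c(0.9, 0.91, 0.92, 0.89); b <- c(0.1, 0.11, 0.12, 0.09)
  expect_lt(compare_scores_ttest(a, b)$p_value, 0.05)
  ab <- compare_scores_ttest(a, b); ba <- compare_scores_ttest(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$t, -ba$t)
  expect_error(compare_scores_ttest(1, c(1, 2)), "at least 2")
})

test_that("two-class evaluation drops 'same' rows before splitting", {
  set.seed(31)
  n <- 90
  m <- data.frame(patient_id = rep(sprintf("P%d", 1:3), each = 30),
                  date = rep(as.Date("2023-01-01") + 0:29, 3),
                  label = sample(c("worse", "same", "better"), n, TRUE,
                                 prob = c(0.3, 0.4, 0.3)),
                  f1 = rnorm(n), f2 = rnorm(n), stringsAsFactors = FALSE)
  ev <- evaluate_matrix(m, "kfold10", n_classes = 2, seed = 1)
  expect_equal(sum(ev$per_split$n_test), sum(m$label != "same"))
  expect_setequal(rownames(ev$confusion), c("worse", "better"))
})

test_that("oversampled rows never reach a test partition", {
  # the test partitions index the pre-SMOTE matrix, so a synthetic row can
  # only leak through the training frame; check the guard flag end to end
  set.seed(8)
  x <- data.frame(f1 = rnorm(30), f2 = rnorm(30))
  y <- rep(c("worse", "same", "better"), times = c(5, 18, 7))
  sm <- oversample_train(x, y, seed = 3)
  expect_equal(which(!sm$synthetic), 1:30)
  expect_true(all(sm$synthetic[31:length(sm$y)]))
})

test_that("the end-to-end experiment runner returns coherent results", {
  cfg <- sim_config(n_patients = 5, n_days = 25, effect_size = 2,
                    missing_rate_channel = 0.1, report_prob = 0.9, seed = 77)
  res <- run_experiment(cfg, schemes = c("kfold10", "loso"), n_classes = 3,
                        plan = imputation_plan("knn", "global"))
  expect_named(res, c("kfold10", "loso"))
  for (ev in res) {
    expect_s3_class(ev, "foh_eval")
    expect_true(all(ev$per_split$macro_f1 >= 0 & ev$per_split$macro_f1 <= 1))
    expect_equal(sum(ev$confusion), sum(ev$per_split$n_test))
  }
  m <- attr(res, "matrix")
  expect_true(all(c("patient_id", "date", "label") %in% names(m)))
})
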
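test_that("curation drops out-of-bound values, keeps values at the limit", {
  meas <- make_meas("P1", rep("2023-01-01", 4), c(0, 10, 20, 30),
                    c("hr", "sbp", "dbp", "hr"), c(39, 200, 39, 40))
  out <- curate_measurements(meas)
  expect_equal(nrow(out$rejected), 2)
  expect_setequal(out$rejected$value, c(39, 39))
  expect_setequal(out$curated$value, c(200, 40))   # inclusive bounds kept
  # idempotent
  again <- curate_measurements(out$curated)
  expect_equal(again$curated, out$curated)
  expect_equal(nrow(again$rejected), 0)
})

test_that("window statistics match direct arithmetic and empty-window rules", {
  meas <- make_meas("P1", rep("2023-01-05", 3), c(1100, 1150, 1190),
                    "hr", c(70, 80, 90))
  expect_equal(window_statistics(meas, "hr", "2023-01-05", 1200, "3h", "mean"), 80)
  expect_equal(window_statistics(meas, "hr", "2023-01-05", 1200, "3h", "sd"), 10)
  expect_true(is.na(window_statistics(meas, "hr", "2023-01-04", 1200, "day", "mean")))
  # single sample: SD undefined, not zero
  one <- make_meas("P1", "2023-01-05", 1100, "hr", 72)
  expect_true(is.na(window_statistics(one, "hr", "2023-01-05", 1200, "day", "sd")))
  expect_error(window_statistics(meas, "hr", "2023-01-05", 1200, "fortnight"),
               "unknown window")
})

test_that("window statistics agree with a brute-force scan on random streams", {
  set.seed(14)
  n <- 200
  meas <- make_meas("P1", as.Date("2023-02-01") + sample(0:9, n, TRUE),
                    sample(0:1439, n, TRUE), "hr", rnorm(n, 75, 8))
  for (w in c("3h", "24h", "day", "week")) {
    for (s in c("mean", "sd")) {
      got <- window_statistics(meas, "hr", "2023-02-06", 1200, w, s)
      t <- as.numeric(meas$date) * 1440 + meas$minute
      at <- as.numeric(as.Date("2023-02-06")) * 1440 + 1200
      v <- switch(w,
        "3h" = meas$value[t > at - 180 & t <= at],
        "24h" = meas$value[t > at - 1440 & t <= at],
        "week" = meas$value[t > at - 7 * 1440 & t <= at],
        "day" = meas$value[meas$date == as.Date("2023-02-06")])
      want <- if (s == "mean") mean(v) else if (length(v) > 1) sd(v) else NA_real_
      if (length(v) == 0) want <- NA_real_
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("rate-pressure product multiplies SBP by nearby mean HR", {
  t0 <- as.numeric(as.Date("2023-01-01")) * 1440 + 600   # 10:00
  expect_equal(compute_rpp(t0, 120, c(t0 - 5, t0 + 5), c(78, 82)), 9600)
  expect_true(is.na(compute_rpp(t0, 120, c(t0 - 11, t0 + 30), c(78, 82))))
  # brute force on random samples
  set.seed(3)
  ht <- t0 + sample(-60:60, 40)
  hv <- rnorm(40, 70, 5)
  sel <- ht >= t0 - 10 & ht <= t0 + 10
  expect_equal(compute_rpp(t0, 130, ht, hv), 130 * mean(hv[sel]))
})

test_that("weight deltas use the stated fallback windows", {
  d <- as.Date("2023-01-10")
  expect_equal(weight_delta(c(d, d - 4), c(80, 79), d, 4), 1.0)
  expect_equal(weight_delta(c(d, d - 6), c(80, 78), d, 4), 2.0)
  expect_true(is.na(weight_delta(c(d, d - 8), c(80, 78), d, 4)))
  expect_equal(weight_delta(c(d, d - 1), c(80, 79.5), d, 1), 0.5)
  expect_equal(weight_delta(c(d, d - 3), c(80, 79), d, 1), 1.0)
  expect_true(is.na(weight_delta(c(d, d - 4), c(80, 79), d, 1)))
  # exact 4-day-old value preferred over closer fallbacks
  expect_equal(weight_delta(c(d, d - 4, d - 5), c(80, 79, 70), d, 4), 1.0)
})

test_that("personal ratios divide by the patient aggregate", {
  x <- c(80, 90, 100, 10, 30)
  p <- c("A", "A", "A", "B", "B")
  r <- personal_ratio(x, p)
  expect_equal(r[2], 1.0)            # 90 / mean(80,90,100)
  expect_equal(r[4], 0.5)            # 10 / mean(10,30)
  # constant column under the SD aggregate: zero denominator -> missing
  expect_true(all(is.na(personal_ratio(rep(5, 3), rep("A", 3), stat = "sd"))))
  # mean-ratio identity: patient-wise mean of ratios is 1
  set.seed(8)
  x2 <- rnorm(60, 50, 10)
  p2 <- rep(c("A", "B", "C"), each = 20)
  r2 <- personal_ratio(x2, p2)
  expect_equal(as.numeric(tapply(r2, p2, mean)), rep(1, 3), tolerance = 1e-12)
})

test_that("the feature registry is consistent and names are unique", {
  for (dia in c("heartman", "chiron")) {
    reg <- feature_registry(dia)
    expect_false(any(duplicated(reg$name)))
    expect_true(all(reg$group %in% c("cont", "disc", "act", "ex", "env", "derived")))
  }
  # exercise features never get personal ratios
  regh <- feature_registry("heartman")
  expect_true(all(!regh$pratio[regh$group == "ex"]))
  expect_true(all(regh$pratio[regh$group %in% c("cont", "disc", "env")]))
})

test_that("dialect matrices share exactly the registry's shared columns", {
  cfg <- function(dia) sim_config(n_patients = 3, n_days = 15, dialect = dia,
                                  missing_rate_channel = 0.05, seed = 17)
  mh <- build_feature_matrix(generate_cohort(cfg("heartman")), threshold = 1)
  mc <- build_feature_matrix(generate_cohort(cfg("chiron")), threshold = 1)
  common <- compatible_feature_set(mh, mc)
  regh <- feature_registry("heartman"); regc <- feature_registry("chiron")
  names_of <- function(reg) c(reg$name, paste0(reg$name[reg$pratio], ".pratio"))
  expect_setequal(common, intersect(names_of(regh), names_of(regc)))
  # shared base columns are flagged 'shared' in both registries
  base_common <- intersect(regh$name, regc$name)
  expect_setequal(base_common, regh$name[regh$shared])
  expect_setequal(base_common, regc$name[regc$shared])
  # disjoint schemas error
  expect_error(compatible_feature_set(mh[c("patient_id", "date", "label",
                                           "cont.gsr.day.mean")],
                                      mc[c("patient_id", "date", "label",
                                           "cont.body_humidity.day.mean")]))
})

test_that("activity fractions over a fully observed day sum to 1", {
  cfg <- sim_config(n_patients = 2, n_days = 10, missing_rate_channel = 0,
                    nonwear_block_prob = 0, report_prob = 1, seed = 23)
  m <- build_feature_matrix(generate_cohort(cfg), threshold = 1)
  fr <- m[paste0("act.frac_", c("walking", "running", "other", "standing",
                                "rest"), ".day")]
  expect_equal(rowSums(as.matrix(fr)), rep(1, nrow(m)), tolerance = 1e-12)
})

test_that("every registered feature matches brute-force recomputation", {
  for (dia in c("heartman", "chiron")) {
    cfg <- sim_config(n_patients = 2, n_days = 12, dialect = dia,
                      missing_rate_channel = 0.25, nonwear_block_prob = 0.05,
                      report_prob = 0.8, seed = 41)
    co <- generate_cohort(cfg)
    cur <- curate_measurements(co$measurements)$curated
    m <- if (dia == "heartman") extract_heartman_features(cur, co$reports)
      else extract_chiron_features(cur, co$reports)
    reg <- feature_registry(dia)
    # a handful of rows, every feature
    set.seed(5)
    rows <- sample(nrow(m), min(6, nrow(m)))
    for (r in rows) {
      for (k in seq_len(nrow(reg))) {
        want <- oracle_feature(cur, m$patient_id[r], m$date[r], 1200,
                               reg[k, ], dia)
        got <- m[[reg$name[k]]][r]
        if (is.na(want) || !is.finite(want)) {
          expect_true(is.na(got),
                      label = paste(dia, reg$name[k], "row", r, "expected NA"))
        } else {
          expect_equal(got, want, tolerance = 1e-9,
                       label = paste(dia, reg$name[k], "row", r))
        }
      }
    }
  }
})

test_that("no feature uses data after the entry's calendar day", {
  # truncating every measurement after the FOH day leaves features unchanged
  cfg <- sim_config(n_patients = 2, n_days = 10, missing_rate_channel = 0,
                    nonwear_block_prob = 0, report_prob = 1, seed = 19)
  co <- generate_cohort(cfg)
  cur <- curate_measurements(co$measurements)$curated
  m <- extract_heartman_features(cur, co$reports)
  r <- which(m$date == as.Date("2023-01-06"))[1]
  pid <- m$patient_id[r]
  keep <- cur$patient_id != pid | cur$date <= as.Date("2023-01-06")
  m2 <- extract_heartman_features(cur[keep, ], co$reports)
  fc <- setdiff(feature_cols(m), grep("pratio", names(m), value = TRUE))
  expect_equal(unlist(m[r, fc]), unlist(m2[r, fc]))
})
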
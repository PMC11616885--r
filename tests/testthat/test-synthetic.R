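small_cfg <- function(...) {
  sim_config(n_patients = 3, n_days = 20, seed = 11, ...)
}

test_that("latent chain honours degenerate persistence and point masses", {
  x <- simulate_latent_foh(10, persistence = 1, probs = c(0.2, 0.6, 0.2),
                           rng_seed = 1)
  expect_length(unique(x), 1)
  expect_equal(simulate_latent_foh(5, 0, probs = c(0, 1, 0), rng_seed = 2),
               rep("same", 5))
  expect_error(simulate_latent_foh(5, 0.5, probs = c(0.5, 0.2, 0.2)))
  expect_error(simulate_latent_foh(0, 0.5, probs = c(0.2, 0.6, 0.2)))
})

test_that("latent chain marginals match the stationary distribution", {
  # redrawing from `probs` on non-persistent days makes `probs` stationary
  probs <- c(worse = 0.2, same = 0.6, better = 0.2)
  x <- simulate_latent_foh(10000, 0.8, probs, rng_seed = 5)
  emp <- table(factor(x, names(probs))) / length(x)
  expect_true(all(abs(as.numeric(emp) - probs) < 0.02))
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$reports, b$reports)
  expect_identical(a$truth$latent, b$truth$latent)
  c2 <- generate_cohort(sim_config(n_patients = 3, n_days = 20, seed = 12))
  expect_false(identical(a$measurements, c2$measurements))
})

test_that("zero missingness yields a fully observed cohort with daily reports", {
  cfg <- sim_config(n_patients = 2, n_days = 15, missing_rate_channel = 0,
                    nonwear_block_prob = 0, report_prob = 1, seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth$masked_values), 0)
  expect_equal(nrow(co$reports), 2 * 15)
  # every channel present on every patient-day
  for (ch in c("hr", "weight", "air_temp")) {
    sub <- co$measurements[co$measurements$channel == ch, ]
    expect_equal(nrow(unique(sub[c("patient_id", "date")])), 30)
  }
})

test_that("yesterday-relative derivation follows the day-over-day rule", {
  d <- as.Date("2023-01-01") + 0:3
  expect_equal(derive_yesterday_relative(c("same", "worse", "worse", "better"), d),
               c("same", "worse", "same", "better"))
  expect_equal(derive_yesterday_relative(rep("better", 4), d), rep("same", 4))
  # a gap restarts the comparison: second report is a run start
  d2 <- as.Date("2023-01-01") + c(0, 5)
  expect_equal(derive_yesterday_relative(c("worse", "better"), d2),
               c("same", "same"))
})

test_that("masking conserves values and stays within binomial bounds", {
  cfg <- sim_config(n_patients = 5, n_days = 40, missing_rate_channel = 0,
                    nonwear_block_prob = 0, report_prob = 1, seed = 9)
  full <- generate_cohort(cfg)
  cfg2 <- cfg; cfg2$missing_rate_channel <- 0.3; cfg2$nonwear_block_prob <- 0
  masked <- apply_missingness(full, cfg2, rng_seed = 21)
  # conservation: observed + masked = full, disjointly
  comb <- rbind(masked$measurements, masked$truth$masked_values)
  o <- order(comb$patient_id, comb$channel, comb$date, comb$minute)
  f <- full$measurements
  of <- order(f$patient_id, f$channel, f$date, f$minute)
  expect_equal(comb[o, ], f[of, ], ignore_attr = TRUE)
  # day-level Bernoulli rate ~ 0.3 (99% binomial interval, 5*40 days/channel)
  mk <- masked$truth$masked_values
  wd <- unique(paste(mk$patient_id[mk$channel == "weight"],
                     mk$date[mk$channel == "weight"]))
  n_days <- 5 * 40
  p_hat <- length(wd) / n_days
  expect_lt(abs(p_hat - 0.3), 2.58 * sqrt(0.3 * 0.7 / n_days))
})

test_that("non-wear blocks mask wearable channels but not manual entries", {
  cfg <- sim_config(n_patients = 1, n_days = 30, missing_rate_channel = 0,
                    nonwear_block_prob = 0, report_prob = 1, seed = 2)
  full <- generate_cohort(cfg)
  cfg2 <- cfg; cfg2$nonwear_block_prob <- 0.15; cfg2$nonwear_block_len <- 3
  masked <- apply_missingness(full, cfg2, rng_seed = 33)
  mk <- masked$truth$masked_values
  expect_gt(nrow(mk), 0)
  expect_true(all(mk$channel %in%
                    c("hr", "skin_temp", "gsr", "energy", "activity",
                      "exercise", "exercise_valid")))
  # manual channels survive in full on every day
  w <- masked$measurements[masked$measurements$channel == "weight", ]
  expect_equal(nrow(w), 30)
})

test_that("the daily-value matrix holds per-day channel means", {
  co <- generate_cohort(sim_config(n_patients = 2, n_days = 6, seed = 13))
  dv <- daily_value_matrix(co)
  expect_equal(nrow(dv), 12)
  mm <- co$measurements
  sub <- mm[mm$channel == "hr" & mm$patient_id == "P001", ]
  for (d in unique(sub$date)) {
    expect_equal(dv$hr[dv$patient_id == "P001" & dv$date == d],
                 mean(sub$value[sub$date == d]))
  }
  # a masked day shows up as NA
  ch <- unique(mm$channel)[1]
  miss_days <- setdiff(paste(co$truth$latent$patient_id, co$truth$latent$date),
                       paste(mm$patient_id[mm$channel == "hr"],
                             mm$date[mm$channel == "hr"]))
  if (length(miss_days)) {
    key <- paste(dv$patient_id, dv$date)
    expect_true(all(is.na(dv$hr[key %in% miss_days])))
  }
})

test_that("large effects separate worse from better days in the features", {
  cfg <- sim_config(n_patients = 6, n_days = 40, effect_size = 3,
                    missing_rate_channel = 0.05, nonwear_block_prob = 0,
                    report_prob = 1, seed = 31)
  co <- generate_cohort(cfg)
  m <- build_feature_matrix(co)
  m2 <- m[m$label != "same", ]
  hr <- m2$cont.hr.day.mean
  ok <- !is.na(hr)
  # worse days should show clearly elevated heart rate
  expect_gt(mean(hr[ok & m2$label == "worse"]),
            mean(hr[ok & m2$label == "better"]) + 5)
})
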
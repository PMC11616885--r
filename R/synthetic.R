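# Synthetic telemonitoring cohort generator.
#
# Emulates the data structure of the two telemonitoring studies: per-patient
# physiological baselines, a sticky 3-state latent daily health state that
# shifts the channels, wearable channels sampled many times a day, daily
# manual entries, ambient channels, an activity-annotation stream, exercise
# logs, two FOH label dialects, and heavy structured missingness (per-channel
# day-level dropout plus multi-day non-wear blocks).  Ground truth (latent
# states, masked values, baselines) is returned for recovery tests.

#' Default channel parameter table
#'
#' One row per channel: population mean, between-patient SD, within-patient
#' SD, samples per day, which dialect's device records it, the channel kind
#' (wearable, manual entry, ambient sensor) and the shift (in channel units,
#' scaled by `effect_size`) applied on latent 'worse' days (negated on
#' 'better' days).  Means and SDs are plausible values for an elderly
#' heart-failure cohort; the real studies' channel distributions are not
#' published, so these are free choices documented in the vignette.
#'
#' @return A data frame with columns `channel`, `kind`, `dialect`, `mean`,
#'   `between_sd`, `within_sd`, `freq`, `effect`.
#' @export
default_channels <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    df(channel = "hr",           kind = "wearable", dialect = "both",     mean = 72,   between_sd = 8,   within_sd = 6,    freq = 96, effect = 5),
    df(channel = "skin_temp",    kind = "wearable", dialect = "both",     mean = 33,   between_sd = 0.8, within_sd = 0.5,  freq = 96, effect = 0.4),
    df(channel = "energy",       kind = "wearable", dialect = "both",     mean = 1.5,  between_sd = 0.3, within_sd = 0.35, freq = 96, effect = -0.25),
    df(channel = "gsr",          kind = "wearable", dialect = "heartman", mean = 5,    between_sd = 1.5, within_sd = 1,    freq = 96, effect = 0.8),
    df(channel = "body_humidity",kind = "wearable", dialect = "chiron",   mean = 40,   between_sd = 8,   within_sd = 5,    freq = 96, effect = 3),
    df(channel = "qt_interval",  kind = "wearable", dialect = "chiron",   mean = 400,  between_sd = 20,  within_sd = 12,   freq = 96, effect = 8),
    df(channel = "qrs_duration", kind = "wearable", dialect = "chiron",   mean = 95,   between_sd = 8,   within_sd = 5,    freq = 96, effect = 2),
    df(channel = "weight",       kind = "manual",   dialect = "both",     mean = 82,   between_sd = 12,  within_sd = 0.4,  freq = 1,  effect = 0.5),
    df(channel = "sbp",          kind = "manual",   dialect = "both",     mean = 125,  between_sd = 12,  within_sd = 8,    freq = 1,  effect = 4),
    df(channel = "dbp",          kind = "manual",   dialect = "both",     mean = 78,   between_sd = 8,   within_sd = 5,    freq = 1,  effect = 2),
    df(channel = "spo2",         kind = "manual",   dialect = "chiron",   mean = 96,   between_sd = 1.5, within_sd = 1,    freq = 1,  effect = -1),
    df(channel = "air_temp",     kind = "ambient",  dialect = "both",     mean = 21,   between_sd = 2,   within_sd = 1.5,  freq = 24, effect = 0),
    df(channel = "air_humidity", kind = "ambient",  dialect = "both",     mean = 45,   between_sd = 8,   within_sd = 6,    freq = 24, effect = 0),
    df(channel = "air_pressure", kind = "ambient",  dialect = "heartman", mean = 1013, between_sd = 5,   within_sd = 4,    freq = 24, effect = 0)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients (>= 1).
#' @param n_days Days of observation per patient; a scalar, or a length-2
#'   range from which each patient's duration is drawn uniformly.
#' @param dialect Which study schema to emulate: `"chiron"` (FOH asked
#'   relative to yesterday) or `"heartman"` (relative to usual).
#' @param state_persistence Probability that today's latent health state
#'   repeats yesterday's ("a bad spell lasts a few days").
#' @param state_probs Probability triple over worse/same/better used on the
#'   first day and on each non-persistent day; must sum to 1.  Because
#'   non-persistent days redraw from this distribution, it is also the
#'   chain's stationary distribution.
#' @param effect_size Global multiplier on the per-channel latent-state
#'   shifts in `channel_params$effect`; 0 disconnects channels from FOH.
#' @param effect_heterogeneity In [0, 1]: 0 gives every patient the same
#'   feature-FOH link; 1 replaces it with a patient-specific random
#'   coefficient (mean 0 across patients), so population models collapse
#'   while personalized ones still work.
#' @param channel_params Channel table as from [default_channels()]; an
#'   empty data frame generates labels only (no measurements).
#' @param missing_rate_channel Per-channel probability that a day's
#'   measurements for that channel are absent (scalar, or named per channel).
#' @param nonwear_block_prob Per-day probability that a multi-day non-wear
#'   block starts (masks all wearable channels).
#' @param nonwear_block_len Mean length, in days, of a non-wear block.
#' @param report_prob Probability that a day's FOH is self-reported.
#' @param report_minute Minute-of-day at which the FOH entry is made (used
#'   as the anchor for windowed features).
#' @param exercise_rate Mean number of guided exercises per day (HeartMan).
#' @param start_date First observation date for every patient.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `foh_sim_config`.
#' @export
sim_config <- function(n_patients = 20,
                       n_days = 84,
                       dialect = c("heartman", "chiron"),
                       state_persistence = 0.8,
                       state_probs = c(worse = 0.2, same = 0.6, better = 0.2),
                       effect_size = 1,
                       effect_heterogeneity = 0,
                       channel_params = default_channels(),
                       missing_rate_channel = 0.2,
                       nonwear_block_prob = 0.02,
                       nonwear_block_len = 3,
                       report_prob = 0.8,
                       report_minute = 1200,
                       exercise_rate = 0.7,
                       start_date = as.Date("2023-01-01"),
                       seed = 1L) {
  dialect <- match.arg(dialect)
  .assert(n_patients >= 1, "n_patients must be >= 1")
  .assert(all(n_days >= 1) && length(n_days) %in% 1:2, "invalid n_days")
  .assert(length(state_probs) == 3 && abs(sum(state_probs) - 1) < 1e-8 &&
            all(state_probs >= 0), "state_probs must be 3 non-negative values summing to 1")
  for (p in c(state_persistence, missing_rate_channel, nonwear_block_prob,
              report_prob, effect_heterogeneity)) {
    .assert(all(p >= 0 & p <= 1), "probabilities must lie in [0, 1]")
  }
  structure(list(
    n_patients = as.integer(n_patients), n_days = as.integer(n_days),
    dialect = dialect, state_persistence = state_persistence,
    state_probs = stats::setNames(as.numeric(state_probs), FOH_LEVELS),
    effect_size = effect_size, effect_heterogeneity = effect_heterogeneity,
    channel_params = channel_params,
    missing_rate_channel = missing_rate_channel,
    nonwear_block_prob = nonwear_block_prob,
    nonwear_block_len = nonwear_block_len,
    report_prob = report_prob, report_minute = as.integer(report_minute),
    exercise_rate = exercise_rate,
    start_date = as.Date(start_date), seed = as.integer(seed)
  ), class = "foh_sim_config")
}

#' Simulate the latent daily health-state chain
#'
#' A sticky 3-state Markov chain over worse/same/better: day 1 is drawn from
#' `probs`; each later day repeats the previous day with probability
#' `persistence` and is otherwise redrawn from `probs`.  The redraw makes
#' `probs` the stationary distribution.
#'
#' @param n_days Number of days (>= 1).
#' @param persistence Probability in [0, 1] of repeating yesterday's state.
#' @param probs Probability triple over worse/same/better, summing to 1.
#' @param rng_seed Optional integer seed; if `NULL` the current RNG stream
#'   is used.
#' @return Character vector of length `n_days` over worse/same/better.
#' @export
simulate_latent_foh <- function(n_days, persistence, probs, rng_seed = NULL) {
  .assert(n_days >= 1, "n_days must be >= 1")
  .assert(length(probs) == 3 && all(probs >= 0) && abs(sum(probs) - 1) < 1e-8,
          "probs must be 3 non-negative values summing to 1")
  .assert(persistence >= 0 && persistence <= 1, "persistence must be in [0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  draw <- function(n) sample(FOH_LEVELS, n, replace = TRUE, prob = probs)
  x <- character(n_days)
  x[1] <- draw(1)
  if (n_days > 1) {
    keep <- stats::runif(n_days - 1) < persistence
    fresh <- draw(n_days - 1)
    for (i in 2:n_days) x[i] <- if (keep[i - 1]) x[i - 1] else fresh[i - 1]
  }
  x
}

#' Derive yesterday-relative (Chiron-dialect) labels from latent states
#'
#' The Chiron question asks how the patient feels compared to yesterday, so
#' a reported day's label is the ordinal change of the latent usual-relative
#' state versus the previous calendar day.  The first day of any run of
#' consecutive reported days (no reported yesterday) is `"same"`: the
#' patient cannot compare against an unreported day.
#'
#' @param latent Character vector of latent states on the reported days.
#' @param dates `Date` vector of the reported days, strictly increasing.
#' @return Character vector of yesterday-relative labels, same length.
#' @export
derive_yesterday_relative <- function(latent, dates) {
  .assert(length(latent) == length(dates), "length mismatch")
  .assert(all(latent %in% FOH_LEVELS), "latent must be worse/same/better")
  if (length(latent) == 0L) return(character(0))
  dates <- as.Date(dates)
  .assert(all(diff(as.numeric(dates)) > 0), "dates must be strictly increasing")
  out <- rep("same", length(latent))
  if (length(latent) > 1) {
    consec <- diff(as.numeric(dates)) == 1
    dlt <- diff(.foh_ord(latent))
    out[-1][consec] <- c("worse", "same", "better")[sign(dlt[consec]) + 2]
  }
  out
}

# Split a canonical 3-class label into a raw 1..5 answer on the given
# dialect's scale ('worse'/'better' split uniformly over the two extremes).
.raw_from_canonical <- function(canonical, dialect) {
  n <- length(canonical)
  extreme <- sample(c(0L, 1L), n, replace = TRUE)    # 0 = moderate, 1 = extreme
  raw <- integer(n)
  if (dialect == "chiron") {       # 1 = much worse ... 5 = much better
    raw[canonical == "worse"]  <- 2L - extreme[canonical == "worse"]
    raw[canonical == "same"]   <- 3L
    raw[canonical == "better"] <- 4L + extreme[canonical == "better"]
  } else {                         # 1 = much better ... 5 = much worse
    raw[canonical == "better"] <- 2L - extreme[canonical == "better"]
    raw[canonical == "same"]   <- 3L
    raw[canonical == "worse"]  <- 4L + extreme[canonical == "worse"]
  }
  raw
}

# Activity composition per kind of day.  HeartMan classes: walking, running,
# other movement, standing, rest; Chiron classes: lying, sitting, moving.
.activity_classes <- function(dialect) {
  if (dialect == "heartman") c("walking", "running", "other", "standing", "rest")
  else c("lying", "sitting", "moving")
}

.activity_base_logw <- function(dialect) {
  if (dialect == "heartman") log(c(0.12, 0.03, 0.10, 0.25, 0.50))
  else log(c(0.35, 0.45, 0.20))
}

# Which classes are sedentary (pushed up on 'worse' days).
.activity_sedentary <- function(dialect) {
  if (dialect == "heartman") c(FALSE, FALSE, FALSE, FALSE, TRUE)
  else c(TRUE, FALSE, FALSE)
}

#' Generate a synthetic telemonitoring cohort
#'
#' Draws per-patient baselines, simulates the latent health state, emits all
#' configured channels (wearable streams at their sampling frequency, daily
#' manual entries, ambient readings, an activity-annotation stream and, for
#' the HeartMan dialect, exercise logs), produces FOH reports in the
#' configured dialect, and finally injects missingness.  All randomness is
#' driven by `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `foh_cohort`: a list with elements
#'   \describe{
#'     \item{measurements}{data frame `patient_id`, `date`, `minute`,
#'       `channel`, `value` (after missingness injection).}
#'     \item{reports}{data frame `patient_id`, `date`, `raw_value`,
#'       `dialect`.}
#'     \item{truth}{list with `latent` (patient, date, state),
#'       `baselines` (patient x channel), `effect_coef` (per-patient
#'       multiplier on the channel shifts), and `masked_values` (the rows
#'       removed by missingness).}
#'     \item{config}{the generating config.}
#'   }
#' @export
generate_cohort <- function(config) {
  .assert(inherits(config, "foh_sim_config"), "config must come from sim_config()")
  set.seed(config$seed)
  ch <- config$channel_params
  use <- if (nrow(ch)) ch[ch$dialect %in% c("both", config$dialect), , drop = FALSE] else ch
  acts <- .activity_classes(config$dialect)
  base_logw <- .activity_base_logw(config$dialect)
  sed <- .activity_sedentary(config$dialect)

  meas <- list(); reports <- list(); latent_all <- list(); base_all <- list()
  eff_coef <- numeric(config$n_patients)
  pid_all <- sprintf("P%03d", seq_len(config$n_patients))

  for (p in seq_len(config$n_patients)) {
    pid <- pid_all[p]
    nd <- if (length(config$n_days) == 2)
      sample(config$n_days[1]:config$n_days[2], 1) else config$n_days
    dates <- config$start_date + seq_len(nd) - 1
    state <- simulate_latent_foh(nd, config$state_persistence, config$state_probs)
    ssign <- c(worse = 1, same = 0, better = -1)[state]
    h <- config$effect_heterogeneity
    m_p <- (1 - h) + h * stats::rnorm(1, 0, 1.5)
    eff_coef[p] <- m_p
    latent_all[[p]] <- data.frame(patient_id = pid, date = dates,
                                  state = state, stringsAsFactors = FALSE)

    if (nrow(use)) {
      basel <- stats::rnorm(nrow(use), use$mean, use$between_sd)
      base_all[[p]] <- data.frame(patient_id = pid, channel = use$channel,
                                  baseline = basel, stringsAsFactors = FALSE)
      for (k in seq_len(nrow(use))) {
        freq <- use$freq[k]
        minutes <- if (freq == 1) config$report_minute - 30L
          else as.integer(round(seq(0, 1440 - 1440 / freq, by = 1440 / freq)))
        shift <- config$effect_size * use$effect[k] * m_p * ssign
        nval <- nd * length(minutes)
        vals <- rep(basel[k] + shift, each = length(minutes)) +
          stats::rnorm(nval, 0, use$within_sd[k])
        meas[[length(meas) + 1]] <- data.frame(
          patient_id = pid, date = rep(dates, each = length(minutes)),
          minute = rep(minutes, nd), channel = use$channel[k], value = vals,
          stringsAsFactors = FALSE)
      }
    }

    # activity annotation stream (codes 1..K), same grid as wearables
    if (nrow(use) && any(use$kind == "wearable")) {
      freq <- 96L
      minutes <- as.integer(seq(0, 1440 - 15, by = 15))
      p_logw <- base_logw + stats::rnorm(length(acts), 0, 0.3)
      codes <- integer(0)
      for (d in seq_len(nd)) {
        lw <- p_logw
        lw[sed] <- lw[sed] + 0.4 * config$effect_size * m_p * ssign[d]
        lw[!sed] <- lw[!sed] - 0.4 * config$effect_size * m_p * ssign[d]
        pr <- exp(lw) / sum(exp(lw))
        codes <- c(codes, sample(seq_along(acts), freq, replace = TRUE, prob = pr))
      }
      meas[[length(meas) + 1]] <- data.frame(
        patient_id = pid, date = rep(dates, each = freq),
        minute = rep(minutes, nd), channel = "activity",
        value = as.numeric(codes), stringsAsFactors = FALSE)
    }

    # exercise logs (HeartMan app-guided sessions)
    if (config$dialect == "heartman" && config$exercise_rate > 0) {
      nex <- stats::rpois(nd, config$exercise_rate)
      for (d in which(nex > 0)) {
        mins <- sort(sample(480:1140, nex[d]))
        dur <- pmax(5, round(stats::rnorm(nex[d], 20, 5)))
        valid <- stats::rbinom(nex[d], 1, 0.9)
        meas[[length(meas) + 1]] <- data.frame(
          patient_id = pid, date = dates[d], minute = mins,
          channel = "exercise", value = as.numeric(dur),
          stringsAsFactors = FALSE)
        meas[[length(meas) + 1]] <- data.frame(
          patient_id = pid, date = dates[d], minute = mins,
          channel = "exercise_valid", value = as.numeric(valid),
          stringsAsFactors = FALSE)
      }
    }

    # FOH reports
    rep_days <- which(stats::runif(nd) < config$report_prob)
    if (length(rep_days)) {
      canon <- if (config$dialect == "heartman") state[rep_days]
        else derive_yesterday_relative(state[rep_days], dates[rep_days])
      reports[[length(reports) + 1]] <- data.frame(
        patient_id = pid, date = dates[rep_days],
        raw_value = .raw_from_canonical(canon, config$dialect),
        dialect = config$dialect, stringsAsFactors = FALSE)
    }
  }

  cohort <- structure(list(
    measurements = if (length(meas)) do.call(rbind, meas) else
      data.frame(patient_id = character(), date = as.Date(character()),
                 minute = integer(), channel = character(), value = numeric()),
    reports = if (length(reports)) do.call(rbind, reports) else
      data.frame(patient_id = character(), date = as.Date(character()),
                 raw_value = integer(), dialect = character()),
    truth = list(latent = do.call(rbind, latent_all),
                 baselines = if (length(base_all)) do.call(rbind, base_all) else NULL,
                 effect_coef = stats::setNames(eff_coef, pid_all),
                 masked_values = NULL),
    config = config), class = "foh_cohort")
  rownames(cohort$measurements) <- NULL
  rownames(cohort$reports) <- NULL

  masked <- apply_missingness(cohort, config, rng_seed = .stage_seed(config$seed, 7L))
  masked
}

#' Inject structured missingness into a fully observed cohort
#'
#' Two MCAR mechanisms: (i) per-channel day-level Bernoulli dropout (a whole
#' day of a channel's measurements disappears), and (ii) contiguous non-wear
#' blocks during which every wearable channel (and the activity annotation)
#' is absent while manual entries and ambient sensors are unaffected.  Every
#' removed row is recorded in `truth$masked_values`.
#'
#' @param cohort A `foh_cohort` (fully observed, or already partially masked
#'   — masking composes).
#' @param config The [sim_config()] controlling the rates.
#' @param rng_seed Integer seed for the masking draws.
#' @return The cohort with masked measurements and `truth$masked_values`
#'   filled in.
#' @export
apply_missingness <- function(cohort, config, rng_seed = 1L) {
  .assert(inherits(cohort, "foh_cohort"), "cohort must be a foh_cohort")
  set.seed(rng_seed)
  m <- cohort$measurements
  if (!nrow(m)) {
    cohort$truth$masked_values <- m
    return(cohort)
  }
  ch <- config$channel_params
  wearable <- c(ch$channel[ch$kind == "wearable"], "activity",
                "exercise", "exercise_valid")
  rate <- config$missing_rate_channel
  chans <- unique(m$channel)
  rates <- if (is.null(names(rate))) stats::setNames(rep_len(rate, length(chans)), chans)
    else rate

  key <- paste(m$patient_id, m$date, m$channel)
  ukey <- unique(key)
  uch <- sub("^\\S+ \\S+ ", "", ukey)
  r <- rates[uch]; r[is.na(r)] <- 0
  drop_day <- stats::runif(length(ukey)) < r
  drop1 <- key %in% ukey[drop_day]

  # non-wear blocks per patient
  drop2 <- rep(FALSE, nrow(m))
  if (config$nonwear_block_prob > 0) {
    for (pid in unique(m$patient_id)) {
      rows <- which(m$patient_id == pid)
      days <- sort(unique(m$date[rows]))
      starts <- which(stats::runif(length(days)) < config$nonwear_block_prob)
      if (!length(starts)) next
      nonwear <- rep(FALSE, length(days))
      for (s in starts) {
        len <- 1L + stats::rpois(1, max(config$nonwear_block_len - 1, 0))
        nonwear[s:min(s + len - 1L, length(days))] <- TRUE
      }
      drop2[rows] <- (m$date[rows] %in% days[nonwear]) &
        (m$channel[rows] %in% wearable)
    }
  }

  drop <- drop1 | drop2
  masked <- m[drop, , drop = FALSE]
  rownames(masked) <- NULL
  cohort$measurements <- m[!drop, , drop = FALSE]
  rownames(cohort$measurements) <- NULL
  cohort$truth$masked_values <- rbind(cohort$truth$masked_values, masked)
  cohort
}

#' Daily-value matrix of a cohort
#'
#' One row per patient-day, one column per channel holding that day's mean
#' measurement (`NA` where the day has none).  This is the natural input for
#' imputation-recovery experiments: masking a fully observed cohort and
#' imputing this matrix can be scored against the true day values.
#'
#' @param cohort A `foh_cohort`.
#' @return A feature matrix (`patient_id`, `date`, `label = "same"`
#'   placeholder, one numeric column per channel).
#' @export
daily_value_matrix <- function(cohort) {
  m <- cohort$measurements
  key <- unique(m[c("patient_id", "date")])
  key <- key[order(key$patient_id, key$date), , drop = FALSE]
  out <- data.frame(patient_id = key$patient_id, date = key$date,
                    label = "same", stringsAsFactors = FALSE)
  for (ch in sort(unique(m$channel))) {
    sub <- m[m$channel == ch, , drop = FALSE]
    agg <- tapply(sub$value, paste(sub$patient_id, sub$date), mean)
    out[[ch]] <- as.numeric(agg[paste(out$patient_id, out$date)])
  }
  rownames(out) <- NULL
  out
}

#' @export
print.foh_cohort <- function(x, ...) {
  cat("Synthetic telemonitoring cohort (", x$config$dialect, " dialect)\n", sep = "")
  cat("  patients:     ", length(unique(x$truth$latent$patient_id)), "\n")
  cat("  patient-days: ", nrow(x$truth$latent), "\n")
  cat("  measurements: ", nrow(x$measurements), " rows, ",
      length(unique(x$measurements$channel)), " channels\n", sep = "")
  cat("  FOH reports:  ", nrow(x$reports), "\n")
  cat("  masked rows:  ",
      if (is.null(x$truth$masked_values)) 0 else nrow(x$truth$masked_values), "\n")
  invisible(x)
}
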
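# Feature extraction.
#
# Turns curated telemonitoring streams into one feature vector per
# FOH-labeled day.  Two dialects are supported, mirroring the two studies'
# devices: the HeartMan dialect computes windowed statistics (3 h and 24 h
# before the FOH entry, the calendar day of the entry, day-over-day
# differences, weekly activity/exercise windows), while the Chiron dialect
# computes day-level and per-activity statistics plus derived daily values.
# A machine-readable registry enumerates every feature column, so the
# cross-dialect compatible set is computable by name.
#
# Feature names follow `<group>.<descriptor>.<window>.<stat>` with a
# `.pratio` suffix for personal-ratio variants.

#' Default physiological-plausibility curation rules
#'
#' Values outside these inclusive bounds are treated as data-entry or sensor
#' errors and removed before feature extraction: systolic blood pressure
#' above 200 mmHg, diastolic below 40 mmHg, heart rate below 40 bpm.
#'
#' @return Data frame with columns `channel`, `lower`, `upper` (`NA` = no
#'   bound on that side).
#' @export
default_curation_rules <- function() {
  data.frame(channel = c("sbp", "dbp", "hr"),
             lower = c(NA, 40, 40),
             upper = c(200, NA, NA),
             stringsAsFactors = FALSE)
}

#' Remove physiologically implausible measurements
#'
#' @param measurements Long-format measurement data frame (`patient_id`,
#'   `date`, `minute`, `channel`, `value`).
#' @param rules Curation rule table as from [default_curation_rules()];
#'   bounds are inclusive (a value exactly at the limit is kept).
#' @return A list with `curated` (the surviving rows) and `rejected` (the
#'   removed rows, with a `rule` column naming the violated bound).
#' @export
curate_measurements <- function(measurements, rules = default_curation_rules()) {
  bad <- rep(FALSE, nrow(measurements))
  why <- character(nrow(measurements))
  for (k in seq_len(nrow(rules))) {
    sel <- measurements$channel == rules$channel[k]
    if (!is.na(rules$lower[k])) {
      v <- sel & measurements$value < rules$lower[k]
      bad[v] <- TRUE; why[v] <- paste0(rules$channel[k], " < ", rules$lower[k])
    }
    if (!is.na(rules$upper[k])) {
      v <- sel & measurements$value > rules$upper[k]
      bad[v] <- TRUE; why[v] <- paste0(rules$channel[k], " > ", rules$upper[k])
    }
  }
  rejected <- measurements[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$rule <- why[bad]
  list(curated = measurements[!bad, , drop = FALSE], rejected = rejected)
}

# ---------------------------------------------------------------------------
# Registry

.win_all <- c("3h", "24h", "day", "diff")

#' Feature registry for a dialect
#'
#' Enumerates every feature column this package extracts for a dialect:
#' name, group, computation kind, source channel(s), window, statistic,
#' whether a personal-ratio variant is emitted, and whether the column is
#' shared between the two dialects (same name, same definition).
#'
#' @param dialect `"heartman"` or `"chiron"`.
#' @return Data frame, one row per base feature column.
#' @export
feature_registry <- function(dialect = c("heartman", "chiron")) {
  dialect <- match.arg(dialect)
  rows <- list()
  add <- function(name, group, kind, channel = NA, channel2 = NA,
                  window = NA, stat = NA, class = NA, pratio = TRUE,
                  shared = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, group = group, kind = kind, channel = channel,
      channel2 = channel2, window = window, stat = stat, class = class,
      pratio = pratio, shared = shared, stringsAsFactors = FALSE)
  }

  if (dialect == "heartman") {
    for (ch in c("hr", "skin_temp", "gsr", "energy"))
      for (w in .win_all)
        for (s in c("mean", "sd"))
          add(paste("cont", ch, w, s, sep = "."), "cont", "win", ch,
              window = w, stat = s,
              shared = (w == "day" && ch != "gsr"))
    for (w in .win_all) {
      add(paste("cont.skin_air_ratio", w, "mean", sep = "."), "cont", "ratio",
          "skin_temp", "air_temp", window = w, stat = "mean",
          shared = (w == "day"))
      add(paste("cont.gsr_humidity_ratio", w, "mean", sep = "."), "cont",
          "ratio", "gsr", "air_humidity", window = w, stat = "mean")
    }
    for (w in c("24h", "day", "diff"))
      add(paste("derived.rpp", w, "mean", sep = "."), "derived", "rpp",
          "sbp", "hr", window = w, stat = "mean", shared = (w == "day"))
    for (ch in c("weight", "sbp", "dbp")) {
      add(paste("disc", ch, "day.mean", sep = "."), "disc", "dayval", ch,
          window = "day", stat = "mean", shared = TRUE)
      add(paste("disc", ch, "diff1", sep = "."), "disc", "delta", ch,
          window = "diff1", stat = "value")
      add(paste("disc", ch, "diff4", sep = "."), "disc", "delta", ch,
          window = "diff4", stat = "value")
    }
    for (cl in c("walking", "running", "other", "standing", "rest"))
      for (w in c("day", "24h", "week", "diff"))
        add(paste0("act.frac_", cl, ".", w), "act", "afrac",
            window = w, stat = "fraction", class = cl)
    add("act.hr_static_dynamic.day.mean", "act", "hr_static_dynamic", "hr",
        window = "day", stat = "mean")
    for (w in c("day", "week")) {
      add(paste0("ex.count.", w), "ex", "excount", window = w,
          stat = "count", pratio = FALSE)
      add(paste0("ex.duration.", w), "ex", "exdur", window = w,
          stat = "sum", pratio = FALSE)
    }
    add("ex.validity.day", "ex", "exvalid", window = "day", stat = "mean",
        pratio = FALSE)
    for (ch in c("air_temp", "air_humidity", "air_pressure"))
      for (w in c("day", "3h"))
        for (s in c("mean", "sd"))
          add(paste("env", ch, w, s, sep = "."), "env", "win", ch,
              window = w, stat = s,
              shared = (w == "day" && ch != "air_pressure"))
  } else {
    cont_ch <- c("hr", "skin_temp", "energy", "body_humidity",
                 "qt_interval", "qrs_duration")
    pratio_day_mean <- c("skin_temp", "body_humidity", "qt_interval",
                         "qrs_duration")
    for (ch in cont_ch) {
      for (s in c("mean", "sd"))
        add(paste("cont", ch, "day", s, sep = "."), "cont", "win", ch,
            window = "day", stat = s,
            pratio = (s == "mean" && ch %in% pratio_day_mean),
            shared = ch %in% c("hr", "skin_temp", "energy"))
      for (cl in c("lying", "sitting", "moving"))
        for (s in c("mean", "sd"))
          add(paste0("cont.", ch, ".act_", cl, ".", s), "cont", "actstat",
              ch, window = "day", stat = s, class = cl, pratio = FALSE)
    }
    add("cont.skin_air_ratio.day.mean", "cont", "ratio", "skin_temp",
        "air_temp", window = "day", stat = "mean", shared = TRUE)
    add("cont.body_air_humidity_ratio.day.mean", "cont", "ratio",
        "body_humidity", "air_humidity", window = "day", stat = "mean")
    for (ch in c("weight", "sbp", "dbp", "spo2"))
      add(paste("disc", ch, "day.mean", sep = "."), "disc", "dayval", ch,
          window = "day", stat = "mean", pratio = FALSE,
          shared = ch != "spo2")
    for (ch in c("air_temp", "air_humidity"))
      for (s in c("mean", "sd"))
        add(paste("env", ch, "day", s, sep = "."), "env", "win", ch,
            window = "day", stat = s, pratio = FALSE, shared = TRUE)
    add("derived.rpp.day.mean", "derived", "rpp", "sbp", "hr",
        window = "day", stat = "mean", pratio = FALSE, shared = TRUE)
    add("derived.double_product.day.mean", "derived", "dprod",
        window = "day", stat = "mean", pratio = FALSE)
    add("derived.sbp_dbp_ratio.day.mean", "derived", "ratio2day", "sbp",
        "dbp", window = "day", stat = "mean", pratio = FALSE)
    add("derived.hr_energy_ratio.day.mean", "derived", "hr_ee", "hr",
        "energy", window = "day", stat = "mean", pratio = TRUE)
    pairs <- list(c("lying", "sitting"), c("lying", "moving"),
                  c("sitting", "moving"))
    for (pr in pairs) {
      pn <- paste(pr, collapse = "_")
      add(paste0("act.dur_ratio.", pn, ".day"), "act", "adur_ratio",
          window = "day", stat = "ratio", class = pn, pratio = FALSE)
      add(paste0("act.hr_diff.", pn, ".day"), "act", "hr_act_diff", "hr",
          window = "day", stat = "diff", class = pn, pratio = FALSE)
      add(paste0("act.hr_ratio.", pn, ".day"), "act", "hr_act_ratio", "hr",
          window = "day", stat = "ratio", class = pn, pratio = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# All column names (base + pratio) a dialect's matrix will contain.
.registry_colnames <- function(reg) {
  c(reg$name, paste0(reg$name[reg$pratio], ".pratio"))
}

# ---------------------------------------------------------------------------
# Window primitives

# Per-patient prepared index: per channel sorted sample times (minutes since
# epoch), values, and per-day row ranges.
.prep_patient <- function(meas) {
  out <- list()
  for (ch in unique(meas$channel)) {
    sel <- meas$channel == ch
    dnum <- as.numeric(meas$date[sel])
    t <- dnum * 1440 + meas$minute[sel]
    o <- order(t)
    v <- meas$value[sel][o]; t <- t[o]; dnum <- dnum[o]
    day_split <- split(seq_along(t), dnum)
    dm <- vapply(day_split, function(i) mean(v[i]), 0)
    dsd <- vapply(day_split, function(i) if (length(i) > 1) stats::sd(v[i]) else NA_real_, 0)
    dn <- vapply(day_split, length, 0L)
    out[[ch]] <- list(t = t, v = v, dnum = dnum, day_idx = day_split,
                      day_mean = dm, day_sd = dsd, day_n = dn)
  }
  out
}

# values of channel in (t0, t1]
.win_vals <- function(chp, t0, t1) {
  if (is.null(chp)) return(numeric(0))
  i <- findInterval(c(t0, t1), chp$t)
  if (i[2] <= i[1]) return(numeric(0))
  chp$v[(i[1] + 1):i[2]]
}

.stat <- function(x, stat) {
  if (!length(x)) return(NA_real_)
  if (stat == "mean") mean(x)
  else if (stat == "sd") { if (length(x) < 2) NA_real_ else stats::sd(x) }
  else if (stat == "count") length(x)
  else if (stat == "sum") sum(x)
  else stop("unknown statistic: ", stat)
}

# day-level statistic lookup
.day_stat <- function(chp, dnum, stat) {
  if (is.null(chp)) return(NA_real_)
  k <- as.character(dnum)
  if (stat == "mean") { x <- chp$day_mean[k]; if (is.na(x)) NA_real_ else unname(x) }
  else if (stat == "sd") { x <- chp$day_sd[k]; if (length(x) == 0) NA_real_ else unname(x) }
  else NA_real_
}

# most recent day with data in [d - hi, d - lo]
.ref_day <- function(avail, d, lo, hi) {
  cand <- avail[avail >= d - hi & avail <= d - lo]
  if (!length(cand)) return(NA_real_)
  max(cand)
}

#' Windowed statistic of one channel relative to an anchor
#'
#' Computes the mean or standard deviation of a channel's samples in one of
#' the supported windows: `"3h"` and `"24h"` end at the anchor timestamp,
#' `"week"` covers the 7 days up to the anchor, and `"day"` is the calendar
#' day of the anchor.  An empty window, or an SD over fewer than two
#' samples, yields `NA`.
#'
#' @param measurements Long-format measurements for one patient.
#' @param channel Channel name.
#' @param anchor_date Calendar date of the FOH entry.
#' @param anchor_minute Minute-of-day of the FOH entry.
#' @param window One of `"3h"`, `"24h"`, `"day"`, `"week"`.
#' @param statistic `"mean"` or `"sd"`.
#' @return A single numeric value or `NA`.
#' @export
window_statistics <- function(measurements, channel, anchor_date,
                              anchor_minute = 1200, window, statistic = "mean") {
  .assert(window %in% c("3h", "24h", "day", "week"),
          paste("unknown window kind:", window))
  prep <- .prep_patient(measurements[measurements$channel == channel, ,
                                     drop = FALSE])
  chp <- prep[[channel]]
  d <- as.numeric(as.Date(anchor_date))
  at <- d * 1440 + anchor_minute
  x <- switch(window,
    "3h"   = .win_vals(chp, at - 180, at),
    "24h"  = .win_vals(chp, at - 1440, at),
    "week" = .win_vals(chp, at - 7 * 1440, at),
    "day"  = .win_vals(chp, d * 1440 - 1, (d + 1) * 1440 - 1))
  .stat(x, statistic)
}

#' Rate-pressure product at a blood-pressure event
#'
#' SBP multiplied by the mean heart rate within 10 minutes either side of
#' the SBP measurement; `NA` when no heart-rate sample falls in that
#' interval.
#'
#' @param sbp_time Sample time of the SBP event, minutes since epoch (or a
#'   list with `date` and `minute`).
#' @param sbp_value SBP in mmHg.
#' @param hr_times,hr_values Heart-rate sample times (same scale) and values.
#' @return Numeric RPP or `NA`.
#' @export
compute_rpp <- function(sbp_time, sbp_value, hr_times, hr_values) {
  sel <- hr_times >= sbp_time - 10 & hr_times <= sbp_time + 10
  if (!any(sel)) return(NA_real_)
  sbp_value * mean(hr_values[sel])
}

#' Day-over-day delta of a daily manual entry with fallback windows
#'
#' For `lag_days = 1` the reference is the most recent prior day with a
#' value within the last 3 days; for `lag_days = 4` it is the day exactly 4
#' days back or, failing that, the most recent available day 5-7 days back.
#' `NA` when the current day or every fallback reference is missing.
#'
#' @param dates `Date` vector of the entry days.
#' @param values Numeric entries (one per day).
#' @param date The day whose delta is wanted.
#' @param lag_days 1 or 4.
#' @return Current minus reference value, or `NA`.
#' @export
weight_delta <- function(dates, values, date, lag_days = 1) {
  .assert(lag_days %in% c(1, 4), "lag_days must be 1 or 4")
  dn <- as.numeric(as.Date(dates))
  d <- as.numeric(as.Date(date))
  cur <- values[match(d, dn)]
  if (is.na(cur)) return(NA_real_)
  ref_d <- if (lag_days == 1) .ref_day(dn, d, 1, 3) else {
    if ((d - 4) %in% dn) d - 4 else .ref_day(dn, d, 5, 7)
  }
  if (is.na(ref_d)) return(NA_real_)
  cur - values[match(ref_d, dn)]
}

#' Personal ratio of a feature column
#'
#' Divides each value by the owning patient's study-period aggregate of the
#' column: the patient mean for mean-type features, the patient SD for
#' SD-type features.  A zero or undefined denominator yields `NA`.
#'
#' @param x Numeric feature column (may contain `NA`).
#' @param patient_id Patient id per row.
#' @param stat `"mean"` (default) or `"sd"`, selecting the aggregate.
#' @return Numeric vector of ratios.
#' @export
personal_ratio <- function(x, patient_id, stat = "mean") {
  agg <- if (stat == "sd") {
    tapply(x, patient_id, function(v) {
      v <- v[!is.na(v)]; if (length(v) > 1) stats::sd(v) else NA_real_
    })
  } else {
    tapply(x, patient_id, function(v) mean(v, na.rm = TRUE))
  }
  denom <- as.numeric(agg[as.character(patient_id)])
  denom[!is.finite(denom) | denom == 0] <- NA_real_
  x / denom
}

# ---------------------------------------------------------------------------
# Full extraction

# compute one registry row for one (patient prep, anchor day) pair
.compute_feature <- function(spec, prep, d, at, act_codes) {
  day0 <- d * 1440 - 1; day1 <- (d + 1) * 1440 - 1
  wv <- function(ch, w) switch(w,
    "3h"   = .win_vals(prep[[ch]], at - 180, at),
    "24h"  = .win_vals(prep[[ch]], at - 1440, at),
    "week" = .win_vals(prep[[ch]], at - 7 * 1440, at),
    "day"  = .win_vals(prep[[ch]], day0, day1))
  avail <- function(ch) if (is.null(prep[[ch]])) numeric(0) else
    as.numeric(names(prep[[ch]]$day_idx))
  refd <- function(ch) .ref_day(avail(ch), d, 1, 3)

  # day-d samples of channel joined to activity codes; returns values per code
  act_join <- function(ch) {
    chp <- prep[[ch]]; ap <- prep[["activity"]]
    if (is.null(chp) || is.null(ap)) return(NULL)
    i <- chp$day_idx[[as.character(d)]]; j <- ap$day_idx[[as.character(d)]]
    if (is.null(i) || is.null(j)) return(NULL)
    m <- match(chp$t[i], ap$t[j])
    ok <- !is.na(m)
    if (!any(ok)) return(NULL)
    list(v = chp$v[i][ok], code = ap$v[j][m[ok]])
  }

  switch(spec$kind,
    win = {
      if (spec$window == "diff") {
        r <- refd(spec$channel)
        if (is.na(r)) NA_real_ else
          .day_stat(prep[[spec$channel]], d, spec$stat) -
          .day_stat(prep[[spec$channel]], r, spec$stat)
      } else .stat(wv(spec$channel, spec$window), spec$stat)
    },
    ratio = {
      day_ratio <- function(dd) {
        a <- .day_stat(prep[[spec$channel]], dd, "mean")
        b <- .day_stat(prep[[spec$channel2]], dd, "mean")
        if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
      }
      if (spec$window == "diff") {
        both <- intersect(avail(spec$channel), avail(spec$channel2))
        r <- .ref_day(both, d, 1, 3)
        if (is.na(r)) NA_real_ else day_ratio(d) - day_ratio(r)
      } else if (spec$window == "day") day_ratio(d)
      else {
        a <- mean(wv(spec$channel, spec$window))
        b <- mean(wv(spec$channel2, spec$window))
        if (!is.finite(a) || !is.finite(b) || b == 0) NA_real_ else a / b
      }
    },
    dayval = .day_stat(prep[[spec$channel]], d, "mean"),
    delta = {
      chp <- prep[[spec$channel]]
      if (is.null(chp)) return(NA_real_)
      dn <- as.numeric(names(chp$day_mean))
      weight_delta(as.Date(dn, origin = "1970-01-01"),
                   as.numeric(chp$day_mean),
                   as.Date(d, origin = "1970-01-01"),
                   lag_days = if (spec$window == "diff1") 1 else 4)
    },
    rpp = {
      sp <- prep[[spec$channel]]; hp <- prep[[spec$channel2]]
      if (is.null(sp) || is.null(hp)) return(NA_real_)
      rpp_day <- function(dd) {
        i <- sp$day_idx[[as.character(dd)]]
        if (is.null(i)) return(NA_real_)
        vals <- vapply(i, function(k)
          compute_rpp(sp$t[k], sp$v[k], hp$t, hp$v), 0)
        vals <- vals[!is.na(vals)]
        if (!length(vals)) NA_real_ else mean(vals)
      }
      if (spec$window == "day") rpp_day(d)
      else if (spec$window == "24h") {
        i <- findInterval(c(at - 1440, at), sp$t)
        if (i[2] <= i[1]) return(NA_real_)
        ks <- (i[1] + 1):i[2]
        vals <- vapply(ks, function(k)
          compute_rpp(sp$t[k], sp$v[k], hp$t, hp$v), 0)
        vals <- vals[!is.na(vals)]
        if (!length(vals)) NA_real_ else mean(vals)
      } else {           # diff
        both <- intersect(as.numeric(names(sp$day_idx)), avail(spec$channel2))
        r <- .ref_day(both, d, 1, 3)
        if (is.na(r)) return(NA_real_)
        a <- rpp_day(d); b <- rpp_day(r)
        if (is.na(a) || is.na(b)) NA_real_ else a - b
      }
    },
    afrac = {
      ap <- prep[["activity"]]
      if (is.null(ap)) return(NA_real_)
      cl_code <- match(spec$class, act_codes)
      frac_day <- function(dd) {
        i <- ap$day_idx[[as.character(dd)]]
        if (is.null(i)) return(NA_real_)
        mean(ap$v[i] == cl_code)
      }
      if (spec$window == "day") frac_day(d)
      else if (spec$window == "diff") {
        r <- .ref_day(as.numeric(names(ap$day_idx)), d, 1, 3)
        if (is.na(r)) return(NA_real_)
        a <- frac_day(d); if (is.na(a)) NA_real_ else a - frac_day(r)
      } else {
        x <- wv("activity", spec$window)
        if (!length(x)) NA_real_ else mean(x == cl_code)
      }
    },
    hr_static_dynamic = {
      aj <- act_join("hr")
      if (is.null(aj)) return(NA_real_)
      static <- aj$code %in% match(c("standing", "rest"), act_codes)
      if (!any(static) || all(static)) return(NA_real_)
      mean(aj$v[static]) / mean(aj$v[!static])
    },
    actstat = {
      aj <- act_join(spec$channel)
      if (is.null(aj)) return(NA_real_)
      .stat(aj$v[aj$code == match(spec$class, act_codes)], spec$stat)
    },
    adur_ratio = {
      ap <- prep[["activity"]]
      if (is.null(ap)) return(NA_real_)
      i <- ap$day_idx[[as.character(d)]]
      if (is.null(i)) return(NA_real_)
      pr <- strsplit(spec$class, "_")[[1]]
      na <- sum(ap$v[i] == match(pr[1], act_codes))
      nb <- sum(ap$v[i] == match(pr[2], act_codes))
      if (nb == 0) NA_real_ else na / nb
    },
    hr_act_diff = ,
    hr_act_ratio = {
      aj <- act_join("hr")
      if (is.null(aj)) return(NA_real_)
      pr <- strsplit(spec$class, "_")[[1]]
      a <- aj$v[aj$code == match(pr[1], act_codes)]
      b <- aj$v[aj$code == match(pr[2], act_codes)]
      if (!length(a) || !length(b)) return(NA_real_)
      if (spec$kind == "hr_act_diff") mean(a) - mean(b)
      else if (mean(b) == 0) NA_real_ else mean(a) / mean(b)
    },
    dprod = {
      s <- .day_stat(prep[["sbp"]], d, "mean")
      db <- .day_stat(prep[["dbp"]], d, "mean")
      h <- .day_stat(prep[["hr"]], d, "mean")
      if (is.na(s) || is.na(db) || is.na(h)) NA_real_ else (s + db) / 2 * h
    },
    ratio2day = {
      a <- .day_stat(prep[[spec$channel]], d, "mean")
      b <- .day_stat(prep[[spec$channel2]], d, "mean")
      if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
    },
    hr_ee = {
      hp <- prep[["hr"]]; ep <- prep[["energy"]]
      if (is.null(hp) || is.null(ep)) return(NA_real_)
      i <- hp$day_idx[[as.character(d)]]; j <- ep$day_idx[[as.character(d)]]
      if (is.null(i) || is.null(j)) return(NA_real_)
      m <- match(hp$t[i], ep$t[j]); ok <- !is.na(m) & ep$v[j][m] != 0
      if (!any(ok)) return(NA_real_)
      mean(hp$v[i][ok] / ep$v[j][m[ok]])
    },
    excount = ,
    exdur = {
      chp <- prep[["exercise"]]
      x <- if (spec$window == "day") {
        if (is.null(chp)) numeric(0) else {
          i <- chp$day_idx[[as.character(d)]]
          if (is.null(i)) numeric(0) else chp$v[i]
        }
      } else .win_vals(chp, at - 7 * 1440, at)
      if (spec$kind == "excount") length(x) else sum(x)
    },
    exvalid = {
      chp <- prep[["exercise_valid"]]
      if (is.null(chp)) return(NA_real_)
      i <- chp$day_idx[[as.character(d)]]
      if (is.null(i)) NA_real_ else mean(chp$v[i])
    },
    stop("unknown feature kind: ", spec$kind)
  )
}

# Core extractor shared by the two dialect entry points.
.extract_matrix <- function(measurements, reports, dialect,
                            anchor_minute = 1200) {
  reg <- feature_registry(dialect)
  specs <- split(reg, seq_len(nrow(reg)))
  act_codes <- .activity_classes(dialect)
  reports <- reports[order(reports$patient_id, reports$date), , drop = FALSE]
  labs <- merge_five_to_three(reports$raw_value, reports$dialect)

  n <- nrow(reports)
  mat <- matrix(NA_real_, n, nrow(reg), dimnames = list(NULL, reg$name))
  for (pid in unique(reports$patient_id)) {
    prep <- .prep_patient(
      measurements[measurements$patient_id == pid, , drop = FALSE])
    rows <- which(reports$patient_id == pid)
    for (r in rows) {
      d <- as.numeric(reports$date[r])
      at <- d * 1440 + anchor_minute
      for (k in seq_along(specs)) {
        val <- .compute_feature(specs[[k]], prep, d, at, act_codes)
        if (length(val) == 1 && is.finite(val)) mat[r, k] <- val
      }
    }
  }
  out <- data.frame(patient_id = reports$patient_id, date = reports$date,
                    label = labs, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  # personal-ratio variants
  for (k in which(reg$pratio)) {
    stat <- if (identical(reg$stat[k], "sd")) "sd" else "mean"
    out[[paste0(reg$name[k], ".pratio")]] <-
      personal_ratio(out[[reg$name[k]]], out$patient_id, stat)
  }
  rownames(out) <- NULL
  out
}

#' Extract the HeartMan-dialect feature matrix
#'
#' One row per FOH report: windowed continuous statistics (3 h, 24 h, day,
#' day-over-day difference), skin/air-temperature and GSR/humidity ratios,
#' rate-pressure product, weight and blood-pressure deltas with fallback
#' windows, activity-fraction features (day, 24 h, week, difference), the
#' static/dynamic heart-rate ratio, exercise counts and durations, ambient
#' statistics, and personal ratios for everything except exercise features.
#'
#' @param measurements Curated long-format measurements.
#' @param reports FOH reports data frame (`patient_id`, `date`, `raw_value`,
#'   `dialect`).
#' @param anchor_minute Minute-of-day of the FOH entry (window anchor).
#' @return A feature matrix data frame with `patient_id`, `date`, `label`
#'   metadata columns; missing features are `NA`.
#' @export
extract_heartman_features <- function(measurements, reports,
                                      anchor_minute = 1200) {
  .extract_matrix(measurements, reports, "heartman", anchor_minute)
}

#' Extract the Chiron-dialect feature matrix
#'
#' One row per FOH report: day-level means/SDs of the multi-per-day channels
#' plus per-activity (lying/sitting/moving) statistics, the daily manual
#' entries, derived daily values (temperature and humidity ratios, RPP,
#' double product, SBP/DBP ratio, activity-duration ratios, per-activity
#' heart-rate differences and ratios, heart-rate/energy-expenditure ratio),
#' and personal ratios for the personalized subset.
#'
#' @inheritParams extract_heartman_features
#' @return A feature matrix data frame.
#' @export
extract_chiron_features <- function(measurements, reports,
                                    anchor_minute = 1200) {
  .extract_matrix(measurements, reports, "chiron", anchor_minute)
}

#' Common feature columns of two feature matrices
#'
#' Name-matched intersection of the two matrices' feature columns, in
#' deterministic (sorted) order; metadata columns are excluded.  Used for
#' cross-dataset experiments, which keep only the intersecting features.
#'
#' @param a,b Feature matrices.
#' @return Character vector of shared feature names.
#' @export
compatible_feature_set <- function(a, b) {
  common <- sort(intersect(feature_cols(a), feature_cols(b)))
  .assert(length(common) > 0, "the feature matrices share no columns")
  common
}
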
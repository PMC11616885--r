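# Independent oracles used to cross-check the package implementation.
# These are written as direct transcriptions of the definitions, with no
# shared code paths with the package internals.

# --- Label-transformation oracle -------------------------------------------
# Declarative per-position reading of the rules, applied to one run of
# consecutive days:
#   * a non-'same' day immediately preceded by its opposite becomes 'same'
#     (the worse->better rule and its mirror); such a day is "consumed" and
#     propagates nothing;
#   * a 'same' day looks back to the nearest non-'same' day j: if j was not
#     consumed and lies within the 5-day window (trigger day counts as day
#     1, so at most 4 days back), the trigger's label propagates;
#   * everything else keeps its own label.
oracle_transform_run <- function(x) {
  n <- length(x)
  opposite <- c(worse = "better", better = "worse")
  consumed <- logical(n)
  for (i in seq_len(n)) {
    consumed[i] <- x[i] != "same" && i > 1 && !consumed[i - 1] &&
      x[i - 1] == opposite[[x[i]]]
  }
  vapply(seq_len(n), function(i) {
    if (x[i] != "same") {
      if (consumed[i]) "same" else x[i]
    } else {
      j <- i - 1
      while (j >= 1 && x[j] == "same") j <- j - 1
      if (j >= 1 && !consumed[j] && (i - j) <= 4) x[j] else "same"
    }
  }, "")
}

oracle_transform <- function(labels, dates) {
  dates <- as.Date(dates)
  run_id <- cumsum(c(1, diff(as.numeric(dates)) != 1))
  out <- labels
  for (r in split(seq_along(labels), run_id)) {
    out[r] <- oracle_transform_run(labels[r])
  }
  out
}

# --- Metric oracles ---------------------------------------------------------
oracle_accuracy <- function(truth, pred) sum(truth == pred) / length(truth)

oracle_macro_f1 <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, 0)
  mean(f1s)
}

# --- Brute-force feature oracle --------------------------------------------
# Recomputes one registry feature for one (patient, day) directly from the
# raw long-format measurements with plain subsetting.
oracle_feature <- function(meas, pid, date, anchor_minute, spec, dialect) {
  sub <- meas[meas$patient_id == pid, , drop = FALSE]
  d <- as.numeric(as.Date(date))
  t <- as.numeric(sub$date) * 1440 + sub$minute
  at <- d * 1440 + anchor_minute
  acts <- if (dialect == "heartman")
    c("walking", "running", "other", "standing", "rest")
  else c("lying", "sitting", "moving")

  vals_in <- function(ch, t0, t1) sub$value[sub$channel == ch & t > t0 & t <= t1]
  vals_day <- function(ch, dd) sub$value[sub$channel == ch & as.numeric(sub$date) == dd]
  win_vals <- function(ch, w) switch(w,
    "3h" = vals_in(ch, at - 180, at),
    "24h" = vals_in(ch, at - 1440, at),
    "week" = vals_in(ch, at - 7 * 1440, at),
    "day" = vals_day(ch, d))
  stat <- function(x, s) {
    if (length(x) == 0) return(NA_real_)
    if (s == "mean") mean(x)
    else if (s == "sd") { if (length(x) < 2) NA_real_ else sd(x) }
    else if (s == "count") length(x) else sum(x)
  }
  day_stat <- function(ch, dd, s) stat(vals_day(ch, dd), s)
  days_with <- function(ch) sort(unique(as.numeric(sub$date[sub$channel == ch])))
  recent <- function(avail, lo, hi) {
    cand <- avail[avail >= d - hi & avail <= d - lo]
    if (length(cand) == 0) NA_real_ else max(cand)
  }
  # day-d values of a channel matched minute-by-minute to activity codes
  joined <- function(ch) {
    a <- sub[sub$channel == ch & as.numeric(sub$date) == d, , drop = FALSE]
    b <- sub[sub$channel == "activity" & as.numeric(sub$date) == d, , drop = FALSE]
    m <- match(a$minute, b$minute)
    ok <- !is.na(m)
    list(v = a$value[ok], code = b$value[m[ok]])
  }
  rpp_on_day <- function(dd) {
    bp <- sub[sub$channel == "sbp" & as.numeric(sub$date) == dd, , drop = FALSE]
    if (nrow(bp) == 0) return(NA_real_)
    hrt <- t[sub$channel == "hr"]; hrv <- sub$value[sub$channel == "hr"]
    out <- numeric(0)
    for (i in seq_len(nrow(bp))) {
      bt <- as.numeric(bp$date[i]) * 1440 + bp$minute[i]
      h <- hrv[hrt >= bt - 10 & hrt <= bt + 10]
      if (length(h)) out <- c(out, bp$value[i] * mean(h))
    }
    if (length(out) == 0) NA_real_ else mean(out)
  }

  k <- spec$kind
  if (k == "win") {
    if (spec$window == "diff") {
      r <- recent(days_with(spec$channel), 1, 3)
      if (is.na(r)) NA_real_
      else day_stat(spec$channel, d, spec$stat) - day_stat(spec$channel, r, spec$stat)
    } else stat(win_vals(spec$channel, spec$window), spec$stat)
  } else if (k == "ratio") {
    dr <- function(dd) {
      a <- day_stat(spec$channel, dd, "mean"); b <- day_stat(spec$channel2, dd, "mean")
      if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
    }
    if (spec$window == "day") dr(d)
    else if (spec$window == "diff") {
      r <- recent(intersect(days_with(spec$channel), days_with(spec$channel2)), 1, 3)
      if (is.na(r)) NA_real_ else dr(d) - dr(r)
    } else {
      a <- win_vals(spec$channel, spec$window); b <- win_vals(spec$channel2, spec$window)
      if (length(a) == 0 || length(b) == 0 || mean(b) == 0) NA_real_
      else mean(a) / mean(b)
    }
  } else if (k == "dayval") {
    day_stat(spec$channel, d, "mean")
  } else if (k == "delta") {
    avail <- days_with(spec$channel)
    cur <- day_stat(spec$channel, d, "mean")
    if (is.na(cur) || !(d %in% avail)) return(NA_real_)
    ref <- if (spec$window == "diff1") recent(avail, 1, 3)
      else if ((d - 4) %in% avail) d - 4 else recent(avail, 5, 7)
    if (is.na(ref)) NA_real_ else cur - day_stat(spec$channel, ref, "mean")
  } else if (k == "rpp") {
    if (spec$window == "day") rpp_on_day(d)
    else if (spec$window == "diff") {
      both <- intersect(days_with("sbp"), days_with("hr"))
      r <- recent(both, 1, 3)
      if (is.na(r)) return(NA_real_)
      a <- rpp_on_day(d); b <- rpp_on_day(r)
      if (is.na(a) || is.na(b)) NA_real_ else a - b
    } else {
      bp <- sub[sub$channel == "sbp", , drop = FALSE]
      bt <- as.numeric(bp$date) * 1440 + bp$minute
      bp <- bp[bt > at - 1440 & bt <= at, , drop = FALSE]
      if (nrow(bp) == 0) return(NA_real_)
      hrt <- t[sub$channel == "hr"]; hrv <- sub$value[sub$channel == "hr"]
      out <- numeric(0)
      for (i in seq_len(nrow(bp))) {
        b2 <- as.numeric(bp$date[i]) * 1440 + bp$minute[i]
        h <- hrv[hrt >= b2 - 10 & hrt <= b2 + 10]
        if (length(h)) out <- c(out, bp$value[i] * mean(h))
      }
      if (length(out) == 0) NA_real_ else mean(out)
    }
  } else if (k == "afrac") {
    code <- match(spec$class, acts)
    if (spec$window == "diff") {
      r <- recent(days_with("activity"), 1, 3)
      a <- vals_day("activity", d)
      if (is.na(r) || length(a) == 0) return(NA_real_)
      mean(a == code) - mean(vals_day("activity", r) == code)
    } else {
      x <- win_vals("activity", spec$window)
      if (length(x) == 0) NA_real_ else mean(x == code)
    }
  } else if (k == "hr_static_dynamic") {
    j <- joined("hr")
    st <- j$code %in% match(c("standing", "rest"), acts)
    if (length(j$v) == 0 || !any(st) || all(st)) NA_real_
    else mean(j$v[st]) / mean(j$v[!st])
  } else if (k == "actstat") {
    j <- joined(spec$channel)
    stat(j$v[j$code == match(spec$class, acts)], spec$stat)
  } else if (k == "adur_ratio") {
    pr <- strsplit(spec$class, "_")[[1]]
    a <- vals_day("activity", d)
    if (length(a) == 0) return(NA_real_)
    na_ <- sum(a == match(pr[1], acts)); nb <- sum(a == match(pr[2], acts))
    if (nb == 0) NA_real_ else na_ / nb
  } else if (k %in% c("hr_act_diff", "hr_act_ratio")) {
    pr <- strsplit(spec$class, "_")[[1]]
    j <- joined("hr")
    a <- j$v[j$code == match(pr[1], acts)]; b <- j$v[j$code == match(pr[2], acts)]
    if (length(a) == 0 || length(b) == 0) NA_real_
    else if (k == "hr_act_diff") mean(a) - mean(b)
    else if (mean(b) == 0) NA_real_ else mean(a) / mean(b)
  } else if (k == "dprod") {
    s <- day_stat("sbp", d, "mean"); db <- day_stat("dbp", d, "mean")
    h <- day_stat("hr", d, "mean")
    if (is.na(s) || is.na(db) || is.na(h)) NA_real_ else (s + db) / 2 * h
  } else if (k == "ratio2day") {
    a <- day_stat(spec$channel, d, "mean"); b <- day_stat(spec$channel2, d, "mean")
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  } else if (k == "hr_ee") {
    a <- sub[sub$channel == "hr" & as.numeric(sub$date) == d, , drop = FALSE]
    b <- sub[sub$channel == "energy" & as.numeric(sub$date) == d, , drop = FALSE]
    m <- match(a$minute, b$minute)
    ok <- !is.na(m) & b$value[m] != 0
    if (!any(ok)) NA_real_ else mean(a$value[ok] / b$value[m[ok]])
  } else if (k %in% c("excount", "exdur")) {
    x <- if (spec$window == "day") vals_day("exercise", d)
      else vals_in("exercise", at - 7 * 1440, at)
    if (k == "excount") length(x) else sum(x)
  } else if (k == "exvalid") {
    x <- vals_day("exercise_valid", d)
    if (length(x) == 0) NA_real_ else mean(x)
  } else stop("oracle: unknown kind ", k)
}

# Build a small long-format measurement frame from vectors (test fixture).
make_meas <- function(pid, dates, minutes, channel, values) {
  data.frame(patient_id = pid, date = as.Date(dates), minute = as.integer(minutes),
             channel = channel, value = values, stringsAsFactors = FALSE)
}
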
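# Label-schema harmonization.
#
# Two studies asked the daily feeling-of-health (FOH) question differently:
# the Chiron dialect asks "compared to yesterday" on a scale where 1 is much
# worse, while the HeartMan dialect asks "compared to usual" on a scale where
# 1 is much better.  Both are 5-point; the analysis merges the extremes into
# three classes and, for the Chiron dialect, rewrites day-over-day labels
# into usual-relative labels with a small rule set.

#' Merge a 5-point FOH answer into three canonical classes
#'
#' Collapses 1/2 and 4/5 of the raw 5-point scale and absorbs the opposite
#' scale directions of the two dialects: in the Chiron dialect 1 means "much
#' worse than yesterday", in the HeartMan dialect 1 means "much better than
#' usual".
#'
#' @param raw_value Integer vector with values in 1..5.
#' @param dialect `"chiron"` or `"heartman"` (scalar or vector).
#' @return Character vector over `c("worse", "same", "better")`.
#' @export
#' @examples
#' merge_five_to_three(1, "chiron")   # "worse"
#' merge_five_to_three(1, "heartman") # "better"
merge_five_to_three <- function(raw_value, dialect) {
  .assert(all(raw_value %in% 1:5), "raw_value must be an integer in 1..5")
  .assert(all(dialect %in% c("chiron", "heartman")),
          "dialect must be 'chiron' or 'heartman'")
  dialect <- rep_len(dialect, length(raw_value))
  base <- c("worse", "worse", "same", "better", "better")[raw_value]
  flip <- c(worse = "better", same = "same", better = "worse")
  ifelse(dialect == "heartman", flip[base], base)
}

# Transform one run of consecutive-day labels from yesterday-relative to
# usual-relative.  Scan left-to-right; for a 'worse' trigger: an immediately
# following 'better' becomes 'same' (and is consumed); otherwise following
# 'same' days are overwritten with 'worse' for at most 5 consecutive days
# counting the trigger as day 1.  Mirrored for 'better'.  A later trigger
# restarts its own window.
.transform_run <- function(x) {
  n <- length(x)
  y <- x
  opp <- c(worse = "better", better = "worse")
  i <- 1L
  while (i <= n) {
    lab <- x[i]
    if (lab %in% c("worse", "better")) {
      if (i < n && x[i + 1L] == opp[[lab]]) {
        y[i + 1L] <- "same"     # worse->better (or mirror): second day is 'same'
        i <- i + 2L
        next
      }
      j <- i + 1L
      while (j <= n && j <= i + 4L && x[j] == "same") {
        y[j] <- lab             # propagate over trailing 'same' days, capped
        j <- j + 1L
      }
    }
    i <- i + 1L
  }
  y
}

#' Rewrite yesterday-relative FOH labels as usual-relative labels
#'
#' Applies the rule set that aligns Chiron-dialect (day-over-day) labels with
#' the HeartMan (relative-to-usual) reading:
#' \itemize{
#'   \item by default worse/same/better-than-yesterday map to the same class
#'     relative to usual;
#'   \item a 'worse' followed by 'same' days propagates 'worse' over at most
#'     five consecutive days (the triggering day counts as day 1);
#'   \item consecutive 'worse' days all stay 'worse';
#'   \item a 'worse' immediately followed by 'better' turns that second day
#'     into 'same';
#'   \item nothing propagates across gaps in daily reporting;
#'   \item the same rules apply symmetrically to 'better'.
#' }
#' The output has the same length as the input; no records are removed.
#'
#' @param labels Character vector of canonical 3-class labels.
#' @param dates `Date` vector, strictly increasing, one report per date.
#' @return Character vector of usual-relative labels, same length.
#' @export
transform_yesterday_to_usual <- function(labels, dates) {
  .assert(length(labels) == length(dates), "labels and dates differ in length")
  .assert(all(labels %in% FOH_LEVELS), "labels must be worse/same/better")
  if (length(labels) == 0L) return(character(0))
  dates <- as.Date(dates)
  .assert(!anyNA(dates), "dates must be valid")
  .assert(all(diff(as.numeric(dates)) > 0),
          "dates must be strictly increasing with no duplicates")
  # maximal runs of consecutive calendar days
  run_id <- cumsum(c(1, diff(as.numeric(dates)) != 1))
  out <- labels
  for (r in split(seq_along(labels), run_id)) {
    out[r] <- .transform_run(labels[r])
  }
  out
}

#' Indices of rows kept after removing the middle class
#'
#' For two-class experiments the 'same' class is dropped, reducing the
#' prediction to worse vs. better.
#'
#' @param labels Character vector of canonical labels.
#' @return Integer indices of rows whose label is not `"same"`, in order.
#' @export
drop_same_class <- function(labels) {
  .assert(all(labels %in% FOH_LEVELS), "labels must be worse/same/better")
  which(labels != "same")
}
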
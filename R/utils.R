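# Shared internal helpers.

# Canonical 3-class FOH levels, ordered worst to best.
FOH_LEVELS <- c("worse", "same", "better")

# Metadata columns of a feature matrix; everything else is a feature.
META_COLS <- c("patient_id", "date", "label")

.foh_ord <- function(x) match(x, FOH_LEVELS)

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Feature column names of a feature matrix
#'
#' @param m A feature matrix (data frame with `patient_id`, `date`, `label`
#'   metadata columns).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(m) {
  nm <- setdiff(names(m), META_COLS)
  nm[!startsWith(nm, ".")]      # dot-prefixed columns are audit metadata
}

# Derive a stage seed from a master seed; keeps results < 2^31.
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9973) %% 2147483629)
}
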
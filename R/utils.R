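# Internal helpers shared across modules.

#' Normalize a label for matching
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds.  Used only for *matching* labels (duplicate
#' detection, taxonomy lookup); original spellings are preserved in outputs.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @keywords internal
#' @noRd
normalize_label <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  tolower(x)
}

# Classed error constructor so callers can condition on failure mode.
bt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "betataxa_error")))
}

bt_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "betataxa_warning")))
}

# Draw a module-specific seed from a master seed without exhausting it.
# Keeps derived seeds within the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}
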
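#' @include aversion.R decoder.R
NULL

#' Behavior-score feature matrix for decoding
#'
#' Numeric metric columns of a score table, prepared for the logistic
#' decoder: identifier columns removed and any column carrying a flagged
#' (NA) value dropped, since undefined ratios (e.g. reactivity with zero
#' conspecific sniffs, latency of a subject that never entered) have no
#' imputable value.
#'
#' @param scores behavior score table.
#' @return numeric matrix [subjects x features].
#' @export
behaviorFeatureMatrix <- function(scores) {
  num <- scores[, setdiff(names(scores), c("subject_id", "sex", "condition")),
                drop = FALSE]
  num <- num[, vapply(num, is.numeric, TRUE), drop = FALSE]
  keep <- vapply(num, function(col) !anyNA(col), TRUE)
  as.matrix(num[, keep, drop = FALSE])
}

#' Decode housing condition from behavior scores
#'
#' Fits the penalized logistic decoder on the standardized behavior-score
#' features of a cohort and reports training accuracy and ranked
#' coefficients.
#'
#' @param scores behavior score table with a condition column.
#' @param l2Strength ridge penalty.
#' @return A \linkS4class{DecoderReport}.
#' @export
decodeCondition <- function(scores, l2Strength = 1) {
  fitLogisticDecoder(behaviorFeatureMatrix(scores), scores$condition,
                     l2Strength = l2Strength)
}
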
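#' @include AllClasses.R
NULL

#' Default behavior-to-category map for the aversion composite
#'
#' Maps each composite behavior to its category (social fear, social
#' hesitancy, social motivation) and its aversion sign: +1 when larger
#' values mean more aversion, -1 for motivation-direction metrics (prosocial
#' initiations, chamber preference), which are negated before averaging so
#' the composite is monotone increasing in aversion.
#'
#' @return data.frame(behavior, category, sign).
#' @export
defaultCategoryMap <- function() {
  data.frame(
    behavior = c("first_tunnel_shelter_s", "reverse_count", "reverse_s",
                 "latency_to_social_s",
                 "social_freeze_s", "social_reactivity_pct",
                 "prosocial_initiations", "chamber_preference_pct"),
    category = c(rep("social_hesitancy", 4), rep("social_fear", 2),
                 rep("social_motivation", 2)),
    sign = c(1, 1, 1, 1, 1, 1, -1, -1),
    stringsAsFactors = FALSE)
}

#' Z-score behavior columns of a score table
#'
#' Converts each requested behavior column into z-scores, z = (x - mean) /
#' sd, computed over the reference population (by default the pooled cohort,
#' both groups) using the sample (n - 1) standard deviation. Flagged-missing
#' entries (NA) are skipped in the reference statistics and stay NA.
#'
#' @param scores behavior score table (one row per subject).
#' @param behaviors character vector of columns to transform; defaults to
#'   the composite set of \code{\link{defaultCategoryMap}}.
#' @param reference "pooled" (default) or the label of the reference group
#'   whose mean/sd standardize both groups (requires a condition column).
#' @return numeric matrix [subjects x behaviors], rownames = subject ids.
#' @export
zscoreTable <- function(scores, behaviors = defaultCategoryMap()$behavior,
                        reference = "pooled") {
  missing <- setdiff(behaviors, names(scores))
  if (length(missing))
    stop("score table lacks behavior column(s): ",
         paste(missing, collapse = ", "))
  refRows <- if (identical(reference, "pooled")) seq_len(nrow(scores)) else {
    which(scores$condition == reference)
  }
  if (!length(refRows)) stop("empty reference population: ", reference)
  z <- matrix(NA_real_, nrow(scores), length(behaviors),
              dimnames = list(scores$subject_id, behaviors))
  for (b in behaviors) {
    x <- scores[[b]]
    xr <- x[refRows]
    ok <- !is.na(xr)
    if (sum(ok) < 2L)
      stop("degenerate-feature error: fewer than 2 defined values for \"",
           b, "\"")
    mu <- mean(xr[ok]); sdev <- stats::sd(xr[ok])
    if (!is.finite(sdev) || sdev == 0)
      stop("degenerate-feature error: zero variance for \"", b, "\"")
    z[, b] <- (x - mu) / sdev
  }
  z
}

#' Composite social-aversion index
#'
#' The per-subject mean of sign-aligned behavior z-scores: each behavior's z
#' is multiplied by its aversion sign (motivation metrics -1) and averaged,
#' skipping flagged-missing entries. Per-category sub-means (fear,
#' hesitancy, motivation) are returned alongside. Subjects with no defined
#' behavior get a flagged (NA) composite.
#'
#' @param z z-score matrix from \code{\link{zscoreTable}}.
#' @param map category map, see \code{\link{defaultCategoryMap}}; must cover
#'   every column of \code{z}.
#' @return data.frame(subject_id, composite, and one column per category).
#' @export
compositeAversion <- function(z, map = defaultCategoryMap()) {
  uncovered <- setdiff(colnames(z), map$behavior)
  if (length(uncovered))
    stop("category map does not cover column(s): ",
         paste(uncovered, collapse = ", "))
  m <- map[match(colnames(z), map$behavior), ]
  signed <- sweep(z, 2, m$sign, `*`)
  comp <- rowMeans(signed, na.rm = TRUE)
  comp[rowSums(!is.na(signed)) == 0L] <- NA_real_
  out <- data.frame(subject_id = rownames(z), composite = comp,
                    stringsAsFactors = FALSE)
  for (cat in unique(m$category)) {
    cols <- which(m$category == cat)
    cm <- rowMeans(signed[, cols, drop = FALSE], na.rm = TRUE)
    cm[rowSums(!is.na(signed[, cols, drop = FALSE])) == 0L] <- NA_real_
    out[[cat]] <- cm
  }
  rownames(out) <- NULL
  out
}

#' Two-sample t test between groups
#'
#' Independent-samples Student t test with pooled variance (two-tailed) by
#' default; set \code{welch = TRUE} for the unequal-variance form. Zero
#' pooled variance returns a degenerate flag instead of an infinite
#' statistic.
#'
#' @param values numeric per-subject metric.
#' @param labels two-level grouping (factor or character).
#' @param welch use the Welch correction instead of pooled variance.
#' @return list(t, df, p, estimate, degenerate).
#' @export
groupTTest <- function(values, labels, welch = FALSE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two groups required, got ", nlevels(labels))
  keep <- !is.na(values)
  values <- values[keep]; labels <- droplevels(labels[keep])
  ns <- table(labels)
  if (nlevels(labels) != 2L || any(ns < 2L))
    stop("each group needs at least 2 defined values")
  fit <- tryCatch(stats::t.test(values ~ labels, var.equal = !welch),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                estimate = NA_real_, degenerate = TRUE))
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, estimate = unname(diff(rev(fit$estimate))),
       degenerate = FALSE)
}

#' Full aversion analysis of a scored cohort
#'
#' Z-scores the composite behaviors over the pooled cohort, averages the
#' sign-aligned z-scores into the social-aversion index, and compares the
#' two conditions with a two-tailed pooled-variance t test.
#'
#' @param scores behavior score table with a condition column.
#' @param map category map, see \code{\link{defaultCategoryMap}}.
#' @param reference z-score reference population, see
#'   \code{\link{zscoreTable}}.
#' @return list(z, composite, test, groupMeans).
#' @export
aversionAnalysis <- function(scores, map = defaultCategoryMap(),
                             reference = "pooled") {
  # behaviors no animal expressed carry no information; drop rather than fail
  sds <- vapply(map$behavior, function(b) stats::sd(scores[[b]], na.rm = TRUE),
                0)
  if (any(degenerate <- !is.finite(sds) | sds == 0)) {
    warning("dropping constant behavior(s) from the composite: ",
            paste(map$behavior[degenerate], collapse = ", "))
    map <- map[!degenerate, , drop = FALSE]
  }
  z <- zscoreTable(scores, map$behavior, reference)
  comp <- compositeAversion(z, map)
  comp$condition <- scores$condition
  tt <- groupTTest(comp$composite, comp$condition)
  gm <- tapply(comp$composite, comp$condition, mean, na.rm = TRUE)
  list(z = z, composite = comp, test = tt, groupMeans = gm)
}
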
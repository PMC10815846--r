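#' ROC AUC by the Mann-Whitney estimator
#'
#' The probability that a random positive score exceeds a random negative
#' score, with ties counted half: the mean over all (positive, negative)
#' pairs of 1/0.5/0. Computed from ranks in O(n log n).
#'
#' @param scores_pos,scores_neg numeric score vectors for the positive and
#'   negative class (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores_pos, scores_neg) {
  n1 <- as.numeric(length(scores_pos)); n0 <- as.numeric(length(scores_neg))
  if (!n1 || !n0) stopf("both score groups must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil standard error and significance of an AUC
#'
#' Closed-form standard error of a nonparametric AUC `A` with `n_pos`
#' positive and `n_neg` negative cases:
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`,
#' `se = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))`. The z-statistic compares `A` against the null value
#' 0.5 and the p-value is the two-sided standard-normal tail.
#'
#' @param A AUC strictly inside (0, 1).
#' @param n_pos,n_neg class sizes (>= 1).
#' @return A list with `se`, `z`, `p`.
#' @export
hanley_mcneil <- function(A, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) stopf("class sizes must be >= 1")
  if (A <= 0 || A >= 1)
    stopf("A = %g is degenerate for the Hanley-McNeil formula; use exact methods", A)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n_pos - 1) * (q1 - A^2) +
                (n_neg - 1) * (q2 - A^2)) / (n_pos * n_neg))
  z <- (A - 0.5) / se
  list(se = se, z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Screen radiomic features by AUC with Hanley-McNeil significance
#'
#' Computes per-feature ROC AUC (positive class = label 1), Hanley-McNeil
#' standard error, z against 0.5 and two-sided p-value, and marks features
#' with AUC at or above `threshold` as selected (inclusive, "0.68 or
#' higher"). Constant features score AUC 0.5 by the tie rule and are never
#' selected at any threshold above 0.5. With `direction = "auto"` the
#' larger of A and 1 - A is screened instead (off by default).
#'
#' @param table samples x features numeric matrix or data.frame.
#' @param labels 0/1 vector aligned with rows.
#' @param threshold selection threshold on the AUC (default 0.68).
#' @param modality optional modality tag recorded per feature.
#' @param direction `"greater"` (default) screens A as-is; `"auto"`
#'   screens `max(A, 1 - A)`.
#' @return data.frame of class `roc_screen`: `feature`, `modality`, `auc`,
#'   `n_pos`, `n_neg`, `se`, `z`, `p`, `selected`.
#' @export
select_features <- function(table, labels, threshold = 0.68,
                            modality = NA_character_,
                            direction = c("greater", "auto")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  labels <- as.integer(labels)
  if (nrow(table) != length(labels))
    stopf("feature table rows must align with labels")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (!n_pos || !n_neg) stopf("both classes must be present")
  rows <- lapply(seq_len(ncol(table)), function(j) {
    x <- table[, j]
    A <- auc_mw(x[labels == 1], x[labels == 0])
    A_screen <- if (direction == "auto") max(A, 1 - A) else A
    hm <- if (A > 0 && A < 1) hanley_mcneil(A, n_pos, n_neg)
          else list(se = NA_real_, z = NA_real_, p = NA_real_)
    data.frame(feature = colnames(table)[j], modality = modality,
               auc = A, n_pos = n_pos, n_neg = n_neg,
               se = hm$se, z = hm$z, p = hm$p,
               selected = A_screen >= threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("roc_screen", class(out))
  attr(out, "threshold") <- threshold
  out
}
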
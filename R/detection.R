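#' Rank-statistic ROC AUC
#'
#' The Mann-Whitney form of the area under the ROC curve: over all
#' case-control pairs, the fraction in which the case scores higher than
#' the control, counting ties as 1/2. Computed via mid-ranks, which is
#' mathematically identical to trapezoidal integration of the empirical
#' ROC curve.
#'
#' @param score Numeric vector of per-image detection scores.
#' @param label Factor or character vector with values `case`/`control`.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, label) {
  label <- as.character(label)
  is_case <- label == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires at least one case and one control")
  }
  if (any(!is.finite(score))) stop("non-finite detection score")
  r <- rank(score) # mid-ranks handle ties as 1/2
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with stratified percentile bootstrap confidence interval
#'
#' Point estimate by [auc_rank()]; uncertainty by a stratified nonparametric
#' bootstrap in which cases and controls are resampled separately with
#' replacement (the case-control design fixes the class sizes, and no
#' replicate can lose a class). The CI is the percentile interval of the
#' bootstrap AUC distribution. Significance versus chance is declared when
#' the CI strictly excludes 0.5 (two-sided at alpha = 1 - level).
#'
#' @param score,label As for [auc_rank()].
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; mandatory so every run is reproducible.
#' @param cluster Optional vector of cluster ids (e.g. woman ids) of the
#'   same length as `score`; when given, whole clusters are resampled
#'   within class instead of individual images, acknowledging within-woman
#'   correlation across views.
#' @return Object of class `auc_boot` with fields `auc`, `ci_low`,
#'   `ci_high`, `n_boot`, `level`, `seed`, `significant`, `n_cases`,
#'   `n_controls`, and the input `score`/`label` (for ROC plotting).
#' @export
auc_boot <- function(score, label, n_boot = 2000, level = 0.95, seed,
                     cluster = NULL) {
  if (missing(seed)) stop("a seed is required for the bootstrap")
  label <- as.character(label)
  est <- auc_rank(score, label)
  is_case <- label == "case"
  case_scores <- score[is_case]
  ctrl_scores <- score[!is_case]
  n1 <- length(case_scores)
  n0 <- length(ctrl_scores)

  set.seed(as.integer(seed))
  boot <- numeric(n_boot)
  if (is.null(cluster)) {
    for (b in seq_len(n_boot)) {
      cs <- case_scores[sample.int(n1, n1, replace = TRUE)]
      ct <- ctrl_scores[sample.int(n0, n0, replace = TRUE)]
      boot[b] <- auc_pair(cs, ct)
    }
  } else {
    case_cl <- split(case_scores, cluster[is_case])
    ctrl_cl <- split(ctrl_scores, cluster[!is_case])
    k1 <- length(case_cl)
    k0 <- length(ctrl_cl)
    for (b in seq_len(n_boot)) {
      cs <- unlist(case_cl[sample.int(k1, k1, replace = TRUE)],
                   use.names = FALSE)
      ct <- unlist(ctrl_cl[sample.int(k0, k0, replace = TRUE)],
                   use.names = FALSE)
      boot[b] <- auc_pair(cs, ct)
    }
  }
  alpha <- 1 - level
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  structure(
    list(auc = est, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         level = level, seed = as.integer(seed),
         significant = ci[1] > 0.5 || ci[2] < 0.5,
         n_cases = n1, n_controls = n0,
         score = score, label = label),
    class = "auc_boot"
  )
}

# AUC from the two score vectors directly (bootstrap inner loop)
auc_pair <- function(case_scores, ctrl_scores) {
  n1 <- length(case_scores)
  n0 <- length(ctrl_scores)
  r <- rank(c(case_scores, ctrl_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Significance of an AUC versus chance
#'
#' Significant (two-sided, alpha = 1 - level) iff the percentile bootstrap
#' CI strictly excludes 0.5. A CI touching 0.5 is not significant.
#'
#' @param result An `auc_boot` object, or any list with `ci_low`/`ci_high`.
#' @return Logical.
#' @export
significance <- function(result) {
  result$ci_low > 0.5 || result$ci_high < 0.5
}

#' @export
print.auc_boot <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f, %g%% CI %.3f–%.3f (%s vs 0.5; %d cases / %d controls, %d bootstrap replicates)\n",
    x$auc, 100 * x$level, x$ci_low, x$ci_high,
    if (x$significant) "significant" else "not significant",
    x$n_cases, x$n_controls, x$n_boot
  ))
  invisible(x)
}

#' @export
summary.auc_boot <- function(object, ...) {
  print(object)
  cat(sprintf("  seed: %d; percentile interval; stratified resampling\n",
              object$seed))
  invisible(object)
}

#' Empirical ROC curve coordinates
#'
#' False-positive and true-positive rates at every distinct score
#' threshold (descending), including the (0,0) and (1,1) endpoints.
#'
#' @param score,label As for [auc_rank()].
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(score, label) {
  label <- as.character(label)
  is_case <- label == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("ROC requires both classes")
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  tp <- cumsum(is_case[o])
  fp <- cumsum(!is_case[o])
  idx <- c(which(diff(s) != 0), length(s))
  data.frame(
    threshold = c(Inf, s[idx]),
    fpr = c(0, fp[idx] / n0),
    tpr = c(0, tp[idx] / n1)
  )
}

#' @export
plot.auc_boot <- function(x, ...) {
  rc <- roc_points(x$score, x$label)
  graphics::plot(rc$fpr, rc$tpr, type = "l",
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 main = sprintf("ROC, AUC = %.3f (%g%% CI %.3f–%.3f)",
                                x$auc, 100 * x$level, x$ci_low, x$ci_high),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Aggregate per-image scores to one score per woman
#'
#' Takes the maximum score over a woman's images (any view flagging
#' suspicion flags the woman). Off by default in the pipeline; the primary
#' analysis unit is the image.
#'
#' @param scores Data frame from [read_scores()].
#' @return Data frame with one row per woman (`image_id` = `woman_id`).
#' @export
aggregate_by_woman <- function(scores) {
  agg <- stats::aggregate(score ~ woman_id + label, data = scores, FUN = max)
  data.frame(
    image_id = agg$woman_id, woman_id = agg$woman_id,
    label = agg$label, score = agg$score,
    stringsAsFactors = FALSE
  )
}
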
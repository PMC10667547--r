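# Independent oracles, deliberately naive and separate from the package
# implementations they check.

# Dice by direct set counting.
oracle_dsc <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Optimal threshold by exhaustive evaluation of DSC at every distinct
# saliency value; strict improvement keeps the largest tie-breaking
# threshold because values are visited in descending order.
oracle_optimal_aoi <- function(map, mask) {
  taus <- sort(unique(as.vector(map)), decreasing = TRUE)
  best <- -Inf
  best_tau <- NA_real_
  for (tau in taus) {
    a <- map >= tau
    d <- 2 * sum(a & mask) / (sum(a) + sum(mask))
    if (d > best) {
      best <- d
      best_tau <- tau
    }
  }
  list(threshold = best_tau, dsc = best)
}

# Trapezoidal area under the empirical ROC curve, built point by point
# from threshold sweeps over the raw scores.
oracle_auc_trapezoid <- function(score, label) {
  is_case <- label == "case"
  taus <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(taus, function(t) mean(score[is_case] >= t), numeric(1)))
  fpr <- c(0, vapply(taus, function(t) mean(score[!is_case] >= t), numeric(1)))
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

# Linear interpolation between order statistics at h = (n-1)p + 1.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Random saliency/mask instance; rounding the saliency values induces
# ties so value-level semantics get exercised.
random_instance <- function(h = 16, w = 16, p_lesion = 0.15, digits = 2) {
  map <- matrix(round(stats::runif(h * w), digits), h, w)
  mask <- matrix(stats::runif(h * w) < p_lesion, h, w)
  if (!any(mask)) mask[sample.int(h * w, 1)] <- TRUE
  list(map = map, mask = mask)
}

# Point-in-ellipse rasterization by explicit double loop.
oracle_ellipse_count <- function(height, width, center, axes) {
  n <- 0L
  for (r in 0:(height - 1)) {
    for (cc in 0:(width - 1)) {
      if (((r - center[1]) / axes[1])^2 +
          ((cc - center[2]) / axes[2])^2 <= 1) {
        n <- n + 1L
      }
    }
  }
  n
}

# Small on-disk synthetic dataset shared by pipeline tests.
make_test_dataset <- function(dir, n_cases = 20, n_controls = 20,
                              systems = list(good = list(lambda = 1, mu = 3),
                                             diffuse = list(lambda = 0, mu = 0)),
                              p_unsegmented = 0.1, seed = 11) {
  make_dataset(dir, n_cases = n_cases, n_controls = n_controls,
               systems = systems, p_unsegmented = p_unsegmented, seed = seed)
}
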
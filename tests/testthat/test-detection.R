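test_that("rank AUC matches pair enumeration on hand cases", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1),
                        c("case", "case", "control", "control")), 1.0)
  expect_equal(auc_rank(rep(0.5, 6),
                        rep(c("case", "control"), 3)), 0.5)
  # pairs: (0.8>0.6), (0.8>0.4), (0.4<0.6), (0.4=0.4 -> 1/2)
  expect_equal(auc_rank(c(0.8, 0.4, 0.6, 0.4),
                        c("case", "case", "control", "control")), 0.625)
  expect_error(auc_rank(c(1, 2), c("case", "case")), "at least one")
})

test_that("rank AUC equals trapezoidal ROC area and obeys symmetries", {
  set.seed(8)
  for (i in 1:40) {
    n1 <- sample(3:30, 1)
    n0 <- sample(3:30, 1)
    score <- round(c(stats::rnorm(n1, 0.5), stats::rnorm(n0)), 1) # ties likely
    label <- rep(c("case", "control"), c(n1, n0))
    a <- auc_rank(score, label)
    expect_equal(a, oracle_auc_trapezoid(score, label), tolerance = 1e-12)
    # label flip antisymmetry
    flipped <- ifelse(label == "case", "control", "case")
    expect_equal(auc_rank(score, flipped), 1 - a, tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(auc_rank(exp(score), label), a, tolerance = 1e-12)
    expect_equal(auc_rank(rank(score, ties.method = "average"), label), a,
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  set.seed(12)
  score <- c(stats::rnorm(40, 0.7), stats::rnorm(50))
  label <- rep(c("case", "control"), c(40, 50))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = label, predictor = score,
    levels = c("control", "case"), direction = "<", quiet = TRUE
  )))
  expect_equal(auc_rank(score, label), ref, tolerance = 1e-12)
})

test_that("bootstrap CIs are deterministic, stratified and percentile", {
  s <- make_scores(60, 60, mu = 1, seed = 5)
  b1 <- auc_boot(s$score, s$label, n_boot = 400, seed = 21)
  b2 <- auc_boot(s$score, s$label, n_boot = 400, seed = 21)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)
  expect_error(auc_boot(s$score, s$label, n_boot = 10), "seed is required")

  # zero-variance data: every replicate has AUC exactly 1
  score <- c(rep(1, 5), rep(0, 5))
  label <- rep(c("case", "control"), each = 5)
  b <- auc_boot(score, label, n_boot = 200, seed = 1)
  expect_equal(b$ci_low, 1.0)
  expect_equal(b$ci_high, 1.0)
  expect_true(b$significant) # [1,1] strictly excludes 0.5
})

test_that("CI width shrinks with sample size", {
  wider <- narrower <- numeric(12)
  for (i in 1:12) {
    s_small <- make_scores(100, 100, mu = 1, seed = 100 + i)
    s_big <- make_scores(400, 400, mu = 1, seed = 200 + i)
    b_small <- auc_boot(s_small$score, s_small$label, n_boot = 300,
                        seed = 300 + i)
    b_big <- auc_boot(s_big$score, s_big$label, n_boot = 300, seed = 400 + i)
    wider[i] <- b_small$ci_high - b_small$ci_low
    narrower[i] <- b_big$ci_high - b_big$ci_low
  }
  expect_gte(mean(narrower < wider), 0.95)
})

test_that("significance requires the CI to strictly exclude 0.5", {
  expect_true(significance(list(ci_low = 0.535, ci_high = 0.606)))
  expect_false(significance(list(ci_low = 0.494, ci_high = 0.561)))
  expect_false(significance(list(ci_low = 0.5, ci_high = 0.5)))
  expect_true(significance(list(ci_low = 0.2, ci_high = 0.45)))
})

test_that("cluster bootstrap resamples whole women deterministically", {
  s <- make_scores(30, 30, mu = 1, seed = 9)
  cl <- rep(sprintf("w%02d", 1:20), 3) # 3 images per woman
  b1 <- auc_boot(s$score, s$label, n_boot = 200, seed = 4, cluster = cl)
  b2 <- auc_boot(s$score, s$label, n_boot = 200, seed = 4, cluster = cl)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)
})

test_that("ROC coordinates integrate to the rank AUC", {
  set.seed(44)
  score <- round(stats::rnorm(60), 1)
  label <- rep(c("case", "control"), 30)
  rc <- roc_points(score, label)
  trap <- sum(diff(rc$fpr) * (rc$tpr[-nrow(rc)] + rc$tpr[-1]) / 2)
  expect_equal(trap, auc_rank(score, label), tolerance = 1e-12)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1)
})

test_that("per-woman aggregation takes the maximum score per woman", {
  sc <- data.frame(
    image_id = c("i1", "i2", "i3", "i4"),
    woman_id = c("w1", "w1", "w2", "w2"),
    label = factor(c("case", "case", "control", "control"),
                   levels = c("case", "control")),
    score = c(0.2, 0.9, 0.4, 0.1),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_by_woman(sc)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$score[agg$woman_id == "w1"], 0.9)
  expect_equal(agg$score[agg$woman_id == "w2"], 0.4)
})
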
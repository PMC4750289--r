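test_that("roc_auc handles separation, ties and reversal", {
  labels <- c(rep(0, 5), rep(1, 5))
  expect_equal(roc_auc(1:10, labels), 1)
  expect_equal(roc_auc(rep(3, 10), labels), 0.5)
  expect_equal(roc_auc(10:1, labels), 0)
  expect_error(roc_auc(1:5, rep(1, 5)), "positive and a negative")
  expect_error(roc_auc(1:4, c(0, 1, 2, 1)), "binary")
})

test_that("roc_auc matches pROC on random data including ties", {
  skip_if_not_installed("pROC")
  set.seed(81)
  for (i in 1:10) {
    labels <- rbinom(60, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(60, mean = labels), 1)  # rounding induces ties
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_auc(scores, labels), want, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(82)
  labels <- rbinom(80, 1, 0.5)
  scores <- rnorm(80)
  a0 <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a0)
  expect_equal(roc_auc(3 * scores - 10, labels), a0)
  expect_equal(roc_auc(atan(scores), labels), a0)
})

test_that("equal-variance equal-weight components intersect at the midpoint", {
  thr <- gmm_thresholds(mu = c(0, 4), sigma = c(0.5, 0.5))
  expect_equal(thr$X, 2)
  expect_equal(thr$resistant_cutoff, 0.5)   # min(2, 0 + 0.5)
  expect_equal(thr$sensitive_cutoff, 4.5)   # max(2, 4 + 0.5)
  # component order is normalized
  thr2 <- gmm_thresholds(mu = c(4, 0), sigma = c(0.5, 0.5))
  expect_equal(thr2$X, 2)
})

test_that("the density intersection respects weights and variances", {
  mu <- c(0, 3); sigma <- c(0.6, 1.1); w <- c(0.7, 0.3)
  X <- gmm_thresholds(mu, sigma, w)$X
  d1 <- w[1] * dnorm(X, mu[1], sigma[1])
  d2 <- w[2] * dnorm(X, mu[2], sigma[2])
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_gt(X, mu[1]); expect_lt(X, mu[2])
})

test_that("widening the component gap never narrows the intermediate zone", {
  width <- vapply(seq(1, 6, by = 0.5), function(gap) {
    thr <- gmm_thresholds(c(0, gap), c(0.5, 0.5))
    thr$sensitive_cutoff - thr$resistant_cutoff
  }, numeric(1))
  expect_true(all(diff(width) >= -1e-12))
})

test_that("EM recovers a well-separated mixture from 500 draws", {
  set.seed(83)
  x <- c(rnorm(250, 0, 0.5), rnorm(250, 4, 0.5))
  out <- gmm_sensitivity_calls(x)
  thr <- out$thresholds
  expect_lt(abs(thr$mu1 - 0), 0.15)
  expect_lt(abs(thr$mu2 - 4), 0.15)
  expect_lt(abs(thr$X - 2), 0.25)
  # calls follow the strict cutoffs
  expect_true(all(x[out$calls == "resistant"] < thr$resistant_cutoff))
  expect_true(all(x[out$calls == "sensitive"] > thr$sensitive_cutoff))
  expect_true(all(out$calls[x > thr$resistant_cutoff &
                              x < thr$sensitive_cutoff] == "intermediate"))
  # deterministic: same data, same fit
  expect_identical(gmm_sensitivity_calls(x)$thresholds, thr)
})

test_that("EM agrees with mclust on a clean mixture", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  set.seed(84)
  x <- c(rnorm(300, 1, 0.6), rnorm(200, 5, 0.8))
  fit <- gmm_sensitivity_calls(x)$fit
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("mixture fitting needs enough data and refuses degenerate fits", {
  expect_error(gmm_sensitivity_calls(rnorm(10)), "at least 20")
})

test_that("fixed compound thresholds classify long-format response tables", {
  cfgrows <- compound_config()
  expect_setequal(unique(cfgrows$compound),
                  c("PLX4720", "AZD6244", "Erlotinib", "Nutlin-3", "BYL719"))
  resp <- data.frame(sample = c("A", "B", "C"), metric = "ActArea",
                     value = c(2.5, 0.3, 1.0))
  calls <- fixed_threshold_calls(resp, "PLX4720")
  expect_equal(as.character(calls[c("A", "B", "C")]),
               c("sensitive", "resistant", "intermediate"))
  # multi-metric compound: all conditions must agree
  resp2 <- data.frame(sample = rep(c("A", "B", "C"), each = 2),
                      metric = rep(c("EC50", "Amax"), 3),
                      value = c(1.0, -50,    # sensitive on both
                                5.0, -10,    # resistant on both
                                1.0, -10))   # split: intermediate
  calls2 <- fixed_threshold_calls(resp2, "BYL719")
  expect_equal(as.character(calls2[c("A", "B", "C")]),
               c("sensitive", "resistant", "intermediate"))
  expect_error(fixed_threshold_calls(resp, "nosuchdrug"), "not in config")
})

test_that("bootstrap AUC comparison is symmetric, calibrated and seeded", {
  set.seed(85)
  labels <- rep(c(0, 1), each = 100)
  a <- labels + rnorm(200, 0, 0.1)        # near-perfect predictor
  b <- rnorm(200)                         # uninformative predictor
  # identical predictors: every replicate difference is zero
  same <- bootstrap_auc_compare(a, a, labels, n_boot = 200, seed = 1)
  expect_equal(same$p_value, 1)
  cmp <- bootstrap_auc_compare(a, b, labels, n_boot = 2000, seed = 2)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$auc_a, cmp$auc_b)
  # two-sided symmetry under swapping the predictors
  swp <- bootstrap_auc_compare(b, a, labels, n_boot = 2000, seed = 2)
  expect_equal(swp$p_value, cmp$p_value)
  # determinism given the seed
  again <- bootstrap_auc_compare(a, b, labels, n_boot = 2000, seed = 2)
  expect_identical(again$p_value, cmp$p_value)
})

test_that("activity scores out-predict the bare mutation flag for a graded driver", {
  # directional check over seeds: response grades with the driver's activity,
  # so the continuous gof score should beat the binary mutation indicator
  diffs <- vapply(1:4, function(seed) {
    sim <- generate_cohort(synth_config(n_samples = 150, n_genes = 6,
                                        n_oncogenes = 1, n_tsgs = 1,
                                        n_special = 0, seed = seed))
    res <- score_cohort(sim$cohort, quiet = TRUE)
    onc <- sim$truth$gene[sim$truth$role == "oncogene"][1]
    calls <- gmm_sensitivity_calls(sim$response$value)
    keep <- calls$calls != "intermediate"
    y <- calls$calls[keep] == "sensitive"
    if (length(unique(y)) < 2) return(NA_real_)
    mut_flag <- sim$cohort$samples %in%
      sim$cohort$variants$sample[sim$cohort$variants$gene == onc]
    roc_auc(res$gof[onc, sim$cohort$samples[keep]], y) -
      roc_auc(as.numeric(mut_flag)[keep], y)
  }, numeric(1))
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})
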
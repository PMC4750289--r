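#' ROC AUC by the Mann-Whitney formulation
#'
#' The probability that a randomly chosen positive sample scores higher than a
#' randomly chosen negative one, with ties contributing 1/2.  Equivalent to a
#' rank-sum statistic and to the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores Numeric predictor values, one per sample.
#' @param labels Binary outcome (logical, or 0/1), same length; both classes
#'   must be present.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("'labels' must be binary",
                                        call. = FALSE)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both a positive and a negative sample are required", call. = FALSE)
  r <- rank(scores)                       # average ranks handle ties as 0.5
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-component Gaussian-mixture sensitivity thresholds
#'
#' From mixture parameters (means \code{mu1 <= mu2}, standard deviations,
#' weights), computes the intersection point \code{X} of the two weighted
#' component densities inside \code{(mu1, mu2)} and derives the sensitivity
#' cutoffs \code{resistant_cutoff = min(X, mu1 + sigma1)} and
#' \code{sensitive_cutoff = max(X, mu2 + sigma2)}.  For metrics where larger
#' means more sensitive (e.g. activity area), values strictly below the
#' resistant cutoff are resistant and strictly above the sensitive cutoff are
#' sensitive; everything else is intermediate.
#'
#' @param mu,sigma,w Numeric length-2 vectors of component means, standard
#'   deviations and weights (components are reordered so \code{mu[1] <=
#'   mu[2]}).
#' @return An object of class \code{oncofuzz_gmm} with fields \code{mu1},
#'   \code{mu2}, \code{sigma1}, \code{sigma2}, \code{w1}, \code{w2}, \code{X},
#'   \code{resistant_cutoff}, \code{sensitive_cutoff}.
#' @export
gmm_thresholds <- function(mu, sigma, w = c(0.5, 0.5)) {
  stopifnot(length(mu) == 2L, length(sigma) == 2L, length(w) == 2L,
            all(is.finite(c(mu, sigma, w))), all(sigma > 0), all(w > 0))
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]; w <- w[o] / sum(w)
  X <- gaussian_intersection(mu, sigma, w)
  structure(list(mu1 = mu[1], mu2 = mu[2], sigma1 = sigma[1],
                 sigma2 = sigma[2], w1 = w[1], w2 = w[2], X = X,
                 resistant_cutoff = min(X, mu[1] + sigma[1]),
                 sensitive_cutoff = max(X, mu[2] + sigma[2])),
            class = "oncofuzz_gmm")
}

#' @export
print.oncofuzz_gmm <- function(x, ...) {
  cat(sprintf(paste0("<gmm: mu = (%.4g, %.4g), sigma = (%.4g, %.4g), ",
                     "w = (%.3g, %.3g)\n  X = %.4g, resistant < %.4g, ",
                     "sensitive > %.4g>\n"),
              x$mu1, x$mu2, x$sigma1, x$sigma2, x$w1, x$w2, x$X,
              x$resistant_cutoff, x$sensitive_cutoff))
  invisible(x)
}

# intersection of w1*N(mu1,s1) and w2*N(mu2,s2) inside [mu1, mu2]: the root of
# a quadratic in x (linear when variances are equal)
gaussian_intersection <- function(mu, sigma, w) {
  a <- 1 / (2 * sigma[2]^2) - 1 / (2 * sigma[1]^2)
  b <- mu[1] / sigma[1]^2 - mu[2] / sigma[2]^2
  cc <- mu[2]^2 / (2 * sigma[2]^2) - mu[1]^2 / (2 * sigma[1]^2) +
    log((w[1] * sigma[2]) / (w[2] * sigma[1]))
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return(mean(mu))  # identical components
    x <- -cc / b
    return(min(max(x, mu[1]), mu[2]))
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(mean(mu))          # no real crossing; midpoint fallback
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots >= mu[1] & roots <= mu[2]]
  if (length(inside)) inside[1]
  else min(max(roots[which.min(abs(roots - mean(mu)))], mu[1]), mu[2])
}

# deterministic univariate 2-component EM, initialized by a median split
fit_gmm2 <- function(x, max_iter = 200L, tol = 1e-8) {
  n <- length(x)
  med <- stats::median(x)
  lo <- x <= med; hi <- !lo
  if (sum(hi) < 2L) {                      # heavy ties at the median
    o <- order(x)
    lo <- seq_len(n) %in% o[seq_len(n %/% 2)]
    hi <- !lo
  }
  mu <- c(mean(x[lo]), mean(x[hi]))
  sigma <- pmax(c(stats::sd(x[lo]), stats::sd(x[hi])),
                1e-6 * (stats::sd(x) + 1e-12))
  sigma[!is.finite(sigma)] <- stats::sd(x)
  w <- c(mean(lo), mean(hi))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot)))
      stop("EM degeneracy while fitting the mixture; supply thresholds manually",
           call. = FALSE)
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8)
      stop("EM degeneracy: a mixture component vanished; supply thresholds manually",
           call. = FALSE)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                    sum((1 - g) * (x - mu[2])^2) / n2))
    sigma <- pmax(sigma, 1e-8 * diff(range(x)))
    w <- c(n1, n2) / n
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old, iterations = it)
}

#' Gaussian-mixture drug-sensitivity calls
#'
#' Fits a two-component univariate Gaussian mixture to a drug-response metric
#' (e.g. activity area) by EM with a deterministic median-split
#' initialization, derives the thresholds of [gmm_thresholds()] and assigns
#' each sample a call.
#'
#' @param values Numeric response values, at least 20 finite ones.
#' @param seed Unused by the deterministic fit but accepted (and recorded) so
#'   callers can treat this like other seeded procedures.
#' @return A list with \code{thresholds} (an \code{oncofuzz_gmm}),
#'   \code{calls} (factor with levels resistant/intermediate/sensitive) and
#'   \code{fit} (EM parameters and log-likelihood).
#' @export
gmm_sensitivity_calls <- function(values, seed = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 20L)
    stop("need at least 20 finite values to fit the mixture", call. = FALSE)
  fit <- fit_gmm2(x)
  thr <- gmm_thresholds(fit$mu, fit$sigma, fit$w)
  calls <- rep("intermediate", length(values))
  calls[values < thr$resistant_cutoff] <- "resistant"
  calls[values > thr$sensitive_cutoff] <- "sensitive"
  calls[!is.finite(values)] <- NA
  list(thresholds = thr,
       calls = factor(calls, levels = c("resistant", "intermediate",
                                        "sensitive")),
       fit = fit, seed = seed)
}

#' Fixed-threshold sensitivity calls from the compound table
#'
#' Applies the shipped per-compound thresholds (see [compound_config()]) to a
#' long-format response table.  For multi-metric compounds, a sample is
#' sensitive only if every metric satisfies its sensitive condition and
#' resistant only if every metric satisfies its resistant condition.
#'
#' @param response Data.frame with columns \code{sample}, \code{metric},
#'   \code{value}.
#' @param compound Compound name present in the config.
#' @param config Compound config table, default the shipped one.
#' @return Named factor of calls (resistant/intermediate/sensitive) indexed by
#'   sample; samples missing any required metric get \code{NA}.
#' @export
fixed_threshold_calls <- function(response, compound,
                                  config = compound_config()) {
  rows <- config[config$compound == compound, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("compound not in config: ", compound, call. = FALSE)
  samples <- unique(response$sample)
  cmp <- function(v, op, thr)
    switch(op, "<=" = v <= thr, ">=" = v >= thr, "<" = v < thr, ">" = v > thr)
  sens <- res <- matrix(NA, length(samples), nrow(rows))
  for (j in seq_len(nrow(rows))) {
    r <- response[response$metric == rows$metric[j], , drop = FALSE]
    v <- r$value[match(samples, r$sample)]
    sens[, j] <- cmp(v, rows$sensitive_cmp[j], rows$sensitive_value[j])
    res[, j] <- cmp(v, rows$resistant_cmp[j], rows$resistant_value[j])
  }
  call <- ifelse(apply(sens, 1, all), "sensitive",
                 ifelse(apply(res, 1, all), "resistant", "intermediate"))
  stats::setNames(factor(call, levels = c("resistant", "intermediate",
                                          "sensitive")), samples)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Tests whether two predictors measured on the same samples have equal AUC
#' against the same binary outcome.  Samples are resampled with replacement;
#' in each replicate the AUC difference is recomputed, and the two-sided
#' p-value comes from the normal approximation
#' \code{z = observed difference / bootstrap sd} (replicates without both
#' classes are redrawn).  With identical predictors every replicate difference
#' is zero and the p-value is 1.
#'
#' @param scores_a,scores_b Paired numeric predictors.
#' @param labels Binary outcome, same length.
#' @param n_boot Number of bootstrap replicates (>= 1000 recommended).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return List with \code{p_value}, \code{auc_a}, \code{auc_b},
#'   \code{difference} and \code{n_boot}.
#' @export
bootstrap_auc_compare <- function(scores_a, scores_b, labels,
                                  n_boot = 2000L, seed = 1L) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  if (is.logical(labels)) labels <- as.integer(labels)
  auc_a <- roc_auc(scores_a, labels)
  auc_b <- roc_auc(scores_b, labels)
  d_obs <- auc_a - auc_b
  n <- length(labels)
  diffs <- numeric(n_boot)
  with_preserved_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      diffs[b] <- roc_auc(scores_a[idx], labels[idx]) -
        roc_auc(scores_b[idx], labels[idx])
    }
  })
  s <- stats::sd(diffs)
  p <- if (s == 0) {
    if (d_obs == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(d_obs) / s)
  list(p_value = p, auc_a = auc_a, auc_b = auc_b, difference = d_obs,
       n_boot = n_boot)
}

# run code under a given seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
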
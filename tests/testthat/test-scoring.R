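test_that("prototypical variants score at the extremes of their categories", {
  rb <- default_rulebase()
  ev <- steep_expr()
  # recurrent activating variant, high expression, amplified: dominant GoF
  s_gof <- score_variant(rb, list(class = "Missense_Mutation",
                                  recurrent = TRUE), 20, 1, expr_var = ev)
  expect_gt(s_gof, 0.8)
  # truncating variant, low expression, deleted: dominant LoF
  s_lof <- score_variant(rb, list(class = "Frame_Shift_Del",
                                  recurrent = FALSE), -10, -1, expr_var = ev)
  expect_lt(s_lof, -0.8)
  # wild type at the medium-expression center with neutral copy number:
  # only the symmetric no-effect rule fires
  s0 <- score_variant(rb, list(class = "No_Mutation", recurrent = FALSE),
                      5, 0, expr_var = ev)
  expect_lt(abs(s0), 1e-6)
})

test_that("special-gene mirroring negates activating-context scores exactly", {
  rb <- default_rulebase()
  rs <- apply_special_rules(rb)
  ev <- steep_expr()
  set.seed(31)
  for (i in 1:12) {
    e <- runif(1, 0, 10); c0 <- runif(1, -1.5, 1.5)
    v <- list(class = sample(c("Missense_Mutation", "In_Frame_Ins",
                               "In_Frame_Del"), 1),
              recurrent = sample(c(TRUE, FALSE), 1))
    plain <- score_variant(rs$default, v, e, c0, expr_var = ev)
    mirrored <- score_variant(rs$special, v, e, c0, expr_var = ev)
    expect_equal(mirrored, -plain, tolerance = 1e-12)
  }
})

test_that("truncating and wild-type rules are untouched by mirroring", {
  rs <- apply_special_rules(default_rulebase())
  ev <- steep_expr()
  for (cls in c("Nonsense_Mutation", "Frame_Shift_Ins", "Splice_Site",
                "No_Mutation")) {
    v <- list(class = cls, recurrent = FALSE)
    expect_identical(score_variant(rs$default, v, 1, -0.8, expr_var = ev),
                     score_variant(rs$special, v, 1, -0.8, expr_var = ev))
  }
  # TP53-style gene still scores strongly negative for truncating variants
  s <- score_variant(rs$special, list(class = "Nonsense_Mutation",
                                      recurrent = FALSE), -10, -1,
                     expr_var = steep_expr())
  expect_lt(s, -0.8)
  # and strongly negative (not positive) for recurrent missense in a
  # high-expression amplified context
  s2 <- score_variant(rs$special, list(class = "Missense_Mutation",
                                       recurrent = TRUE), 20, 1,
                      expr_var = steep_expr())
  expect_lt(s2, -0.8)
})

test_that("rulebase_for_gene dispatches only listed genes to mirrored rules", {
  rb <- default_rulebase()
  rs <- apply_special_rules(rb, special_genes = c("TP53", "CDKN2A"))
  expect_identical(rulebase_for_gene(rs, "KRAS"), rs$default)
  expect_identical(rulebase_for_gene(rs, "TP53"), rs$special)
  expect_identical(rulebase_for_gene(rs, "CDKN2A"), rs$special)
  # a plain rulebase passes through untouched
  expect_identical(rulebase_for_gene(rb, "TP53"), rb)
})

test_that("per-sample aggregation takes max of GoF and min of LoF variants", {
  expect_equal(score_gene_sample(c(0.9, -0.7)), c(gof = 0.9, lof = -0.7))
  expect_equal(score_gene_sample(c(0.3, 0.8)), c(gof = 0.8, lof = 0))
  expect_equal(score_gene_sample(numeric(0), no_mutation_score = -0.4),
               c(gof = 0, lof = -0.4))
  expect_equal(score_gene_sample(numeric(0), no_mutation_score = 0.25),
               c(gof = 0.25, lof = 0))
  expect_error(score_gene_sample(numeric(0)), "no no-mutation score")
})

test_that("scores track expression monotonically within rule contexts", {
  rb <- set_variable(default_rulebase(), default_cn_variable())
  set.seed(33)
  vals <- rnorm(200, 8, 1.2)
  ev <- fit_expression_memberships(vals)
  rbg <- set_variable(rb, ev)
  fit <- attr(ev, "fit")
  xs <- seq(min(vals) - 1, max(vals) + 1, length.out = 150)
  for (cn in c(-1, 0, 1)) {
    for (ctx in list(c(1, 1), c(1, 0), c(7, 0))) {
      s <- aggregate_and_defuzzify(rbg, fire_rules(rbg, list(
        Mutation = ctx[1], Recurrence = ctx[2], Expression = xs, CN = cn)))
      # non-decreasing up to the small centroid wiggle of max-union Mamdani
      # aggregation in tertile transition zones
      expect_gt(min(diff(s)), -0.02)
      # deep in the low vs. high tertile, where a single rule dominates, the
      # consequent ordering shows cleanly
      deep <- aggregate_and_defuzzify(rbg, fire_rules(rbg, list(
        Mutation = ctx[1], Recurrence = ctx[2],
        Expression = c(fit$m[1] - 5 * fit$s[1], fit$m[3] + 5 * fit$s[3]),
        CN = cn)))
      expect_gte(deep[2], deep[1] - 1e-9)
    }
  }
})

test_that("recurrent activating variants never score below non-recurrent ones", {
  rb <- set_variable(default_rulebase(), default_cn_variable())
  set.seed(34)
  ev <- fit_expression_memberships(rnorm(200, 8, 1.2))
  rbg <- set_variable(rb, ev)
  xs <- seq(4, 12, length.out = 60)
  for (cn in seq(-1.2, 1.2, by = 0.4)) {
    rec <- aggregate_and_defuzzify(rbg, fire_rules(rbg, list(
      Mutation = 1, Recurrence = 1, Expression = xs, CN = cn)))
    non <- aggregate_and_defuzzify(rbg, fire_rules(rbg, list(
      Mutation = 1, Recurrence = 0, Expression = xs, CN = cn)))
    expect_true(all(rec >= non - 1e-12))
  }
})

make_tiny_cohort <- function(n = 40, seed = 51, variants = NULL) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n))
  genes <- c("GA", "GB")
  expression <- rbind(GA = rnorm(n, 8, 1), GB = rnorm(n, 6, 1.5))
  colnames(expression) <- samples
  copy_number <- matrix(rnorm(2 * n, 0, 0.1), 2, n,
                        dimnames = list(genes, samples))
  omics_cohort(expression, copy_number, variants)
}

test_that("a zero-variant cohort is scored purely by the wild-type rules", {
  # three tight, well-separated expression clusters: at the middle cluster's
  # center with neutral copy number, only the no-effect rule fires
  n <- 9
  samples <- sprintf("S%02d", 1:n)
  expression <- matrix(c(1, 1.01, 1.02, 5, 5.01, 5.02, 9, 9.01, 9.02), 1, n,
                       dimnames = list("GA", samples))
  copy_number <- matrix(0, 1, n, dimnames = list("GA", samples))
  co <- omics_cohort(expression, copy_number)
  res <- score_cohort(co, quiet = TRUE)
  expect_equal(unname(res$gof["GA", "S05"]), 0)   # the 5.01 middle sample
  expect_equal(unname(res$lof["GA", "S05"]), 0)
  expect_true(all(res$gof >= 0, na.rm = TRUE))
  expect_true(all(res$lof <= 0, na.rm = TRUE))
})

test_that("cohort scoring is deterministic and permutation-equivariant", {
  v <- data.frame(sample = c("S01", "S03"), gene = "GA",
                  class = c("Missense_Mutation", "Nonsense_Mutation"),
                  protein_position = c(10L, 22L), contig = NA_character_,
                  genomic_position = NA_real_, stringsAsFactors = FALSE)
  co <- make_tiny_cohort(variants = v)
  r1 <- score_cohort(co, quiet = TRUE)
  r2 <- score_cohort(co, quiet = TRUE)
  expect_identical(r1$gof, r2$gof)
  expect_identical(r1$lof, r2$lof)
  # permuting sample columns permutes score columns identically
  perm <- rev(co$samples)
  co_p <- omics_cohort(co$expression[, perm], co$copy_number[, perm], v)
  r3 <- score_cohort(co_p, quiet = TRUE)
  expect_equal(r3$gof, r1$gof[, perm])
  expect_equal(r3$lof, r1$lof[, perm])
})

test_that("genes with constant expression are skipped with all-NA scores", {
  co <- make_tiny_cohort()
  co$expression["GB", ] <- 4
  expect_message(res <- score_cohort(co, quiet = FALSE), "degenerate")
  expect_equal(res$skipped, "GB")
  expect_true(all(is.na(res$gof["GB", ])))
  expect_false(anyNA(res$gof["GA", ]))
})

test_that("mutant samples of a planted oncogene outscore wild-type samples", {
  sim <- generate_cohort(synth_config(n_samples = 120, n_genes = 10,
                                      n_oncogenes = 2, n_tsgs = 2,
                                      n_special = 1, seed = 61))
  res <- score_cohort(sim$cohort, quiet = TRUE)
  onc <- sim$truth$gene[sim$truth$role == "oncogene"][1]
  mut <- unique(sim$cohort$variants$sample[sim$cohort$variants$gene == onc])
  wt <- setdiff(sim$cohort$samples, mut)
  expect_gt(mean(res$gof[onc, mut]), mean(res$gof[onc, wt]))
  tsg <- sim$truth$gene[sim$truth$role == "tsg"][1]
  mut_t <- unique(sim$cohort$variants$sample[sim$cohort$variants$gene == tsg])
  expect_lt(mean(res$lof[tsg, mut_t]),
            mean(res$lof[tsg, setdiff(sim$cohort$samples, mut_t)]))
})
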
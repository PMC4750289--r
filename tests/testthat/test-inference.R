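make_scoring_rb <- function() {
  set_variable(set_variable(default_rulebase(), steep_expr()),
               default_cn_variable())
}

test_that("rule activations follow min/max fuzzy logic on crisp inputs", {
  rb <- make_scoring_rb()
  # every leaf of rule 1 at degree 1: recurrent missense, expression deep in
  # the high tertile, strongly amplified copy number
  acts <- fire_rules(rb, list(Mutation = 1, Recurrence = 1,
                              Expression = 20, CN = 1))
  expect_equal(unname(acts[1, "1"]), 1)
  # all rules keyed on a different mutation class are silent
  expect_equal(unname(acts[1, as.character(19:30)]), rep(0, 12))
  # expression exactly at the high sigmoid inflection halves the activation
  m_high <- attr(steep_expr(), "fit")$m[3]
  acts2 <- fire_rules(rb, list(Mutation = 1, Recurrence = 1,
                               Expression = m_high, CN = 1))
  expect_equal(unname(acts2[1, "1"]), 0.5)
  # missing input is an error
  expect_error(fire_rules(rb, list(Mutation = 1, Recurrence = 1,
                                   Expression = 20)),
               "missing crisp input")
})

test_that("activations match an independent recursive tree-walk oracle", {
  rb <- make_scoring_rb()
  set.seed(7)
  for (i in 1:40) {
    inputs <- list(Mutation = sample(0:8, 1), Recurrence = sample(0:1, 1),
                   Expression = runif(1, -2, 12), CN = runif(1, -2, 2))
    acts <- fire_rules(rb, inputs)
    oracle <- vapply(rb$rules, function(r)
      bf_antecedent(r$antecedent, inputs, rb$inputs), numeric(1))
    expect_equal(unname(acts[1, ]), oracle, tolerance = 1e-12)
  }
})

test_that("symmetric aggregated curves defuzzify to exactly zero", {
  rb <- make_scoring_rb()
  n_rules <- length(rb$rules)
  # only the no_effect consequent fired (rule 30), at full degree
  a <- numeric(n_rules); a[30] <- 1
  expect_equal(aggregate_and_defuzzify(rb, a), 0)
  # GoF and LoF mirror-image consequents fired at equal degree
  b <- numeric(n_rules); b[5] <- 0.6; b[23] <- 0.6   # GoF and LoF
  expect_equal(aggregate_and_defuzzify(rb, b), 0)
  # nothing fired at all: neutral score by convention
  expect_equal(aggregate_and_defuzzify(rb, numeric(n_rules)), 0)
})

test_that("centroid matches a trapezoidal-integration oracle and is grid-stable", {
  rb <- make_scoring_rb()
  grid <- oncofuzz:::output_grid(rb$output$domain, 2001L)
  set.seed(11)
  for (i in 1:25) {
    a <- runif(length(rb$rules)) * rbinom(length(rb$rules), 1, 0.3)
    got <- aggregate_and_defuzzify(rb, a, resolution = 2001L)
    agg <- bf_curve(rb, a, grid)
    denom <- pracma::trapz(grid, agg)
    want <- if (denom == 0) 0 else pracma::trapz(grid, grid * agg) / denom
    expect_equal(got, want, tolerance = 1e-6)
    # refining the grid tenfold moves the centroid by less than 1e-3
    fine <- aggregate_and_defuzzify(rb, a, resolution = 20001L)
    expect_lt(abs(got - fine), 1e-3)
  }
})

test_that("defuzzified scores never leave the output domain", {
  rb <- make_scoring_rb()
  set.seed(3)
  inputs <- list(Mutation = sample(0:8, 400, replace = TRUE),
                 Recurrence = sample(0:1, 400, replace = TRUE),
                 Expression = runif(400, -10, 25),
                 CN = runif(400, -4, 4))
  s <- aggregate_and_defuzzify(rb, fire_rules(rb, inputs))
  expect_true(all(abs(s) <= 1))
})

test_that("duplicating a rule leaves the score unchanged (union idempotence)", {
  rb <- default_rulebase()
  lines <- format_fcl(rb)
  dup <- sub("RULE 5:", "RULE 31:", lines[grepl("RULE 5:", lines)])
  lines2 <- append(lines, dup, after = which(grepl("RULE 30:", lines)))
  rb2 <- parse_rulebase(lines2)
  expect_length(rb2$rules, 31)
  ev <- steep_expr(); cn <- default_cn_variable()
  set.seed(5)
  for (i in 1:10) {
    v <- list(class = "Missense_Mutation", recurrent = TRUE)
    e <- runif(1, 0, 10); c0 <- runif(1, -1.5, 1.5)
    expect_equal(score_variant(rb, v, e, c0, expr_var = ev, cn_var = cn),
                 score_variant(rb2, v, e, c0, expr_var = ev, cn_var = cn))
  }
})

test_that("union aggregation is monotone: extra fired rules never lower the curve", {
  rb <- make_scoring_rb()
  grid <- oncofuzz:::output_grid(rb$output$domain, 1001L)
  set.seed(13)
  for (i in 1:20) {
    a <- runif(length(rb$rules)) * rbinom(length(rb$rules), 1, 0.25)
    b <- a
    off <- which(b == 0)
    if (length(off) == 0) next
    b[sample(off, 1)] <- runif(1)
    expect_true(all(bf_curve(rb, b, grid) >= bf_curve(rb, a, grid) - 1e-15))
  }
})

test_that("inference on random small systems matches the brute-force oracle", {
  for (seed in 1:20) {
    rb <- random_system(seed)
    grid <- oncofuzz:::output_grid(rb$output$domain, 2001L)
    set.seed(seed + 1000)
    for (i in 1:5) {
      inputs <- as.list(stats::setNames(runif(length(rb$inputs), -2, 2),
                                        names(rb$inputs)))
      got <- aggregate_and_defuzzify(rb, fire_rules(rb, inputs), 2001L)
      expect_equal(got, bf_score(rb, inputs, grid), tolerance = 1e-9)
    }
  }
})

test_that("resolution below the documented minimum is rejected", {
  rb <- make_scoring_rb()
  expect_error(aggregate_and_defuzzify(rb, numeric(30), resolution = 50),
               ">= 101")
})
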
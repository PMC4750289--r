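# Independent brute-force oracle for Mamdani inference, deliberately written
# from first principles (its own membership formulas, its own tree walk, and
# trapezoidal integration via pracma) so it shares no code path with the
# package implementation.

bf_mf <- function(mf, x) {
  p <- mf$params
  if (mf$kind == "sigmoid_increasing") return(1 / (1 + exp(-p$a * (x - p$c))))
  if (mf$kind == "sigmoid_decreasing") return(1 - 1 / (1 + exp(-p$a * (x - p$c))))
  if (mf$kind == "gaussian") return(exp(-0.5 * ((x - p$mean) / p$sd)^2))
  if (mf$kind == "triangle") {
    y <- ifelse(x < p$left | x > p$right, 0,
                ifelse(x <= p$peak,
                       ifelse(p$peak == p$left, 1, (x - p$left) / (p$peak - p$left)),
                       ifelse(p$right == p$peak, 1, (p$right - x) / (p$right - p$peak))))
    return(y)
  }
  if (mf$kind == "trapezoid") {
    y <- ifelse(x < p$lf | x > p$rf, 0,
                ifelse(x < p$ls,
                       ifelse(p$ls == p$lf, 1, (x - p$lf) / (p$ls - p$lf)),
                       ifelse(x <= p$rs, 1,
                              ifelse(p$rf == p$rs, 1, (p$rf - x) / (p$rf - p$rs)))))
    return(y)
  }
  if (mf$kind == "singleton") return(ifelse(abs(x - p$location) < p$tol, 1, 0))
  stop("oracle: unknown kind ", mf$kind)
}

bf_antecedent <- function(e, inputs, vars) {
  if (e$op == "is")
    return(bf_mf(vars[[e$variable]]$categories[[e$category]],
                 inputs[[e$variable]]))
  vals <- vapply(e$children, bf_antecedent, numeric(1), inputs = inputs,
                 vars = vars)
  if (e$op == "and") min(vals) else max(vals)
}

# aggregated output curve on a supplied grid (clip at activation, union by max)
bf_curve <- function(rb, activations, grid) {
  agg <- rep(0, length(grid))
  for (j in seq_along(rb$rules)) {
    cons <- rb$output$categories[[rb$rules[[j]]$consequent]]
    agg <- pmax(agg, pmin(activations[j], bf_mf(cons, grid)))
  }
  agg
}

# full scalar inference oracle: centroid by trapezoidal integration
bf_score <- function(rb, inputs, grid) {
  acts <- vapply(rb$rules, function(r)
    bf_antecedent(r$antecedent, inputs, rb$inputs), numeric(1))
  agg <- bf_curve(rb, acts, grid)
  denom <- pracma::trapz(grid, agg)
  if (denom == 0) 0 else pracma::trapz(grid, grid * agg) / denom
}

# expression fixture with widely separated, tight tertiles: membership tails
# vanish (< 1e-40), so exactly one expression category is active at each center
steep_expr <- function() {
  fit_expression_memberships(c(1, 1.01, 1.02, 5, 5.01, 5.02, 9, 9.01, 9.02))
}

# random small fuzzy system (<= 3 input variables, <= 6 rules) for
# oracle-equivalence checks
random_system <- function(seed) {
  set.seed(seed)
  n_var <- sample(1:3, 1)
  mk_mf <- function(dom) {
    k <- sample(1:4, 1)
    if (k == 1) mf_gaussian(runif(1, dom[1], dom[2]), runif(1, 0.2, 1))
    else if (k == 2) {
      pts <- sort(runif(3, dom[1], dom[2]))
      mf_triangle(pts[1], pts[2], pts[3])
    } else if (k == 3) mf_sigmoid_increasing(runif(1, dom[1], dom[2]),
                                             runif(1, 0.5, 5))
    else mf_sigmoid_decreasing(runif(1, dom[1], dom[2]), runif(1, 0.5, 5))
  }
  vars <- lapply(seq_len(n_var), function(i) {
    cats <- lapply(seq_len(sample(2:3, 1)), function(j) mk_mf(c(-2, 2)))
    names(cats) <- paste0("c", seq_along(cats))
    linguistic_variable(paste0("V", i), c(-2, 2), cats)
  })
  out_cats <- lapply(seq_len(sample(2:4, 1)), function(j)
    mf_gaussian(runif(1, -0.8, 0.8), runif(1, 0.1, 0.4)))
  names(out_cats) <- paste0("o", seq_along(out_cats))
  output <- linguistic_variable("Out", c(-1, 1), out_cats)
  rnd_expr <- function(depth) {
    if (depth >= 2 || runif(1) < 0.5) {
      v <- vars[[sample(n_var, 1)]]
      return(oncofuzz:::atom(v$name, sample(names(v$categories), 1)))
    }
    oncofuzz:::node(sample(c("and", "or"), 1),
                    lapply(seq_len(sample(2:3, 1)),
                           function(i) rnd_expr(depth + 1)))
  }
  rules <- lapply(seq_len(sample(2:6, 1)), function(i)
    oncofuzz:::fuzzy_rule(rnd_expr(0), sample(names(out_cats), 1), i))
  rulebase(vars, output, rules)
}

# gene-by-sample fixture for classifier boundary tests: m of n mutated samples
# satisfy gof > |lof|, the rest |lof| > gof
classify_fixture <- function(m, n = 100L, gene = "G1") {
  samples <- sprintf("S%03d", seq_len(n))
  gof <- matrix(c(rep(0.7, m), rep(0.2, n - m)), 1, n,
                dimnames = list(gene, samples))
  lof <- matrix(c(rep(-0.2, m), rep(-0.7, n - m)), 1, n,
                dimnames = list(gene, samples))
  variants <- data.frame(sample = samples, gene = gene,
                         class = "Missense_Mutation",
                         protein_position = 10L, contig = NA_character_,
                         genomic_position = NA_real_,
                         stringsAsFactors = FALSE)
  list(gof = gof, lof = lof, variants = variants, n = n)
}

# variant table with k samples mutated at one shared position of one gene
recurrence_fixture <- function(k, gene = "G1", position = 42L) {
  data.frame(sample = sprintf("S%04d", seq_len(k)), gene = gene,
             class = "Missense_Mutation", protein_position = position,
             contig = NA_character_, genomic_position = NA_real_,
             stringsAsFactors = FALSE)
}
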
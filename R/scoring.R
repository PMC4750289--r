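#' Assemble an aligned multi-omics cohort
#'
#' Couples a variant table with expression and copy-number matrices that share
#' the same gene rows and sample columns.
#'
#' @param expression Numeric genes-x-samples matrix of normalized expression.
#' @param copy_number Numeric genes-x-samples matrix of log2 copy ratios, with
#'   identical dimnames.
#' @param variants Variant data.frame (see [read_mutations()]); every variant
#'   must refer to a gene and sample present in the matrices.  May have zero
#'   rows.
#' @return An object of class \code{oncofuzz_cohort}.
#' @export
omics_cohort <- function(expression, copy_number, variants = NULL) {
  stopifnot(is.matrix(expression), is.matrix(copy_number))
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("'expression' needs gene rownames and sample colnames", call. = FALSE)
  if (!identical(dimnames(expression), dimnames(copy_number)))
    stop("expression and copy-number matrices must share gene and sample order",
         call. = FALSE)
  if (is.null(variants))
    variants <- data.frame(sample = character(0), gene = character(0),
                           class = character(0),
                           protein_position = integer(0),
                           contig = character(0),
                           genomic_position = numeric(0),
                           stringsAsFactors = FALSE)
  need <- c("sample", "gene", "class", "protein_position")
  missing <- setdiff(need, names(variants))
  if (length(missing))
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"contig" %in% names(variants)) variants$contig <- NA_character_
  if (!"genomic_position" %in% names(variants))
    variants$genomic_position <- NA_real_
  bad_s <- setdiff(variants$sample, colnames(expression))
  bad_g <- setdiff(variants$gene, rownames(expression))
  if (length(bad_s) || length(bad_g))
    stop("variants reference unknown ",
         if (length(bad_s)) paste0("sample(s) ", paste(utils::head(bad_s, 3),
                                                       collapse = ", ")),
         if (length(bad_s) && length(bad_g)) " and ",
         if (length(bad_g)) paste0("gene(s) ", paste(utils::head(bad_g, 3),
                                                     collapse = ", ")),
         call. = FALSE)
  unknown <- setdiff(unique(variants$class), names(mutation_codes))
  if (length(unknown))
    stop("unknown mutation class(es): ", paste(unknown, collapse = ", "),
         " (run normalize_variant_class first)", call. = FALSE)
  structure(list(samples = colnames(expression),
                 genes = rownames(expression),
                 expression = expression,
                 copy_number = copy_number,
                 variants = variants),
            class = "oncofuzz_cohort")
}

#' @export
print.oncofuzz_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d genes x %d samples, %d variant records>\n",
              length(x$genes), length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Score one variant
#'
#' Fuzzifies (mutation class, recurrence, expression, copy number), fires all
#' rules and returns the centroid activity score in the output domain.
#'
#' @param rb Rule base (typically [default_rulebase()], with the
#'   \code{Expression} variable replaced per gene).
#' @param variant A one-row variant record, or a list with elements
#'   \code{class} and \code{recurrent}.
#' @param expr_value,cn_value Crisp expression and log2 copy-ratio values.
#' @param expr_var,cn_var Optional variable overrides substituted into
#'   \code{rb} before firing (e.g. the output of
#'   [fit_expression_memberships()]).
#' @param resolution Defuzzification grid size, see
#'   [aggregate_and_defuzzify()].
#' @return A single score in \code{[-1, 1]} under the default output domain.
#' @export
score_variant <- function(rb, variant, expr_value, cn_value,
                          expr_var = NULL, cn_var = NULL,
                          resolution = 2001L) {
  if (!is.null(expr_var)) rb <- set_variable(rb, expr_var)
  if (!is.null(cn_var)) rb <- set_variable(rb, cn_var)
  cls <- as.character(variant$class)
  if (!cls %in% names(mutation_codes))
    stop("unknown mutation class: ", cls, call. = FALSE)
  rec <- isTRUE(as.logical(variant$recurrent))
  acts <- fire_rules(rb, list(Mutation = as.numeric(mutation_codes[[cls]]),
                              Recurrence = as.numeric(rec),
                              Expression = expr_value,
                              CN = cn_value))
  aggregate_and_defuzzify(rb, acts, resolution)
}

mirror_map <- c(high_GoF = "high_LoF", GoF = "LoF", low_GoF = "low_LoF",
                no_effect = "no_effect",
                low_LoF = "low_GoF", LoF = "GoF", high_LoF = "high_GoF")

rule_is_activating <- function(rule) {
  any(vapply(expr_leaves(rule$antecedent), function(l)
    l$variable == "Mutation" && l$category %in% activating_classes,
    logical(1)))
}

#' Special-gene rule mirroring
#'
#' For genes such as TP53 whose recurrent missense mutations inactivate rather
#' than activate the protein, every rule conditioned on an activating mutation
#' class (missense or in-frame indel) has its consequent mirrored to the LoF
#' counterpart (\code{high_GoF <-> high_LoF}, \code{GoF <-> LoF},
#' \code{low_GoF <-> low_LoF}; \code{no_effect} is its own mirror).  Rules for
#' truncating or absent mutations are untouched.
#'
#' @param rb A rule base whose output categories use the default seven labels.
#' @param special_genes Genes scored with the mirrored base (default
#'   \code{"TP53"}).
#' @return An object of class \code{oncofuzz_ruleset} holding the original and
#'   mirrored rule bases; [rulebase_for_gene()] dispatches per gene.
#' @export
apply_special_rules <- function(rb, special_genes = "TP53") {
  stopifnot(inherits(rb, "oncofuzz_rulebase"))
  rules <- lapply(rb$rules, function(r) {
    if (rule_is_activating(r)) {
      to <- mirror_map[[r$consequent]]
      if (is.null(to))
        stop("cannot mirror output category '", r$consequent,
             "': not one of the default seven labels", call. = FALSE)
      fuzzy_rule(r$antecedent, to, r$number)
    } else r
  })
  structure(list(default = rb,
                 special = rulebase(unname(rb$inputs), rb$output, rules),
                 special_genes = unique(as.character(special_genes))),
            class = "oncofuzz_ruleset")
}

#' @rdname apply_special_rules
#' @param rs An \code{oncofuzz_ruleset} (or plain rule base, returned as is).
#' @param gene Gene identifier.
#' @export
rulebase_for_gene <- function(rs, gene) {
  if (inherits(rs, "oncofuzz_rulebase")) return(rs)
  stopifnot(inherits(rs, "oncofuzz_ruleset"))
  if (gene %in% rs$special_genes) rs$special else rs$default
}

#' Summarize variant scores into per-sample GoF and LoF activities
#'
#' Positive-scoring variants are the gain-of-function candidates and
#' negative-scoring ones the loss-of-function candidates; the sample's GoF
#' activity is the maximum across GoF variants (0 if none) and its LoF
#' activity the minimum across LoF variants (0 if none).  An unmutated
#' gene/sample pair is summarized from its single no-mutation score by the
#' same sign split.
#'
#' @param variant_scores Numeric vector of scores for one gene/sample pair
#'   (may be empty when \code{no_mutation_score} is given).
#' @param no_mutation_score Optional single score from the no-mutation rules.
#' @return Named numeric vector \code{c(gof = ..., lof = ...)} with
#'   \code{gof >= 0} and \code{lof <= 0}.
#' @export
score_gene_sample <- function(variant_scores, no_mutation_score = NULL) {
  if (length(variant_scores) == 0L) {
    if (is.null(no_mutation_score))
      stop("no variant scores and no no-mutation score", call. = FALSE)
    variant_scores <- no_mutation_score
  }
  c(gof = max(0, max(variant_scores)), lof = min(0, min(variant_scores)))
}

#' Score a whole cohort
#'
#' Fits expression membership functions per gene, calls hotspot recurrence,
#' scores every variant and every unmutated gene/sample pair, and aggregates
#' to gene-by-sample GoF and LoF matrices.  Genes with constant expression
#' cannot be fitted and are returned as all-\code{NA} rows (with a warning).
#'
#' @param cohort An [omics_cohort()].
#' @param rb Rule base; default [default_rulebase()].
#' @param cfg Recurrence configuration, see [recurrence_config()].
#' @param special_genes Genes scored with mirrored activating rules
#'   (see [apply_special_rules()]); default \code{"TP53"}.  Use
#'   \code{character(0)} to disable.
#' @param cn_var Copy-number variable; default [default_cn_variable()].
#' @param resolution Defuzzification grid size.
#' @param quiet Suppress progress/filter log messages.
#' @return List with elements \code{gof} (matrix in \code{[0, 1]}), \code{lof}
#'   (matrix in \code{[-1, 0]}), \code{variant_scores} (the variant table with
#'   \code{recurrent} flags and a \code{score} column), and \code{skipped}
#'   (genes that could not be fitted).
#' @export
score_cohort <- function(cohort, rb = default_rulebase(),
                         cfg = recurrence_config(),
                         special_genes = "TP53",
                         cn_var = default_cn_variable(),
                         resolution = 2001L, quiet = FALSE) {
  stopifnot(inherits(cohort, "oncofuzz_cohort"))
  rs <- apply_special_rules(rb, special_genes)
  n_samples <- length(cohort$samples)
  variants <- cohort$variants
  variants$recurrent <- compute_recurrence(variants, n_samples, cfg)
  if (!quiet)
    message(sprintf("score_cohort: %d variants, %d flagged recurrent",
                    nrow(variants), sum(variants$recurrent)))
  gof <- matrix(NA_real_, length(cohort$genes), n_samples,
                dimnames = list(cohort$genes, cohort$samples))
  lof <- gof
  variants$score <- rep(NA_real_, nrow(variants))
  skipped <- character(0)
  vg_split <- split(seq_len(nrow(variants)), variants$gene)

  for (g in cohort$genes) {
    expr_var <- tryCatch(fit_expression_memberships(cohort$expression[g, ]),
                         error = function(e) NULL)
    if (is.null(expr_var)) {
      skipped <- c(skipped, g)
      next
    }
    rb_g <- set_variable(set_variable(rulebase_for_gene(rs, g), expr_var),
                         cn_var)
    vi <- vg_split[[g]]
    vi <- vi[variants$class[vi] != "No_Mutation"]
    mut_samples <- character(0)
    if (length(vi)) {
      scores <- aggregate_and_defuzzify(rb_g, fire_rules(rb_g, list(
        Mutation = as.numeric(mutation_codes[variants$class[vi]]),
        Recurrence = as.numeric(variants$recurrent[vi]),
        Expression = cohort$expression[g, variants$sample[vi]],
        CN = cohort$copy_number[g, variants$sample[vi]])), resolution)
      variants$score[vi] <- scores
      for (s in unique(variants$sample[vi])) {
        sc <- scores[variants$sample[vi] == s]
        gl <- score_gene_sample(sc)
        gof[g, s] <- gl[["gof"]]
        lof[g, s] <- gl[["lof"]]
      }
      mut_samples <- unique(variants$sample[vi])
    }
    wt <- setdiff(cohort$samples, mut_samples)
    if (length(wt)) {
      s0 <- aggregate_and_defuzzify(rb_g, fire_rules(rb_g, list(
        Mutation = 0, Recurrence = 0,
        Expression = cohort$expression[g, wt],
        CN = cohort$copy_number[g, wt])), resolution)
      gof[g, wt] <- pmax(0, s0)
      lof[g, wt] <- pmin(0, s0)
    }
  }
  if (length(skipped) && !quiet)
    message("score_cohort: skipped ", length(skipped),
            " gene(s) with degenerate expression: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  list(gof = gof, lof = lof, variant_scores = variants, skipped = skipped)
}
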
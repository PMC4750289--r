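#' Classify genes as GoF (oncogene-like) or LoF (tumor-suppressor-like)
#'
#' Restricts to genes mutated in strictly more than \code{min_mut_fraction} of
#' the cohort's samples.  Among a gene's mutated samples, the GoF gene score
#' is the fraction with \code{gof > |lof|} and the LoF gene score the fraction
#' with \code{|lof| > gof} (strict comparisons; exact ties count toward
#' neither).  A gene is labeled \code{GoF} or \code{LoF} when the
#' corresponding fraction exceeds 0.5, else \code{unclassified}.
#'
#' @param gof,lof Gene-by-sample activity matrices from [score_cohort()].
#' @param variants Variant table for the same cohort (defines which samples
#'   count as mutated: those carrying at least one non-silent variant of the
#'   gene).
#' @param n_samples Total cohort size, the denominator of the mutation
#'   frequency filter.
#' @param min_mut_fraction Frequency filter threshold (strict; default 0.01).
#' @param quiet Suppress the filter log message.
#' @return A data.frame with columns \code{gene}, \code{status},
#'   \code{gof_gene_score}, \code{lof_gene_score}, \code{n_mutated_samples},
#'   one row per gene passing the frequency filter.
#' @export
classify_genes <- function(gof, lof, variants, n_samples,
                           min_mut_fraction = 0.01, quiet = FALSE) {
  stopifnot(is.matrix(gof), is.matrix(lof),
            identical(dimnames(gof), dimnames(lof)),
            is.numeric(n_samples), n_samples >= 1)
  real <- variants[variants$class != "No_Mutation", , drop = FALSE]
  mut_by_gene <- lapply(split(real$sample, real$gene), unique)
  n_mut <- lengths(mut_by_gene)
  keep <- names(n_mut)[n_mut / n_samples > min_mut_fraction]
  keep <- intersect(rownames(gof), keep)
  if (!quiet)
    message(sprintf(
      "classify_genes: %d of %d mutated genes pass the > %g%% frequency filter",
      length(keep), length(n_mut), 100 * min_mut_fraction))
  out <- data.frame(gene = keep,
                    status = rep("unclassified", length(keep)),
                    gof_gene_score = rep(NA_real_, length(keep)),
                    lof_gene_score = rep(NA_real_, length(keep)),
                    n_mutated_samples = unname(n_mut[keep]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(keep)) {
    g <- keep[i]
    s <- intersect(mut_by_gene[[g]], colnames(gof))
    gv <- gof[g, s]; lv <- abs(lof[g, s])
    ok <- !is.na(gv) & !is.na(lv)
    gv <- gv[ok]; lv <- lv[ok]
    if (length(gv) == 0L) next
    out$gof_gene_score[i] <- mean(gv > lv)
    out$lof_gene_score[i] <- mean(lv > gv)
    if (out$gof_gene_score[i] > 0.5) out$status[i] <- "GoF"
    else if (out$lof_gene_score[i] > 0.5) out$status[i] <- "LoF"
  }
  rownames(out) <- NULL
  out
}
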
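#' Mutation classes and their integer codes
#'
#' Eight somatic variant classes are modeled, plus \code{No_Mutation} (code 0)
#' for wild-type gene/sample pairs.  Silent and unrecognized variant
#' classifications are mapped to \code{No_Mutation} upstream by
#' [read_mutations()] / [normalize_variant_class()].
#'
#' @format Named integer vector of codes.
#' @export
mutation_codes <- c(
  No_Mutation       = 0L,
  Missense_Mutation = 1L,
  In_Frame_Ins      = 2L,
  In_Frame_Del      = 3L,
  Nonsense_Mutation = 4L,
  Nonstop_Mutation  = 5L,
  Frame_Shift_Ins   = 6L,
  Frame_Shift_Del   = 7L,
  Splice_Site       = 8L
)

activating_classes <- c("Missense_Mutation", "In_Frame_Ins", "In_Frame_Del")

#' Map raw variant classifications onto the modeled classes
#'
#' Silent variants carry no protein change and anything outside the eight
#' modeled classes (e.g. \code{3'UTR}, \code{Intron}) is not interpretable by
#' the rules, so both are treated as \code{No_Mutation}.
#'
#' @param x Character vector of MAF-style \code{Variant_Classification}
#'   values.
#' @return Character vector of modeled class names.
#' @export
normalize_variant_class <- function(x) {
  ifelse(x %in% names(mutation_codes), x, "No_Mutation")
}

#' The categorical mutation and recurrence variables
#'
#' Integer-coded categorical variables with singleton membership functions:
#' \code{Mutation} has the eight variant classes plus \code{No_Mutation};
#' \code{Recurrence} has \code{non_recurrent} (0) and \code{recurrent} (1).
#'
#' @return An \code{oncofuzz_variable}.
#' @export
mutation_variable <- function() {
  cats <- lapply(mutation_codes, function(code) mf_singleton(code))
  linguistic_variable("Mutation", c(-0.5, 8.5), cats)
}

#' @rdname mutation_variable
#' @export
recurrence_variable <- function() {
  linguistic_variable("Recurrence", c(-0.5, 1.5),
                      list(non_recurrent = mf_singleton(0),
                           recurrent = mf_singleton(1)))
}

#' Fit expression membership functions from tertiles
#'
#' Splits one gene's expression values into three equal-rank groups (tertiles)
#' and summarizes each by mean and standard deviation.  The \code{medium}
#' category is a Gaussian at the middle tertile's mean/sd; \code{low} and
#' \code{high} are decreasing/increasing sigmoids with inflection at the outer
#' tertile means and slope [slope_from_std()] of the group's own sd.
#'
#' Tertile grouping is by rank with ties broken by input order; group sizes
#' differ by at most one, extra members going to the lower groups first.
#' Group standard deviations are floored at \code{1e-3} of the observed range
#' so that degenerate groups still yield valid (steep) shapes.
#'
#' @param values Numeric vector of one gene's expression across samples; at
#'   least 6 finite values with at least 3 distinct values.
#' @param name Variable name, default \code{"Expression"} to slot into the
#'   default rule base.
#' @return An \code{oncofuzz_variable} with categories \code{low},
#'   \code{medium}, \code{high}; tertile statistics are attached as attribute
#'   \code{"fit"} (means \code{m}, sds \code{s}).
#' @export
fit_expression_memberships <- function(values, name = "Expression") {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 6L) stop("need at least 6 finite expression values", call. = FALSE)
  if (length(unique(values)) < 3L)
    stop("degenerate expression vector: fewer than 3 distinct values",
         call. = FALSE)
  ord <- order(values)                      # stable: ties keep input order
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep(1:3, times = sizes)
  m <- vapply(1:3, function(g) mean(values[ord[grp == g]]), numeric(1))
  s <- vapply(1:3, function(g) stats::sd(values[ord[grp == g]]), numeric(1))
  floor_s <- 1e-3 * diff(range(values))
  s[!is.finite(s) | s < floor_s] <- floor_s
  dom <- c(min(values) - 3 * s[2], max(values) + 3 * s[2])
  var <- linguistic_variable(name, dom, list(
    low = mf_sigmoid_decreasing(m[1], slope_from_std(s[1])),
    medium = mf_gaussian(m[2], s[2]),
    high = mf_sigmoid_increasing(m[3], slope_from_std(s[3]))
  ))
  attr(var, "fit") <- list(m = m, s = s)
  var
}

#' The fixed copy-number variable
#'
#' On the log2 copy-ratio scale every gene shares the same three categories:
#' \code{deleted} (trapezoid, plateau 1 below -0.6, falling to 0 at -0.2),
#' \code{neutral} (triangle peaking at 0 with feet at -0.4/0.4) and
#' \code{amplified} (trapezoid rising from 0 at 0.2 to plateau 1 above 0.6).
#' The +/-0.2 and +/-0.6 breakpoints are the conventional SNP-array gain/loss
#' cutoffs and can be overridden.
#'
#' @param breaks Numeric length-2 vector: inner and outer breakpoint
#'   magnitudes, default \code{c(0.2, 0.6)}.
#' @param domain Variable domain on the log2 ratio scale.
#' @return An \code{oncofuzz_variable} with categories \code{deleted},
#'   \code{neutral}, \code{amplified}.
#' @export
default_cn_variable <- function(breaks = c(0.2, 0.6), domain = c(-5, 5)) {
  stopifnot(is.numeric(breaks), length(breaks) == 2L,
            0 < breaks[1], breaks[1] < breaks[2])
  b1 <- breaks[1]; b2 <- breaks[2]
  linguistic_variable("CN", domain, list(
    deleted = mf_trapezoid(domain[1], domain[1], -b2, -b1),
    neutral = mf_triangle(-2 * b1, 0, 2 * b1),
    amplified = mf_trapezoid(b1, b2, domain[2], domain[2])
  ))
}

#' Recurrence-calling configuration
#'
#' @param threshold_fraction A variant position is recurrent when strictly
#'   more than this fraction of all cohort samples carry a variant at the same
#'   position (default 0.01, i.e. more than 1\%).
#' @param position_mode Preferred coordinate for "same position":
#'   \code{"protein"} (amino-acid position, falling back to genomic
#'   coordinates when absent) or \code{"genomic"}.
#' @return A list of class \code{oncofuzz_recurrence_config}.
#' @export
recurrence_config <- function(threshold_fraction = 0.01,
                              position_mode = c("protein", "genomic")) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      !is.finite(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must be in (0, 1)", call. = FALSE)
  structure(list(threshold_fraction = threshold_fraction,
                 position_mode = match.arg(position_mode)),
            class = "oncofuzz_recurrence_config")
}

variant_position_key <- function(variants, cfg) {
  prot <- as.character(variants$protein_position)
  genom <- ifelse(!is.na(variants$contig) & !is.na(variants$genomic_position),
                  paste0(variants$contig, ":", variants$genomic_position),
                  NA_character_)
  if (cfg$position_mode == "protein") ifelse(!is.na(prot) & nzchar(prot),
                                             paste0("p", prot), genom)
  else ifelse(!is.na(genom), genom, paste0("p", prot))
}

#' Flag recurrent (hotspot) variants
#'
#' For every (gene, position) pair, counts the distinct samples carrying any
#' variant at that position; the position is recurrent when the count exceeds
#' \code{cfg$threshold_fraction} of the full cohort size (strictly).
#' \code{No_Mutation} records and variants without a resolvable position are
#' never recurrent; the latter raise a warning.
#'
#' @param variants A variant table as returned by [read_mutations()] (columns
#'   \code{sample}, \code{gene}, \code{class}, \code{protein_position},
#'   \code{contig}, \code{genomic_position}).
#' @param n_samples Total number of samples in the cohort (the denominator;
#'   not just the mutated ones).
#' @param cfg A [recurrence_config()].
#' @return Logical vector, one flag per variant row.
#' @export
compute_recurrence <- function(variants, n_samples, cfg = recurrence_config()) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1)
  if (nrow(variants) == 0L) return(logical(0))
  real <- variants$class != "No_Mutation"
  key <- variant_position_key(variants, cfg)
  if (any(real & is.na(key))) {
    warning(sum(real & is.na(key)),
            " variant(s) without a resolvable position flagged non-recurrent")
  }
  flag <- logical(nrow(variants))
  idx <- which(real & !is.na(key))
  if (length(idx)) {
    gk <- paste0(variants$gene[idx], "\r", key[idx])
    counts <- tapply(variants$sample[idx], gk,
                     function(s) length(unique(s)))
    flag[idx] <- counts[gk] / n_samples > cfg$threshold_fraction
  }
  flag
}
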
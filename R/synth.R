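#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a cancer cell-line panel with
#' matched mutation, expression and copy-number data: per-gene Gaussian
#' background expression on a log2 microarray-like scale, log2 copy-ratio
#' noise around 0, categorical somatic variant classes with hotspot
#' recurrence, and planted driver genes.
#'
#' Planted roles and their defaults:
#' \describe{
#'   \item{oncogene}{a shared missense hotspot mutated in \code{p_mut} of
#'     samples; mutant samples have expression raised by \code{delta_expr}
#'     within-gene standard deviations and copy number raised by
#'     \code{delta_cn} log2 units.}
#'   \item{tsg}{truncating variants (nonsense, frame-shift, splice-site) at
#'     scattered positions; mutant samples have expression and copy number
#'     lowered by the same shifts.}
#'   \item{special_tsg}{a TP53-like gene: a recurrent missense hotspot whose
#'     mutants nevertheless lose function (scored through the mirrored rules);
#'     mutant expression is raised, as mutant protein often accumulates.}
#'   \item{neutral}{sparse non-recurrent passenger variants
#'     (\code{p_passenger} per sample), no expression/copy-number coupling.}
#' }
#'
#' @param n_samples Cohort size (>= 30 so tertile fitting is stable).
#' @param n_genes Total genes including the planted drivers.
#' @param n_oncogenes,n_tsgs,n_special Number of planted genes per role.
#' @param p_mut Hotspot/driver mutation fraction per driver gene.
#' @param p_passenger Per-sample passenger probability for neutral genes.
#' @param delta_expr Expression shift in mutants, in within-gene sd units.
#' @param delta_cn Copy-number shift in mutants, log2 units.
#' @param expr_mean_range,expr_sd_range Ranges the per-gene background
#'   expression mean/sd are drawn from (log2 intensity scale).
#' @param cn_sd Standard deviation of background log2 copy-ratio noise.
#' @param beta Drug-response coupling strength: \code{ActArea = beta *
#'   activity + noise}, where activity is 0 for samples without a mutation in
#'   the first planted oncogene and, for mutants, grades with how far the
#'   sample's expression sits above the gene's background.
#' @param response_sd Noise sd of the simulated response.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class \code{oncofuzz_synth_config}.
#' @export
synth_config <- function(n_samples = 300L, n_genes = 50L,
                         n_oncogenes = 5L, n_tsgs = 5L, n_special = 1L,
                         p_mut = 0.2, p_passenger = 0.01,
                         delta_expr = 1.5, delta_cn = 0.8,
                         expr_mean_range = c(5, 11),
                         expr_sd_range = c(0.6, 1.4),
                         cn_sd = 0.15, beta = 3, response_sd = 0.5,
                         seed = 1L) {
  if (n_samples < 30L)
    stop("'n_samples' must be >= 30 for stable tertile fitting", call. = FALSE)
  if (n_oncogenes + n_tsgs + n_special > n_genes)
    stop("more planted drivers than genes", call. = FALSE)
  if (p_mut < 0 || p_mut >= 1 || p_passenger < 0 || p_passenger >= 1)
    stop("mutation fractions must lie in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "oncofuzz_synth_config")
}

#' Generate a synthetic multi-omics cohort with planted drivers
#'
#' @param cfg A [synth_config()].
#' @return A list with \code{cohort} (an [omics_cohort()]), \code{truth}
#'   (data.frame gene/role), and \code{response} (long-format drug response
#'   with an \code{ActArea} metric coupled to the first planted oncogene).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "oncofuzz_synth_config"))
  with_preserved_seed(cfg$seed, {
    samples <- sprintf("S%03d", seq_len(cfg$n_samples))
    genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
    roles <- rep("neutral", cfg$n_genes)
    if (cfg$n_oncogenes > 0) roles[seq_len(cfg$n_oncogenes)] <- "oncogene"
    if (cfg$n_tsgs > 0)
      roles[cfg$n_oncogenes + seq_len(cfg$n_tsgs)] <- "tsg"
    if (cfg$n_special > 0) {
      idx <- cfg$n_oncogenes + cfg$n_tsgs + seq_len(cfg$n_special)
      roles[idx] <- "special_tsg"
      genes[idx] <- if (cfg$n_special == 1L) "TP53"
        else sprintf("TP53L%02d", seq_len(cfg$n_special))
    }

    expr_mean <- stats::runif(cfg$n_genes, cfg$expr_mean_range[1],
                              cfg$expr_mean_range[2])
    expr_sd <- stats::runif(cfg$n_genes, cfg$expr_sd_range[1],
                            cfg$expr_sd_range[2])
    expression <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples,
                                      mean = expr_mean, sd = expr_sd),
                         cfg$n_genes, cfg$n_samples,
                         dimnames = list(genes, samples))
    copy_number <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0,
                                       cfg$cn_sd),
                          cfg$n_genes, cfg$n_samples,
                          dimnames = list(genes, samples))

    trunc_classes <- c("Nonsense_Mutation", "Frame_Shift_Ins",
                       "Frame_Shift_Del", "Splice_Site")
    vs <- list()
    add <- function(sample, gene, class, pos)
      vs[[length(vs) + 1L]] <<- data.frame(
        sample = sample, gene = gene, class = class,
        protein_position = as.integer(pos), contig = NA_character_,
        genomic_position = NA_real_, stringsAsFactors = FALSE)

    for (i in seq_len(cfg$n_genes)) {
      g <- genes[i]
      if (roles[i] %in% c("oncogene", "special_tsg")) {
        hot <- 100L + i                     # one shared hotspot per gene
        mut <- samples[stats::runif(cfg$n_samples) < cfg$p_mut]
        for (s in mut) add(s, g, "Missense_Mutation", hot)
        expression[i, mut] <- expression[i, mut] + cfg$delta_expr * expr_sd[i]
        if (roles[i] == "oncogene")
          copy_number[i, mut] <- copy_number[i, mut] + cfg$delta_cn
      } else if (roles[i] == "tsg") {
        mut <- samples[stats::runif(cfg$n_samples) < cfg$p_mut]
        for (s in mut)
          add(s, g, sample(trunc_classes, 1L),
              sample.int(1000L, 1L))          # scattered, mostly unique
        expression[i, mut] <- expression[i, mut] - cfg$delta_expr * expr_sd[i]
        copy_number[i, mut] <- copy_number[i, mut] - cfg$delta_cn
      } else if (cfg$p_passenger > 0) {
        mut <- samples[stats::runif(cfg$n_samples) < cfg$p_passenger]
        for (s in mut)
          add(s, g, sample(c("Missense_Mutation", trunc_classes), 1L),
              sample.int(1000L, 1L))
      }
    }
    variants <- if (length(vs)) do.call(rbind, vs)
      else data.frame(sample = character(0), gene = character(0),
                      class = character(0), protein_position = integer(0),
                      contig = character(0), genomic_position = numeric(0),
                      stringsAsFactors = FALSE)

    # response couples to the first oncogene's graded activity: mutants
    # respond in proportion to how far their (shifted) expression sits above
    # the gene's background, so activity scores carry signal beyond the
    # binary mutation status
    driver <- genes[1L]
    driver_mut <- samples %in% variants$sample[variants$gene == driver]
    activity <- as.numeric(driver_mut) *
      stats::pnorm((expression[1L, ] - expr_mean[1L]) / expr_sd[1L])
    act_area <- cfg$beta * activity +
      stats::rnorm(cfg$n_samples, 0, cfg$response_sd)
    response <- data.frame(sample = samples, metric = "ActArea",
                           value = act_area, stringsAsFactors = FALSE)

    list(cohort = omics_cohort(expression, copy_number, variants),
         truth = data.frame(gene = genes, role = roles,
                            expr_mean = expr_mean, expr_sd = expr_sd,
                            stringsAsFactors = FALSE),
         response = response)
  })
}

#' Write a synthetic cohort to disk in the formats the readers consume
#'
#' @param sim Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    copy_number = file.path(dir, "copy_number.tsv"),
    mutations = file.path(dir, "mutations.maf.tsv"),
    truth = file.path(dir, "truth.tsv"),
    response = file.path(dir, "drug_response.tsv")
  )
  write_matrix(sim$cohort$expression, paths[["expression"]])
  write_matrix(sim$cohort$copy_number, paths[["copy_number"]])
  write_mutations(sim$cohort$variants, paths[["mutations"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$response, paths[["response"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
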
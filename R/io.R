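#' Read a MAF-like somatic mutation table
#'
#' Expects a tab-delimited file with required columns
#' \code{Tumor_Sample_Barcode}, \code{Hugo_Symbol},
#' \code{Variant_Classification} and at least one of \code{Protein_Change} or
#' \code{Start_position} (optionally with \code{Chromosome}); extra columns
#' are ignored.  Rows are deduplicated on (sample, gene, class, position) and
#' Silent/unmodeled classifications are mapped to \code{No_Mutation}.
#'
#' @param path Path to the TSV file.
#' @param quiet Suppress the row-count log messages.
#' @return A data.frame with columns \code{sample}, \code{gene}, \code{class},
#'   \code{protein_position}, \code{contig}, \code{genomic_position}.
#' @export
read_mutations <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("mutation file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("mutation file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!any(c("Protein_Change", "Start_position") %in% names(raw)))
    stop("mutation file lacks required column(s): ",
         "Protein_Change or Start_position", call. = FALSE)
  n_read <- nrow(raw)
  cls <- normalize_variant_class(raw$Variant_Classification)
  n_silent <- sum(cls == "No_Mutation" &
                    raw$Variant_Classification != "No_Mutation")
  prot <- if ("Protein_Change" %in% names(raw))
    parse_protein_position(raw$Protein_Change) else rep(NA_integer_, n_read)
  contig <- if ("Chromosome" %in% names(raw))
    as.character(raw$Chromosome) else rep(NA_character_, n_read)
  genom <- if ("Start_position" %in% names(raw))
    suppressWarnings(as.numeric(raw$Start_position)) else rep(NA_real_, n_read)
  variants <- data.frame(
    sample = as.character(raw$Tumor_Sample_Barcode),
    gene = as.character(raw$Hugo_Symbol),
    class = cls,
    protein_position = prot,
    contig = contig,
    genomic_position = genom,
    stringsAsFactors = FALSE
  )
  key <- paste(variants$sample, variants$gene, variants$class,
               variants$protein_position, variants$contig,
               variants$genomic_position, sep = "\r")
  variants <- variants[!duplicated(key), , drop = FALSE]
  rownames(variants) <- NULL
  if (!quiet)
    message(sprintf(
      "read_mutations: %d rows read, %d kept after deduplication, %d silent/unmodeled mapped to No_Mutation",
      n_read, nrow(variants), n_silent))
  variants
}

# "p.V600E" / "p.K601del" / "p.*757L" -> first integer in the string
parse_protein_position <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+", x))
  out <- rep(NA_integer_, length(x))
  out[regexpr("[0-9]+", x) > 0] <- as.integer(m)
  out
}

#' Read a genes-x-samples numeric matrix
#'
#' Tab-delimited: first column gene identifiers, header row of sample
#' identifiers, numeric body (scientific notation allowed).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("matrix file needs a gene column plus at least one sample: ", path,
         call. = FALSE)
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "nan", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell in %s at gene '%s', sample '%s': '%s'",
                 path, genes[bad[1, 1]], colnames(raw)[-1L][bad[1, 2]],
                 body[bad[1, , drop = FALSE]]), call. = FALSE)
  dimnames(num) <- list(genes, colnames(raw)[-1L])
  num
}

#' Write a genes-x-samples matrix as TSV
#'
#' Values are written in 6-decimal fixed point, the precision at which the
#' reader/writer pair round-trips.
#'
#' @param mat Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @param digits Decimal places.
#' @export
write_matrix <- function(mat, path, digits = 6L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- formatC(mat, format = "f", digits = digits)
  body[is.na(mat)] <- "NA"
  lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], body[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant table in MAF-like TSV form
#'
#' @param variants Variant data.frame as produced by [read_mutations()] or
#'   [generate_cohort()].
#' @param path Output path.
#' @export
write_mutations <- function(variants, path) {
  out <- data.frame(
    Tumor_Sample_Barcode = variants$sample,
    Hugo_Symbol = variants$gene,
    Variant_Classification = variants$class,
    Protein_Change = ifelse(is.na(variants$protein_position), "",
                            paste0("p.X", variants$protein_position, "X")),
    Chromosome = ifelse(is.na(variants$contig), "", variants$contig),
    Start_position = ifelse(is.na(variants$genomic_position), "",
                            format(variants$genomic_position,
                                   scientific = FALSE, trim = TRUE)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format drug response table
#'
#' Tab-delimited with columns \code{sample}, \code{metric}, \code{value};
#' one value per sample per metric.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with those three columns.
#' @export
read_drug_response <- function(path) {
  if (!file.exists(path)) stop("drug response file not found: ", path,
                               call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("sample", "metric", "value")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("drug response file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d[, c("sample", "metric")]))
    stop("duplicate (sample, metric) pair in ", path, call. = FALSE)
  d$value <- as.numeric(d$value)
  d[, need]
}

#' Compound sensitivity threshold table
#'
#' Returns the shipped compound configuration: for each compound its direct
#' target, the sensitivity-predictor gene(s), and fixed sensitive/resistant
#' thresholds on a named response metric.  Multi-row compounds (e.g. a
#' combined Amax + EC50 definition) require all their rows' sensitive
#' conditions for a sensitive call, and all resistant conditions for a
#' resistant call.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return A data.frame with columns \code{compound}, \code{target},
#'   \code{predictors}, \code{metric}, \code{sensitive_cmp},
#'   \code{sensitive_value}, \code{resistant_cmp}, \code{resistant_value}.
#' @export
compound_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compound_thresholds.tsv",
                        package = "oncofuzz", mustWork = TRUE)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("compound", "target", "predictors", "metric", "sensitive_cmp",
            "sensitive_value", "resistant_cmp", "resistant_value")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("compound config lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(d$sensitive_cmp %in% c("<=", ">=", "<", ">")) ||
      !all(d$resistant_cmp %in% c("<=", ">=", "<", ">")))
    stop("comparison operators must be one of <=, >=, <, >", call. = FALSE)
  d
}
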
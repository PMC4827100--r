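#' Filter an annotated rare-variant table by mode of inheritance
#'
#' Retains protein-altering variants that are absent from the reference
#' population (missing allele frequency) or rarer than the mode-specific
#' threshold: below 1/1,000 for recessive and below 1/10,000 for dominant
#' and high-impact dominant analyses (strict inequalities). The high-impact
#' dominant mode additionally restricts the consequence class to splice
#' aberration, frameshift, start loss or stop gain.
#'
#' @param variants A data.frame with columns `subject_id`, `gene`,
#'   `allele_count` (1 or 2), `population_af` (in `[0, 1]`, `NA` = absent
#'   from the reference) and `consequence_class` (one of
#'   `"protein_altering"`, `"splice_aberration"`, `"frameshift"`,
#'   `"start_loss"`, `"stop_gain"`, `"other"`).
#' @param mode `"dominant"`, `"recessive"` or `"high_impact_dominant"`.
#' @return The filtered data.frame.
#' @export
filter_variants <- function(variants,
                            mode = c("dominant", "recessive",
                                     "high_impact_dominant")) {
  mode <- match.arg(mode)
  req <- c("subject_id", "gene", "allele_count", "population_af",
           "consequence_class")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  af <- variants$population_af
  if (any(af < 0, na.rm = TRUE)) stop("negative population allele frequency")
  if (!all(variants$allele_count %in% 1:2))
    stop("allele_count must be 1 or 2")
  high_impact <- c("splice_aberration", "frameshift", "start_loss",
                   "stop_gain")
  protein_altering <- c("protein_altering", high_impact)
  keep <- variants$consequence_class %in%
    (if (mode == "high_impact_dominant") high_impact else protein_altering)
  thresh <- if (mode == "recessive") 1 / 1000 else 1 / 10000
  keep <- keep & (is.na(af) | af < thresh)
  variants[keep, , drop = FALSE]
}

#' Encode binary genotypes from filtered variants
#'
#' Aggregates rare alleles within a gene: under dominant and high-impact
#' dominant inheritance a subject carries the rare genotype with at least
#' one rare allele; under recessive inheritance with at least two (two
#' heterozygous variants or one homozygous; phase is not considered).
#' Subjects without qualifying variants get 0.
#'
#' @param variants A filtered variant table (see [filter_variants()]).
#' @param subjects Character vector of unique subject IDs defining the
#'   output order.
#' @param gene Gene to encode.
#' @param mode Mode of inheritance (see [filter_variants()]).
#' @return Named integer vector of 0/1 genotypes aligned with `subjects`.
#' @export
encode_genotypes <- function(variants, subjects, gene,
                             mode = c("dominant", "recessive",
                                      "high_impact_dominant")) {
  mode <- match.arg(mode)
  if (anyDuplicated(subjects)) stop("subject IDs must be unique")
  v <- variants[variants$gene == gene, , drop = FALSE]
  unknown <- setdiff(unique(v$subject_id), subjects)
  if (length(unknown)) {
    warning(length(unknown), " variant record subject(s) not in the subject",
            " list; skipped: ", paste(utils::head(unknown, 5), collapse = ", "))
    v <- v[v$subject_id %in% subjects, , drop = FALSE]
  }
  counts <- structure(integer(length(subjects)), names = subjects)
  if (nrow(v)) {
    agg <- tapply(v$allele_count, v$subject_id, sum)
    counts[names(agg)] <- as.integer(agg)
  }
  need <- if (mode == "recessive") 2L else 1L
  structure(as.integer(counts >= need), names = subjects)
}

#' Plug-in offsets from batch-level rare-genotype rates
#'
#' Estimates per-subject log-odds offsets to absorb batch effects (e.g.
#' sequencing platform) on the background rate of rare genotypes: each
#' subject receives the logit of their batch's mean rare-genotype rate
#' across genes and batch members, centred to mean zero across subjects.
#'
#' @param y_matrix Binary matrix, subjects by genes (at least 2 genes),
#'   with rownames giving subject IDs.
#' @param batch Named vector mapping subject IDs to batch labels.
#' @return Named numeric offset vector aligned with the rows of `y_matrix`.
#' @export
estimate_offsets <- function(y_matrix, batch) {
  if (is.null(rownames(y_matrix))) stop("'y_matrix' needs subject rownames")
  if (ncol(y_matrix) < 2) stop("at least 2 genes are required")
  subjects <- rownames(y_matrix)
  batch <- batch[subjects]
  if (any(is.na(batch))) stop("every subject needs a batch label")
  if (length(unique(batch)) == 1L)
    return(structure(numeric(length(subjects)), names = subjects))
  rate <- tapply(rowMeans(y_matrix), batch, mean)
  rate <- pmin(pmax(rate, 1e-6), 1 - 1e-6)
  h <- stats::qlogis(rate[as.character(batch)])
  h <- h - mean(h)
  structure(as.numeric(h), names = subjects)
}

#' Read variants from a VCF file (thin optional reader)
#'
#' Converts a biallelic VCF into the annotated variant table consumed by
#' [filter_variants()]: genotype calls become per-subject allele counts and
#' the gene, population allele frequency and consequence class are taken
#' from INFO keys named by the caller. Annotation (consequence prediction,
#' reference-population frequencies) is an upstream concern; this reader
#' only reshapes. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file.
#' @param gene_key,af_key,csq_key INFO keys holding the gene symbol, the
#'   population allele frequency (absent key = missing) and the consequence
#'   class (values as in [filter_variants()]).
#' @return A data.frame with columns `subject_id`, `gene`, `allele_count`,
#'   `population_af`, `consequence_class`.
#' @export
read_vcf_variants <- function(path, gene_key = "GENE", af_key = "AF",
                              csq_key = "CSQ") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the optional VCF reader requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  info_field <- function(key) vcfR::extract.info(v, element = key)
  gene <- info_field(gene_key)
  af <- suppressWarnings(as.numeric(info_field(af_key)))
  csq <- info_field(csq_key)
  if (all(is.na(gene))) stop("INFO key '", gene_key, "' not found")
  out <- list()
  for (j in seq_len(ncol(gt))) {
    ac <- vapply(gt[, j], function(g) {
      if (is.na(g)) return(0L)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }, 0L)
    keep <- ac > 0L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      subject_id = colnames(gt)[[j]],
      gene = as.character(gene[keep]),
      allele_count = pmin(as.integer(ac[keep]), 2L),
      population_af = af[keep],
      consequence_class = as.character(csq[keep]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(subject_id = character(0), gene = character(0),
                      allele_count = integer(0), population_af = numeric(0),
                      consequence_class = character(0)))
  do.call(rbind, out)
}
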
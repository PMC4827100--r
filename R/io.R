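#' Read subject phenotypes from a TSV file
#'
#' Expects a tab-separated file with header columns `subject_id` and
#' `term_id`, one row per subject-term annotation. Terms are resolved
#' through alternative IDs; terms absent from the ontology are dropped with
#' a single summary warning; each subject's terms are reduced to a minimal
#' set. Subjects whose terms are all unknown are retained with an empty
#' phenotype.
#'
#' @param path Path to the TSV file.
#' @param ontology A `"phe_ontology"` object.
#' @return Named list of minimal sets (character vectors), one per subject,
#'   in first-appearance order.
#' @export
read_phenotypes <- function(path, ontology) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("subject_id", "term_id") %in% names(tab)))
    stop("phenotype file needs columns subject_id and term_id: ", path)
  bad <- which(!nzchar(tab$subject_id) | !nzchar(tab$term_id))
  if (length(bad))
    stop("malformed phenotype row at line ", bad[[1L]] + 1L, " of ", path)
  subjects <- unique(tab$subject_id)
  n_dropped <- 0L
  out <- lapply(subjects, function(s) {
    terms <- resolve_terms(ontology, tab$term_id[tab$subject_id == s],
                           drop = TRUE)
    n_dropped <<- n_dropped + (attr(terms, "n_dropped") %||% 0L)
    minimal_set(ontology, terms)
  })
  names(out) <- subjects
  if (n_dropped > 0L)
    warning(n_dropped, " annotation(s) used terms absent from the ontology",
            " and were dropped")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read binary genotypes from a TSV file
#'
#' Expects columns `subject_id` and `y` (0/1).
#'
#' @param path Path to the TSV file.
#' @return Named integer vector of genotypes.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("subject_id", "y") %in% names(tab)))
    stop("genotype file needs columns subject_id and y: ", path)
  structure(as.integer(tab$y), names = as.character(tab$subject_id))
}

#' Read an annotated variant table from a TSV file
#'
#' Expects columns `subject_id`, `gene`, `allele_count`, `population_af`
#' (empty = absent from the reference population) and `consequence_class`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame suitable for [filter_variants()].
#' @export
read_variants <- function(path) {
  tab <- utils::read.delim(path, na.strings = c("NA", ""))
  req <- c("subject_id", "gene", "allele_count", "population_af",
           "consequence_class")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("variant file lacks columns: ",
                         paste(miss, collapse = ", "), ": ", path)
  tab$subject_id <- as.character(tab$subject_id)
  tab$gene <- as.character(tab$gene)
  tab$allele_count <- as.integer(tab$allele_count)
  tab$population_af <- as.numeric(tab$population_af)
  tab$consequence_class <- as.character(tab$consequence_class)
  tab
}

#' Write a fit to disk
#'
#' Writes three files into a directory: `summary.json` (probability of
#' association, configuration echo, seed, package version),
#' `marginal_inclusion.tsv` (terms sorted by decreasing inclusion
#' probability) and `pairwise_inclusion.tsv` (square symmetric matrix).
#' All numeric content round-trips losslessly through [read_fit()].
#'
#' @param fit A `"phenoreg"` fit.
#' @param dir Output directory (created if needed).
#' @param traces Also write the parameter traces as `traces.tsv`. Default
#'   `FALSE`.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, traces = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smry <- list(
    mean_gamma = fit$mean_gamma,
    mean_gamma_se = fit$diagnostics$mean_gamma_se,
    n_subjects = fit$n, n_rare = sum(fit$y),
    seed = fit$seed,
    prior = fit$prior[c("pi", "alpha_mean", "alpha_sd", "log_beta_mean",
                        "log_beta_sd", "k", "lit_rate")],
    control = fit$control[c("n_iter", "n_burnin", "thin", "pilot_iter",
                            "pseudo_mix_weight")],
    package_version = as.character(utils::packageVersion("phenoreg")))
  jsonlite::write_json(smry, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  mi <- data.frame(term = names(fit$marginal_inclusion),
                   probability = as.numeric(fit$marginal_inclusion))
  utils::write.table(mi, file.path(dir, "marginal_inclusion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pw <- fit$pairwise_inclusion
  utils::write.table(
    data.frame(term = rownames(pw), pw, check.names = FALSE),
    file.path(dir, "pairwise_inclusion.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (traces)
    utils::write.table(fit$traces, file.path(dir, "traces.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fit summary written by [write_fit()]
#'
#' @param dir Directory written by [write_fit()].
#' @return List with elements `summary` (parsed JSON),
#'   `marginal_inclusion` (named numeric vector) and `pairwise_inclusion`
#'   (numeric matrix).
#' @export
read_fit <- function(dir) {
  smry <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  mi <- utils::read.delim(file.path(dir, "marginal_inclusion.tsv"))
  marg <- structure(as.numeric(mi$probability), names = as.character(mi$term))
  pw <- utils::read.delim(file.path(dir, "pairwise_inclusion.tsv"),
                          check.names = FALSE)
  terms <- as.character(pw$term)
  pw <- as.matrix(pw[, -1, drop = FALSE])
  rownames(pw) <- terms
  list(summary = smry, marginal_inclusion = marg, pairwise_inclusion = pw)
}
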
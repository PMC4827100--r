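#' Assemble a cohort of subjects
#'
#' Bundles aligned subject IDs, minimal-set phenotypes, binary genotypes and
#' per-subject log-odds offsets.
#'
#' @param subjects Character vector of unique subject IDs.
#' @param phenotypes List of character vectors of ontology term IDs, one per
#'   subject (reduced to minimal sets when an ontology is supplied to the
#'   fitting function). Empty phenotypes are allowed.
#' @param y Binary genotype vector: 1 = rare genotype, 0 = common.
#' @param offsets Per-subject offsets on the log-odds scale (recycled;
#'   default 0).
#' @return Object of class `"phe_cohort"`.
#' @export
cohort <- function(subjects, phenotypes, y, offsets = 0) {
  n <- length(subjects)
  if (n < 1L) stop("a cohort needs at least one subject")
  if (anyDuplicated(subjects)) stop("subject IDs must be unique")
  if (length(phenotypes) != n || length(y) != n)
    stop("subjects, phenotypes and y must have the same length")
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% 0:1)) stop("y must be binary 0/1")
  offsets <- rep_len(as.numeric(offsets), n)
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  structure(list(subjects = as.character(subjects),
                 phenotypes = phenotypes, y = y, offsets = offsets),
            class = "phe_cohort")
}

#' @export
print.phe_cohort <- function(x, ...) {
  cat("Cohort: ", length(x$subjects), " subjects, ",
      sum(x$y), " with the rare genotype\n", sep = "")
  cat("  median phenotype size: ",
      stats::median(lengths(x$phenotypes)),
      "; offsets ", if (all(x$offsets == 0)) "all zero" else "supplied",
      "\n", sep = "")
  invisible(x)
}

#' Prior configuration
#'
#' Priors for the model indicator and all within-model parameters:
#' `gamma ~ Bernoulli(pi)`, `alpha ~ Normal(alpha_mean, alpha_sd^2)`,
#' `log beta ~ Normal(log_beta_mean, log_beta_sd^2)` (so `beta > 0`:
#' similarity to the characteristic phenotype can only increase the odds of
#' the rare genotype), independent log-normal priors on the four beta-CDF
#' shape parameters, and a prior over characteristic phenotypes that is
#' uniform on all minimal sets of size 1..k, or literature-weighted when a
#' literature phenotype is supplied.
#'
#' @param pi Prior probability of association, `P(gamma = 1)`. Default 0.05.
#' @param alpha_mean,alpha_sd Normal prior on the intercept. Defaults 0, 5.
#' @param log_beta_mean,log_beta_sd Normal prior on `log beta`. Defaults 2, 1.
#' @param k Maximum size of the characteristic phenotype. Default 3: three
#'   terms generally suffice to distinguish the primary features of a rare
#'   disease.
#' @param literature Optional character vector: a literature phenotype `M`
#'   (term set) used to up-weight characteristic phenotypes similar to
#'   previously reported phenotypes for the genomic unit under test.
#' @param lit_rate Rate `c` of the unstandardized literature similarity
#'   `S'(M -> phi) = exp(c * sum_{t in phi} max_{u in M} s(t, u))`; as
#'   `c -> 0` the prior reduces to uniform. Default 1.
#' @param transform_log_mean,transform_log_sd Mean and sd (recycled to
#'   length 4: `a_f`, `b_f`, `a_g`, `b_g`) of the normal priors on the log
#'   shape parameters. The defaults (`a_f` centred at 6, `b_f` at 4,
#'   `a_g` at 0.5, `b_g` at 1, sd 0.6 on the log scale) concentrate `f` on
#'   threshold-like sigmoid shapes: a subject matching most of the
#'   characteristic phenotype gets near-full credit while sub-half matches
#'   get almost none, which penalizes over-specific characteristic terms
#'   and favors parsimonious phenotypes. `g` is kept permissive (concave)
#'   so sporadic extra terms in a subject's coding do not destroy
#'   similarity.
#' @return Object of class `"phe_prior"`.
#' @export
prior_config <- function(pi = 0.05, alpha_mean = 0, alpha_sd = 5,
                         log_beta_mean = 2, log_beta_sd = 1, k = 3,
                         literature = NULL, lit_rate = 1,
                         transform_log_mean = c(log(6), log(4), log(0.5), 0),
                         transform_log_sd = 0.6) {
  if (pi <= 0 || pi >= 1) stop("'pi' must lie strictly between 0 and 1")
  if (alpha_sd <= 0 || log_beta_sd <= 0) stop("prior sds must be positive")
  if (k < 1) stop("'k' must be at least 1")
  structure(list(pi = pi, alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 log_beta_mean = log_beta_mean, log_beta_sd = log_beta_sd,
                 k = as.integer(k), literature = literature,
                 lit_rate = lit_rate,
                 transform_log_mean = rep_len(transform_log_mean, 4L),
                 transform_log_sd = rep_len(transform_log_sd, 4L)),
            class = "phe_prior")
}

#' Log-likelihood of the two-model logistic regression
#'
#' Bernoulli log-likelihood with `logit p_i = alpha + offset_i` under the
#' baseline model and `logit p_i = alpha + offset_i + beta * s_i` under the
#' alternative, where `s_i` is the subject's overall similarity to the
#' characteristic phenotype.
#'
#' @param y Binary genotype vector.
#' @param alpha Intercept.
#' @param beta Optional positive similarity coefficient; `NULL` (or 0) gives
#'   the baseline model.
#' @param s Per-subject similarity vector (required when `beta` is
#'   supplied and nonzero).
#' @param offsets Per-subject offsets (recycled, default 0).
#' @return The log-likelihood (a scalar).
#' @export
model_loglik <- function(y, alpha, beta = NULL, s = NULL, offsets = 0) {
  if (!is.finite(alpha)) stop("'alpha' must be finite")
  eta <- alpha + rep_len(offsets, length(y))
  if (!is.null(beta) && beta != 0) {
    if (!is.finite(beta)) stop("'beta' must be finite")
    if (is.null(s)) stop("'s' is required when beta is supplied")
    eta <- eta + beta * s
  }
  # y*eta - log(1 + e^eta), computed stably
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

# Lin similarity of each usable term to its best match in a term set M
# (unrestricted: used by the literature prior).
literature_scores <- function(ontology, ic, literature, terms) {
  literature <- resolve_terms(ontology, literature)
  bad <- literature[!is.finite(ic[literature])]
  if (length(bad))
    stop("literature terms with non-finite IC: ", paste(bad, collapse = ", "))
  vapply(terms, function(t)
    max(vapply(literature, function(u)
      lin_similarity(ontology, ic, t, u), 1)), 1)
}

# log of the literature-prior normaliser Z = sum_{psi in Phi(k)} S'(M -> psi).
# Exact enumeration when |Phi(k)| is modest, otherwise self-normalised
# importance sampling with proposals induced by uniform k-vectors
# (q(phi) = N(phi)/u^k), which reaches every minimal set of size <= k.
lit_log_normaliser <- function(ontology, ic, prior, terms,
                               enumerate_limit = 2e5, n_is = 2e4) {
  ls <- literature_scores(ontology, ic, prior$literature, terms)
  n_sets <- count_min_sets(ontology, prior$k, terms)
  if (n_sets <= enumerate_limit) {
    sets <- enumerate_min_sets(ontology, prior$k, terms)
    vals <- vapply(sets, function(s) prior$lit_rate * sum(ls[s]), 1)
    m <- max(vals)
    return(m + log(sum(exp(vals - m))))
  }
  u <- length(terms)
  k <- prior$k
  logw <- vapply(seq_len(n_is), function(i) {
    v <- sample(terms, k, replace = TRUE)
    phi <- minimal_set(ontology, v)
    prior$lit_rate * sum(ls[phi]) + k * log(u) -
      log(count_preimage(ontology, phi, k, terms))
  }, 1)
  m <- max(logw)
  m + log(mean(exp(logw - m)))
}

#' Log prior of a characteristic phenotype
#'
#' Uniform case: `-log |Phi(k)|`, where `Phi(k)` is the set of all minimal
#' sets of size 1..k over the usable terms. Literature case:
#' `log S'(M -> phi) - log sum_psi S'(M -> psi)` with the unstandardized
#' similarity `S'(M -> phi) = exp(c sum_{t in phi} max_{u in M} s(t, u))`,
#' which up-weights characteristic phenotypes resembling the literature
#' phenotype and reduces to the uniform prior as `c -> 0`.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param phi Nonempty minimal set of size at most `prior$k` over `terms`.
#' @param prior A `"phe_prior"` object.
#' @param terms Usable-term universe (see [usable_terms()]).
#' @param ic Named IC vector; required for the literature-weighted case.
#' @return Log prior probability of `phi`.
#' @export
log_prior_phi <- function(ontology, phi, prior, terms, ic = NULL) {
  phi <- resolve_terms(ontology, phi)
  if (!length(phi) || length(phi) > prior$k)
    stop("'phi' must have between 1 and k = ", prior$k, " terms")
  if (!setequal(minimal_set(ontology, phi), phi))
    stop("'phi' is not a minimal set")
  if (!all(phi %in% terms))
    stop("'phi' contains terms outside the usable universe")
  if (is.null(prior$literature))
    return(-log(count_min_sets(ontology, prior$k, terms)))
  if (is.null(ic)) stop("'ic' is required for the literature-weighted prior")
  ls <- literature_scores(ontology, ic, prior$literature, phi)
  prior$lit_rate * sum(ls) -
    lit_log_normaliser(ontology, ic, prior, terms)
}

#' Log prior of an unrestricted term vector
#'
#' The sampler proposes ordered k-vectors `phi_tilde` rather than minimal
#' sets; the induced prior divides the minimal-set prior by the number of
#' vectors reducing to the same set:
#' `P(phi_tilde) = P(v(phi_tilde)) / |{phi_tilde' : v(phi_tilde') =
#' v(phi_tilde)}|`, so the total mass over all `u^k` vectors is exactly 1.
#'
#' @inheritParams log_prior_phi
#' @param phi_tilde Character vector of length `prior$k` (duplicates and
#'   ancestor-descendant pairs allowed); all coordinates must be usable.
#' @return Log prior probability of the vector.
#' @export
log_prior_phi_tilde <- function(ontology, phi_tilde, prior, terms, ic = NULL) {
  phi_tilde <- resolve_terms(ontology, phi_tilde)
  if (length(phi_tilde) != prior$k)
    stop("'phi_tilde' must have exactly k = ", prior$k, " coordinates")
  if (!all(phi_tilde %in% terms))
    stop("'phi_tilde' contains terms outside the usable universe")
  phi <- minimal_set(ontology, phi_tilde)
  log_prior_phi(ontology, phi, prior, terms, ic) -
    log(count_preimage(ontology, phi, prior$k, terms))
}

#' Log prior density of the regression and transform parameters
#'
#' Sum of the normal log-density of `alpha`, the log-normal log-density of
#' `beta` (normal on `log beta` including the Jacobian), and the log-normal
#' log-densities of the four transform parameters.
#'
#' @param alpha Intercept.
#' @param beta Positive similarity coefficient.
#' @param transform A `"phe_transform"` object, or `NULL` to omit the
#'   transform contribution (fixed-transform mode).
#' @param prior A `"phe_prior"` object.
#' @return Log prior density; `-Inf` if `beta <= 0`.
#' @export
log_prior_params <- function(alpha, beta, transform = NULL,
                             prior = prior_config()) {
  if (!is.finite(alpha)) stop("'alpha' must be finite")
  if (!is.finite(beta) || beta <= 0) return(-Inf)
  lp <- stats::dnorm(alpha, prior$alpha_mean, prior$alpha_sd, log = TRUE) +
    stats::dnorm(log(beta), prior$log_beta_mean, prior$log_beta_sd,
                 log = TRUE) - log(beta)
  if (!is.null(transform)) {
    tv <- unlist(transform, use.names = FALSE)
    lp <- lp + sum(stats::dnorm(log(tv), prior$transform_log_mean,
                                prior$transform_log_sd, log = TRUE) - log(tv))
  }
  lp
}

#' Full conditional probability of the alternative model
#'
#' In the Carlin-Chib construction the model indicator has a tractable full
#' conditional: `P(gamma = 1 | ...) = pi A1 / (pi A1 + (1 - pi) A0)`, where
#' `A_g` is the likelihood under model `g` times the prior density of model
#' `g`'s parameters times the pseudoprior density of the other model's
#' parameters. This helper combines the two log-weights stably.
#'
#' @param log_a1,log_a0 Log weights `log A1` and `log A0`.
#' @param pi Prior probability of association.
#' @return `P(gamma = 1 | everything else)` in `[0, 1]`.
#' @export
gamma_full_conditional <- function(log_a1, log_a0, pi) {
  if (pi < 0 || pi > 1) stop("'pi' must lie in [0, 1]")
  if (pi == 0) return(0)
  if (pi == 1) return(1)
  if (!is.finite(log_a1) && !is.finite(log_a0))
    stop("both model weights are non-finite")
  d <- log_a1 - log_a0
  if (!is.finite(d)) return(if (d > 0) 1 else 0)
  1 / (1 + exp(log((1 - pi) / pi) - d))
}
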
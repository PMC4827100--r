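#' Generate a random synthetic ontology
#'
#' Builds a rooted random DAG for self-contained experiments: terms are
#' added in order and each non-root term receives one or two parents drawn
#' uniformly among earlier terms. The construction mirrors the shape of
#' real phenotype ontologies (single root, increasing specificity with
#' depth) at a reduced scale.
#'
#' @param n_terms Total number of terms including the root.
#' @param p_two_parents Probability that a term gets two parents. Default
#'   0.3.
#' @param seed Optional seed.
#' @return A `"phe_ontology"` object with terms `SYN:0000001` (root) ...
#' @export
random_ontology <- function(n_terms, p_two_parents = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_terms < 2) stop("need at least 2 terms")
  ids <- sprintf("SYN:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[1L]] <- character(0)
  for (i in 2:n_terms) {
    np <- if (i > 2 && stats::runif(1) < p_two_parents) 2L else 1L
    parents[[i]] <- sample(ids[seq_len(i - 1L)], np)
  }
  phe_ontology(parents,
               name = structure(paste("synthetic term", seq_len(n_terms)),
                                names = ids))
}

#' Simulation configuration
#'
#' Parameters of the template-expressivity-noise phenotype generator. Under
#' an association (`gamma_true = 1`), each rare-genotype subject manifests
#' each disease-template term independently with probability `r` (the
#' "expressivity") plus `Poisson(lambda_case)` noise terms; all other
#' subjects (and all subjects when `gamma_true = 0`) receive
#' `Poisson(lambda_other)` noise terms. With the default 3-term template,
#' `3r + lambda_case = lambda_other` holds exactly at r = 1, so subjects
#' carry about 8 raw terms regardless of genotype. Noise terms are drawn
#' uniformly with replacement from a noise set built by
#' [build_noise_set()].
#'
#' @param ontology A `"phe_ontology"` object the cohort will be simulated
#'   on.
#' @param gamma_true 1 = phenotypes depend on genotype through the
#'   template; 0 = phenotypes independent of genotype.
#' @param template Character vector: the disease template (a minimal set).
#'   Default: 3 mutually incomparable terms sampled from the deepest
#'   quartile of the ontology, mirroring a template of specific clinical
#'   terms.
#' @param r Expressivity in (0, 1].
#' @param n_subjects Cohort size N. Default 1,000.
#' @param n_rare Number of rare-genotype subjects (`sum(y)`).
#' @param lambda_case Poisson noise rate for rare-genotype subjects under
#'   association. Default 5.
#' @param lambda_other Poisson noise rate otherwise. Default 8.
#' @param n_noise_base_terms Number of random terms seeding the noise set
#'   before template union and ancestral closure. Default 200 (the value
#'   used with the full-size ontology; reduce for small synthetic
#'   ontologies).
#' @param noise_set Optional precomputed noise set (character vector); when
#'   supplied it is used as-is, allowing a fixed noise set across
#'   replicates.
#' @param heterogeneity_fraction Optional fraction in `[0, 1)`: additional
#'   subjects are drawn from the template (same expressivity) but keep the
#'   common genotype, emulating genetic heterogeneity. Default 0 (off).
#' @return Object of class `"phe_simconfig"`.
#' @export
sim_config <- function(ontology, gamma_true = 1, template = NULL, r = 1,
                       n_subjects = 1000, n_rare = 10, lambda_case = 5,
                       lambda_other = 8, n_noise_base_terms = 200,
                       noise_set = NULL, heterogeneity_fraction = 0) {
  if (!gamma_true %in% 0:1) stop("'gamma_true' must be 0 or 1")
  if (r <= 0 || r > 1) stop("'r' must lie in (0, 1]")
  if (n_rare > n_subjects) stop("'n_rare' cannot exceed 'n_subjects'")
  if (lambda_case <= 0 || lambda_other <= 0) stop("Poisson rates must be > 0")
  if (heterogeneity_fraction < 0 || heterogeneity_fraction >= 1)
    stop("'heterogeneity_fraction' must lie in [0, 1)")
  if (is.null(template)) {
    depth <- lengths(ontology$ancestors)
    deep <- ontology$id[depth >= stats::quantile(depth, 0.75)]
    template <- character(0)
    for (t in sample(deep)) {
      if (length(template) == 3L) break
      if (length(minimal_set(ontology, c(template, t))) == length(template) + 1L)
        template <- c(template, t)
    }
    if (length(template) < 3L)
      stop("could not find 3 incomparable template terms; supply 'template'")
  } else {
    template <- resolve_terms(ontology, template)
    if (!setequal(minimal_set(ontology, template), template))
      stop("'template' must be a minimal set")
  }
  structure(list(gamma_true = gamma_true, template = template, r = r,
                 n_subjects = as.integer(n_subjects),
                 n_rare = as.integer(n_rare),
                 lambda_case = lambda_case, lambda_other = lambda_other,
                 n_noise_base_terms = as.integer(n_noise_base_terms),
                 noise_set = noise_set,
                 heterogeneity_fraction = heterogeneity_fraction),
            class = "phe_simconfig")
}

#' Build the noise-term set
#'
#' Selects `n_base` ontology terms uniformly at random, unions them with
#' the disease template, and closes the result under ancestors. On the
#' full-size phenotype ontology with `n_base = 200` this yields on the
#' order of a thousand terms.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param template Character vector of template terms (always included).
#' @param n_base Number of random seed terms.
#' @return Character vector of noise terms (ancestor-closed, includes the
#'   template and the root).
#' @export
build_noise_set <- function(ontology, template, n_base) {
  template <- resolve_terms(ontology, template)
  if (n_base > length(ontology$id))
    stop("'n_base' exceeds the number of ontology terms")
  base <- union(sample(ontology$id, n_base), template)
  sort(unique(unlist(ontology$ancestors[base], use.names = FALSE)))
}

#' Simulate a cohort under the template-expressivity-noise model
#'
#' Generates genotypes with exactly `n_rare` rare-genotype subjects and
#' phenotypes according to the configuration: under an association each
#' rare subject receives each template term with probability `r` plus
#' Poisson noise; every phenotype is reduced to a minimal set. The raw
#' template subset drawn for each template-exposed subject is recorded in
#' the `template_subsets` element (used to study expressivity analytically).
#'
#' @param ontology A `"phe_ontology"` object.
#' @param config A `"phe_simconfig"` object.
#' @param seed Optional seed.
#' @return A `"phe_cohort"` with extra elements `template`, `noise_set` and
#'   `template_subsets` (list, `NULL` for subjects not drawn from the
#'   template).
#' @export
simulate_cohort <- function(ontology, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "phe_simconfig"))
  n <- config$n_subjects
  noise <- config$noise_set
  if (is.null(noise))
    noise <- build_noise_set(ontology, config$template,
                             config$n_noise_base_terms)
  y <- integer(n)
  y[sample.int(n, config$n_rare)] <- 1L
  from_template <- y == 1L & config$gamma_true == 1
  if (config$heterogeneity_fraction > 0 && config$gamma_true == 1) {
    # template-drawn subjects of which only (1 - f) carry the rare genotype
    extra <- round(config$n_rare * config$heterogeneity_fraction /
                     (1 - config$heterogeneity_fraction))
    pool <- which(!from_template)
    from_template[sample(pool, min(extra, length(pool)))] <- TRUE
  }
  phen <- vector("list", n)
  tsub <- vector("list", n)
  ndraws <- integer(n)
  for (i in seq_len(n)) {
    if (from_template[[i]]) {
      tt <- config$template[stats::runif(length(config$template)) < config$r]
      m <- stats::rpois(1, config$lambda_case)
      tsub[[i]] <- tt
    } else {
      tt <- character(0)
      m <- stats::rpois(1, config$lambda_other)
    }
    ndraws[[i]] <- m
    raw <- c(tt, if (m > 0) sample(noise, m, replace = TRUE))
    phen[[i]] <- minimal_set(ontology, raw)
  }
  out <- cohort(sprintf("S%04d", seq_len(n)), phen, y)
  out$template <- config$template
  out$noise_set <- noise
  out$template_subsets <- tsub
  out$noise_draws <- ndraws
  out$config <- config
  out
}

#' Power and specificity study over a simulation grid
#'
#' For each combination of `gamma_true`, expressivity `r` and rare-genotype
#' count, simulates `n_reps` cohorts (with the disease template and noise
#' set held fixed across all cells, as in a designed simulation study) and
#' fits the similarity regression to each, recording the posterior
#' probability of association.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param r_values Expressivities to scan.
#' @param n_rare_values Rare-genotype counts to scan.
#' @param gamma_true_values Scenarios (subset of `c(1, 0)`).
#' @param n_reps Replicate datasets per cell.
#' @param n_subjects Cohort size. Default 1,000.
#' @param template Optional template (defaults as in [sim_config()]).
#' @param n_noise_base_terms Noise-set seed size (see [build_noise_set()]).
#' @param noise_set Optional precomputed noise set shared across cells (built
#'   once from the template when missing).
#' @param prior,control Model and sampler settings passed to [phenoreg()].
#' @param seed Seed for the whole study; each cell/replicate receives a
#'   deterministic sub-seed.
#' @return A data.frame with one row per fitted replicate: `gamma_true`,
#'   `r`, `n_rare`, `rep`, `mean_gamma` (`NA` with a message on the rare
#'   event of a failed fit), `seed_used`.
#' @export
run_power_study <- function(ontology, r_values, n_rare_values,
                            gamma_true_values = c(1, 0), n_reps = 8,
                            n_subjects = 1000, template = NULL,
                            n_noise_base_terms = 200, noise_set = NULL,
                            prior = prior_config(), control = mcmc_config(),
                            seed = 1) {
  set.seed(seed)
  base_cfg <- sim_config(ontology, gamma_true = 1, template = template,
                         n_subjects = n_subjects,
                         n_noise_base_terms = n_noise_base_terms)
  noise <- if (is.null(noise_set))
    build_noise_set(ontology, base_cfg$template, n_noise_base_terms)
  else noise_set
  grid <- expand.grid(rep = seq_len(n_reps), n_rare = n_rare_values,
                      r = r_values, gamma_true = gamma_true_values)
  grid$mean_gamma <- NA_real_
  grid$seed_used <- seed + seq_len(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(ontology, gamma_true = grid$gamma_true[[i]],
                      template = base_cfg$template, r = grid$r[[i]],
                      n_subjects = n_subjects, n_rare = grid$n_rare[[i]],
                      noise_set = noise)
    coh <- simulate_cohort(ontology, cfg, seed = grid$seed_used[[i]])
    fit <- tryCatch(
      phenoreg(coh, ontology = ontology, prior = prior, control = control,
               seed = grid$seed_used[[i]] + 1L),
      error = function(e) {
        message("fit failed in cell (gamma_true=", grid$gamma_true[[i]],
                ", r=", grid$r[[i]], ", n_rare=", grid$n_rare[[i]],
                ", rep=", grid$rep[[i]], "): ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) grid$mean_gamma[[i]] <- fit$mean_gamma
  }
  grid[, c("gamma_true", "r", "n_rare", "rep", "mean_gamma", "seed_used")]
}
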
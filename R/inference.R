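#' MCMC configuration
#'
#' Run-length, proposal and pseudoprior-tuning settings for the Carlin-Chib
#' sampler. Proposal scales are adapted during burn-in toward an acceptance
#' rate between 0.23 and 0.44.
#'
#' @param n_iter Total iterations of the main chain. Default 10,000.
#' @param n_burnin Burn-in iterations discarded from summaries. Default 2,500.
#' @param thin Keep every `thin`-th post-burn-in draw. Default 1.
#' @param pilot_iter,pilot_burnin Length and burn-in of each pseudoprior
#'   pilot chain. Defaults 1,500 and 500.
#' @param scale_alpha,scale_log_beta,scale_log_transform Initial random-walk
#'   proposal standard deviations.
#' @param phi_proposal_weights Mixture weights of the three
#'   characteristic-phenotype coordinate proposals: uniform over usable
#'   terms, a graph neighbour (parent or child) of the current term, and a
#'   draw from the cohort annotation frequencies. Must sum to 1.
#' @param phi_moves Coordinate updates of the characteristic phenotype
#'   attempted per iteration while the alternative model is active.
#' @param pseudo_mix_weight Weight of the empirical (pilot-visited)
#'   component in the characteristic-phenotype pseudoprior; the remainder is
#'   uniform over unrestricted k-vectors so the pseudoprior has full
#'   support. Default 0.9.
#' @param fixed_transform Optional numeric vector `c(a_f, b_f, a_g, b_g)`:
#'   hold the similarity transforms fixed instead of sampling them.
#' @param alpha_grid,beta_grid Optional grids; when supplied, the intercept
#'   and slope take values on these grids under discrete uniform priors
#'   (used to validate the sampler against exhaustive enumeration). Grid
#'   mode requires `fixed_transform`.
#' @param adapt Adapt proposal scales during burn-in. Default `TRUE`.
#' @return Object of class `"phe_mcmc"`.
#' @export
mcmc_config <- function(n_iter = 10000, n_burnin = 2500, thin = 1,
                        pilot_iter = 1500, pilot_burnin = 500,
                        scale_alpha = 0.5, scale_log_beta = 0.5,
                        scale_log_transform = 0.25,
                        phi_proposal_weights = c(0.4, 0.3, 0.3),
                        phi_moves = 2,
                        pseudo_mix_weight = 0.9,
                        fixed_transform = NULL,
                        alpha_grid = NULL, beta_grid = NULL,
                        adapt = TRUE) {
  if (n_iter <= n_burnin || n_burnin < 0) stop("need n_iter > n_burnin >= 0")
  if (pilot_iter <= pilot_burnin) stop("need pilot_iter > pilot_burnin")
  if (any(c(scale_alpha, scale_log_beta, scale_log_transform) <= 0))
    stop("proposal scales must be positive")
  w <- phi_proposal_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("'phi_proposal_weights' must be 3 non-negative weights summing to 1")
  if (pseudo_mix_weight < 0 || pseudo_mix_weight >= 1)
    stop("'pseudo_mix_weight' must lie in [0, 1)")
  if (!is.null(alpha_grid) && is.null(beta_grid))
    stop("grid mode needs both alpha_grid and beta_grid")
  if (!is.null(alpha_grid) && is.null(fixed_transform))
    stop("grid mode requires fixed_transform")
  if (!is.null(fixed_transform)) {
    fixed_transform <- as.numeric(fixed_transform)
    if (length(fixed_transform) != 4 || any(fixed_transform <= 0))
      stop("'fixed_transform' must be 4 positive values (a_f, b_f, a_g, b_g)")
  }
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), pilot_iter = as.integer(pilot_iter),
                 pilot_burnin = as.integer(pilot_burnin),
                 scale_alpha = scale_alpha, scale_log_beta = scale_log_beta,
                 scale_log_transform = scale_log_transform,
                 phi_proposal_weights = w, phi_moves = as.integer(phi_moves),
                 pseudo_mix_weight = pseudo_mix_weight,
                 fixed_transform = fixed_transform,
                 alpha_grid = alpha_grid, beta_grid = beta_grid,
                 adapt = isTRUE(adapt)),
            class = "phe_mcmc")
}

# ---- internal data preparation -------------------------------------------

# Everything the C++ sampler needs, with 0-based indices.
prepare_fit_data <- function(ontology, phenotypes, ic, prior) {
  usable <- usable_terms(ontology, ic)
  if (length(usable) < 2L)
    stop("fewer than two usable terms (finite positive IC); ",
         "cannot search for a characteristic phenotype")
  simdat <- build_sim_data(ontology, ic, phenotypes, usable)
  upos <- structure(seq_along(usable), names = usable)
  anc0 <- lapply(usable, function(t) {
    a <- intersect(ontology$ancestors[[t]], usable)
    sort(unname(upos[a]) - 1L)
  })
  nb0 <- lapply(usable, function(t) {
    nbs <- intersect(c(ontology$parents[[t]], ontology$children[[t]]), usable)
    sort(unname(upos[nbs]) - 1L)
  })
  freq <- exp(-ic[usable])
  term_w <- freq / sum(freq)
  x_lens <- lengths(simdat$x_idx)
  x_flat <- unlist(simdat$x_idx, use.names = FALSE)
  x_flat <- if (length(x_flat)) as.integer(x_flat - 1L) else integer(0)
  x_ptr <- as.integer(c(0L, cumsum(x_lens)))
  lit <- !is.null(prior$literature)
  if (lit) {
    lit_score <- prior$lit_rate *
      literature_scores(ontology, ic, prior$literature, usable)
    log_lit_Z <- lit_log_normaliser(ontology, ic, prior, usable)
    log_unif_phi <- 0
  } else {
    lit_score <- numeric(length(usable))
    log_lit_Z <- 0
    log_unif_phi <- -log(count_min_sets(ontology, prior$k, usable))
  }
  list(usable = usable, P = simdat$P, dterms = simdat$dterms,
       x_flat = x_flat, x_ptr = x_ptr, anc0 = anc0, nb0 = nb0,
       term_w = unname(term_w), lit = lit, lit_score = unname(lit_score),
       log_lit_Z = log_lit_Z, log_unif_phi = log_unif_phi)
}

sampler_init <- function(y, prep, prior, control) {
  n <- length(y)
  a0 <- stats::qlogis((sum(y) + 0.5) / (n + 1))
  init <- list(alpha0 = a0, alpha1 = a0, log_beta = prior$log_beta_mean,
               log_transform = prior$transform_log_mean,
               phi = sample.int(length(prep$usable), prior$k,
                                replace = TRUE) - 1L,
               ia0 = 0L, ia1 = 0L, ib = 0L)
  if (!is.null(control$alpha_grid)) {
    init$ia0 <- init$ia1 <- which.min(abs(control$alpha_grid - a0)) - 1L
    init$ib <- 0L
  }
  init
}

run_sampler <- function(y, offsets, prep, prior, control, fix_gamma = -1L,
                        pseudo = list(), init = NULL,
                        n_iter = control$n_iter, n_burnin = control$n_burnin) {
  if (is.null(init)) init <- sampler_init(y, prep, prior, control)
  fixed <- !is.null(control$fixed_transform)
  .cc_sampler(
    y = as.integer(y), h = as.numeric(offsets), P = prep$P,
    x_flat = prep$x_flat, x_ptr = prep$x_ptr,
    anc = prep$anc0, nb = prep$nb0, term_w = prep$term_w,
    phi_prop_w = control$phi_proposal_weights, k = prior$k,
    pi = prior$pi, alpha_mean = prior$alpha_mean, alpha_sd = prior$alpha_sd,
    log_beta_mean = prior$log_beta_mean, log_beta_sd = prior$log_beta_sd,
    trans_log_mean = prior$transform_log_mean,
    trans_log_sd = prior$transform_log_sd,
    lit = prep$lit, log_unif_phi = prep$log_unif_phi,
    lit_score = prep$lit_score, log_lit_Z = prep$log_lit_Z,
    fixed_trans = fixed,
    trans_init = if (fixed) control$fixed_transform else rep(1, 4),
    alpha_grid = if (is.null(control$alpha_grid)) numeric(0)
                 else as.numeric(control$alpha_grid),
    beta_grid = if (is.null(control$beta_grid)) numeric(0)
                else as.numeric(control$beta_grid),
    n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
    thin = control$thin, fix_gamma = as.integer(fix_gamma),
    scales = c(control$scale_alpha, control$scale_log_beta,
               control$scale_log_transform),
    phi_moves = control$phi_moves, adapt = control$adapt,
    pseudo = pseudo, init = init)
}

#' Tune Carlin-Chib pseudopriors from pilot chains
#'
#' Runs two pilot chains with the model indicator fixed at 0 and at 1, then
#' fits closed-form pseudoprior densities to the pilot posteriors: normal
#' for the intercepts, `log beta` and the log transform parameters (or
#' categorical over the grids in grid mode), and, for the characteristic
#' phenotype vector, the empirical distribution of pilot-visited vectors
#' mixed with a uniform distribution over all k-vectors so that the
#' pseudoprior has full support. Good pseudopriors approximate each model's
#' posterior; they affect sampling efficiency but not the posterior of the
#' model indicator.
#'
#' @param y Binary genotype vector.
#' @param offsets Per-subject log-odds offsets.
#' @param prep Internal prepared data (as built by [phenoreg()]).
#' @param prior A `"phe_prior"` object.
#' @param control A `"phe_mcmc"` object.
#' @return A list of pseudoprior parameters (class `"phe_pseudo"`).
#' @keywords internal
tune_pseudopriors <- function(y, offsets, prep, prior, control) {
  p0 <- run_sampler(y, offsets, prep, prior, control, fix_gamma = 0L,
                    n_iter = control$pilot_iter,
                    n_burnin = control$pilot_burnin)
  p1 <- run_sampler(y, offsets, prep, prior, control, fix_gamma = 1L,
                    n_iter = control$pilot_iter,
                    n_burnin = control$pilot_burnin)
  acc0 <- p0$acceptance[["alpha0"]]
  acc1 <- p1$acceptance[["alpha1"]]
  if (!is.na(acc0) && acc0 == 0)
    stop("degenerate baseline pilot: zero acceptance for alpha (",
         "acceptance rates: ",
         paste(names(p0$acceptance), round(p0$acceptance, 3),
               sep = "=", collapse = ", "), ")")
  if (!is.na(acc1) && acc1 == 0)
    stop("degenerate alternative pilot: zero acceptance for alpha (",
         "acceptance rates: ",
         paste(names(p1$acceptance), round(p1$acceptance, 3),
               sep = "=", collapse = ", "), ")")
  norm_fit <- function(x) c(mean(x), max(stats::sd(x), 1e-3))
  lt <- log(p1$transform)
  phi_tab <- table(apply(p1$phi_tilde, 2, paste, collapse = ","))
  phi_vecs <- vapply(strsplit(names(phi_tab), ",", fixed = TRUE),
                     function(v) as.integer(v), integer(nrow(p1$phi_tilde)))
  phi_vecs <- matrix(phi_vecs, nrow = nrow(p1$phi_tilde))
  ps <- list(alpha0 = norm_fit(p0$alpha0),
             alpha1 = norm_fit(p1$alpha1),
             log_beta = norm_fit(log(p1$beta)),
             log_transform = rbind(norm_fit(lt[, 1]), norm_fit(lt[, 2]),
                                   norm_fit(lt[, 3]), norm_fit(lt[, 4])),
             phi_mix_w = control$pseudo_mix_weight,
             phi_probs = as.numeric(phi_tab) / sum(phi_tab),
             phi_vecs = phi_vecs)
  if (!is.null(control$alpha_grid)) {
    grid_p <- function(values, grid) {
      cnt <- tabulate(match(round(values, 10), round(grid, 10)),
                      nbins = length(grid))
      p <- 0.9 * cnt / max(sum(cnt), 1) + 0.1 / length(grid)
      p / sum(p)
    }
    ps$alpha0_grid_p <- grid_p(p0$alpha0, control$alpha_grid)
    ps$alpha1_grid_p <- grid_p(p1$alpha1, control$alpha_grid)
    ps$beta_grid_p <- grid_p(p1$beta, control$beta_grid)
  } else {
    ps$alpha0_grid_p <- ps$alpha1_grid_p <- ps$beta_grid_p <- numeric(0)
  }
  structure(ps, class = "phe_pseudo", pilots = list(baseline = p0$acceptance,
                                                    alternative = p1$acceptance))
}

#' Monte Carlo standard error by batch means
#'
#' @param x Numeric chain.
#' @param n_batch Number of batches (default 30).
#' @return Estimated standard error of `mean(x)` accounting for
#'   autocorrelation.
#' @export
mcmc_se <- function(x, n_batch = 30) {
  n <- length(x)
  m <- floor(n / n_batch)
  if (m < 2) return(stats::sd(x) / sqrt(max(n, 1)))
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  stats::sd(bm) / sqrt(n_batch)
}

#' Fit the phenotype similarity regression
#'
#' Compares the baseline logistic model, in which every subject has the
#' same probability of carrying the rare genotype, against the alternative
#' in which the log-odds increase with the subject's semantic similarity to
#' a latent characteristic phenotype (an antichain of at most `prior$k`
#' ontology terms), using Carlin-Chib MCMC over both models jointly. The
#' headline statistic is the posterior mean of the model indicator, the
#' probability of association.
#'
#' @param y Binary genotype vector (1 = rare genotype), or a
#'   `"phe_cohort"` object, in which case `phenotypes` and `offsets` are
#'   taken from it.
#' @param phenotypes List of character vectors of ontology term IDs, one per
#'   subject; each is reduced to a minimal set.
#' @param ontology A `"phe_ontology"` object.
#' @param ic Optional named IC vector; computed from `phenotypes` via
#'   [information_content()] when missing.
#' @param offsets Optional per-subject log-odds offsets (e.g. from
#'   [estimate_offsets()]); default 0.
#' @param prior A `"phe_prior"` object from [prior_config()].
#' @param control A `"phe_mcmc"` object from [mcmc_config()].
#' @param seed Optional integer seed; the fit is fully reproducible given
#'   the seed and configuration.
#' @param pseudopriors Optional pre-tuned pseudopriors (from a previous fit
#'   on the same data); tuned from pilot chains when missing.
#' @return Object of class `"phenoreg"` with components `mean_gamma`,
#'   `marginal_inclusion` (per-term inclusion probabilities given
#'   association, sorted), `pairwise_inclusion`, `traces`, `diagnostics`,
#'   and the resolved configuration. See [summary.phenoreg()].
#' @examples
#' ont <- random_ontology(40, seed = 1)
#' cfg <- sim_config(ontology = ont, gamma_true = 1, r = 1, n_subjects = 120,
#'                   n_rare = 8, n_noise_base_terms = 15)
#' coh <- simulate_cohort(ont, cfg, seed = 2)
#' fit <- phenoreg(coh, ontology = ont, seed = 3,
#'                 control = mcmc_config(n_iter = 1500, n_burnin = 500,
#'                                       pilot_iter = 500))
#' fit$mean_gamma
#' @export
phenoreg <- function(y, phenotypes = NULL, ontology, ic = NULL, offsets = NULL,
                     prior = prior_config(), control = mcmc_config(),
                     seed = NULL, pseudopriors = NULL) {
  cl <- match.call()
  if (inherits(y, "phe_cohort")) {
    coh <- y
    phenotypes <- coh$phenotypes
    if (is.null(offsets)) offsets <- coh$offsets
    subjects <- coh$subjects
    y <- coh$y
  } else {
    subjects <- names(y)
    if (is.null(subjects)) subjects <- paste0("S", seq_along(y))
  }
  if (is.null(phenotypes)) stop("'phenotypes' is required")
  if (length(phenotypes) != length(y))
    stop("'phenotypes' and 'y' must have the same length")
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("'y' must be binary 0/1")
  if (is.null(offsets)) offsets <- 0
  offsets <- rep_len(as.numeric(offsets), length(y))
  if (!is.null(seed)) set.seed(seed)
  if (prior$k > 3)
    stop("characteristic phenotypes of size k > 3 are not supported")

  phenotypes <- lapply(phenotypes, function(x) minimal_set(ontology, x))
  if (is.null(ic)) ic <- information_content(ontology, phenotypes)
  prep <- prepare_fit_data(ontology, phenotypes, ic, prior)
  if (is.null(pseudopriors))
    pseudopriors <- tune_pseudopriors(y, offsets, prep, prior, control)
  res <- run_sampler(y, offsets, prep, prior, control,
                     fix_gamma = -1L, pseudo = unclass(pseudopriors))

  n_kept <- length(res$gamma)
  mean_gamma <- mean(res$gamma)
  g1 <- res$gamma == 1L
  n1 <- sum(g1)
  warn <- character(0)
  if (n1 == 0L) {
    warn <- c(warn, "no alternative-model visits after burn-in; the characteristic phenotype is unidentified")
    marg <- numeric(0)
    pair <- matrix(numeric(0), 0, 0)
  } else {
    phi_red <- res$phi[, g1, drop = FALSE]          # 0-based usable indices
    idx <- as.vector(phi_red)
    idx <- idx[!is.na(idx)] + 1L
    cnt <- tabulate(idx, nbins = length(prep$usable))
    marg <- cnt / n1
    names(marg) <- prep$usable
    keep <- marg > 0
    marg <- sort(marg[keep], decreasing = TRUE)
    terms_in <- names(marg)
    ind <- matrix(0L, nrow = length(terms_in), ncol = n1,
                  dimnames = list(terms_in, NULL))
    for (j in seq_len(n1)) {
      tj <- prep$usable[phi_red[, j][!is.na(phi_red[, j])] + 1L]
      ind[match(tj, terms_in), j] <- 1L
    }
    pair <- tcrossprod(ind) / n1
  }

  phi_terms <- apply(res$phi, 2, function(col)
    paste(prep$usable[col[!is.na(col)] + 1L], collapse = ";"))
  traces <- data.frame(
    iteration = seq_len(n_kept), gamma = res$gamma,
    alpha0 = res$alpha0, alpha1 = res$alpha1, beta = res$beta,
    a_f = res$transform[, 1], b_f = res$transform[, 2],
    a_g = res$transform[, 3], b_g = res$transform[, 4],
    phi = phi_terms, stringsAsFactors = FALSE)

  diagnostics <- list(
    acceptance = res$acceptance,
    n_gamma1 = n1,
    mean_gamma_se = mcmc_se(res$gamma),
    # effective sample size of alpha0 from the batch-means variance ratio
    ess_alpha0 = if (stats::sd(res$alpha0) > 0)
      min((stats::sd(res$alpha0) / mcmc_se(res$alpha0))^2, n_kept)
      else NA_real_,
    warnings = warn)

  out <- structure(list(
    mean_gamma = mean_gamma,
    marginal_inclusion = marg,
    pairwise_inclusion = pair,
    traces = traces,
    diagnostics = diagnostics,
    prior = prior, control = control, seed = seed,
    pseudopriors = pseudopriors,
    subjects = subjects, y = y, offsets = offsets,
    usable = prep$usable, ic = ic,
    n = length(y), call = cl), class = "phenoreg")
  attr(out, "prep") <- prep
  if (length(warn)) for (w in warn) warning(w, call. = FALSE)
  out
}

#' @export
print.phenoreg <- function(x, ...) {
  cat("Phenotype similarity regression\n")
  cat("  subjects: ", x$n, " (", sum(x$y), " rare genotype)\n", sep = "")
  cat("  P(association | data) = ", format(round(x$mean_gamma, 4)),
      "  [prior ", x$prior$pi, "]\n", sep = "")
  if (length(x$marginal_inclusion)) {
    top <- utils::head(x$marginal_inclusion, 5)
    cat("  top characteristic-phenotype terms (P(term in phi | assoc)):\n")
    for (t in names(top))
      cat(sprintf("    %-24s %.3f\n", t, top[[t]]))
  } else {
    cat("  characteristic phenotype: not identified (no alternative-model visits)\n")
  }
  invisible(x)
}

#' Summarize a phenotype similarity regression fit
#'
#' @param object A `"phenoreg"` fit.
#' @param ... Unused.
#' @return A `"summary.phenoreg"` list: probability of association with its
#'   Monte Carlo standard error, posterior parameter summaries (the
#'   alternative-model parameters conditional on association), top
#'   characteristic-phenotype terms and pairwise co-inclusions, and sampler
#'   diagnostics.
#' @export
summary.phenoreg <- function(object, ...) {
  tr <- object$traces
  g1 <- tr$gamma == 1
  qtl <- function(v) if (length(v)) stats::quantile(v, c(0.025, 0.5, 0.975))
    else c(`2.5%` = NA_real_, `50%` = NA_real_, `97.5%` = NA_real_)
  params <- rbind(
    alpha0 = c(mean = mean(tr$alpha0), qtl(tr$alpha0)),
    alpha1 = c(mean = mean(tr$alpha1[g1]), qtl(tr$alpha1[g1])),
    beta = c(mean = mean(tr$beta[g1]), qtl(tr$beta[g1])),
    a_f = c(mean = mean(tr$a_f[g1]), qtl(tr$a_f[g1])),
    b_f = c(mean = mean(tr$b_f[g1]), qtl(tr$b_f[g1])),
    a_g = c(mean = mean(tr$a_g[g1]), qtl(tr$a_g[g1])),
    b_g = c(mean = mean(tr$b_g[g1]), qtl(tr$b_g[g1])))
  structure(list(mean_gamma = object$mean_gamma,
                 mean_gamma_se = object$diagnostics$mean_gamma_se,
                 n = object$n, n_rare = sum(object$y),
                 params = params,
                 marginal_inclusion = object$marginal_inclusion,
                 pairwise_inclusion = object$pairwise_inclusion,
                 diagnostics = object$diagnostics,
                 prior = object$prior), class = "summary.phenoreg")
}

#' @export
print.summary.phenoreg <- function(x, ...) {
  cat("Phenotype similarity regression: posterior summary\n")
  cat(sprintf("  P(gamma = 1 | y) = %.4f (MC-SE %.4f), prior pi = %g\n",
              x$mean_gamma, x$mean_gamma_se, x$prior$pi))
  cat(sprintf("  %d subjects, %d with the rare genotype\n", x$n, x$n_rare))
  cat("  parameters (alternative-model rows conditional on gamma = 1):\n")
  print(round(x$params, 3))
  if (length(x$marginal_inclusion)) {
    cat("  marginal inclusion probabilities (top 10):\n")
    print(round(utils::head(x$marginal_inclusion, 10), 3))
  }
  cat("  acceptance rates:\n")
  print(round(x$diagnostics$acceptance, 3))
  invisible(x)
}

#' @export
coef.phenoreg <- function(object, ...) {
  tr <- object$traces
  g1 <- tr$gamma == 1
  c(mean_gamma = object$mean_gamma,
    alpha0 = mean(tr$alpha0),
    alpha1 = if (any(g1)) mean(tr$alpha1[g1]) else NA_real_,
    beta = if (any(g1)) mean(tr$beta[g1]) else NA_real_,
    a_f = if (any(g1)) mean(tr$a_f[g1]) else NA_real_,
    b_f = if (any(g1)) mean(tr$b_f[g1]) else NA_real_,
    a_g = if (any(g1)) mean(tr$a_g[g1]) else NA_real_,
    b_g = if (any(g1)) mean(tr$b_g[g1]) else NA_real_)
}

# posterior draws of per-subject linear predictors, averaging over the
# model indicator; used by predict/residuals/simulate
posterior_eta <- function(object, prep, x_flat, x_ptr, offsets, max_draws = 400) {
  tr <- object$traces
  n_kept <- nrow(tr)
  keep <- unique(round(seq(1, n_kept, length.out = min(max_draws, n_kept))))
  n_sub <- length(x_ptr) - 1L
  eta <- matrix(NA_real_, nrow = n_sub, ncol = length(keep))
  for (m in seq_along(keep)) {
    j <- keep[[m]]
    if (tr$gamma[[j]] == 1) {
      phi <- strsplit(tr$phi[[j]], ";", fixed = TRUE)[[1]]
      phi_idx <- match(phi, prep$usable) - 1L
      pr <- .sim_profile(prep$P, x_flat, x_ptr, as.integer(phi_idx),
                         c(tr$a_f[[j]], tr$b_f[[j]], tr$a_g[[j]], tr$b_g[[j]]))
      eta[, m] <- tr$alpha1[[j]] + offsets + tr$beta[[j]] * pr$s
    } else {
      eta[, m] <- tr$alpha0[[j]] + offsets
    }
  }
  eta
}

#' Posterior predictive probabilities of the rare genotype
#'
#' Evaluates, for each subject, the posterior mean of the linear predictor
#' or of the rare-genotype probability, averaging over the posterior of the
#' model indicator, the characteristic phenotype and all parameters. With
#' `newdata`, phenotypes of new subjects are scored against the fitted
#' posterior (phenotype-only genotype prediction).
#'
#' @param object A `"phenoreg"` fit.
#' @param newdata Optional list of phenotypes (character vectors of term
#'   IDs) for new subjects.
#' @param ontology Required with `newdata`: the ontology used in the fit.
#' @param offsets Offsets for new subjects (default 0).
#' @param type `"response"` (probability scale, default) or `"link"`.
#' @param max_draws Posterior draws used for the average. Default 400.
#' @param ... Unused.
#' @return Named numeric vector, one value per subject.
#' @export
predict.phenoreg <- function(object, newdata = NULL, ontology = NULL,
                             offsets = NULL, type = c("response", "link"),
                             max_draws = 400, ...) {
  type <- match.arg(type)
  prep <- attr(object, "prep")
  if (is.null(prep))
    stop("the fit no longer carries its prepared data; refit to predict")
  if (is.null(newdata)) {
    x_flat <- prep$x_flat; x_ptr <- prep$x_ptr
    offs <- object$offsets
    who <- object$subjects
  } else {
    if (is.null(ontology)) stop("'ontology' is required with 'newdata'")
    newdata <- lapply(newdata, function(x) minimal_set(ontology, x))
    sd2 <- build_sim_data(ontology, object$ic, newdata, prep$usable)
    # new phenotypes may use annotated terms unseen in the fit; rebuild flat
    x_flat <- as.integer(unlist(sd2$x_idx, use.names = FALSE) - 1L)
    x_ptr <- as.integer(c(0L, cumsum(lengths(sd2$x_idx))))
    prep <- list(P = sd2$P, usable = prep$usable)
    offs <- rep_len(if (is.null(offsets)) 0 else offsets, length(newdata))
    who <- names(newdata)
    if (is.null(who)) who <- paste0("N", seq_along(newdata))
  }
  eta <- posterior_eta(object, prep, x_flat, x_ptr, offs,
                       max_draws = max_draws)
  out <- if (type == "response") rowMeans(stats::plogis(eta))
         else rowMeans(eta)
  names(out) <- who
  out
}

#' @export
residuals.phenoreg <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, type = "response")
  r <- object$y - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  names(r) <- object$subjects
  r
}

#' @export
fitted.phenoreg <- function(object, ...) predict(object, type = "response")

#' Simulate genotypes from the posterior predictive
#'
#' Draws replicate binary genotype vectors: for each replicate one posterior
#' draw is selected and genotypes are sampled from the corresponding
#' per-subject probabilities.
#'
#' @param object A `"phenoreg"` fit.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Integer matrix, subjects by `nsim`.
#' @export
simulate.phenoreg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prep <- attr(object, "prep")
  eta <- posterior_eta(object, prep, prep$x_flat, prep$x_ptr,
                       object$offsets, max_draws = 400)
  draws <- sample.int(ncol(eta), nsim, replace = TRUE)
  out <- vapply(draws, function(m)
    stats::rbinom(nrow(eta), 1L, stats::plogis(eta[, m])), integer(nrow(eta)))
  rownames(out) <- object$subjects
  out
}

#' @export
plot.phenoreg <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tr <- x$traces
  cummean <- cumsum(tr$gamma) / seq_along(tr$gamma)
  graphics::plot(tr$iteration, cummean, type = "l",
                 xlab = "kept iteration", ylab = "running mean of gamma",
                 main = "P(association)", ylim = c(0, 1))
  graphics::abline(h = x$mean_gamma, lty = 2)
  if (length(x$marginal_inclusion)) {
    top <- utils::head(x$marginal_inclusion, 10)
    graphics::barplot(rev(top), horiz = TRUE, las = 1,
                      xlab = "P(term in phi | association)",
                      main = "characteristic phenotype", cex.names = 0.6)
  } else {
    graphics::plot.new()
    graphics::title("no alternative-model visits")
  }
  invisible(x)
}

#' Per-subject similarity scores for a fixed characteristic phenotype
#'
#' Scores every subject phenotype against a given characteristic phenotype
#' under fixed transform parameters, returning the two asymmetric
#' similarities and their transformed product.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param ic Named IC vector.
#' @param phenotypes List of character term vectors, one per subject.
#' @param phi Characteristic phenotype (nonempty term vector; reduced to a
#'   minimal set).
#' @param params A `"phe_transform"` object.
#' @return A data.frame with columns `subject`, `s_phi`, `s_x`, `s`.
#' @export
score_similarity <- function(ontology, ic, phenotypes, phi,
                             params = transform_params()) {
  phi <- minimal_set(ontology, phi)
  if (!length(phi)) stop("'phi' must be nonempty")
  phenotypes <- lapply(phenotypes, function(x) minimal_set(ontology, x))
  who <- names(phenotypes)
  if (is.null(who)) who <- paste0("S", seq_along(phenotypes))
  rows <- lapply(phenotypes, function(x)
    overall_similarity(ontology, ic, phi, x, params))
  data.frame(subject = who,
             s_phi = vapply(rows, `[[`, 1, "s_phi"),
             s_x = vapply(rows, `[[`, 1, "s_x"),
             s = vapply(rows, `[[`, 1, "s"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gelman-Rubin diagnostic across replicate fits
#'
#' Potential scale reduction factor of the baseline intercept chain across
#' independently seeded fits of the same data — the multi-chain convergence
#' check for the single-chain-by-default sampler.
#'
#' @param fits List of `"phenoreg"` fits of the same data with different
#'   seeds.
#' @return The potential scale reduction factor (values near 1 indicate
#'   convergence).
#' @export
gelman_rubin <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits")
  chains <- lapply(fits, function(f) f$traces$alpha0)
  n <- min(lengths(chains))
  chains <- vapply(chains, function(x) x[seq_len(n)], numeric(n))
  m <- ncol(chains)
  means <- colMeans(chains)
  b <- n * stats::var(means)
  w <- mean(apply(chains, 2, stats::var))
  sqrt(((n - 1) / n * w + b / n) / w)
}
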
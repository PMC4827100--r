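test_that("cohort constructor validates alignment and genotype coding", {
  coh <- cohort(c("a", "b"), list("A", "B"), c(1, 0))
  expect_s3_class(coh, "phe_cohort")
  expect_equal(coh$offsets, c(0, 0))
  expect_error(cohort(c("a", "a"), list("A", "B"), c(1, 0)), "unique")
  expect_error(cohort(c("a", "b"), list("A"), c(1, 0)), "same length")
  expect_error(cohort(c("a", "b"), list("A", "B"), c(1, 2)), "binary")
})

test_that("log-likelihood matches direct Bernoulli evaluation", {
  # gamma = 0, alpha = 0: both subjects have p = 1/2
  expect_equal(model_loglik(c(1, 0), alpha = 0), 2 * log(0.5))
  # gamma = 1, alpha = 0, beta = 2, s = (1, 0)
  expect_equal(model_loglik(c(1, 0), alpha = 0, beta = 2, s = c(1, 0)),
               log(plogis(2)) + log(1 - plogis(0)), tolerance = 1e-12)
  expect_equal(model_loglik(c(1, 0), alpha = 0, beta = 2, s = c(1, 0)),
               -0.8201, tolerance = 1e-4)
  # nesting: beta -> 0 reproduces the baseline likelihood
  expect_equal(model_loglik(c(1, 0, 1), alpha = -0.3, beta = 1e-14,
                            s = c(0.2, 0.9, 0.4)),
               model_loglik(c(1, 0, 1), alpha = -0.3), tolerance = 1e-10)
  expect_error(model_loglik(c(1, 0), alpha = Inf), "finite")
})

test_that("offsets shift the intercept exactly", {
  set.seed(42)
  y <- rbinom(20, 1, 0.3)
  s <- runif(20)
  h <- rnorm(20)
  for (cc in c(-1.3, 0.7))
    expect_equal(model_loglik(y, alpha = 0.5, beta = 2, s = s, offsets = h + cc),
                 model_loglik(y, alpha = 0.5 + cc, beta = 2, s = s,
                              offsets = h),
                 tolerance = 1e-10)
})

test_that("uniform characteristic-phenotype prior is uniform over Phi(k)", {
  ont <- toy_ontology()
  terms <- c("A", "B", "C")
  pr <- prior_config(k = 2)
  # Phi(2) has 5 members -> each gets prior 1/5
  for (phi in list("A", "B", "C", c("A", "C"), c("B", "C")))
    expect_equal(log_prior_phi(ont, phi, pr, terms), log(1 / 5))
  pr1 <- prior_config(k = 1)
  expect_equal(log_prior_phi(ont, "B", pr1, terms), log(1 / 3))
  expect_error(log_prior_phi(ont, c("A", "B"), pr, terms), "not a minimal")
  expect_error(log_prior_phi(ont, c("A", "B", "C"), pr1, terms), "between 1")
})

test_that("prior over phi sums to 1, uniform and literature-weighted", {
  for (seed in 1:3) {
    ont <- random_ontology(10, seed = seed)
    set.seed(seed)
    phen <- replicate(8, sample(ont$id, 2), simplify = FALSE)
    ic <- information_content(ont, phen)
    terms <- usable_terms(ont, ic)
    if (length(terms) < 4) next
    lit <- sample(terms, 2)
    for (pr in list(prior_config(k = 2),
                    prior_config(k = 2, literature = lit, lit_rate = 1.5))) {
      sets <- enumerate_min_sets(ont, pr$k, terms)
      total <- sum(vapply(sets, function(phi)
        exp(log_prior_phi(ont, phi, pr, terms, ic)), 1))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("literature weighting up-weights phenotypes similar to M", {
  ont <- toy_ontology()
  ic <- toy_ic(ont)
  terms <- c("A", "B", "C")
  pr <- prior_config(k = 2, literature = c("B", "C"), lit_rate = 2)
  lp <- vapply(enumerate_min_sets(ont, 2, terms), function(phi)
    log_prior_phi(ont, phi, pr, terms, ic), 1)
  sets <- enumerate_min_sets(ont, 2, terms)
  labels <- vapply(sets, paste, "", collapse = ",")
  # M itself carries the maximum prior mass
  expect_equal(labels[[which.max(lp)]], "B,C")
})

test_that("unrestricted-vector prior matches the preimage-division identity", {
  ont <- toy_ontology()
  terms <- c("A", "B", "C")
  pr <- prior_config(k = 2)
  expect_equal(log_prior_phi_tilde(ont, c("A", "B"), pr, terms),
               log(1 / 5) - log(3))
  pr1 <- prior_config(k = 1)
  expect_equal(log_prior_phi_tilde(ont, "C", pr1, terms),
               log_prior_phi(ont, "C", pr1, terms))
  # total mass over all of H^k is exactly 1 (9 vectors on the toy)
  vecs <- expand.grid(terms, terms, stringsAsFactors = FALSE)
  total <- sum(apply(vecs, 1, function(v)
    exp(log_prior_phi_tilde(ont, v, pr, terms))))
  expect_equal(total, 1, tolerance = 1e-12)
  # marginalization: preimages of each phi sum to P(phi)
  for (phi in list("B", c("A", "C"))) {
    pre <- apply(vecs, 1, function(v)
      setequal(minimal_set(ont, v), phi))
    expect_equal(sum(apply(vecs[pre, ], 1, function(v)
      exp(log_prior_phi_tilde(ont, v, pr, terms)))),
      exp(log_prior_phi(ont, phi, pr, terms)), tolerance = 1e-12)
  }
})

test_that("parameter log-prior combines normal, log-normal and support", {
  pr <- prior_config()
  # alpha at its mode, beta at the log-normal mode of log beta
  lp <- log_prior_params(0, exp(2), transform = NULL, prior = pr)
  expect_equal(lp, dnorm(0, 0, 5, log = TRUE) +
                 dnorm(2, 2, 1, log = TRUE) - 2, tolerance = 1e-12)
  expect_gt(log_prior_params(0, exp(2), prior = pr),
            log_prior_params(0, exp(5), prior = pr))
  expect_equal(log_prior_params(0, -1, prior = pr), -Inf)
  tp <- transform_params(1, 1, 1, 1)
  expect_equal(log_prior_params(0, exp(2), tp, pr),
               log_prior_params(0, exp(2), NULL, pr) +
                 sum(dnorm(0, pr$transform_log_mean, pr$transform_log_sd,
                           log = TRUE)), tolerance = 1e-12)
})

test_that("gamma full conditional follows the Carlin-Chib algebra", {
  expect_equal(gamma_full_conditional(-5, -3, 0), 0)
  expect_equal(gamma_full_conditional(-7.7, -7.7, 0.05), 0.05)
  expect_equal(gamma_full_conditional(log(2) - 1, -1, 0.5), 2 / 3)
  expect_gt(gamma_full_conditional(-1, -4, 0.05), 0.05)
  expect_equal(gamma_full_conditional(-Inf, -2, 0.5), 0)
  expect_equal(gamma_full_conditional(-2, -Inf, 0.5), 1)
})

test_that("literature normaliser: importance sampling agrees with enumeration", {
  ont <- random_ontology(12, seed = 9)
  set.seed(9)
  phen <- replicate(10, sample(ont$id, 2), simplify = FALSE)
  ic <- information_content(ont, phen)
  terms <- usable_terms(ont, ic)
  pr <- prior_config(k = 2, literature = sample(terms, 2))
  exact <- phenoreg:::lit_log_normaliser(ont, ic, pr, terms)
  set.seed(11)
  is_est <- phenoreg:::lit_log_normaliser(ont, ic, pr, terms,
                                          enumerate_limit = 0, n_is = 20000)
  expect_equal(is_est, exact, tolerance = 0.05)
})
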
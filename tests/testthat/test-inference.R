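# shared small test fixture: an ontology with a planted 3-term template
inference_fixture <- function(n_subjects = 200, n_rare = 10, r = 1,
                              gamma_true = 1, seed = 31) {
  ont <- random_ontology(50, seed = 30)
  cfg <- sim_config(ont, gamma_true = gamma_true, r = r,
                    n_subjects = n_subjects, n_rare = n_rare,
                    n_noise_base_terms = 12)
  coh <- simulate_cohort(ont, cfg, seed = seed)
  list(ont = ont, cfg = cfg, coh = coh)
}

test_that("fits are reproducible given the seed", {
  fx <- inference_fixture()
  f1 <- phenoreg(fx$coh, ontology = fx$ont, seed = 99,
                 control = quick_control())
  f2 <- phenoreg(fx$coh, ontology = fx$ont, seed = 99,
                 control = quick_control())
  expect_identical(f1$mean_gamma, f2$mean_gamma)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$marginal_inclusion, f2$marginal_inclusion)
})

test_that("pseudoprior tuning approximates the within-model posteriors", {
  fx <- inference_fixture()
  coh <- fx$coh
  phen <- lapply(coh$phenotypes, function(x) minimal_set(fx$ont, x))
  ic <- information_content(fx$ont, phen)
  prior <- prior_config()
  ctl <- mcmc_config(n_iter = 4000, n_burnin = 1000, pilot_iter = 2000,
                     pilot_burnin = 500)
  set.seed(41)
  prep <- phenoreg:::prepare_fit_data(fx$ont, phen, ic, prior)
  ps <- phenoreg:::tune_pseudopriors(coh$y, coh$offsets, prep, prior, ctl)
  # the baseline pseudoprior mean should sit near the analytic posterior
  # mode of alpha under gamma = 0 (approx. logit of the rare fraction)
  expect_lt(abs(ps$alpha0[1] - qlogis(mean(coh$y))), 4 * ps$alpha0[2])
  expect_true(all(is.finite(unlist(ps[c("alpha0", "alpha1", "log_beta")]))))
  expect_equal(sum(ps$phi_probs), 1, tolerance = 1e-12)
  # all y = 0 still yields finite pseudopriors (well-posedness)
  y0 <- integer(length(coh$y))
  ps0 <- phenoreg:::tune_pseudopriors(y0, coh$offsets, prep, prior, ctl)
  expect_true(all(is.finite(unlist(ps0[c("alpha0", "alpha1", "log_beta")]))))
})

test_that("summaries satisfy the inclusion-probability identities", {
  fx <- inference_fixture()
  fit <- phenoreg(fx$coh, ontology = fx$ont, seed = 51,
                  control = quick_control())
  expect_gte(fit$mean_gamma, 0); expect_lte(fit$mean_gamma, 1)
  marg <- fit$marginal_inclusion
  pw <- fit$pairwise_inclusion
  expect_true(all(marg >= 0 & marg <= 1))
  # symmetric, diagonal equals marginal, off-diagonals bounded by marginals
  expect_equal(pw, t(pw))
  expect_equal(diag(pw), marg[rownames(pw)])
  for (a in rownames(pw)) for (b in colnames(pw))
    expect_lte(pw[a, b], min(marg[[a]], marg[[b]]) + 1e-12)
})

test_that("a strongly associated cohort yields a confident association", {
  fx <- inference_fixture(n_subjects = 400, n_rare = 20, r = 1)
  fit <- phenoreg(fx$coh, ontology = fx$ont, seed = 61,
                  control = mcmc_config(n_iter = 3000, n_burnin = 1000,
                                        pilot_iter = 800, pilot_burnin = 300))
  expect_gt(fit$mean_gamma, 0.95)
  # the planted template terms dominate the characteristic phenotype
  top <- names(fit$marginal_inclusion)[1:3]
  expect_gte(length(intersect(top, fx$cfg$template)), 2)
})

test_that("subject relabelling leaves the posterior unchanged", {
  fx <- inference_fixture(n_subjects = 150, n_rare = 8)
  coh <- fx$coh
  set.seed(71)
  perm <- sample(length(coh$y))
  coh2 <- cohort(coh$subjects, coh$phenotypes[perm], coh$y[perm])
  f1 <- phenoreg(coh, ontology = fx$ont, seed = 72, control = quick_control())
  f2 <- phenoreg(coh2, ontology = fx$ont, seed = 72, control = quick_control())
  # identical data in permuted order: same IC, same posterior target; the
  # realized chains differ only through Monte Carlo noise
  expect_lt(abs(f1$mean_gamma - f2$mean_gamma),
            3 * (f1$diagnostics$mean_gamma_se + f2$diagnostics$mean_gamma_se
                 + 0.01))
})

test_that("posterior predictions separate carriers under association", {
  fx <- inference_fixture(n_subjects = 250, n_rare = 12, r = 1)
  fit <- phenoreg(fx$coh, ontology = fx$ont, seed = 81,
                  control = quick_control())
  p <- predict(fit)
  expect_length(p, 250)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[fx$coh$y == 1]), mean(p[fx$coh$y == 0]))
  # link scale is the logit of nothing other than the same eta average
  eta <- predict(fit, type = "link")
  expect_true(all(is.finite(eta)))
  # residuals complement fitted values
  r <- residuals(fit)
  expect_equal(unname(r), unname(fx$coh$y - fitted(fit)), tolerance = 1e-12)
  # new subjects: a template phenotype scores higher than an unrelated one
  nd <- list(tmpl = fx$cfg$template,
             none = setdiff(fx$ont$id, unlist(lapply(
               fx$cfg$template, term_ancestors, ontology = fx$ont)))[1:2])
  pn <- predict(fit, newdata = nd, ontology = fx$ont)
  expect_gt(pn[["tmpl"]], pn[["none"]])
  # posterior predictive simulation has the right shape
  yy <- simulate(fit, nsim = 3, seed = 82)
  expect_equal(dim(yy), c(250, 3))
  expect_true(all(yy %in% 0:1))
})

test_that("print, summary, coef and plot run on a fitted object", {
  fx <- inference_fixture(n_subjects = 120, n_rare = 8)
  fit <- phenoreg(fx$coh, ontology = fx$ont, seed = 91,
                  control = quick_control())
  expect_output(print(fit), "P\\(association")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.phenoreg")
  expect_output(print(sm), "posterior summary")
  cf <- coef(fit)
  expect_true(all(c("mean_gamma", "alpha0", "beta") %in% names(cf)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the gamma-marginal is robust to the pseudoprior tuning", {
  fx <- inference_fixture(n_subjects = 200, n_rare = 10, r = 2 / 3)
  coh <- fx$coh
  ctl_a <- mcmc_config(n_iter = 6000, n_burnin = 1500, pilot_iter = 1500,
                       pilot_burnin = 400, pseudo_mix_weight = 0.9)
  ctl_b <- mcmc_config(n_iter = 6000, n_burnin = 1500, pilot_iter = 600,
                       pilot_burnin = 200, pseudo_mix_weight = 0.5)
  fa <- phenoreg(coh, ontology = fx$ont, seed = 95, control = ctl_a)
  fb <- phenoreg(coh, ontology = fx$ont, seed = 96, control = ctl_b)
  se <- fa$diagnostics$mean_gamma_se + fb$diagnostics$mean_gamma_se
  expect_lt(abs(fa$mean_gamma - fb$mean_gamma), 3 * se + 0.05)
})

test_that("replicate chains agree by the Gelman-Rubin diagnostic", {
  fx <- inference_fixture(n_subjects = 120, n_rare = 8)
  fits <- lapply(c(201, 202, 203), function(s)
    phenoreg(fx$coh, ontology = fx$ont, seed = s, control = quick_control()))
  psrf <- gelman_rubin(fits)
  expect_true(is.finite(psrf))
  expect_lt(psrf, 1.2)
  expect_error(gelman_rubin(fits[1]), "at least two")
})
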
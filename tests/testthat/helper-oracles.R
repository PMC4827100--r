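# Toy ontologies and independent brute-force oracles used across the suite.

# root <- A <- B, plus root <- C
toy_ontology <- function() {
  phe_ontology(list(root = character(0), A = "root", B = "A", C = "root"))
}

# diamond: root <- {A, B} <- C
diamond_ontology <- function() {
  phe_ontology(list(root = character(0), A = "root", B = "root",
                    C = c("A", "B")))
}

# Cohort of 4 subjects chosen so that, with annotation propagation,
# freq(A) = 1/2, freq(B) = 1/4, freq(C) = 1/2, freq(root) = 1:
# ic(A) = ic(C) = log 2, ic(B) = 2 log 2, and s(A, B) = 2/3.
toy_phenotypes <- function() list(s1 = "B", s2 = "A", s3 = "C", s4 = "C")

toy_ic <- function(ont = toy_ontology())
  information_content(ont, toy_phenotypes())

# transitive closure by repeated parent lookup, independent of the
# package's precomputed ancestor lists
brute_ancestors <- function(parents, t) {
  out <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

brute_minimal <- function(parents, terms) {
  terms <- unique(terms)
  keep <- vapply(terms, function(t) {
    !any(vapply(setdiff(terms, t), function(u)
      t %in% setdiff(brute_ancestors(parents, u), u), TRUE))
  }, TRUE)
  sort(terms[keep])
}

# enumerate every ordered k-vector over `terms` and count those whose
# minimal reduction equals phi
brute_preimage <- function(ont, phi, k, terms) {
  grids <- rep(list(terms), k)
  vecs <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  sum(apply(vecs, 1, function(v) setequal(minimal_set(ont, v), phi)))
}

# nested-loop similarity straight from the definitions (no caching, no
# shared code with the package's vectorized path beyond lin_similarity's
# formula re-derived here)
brute_lin <- function(ont, ic, t1, t2) {
  common <- intersect(brute_ancestors(ont$parents, t1),
                      brute_ancestors(ont$parents, t2))
  d <- ic[[t1]] + ic[[t2]]
  if (d < 1e-12) 0 else 2 * max(ic[common]) / d
}

brute_similarity <- function(ont, ic, phi, x, trans = c(1, 1, 1, 1)) {
  restricted <- function(tp, tx) {
    if (!(tp %in% brute_ancestors(ont$parents, tx))) return(0)
    brute_lin(ont, ic, tp, tx)
  }
  if (!length(x)) return(list(s_phi = 0, s_x = 0, s = 0))
  sp <- mean(vapply(phi, function(tp)
    max(c(0, vapply(x, function(tx) restricted(tp, tx), 1))), 1))
  sx <- mean(vapply(x, function(tx)
    max(c(0, vapply(phi, function(tp) restricted(tp, tx), 1))), 1))
  list(s_phi = sp, s_x = sx,
       s = pbeta(sp, trans[1], trans[2]) * pbeta(sx, trans[3], trans[4]))
}

# Exhaustive posterior over (gamma, phi, alpha, beta) for k = 1, fixed
# transforms and discrete uniform grids on alpha and beta: the enumeration
# oracle the sampler is validated against. Uses only R-level package
# pieces (model_loglik, overall_similarity), not the C++ sampler.
enumerate_posterior <- function(ont, ic, phenotypes, y, alpha_grid, beta_grid,
                                trans, pi) {
  usable <- usable_terms(ont, ic)
  params <- transform_params(trans[1], trans[2], trans[3], trans[4])
  z0 <- sum(vapply(alpha_grid, function(a)
    exp(model_loglik(y, a)), 1)) / length(alpha_grid)
  s_by_phi <- lapply(usable, function(t)
    vapply(phenotypes, function(x)
      overall_similarity(ont, ic, t, x, params)$s, 1))
  z1_by_phi <- vapply(seq_along(usable), function(j) {
    s <- s_by_phi[[j]]
    mean(outer(alpha_grid, beta_grid, Vectorize(function(a, b)
      exp(model_loglik(y, a, b, s)))))
  }, 1)
  z1 <- mean(z1_by_phi)  # uniform prior over singleton phi
  post_gamma <- pi * z1 / (pi * z1 + (1 - pi) * z0)
  list(post_gamma = post_gamma,
       post_phi = structure(z1_by_phi / sum(z1_by_phi), names = usable))
}

# Cheap fit settings for unit tests (not the package defaults)
quick_control <- function(...) {
  mcmc_config(n_iter = 1200, n_burnin = 400, pilot_iter = 400,
              pilot_burnin = 150, ...)
}
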
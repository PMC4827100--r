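#' Lin similarity between two terms
#'
#' `s(t1, t2) = 2 max_{t in anc(t1) ^ anc(t2)} IC(t) / (IC(t1) + IC(t2))`,
#' the classical information-theoretic term similarity. Because IC is
#' monotone non-decreasing along descent, the value lies in `[0, 1]`. When
#' both terms carry zero IC (e.g. both are the root) the similarity is
#' defined as 0.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param ic Named IC vector from [information_content()].
#' @param t1,t2 Single term IDs with finite IC.
#' @return Similarity in `[0, 1]`.
#' @export
lin_similarity <- function(ontology, ic, t1, t2) {
  t1 <- resolve_terms(ontology, t1); t2 <- resolve_terms(ontology, t2)
  if (!is.finite(ic[[t1]]) || !is.finite(ic[[t2]]))
    stop("Lin similarity requires terms with finite IC (got ",
         t1, ": ", ic[[t1]], ", ", t2, ": ", ic[[t2]], ")")
  denom <- ic[[t1]] + ic[[t2]]
  if (denom < 1e-12) return(0)
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  2 * max(ic[common]) / denom
}

# Restricted pairwise similarity s(tphi, tx) * 1[tphi in anc(tx)].
# When tphi is an ancestor of tx the best common ancestor is tphi itself,
# so the value collapses to 2 IC(tphi) / (IC(tphi) + IC(tx)).
restricted_pair_sim <- function(ontology, ic, tphi, tx) {
  if (!tphi %in% ontology$ancestors[[tx]]) return(0)
  denom <- ic[[tphi]] + ic[[tx]]
  if (denom < 1e-12) return(0)
  2 * ic[[tphi]] / denom
}

#' Asymmetric best-match similarity from the characteristic phenotype
#'
#' `S_phi(phi -> x) = (1/|phi|) sum_{t_phi} max_{t_x} s(t_phi, t_x)
#' 1[t_phi in anc(t_x)]`: each characteristic term is credited with its best
#' match among the subject's terms, but only when it is an ancestor of (or
#' equal to) that match, which penalises over-specific characteristic
#' phenotypes. The max over an empty candidate set is 0, so an empty
#' subject phenotype scores 0.
#'
#' @param ontology A `"phe_ontology"` object.
#' @param ic Named IC vector.
#' @param phi Nonempty minimal set (character vector).
#' @param x Subject phenotype (character vector, may be empty).
#' @return Similarity in `[0, 1]`.
#' @export
asym_sim_phi <- function(ontology, ic, phi, x) {
  if (!length(phi)) stop("'phi' must be nonempty")
  phi <- resolve_terms(ontology, phi)
  if (!length(x)) return(0)
  x <- resolve_terms(ontology, x)
  best <- vapply(phi, function(tp)
    max(vapply(x, function(tx)
      restricted_pair_sim(ontology, ic, tp, tx), 1)), 1)
  mean(best)
}

#' Asymmetric best-match similarity from the subject phenotype
#'
#' `S_x(x -> phi) = (1/|x|) sum_{t_x} max_{t_phi} s(t_x, t_phi)
#' 1[t_phi in anc(t_x)]`: the mirror of [asym_sim_phi()], averaging over the
#' subject's terms; the indicator still requires the characteristic term to
#' be an ancestor of the subject term. An empty subject phenotype returns 0
#' by convention (empty sum).
#'
#' @inheritParams asym_sim_phi
#' @return Similarity in `[0, 1]`.
#' @export
asym_sim_x <- function(ontology, ic, x, phi) {
  if (!length(phi)) stop("'phi' must be nonempty")
  phi <- resolve_terms(ontology, phi)
  if (!length(x)) return(0)
  x <- resolve_terms(ontology, x)
  best <- vapply(x, function(tx)
    max(vapply(phi, function(tp)
      restricted_pair_sim(ontology, ic, tp, tx), 1)), 1)
  mean(best)
}

#' Regularized incomplete beta function (beta CDF)
#'
#' The shape transform applied to the asymmetric similarities: the beta CDF
#' `I_z(a, b)` maps `[0, 1]` onto `[0, 1]` monotonically and accommodates
#' convex, concave and sigmoid shapes as `(a, b)` vary.
#'
#' @param z Value(s) in `[0, 1]`.
#' @param a,b Strictly positive shape parameters.
#' @return `I_z(a, b)`.
#' @export
beta_cdf <- function(z, a, b) {
  if (any(a <= 0) || any(b <= 0))
    stop("beta CDF shape parameters must be strictly positive")
  if (any(z < 0 | z > 1)) stop("'z' must lie in [0, 1]")
  stats::pbeta(z, a, b)
}

#' Transform parameters for the similarity shape functions
#'
#' @param a_f,b_f Shape parameters of the transform applied to
#'   `S_phi(phi -> x)`.
#' @param a_g,b_g Shape parameters of the transform applied to
#'   `S_x(x -> phi)`.
#' @return A named list of class `"phe_transform"`.
#' @export
transform_params <- function(a_f = 1, b_f = 1, a_g = 1, b_g = 1) {
  v <- c(a_f = a_f, b_f = b_f, a_g = a_g, b_g = b_g)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all four transform parameters must be finite and > 0")
  structure(as.list(v), class = "phe_transform")
}

#' Overall similarity between a subject and the characteristic phenotype
#'
#' `S(phi, x) = f(S_phi(phi -> x)) * g(S_x(x -> phi))` with `f`, `g` beta
#' CDFs. The multiplicative form means the overall similarity is high only
#' when both asymmetric similarities are high; either component at 0 forces
#' `S = 0`.
#'
#' @inheritParams asym_sim_phi
#' @param params A `"phe_transform"` object from [transform_params()].
#' @return List with components `s_phi`, `s_x` and `s`.
#' @export
overall_similarity <- function(ontology, ic, phi, x, params = transform_params()) {
  stopifnot(inherits(params, "phe_transform"))
  sp <- asym_sim_phi(ontology, ic, phi, x)
  sx <- asym_sim_x(ontology, ic, x, phi)
  list(s_phi = sp, s_x = sx,
       s = beta_cdf(sp, params$a_f, params$b_f) *
           beta_cdf(sx, params$a_g, params$b_g))
}

# ---- internal: packed similarity data for the sampler --------------------
#
# Builds the U x D matrix of restricted pairwise similarities
# P[t, d] = s(t, d) 1[t in anc(d)] between every usable term t and every
# distinct annotated term d, plus integer-indexed subject phenotypes.
# All heavy per-iteration similarity work in the sampler runs off this.
build_sim_data <- function(ontology, ic, phenotypes, usable) {
  dterms <- unique(unlist(phenotypes, use.names = FALSE))
  dterms <- dterms[order(match(dterms, ontology$id))]
  U <- length(usable); D <- length(dterms)
  P <- matrix(0, nrow = U, ncol = D, dimnames = list(usable, dterms))
  for (j in seq_len(D)) {
    d <- dterms[[j]]
    anc <- intersect(ontology$ancestors[[d]], usable)
    if (!length(anc)) next
    denom <- ic[anc] + ic[[d]]
    v <- ifelse(denom < 1e-12, 0, 2 * ic[anc] / denom)
    P[anc, j] <- v
  }
  x_idx <- lapply(phenotypes, function(x)
    match(x, dterms))
  list(P = P, usable = usable, dterms = dterms, x_idx = x_idx)
}
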
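# phenoreg

Bayesian **phenotype similarity regression** for rare-disease genetics: test
whether carriers of a rare genotype (for a gene, or any genomic grouping)
cluster around a *characteristic phenotype* — a small set of ontology terms —
and estimate that phenotype at the same time.

## Who this is for

Rare-disease sequencing studies code each patient's clinical presentation as
a set of terms from an ontology such as the Human Phenotype Ontology (HPO), a
rooted DAG in which specific terms imply their more general ancestors.
Standard rare-variant association tests need the disease phenotype specified
*a priori* as a single variable; with heterogeneous, multi-system disorders
that choice is both arbitrary and lossy. `phenoreg` is for analysts who have
per-subject HPO-style term sets plus rare-variant genotypes and want a
per-gene probability of association that uses the full ontological structure
of the phenotype without pre-specifying the disease.

## The model

Genotype is regressed on phenotype (inverse regression). With binary
genotypes `y_i` (1 = rare genotype), minimal-set phenotypes `x_i`, optional
per-subject offsets `h_i`, and a model indicator `γ`:

    y_i ~ Bernoulli(p_i)
    γ = 0:  logit p_i = α + h_i
    γ = 1:  logit p_i = α + h_i + β · S(φ, x_i)

`φ` is the latent characteristic phenotype: an antichain of at most `k = 3`
ontology terms with a uniform prior over all such sets (optionally
up-weighted toward a literature phenotype). The similarity

    S(φ, x) = f(S_φ(φ→x); a_f, b_f) · g(S_x(x→φ); a_g, b_g)

multiplies two asymmetric, ancestor-restricted best-match Lin similarities,
each warped by an estimated beta-CDF shape, so similarity is high only when
the subject matches `φ` *and* `φ` accounts for the subject's terms.
Priors: `γ ~ Bernoulli(π = 0.05)`, `α ~ N(0, 5²)`, `log β ~ N(2, 1)`,
log-normal priors on the four shape parameters. Inference is by Carlin–Chib
MCMC (compiled sampler), which keeps both models in the chain, draws `γ`
from its full conditional, and refreshes the inactive model's parameters
from pilot-tuned pseudopriors. The headline output is the posterior mean of
`γ` — the probability of association — plus per-term and pairwise inclusion
probabilities for `φ`. See the methods vignette
(`vignettes/phenotype-similarity-regression.Rmd`) for the full model,
priors and design decisions.

## Worked example

Simulate a 500-subject cohort in which the 10 rare-genotype carriers express
a 3-term disease template with probability 2/3 per term, buried in Poisson
noise terms, and fit the regression:

```r
library(phenoreg)

ont <- random_ontology(400, seed = 42)          # synthetic ontology
cfg <- sim_config(ont, gamma_true = 1, r = 2/3, n_subjects = 500,
                  n_rare = 10, n_noise_base_terms = 60)
coh <- simulate_cohort(ont, cfg, seed = 43)
cfg$template
#> [1] "SYN:0000308" "SYN:0000188" "SYN:0000267"

fit <- phenoreg(coh, ontology = ont, seed = 44)
fit
#> Phenotype similarity regression
#>   subjects: 500 (10 rare genotype)
#>   P(association | data) = 1  [prior 0.05]
#>   top characteristic-phenotype terms (P(term in phi | assoc)):
#>     SYN:0000267              0.899
#>     SYN:0000308              0.837
#>     SYN:0000188              0.747
#>     SYN:0000146              0.169
#>     SYN:0000129              0.101
```

The probability of association is 1 and the three template terms dominate
the estimated characteristic phenotype — the fit recovers both the fact and
the content of the planted association. Posterior parameter means
(`coef(fit)`) show the similarity effect (`beta ≈ 16.7`) and the estimated
transform shapes; `predict(fit)` returns each subject's posterior
probability of carrying the rare genotype (0.67 on average for true
carriers versus 0.008 for the rest in this run). `summary()`, `plot()`,
`residuals()` and `simulate()` behave as for other fitted-model classes,
and `write_fit()` exports the summaries as JSON/TSV.

Real-data inputs come in through `read_obo()` (ontology), `read_phenotypes()`
(subject–term TSV), and `filter_variants()`/`encode_genotypes()` (annotated
rare-variant table → binary genotypes under dominant, recessive or
high-impact dominant inheritance), with `estimate_offsets()` supplying
batch-effect offsets.

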
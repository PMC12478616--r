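# gbdcm — generalized Bayesian estimation for diagnostic classification models

Diagnostic classification models (DCMs) infer which binary skills
("attributes") each examinee has mastered from binary test responses and a
Q-matrix saying which attributes each item requires. Nonparametric
classifiers — NPC (Hamming distance to conjunctive DINA ideal responses)
and GNPC (squared-Euclidean distance to weighted DINA/DINO ideal
responses) — are popular because they need no item response function, but
they return bare point classifications with no uncertainty.

`gbdcm` treats the same losses as the engine of a *generalized* (Gibbs)
posterior,

```
p(alpha, pi, w | X)  ∝  exp{ -ω · L(X; alpha, w) } · Π_i pi_{c_i} · p(pi) · p(w),
```

where `L` is the summed classification loss, `ω` the learning rate that
tempers data against prior, `pi` the latent-class mixing proportions
(Dirichlet prior) and `w` the DINA/DINO blending weights (independent Beta
priors at the positions where the two ideals differ). A
Metropolis–Hastings-within-Gibbs chain then yields per-person posterior
attribute mastery *probabilities* — so a diagnosis of "mastered, but at
0.52" can be distinguished from "mastered at 0.99".

The package provides, for audiences in psychometrics / educational
measurement and anyone fitting restricted latent class models:

* `gbdcm()` — the generalized Bayesian sampler; `loss = "hamming"` (GBNPC)
  or `loss = "sq_euclid"` (GBGNPC); S3 methods `print`, `summary`, `coef`,
  `plot`, `fitted`, `residuals`, plus `classify()`.
* `npc()`, `gnpc()` — the nonparametric point estimators (also the
  sampler's initializers).
* `map_dcm()` — MAP / joint-maximum-likelihood coordinate descent under
  the Q-matrix constraint.
* `sim_dcm()`, `sim_q_matrix()`, `run_design()` — the factorial
  recovery-study generator (correlated attributes from a thresholded
  compound-symmetry normal; DINA or general monotone item probabilities
  with high `(0.1, 0.9)` / low `(0.3, 0.7)` quality endpoints).
* `attribute_agreement()`, `pattern_agreement()`,
  `half_split_correlation()`, `tabulate_patterns()`, `cross_tab()` —
  recovery and stability metrics.
* `read_q_matrix()`, `read_responses()`, `write_gbdcm()` — CSV interface
  and a JSON run manifest sufficient to re-run a fit bit-identically.

## Worked example

Simulate one cell of a recovery study (300 examinees, 20 items, 4
correlated attributes, low-quality items generated from a general monotone
DCM) and fit the GBGNPC:

```r
library(gbdcm)

Q   <- sim_q_matrix(c(8, 6, 5, 1), K = 4)   # 8 one- ... 1 four-attribute item
dat <- sim_dcm(300, Q, model = "general", quality = "low", rho = 0.8, seed = 20)
fit <- gbdcm(dat$X, Q, loss = "sq_euclid", seed = 20)
fit
#> Generalized Bayesian diagnostic classification: GBGNPC (squared-Euclidean loss)
#>   300 examinees, 20 items, 4 attributes (16 classes)
#>   1000 iterations (500 retained), learning rate 1, init gnpc
#>   weight MH acceptance rate 0.933
#>   mean half-split stability correlation 0.9848
```

The half-split correlation (first vs second half of the retained draws)
near 1 says the chain is stable; the acceptance rate refers to the weight
random-walk step. Posterior mastery probabilities are per person and
attribute:

```r
round(head(fit$attr_prob, 3), 3)
#>         A1    A2    A3    A4
#> [1,] 0.999 0.200 0.997 0.953
#> [2,] 0.886 0.197 0.085 0.203
#> [3,] 0.996 0.983 0.719 0.077
```

Person 3's third attribute (0.719) is mastered but with visible
uncertainty — the information a point classifier discards. Scoring against
the generating truth and comparing with the nonparametric baseline:

```r
attribute_agreement(fit$classification, dat$alpha)   # 0.816
pattern_agreement(fit$classification, dat$alpha)     # 0.433
attribute_agreement(npc(dat$X, Q)$pattern, dat$alpha) # 0.769
```

Under these low-quality, correlated-attribute conditions the generalized
Bayesian fit recovers more attribute masteries than the NPC baseline.
Real datasets enter through the same interface from CSV
(`read_q_matrix()`, `read_responses()`), e.g. the 2,922 × 28 three-attribute
English proficiency (ECPE) responses as exported from existing DCM
toolkits.

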
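---
title: "Inferring regulatory networks from multi-omics data with bnomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks from multi-omics data with bnomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnomics)
```

## The inference problem

`bnomics` reconstructs gene regulatory networks from three matched data
layers measured on the same individuals: gene expression (GE), copy-number
variation (CNV, segment-mean values) and DNA methylation (METH, beta-values
in $[0,1]$). The model is a Gaussian Bayesian network over typed nodes. GE
nodes may be regulated by up to three other GE nodes, by the CNV node of
their own gene (copy-number gains and losses act on expression through gene
dosage, hence the positive-effect expectation), and by methylation probes of
their own gene (promoter methylation typically represses transcription).
CNV and METH nodes are exogenous: they never have parents. These
type constraints encode the biology — transcription is controlled by few
regulators, while copy number and methylation are causes, not consequences,
of expression on the timescale of one snapshot — and they shrink the search
space substantially.

The posterior over structures $G$ is

$$P(G \mid D, \beta) \propto P(D \mid G)\, P(G \mid \beta),$$

with a BGe marginal likelihood and an energy-based knowledge prior, sampled
by Metropolis–Hastings over DAG space.

## The BGe score

$P(D\mid G)$ factorises over nodes under the normal–Wishart conjugate
model. We use the score-equivalent (corrected) normalisation; the
contribution of node $j$ with parent set $Pa_j$ is the ratio of two subset
marginals, $\log p(d^{\,Pa_j \cup \{j\}}) - \log p(d^{\,Pa_j})$, each a
closed form in the determinant of a submatrix of the posterior parametric
matrix $R = T + S + \frac{n\alpha_\mu}{n+\alpha_\mu}\bar x \bar x^\top$.
Working with subset marginals makes score equivalence of Markov-equivalent
DAGs an algebraic identity rather than a numerical accident, which the test
suite confirms to $10^{-8}$ by exhaustive enumeration of the three-node
equivalence classes and against a one-dimensional numerical integration of
the normal–gamma marginal.

Hyperparameters are the standard defaults of the BGe literature:
$\alpha_\mu = 1$, $\alpha_w = N + 2$, prior mean zero on
column-standardised data, and $T = t I$ with
$t = \alpha_\mu(\alpha_w - N - 1)/(\alpha_\mu + 1)$, the value that
preserves score equivalence. All columns are standardised once at problem
assembly; methylation beta-values are first mapped to normal scores by the
ordered quantile transform $\Phi^{-1}((r_i - 0.5)/n)$ (average ranks on
ties), since beta-values are bounded and skewed while the score assumes
joint Gaussianity. The $T = tI$ ridge keeps subset scatter matrices
positive definite, so perfectly collinear parents yield a finite score
rather than `NaN`.

## The knowledge prior

Prior knowledge enters as a matrix $B$ over admissible ordered pairs:
$B_{ij} = 1$ for a documented direct interaction, $0.75$ for a
transcription-factor/target pair, $0$ for a documented non-edge, $0.5$ for
"no knowledge". The energy of a structure,

$$E(G) = \sum_j \Big[ \sum_{i \in Pa_j} (1 - B_{ij}) +
  \sum_{i \in C_j \setminus Pa_j} B_{ij} \Big],$$

counts disagreement with $B$ (candidate sets $C_j$ are the admissible
parents of $j$), and the prior is $P(G\mid\beta) = e^{-\beta E(G)}/Z(\beta)$.
The normaliser is intractable over acyclic structures, so the
node-decomposable upper bound $\prod_j \sum_{Pa_j} e^{-\beta\varepsilon_j}$
is used, with the inner sums computed per parent type via elementary
symmetric polynomials under the cardinality caps (a small dynamic programme,
evaluated stably in the log domain). Two deliberate design points:

* Every admissible pair carries a $B$ entry, including CNV→GE and METH→GE
  pairs, initialised at 0.5 — no interaction database covers those layers,
  and they are exactly the entries the empirical-knowledge phase fills in.
* Type-forbidden edges are excluded from the move space entirely (no $B$
  entry), whereas $B_{ij} = 0$ on an admissible pair is a soft penalty.
  This keeps the prior normalisable over the space the sampler actually
  explores.

The strength $\beta$ is itself sampled (Gaussian random-walk proposals,
accepted by the prior ratio $-\Delta\beta\,E(G) - \Delta\log Z$). Its
support is truncated to $[0.5, 10]$. The lower bound keeps the prior
relevant. The upper bound, matching the $U[0,10]$ initialisation, is needed
for propriety: whenever the current structure attains the per-node minimum
energy — always true under a no-knowledge prior, where every parent set has
equal energy — the conditional of $\beta$ is flat and an unbounded support
would let $\beta$ random-walk to arbitrarily large values, freezing the
subsequent sampling phase into near-hard constraints. We observed exactly
this failure mode before bounding the support.

## Proposal kernels

Single-edge moves (add / delete / reverse) are drawn uniformly from the
valid neighbourhood — all moves that respect acyclicity, type
admissibility and the parent caps — with the exact Hastings correction
$|N(G_s)|/|N(G_c)|$. Reversals are offered only where the reversed pair is
itself admissible, hence only for GE–GE edges. With probability
$p_{\mathrm{MBR}} = 1/15$ a Markov-blanket-resampling move replaces the
single-edge move: a GE node is chosen uniformly, its parent set and its
children's parent sets are detached and redrawn sequentially in proportion
to $e^{\text{BGe node score}}$ over admissible, acyclicity-preserving,
cap-respecting parent sets (children are constrained to keep the resampled
node as a parent, and the resampled node may not adopt a current child as a
parent — both required for the reverse move to exist). The exact reverse-path
probability is obtained by replaying the same construction towards the
original parent sets; if no admissible reassignment exists the move
degenerates to the identity with ratio 0. The test suite audits the
combined kernel by detailed balance on all three-node transitions
($10^{-10}$) and by comparing long-run edge posteriors against exhaustive
enumeration of all 25 three-node and 543 four-node DAGs ($\pm 0.03$).

## The four phases

1. **Rough adaptation** (default 2,000 iterations): structure and $\beta$
   moves interleave; every 100 $\beta$ proposals the proposal s.d.
   ($\sigma$, initial value 5) is scaled by $e^{\pm 0.5}$ to steer the
   acceptance rate into $[0.28, 0.60]$, the band around the scalar-optimal
   0.44.
2. **Transient detection**: the chain runs in windows (default 500
   iterations) until a Geweke-style standardised mean difference between
   the last two windows of the log-posterior trace drops below 1.96.
3. **Fine adaptation** (default 10,000 iterations): $\sigma$ tuning
   continues with $e^{\pm 0.1}$ steps; after every single-edge proposal the
   per-pair counts are updated — proposing an edge increments $f_{ij}$,
   and the outcome increments $a_{ij}$ whenever it constitutes evidence
   *for* the edge: an accepted addition, a rejected deletion; a reversal
   is bookkept as deleting $i\!\to\!j$ and adding $j\!\to\!i$. The
   empirical knowledge is $\hat B_{ij} = a_{ij}/f_{ij}$ (0.5 where never
   proposed); it replaces the $B$ entries of unknown provenance at the end
   of the phase — not during it, which would make the target distribution
   non-Markovian — while database, TF and forbidden entries are kept
   verbatim. The $\beta$ point estimate is the phase mean.
4. **Sampling** (default 200,000 iterations per chain, two independent
   chains): $\beta$ is fixed and a greedy horizon is applied — three
   independent 500-iteration paths of the full kernel are spawned from the
   current state and the highest-posterior endpoint is kept. Structures
   are thinned every 500 iterations and the first 100,000 iterations are
   flagged as burn-in.

Sampled DAGs are converted to CPDAGs (order-based compelled-edge
labelling, verified against a brute-force equivalence-class oracle on all
DAGs of up to four nodes), deduplicated per chain post burn-in, pooled, and
summarised as edge weights — the empirical frequency of each ordered pair,
with an undirected CPDAG edge counting towards both directions so that
reversible evidence is never discarded. Reported edges are those at or
above the 0.75 type-7 quantile of the positive weights.

Convergence is monitored by $c_{\mathrm{rms}}$: at each thinned index the
root-mean-square difference between the two chains' running edge
frequencies (computed on the un-deduplicated thinned CPDAG snapshots). The
chains stop when each of the last 100 values lies below the third quartile
of the successive absolute differences; otherwise sampling is extended in
blocks of 50,000 iterations. A perfectly constant series has threshold 0
and never stops by the strict inequality — callers should recognise
identical chains separately; in practice the series always carries jitter.

## Methylation preprocessing

Probes become METH nodes only if they pass a per-probe linear screen
against their own gene's expression: slope p-value below `meth_p_threshold`
and $R^2 > 0.3$, computed on ordered-quantile-transformed probe values (the
transform is applied before the regression; the screen is invariant to
affine rescaling of expression). The default significance level is 0.05;
a looser 0.5 can be configured. Where two sample groups are available, the
two-group filter keeps probes with a Welch-test p-value below 0.05 and
$|\Delta\beta|$ at or above the 0.75 quantile of all $|\Delta\beta|$
(at-or-above, so a vacuous quantile of 0 keeps everything).

## The synthetic benchmark

The generator emulates the mechanisms the model targets: a random GE–GE
DAG under the parent cap (edge density 0.25 by default), positive CNV
dosage effects on the own gene, methylation effects on the own gene
(negative by default, configurable — gene-body methylation can act in
either direction), linear-Gaussian structural equations with unit noise and
coefficients drawn from $\pm U[0.3, 1]$ (bounded away from zero so every
edge is in principle detectable at moderate sample size). METH nodes are
generated in a latent Gaussian space and observed through the logistic
function as beta-values, so the ordered quantile transform approximately
recovers the latent scale. Prior corruption reveals a uniformly random
`floor(keep_fraction * n_edges)` subset of true GE–GE edges as $B = 1$.

What passing the synthetic tests does and does not show: the generator is
linear-Gaussian by construction — exactly the BGe model class — so recovery
there demonstrates the correctness of the sampler and scoring, not
robustness to the nonlinearities, heavy tails, batch structure and
measurement error of real tumour data. The standard operating point used
in the tests and in `scripts/acceptance.R` is 10 genes, 4 CNV profiles, 6
methylation probes, 100 samples and a half-revealed prior; with sampling
shortened to 20,000 iterations per chain (the problem is small and mixes
quickly; full-length defaults remain 200,000) the mean GE–GE AUC across
seeds is required to reach 0.70, the half prior may not hurt relative to no
prior, and strong (coefficient 0.9) dosage links must outweigh the median
admissible-pair weight.

Evaluation metrics follow standard practice: rank-formulation AUC over an
explicit pair universe (the universe matters — inadmissible pairs and
self-pairs are excluded, and a GE-only restriction is available for
comparing against expression-only methods), 83% confidence intervals by
the Hanley–McNeil normal approximation (the level at which interval
disjointness approximates a 5% pairwise test; a bootstrap alternative is
provided), and Cohen's $\kappa$ for method agreement.

## Numerical and degenerate-input conventions

* Ties in the ordered quantile transform take average ranks; the offset
  $(r - 0.5)/n$ avoids infinite normal scores; an all-constant vector is an
  error.
* Zero-variance features are dropped at load with a message (the score and
  the regressions are undefined for them).
* Sample alignment is by identifier intersection, in GE order.
* Identical-group differential methylation yields $p = 1$, $\Delta\beta = 0$
  and an empty selection.
* Quantile thresholds use R's default type-7 (linear interpolation)
  convention throughout.
* All chain randomness flows from a single integer seed; chain-specific
  seeds are small fixed offsets, and identical seeds reproduce runs
  bit for bit.

## Known limitations

* The partition function is an upper bound, not the acyclic sum; the prior
  is therefore slightly flatter than nominal. Ratios between structures at
  fixed $\beta$ are exact (the bound cancels), only $\beta$ moves feel it.
* Edge weights from CPDAG frequencies attribute undirected evidence to
  both directions; a direction-blind consumer should symmetrise first.
* Empirical knowledge $\hat B$ is a finite-sample acceptance ratio: pairs
  proposed rarely during the fine-adaptation phase carry noisy estimates.
* Parent-set enumeration inside the Markov-blanket move grows with the
  candidate count (capped at 50,000 sets per node); problems far beyond
  ~40 genes need the single-edge kernel alone or a longer runtime.
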
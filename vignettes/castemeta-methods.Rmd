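---
title: "Methods: cross-species detection of a reproductive toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species detection of a reproductive toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the design

Rudimentary insect societies — small nests of paper wasps, small carpenter
bees, sweat bees — contain females that lay eggs and females that do not.
A long-standing hypothesis holds that a conserved "genetic toolkit"
underlies this reproductive division of labour across independently
evolved social lineages. Testing it requires comparing brain expression of
reproductive and non-reproductive females across species separated by up
to ~200 My, where conventional per-species differential expression finds
almost nothing in common.

`castemeta` implements a standardized meta-analysis over a multi-species
design: per-species RNA-seq count matrices are collapsed to nearly
single-copy orthogroups (at most 3 gene copies per species, absent from at
most one species), variance-stabilized with species awareness, and passed
to three complementary detection arms:

1. **PCA trait screening** — are the dominant expression axes phylogenetic
   or phenotypic?
2. **Leave-one-species-out SVM recursive feature elimination** — which
   genes predict phenotype in a species the classifier has never seen?
3. **Consensus weighted co-expression networks** — which co-expression
   modules, preserved across all species, track phenotype?

with a per-species negative-binomial differential expression baseline, and
the putative toolkit defined as the intersection of the SVM and network
arms.

## The synthetic study and what it does (not) emulate

Because the real study's inputs are six external sequencing archives plus
genome-scale orthology inference, the package validates itself on a
synthetic generator with planted truth (`simulate_dataset()`). Counts for
gene $g$ in sample $j$ of species $s$ are

$$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
\mu_{gj} = L_j \exp\!\big(b_g + c_{g,\mathrm{clade}(s)} + e_{gs}
  + l_g f_j + \ln 2 \cdot \lambda_{gs} \cdot \mathrm{pheno}_j\big)$$

with variance $\mu + \alpha\mu^2$. Defaults, chosen once as the package's
study conditions:

* **Baseline** $b_g \sim N(\ln 150, 1.2^2)$ — a realistic spread of
  orthogroup expression levels.
* **Species and clade shifts** $e_{gs} \sim N(0, 0.9^2)$,
  $c \sim N(0, 0.4^2)$ (natural log). Cross-species expression divergence
  dominates everything else, as it does in the real data, where
  phylogeny accounts for the overwhelming majority of expression variance;
  principal components correlated with species/clade carry > 50% of
  variance under these defaults.
* **Dispersion** $\alpha_g \sim \mathrm{logNormal}(\ln 0.2, 0.7)$ —
  typical of field-collected, cross-study insect RNA-seq, far noisier than
  inbred-line experiments.
* **Library sizes** log-uniform on $[0.5, 2]$, exercising size-factor
  normalization.
* **Toolkit genes** (default 40): a per-gene sign (fixed across species)
  and a per-species realized magnitude
  $\lambda_{gs} = \mathrm{sign}_g \cdot \mathrm{lfc} \cdot
  \max(N(1, 1/3), 0.25)$. Conserved effects differ in strength, not
  direction, between species; the truth object records every realized
  value. Because the magnitude scales with the nominal lfc, a null
  configuration is exactly null.
* **Clade-specific genes**: the same construction restricted to one clade.
* **Modules** (default 8 of 20-40 genes): per-sample latent factors
  $f_j \sim N(\delta \cdot \mathrm{pheno}_j, 1)$ with loadings
  $l_g \sim \pm U(0.5, 1)$, loading signs fixed across species so that
  consensus co-expression exists; trait modules have $\delta = 0.8$,
  others $\delta = 0$.

What passing tests on this generator do **not** show: robustness to
orthology errors, to tissue or platform heterogeneity between studies, to
unbalanced and small designs beyond the 3-12 samples per phenotype the
configuration enforces, or to phylogenetic correlation of effect sizes
(species are exchangeable here; there is no branch-length model).

## Preprocessing

Size factors are median-of-ratios over genes expressed in all samples,
with a total-count fallback. The variance-stabilizing transform uses the
closed form

$$g(q) = \log_2 \frac{1 + b + 2aq + 2\sqrt{aq(1 + b + aq)}}{4a}$$

which is $\int dq / \sqrt{q(1+b) + aq^2}$ — the exact stabilizer for the
parametric dispersion trend $\alpha(\mu) = a + b/\mu$ with $a$ the
asymptotic dispersion and $b$ the extra-Poisson (shot-noise) coefficient.
The trend is fitted by trimmed least squares of per-gene moment
dispersions on $1/\mu$; "species awareness" enters by estimating those
dispersions from within-species residuals, so between-species shifts do
not masquerade as biological dispersion. If the fitted $a \le 0$ the
package falls back to $\log_2(q + 1)$ and says so. $b$ is clamped at 0.
Center-scaling (mean 0, sd 1 per gene) is applied globally or per species;
the SVM arm uses per-species scaling, which removes each species' mean
expression profile and is what makes cross-species classification
meaningful at all.

## PCA screening

`run_pca()` is sample-space PCA (deterministic sign: the largest-|loading|
gene is positive). Multi-level traits are screened as one-vs-rest 0/1
codings — integer coercion of a factor would impose an arbitrary species
order on a Pearson correlation — and BH correction is joint across all
(PC, coding) pairs. The variance "accounted for" by a trait is defined as
$\sum_{\mathrm{sig.\ PCs}} \mathrm{EVF}_k \cdot r_k^2$ and reported with
that definition. The randomized-phenotype control shuffles labels within
species, preserving the phylogenetic signal under the null; since PCA is
unsupervised, only the correlations move.

## SVM recursive feature elimination

The outer loop is leave-one-species-out; the inner loop is seeded
stratified 3-fold cross-validation on the five training species for
hyperparameter selection over the radial-kernel grid
$\gamma \in \{10^{-7}, 10^{-6}, 10^{-5}\}$, $C \in \{8, 16, 32\}$ (ties
toward smaller cost, then smaller gamma). At each elimination step the
model is re-tuned, the held-out species' misclassification recorded, and
the gene with the smallest $|w_g|$ removed, where
$w_g = \sum_i \alpha_i y_i x_{ig}$ — the matrix product of the model
coefficients with its support vectors, exact for a linear kernel and used
as the ranking heuristic for the radial one. Elimination stops at the
floor (default 100 genes; 20 in the down-scaled validation runs).

**Best-model selection.** The best model is the trace entry with the
lowest held-out error. On strongly separable data the misclassification
error of a 16-sample test set saturates at 0 across essentially the whole
trace, so ties are resolved by a continuous margin-quality score, the mean
squared deviation of the decision values from the $\pm 1$ class targets on
the held-out species (echoing the regression-style mean squared error that
SVM tuning frameworks report), and only then by parsimony. Without this,
"lowest error" selects nothing.

**Solver numerics.** The C-SVC dual is solved by a compiled SMO solver
(second-order working-set selection) on a precomputed kernel, with the
squared-distance matrix maintained incrementally across elimination steps.
Because $(K, C)$ is exactly equivalent to $((K - c)/s, Cs)$ under the dual
equality constraint, the kernel is centered and rescaled to unit spread
before solving — at $\gamma = 10^{-7}$ on center-scaled data the raw RBF
kernel is constant to within $\sim 10^{-5}$, and a fixed stopping
tolerance otherwise terminates on half-converged, degenerate solutions.
The solver is cross-checked against e1071 (decision values and dual
objectives) in the test suite.

The randomization test shuffles the focal species' labels against the
fixed predictions; the reported p is the add-one estimator
$(1 + \#\{e_b \le e_{\mathrm{obs}}\})/(B + 1)$. Error rates on small test
sets are heavily tied, which makes that estimator conservative and
non-uniform under the null, so a tie-randomized variant
$(\#\{e_b < e\} + U \cdot (1 + \#\{e_b = e\}))/(B + 1)$ — exactly uniform
under exchangeability — is returned alongside and used for calibration
checks.

## Consensus networks

Per species: unsigned adjacency $|r|^\beta$ (the smallest
$\beta \in 1..20$ reaching a median scale-free fit $R^2 \ge 0.8$, else 6),
topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}.$$

Per-species TOMs are calibrated so their 95th percentiles match the first
species' (otherwise one noisy dataset's scale dominates a minimum), and
the consensus is the entry-wise quantile across species (default 0, the
minimum — an edge exists only if it exists everywhere). Modules come from
average-linkage clustering of $1 - \mathrm{TOM}$ with a static cut at
0.995 of the maximum merge height and a minimum-size filter swept
30 → 20 → 10; the full dynamic hybrid tree cut is deliberately out of
scope, and because the dendrogram is fixed, assignments are nested along
the sweep. Eigengenes are module PC1s; within a species the PC sign is
arbitrary (unsigned modules mix positively and negatively loaded genes),
so each species' eigengene is flipped to align its kME profile with the
first species' — without this the per-species trait correlations cancel
at random in the meta-analysis.

Trait association uses the weighted Stouffer combination
$z_s = \mathrm{atanh}(r_s)\sqrt{n_s - 3}$, $w_s = \sqrt{n_s}$,
$Z = \sum w_s z_s / \sqrt{\sum w_s^2}$, BH-adjusted across entities. A
gene is trait-associated iff (i) its own meta-p is significant, (ii) it
sits in a module whose eigengene meta-p is significant, and (iii) its kME
meta-p in that module is significant — the strictest reading of
"significant membership in a phenotype-correlated module and significant
correlation with phenotype". Module preservation is a permutation Z on
mean intramodular |kME|.

The resampling null shuffles phenotype labels within species, rebuilds the
whole network, and records the proportion of the point-estimate gene set
recovered. The literal two-tailed rule (count resamples whose proportion
deviates from the 50% null expectation at least as much as the observed
100% recovery does) is reported, but it is degenerate whenever all null
proportions sit on one side — with nothing recovered it returns 1.0 by
construction — so a conventional exceedance p
$(1 + \#\{\mathrm{prop}_b \ge 1\})/(k + 1)$ is reported alongside and is
the one to interpret.

## Differential expression

Per gene: NB log-link regression on phenotype (plus clade, for the joint
model) with offset $\log(\mathrm{size\ factor})$, gene-wise dispersion by
Cox-Reid-adjusted maximum likelihood alternated with IRLS, Wald test on
the phenotype coefficient. This is a deliberate re-implementation without
fold-change shrinkage, independent filtering or outlier replacement; it is
validated by calibration (type-I error within [0.03, 0.08] at nominal
0.05 under a 10,000-gene null), not by equality with any package. The
Wald statistic is referred to $t_{n-p}$ rather than the normal: at 6 + 6
samples the normal reference rejects at 0.078 for a nominal 0.05 purely
from the unaccounted degrees of freedom. Unequal group sizes are handled
by permutation balancing: subsample the larger group to the smaller size,
re-test, and keep genes significant in at least half the subsamples.

## Integration and enrichment

The toolkit is SVM ∩ WGCNA; the DE overlap is reported (pairwise and
three-way) but does not gate the toolkit, mirroring the observation that
conventional DE finds almost nothing shared across all species. All
percentages are recomputed from the stored sets with named denominators.
Term enrichment is plain per-term one-sided Fisher ("classic" algorithm,
no graph decorrelation), terms with < 5 annotated genes excluded, BH
across tested terms, background defaulting to the analyzed orthogroups
rather than a genome.

## Problem sizes and determinism

The packaged validation runs use 6 species × (8+8) samples, 300
orthogroups, 40 planted toolkit genes at lfc 1.5, an elimination floor of
20, module-size sweep 30→10, resampling k = 100, and a 10,000-gene null
for type-I calibration; these sizes keep a full recovery run around a
minute while leaving all operating characteristics measurable. Every
stochastic stage takes a seed; `run_pipeline()` derives per-stage seeds
from the global seed via a stable name hash, so adding a stage never
shifts another stage's random stream, and identical configurations
reproduce byte-identical outputs.

## Known limitations

* The RBF weight formula is the linear-kernel operator applied to a
  radial model — kept because it is what the field's pipelines compute,
  but it is a heuristic.
* The static tree cut is cruder than the dynamic hybrid cut; very close
  modules can merge below the cut height.
* No empirical-Bayes dispersion moderation: per-gene ML dispersions are
  noisier than moderated ones at 3-6 samples per group, which mainly
  costs DE power, not calibration.
* The literal resampling p-value is reported for fidelity but is
  uninformative in the regimes the synthetic data produces; use the
  exceedance p.
* Orthology is consumed, not inferred; mis-grouped orthogroups are
  outside the model.
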
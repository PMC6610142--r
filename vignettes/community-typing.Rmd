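---
title: "Community typing of the equine gut microbiota: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community typing of the equine gut microbiota: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equitype)
```

# The problem

16S rRNA gene surveys of the hindgut microbiota of endurance horses — like
human gut surveys before them — often show that animals fall into a small
number of discrete *community types* (enterotype-like clusters): groups of
samples with similar taxonomic composition. Once such a structure is
established, the downstream questions are always the same. Which genera
drive the separation, and how few of them suffice to predict it? Is the
structure an artifact of one distance measure or one clustering method? How
do the types differ in diversity, in fermentation products (SCFA), in diet,
and in the host's blood metabolome? And, for every host variable that shows
no association, what sample size would have been needed to detect the
observed effect at all?

`equitype` implements this entire downstream pipeline — diversity profiling,
PAM community typing with silhouette-based model selection, discriminant
genus ranking, PCIT co-occurrence networks, association screening and
simulation-based power analysis — together with a synthetic cohort generator
so that every stage can be exercised and tested end-to-end without any
sequencing data.

# Community typing

Samples are clustered with **partitioning around medoids** (PAM; BUILD +
SWAP to convergence, via the `cluster` package) on a pre-computed distance
matrix, by default the **weighted UniFrac** distance of the normalized OTU
counts. The number of clusters $K$ is chosen to maximize the **silhouette
coefficient**

$$ s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))}, \qquad
   \mathrm{SC} = \frac{1}{n}\sum_i s(i), $$

where $a(i)$ is a sample's mean distance to its own cluster and $b(i)$ its
mean distance to the nearest other cluster; `select_k()` scans
$K = 2, \dots, k_\max$ (default 10) and flags $\mathrm{SC} > 0.5$ as a
*reasonable structure*, the accepted interpretation of the silhouette scale.
PAM on a fixed dissimilarity matrix is deterministic, so no seed is
involved; silhouette ties between two values of $K$ are broken toward the
smaller $K$.

Robustness is assessed two ways:

* **Cross-distance concordance** (`concordance()`): the typing is repeated
  with unweighted UniFrac, Bray-Curtis and Euclidean distances, and
  partitions are compared by adjusted Rand index and by exact agreement
  after optimal label matching (exhaustive search over label permutations,
  which is cheap at the small $K$ of community typing).
* **Top-$k$ genus deletion** (`topk_deletion()`): after ranking genera by
  their PLS-DA loadings, the $k$ top-ranked genera are removed
  ($k = 0, \dots, 100$ by default), each sample's remaining composition is
  re-normalized (so it stays a composition), Bray-Curtis distances and PAM
  are recomputed **at the reference $K$** (the procedure tests the stability
  of a given partition, so $K$ is not re-selected), and misclassifications
  are counted after optimal label matching.

# Distances and ordination

Weighted UniFrac between samples $A$ and $B$ is computed by post-order
accumulation of tip relative abundances over the rooted tree:

$$ d_W(A, B) = \frac{\sum_i b_i\, |A_i - B_i|}{\sum_i b_i\, (A_i + B_i)}, $$

with $b_i$ the branch length and $A_i$ the fraction of sample $A$'s
abundance descending from branch $i$; the root has no incoming branch and
is excluded. The denominator normalizes the distance into $[0, 1]$.
Whether the original analysis normalized is not recoverable from the
methods as published; normalization is the default here and is exposed as a
flag. Unweighted UniFrac replaces abundances with presence and is the
classic unique/total branch-length ratio. Both variants are verified in the
test suite against a naive branch-enumeration oracle on random small trees.

PCoA uses Gower double-centering and an eigendecomposition; axes are scaled
by the square root of their eigenvalues, negative eigenvalues are reported
but not corrected (no Cailliez/Lingoes adjustment — distances are analysed
as they are, and the share of negative inertia is visible to the user).
NMDS minimizes Kruskal stress-1 via `vegan::metaMDS` (monotone regression,
20 random restarts, 300 iterations by default); non-convergence is flagged
on the returned object rather than raised, and the best configuration is
always returned.

# Diversity

Alpha diversity works on rarefied counts (subsampling without replacement
to a common depth, seeded): observed richness, bias-corrected Chao1
$S_{obs} + F_1(F_1 - 1) / (2(F_2 + 1))$, Shannon entropy (natural log),
Pielou evenness $J = H / \ln S$, dominance (relative abundance of the most
abundant taxon) and rarity (summed relative abundance of taxa individually
below a detection threshold, default 0.2% — the rarity concept is standard
but its threshold is a package choice, so it is a parameter). Singleton
OTUs are retained during this step, as is standard for richness estimators.
For a single-taxon sample Pielou's $J$ is $0/0$; it is reported as missing
rather than forced to 0 or 1.

The **core microbiota** is the set of genera exceeding a detection
threshold (default $10^{-5}$ relative abundance, i.e. 0.001%) in at least a
prevalence fraction of samples. The default prevalence is 99.9%; a looser
99% convention also circulates, so prevalence is an explicit argument
rather than a constant.

# Discriminant genera

`differential_genera()` tests every genus two ways: Mann-Whitney $U$ on
relative abundances and Fisher's exact test on presence/absence counts,
each family of p-values BH-adjusted separately. A genus is flagged
significant when **either** adjusted p-value is below $\alpha$; both
p-values are always reported so the stricter both-tests rule can be applied
downstream. This disjunctive reading of "both tests combined" is a design
choice — a conjunctive rule is the obvious alternative — and the output
makes either computable. Fold changes are natural logs of community mean
abundances with a pseudo-abundance of $10^{-6}$, so genera exclusive to one
community (which are flagged as such) keep finite fold changes.

`plsda_fit()` is a NIPALS partial least squares regression against the
centered one-hot class matrix with deflation after each component; genera
are ranked by their maximum absolute loading weight across components. Two
components and unit-variance scaling are the defaults (scores are plotted
in two dimensions; the original choice is not recoverable). The sparse
variant (`sparse_plsda_cv()`) soft-thresholds each component's weight
vector to a fixed cardinality, estimates a ROC-AUC by stratified
cross-validation (10 folds by default, reduced to the smallest class size
with a warning), and returns the smallest genus set whose AUC is within a
tolerance (default 0.01) of the best — the "minimum discriminant set".
Out-of-fold predicted class scores are pooled into a single AUC rather than
averaged per fold, which is the more stable choice at cohort-scale $n$.

`sparse_kmeans()` implements the Witten-Tibshirani alternating scheme:
k-means on feature-weighted standardized data, then feature weights
maximizing the weighted between-cluster sum of squares under
$\|w\|_2 \le 1$, $\|w\|_1 \le s$, $w \ge 0$ (soft-thresholding with a
binary search on the threshold). Iteration stops when the relative L1
change of $w$ drops below $10^{-4}$; an empty cluster during iteration
triggers a logged restart with more random starts. At $s = \sqrt{p}$ the
constraint is inactive and the procedure reduces to plain k-means on
standardized data.

# Co-occurrence networks

Per community type, Pearson correlations among genera with mean relative
abundance $\ge$ 0.1% are filtered three ways: the **PCIT** rule, a
correlation magnitude cutoff $|r| \ge 0.35$, and a two-sided $t$-test
p-value cutoff $p \le 0.05$ ($n - 2$ df, unadjusted — the conventional
plain cutoff for this step). Edges with $|r| \ge 0.60$ carry a `strong`
flag. PCIT examines every trio $(x, y, z)$: with first-order partials

$$ r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}} $$

(and permutations), the trio tolerance is
$\varepsilon = \tfrac13 (|r_{xy \cdot z}/r_{xy}| + |r_{xz \cdot y}/r_{xz}| +
|r_{yz \cdot x}/r_{yz}|)$, and edge $(x, y)$ is discarded if **some** third
node $z$ satisfies $|r_{xy}| \le \varepsilon |r_{xz}|$ **and**
$|r_{xy}| \le \varepsilon |r_{yz}|$. Trios with an undefined partial
($|r| = 1$ in a denominator) or a zero direct correlation in a ratio are
skipped and counted. Two numerical consequences of the rule are worth
knowing: it is *conservative on exactly mediated chains* (a zero partial
pulls $\varepsilon$ down, protecting the mediated edge), and under pure
noise it removes the majority of all pairs while sparing the locally
strongest — so the null edge rate of the full pipeline sits at, not far
below, the tail probability of the $|r|$ cutoff. The test suite pins both
behaviors against a literal trio-enumeration oracle.

Correlations are computed on relative abundances, as is conventional for
this pipeline; compositional closure can induce spurious negative
correlations, and PCIT is the mitigation used here rather than a
log-ratio transform. Node topology uses `igraph`: degree, betweenness
centrality normalized by $(n-1)(n-2)/2$, local clustering coefficient
(0 for nodes of degree < 2), and a network-level scale-free fit — the
squared correlation of log frequency versus log degree over observed
degrees $\ge 1$.

# Association screening

* `permanova()` wraps `vegan::adonis2` with sequential (Type I) sums of
  squares, so a block of covariates (e.g. a diet block) is tested in the
  order given, which is reported in the output. Permutation p-values use
  the add-one rule $p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})$, hence
  $p \ge 1/(n_{perm}+1)$ always.
* `envfit_screen()` fits continuous variables onto ordination axes by least
  squares (`vegan::envfit`, 10,000 permutations by default) and
  BH-adjusts across variables; constant variables get $r^2 = 0$, $p = 1$ by
  convention instead of an error.
* `screen_variables()` applies Mann-Whitney to continuous and Fisher's
  exact test to categorical variables, BH within declared variable
  families (host, diet, ...). Tables larger than 2x5 or $n > 60$ switch to
  a Monte-Carlo Fisher p-value with $10^5$ draws and a recorded seed.
  Missing values are pairwise-deleted, never imputed; a variable with fewer
  than 3 non-missing values in either community is skipped and logged.
  Paired race measurements should be passed as pre-computed deltas
  (T1 - T0) to remove inter-individual level differences.
* `two_way_anova()` fits the additive model with Type II sums of squares
  (`car::Anova`), appropriate for the unbalanced community-by-distance
  design; an interaction is fitted only on request and dropped with a
  warning when a cell is empty.
* `pq_normalize()` removes per-sample dilution from NMR-style bin tables by
  the probabilistic quotient: each spectrum is divided by the median of its
  bin-wise quotients to the median reference spectrum (zero-reference bins
  excluded).

# Power analysis

Post-hoc power is estimated by Monte-Carlo simulation, preserving the
observed community split (15/51 by default) at every total size:

* `power_fisher()` draws binomial "success" counts (e.g. race elimination)
  per community and applies the two-sided Fisher exact test; p-values are
  memoized over distinct tables, making 10,000 replicates cheap.
* `power_mannwhitney()` draws group values from uniform distributions
  matched to the target mean and SD (support $m \pm \sqrt{3}\,s$). A
  "skewed uniform" was named but not specified in the tradition this
  follows; the matched symmetric uniform is the reproducible
  operationalization chosen here, with an optional support floor (ages
  cannot be negative) that truncates with a warning. Large samples use a
  direct normal-approximation p-value with continuity and tie corrections,
  verified to match `wilcox.test` exactly.
* `required_n()` walks an increasing grid with **common random numbers**
  (the same seed at every size, so the power curve is monotone without
  Monte-Carlo crossings) and refines the first bracketing interval by
  bisection; the bracket is returned as the uncertainty statement. An
  unreachable target returns a sentinel rather than extrapolating.
* `power_by_effect()` scales the observed effect around the null —
  proportions around the pooled proportion for Fisher, the mean ratio for
  Mann-Whitney — and estimates power at the observed cohort size, clipping
  proportions to $[0, 1]$ with a warning.

With the cohort's own parameters (elimination 33% vs 16%, split 15/51) the
Fisher-based required size for 90% power lands in the low-to-mid 300s, and
the age contrast (9.4 +/- 2.41 vs 9.2 +/- 2.08 years) has power well below
0.9 even at $n = 1000$ — the two headline numbers `scripts/acceptance.R`
recomputes.

# The synthetic cohort generator

No generative model is implied by the kind of cohort this package is built
around, so `generate_cohort()` makes the structure the analysis assumes
explicit and configurable:

* **Counts.** OTU counts are Dirichlet-multinomial: a heavy-tailed base
  Dirichlet parameter vector over 100 genera (log-normal masses, total
  concentration 200), community-specific modifications, per-sample
  log-normal depths (median 5,000 reads — desk-scale; real cohorts run an
  order of magnitude deeper, which only sharpens every contrast), and a
  multinomial draw per sample. The Dirichlet layer gives the
  overdispersion that makes 16S tables subject-specific.
* **Phylogeny.** A genus backbone tree with each genus expanded into a
  short-branched clade of its OTUs, so genus-level abundance shifts — not
  within-genus noise — dominate UniFrac.
* **The two communities** (15/36 by default): 30% of genera have their
  Dirichlet mass multiplied by $e^{\pm\text{effect}}$ in community 1
  (alternating sign), 10% are exclusive to one community, and community 1
  additionally has a quarter of multi-OTU-genus tips silenced
  (re-normalized within genus, so genus-level means are untouched) to
  reproduce its lower OTU richness. The default effect size 3 and
  concentration 200 were chosen so the default cohort reproduces the
  observed study conditions — a distinct two-type structure with
  silhouette coefficient in the 0.55-0.70 range ("reasonable structure")
  and near-perfect recovery by weighted-UniFrac PAM — while
  `effect_size = 0` with no exclusive genera yields SC below 0.15.
* **Metadata.** Age, sex and breed are drawn identically in both
  communities (the null variables); race elimination is Bernoulli(0.33) vs
  Bernoulli(0.16); protein, fiber, ash and UFC intakes are higher in
  community 2; SCFA proportions are Dirichlet with acetate higher in
  community 1 and propionate/butyrate higher in community 2; metabolite
  bins are a rank-3 log-normal spectrum with designated alanine/valine
  proxy bins elevated in community 1 and a random per-sample dilution
  factor, which is exactly what probabilistic-quotient normalization is
  meant to remove.

Everything is reproducible from a single integer seed, and
`write_cohort()` serializes the whole cohort (plus its configuration) as
plain TSV/Newick/JSON.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: there is no sequencing-error or chimera
model, no phylogenetic signal in which genera are discriminant, no
covariance between diet and microbiota beyond the shared community label,
no kinship structure among animals, and the Dirichlet-multinomial cannot
produce the zero-inflation in excess of its own sampling zeros that real
tables sometimes show. Recovery results on synthetic cohorts demonstrate
the *statistical machinery* is correct and calibrated, not that any real
cohort has this structure.

# Numerical choices and test scales

* PAM ties and label matching are deterministic (lowest index / exhaustive
  matching), so community typing has no hidden randomness.
* All randomized stages (rarefaction, NMDS restarts, CV folds, permutation
  tests, Monte-Carlo power) take explicit seeds and record them in their
  outputs; seeded code restores the caller's RNG state.
* Permutation p-values use the add-one rule everywhere.
* The test suite checks calibration at 500 null replicates, community-type
  recovery on 50 synthetic cohorts per regime, and oracle equivalence on
  hundreds of small random instances (trees with at most 8 tips,
  correlation matrices with at most 10 variables, exact Mann-Whitney up to
  10+10) — sizes chosen so the full suite runs in about a minute while
  leaving the asserted margins wide.

# Limitations

Correlation networks on relative abundances remain compositional even
after PCIT; the exact PCIT variant (epsilon averaging, quantifier over
third nodes) follows the published rejection rule but other
implementations differ in tie and degenerate-trio handling. The
"combined" two-test significance rule is disjunctive by default. Power
simulations assume the uniform operationalization described above; other
shapes matched to the same moments give slightly different required sizes.
And all defaults describe a 51-animal, two-community endurance cohort —
other designs should set their own `synthetic_config()`.
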
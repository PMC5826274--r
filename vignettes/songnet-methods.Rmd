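---
title: "Methods: behavior-coupled coexpression networks in songnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior-coupled coexpression networks in songnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songnet)
```

songnet implements the complete computational path from a bulk RNA-seq
count matrix and per-animal behavioral metrics to behavior-correlated
coexpression modules, cross-condition preservation statistics, and
prioritized gene, term and interaction lists. This vignette records the
model, the parameters that matter, and the design choices made where the
procedure left genuine freedom.

## Preprocessing

Counts are converted to TPM (per sample,
$\mathrm{TPM}_i = 10^6 (c_i/\ell_i)/\sum_j (c_j/\ell_j)$), then
log2-transformed with a pseudocount. The pseudocount defaults to 1 —
zeros are common in real counts and $\log_2(x+1)$ is the standard
convention — and is configurable; with a pseudocount of 0 a zero value
is an error by default (`zero_policy = "allow"` yields $-\infty$
instead). Zero-variance genes are removed at this point.

Two robustness filters follow, in fixed order:

* **Iterative outlier masking** (`iterative_outlier_mask`): per gene,
  cells more than 2.5 sample standard deviations (n − 1 denominator
  throughout) from the gene's mean are masked, and passes repeat until a
  full pass masks nothing. The inequality is strict, so a cell exactly
  at 2.5 SD is retained. Genes left with fewer than 3 unmasked cells are
  dropped with a warning. Masking is idempotent at convergence.
* **Intrasample correlation (ISC) filter**
  (`filter_samples_by_isc`): a sample's ISC is its mean pairwise Pearson
  correlation with every other sample (the median is available via
  `summary = "median"`); samples strictly below the group mean minus
  2 SD are removed. The mean was chosen as the default because ISC is
  conventionally reported as an average agreement score; nothing
  downstream depends on the choice for well-behaved data.

Quantile normalization is deliberately the **last** step: each sample's
sorted values are replaced by the across-sample mean of sorted values,
ties receiving the mean of their tied ranks (`limma::normalizeQuantiles`
with tie averaging). Because quantile normalization needs complete
columns, masked cells are first imputed to the gene's unmasked mean —
mean imputation is correlation-neutral, which is what matters for the
network stage. Quantile normalization is idempotent.

## Signed network and modules

The adjacency is $a_{ij} = ((1 + \mathrm{cor}(x_i, x_j))/2)^\beta$
(signed; `"unsigned"` uses $|\mathrm{cor}|^\beta$), with Pearson
correlation over pairwise-complete samples. Signed networks are the
default because anti-correlated genes should *not* cluster together when
module eigengenes are later correlated with behavior. Connectivity
excludes the self-term, $k_i = \sum_{j \ne i} a_{ij}$; this convention
is forced by the topological-overlap formula — with $a_{ii}$ included,
an isolated perfect pair would not reach $\omega = 1$.

$\beta$ is selected by `pick_soft_threshold`: for each candidate the
connectivity vector is binned into 10 equal-width bins, and
$\log_{10}$ bin frequency is regressed on $\log_{10}$ mean bin
connectivity; the signed fit index is $-\mathrm{sign}(\text{slope})
\cdot R^2$ and the smallest power reaching 0.8 (a conventional cut; the
scan table is always returned, with an `NA` sentinel when no power
qualifies) is chosen. Mean connectivity is strictly decreasing in
$\beta$, which the tests assert.

Topological overlap
$\omega_{ij} = (l_{ij} + a_{ij})/(\min\{k_i,k_j\} + 1 - a_{ij})$ is
computed by matrix multiplication and verified against a brute-force
triple loop to $10^{-12}$ on random matrices. Modules come from
average-linkage clustering of $1-\omega$ with a simplified
dynamic-height cut: the tree is cut at a `deep_split`-dependent fraction
of the merge-height range (`deep_split` 0–4 maps linearly to 0.99–0.85;
higher values cut lower and yield finer modules), and branches smaller
than `min_module_size` go to the reserved grey label. This is a
granularity knob, not a line-by-line port of the dynamic hybrid
algorithm; correctness is assessed by planted-module recovery rather
than label-identical replication, and small branches go straight to
grey because the membership rules below can rescue genuinely coherent
genes in later iterations.

Eigengenes are first right singular vectors of the module's
standardized gene × sample block, scaled to unit variance and
sign-oriented to correlate positively with the module's mean expression
profile (SVD sign is arbitrary; alignment with the mean profile makes
results deterministic). Membership rules then apply: genes with
kME < 0.3 to their own eigengene are reassigned to grey, and a module is
disbanded entirely unless a core of at least ⌈`min_module_size`/3⌉
genes reaches kME ≥ 0.5. `build_network` iterates
adjacency → TOM → cut → eigengenes → rules, dropping grey genes each
round, until no gene is grey (or `max_iter`, default 10, with a warning
flag). On clean modular data this converges in one or two rounds; on
pure noise it terminates with everything unassigned.

## Behavior correlation

Four behavioral traits mirror the songbird study design: motifs sung in
the two hours before sacrifice, tutor similarity (%), variability
induction — the effect size $(NS-UD)/(NS+UD)$ applied to song-feature
CVs, negative when undirected singing increases variability — and motif
identity (similarity × accuracy / 100). Gene significance is the signed
Pearson correlation of a gene with a trait; module–trait relationships
use the eigengene correlation with a two-sided Fisher-transform p-value
$z = \mathrm{atanh}(\rho)\sqrt{n-3}$ (the Student-t form is available
via `method = "student"`; at $|\rho| = 1$ the p-value is clamped to 0).
Two-sided tests were chosen because the display convention is a signed
two-color heatmap. BH correction runs over exactly
(modules × traits) hypotheses — `fdr_adjust(p, m)` pads with implicit
p = 1 entries when fewer p-values are supplied — and both the raw
p-values and an FDR pass flag at q ≤ 0.05 are reported, since with
~19 samples uncorrected p ≤ 0.05 is the practical screening threshold
while FDR-passing entries deserve flagging.

## Module preservation

`module_preservation` fixes a roster of six statistics: three density
statistics computed in the test data (mean within-module signed
adjacency, eigengene variance explained, mean |kME|) and three
connectivity statistics comparing the datasets (correlation between
datasets of intramodular connectivity, of kME, and of the vectorized
within-module correlation matrix). This is a deliberately small,
documented subset of the published composite suite; the roster is
extensible but fixed here for interpretability. The null is the
standard permutation scheme: the module's genes stay fixed on the
reference side while a random same-size gene set from the common-gene
universe (sampled without replacement) replaces them on the test side,
breaking the gene correspondence. Then
$Z = (\mathrm{obs} - \bar{\mathrm{null}})/\mathrm{sd}_{\mathrm{null}}$,
Zdensity and Zconnectivity are medians of their three Zs, and
Zsummary is their mean. A null spread of zero sets Z to 0. The 2/10
interpretation thresholds are the field's convention, not a fitted
value. Test-side adjacency uses the test dataset's own power
(`beta_test`), mirroring the use of different powers for different
brain regions.

## Term and interaction prioritization

Module significance of an annotation term is
MS = mean(kME of the term's in-module genes) × (1 − p); term
significance weights MS by the mean gene significance of those genes
for a chosen trait. The aggregation uses |GS| by default — the weighting
was left open, and absolute values avoid penalizing strong negative
correlates; `signed = TRUE` restores the signed mean. Interaction lists
are filtered to confidence ≥ 0.9 first, then ranked under one of four
metrics (hub–hub, differential-connectivity, behavior–behavior, or
hub × behavior products with confidence); ties break lexicographically
by gene pair so rankings are deterministic.

Visualization sparsification follows the display workflow: retain the
top `keep_fraction` (default 0.02) of edges by weight with ties at the
cutoff all retained, drop degree-0 nodes, keep the largest connected
component (size ties go to the component containing the
lexicographically smallest node id). The count-based "top 2%" reading
means a second application at the same fraction can prune further; the
degree and component stages themselves are idempotent, and the tests
pin the tie rule and the monotone node counts.

## Promoter scanning

PWMs are built from base counts with a total pseudocount (default 0.8)
spread uniformly across bases, column-normalized and converted to log2
odds against a uniform background (the background model is uniform
because no genome composition is assumed). The "80% hit score" is
interpreted relative to the score *range*,
$(s - s_{\min})/(s_{\max} - s_{\min}) \ge 0.80$, matching the scanning
convention of the cited matcher; a fraction-of-max alternative can be
had by rescaling. Both strands are scanned by default (the original
analysis does not state strandedness), minus-strand hits are mapped
back to forward 0-based half-open coordinates, and windows containing N
are skipped. Promoters are the 1000 bp upstream of the TSS —
$[\mathrm{TSS}-1000, \mathrm{TSS})$ on the plus strand, the reverse
complement of $(\mathrm{TSS}, \mathrm{TSS}+1000]$ on the minus strand —
truncated with a warning at contig edges. Mismatch tolerance is
expressed entirely through the relative-score threshold rather than a
separate mismatch count.

## The synthetic-data generator

The generator emulates the study design: ~19 samples by default,
modules of 100–2,000 genes plus independent background genes
(~13,000 genes in total), four traits linearly coupled to chosen module
eigengenes, and a second condition in which designated modules are
preserved and the rest scrambled. Latent eigengenes are i.i.d. standard
normal per sample — consistent with the eigengene-as-first-PC model and
giving closed-form membership targets. A module gene with loading $r_i$
(drawn near the module's kME target with SD 0.03) is
$x_i = \mu_i + s_i(r_i E_m + \sqrt{1-r_i^2}\,\sigma z)$; at the default
residual scale $\sigma = 1$ the realized gene–eigengene correlation
equals the target in expectation. Gene means ($\mathcal{N}(6, 2^2)$)
and scales (uniform 0.5–2) mimic log2 TPM data. Traits are linear
transforms of $\rho E_m + \sqrt{1-\rho^2} z$ onto realistic scales
(counts, percentages, an effect size); linearity preserves the Pearson
target, and rounding the motif count to a non-negative integer
attenuates it only negligibly. Counts are negative binomial
(configurable dispersion; Poisson in the limit) with expected reads
proportional to abundance × length, so TPM recovers the planted
abundances.

Condition-2 scrambling permutes a module's loadings across its genes
and attaches each to an independent per-gene latent factor: marginal
means and variances are retained while the shared factor — and with it
all within-module coexpression — is removed. Permuting loadings onto
the *same* shared eigengene would leave coexpression intact, which is
why the permutation is combined with factor replacement. An
`attenuation` argument scales preserved-module loadings, giving graded
preservation levels for monotonicity checks.

What the generator does **not** emulate: count overdispersion structure
beyond a single dispersion parameter, batch effects (none were observed
in the motivating study), correlated traits, gene–gene correlation
beyond the single-factor module model, and annotation/interaction noise
beyond uniform sampling. Passing tests therefore demonstrate that the
pipeline recovers planted single-factor module structure and planted
couplings — not that it is robust to real-data pathologies such as
outlier samples beyond those the masking stage plants, mappability
artifacts, or compositional effects.

## Determinism and problem sizes

All randomness flows through explicit integer seeds; stage sub-seeds
are derived additively from the master seed so disabling one stage does
not shift another's draws, and identical configurations give
bit-identical outputs (asserted in the tests). The test and example
workloads use desk-scale designs chosen to make every statistical claim
measurable in seconds to a couple of minutes: parameter recovery uses
five modules of 100–300 genes across 60 samples; preservation uses
modules of 100–150 genes over a ~2,000-gene universe with 200
permutations; motif recall uses 200 promoters of 1,000 bp. The
full-size default configuration (~13,000 genes × 19 samples) is the
study-scale emulation and runs through the same code paths.

## Known limitations

* The tree cut is a simplified dynamic-height procedure; module labels
  and exact boundaries will differ from the dynamic hybrid algorithm,
  and only planted-structure recovery is guaranteed.
* The preservation roster is a six-statistic subset; absolute Zsummary
  values are not comparable to runs of the full published composite,
  and with few samples Zconnectivity is noisy for small modules.
* With ~19 samples, module–trait p-values rarely survive FDR correction;
  the uncorrected screen plus pass flag mirrors the intended use.
* Homolog mapping between species is out of scope; gene identifiers are
  assumed pre-harmonized across datasets and annotation tables.
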
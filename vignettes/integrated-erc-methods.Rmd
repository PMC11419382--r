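---
title: "Integrated evolutionary rate covariation: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated evolutionary rate covariation: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecov)
```

## The model

Evolutionary rate covariation (ERC) rests on a simple premise: genes whose
products work together experience shared shifts in selective pressure, so
their evolutionary rates speed up and slow down on the same lineages. The
signature of shared function is therefore *correlation of branch-specific
rates* across a phylogeny, after removing everything that is not
branch-specific.

`ratecov` works from per-clade inputs: for each independent clade dataset
(the canonical design uses mammals, vertebrates, flies, yeast and
nematodes, with 62, 39, 22, 18 and 17 species respectively) a master tree
and a genes × branches table of branch lengths in substitutions/site, in a
shared gene-identifier namespace (orthologs are assumed pre-mapped; the
package does not call orthologs).

The pipeline has three stages.

**1. Relative evolutionary rates (RER).** For clade branch $b$, the master
profile is the genome-wide average branch length
$A_b = \mathrm{mean}_g\, L_{gb}$ over genes present at $b$. Each gene is
then normalized by the centered log-ratio

$$
R_{gb} \;=\; \ln\frac{L_{gb}+\varepsilon}{A_b+\varepsilon}
\;-\; \frac{1}{|B_g|}\sum_{b'\in B_g}\ln\frac{L_{gb'}+\varepsilon}{A_{b'}+\varepsilon},
$$

over the gene's present, usable branches $B_g$. The log-ratio removes the
shared branch profile (long branches are long for every gene); the
per-gene centering removes the gene's overall rate (a uniformly fast gene
is not thereby covarying with anything). The result is exactly
scale-invariant per gene when $\varepsilon = 0$ and rows have positive
lengths — an invariant the test suite asserts to $10^{-12}$ — and each
row has mean zero by construction (asserted to $10^{-10}$). We chose the
centered log-ratio over a weighted-regression residual because it is the
minimal transform that removes both nuisance structures at once and makes
the downstream Pearson step clean under location/scale changes; it also
needs no fitted model whose misfit could leak into the correlations.

**2. Per-clade correlation and the Fisher transform.** For each gene pair
and clade, the ERC value is the Pearson correlation $r$ of the two RER
profiles over the $n$ branches present for both (requiring
$n \ge n_{\min}$, default 5). To make clades of very different tree sizes
commensurable, $r$ is variance-stabilized and scaled by its precision:

$$ z \;=\; \operatorname{atanh}(r)\,\sqrt{n-3}. $$

Under the null of no covariation, $z$ is approximately standard normal
*regardless of the branch count*, which is the property that licenses the
next step. The acceptance checks verify this calibration on null
simulations: with 500 genes and 50 branches per clade the per-clade $z$
has mean within $\pm 0.05$ and SD within $[0.9, 1.1]$.

**3. Integration across clades.** The integrated FtERC score is the plain
sum of the per-clade $z$ values over the clades in which the pair
qualifies. Summing (rather than averaging or dividing by $\sqrt{k}$)
follows the original convention; the consequence — pairs observed in more
clades can reach larger $|FtERC|$ — is deliberate, treating breadth of
evidence as part of the signal. Pairs qualifying in no clade are *absent*
(`NA`), never zero: zero is a real score. With five clades a null pair has
SD $\approx \sqrt{5}$, and the conventional significance threshold is the
genome-wide mean plus two SDs of the scored values
(`significance_threshold()`); applied to the published genome-wide summary
(mean 0.12, SD 1.47) it gives 3.06, the familiar "$\ge 3$" rule.

Two numerical guards: $|r|$ is clamped at $1 - 10^{-6}$ so perfectly
correlated profiles give a large finite $z$ rather than infinity, and
pairs whose shared-branch RER vector has zero variance are treated as
absent in that clade (a correlation with a constant is undefined, not
zero). Genes with fewer than 4 usable branches are dropped so that
$n - 3 \ge 1$ always holds; $\varepsilon = 10^{-6}$ substitutions/site
keeps zero-length branches informative rather than discarding them.

## Gene-set statistics

`permute_within()` tests whether a gene set's mean pairwise FtERC is
elevated: the observed mean over scored within-set pairs is compared to
the means of `n_perm` random same-size groups drawn from the scored
universe (100,000 draws by default, so the smallest reportable nonzero
p is $10^{-5}$ and stronger results are reported as the floor
`"<1e-05"`). The p-value estimator is the plain exceedance proportion,
matching the floor convention; replacement groups are drawn from the full
universe *including* the tested genes (the literal reading of "random
groups from the entire proteome"), with an `exclude_group` switch for the
stricter variant. `permute_between()` runs the two-group version both
ways — hold A and randomize B, hold B and randomize A — and reports the
more conservative (higher) p.

Absent pairs are excluded from both numerator and denominator of every
mean. A random draw with no scored pairs at all (possible only under
extreme missingness) is dropped from the null rather than imputed.

## Top-quantile enrichment

For a focal set of $K$ proteins, `focal_pairs()` collects every scored
pair touching the set, `top_quantile()` keeps the top
$\lceil qN \rceil$ by score (ties at the cutoff broken by lexicographic
pair id, so the selection is deterministic), and
`occurrence_enrichment()` counts each protein's occurrences $O$ among the
$T$ top values against the even-share expectation $E = T/K$. The signed
fold change is $O/E$ when $O \ge E$ and $-(E/O)$ otherwise — never inside
$(-1, 1)$ — and each protein gets a one-versus-rest 1-df chi-squared
goodness-of-fit test without continuity or multiple-testing correction,
matching the convention of reporting raw per-protein p-values. With
$T = 5685$ and $K = 30$, $E = 189.5$ and counts of 552 and 526 give
folds $+2.91$ and $+2.78$; a count of 8 gives $-23.69$ by the same
arithmetic. A pair containing two focal proteins increments both counts
by default (`double_count = FALSE` switches to crediting only the first),
which is why $\sum_g O_g$ can exceed $T$ while $E$ stays $T/K$.

## Complex benchmark

To ask whether the integrated score separates genuinely co-functional
sets from noise, `complex_empirical_p()` compares each real complex's
mean pairwise FtERC to "representation-matched" simulated complexes:
`simulate_null_complexes()` draws each null complex's size from the real
size distribution and samples genes with probability proportional to
their frequency of complex membership, so promiscuous subunits are
equally promiscuous in the null. The empirical p is computed within the
same-size stratum (the variance of a mean over $\binom{s}{2}$ pairs
depends on $s$), floored at `1/n_stratum`, and passed through
Benjamini–Hochberg (via `stats::p.adjust`) for an FDR-5% call.
`precision_recall_foldchange()` then ranks real and null complexes
together by mean score and normalizes precision by its value at 100%
recall (the class prevalence), so a useless scorer sits at fold-change 1;
this is the comparison used to show that the five-clade integrated score
out-separates any single clade's score.

Two interpretation choices were genuinely open. "Representation-matched"
is implemented as membership-frequency-weighted sampling with matched
sizes (a `uniform` switch exists for sensitivity analysis). The null pool
is shared across sizes and stratified at test time rather than simulated
per size; with the default pool sizes each stratum stays large enough
that the floor is well below any interesting p.

## The synthetic-data generator

Because real multi-clade rate datasets are built from hundreds of
alignments, the package ships a generative model with known ground truth.
For clade $c$ with master lengths $A_b$:

$$
L_{gb} \;=\; A_b \; s_g \; \exp(\sigma\, d_{gb}), \qquad
d_{gb} = \sqrt{\rho_m}\, f_{mb} + \sqrt{1-\rho_m}\, e_{gb},
$$

with $\log s_g \sim N(0, \tau^2)$ a per-gene rate scalar, $f_{mb}$ a
module-shared standard-normal factor drawn independently per clade, and
$e_{gb}$ gene-private noise. On the log scale two same-module genes have
RER correlation exactly $\rho_m$ in expectation; background genes have
$\rho = 0$. Multiplicative log-normal deviations keep branch lengths
positive and make the target correlation exact on the scale RER uses.
Missingness is whole-gene-per-clade (ortholog absence), with probability
0.1 by default. Master trees are random rooted binary topologies with
log-normal branch lengths centered on 0.05 substitutions/site.

Defaults mirror the five-clade study design (62/39/22/18/17 species);
$\sigma = 0.3$ and $\tau = 0.3$ give per-branch rate wobble and
between-gene rate spread of a few tens of percent, in the range typical
of protein-coding genes. No effect-size scale is prescribed for "true"
coevolution, so power studies use a $\rho$ grid
$\{0.2, 0.4, 0.6, 0.8\}$ as a choice, not an empirical estimate.

One subtlety the generator exposed: the master profile is *re-estimated
from the data* as a per-branch mean, so if coevolving module genes
dominate the gene set, the estimated master absorbs their shared factor
and the within-module RER correlation collapses toward zero. Module
recovery is therefore always assessed with the module embedded in a
background that dominates the master (as in any genome-scale analysis,
where a 27-gene pathway is a negligible fraction of ~19,000 genes).

What the generator does *not* emulate: phylogenetic autocorrelation along
the tree (branch deviations are i.i.d.), tree-topology estimation error,
gene-specific branch support, codon-level processes, or correlated
missingness. Passing tests on synthetic data therefore demonstrate
correctness of the statistical machinery and its calibration under the
stated model, not robustness to every pathology of real alignments.

## Problem sizes and determinism

The shipped analyses and checks use a 300-gene universe with five clades
at the study's species counts, 100,000 permutations for the floor
convention and group tests, 10,000 permutations per seed for power
sweeps, and a few thousand simulated null complexes — sizes chosen so the
whole suite runs comfortably on a laptop while keeping every empirical
band (uniformity of null p-values, $z$ calibration, 9-of-10-seed power
properties) well-resolved. Every stochastic function takes an explicit
integer seed and restores the caller's RNG state; identical inputs and
seeds give byte-identical outputs, which the pipeline manifest verifies
by hashing.

## Known limitations

- The integrated sum favors genes observed in many clades; a pair present
  in one clade can never reach the magnitude of a five-clade pair. This
  matches the reference convention but means FtERC magnitudes are not
  comparable across pairs with different clade coverage (the per-pair
  clade components are retained for that reason).
- The chi-squared occurrence test treats top-set memberships as
  independent across pairs, which is approximate when a protein's pairs
  share the protein's own rate profile.
- Branch identifiers are content-addressed (hash of the child leaf set),
  so relabeling a species changes branch ids — intentional, since a
  relabeled species is a different datum.
- `n_min = 5` shared branches per clade is a pragmatic default; with very
  small trees (near the 4-branch Fisher limit) single-clade z values are
  noisy and the integrated score inherits that noise.
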
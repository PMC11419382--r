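# ratecov

Integrated evolutionary rate covariation (ERC) across independent clades.

Genes whose proteins work together — in a complex, a pathway, or as
modifiers of one another — tend to speed up and slow down their evolution
on the same lineages. `ratecov` turns that signal into a genome-scale
statistic and the analyses built on it. It was written with congenital
disorders of glycosylation in mind, where pathway-level ERC is used to
prioritize candidate genetic modifiers, but the machinery is generic: any
set of per-clade gene × branch-length tables in a shared ortholog
namespace will do.

## The statistic

For each clade (e.g. mammals, vertebrates, flies, yeast, nematodes), gene
branch lengths are normalized to **relative evolutionary rates** by a
centered log-ratio against the genome-wide average branch profile
`A_b`:

```
R[g,b] = ln((L[g,b]+ε)/(A_b+ε)) − mean_b' ln((L[g,b']+ε)/(A_b'+ε))
```

Per gene pair and clade, the ERC value is the Pearson correlation `r` of
the two RER profiles over their `n` shared branches, Fisher-transformed
with a branch-count adjustment so every clade contributes on a common
standard-normal null scale:

```
z = atanh(r) · sqrt(n − 3)
```

The **integrated FtERC** score is the sum of `z` over qualifying clades.
Scores two standard deviations above the genome-wide mean (`≥ 3` for the
published genome-wide summary of 0.12 ± 1.47) are conventionally called
notably elevated.

On top of the matrix the package provides one- and two-group permutation
tests for elevated mean ERC (empirical p, 100,000 permutations, floor
`<1e-05`), top-quantile occurrence enrichment with signed fold changes
and per-protein chi-squared tests, a protein-complex benchmark against
representation-matched simulated complexes with BH FDR and
precision–recall fold-change curves, and a synthetic multi-clade
generator with planted coevolving modules for calibration and power
studies.

## Worked example

```r
library(ratecov)

# five clades sized like the canonical design; a 10-gene coevolving
# module (rho = 0.6) planted in a 100-gene background
g <- sprintf("g%04d", 1:100)
cfg <- simulation_config(n_genes = 100,
                         species_per_clade = c(62, 39, 22, 18, 17),
                         modules = list(list(genes = g[1:10], rho = 0.6)),
                         missing_prob = 0.1, seed = 42)
sim  <- simulate_branch_tables(cfg)
rers <- lapply(sim$tables, function(tb) compute_rer(tb, master_profile(tb)))
erc  <- build_erc_matrix(rers, n_min = 5)
print(erc)
#> <erc_matrix> 100 genes; 4950 scored pairs
#>   FtERC mean -0.278 sd 2.62 range [ -8.34 , 24 ]

significance_threshold(erc)
#> [1] 4.955027

permute_within(erc, g[1:10], n_perm = 100000, seed = 7)
#> <permutation_result> observed mean 15.49 over 45 pairs
#>   null -0.276 +/- 0.3675 ( 1e+05 permutations ) p <1e-05 ( 42.92 SD above null )
```

The module's mean pairwise score (15.49 over its 45 pairs) sits ~43 null
SDs above the mean of 100,000 random 10-gene groups, so the empirical p
bottoms out at the floor `<1e-05` — the generator's planted signal,
recovered. (The threshold here is higher than the genome-wide 3.06
because a tenth of this small universe is genuinely coevolving.)

The `analysis/` directory holds the same workflow as numbered stages over
a 300-gene, five-clade dataset — simulate, RER + integrated ERC, group
permutation tests, top-1% enrichment, complex benchmark — each a thin
script over the package that prints what it found and writes tables under
`results/`.

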
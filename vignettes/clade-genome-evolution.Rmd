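---
title: "Clade-comparative gene family and pathway evolution with cladevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-comparative gene family and pathway evolution with cladevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladevol)
```

## The analysis

`cladevol` compares genome evolution between two named clades of a
time-calibrated phylogeny — the motivating system is the split of
wasp-waisted Hymenoptera into non-stinging parasitoid wasps and their
stinging sister clade, but nothing in the package is specific to it. The
inputs are a rooted Newick tree with branch lengths in million years (My),
a gene-family count matrix (orthogroup x species, the `GeneCount` TSV
dialect of orthology inference tools), a per-branch dN/dS table, per-species
enzyme (EC number) annotations, and a reference pathway table. From these
the package derives:

1. **Family dynamics.** Ancestral family sizes by integer-count parsimony,
   per-branch signed count changes, gain-and-loss rates per My, and "rapid"
   event flags against a Poisson background.
2. **Clade contrasts.** Rapid-event enrichment (Pearson chi-square with
   odds ratio), per-family turnover-rate and family-size shifts
   (Mann-Whitney U with Benjamini-Hochberg correction), and the
   presence/absence classification rules (missing families, novel core
   families, differentially lost families).
3. **Selection-pressure contrasts.** Per-OG dN/dS location tests, the
   coefficient of variation (CoV) of dN/dS per clade with a
   decile-intersection screen, and normalized per-OG substitution rates.
4. **Pathway coverage.** Ancestral pathways reconstructed from outgroup EC
   annotations, per-species pathway coverage (PC), and clade contrasts of
   PC and of its variability per superpathway.

A synthetic-data generator produces all inputs with the statistical
structure the analysis assumes, so the full pipeline is exercisable and
testable without any genome downloads.

## Models and estimators

### Branch identity

Every non-root branch is identified by the sorted set of leaf names below
it (hashed for internal branches). Identifiers are therefore invariant to
the leaf order of the input Newick and stable across serialisations; they
are the join keys between the tree and all per-branch tables. Unary
(singleton) nodes are disambiguated deterministically by depth. Polytomies
are accepted as-is: every statistic is defined on branches, not on
bifurcations. Zero-length branches are allowed but excluded from any per-My
denominator.

### Parsimony reconstruction of family sizes

Ancestral counts are reconstructed per family by a Sankoff dynamic program
over the integer states `0..max(count)` with linear cost `|i - j|` per
branch (asymmetric gain/loss unit costs are available). Because the cost is
linear, each upward message is a one-dimensional distance transform and is
computed in two cumulative passes, so the program is `O(nodes x states)`
rather than `O(nodes x states^2)`. Ties are broken deterministically: the
root takes the smallest minimising state, every other node the admissible
state closest to its parent (smaller state on an exact tie). The
reconstruction is verified in the test suite against exhaustive enumeration
of all ancestral assignments on small trees.

The per-branch change is `delta = count(child) - count(parent)`; gains and
losses are its positive and negative parts, and the gain-and-loss rate of
any branch set is

```
rate = sum(|delta|) / sum(branch lengths in scope)   [events / My]
```

The denominator is the summed branch time of the scope, not the clade age;
this makes the global, clade-level and per-branch definitions consistent
(dividing by root age instead is available as an option).

### Rapid-event flags

A background per-family event rate is estimated as
`r = sum(|delta|) / (n_families x total tree length)` and each change of
magnitude `d >= 1` on a branch of length `t` is scored with the Poisson
tail `p = P(Poisson(r t) >= d)`; flags use `p < 0.05` by default. This is a
transparent closed-form stand-in for the per-family significance of
likelihood-based gain/loss tools. Its key limitation is discussed under
*Calibration* below.

### Two-sample statistics

The Mann-Whitney U statistic uses midranks. When the pooled sample size is
at most 12 the p-value is exact: all `choose(na+nb, na)` group labelings
are enumerated, which handles ties exactly. Larger samples use the normal
approximation with tie correction and a 0.5 continuity correction. The
chi-square test on 2x2 tables is Pearson's without Yates correction (the
common choice for enrichment scans; a flag enables it), with the odds ratio
`ad/bc` and the Haldane-Anscombe +0.5 correction applied to all cells when
any cell is zero. Degenerate tables (a zero row or column margin) return
`chi2 = 0, p = 1` and are flagged. CoV uses the sample (n-1) standard
deviation; it is undefined (returned `NA`, logged) for fewer than two
values or a zero mean. Benjamini-Hochberg adjustment is applied over
exactly the units tested in the same scan; untestable units (e.g. OGs with
no rapid events anywhere) are excluded *before* adjustment, so the
correction count equals the number of tests actually run.

One caution on a tempting algebraic shortcut: Benjamini-Hochberg is not
idempotent. Re-adjusting already-adjusted values can change them (e.g.
`BH([.005,.01,.03,.04]) = [.02,.02,.04,.04]`, but adjusting that vector
again gives `[.04,.04,.04,.04]`), so reports always keep raw and adjusted
columns side by side and decisions are derived from the single adjustment.

### Presence/absence rules

Presence means count >= 1. *Missing* families are present in strictly more
than 70% of outgroup species and absent from every test-group species;
*novel core* families are the mirror image. The retention side of the
novel-core rule is the quoted definition; requiring complete absence in the
outgroup is this package's tightening (configurable), since a "novel"
family observed in the outgroup would not be novel. *Differential loss*
selects families lost (count 0) in strictly more than 20% of the clade's
species but in at most 2% of the remaining species. Boundary semantics are
literal: "over 70%" and "more than 20%" are strict, "no more than 2%" is
inclusive, and the tests pin the boundaries.

### Pathway coverage

Ancestral pathways are built by combining the outgroup species' EC sets —
union by default; intersection and majority(>50%) modes exist — and
intersecting with each reference pathway's EC set. The union default
maximises retained ancestral content under incomplete per-species
annotation; strict intersection across eight outgroup genomes would
discard most real enzymes because annotation gaps are independent across
species. A pathway is kept when at least 5 ECs are retained and a
reference-species flag is set (both configurable; the flag is a column in
the pathway table rather than a live database query, keeping runs offline
and reproducible). Coverage is
`PC(pathway, species) = |ECs(species) ∩ retained| / |retained|`. The global
clade contrast pools all (pathway, species) values; per-pathway tests run
in both directions with BH per direction; the variability contrast
compares per-pathway CoVs of PC within superpathways (skipping
superpathways with fewer than two pathways). EC strings are validated
against the `d.d.d.d` pattern with `-` wildcards allowed; matching is
literal by default.

### Decile intersection

The dN/dS dispersion screen reports OGs in the top 10% of CoV in clade A
and the bottom 10% in clade B. Selection is rank-based: the top
`ceiling(f x n)` OGs per side, with rank ties resolved by OG identifier so
results are deterministic.

## The synthetic-data generator

Counts evolve by a linear birth-death process *per gene copy* (per-copy
gain and loss rates, optionally scaled per clade), stepped event by event
along each branch. Family size 0 is absorbing — a gain needs a template
copy — which gives "lost family" a real meaning for the 20%/2% rule. Root
sizes default to a shifted geometric `1 + Geom(0.5)` (mean 2), mimicking
heavy-tailed family-size distributions. dN/dS values are
`base x clade shift x lognormal noise` with mean-1 noise of configurable
CV, optionally per clade (dispersion shifts). EC profiles give outgroup
species the full ancestral complement and drop each EC independently per
species at a clade-specific probability. Every per-family, per-OG and
per-species stream is seeded by a counter derived from one master seed, so
outputs are byte-identical across runs and independent of iteration order.

The default study conditions used throughout the tests are a 32-leaf
ultrametric tree (8 outgroup + 12 + 12 species, crown ages mirroring the
hymenopteran time scale, rescaled to 500 My of total branch length), 2,000
families, and symmetric per-copy rates of 0.1/My. These sizes keep the
complete suite and the acceptance script within a few minutes on one CPU.

What the generator does *not* emulate: annotation error, correlated loss
across pathways, rate variation over time within a branch, and any
likelihood surface of gene-count models. Passing tests therefore show the
statistic layer is correct and calibrated *for data meeting its
assumptions*; they do not show the upstream inferences on real genomes are
unbiased.

## Calibration findings and known limitations

Three findings from the package's own null simulations (no clade effects)
deserve emphasis, because they are properties of the method design, not
implementation defects — each implementation is verified against exact
enumeration oracles:

* **The Poisson background over-flags under family heterogeneity.** The
  background rate averages over all families, but under heavy-tailed root
  sizes most families are small or extinct and contribute nothing, so the
  averaged rate underestimates the active families and the majority of
  nonzero changes can be flagged "rapid". Likelihood tools condition on
  per-family size; the closed-form stand-in does not.
* **Branch-length asymmetry leaks into the enrichment scan.** A change of
  fixed size is more surprising on a short branch, so the clade with
  shorter branches accumulates more rapid flags and the per-family 2x2
  chi-square detects this clade-length artifact even without any clade
  effect.
* **Species are not independent.** Per-species counts within a clade
  inherit their stem ancestor's fluctuations, so the family-size contrast
  across species exceeds its nominal false-positive rate under the iid
  null. This caveat applies equally to the species-level Mann-Whitney
  design in the literature this package operationalises. The dN/dS
  contrast, whose branch values are simulated independently, is exactly
  calibrated in the same runs.

Relatedly, parsimony is a deliberate undercounter: when many lineages lose
a family independently, the reconstruction explains them with fewer,
earlier losses. At the default study conditions the global parsimony rate
is roughly half the generator's true net-change rate. Estimated rates
should be read as conservative lower bounds; contrasts between clades are
affected far less because both clades are reconstructed the same way.
Similarly, with heavy extinction a rate *increase* inside one clade can
concentrate all signal onto a handful of early branches (or the excluded
stem), which limits the power of the per-branch rank test — an effect worth
keeping in mind when interpreting modest flagged fractions.

## Numerical choices

* Exact Mann-Whitney cutoff at pooled n = 12 (configurable): per-family
  contrasts typically involve tens of branches, where the corrected normal
  approximation is standard, while small fixtures stay exact.
* All flags and decisions are recomputed from the stored `p` columns and
  one BH pass — no hidden state in reports.
* Reports are plain TSV with a provenance comment line (package version,
  seed, configuration hash over the scientific settings only), so reruns
  of identical configurations are byte-identical.
* Skipped units (zero-length branches, OGs below support floors, dropped
  pathways, sub-floor superpathways) are logged via
  `options(cladevol.verbose = TRUE)` and excluded before multiple-testing
  correction.

## Running the pipeline

```{r pipeline, eval = FALSE}
cfg <- run_config(
  input_dir = "demo/in", output_dir = "demo/out", seed = 1,
  sim = sim_config(seed = 1, n_families = 2000,
                   clade_multipliers = c(PAR = 5),
                   omega_cv_clade = c(PAR = 0.6, ACU = 0.2))
)
simulate_dataset(cfg)   # writes tree, counts, rates, EC and pathway files
report <- run_pipeline(cfg)
report$summary
```

The same readers consume user-supplied files in place of the simulated
bundle; externally produced per-branch event tables (e.g. from a
likelihood-based tool) can be supplied through `read_events()` in place of
the built-in parsimony reconstruction.
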
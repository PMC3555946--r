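---
title: "Profiling islet miRNAs: methods and design notes"
author: "isletmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling islet miRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmir)
```

# What the package computes

`isletmir` implements a small RNA sequencing analysis chain for microRNA
(miRNA) profiling of human pancreatic islets and FACS-enriched beta-cells,
together with the two downstream analyses that make such a profile useful
for type 2 diabetes (T2D) genetics: scoring how tissue-specific each miRNA
is across a panel of tissue profiles, and testing whether the predicted
target genes of islet-expressed miRNAs are enriched for T2D association
signal. Every input the pipeline consumes can be generated by the built-in
synthetic-data module, so the whole chain is testable end to end without
external downloads.

# Read processing and quantification

**Adaptor clipping.** Single-end 50 bp reads contain a ~22 nt insert
followed by the 3' sequencing adaptor. `clip_adaptor()` removes everything
from the leftmost exact match of an adaptor prefix of at least
`min_overlap` (default 6) nt; at the 3' end of the read a prefix of the
remaining length suffices. Exact matching with a declared minimum overlap
was chosen over a heuristic mismatch-tolerant search because it is
deterministic and directly checkable against an exhaustive scan. Reads
shorter than 16 nt after clipping, and reads with more than 50% N bases
("primarily N"), are removed; length is checked first, so a read failing
both criteria is counted once, as short. Adaptor dimers clip to the empty
string and leave via the length filter.

**Three-tier alignment.** Cleaned reads are searched against three
references in priority order: contaminants (adaptor, adaptor dimers and
concatemers), then miRNA hairpins together with other ncRNAs (miRNA
prioritised over ncRNA), then the genome. The aligner is an exhaustive
Hamming-distance matcher (`align_simple()`, default 1 mismatch, no indels):
at the scale of a hairpin/ncRNA reference an exhaustive matcher is exact,
fast enough, and verifiable position by position, which keeps the counting
semantics — the interesting part — fully testable. Two declared choices
where conventions differ:

* **Priority before distance.** A 1-mismatch hairpin hit beats a 0-mismatch
  ncRNA hit; minimum edit distance is applied only *within* the winning
  class. The alternative (global minimum distance, then priority) is
  defensible; the class-first reading matches how a tiered search is
  normally run.
* **Strandedness.** Small RNA libraries are stranded, so the contaminant,
  hairpin and ncRNA tiers are searched sense-only; the genome tier searches
  both strands.

**Mature / star windows.** A hairpin hit is classified `mature` (or `star`)
when the read interval lies entirely within the annotated mature (star)
window extended by 3 nt on each side; otherwise `hairpin_only`. Mature is
checked before star, and ties across windows resolve mature > star >
hairpin-only. All coordinates are 0-based half-open internally; 1-based
inputs (variant positions) are converted at the reader boundary.

**Fractional counting.** A read mapping equally well to k features
contributes 1/k to each ("1/k counting"), with k the number of distinct
surviving feature targets within the winning reference; splitting is not
applied across reference tiers. Contaminant reads are excluded entirely.
Column sums of the resulting count matrix therefore equal the number of
mapped, non-contaminant reads per library — an invariant the tests enforce
to 1e-9. Features seen fewer than 100 times across all libraries are
dropped as background; a feature at exactly 100 is retained (the boundary
is declared, since "less than 100 excluded" and "more than 100 expressed"
leave 100 itself ambiguous).

# Normalization

Libraries differ in depth, so counts are scaled by a per-library inflation
factor, the median-of-ratios estimator:
$$ i_l = \mathrm{median}_g \left( \frac{n_{gl}}{\mathrm{GM}_g} \right), $$
with $\mathrm{GM}_g$ the geometric mean of feature $g$ across libraries.
Features with a zero anywhere are excluded from the median (their geometric
mean is zero and the ratio undefined); an even number of qualifying
features takes the arithmetic midpoint of the central pair. Expression is
then $\log_2(n_{gl}/i_l)$; with the default pseudocount of 0, zero counts
map to `-Inf`, an explicit below-detection sentinel that downstream
correlations treat as missing (pairwise-complete). A linear-scale
counterpart $n_{gl}/i_l$ feeds the specificity module's minimum-expression
filter, which plainly operates on linear counts (log2 values could not
plausibly sum to 1000).

One subtlety worth recording: median-of-ratios is *not* invariant to
rescaling a single library in isolation (scaling library $l$ by $c$ scales
$i_l$ by $c^{(L-1)/L}$, not $c$). What does hold, and what the tests
assert, is that proportional libraries receive proportional factors and
identical normalized columns, and that within-library expression
differences are depth-invariant.

# Tissue specificity

The tissue panel is a matrix of linear normalized counts, one profile per
tissue (replicate libraries averaged; an islet profile and a beta-cell
profile would likewise be combined by averaging before comparison, since
they are far more similar to each other than to any other tissue). miRNAs
with fewer than 1000 normalized reads summed across the panel are dropped.

**Profile merging.** Near-duplicate tissues (e.g. two liver datasets)
would dilute specificity scores, so profiles are clustered and redundant
ones merged: the Spearman correlation matrix between profiles is computed
on log2 values (pairwise-complete over the detection sentinel), tissue
distance is the *Euclidean distance between correlation-matrix rows* — the
scale on which a 0.25 cut is dimensionally sensible — and single-linkage
clusters joined strictly below height 0.25 are averaged (arithmetic mean
of the linear vectors). Spearman was chosen because rank correlation is
the package's reproducibility metric throughout; 1 − r distance is the
common alternative and is deliberately not used.

**Score and calls.** The specificity score of miRNA $m$ in profile $t$ is
$s(m,t) = x(m,t) / \sum_{t'} x(m,t')$, the fraction of the miRNA's summed
normalized expression attributable to that profile; rows sum to 1, and a
score strictly greater than 0.5 defines tissue-specificity (at most one
call per miRNA). The score is invariant to rescaling a miRNA's whole row
but not to rescaling a single profile — an asymmetry the tests pin down.

**Permutation FDR.** The null for a call "(m, t)" is that m's expression
vector carries no tissue information: the vector is permuted across
profiles — preserving the miRNA's marginal abundance, the minimal
exchangeability behind a row-normalized score — and the recomputed score
*at the called profile* is compared to the cutoff. The FDR estimate is the
mean number of recurring calls per permutation divided by the observed
call count. The positional evaluation is essential: permuting a row leaves
its score multiset unchanged, so counting null calls anywhere in the
matrix would return FDR = 1 identically and estimate nothing. For a miRNA
dominated by one profile the per-call chance level is 1/T, so a panel of
~11 merged profiles yields estimates around 8–9%, and the package's
default 8-tissue panel (7 profiles after merging) around 14%. Shuffling
within profiles instead (preserving tissue marginals) was considered and
rejected: with realistically heavy-tailed abundances, scale mixing across
rows manufactures spurious dominance and the estimator saturates near 1
regardless of how much true specificity is present. The default is 10,000
permutations (1,000,000 is the published scale; the estimator is unbiased
in the number of permutations, so desk-scale runs only widen the Monte
Carlo error).

# LD proxies, overlap, and target-set enrichment

**LD.** $r^2$ between variants is computed on phased haplotypes,
$(p_{AB} - p_A p_B)^2 / (p_A(1-p_A)p_B(1-p_B))$; proxies of a lead are
panel variants with $r^2$ strictly greater than 0.8, searched panel-wide
(no window is imposed — a declared choice). Monomorphic variants have
undefined $r^2$ and fail loudly as leads.

**Overlap.** A variant at 1-based position p hits a 0-based half-open
interval [start, end) iff start ≤ p−1 < end; strand is ignored (a SNP
hits a target site regardless of orientation). Pairs collapse to distinct
(locus, variant) counts for locus-level summaries.

**Enrichment.** Each gene's raw score is the minimum association p-value
over the variants in its body (window 0 bp by default; MAGENTA-style
windows are available via an argument). Because minimum-p scores are
confounded by transcript span, variant count and local LD, −log10 raw
scores are regressed on those three confounders by least squares and the
residual is the adjusted score — a deliberately simple, transparent
correction with the same structure as the published one. The test statistic
for a gene set is the number of members strictly above the 75th percentile
of *all* scored genes' adjusted scores; the null is the count in random
same-size draws of genes without replacement, and
$p = (1 + \#\{null \ge obs\})/(B+1)$ with $B = 10{,}000$ by default
(100,000 in the published setting). The null count in a size-s draw
without replacement is exactly hypergeometric, so the implementation
samples it directly with `rhyper`; a test verifies distributional equality
against explicit `sample()` permutations. Sets with fewer than 3 scored
members are excluded and reported.

**Multiple testing.** Storey robust q-values: $\pi_0$ from the cubic-
polynomial smoother on $\lambda = 0.05, \dots, 0.95$ evaluated at 0.95
and clamped into (0, 1] (fixed at 1 below 10 p-values, where the smoother
is unstable), robust denominator $i\,(1-(1-p_i)^m)$, running-minimum
monotonicity. A set is significant at p < 0.01 *and* q < 0.1, both strict.
(A stricter p < 0.001 display threshold appears in some summaries of this
kind of analysis; the Methods-level 0.01 is the default and the threshold
is an argument.)

# The synthetic-data module

The generators produce data with exactly the structure the analysis
assumes, plus ground-truth files so recovery is never judged against the
pipeline under test. All generators are pure functions of
(configuration, seed).

* **Reference** (`make_reference()`): hairpins of ~70–90 nt with one
  mature and one star window each (lengths 20–24 nt peaking at the
  canonical 22), the first two hairpins sharing an identical mature
  sequence to exercise 1/k splitting; contaminants containing the adaptor,
  a dimer and a read-length concatemer; genome contigs embedding each
  hairpin in random flank.
* **Reads** (`simulate_reads()`): 50 bp reads (matching the sequenced read
  length, so short inserts read through into adaptor), ±2 nt end jitter as
  a minimal isomiR model, star reads at 5%, 5% adaptor-dimer reads, 1%
  N-dominated reads, library depths log-normal (sdlog 0.3) around the
  target. Sequencing error and quality modelling are deliberately out of
  scope.
* **Tissue panel** (`simulate_tissue_panel()`): log-normal miRNA
  abundances with sdlog 1.2, chosen so that on a 60-miRNA reference a few
  dozen miRNAs carry ~90% of reads ("medium complexity"); Dirichlet(3)
  tissue weights; twelve planted tissue-specific miRNAs with 85% of their
  expression in the designated tissue, drawn from the moderately-to-highly
  expressed band (1–2 sdlog above median) because specificity is only
  discoverable for miRNAs that clear the expression filter; the last two
  tissues are near-duplicates (weights copied with 5% log-normal noise) to
  exercise branch averaging; Poisson counts.
* **GWAS** (`simulate_gwas()`): 120 haplotypes with block LD (blocks of 10
  variants, each column copied from its neighbour with 5% per-site flips,
  giving a tunable r² spectrum with an analytic check); uniform null
  p-values; planted enriched sets draw members from a shared pool of
  associated genes — mimicking the heavy target overlap of miRNAs that
  share a seed family — whose variants get $p = u^{5}$ by default; gene
  span and variant count arise organically as confounders (longer genes
  catch more variants, hence smaller minimum p even under the null, which
  is precisely what the adjustment step must remove).

What the generators do *not* emulate: sequencing error, isomiR biology
beyond end jitter, population structure, imputation uncertainty, and
cross-tissue batch effects. Passing tests therefore demonstrate the
correctness and calibration of the computations, not robustness to every
artefact of real libraries.

# Numerical conventions and edge cases

* Strict inequalities wherever the analysis defines a threshold: score
  > 0.5, r² > 0.8, p < 0.01, q < 0.1, merge heights strictly below the
  cut; and inclusive boundaries where declared: ≥ 16 nt, ≥ 100 raw reads,
  ≥ 1000 normalized reads.
* Zero expression: all-zero score rows are NA ("undefined"), zero observed
  calls make the FDR undefined rather than 0/0, no all-positive feature
  makes inflation factors fail loudly.
* Permutation p-values carry the +1 correction and respect their floor
  1/(B+1).
* Collinear confounders are dropped with a warning rather than silently
  regularized.

# Scale of the shipped checks

The test-suite and acceptance-script problem sizes are the package's
defaults: 60 hairpins, 8 tissues, ~10,000 reads per library, 6,000
variants / 1,500 genes / 60 gene sets, 10,000 permutations for single
enrichment runs, 200–2,000 for replicate sweeps; 50 replicate panels for
specificity recovery and 100 replicate GWAS for enrichment power. Null
calibration pools 500 sets across 10 independent null simulations, because
sets tested within one simulation share a score vector whereas the
calibration claim is about the marginal distribution of the p-value.

# A small worked example

```{r example}
cfg <- sim_config(seed = 1, n_hairpins = 20, reads_per_library = 2000)
sim <- simulate_tissue_panel(cfg)
ts <- tissue_specificity(sim$counts, sim$tissue,
                         n_permutations = 1000, seed = 1)
head(ts$calls)
ts$fdr
```

# Known limitations

* The aligner is substitution-only; indel-bearing reads go uncounted.
* The confounder adjustment is a linear model on three covariates; it
  removes linear trends, not arbitrary dependence.
* The permutation FDR is a per-call chance-level estimate under row
  exchangeability; under a fully exchangeable (no-signal) panel every call
  is false and the realized false proportion exceeds the estimate — as for
  any selection-conditioned permutation argument.
* Discrete test statistics make permutation p-values slightly conservative
  at small set sizes; the q-value machinery inherits that conservatism.
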
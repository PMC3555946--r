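# isletmir

Small RNA-seq miRNA profiling for pancreatic islets and beta-cells, with
tissue-specificity scoring and GWAS target-gene enrichment.

## The problem

MicroRNAs (miRNAs) are ~22 nt regulators of mRNA stability and
translation, and several (miR-375 most prominently) control
glucose-stimulated insulin secretion in the pancreatic beta-cell. Working
out which miRNAs a tissue like the islet actually expresses — and whether
the genes those miRNAs are predicted to target carry type 2 diabetes (T2D)
association signal — takes a chain of careful computation: adaptor
clipping of 50 bp small RNA reads, alignment against contaminant / hairpin
/ ncRNA / genome references with principled handling of multi-mapping
reads, depth normalization, cross-tissue specificity scoring with a
permutation false-discovery rate, linkage-disequilibrium (LD) expansion of
GWAS lead variants, and a percentile-cutoff permutation test for gene-set
enrichment. `isletmir` implements that chain as an R package, for anyone
who analyses small RNA sequencing of endocrine (or any other) tissue and
wants every step testable.

## The statistics at the core

* **Fractional counting:** a read mapping equally well to *k* features
  adds 1/*k* to each, within one reference tier; tiers are prioritised
  contaminant → miRNA > ncRNA → genome, and hairpin hits are split into
  mature / star / hairpin-only by windows extended 3 nt each side.
* **Median-of-ratios normalization:**
  `i_l = median_g( n_gl / GM_g(n_g·) )`, then `log2(n_gl / i_l)`.
* **Tissue-specificity score:** `s(m,t) = x(m,t) / Σ_t' x(m,t')` over
  merged tissue profiles (single-linkage on correlation-row Euclidean
  distance, branches below 0.25 averaged); `s > 0.5` calls a miRNA
  tissue-specific, with a permutation FDR from within-miRNA shuffles
  evaluated at the called profile.
* **LD proxies:** haplotype `r² = (p_AB − p_A p_B)² / (p_A(1−p_A)p_B(1−p_B))`,
  strong LD meaning `r² > 0.8`.
* **Enrichment:** genes scored by minimum variant p-value, adjusted for
  transcript span / variant count / LD proxies by least-squares residuals;
  a set's statistic is its member count above the 75th percentile of all
  adjusted scores, with a permutation p-value
  `(1 + #{null ≥ obs}) / (B + 1)`, Storey robust q-values, and
  significance at `p < 0.01` and `q < 0.1`.

A synthetic-data module (`sim_config()`, `make_reference()`,
`simulate_reads()`, `simulate_tissue_panel()`, `simulate_gwas()`)
generates every input with the structure the analysis assumes — planted
tissue-specific miRNAs, near-duplicate tissue profiles, block LD, planted
enriched gene sets — alongside ground-truth files.

## A worked example

```r
library(isletmir)
cfg <- sim_config(seed = 1, n_hairpins = 20, reads_per_library = 2000)
sim <- simulate_tissue_panel(cfg)
ts  <- tissue_specificity(sim$counts, sim$tissue,
                          n_permutations = 1000, seed = 1)
head(ts$calls)
#>       mirna profile     score
#> 1   mir1-5p   islet 0.8759976
#> 8  mir10-5p tissue4 0.8505767
#> 10 mir11-5p tissue5 0.8551075
#> 12 mir12-5p tissue6 0.9063560
#> 3   mir2-5p tissue2 0.8408247
#> 5   mir3-5p tissue3 0.8745190
ts$fdr
#> Permutation FDR at score > 0.5: 12 observed calls, 1.661 expected under
#> the null (1000 permutations) -> FDR 0.1384
```

All twelve planted tissue-specific miRNAs are called in their planted
tissues with scores near the planted 0.85 fraction, and the permutation
FDR sits at the positional chance level (~1/T for T = 7 merged profiles:
the two near-duplicate tissues in the simulation were merged first).

The miR-375 abundance arithmetic — 42% of beta-cell reads versus 27% of
islet reads — is one function call:

```r
fold_enrichment(42, 27)
#> [1] 1.555556            # the ~1.5-fold beta-cell enrichment
deconvolve_two_populations(27, 42)
#>          beta      non_beta beta_fraction
#>    45.7500000     8.2500000     0.8472222
```

i.e. with islets ~50% beta-cells and FACS preparations ~90% pure, ~85% of
miR-375 expression is attributable to beta-cells.

A command-line veneer covering each stage
(`simulate`, `preprocess`, `quantify`, `normalize`, `specificity`,
`overlap`, `enrich`) ships as `inst/scripts/isletmir.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/isletmir.R", package="isletmir"))')" \
  simulate --seed 4 --out sim/
```

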
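# heterosiskit

Analysis toolkit for **heterosis** (hybrid vigor) in hybrid–parent
trios under thermal stress, built for studies that pair a physiological
thermal-limit assay with triad RNA-seq: two parental populations (P1,
P2) and their F1 hybrid, each sampled under a control and a heat
condition.

It is aimed at researchers asking *why* an interspecific hybrid — e.g. a
hybrid abalone — tolerates heat better than either parent, and who need
the standard chain of computations from raw measurements to candidate
genes, reproducibly and with testable ground truth.

## What it computes

**Arrhenius break temperature (ABT).** Cardiac thermal limits from
heart-rate ramps. A trace is transformed to Arrhenius coordinates,
`y = ln(bpm)` vs `x = 1000/(T + 273.15)`, and a two-segment least-squares
regression locates the break: the split of the series minimizing the
total residual sum of squares over all admissible splits, each side
fitted by OLS. Group ABTs are compared by one-way ANOVA with pairwise
mean differences in °C.

**Dominance-mode classification.** Per gene, the ratio of the hybrid's
deviation from the mid-parent to the parental gap,

```
d/|a| = (F1 - (P1 + P2)/2) / |P1 - P2|
```

is classified into additive (ADD, `[-0.2, 0.2]`), positive/negative
partial dominance (PPD `(0.2, 0.8]`, NPD `[-0.8, -0.2)`), high/low-parent
dominance (HPD `(0.8, 1.2]`, LPD `[-1.2, -0.8)`), and over-/under-
dominance (ODO `(1.2, ∞)`, UDO `(-∞, -1.2)`). Genes with equal parents
are reported separately (`PARENT_EQUAL`), and both the full-gap and the
classical half-gap denominator conventions are available.

**Differential expression (stand-in).** TMM normalization (doubly
trimmed, precision-weighted mean of M-values) to CPM, then a per-gene
Welch test on `log2(CPM + 0.5)` between control and heat within a
population, BH-adjusted, significant at FDR < 0.05 and |log2FC| > 1.
This is a deliberate, documented stand-in for a count-model DE fit —
downstream analyses only consume the gene sets.

**Splicing divergence.** Percent-spliced-in from junction counts,
`psi = (I/lI) / (I/lI + S/lS)`; events tested on replicate psi (Welch or
exhaustive permutation), then filtered exactly as published: mean
junction reads > 5 (strict), |Δψ| ≥ 0.1 (inclusive), FDR < 0.05.

**Integration.** Exact Venn partitions of gene sets, the candidate
cascade `Common_DEGs ∩ H_ODO_NAGs ∩ SD_DAGs` (three-way DEG intersection
∩ heat-condition over-dominant genes ∩ hybrid divergently-spliced
genes), and hypergeometric over-representation tests against a
user-supplied pathway map.

**Synthetic data.** Generators with planted ground truth for all three
input types — NB triad counts with planted dominance classes, piecewise
Arrhenius cardiac traces with a known break, and replicated splice-event
junction tables with planted Δψ — so the entire pipeline installs, runs
and validates with no external data.

## Worked example

```r
library(heterosiskit)

# simulate a 2000-gene triad and classify hybrid expression modes
sim   <- simulate_triad_counts(triad_sim_config(n_genes = 2000, seed = 1))
calls <- classify_matrix(sim$counts, sim$samples,
                         condition = "heat", normalization = "log2")
summarize_modes(calls)
#> Hybrid expression modes: 2000 genes classified
#> Non-additive: 1867 (93.35%)
#> Class shares (of non-additive genes):
#>   class n   pct
#> 1 UDO   524 28.07
#> 2 LPD    99 5.30
#> 3 NPD   188 10.07
#> 4 ADD   133 7.12
#> 5 PPD   183 9.80
#> 6 HPD   100 5.36
#> 7 ODO   773 41.40

# cardiac trace with a true break at 32 degC, estimated from noisy data
trace <- simulate_cardiac_trace(cardiac_sim_config(true_abt_celsius = 32,
                                                   noise_sd = 0.05, seed = 1))
fit_breakpoint(arrhenius_transform(trace$trace))
#> Two-segment Arrhenius fit (181 points)
#> ABT: 32.10 degC (break after point 122)
#> Slopes (y vs 1000/K): left -5.987, right 29.205; total RSS 0.3732
```

The mode summary reads: of 2000 simulated genes, 93.35% express
non-additively in the hybrid under heat, and over-dominant genes are
the largest class (41.40% of non-additive genes) — mirroring the planted
class mix. The ABT fit recovers the planted 32 °C break to within one
0.1 °C ramp step under realistic noise.

`run_pipeline(pipeline_config(...))` chains normalization, per-population
DE, mode classification, the splice filter and integration, writing
stamped TSV outputs and a JSON manifest; reruns with the same seed are
byte-identical. A thin CLI wrapper lives at
`inst/scripts/heterosiskit.R`.

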
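# paleomic

Total DNA extracted from ancient permafrost is a mixed archive of the past
and the present: extracellular DNA (eDNA) liberated from long-dead, lysed
cells persists for tens of millennia next to intracellular DNA (iDNA) from
intact cells that may be living, dormant, or dead. Sequence presence alone
therefore cannot say whether a genome recovered from frozen sediment belongs
to a fossil population or to one that is still metabolically active.

`paleomic` implements, as tested and seed-reproducible R code, the
measurement framework that makes that call from physical evidence:

* **Taphonomy simulator with ground truth.** Reference genomes of chosen GC
  and abundance are fragmented (lognormal lengths: ~100–300 bp relic DNA vs
  >10 kb intact DNA), deaminated with the canonical ancient-DNA 5' overhang
  enrichment `P(C→U at offset p) = δ_ds + (δ_ss − δ_ds)·q^p` (mirrored as
  G→A from the 3' end), and loaded with Poisson nicks and blocking lesions.
  Fragments are partitioned into iDNA/eDNA pools by vitality, optionally
  repaired (each lesion reverted with probability ρ), and sequenced into the
  2×2 iDNA/eDNA × ±repair library design; a fragment converts to the library
  with probability `(1 − π)^#blocking lesions`. FASTA/FASTQ/SAM/TSV out.
* **Damage profiler.** Position-specific C→T (5') and G→A (3') frequencies
  over the first 25 read positions from SAM alignments, plus a deterministic
  box-constrained least-squares fit of `(δ_ss, δ_ds, q)`.
* **Repair assay.** Windowed breadth-of-coverage completeness per genome and
  library, the repaired-vs-unrepaired regression against the theoretical 1:1
  line, unique-read fractions, fragment-size quantiles, eDNA/iDNA yield
  ratios and cell-count conversion (2×10⁻¹⁵ g DNA/cell).
* **Aspartate racemization clock.** Arrhenius rate `k = A·e^(−Ea/RT)` and
  the kinetic law `ln[(1+D/L)/(1−D/L)]_t − ln[(1+D/L)/(1−D/L)]_0 = 2kt`,
  solved as `D/L(t) = tanh(kt + artanh(D/L₀))`, with exact age inversion and
  a predicted-vs-observed report (observations far below the kinetic
  prediction indicate active protein turnover, i.e. living biomass).
* **Replication index.** Peak-to-trough coverage ratio on a smoothed
  circular profile with dnaA/dif locus concordance checks (> 0.8) and a
  strain-heterogeneity gate (< 0.3).
* **Classifier.** A four-rule decision table mapping per-fraction presence,
  unrepaired damage scores (< 0.1 ⇒ undamaged) and repair-induced
  completeness gains (|Δ| < 0.05 ⇒ negligible) to
  `living / fossil_intracellular / fossil_extracellular / ambiguous`, with
  advisory (upgrade-only) protein evidence via balanced spectral counts.

## Worked example

```r
library(paleomic)

# the aspartate clock at permafrost conditions
k <- arrhenius_rate(arrhenius_params())   # Ea 101.7 kJ/mol, A 1.43e15 /yr, -7.7 C
k
#> [1] 1.387782e-05
predict_dl(k, c(26000, 100000))           # D/L after 26 and 100 kyr
#> [1] 0.3459391 0.8826820

# a three-population community through the full pipeline
res <- run_scenario(default_scenario(seed = 1))
res
#> <scenario_result> 3 populations, 4 libraries, seed 1
#>   calls:
#>     young_living    -> living (truth: living)
#>     fossil_aerobe   -> fossil_intracellular (truth: dead_intact)
#>     lysed_relic     -> fossil_extracellular (truth: lysed)
#>   vitality->label accuracy: 1.00
#>   repair regression: slope 0.028, r 0.755, mean delta +0.2600
#>   eDNA/iDNA mass ratio: 0.299
```

The three populations carry identical damage parameters within their
vitality class, yet the evidence separates them: the living genome shows a
damage score at the sequencing-error floor and no response to repair; the
intact dead genome is heavily deaminated (score ≈ 0.3 at the terminal
position) and gains ~0.5 in completeness when repaired; the lysed genome is
absent from the iDNA fraction entirely. `res$evidence` holds the per-bin
numbers behind each call and `res$calls$rationale` the rule trace.

Scenario configurations can also be read from YAML
(`read_scenario(system.file("extdata", "default-scenario.yaml",
package = "paleomic"))`) and written to disk with full artifacts and a
checksum manifest via `run_scenario(cfg, out_dir = "out")`.

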
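---
title: "Discriminating fossil from living microorganisms: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating fossil from living microorganisms: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomic)
```

## The problem

Perennially frozen sediment preserves DNA exceptionally well, so a
metagenome from ancient permafrost mixes three kinds of source material:
genomes of metabolically active cells, genomes locked inside structurally
intact dead cells, and extracellular relic DNA from cells that lysed long
ago. Presence of a genome says nothing about vitality. Three physical
signals do:

1. **Accumulated DNA damage.** Post-mortem cytosine deamination (read as
   C→T) concentrates at fragment 5' termini; strand breaks and blocking
   lesions (abasic sites, dimers) stop library conversion. Living cells
   repair these continuously.
2. **Response to in-vitro repair.** A glycosylase/endonuclease cocktail
   applied before library preparation rescues damaged templates. If DNA is
   intact, repaired and unrepaired libraries recover a genome equally well —
   paired completeness falls on the 1:1 line; fossil DNA shifts up.
3. **Aspartate racemization.** Protein-bound L-aspartate racemizes toward
   D/L = 1 at a temperature-dependent rate after death; active protein
   turnover resets it. Observed D/L far below the age prediction means
   living biomass.

`paleomic` implements all three measurements, a simulator that produces
ground-truthed test beds for them, and a decision table that integrates the
evidence per genome.

## The taphonomy model

Each population carries a `damage_params` set:

| parameter | meaning | unit | typical fossil value |
|---|---|---|---|
| `delta_ss` | deamination probability in single-stranded overhangs | per C site | 0.3 |
| `delta_ds` | deamination probability in duplex DNA | per C site | 0.01 |
| `overhang_decay` (q) | geometric persistence of the overhang effect | – | 0.6 |
| `nick_rate` | single-strand breaks | per bp | 0.005 |
| `blocker_rate` | abasic sites / dimers | per bp | 0.01 |
| `frag_mu`, `frag_sigma` | lognormal fragment length (log scale) | log bp | log(200), 0.5 |

A cytosine at 0-based 5' offset `p` deaminates with probability
`delta_ds + (delta_ss − delta_ds) · q^p`; guanines mirror the process from
the 3' end (they are cytosines of the complementary strand, read as G→A).
This overhang-decay form is the standard ancient-DNA phenomenology: only
the 5' C→T channel is commonly measured, and the two-parameter-plus-decay
law reproduces the observed monotone terminal enrichment. Fragment lengths
are truncated lognormal on [30 bp, genome length]: relic DNA sits in the
~100–300 bp regime, intact DNA above 10 kb.

Living populations default to zero lesion rates. The simulator short-cuts
sequence inspection in that case, which is what makes high-molecular-weight
intact DNA cheap to simulate; the damage floor observed for living genomes
is then set by the sequencing error rate, as in real data.

Library conversion failure is the mechanism by which damage hides genomes:
a fragment converts with probability `(1 − π)^b` where `b` counts its
surviving blocking lesions (nicks + blockers) and `π` (`block_prob`,
default 0.9) is the per-lesion failure probability. Repair removes each
lesion independently with probability ρ (`repair_efficiency`, default 1;
no efficiency is published for the enzyme cocktail, so complete repair is
the reference point). Reads are taken from the fragment 5' end
(ligation-style; terminal damage stays read-visible), clipped to the
fragment when it is shorter than the read length.

### What the generator emulates, and what it does not

Emulated: the three vitality classes and their iDNA/eDNA routing;
age-contrasted fragment-size regimes; 5'-enriched deamination with 3'
symmetry; conversion failure at blocking lesions and its reversal by
repair; the 2×2 fraction × repair design with paired random streams;
replication-driven origin-to-terminus coverage skew; sequencing error.

Not emulated: PCR amplification bias, adapter chimeras, paired-end inserts,
quality-score miscalibration, real enzyme kinetics, assembly and binning.
Passing tests therefore demonstrate that the *measurements* recover the
*simulated* processes; they do not certify behaviour under artifacts the
generator omits (e.g. mapping error against diverged references).

### Pool sizes and random streams

Fragment counts are set by `fragment_redundancy` (default 5): each
population contributes `redundancy × genome_length / min(median fragment,
read length)` distinct templates, scaled by relative abundance. This models
the attrition-limited template pool of relic DNA and places unrepaired
fossil libraries in the breadth-limited regime where repair visibly rescues
completeness. Living populations are given a 4× larger pool: fresh DNA from
active cells is not attrition-limited, and the larger pool keeps their
coverage statistics smooth in libraries whose depth is shared with rescued
fossil templates.

All randomness derives from one master seed through fixed labels
(`derive_seed(seed, "taphonomy-<id>")`, …). The read-sampling stream of a
library is keyed by its *fraction only*, not by the repair flag: repaired
and unrepaired libraries of a fraction draw the same conversion and
sampling randomness, so for undamaged DNA the two libraries are identical
read-for-read and the 1:1-line contrast is exactly paired (common random
numbers). `library_spec` exposes a `downsample` factor (1 by default; 0.8
mimics the lower read yield often seen in repaired libraries) — it is off
by default because the paired contrast, not the yield difference, is the
assay's subject, and a yield cut biases completeness for depth-limited
bins.

The iDNA/eDNA partition leaks a fraction of each population to the minority
pool: living 0.23 (which reproduces a young-stratum eDNA/iDNA mass ratio of
about 0.3 = 0.23/0.77), intact-dead 0.2, lysed 0. How much eDNA derives
from recently expired living cells versus ancient lysis is not established;
the leakage parameter exposes the choice, and the lysed default of 0 makes
the extracellular signature exact rather than asserting a biological value.

## Measurements

**Damage profile.** For every aligned read, reference-C positions within 25
bp of the read 5' end are opportunities; C read as T increments the
numerator (other mismatches do not). G→A is tallied symmetrically from the
3' end. Reverse-strand alignments are reoriented first; indel columns are
skipped; soft-clips are excluded; overlapping reads count independently.
The scalar damage score is the terminal-position frequency `ct5[1]` —
the most damage-enriched coordinate. The parametric fit profiles the
amplitude out by linear least squares over a deterministic grid on `q`,
then refines with box-constrained quasi-Newton; a flat profile returns the
common level with `q_identifiable = FALSE` rather than an arbitrary decay.

**Completeness.** Windowed breadth of coverage: 500 bp windows, recovered
iff mean depth ≥ 1. Marker-gene completeness would need annotation
machinery; the paired repaired-vs-unrepaired contrast only needs a recovery
measure that responds to conversion failure, which breadth does directly.
The regression puts unrepaired on x and repaired on y.

**Racemization.** `k = A·exp(−Ea/(R·T))` with Ea = 101.7 kJ/mol,
A = 1.43×10¹⁵ /yr, R = 8.314×10⁻³ kJ/(K·mol); the kinetic law integrates
to `D/L(t) = tanh(k·t + artanh(D/L₀))`. The tanh/artanh formulation is
used instead of the exponential ratio so saturating arguments neither
overflow nor leave [0, 1); outputs are clamped just below 1 at the double-
precision boundary. The initial ratio defaults to 0 (none is published;
the ±0.02 comparison band absorbs it — at 26 kyr the linearized small-ratio
solution gives 0.361 while the exact tanh gives 0.346, both inside the
band, and the exact solution is reported). Default temperature −7.7 °C
(265.45 K, 273.15 offset), the mean of the measured −7 to −8 °C range.

**Replication index.** Coverage in 1 kb circular bins, moving-average
smoothed (default window 10 bins; parameter-recovery simulations use 15 on
300 kb genomes, where the wider window trades a ~3% amplitude attenuation
for much lower extreme-value noise). Origin = argmax, terminus = argmin,
index = ratio ≥ 1, invariant to uniform scaling and bin rotation. The
published validity criterion is stated in two mutually contradictory
directions; this implementation treats locus *concordance* as validating —
dnaA-bin/peak and trough/dif-bin coverage ratios must both exceed 0.8 —
plus strain heterogeneity below 0.3 (heterogeneity is a scenario input, not
estimated). Fragments are placed on a linear chromosome; edge attenuation
is negligible when fragments are much shorter than a bin, which the
recovery simulations respect.

**Classifier.** The decision table is total and deterministic: (1) eDNA-only
presence → `fossil_extracellular`; (2) iDNA presence with damage < 0.1 and
|Δcompleteness| < 0.05 in every present fraction → `living`; (3) iDNA
presence with damage or repair gain at threshold → `fossil_intracellular`;
(4) otherwise `ambiguous`. The damage bound 0.1 is the descriptive value
separating undamaged young-stratum genomes; the Δ bound 0.05 is this
package's choice (no quantitative bound is published for "negligible
impact") and both are exposed as `classification_thresholds()`. Protein
evidence (balanced spectral counts: unique spectra count 1, a spectrum
matching n proteins contributes 1/n) is corroborative only — it can upgrade
`ambiguous` to `living` when the damage clause already holds, never
downgrade. Taxon-level ecological priors (aerobe vs anaerobe) are
deliberately not encoded; calls are purely data-driven.

## Numerical and scale choices

Desk-scale problem sizes keep the full suite in minutes while leaving
comfortable statistical margins: 40 kb genomes and 15× libraries for the
three-population benchmark (damage-score standard error ≈ 0.01 for living
bins); 10⁵ reads for profile recovery (ct5[1] standard error ≈ 0.003);
300 kb genomes at 20× for replication-index recovery; 12-population
living-only panels with abundances spanning 0.15–3 for the 1:1 regression,
where the paired streams make per-bin deltas exactly zero and the spread in
x comes from abundance alone.

Degenerate inputs are handled explicitly: empty alignment sets yield
all-undefined profiles (scores propagate as `NA`, which the classifier
treats as not-callable rather than guessing); zero trough depth flags the
replication index as undefined; constant unrepaired completeness flags the
regression correlation as undefined; fragments shorter than the read are
emitted clipped with a warning.

## Known limitations

* The damage process applies a single overhang-decay law per population;
  real communities mix post-mortem ages within a taxon.
* Completeness is breadth against the *known* reference, not assembly-based
  completeness; absolute values are not comparable to marker-gene scores,
  only the paired contrast is.
* The replication index inherits the extreme-value bias of max/min
  statistics at low depth; below ~10× the index is biased upward.
* The classifier's two thresholds are calibrated to the simulated damage
  regimes; real datasets with intermediate damage will produce `ambiguous`
  calls, which is intended behaviour, not failure.
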
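---
title: "Ancestry-aware reassessment of reported pathogenic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-aware reassessment of reported pathogenic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afreclass)
```

## The problem

Variant databases accumulate "pathogenic" labels faster than they shed
them. For a rare monogenic disease, a variant that truly causes the
disease cannot be common in any ancestry: its population allele frequency
is bounded by how prevalent the disease is, how much of the genetic
burden a single variant can carry, and how reliably carriers develop the
phenotype. Large multi-ancestry panels (gnomAD-style resources plus
population-specific biobanks such as the Taiwan Biobank and the Japanese
3.5K whole-genome panel) make that bound testable per ancestry, and a
number of reported pathogenic variants turn out to be common somewhere —
most often in an ancestry the original case-control study never sampled.

afreclass implements this frequency-axis reassessment as a pipeline:

1. **registry** — read tab-delimited registry extracts, normalize HGVS
   strings, deduplicate, and merge across source databases;
2. **frequency** — load per-population allele frequencies from tables or
   from VCF `INFO` fields and annotate each variant;
3. **classify** — compute the maximum credible allele frequency, flag
   variants meeting the applied cutoff in any population, and label
   ancestry restriction;
4. **stats** — compare flagging rates between strata with an exact
   two-sided test and a Pearson chi-square;
5. **domains** — map flagged residues onto an ion-channel topology;
6. **synthetic_data** — generate seeded datasets with known ground truth.

The packaged worked example is Brugada syndrome (BrS), an inherited
arrhythmia diagnosed by a type 1 coved ST-elevation ECG and a cause of
sudden cardiac death in structurally normal hearts.

## The model

The maximum credible allele frequency of a pathogenic variant is

$$\mathrm{AF}_{\max} \;=\; \frac{\text{prevalence} \times \text{maximal allelic contribution}}{\text{penetrance}}.$$

The three parameters, with the packaged BrS defaults
(`inst/extdata/brs_params.yaml`):

| parameter | meaning | default | basis |
|---|---|---|---|
| `prevalence` | disease prevalence (proportion) | 0.0012 | East Asian populations, where BrS is most prevalent |
| `allelic_contribution` | largest share of genetic cases any single variant explains | 0.01 | no single BrS variant exceeds ~1% |
| `penetrance` | probability a carrier expresses the phenotype | 0.16 | conservative end of the 16–32.7% co-segregation range |
| `applied_cutoff` | allele frequency actually used for flagging | 0.001 | relaxes the bound by >10× |

With these values $\mathrm{AF}_{\max} = 7.5\times10^{-5}$. The applied
cutoff of $10^{-3}$ deliberately relaxes this bound by more than an
order of magnitude: some high-frequency variants show functional effects
in vitro and are better read as disease-predisposing than as benign, so
a loose first-pass cutoff avoids discarding true pathogenic variants.
The `credible_af_params()` constructor enforces the direction of that
slack as a type invariant — the applied cutoff may only relax, never
tighten, the credible bound. The penetrance default uses the lower end
of the reported range because it maximizes the bound, which is again the
conservative choice for flagging.

This is the plain ratio form of the bound. Two refinements are
deliberately not modeled: the factor of ½ for strictly monoallelic
architectures, and the confidence-interval-based "filtering allele
frequency" that accounts for sampling noise in small panels. Both would
tighten the bound; the pipeline applies the printed ratio exactly, and a
CI-based cutoff is a possible extension, not implemented.

## Flagging and ancestry restriction

A variant is *flagged* (of questionable pathogenicity) when its allele
frequency in **at least one** population meets the applied cutoff. The
comparison is inclusive (`>=`): the packaged fixture contains one cell
printed exactly at 0.001 (SCNN1A R350Q in the Japanese panel), and under
the inclusive rule it flags. A printed 0.001 could be the rounding of a
value just below the cutoff in the source resource; the rule is applied
uniformly rather than special-casing that cell.

Absent frequencies (variant not seen by a resource) are kept distinct
from explicit zeros for provenance, but both sit below any positive
cutoff, so flagging treats them identically. When the same (variant,
population) pair appears in two resources the **maximum** is kept — the
conservative choice for questioning pathogenicity — and a message is
emitted.

A flagged variant is *restricted* to a population group when every
population in which it meets the cutoff belongs to that group. The
grouping is configuration, not code. The packaged Asian group is
`{EAS, SAS, JEW, JPN3K, TWB}`, which calls for a caveat: `JEW` is the
Ashkenazi Jewish panel of the gnomAD-style resource and `SAS` the South
Asian one, and neither is East Asian. This grouping is the one under
which the worked example's own arithmetic is internally consistent
(14 of 18 flagged variants Asian-restricted, including all flagged
non-SCN5A variants except the RANGRF stop-gain and the two SCN10A
variants), so it ships as the default — but users studying a specific
ancestry should edit the grouping in the YAML config, and the pipeline
recomputes everything downstream. Narrowing the group to
`{EAS, JPN3K, TWB}` drops the restricted count from 14 to 8, which
`reproduce_brs_summary(grouping = ...)` will demonstrate.

## Stratum comparisons

Strata are compared on 2×2 tables (stratum × flagged). Because a
published flagged-variant table usually ships without the full registry
behind it, `compare_strata()` accepts the stratum denominators as an
override (`totals_override`); the worked example takes them from the
packaged marginal counts (440 variants, 385 SCN5A, 405 HGMD, 68 ClinVar,
113 radical, 304 missense).

Both tests are always computed and reported side by side:

* `fisher_exact_two_sided()` — exact conditional test. The two-sided
  p-value follows the point-probability (minimum-likelihood) convention
  of mainstream statistical software: the sum of all hypergeometric
  point probabilities no greater than the observed one. Ties are
  included up to a relative tolerance of $10^{-12}$, and the sum is
  accumulated in log space. The test suite checks this implementation
  against exhaustive enumeration for every 2×2 table with total at most
  60 (628,055 tables) at $10^{-12}$ relative error, and against
  `stats::fisher.test()` on random tables.
* `chi_square()` — Pearson statistic on 1 degree of freedom, without
  continuity correction by default (a `yates` flag enables it), checked
  against `stats::chisq.test()`.

No multiple-testing correction is applied, matching the analysis the
package reproduces. Percentages are rounded to one decimal only at the
reporting layer.

## Protein topology

`topology_map()` holds an ordered, gap-free, non-overlapping list of
1-based inclusive residue segments labelled `VSD`, `pore`,
`other-transmembrane`, `extracellular` or `cytoplasmic`. The packaged
SCN5A map (`scn5a_topology.tsv`, NM_198056.2 numbering, 2016 residues)
follows the standard four-repeat Nav1.5 architecture with one
deliberate convention: only the S4 helices — the voltage-sensing
elements proper — are labelled `VSD`; S1–S3 are `other-transmembrane`,
and each repeat's S5–P–S6 module is one `pore` segment. Under the
common broader convention (VSD = S1–S4) the six flagged SCN5A variants
would tally two VSD residues and no other-transmembrane one, which
contradicts the reassessment this package reproduces (1 VSD, 1 pore,
1 other-transmembrane, 3 cytoplasmic, with D1243 in the DIII S1–S4
region but outside S4). The segment boundaries are approximate —
UniProt-style annotations differ by a few residues between releases —
and only six assignments are contract-tested (A226 in the DI S4, V1340
in the DIII pore module, and R27/R1023/D1243/A1924 as above). The map
is a data file: users with a preferred boundary set edit the TSV, not
the code.

Variants without a parseable protein position (splice-site changes) are
reported as unmapped and excluded from tallies, not treated as errors.

## HGVS scope

The parser covers what registry extracts actually contain: one- and
three-letter substitutions, stop gains in the `*`, `X` and `Ter`
spellings, `fs`-marked frameshifts, and the intron-offset heuristic
(`4813+1G>A`, `535-2A>G`) for splice-site changes. Duplications,
delins, repeats and genomic-coordinate liftover are out of scope. When
cDNA and protein descriptions disagree, precedence is
frameshift > nonsense > splice > missense — a stated protein
consequence wins over the cDNA heuristic. Synonymous and other
non-categorized changes fall into `other`; *radical* means frameshift
plus nonsense, and excludes splice.

Registry deduplication keys on the normalized triple (gene, transcript
without version, whitespace-stripped cDNA change), falling back to the
dbSNP id when the cDNA change is absent. Source databases rarely state
their matching rule; this is the most conservative key that merges
obvious re-reports without conflating distinct alleles, and rsID
matching is also accepted when annotating against tabular resources.

## The synthetic-data generator

`simulate_variant_data()` emulates the structure of the worked example:
440 variants, 87.5% in SCN5A, the published mutation-type mix (304
missense / 40 nonsense / 73 frameshift / 23 splice), two sources of 405
and 68 records sharing 33, and per-stratum planting rates near the
observed flagging rates (22% for non-SCN5A missense, 2% for SCN5A
missense, 2.5% for nonsense, zero for frameshift and splice). Planted
variants receive frequencies drawn uniformly in
`[cutoff, 10 × cutoff]` within the populations of their ancestry
scenario (Asian-restricted with probability 14/18, mirroring the worked
example); all other frequencies are uniform in `[0, cutoff)` or absent
with probability 0.5.

Uniform draws are a deliberate simplification: the pipeline's behavior
depends only on the cutoff comparison, so a realistic site-frequency
spectrum would change nothing the pipeline can see. Passing recovery
tests therefore demonstrates the bookkeeping (merging, annotation,
flagging, restriction) is exact — they say nothing about panel sampling
noise, genotype-level error, or frequency estimation, none of which the
generator models. All randomness flows from the single `seed` of
`sim_config()`, so runs are byte-reproducible.

## Numerical and testing choices

* Flagging, merging and classification are deterministic; the only
  stochastic component is the generator, always run under fixed seeds.
* The exhaustive exact-test check enumerates all 628,055 tables with
  total ≤ 60 (about half a minute); recovery and property tests use
  seeded synthetic registries of 50–300 variants, and the worked
  example itself is 18 variants plus printed denominators — everything
  recomputes at desk scale.
* Degenerate 2×2 tables (a zero margin) are rejected rather than given
  a conventional p-value.
* Cross-resource frequency collisions resolve to the maximum; registry
  merges union the source labels and keep the first registry's
  metadata, filling gaps from the second.

## Limitations

* Only the frequency axis of pathogenicity assessment is implemented;
  segregation, functional and computational-prediction evidence are
  pass-through annotations at best. A variant flagged here may still be
  disease-predisposing in the ancestry where it is common.
* The cohort-level figures in the worked example (carriers among 124
  patients; 2 of 440 variants seen in the cohort) reproduce printed
  ratios from packaged marginals — the underlying cohort genotypes are
  not, and cannot be, packaged.
* Registry ingestion expects minimal tabular extracts, not full ClinVar
  XML/VCF releases; frequency ingestion reads per-population `AF`
  fields, and does not recompute frequencies from genotypes or lift
  over genome builds.
* With ~18 flagged variants the exact test is the one to trust near
  small expected counts; the chi-square is reported alongside because
  both are conventional, and they can disagree (the radical-vs-missense
  comparison is significant by uncorrected chi-square, not by the exact
  test — the package reports both and asserts neither as "the" answer).
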
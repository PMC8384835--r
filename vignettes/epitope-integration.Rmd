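---
title: "Methods: integrated CD4+ T-cell epitope mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated CD4+ T-cell epitope mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

# The problem

Therapeutic proteins of non-human origin — bacterial Cas9 nucleases being a
prominent example — can be taken up by antigen-presenting cells, cut into
peptides, displayed on MHC class II (in humans, dominated by the HLA-DRB1
locus), and recognised by CD4+ T-cells. Knowing *which* regions of the
protein drive this response matters for immunogenicity risk assessment.
Two complementary ex vivo assays localise such epitopes:

1. **Overlapping-peptide-pool stimulation.** The protein is tiled into
   short synthetic peptides (here 15-mers staggered by 5 residues), the
   peptides are grouped into pools, and PBMCs from HLA-typed donors are
   stimulated pool by pool. Intracellular staining for IFN-γ, TNF-α and
   IL-2 gives, per donor × pool × cytokine, a count of activated CD4+
   cells out of a total. This shows which regions *can stimulate T-cells*,
   at pool (~60-residue) resolution.
2. **MHC-II immunopeptidomics (MAPPs).** Dendritic cells fed the intact
   protein are lysed, MHC-II–DR complexes are immunoprecipitated, and the
   eluted peptides are sequenced by LC-MS/MS. This shows which regions
   *are actually processed and presented*, at residue resolution, but says
   nothing about T-cell recognition.

An epitope worth reporting is a region supported by **both** assays in
donors with compatible HLA — that intersection is what this package
computes, end to end, together with the statistics around it.

# The procedure

## Library design

`tile_protein()` emits `window`-mers starting at 1, 1+`stagger`,
1+2·`stagger`, … For a 1053-residue protein at the default window 15 /
stagger 5 this gives 208 full windows; because the last full window ends
at residue 1050, one terminal 13-mer covering 1041–1053 is appended, for
209 peptides total. The terminal fragment is only emitted when it is at
least `min_terminal` residues long (default 7, the shortest peptide
MHC-II elution data typically contains — anything shorter is unmappable
noise). `assign_pools()` makes consecutive chunks of `pool_size`
(default 10; 209 peptides → 21 pools, the last with 9). All coordinates
in the package are 1-based and inclusive at both ends.

## Cohort selection

So that per-pool response rates generalise, the T-cell cohort should have
a DRB1 allele spectrum close to the reference population's.
`select_cohort()` minimises the L1 distance between the cohort's
slot-count spectrum (each donor contributes two alleles; homozygotes
count twice) and the target frequencies, by simulated annealing over
fixed-size subsets: the move swaps one selected donor for one unselected
donor, acceptance is Metropolis, and the temperature decays geometrically
(`T0 = 1`, `cooling = 0.995`, 20 000 iterations by default). The L1
objective was chosen over L2 or a likelihood-based divergence because it
is insensitive to how mass is split among rare alleles and is exactly
zero only for identical spectra; an L2 hook exists. Alleles present in
the cohort but absent from the reference table contribute their full
cohort frequency, so the search actively avoids unrepresentative
genotypes. The best-ever subset is returned, making the procedure a
strict improvement over its random start. On pools small enough to
enumerate (≤12 donors) the default schedule recovers the exhaustive
optimum in ≥95% of seeded runs; this is asserted in the test suite.

## Responder calling

For each donor × stimulus × cytokine, the positive count out of total
CD4+ cells is compared to the same donor/cytokine's unstimulated well by
a one-sided Fisher exact test (`fisher_one_sided()`), i.e. the upper
hypergeometric tail of the 2×2 table conditioned on its margins —
alternative: the stimulated proportion is greater. Degenerate tables
(zero positives anywhere enrichment is impossible) give p = 1, never an
error. The p-values are then Holm step-down adjusted within a family and
calls are positive when the adjusted p < `alpha` (default 0.05).

Two deliberate choices here:

* **Family scope.** The adjustment family is *all stimulus × marker tests
  of one donor* (63 tests for 21 pools × 3 cytokines, plus protein and
  control rows). Adjusting per donor matches how the experiment is
  organised — each donor has its own unstimulated reference and its own
  multiplicity burden — and is the package default; a single global
  family is available via `family = "global"`.
* **Error-rate naming.** Holm controls the family-wise error rate, not
  the false-discovery rate; assay reports in this field sometimes label
  Holm-adjusted thresholds "FDR < 0.05". The package implements and
  documents FWER control and does not attempt to reproduce the looser
  terminology.

The worst-case responder rule (`donor_positive()`) declares a donor
positive for a stimulus if *any* of the three cytokines was called —
appropriate when the cost of missing a real epitope exceeds the cost of a
false alarm. `percent_responders()`, `pools_per_donor()` and
`log_fold_change_table()` (log2 with pseudocount 0.5 by default; both
configurable) provide the cohort summaries. SEB superantigen rows are
carried as assay QC — they should always be positive — but are excluded
from pool counts and promiscuity.

## Allele association and promiscuity

`build_association_map()` marks an (allele, pool) pair associated under
two rules: **any** — at least one cohort donor carrying the allele
responded; **all** — every cohort carrier responded. The `all` rule's
denominator is the set of cohort carriers, so a singleton carrier makes
the two rules agree. The `any` map always contains the `all` map
cellwise; this is a tested invariant. `promiscuity_scores()` weights each
pool's associated alleles by their reference-population frequency — an
approximation of the fraction of the population whose MHC-II repertoire
could engage the pool. `cumulative_allele_frequency()` is the plain sum
of distinct-allele frequencies (the convention used when reporting
population coverage of an epitope list); `carrier_coverage()` offers the
Hardy-Weinberg carrier probability `1 − (1 − Σf)²` for readers who want a
per-individual interpretation, but it is not the default anywhere.

## MAPPs processing

Identifications arrive as (donor, peptide sequence, Expect Value).
`filter_by_expect_value()` keeps EV ≤ 0.05 (boundary inclusive), the
standard confidence cutoff below which reported false-discovery
proportions are typically under 1%. `map_mapps_peptides()` places each
sequence by exact substring search; peptides that do not occur in the
protein (chimeric or mis-assigned spectra) are dropped with a warning and
counted, and multi-occurrence peptides take the first position with an
ambiguity flag — at study scale, 7+-mers of a ~1000-residue protein
essentially never repeat, and the flag surfaces exceptions rather than
guessing. `merge_regions()` merges spans that share at least
`min_overlap = 1` residue (merely adjacent spans stay separate; the
threshold is configurable since no canonical value exists) into maximal
continuous regions, either per donor (the per-donor unique-peptide counts)
or across the cohort (the "distinct peptides" of the summary table).
Because MHC-II binding is open-ended, real elution data is dominated by
nested/staggered length variants of a core; merged regions, not distinct
sequences, are therefore the natural unit — `summarize_mapps()` reports
both counts so either convention can be read off.

## Integration

`integrate_epitopes()` runs the four-step merge:

1. **Donor matching** — a MAPPs donor and a T-cell donor match if their
   DRB1 genotypes share ≥1 allele (`match_donors()`); all cross-cohort
   pairs are kept, and a donor may appear in many pairs.
2. **Matched residues** — per pair, the residues covered by at least one
   of the MAPPs donor's peptides *and* at least one of the T-cell donor's
   positive pool spans (`matched_residues()`). Partial overlap is kept
   (a peptide protruding past a pool boundary contributes the
   intersection); a stricter full-containment mode is available. Pool
   spans (min start–max end over member peptides) are the default unit on
   the T-cell side; this is the only residue-level reading under which
   "combining matching residues" across donors is well defined.
3. **Combine and filter** — the union of residue sets over all pairs is
   split into maximal runs of consecutive positions and runs shorter than
   `min_length = 9` residues are discarded (boundary inclusive: a 9-mer
   survives). Nine residues is the canonical MHC-II core length.
4. **Cross-reference** — each distinct cohort-scope MAPPs region whose
   span shares ≥ `min_length` residues with a surviving run becomes a
   candidate. Requiring ≥ `min_length` rather than ≥1 keeps the length
   filter meaningful through the final step. The candidate's sequence is
   read off the protein at the region's span (a region may be longer than
   any single identification). Each candidate carries the matched pairs
   whose residues intersect it and the union of their shared alleles;
   `epitope_population_coverage()` sums reference frequencies over the
   distinct alleles of the whole list.

The pipeline is monotone by construction: adding a MAPPs peptide or a
positive call can only grow the matched-residue union, and no step
removes previously supported residues. On small instances the whole
procedure is tested against a brute-force enumeration that works directly
on logical residue vectors.

# The synthetic-data generator

`simulate_study()` emulates every input role so the pipeline is testable
without any external data. What it generates, and why those defaults:

* **Reference population and genotypes.** `n_alleles = 15` DRB1 alleles
  with symmetric-Dirichlet frequencies (concentration 1.5 — a moderately
  skewed spectrum with a few common and several rare alleles, the shape
  DRB1 tables show); genotypes are two independent draws
  (Hardy-Weinberg). No linkage or haplotype structure is simulated.
* **Cohorts.** A 50-donor HLA-typed pool from which 21 T-cell donors are
  annealed against the reference spectrum, and 18 immunopeptidomics
  donors drawn directly from the population.
* **Ground truth.** `n_epitopes = 8` planted regions of 15–25 residues,
  one per equal-width protein block with margins so neighbours stay ≥40
  residues apart; each epitope is presented by 1–3 alleles drawn with
  probability proportional to population frequency (common alleles
  present more often, which is what frequency-weighted binding repertoires
  look like), and elicits 1–3 of the three cytokines.
* **Cell counts.** Totals uniform on 5·10^4–10^5 CD4+ cells; positives
  binomial with background rate 10^-4, multiplied by
  `effect_multiplier = 20` for (donor, pool, marker) combinations where
  the donor carries a presenting allele of an epitope overlapping the
  pool, and by 50 for the SEB control. These rates put the Fisher test in
  a realistic regime — single positives are uninformative, genuine
  responses are unambiguous — rather than at a power cliff.
  `effect_multiplier = 1` produces an exchangeable null dataset used for
  the family-wise-error checks.
* **MAPPs identifications.** Per donor and presented epitope, a ladder of
  5–12 peptides staggered by 1–3 residues with lengths from a clipped
  normal(15, 3) on 7–24 — the nested length-variant structure of MHC-II
  elution data — all with EV ≤ 0.05. Decoys arrive at Poisson rate 2 per
  donor with log10 EV uniform on (−1.4, 2), so only a small fraction
  survives the EV filter, consistent with the <1% post-filter
  false-discovery proportions reported for this assay class; 30% of
  decoys are shuffled sequences that fail mapping, exercising the drop
  path.

What the generator does **not** emulate: MS intensities and spectral
quality, HLA linkage disequilibrium, T-cell receptor cross-reactivity,
donor-specific assay batch effects, and non-DRB1 class II loci. Passing
recovery tests therefore demonstrate that the *pipeline logic* is correct
and well calibrated under its stated statistical model — not that the
model captures every failure mode of real data.

# Numerical and degenerate-input choices

* Fisher p-values are computed as exact hypergeometric upper tails
  (`phyper`); impossible-enrichment tables return p = 1.
* Holm adjustment delegates to `stats::p.adjust`; hand-computed
  step-down values pin its behaviour in the tests.
* Interval work (region merging, residue intersection, overlap widths)
  delegates to IRanges; an independent sort-and-scan oracle pins it in
  the tests.
* Empty inputs: an empty candidate list has precision 1 by convention in
  `recovery_metrics()`; empty residue sets, empty pool lists and empty
  match lists propagate to empty outputs, never errors.
* `run_pipeline()` writes no timestamps, so identical inputs give
  byte-identical artifacts; this is tested.

# Problem sizes used by the test suite

The suite exercises full study-scale instances (1053 residues, 21 + 18
donors) for the acceptance-style checks — 20 seeded end-to-end runs for
recovery, a 600-donor null cohort for family-wise error, a dense sweep of
2×2 tables with margins ≤200 against the tail-sum oracle — and
downsized instances (320 residues, ~7 donors per cohort) for the
module-level property tests. These sizes were chosen so the complete
suite exercises every claim at full design scale while remaining quick to
run during development.

# Known limitations

* Pool-level stimulation caps localisation on the T-cell side at the
  pool span; the residue resolution of the final list comes entirely
  from the MAPPs side.
* Donor matching by a single shared DRB1 allele is permissive: a match
  does not prove the shared allele presented the peptide, and the assay
  cannot resolve which allele of a pair did. Associated-allele sets are
  therefore unions of shared alleles, not presentation calls.
* The cumulative-frequency coverage number is a sum of allele
  frequencies, not a carrier probability; use `carrier_coverage()` for
  the latter.
* The annealing objective and schedule are this package's own documented
  choices for spectrum matching; other cohort-selection tools may use
  different internals and return different (equally valid) cohorts.
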
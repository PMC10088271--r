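---
title: "Strand-aware quadruplex analysis of telomeric retrotransposon arrays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware quadruplex analysis of telomeric retrotransposon arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4telo)
```

## The scientific setting

In *Drosophila melanogaster* the telomerase gene is absent and chromosome
ends are maintained by head-to-tail arrays of three non-LTR (Jockey-clade)
retrotransposons — Het-A, TART and TAHRE — always oriented with their poly(A)
tails toward the centromere. Like canonical telomerase-synthesized repeats,
these arrays are G-rich on one strand, and sequences able to fold into
four-stranded G-quadruplexes (G4) concentrate on that strand: the predicted
quadruplex motifs (PQS) sit almost exclusively on the non-coding strand of
the *gag*-encoding elements, so a one-orientation array places every PQS on a
single genomic strand.

`g4telo` packages the computational side of this analysis as reusable,
tested components: a fully specified PQS scanner, strand-aware intersection
of PQS with repeat annotations and the derived density/proportion
statistics, DNA-versus-protein conservation-bias metrics, Nei–Gojobori
dN/dS, codon-level selection signatures around PQS loci, simple enrichment
statistics, and a synthetic-data generator that emulates the telomeric array
structure with planted ground truth. Everything runs on user-supplied FASTA
and GFF3/BED inputs; no external genome or accession is required.

## The PQS scanner

A candidate is any four ordered G-runs on one strand. A run is either a
perfect tract of `min_run`–`max_run` guanines (defaults 3–7) or a
"defective" run: two G stretches separated by exactly one non-G base (a
single-base bulge) that together still hold at least `min_run` G's. Runs are
separated by loops of `loop_min`–`loop_max` bases (defaults 1–12, any
composition), the whole candidate spans at most `max_len` = 50 bp, at most
one run may be defective, and a candidate may never span an `N` — assembly
gaps must not masquerade as loops.

Scoring is additive and exactly reproducible:

score = `tetrad_bonus`·(t − 1) − `loop_penalty`·Σ max(0, lᵢ − `loop_free`) −
`defect_penalty`·n_defects

where *t*, the number of stackable tetrads, is the minimum over the four
runs of the longest contiguous G stretch inside the run, and lᵢ are the
three loop lengths. With the defaults (bonus 30, penalty 2 beyond 3 free
loop bases, 10 per defect) a canonical three-tetrad motif such as
`GGGTGGGTGGGTGGG` scores 60, a four-tetrad motif with 4-base loops scores
84, and a perfect two-tetrad motif scores 30. The default reporting
threshold is 47, the published score level at which roughly three quarters
of predicted motifs form G4 in sequencing-based validation data; motifs
scoring 47+ are reported, so canonical three-tetrad motifs pass and
two-tetrad motifs do not. The threshold and every other parameter are
plain arguments of `scan_params()`.

Both strands are scanned: the reverse strand is scanned on the reverse
complement and mapped back to forward-axis coordinates with strand `-`.
Within a strand, overlapping candidates are resolved greedily — keep the
highest score, drop same-strand overlaps, repeat — with a deterministic tie
order (leftmost start, then shortest, then lexicographically smallest
motif), so outputs are byte-stable. Greedy selection runs in the G-rich
strand's own orientation *before* coordinate mapping, which makes
`scan(revcomp(x))` an exact mirror image of `scan(x)`. Hits on opposite
strands may overlap and are both kept, because sense and antisense PQS are
counted separately downstream.

The scanner is validated against an independent exhaustive enumerator
(regex-based run validity, brute-force 4-tuples, an independently coded
greedy pass) on seeded random sequences; the test suite requires exact
agreement of coordinates, strands and scores.

## Intersection, orientation and density conventions

`intersect_pqs_repeats()` follows bedtools-intersect semantics: one record
per (PQS, repeat) pair with ≥ 1 bp overlap, so a PQS straddling two repeats
is recorded once per repeat. A PQS is *sense* to a repeat when its G-rich
strand equals the repeat's coding-strand orientation. Two deliberate
counting conventions coexist:

* **Midpoint rule** for `pqs_density()` and `partition_summary()`: a PQS
  belongs to a region iff its midpoint lies inside, so boundary PQS are
  never double-counted in densities. N bases (given as mask intervals, or
  derived from the sequence in the pipeline) are subtracted from the
  effective region length before normalizing to PQS per 10 kbp.
* **Base-pair overlap** for `bp_proportion()`: the summed overlap in bp of a
  family's PQS divided by the summed length of that family's *PQS-containing*
  fragments (fragments without a PQS are excluded, families without any
  PQS-containing fragment are omitted rather than reported as zero).

`count_pqs_by_region()` intentionally double-counts a PQS for every region
it touches and reports how many were double-counted, matching the
boundary-inclusive bookkeeping used for gene sub-regions in this analysis
tradition.

## Conservation bias

`thread_codons()` maps a protein alignment back onto its in-frame CDS
("alignment by translation"): each residue becomes its source codon, each
gap becomes `---`, a single terminal stop is trimmed, and every codon must
translate to its residue. DNA and protein are then compared over exactly
the same residues:

* **identity** — percent of columns with identical symbols, after pairwise
  gap deletion (columns with a gap in either row are dropped from numerator
  and denominator);
* **similarity** — percent of comparable columns whose BLOSUM62 score is
  strictly positive, with `X` treated like a gap. This is the convention
  used by mainstream alignment viewers; the similarity of a pair is never
  below its identity because diagonal BLOSUM62 entries are positive.

`conservation_report()` averages the pairwise values over all unordered row
pairs and reports DNA − AA differences, so a family whose substitutions are
mostly synonymous has AA identity near 100 and a *negative* identity
difference. Region reports slice protein columns and the corresponding
3× DNA columns, so on gap-free alignments the full-alignment report is the
column-weighted blend of tiling region reports.

## dN/dS and codon signatures

`ng86_pairwise()` implements Nei–Gojobori (1986) counting. Per codon
position, the synonymous site fraction is the number of synonymous
single-base changes divided by the number of changes not producing a stop —
changes to stops are excluded from numerator and denominator, so S + N = 3
per codon. For codon pairs differing at k > 1 positions, all k! mutational
pathways are weighted equally and pathways through stop codons are dropped
with the rest re-weighted; a codon pair whose pathways are all blocked is
skipped and counted. Site counts are averaged over the two sequences, and
observed proportions are corrected with the Jukes–Cantor transform
d = −(3/4)·ln(1 − (4/3)p), which is undefined at p ≥ 3/4 (reported as a
saturation error rather than silently clipped). The ratio dn/ds is `NA`
when both distances are zero and `Inf` when only ds is; `dnds_alignment()`
averages pairwise ds, dn and ratio per region, excludes undefined ratios
from the ratio mean and always reports how many were excluded. The
pathway-averaged differences are verified against a brute-force permutation
enumerator in the tests.

`delta_gc()` compares a codon's GC fraction with the mean over its *full*
synonymous family under the standard nuclear code (the proline family
CCT/CCC/CCA/CCG has mean GC 10/12 ≈ 83.3%), so the family-averaged delta is
exactly zero for every amino acid. `partition_by_pqs()` assigns a codon to
the PQS set on ≥ 1 bp overlap, and `codon_position_stats()` contrasts
third-position-cytosine fractions and per-amino-acid usage between the PQS
and non-PQS codon sets.

## Enrichment statistics

`tukey_upper_outliers()` uses type-7 quantiles (linear interpolation at
position (n−1)q) and the upper fence q3 + 1.5·IQR; how "upper outlier"
should be defined for per-clade PQS counts is not settled, so percentile
ranks are reported alongside the flags to keep the call auditable under
other conventions. `strand_asymmetry_test()` reports
|n₊ − n₋|/(n₊ + n₋) together with the exact two-sided binomial p-value at
p = 0.5; counts per element family are small, so no normal approximation is
used. The binomial p is checked against exhaustive outcome enumeration in
the tests.

## What the generator emulates — and what it does not

The synthetic generator exists so that every analysis stage can be tested
against known truth:

* `gen_background()` draws i.i.d. bases at a target GC (default 0.40,
  a fly-euchromatin-like value) and then rescans and locally resamples any
  accidental PQS at or above the reporting threshold. Cleaning the whole
  sequence (not just plant-site neighbourhoods) keeps recovery tests exact:
  every reported hit must be a planted one.
* `gen_element()` builds a 5'UTR/gag/pol/3'UTR element (defaults 400/2400/
  3000/800 bp, a Het-A-scale ~6.6 kb element) and plants the PQS plan; the
  default plan is four antisense three-tetrad motifs, three in *gag* and one
  in the 3'UTR, mirroring the observed architecture where most PQS sit in
  *gag* on the non-coding strand. Antisense motifs are planted as reverse
  complements on the coding strand; plant sites keep ≥ 13 bp spacing (more
  than the maximal loop) so candidates cannot bridge motifs, and flanking
  bases are forced non-G so runs cannot extend across plant boundaries.
* `gen_htt_array()` lays identical copies head-to-tail with poly(A) spacers
  (≥ 20 bp, so no candidate bridges copies), optionally reverse-complementing
  the whole array. One-orientation arrays therefore place all planted PQS on
  one genomic strand — the structural property under test.
* `gen_cds_family()` evolves descendants from a codon-wise random ancestor:
  per codon a Poisson number of single-base substitution attempts, accepted
  with probability 1 if synonymous, ω(region) if nonsynonymous, rejected if
  creating a stop. This per-codon acceptance scheme is deliberately *not* a
  full codon-model rate matrix: it is sufficient to plant a recoverable
  ordering of region-wise dN/dS and simple enough to verify by direct
  counting. Usage biases are planted so the *expected* PQS/non-PQS ratios
  equal the requested multipliers: proline probability is multiplied
  directly, and the third-position-C probability is steered inside each
  synonymous family toward an overall target (baselines: proline 0.05,
  C3 0.25).

Real data differ in ways the generator does not model: no indels or
fragmented copies, array copies are identical rather than diverged, the
background is i.i.d. rather than isochore-structured, and elements carry no
regulatory motifs. Passing the recovery tests therefore demonstrates the
correctness of the *measurement machinery* on structurally faithful input,
not the detectability of PQS in any particular genome.

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open everywhere; the only conversions
happen in `read_features()`/`write_features()` (GFF3 is 1-based inclusive,
BED passes through). Sequences are uppercased on ingest and soft-masking is
discarded; masking analyses are driven by explicit feature files. Zero
effective region length (all-N), empty codon partitions, all-gap column
pairs, quartiles on fewer than four values, and both-zero strand counts all
raise informative errors instead of returning NaN. Ratio means never impute
undefined pairs. All generators are pure functions of their seed and the
analysis stages contain no randomness.

Problem sizes in the shipped test and acceptance runs were chosen to keep a
complete run comfortable on a laptop while leaving the statistical
properties sharp: oracle equivalence on one hundred 2-kb sequences at GC
0.3–0.6, planted recovery on a ~100-kb array with 50 motifs, fifty
replicates of 20 × 300-codon families for the dN/dS ordering, twenty
replicates for the codon-signature ratios, and fifty replicates of
8 × 200-codon families for the conservation direction.

## Known limitations

* The scanner is a fully specified re-design, not a reimplementation of any
  published scoring engine; absolute scores are comparable only within this
  package, and published per-accession PQS counts are not expected to be
  reproduced number-for-number.
* At most one single-base bulge per candidate is modelled; longer
  interruptions, two-tetrad stabilized structures and RNA or intermolecular
  quadruplexes are out of scope, as is any thermodynamic stability
  prediction.
* dN/dS uses plain NG86 counting with equal pathway weights; maximum
  likelihood branch/site models are out of scope.
* With the default penalties a bulged run is usually dominated by a
  defect-free parse that treats the bulge as loop sequence; defective runs
  widen the candidate space mainly for sequences whose G-runs are scarce.
* The Tukey-fence definition of "upper outlier" is one of several
  reasonable conventions; the percentile ranks are reported so the flags
  can be re-derived under others.
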
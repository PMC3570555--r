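---
title: "Selecting microsatellite markers from pyrosequencing reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting microsatellite markers from pyrosequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatselect)
```

## The problem

Microsatellites (SSRs) — tandem arrays of 2–6 bp motifs — remain a
workhorse codominant marker for non-model organisms. Long-read shotgun or
repeat-enriched sequencing yields thousands of candidate loci, but most of
the cost of marker development is downstream: synthesizing and testing
primer pairs that then fail to amplify a clean single-locus product.
Amplification failure has two dominant causes that are both visible *in
silico*:

1. **Base-calling errors in the primer binding sites.** If the flank
   sequence used to design a primer is wrong, the primer will not anneal.
2. **Repeat-associated loci.** Microsatellites frequently sit inside
   transposable elements and other multicopy DNA; primers designed there
   amplify many loci at once.

`msatselect` implements a post-sequencing selection pipeline that attacks
both: aggressive sliding-window quality trimming, redundancy resolution
with error-correcting consensus building, screening against a
repetitive-element library, and tightly constrained primer design. A
deterministic read simulator with a machine-readable truth table makes
every stage testable without any external data.

## Quality trimming

Trimming operates on per-base error probabilities $p_i = 10^{-q_i/10}$
(an `N` call is assigned $p = 1$). For each read, three steps are applied:

1. **Bracket trimming.** Leading and trailing bases are removed while the
   terminal window of `bracket_window` bp (default 10) has mean error
   above `bracket_max_err`.
2. **Interior windows.** Every sliding window of the configured length
   inside the candidate region must satisfy its mean-error cap. A region
   shorter than the window length is judged as a single truncated window
   of its actual length — this removes any undefined edge behaviour.
3. **Largest admissible region.** Among all contiguous regions satisfying
   step 2, the longest one whose *overall* mean error is at most
   `global_max_err` and whose two terminal bracket windows stay below
   `tail_max_err` is retained. Ties are broken by smaller mean error, then
   leftmost position, so trimming is fully deterministic. Regions shorter
   than `min_len` (default 100 bp — enough for a primer pair plus the
   smallest admissible product) reject the read.

Two presets are built in. The high-stringency preset demands a mean error
of at most 0.003 (≈ Q25) in every 10 bp window and overall; the
low-stringency preset relaxes the bracket to 0.02, the window to 50 bp at
0.08, and the overall mean to 0.025. Both cap terminal windows at 0.02.
The search is exact: an internal pruned scan is validated in the test
suite against a full $O(n^2)$ enumeration of all subintervals.

Interpreting the two numbers of the final criterion as (overall mean-error
cap, terminal-window cap) follows the semantics of the classic `lucy`
trimmer on which such parameter strings are modelled.

## Repeat mining

`find_perfect_repeats()` reports every maximal perfect tandem array with a
primitive motif of 2–6 bp and at least five complete units. Primitivity
excludes homopolymers (an `AA` motif reduces to `A`) and avoids reporting
the same array under a composite motif. Motifs are canonicalised to the
lexicographically smallest rotation over both strands, so `TG`, `GT`,
`CA` and `AC` are one motif class. Interrupted and compound repeats are
*not* merged: the method targets perfect arrays only, and two arrays
separated by even a single base are distinct loci. When a read carries
several qualifying arrays, the one with the most units (ties: leftmost)
becomes the primer target — unit count is the best single predictor of
polymorphism.

## Redundancy resolution

Repeat-bearing reads are compared all-against-all with exact local
alignment (match +1, mismatch −2, gap open 5, gap extend 2), in both
orientations. Repeat arrays are soft-masked and excluded from both the
identity numerator and denominator, so similarity is judged along the
repeat *flanking* regions — two unrelated loci that share a motif must
not be linked by their repeats. Identity is computed over alignment
columns (gap columns count). Three verdicts follow:

* **Contigs.** Single-linkage components over hits with identity
  strictly above 95% (and at least `min_aln_len` = 50 unmasked columns).
  Contig membership is decided first.
* **Eliminated.** Any remaining sequence with a hit in the closed 80–95%
  band is a partial homolog — likely a member of a multicopy family —
  and is removed; boundary hits at exactly 95% eliminate rather than
  group.
* **Singletons.** Sequences with only self-hits.

Each contig is represented by a majority-rule consensus: members are
oriented and aligned center-star against the longest member, and a column
symbol is emitted when at least 66% of members share it (a modal gap drops
the column; anything else becomes `N`). With three members, two agreeing
reads reach 66.7%, so moderate-depth contigs already correct isolated
base-calling errors — the rationale for preferring contig consensuses
where depth allows. Center-star progressive alignment is adequate here
because members are by construction >95% identical; an external MSA engine
would add a dependency without changing the outcome. Members that share
only an internal segment with the reference (contigs chained through a
common repetitive element) fall back to local alignment, and members with
no alignable overlap at all are a hard error.

An optional shared-k-mer prefilter (16-mers, both orientations, drawn from
unmasked flanks only, with low-complexity k-mers of period ≤ 6 removed)
restricts alignment to plausible pairs. Any pair reportable at ≥80%
identity over ≥50 columns shares such k-mers with overwhelming
probability, so the prefilter is a speed device, not a threshold change;
the test suite verifies hit-for-hit agreement with the unfiltered search.
It is off by default at the function level and on in the pipeline driver.

## Repetitive-element screening

Candidates (contig consensuses and singletons alike) are locally aligned
against every element of a user-supplied repetitive-element FASTA in both
orientations. A sequence is excluded when any hit exceeds 65% identity
over at least 50 alignment columns. Two deliberate choices: "homology" is
operationalised as local-alignment identity (a composite element score is
not reproduced), and repeat soft-masking is *ignored* here — repetitive
elements legitimately contain microsatellites, so the repeat span itself
is evidence. Because local alignment trims low-identity ends, planted
copies slightly above ~35% divergence can still produce short
high-identity subsegments; the decision threshold therefore behaves as a
transition band rather than a knife edge, which the acceptance tests
bracket empirically (≥95% flagging at ≤30% divergence, ≤5% at ≥45%).

## Primer design

For each surviving candidate the full constraint block is enforced:
product 90–300 bp containing the *entire* repeat array, primer length
18–27 (optimum 20), Tm 57–63 °C (optimum 60) with at most 1 °C difference
within a pair, GC 20–80% (optimum 50), no GC clamp required, no
mononucleotide run longer than 4 inside a primer (homopolymer miscalls
are the dominant pyrosequencing error), and no primer over a consensus
`N` (an `N` inside the product but outside the primers is tolerated).

Melting temperature uses the SantaLucia (1998) unified nearest-neighbor
parameters with the entropy salt correction
$\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$ at 50 mM
monovalent salt and $C_T/4$ with $C_T = 50$ nM. This combination
reproduces the conventional primer-design Tm scale on which a 57–63 °C
window is meaningful (at these conditions a 20-mer needs roughly 65% GC
to melt near 60 °C); the older Schildkraut correction would shift all
values down by ≈ 21 °C and make the window unsatisfiable for ordinary
primers. The implementation agrees with an independent reference
implementation of the same model to < 0.01 °C, and the design stage's
prefix-sum evaluation is bit-identical to the direct per-oligo
computation.

All admissible placements are enumerated exactly and ranked by a penalty
summing each primer's weighted deviations from the optimum: 1 per bp of
length, 1 per °C of Tm, 0.01 per percentage point of GC — the classic
default weighting. Ties break by leftmost left primer, then shortest
product, making the ranking total and deterministic; the top 3 pairs per
locus are reported. Self-complementarity and hairpin screening are not
implemented; this is a known divergence from full primer-design engines
and is listed under limitations.

## The two-track pipeline

The driver runs both stringency tracks on the same input:

* **Track A (low stringency → contigs).** Relaxed trimming keeps more
  reads, maximising the chance that multiple reads of one locus survive
  and form a contig; only contig *consensuses* go forward. Accuracy comes
  from the consensus, not the trimming.
* **Track B (high stringency → singletons).** Aggressive trimming keeps
  only high-confidence regions; only *singletons* go forward. Accuracy
  comes from the trimming, since no consensus can correct a singleton.

Both tracks pass the repetitive-element screen and primer design. A locus
recovered by both tracks (cross-track identity ≥ 95% over the flanks) is
reported once, preferring the contig version; the per-track ledger counts
are kept un-deduplicated so the track totals remain additive, and the
number of cross-track duplicates is reported separately. The ledger
follows the conventional summary-table layout: sequences before and after
QC, repeat-bearing candidates, candidates without repetitive elements,
primer pairs per track, and the total.

Every stage writes plain-text artifacts (FASTQ/FASTA/TSV/JSON) when an
output directory is given, and `run_pipeline(resume_from = ...)` restarts
any stage from those artifacts; because no stage uses random numbers,
fixed inputs give byte-identical outputs, which the test suite asserts.

## The read simulator

`simulate_library()` generates the synthetic study conditions every test
runs against. Defaults: 2,000 templates of 300–600 bp; 30% carry a planted
perfect repeat (60% in enriched mode, emulating hybridisation capture)
with motif length weighted toward dinucleotides (0.45/0.25/0.15/0.08/0.07
for 2–6), 5–14 units, and at least 80 bp of flank on each side; 5% of
repeat-free templates carry a 4-unit decoy; 10% of templates receive a
150–300 bp segment of one of 12 synthetic repetitive elements diverged by
0–30% substitutions; 70% of templates are sequenced once and the rest at
depth 3. Reads carry an 11 bp MID barcode (error rate 0.002 per base,
matching the few-percent unassigned fractions typical of pooled runs),
linear Phred decay from Q40 to Q25 with jitter (sd 2), substitutions drawn
per base from the stated quality so the emitted Phred scores are
calibrated, and ±1 length miscalls at homopolymer runs ≥ 3 at rate 0.005
per run.

Construction guarantees make the truth table exact: planted arrays carry
guard bases so they cannot extend in phase, and template backbones,
repetitive elements, and diverged copies are rejected and redrawn if an
unplanned qualifying array appears (checked by a regex scanner independent
of the package's repeat finder). Consequently, on error-free reads the
pipeline's repeat census must equal the truth table exactly, and the test
suite asserts that it does.

What the simulator does *not* emulate: flowgram-level pyrosequencing
noise (homopolymer errors are modelled as simple ±1 indels), chimeric
reads, coverage biases of real enrichment chemistry, quality-score
miscalibration, and real repetitive-element families (elements are random
sequences, so screening tests measure threshold behaviour, not database
coverage). Passing tests therefore demonstrate the pipeline's internal
correctness and its behaviour under idealised error models — not marker
yield on any particular genome. The default quality decay (Q40→Q25) is
also milder than the worst 3′ tails of early pyrosequencing chemistry;
with harsher decay the high-stringency track simply rejects more reads,
shifting yield toward the contig track.

Problem sizes used by the automated checks — 1,000 random strings for the
repeat-finder oracle, 500 reads for the trimming oracle, 200 templates for
redundancy classification and per-divergence screening, 50 templates for
the primer-design cross-check, and the full 2,000-template default run for
end-to-end recovery — were chosen so the whole suite completes on a single
CPU in well under half an hour while keeping every stochastic assertion
far from its tolerance boundary.

## Numerical and degenerate-input choices

* All interval coordinates are 0-based half-open internally; report
  layers render 1-based where conventional.
* Quality thresholds compare means of double-precision error
  probabilities; ties on real data are measure-zero and tie-breaking is
  positional, so results are reproducible across platforms.
* Empty FASTQ input yields a zero ledger and an exit status of success;
  an empty repetitive-element library is a hard error (skipping the
  screen must be explicit), and a bases/quality length mismatch is a hard
  error naming the record.
* Duplicate read identifiers get deterministic numeric suffixes with a
  warning.
* When an interior low-quality patch splits a read into two admissible
  windows, the stringent and relaxed presets may retain regions on
  opposite sides of the patch; only the retained *length* is guaranteed
  monotone in the thresholds (every stringently admissible region is also
  admissible under relaxed thresholds).
* Phred+33 is assumed; qualities decoding above 62 are rejected as
  probable Phred+64 input.

## Known limitations

* No self-complementarity, hairpin, or primer-dimer screening.
* No SFF parsing; FASTQ is the entry point, and any vendor clip points
  must already be applied.
* Identity is computed over alignment columns; the alternative
  (shorter-sequence length) is not offered.
* The screen depends entirely on the supplied element library; taxa with
  poor database coverage will leak repeat-associated loci through, which
  is why the 80–95% within-dataset elimination band exists as a
  database-free complement.
* Single-linkage contig building can chain loci through a shared
  near-identical element copy; such chimeric contigs survive to the
  screen, where their element content is usually caught.
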
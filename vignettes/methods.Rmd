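---
title: "Methods: model validation, boundary refinement and reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model validation, boundary refinement and reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecurate)
```

# Scope and model of the problem

`genecurate` supports manual curation of protein-coding gene models on draft
genome assemblies. The unit of work is an *isoform model*: an ordered set of
coding-exon intervals on one scaffold and strand. The package validates such
models against a checklist of biological constraints, refines approximate
exon boundaries, searches for small exons that similarity search misses,
applies consensus-error corrections to the underlying sequence, supports
ortholog assignment by reciprocal best hits plus local synteny, and
reconciles independently built models of the same gene.

Assumptions baked into the model:

* Coordinates are 1-based, inclusive, and always refer to the forward strand;
  transcript order is encoded by the exon *ordinal*, which runs 5' to 3' in
  mRNA sense (descending coordinates on the minus strand).
* Only coding exons are modeled. UTRs, promoters and non-coding transcripts
  are out of scope.
* Genes follow the standard nuclear genetic code and the GT–AG intron rule,
  with the naturally occurring GC donor admitted as a warning and every other
  signal requiring an explicitly declared allowance.

# Splice-phase conventions

For the intron after exon $k$, the *donor phase* is the number of
nucleotides by which the coding sequence through exon $k$ overhangs the last
complete codon: `sum(lengths[1:k]) %% 3`. The *acceptor phase* is the number
of nucleotides of exon $k+1$ consumed before its first complete codon.
A junction preserves the reading frame exactly when the two phases sum to 0
or 3. `junction_phases()` computes the donor phase from the cumulative length
and the acceptor phase by independently walking the frame into the downstream
exon, so a bookkeeping inconsistency would surface as a phase-sum violation
rather than being assumed away.

A codon split across a junction is attributed to the exon that contributes at
least two of its three nucleotides — equivalently, the exon holding the
codon's middle nucleotide. Splits are always 1+2 or 2+1, so no tie can arise.
This rule drives the per-exon peptide segments of `reference_record()`.

# The checklist and its ordering

`check_model()` emits one row per constraint, ordered 5' to 3' along the
transcript with the two global items (coding length divisible by three, exon
count versus the reference record) last: start codon, then for each exon its
internal-stop item followed by its junction's donor, acceptor and
phase-compatibility items. The report's `first_failure` is therefore the
most upstream broken constraint. This ordering is a deliberate diagnostic
choice: a single misplaced boundary typically shifts the frame for everything
downstream, producing a cascade of stop-codon and divisibility failures that
all resolve once the first one is fixed.

Two demotion rules keep honest edge cases checkable. Partial models
(`complete = FALSE`, e.g. genes truncated at assembly gaps) demote the
start/stop and divisibility failures to warnings. Declared allowances
(non-canonical start, per-junction non-canonical donor/acceptor, stop
readthrough) demote exactly the matching failures to warnings, so the
checklist records the exception without hiding it. The stop codon counts
toward the coding span, so "length divisible by three" is evaluated on the
full CDS including the stop; reported peptides strip the terminal `*`.

# Boundary refinement

Similarity-search alignments only cover complete codons, so approximate exon
boundaries usually sit a few nucleotides short of the true splice sites.
`refine_boundary()` searches a window (default 15 nt) around each
approximate boundary for coordinates where: the exon start abuts an AG
acceptor (or an allowed start codon for the initial exon), the exon end abuts
a GT donor (GC optionally), the leading partial codon matches the acceptor
phase required by the *running* reading frame, and no in-frame stop appears
among the exon's complete codons. Among valid candidates the smallest total
absolute shift wins, ties broken toward the longer exon.

Anchoring the frame on the running donor phase of the preceding intron —
rather than on the alignment's claimed frame — is a deliberate design choice:
`refine_model()` carries the refined frame forward exon by exon, so an
upstream refinement automatically constrains every downstream search, and a
perturbed approximate start cannot poison the frame anchor. The 15 nt default
reflects the scale of the problem: curated adjustments are typically 1–2 nt,
and a small window keeps the candidate set nearly always unambiguous.

# Small-exon search

Coding exons under roughly 30 nt are routinely missed by similarity search
but are strongly constrained: an internal exon of length $L$ joining an
acceptor of phase $a$ and a donor of phase $d$ satisfies
$L = a + 3k + d$, must be preceded by AG and followed by GT, and must be
stop-free in the frame that starts after its $a$ leading nucleotides.
`find_small_exons()` enumerates *every* candidate in a window meeting the
constraints (initial and terminal variants swap the boundary conditions for
a start codon or an in-frame stop). Candidates are ordered by position then
descending length; the ranking is deterministic and carries no score model.
The test suite checks the enumeration against a brute-force scan of all
(start, end) pairs written directly from the biological definition.

# Consensus-error correction

Draft assemblies carry base errors and small indels that can break otherwise
sound models. Corrections travel as a minimal VCF dialect: CHROM, POS, ID,
REF and ALT are honored, indels are anchored on a shared first base,
multi-allelic and complex records are rejected, REF is validated against the
scaffold, and edits must not overlap. `apply_edits()` rebuilds the sequence
and returns a coordinate map; `lift_position()` and `lift_model()` re-anchor
coordinates and whole models across it, with positions inside deleted spans
reported as unmappable rather than silently approximated. Maps are invertible
(`invert_coordinate_map()`), so the corrupted-assembly view of a model and
its corrected view are mutually reachable.

# Orthology and reconciliation

Ortholog pairing uses reciprocal best hits over standard 12-column tabular
hit records (best = lowest E-value, then highest bit score, then highest
percent identity; only mutual bests pair). Local synteny is assessed from the
two nearest genes on each side plus nesting relationships: all four neighbors
matching with orientations and consistent nesting is `conserved`, at least
two matches is `partial`. When best hit and synteny disagree on the locus the
package reports a `conflict` for curator review — it never overrules one line
of evidence with the other.

Reconciliation classifies the discrepancy between two independent models
with a fixed precedence: different scaffolds or non-overlapping spans →
`ortholog_mismatch`; differing exon counts → `exon_gain_loss`; any non-zero
boundary offset → `splice_site` (with signed per-boundary offsets, B minus
A); identical coordinates → `congruent`. Whole-submission comparison
additionally flags isoforms present on one side only and *label swaps* —
pairs of isoforms whose structures are exchanged between submissions,
detected by structural identity of their coordinate keys; with reference
records available, a model whose structure instead matches a different
reference isoform (same exon count, ≥95% peptide identity) is flagged the
same way. `summarize_error_rates()` reports the percentage of congruent
models and, over erroneous models only, each error class's integer-rounded
share, retaining raw counts so percentages can always be recomputed.

# Synthetic loci as study conditions

All tests and the acceptance run are driven by `generate_locus()`, which
builds a locus transcript-first — a start codon, stop-free random codons and
a stop, split into exons, joined by introns with forced donor classes and AG
acceptors, padded with flanks, reverse-complemented for minus-strand loci —
so coordinates, phases and the peptide are known exactly by construction.
The default study condition (`random_locus_spec()`) draws 2–6 exons of
20–200 nt summing to a codon multiple and introns of 8–60 nt. These sizes
are the package's own choices: large enough to exercise multi-junction frame
propagation, small enough that property suites over hundreds of loci run in
seconds. Generation is deterministic per seed and leaves the caller's RNG
stream untouched. `corrupt_model()` injects one controlled error — boundary
shift, dropped/invented exon, label swap, relocation, or scaffold indel with
matching repair edits — together with a truth record naming the expected
discrepancy class, so classifiers are scored against known ground truth.

Realism limits worth noting: flanks and introns are i.i.d. nucleotides with
no repeats, pseudogenes or paralogs; splice sites carry no motif beyond the
boundary dinucleotides; and real intergenic sequence is far richer in decoy
signals. Properties proved on these fixtures are necessary, not sufficient,
for performance on real assemblies.

# Summary arithmetic

Congruence statistics are computed as: percent congruent = rounded share of
congruent models over all models; error shares = rounded share of each error
class over erroneous models only. With a cohort of 588 models of which 488
are congruent and the remaining 100 split 38/41/19/2 across mislabeled
isoforms, splice-site errors, exon gain/loss and ortholog mismatches, the
summary reports 83% congruence with error shares of 38%, 41%, 19% and 2% —
the worked example used by the acceptance suite.

# Known limitations

* Single-scaffold models only; trans-spliced or scaffold-spanning genes are
  not representable.
* The checker validates structure, not expression: it cannot distinguish a
  real isoform from a structurally valid but unexpressed one.
* Dot plots and global alignment use fixed scoring (BLOSUM62, affine gaps);
  there is no tuning for highly divergent orthologs.
* The small-exon search reports all constraint-satisfying candidates; in
  GC-poor windows the candidate list can be long, and ranking is positional,
  not probabilistic.
* Synteny assessment is position-wise over a depth-2 neighborhood and does
  not model inversions that reorder neighbors while preserving linkage.
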
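---
title: "Evaluating a pair of assembly versions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a pair of assembly versions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmeval)
```

# The problem

A coordinate-changing update of a clone-based reference assembly mixes
several kinds of curation: duplicated loci that had been collapsed into a
single copy regain their second copy; false duplications are removed;
gaps are closed with real sequence; centromeric gaps are replaced by
modeled satellite arrays; tiling paths are replaced component by
component; and single erroneous bases are corrected against the source
clone's own reads. `asmeval` quantifies the consequences of such an
update along four axes: where each version is collapsed or expanded
relative to the other, how read mappings move between versions even in
unchanged regions, which candidate base errors the read evidence actually
supports, and where variant sites gain, lose, or ambiguously transfer
coverage. A bundled simulator generates two-version pairs with known
ground truth so that every stage is testable end to end.

Throughout the package, the *old* version is called assembly A and the
*updated* version assembly B. The unit of provenance is the AGP
component: a contributing sequence identified by an accession.version,
so that a re-finished component is, by construction, different sequence.

# Coordinates

All internal coordinates are 1-based and inclusive, the native convention
of AGP, VCF, SAM and the Bioconductor ranges infrastructure this package
is built on (IRanges/GenomicRanges). Formats with 0-based conventions
(PAF, BED) are converted at their parsers and writers, and nowhere else.
Keeping a single arithmetic convention inside the package is the point;
1-based inclusive was chosen because every container the package
manipulates (GRanges, XStringViews, AGP rows) already uses it.

# Collapse and expansion

Given best-hit alignment blocks between the two assemblies — each block
tagged as a reciprocal best hit (best in both directions, first alignment
pass) or a nonreciprocal best hit (second pass) — each base of the focal
assembly is labeled:

* `COLLAPSED`: covered by at least one reciprocal and one nonreciprocal
  segment. Two regions of the other assembly align here; a duplicate
  copy is missing from the focal assembly.
* `EXPANDED`: covered only by nonreciprocal segments. This sequence is
  extra relative to the other assembly (often a false duplication).
* `UNIQUE`: covered only by reciprocal segments.
* `UNALIGNED`: covered by nothing.

Two choices deserve justification because the original summarization
code's internals are not published:

* **Coverage is computed at segment (post-CIGAR) resolution**, not over
  whole-block envelopes. An envelope treats the bases of a long deletion
  as covered and inflates labels across indels; segments do not.
* **Candidate regions are maximal inter-gap segments**, using AGP gap
  rows as separators (N-run detection is the fallback without an AGP),
  and a region is kept if and only if its non-N fraction strictly
  exceeds 0.5. Gap rows are the only segmentation both assemblies
  objectively share. A 100-base region with 60 N (fraction 0.40) is
  dropped; one with 49 N (0.51) is kept. Whether regions touching
  sequence ends should be filtered is not specified anywhere we could
  find; they are kept.

Label lengths are counted inside kept regions only and always partition
the kept length — this conservation property is asserted in the test
suite on every randomized instance, alongside exact equivalence with a
brute-force per-base oracle.

# Read movement between versions

The analysis is restricted to *unchanged regions*: for every component
accession.version placed in both AGPs with equal orientation, the
component-coordinate intersection of the two placements, mapped into both
object coordinate systems. A version bump makes a component changed; an
orientation flip excludes it.

Eligibility: both mates mapped, primary, MAPQ ≥ 20, and both aligned
spans fully inside the *union* of unchanged intervals on A. The union
matters: a read crossing the joint between two adjacent unchanged
components is still entirely inside unchanged sequence. "Uniquely
mapped" is operationalized as primary + MAPQ ≥ 20 because the original
criterion is unstated and 20 is the threshold used by every other filter
in this methodology; it is configurable.

A pair *moves* when at least one mate's primary placement midpoint on B
lies on a different component accession.version than the component under
its A midpoint. The midpoint rule resolves reads straddling two AGP rows
deterministically. The mate-level OR is the permissive reading of
"pairs that move"; the per-read six-way classification is then
read-level:

| category | destination |
|---|---|
| `ON` / `ONCEN` | same chromosome, noncentromeric / centromeric |
| `OFF` / `OFFCEN` | different chromosome, noncentromeric / centromeric |
| `TOSCAF` | noncentromeric unlocalized/unplaced scaffold |
| `UNCEN` | unplaced scaffold carrying centromere-associated annotation |

"Centromeric" means any overlap of the aligned span with a centromere
interval; a scaffold is centromere-associated if it carries any
centromere annotation at all. Rescue statistics (unmapped on A but
mapped on the B primary units; still unmapped there but mapped on the
full assembly with alternate loci) are read-level, and zero denominators
are reported as undefined rather than zero.

# Candidate-base validation

Alleles are tallied from primary alignments with MAPQ ≥ 20. SNV sites
count the aligned base at the position, with spanning deletions counted
as a distinct `del` allele; insertion/deletion sites count presence or
absence of the left-anchored event at the anchor (a read is informative
only if it aligns across the anchor junction). Classification compares
the *majority-allele* fraction — majority, not reference, because
homozygous-alternate detection anchors on whichever allele dominates —
to the cutoff: 0.90 for SNVs, 0.70 for indels. A boundary fraction
counts as homozygous (the cutoffs are stated as plain percentages, so
`>=` is the natural reading; it is recorded in the output). More than
two alleles at an SNV, or any allele outside {ref, alt}, routes the site
to review.

Decisions are a pure function of classification, site type and
provenance: homozygous-alternate applies the update; homozygous-reference
refutes the candidate; heterozygous inside a source-library component
retains the reference, because the reference deliberately preserves the
source clone library's haplotype and a het there is a real allele, not an
error. A heterozygous call *outside* the source library says nothing
about the source haplotype, so it goes to manual review — this case is
unspecified in the methodology the package follows, and review is the
conservative completion. Indel sites that are not homozygous-alternate
are always reviewed.

Mini-contig validation aligns each replacement contig to its reference
window with an end-free overlap alignment (match 1, mismatch −2, gap
open −4, gap extend −1 — a scheme that favors reporting a single clean
edit over splitting it into end trims) and passes the contig only if the
difference set is exactly the expected alternate allele at the target
site. Observed and expected indels are both left-normalized through
repeat runs before comparison, so alignment-equivalent placements
compare equal. A contig aligning with less than 80% of its length is an
error, distinct from a failing validation.

# Variant coverage and remapping

A site is `COVERED` when at least one primary alignment with MAPQ ≥ 20
overlaps it. Sites are projected through every alignment block
containing their position (indels by their anchor base); placements are
deduplicated at exact (sequence, position, strand) — no fuzz radius,
the conservative choice given that none is published — and a site is
*ambiguous* when two or more distinct placements land on primary-unit
sequences; alternate-locus placements are reported but never counted
toward ambiguity. For coverage transitions, the remap position of a site
is its reciprocal-best-hit placement when one exists (that is the
placement a remapping service reports as primary), with nonreciprocal
placements used only as fallback; gained (zero on A, covered on B) and
lost (covered on A, zero on B) sites are grouped into regions by single
linkage within 100 kb, a configurable default standing in for an
unpublished grouping rule.

# The simulator

The simulator is the package's ground-truth generator, not a sequencing
model. Assembly B shares its chromosome coordinates with a donor genome;
assembly A is derived from the donor by implanting the *defects* that
the update corrects:

* `ev_false_duplication(length, divergence)` — A gains a near-identical
  extra copy next to the donor locus.
* `ev_collapse(length, divergence, dest)` — the donor and B carry two
  copies; A lost one. `dest` places the B-only copy on the same or
  another chromosome arm, in the pericentromeric region, or on an
  unplaced scaffold with or without satellite-associated sequence —
  which is exactly what drives the six movement categories: reads truly
  from the B-only copy place on the retained copy in A (uniquely, albeit
  imperfectly, when the copies are diverged) and on their own copy in B.
* `ev_gap_closure(length)` — A shows an N gap written at the 50,000-base
  convention for gaps of unknown size; B carries the real bases. The
  convention matters for length accounting: the gap length says nothing
  about how much sequence was actually missing.
* `ev_centromere_model()` — A has a centromeric gap; B carries a tandem
  satellite array (171-base monomers, 100 copies, 5% per-copy
  divergence by default — enough divergence that per-copy placements are
  ambiguous, which is the property a centromeric read sink needs).
* `ev_inversion`, `ev_base_error`, `ev_retile`, `ev_alt_locus` — an
  inverted segment in A, a single erroneous base in A with the component
  re-finished (version-bumped) in B, a tiling-path swap (new
  accession.versions, identical sequence), and an alternate-locus
  scaffold in B's full assembly whose novel core is absent from both
  primary units.

Reads are drawn from the full B assembly at a configured depth with
normal insert sizes truncated below at the read length, optional
substitution errors, and an optional contaminant fraction that is
unmappable everywhere. Truth placements against A are obtained by
projecting each span through the truth alignment map; spans not fully
inside one mapped interval are truth-unmapped. The MAPQ convention is a
single rule: a placement wholly inside a region with two effectively
identical copies in that assembly (per-event divergence 0, or the
satellite array) gets MAPQ 0, everything else 60. At 150-base reads,
copies diverged by ≥1% are treated as uniquely anchorable. This one
rule produces the coverage-loss mechanism at added paralogs, the
coverage gain at removed false duplications, and a nontrivial
"moved pairs also unique on B" fraction.

What the simulator does **not** emulate: sequencing-technology error
profiles (errors are uniform substitutions), diploid phasing beyond the
two-allele candidate sites, indel sequencing errors, mapping artifacts
other than the exact-duplicate rule, optical maps, and real aligner
behavior — truth SAMs encode where reads *belong*, not what any
particular aligner would do. Passing tests therefore demonstrate the
correctness of the analysis logic on well-defined inputs, not robustness
to real-world mapping noise.

All randomness flows through one seeded generator stream; identical
configuration and seed give byte-identical FASTA/AGP/SAM/VCF outputs,
which the test suite asserts. Event loci are allocated deterministically
(30-kb end margins, 20-kb spacing, satellite at 45% of chromosome 1, the
second copy of a same-arm duplication forced onto a different baseline
component so that its reads can register as moved).

# Candidate sites and their reads

Candidate sites are planted on truth-unchanged, ungapped A sequence with
at least 160 bases between sites, assigned SNV/insertion/deletion types
and truth genotypes by configurable mixes, and flagged by whether their
component belongs to the source clone library (a per-component Bernoulli
draw at the configured fraction, default 0.7 — the dominant-library
share of a clone-based reference). Site-level reads are generated
directly over each site at a configured depth with the event carried in
the CIGAR of alternate-haplotype reads; heterozygous sites draw each
read's haplotype with probability one half, so at depth 30 the
heterozygous call rate has the closed-form binomial prediction
`1 − P(majority ≥ 0.9)` that the acceptance suite checks.

# Pipeline and problem sizes

`run_pipeline()` runs simulate → collapse/expand → read movement → base
validation → variant transitions from one YAML/list configuration,
writing every intermediate in its standard interchange format and
re-reading it in the next stage, so the parsers and writers are on the
critical path of every run. The summary JSON records resolved
parameters, per-stage statistics, and truth concordance, and is
byte-reproducible for a fixed configuration and seed.

The bundled fixture (`inst/extdata/fixture_config.yaml`) uses two 5-Mb
chromosomes, every event kind, ≈50,000 read pairs (depth 1.5×) and 300
candidate sites at depth 30 — sizes chosen so a full run plus its
repeat-run reproducibility check completes in minutes on one CPU while
still exercising every code path; unit tests use 0.3–1-Mb chromosomes
for the same reason. Randomized oracle comparisons use up to ten
sequences of up to tens of kilobases per instance, 100 instances.

# Known limitations

* The reciprocity tag (`rc:A:R|N`) is a PAF dialect standing in for the
  richer report format of the alignment pipeline that produces
  reciprocal/nonreciprocal best hits; blocks must be supplied, the
  package never computes alignments.
* Movement analysis requires truthful primary placements in both SAM
  inputs; it does not model or correct mapping ambiguity itself beyond
  the MAPQ filter.
* The collapse/expansion classifier's region segmentation follows gap
  rows; a curator using fixed windows for sensitivity analysis can pass
  window intervals as `regions` to `summarize_labels()`.
* Coverage transitions are evaluated in the A→B direction with the
  reciprocal-preferred placement; the symmetric B→A direction is
  obtained by swapping inputs and inverting blocks.
* CRAM is out of scope; BAM is read through Rsamtools, SAM text is
  written only for fixtures.
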
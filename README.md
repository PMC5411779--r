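# asmeval

Evaluation of genome assembly version pairs in R.

When a clone-based reference assembly is updated — duplicate copies that
were wrongly collapsed into one get their missing copy back, false
duplications are removed, gaps are closed with real sequence, centromere
gaps are replaced by satellite models, tiling paths are swapped and single
erroneous bases corrected — every downstream analysis feels the change,
even in regions whose underlying components did not change at all.
`asmeval` implements the evaluation methodology for such version pairs,
aimed at assembly curators and pipeline developers who need to quantify
what an update did:

* **Collapse/expansion classification.** From best-hit assembly–assembly
  alignment blocks, each base of an assembly is labeled by the pass
  classes of the segments covering it: covered by reciprocal *and*
  nonreciprocal best hits → `COLLAPSED` (a duplicate copy is missing
  here); only nonreciprocal → `EXPANDED` (extra, often falsely duplicated
  sequence); only reciprocal → `UNIQUE`; none → `UNALIGNED`. Lengths are
  accounted per chromosome inside ungapped regions (kept when strictly
  more than 50% non-N).
* **Read movement across versions.** Restricted to regions whose AGP
  component accession.version is identical in both versions, read pairs
  that map uniquely (primary, MAPQ ≥ 20) on the old assembly are tested
  for movement: a pair moves when a mate's placement midpoint on the new
  assembly falls on a different component. Moved reads are classified
  into the six-way destination taxonomy `ON`/`ONCEN`/`OFF`/`OFFCEN`/
  `TOSCAF`/`UNCEN` (same/other chromosome or unplaced scaffold ×
  centromeric/noncentromeric), and unmapped-read rescue fractions are
  computed across the old assembly, the new primary units, and the new
  full assembly.
* **Candidate-base validation.** Pileups at candidate reference-error
  sites (MAPQ ≥ 20, primary alignments only) are classified with the
  homozygosity cutoffs 90% (SNV) and 70% (indel): majority fraction at or
  above the cutoff is homozygous, below is heterozygous; more than two
  alleles or unexpected alleles trigger review. Heterozygous calls inside
  a source-library component retain the reference (the base is a real
  allele of the source haplotype); homozygous-alternate calls apply the
  update; everything else goes to manual review. Replacement mini-contigs
  pass only if an end-free alignment to their reference window shows
  exactly the expected single edit.
* **Variant coverage and remapping.** Sites are scored `COVERED`/`ZERO`
  by MAPQ-filtered depth on both versions, projected through the
  alignment blocks (reciprocal placements preferred; two or more distinct
  primary-unit placements flag the site ambiguous), and reported as
  gained/lost coverage lists with single-linkage region grouping.
* **A deterministic simulator** builds two-version assembly pairs with
  implanted curation events (false duplication, collapse with six
  destination choices, gap closure, inversion, base error, retiling,
  centromere model, alternate locus), paired reads with truth placements
  against both versions, and candidate sites with truth genotypes — so
  every stage above can be validated against ground truth.

## Worked example

Simulate a pair in which the old version (A) carries a 20-kb false
duplication and is missing one copy of a 15-kb duplicated locus that the
new version (B) carries, then classify A from the truth alignment:

```r
library(asmeval)
cfg <- sim_config(n_chromosomes = 2, chromosome_length = 500000, seed = 1)
pair <- simulate_assembly_pair(cfg, list(
  ev_false_duplication(20000, divergence = 0.01),
  ev_collapse(15000, divergence = 0.02, dest = "other_arm")))
lens <- setNames(Biostrings::width(pair$A$seq), names(pair$A$seq))
regions <- ungapped_regions(pair$A$seq, pair$A$agp)
track <- label_bases(pair$truth$blocks, lens)
summarize_labels(track, regions)$lengths
#>   seq_id     label  bases
#> 1   chr1 COLLAPSED      0
#> 2   chr1  EXPANDED  20000
#> 3   chr1    UNIQUE 485000
#> 4   chr1 UNALIGNED      0
#> 5   chr2 COLLAPSED  15000
#> 6   chr2  EXPANDED      0
#> 7   chr2    UNIQUE 485000
#> 8   chr2 UNALIGNED      0
```

The 20,000 `EXPANDED` bases on chr1 are the false duplication (covered
only by a nonreciprocal best hit from B's single copy); the 15,000
`COLLAPSED` bases on chr2 are the locus whose second copy A lacks
(covered by B's retained copy reciprocally *and* by B's extra copy
nonreciprocally). Label lengths always sum to the kept ungapped length.

The full pipeline — simulation, all four analysis stages, per-stage
TSV/BED/VCF outputs and a `summary.json` with truth concordance — runs
from one declarative configuration:

```r
run_pipeline(system.file("extdata", "fixture_config.yaml",
                         package = "asmeval"), "eval_out")
```

or from a shell via the bundled CLI
(`inst/scripts/asmeval.R`), which also exposes each stage as a
subcommand (`simulate`, `collapse-expand`, `read-movement`,
`base-validate`, `variant-transition`, `run-all`).

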
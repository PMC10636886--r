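---
title: "Methods: A-to-I editing-site discovery, filtering and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-to-I editing-site discovery, filtering and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical design of the package: what
each stage computes, which constants it uses and why, and where the
known limitations are. The README shows a worked end-to-end example;
here the focus is on method rationale.

## 1. Candidate discovery

`pileup_counts()` walks CIGAR-aligned reads and tallies per-position
base counts under three gates: mapping quality ≥ 30, base quality ≥ 30,
and once-per-fragment counting (overlapping mate bases are counted
once, keeping the higher-quality call). Library strandedness is a
three-valued code: `0` treats everything as the `+` strand (an
unstranded pileup sees a `-`-strand A→G event as its T→C genomic
image), `1` assigns first-in-pair reverse alignments to the `-`
transcript strand (FR library), `2` flips that assignment (RF).

`call_candidates()` keeps positions with total coverage ≥ 10, variant
reads ≥ 3 and editing level ≥ 1%. These joint thresholds control the
binomial noise floor: at a 0.2% per-base error rate and 10–400×
coverage, three co-occurring identical errors at one position are rare,
and the per-type excess that does pass is measured rather than assumed
(next section).

## 2. Filter cascade and spectrum-based FDR

The cascade applies, in order:

1. **Genomic-variant removal** — candidate positions overlapping a
   *strong* variant call (depth ≥ 10 and quality ≥ 20) are removed.
   Weaker variant evidence is deliberately not used: a low-quality
   variant call is as likely to be noise as the site is.
2. **Multi-mismatch window filter** — a candidate with a
   *different-type* candidate within ±20 nt is removed; co-located
   heterogeneous mismatches are the signature of misalignment or
   paralog collapse, whereas true editing clusters are type-pure A→G.
3. **Clustered/isolated split** — candidates with a same-type neighbor
   within ±20 nt form the high-confidence clustered set (ADAR acts
   processively on duplex regions, so real sites cluster).
4. **Cross-study rescue** — isolated sites return if they have ≥ 5
   variant reads in ≥ 2 independent studies; independent replication
   substitutes for local clustering.

**FDR estimation.** Editing produces A→G (and, on the unstranded
image, T→C); sequencing error is symmetric over the 12 ordered
mismatch types. The count of the reverse-complement control type G→A
therefore estimates the noise contribution to A→G, giving
`FDR = 100 · n(GA) / n(AG)`. `run_filter_cascade()` records the
spectrum and this estimate after every step.

*Reporting convention:* on a fully null dataset the clustering step
empties the site set (errors do not cluster), so the null calibration
(estimated FDR ≈ 100%) is assessed on the post-multi-mismatch
spectrum, the last step at which a null spectrum exists; on planted
data the quoted FDR is the clustered-step estimate. Both are exposed in
`cascade$report`, nothing is hidden in either direction.

**WGS diagnostic.** `genomic_support_check()` labels every catalog
site by its DNA pileup (homozygous-reference / non-reference /
insufficient) without removing anything: editing leaves DNA untouched,
so a high supported fraction is a global sanity check, and the
non-reference residue is exactly where rescue-leaked weak variants
(see §7) surface.

## 3. Hyper-editing

Reads edited at many positions exceed any aligner's mismatch budget
and vanish from the pileup. The recovery scheme transforms one base to
another (A→G for the canonical case; all 12 ordered schemes are run so
the scheme spectrum itself is a control) in both the unmapped reads
and the reference, realigns, restores the original read, and calls
dense clusters.

The included aligner is deliberately a toy — exact 16-mer seeding at a
fixed stride in both orientations, extension with Hamming mismatches,
unique-best-hit requirement — because the method's contribution is the
transform-and-verify logic, not alignment engineering. Its two
tolerances are set a priori:

- *transformed space*: ≤ 10% of read length, generous because true
  scheme-type mismatches have been erased by the transform;
- *verification ("normal") space*: ≤ 3% of read length (2 mismatches at
  75 nt), matching strict spliced-aligner defaults; a read passing this
  would have aligned normally, so it cannot be claimed as hyper-edited.

A verified read is *emitted* if, after restoration, it shows ≥ 5
scheme-type mismatches, ≥ 5% of its length scheme-type, and ≤ 5%
any-other-type; the first/last 2 aligned positions are excluded from
site calling (edge bases are the least reliable). Per-site evidence
separates `variant` (emitted reads carrying the mismatch) from
`coverage` (all verified reads spanning the position).

Hyper regions are planted as ~20 sites over ~200 nt — denser than one
edit per read-length window and *longer than a read* — so reads falling
inside a region cannot align normally. Only reads overhanging a region
edge (covering ≤ 2 edited sites) align, which is why a regular pileup
recovers only the outermost sites (< 20% of the planted set) while the
transformed pipeline recovers > 80%: the disjointness of the two
pipelines is a geometric consequence, not a tuning target.

## 4. Repeat editing index

`repeat_editing_index()` is the AEI-style read-weighted aggregate:
`100 · Σ n(G) / Σ (n(A) + n(G))` over all repeat positions whose
genomic base is A (on `-`-strand repeats the unstranded image T→C is
used). Weighting by reads rather than averaging per-site levels makes
the index robust at positions with few reads and recovers a uniform
planted rate within binomial error. `group_minor_families()` merges
rare repeat families into `other` deterministically (by count, ties
by name) so per-family indices are reportable without unstable
small-denominator classes.

## 5. Context-specific sites

`per_context_levels()` computes a site's level per developmental
context through a fixed three-level hierarchy: reads are pooled within
each study × context (levels are read-weighted where it matters —
within a library), study levels are averaged per context
(studies are equal witnesses regardless of depth), and a study ×
context enters only with pooled coverage ≥ 10. `call_context_specific()`
then requires: focal level ≥ 1%, measured in ≥ 2 contexts, and ≥ 3-fold
above *each* other context (default; `fold_vs = "mean"` relaxes to the
mean of the others). The each-mode is the stricter, presented rule; a
site elevated in two contexts is, by this definition, not specific to
either.

## 6. Conservation, homeologs and recoding

`liftover_site()` implements single-base UCSC-chain mapping natively:
a position inside a block at offset `off` maps to
`tgt_start0 + off + 1` on `+` chains and to
`tgt_size − (tgt_start0 + off)` on `−` chains (chain target starts are
0-based in strand coordinates). `mode = "single"` keeps the
best-scoring chain; `mode = "homeolog"` keeps exactly two targets when
they differ only in the `.L`/`.S` subgenome suffix — the allotetraploid
case where one diploid position legitimately has two homeologous
images.

`compare_species()` classifies lifted sites as conserved-similar /
conserved-differential / species-specific / fixed-G / unassessable
using the target genomic base and both species' levels at ≥ 10×.
`resolve_gene_symbols()` flags cross-species symbol conflicts but
spares uninformative accession-style names (LOC/XB/MGC/XM/NM/XR/c_orf_
prefixes) and listed synonyms. `annotate_recoding()` recomputes each
site's codon from the CDS intervals and genome sequence (never from
stored annotations), substitutes G at the edited position, and
translates; it is validated against exhaustive enumeration of every
A-containing codon.

## 7. Long-read phasing

`site_calls_from_sam()` assigns each (read, site) pair a state —
`edited`, `unedited`, or `uncovered` (splice gap, read boundary, base
quality < 30, or third allele) — so downstream 2×2 tables are built
only from doubly informative reads. `coedit_association()` is
Pearson's χ² without continuity correction (the closed form
Σ(O−E)²/E is kept as an independent test oracle), requiring ≥ 10
dual-covering reads and nonzero marginals; significance is `p < 0.01`.

Co-editing groups are classified on the *raw* (unoriented) proportion
vectors (both, only-site1, only-site2, neither): hierarchical
clustering (average linkage, Euclidean) cut at four groups, then
labeled by centroid — low-coverage-of-both (group 2), high-both
(group 1), and the two one-sided groups by which "only" arm leads.
Orienting the vectors before clustering would make the two one-sided
groups indistinguishable, which is why the classification operates in
the unoriented space and reports the lead site separately.

In the long-read generator, a transcript whose junction-proximal site
is edited retains its intron with probability `coupling` (default 1);
unedited transcripts splice with probability `base_splice` (0.1).
With full coupling the spliced population is purely unedited, so the
unspliced-minus-spliced rate difference at the junction site
approaches `100 · p_edit / (p_edit + (1 − p_edit)(1 − base_splice))`
— about 62% at the defaults — giving the splice-distance analysis a
strong planted signal without forbidding edited-and-spliced reads
outright when `coupling < 1`.

## 8. The synthetic generator as study conditions

The generator's defaults are the package's study conditions: 2 × 1 Mb
subgenome contigs (`chr1.L`, `chr1.S`), 8 genes per contig with
in-frame CDS, 40 repeats per contig in four families, 25 strong + 4
weak variants per contig, a diverged second genome (2% point
divergence, 500 nt insertions every 50 kb, second contig stored
reverse-complemented so the chain exercises the `−`-strand path), and
3 studies × 4 contexts × 2 replicates at 50×, 0.2% error. Each
simulation stage reseeds deterministically from the user seed plus a
fixed stage offset, so genomes, editome placement, and read draws are
independently reproducible.

Planted classes and their placement invariants: clusters (3 sites,
gaps ≤ 20 nt), isolated sites (≥ 41 nt clearance from everything),
hyper regions (§3), context-specific pairs (≤ 20 nt apart, one focal
context at 20% vs 2% elsewhere), coding sites (existing AAA/AAG lysine
codons inside plus-strand CDS, so K→E and K→R arise without modifying
the genome), and SNP decoys in two classes — strong (must be removed
by the cascade) and deliberately weak (qual 10 / depth 5, *expected*
to leak through rescue; the WGS diagnostic exists to catch them).

**Sparse counts are exact.** Materializing a dense 2 Mb × 24-sample
pileup is wasteful, but naive per-sample sparse error rows would
understate pooled coverage (a position absent from other samples
deflates the pooled denominator and inflates apparent levels). The
generator therefore draws sequencing errors once per study at the
pooled depth, keeps only positions whose pooled error count reaches
the caller's variant-read minimum (3), splits the kept counts
multinomially over the study's samples, and emits a row in *every*
sample at a kept position. Positions below the pooled minimum can
never be called under any within-study pooling, so for every
thresholded computation the sparse tables are exactly equivalent to
the dense pileup — this is an identity, not an approximation.

## 9. Limitations

- The error model is uniform and strand-symmetric: no quality decay,
  homopolymer effects, or damage asymmetries. This is what makes the
  null spectrum analytically flat (the FDR calibration regime); it
  also means the estimator is untested here against asymmetric error
  processes.
- Counts-mode simulation is pileup-equivalent by construction and so
  cannot express alignment dropout; hyper-editing realism lives only
  in read-mode (`simulate_region_reads()`).
- The toy aligner indexes exact 16-mers at a fixed stride; reads whose
  sampled seeds all straddle errors are lost, and the unique-best rule
  discards genuinely repetitive placements rather than resolving them.
- Cross-study rescue trades specificity for sensitivity by design:
  sub-threshold genomic variants that replicate across studies are
  rescued as sites. They are flagged, not removed, by the WGS
  diagnostic.
- The co-editing group classifier assumes the four archetypes span the
  observed tables; gene sets smaller than four fall back to
  nearest-archetype assignment.
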
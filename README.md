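# editome

Discovery and characterization of A-to-I RNA editing sites from
RNA-seq, DNA-seq and long-read data, with a fully synthetic,
truth-tracked benchmark generator.

Adenosine deaminases (ADARs) convert adenosine to inosine in
double-stranded RNA; sequencers read inosine as guanosine, so editing
appears as A→G mismatches between RNA reads and the genome. Separating
real editing from genomic variants and sequencing noise is the central
statistical problem: the package implements a pileup-based candidate
caller, a multi-step filter cascade whose false discovery rate is
estimated from the mismatch spectrum (non-A→G types act as an internal
negative control), a transformed-alignment pipeline for hyper-edited
reads that fail normal alignment, an AEI-style repeat editing index,
developmental-context specificity calls, cross-species conservation via
a native chain-file liftover (including homeolog-aware dual-target
mapping for allotetraploid genomes), recoding (amino-acid-changing)
annotation, and read-level phasing of editing against splicing from
long reads.

Every analysis stage has a matching synthetic-data generator that
plants a known editome (clustered, isolated, hyper-edited,
context-specific, coding, and SNP decoy sites) so the whole pipeline is
testable against ground truth.

## Worked example

Simulate a small two-subgenome study, call and filter sites, and
characterize the result (all output below is real):

```r
library(editome)

# 1. Simulate a small study (200 kb per contig, planted truth)
cfg <- sim_config(seed = 7, genome = list(length = 200000L),
                  editome = list(n_clusters = 12L, n_isolated = 8L,
                                 n_hyper = 2L, n_context = 6L, n_coding = 4L),
                  snps = list(n_per_contig = 10L))
sim   <- simulate_genomes(cfg)
truth <- plant_editome(sim, cfg)
cs    <- simulate_counts(sim, truth, cfg)
wgs   <- simulate_wgs(sim, truth, cfg)

# 2. Candidate sites per study (>=10 reads, >=3 variant reads, >=1% level)
per_study <- lapply(split(cs$context_map$sample, cs$context_map$study),
                    function(ss) call_candidates(pool_samples(cs$samples[ss])))
sapply(per_study, nrow)
#> study1 study2 study3
#>    303    339    327

# 3. Filter cascade: SNP removal, +/-20 nt window filters, cross-study rescue
cascade <- run_filter_cascade(per_study, variants = wgs$variants)
cascade$report$clustered$spectrum
#> mismatch spectrum over 82 sites
#>  AC  AG  AT  CA  CG  CT  GA  GC  GT  TA  TC  TG
#>   0 100   0   0   0   0   0   0   0   0   0   0

catalog <- build_catalog(pooled = cascade$clustered, rescued = cascade$rescued)
nrow(catalog)
#> [1] 96

# 4. Score against the planted truth
score_recovery(catalog, truth)
#>               class n_planted n_recovered pct_recovered
#> 1:        clustered        36          36           100
#> 2:         isolated         8           8           100
#> 3:            hyper        40          40           100
#> 4: context_specific         6           6           100
#> 5:           coding         4           4           100
#> 6:              SNP        20           0             0
#> 7:      SNP_lowqual         8           2            25

# 5. Hyper-editing: transformed realignment of reads too edited to map
tr  <- data.table::as.data.table(truth)
hyp <- tr[class == "hyper"]
regions <- hyp[, .(start = min(pos) - 10L, end = max(pos) + 10L),
               by = .(contig, region_id)]
rr <- simulate_region_reads(sim, truth, regions, cfg)
hy <- run_hyper_pipeline(rr$unmapped, sim$genome_a)
mean(paste(hyp$contig, hyp$pos) %in% paste(hy$sites$contig, hy$sites$pos))
#> [1] 1

# 6. Repeat editing index (read-weighted aggregate over repeat adenosines)
rc <- simulate_repeat_counts(sim, rate = 0.15, cfg = cfg)
repeat_editing_index(rc$counts, rc$repeats)
#> editing index [all-repeats]: 14.89% (45170 G / 303450 A+G reads over 6049 A positions)

# 7. Recoding annotation of the planted coding sites
coding <- tr[class == "coding", .(contig, pos, strand, type)]
annotate_recoding(coding, sim$genes_a, sim$genome_a)[
  , .(contig, pos, ref_codon, edited_codon, ref_aa, edited_aa)]
#>    contig    pos ref_codon edited_codon ref_aa edited_aa
#> 1: chr1.L 160257       AAA          GAA      K         E
#> 2: chr1.L 160176       AAA          GAA      K         E
#> 3: chr1.L  40829       AAG          AGG      K         R
#> 4: chr1.L 140233       AAA          GAA      K         E
```

The two recoding outcomes above, K→E (AAA→GAA) and K→R (AAG→AGG), are
the two most common recoding event types at A-to-I sites.

Note the `SNP` row in step 4: strong genomic variants are removed
completely, while the deliberately weak `SNP_lowqual` decoys (below the
depth ≥ 10 / qual ≥ 20 removal thresholds) can leak back in through the
cross-study rescue — the known failure mode that motivates the
whole-genome support diagnostic (`genomic_support_check()`).

## Modules

| File | Contents |
|---|---|
| `R/formats_io.R` | FASTA / GFF3 / BED / VCF / SAM / chain / counts readers and writers |
| `R/site_discovery.R` | quality-filtered pileup, candidate caller, pooling, mismatch spectrum + FDR |
| `R/filter_cascade.R` | SNP removal, ±20 nt window filters, clustered/isolated split, cross-study rescue, catalog, WGS diagnostic |
| `R/hyper_editing.R` | 12 base-transform schemes, toy seed-and-verify aligner, dense-cluster site caller |
| `R/editome_metrics.R` | repeat editing index, context-specificity calls, location/repeat/motif annotation, overlap enrichment |
| `R/coding_conservation.R` | native chain liftover (single / homeolog), cross-species comparison, symbol resolution, recoding annotation |
| `R/longread_phasing.R` | per-read site states, isoform editing rates, splice-distance table, χ² co-editing, co-editing group classification |
| `R/synthetic_data.R` | genome/editome/read simulators with per-class truth tracking and recovery scoring |

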
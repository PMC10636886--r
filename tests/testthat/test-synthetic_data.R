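# Generator invariants: determinism, planted-structure constraints,
# coverage honesty of the counts tables, on-disk materialization.

test_that("the full generator chain is deterministic under a seed", {
  cfg <- sim_config(seed = 13L, genome = list(length = 60000L),
                    genes = list(n_per_contig = 3L),
                    editome = list(n_clusters = 4L, n_isolated = 3L,
                                   n_hyper = 1L, n_context = 2L,
                                   n_coding = 2L),
                    snps = list(n_per_contig = 5L))
  run <- function() {
    sim <- simulate_genomes(cfg)
    truth <- plant_editome(sim, cfg)
    cs <- simulate_counts(sim, truth, cfg)
    list(g = as.character(sim$genome_a), t = truth, s1 = cs$samples[[1]])
  }
  a <- run(); b <- run()
  expect_identical(a$g, b$g)
  expect_identical(as.data.frame(a$t), as.data.frame(b$t))
  expect_identical(as.data.frame(a$s1), as.data.frame(b$s1))
})

test_that("planted classes respect their geometric constraints", {
  sc <- small_scenario()
  tr <- data.table::as.data.table(sc$truth)
  ed <- tr[!tr$class %in% c("SNP", "SNP_lowqual"), ]
  # every edited position is a genomic adenosine on the plus strand
  expect_true(all(genome_base(sc$sim$genome_a, ed$contig, ed$pos) == "A"))
  # clusters: intra-cluster gaps <= 20 nt so the sites mutually rescue
  gaps <- ed[ed$class == "clustered",
             list(gmax = max(diff(sort(pos)))), by = "region_id"]
  expect_true(all(gaps$gmax <= 20L))
  # hyper regions: the configured number of sites inside the span
  hspan <- ed[ed$class == "hyper",
              list(n = .N, span = max(pos) - min(pos)), by = "region_id"]
  expect_true(all(hspan$n == sc$cfg$editome$hyper_sites))
  expect_true(all(hspan$span <= sc$cfg$editome$hyper_span))
  # isolated sites keep >= 41 nt clearance from every other planted site
  iso <- ed[ed$class == "isolated", ]
  for (i in seq_len(nrow(iso))) {
    d <- abs(ed$pos[ed$contig == iso$contig[i]] - iso$pos[i])
    expect_true(all(d[d > 0] > 40L))
  }
  # context-specific sites come in within-20-nt pairs sharing a context
  cxp <- ed[ed$class == "context_specific", ]
  pair <- cxp[, list(n = .N, span = max(pos) - min(pos),
                     one_ctx = data.table::uniqueN(focal_context) == 1L),
              by = "region_id"]
  expect_true(all(pair$n == 2L & pair$span <= 20L & pair$one_ctx))
})

test_that("conserved sites map to adenosines in genome B", {
  sc <- small_scenario()
  tr <- data.table::as.data.table(sc$truth)
  cons <- tr[tr$conserved == TRUE, ]
  expect_gt(nrow(cons), 0L)
  lf <- liftover_site(sc$sim$chain, cons$contig, cons$pos)
  tb <- check_target_base(sc$sim$genome_b, lf)
  expect_true(all(tb$target_class == "A"))
  expect_equal(lf$tgt_pos, cons$partner_pos)
  # at least one conserved site crosses the '-'-strand chain
  expect_true(any(lf$tgt_strand == "-"))
})

test_that("counts tables are coverage-honest at materialized positions", {
  sc <- small_scenario()
  cs <- small_counts()
  depth <- sc$cfg$sequencing$depth
  s1 <- cs$samples[[1]]
  expect_true(all(s1$total == depth))
  # planted sites appear in every sample; pooled coverage is exact
  tr <- data.table::as.data.table(sc$truth)
  pooled <- pool_samples(cs$samples)
  m <- pooled[tr[, c("contig", "pos")], on = c("contig", "pos")]
  expect_true(all(m$total == depth * length(cs$samples)))
})

test_that("truth_rate switches context-specific sites only", {
  sc <- small_scenario()
  tr <- data.table::as.data.table(sc$truth)
  cx <- which(tr$class == "context_specific")[1]
  focal <- tr$focal_context[cx]
  other <- setdiff(sc$cfg$sequencing$contexts, focal)[1]
  expect_equal(truth_rate(tr, focal)[cx], sc$cfg$editome$context_rate)
  expect_equal(truth_rate(tr, other)[cx], sc$cfg$editome$context_rate_other)
  cl <- which(tr$class == "clustered")[1]
  expect_equal(truth_rate(tr, focal)[cl], truth_rate(tr, other)[cl])
})

test_that("null_editome zeroes editing but keeps variants and errors", {
  sc <- small_scenario()
  cfg <- sc$cfg
  cs0 <- simulate_counts(sc$sim, sc$truth, cfg, null_editome = TRUE)
  tr <- data.table::as.data.table(sc$truth)
  ed <- tr[tr$class == "clustered", ]
  pooled <- pool_samples(cs0$samples)
  m <- pooled[ed[, c("contig", "pos")], on = c("contig", "pos")]
  expect_true(all(m$nG == 0L))
  snp <- tr[tr$class == "SNP" & tr$rate == 1, ][1]
  msnp <- pooled[snp[, c("contig", "pos")], on = c("contig", "pos")]
  vb <- substring(snp$type, 2L, 2L)
  expect_gt(msnp[[paste0("n", vb)]], 0L)
})

test_that("region reads route dense edits to the unmapped pool", {
  sc <- small_scenario()
  tr <- data.table::as.data.table(sc$truth)
  hr <- tr[tr$class == "hyper",
           list(start = min(pos), end = max(pos)),
           by = c("contig", "region_id")]
  rr <- simulate_region_reads(sc$sim, sc$truth, hr, sc$cfg, depth = 25)
  L <- sc$cfg$sequencing$read_len
  # aligned reads never exceed the mismatch tolerance
  for (i in seq_len(min(nrow(rr$sam), 20L))) {
    ref <- genome_seq(sc$sim$genome_a, rr$sam$contig[i], rr$sam$pos[i],
                      rr$sam$pos[i] + L - 1L)
    nm <- sum(strsplit(ref, "")[[1]] != strsplit(rr$sam$seq[i], "")[[1]])
    expect_lte(nm, floor(0.03 * L))
  }
  expect_gt(length(rr$unmapped), nrow(rr$sam))  # 80% editing of 8 sites
})

test_that("write_simulation materializes a readable dataset", {
  cfg <- sim_config(seed = 3L, genome = list(length = 60000L),
                    genes = list(n_per_contig = 3L),
                    editome = list(n_clusters = 4L, n_isolated = 2L,
                                   n_hyper = 1L, n_context = 2L,
                                   n_coding = 1L),
                    snps = list(n_per_contig = 4L))
  sim <- simulate_genomes(cfg)
  truth <- plant_editome(sim, cfg)
  d <- withr::local_tempdir()
  p <- write_simulation(sim, truth, d)
  expect_true(all(file.exists(p)))
  expect_equal(as.character(read_genome(p["genome_a"])),
               as.character(sim$genome_a))
  ch <- read_chain(p["chain"])
  expect_equal(as.data.frame(ch[order(chain_id, src_start)]),
               as.data.frame(sim$chain[order(chain_id, src_start)]))
  expect_equal(nrow(read_vcf(p["vcf"])), nrow(sim$snps))
  expect_gt(nrow(read_annotation(p["genes_a"])), 0L)
})

test_that("score_recovery counts per-class hits", {
  truth <- data.table::data.table(
    contig = "c1", pos = 1:6, strand = "+", type = "AG",
    class = c(rep("clustered", 3), rep("SNP", 3)))
  catalog <- data.table::data.table(contig = "c1", pos = c(1L, 2L, 9L))
  r <- score_recovery(catalog, truth)
  expect_equal(r$n_recovered[r$class == "clustered"], 2L)
  expect_equal(r$pct_recovered[r$class == "SNP"], 0)
})
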
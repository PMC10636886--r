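# Editing index, context-specificity, annotation layers, motif, enrichment.

test_that("editing index matches the hand-computed read-weighted aggregate", {
  cnt <- data.table::data.table(
    contig = "c1", pos = c(10L, 11L, 12L, 30L, 31L), strand = "*",
    ref = c("A", "A", "C", "T", "A"),
    nA = c(18L, 10L, 0L, 0L, 20L), nC = c(0L, 0L, 20L, 3L, 0L),
    nG = c(2L, 10L, 0L, 0L, 0L), nT = c(0L, 0L, 0L, 17L, 0L))
  reps <- data.table::data.table(contig = "c1", start = c(5L, 28L),
                                 end = c(15L, 35L), family = c("Alu-like", "L1"),
                                 strand = c("+", "-"))
  idx <- repeat_editing_index(cnt, reps)
  # '+' repeat A positions: (2+10) G over (18+2 + 10+10) A+G
  # '-' repeat T positions: 3 C over (17+3) T+C
  expect_equal(idx$numerator, 15L)
  expect_equal(idx$denominator, 60L)
  expect_equal(idx$index, 25)
  # family restriction
  idx_alu <- repeat_editing_index(cnt, reps, family = "Alu-like")
  expect_equal(idx_alu$index, 100 * 12 / 40)
  expect_error(repeat_editing_index(cnt, reps, family = "absent"),
               "undefined")
})

test_that("uniform planted repeat editing is recovered by the index", {
  sc <- small_scenario()
  rc <- simulate_repeat_counts(sc$sim, rate = 0.15, n_repeats = 20)
  idx <- repeat_editing_index(rc$counts, rc$repeats)
  expect_lt(abs(idx$index - 15), 2)
})

test_that("minor repeat families are grouped deterministically", {
  fc <- c(Alu = 800L, L1 = 150L, DNA = 30L, LTR = 12L, Sat = 8L)
  g <- group_minor_families(fc, min_frac = 0.05)
  expect_equal(unname(g[c("Alu", "L1")]), c("Alu", "L1"))
  expect_equal(unname(g[c("DNA", "LTR", "Sat")]), rep("other", 3))
  g2 <- group_minor_families(fc, keep_top = 3)
  expect_equal(unname(g2["DNA"]), "DNA")
})

test_that("per-context levels follow the pool-then-average hierarchy", {
  site <- data.table::data.table(contig = "c1", pos = 50L, strand = "+",
                                 type = "AG")
  mk <- function(nA, nG) data.table::data.table(
    contig = "c1", pos = 50L, strand = "*", ref = "A",
    nA = nA, nC = 0L, nG = nG, nT = 0L)
  samples <- list(a1 = mk(90L, 10L), a2 = mk(80L, 20L),   # study A: pooled 30/200
                  b1 = mk(95L, 5L))                       # study B: 5/100
  cmap <- data.table::data.table(sample = c("a1", "a2", "b1"),
                                 study = c("A", "A", "B"),
                                 context = "ctx1")
  lv <- per_context_levels(site, samples, cmap)
  # study A level 15%, study B 5% -> stage mean 10%
  expect_equal(lv$level, 10)
  expect_equal(lv$context, "ctx1")
  # coverage gate: a study-stage below min_cov drops out of the mean
  lv2 <- per_context_levels(site, samples, cmap, min_cov = 150L)
  expect_equal(lv2$level, 15)
})

test_that("context-specific calls enforce level, coverage and fold rules", {
  prof <- data.table::data.table(
    contig = "c1", pos = rep(c(1L, 2L, 3L, 4L), each = 2L), strand = "+",
    type = "AG",
    context = rep(c("early", "late"), 4L),
    level = c(9, 2,      # 4.5-fold -> specific to early
              9, 4,      # 2.25-fold -> not specific
              0.9, 0.2,  # focal below 1% -> not called
              6, 0),     # zero elsewhere -> specific
    n_stages = 2L)
  cx <- call_context_specific(prof)
  expect_setequal(cx$pos, c(1L, 4L))
  expect_equal(cx$context[cx$pos == 1L], "early")
  # mean mode: focal 9 vs mean(3,3.5) -> pos 2 has others 4 only, 9/4 < 3
  prof3 <- data.table::data.table(
    contig = "c1", pos = 9L, strand = "+", type = "AG",
    context = c("a", "b", "c"), level = c(9, 1, 5), n_stages = 1L)
  expect_equal(nrow(call_context_specific(prof3)), 0L)   # 9/5 < 3 vs each
  cx_mean <- call_context_specific(
    prof3, specificity_config(fold_vs = "mean"))
  expect_equal(cx_mean$context, "a")                     # 9/mean(1,5)=3 -> called
  # a single measured context can never be specific
  prof1 <- prof3[1]
  expect_equal(nrow(call_context_specific(prof1)), 0L)
})

test_that("planted context-specific sites are called exactly on simulation", {
  sc <- small_scenario()
  cs <- small_counts()
  tr <- data.table::as.data.table(sc$truth)
  catal <- tr[tr$class %in% c("clustered", "context_specific"),
              c("contig", "pos", "strand", "type")]
  lv <- per_context_levels(catal, cs$samples, cs$context_map)
  cx <- call_context_specific(lv)
  want <- tr[tr$class == "context_specific", ]
  expect_setequal(paste(cx$contig, cx$pos), paste(want$contig, want$pos))
  m <- match(paste(cx$contig, cx$pos), paste(want$contig, want$pos))
  expect_equal(cx$context, want$focal_context[m])
})

test_that("location annotation applies the CDS-over-UTR-over-intron priority", {
  genes <- data.table::data.table(
    gene = "g1", transcript = "t1", contig = "c1", strand = "+",
    feature = c("exon", "exon", "five_prime_UTR", "CDS", "CDS",
                "three_prime_UTR"),
    start = c(100L, 300L, 100L, 150L, 300L, 350L),
    end = c(200L, 400L, 149L, 200L, 349L, 400L))
  sites <- data.table::data.table(
    contig = "c1", pos = c(120L, 180L, 250L, 360L, 900L), strand = "+",
    type = "AG")
  ann <- annotate_location(sites, genes)
  expect_equal(ann$feature_class,
               c("5'UTR", "CDS", "intron", "3'UTR", "intergenic"))
  expect_equal(ann$gene[1:4], rep("g1", 4))
  expect_true(is.na(ann$gene[5]))
})

test_that("repeat annotation picks the smallest covering repeat", {
  reps <- data.table::data.table(
    contig = "c1", start = c(100L, 140L), end = c(400L, 160L),
    family = c("L1", "Alu-like"), strand = "+")
  sites <- data.table::data.table(contig = "c1", pos = c(150L, 300L, 500L),
                                  strand = "+", type = "AG")
  ann <- annotate_repeat(sites, reps)
  expect_equal(ann$repeat_family, c("Alu-like", "L1", NA))
})

test_that("neighbor motif counts sense-strand flanks with row sums of 1", {
  g <- Biostrings::DNAStringSet(c(cM = "TTACGTT"))
  # '+' site at 4 (G upstream is position 3 = A); '-' site at 4
  plus <- data.table::data.table(contig = "cM", pos = 4L, strand = "+")
  mm <- neighbor_motif(plus, g, k = 1L)
  expect_equal(rownames(mm), c("-1", "+1"))
  expect_equal(unname(mm["-1", "A"]), 1)     # upstream base A
  expect_equal(unname(mm["+1", "G"]), 1)     # downstream base G
  minus <- data.table::data.table(contig = "cM", pos = 4L, strand = "-")
  mm2 <- neighbor_motif(minus, g, k = 1L)
  # sense upstream of a '-' site is genomic pos 5 complemented: G -> C
  expect_equal(unname(mm2["-1", "C"]), 1)
  expect_true(all(abs(rowSums(mm2) - 1) < 1e-12))
})

test_that("overlap enrichment reproduces the hypergeometric computation", {
  u <- paste0("g", 1:100)
  a <- u[1:20]; b <- u[11:40]
  en <- overlap_enrichment(a, b, u)
  expect_equal(en$n_overlap, 10L)
  expect_equal(en$expected, 20 * 30 / 100)
  expect_equal(en$representation_factor, 10 / 6)
  expect_equal(en$p_value,
               stats::phyper(9, 20, 80, 30, lower.tail = FALSE))
})
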
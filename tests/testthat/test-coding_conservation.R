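# Native chain liftover, cross-species comparison, symbol resolution,
# high-confidence coding tiers, recoding annotation, external-site audit.

toy_chain <- function() {
  # two chains from srcX: a '+' target and a lower-scoring '-' target
  data.table::data.table(
    chain_id = c("1", "1", "2"), score = c(1000, 1000, 900),
    src_contig = "srcX", src_size = 100L,
    src_start = c(11L, 51L, 11L), src_end = c(40L, 80L, 80L),
    tgt_contig = c("tgtP", "tgtP", "tgtM"), tgt_size = c(200L, 200L, 120L),
    tgt_strand = c("+", "+", "-"), tgt_start0 = c(20L, 60L, 10L))
}

test_that("liftover matches hand-computed '+' and '-' block arithmetic", {
  ch <- toy_chain()[chain_id == "1"]
  lf <- liftover_site(ch, "srcX", c(11L, 40L, 45L, 51L, 80L))
  expect_equal(lf$mapped, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # block 1: offset = pos - 11; tgt = 20 + off + 1
  expect_equal(lf$tgt_pos[1:2], c(21L, 50L))
  expect_equal(lf$tgt_pos[4:5], c(61L, 90L))
  chm <- toy_chain()[chain_id == "2"]
  lfm <- liftover_site(chm, "srcX", c(11L, 80L))
  # '-' strand: tgt_pos = tgt_size - (tgt_start0 + off)
  expect_equal(lfm$tgt_pos, c(110L, 41L))
  expect_equal(lfm$tgt_strand, c("-", "-"))
})

test_that("single mode picks the best-scoring chain; homeolog keeps .L/.S", {
  lf <- liftover_site(toy_chain(), "srcX", 20L)
  expect_equal(nrow(lf), 1L)
  expect_equal(lf$tgt_contig, "tgtP")      # score 1000 beats 900
  hch <- data.table::data.table(
    chain_id = c("1", "2"), score = c(1000, 900),
    src_contig = "srcX", src_size = 100L,
    src_start = 1L, src_end = 100L,
    tgt_contig = c("chr2.L", "chr2.S"), tgt_size = 500L,
    tgt_strand = "+", tgt_start0 = c(0L, 100L))
  hl <- liftover_site(hch, "srcX", 10L, mode = "homeolog")
  expect_equal(nrow(hl), 2L)
  expect_setequal(hl$tgt_contig, c("chr2.L", "chr2.S"))
  # non-homeolog second target is not kept
  hch2 <- data.table::copy(hch)[2, tgt_contig := "other3"]
  hl2 <- liftover_site(hch2, "srcX", 10L, mode = "homeolog")
  expect_equal(nrow(hl2), 1L)
})

test_that("liftover agrees with the brute-force walk on simulated chains", {
  sc <- small_scenario()
  ch <- sc$sim$chain
  set.seed(31)
  pos <- sample.int(200000L, 300L)
  contig <- sample(names(sc$sim$genome_a), 300L, replace = TRUE)
  lf <- liftover_site(ch, contig, pos)
  for (i in seq_len(300L)) {
    o <- oracle_lift(ch, contig[i], pos[i])
    if (is.null(o)) {
      expect_false(lf$mapped[i])
    } else {
      best <- o[order(-score, chain_id)][1]
      expect_true(lf$mapped[i])
      expect_equal(lf$tgt_pos[i], best$tgt_pos)
      expect_equal(lf$tgt_contig[i], best$tgt_contig)
    }
  }
})

test_that("target-base check complements across '-' mappings", {
  g <- Biostrings::DNAStringSet(c(t1 = "AACGT"))
  lifted <- data.table::data.table(
    mapped = c(TRUE, TRUE, TRUE, FALSE),
    tgt_contig = c("t1", "t1", "t1", NA), tgt_pos = c(1L, 5L, 3L, NA),
    tgt_strand = c("+", "-", "+", NA))
  tb <- check_target_base(g, lifted)
  # pos 5 on '-' is complement of T, i.e. an A on the aligned strand
  expect_equal(tb$target_base, c("A", "A", "C", NA))
  expect_equal(tb$target_class, c("A", "A", "other", "unassessable"))
})

test_that("symbol conflicts spare general names and listed synonyms", {
  lifted <- data.table::data.table(
    src_contig = "s", src_pos = 1:5, tgt_contig = "t", tgt_pos = 1:5,
    gene_a = c("ncl", "ncl", "ncl", "LOC1234", "gsc"),
    gene_b = c("ncl", "nucleolin", "alt9", "whatever", "MGC0001"))
  syn <- data.table::data.table(symbol = "ncl", synonym = "nucleolin")
  rs <- resolve_gene_symbols(lifted, synonyms = syn)
  expect_equal(rs$symbol_conflict, c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("species comparison assigns all conservation classes", {
  lifted <- data.table::data.table(
    src_contig = "s", src_pos = 1:5,
    tgt_contig = "t", tgt_pos = 1:5, tgt_strand = "+", mapped = TRUE,
    target_class = c("A", "A", "A", "G", "A"))
  profA <- data.table::data.table(contig = "s", pos = 1:5,
                                  level = c(20, 20, 20, 20, 20),
                                  coverage = 100L)
  profB <- data.table::data.table(contig = "t", pos = 1:5,
                                  level = c(18, 0.2, 45, 50, 10),
                                  coverage = c(100L, 100L, 100L, 100L, 5L))
  cc <- compare_species(profA, profB, lifted)
  expect_equal(cc$conservation_class,
               c("conserved-similar", "species-specific",
                 "conserved-differential", "fixed-G", "unassessable"))
})

test_that("high-confidence tiers follow both-pipelines then same-gene logic", {
  genes <- data.table::data.table(
    gene = rep(c("gA", "gB"), each = 2L),
    transcript = rep(c("tA", "tB"), each = 2L), contig = "c1", strand = "+",
    feature = rep(c("exon", "CDS"), 2L),
    start = c(100L, 100L, 500L, 500L), end = c(200L, 200L, 600L, 600L))
  mk <- function(pos) data.table::data.table(
    contig = "c1", pos = pos, strand = "+", type = "AG",
    coverage = 50L, variant = 5L, rate = 10)
  reg <- mk(c(110L, 120L, 550L))
  hyp <- mk(c(110L, 130L))
  hc <- high_confidence_coding(reg, hyp, genes)
  expect_equal(hc$pos[hc$tier == 1L], 110L)          # in both pipelines
  expect_setequal(hc$pos[hc$tier == 2L], c(120L, 130L))  # same gene gA
  expect_false(550L %in% hc$pos)                     # gB has no tier-1 site
  # tier 3 requires local variant evidence
  oc <- data.table::data.table(contig = "c1", pos = c(560L, 570L),
                               strand = "+", type = "AG",
                               coverage = 50L, variant = c(2L, 0L), rate = 4)
  hc3 <- high_confidence_coding(reg, hyp, genes, ortholog_candidates = oc)
  expect_equal(hc3$pos[hc3$tier == 3L], 560L)
})

test_that("recoding annotation is exact on plus and minus strand genes", {
  # genome: + gene CDS 1..6 = ATG AAG ; - gene CDS on reverse of 11..16
  # reverse complement of CCTCAT is ATGAGG = M R
  g <- Biostrings::DNAStringSet(c(cR = "ATGAAGTTTTCCTCATTTT"))
  genes <- data.table::data.table(
    gene = c("gp", "gm"), transcript = c("tp", "tm"),
    contig = "cR", strand = c("+", "-"),
    feature = "CDS", start = c(1L, 11L), end = c(6L, 16L))
  genes <- rbind(genes, data.table::copy(genes)[, feature := "exon"])
  sites <- data.table::data.table(
    contig = "cR", pos = c(5L, 13L), strand = c("+", "-"), type = "AG")
  rec <- annotate_recoding(sites, genes, g)
  # + site at 5: codon AAG position 2 -> AGG (K->R)
  expect_equal(rec$ref_codon[1], "AAG")
  expect_equal(rec$edited_codon[1], "AGG")
  expect_equal(rec$ref_aa[1], "K")
  expect_equal(rec$edited_aa[1], "R")
  # - site at genomic 13 (sense A in AGG codon of ATGAGG): codon 2 pos 1
  expect_equal(rec$ref_codon[2], "AGG")
  expect_equal(rec$edited_codon[2], "GGG")
  expect_equal(rec$ref_aa[2], "R")
  expect_equal(rec$edited_aa[2], "G")
  expect_false(any(rec$synonymous))
})

test_that("external-site audit applies the category precedence", {
  ext <- data.table::data.table(
    tgt_contig = "c1", tgt_pos = c(10L, 20L, 30L, 40L, 50L),
    target_class = c("A", "A", "A", "A", "other"))
  cat2 <- data.table::data.table(contig = "c1", pos = 10L, strand = "+",
                                 type = "AG")
  raw <- data.table::data.table(contig = "c1", pos = c(10L, 20L),
                                rate = c(15, 5))
  cnt <- data.table::data.table(contig = "c1", pos = c(10L, 20L, 30L, 40L),
                                strand = "*", ref = "A",
                                nA = c(50L, 50L, 50L, 4L), nC = 0L, nG = 0L,
                                nT = 0L)
  ev <- evaluate_external_sites(ext, cat2, raw, cnt)
  expect_equal(ev$category,
               c("in-catalog", "filtered-but-edited", "covered-no-editing",
                 "no-coverage", "unmapped/not-A"))
})
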
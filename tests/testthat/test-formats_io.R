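# Readers/writers: round trips, coordinate-convention conversions,
# validation of malformed inputs.

test_that("FASTA round trip preserves sequence and names, folds case", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgtACGT", ">c2", "NNNACGT"), f)
  g <- read_genome(f)
  expect_equal(names(g), c("c1", "c2"))
  expect_equal(as.character(g[["c1"]]), "ACGTACGT")
  expect_equal(as.character(g[["c2"]]), "NNNACGT")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f2)
  expect_equal(as.character(read_genome(f2)), as.character(g))
})

test_that("read_genome rejects duplicate contigs and bad alphabets", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), f)
  expect_error(read_genome(f), "duplicate contig")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(">c1\nAC-T", f2)
  expect_error(suppressWarnings(read_genome(f2)))
})

test_that("genome_base and genome_seq enforce bounds", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  expect_equal(genome_base(g, "c1", c(1L, 4L, 8L)), c("A", "T", "T"))
  expect_equal(genome_seq(g, "c1", 2L, 5L), "CGTA")
  expect_error(genome_base(g, "c1", 9L), "out of range")
  expect_error(genome_base(g, "nope", 1L), "unknown contig")
  expect_error(genome_seq(g, "c1", 5L, 2L), "out of range")
})

test_that("counts-table round trip recomputes total and validates", {
  cnt <- data.table::data.table(
    contig = "c1", pos = 1:3, strand = c("+", "-", "*"), ref = c("A", "C", "G"),
    nA = c(10L, 0L, 1L), nC = c(0L, 9L, 0L), nG = c(2L, 0L, 7L),
    nT = c(0L, 1L, 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(cnt, f)
  back <- read_counts_table(f)
  expect_equal(back$total, c(12L, 10L, 8L))
  expect_equal(back$pos, cnt$pos)
  bad <- data.table::copy(cnt)[1, nA := -1L]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(bad, f2, sep = "\t")
  expect_error(read_counts_table(f2), "negative count")
})

test_that("VCF reading handles missing QUAL and DP conservatively", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "c1\t100\t.\tA\tG\t50\t.\tDP=30",
               "c1\t200\t.\tC\tT\t.\t.\tDP=12",
               "c1\t300\t.\tG\tA\t40\t.\t."), f)
  v <- read_vcf(f)
  expect_equal(v$qual, c(50, 0, 40))
  expect_equal(v$depth, c(30L, 12L, 0L))
  # write_vcf round trip
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f2, contig_lengths = c(c1 = 1000L))
  v2 <- read_vcf(f2)
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$depth, v$depth)
})

test_that("BED repeats convert to 1-based inclusive and require a family", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t99\t200\tAlu-like\t0\t+",
               "c1\t500\t600\tLINE\t0\t-"), f)
  r <- read_repeats(f)
  expect_equal(r$start, c(100L, 501L))
  expect_equal(r$end, c(200L, 600L))
  expect_equal(r$family, c("Alu-like", "LINE"))
  expect_equal(r$strand, c("+", "-"))
})

test_that("chain parsing matches a hand-computed example", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 1000 srcA 100 + 10 60 tgtB 200 + 20 75 7",
               "30\t5\t10",
               "15", ""), f)
  ch <- read_chain(f)
  expect_equal(nrow(ch), 2L)
  # block 1: src 0-based [10,40) -> 1-based [11,40]; tgt starts at 20
  expect_equal(ch$src_start, c(11L, 46L))
  expect_equal(ch$src_end, c(40L, 60L))
  expect_equal(ch$tgt_start0, c(20L, 60L))
  expect_equal(ch$tgt_strand, c("+", "+"))
  expect_equal(ch$score, c(1000, 1000))
  expect_equal(ch$chain_id, c("7", "7"))
  f2 <- withr::local_tempfile(fileext = ".chain")
  write_chain(ch, f2)
  expect_equal(as.data.frame(read_chain(f2)), as.data.frame(ch))
})

test_that("chain parser rejects overlapping source blocks", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 1000 srcA 100 + 10 60 tgtB 200 + 20 75 7",
               "30\t-5\t0",
               "25", ""), f)
  expect_error(read_chain(f))
})

test_that("GFF3 gene models round trip through write_gff3/read_annotation", {
  sc <- small_scenario()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sc$sim$genes_a, f)
  an <- read_annotation(f)
  want <- data.table::as.data.table(sc$sim$genes_a)
  got <- merge(an, want, by = c("gene", "transcript", "contig", "strand",
                                "feature", "start", "end"))
  expect_equal(nrow(got), nrow(want))
  expect_length(attr(an, "incomplete_cds_transcripts"), 0L)
})

test_that("read_annotation flags transcripts with CDS not divisible by 3", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tgene\t1\t100\t.\t+\t.\tID=gA;gene=gA",
               "c1\tx\tmRNA\t1\t100\t.\t+\t.\tID=tA;Parent=gA",
               "c1\tx\texon\t1\t100\t.\t+\t.\tParent=tA",
               "c1\tx\tCDS\t10\t29\t.\t+\t0\tParent=tA"), f)
  an <- read_annotation(f)
  expect_equal(attr(an, "incomplete_cds_transcripts"), "tA")
})

test_that("BED12 annotation derives exon/CDS/UTR structure", {
  # one + transcript: chrom 0-start 0, end 100, thick [20,80), two blocks
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("c1", 0, 100, "tx1", 0, "+", 20, 80, 0, 2,
                     "40,40,", "0,60,"), collapse = "\t"), f)
  an <- read_annotation(f)
  ex <- an[an$feature == "exon", ]
  expect_equal(ex$start, c(1L, 61L))
  expect_equal(ex$end, c(40L, 100L))
  cds <- an[an$feature == "CDS", ]
  expect_equal(cds$start, c(21L, 61L))
  expect_equal(cds$end, c(40L, 80L))
  expect_setequal(an$feature[an$start == 1L & an$end == 20L][1], "five_prime_UTR")
})

test_that("catalog writer rounds rates to one decimal", {
  cat2 <- data.table::data.table(
    contig = "c1", pos = 1:2, strand = "+", type = "AG",
    coverage = c(100L, 50L), variant = c(7L, 3L),
    rate = c(7.0412, 6.6666))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat2, f)
  back <- read_catalog(f)
  expect_equal(back$rate, c(7.0, 6.7))
})

test_that("SAM and FASTQ writers produce readable files", {
  rec <- data.table::data.table(qname = "r1", flag = 0L, contig = "c1",
                                pos = 3L, mapq = 60L, cigar = "4M",
                                seq = "ACGT")
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(rec, c(c1 = 50L), f)
  lines <- readLines(f)
  expect_true(any(grepl("^@SQ\tSN:c1\tLN:50$", lines)))
  expect_true(any(grepl("^r1\t0\tc1\t3\t60\t4M", lines)))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(c(a = "ACGT", b = "GGTT"), fq)
  back <- read_fastq(fq)
  expect_equal(back, c(a = "ACGT", b = "GGTT"))
})
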
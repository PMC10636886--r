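# Read-level site states, isoform rates, splice distances, co-editing.

test_that("site calls handle splices, quality gating and uncovered sites", {
  g <- Biostrings::DNAStringSet(c(chrT = paste(rep("ACGTA", 12),
                                               collapse = "")))
  ex <- paste0(genome_seq(g, "chrT", 1, 20), genome_seq(g, "chrT", 41, 60))
  ed <- ex
  substr(ed, 5, 5) <- "G"     # genomic pos 5
  substr(ed, 25, 25) <- "G"   # genomic pos 45 (exon 2 offset 5)
  qual_hi <- paste(rep("I", 40), collapse = "")
  qual_low5 <- qual_hi; substr(qual_low5, 5, 5) <- "#"
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrT\tLN:60",
    sprintf("r1\t0\tchrT\t1\t60\t20M20N20M\t*\t0\t0\t%s\t%s", ed, qual_hi),
    sprintf("r2\t0\tchrT\t1\t60\t20M20N20M\t*\t0\t0\t%s\t%s", ex, qual_low5),
    sprintf("r3\t0\tchrT\t41\t60\t20M\t*\t0\t0\t%s\t%s",
            genome_seq(g, "chrT", 41, 60), paste(rep("I", 20), collapse = ""))),
    f)
  sites <- data.table::data.table(contig = "chrT", pos = c(5L, 30L, 45L),
                                  strand = "+", type = "AG")
  iso <- data.table::data.table(read_id = c("r1", "r2", "r3"),
                                isoform = c("spliced", "spliced", "partial"))
  calls <- site_calls_from_sam(f, sites, iso)
  gs <- function(r, p) calls$state[calls$read_id == r & calls$pos == p]
  expect_equal(gs("r1", 5L), "edited")
  expect_equal(gs("r1", 30L), "uncovered")   # inside the N gap
  expect_equal(gs("r1", 45L), "edited")
  expect_equal(gs("r2", 5L), "uncovered")    # base below quality threshold
  expect_equal(gs("r2", 45L), "unedited")
  expect_equal(gs("r3", 5L), "uncovered")    # read starts downstream
  expect_equal(gs("r3", 45L), "unedited")
})

test_that("isoform rates respect the minimum read count", {
  calls <- data.table::data.table(
    read_id = sprintf("r%02d", 1:15), isoform = c(rep("u", 12), rep("s", 3)),
    contig = "c1", pos = 10L, strand = "+", type = "AG",
    state = c(rep("edited", 6), rep("unedited", 6), rep("edited", 3)))
  r <- isoform_site_rates(calls, min_reads = 10L)
  expect_equal(nrow(r), 1L)            # spliced isoform has only 3 reads
  expect_equal(r$isoform, "u")
  expect_equal(r$rate, 50)
})

test_that("splice distances use the nearest annotated boundary", {
  genes <- data.table::data.table(
    gene = "g1", transcript = "t1", contig = "c1", strand = "+",
    feature = "exon", start = c(1L, 101L), end = c(50L, 200L))
  rates <- data.table::data.table(
    contig = "c1", pos = rep(c(104L, 180L), each = 2L), strand = "+",
    type = "AG", isoform = rep(c("spliced", "unspliced"), 2L),
    n = 50L, g = c(40L, 2L, 5L, 4L), rate = c(80, 4, 10, 8))
  sd <- splice_distance_table(rates, genes)
  expect_equal(nrow(sd), 2L)
  # boundaries at 50 (exon1 end) and 101 (exon2 start)
  expect_equal(sd$distance[sd$pos == 104L], 3L)
  expect_equal(sd$distance[sd$pos == 180L], 79L)
  expect_equal(sd$delta_rate[sd$pos == 104L], 76)
})

test_that("co-editing contingency and chi-square match the closed form", {
  st <- function(rid, pos, state) data.table::data.table(
    read_id = rid, isoform = "i", contig = "c1", pos = pos, strand = "+",
    type = "AG", state = state)
  reads <- sprintf("r%02d", 1:60)
  calls <- rbind(
    st(reads, 100L, c(rep("edited", 30), rep("unedited", 30))),
    st(reads, 200L, c(rep("edited", 30), rep("unedited", 30))))
  tab <- coedit_contingency(calls, "c1:100", "c1:200")
  expect_equal(unname(tab[1, 1]), 30L)
  expect_equal(unname(tab[2, 2]), 30L)
  expect_equal(unname(tab[1, 2] + tab[2, 1]), 0L)
  assoc <- coedit_association(tab)
  expect_true(assoc$defined)
  expect_equal(assoc$chisq, 60)
  expect_true(assoc$significant)
  # uncovered reads are excluded from the table
  calls2 <- rbind(calls, st("r99", 100L, "edited"),
                  st("r99", 200L, "uncovered"))
  tab2 <- coedit_contingency(calls2, "c1:100", "c1:200")
  expect_equal(sum(tab2), 60L)
})

test_that("association is undefined for degenerate or small tables", {
  small <- matrix(c(3L, 1L, 1L, 3L), 2L)
  expect_false(coedit_association(small)$defined)
  zero_marg <- matrix(c(30L, 0L, 30L, 0L), 2L)
  expect_false(coedit_association(zero_marg)$defined)
})

test_that("worked archetype profiles classify to their groups", {
  # nearest-archetype path (< 4 genes)
  t1 <- data.table::data.table(gene = c("x", "y"),
                               n_both = c(80L, 30L), n_only1 = c(5L, 2L),
                               n_only2 = c(5L, 2L), n_neither = c(10L, 66L))
  cls <- classify_coedit_groups(t1)
  expect_equal(cls$group[cls$gene == "x"], 1L)
  expect_equal(cls$group[cls$gene == "y"], 2L)
  # lead-site orientation decides group 3 vs 4
  t2 <- data.table::data.table(gene = c("u", "v"),
                               n_both = c(40L, 40L), n_only1 = c(18L, 2L),
                               n_only2 = c(2L, 18L), n_neither = c(40L, 40L))
  cls2 <- classify_coedit_groups(t2)
  expect_equal(cls2$group[cls2$gene == "u"], 3L)
  expect_equal(cls2$group[cls2$gene == "v"], 4L)
  expect_equal(cls2$lead_site, c("s1", "s2"))
})

test_that("simulated archetype tables are recovered by clustering", {
  ct <- simulate_coedit_tables(sim_config(seed = 5L), n_per_group = 4L)
  cls <- classify_coedit_groups(ct)
  m <- match(cls$gene, ct$gene)
  expect_gte(mean(cls$group == ct$group_true[m]), 0.9)
})

test_that("long-read simulation shows splice-coupled editing and dependence", {
  sc <- small_scenario()
  lr <- simulate_long_reads(sc$sim, sc$cfg)
  rates <- isoform_site_rates(lr$calls, min_reads = 5L)
  junc <- lr$sites[lr$sites$role == "junction", ]
  for (i in seq_len(nrow(junc))) {
    r <- rates[rates$pos == junc$pos[i], ]
    ru <- r$rate[r$isoform == "unspliced"]
    rs <- r$rate[r$isoform == "spliced"]
    if (length(rs) == 0L) rs <- 0       # spliced arm can fall under min_reads
    expect_gt(ru, rs)
    # unspliced-spliced difference tracks the overall editing rate
    expect_lt(abs((ru - rs) - 100 * sc$cfg$longread$p_edit), 15)
  }
  # the planted site pair is strongly associated
  g1 <- lr$sites$gene[1]
  s <- lr$sites[lr$sites$gene == g1, ]
  tab <- coedit_contingency(lr$calls[lr$calls$gene == g1, ],
                            paste0(s$contig[1], ":", s$pos[1]),
                            paste0(s$contig[2], ":", s$pos[2]))
  assoc <- coedit_association(tab)
  expect_true(assoc$defined)
  expect_true(assoc$significant)
})
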
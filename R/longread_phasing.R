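# Long-read analyses: per-read editing states at catalog sites,
# per-isoform editing rates, the editing-to-splice-junction distance
# relation, and two-site co-editing contingency, association and
# 4-group classification.

#' Extract per-read editing states at sites from long-read alignments
#'
#' For every read and every site within its aligned span, records the
#' state `edited` (variant base called with sufficient base quality),
#' `unedited` (reference base), or `uncovered` (deleted, skipped, other
#' base, or low quality). Site strand is honored: a `-`-strand A-to-G
#' site is checked against the complementary genomic bases.
#'
#' @param path SAM/BAM file of long reads.
#' @param sites Site table (`contig`, `pos`, `strand`, `type`).
#' @param isoforms Table assigning reads to isoforms (`read_id`,
#'   `isoform`); reads without an assignment are dropped.
#' @param min_baseq Minimum base quality for a defined state.
#' @param min_mapq Minimum mapping quality.
#' @return `data.table` with `read_id`, `isoform`, `contig`, `pos`,
#'   `strand`, `type`, `state`.
#' @export
site_calls_from_sam <- function(path, sites, isoforms, min_baseq = 30L,
                                min_mapq = 30L) {
  sites <- as.data.table(sites)
  iso <- as.data.table(isoforms)
  assert_cols(iso, c("read_id", "isoform"), "isoform assignment table")
  bam <- .as_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  al <- Rsamtools::scanBam(bam, param = p)[[1]]
  empty <- data.table(read_id = character(), isoform = character(),
                      contig = character(), pos = integer(),
                      strand = character(), type = character(),
                      state = character())
  if (length(al$pos) == 0L) return(empty)
  keep <- !is.na(al$pos) & al$mapq >= min_mapq & al$qname %in% iso$read_id
  if (!any(keep)) return(empty)
  qname <- al$qname[keep]; rname <- as.character(al$rname)[keep]
  pos <- al$pos[keep]; cigar <- al$cigar[keep]
  seqs <- al$seq[keep]; quals <- al$qual[keep]

  ops <- c("M", "=", "X")
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos,
                                                            ops = ops)
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = ops)
  nseg <- S4Vectors::elementNROWS(refR)
  rid_seg <- rep(seq_along(cigar), nseg)
  w <- unlist(IRanges::width(refR), use.names = FALSE)
  rid <- rep(rid_seg, w)
  refpos <- rep(unlist(IRanges::start(refR), use.names = FALSE), w) +
    sequence(w) - 1L
  qpos <- rep(unlist(IRanges::start(qryR), use.names = FALSE), w) +
    sequence(w) - 1L

  seq_chr <- paste(as.character(seqs), collapse = "")
  offs <- cumsum(Biostrings::width(seqs)) - Biostrings::width(seqs)
  gidx <- offs[rid] + qpos
  base <- substring(seq_chr, gidx, gidx)
  qint <- unlist(methods::as(quals, "IntegerList"), use.names = FALSE)[gidx]

  aligned <- data.table(read_id = qname[rid], contig = rname[rid],
                        pos = refpos, base = base, bq = qint)
  gsite <- data.table::copy(sites)
  gsite[, g_ref := ifelse(strand == "-", comp_base(substring(type, 1, 1)),
                          substring(type, 1, 1))]
  gsite[, g_var := ifelse(strand == "-", comp_base(substring(type, 2, 2)),
                          substring(type, 2, 2))]
  # every (read, same-contig site) pair gets a row; sites the read does
  # not align across (splice gaps, reads starting downstream) stay
  # "uncovered", as do low-quality and third-allele bases
  rd <- unique(data.table(read_id = qname, contig = rname))
  combos <- gsite[rd, on = "contig", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(combos) == 0L) return(empty)
  m <- aligned[gsite, on = c("contig", "pos"), nomatch = NULL]
  m[, state := ifelse(bq < min_baseq, "uncovered",
                      ifelse(base == g_var, "edited",
                             ifelse(base == g_ref, "unedited", "uncovered")))]
  out <- m[, .(read_id, contig, pos, state)][
    combos, on = c("read_id", "contig", "pos")]
  out[is.na(state), state := "uncovered"]
  out <- iso[out, on = "read_id", nomatch = NULL][
    , .(read_id, isoform, contig, pos, strand, type, state)]
  data.table::setorder(out, contig, pos, read_id)
  out[]
}

#' Per-isoform editing rates
#'
#' For each (site, isoform): `n` reads with a defined state, `g` edited
#' reads, and the rate `100 * g / n`. Isoforms with fewer than
#' `min_reads` informative reads at the site are omitted.
#'
#' @param calls Per-read state table from [site_calls_from_sam()] (or
#'   the simulator).
#' @param min_reads Minimum informative reads per (site, isoform).
#' @return `data.table` with `contig`, `pos`, `strand`, `type`,
#'   `isoform`, `n`, `g`, `rate`.
#' @export
isoform_site_rates <- function(calls, min_reads = 10L) {
  calls <- as.data.table(calls)
  def <- calls[state %in% c("edited", "unedited")]
  if (nrow(def) == 0L)
    return(data.table(contig = character(), pos = integer(),
                      strand = character(), type = character(),
                      isoform = character(), n = integer(), g = integer(),
                      rate = numeric()))
  r <- def[, .(n = .N, g = sum(state == "edited")),
           by = .(contig, pos, strand, type, isoform)]
  r <- r[n >= min_reads]
  r[, rate := 100 * g / n]
  data.table::setorder(r, contig, pos, isoform)
  r[]
}

#' Splice-junction boundary positions of each gene
#'
#' The last exonic base before and the first exonic base after every
#' intron, in genomic coordinates, per gene (union over transcripts).
#'
#' @param genes Gene-model table.
#' @return `data.table` with `gene`, `contig`, `boundary`.
#' @keywords internal
splice_boundaries <- function(genes) {
  genes <- as.data.table(genes)
  ex <- genes[feature == "exon"][order(transcript, start)]
  b <- ex[, {
    if (.N >= 2L) {
      .(boundary = c(end[-.N], start[-1L]), contig = contig[1])
    } else NULL
  }, by = .(gene, transcript)]
  if (nrow(b) == 0L)
    return(data.table(gene = character(), contig = character(),
                      boundary = integer()))
  unique(b[, .(gene, contig, boundary)])
}

#' Isoform editing-rate differences versus splice-junction distance
#'
#' For each site quantified in at least two isoforms, emits one row per
#' isoform pair with the absolute difference in editing rate and the
#' distance of the site to the gene's nearest splice-junction boundary.
#' Sites with larger between-isoform differences sitting closer to
#' junctions indicate editing that promotes or suppresses splicing.
#'
#' @param rates Output of [isoform_site_rates()].
#' @param genes Gene-model table.
#' @return `data.table` with site key columns, `isoform1`, `isoform2`,
#'   `delta_rate`, `gene`, `distance`.
#' @export
splice_distance_table <- function(rates, genes) {
  rates <- as.data.table(rates)
  empty <- data.table(contig = character(), pos = integer(),
                      strand = character(), type = character(),
                      isoform1 = character(), isoform2 = character(),
                      delta_rate = numeric(), gene = character(),
                      distance = integer())
  if (nrow(rates) == 0L) return(empty)
  ann <- annotate_location(unique(rates[, .(contig, pos, strand, type)]),
                           genes)
  bnd <- splice_boundaries(genes)
  rows <- rates[, {
    if (.N >= 2L) {
      pr <- utils::combn(seq_len(.N), 2L)
      .(isoform1 = isoform[pr[1, ]], isoform2 = isoform[pr[2, ]],
        delta_rate = abs(rate[pr[1, ]] - rate[pr[2, ]]))
    } else NULL
  }, by = .(contig, pos, strand, type)]
  if (nrow(rows) == 0L) return(empty)
  rows <- ann[, .(contig, pos, strand, type, gene)][
    rows, on = c("contig", "pos", "strand", "type")]
  dist <- vapply(seq_len(nrow(rows)), function(i) {
    g <- rows$gene[i]
    bb <- bnd[gene == g & contig == rows$contig[i], boundary]
    if (length(bb) == 0L) NA_integer_
    else as.integer(min(abs(rows$pos[i] - bb)))
  }, integer(1))
  rows[, distance := dist]
  rows[]
}

#' Two-site co-editing contingency table
#'
#' Tallies reads with defined states at both sites into a 2x2 table:
#' both edited, only the first, only the second, neither.
#'
#' @param calls Per-read state table.
#' @param s1,s2 Site keys as `"contig:pos"` strings, or 1-row site
#'   tables.
#' @return A 2x2 integer matrix (rows: site 1 edited/unedited; columns:
#'   site 2).
#' @export
coedit_contingency <- function(calls, s1, s2) {
  calls <- as.data.table(calls)
  keyof <- function(s) {
    if (is.character(s)) s else paste(s$contig, s$pos, sep = ":")
  }
  calls[, .key := paste(contig, pos, sep = ":")]
  a <- calls[.key == keyof(s1) & state %in% c("edited", "unedited")]
  b <- calls[.key == keyof(s2) & state %in% c("edited", "unedited")]
  calls[, .key := NULL]
  m <- merge(a[, .(read_id, state1 = state)], b[, .(read_id, state2 = state)],
             by = "read_id")
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(s1 = c("edited", "unedited"),
                                s2 = c("edited", "unedited")))
  if (nrow(m)) {
    t0 <- table(factor(m$state1, c("edited", "unedited")),
                factor(m$state2, c("edited", "unedited")))
    tab[] <- as.integer(t0)
  }
  tab
}

#' Chi-squared association between two sites' editing states
#'
#' Pearson's chi-squared test without continuity correction on the 2x2
#' co-editing table; association is called significant at `p < 0.01`.
#' Tables with a zero row or column marginal have no defined
#' association.
#'
#' @param tab A 2x2 contingency matrix (see [coedit_contingency()]).
#' @param min_total Minimum dual-covering reads for the test.
#' @param alpha Significance threshold.
#' @param yates Apply the continuity correction.
#' @return A list with `chisq`, `p`, `significant`, `defined`, `n`.
#' @export
coedit_association <- function(tab, min_total = 10L, alpha = 0.01,
                               yates = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  n <- sum(tab)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L) || n < min_total)
    return(list(chisq = NA_real_, p = NA_real_, significant = FALSE,
                defined = FALSE, n = n))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chisq = unname(ct$statistic), p = unname(ct$p.value),
       significant = unname(ct$p.value) < alpha, defined = TRUE, n = n)
}

# Archetype centroids in the oriented proportion space
# (both, only-lead, only-other, neither).
.coedit_archetypes <- function() {
  rbind(g1 = c(0.75, 0.10, 0.02, 0.13),   # both sites highly edited
        g2 = c(0.40, 0.02, 0.02, 0.56),   # edited together or not at all
        g34 = c(0.40, 0.18, 0.02, 0.40))  # one site leads
}

#' Classify co-edited gene pairs into four groups
#'
#' Each gene is represented by its normalized co-editing 4-vector
#' (proportions of both / only site 1 / only site 2 / neither), with the
#' more-edited site relabeled as site 1 for symmetry (the physical lead
#' site is reported alongside). With four or more genes, average-linkage
#' hierarchical clustering on Euclidean distances is cut at four
#' clusters; clusters are labeled 1-4 by descending mean "both"
#' proportion, with the cluster closest to the
#' together-or-not-at-all archetype (high both + neither, low singles)
#' labeled 2. With fewer genes each is assigned its nearest archetype
#' (the one-site-leads archetype resolving to group 3 or 4 by which
#' physical site leads).
#'
#' @param tables `data.table` with columns `gene`, `n_both`, `n_only1`,
#'   `n_only2`, `n_neither` (one row per significant gene).
#' @return `tables` with `p_both`, `p_only_lead`, `p_only_other`,
#'   `p_neither`, `lead_site` (`s1`/`s2`) and `group` (1-4) columns.
#' @export
classify_coedit_groups <- function(tables) {
  dt <- data.table::copy(as.data.table(tables))
  assert_cols(dt, c("gene", "n_both", "n_only1", "n_only2", "n_neither"),
              "co-editing table")
  tot <- dt$n_both + dt$n_only1 + dt$n_only2 + dt$n_neither
  m1 <- (dt$n_both + dt$n_only1) / tot
  m2 <- (dt$n_both + dt$n_only2) / tot
  lead <- ifelse(m2 > m1, "s2", "s1")
  only_lead <- ifelse(lead == "s1", dt$n_only1, dt$n_only2)
  only_other <- ifelse(lead == "s1", dt$n_only2, dt$n_only1)
  P <- cbind(dt$n_both, only_lead, only_other, dt$n_neither) / tot
  dt[, `:=`(p_both = P[, 1], p_only_lead = P[, 2], p_only_other = P[, 3],
            p_neither = P[, 4], lead_site = lead)]
  arch <- .coedit_archetypes()
  nearest <- apply(P, 1L, function(v) {
    which.min(colSums((t(arch) - v)^2))
  })
  if (nrow(dt) >= 4L) {
    # cluster the raw (unoriented) proportions so the two one-site-leads
    # groups, which differ only in WHICH site is edited alone, separate
    dt2 <- dt[order(gene)]
    tot2 <- dt2$n_both + dt2$n_only1 + dt2$n_only2 + dt2$n_neither
    P2 <- cbind(dt2$n_both, dt2$n_only1, dt2$n_only2, dt2$n_neither) / tot2
    cl <- cutree(hclust(dist(P2), method = "average"), k = 4L)
    cent <- vapply(1:4, function(g) colMeans(P2[cl == g, , drop = FALSE]),
                   numeric(4))
    lab <- integer(4L)
    c2 <- which.min(colSums((cent - arch["g2", ])^2))  # together-or-not-at-all
    lab[c2] <- 2L
    rest <- setdiff(1:4, c2)
    c1 <- rest[which.max(cent[1, rest])]               # highest "both"
    lab[c1] <- 1L
    rest <- setdiff(rest, c1)
    c3 <- rest[which.max(cent[2, rest] - cent[3, rest])]  # site 1 leads
    lab[c3] <- 3L
    lab[setdiff(rest, c3)] <- 4L
    dt2[, group := lab[cl]]
    dt <- dt2[dt[, .(gene)], on = "gene"]
  } else {
    grp <- c(1L, 2L, 3L)[nearest]
    grp[grp == 3L & dt$lead_site == "s2"] <- 4L
    dt[, group := grp]
  }
  dt[]
}
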
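# Candidate-site discovery: quality-filtered pileups from aligned reads,
# thresholded mismatch calling, sample pooling, and the 12-type mismatch
# spectrum with its false-discovery estimate.

#' Pileup configuration
#'
#' @param min_mapq Minimum read mapping quality (default 30).
#' @param min_baseq Minimum base quality (default 30).
#' @param strandedness Library strandedness code: 0 unstranded, 1
#'   second-strand, 2 first-strand.
#' @return A `pileup_config` list.
#' @export
pileup_config <- function(min_mapq = 30L, min_baseq = 30L, strandedness = 0L) {
  if (min_mapq < 0 || min_baseq < 0) stopf("quality thresholds must be >= 0")
  if (!strandedness %in% 0:2) stopf("strandedness must be 0, 1 or 2")
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 strandedness = as.integer(strandedness)),
            class = "pileup_config")
}

#' Per-position base counts from aligned reads
#'
#' Walks the CIGAR of every alignment in a SAM/BAM file and tallies
#' quality-filtered base calls per reference position. Deletions and
#' intron skips contribute nothing; `N` calls are excluded from both
#' numerator and denominator. Bases shared by overlapping mates of a pair
#' are counted once per fragment (the higher-base-quality mate wins). For
#' stranded libraries the counts are assigned to the transcribed strand
#' and the reference base is complemented on `-`, so a genomic T>C event
#' on `-` is recorded as an A>G mismatch; unstranded data is reported on
#' the genomic `+` strand.
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly).
#' @param genome A `DNAStringSet` covering every contig the reads map to.
#' @param cfg A [pileup_config()].
#' @return A position-counts `data.table` (`contig`, `pos`, `strand`,
#'   `ref`, `nA`, `nC`, `nG`, `nT`, `total`).
#' @export
pileup_counts <- function(path, genome, cfg = pileup_config()) {
  bam <- .as_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  al <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(al$pos) == 0L) return(empty_counts())

  used <- unique(as.character(al$rname[!is.na(al$pos)]))
  unknown <- setdiff(used, names(genome))
  if (length(unknown))
    stopf("alignments reference contig(s) absent from genome: %s",
          paste(unknown, collapse = ", "))

  keep <- !is.na(al$pos) & al$mapq >= cfg$min_mapq
  if (!any(keep)) return(empty_counts())
  qname <- al$qname[keep]; flag <- al$flag[keep]
  rname <- as.character(al$rname)[keep]; pos <- al$pos[keep]
  cigar <- al$cigar[keep]; seqs <- al$seq[keep]; quals <- al$qual[keep]

  ops <- c("M", "=", "X")
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos,
                                                            ops = ops)
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = ops)
  nseg <- S4Vectors::elementNROWS(refR)
  rid_seg <- rep(seq_along(cigar), nseg)
  rs <- unlist(IRanges::start(refR), use.names = FALSE)
  qs <- unlist(IRanges::start(qryR), use.names = FALSE)
  w <- unlist(IRanges::width(refR), use.names = FALSE)

  rid <- rep(rid_seg, w)
  refpos <- rep(rs, w) + sequence(w) - 1L
  qpos <- rep(qs, w) + sequence(w) - 1L

  seq_chr <- paste(as.character(seqs), collapse = "")
  offs <- cumsum(Biostrings::width(seqs)) - Biostrings::width(seqs)
  gidx <- offs[rid] + qpos
  base <- substring(seq_chr, gidx, gidx)
  qint <- unlist(methods::as(quals, "IntegerList"), use.names = FALSE)[gidx]

  ok <- base %in% BASES & qint >= cfg$min_baseq
  dt <- data.table(qname = qname[rid[ok]], flag = flag[rid[ok]],
                   contig = rname[rid[ok]], pos = refpos[ok],
                   base = base[ok], qual = qint[ok])

  # one count per fragment at positions covered by both mates
  data.table::setorder(dt, -qual)
  dt <- unique(dt, by = c("qname", "contig", "pos"))

  # strand assignment
  aln_minus <- bitwAnd(dt$flag, 16L) > 0L
  if (cfg$strandedness == 0L) {
    dt[, strand := "+"]
  } else {
    is_read2 <- bitwAnd(dt$flag, 128L) > 0L
    tx_minus <- xor(aln_minus, cfg$strandedness == 2L)
    tx_minus <- xor(tx_minus, is_read2)
    dt[, strand := ifelse(tx_minus, "-", "+")]
    flip <- dt$strand == "-"
    dt[flip, base := comp_base(base)]
  }

  cnt <- dt[, .N, by = .(contig, pos, strand, base)]
  wide <- data.table::dcast(cnt, contig + pos + strand ~ base,
                            value.var = "N", fill = 0L)
  for (b in BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  data.table::setnames(wide, BASES, paste0("n", BASES))
  wide[, ref := genome_base(genome, contig, pos)]
  wide[strand == "-", ref := comp_base(ref)]
  wide[, total := nA + nC + nG + nT]
  data.table::setcolorder(wide, c("contig", "pos", "strand", "ref",
                                  "nA", "nC", "nG", "nT", "total"))
  data.table::setorder(wide, contig, pos, strand)
  wide[]
}

.as_bam <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE, format = "sam")
}

#' Call candidate variant sites from position counts
#'
#' Emits one candidate per (position, non-reference base) meeting a
#' minimum total coverage, minimum variant-read count, and minimum
#' mismatch rate (in percent, `100 * v / N`). Defaults are total coverage
#' >= 10, variant reads >= 3 and rate >= 1%.
#'
#' @param counts A position-counts table.
#' @param min_total Minimum total coverage N.
#' @param min_variant Minimum variant reads v.
#' @param min_rate_pct Minimum editing rate in percent.
#' @param study,sample,pipeline Provenance labels stored on each
#'   candidate.
#' @return A candidate-site `data.table` (`contig`, `pos`, `strand`,
#'   `type`, `coverage`, `variant`, `rate`, `study`, `sample`,
#'   `pipeline`).
#' @export
call_candidates <- function(counts, min_total = 10L, min_variant = 3L,
                            min_rate_pct = 1.0, study = NA_character_,
                            sample = NA_character_, pipeline = "separate") {
  counts <- as_counts_dt(counts)
  if (nrow(counts) == 0L) return(empty_sites())
  long <- data.table::melt(counts,
                           id.vars = c("contig", "pos", "strand", "ref", "total"),
                           measure.vars = paste0("n", BASES),
                           variable.name = "base_col", value.name = "variant",
                           variable.factor = FALSE)
  long[, base := substring(base_col, 2L, 2L)]
  hits <- long[base != ref & total >= min_total & variant >= min_variant &
                 100 * variant / total >= min_rate_pct]
  if (nrow(hits) == 0L) return(empty_sites())
  out <- hits[, .(contig, pos = as.integer(pos), strand,
                  type = paste0(ref, base), coverage = as.integer(total),
                  variant = as.integer(variant),
                  rate = 100 * variant / total,
                  study = study, sample = sample, pipeline = pipeline)]
  data.table::setorder(out, contig, pos, strand, type)
  out[]
}

#' Pool position counts across samples
#'
#' Element-wise sum of base counts over a list of position-count tables,
#' keyed by (contig, position, strand). Positions present in any input
#' appear in the output; a reference-base conflict at a shared position is
#' an error.
#'
#' @param tables A list of position-counts tables (or a single table).
#' @return A pooled position-counts `data.table`.
#' @export
pool_samples <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- lapply(tables, as_counts_dt)
  all <- data.table::rbindlist(tables, use.names = TRUE)
  if (nrow(all) == 0L) return(empty_counts())
  conf <- all[, .(nref = data.table::uniqueN(ref)), by = .(contig, pos, strand)]
  if (any(conf$nref > 1L)) {
    bad <- conf[nref > 1L][1]
    stopf("conflicting reference base at %s:%d (%s)", bad$contig, bad$pos,
          bad$strand)
  }
  out <- all[, .(nA = sum(nA), nC = sum(nC), nG = sum(nG), nT = sum(nT)),
             by = .(contig, pos, strand, ref)]
  out[, total := nA + nC + nG + nT]
  data.table::setorder(out, contig, pos, strand)
  out[]
}

#' Mismatch spectrum of a candidate-site set
#'
#' Tallies sites over the 12 ordered reference-to-variant mismatch types
#' and derives per-type percentages and the A-to-G percentage.
#'
#' @param sites A candidate-site table.
#' @return An object of class `mismatch_spectrum` with elements `counts`
#'   (named integer vector over the 12 types), `pct`, `n`, `ag_pct`, and
#'   `empty`.
#' @export
mismatch_spectrum <- function(sites) {
  sites <- as.data.table(sites)
  n <- nrow(sites)
  counts <- if (n) table(factor(sites$type, levels = MISMATCH_TYPES))
            else table(factor(character(), levels = MISMATCH_TYPES))
  counts <- setNames(as.integer(counts), MISMATCH_TYPES)
  pct <- if (n) 100 * counts / n else setNames(rep(NA_real_, 12L), MISMATCH_TYPES)
  structure(list(counts = counts, pct = pct, n = n,
                 ag_pct = unname(pct["AG"]), empty = n == 0L),
            class = "mismatch_spectrum")
}

#' @export
print.mismatch_spectrum <- function(x, ...) {
  if (x$empty) {
    cat("mismatch spectrum: empty (no sites)\n")
  } else {
    cat(sprintf("mismatch spectrum over %d sites\n", x$n))
    print(round(x$pct, 1))
  }
  invisible(x)
}

#' Spectrum-based false-discovery estimate
#'
#' The G-to-A percentage divided by the A-to-G percentage, multiplied by
#' 100 - equivalently `100 * nGA / nAG`. G-to-A mismatches have no known
#' biological source in this setting, so their abundance relative to
#' A-to-G measures the residual artifact rate.
#'
#' @param spec A `mismatch_spectrum`.
#' @return The FDR estimate in percent.
#' @export
estimate_fdr <- function(spec) {
  stopifnot(inherits(spec, "mismatch_spectrum"))
  if (spec$counts["AG"] == 0L)
    stopf("FDR undefined: no A-to-G sites in spectrum")
  unname(100 * spec$counts["GA"] / spec$counts["AG"])
}
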
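# Readers and writers for the external formats the pipeline touches.
# Internal coordinates are 1-based inclusive everywhere; BED half-open and
# chain 0-based conventions are converted here, at the boundary, and nowhere
# else.

#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into a [Biostrings::DNAStringSet],
#' folding sequence to uppercase. Contig names are taken as the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per contig.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stopf("FASTA file '%s' contains no records", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate contig name(s) in '%s': %s", path,
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad))
    stopf("contig(s) with characters outside A/C/G/T/N: %s",
          paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Look up reference bases
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param contig Contig name(s).
#' @param pos 1-based position(s).
#' @return Character vector of single bases.
#' @export
genome_base <- function(genome, contig, pos) {
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n)
  unknown <- !contig %in% names(genome)
  if (any(unknown))
    stopf("unknown contig(s): %s", paste(unique(contig[unknown]), collapse = ", "))
  lens <- Biostrings::width(genome)[match(contig, names(genome))]
  if (any(pos < 1L | pos > lens))
    stopf("position out of range for contig %s",
          paste(unique(contig[pos < 1L | pos > lens]), collapse = ", "))
  out <- character(n)
  for (ct in unique(contig)) {
    i <- contig == ct
    out[i] <- as.character(Biostrings::extractAt(
      genome[[ct]], IRanges::IRanges(pos[i], pos[i])))
  }
  out
}

#' Extract a genomic interval as a character string
#' @inheritParams genome_base
#' @param start,end 1-based inclusive bounds.
#' @export
genome_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stopf("unknown contig '%s'", contig)
  len <- Biostrings::width(genome)[match(contig, names(genome))]
  if (start < 1L || end > len || start > end)
    stopf("interval %s:%d-%d out of range (contig length %d)", contig, start, end, len)
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

#' Read a per-position base-count table
#'
#' Parses a tab-delimited table with columns `contig`, `pos`, `strand`,
#' `ref`, `nA`, `nC`, `nG`, `nT` (REDItools-style output is the model).
#' A `total` column is recomputed as the sum of the four base counts.
#'
#' @param path Path to a TSV file; lines starting with `#` are ignored.
#' @return A `data.table` of position counts.
#' @export
read_counts_table <- function(path) {
  dt <- suppressWarnings(
    data.table::fread(path, sep = "\t", header = TRUE, skip = "contig"))
  if (nrow(dt) == 0L) return(empty_counts())
  assert_cols(dt, c("contig", "pos", "strand", "ref", "nA", "nC", "nG", "nT"),
              sprintf("counts table '%s'", path))
  for (cc in c("nA", "nC", "nG", "nT"))
    if (any(dt[[cc]] < 0)) stopf("negative count in column %s of '%s'", cc, path)
  if (!all(dt$strand %in% c("+", "-", "*")))
    stopf("unknown strand code in '%s' (expect '+', '-' or '*')", path)
  if (!all(dt$ref %in% BASES))
    stopf("reference base outside A/C/G/T in '%s'", path)
  dt[, pos := as.integer(pos)]
  dt[, total := nA + nC + nG + nT]
  dt[]
}

#' Write a per-position base-count table
#' @param counts A position-counts table.
#' @param path Output TSV path.
#' @export
write_counts_table <- function(counts, path) {
  counts <- as_counts_dt(counts)
  data.table::fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' Read genomic variants from VCF
#'
#' Extracts CHROM/POS/REF/ALT/QUAL and depth (INFO `DP`) from a VCF 4.x
#' file. A missing QUAL (`.`) is parsed as 0 so that downstream
#' quality-threshold filters treat such records conservatively (the record
#' does not pass); a missing DP is parsed as 0 for the same reason.
#'
#' @param path Path to a VCF file.
#' @return `data.table` with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual`, `depth`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.table(contig = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), depth = integer()))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  dp[is.na(dp)] <- 0L
  data.table(contig = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, qual = qual, depth = dp)
}

#' Read repeat annotations from BED
#'
#' BED 0-based half-open intervals are converted to 1-based inclusive.
#' The BED name field carries the repeat family label.
#'
#' @param path Path to a BED file (>= 4 columns).
#' @return `data.table` with columns `contig`, `start`, `end`, `family`,
#'   `strand`.
#' @export
read_repeats <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  fam <- if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name)
         else rep(NA_character_, length(gr))
  if (any(is.na(fam) | fam == ""))
    stopf("repeat BED '%s' has records without a family label", path)
  data.table(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             family = fam,
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Read gene models from GFF3/GTF or BED12
#'
#' Produces the package's flat gene-model table: one row per feature
#' interval with columns `gene`, `transcript`, `contig`, `strand`,
#' `feature` (one of `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`)
#' and 1-based inclusive `start`/`end`. Gene symbols are taken from the
#' `gene` attribute, else `Name`, else the ID. Transcripts whose total CDS
#' length is not divisible by 3 are flagged (attribute
#' `incomplete_cds_transcripts`), not rejected.
#'
#' @param path Path to a GFF3/GTF or BED12 file.
#' @return `data.table` of feature intervals.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gm <- if (ext %in% c("bed", "bed12")) .annotation_from_bed12(path)
        else .annotation_from_gff(path)
  gm <- gm[order(contig, gene, transcript, start)]
  cds_len <- gm[feature == "CDS", .(len = sum(end - start + 1L)), by = transcript]
  bad <- cds_len[len %% 3L != 0L, transcript]
  data.table::setattr(gm, "incomplete_cds_transcripts", bad)
  gm[]
}

.annotation_from_gff <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR",
                      "5UTR", "3UTR", "UTR")
  feat <- gr[keep]
  fmd <- S4Vectors::mcols(feat)
  ftype <- as.character(fmd$type)
  ftype[ftype == "5UTR"] <- "five_prime_UTR"
  ftype[ftype == "3UTR"] <- "three_prime_UTR"

  # transcript id: GFF3 Parent, or GTF transcript_id
  tx <- if ("transcript_id" %in% names(fmd)) as.character(fmd$transcript_id)
        else vapply(fmd$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  if (anyNA(tx)) stopf("annotation '%s': feature without transcript parent", path)

  # map transcript -> gene id through mRNA/transcript records when present
  tx_rec <- gr[type %in% c("mRNA", "transcript")]
  tmd <- S4Vectors::mcols(tx_rec)
  tx_ids <- as.character(tmd$ID %||% tmd$transcript_id)
  tx_parent <- if ("Parent" %in% names(tmd))
    vapply(tmd$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  else as.character(tmd$gene_id %||% tx_ids)
  tx2gene <- setNames(tx_parent, tx_ids)

  gene_rec <- gr[type == "gene"]
  gmd <- S4Vectors::mcols(gene_rec)
  gene_ids <- as.character(gmd$ID %||% gmd$gene_id)
  sym <- rep(NA_character_, length(gene_rec))
  for (field in c("gene", "Name")) {
    if (field %in% names(gmd)) {
      val <- as.character(gmd[[field]])
      sym[is.na(sym) & !is.na(val) & val != ""] <-
        val[is.na(sym) & !is.na(val) & val != ""]
    }
  }
  sym[is.na(sym)] <- gene_ids[is.na(sym)]
  gene_sym <- setNames(sym, gene_ids)

  gid <- unname(tx2gene[tx])
  gid[is.na(gid)] <- tx[is.na(gid)]
  symbol <- unname(gene_sym[gid])
  symbol[is.na(symbol)] <- gid[is.na(symbol)]

  data.table(gene = symbol, transcript = tx,
             contig = as.character(GenomicRanges::seqnames(feat)),
             strand = as.character(GenomicRanges::strand(feat)),
             feature = ftype,
             start = GenomicRanges::start(feat),
             end = GenomicRanges::end(feat))
}

.annotation_from_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$blocks)) stopf("BED file '%s' lacks block (BED12) columns", path)
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    tx <- as.character(md$name[i])
    strand <- as.character(GenomicRanges::strand(gr[i]))
    contig <- as.character(GenomicRanges::seqnames(gr[i]))
    ex <- IRanges::shift(md$blocks[[i]], GenomicRanges::start(gr[i]) - 1L)
    exons <- data.table(feature = "exon", start = IRanges::start(ex),
                        end = IRanges::end(ex))
    thick <- md$thick[i]
    rows <- exons
    ts <- IRanges::start(thick); te <- IRanges::end(thick)
    if (IRanges::width(thick) > 0L && te >= ts) {
      cds <- exons[end >= ts & start <= te,
                   .(feature = "CDS", start = pmax(start, ts), end = pmin(end, te))]
      utr_left <- exons[start < ts,
                        .(feature = "UTRL", start = start, end = pmin(end, ts - 1L))]
      utr_left <- utr_left[end >= start]
      utr_right <- exons[end > te,
                         .(feature = "UTRR", start = pmax(start, te + 1L), end = end)]
      utr_right <- utr_right[end >= start]
      utr_left[, feature := if (strand == "-") "three_prime_UTR" else "five_prime_UTR"]
      utr_right[, feature := if (strand == "-") "five_prime_UTR" else "three_prime_UTR"]
      rows <- rbind(exons, cds, utr_left, utr_right)
    }
    rows[, `:=`(gene = tx, transcript = tx, contig = contig, strand = strand)]
    out[[i]] <- rows
  }
  data.table::rbindlist(out, use.names = TRUE)[
    , .(gene, transcript, contig, strand, feature, start, end)]
}

#' Read a UCSC chain file
#'
#' Parses pairwise-alignment chains into a flat block table. Source
#' coordinates (the assembly mapped *from*, the chain's `t` fields) are
#' stored 1-based inclusive on the forward strand; target block starts are
#' kept in strand coordinates as in the file, with the target size
#' retained so '-'-strand blocks can be mapped to forward coordinates.
#'
#' @param path Path to a chain file.
#' @return `data.table` with one row per aligned block: `chain_id`,
#'   `score`, `src_contig`, `src_size`, `src_start`, `src_end`,
#'   `tgt_contig`, `tgt_size`, `tgt_strand`, `tgt_start0` (0-based strand
#'   coordinate of the block start).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  out <- list(); k <- 0L
  i <- 1L
  auto_id <- 0L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12L)
      stopf("chain file '%s': malformed header at line %d", path, i)
    score <- as.numeric(f[2])
    t_name <- f[3]; t_size <- as.integer(f[4]); t_strand <- f[5]
    t_start <- as.integer(f[6]); t_end <- as.integer(f[7])
    q_name <- f[8]; q_size <- as.integer(f[9]); q_strand <- f[10]
    q_start <- as.integer(f[11]); q_end <- as.integer(f[12])
    auto_id <- auto_id + 1L
    id <- if (length(f) >= 13L) f[13] else as.character(auto_id)
    if (t_strand != "+")
      stopf("chain file '%s': source strand must be '+' (line %d)", path, i)
    cur_t <- t_start; cur_q <- q_start
    i <- i + 1L
    repeat {
      if (i > length(lines)) stopf("chain file '%s': truncated chain %s", path, id)
      ln <- lines[i]; i <- i + 1L
      if (ln == "") break
      b <- as.integer(strsplit(ln, "[ \t]+")[[1]])
      size <- b[1]
      if (is.na(size) || size <= 0L)
        stopf("chain file '%s': bad block size at line %d", path, i - 1L)
      k <- k + 1L
      out[[k]] <- data.table(chain_id = id, score = score,
                             src_contig = t_name, src_size = t_size,
                             src_start = cur_t + 1L, src_end = cur_t + size,
                             tgt_contig = q_name, tgt_size = q_size,
                             tgt_strand = q_strand, tgt_start0 = cur_q)
      if (length(b) == 1L) break
      if (length(b) != 3L)
        stopf("chain file '%s': malformed block line at line %d", path, i - 1L)
      cur_t <- cur_t + size + b[2]
      cur_q <- cur_q + size + b[3]
    }
  }
  if (k == 0L) stopf("chain file '%s' contains no chains", path)
  blocks <- data.table::rbindlist(out)
  # blocks must be strictly increasing and non-overlapping in source coords
  chk <- blocks[, .(ok = all(diff(src_start) > 0) &&
                      all(head(src_end, -1L) < tail(src_start, -1L))),
                by = chain_id]
  if (!all(chk$ok))
    stopf("chain file '%s': overlapping or unordered blocks in chain(s) %s",
          path, paste(chk[ok == FALSE, chain_id], collapse = ", "))
  blocks[]
}

#' Write a chain table back to UCSC chain format
#' @param blocks A block table from [read_chain()] (or built in code).
#' @param path Output path.
#' @export
write_chain <- function(blocks, path) {
  blocks <- as.data.table(blocks)
  con <- file(path, "w"); on.exit(close(con))
  for (id in unique(blocks$chain_id)) {
    b <- blocks[chain_id == id][order(src_start)]
    t_start <- b$src_start[1] - 1L
    t_end <- b$src_end[nrow(b)]
    q_start <- b$tgt_start0[1]
    q_end <- b$tgt_start0[nrow(b)] + (b$src_end[nrow(b)] - b$src_start[nrow(b)] + 1L)
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                       format(b$score[1], scientific = FALSE),
                       b$src_contig[1], b$src_size[1], t_start, t_end,
                       b$tgt_contig[1], b$tgt_size[1], b$tgt_strand[1],
                       q_start, q_end, id), con)
    sizes <- b$src_end - b$src_start + 1L
    if (nrow(b) > 1L) {
      dt <- b$src_start[-1L] - b$src_end[-nrow(b)] - 1L
      dq <- b$tgt_start0[-1L] - (b$tgt_start0[-nrow(b)] + sizes[-nrow(b)])
      writeLines(paste(sizes[-nrow(b)], dt, dq, sep = "\t"), con)
    }
    writeLines(as.character(sizes[nrow(b)]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write an editing catalog to TSV
#'
#' Serializes a catalog (or any site table) to a tab-delimited file.
#' Editing levels and rates (columns named `rate` or starting with
#' `level`) are written with one decimal place; all other fields are
#' written verbatim, so `read_catalog(write_catalog(x))` returns `x` up to
#' that stated rounding.
#'
#' @param catalog A site/catalog `data.table`.
#' @param path Output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  cat2 <- as.data.table(catalog)
  assert_cols(cat2, c("contig", "pos", "strand", "type"), "catalog")
  cat2 <- data.table::copy(cat2)
  num <- names(cat2)[vapply(cat2, is.numeric, logical(1))]
  lvl <- num[num == "rate" | startsWith(num, "level")]
  for (cc in lvl) cat2[[cc]] <- round(cat2[[cc]], 1L)
  data.table::fwrite(cat2, path, sep = "\t")
  invisible(path)
}

#' Read an editing catalog written by [write_catalog()]
#' @param path Path to the TSV file.
#' @return A `data.table`.
#' @export
read_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (nrow(dt)) assert_cols(dt, c("contig", "pos", "strand", "type"),
                            sprintf("catalog '%s'", path))
  dt[]
}

#' Write a genome to FASTA
#' @param genome A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write a gene-model table to GFF3
#' @param genes Gene-model table (see [read_annotation()]).
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  genes <- as.data.table(genes)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  span_g <- genes[, .(start = min(start), end = max(end)),
                  by = .(gene, contig, strand)]
  span_t <- genes[, .(start = min(start), end = max(end)),
                  by = .(gene, transcript, contig, strand)]
  for (i in seq_len(nrow(span_g))) {
    g <- span_g[i]
    writeLines(sprintf("%s\teditome\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s",
                       g$contig, g$start, g$end, g$strand, g$gene, g$gene), con)
    txs <- span_t[gene == g$gene]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j]
      writeLines(sprintf("%s\teditome\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         t$contig, t$start, t$end, t$strand, t$transcript,
                         g$gene), con)
      ft <- genes[transcript == t$transcript][order(start)]
      phase_feats <- sprintf(
        "%s\teditome\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
        ft$contig, ft$feature, ft$start, ft$end, ft$strand,
        ifelse(ft$feature == "CDS", "0", "."), t$transcript)
      writeLines(phase_feats, con)
    }
  }
  invisible(path)
}

#' Write repeat intervals to BED
#' @param repeats Repeat table (`contig`, `start`, `end`, `family`,
#'   optional `strand`).
#' @param path Output path.
#' @export
write_bed <- function(repeats, path) {
  r <- as.data.table(repeats)
  strand <- if ("strand" %in% names(r)) r$strand else "."
  strand[is.na(strand) | strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", r$contig, r$start - 1L, r$end,
                   r$family, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write variants to a minimal VCF
#' @param variants Table with `contig`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`.
#' @param path Output path.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  v <- as.data.table(variants)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">"),
             con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(v)) {
    qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d",
                       v$contig, v$pos, v$ref, v$alt, qual, v$depth), con)
  }
  invisible(path)
}

#' Write alignment records to SAM
#'
#' @param records Table with `qname`, `flag`, `contig`, `pos`, `mapq`,
#'   `cigar`, `seq` (and optionally `qual` strings; a uniform high
#'   quality is filled in when absent).
#' @param contig_lengths Named vector of contig lengths for the header.
#' @param path Output path.
#' @export
write_sam <- function(records, contig_lengths, path) {
  r <- as.data.table(records)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(r)) {
    qual <- if ("qual" %in% names(r)) r$qual
            else vapply(nchar(r$seq), function(n)
              paste(rep("I", n), collapse = ""), character(1))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       r$qname, r$flag, r$contig, r$pos, r$mapq, r$cigar,
                       r$seq, qual), con)
  }
  invisible(path)
}

#' Write reads to FASTQ
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) { writeLines(character(), path); return(invisible(path)) }
  qual <- vapply(nchar(reads), function(n) paste(rep("I", n), collapse = ""),
                 character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", unname(qual)))
  writeLines(lines, path)
  invisible(path)
}
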
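# Hyper-editing detection: reads too densely edited to align normally are
# recovered by transforming one base to another (canonically all A to G) in
# both the unmapped reads and the reference, realigning in the transformed
# space where the edits vanish, restoring the original sequences, and
# calling reads that carry a dense cluster of scheme-type mismatches.

#' The 12 base-transformation schemes
#'
#' @param from,to Single bases; `from != to`.
#' @return A `transform_scheme` list with `from`, `to` and the mismatch
#'   type label (e.g. `"AG"`).
#' @export
transform_scheme <- function(from = "A", to = "G") {
  if (!from %in% BASES || !to %in% BASES || from == to)
    stopf("scheme must be an ordered pair of distinct bases")
  structure(list(from = from, to = to, type = paste0(from, to)),
            class = "transform_scheme")
}

#' All 12 transformation schemes
#' @return A named list of [transform_scheme()] objects.
#' @export
all_schemes <- function() {
  out <- list()
  for (t in MISMATCH_TYPES)
    out[[t]] <- transform_scheme(substring(t, 1, 1), substring(t, 2, 2))
  out
}

#' Transform a nucleotide sequence under a scheme
#'
#' Replaces every occurrence of the scheme's `from` base with its `to`
#' base; length and all other bases are preserved, so the operation is
#' idempotent.
#'
#' @param seq Character vector of nucleotide strings.
#' @param scheme A [transform_scheme()].
#' @return The transformed character vector.
#' @export
transform_sequence <- function(seq, scheme) {
  chartr(scheme$from, scheme$to, seq)
}

#' Hyper-editing call configuration
#'
#' Thresholds for emitting a read as hyper-edited. The defaults (at least
#' 5 scheme-type mismatches covering at least 5% of the read, at most 5%
#' other-type mismatches, unique best alignment, 2 bases excluded at each
#' read end) are this package's own choices in the spirit of dense-cluster
#' detection; they are not prescribed values.
#'
#' @param min_sites Minimum scheme-type mismatches per read.
#' @param min_frac Minimum scheme-type mismatch fraction of read length.
#' @param max_other_frac Maximum other-type mismatch fraction.
#' @param unique_best Drop reads with tied best alignments.
#' @param edge_exclude Bases ignored at each read end.
#' @return A `hyper_config` list.
#' @export
hyper_config <- function(min_sites = 5L, min_frac = 0.05,
                         max_other_frac = 0.05, unique_best = TRUE,
                         edge_exclude = 2L) {
  stopifnot(min_frac >= 0, min_frac <= 1, max_other_frac >= 0,
            max_other_frac <= 1)
  structure(list(min_sites = as.integer(min_sites), min_frac = min_frac,
                 max_other_frac = max_other_frac, unique_best = unique_best,
                 edge_exclude = as.integer(edge_exclude)),
            class = "hyper_config")
}

#' Seed-and-extend alignment of transformed reads
#'
#' The built-in toy aligner: exact k-mer seeds from both read ends are
#' looked up in the (already transformed) genome, candidate loci are
#' verified by ungapped full-length comparison in the transformed space,
#' and the locus with the fewest transformed-space mismatches wins. Both
#' read orientations are tried (the reverse complement is taken before
#' transformation). Reads whose best alignment is tied between loci are
#' dropped when `unique_best` is set. Production users can substitute any
#' aligner that returns the same record layout.
#'
#' @param reads Named character vector of (already transformed) read
#'   sequences when `scheme` is `NULL`, or original reads plus a
#'   [transform_scheme()] to apply internally.
#' @param genome_t Transformed genome as a named character vector or
#'   `DNAStringSet`.
#' @param scheme Optional [transform_scheme()] applied to the reads (and
#'   their reverse complements) before seeding.
#' @param k Seed length.
#' @param max_mismatch_frac Maximum transformed-space mismatch fraction
#'   for a locus to be considered.
#' @param unique_best Drop multi-mapping reads.
#' @return `data.table` with columns `read_id`, `contig`, `start`, `end`,
#'   `orient` (`F`/`R`) and `n_mismatch` (transformed space).
#' @export
align_transformed <- function(reads, genome_t, scheme = NULL, k = 16L,
                              max_mismatch_frac = 0.1, unique_best = TRUE) {
  if (length(reads) == 0L)
    return(data.table(read_id = character(), contig = character(),
                      start = integer(), end = integer(), orient = character(),
                      n_mismatch = integer()))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  gchar <- if (inherits(genome_t, "DNAStringSet")) {
    setNames(as.character(genome_t), names(genome_t))
  } else genome_t
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    hits <- list(); h <- 0L
    for (orient in c("F", "R")) {
      rseq <- if (orient == "F") reads[[i]] else revcomp(reads[[i]])
      if (!is.null(scheme)) rseq <- transform_sequence(rseq, scheme)
      L <- nchar(rseq)
      if (L < k) next
      max_mm <- floor(max_mismatch_frac * L)
      seed_off <- unique(c(1L, L - k + 1L))
      cand <- list()
      for (so in seed_off) {
        seed <- substring(rseq, so, so + k - 1L)
        for (ct in names(gchar)) {
          m <- gregexpr(seed, gchar[[ct]], fixed = TRUE)[[1]]
          if (m[1] == -1L) next
          starts <- as.integer(m) - (so - 1L)
          for (s in starts) {
            if (s < 1L || s + L - 1L > nchar(gchar[[ct]])) next
            cand[[length(cand) + 1L]] <- c(ct, s)
          }
        }
      }
      if (length(cand) == 0L) next
      cand <- unique(cand)
      for (cc in cand) {
        ct <- cc[1]; s <- as.integer(cc[2])
        ref <- substring(gchar[[ct]], s, s + L - 1L)
        mm <- sum(strsplit(ref, "")[[1]] != strsplit(rseq, "")[[1]])
        if (mm <= max_mm) {
          h <- h + 1L
          hits[[h]] <- data.table(read_id = names(reads)[i], contig = ct,
                                  start = s, end = s + L - 1L,
                                  orient = orient, n_mismatch = mm)
        }
      }
    }
    if (h == 0L) next
    ht <- unique(data.table::rbindlist(hits),
                 by = c("contig", "start", "orient"))
    best <- min(ht$n_mismatch)
    ht <- ht[n_mismatch == best]
    if (nrow(ht) > 1L && unique_best) next
    out[[i]] <- ht[1]
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    return(data.table(read_id = character(), contig = character(),
                      start = integer(), end = integer(), orient = character(),
                      n_mismatch = integer()))
  res[]
}

#' Call hyper-edited reads and their sites
#'
#' Restores the original read and reference bases over each aligned span,
#' counts scheme-type and other-type mismatches (excluding the configured
#' edge bases), and emits the read when the scheme-type cluster passes the
#' thresholds. Per-position candidate sites are aggregated over the
#' emitted reads: `v` counts emitted reads carrying the variant base and
#' `N` counts covering reads that were emitted or aligned concordantly
#' (passing the other-type filter).
#'
#' @param alignments Output of [align_transformed()].
#' @param original_reads Named character vector of untransformed reads.
#' @param genome The untransformed genome (`DNAStringSet`).
#' @param scheme The [transform_scheme()] used for the alignment.
#' @param cfg A [hyper_config()].
#' @param study,sample Provenance labels.
#' @return A list with `reads` (per-read calls: read id, span, mismatch
#'   counts, emitted flag) and `sites` (candidate-site table, pipeline
#'   `"hyper"`, genomic forward coordinates).
#' @export
call_hyper_sites <- function(alignments, original_reads, genome, scheme,
                             cfg = hyper_config(), study = NA_character_,
                             sample = NA_character_) {
  alignments <- as.data.table(alignments)
  empty <- list(reads = data.table(read_id = character(), contig = character(),
                                   start = integer(), end = integer(),
                                   n_scheme = integer(), n_other = integer(),
                                   read_len = integer(), emitted = logical()),
                sites = empty_sites())
  if (nrow(alignments) == 0L) return(empty)
  per_read <- vector("list", nrow(alignments))
  site_rows <- list(); cov_rows <- list()
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i]
    rseq <- original_reads[[a$read_id]]
    if (is.null(rseq)) stopf("alignment for unknown read '%s'", a$read_id)
    if (a$orient == "R") rseq <- revcomp(rseq)
    L <- nchar(rseq)
    ref <- genome_seq(genome, a$contig, a$start, a$end)
    rs <- strsplit(rseq, "")[[1]]; gs <- strsplit(ref, "")[[1]]
    core <- seq.int(cfg$edge_exclude + 1L, L - cfg$edge_exclude)
    mism <- which(rs != gs)
    mism <- mism[mism %in% core]
    is_scheme <- gs[mism] == scheme$from & rs[mism] == scheme$to
    m <- sum(is_scheme); other <- length(mism) - m
    emitted <- m >= cfg$min_sites && m / L >= cfg$min_frac &&
      other / L <= cfg$max_other_frac
    concordant <- other / L <= cfg$max_other_frac
    per_read[[i]] <- data.table(read_id = a$read_id, contig = a$contig,
                                start = a$start, end = a$end,
                                n_scheme = m, n_other = other,
                                read_len = L, emitted = emitted)
    if (concordant || emitted)
      cov_rows[[length(cov_rows) + 1L]] <-
        data.table(contig = a$contig, pos = seq.int(a$start, a$end)[core])
    if (emitted && m > 0L)
      site_rows[[length(site_rows) + 1L]] <-
        data.table(contig = a$contig, pos = a$start + mism[is_scheme] - 1L)
  }
  reads_dt <- data.table::rbindlist(per_read)
  if (length(site_rows) == 0L) return(list(reads = reads_dt, sites = empty_sites()))
  v <- data.table::rbindlist(site_rows)[, .(variant = .N), by = .(contig, pos)]
  N <- data.table::rbindlist(cov_rows)[, .(coverage = .N), by = .(contig, pos)]
  sites <- N[v, on = c("contig", "pos")]
  sites[, `:=`(strand = "+", type = scheme$type,
               rate = 100 * variant / coverage,
               study = study, sample = sample, pipeline = "hyper")]
  data.table::setcolorder(sites, names(empty_sites()))
  data.table::setorder(sites, contig, pos)
  sites <- sites[]
  list(reads = reads_dt, sites = sites)
}

#' Run the hyper-editing pipeline over one or all schemes
#'
#' For each scheme: transform the genome and the unmapped reads, align in
#' transformed space, restore the originals, and call hyper-edited reads
#' and sites. The per-scheme site counts form the hyper-editing mismatch
#' spectrum; no clustering filter is applied afterwards because emitted
#' sites are clustered by construction (genomic-variant and
#' multi-mismatch filters still apply downstream).
#'
#' @param reads Named character vector of unmapped read sequences (e.g.
#'   from [read_fastq()]).
#' @param genome The reference `DNAStringSet`.
#' @param cfg A [hyper_config()].
#' @param schemes `"all"` for the 12-scheme battery, or a list of
#'   [transform_scheme()] objects (or a single scheme).
#' @param k,max_mismatch_frac Toy-aligner parameters (see
#'   [align_transformed()]).
#' @param study,sample Provenance labels.
#' @return A list with `sites` (all schemes combined), `reads` (per-read
#'   calls with a `scheme` column) and `spectrum`.
#' @export
run_hyper_pipeline <- function(reads, genome, cfg = hyper_config(),
                               schemes = "all", k = 16L,
                               max_mismatch_frac = 0.1,
                               study = NA_character_, sample = NA_character_) {
  if (identical(schemes, "all")) schemes <- all_schemes()
  if (inherits(schemes, "transform_scheme")) schemes <- list(schemes)
  gchar <- setNames(as.character(genome), names(genome))
  all_sites <- list(); all_reads <- list()
  for (sc in schemes) {
    gt <- transform_sequence(gchar, sc)
    aln <- align_transformed(reads, gt, scheme = sc, k = k,
                             max_mismatch_frac = max_mismatch_frac,
                             unique_best = cfg$unique_best)
    res <- call_hyper_sites(aln, reads, genome, sc, cfg,
                            study = study, sample = sample)
    if (nrow(res$sites)) all_sites[[sc$type]] <- res$sites
    if (nrow(res$reads)) {
      res$reads[, scheme := sc$type]
      all_reads[[sc$type]] <- res$reads
    }
  }
  sites <- if (length(all_sites)) data.table::rbindlist(all_sites)
           else empty_sites()
  list(sites = sites,
       reads = if (length(all_reads)) data.table::rbindlist(all_reads)
               else NULL,
       spectrum = hyper_spectrum(sites))
}

#' Hyper-editing mismatch spectrum
#'
#' The per-scheme site counts of a 12-scheme run, as a
#' [mismatch_spectrum()].
#'
#' @param sites Combined hyper candidate sites from all schemes run.
#' @return A `mismatch_spectrum`.
#' @export
hyper_spectrum <- function(sites) {
  mismatch_spectrum(sites)
}

#' Read sequences from FASTQ
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
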
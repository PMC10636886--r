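# High-confidence coding sites with recoding annotation, native chain-file
# liftover, cross-species conservation classification, and evaluation of
# externally curated site lists against the local editome.

#' Lift genomic positions through a chain
#'
#' Maps 1-based source positions to target coordinates by walking the
#' aligned blocks of a UCSC chain: a position inside a block maps by its
#' offset (strand-aware for '-'-strand chains); positions in inter-block
#' gaps or outside every chain do not map. When several chains cover a
#' position, the retained targets follow the selection `mode`:
#' `"single"` keeps the best-scoring target (one-to-one mapping);
#' `"homeolog"` keeps up to two targets when the two best-scoring target
#' contigs are an `.L`/`.S` homeolog pair, otherwise the best one.
#'
#' @param chain A chain block table from [read_chain()].
#' @param contig,pos Equal-length vectors of source coordinates.
#' @param mode Target selection mode.
#' @return `data.table` with one row per input position: `src_contig`,
#'   `src_pos`, `mapped`, and for mapped rows `tgt_contig`, `tgt_pos`,
#'   `tgt_strand`, `chain_id`, `score` (unmapped rows carry `NA`s;
#'   homeolog dual targets yield two rows).
#' @export
liftover_site <- function(chain, contig, pos, mode = c("single", "homeolog")) {
  mode <- match.arg(mode)
  chain <- as.data.table(chain)
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n); pos <- rep_len(as.integer(pos), n)
  q <- data.table(src_contig = contig, start = pos, end = pos, qid = seq_len(n))
  blk <- data.table::copy(chain)
  blk[, `:=`(start = src_start, end = src_end)]
  data.table::setkey(blk, src_contig, start, end)
  ov <- data.table::foverlaps(q, blk, by.x = c("src_contig", "start", "end"),
                              type = "within", nomatch = NULL)
  out <- list()
  if (nrow(ov)) {
    ov[, src_pos := i.start]
    ov[, off := src_pos - src_start]
    ov[, tgt_pos := ifelse(tgt_strand == "+",
                           tgt_start0 + off + 1L,
                           tgt_size - (tgt_start0 + off))]
    # per query, rank candidate targets by chain score
    data.table::setorder(ov, qid, -score, chain_id)
    picks <- ov[, {
      if (mode == "single" || .N == 1L) {
        .SD[1L]
      } else {
        c1 <- tgt_contig[1L]; c2 <- tgt_contig[2L]
        base1 <- sub("\\.(L|S)$", "", c1); base2 <- sub("\\.(L|S)$", "", c2)
        sfx1 <- sub("^.*\\.", "", c1); sfx2 <- sub("^.*\\.", "", c2)
        if (base1 == base2 && c1 != c2 &&
            all(c(sfx1, sfx2) %in% c("L", "S"))) .SD[1:2] else .SD[1L]
      }
    }, by = qid]
    out[["hit"]] <- picks[, .(qid, src_contig, src_pos,
                              mapped = TRUE, tgt_contig, tgt_pos,
                              tgt_strand, chain_id, score)]
  }
  missed <- setdiff(seq_len(n), if (nrow(ov)) ov$qid else integer())
  if (length(missed))
    out[["miss"]] <- data.table(qid = missed, src_contig = contig[missed],
                                src_pos = pos[missed], mapped = FALSE,
                                tgt_contig = NA_character_,
                                tgt_pos = NA_integer_,
                                tgt_strand = NA_character_,
                                chain_id = NA_character_, score = NA_real_)
  res <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setorder(res, qid, -mapped)
  res[, qid := NULL]
  res[]
}

#' Classify the genomic base at lifted positions
#'
#' Reads the target-genome base under each mapped site (complemented for
#' `-`-strand mappings) and assigns a class: `A` (assessable for
#' editing), `G` (the edited state is genomically hard-coded, "fixed-G"),
#' `other`, or `unassessable` (unmapped or beyond the contig end).
#'
#' @param genome The target `DNAStringSet`.
#' @param lifted A lifted-site table from [liftover_site()].
#' @return `lifted` with `target_base` and `target_class` columns.
#' @export
check_target_base <- function(genome, lifted) {
  lifted <- data.table::copy(as.data.table(lifted))
  base <- rep(NA_character_, nrow(lifted))
  cls <- rep("unassessable", nrow(lifted))
  lens <- setNames(Biostrings::width(genome), names(genome))
  ok <- lifted$mapped & lifted$tgt_contig %in% names(genome) &
    lifted$tgt_pos >= 1L & lifted$tgt_pos <= lens[lifted$tgt_contig]
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    b <- genome_base(genome, lifted$tgt_contig[ok], lifted$tgt_pos[ok])
    minus <- lifted$tgt_strand[ok] == "-"
    b[minus] <- comp_base(b[minus])
    base[ok] <- b
    cls[ok] <- ifelse(b == "A", "A", ifelse(b == "G", "G", "other"))
  }
  lifted[, `:=`(target_base = base, target_class = cls)]
  lifted[]
}

.is_general_name <- function(x) {
  is.na(x) | x == "" | grepl("LOC|XB|MGC|XM|NM|XR|c_orf_", x)
}

#' Flag conflicting gene symbols on lifted sites
#'
#' A lifted pair is flagged as a symbol conflict when both the source and
#' target gene symbols are informative (not a general accession-style
#' name containing LOC/XB/MGC/XM/NM/XR/c_orf_), differ, and are not
#' listed as synonyms. Conflicting pairs are usually discarded before
#' conservation analysis.
#'
#' @param lifted A lifted-site table with `gene_a`/`gene_b` columns, or
#'   one to be annotated via `genesA`/`genesB`.
#' @param genesA,genesB Optional gene-model tables used to fill
#'   `gene_a` (at source coordinates) and `gene_b` (at target
#'   coordinates).
#' @param synonyms Optional two-column table of equivalent symbol pairs.
#' @return `lifted` with `gene_a`, `gene_b` and `symbol_conflict`
#'   columns.
#' @export
resolve_gene_symbols <- function(lifted, genesA = NULL, genesB = NULL,
                                 synonyms = NULL) {
  lifted <- data.table::copy(as.data.table(lifted))
  if (!is.null(genesA)) {
    ann <- annotate_location(
      data.table(contig = lifted$src_contig, pos = lifted$src_pos,
                 strand = "+", type = "AG"), genesA)
    lifted[, gene_a := ann$gene]
  }
  if (!is.null(genesB)) {
    tgt <- data.table(contig = lifted$tgt_contig, pos = lifted$tgt_pos,
                      strand = "+", type = "AG")
    gene_b <- rep(NA_character_, nrow(tgt))
    ok <- !is.na(tgt$contig)
    if (any(ok)) gene_b[ok] <- annotate_location(tgt[ok], genesB)$gene
    lifted[, gene_b := gene_b]
  }
  assert_cols(lifted, c("gene_a", "gene_b"), "lifted table")
  syn_keys <- character()
  if (!is.null(synonyms) && nrow(synonyms)) {
    s <- as.data.table(synonyms)
    syn_keys <- c(paste(s[[1]], s[[2]], sep = "\r"),
                  paste(s[[2]], s[[1]], sep = "\r"))
  }
  genA <- .is_general_name(lifted$gene_a)
  genB <- .is_general_name(lifted$gene_b)
  conflict <- !genA & !genB & lifted$gene_a != lifted$gene_b &
    !(paste(lifted$gene_a, lifted$gene_b, sep = "\r") %in% syn_keys)
  conflict[is.na(conflict)] <- FALSE
  lifted[, symbol_conflict := conflict]
  lifted[]
}

#' Classify cross-species conservation of editing
#'
#' For each lifted pair whose target genomic base is `A`, compares the
#' editing level in the two species: `species-specific` when the other
#' species is well covered but essentially unedited; `conserved-similar`
#' when both are edited with levels within the difference threshold;
#' `conserved-differential` when both are edited but differ by more than
#' the threshold (in percentage points); `fixed-G` when the target base
#' is genomically G; `unassessable` otherwise (unmapped, non-A target, or
#' insufficient coverage).
#'
#' @param profilesA Level table for the source species: `contig`, `pos`,
#'   (`strand`,) `level`, `coverage`.
#' @param profilesB Same for the target species, keyed on target
#'   coordinates.
#' @param lifted A lifted-site table with `target_class` (see
#'   [check_target_base()]).
#' @param min_cov Minimum coverage in species B for assessment.
#' @param min_level Minimum level (percent) to call a site edited.
#' @param diff_threshold Conserved-differential threshold in percentage
#'   points.
#' @return `lifted` with `level_a`, `level_b`, `coverage_b` and
#'   `conservation_class` columns.
#' @export
compare_species <- function(profilesA, profilesB, lifted, min_cov = 10L,
                            min_level = 1.0, diff_threshold = 10.0) {
  lifted <- data.table::copy(as.data.table(lifted))
  pa <- as.data.table(profilesA); pb <- as.data.table(profilesB)
  ia <- match(paste(lifted$src_contig, lifted$src_pos),
              paste(pa$contig, pa$pos))
  ib <- match(paste(lifted$tgt_contig, lifted$tgt_pos),
              paste(pb$contig, pb$pos))
  lifted[, `:=`(level_a = pa$level[ia],
                level_b = pb$level[ib],
                coverage_b = pb$coverage[ib])]
  cls <- rep("unassessable", nrow(lifted))
  isG <- lifted$target_class == "G"
  cls[isG] <- "fixed-G"
  assess <- lifted$target_class == "A" & !is.na(lifted$level_a)
  covB <- !is.na(lifted$coverage_b) & lifted$coverage_b >= min_cov
  lb <- lifted$level_b; lb[is.na(lb)] <- 0
  d <- abs(lifted$level_a - lb)
  cls[assess & covB & lb < min_level] <- "species-specific"
  cls[assess & covB & lb >= min_level & lifted$level_a >= min_level &
        d <= diff_threshold] <- "conserved-similar"
  cls[assess & covB & lb >= min_level & lifted$level_a >= min_level &
        d > diff_threshold] <- "conserved-differential"
  lifted[, conservation_class := cls]
  lifted[]
}

#' Derive high-confidence coding sites
#'
#' Tier 1 are CDS A-to-G sites identified by both the regular and the
#' hyper-editing pipelines (matched on contig and position). Tier 2 adds
#' the remaining CDS A-to-G sites, from either pipeline, that lie in a
#' gene already containing a tier-1 site. Tier 3 optionally adds CDS
#' positions whose orthologous position is high-confidence in the other
#' species, provided they show local evidence (at least
#' `min_tier3_variant` variant reads) so conservation alone never
#' asserts editing.
#'
#' @param regular Catalog or site table from the regular pipelines.
#' @param hyper Site table from the hyper-editing pipeline.
#' @param genes Gene-model table.
#' @param ortholog_candidates Optional site table of local positions
#'   whose orthologs are tier-1/2 in the other species, with a `variant`
#'   column of local variant reads.
#' @param min_tier3_variant Local evidence threshold for tier 3.
#' @return `data.table` of coding sites with `tier` (1, 2 or 3), `gene`
#'   and `feature_class` columns.
#' @export
high_confidence_coding <- function(regular, hyper, genes,
                                   ortholog_candidates = NULL,
                                   min_tier3_variant = 1L) {
  reg <- as.data.table(regular)[type == "AG"]
  hyp <- as.data.table(hyper)[type == "AG"]
  ann <- function(x) {
    if (nrow(x) == 0L) return(x)
    annotate_location(unique(x, by = c("contig", "pos")), genes)
  }
  reg <- ann(reg); hyp <- ann(hyp)
  reg_cds <- reg[feature_class == "CDS"]
  hyp_cds <- hyp[feature_class == "CDS"]
  kr <- paste(reg_cds$contig, reg_cds$pos)
  kh <- paste(hyp_cds$contig, hyp_cds$pos)
  tier1 <- reg_cds[kr %in% kh]
  tier1[, tier := 1L]
  either <- unique(rbind(reg_cds, hyp_cds, fill = TRUE),
                   by = c("contig", "pos"))
  t1_genes <- unique(tier1$gene)
  tier2 <- either[!paste(contig, pos) %in% paste(tier1$contig, tier1$pos) &
                    gene %in% t1_genes]
  if (nrow(tier2)) tier2[, tier := 2L]
  out <- rbind(tier1, tier2, fill = TRUE)
  if (!is.null(ortholog_candidates) && nrow(ortholog_candidates)) {
    oc <- annotate_location(as.data.table(ortholog_candidates), genes)
    oc <- oc[feature_class == "CDS" & variant >= min_tier3_variant &
               !paste(contig, pos) %in% paste(out$contig, out$pos)]
    if (nrow(oc)) {
      oc[, tier := 3L]
      out <- rbind(out, oc, fill = TRUE)
    }
  }
  data.table::setorder(out, tier, contig, pos)
  out[]
}

#' Annotate the recoding consequence of coding A-to-G sites
#'
#' For each site inside a CDS, extracts the codon on the coding strand
#' (reverse-complementing for `-`-strand genes), substitutes the edited
#' base at the codon position, and translates both codons under the
#' standard genetic code. When several transcripts contain the site the
#' one with the longest CDS is used (a deterministic, annotation-robust
#' choice).
#'
#' @param sites A site table (CDS A-to-G sites).
#' @param genes Gene-model table.
#' @param genome The reference `DNAStringSet`.
#' @return The sites with `transcript`, `codon_position`, `ref_codon`,
#'   `edited_codon`, `ref_aa`, `edited_aa` and `synonymous` columns;
#'   sites not inside any complete codon get `NA`s.
#' @export
annotate_recoding <- function(sites, genes, genome) {
  sites <- data.table::copy(as.data.table(sites))
  genes <- as.data.table(genes)
  code <- Biostrings::GENETIC_CODE
  n <- nrow(sites)
  res <- data.table(transcript = rep(NA_character_, n),
                    codon_position = rep(NA_integer_, n),
                    ref_codon = rep(NA_character_, n),
                    edited_codon = rep(NA_character_, n),
                    ref_aa = rep(NA_character_, n),
                    edited_aa = rep(NA_character_, n),
                    synonymous = rep(NA, n))
  cds <- genes[feature == "CDS"]
  cds_len <- cds[, .(len = sum(end - start + 1L)), by = transcript]
  for (i in seq_len(n)) {
    ct <- sites$contig[i]; p <- sites$pos[i]
    hit <- cds[contig == ct & start <= p & end >= p]
    if (nrow(hit) == 0L) next
    txs <- unique(hit$transcript)
    tx <- txs[order(-cds_len[match(txs, transcript), len], txs)][1]
    iv <- cds[transcript == tx][order(start)]
    strand <- iv$strand[1]
    widths <- iv$end - iv$start + 1L
    j <- which(iv$start <= p & iv$end >= p)
    off <- if (strand == "+") {
      sum(widths[seq_len(j - 1L)]) + (p - iv$start[j] + 1L)
    } else {
      sum(widths[seq_along(widths) > j]) + (iv$end[j] - p + 1L)
    }
    cds_seq <- paste(vapply(seq_len(nrow(iv)), function(r)
      genome_seq(genome, ct, iv$start[r], iv$end[r]), character(1)),
      collapse = "")
    if (strand == "-") cds_seq <- revcomp(cds_seq)
    cp <- ((off - 1L) %% 3L) + 1L
    cstart <- off - cp + 1L
    if (cstart + 2L > nchar(cds_seq)) {
      warnf("site %s:%d maps to an incomplete terminal codon of %s", ct, p, tx)
      next
    }
    codon <- substring(cds_seq, cstart, cstart + 2L)
    if (substring(codon, cp, cp) != "A") next
    edited <- codon
    substring(edited, cp, cp) <- "G"
    res$transcript[i] <- tx
    res$codon_position[i] <- cp
    res$ref_codon[i] <- codon
    res$edited_codon[i] <- edited
    res$ref_aa[i] <- code[[codon]]
    res$edited_aa[i] <- code[[edited]]
    res$synonymous[i] <- code[[codon]] == code[[edited]]
  }
  cbind(sites, res)
}

#' Evaluate an external site list against the local editome
#'
#' Assigns each externally curated (lifted) site exactly one category by
#' the precedence `in-catalog` > `filtered-but-edited` >
#' `covered-no-editing` > `no-coverage` > `unmapped/not-A`: a site lifted
#' to a genomic A is looked up in the curated catalog, then in the raw
#' (unfiltered) candidate output at the minimum editing level, then in
#' the coverage table.
#'
#' @param external A lifted-site table with `target_class`, `tgt_contig`,
#'   `tgt_pos`.
#' @param catalog The curated catalog.
#' @param raw_candidates Unfiltered candidate sites (with `rate`).
#' @param counts Position-counts table providing coverage.
#' @param min_cov Coverage needed to claim `covered-no-editing`.
#' @param min_level Editing level (percent) for `filtered-but-edited`.
#' @return `external` with a `category` column.
#' @export
evaluate_external_sites <- function(external, catalog, raw_candidates,
                                    counts, min_cov = 10L, min_level = 1.0) {
  ext <- data.table::copy(as.data.table(external))
  cat2 <- as.data.table(catalog)
  raw <- as.data.table(raw_candidates)
  cnt <- as_counts_dt(counts)
  k <- function(c, p) paste(c, p)
  key <- k(ext$tgt_contig, ext$tgt_pos)
  categ <- rep("unmapped/not-A", nrow(ext))
  isA <- !is.na(ext$target_class) & ext$target_class == "A"
  cov <- cnt$total[match(key, k(cnt$contig, cnt$pos))]
  cov[is.na(cov)] <- 0L
  categ[isA & cov < min_cov] <- "no-coverage"
  categ[isA & cov >= min_cov] <- "covered-no-editing"
  edited <- key %in% k(raw$contig[raw$rate >= min_level],
                       raw$pos[raw$rate >= min_level])
  categ[isA & edited] <- "filtered-but-edited"
  incat <- key %in% k(cat2$contig, cat2$pos)
  categ[isA & incat] <- "in-catalog"
  ext[, category := categ]
  ext[]
}
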
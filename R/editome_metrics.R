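# Global and per-family repeat editing indices, context-specific site
# calling over a study/stage/process averaging hierarchy, genomic feature
# and repeat annotation, the neighbor motif, and gene-set overlap
# enrichment.

#' Repeat editing index
#'
#' A read-weighted aggregate editing measure over adenosine positions
#' inside repeat intervals, modeled after the Alu editing index:
#' `100 * sum(G reads) / sum(A reads + G reads)`. Every genomic-A
#' position inside the selected repeats contributes, whether or not it
#' was ever called as a site, so the index is coverage-weighted by
#' construction.
#'
#' Strand handling: with strand-resolved counts (any `-` rows present)
#' the reference base is already on the transcribed strand, so A
#' positions are rows with `ref == "A"`, matched to the repeat strand
#' when the repeat has one. With unstranded genomic counts, `+`-strand
#' (or unstranded) repeats use genomic `A` positions (G evidence) and
#' `-`-strand repeats use genomic `T` positions (C evidence); repeats
#' without strand use both.
#'
#' @param counts A position-counts table.
#' @param repeats A repeat-interval table (`contig`, `start`, `end`,
#'   `family`, optional `strand`).
#' @param family Optional family label to restrict to.
#' @return An `editing_index` list: `scope`, `numerator`, `denominator`,
#'   `index` (percent), `n_positions`.
#' @export
repeat_editing_index <- function(counts, repeats, family = NULL) {
  counts <- as_counts_dt(counts)
  reps <- if (data.table::is.data.table(repeats)) data.table::copy(repeats)
          else as.data.table(repeats)
  assert_cols(reps, c("contig", "start", "end", "family"), "repeat table")
  if (!"strand" %in% names(reps)) reps[, strand := "*"]
  fam_sel <- family
  if (!is.null(fam_sel)) reps <- reps[family == fam_sel]
  if (nrow(reps) == 0L || nrow(counts) == 0L)
    stopf("editing index undefined: no repeat A positions covered")
  cnt <- data.table::copy(counts)
  cnt[, `:=`(start = pos, end = pos)]
  data.table::setkey(reps, contig, start, end)
  ov <- data.table::foverlaps(cnt, reps, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L)
    stopf("editing index undefined: no repeat A positions covered")
  stranded_counts <- any(counts$strand == "-")
  if (stranded_counts) {
    ov <- ov[ref == "A" & (strand == "*" | i.strand == "*" | strand == i.strand)]
    num <- sum(ov$nG); den <- sum(ov$nA + ov$nG)
  } else {
    plusy <- ov[strand %in% c("+", "*") & ref == "A"]
    minusy <- ov[strand %in% c("-", "*") & ref == "T"]
    num <- sum(plusy$nG) + sum(minusy$nC)
    den <- sum(plusy$nA + plusy$nG) + sum(minusy$nT + minusy$nC)
    ov <- rbind(plusy, minusy)
  }
  if (den == 0L)
    stopf("editing index undefined: no repeat A positions covered")
  structure(list(scope = family %||% "all-repeats",
                 numerator = num, denominator = den,
                 index = 100 * num / den,
                 n_positions = data.table::uniqueN(ov[, .(contig, pos)])),
            class = "editing_index")
}

#' @export
print.editing_index <- function(x, ...) {
  cat(sprintf("editing index [%s]: %.2f%% (%d G / %d A+G reads over %d A positions)\n",
              x$scope, x$index, x$numerator, x$denominator, x$n_positions))
  invisible(x)
}

#' Group repeat families with few editing events
#'
#' Families are ranked by site count (ties broken lexicographically) and
#' those below the cut are merged into one `"other"` group for index
#' reporting. The cut is either an explicit number of retained families
#' (`keep_top`) or a minimum fraction of all repeat sites (`min_frac`,
#' default 1%).
#'
#' @param family_counts Named integer vector (family to site count) or a
#'   table with `family` and `n` columns.
#' @param keep_top Optional number of families to keep ungrouped.
#' @param min_frac Minimum fraction of total sites for a family to stand
#'   alone (used when `keep_top` is `NULL`).
#' @param other_label Label of the merged group.
#' @return Named character vector: family to group label.
#' @export
group_minor_families <- function(family_counts, keep_top = NULL,
                                 min_frac = 0.01, other_label = "other") {
  if (is.data.frame(family_counts)) {
    fc <- setNames(family_counts$n, family_counts$family)
  } else fc <- family_counts
  ord <- order(-fc, names(fc))
  fc <- fc[ord]
  if (length(fc) <= 1L) return(setNames(names(fc), names(fc)))
  keep <- if (!is.null(keep_top)) {
    names(fc)[seq_len(min(keep_top, length(fc)))]
  } else {
    names(fc)[fc >= min_frac * sum(fc)]
  }
  grp <- ifelse(names(fc) %in% keep, names(fc), other_label)
  setNames(grp, names(fc))
}

#' Context specificity configuration
#'
#' @param min_level Minimum editing level (percent) in the focal context.
#' @param fold Fold threshold over the other contexts.
#' @param min_contexts Minimum number of contexts with a level
#'   measurement.
#' @param min_cov Minimum coverage for a level measurement to count.
#' @param fold_vs Compare the focal level against `"each"` other context
#'   (the strictest reading) or against their `"mean"`.
#' @return A `specificity_config` list.
#' @export
specificity_config <- function(min_level = 1.0, fold = 3.0,
                               min_contexts = 2L, min_cov = 10L,
                               fold_vs = c("each", "mean")) {
  if (fold <= 1) stopf("fold threshold must exceed 1")
  structure(list(min_level = min_level, fold = fold,
                 min_contexts = as.integer(min_contexts),
                 min_cov = as.integer(min_cov),
                 fold_vs = match.arg(fold_vs)),
            class = "specificity_config")
}

#' Per-context editing levels with hierarchical averaging
#'
#' For each catalog site, the editing level within a stage is first the
#' pooled rate `100 * sum(v) / sum(N)` over a study's samples at that
#' stage (counted only when the pooled coverage reaches `min_cov`), then
#' averaged (unweighted) across studies; the level of a broader context
#' (developmental process, tissue) is the unweighted mean over its
#' stages with data.
#'
#' @param catalog An editing catalog (keyed site table).
#' @param per_sample_counts Named list: sample id to position-counts
#'   table.
#' @param context_map Table with columns `sample`, `study`, `context`
#'   and optionally `stage` (when absent each context is its own stage).
#' @param min_cov Minimum pooled coverage per study-stage measurement.
#' @return A long `data.table`: site key columns, `context`, `level`
#'   (percent), `n_stages` contributing.
#' @export
per_context_levels <- function(catalog, per_sample_counts, context_map,
                               min_cov = 10L) {
  cat2 <- as.data.table(catalog)
  assert_cols(cat2, c("contig", "pos", "strand", "type"), "catalog")
  cmap <- if (data.table::is.data.table(context_map))
    data.table::copy(context_map) else as.data.table(context_map)
  assert_cols(cmap, c("sample", "study", "context"), "context map")
  if (!"stage" %in% names(cmap)) cmap[, stage := context]
  unknown <- setdiff(names(per_sample_counts), cmap$sample)
  if (length(unknown))
    stopf("sample(s) missing from context map: %s", paste(unknown, collapse = ", "))

  key <- cat2[, .(contig, pos, strand, type)]
  var_base <- substring(key$type, 2L, 2L)
  obs <- list()
  for (s in names(per_sample_counts)) {
    cc <- as_counts_dt(per_sample_counts[[s]])
    # join on position only: unstranded pileups store strand "*" while
    # catalog sites carry the editing strand
    m <- cc[key, on = c("contig", "pos"), mult = "first"]
    v <- as.matrix(m[, .(nA, nC, nG, nT)])[
      cbind(seq_len(nrow(m)), match(var_base, BASES))]
    o <- data.table(key, v = v, N = m$total, sample = s)
    obs[[s]] <- o[!is.na(N)]
  }
  obs <- data.table::rbindlist(obs)
  if (nrow(obs) == 0L)
    return(data.table(contig = character(), pos = integer(),
                      strand = character(), type = character(),
                      context = character(), level = numeric(),
                      n_stages = integer()))
  obs <- cmap[obs, on = "sample"]
  study_stage <- obs[, .(v = sum(v), N = sum(N)),
                     by = .(contig, pos, strand, type, context, stage, study)]
  study_stage <- study_stage[N >= min_cov]
  stage_lvl <- study_stage[, .(level = mean(100 * v / N)),
                           by = .(contig, pos, strand, type, context, stage)]
  ctx <- stage_lvl[, .(level = mean(level), n_stages = .N),
                   by = .(contig, pos, strand, type, context)]
  data.table::setorder(ctx, contig, pos, strand, context)
  ctx[]
}

#' Call context-specific editing sites
#'
#' A site is specific to a context when it has level measurements in at
#' least `min_contexts` contexts, its focal level is at least
#' `min_level`, and the focal level is at least `fold` times the level
#' of every other measured context (zero levels elsewhere satisfy the
#' inequality; with `fold_vs = "mean"` the comparison is against the
#' mean of the other contexts).
#'
#' @param profiles Long per-context level table from
#'   [per_context_levels()].
#' @param cfg A [specificity_config()].
#' @return `data.table` of specific sites with their assigned `context`
#'   (empty when none qualify).
#' @export
call_context_specific <- function(profiles, cfg = specificity_config()) {
  prof <- as.data.table(profiles)
  if (nrow(prof) == 0L)
    return(data.table(contig = character(), pos = integer(),
                      strand = character(), type = character(),
                      context = character(), level = numeric()))
  res <- prof[, {
    if (.N >= cfg$min_contexts) {
      i <- which.max(level)
      others <- level[-i]
      ok <- level[i] >= cfg$min_level &&
        (if (cfg$fold_vs == "each") all(level[i] >= cfg$fold * others)
         else level[i] >= cfg$fold * mean(others))
      if (ok) .(context = context[i], level = level[i]) else NULL
    } else NULL
  }, by = .(contig, pos, strand, type)]
  data.table::setorder(res, contig, pos, strand)
  res[]
}

.genes_granges <- function(genes, feature_sel) {
  g <- genes[feature %in% feature_sel]
  if (nrow(g) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene = g$gene)
}

#' Annotate sites with genomic feature classes
#'
#' Assigns each site exactly one class by deterministic priority across
#' all overlapping transcripts: `CDS` > `5'UTR`/`3'UTR` >
#' `noncoding-exon` > `intron` > `intergenic`. CDS outranks UTR so
#' recoding candidates are never mislabeled when transcripts disagree.
#'
#' @param sites A site table.
#' @param genes A gene-model table from [read_annotation()].
#' @return The sites with `feature_class` and `gene` columns added.
#' @export
annotate_location <- function(sites, genes) {
  sites <- data.table::copy(as.data.table(sites))
  genes <- as.data.table(genes)
  if (nrow(sites) == 0L) {
    sites[, `:=`(feature_class = character(), gene = character())]
    return(sites[])
  }
  sgr <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
  cls <- rep("intergenic", nrow(sites))
  gene_lab <- rep(NA_character_, nrow(sites))
  span <- genes[, .(start = min(start), end = max(end)),
                by = .(gene, transcript, contig, strand)]
  layers <- list(
    intron = GenomicRanges::GRanges(span$contig,
                                    IRanges::IRanges(span$start, span$end),
                                    gene = span$gene),
    `noncoding-exon` = .genes_granges(genes, "exon"),
    `3'UTR` = .genes_granges(genes, "three_prime_UTR"),
    `5'UTR` = .genes_granges(genes, "five_prime_UTR"),
    CDS = .genes_granges(genes, "CDS"))
  for (nm in names(layers)) {
    gr <- layers[[nm]]
    if (length(gr) == 0L) next
    hit <- GenomicRanges::findOverlaps(sgr, gr, select = "first",
                                       ignore.strand = TRUE)
    has <- !is.na(hit)
    cls[has] <- nm
    gene_lab[has] <- S4Vectors::mcols(gr)$gene[hit[has]]
  }
  sites[, `:=`(feature_class = cls, gene = gene_lab)]
  sites[]
}

#' Annotate sites with repeat families
#'
#' Assigns each overlapping site its repeat family; when several repeats
#' overlap, the innermost (smallest) interval wins, ties broken by
#' sorted family label.
#'
#' @param sites A site table.
#' @param repeats A repeat-interval table.
#' @return The sites with a `repeat_family` column (`NA` outside
#'   repeats).
#' @export
annotate_repeat <- function(sites, repeats) {
  sites <- data.table::copy(as.data.table(sites))
  reps <- data.table::copy(as.data.table(repeats))
  if (nrow(sites) == 0L) {
    sites[, repeat_family := character()]
    return(sites[])
  }
  sites[, .row := .I]
  if (nrow(reps) == 0L) {
    sites[, repeat_family := NA_character_]
    sites[, .row := NULL]
    return(sites[])
  }
  cnt <- sites[, .(contig, pos, .row)]
  cnt[, `:=`(start = pos, end = pos)]
  data.table::setkey(reps, contig, start, end)
  ov <- data.table::foverlaps(cnt, reps, type = "within", nomatch = NULL)
  fam <- rep(NA_character_, nrow(sites))
  if (nrow(ov)) {
    ov[, width := end - start + 1L]
    data.table::setorder(ov, .row, width, family)
    pick <- ov[!duplicated(.row)]
    fam[pick$.row] <- pick$family
  }
  sites[, repeat_family := fam]
  sites[, .row := NULL]
  sites[]
}

#' Nucleotide frequencies flanking editing sites
#'
#' Base frequencies at each relative position around the edited
#' adenosine on the sense strand (`-`-strand sites are
#' reverse-complemented before counting). Sites too close to a contig
#' edge contribute only their defined positions. The canonical ADAR
#' signature is a depletion of G immediately upstream.
#'
#' @param sites A strand-resolved site table.
#' @param genome The reference `DNAStringSet`.
#' @param k Flank width (positions -k..-1 and +1..+k are reported).
#' @return A `motif_matrix`: rows = relative positions, columns =
#'   A/C/G/T frequencies (each row sums to 1).
#' @export
neighbor_motif <- function(sites, genome, k = 1L) {
  sites <- as.data.table(sites)
  rel <- c(-seq.int(k, 1L), seq_len(k))
  mat <- matrix(0, nrow = length(rel), ncol = 4L,
                dimnames = list(ifelse(rel > 0, paste0("+", rel), rel), BASES))
  lens <- setNames(Biostrings::width(genome), names(genome))
  for (j in seq_along(rel)) {
    d <- rel[j]
    gpos <- ifelse(sites$strand == "-", sites$pos - d, sites$pos + d)
    ok <- gpos >= 1L & gpos <= lens[sites$contig]
    if (!any(ok)) next
    b <- genome_base(genome, sites$contig[ok], gpos[ok])
    b[sites$strand[ok] == "-"] <- comp_base(b[sites$strand[ok] == "-"])
    tab <- table(factor(b, levels = BASES))
    mat[j, ] <- as.numeric(tab) / sum(tab)
  }
  structure(mat, class = c("motif_matrix", class(mat)))
}

#' Gene-set overlap enrichment
#'
#' Representation factor (observed over expected overlap size) and
#' upper-tail hypergeometric p-value for the overlap of two gene sets
#' within a common universe.
#'
#' @param setA,setB Character vectors of gene identifiers.
#' @param universe Character vector containing both sets.
#' @return A list with `n_overlap`, `expected`, `representation_factor`
#'   and `p_value`.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (length(universe) == 0L) stopf("empty gene universe")
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stopf("gene sets must be subsets of the universe")
  k <- length(intersect(setA, setB))
  expected <- length(setA) * length(setB) / length(universe)
  rf <- if (expected > 0) k / expected else NA_real_
  p <- phyper(k - 1L, length(setA), length(universe) - length(setA),
              length(setB), lower.tail = FALSE)
  list(n_overlap = k, expected = expected, representation_factor = rf,
       p_value = p)
}
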
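# The sequential filter cascade: genomic-variant removal, the +/-20 nt
# multi-mismatch window filter, clustered/isolated partitioning with
# cross-study rescue of isolated sites, catalog assembly, and the WGS
# homozygous-reference diagnostic.

#' Filter cascade configuration
#'
#' @param window Half-width of the neighborhood window in nt (default 20).
#' @param snp_depth,snp_qual Depth and quality thresholds a VCF record
#'   must meet to remove a site (defaults 10 and 20).
#' @param rescue_min_var Minimum variant reads per study for isolated-site
#'   rescue (default 5).
#' @param rescue_min_studies Minimum number of qualifying studies
#'   (default 2).
#' @return A `filter_config` list.
#' @export
filter_config <- function(window = 20L, snp_depth = 10L, snp_qual = 20L,
                          rescue_min_var = 5L, rescue_min_studies = 2L) {
  if (window < 0) stopf("window must be >= 0")
  structure(list(window = as.integer(window), snp_depth = snp_depth,
                 snp_qual = snp_qual, rescue_min_var = rescue_min_var,
                 rescue_min_studies = as.integer(rescue_min_studies)),
            class = "filter_config")
}

#' Remove candidate sites at genomic variant positions
#'
#' Drops candidates at any position carried by a variant record with
#' depth and quality at or above the configured thresholds; weaker
#' variant records are ignored.
#'
#' @param sites Candidate-site table.
#' @param variants Variant table from [read_vcf()].
#' @param cfg A [filter_config()].
#' @return The filtered candidate-site table.
#' @export
remove_genomic_variants <- function(sites, variants, cfg = filter_config()) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L || is.null(variants) || nrow(variants) == 0L)
    return(sites)
  variants <- as.data.table(variants)
  strong <- variants[depth >= cfg$snp_depth & qual >= cfg$snp_qual,
                     .(contig, pos)]
  if (nrow(strong) == 0L) return(sites)
  sites[!strong, on = c("contig", "pos")]
}

# Per-site neighborhood tallies: number of candidates (n_window) and
# same-type candidates (n_same) within +/- w nt on the same contig,
# including the site itself. Distance is strand-agnostic.
.window_counts <- function(sites, w) {
  dt <- data.table::copy(as.data.table(sites))
  dt[, .row := .I]
  cnt_in <- function(sorted_pos, p) {
    findInterval(p + w, sorted_pos) - findInterval(p - w - 1L, sorted_pos)
  }
  dt[, n_window := {
    sp <- sort(pos); cnt_in(sp, pos)
  }, by = contig]
  dt[, n_same := {
    sp <- sort(pos); cnt_in(sp, pos)
  }, by = .(contig, type)]
  data.table::setorder(dt, .row)
  res <- dt[, .(n_window, n_same)]
  dt[, c(".row", "n_window", "n_same") := NULL]
  res
}

#' Remove sites flanked by mismatches of other types
#'
#' A site is removed if and only if another candidate on the same contig
#' within the window carries a different mismatch type; clusters mixing
#' substitution types are characteristic of mapping errors. Evaluation is
#' against the input set in one pass, not iteratively.
#'
#' @param sites Candidate-site table (one sample-set).
#' @param w Window half-width in nt.
#' @return The filtered candidate-site table.
#' @export
filter_multi_mismatch <- function(sites, w = 20L) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) return(sites)
  wc <- .window_counts(sites, w)
  sites[wc$n_window == wc$n_same]
}

#' Partition candidates into clustered and isolated sites
#'
#' A site is clustered when at least one other same-type candidate lies
#' within the window; A-to-I editing characteristically occurs in
#' clusters, so isolated sites are set aside (and may later be rescued
#' across studies).
#'
#' @inheritParams filter_multi_mismatch
#' @return A list with elements `clustered` and `isolated`.
#' @export
split_clustered_isolated <- function(sites, w = 20L) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) return(list(clustered = sites, isolated = sites))
  wc <- .window_counts(sites, w)
  list(clustered = sites[wc$n_same >= 2L],
       isolated = sites[wc$n_same < 2L])
}

#' Rescue isolated sites recurring across studies
#'
#' An isolated site is rescued when the same (contig, position, strand,
#' type) key is found in at least `rescue_min_studies` studies with at
#' least `rescue_min_var` variant reads in each qualifying study.
#'
#' @param per_study_isolated Named list, study id to isolated-site table
#'   (each already past the variant and multi-mismatch filters). When a
#'   study contributed several samples, the per-study evidence for a key
#'   is its maximum variant-read count.
#' @param cfg A [filter_config()].
#' @return Rescued sites, one row per key, with an `n_studies` column.
#' @export
rescue_isolated <- function(per_study_isolated, cfg = filter_config()) {
  stopifnot(is.list(per_study_isolated))
  if (length(per_study_isolated) < 2L) {
    warnf("isolated-site rescue requires >= 2 studies; returning no sites")
    return(cbind(empty_sites(), data.table(n_studies = integer())))
  }
  studies <- names(per_study_isolated) %||% as.character(seq_along(per_study_isolated))
  all <- data.table::rbindlist(
    lapply(seq_along(per_study_isolated), function(i) {
      dt <- data.table::copy(as.data.table(per_study_isolated[[i]]))
      if (nrow(dt)) dt[, study := studies[i]]
      dt
    }), use.names = TRUE, fill = TRUE)
  if (nrow(all) == 0L)
    return(cbind(empty_sites(), data.table(n_studies = integer())))
  ev <- all[, .SD[which.max(variant)], by = .(contig, pos, strand, type, study)]
  qual <- ev[variant >= cfg$rescue_min_var]
  keys <- qual[, .(n_studies = data.table::uniqueN(study)),
               by = .(contig, pos, strand, type)]
  keys <- keys[n_studies >= cfg$rescue_min_studies]
  if (nrow(keys) == 0L)
    return(cbind(empty_sites(), data.table(n_studies = integer())))
  best <- qual[keys, on = c("contig", "pos", "strand", "type")]
  out <- best[, .SD[which.max(variant)], by = .(contig, pos, strand, type)]
  out[, pipeline := paste0(pipeline, "+rescued")]
  data.table::setorder(out, contig, pos, strand)
  out[]
}

#' Assemble the curated editing catalog
#'
#' Takes the A-to-G output of the separate-sample, pooled, hyper-editing
#' and rescue pipelines, deduplicates by (contig, position, strand, type)
#' and records which pipelines support each site.
#'
#' @param separate,pooled,hyper,rescued Candidate-site tables (any may be
#'   `NULL`).
#' @param type_filter Mismatch type retained in the catalog (default
#'   `"AG"`, the transcript-strand A-to-G convention).
#' @return The catalog `data.table` with logical provenance flags and the
#'   strongest per-site evidence (`coverage`, `variant`, `rate`,
#'   `n_studies`).
#' @export
build_catalog <- function(separate = NULL, pooled = NULL, hyper = NULL,
                          rescued = NULL, type_filter = "AG") {
  inputs <- list(separate = separate, pooled = pooled, hyper = hyper,
                 rescued = rescued)
  pieces <- list()
  for (nm in names(inputs)) {
    x <- inputs[[nm]]
    if (is.null(x) || nrow(x) == 0L) next
    x <- as.data.table(x)[type %in% type_filter]
    if (nrow(x) == 0L) next
    x <- data.table::copy(x)
    x[, provenance := nm]
    pieces[[nm]] <- x
  }
  if (length(pieces) == 0L) {
    out <- empty_sites()[, .(contig, pos, strand, type)]
    out[, `:=`(separate = logical(), pooled = logical(), hyper = logical(),
               rescued = logical(), coverage = integer(), variant = integer(),
               rate = numeric(), n_studies = integer())]
    return(out[])
  }
  all <- data.table::rbindlist(pieces, use.names = TRUE, fill = TRUE)
  cat <- all[, .(
    separate = any(provenance == "separate"),
    pooled = any(provenance == "pooled"),
    hyper = any(provenance == "hyper"),
    rescued = any(provenance == "rescued"),
    coverage = as.integer(max(coverage, na.rm = TRUE)),
    variant = as.integer(max(variant, na.rm = TRUE)),
    rate = rate[which.max(variant)],
    n_studies = data.table::uniqueN(study[!is.na(study)])
  ), by = .(contig, pos, strand, type)]
  data.table::setorder(cat, contig, pos, strand)
  cat[]
}

#' Overlap between two site sets
#'
#' Compares two site tables by their (contig, position, strand, type)
#' keys and reports the overlap count and the percentage of each set
#' covered by the other.
#'
#' @param a,b Site tables.
#' @return A list with `n_a`, `n_b`, `n_overlap`, `pct_of_a`, `pct_of_b`.
#' @export
catalog_overlap <- function(a, b) {
  ka <- unique(with(as.data.table(a), site_key(contig, pos, strand, type)))
  kb <- unique(with(as.data.table(b), site_key(contig, pos, strand, type)))
  n <- length(intersect(ka, kb))
  list(n_a = length(ka), n_b = length(kb), n_overlap = n,
       pct_of_a = if (length(ka)) 100 * n / length(ka) else NA_real_,
       pct_of_b = if (length(kb)) 100 * n / length(kb) else NA_real_)
}

#' WGS homozygous-reference diagnostic
#'
#' Labels each catalog site by its whole-genome-sequencing pileup:
#' `homozygous-reference` (at least `min_ref_reads` reference-base reads
#' and zero variant-base reads), `non-reference` (any variant-base
#' reads), or `insufficient-coverage`. The WGS table is genomic
#' (unstranded), so sites on the `-` strand are checked against the
#' complementary genomic bases. The check is diagnostic: sites are
#' labeled, never removed.
#'
#' @param catalog An editing catalog.
#' @param wgs_counts Genomic position-counts table from WGS reads.
#' @param min_ref_reads Minimum supporting reference reads (default 10).
#' @return A list with `labels` (catalog plus `wgs_label`) and
#'   `pct_supported` = 100 * supported / (supported + non-reference).
#' @export
genomic_support_check <- function(catalog, wgs_counts, min_ref_reads = 10L) {
  cat2 <- data.table::copy(as.data.table(catalog))
  wgs <- as_counts_dt(wgs_counts)
  ref_b <- substring(cat2$type, 1L, 1L)
  var_b <- substring(cat2$type, 2L, 2L)
  minus <- cat2$strand == "-"
  ref_b[minus] <- comp_base(ref_b[minus])
  var_b[minus] <- comp_base(var_b[minus])
  m <- wgs[cat2[, .(contig, pos)], on = c("contig", "pos")]
  getc <- function(tbl, base) {
    as.matrix(tbl[, .(nA, nC, nG, nT)])[
      cbind(seq_len(nrow(tbl)), match(base, BASES))]
  }
  nref <- getc(m, ref_b); nvar <- getc(m, var_b)
  nref[is.na(nref)] <- 0L; nvar[is.na(nvar)] <- 0L
  lab <- ifelse(nvar > 0L, "non-reference",
                ifelse(nref >= min_ref_reads, "homozygous-reference",
                       "insufficient-coverage"))
  cat2[, wgs_label := lab]
  supported <- sum(lab == "homozygous-reference")
  nonref <- sum(lab == "non-reference")
  pct <- if (supported + nonref > 0L) 100 * supported / (supported + nonref)
         else NA_real_
  list(labels = cat2[], pct_supported = pct)
}

#' Run the full filter cascade for one pipeline
#'
#' Applies, in order: genomic-variant removal, the multi-mismatch window
#' filter, and the clustered/isolated partition per sample-set; then
#' rescues isolated sites across studies. Also records the mismatch
#' spectrum (and FDR when defined) after each step, the machine-readable
#' analogue of a per-step mismatch-type histogram.
#'
#' @param per_study_sites Named list: study id to either a single
#'   candidate-site table (pooled mode) or a list of per-sample tables
#'   (separate mode).
#' @param variants Variant table (or `NULL`).
#' @param cfg A [filter_config()].
#' @return A list with `clustered` (rbind over studies), `isolated`,
#'   `rescued`, and `report` (per-step list of `spectrum` / `fdr_pct`).
#' @export
run_filter_cascade <- function(per_study_sites, variants = NULL,
                               cfg = filter_config()) {
  norm <- lapply(per_study_sites, function(x) {
    if (is.data.frame(x)) list(x) else x
  })
  step_sets <- list(raw = list(), snp = list(), multi = list(),
                    clustered = list(), isolated = list())
  per_study_isolated <- list()
  for (study in names(norm)) {
    iso_study <- list()
    for (s in seq_along(norm[[study]])) {
      x0 <- as.data.table(norm[[study]][[s]])
      x1 <- remove_genomic_variants(x0, variants, cfg)
      x2 <- filter_multi_mismatch(x1, cfg$window)
      sp <- split_clustered_isolated(x2, cfg$window)
      step_sets$raw[[length(step_sets$raw) + 1L]] <- x0
      step_sets$snp[[length(step_sets$snp) + 1L]] <- x1
      step_sets$multi[[length(step_sets$multi) + 1L]] <- x2
      step_sets$clustered[[length(step_sets$clustered) + 1L]] <- sp$clustered
      step_sets$isolated[[length(step_sets$isolated) + 1L]] <- sp$isolated
      iso_study[[s]] <- sp$isolated
    }
    per_study_isolated[[study]] <- data.table::rbindlist(iso_study,
                                                         use.names = TRUE)
  }
  rescued <- if (length(norm) >= 2L) rescue_isolated(per_study_isolated, cfg)
             else suppressWarnings(rescue_isolated(per_study_isolated, cfg))
  report <- lapply(step_sets, function(sets) {
    all <- unique(data.table::rbindlist(sets, use.names = TRUE),
                  by = c("contig", "pos", "strand", "type"))
    spec <- mismatch_spectrum(all)
    fdr <- if (!spec$empty && spec$counts["AG"] > 0L) estimate_fdr(spec)
           else NA_real_
    list(n = spec$n, spectrum = spec, fdr_pct = fdr)
  })
  list(clustered = data.table::rbindlist(step_sets$clustered, use.names = TRUE),
       isolated = data.table::rbindlist(step_sets$isolated, use.names = TRUE),
       rescued = rescued,
       report = report)
}
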
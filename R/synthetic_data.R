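# Synthetic data generator: genomes, gene models, repeats, a planted
# editome with known per-context rates, genomic variants, RNA-seq counts,
# read-level alignments for dense regions, and long-read co-editing data.
# Every generator is deterministic given `cfg$seed`; each stage re-seeds
# with a fixed offset so outputs do not depend on call order.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' define the standard study conditions used throughout the package:
#' a 2 Mb two-contig genome, 3 studies x 4 developmental contexts x
#' 2 replicate samples at 50x depth, clustered sites edited at 15% in
#' triplets spanning 30 nt, isolated sites at 10%, hyper-edited regions
#' of 8 sites over 60 nt at 80%, and context-specific sites at 20% in
#' their focal context versus 2% elsewhere.
#'
#' @param seed Integer seed (< 2^31); every generator derives its RNG
#'   state from this.
#' @param genome List: `contigs` (names; a `.L`/`.S` suffix pair by
#'   default), `length` (per contig).
#' @param genes List: `n_per_contig`, `exon_len`, `intron_len`,
#'   `utr5_len`, `utr3_len`, `minus_frac` (fraction of genes on the
#'   minus strand).
#' @param repeats List: `n_per_contig`, `len`, `families`,
#'   `inverted_frac` (fraction created as inverted +/- pairs).
#' @param snps List: `n_per_contig`, `het_frac`, `depth`, `qual`
#'   (depth/quality written to the VCF), `n_weak` (variants written
#'   with sub-threshold depth/quality, which a depth>=10 & quality>=20
#'   variant filter must ignore).
#' @param editome List of planted-site counts and rates; see Details.
#' @param species List: `divergence` (point-substitution rate in the
#'   second genome), `insertion_every`/`insertion_len` (spacing and size
#'   of insertions that split chain blocks), `conserved_frac` (fraction
#'   of eligible sites that are edited in both species).
#' @param sequencing List: `read_len`, `depth`, `error_rate`,
#'   `n_studies`, `contexts`, `samples_per_context`, `wgs_depth`.
#' @param longread List: `n_reads` per gene, `p_edit` (junction-site
#'   editing probability), `p_partner_given_edit` /
#'   `p_partner_given_unedit` (dependence of the partner site),
#'   `base_splice` (splicing probability for unedited transcripts),
#'   `coupling` (1 = editing fully blocks splicing).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = list(),
                       genes = list(),
                       repeats = list(),
                       snps = list(),
                       editome = list(),
                       species = list(),
                       sequencing = list(),
                       longread = list()) {
  merge_defaults <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stopf("unknown sim_config field(s): %s", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stopf("seed must be a non-negative integer below 2^31")
  cfg <- list(
    seed = seed,
    genome = merge_defaults(genome, list(
      contigs = c("chr1.L", "chr1.S"), length = 1000000L)),
    genes = merge_defaults(genes, list(
      n_per_contig = 8L, exon_len = 300L, intron_len = 400L,
      utr5_len = 100L, utr3_len = 200L, minus_frac = 0.3)),
    repeats = merge_defaults(repeats, list(
      n_per_contig = 40L, len = 300L,
      families = c("SINE/Alu-like", "LINE", "DNA", "LTR"),
      inverted_frac = 0.3)),
    snps = merge_defaults(snps, list(
      n_per_contig = 25L, het_frac = 0.5, depth = 30L, qual = 50,
      n_weak = 4L)),
    editome = merge_defaults(editome, list(
      n_clusters = 40L, cluster_size = 3L, cluster_span = 30L,
      cluster_rate = 0.15,
      n_isolated = 20L, isolated_rate = 0.10,
      n_hyper = 6L, hyper_sites = 20L, hyper_span = 200L, hyper_rate = 0.80,
      n_context = 10L, context_rate = 0.20, context_rate_other = 0.02,
      n_coding = 6L, coding_rate = 0.20)),
    species = merge_defaults(species, list(
      divergence = 0.02, insertion_every = 50000L, insertion_len = 500L,
      conserved_frac = 0.5)),
    sequencing = merge_defaults(sequencing, list(
      read_len = 75L, depth = 50L, error_rate = 0.002,
      n_studies = 3L,
      contexts = c("cleavage", "gastrulation", "neurulation", "organogenesis"),
      samples_per_context = 2L, wgs_depth = 30L)),
    longread = merge_defaults(longread, list(
      n_reads = 300L, p_edit = 0.6, p_partner_given_edit = 0.8,
      p_partner_given_unedit = 0.05, base_splice = 0.1, coupling = 1.0))
  )
  structure(cfg, class = "sim_config")
}

# stage-specific deterministic seeding (offsets fixed, documented here once)
.sim_seed <- function(cfg, stage) {
  offsets <- c(genomes = 11L, editome = 23L, counts = 37L, wgs = 41L,
               reads = 53L, longread = 67L, coedit = 71L)
  set.seed(cfg$seed + offsets[[stage]])
}

.random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate a genome pair, gene models, repeats and a liftover chain
#'
#' Builds genome A from uniform random sequence, lays out gene models
#' (UTR/exon/intron structure with in-frame CDS) and repeat intervals,
#' then derives genome B from A by point substitution plus periodic
#' insertions, recording the alignment as a chain. The second contig of
#' B is stored reverse-complemented so its chain records carry a `-`
#' target strand. B gene models are obtained by mapping A gene features
#' through the chain; B symbols reuse the A symbol for most genes, with
#' a fraction renamed to provisional `LOC`-style identifiers, listed
#' synonyms, or conflicting symbols.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome_a`, `genome_b` (`DNAStringSet`), `chain`
#'   (A -> B, [read_chain()] layout), `genes_a`, `genes_b`, `repeats`,
#'   `snps`, `synonyms`, and `cfg`.
#' @export
simulate_genomes <- function(cfg = sim_config()) {
  .sim_seed(cfg, "genomes")
  gcf <- cfg$genome; ecf <- cfg$genes; rcf <- cfg$repeats
  contigs <- gcf$contigs
  glen <- rep_len(as.integer(gcf$length), length(contigs))
  names(glen) <- contigs

  genome_a <- Biostrings::DNAStringSet(
    vapply(glen, .random_dna, character(1)))

  # --- gene models on genome A -------------------------------------------
  exon_n <- 3L
  tx_len <- exon_n * ecf$exon_len
  cds_len <- tx_len - ecf$utr5_len - ecf$utr3_len
  if (cds_len %% 3L != 0L)
    stopf("gene geometry gives CDS length %d, not a multiple of 3", cds_len)
  span <- exon_n * ecf$exon_len + (exon_n - 1L) * ecf$intron_len
  genes_a <- vector("list", length(contigs))
  gid <- 0L
  symbols <- c("adarb1", "gria2", "cdc27", "ncl", "ddx3x", "eif4a1", "tuba1a",
               "actb1", "sox3", "pou5f3", "vegt", "nodal1", "bmp4", "chrd",
               "gsc", "otx2", "rax", "pax6", "myod1", "tbxt")
  for (ci in seq_along(contigs)) {
    ct <- contigs[ci]
    n <- ecf$n_per_contig
    margin <- min(20000L, glen[ci] %/% 10L)
    spacing <- (glen[ci] - 2L * margin) %/% n
    if (spacing < span + 1000L) stopf("contig too short for %d genes", n)
    starts <- margin + (seq_len(n) - 1L) * spacing + 1L
    strands <- ifelse(stats::runif(n) < ecf$minus_frac, "-", "+")
    rows <- vector("list", n)
    for (gi in seq_len(n)) {
      gid <- gid + 1L
      sym <- if (gid <= length(symbols)) symbols[gid] else sprintf("gene%02d", gid)
      g0 <- starts[gi]
      ex_start <- g0 + (seq_len(exon_n) - 1L) * (ecf$exon_len + ecf$intron_len)
      ex_end <- ex_start + ecf$exon_len - 1L
      # transcript coordinates of each exon (on the + template layout)
      t_start <- (seq_len(exon_n) - 1L) * ecf$exon_len + 1L
      t_end <- t_start + ecf$exon_len - 1L
      cut <- function(lo, hi) {        # transcript interval -> genomic pieces
        keep <- pmax(t_start, lo) <= pmin(t_end, hi)
        data.table(start = ex_start[keep] + pmax(t_start[keep], lo) - t_start[keep],
                   end = ex_start[keep] + pmin(t_end[keep], hi) - t_start[keep])
      }
      cds_lo <- ecf$utr5_len + 1L; cds_hi <- tx_len - ecf$utr3_len
      feat <- rbind(
        data.table(feature = "exon", start = ex_start, end = ex_end),
        cbind(feature = "five_prime_UTR", cut(1L, ecf$utr5_len)),
        cbind(feature = "CDS", cut(cds_lo, cds_hi)),
        cbind(feature = "three_prime_UTR", cut(cds_hi + 1L, tx_len)))
      if (strands[gi] == "-") {
        f <- feat$feature
        f[feat$feature == "five_prime_UTR"] <- "three_prime_UTR"
        f[feat$feature == "three_prime_UTR"] <- "five_prime_UTR"
        feat$feature <- f
      }
      rows[[gi]] <- data.table(gene = sym, transcript = paste0(sym, ".t1"),
                               contig = ct, strand = strands[gi],
                               feature = feat$feature,
                               start = as.integer(feat$start),
                               end = as.integer(feat$end))
    }
    genes_a[[ci]] <- rbindlist(rows)
  }
  genes_a <- rbindlist(genes_a)

  # --- repeats ------------------------------------------------------------
  reps <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    n <- rcf$n_per_contig
    n_pair <- as.integer(round(n * rcf$inverted_frac / 2))
    n_single <- n - 2L * n_pair
    s_start <- sort(sample.int(glen[ci] - rcf$len, n_single + n_pair))
    fam <- sample(rcf$families, n_single + n_pair, replace = TRUE)
    single <- data.table(contig = contigs[ci],
                         start = s_start[seq_len(n_single)],
                         end = s_start[seq_len(n_single)] + rcf$len - 1L,
                         family = fam[seq_len(n_single)],
                         strand = sample(c("+", "-"), n_single, replace = TRUE))
    pa <- s_start[n_single + seq_len(n_pair)]
    pairs <- data.table(
      contig = contigs[ci],
      start = c(pa, pa + rcf$len + 100L),
      end = c(pa + rcf$len - 1L, pa + 2L * rcf$len + 99L),
      family = rep(fam[n_single + seq_len(n_pair)], 2L),
      strand = rep(c("+", "-"), each = n_pair))
    reps[[ci]] <- rbind(single, pairs)
  }
  reps <- rbindlist(reps)[order(contig, start)]

  # --- genomic variants (SNPs) -------------------------------------------
  snps <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    n <- cfg$snps$n_per_contig + cfg$snps$n_weak
    pos <- sort(sample.int(glen[ci], n))
    ref <- genome_base(genome_a, contigs[ci], pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    het <- stats::runif(n) < cfg$snps$het_frac
    weak <- c(rep(FALSE, cfg$snps$n_per_contig), rep(TRUE, cfg$snps$n_weak))
    snps[[ci]] <- data.table(
      contig = contigs[ci], pos = pos, ref = ref, alt = unname(alt),
      af = ifelse(het, 0.5, 1.0),
      qual = ifelse(weak, 10, cfg$snps$qual),
      depth = ifelse(weak, 5L, cfg$snps$depth))
  }
  snps <- rbindlist(snps)

  # --- genome B + chain ---------------------------------------------------
  scf <- cfg$species
  chain_rows <- vector("list", length(contigs))
  b_seqs <- character(length(contigs))
  b_names <- paste0("b_", sub("\\.(L|S)$", "", contigs), "_", seq_along(contigs))
  for (ci in seq_along(contigs)) {
    a_chars <- strsplit(as.character(genome_a[[ci]]), "")[[1]]
    nmut <- as.integer(round(glen[ci] * scf$divergence))
    mpos <- sample.int(glen[ci], nmut)
    a_chars[mpos] <- vapply(a_chars[mpos],
                            function(b) sample(setdiff(BASES, b), 1L), character(1))
    ins_at <- seq(scf$insertion_every, glen[ci] - 1L, by = scf$insertion_every)
    # chain blocks: source runs of A separated by target-only insertions
    blk_src_start0 <- c(0L, ins_at)                  # 0-based
    blk_src_end0 <- c(ins_at, glen[ci])
    sizes <- blk_src_end0 - blk_src_start0
    ins_seq <- vapply(seq_along(ins_at), function(i) .random_dna(scf$insertion_len),
                      character(1))
    pieces <- character(2L * length(sizes) - 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <-
      vapply(seq_along(sizes), function(i)
        paste(a_chars[(blk_src_start0[i] + 1L):blk_src_end0[i]], collapse = ""),
        character(1))
    if (length(ins_seq)) pieces[seq(2L, length(pieces), by = 2L)] <- ins_seq
    b_fwd <- paste(pieces, collapse = "")
    b_len <- nchar(b_fwd)
    tgt_start0 <- blk_src_start0 + (seq_along(sizes) - 1L) * scf$insertion_len
    minus <- ci %% 2L == 0L        # every second contig aligns on '-'
    if (minus) {
      b_seqs[ci] <- revcomp(b_fwd)
      # reverse-strand coordinates of the stored sequence equal forward
      # coordinates of b_fwd, so tgt_start0 is reused unchanged
    } else {
      b_seqs[ci] <- b_fwd
    }
    chain_rows[[ci]] <- data.table(
      chain_id = as.character(ci), score = 1e6 - ci,
      src_contig = contigs[ci], src_size = glen[ci],
      src_start = blk_src_start0 + 1L, src_end = blk_src_end0,
      tgt_contig = b_names[ci], tgt_size = b_len,
      tgt_strand = if (minus) "-" else "+", tgt_start0 = tgt_start0)
  }
  genome_b <- Biostrings::DNAStringSet(b_seqs)
  names(genome_b) <- b_names
  chain <- rbindlist(chain_rows)

  # --- genome B gene models + symbol table -------------------------------
  sim <- list(genome_a = genome_a, genome_b = genome_b, chain = chain)
  genes_b <- .lift_gene_models(genes_a, chain)
  n_g <- length(unique(genes_b$gene))
  a_syms <- unique(genes_b$gene)
  kind <- sample(c(rep("same", ceiling(0.7 * n_g)),
                   rep("loc", ceiling(0.15 * n_g)),
                   rep("synonym", ceiling(0.1 * n_g)),
                   rep("conflict", n_g)))[seq_len(n_g)]
  b_syms <- a_syms
  b_syms[kind == "loc"] <- sprintf("LOC%06d", 100000L + seq_len(sum(kind == "loc")))
  b_syms[kind == "synonym"] <- paste0(a_syms[kind == "synonym"], "-b")
  b_syms[kind == "conflict"] <- paste0("alt", seq_len(sum(kind == "conflict")))
  synonyms <- data.table(symbol = a_syms[kind == "synonym"],
                         synonym = b_syms[kind == "synonym"])
  genes_b[, gene := b_syms[match(gene, a_syms)]]
  genes_b[, transcript := paste0(gene, ".t1")]

  list(genome_a = genome_a, genome_b = genome_b, chain = chain,
       genes_a = genes_a, genes_b = genes_b, repeats = reps, snps = snps,
       synonyms = synonyms, cfg = cfg)
}

# Map A gene features to B coordinates through the chain (feature by
# feature; both endpoints always fall inside one block by construction
# except when an insertion splits a feature, in which case the mapped
# interval simply spans the insertion).
.lift_gene_models <- function(genes, chain) {
  g <- copy(as.data.table(genes))
  m1 <- liftover_site(chain, g$contig, g$start)
  m2 <- liftover_site(chain, g$contig, g$end)
  ok <- m1$mapped & m2$mapped
  out <- g[ok]
  lo <- pmin(m1$tgt_pos[ok], m2$tgt_pos[ok])
  hi <- pmax(m1$tgt_pos[ok], m2$tgt_pos[ok])
  flip <- m1$tgt_strand[ok] == "-"
  str <- out$strand
  str[flip] <- ifelse(out$strand[flip] == "+", "-", "+")
  out[, `:=`(contig = m1$tgt_contig[ok], start = lo, end = hi, strand = str)]
  out[order(contig, gene, start)]
}

# positions (1-based) of a given base in a contig, cached per call site
.base_positions <- function(genome, contig, base = "A") {
  which(strsplit(as.character(genome[[contig]]), "")[[1]] == base)
}

#' Plant a ground-truth editome
#'
#' Chooses genomic adenosines for every planted class and fixes their
#' true editing rates. Clustered sites are laid down in runs of
#' `cluster_size` with inter-site gaps <= 20 nt; isolated and
#' context-specific sites keep >= 41 nt clearance from all other planted
#' positions, with context-specific sites planted as within-20-nt pairs
#' sharing a focal context; hyper-edited regions pack `hyper_sites`
#' adenosines into `hyper_span` nt; coding sites reuse existing
#' AAA / AAG lysine codons of plus-strand CDS so that editing recodes
#' K->E / K->R. A fraction of cluster/isolated sites whose position maps
#' through the chain onto an adenosine in genome B is flagged conserved
#' (edited at the same rate there); the remainder are species-specific.
#' Genomic variants from `sim$snps` are appended as class `"SNP"` rows.
#'
#' @param sim Output of [simulate_genomes()].
#' @param cfg A [sim_config()]; defaults to `sim$cfg`.
#' @return A `data.table` (class `truth_set`) with columns `contig`,
#'   `pos`, `strand`, `type`, `class`, `rate`, `focal_context`,
#'   `rate_other`, `conserved`, `rate_b`, `partner_contig`,
#'   `partner_pos`, `partner_strand`, `region_id`.
#' @export
plant_editome <- function(sim, cfg = sim$cfg) {
  .sim_seed(cfg, "editome")
  e <- cfg$editome
  contigs <- names(sim$genome_a)
  a_pos <- lapply(contigs, function(ct) .base_positions(sim$genome_a, ct))
  names(a_pos) <- contigs
  taken <- lapply(a_pos, function(p) logical(max(p)))   # occupied +/- 40 nt
  occupy <- function(ct, pos, clearance = 40L) {
    lo <- max(1L, min(pos) - clearance); hi <- min(length(taken[[ct]]), max(pos) + clearance)
    taken[[ct]][lo:hi] <<- TRUE
  }
  free <- function(ct, pos) !any(taken[[ct]][pmax(1L, min(pos) - 40L):pmin(length(taken[[ct]]), max(pos) + 40L)])
  # avoid planting on top of genomic variants
  for (i in seq_len(nrow(sim$snps))) occupy(sim$snps$contig[i], sim$snps$pos[i])

  pick_run <- function(ct, k, span, max_gap) {
    # k adenosines with consecutive gaps <= max_gap, total span <= span
    ap <- a_pos[[ct]]
    for (try in 1:500) {
      i0 <- sample.int(length(ap) - 4L * k, 1L)
      run <- ap[i0]
      j <- i0
      target_gap <- max(2L, span %/% k)
      while (length(run) < k) {
        nxt <- ap[ap > run[length(run)] + 1L &
                  ap <= run[length(run)] + min(max_gap, target_gap + 4L)]
        if (!length(nxt)) break
        run <- c(run, nxt[which.min(abs(nxt - (run[length(run)] + target_gap)))])
      }
      if (length(run) == k && run[k] - run[1] <= span && free(ct, run)) {
        occupy(ct, run)
        return(run)
      }
    }
    stopf("could not place a %d-site run on %s", k, ct)
  }
  pick_one <- function(ct) {
    ap <- a_pos[[ct]]
    for (try in 1:500) {
      p <- ap[sample.int(length(ap), 1L)]
      if (free(ct, p)) { occupy(ct, p); return(p) }
    }
    stopf("could not place an isolated site on %s", ct)
  }
  rot <- function(n) contigs[(seq_len(n) - 1L) %% length(contigs) + 1L]

  rows <- list()
  # clustered
  ct_cl <- rot(e$n_clusters)
  for (i in seq_len(e$n_clusters)) {
    run <- pick_run(ct_cl[i], e$cluster_size, e$cluster_span, 20L)
    rows[[length(rows) + 1L]] <- data.table(
      contig = ct_cl[i], pos = run, class = "clustered", rate = e$cluster_rate,
      region_id = sprintf("cluster%03d", i))
  }
  # isolated
  ct_is <- rot(e$n_isolated)
  for (i in seq_len(e$n_isolated))
    rows[[length(rows) + 1L]] <- data.table(
      contig = ct_is[i], pos = pick_one(ct_is[i]), class = "isolated",
      rate = e$isolated_rate, region_id = sprintf("isolated%03d", i))
  # hyper regions
  ct_hy <- rot(e$n_hyper)
  for (i in seq_len(e$n_hyper)) {
    run <- pick_run(ct_hy[i], e$hyper_sites, e$hyper_span, 15L)
    rows[[length(rows) + 1L]] <- data.table(
      contig = ct_hy[i], pos = run, class = "hyper", rate = e$hyper_rate,
      region_id = sprintf("hyper%03d", i))
  }
  # context-specific pairs
  contexts <- cfg$sequencing$contexts
  n_pairs <- ceiling(e$n_context / 2)
  ct_cx <- rot(n_pairs)
  for (i in seq_len(n_pairs)) {
    run <- pick_run(ct_cx[i], 2L, 20L, 20L)
    rows[[length(rows) + 1L]] <- data.table(
      contig = ct_cx[i], pos = run, class = "context_specific",
      rate = e$context_rate,
      focal_context = contexts[(i - 1L) %% length(contexts) + 1L],
      region_id = sprintf("context%03d", i))
  }
  # coding sites: reuse AAA/AAG lysine codons in plus-strand CDS
  rows[[length(rows) + 1L]] <- .plant_coding(sim, cfg, occupy, free)

  truth <- rbindlist(rows, fill = TRUE)
  truth[, `:=`(strand = "+", type = "AG")]
  if (is.null(truth$focal_context)) truth[, focal_context := NA_character_]
  truth[, rate_other := ifelse(class == "context_specific",
                               e$context_rate_other, NA_real_)]

  # conservation flags for cluster/isolated sites
  lift <- liftover_site(sim$chain, truth$contig, truth$pos)
  tb <- check_target_base(sim$genome_b, lift)
  eligible <- truth$class %in% c("clustered", "isolated") &
    lift$mapped & tb$target_class == "A"
  conserved <- eligible & stats::runif(nrow(truth)) < cfg$species$conserved_frac
  truth[, conserved := conserved]
  truth[, rate_b := ifelse(conserved, rate, ifelse(eligible, 0, NA_real_))]
  truth[, `:=`(partner_contig = ifelse(lift$mapped, lift$tgt_contig, NA_character_),
               partner_pos = ifelse(lift$mapped, lift$tgt_pos, NA_integer_),
               partner_strand = ifelse(lift$mapped, lift$tgt_strand, NA_character_))]

  snp <- sim$snps[, .(contig, pos, strand = "+", type = paste0(ref, alt),
                      class = ifelse(qual >= 20 & depth >= 10, "SNP", "SNP_lowqual"),
                      rate = af, focal_context = NA_character_,
                      rate_other = NA_real_, conserved = FALSE, rate_b = NA_real_,
                      partner_contig = NA_character_, partner_pos = NA_integer_,
                      partner_strand = NA_character_,
                      region_id = NA_character_)]
  truth <- rbind(truth[, names(snp), with = FALSE], snp)
  setattr(truth, "class", c("truth_set", class(truth)))
  truth[]
}

# pick n_coding existing AAA/AAG codons inside plus-strand CDS of genome A
.plant_coding <- function(sim, cfg, occupy, free) {
  e <- cfg$editome
  cds <- as.data.table(sim$genes_a)[feature == "CDS" & strand == "+"]
  found <- list()
  for (tx in unique(cds$transcript)) {
    seg <- cds[transcript == tx][order(start)]
    seq <- paste(vapply(seq_len(nrow(seg)), function(i)
      genome_seq(sim$genome_a, seg$contig[i], seg$start[i], seg$end[i]),
      character(1)), collapse = "")
    gpos <- unlist(lapply(seq_len(nrow(seg)), function(i) seg$start[i]:seg$end[i]))
    n_cod <- nchar(seq) %/% 3L
    codons <- substring(seq, 3L * (seq_len(n_cod) - 1L) + 1L, 3L * seq_len(n_cod))
    for (ci in which(codons %in% c("AAA", "AAG"))) {
      # edited adenosine: AAA -> GAA (codon pos 1, K->E); AAG -> AGG (pos 2, K->R)
      off <- if (codons[ci] == "AAA") 1L else 2L
      found[[length(found) + 1L]] <- data.table(
        contig = seg$contig[1], pos = gpos[3L * (ci - 1L) + off],
        codon = codons[ci], transcript = tx)
    }
  }
  found <- rbindlist(found)
  keep <- integer(0)
  for (i in sample.int(nrow(found))) {
    if (length(keep) >= e$n_coding) break
    if (free(found$contig[i], found$pos[i])) {
      occupy(found$contig[i], found$pos[i])
      keep <- c(keep, i)
    }
  }
  if (length(keep) < e$n_coding)
    warnf("placed only %d of %d requested coding sites", length(keep), e$n_coding)
  found[keep, .(contig, pos, class = "coding", rate = e$coding_rate,
                region_id = paste0("coding_", transcript))]
}

#' True editing rate of each planted site in a given context
#'
#' @param truth A [plant_editome()] table.
#' @param context Context name.
#' @return Numeric vector of per-site rates (allele fraction for SNPs).
#' @export
truth_rate <- function(truth, context) {
  ifelse(truth$class == "context_specific" &
           !is.na(truth$focal_context) & truth$focal_context != context,
         truth$rate_other, truth$rate)
}

#' Simulate per-sample RNA-seq base counts
#'
#' Draws, for every study x context x replicate sample, a sparse
#' position-counts table: planted sites receive binomial variant counts
#' at their true context rate on top of `depth` coverage, SNPs appear at
#' their allele fraction, and sequencing errors are drawn genome-wide at
#' `error_rate` (split evenly over the three non-reference bases), so
#' the tables carry the same error structure a pileup of real alignments
#' would. Positions inside `dense_regions` are emitted even when they
#' have zero variant reads, which is what coverage-based denominators
#' (e.g. the repeat editing index) need.
#'
#' @param sim Output of [simulate_genomes()].
#' @param truth Output of [plant_editome()].
#' @param cfg A [sim_config()]; defaults to `sim$cfg`.
#' @param genome Which genome to sequence: `"a"` (default) or `"b"`
#'   (uses `rate_b` of conserved/species-specific sites at the partner
#'   coordinates; context structure is ignored there).
#' @param dense_regions Optional `data.table` (`contig`, `start`, `end`)
#'   of intervals reported at full density.
#' @param depth Override `cfg$sequencing$depth`.
#' @param null_editome If `TRUE`, all editing rates are forced to zero
#'   (SNPs and errors remain): a negative-control dataset.
#' @return List with `samples` (named list of counts `data.table`s) and
#'   `context_map` (`sample`, `study`, `context`).
#' @export
simulate_counts <- function(sim, truth, cfg = sim$cfg, genome = c("a", "b"),
                            dense_regions = NULL, depth = NULL,
                            null_editome = FALSE) {
  genome <- match.arg(genome)
  .sim_seed(cfg, "counts")
  sq <- cfg$sequencing
  depth <- as.integer(depth %||% sq$depth)
  gen <- if (genome == "a") sim$genome_a else sim$genome_b

  if (genome == "a") {
    site_tab <- as.data.table(truth)
  } else {
    t <- as.data.table(truth)[class != "SNP" & !is.na(partner_pos) & !is.na(rate_b)]
    site_tab <- t[, .(contig = partner_contig, pos = partner_pos,
                      strand = "+", type = type, class = class, rate = rate_b,
                      focal_context = NA_character_, rate_other = NA_real_)]
    # on the '-'-strand-mapped contig the edited adenosine lies on the
    # reverse strand of the stored sequence; an unstranded pileup sees T->C
    flipped <- genome_base(gen, site_tab$contig, site_tab$pos) == "T"
    site_tab[flipped, type := "TC"]
  }
  site_tab <- unique(site_tab, by = c("contig", "pos"))

  contigs <- names(gen)
  glen <- Biostrings::width(gen); names(glen) <- contigs
  ref_chars <- lapply(contigs, function(ct) strsplit(as.character(gen[[ct]]), "")[[1]])
  names(ref_chars) <- contigs

  grid <- data.table(expand.grid(
    rep = seq_len(sq$samples_per_context), context = sq$contexts,
    study = paste0("study", seq_len(sq$n_studies)),
    stringsAsFactors = FALSE))
  grid[, sample := sprintf("%s_%s_r%d", study, context, rep)]

  dense_tmpl <- NULL
  if (!is.null(dense_regions)) {
    dr <- as.data.table(dense_regions)
    dr[, region_i := .I]
    dense_tmpl <- dr[, .(contig = contig, pos = start:end), by = region_i][
      , .(contig, pos)]
    dense_tmpl <- unique(dense_tmpl)
    dense_tmpl[, ref := mapply(function(ct, p) ref_chars[[ct]][p], contig, pos)]
  }

  # Sequencing errors are drawn per study at the pooled level and then
  # split multinomially over the study's samples, and only positions whose
  # study-pooled error count reaches `min_variant` (the candidate caller's
  # variant-read minimum) are materialized -- with a row in EVERY sample of
  # the study, so pooled coverage at those positions is exact. Positions
  # below that pooled total can never be called in any within-study
  # pooling, so omitting them leaves every thresholded computation
  # identical to a fully dense pileup.
  min_variant <- 3L
  err3 <- sq$error_rate / 3
  n_per_study <- length(sq$contexts) * sq$samples_per_context
  studies <- unique(grid$study)
  err_by_study <- vector("list", length(studies))
  names(err_by_study) <- studies
  for (st_name in studies) {
    erows <- list()
    for (ci in seq_along(contigs)) {
      ct <- contigs[ci]
      e <- stats::rbinom(3L * glen[ci], depth * n_per_study, err3)
      nz <- which(e >= min_variant)
      if (!length(nz)) next
      pos <- ((nz - 1L) %/% 3L) + 1L
      slot <- ((nz - 1L) %% 3L) + 1L            # which of the 3 non-ref bases
      ref <- ref_chars[[ct]][pos]
      alt <- vapply(seq_along(pos), function(i)
        setdiff(BASES, ref[i])[slot[i]], character(1))
      split_mat <- vapply(e[nz], function(tot)
        as.vector(stats::rmultinom(1L, tot, rep(1, n_per_study))),
        integer(n_per_study))                   # n_per_study x n_positions
      erows[[ct]] <- data.table(contig = ct, pos = pos, ref = ref,
                                alt = unname(alt),
                                split = t(split_mat))
    }
    err_by_study[[st_name]] <- if (length(erows)) rbindlist(erows) else NULL
  }

  samples <- vector("list", nrow(grid))
  names(samples) <- grid$sample
  grid[, study_idx := seq_len(.N), by = study]
  for (si in seq_len(nrow(grid))) {
    cx <- grid$context[si]
    parts <- vector("list", 3L)
    # planted sites
    st <- copy(site_tab)
    r <- ifelse(st$class == "context_specific" & !is.na(st$focal_context) &
                  st$focal_context != cx, st$rate_other, st$rate)
    if (null_editome) r[!st$class %in% c("SNP", "SNP_lowqual")] <- 0
    v <- stats::rbinom(nrow(st), depth, r)
    ref <- mapply(function(ct, p) ref_chars[[ct]][p], st$contig, st$pos)
    var <- substr(st$type, 2L, 2L)
    cnt <- matrix(0L, nrow(st), 4L, dimnames = list(NULL, BASES))
    cnt[cbind(seq_len(nrow(st)), match(ref, BASES))] <- depth - v
    idx <- cbind(seq_len(nrow(st)), match(var, BASES))
    cnt[idx] <- cnt[idx] + v
    parts[[1L]] <- data.table(contig = st$contig, pos = st$pos, strand = "*",
                              ref = unname(ref), nA = cnt[, "A"], nC = cnt[, "C"],
                              nG = cnt[, "G"], nT = cnt[, "T"])
    # this sample's share of the study's error positions
    ed <- err_by_study[[grid$study[si]]]
    if (!is.null(ed)) {
      k <- grid$study_idx[si]
      e_i <- ed[[paste0("split.V", k)]]
      cnt <- matrix(0L, nrow(ed), 4L, dimnames = list(NULL, BASES))
      cnt[cbind(seq_len(nrow(ed)), match(ed$alt, BASES))] <- e_i
      w <- data.table(contig = ed$contig, pos = ed$pos, strand = "*",
                      ref = ed$ref, nA = cnt[, "A"], nC = cnt[, "C"],
                      nG = cnt[, "G"], nT = cnt[, "T"])
      # collapse multiple error slots at one position, then top up the
      # reference base to the sample depth
      w <- w[, lapply(.SD, sum), by = .(contig, pos, strand, ref),
             .SDcols = c("nA", "nC", "nG", "nT")]
      wm <- as.matrix(w[, .(nA, nC, nG, nT)])
      refcol <- match(w$ref, BASES)
      add <- depth - rowSums(wm)
      wm[cbind(seq_len(nrow(w)), refcol)] <-
        wm[cbind(seq_len(nrow(w)), refcol)] + add
      w[, `:=`(nA = wm[, 1L], nC = wm[, 2L], nG = wm[, 3L], nT = wm[, 4L])]
      parts[[2L]] <- w
    }
    # dense regions: reference-only rows where nothing else was drawn
    if (!is.null(dense_tmpl)) {
      d <- copy(dense_tmpl)
      d[, strand := "*"]
      cnt <- matrix(0L, nrow(d), 4L, dimnames = list(NULL, BASES))
      cnt[cbind(seq_len(nrow(d)), match(d$ref, BASES))] <- depth
      d[, `:=`(nA = cnt[, "A"], nC = cnt[, "C"], nG = cnt[, "G"], nT = cnt[, "T"])]
      parts[[3L]] <- d[, .(contig, pos, strand, ref, nA, nC, nG, nT)]
    }
    out <- rbindlist(parts[!vapply(parts, is.null, logical(1))])
    out <- unique(out, by = c("contig", "pos"))   # first wins: sites > errors > dense
    out[, total := nA + nC + nG + nT]
    setorder(out, contig, pos)
    samples[[si]] <- out
  }
  list(samples = samples,
       context_map = grid[, .(sample, study, context)])
}

#' Simulate whole-genome sequencing evidence
#'
#' Produces (i) a genomic base-count table covering every planted
#' editing site (homozygous reference there, since A-to-I editing leaves
#' DNA untouched) and every genomic variant at its allele fraction, and
#' (ii) the variant table to write out with [write_vcf()]. Weak variants
#' carry sub-threshold depth/quality.
#'
#' @inheritParams simulate_counts
#' @return List with `wgs_counts` and `variants`.
#' @export
simulate_wgs <- function(sim, truth, cfg = sim$cfg) {
  .sim_seed(cfg, "wgs")
  depth <- as.integer(cfg$sequencing$wgs_depth)
  t <- as.data.table(truth)
  ref <- substr(t$type, 1L, 1L)
  alt <- substr(t$type, 2L, 2L)
  v <- ifelse(t$class %in% c("SNP", "SNP_lowqual"),
              stats::rbinom(nrow(t), depth, t$rate), 0L)
  cnt <- matrix(0L, nrow(t), 4L, dimnames = list(NULL, BASES))
  cnt[cbind(seq_len(nrow(t)), match(ref, BASES))] <- depth - v
  idx <- cbind(seq_len(nrow(t)), match(alt, BASES))
  cnt[idx] <- cnt[idx] + as.integer(v)
  wgs <- data.table(contig = t$contig, pos = t$pos, strand = "*", ref = ref,
                    nA = cnt[, "A"], nC = cnt[, "C"], nG = cnt[, "G"],
                    nT = cnt[, "T"])
  wgs[, total := nA + nC + nG + nT]
  setorder(wgs, contig, pos)
  list(wgs_counts = unique(wgs, by = c("contig", "pos")),
       variants = sim$snps[, .(contig, pos, ref, alt, qual, depth)])
}

#' Simulate read-level sequencing of selected regions
#'
#' Emits individual reads over the given intervals: each read copies the
#' reference, flips planted sites at their true rate, adds uniform
#' sequencing errors, and is then routed the way a strict end-to-end
#' aligner would route it -- reads whose total mismatch count exceeds
#' `max_mismatch_frac * read_len` go to the unmapped pool (these are the
#' hyper-edited reads a transformed-alignment pass must recover), the
#' rest become SAM records. Per-position counts are tallied from the
#' aligned reads only.
#'
#' @inheritParams simulate_counts
#' @param regions `data.table` with `contig`, `start`, `end`.
#' @param context Context whose true rates apply (default: first).
#' @param depth Target coverage (default `cfg$sequencing$depth`).
#' @param max_mismatch_frac Aligner mismatch tolerance as a fraction of
#'   read length (default 0.03, i.e. 2 mismatches at 75 nt).
#' @return List with `sam` (record table for [write_sam()]), `unmapped`
#'   (named character vector of read sequences), `counts` (pileup of the
#'   aligned reads), `contig_lengths`.
#' @export
simulate_region_reads <- function(sim, truth, regions, cfg = sim$cfg,
                                  context = NULL, depth = NULL,
                                  max_mismatch_frac = 0.03) {
  .sim_seed(cfg, "reads")
  sq <- cfg$sequencing
  L <- sq$read_len
  depth <- depth %||% sq$depth
  context <- context %||% sq$contexts[1]
  tol <- floor(max_mismatch_frac * L)
  t <- as.data.table(truth)
  t[, eff_rate := truth_rate(t, context)]
  regions <- as.data.table(regions)

  sam <- list(); unmapped <- character(0); cnt_rows <- list()
  rid <- 0L
  for (ri in seq_len(nrow(regions))) {
    ct <- regions$contig[ri]
    lo <- max(1L, regions$start[ri] - L + 1L)
    hi <- regions$end[ri]
    starts <- which(stats::runif(hi - lo + 1L) < depth / L) + lo - 1L
    tsub <- t[contig == ct & pos >= lo & pos <= hi + L]
    for (s in starts) {
      rid <- rid + 1L
      bases <- strsplit(genome_seq(sim$genome_a, ct, s, s + L - 1L), "")[[1]]
      within <- tsub[pos >= s & pos <= s + L - 1L]
      edited <- within[stats::runif(.N) < eff_rate]
      if (nrow(edited))
        bases[edited$pos - s + 1L] <- substr(edited$type, 2L, 2L)
      errs <- which(stats::runif(L) < sq$error_rate)
      for (ei in errs) bases[ei] <- sample(setdiff(BASES, bases[ei]), 1L)
      refb <- strsplit(genome_seq(sim$genome_a, ct, s, s + L - 1L), "")[[1]]
      nm <- sum(bases != refb)
      seq <- paste(bases, collapse = "")
      qn <- sprintf("read%06d", rid)
      if (nm > tol) {
        unmapped[[qn]] <- seq
      } else {
        sam[[length(sam) + 1L]] <- data.table(
          qname = qn, flag = 0L, contig = ct, pos = s, mapq = 60L,
          cigar = paste0(L, "M"), seq = seq)
        cnt_rows[[length(cnt_rows) + 1L]] <- data.table(
          contig = ct, pos = s:(s + L - 1L), base = bases, ref = refb)
      }
    }
  }
  sam <- if (length(sam)) rbindlist(sam) else
    data.table(qname = character(), flag = integer(), contig = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               seq = character())
  counts <- if (length(cnt_rows)) {
    cc <- rbindlist(cnt_rows)
    w <- data.table::dcast(cc[, .N, by = .(contig, pos, ref, base)],
                           contig + pos + ref ~ base, value.var = "N", fill = 0L)
    for (b in BASES) if (!b %in% names(w)) w[, (b) := 0L]
    out <- w[, .(contig, pos, strand = "*", ref,
                 nA = A, nC = C, nG = G, nT = T)]
    out[, total := nA + nC + nG + nT]
    setorder(out, contig, pos)
    out[]
  } else empty_counts()
  glen <- Biostrings::width(sim$genome_a)
  names(glen) <- names(sim$genome_a)
  list(sam = sam, unmapped = unmapped, counts = counts, contig_lengths = glen)
}

#' Simulate uniformly edited repeat regions
#'
#' Plants editing at EVERY adenosine of the selected repeats at a single
#' uniform rate and emits a dense counts table over them, the input an
#' aggregate editing-index computation expects: on `+`/unstranded
#' repeats the A positions gain G reads, on `-` repeats the T positions
#' gain C reads (the reverse-strand image seen by an unstranded pileup).
#'
#' @inheritParams simulate_counts
#' @param rate True per-read editing rate (0-1) applied at every
#'   adenosine of the repeat.
#' @param n_repeats Number of repeats used (default: all).
#' @param depth Read depth per position.
#' @return List with `counts` (dense over the repeats) and `repeats`
#'   (the subset used).
#' @export
simulate_repeat_counts <- function(sim, rate, cfg = sim$cfg, n_repeats = NULL,
                                   depth = NULL) {
  .sim_seed(cfg, "counts")
  depth <- as.integer(depth %||% cfg$sequencing$depth)
  reps <- as.data.table(sim$repeats)
  if (!is.null(n_repeats)) reps <- reps[seq_len(min(n_repeats, .N))]
  reps[, rid := .I]
  pos_tab <- reps[, .(contig = contig, strand = strand, pos = start:end),
                  by = rid][, .(contig, pos, strand)]
  pos_tab <- unique(pos_tab, by = c("contig", "pos"))
  pos_tab[, ref := genome_base(sim$genome_a, contig, pos)]
  edited_base <- ifelse(pos_tab$strand == "-", "T", "A")
  variant <- ifelse(pos_tab$strand == "-", "C", "G")
  is_site <- pos_tab$ref == edited_base
  v <- integer(nrow(pos_tab))
  v[is_site] <- stats::rbinom(sum(is_site), depth, rate)
  cnt <- matrix(0L, nrow(pos_tab), 4L, dimnames = list(NULL, BASES))
  cnt[cbind(seq_len(nrow(pos_tab)), match(pos_tab$ref, BASES))] <- depth - v
  idx <- cbind(seq_len(nrow(pos_tab)), match(variant, BASES))
  cnt[idx] <- cnt[idx] + v
  counts <- data.table(contig = pos_tab$contig, pos = pos_tab$pos,
                       strand = "*", ref = pos_tab$ref,
                       nA = cnt[, "A"], nC = cnt[, "C"], nG = cnt[, "G"],
                       nT = cnt[, "T"])
  counts[, total := nA + nC + nG + nT]
  setorder(counts, contig, pos)
  list(counts = counts[], repeats = reps[, .(contig, start, end, family, strand)])
}

#' Simulate long-read co-editing and splicing data
#'
#' For each selected plus-strand multi-exon gene, places two adenosine
#' sites -- one 3 nt downstream of the last 3' splice site
#' (junction-proximal) and one in the middle of the preceding exon --
#' and draws per-read joint states: the junction site is edited with
#' probability `p_edit`; the partner site with
#' `p_partner_given_edit` / `p_partner_given_unedit`; transcripts whose
#' junction site is edited retain the intron with probability `coupling`
#' (otherwise, and always when unedited, they are spliced with
#' probability `base_splice`). This reproduces the two signatures the
#' long-read analyses quantify: isoform-dependent editing concentrated
#' near splice boundaries, and non-independent co-editing of site pairs.
#'
#' @inheritParams simulate_counts
#' @param n_genes Number of genes to simulate (default 2).
#' @return List with `calls` (read x site state table as produced by
#'   [site_calls_from_sam()]), `isoforms` (read -> isoform), `sites`,
#'   and `genes` (the gene-model subset used).
#' @export
simulate_long_reads <- function(sim, cfg = sim$cfg, n_genes = 2L) {
  .sim_seed(cfg, "longread")
  lr <- cfg$longread
  g <- as.data.table(sim$genes_a)
  cand <- g[feature == "exon" & strand == "+", .N, by = .(gene, contig)][N >= 2L]
  if (nrow(cand) < n_genes) stopf("not enough plus-strand multi-exon genes")
  use <- cand$gene[seq_len(n_genes)]

  nearest_a <- function(ct, p) {
    for (d in 0:10) for (q in c(p + d, p - d))
      if (genome_base(sim$genome_a, ct, q) == "A") return(q)
    stopf("no adenosine near %s:%d", ct, p)
  }
  calls <- list(); isoforms <- list(); sites <- list()
  for (gi in seq_along(use)) {
    sym <- use[gi]
    ex <- g[gene == sym & feature == "exon"][order(start)]
    ct <- ex$contig[1]
    last3ss <- ex$start[nrow(ex)]                # start of final exon
    s_junc <- nearest_a(ct, last3ss + 3L)
    mid <- ex[nrow(ex) - 1L, (start + end) %/% 2L]
    s_far <- nearest_a(ct, mid)
    sites[[gi]] <- data.table(
      gene = sym, contig = ct, pos = c(s_junc, s_far), strand = "+",
      type = "AG", role = c("junction", "far"))
    n <- lr$n_reads
    ej <- stats::runif(n) < lr$p_edit
    ef <- stats::runif(n) < ifelse(ej, lr$p_partner_given_edit,
                                   lr$p_partner_given_unedit)
    p_spl <- ifelse(ej, (1 - lr$coupling) * lr$base_splice, lr$base_splice)
    iso <- ifelse(stats::runif(n) < p_spl, "spliced", "unspliced")
    rd <- sprintf("%s_lr%04d", sym, seq_len(n))
    isoforms[[gi]] <- data.table(read_id = rd, gene = sym, isoform = iso)
    calls[[gi]] <- rbind(
      data.table(read_id = rd, gene = sym, contig = ct, pos = s_junc,
                 strand = "+", type = "AG",
                 state = ifelse(ej, "edited", "unedited")),
      data.table(read_id = rd, gene = sym, contig = ct, pos = s_far,
                 strand = "+", type = "AG",
                 state = ifelse(ef, "edited", "unedited")))
  }
  calls <- rbindlist(calls)
  isoforms <- rbindlist(isoforms)
  calls <- isoforms[, .(read_id, isoform)][calls, on = "read_id"]
  list(calls = calls[], isoforms = isoforms[], sites = rbindlist(sites),
       genes = g[gene %in% use])
}

#' Simulate co-editing contingency tables for site-pair classification
#'
#' Draws one two-site gene per requested archetype: group 1
#' (partner usually edited when the lead site is), group 2
#' (together-or-not-at-all), groups 3/4 (one site edited alone in an
#' appreciable fraction of reads, lead site first or second). Returns
#' per-gene contingency counts in the layout [classify_coedit_groups()]
#' expects.
#'
#' @param cfg A [sim_config()] (only `seed` and `longread$n_reads` used).
#' @param n_per_group Genes per archetype group (default 3).
#' @return `data.table` with `gene`, `group_true`, `n_both`, `n_only1`,
#'   `n_only2`, `n_neither`.
#' @export
simulate_coedit_tables <- function(cfg = sim_config(), n_per_group = 3L) {
  .sim_seed(cfg, "coedit")
  n <- cfg$longread$n_reads
  probs <- list(`1` = c(0.75, 0.10, 0.02, 0.13),
                `2` = c(0.40, 0.02, 0.02, 0.56),
                `3` = c(0.40, 0.18, 0.02, 0.40),
                `4` = c(0.40, 0.02, 0.18, 0.40))
  rows <- list()
  for (grp in names(probs)) for (i in seq_len(n_per_group)) {
    draw <- as.vector(stats::rmultinom(1L, n, probs[[grp]]))
    rows[[length(rows) + 1L]] <- data.table(
      gene = sprintf("g%s_%d", grp, i), group_true = as.integer(grp),
      n_both = draw[1], n_only1 = draw[2], n_only2 = draw[3],
      n_neither = draw[4])
  }
  rbindlist(rows)
}

#' Score catalog recovery against the planted truth
#'
#' @param catalog A site table (e.g. from [build_catalog()] or
#'   [run_hyper_pipeline()]).
#' @param truth A [plant_editome()] table.
#' @param classes Truth classes to score (default: all editing classes).
#' @return `data.table` with per-class `n_planted`, `n_recovered`,
#'   `pct_recovered`.
#' @export
score_recovery <- function(catalog, truth,
                           classes = c("clustered", "isolated", "hyper",
                                       "context_specific", "coding", "SNP",
                                       "SNP_lowqual")) {
  cat_keys <- unique(paste(catalog$contig, catalog$pos))
  t <- as.data.table(truth)[class %in% classes]
  t[, hit := paste(contig, pos) %in% cat_keys]
  t[, .(n_planted = .N, n_recovered = sum(hit),
        pct_recovered = 100 * sum(hit) / .N), by = class]
}

#' Write a complete simulated dataset to disk
#'
#' Materializes a [simulate_genomes()] scenario as the on-disk formats
#' the readers in this package consume: FASTA genomes, GFF3 gene models,
#' BED repeats, a liftover chain, a VCF of genomic variants, and the
#' planted truth as TSV.
#'
#' @param sim Output of [simulate_genomes()].
#' @param truth Output of [plant_editome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(sim, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(genome_a = file.path(dir, "genome_a.fa"),
         genome_b = file.path(dir, "genome_b.fa"),
         genes_a = file.path(dir, "genes_a.gff3"),
         genes_b = file.path(dir, "genes_b.gff3"),
         repeats = file.path(dir, "repeats.bed"),
         chain = file.path(dir, "a_to_b.chain"),
         vcf = file.path(dir, "variants.vcf"),
         truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$genome_a, p["genome_a"])
  write_fasta(sim$genome_b, p["genome_b"])
  write_gff3(sim$genes_a, p["genes_a"])
  write_gff3(sim$genes_b, p["genes_b"])
  write_bed(sim$repeats, p["repeats"])
  write_chain(sim$chain, p["chain"])
  glen <- Biostrings::width(sim$genome_a); names(glen) <- names(sim$genome_a)
  write_vcf(sim$snps[, .(contig, pos, ref, alt, qual, depth)], p["vcf"],
            contig_lengths = glen)
  data.table::fwrite(as.data.table(truth), p["truth"], sep = "\t")
  p
}
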
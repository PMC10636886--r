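# Shared fixtures. Heavy simulations are memoised per test session so
# multiple test files (and acceptance blocks) can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small but complete scenario used by most module tests.
small_cfg <- function(seed = 7L) {
  sim_config(seed = seed, genome = list(length = 200000L),
             editome = list(n_clusters = 12L, n_isolated = 8L, n_hyper = 2L,
                            n_context = 6L, n_coding = 4L),
             snps = list(n_per_contig = 10L))
}

small_scenario <- function() {
  memo("small_scenario", {
    cfg <- small_cfg()
    sim <- simulate_genomes(cfg)
    truth <- plant_editome(sim, cfg)
    list(cfg = cfg, sim = sim, truth = truth)
  })
}

small_counts <- function() {
  memo("small_counts", {
    sc <- small_scenario()
    simulate_counts(sc$sim, sc$truth, sc$cfg)
  })
}

# The default-scale study-conditions run shared by acceptance criteria
# 3 (planted arm) and 4: defaults untouched.
default_run <- function() {
  memo("default_run", {
    cfg <- sim_config(seed = 101L)
    sim <- simulate_genomes(cfg)
    truth <- plant_editome(sim, cfg)
    cs <- simulate_counts(sim, truth, cfg)
    wgs <- simulate_wgs(sim, truth, cfg)
    per_study <- lapply(split(cs$context_map$sample, cs$context_map$study),
                        function(ss) call_candidates(pool_samples(cs$samples[ss])))
    cascade <- run_filter_cascade(per_study, variants = wgs$variants)
    catalog <- build_catalog(pooled = cascade$clustered,
                             rescued = cascade$rescued)
    list(cfg = cfg, sim = sim, truth = truth, counts = cs, wgs = wgs,
         per_study = per_study, cascade = cascade, catalog = catalog)
  })
}

# Brute-force O(n^2) oracles for the +/-20 nt window filters.
oracle_window <- function(sites, window = 20L) {
  n <- nrow(sites)
  same <- integer(n); any_ <- integer(n)
  for (i in seq_len(n)) {
    near <- sites$contig == sites$contig[i] &
      abs(sites$pos - sites$pos[i]) <= window
    any_[i] <- sum(near)
    same[i] <- sum(near & sites$type == sites$type[i])
  }
  list(keep_multi = any_ == same, clustered = same >= 2L)
}

# Brute-force liftover: walk every chain block base by base.
oracle_lift <- function(chain, contig, pos) {
  hits <- list()
  for (i in seq_len(nrow(chain))) {
    b <- chain[i]
    if (b$src_contig != contig || pos < b$src_start || pos > b$src_end) next
    off <- pos - b$src_start
    tp <- if (b$tgt_strand == "+") b$tgt_start0 + off + 1L
          else b$tgt_size - (b$tgt_start0 + off)
    hits[[length(hits) + 1L]] <- data.table::data.table(
      chain_id = b$chain_id, score = b$score, tgt_contig = b$tgt_contig,
      tgt_strand = b$tgt_strand, tgt_pos = tp)
  }
  if (!length(hits)) return(NULL)
  data.table::rbindlist(hits)
}
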
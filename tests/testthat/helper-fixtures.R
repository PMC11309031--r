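# Shared fixtures, all built in code.

# canonical variant data.frame with sensible defaults
variant_df <- function(n = 3, snp_id = sprintf("rs%d", seq_len(n)),
                       chrom = "1", pos_bp = seq_len(n) * 1e6,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9,
                       n_col = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n_col,
             stringsAsFactors = FALSE)
}

make_stats <- function(..., trait = "trait", sampleSize = NA_real_) {
  summaryStats(variant_df(...), trait, sampleSize)
}

# harmonized set straight from aligned effect vectors
hset_from <- function(bx, sx, by, sy, ids = sprintf("rs%d", seq_along(bx))) {
  mrmediate:::.harmonized_set(ids, bx, sx, by, sy)
}

# subset a SummaryStats to a set of snp_ids (keeps order)
subset_stats <- function(x, ids) {
  v <- variants(x)
  summaryStats(v[v$snp_id %in% ids, , drop = FALSE], traitLabel(x),
               sampleSize(x))
}

# one coffee-CAC-scale replicate: the three harmonized sets built from the
# generator's own instrument bookkeeping
preset_replicate <- function(seed, cfg = presetCoffeeCac()) {
  cfg$seed <- seed
  st <- simulateStudy(cfg)
  tr <- st@truth
  ex <- subset_stats(st@exposure, tr$exposureSnps)
  list(
    hxy = harmonizeTables(ex, st@outcome),
    hxm = harmonizeTables(ex, st@mediator),
    hmy = harmonizeTables(subset_stats(st@mediator, tr$mediatorSnps),
                          st@outcome),
    truth = tr)
}

# exposure-outcome harmonized set only, for lighter replicate loops
preset_hxy <- function(seed, cfg = simulationConfig(JMed = 0)) {
  cfg$seed <- seed
  st <- simulateStudy(cfg)
  ex <- subset_stats(st@exposure, st@truth$exposureSnps)
  harmonizeTables(ex, st@outcome)
}
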
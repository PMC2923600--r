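# Shared in-code fixtures: tiny genotype cohorts, a VCF writer, and small
# simulation configs sized for fast tests.

tiny_genotypes <- function() {
  genotype_matrix(
    values = rbind(c(0L, 2L, 1L, 0L),
                   c(1L, NA, 2L, 0L),
                   c(2L, 0L, 0L, NA)),
    snp_meta = data.frame(snp_id = paste0("rs", 1:4),
                          chrom = c("1", "2", "3", "4"),
                          pos = c(100L, 200L, 300L, 400L),
                          ref_allele = c("A", "C", "G", "T"),
                          alt_allele = c("G", "T", "A", "C")),
    sample_ids = c("s1", "s2", "s3")
  )
}

tiny_geo <- function(ids = c("s1", "s2", "s3"),
                     pops = c("north", "north", "south"),
                     lats = c(50, 50, 40), lons = c(5, 5, 15)) {
  geo_table(data.frame(sample_id = ids, population = pops,
                       latitude = lats, longitude = lons))
}

# Deterministic random genotype cohort: every SNP polymorphic, no structure.
random_cohort <- function(n = 20, p = 30, seed = 1, missing_rate = 0) {
  withr::with_seed(seed, {
    v <- matrix(rbinom(n * p, 2L, runif(p, 0.2, 0.8)[rep(1:p, each = n)]),
                n, p)
    if (missing_rate > 0) v[runif(n * p) < missing_rate] <- NA_integer_
    genotype_matrix(
      v,
      data.frame(snp_id = sprintf("snp%03d", 1:p), chrom = "1", pos = 1:p),
      sprintf("ind%03d", 1:n))
  })
}

# Write a minimal VCF 4.2 file; genotypes is SNPs x samples matrix of GT
# strings ("0/0", "0/1", "1/1", "./.").
write_test_vcf <- function(path, chrom, pos, id, ref, alt, gt) {
  samples <- colnames(gt)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(chrom), function(i) {
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Small structured simulation used across modules (16 demes, 10% clinal).
small_sim_config <- function(seed = 1, n_per_deme = 12L, n_clinal = 300L,
                             n_noise = 2700L) {
  sim_config(grid = deme_grid(4L, 4L, n_per_deme = n_per_deme),
             n_clinal_snps = n_clinal, n_noise_snps = n_noise, seed = seed)
}

# One simulation split into a training and an external cohort: same demes,
# same per-deme frequencies, independent genotype draws.
train_external_split <- function(cfg, n_ext_per_deme) {
  sim <- simulate_cohort(cfg)
  pops <- sim$geo$population
  ext_ids <- unlist(lapply(split(sim$geo$sample_id, pops),
                           head, n_ext_per_deme), use.names = FALSE)
  tr_ids <- setdiff(sim$geo$sample_id, ext_ids)
  list(train_g = subset_genotypes(sim$genotypes, samples = tr_ids),
       train_geo = sim$geo[sim$geo$sample_id %in% tr_ids, ],
       test_g = subset_genotypes(sim$genotypes, samples = ext_ids),
       test_geo = sim$geo[sim$geo$sample_id %in% ext_ids, ],
       truth = sim$truth)
}

# Cohort of two populations with identical genotypes within each population.
two_pop_identical_cohort <- function(n_per_pop = 12L, p = 40L, seed = 3) {
  withr::with_seed(seed, {
    a <- rbinom(p, 2L, 0.5)
    b <- rbinom(p, 2L, 0.5)
    while (all(a == b)) b <- rbinom(p, 2L, 0.5)
    v <- rbind(matrix(a, n_per_pop, p, byrow = TRUE),
               matrix(b, n_per_pop, p, byrow = TRUE))
    ids <- c(sprintf("A%02d", 1:n_per_pop), sprintf("B%02d", 1:n_per_pop))
    g <- genotype_matrix(
      v, data.frame(snp_id = sprintf("m%03d", 1:p), chrom = "1", pos = 1:p),
      ids)
    geo <- geo_table(data.frame(
      sample_id = ids,
      population = rep(c("popA", "popB"), each = n_per_pop),
      latitude = rep(c(52, 41), each = n_per_pop),
      longitude = rep(c(0, 20), each = n_per_pop)))
    list(genotypes = g, geo = geo)
  })
}
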
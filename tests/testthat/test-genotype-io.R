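test_that("genotype_matrix enforces its invariants", {
  g <- tiny_genotypes()
  expect_s3_class(g, "genotype_matrix")
  expect_identical(dim(g), c(3L, 4L))

  bad <- tiny_genotypes()
  bad$values[1, 1] <- 3L
  expect_error(validate_genotype_matrix(bad), "not 0, 1, 2")
  expect_error(
    genotype_matrix(matrix(0L, 2, 2),
                    data.frame(snp_id = c("a", "a"), chrom = "1", pos = 1:2),
                    c("x", "y")),
    "duplicate SNP")
  expect_error(
    genotype_matrix(matrix(0L, 2, 1),
                    data.frame(snp_id = "a", chrom = "1", pos = 1),
                    c("x", "x")),
    "duplicate sample")
  expect_error(
    genotype_matrix(matrix(0L, 2, 1),
                    data.frame(snp_id = "a", chrom = "1", pos = 0L),
                    c("x", "y")),
    "1-based")
})

test_that("tsv reader transcribes counts and NA directly", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1\trs2",
               "s1\t0\t2",
               "s2\t1\tNA",
               "s3\t2\t0"), tf)
  g <- read_genotypes(tf, format = "tsv")
  expect_identical(g$sample_ids, c("s1", "s2", "s3"))
  expect_identical(g$snp_meta$snp_id, c("rs1", "rs2"))
  expect_identical(g$values[2, 2], NA_integer_)
  expect_identical(sum(is.na(g$values)), 1L)
  expect_identical(g$values[, 1], c(s1 = 0L, s2 = 1L, s3 = 2L))
})

test_that("VCF reader skips non-autosomes and multi-allelics, maps ./. to NA", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1"),
              c("0/1", "./.", "0/0"),
              c("0/0", "0/0", "0/1"),   # chrX record
              c("1/1", "0/1", "0/0"))   # multi-allelic
  colnames(gt) <- c("s1", "s2", "s3")
  write_test_vcf(tf, chrom = c("1", "2", "X", "3"), pos = c(100, 200, 300, 400),
                 id = c("rs1", "rs2", "rsX", "rsM"),
                 ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C,G"),
                 gt = gt)
  expect_message(g <- read_genotypes(tf), "skipped 2")
  expect_identical(g$snp_meta$snp_id, c("rs1", "rs2"))
  expect_false("rsX" %in% g$snp_meta$snp_id)
  expect_identical(g$values["s2", "rs2"], NA_integer_)
  expect_identical(g$values["s1", "rs1"], 0L)
  expect_identical(g$values["s3", "rs1"], 2L)
})

test_that("VCF and tsv readers agree on the same cohort", {
  vf <- withr::local_tempfile(fileext = ".vcf")
  tfv <- withr::local_tempfile(fileext = ".tsv")
  g0 <- random_cohort(n = 6, p = 8, seed = 4, missing_rate = 0.1)
  gt <- t(apply(g0$values, 1, function(r) {
    c("0/0", "0/1", "1/1")[r + 1]
  }))
  gt[is.na(g0$values)] <- "./."
  gt <- t(gt)  # SNPs x samples
  colnames(gt) <- g0$sample_ids
  write_test_vcf(vf, chrom = g0$snp_meta$chrom, pos = g0$snp_meta$pos,
                 id = g0$snp_meta$snp_id,
                 ref = rep("A", 8), alt = rep("G", 8), gt = gt)
  write_genotypes_tsv(g0, tfv)
  g_vcf <- read_genotypes(vf)
  g_tsv <- read_genotypes(tfv)
  expect_identical(unname(g_vcf$values), unname(g_tsv$values))
  expect_identical(g_vcf$snp_meta$snp_id, g_tsv$snp_meta$snp_id)
  expect_identical(g_vcf$sample_ids, g_tsv$sample_ids)
})

test_that("filters apply in SNP -> sample -> population order and are idempotent", {
  # SNP missing in 11/100 samples at a 10% bound is removed
  withr::with_seed(5, {
    v <- matrix(rbinom(100 * 3, 2, 0.5), 100, 3)
    v[1:11, 1] <- NA
    v[1:5, 2] <- NA
  })
  g <- genotype_matrix(v, data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                                     pos = 1:3),
                       sprintf("s%03d", 1:100))
  geo <- geo_table(data.frame(sample_id = g$sample_ids, population = "pop",
                              latitude = 50, longitude = 5))
  f <- filter_genotypes(g, geo, snp_missing_max = 0.10,
                        sample_missing_max = 1, min_pop_size = 0)
  expect_identical(f$snp_meta$snp_id, c("b", "c"))

  # all-complete matrix with no population rule is untouched
  g2 <- random_cohort(10, 5, seed = 6)
  f2 <- filter_genotypes(g2, NULL, min_pop_size = 0)
  expect_identical(f2$values, g2$values)

  # a 39-member population is removed entirely at min_pop_size = 40
  withr::with_seed(7, v3 <- matrix(rbinom(79 * 4, 2, 0.5), 79, 4))
  ids <- sprintf("x%03d", 1:79)
  g3 <- genotype_matrix(v3, data.frame(snp_id = paste0("s", 1:4), chrom = "1",
                                       pos = 1:4), ids)
  geo3 <- geo_table(data.frame(
    sample_id = ids,
    population = rep(c("big", "small"), c(40, 39)),
    latitude = rep(c(50, 40), c(40, 39)),
    longitude = rep(c(5, 15), c(40, 39))))
  f3 <- filter_genotypes(g3, geo3, min_pop_size = 40)
  expect_identical(length(f3$sample_ids), 40L)
  expect_identical(f3$sample_ids, sprintf("x%03d", 1:40))

  # idempotence: filtering a filtered cohort changes nothing
  ff <- filter_genotypes(f3, geo3, min_pop_size = 40)
  expect_identical(ff$values, f3$values)
  expect_identical(ff$sample_ids, f3$sample_ids)

  # empty survivor set is an explicit error
  expect_error(filter_genotypes(g3, geo3, min_pop_size = 100),
               "no data survives")
})

test_that("encode_center mean-imputes, centers exactly, keeps monomorphic columns", {
  g <- genotype_matrix(
    cbind(c(0L, 2L, NA), c(2L, 2L, 2L)),
    data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2),
    c("s1", "s2", "s3"))
  x <- encode_center(g)
  expect_equal(x$values[, 1], c(-1, 1, 0), ignore_attr = TRUE)
  expect_identical(x$values[3, 1], 0)          # imputed cell exactly zero
  expect_equal(x$values[, 2], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(x$column_means, c(1, 2), ignore_attr = TRUE)

  # zero column sums within tolerance on random missing-data inputs
  for (seed in 1:3) {
    gr <- random_cohort(15, 25, seed = seed, missing_rate = 0.15)
    xr <- encode_center(gr)
    expect_lt(max(abs(colSums(xr$values))), 1e-9 * nrow(xr$values))
    expect_true(all(xr$values[is.na(gr$values)] == 0))
  }

  gna <- genotype_matrix(cbind(c(NA, NA, NA), c(0L, 1L, 2L)),
                         data.frame(snp_id = c("allmiss", "ok"), chrom = "1",
                                    pos = 1:2), c("s1", "s2", "s3"))
  expect_error(encode_center(gna), "allmiss")
})

test_that("panel files round-trip exactly", {
  pan <- snp_panel(
    tibble::tibble(rank = 1:3, snp_id = c("rs9", "rs2", "rs5"),
                   chrom = c("1", "2", "7"), pos = c(11L, 22L, NA),
                   score = c(0.51234567891234, 0.3, 0.1)),
    pool_size = 10L, target_size = 3L, r2_threshold = 0.8, k = 2L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_panel(pan, tf)
  back <- read_panel(tf)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(pan))
  expect_identical(attr(back, "provenance"), attr(pan, "provenance"))

  # empty panel: header-only body
  emp <- snp_panel(tibble::tibble(rank = integer(), snp_id = character(),
                                  chrom = character(), pos = integer(),
                                  score = double()),
                   pool_size = 10L, target_size = 0L, r2_threshold = 0.8,
                   k = 2L)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_panel(emp, tf2)
  lines <- readLines(tf2)
  expect_identical(sum(!grepl("^#", lines)), 1L)
  expect_identical(nrow(read_panel(tf2)), 0L)

  # unknown columns are a parse error
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# pool_size: 1", "# target_size: 1", "# r2_threshold: 1",
               "# k: 2", "rank\tsnp_id\tbogus", "1\trs1\tx"), tf3)
  expect_error(read_panel(tf3), "unknown panel columns")
})

test_that("a 500-SNP panel writes 500 data rows", {
  ids <- sprintf("rs%04d", 1:500)
  pan <- snp_panel(tibble::tibble(rank = 1:500, snp_id = ids, chrom = "1",
                                  pos = 1:500, score = seq(1, 0.5, length.out = 500)),
                   pool_size = 5000L, target_size = 500L, r2_threshold = 0.8,
                   k = 2L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_panel(pan, tf)
  lines <- readLines(tf)
  expect_identical(sum(!grepl("^#", lines)) - 1L, 500L)
})

test_that("allele harmonization flips swapped alleles and drops ambiguous SNPs", {
  train_meta <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    chrom = "1", pos = 1:4,
    ref_allele = c("A", "C", "A", "G"),
    alt_allele = c("G", "T", "T", "A"))
  test_g <- genotype_matrix(
    cbind(a = c(0L, 2L), b = c(2L, 0L), c = c(1L, 1L), d = c(0L, 1L)),
    data.frame(snp_id = c("a", "b", "c", "d"), chrom = "1", pos = 1:4,
               ref_allele = c("G", "C", "T", "G"),   # a: ref/alt swapped
               alt_allele = c("A", "T", "A", "A")),  # c: A/T ambiguous+swapped
    c("t1", "t2"))
  expect_message(h <- harmonize_alleles(test_g, train_meta), "dropped 1")
  expect_setequal(h$snp_meta$snp_id, c("a", "b", "d"))
  expect_identical(unname(h$values[, "a"]), c(2L, 0L))  # flipped
  expect_identical(unname(h$values[, "b"]), c(2L, 0L))  # unchanged
})

test_that("orient_minor makes every counted-allele frequency at most 0.5", {
  g <- random_cohort(30, 20, seed = 9)
  om <- orient_minor(g)
  expect_true(all(colMeans(om$values, na.rm = TRUE) / 2 <= 0.5 + 1e-12))
  # flipping is an affine map: centered encodings differ only by column sign
  x1 <- encode_center(g)$values
  x2 <- encode_center(om)$values
  expect_equal(abs(x1), abs(x2), tolerance = 1e-12, ignore_attr = TRUE)
})
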
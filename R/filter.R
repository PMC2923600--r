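#' Missingness and population-size filters
#'
#' Standard cohort QC applied in a fixed order: (1) drop SNPs whose missing
#' fraction exceeds `snp_missing_max`; (2) drop samples whose missing fraction
#' (over the surviving SNPs) exceeds `sample_missing_max`; (3) drop all
#' members of populations left with fewer than `min_pop_size` samples. The
#' relative order of surviving rows and columns is preserved, so the filter is
#' idempotent.
#'
#' @param g A [genotype_matrix()].
#' @param geo A [geo_table()] covering the samples of `g` (used for the
#'   population-size rule; samples without a geo record count as their own
#'   singleton population). May be `NULL` when `min_pop_size = 0`.
#' @param snp_missing_max Maximum tolerated per-SNP missing fraction
#'   (default 0.10).
#' @param sample_missing_max Maximum tolerated per-sample missing fraction
#'   (default 0.10).
#' @param min_pop_size Minimum surviving population size (default 40, the
#'   cohort convention this pipeline targets).
#' @return A filtered `genotype_matrix`.
#' @export
filter_genotypes <- function(g, geo = NULL, snp_missing_max = 0.10,
                             sample_missing_max = 0.10, min_pop_size = 40L) {
  stopifnot(snp_missing_max >= 0, snp_missing_max <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1,
            min_pop_size >= 0)
  v <- g$values
  snp_miss <- colMeans(is.na(v))
  keep_snp <- snp_miss <= snp_missing_max
  v <- v[, keep_snp, drop = FALSE]

  samp_miss <- if (ncol(v) > 0) rowMeans(is.na(v)) else rep(0, nrow(v))
  keep_samp <- samp_miss <= sample_missing_max
  ids <- g$sample_ids[keep_samp]

  if (min_pop_size > 0) {
    if (is.null(geo)) abort("`geo` is required when min_pop_size > 0.")
    geo <- geo_table(geo)
    pop <- geo$population[match(ids, geo$sample_id)]
    pop[is.na(pop)] <- paste0(".nogeo.", ids[is.na(pop)])
    sizes <- table(pop)
    keep_pop <- pop %in% names(sizes)[sizes >= min_pop_size]
    ids <- ids[keep_pop]
  }
  if (length(ids) == 0 || sum(keep_snp) == 0) {
    abort("no data survives filters.")
  }
  subset_genotypes(g, samples = ids, snps = which(keep_snp))
}

#' Mean-impute and column-center a genotype matrix
#'
#' Missing calls are replaced by the per-SNP mean of the non-missing allele
#' counts, then each column is centered on that mean. An imputed cell is
#' therefore exactly zero and contributes nothing to any inner product — the
#' standard treatment for PCA of genotypes. Monomorphic SNPs become all-zero
#' columns and are retained.
#'
#' @param g A [genotype_matrix()].
#' @return An object of class `centered_matrix`: list with `values` (dense
#'   numeric matrix, zero column means), `column_means` (per-SNP means of the
#'   non-missing entries on the 0–2 scale), `snp_ids`, `sample_ids`.
#' @export
encode_center <- function(g) {
  v <- g$values
  storage.mode(v) <- "double"
  nn <- colSums(!is.na(v))
  if (any(nn == 0)) {
    abort(paste0("SNP(s) with all entries missing: ",
                 paste(g$snp_meta$snp_id[nn == 0], collapse = ", ")))
  }
  mu <- colMeans(v, na.rm = TRUE)
  x <- v - rep(mu, each = nrow(v))
  x[is.na(x)] <- 0
  structure(
    list(values = x, column_means = mu,
         snp_ids = g$snp_meta$snp_id, sample_ids = g$sample_ids),
    class = "centered_matrix"
  )
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat(sprintf("<centered_matrix> %d samples x %d SNPs\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Re-orient columns so the counted allele is the minor allele
#'
#' Flips every column whose counted-allele frequency exceeds 0.5 (entry
#' becomes `2 - entry`) and swaps ref/alt in the metadata. Downstream PC
#' geometry is unaffected (the flip is affine and removed by centering), but a
#' fixed orientation makes panels portable across cohorts.
#'
#' @param g A [genotype_matrix()].
#' @return A `genotype_matrix` with every counted-allele frequency at most 0.5.
#' @export
orient_minor <- function(g) {
  v <- g$values
  af <- colMeans(v, na.rm = TRUE) / 2
  flip <- which(!is.na(af) & af > 0.5)
  if (length(flip)) {
    v[, flip] <- 2L - v[, flip]
    meta <- g$snp_meta
    tmp <- meta$ref_allele[flip]
    meta$ref_allele[flip] <- meta$alt_allele[flip]
    meta$alt_allele[flip] <- tmp
    g <- genotype_matrix(v, meta, g$sample_ids)
  }
  g
}

strand_ambiguous <- function(ref, alt) {
  p <- paste0(toupper(ref), toupper(alt))
  p %in% c("AT", "TA", "CG", "GC")
}

revcomp_allele <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

#' Harmonize a test cohort to a training cohort's allele encoding
#'
#' Matches test SNPs to training SNPs by id and re-orients the counted allele
#' so both cohorts count the same allele: a ref/alt swap flips the counts
#' (`2 - x`), a strand flip relabels alleles by reverse complement, and SNPs
#' whose orientation cannot be resolved — strand-ambiguous A/T or C/G pairs
#' that disagree, or incompatible allele pairs — are dropped with a message.
#' SNPs with missing allele metadata on either side are kept as-is.
#'
#' @param test_g Test-cohort [genotype_matrix()].
#' @param train_meta `snp_meta` tibble of the training cohort.
#' @return A `genotype_matrix` restricted to resolvable shared SNPs, counts on
#'   the training orientation.
#' @export
harmonize_alleles <- function(test_g, train_meta) {
  shared <- intersect(train_meta$snp_id, test_g$snp_meta$snp_id)
  if (length(shared) == 0) abort("no shared SNPs between test data and panel.")
  te <- test_g$snp_meta[match(shared, test_g$snp_meta$snp_id), ]
  tr <- train_meta[match(shared, train_meta$snp_id), ]
  up <- function(x) toupper(ifelse(is.na(x), "", x))
  r1 <- up(tr$ref_allele); a1 <- up(tr$alt_allele)
  r2 <- up(te$ref_allele); a2 <- up(te$alt_allele)
  no_meta <- r1 == "" | a1 == "" | r2 == "" | a2 == ""
  same  <- r1 == r2 & a1 == a2
  swap  <- r1 == a2 & a1 == r2
  flip_same <- r1 == up(revcomp_allele(r2)) & a1 == up(revcomp_allele(a2))
  flip_swap <- r1 == up(revcomp_allele(a2)) & a1 == up(revcomp_allele(r2))
  ambig <- strand_ambiguous(r1, a1) & !no_meta
  keep <- no_meta | ((same | swap | flip_same | flip_swap) & !ambig)
  # strand-ambiguous SNPs are kept only when the direct match is unambiguous
  keep[ambig & same & !swap] <- TRUE
  do_swap <- !no_meta & keep & !same & !flip_same & (swap | flip_swap)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf(
      "harmonize_alleles: dropped %d SNP(s) with unresolvable allele orientation.",
      n_drop))
  }
  out <- subset_genotypes(test_g, snps = shared[keep])
  if (any(do_swap)) {
    sw <- shared[keep][do_swap[keep]]
    j <- match(sw, out$snp_meta$snp_id)
    out$values[, j] <- 2L - out$values[, j]
    tmp <- out$snp_meta$ref_allele[j]
    out$snp_meta$ref_allele[j] <- out$snp_meta$alt_allele[j]
    out$snp_meta$alt_allele[j] <- tmp
    out <- validate_genotype_matrix(out)
  }
  out
}
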
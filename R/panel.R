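#' PCA-informative-marker (PCAIM) leverage scores
#'
#' Scores every SNP by its leverage on the retained principal-component
#' subspace: the sum of its squared loadings over the top-`k` right singular
#' vectors, `score_j = sum_i v_ij^2`. Because the loading columns are
#' orthonormal, the scores of all SNPs sum to `k`. SNPs that score highly are
#' the PCA-informative markers (PCAIMs): they carry the population-structure
#' signal the top components capture. An optional variant weights each
#' component by its squared singular value for sensitivity analyses.
#'
#' @param m A `pca_fit`.
#' @param weight_by_variance Weight component `i` by `d_i^2` (default `FALSE`,
#'   the plain leverage score).
#' @return A tibble with columns `snp_id`, `score`, `rank` (1-based by
#'   descending score, ties broken by SNP id).
#' @export
pcaim_scores <- function(m, weight_by_variance = FALSE) {
  stopifnot(inherits(m, "pca_fit"))
  w <- if (weight_by_variance) m$d^2 else rep(1, m$k)
  score <- as.vector(m$v^2 %*% w)
  tb <- tibble(snp_id = m$snp_ids, score = score)
  tb <- tb[order(-tb$score, tb$snp_id), ]
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Top-scoring SNP pool
#'
#' The candidate pool for panel construction: the `pool_size` top-ranked SNPs
#' of a score table, in rank order.
#'
#' @param scores A score table from [pcaim_scores()].
#' @param pool_size Number of SNPs to keep.
#' @return Character vector of SNP ids, highest score first.
#' @export
build_pool <- function(scores, pool_size) {
  pool_size <- as.integer(pool_size)
  if (pool_size < 1L || pool_size > nrow(scores)) {
    abort(sprintf("pool_size must be in [1, %d].", nrow(scores)))
  }
  scores$snp_id[order(scores$rank)][seq_len(pool_size)]
}

#' SNP panel object
#'
#' A panel is an ordered SNP subset (descending score) with the parameters
#' that produced it. It behaves as a tibble with columns `rank`, `snp_id`,
#' `chrom`, `pos`, `score`; the provenance (pool size, target size, pairwise
#' r-squared threshold, number of components) is kept as an attribute.
#'
#' @param x Data frame with columns `rank`, `snp_id`, `chrom`, `pos`, `score`.
#' @param pool_size,target_size,r2_threshold,k Selection parameters.
#' @return An object of classes `snp_panel` and `tbl_df`.
#' @export
snp_panel <- function(x, pool_size, target_size, r2_threshold, k) {
  x <- as_tibble(x)[, c("rank", "snp_id", "chrom", "pos", "score")]
  x$rank <- as.integer(x$rank)
  x$pos <- as.integer(x$pos)
  x$chrom <- as.character(x$chrom)
  structure(x,
            provenance = list(pool_size = as.integer(pool_size),
                              target_size = as.integer(target_size),
                              r2_threshold = as.numeric(r2_threshold),
                              k = as.integer(k)),
            class = c("snp_panel", class(as_tibble(x))))
}

#' @export
print.snp_panel <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("<snp_panel> %d SNPs (target %d, pool %d, r2 <= %g, k = %d)\n",
              nrow(x), pr$target_size, pr$pool_size, pr$r2_threshold, pr$k))
  NextMethod()
}

# Standardize centered columns to unit norm so crossprod() gives Pearson
# correlations directly; zero-variance columns get norm 0 and correlate with
# nothing (r defined as 0).
standardize_cols <- function(xv) {
  nrm <- sqrt(colSums(xv^2))
  nz <- nrm > 0
  xv[, nz] <- sweep(xv[, nz, drop = FALSE], 2, nrm[nz], "/")
  xv[, !nz] <- 0
  xv
}

#' Greedy redundancy pruning of a scored SNP pool
#'
#' Walks the pool in score order and accepts a SNP only if its squared Pearson
#' correlation (computed on the training genotypes) with every
#' already-accepted SNP is at most `r2_threshold`; stops once `target_size`
#' SNPs are accepted or the pool is exhausted. Monomorphic (zero-variance)
#' columns have undefined correlation and are treated as uncorrelated.
#'
#' @param pool Character vector of SNP ids ordered by descending score.
#' @param x The training `centered_matrix` (source of the genotype columns).
#' @param r2_threshold Pairwise squared-correlation bound, in (0, 1]
#'   (default 0.8).
#' @param target_size Number of SNPs wanted.
#' @param scores Optional score table ([pcaim_scores()]) used to annotate the
#'   panel; scores default to `NA` when absent.
#' @param snp_meta Optional SNP metadata (`snp_id`, `chrom`, `pos`) for
#'   annotation.
#' @return A [snp_panel()]. If the pool is exhausted before `target_size`
#'   SNPs pass the redundancy bound, the shorter panel is returned with a
#'   warning.
#' @export
prune_redundant <- function(pool, x, r2_threshold = 0.8, target_size,
                            scores = NULL, snp_meta = NULL) {
  stopifnot(inherits(x, "centered_matrix"))
  target_size <- as.integer(target_size)
  if (target_size > length(pool)) {
    abort(sprintf("target_size (%d) exceeds pool size (%d).",
                  target_size, length(pool)))
  }
  if (r2_threshold <= 0 || r2_threshold > 1) {
    abort("r2_threshold must lie in (0, 1].")
  }
  idx <- match(pool, x$snp_ids)
  if (anyNA(idx)) abort("pool contains SNPs absent from the centered matrix.")
  z <- standardize_cols(x$values[, idx, drop = FALSE])
  n <- nrow(z)
  acc <- integer(0)
  A <- matrix(0, n, target_size)  # accepted standardized columns
  for (j in seq_along(pool)) {
    if (length(acc) == 0L) {
      ok <- TRUE
    } else {
      r <- crossprod(A[, seq_along(acc), drop = FALSE], z[, j])
      ok <- all(r^2 <= r2_threshold + 1e-12)
    }
    if (ok) {
      acc <- c(acc, j)
      A[, length(acc)] <- z[, j]
      if (length(acc) == target_size) break
    }
  }
  if (length(acc) < target_size) {
    warn(sprintf("pool exhausted: %d of %d requested SNPs pass r2 <= %g.",
                 length(acc), target_size, r2_threshold))
  }
  ids <- pool[acc]
  sc <- rep(NA_real_, length(ids))
  if (!is.null(scores)) sc <- scores$score[match(ids, scores$snp_id)]
  chrom <- rep(NA_character_, length(ids))
  pos <- rep(NA_integer_, length(ids))
  if (!is.null(snp_meta)) {
    mi <- match(ids, snp_meta$snp_id)
    chrom <- snp_meta$chrom[mi]
    pos <- snp_meta$pos[mi]
  }
  snp_panel(tibble(rank = seq_along(ids), snp_id = ids, chrom = chrom,
                   pos = pos, score = sc),
            pool_size = length(pool), target_size = target_size,
            r2_threshold = r2_threshold, k = NA_integer_)
}

#' Build nested PCAIM panels from a genotype cohort
#'
#' The full selection pipeline: encode and center the cohort, fit the top-`k`
#' PCA, compute leverage scores, keep the `pool_size` top-scoring SNPs, prune
#' redundancy once down to the largest requested size, and cut the smaller
#' panels as prefixes — so panels of different sizes are nested.
#'
#' @param g Training [genotype_matrix()].
#' @param sizes Integer vector of panel sizes, ascending (default
#'   `c(500, 800, 1000)`).
#' @param pool_size Candidate pool size (default 5000).
#' @param r2_threshold Pairwise squared-correlation bound (default 0.8).
#' @param k Number of principal components scored against (default 2).
#' @param scale_freq Passed to [fit_pca()].
#' @param weight_by_variance Passed to [pcaim_scores()].
#' @return A named list of [snp_panel()] objects ("p500", "p800", ...), plus
#'   attributes `scores` (the full score table) and `pca` (the fitted model).
#' @export
build_panels <- function(g, sizes = c(500L, 800L, 1000L), pool_size = 5000L,
                         r2_threshold = 0.8, k = 2L, scale_freq = FALSE,
                         weight_by_variance = FALSE) {
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes)) abort("`sizes` must be ascending.")
  x <- encode_center(g)
  pool_size <- min(as.integer(pool_size), ncol(x$values))
  m <- fit_pca(x, k = k, scale_freq = scale_freq)
  scores <- pcaim_scores(m, weight_by_variance = weight_by_variance)
  pool <- build_pool(scores, pool_size)
  big <- prune_redundant(pool, x, r2_threshold = r2_threshold,
                         target_size = min(max(sizes), length(pool)),
                         scores = scores, snp_meta = g$snp_meta)
  panels <- lapply(sizes, function(s) {
    cut <- big[seq_len(min(s, nrow(big))), , drop = FALSE]
    snp_panel(cut, pool_size = pool_size, target_size = s,
              r2_threshold = r2_threshold, k = k)
  })
  names(panels) <- paste0("p", sizes)
  attr(panels, "scores") <- scores
  attr(panels, "pca") <- m
  panels
}
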
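#' Fit a truncated principal-component decomposition of a centered genotype
#' matrix
#'
#' Computes the top-`k` singular value decomposition `X = U D V'` of the
#' centered matrix exactly, via a symmetric eigendecomposition of the Gram
#' matrix on the smaller side (`X X'` when there are fewer samples than SNPs,
#' `X' X` otherwise), which is fast for the tall-thin and short-wide shapes
#' genotype cohorts take. Component signs are canonicalized so that the
#' largest-magnitude loading of each component is positive; nearest-neighbor
#' geometry in score space is unaffected by this choice.
#'
#' Columns may optionally be rescaled by an estimate of the allele-frequency
#' standard deviation `sqrt(p(1-p))` before decomposition
#' (`scale_freq = TRUE`); the default leaves columns unscaled.
#'
#' @param x A `centered_matrix` from [encode_center()].
#' @param k Number of components to retain (default 2, the two components that
#'   carry the latitude/longitude signal in European cohorts).
#' @param scale_freq Scale each column by `1/sqrt(p(1-p))` (with `p` the
#'   allele frequency implied by the column mean) before decomposition.
#' @return An object of class `pca_fit`: `k`, `v` (SNPs x k orthonormal
#'   loadings), `d` (singular values, non-increasing), `column_means`,
#'   `scores` (samples x k, equal to `U D`), `snp_ids`, `sample_ids`,
#'   `scale_freq`, and `col_scale` (the per-SNP scale factors applied, all 1
#'   when unscaled).
#' @export
fit_pca <- function(x, k = 2L, scale_freq = FALSE) {
  stopifnot(inherits(x, "centered_matrix"))
  n <- nrow(x$values); p <- ncol(x$values)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p)) {
    abort(sprintf("k must be in [1, min(n_samples - 1, n_snps)] = [1, %d]; got %d.",
                  min(n - 1L, p), k))
  }
  xv <- x$values
  col_scale <- rep(1, p)
  if (scale_freq) {
    pf <- pmin(pmax(x$column_means / 2, 1e-6), 1 - 1e-6)
    col_scale <- 1 / sqrt(pf * (1 - pf))
    xv <- sweep(xv, 2, col_scale, "*")
  }
  f <- svd_truncated(xv, k)
  structure(
    list(k = k, v = f$v, d = f$d, column_means = x$column_means,
         scores = f$u %*% diag(f$d, k, k),
         snp_ids = x$snp_ids, sample_ids = x$sample_ids,
         scale_freq = scale_freq, col_scale = col_scale),
    class = "pca_fit"
  )
}

# Exact top-k SVD via the smaller-side Gram matrix; falls back to base::svd
# when the Gram route is numerically degenerate (near-zero singular values).
svd_truncated <- function(xv, k) {
  n <- nrow(xv); p <- ncol(xv)
  if (n <= p) {
    e <- eigen(tcrossprod(xv), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    u <- e$vectors[, seq_len(k), drop = FALSE]
    ok <- d > max(d[1], 1) * 1e-6
    v <- matrix(0, p, k)
    if (any(ok)) {
      v[, ok] <- crossprod(xv, u[, ok, drop = FALSE]) %*%
        diag(1 / d[ok], sum(ok), sum(ok))
    }
    if (!all(ok)) {
      s <- svd(xv, nu = k, nv = k)
      return(canonicalize_signs(list(u = s$u, d = s$d[seq_len(k)], v = s$v)))
    }
  } else {
    e <- eigen(crossprod(xv), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    v <- e$vectors[, seq_len(k), drop = FALSE]
    ok <- d > max(d[1], 1) * 1e-6
    u <- matrix(0, n, k)
    if (any(ok)) {
      u[, ok] <- xv %*% v[, ok, drop = FALSE] %*%
        diag(1 / d[ok], sum(ok), sum(ok))
    }
    if (!all(ok)) {
      s <- svd(xv, nu = k, nv = k)
      return(canonicalize_signs(list(u = s$u, d = s$d[seq_len(k)], v = s$v)))
    }
  }
  canonicalize_signs(list(u = u, d = d, v = v))
}

canonicalize_signs <- function(f) {
  for (j in seq_len(ncol(f$v))) {
    i <- which.max(abs(f$v[, j]))
    if (f$v[i, j] < 0) {
      f$v[, j] <- -f$v[, j]
      f$u[, j] <- -f$u[, j]
    }
  }
  f
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> k = %d over %d SNPs, %d training samples\n",
              x$k, length(x$snp_ids), length(x$sample_ids)))
  cat("singular values:", format(x$d, digits = 4), "\n")
  invisible(x)
}

#' Project samples into the fitted principal-component space
#'
#' Genotypes are matched to the model's SNPs by id, mean-imputed and centered
#' using the *training* column means (never the test cohort's own means), then
#' multiplied by the retained loadings. Model SNPs absent from `g` contribute
#' zero, exactly as a training-mean-imputed call would; if fewer than
#' `min_overlap` of the model's SNPs are present the panel is unusable and an
#' error is raised.
#'
#' @param object A `pca_fit`.
#' @param g A [genotype_matrix()] of samples to project.
#' @param min_overlap Minimum fraction of model SNPs that must be present
#'   (default 0.5).
#' @return A numeric matrix (samples x k) of PC scores, rownames = sample ids.
#' @export
project_pca <- function(object, g, min_overlap = 0.5) {
  stopifnot(inherits(object, "pca_fit"), inherits(g, "genotype_matrix"))
  idx <- match(object$snp_ids, g$snp_meta$snp_id)
  present <- !is.na(idx)
  if (mean(present) < min_overlap) {
    abort(sprintf(
      "only %d of %d model SNPs present in the data (< %.0f%%); panel unusable.",
      sum(present), length(idx), 100 * min_overlap))
  }
  v <- g$values[, idx[present], drop = FALSE]
  storage.mode(v) <- "double"
  mu <- object$column_means[present]
  xc <- sweep(v, 2, mu, "-")
  xc[is.na(xc)] <- 0
  if (object$scale_freq) {
    xc <- sweep(xc, 2, object$col_scale[present], "*")
  }
  s <- xc %*% object$v[present, , drop = FALSE]
  rownames(s) <- g$sample_ids
  colnames(s) <- paste0("PC", seq_len(object$k))
  s
}

#' Write a fitted PCA model as a directory of tsv files
#'
#' Emits `means.tsv` (snp_id, column_mean, col_scale), `vectors.tsv` (snp_id +
#' one column per loading vector), `singular_values.tsv`, and `scores.tsv`
#' (sample_id + PC columns) for audit.
#'
#' @param object A `pca_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pca <- function(object, dir) {
  stopifnot(inherits(object, "pca_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pcs <- paste0("PC", seq_len(object$k))
  readr::write_tsv(tibble(snp_id = object$snp_ids,
                          column_mean = object$column_means,
                          col_scale = object$col_scale),
                   file.path(dir, "means.tsv"))
  vt <- as_tibble(object$v, .name_repair = ~pcs)
  readr::write_tsv(dplyr::bind_cols(tibble(snp_id = object$snp_ids), vt),
                   file.path(dir, "vectors.tsv"))
  readr::write_tsv(tibble(component = pcs, singular_value = object$d),
                   file.path(dir, "singular_values.tsv"))
  st <- as_tibble(object$scores, .name_repair = ~pcs)
  readr::write_tsv(dplyr::bind_cols(tibble(sample_id = object$sample_ids), st),
                   file.path(dir, "scores.tsv"))
  invisible(dir)
}
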
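#' Nearest-neighbor prediction of geographic coordinates in PC space
#'
#' For each test sample, finds the `k_neighbors` training samples closest in
#' Euclidean distance in principal-component space (ties broken by training
#' sample id) and predicts its coordinates as the average of the neighbors'
#' latitudes and longitudes. Unweighted averaging is the default; an
#' inverse-distance-power weighting is available (neither scheme showed a
#' consistent advantage in practice, so the simple mean is the default).
#'
#' @param train_scores Numeric matrix (training samples x components) with
#'   rownames set to sample ids, e.g. the `scores` of a `pca_fit` or the
#'   output of [project_pca()].
#' @param train_geo A [geo_table()] covering every training sample.
#' @param test_scores Numeric matrix (test samples x components), rownames =
#'   sample ids.
#' @param k_neighbors Number of neighbors to average (default 10). If the
#'   training set is smaller, all training samples are used with a warning.
#' @param weight_power Exponent `a` for inverse-distance weights
#'   `1/(d^a + eps)`; `0` (default) is the unweighted mean.
#' @return A tibble with one row per test sample: `sample_id`,
#'   `pred_latitude`, `pred_longitude`, and list-columns `neighbor_ids` and
#'   `neighbor_distances` (distances non-decreasing).
#' @export
knn_predict <- function(train_scores, train_geo, test_scores,
                        k_neighbors = 10L, weight_power = 0) {
  train_scores <- as.matrix(train_scores)
  test_scores <- as.matrix(test_scores)
  if (nrow(train_scores) == 0) abort("empty training set.")
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) abort("k_neighbors must be >= 1.")
  train_geo <- geo_table(train_geo)
  train_ids <- rownames(train_scores) %||% as.character(seq_len(nrow(train_scores)))
  gi <- match(train_ids, train_geo$sample_id)
  if (anyNA(gi)) {
    abort(paste0("training sample(s) without coordinates: ",
                 paste(train_ids[is.na(gi)][1:min(5, sum(is.na(gi)))],
                       collapse = ", ")))
  }
  if (k_neighbors > nrow(train_scores)) {
    warn(sprintf("k_neighbors (%d) exceeds training size (%d); using all %d.",
                 k_neighbors, nrow(train_scores), nrow(train_scores)))
    k_neighbors <- nrow(train_scores)
  }
  lat <- train_geo$latitude[gi]
  lon <- train_geo$longitude[gi]
  test_ids <- rownames(test_scores) %||% as.character(seq_len(nrow(test_scores)))

  # squared distances, all test x train at once
  d2 <- outer(rowSums(test_scores^2), rowSums(train_scores^2), "+") -
    2 * tcrossprod(test_scores, train_scores)
  d2[d2 < 0] <- 0

  res <- lapply(seq_len(nrow(test_scores)), function(i) {
    o <- order(d2[i, ], train_ids)[seq_len(k_neighbors)]
    dd <- sqrt(d2[i, o])
    if (weight_power > 0) {
      w <- 1 / (dd^weight_power + 1e-12)
      w <- w / sum(w)
    } else {
      w <- rep(1 / k_neighbors, k_neighbors)
    }
    list(id = test_ids[i],
         lat = sum(w * lat[o]), lon = sum(w * lon[o]),
         nb = train_ids[o], nd = dd)
  })
  tibble(
    sample_id = vapply(res, `[[`, character(1), "id"),
    pred_latitude = vapply(res, `[[`, numeric(1), "lat"),
    pred_longitude = vapply(res, `[[`, numeric(1), "lon"),
    neighbor_ids = lapply(res, `[[`, "nb"),
    neighbor_distances = lapply(res, `[[`, "nd")
  )
}

#' Predict coordinates for a test cohort from a SNP panel
#'
#' The composed pipeline used by both cross-validation designs: restrict both
#' cohorts to the panel SNPs present in the test data (after allele
#' harmonization), encode and center on *training* statistics, fit the
#' top-`k_pcs` PCA on the training cohort, project the test cohort, and run
#' [knn_predict()].
#'
#' @param train_g Training [genotype_matrix()].
#' @param train_geo Training [geo_table()].
#' @param test_g Test [genotype_matrix()]; may lack some panel SNPs or carry
#'   missing calls.
#' @param panel A [snp_panel()] (or character vector of SNP ids).
#' @param k_pcs Number of principal components (default 2). Silently reduced
#'   when the usable panel or training size cannot support it.
#' @param k_neighbors,weight_power Passed to [knn_predict()].
#' @param harmonize Re-orient test alleles to the training encoding by
#'   ref/alt matching (default `TRUE`; set `FALSE` when both cohorts are
#'   known to share an encoding).
#' @param scale_freq Passed to [fit_pca()].
#' @return A prediction tibble as returned by [knn_predict()].
#' @export
predict_from_panel <- function(train_g, train_geo, test_g, panel,
                               k_pcs = 2L, k_neighbors = 10L,
                               weight_power = 0, harmonize = TRUE,
                               scale_freq = FALSE) {
  snp_ids <- if (inherits(panel, "snp_panel")) panel$snp_id else as.character(panel)
  missing_train <- setdiff(snp_ids, train_g$snp_meta$snp_id)
  if (length(missing_train) > 0) {
    abort(sprintf("%d panel SNP(s) absent from the training data.",
                  length(missing_train)))
  }
  test_sub <- subset_genotypes(
    test_g, snps = intersect(snp_ids, test_g$snp_meta$snp_id))
  if (ncol(test_sub$values) == 0) abort("no panel SNPs present in test data.")
  if (harmonize) {
    test_sub <- harmonize_alleles(test_sub, train_g$snp_meta)
  }
  usable <- intersect(snp_ids, test_sub$snp_meta$snp_id)
  if (length(usable) < length(snp_ids)) {
    inform(sprintf("predict_from_panel: %d of %d panel SNPs usable in test data.",
                   length(usable), length(snp_ids)))
  }
  train_sub <- subset_genotypes(train_g, snps = usable)
  x <- encode_center(train_sub)
  k_eff <- min(as.integer(k_pcs), length(usable), nrow(x$values) - 1L)
  m <- fit_pca(x, k = k_eff, scale_freq = scale_freq)
  test_scores <- project_pca(m, test_sub)
  train_scores <- m$scores
  rownames(train_scores) <- m$sample_ids
  knn_predict(train_scores, train_geo, test_scores,
              k_neighbors = k_neighbors, weight_power = weight_power)
}
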
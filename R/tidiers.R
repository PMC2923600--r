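#' Tidy a fitted PCA
#'
#' @param x A `pca_fit`.
#' @param matrix `"scores"` (default): one row per training sample with its
#'   PC coordinates; `"loadings"`: one row per SNP per component;
#'   `"d"`: singular values with variance shares.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pca_fit <- function(x, matrix = c("scores", "loadings", "d"), ...) {
  matrix <- match.arg(matrix)
  pcs <- paste0("PC", seq_len(x$k))
  switch(matrix,
    scores = {
      tb <- as_tibble(x$scores, .name_repair = ~pcs)
      dplyr::bind_cols(tibble(sample_id = x$sample_ids), tb)
    },
    loadings = {
      tb <- as_tibble(x$v, .name_repair = ~pcs)
      dplyr::bind_cols(tibble(snp_id = x$snp_ids), tb) |>
        tidyr::pivot_longer(all_of(pcs), names_to = "component",
                            values_to = "loading")
    },
    d = tibble(component = pcs, singular_value = x$d,
               variance_share = x$d^2 / sum(x$d^2))
  )
}

#' @rdname tidy.pca_fit
#' @export
glance.pca_fit <- function(x, ...) {
  tibble(k = x$k, n_snps = length(x$snp_ids),
         n_samples = length(x$sample_ids),
         top_singular_value = x$d[1], scale_freq = x$scale_freq)
}

#' Tidy a leave-one-out cross-validation result
#'
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @return `tidy()` returns the per-population error report (one row per
#'   population per panel size); `glance()` one row per panel size with the
#'   overall mean errors.
#' @export
tidy.loocv_result <- function(x, ...) {
  as_tibble(x$report)
}

#' @rdname tidy.loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  ov <- x$report[x$report$population == "(overall)", ]
  tibble(panel_size = ov$panel_size, n_samples = ov$n_samples,
         mean_lat_error = ov$mean_lat_error,
         mean_lon_error = ov$mean_lon_error,
         mean_lat_error_km = ov$mean_lat_error_km,
         mean_lon_error_km = ov$mean_lon_error_km)
}

#' @export
tidy.snp_panel <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.snp_panel <- function(x, ...) {
  pr <- attr(x, "provenance")
  tibble(n_snps = nrow(x), pool_size = pr$pool_size,
         target_size = pr$target_size, r2_threshold = pr$r2_threshold,
         k = pr$k)
}
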
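#' Per-axis coordinate errors in degrees
#'
#' The evaluation metric: absolute latitudinal difference, and the minimal
#' angular difference of longitudes (so 179.5 vs -179.5 is 1 degree, not 359).
#'
#' @param pred_lat,pred_lon,true_lat,true_lon Numeric vectors (recycled).
#' @return A tibble with columns `lat_error`, `lon_error`, both non-negative
#'   decimal degrees.
#' @export
coordinate_error <- function(pred_lat, pred_lon, true_lat, true_lon) {
  dlat <- abs(pred_lat - true_lat)
  dlon <- abs(pred_lon - true_lon) %% 360
  dlon <- pmin(dlon, 360 - dlon)
  tibble(lat_error = dlat, lon_error = dlon)
}

km_per_deg_lat <- 111.32

#' Per-population error report
#'
#' Aggregates per-sample prediction errors into the standard report: one row
#' per population with sample count, mean and standard deviation of the
#' latitudinal and longitudinal absolute errors (decimal degrees), sorted by
#' population name, plus an `(overall)` row whose means are weighted by
#' sample counts. Standard deviations use the population denominator `n`.
#' Kilometre equivalents (1 deg lat ~ 111.32 km; 1 deg lon ~ 111.32 x
#' cos(latitude) km at each population's latitude) are added as convenience
#' columns.
#'
#' @param preds Prediction tibble from [knn_predict()] /
#'   [predict_from_panel()] (columns `sample_id`, `pred_latitude`,
#'   `pred_longitude`); extra columns such as `panel_size` are carried into
#'   the grouping.
#' @param geo A [geo_table()] with the true coordinates of every predicted
#'   sample.
#' @return A tibble of class `error_report`.
#' @export
error_summary <- function(preds, geo) {
  geo <- geo_table(geo)
  gi <- match(preds$sample_id, geo$sample_id)
  if (anyNA(gi)) {
    abort(paste0("prediction(s) without a truth record: ",
                 paste(head(preds$sample_id[is.na(gi)], 5), collapse = ", ")))
  }
  err <- coordinate_error(preds$pred_latitude, preds$pred_longitude,
                          geo$latitude[gi], geo$longitude[gi])
  tb <- tibble(population = geo$population[gi],
               true_latitude = geo$latitude[gi],
               lat_error = err$lat_error, lon_error = err$lon_error)
  extra <- intersect("panel_size", names(preds))
  for (e in extra) tb[[e]] <- preds[[e]]
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  by <- c(extra, "population")
  per_pop <- tb |>
    group_by(across(all_of(by))) |>
    summarise(n_samples = n(),
              mean_lat_error = mean(.data$lat_error),
              sd_lat_error = sd_pop(.data$lat_error),
              mean_lon_error = mean(.data$lon_error),
              sd_lon_error = sd_pop(.data$lon_error),
              .latitude = mean(.data$true_latitude),
              .groups = "drop") |>
    arrange(across(all_of(by)))
  overall <- tb |>
    group_by(across(all_of(extra))) |>
    summarise(population = "(overall)", n_samples = n(),
              mean_lat_error = mean(.data$lat_error),
              sd_lat_error = sd_pop(.data$lat_error),
              mean_lon_error = mean(.data$lon_error),
              sd_lon_error = sd_pop(.data$lon_error),
              .latitude = mean(.data$true_latitude),
              .groups = "drop")
  rep <- bind_rows(per_pop, overall) |>
    mutate(mean_lat_error_km = .data$mean_lat_error * km_per_deg_lat,
           mean_lon_error_km = .data$mean_lon_error * km_per_deg_lat *
             cos(.data$.latitude * pi / 180)) |>
    select(-".latitude")
  class(rep) <- c("error_report", class(rep))
  rep
}

# Fit one leave-one-out split: select panels on the n-1 training samples only
# (the held-out sample's genotypes never touch selection, means, or PCA) and
# predict the held-out sample. Exposed so the no-leakage property can be
# audited directly.

#' Train and predict a single leave-one-out split
#'
#' Builds the PCAIM panels from scratch on all samples except `holdout`, then
#' predicts the held-out sample from each panel. The held-out genotypes play
#' no part in panel selection, column means, or the PCA fit — replacing them
#' with arbitrary values changes nothing about the trained model.
#'
#' @param g Full-cohort [genotype_matrix()].
#' @param geo A [geo_table()].
#' @param holdout Sample id (or row index) to hold out.
#' @inheritParams build_panels
#' @param k_neighbors,weight_power Passed to [knn_predict()].
#' @param panels Optional precomputed list of [snp_panel()]s: when supplied,
#'   panel selection is skipped (the reuse-panels design) and only the PCA /
#'   prediction step is run per split.
#' @return A list: `panels` (per size), `predictions` (tibble with one row per
#'   panel size), and `pca` (the per-panel fitted models).
#' @export
loocv_split <- function(g, geo, holdout, sizes = c(500L, 800L, 1000L),
                        pool_size = 5000L, r2_threshold = 0.8, k = 2L,
                        k_neighbors = 10L, weight_power = 0,
                        scale_freq = FALSE, panels = NULL) {
  if (!is.character(holdout)) holdout <- g$sample_ids[holdout]
  tr_ids <- setdiff(g$sample_ids, holdout)
  train_g <- subset_genotypes(g, samples = tr_ids)
  test_g <- subset_genotypes(g, samples = holdout)
  if (is.null(panels)) {
    panels <- build_panels(train_g, sizes = sizes, pool_size = pool_size,
                           r2_threshold = r2_threshold, k = k,
                           scale_freq = scale_freq)
  }
  fits <- list()
  preds <- lapply(seq_along(panels), function(pi) {
    panel <- panels[[pi]]
    train_sub <- subset_genotypes(train_g, snps = panel$snp_id)
    x <- encode_center(train_sub)
    k_eff <- min(k, ncol(x$values), nrow(x$values) - 1L)
    m <- fit_pca(x, k = k_eff, scale_freq = scale_freq)
    fits[[pi]] <<- m
    test_scores <- project_pca(m, test_g)
    train_scores <- m$scores
    rownames(train_scores) <- m$sample_ids
    p <- knn_predict(train_scores, geo, test_scores,
                     k_neighbors = k_neighbors, weight_power = weight_power)
    p$panel_size <- nrow(panel)
    p
  })
  list(panels = panels, predictions = bind_rows(preds), pca = fits)
}

#' Full leave-one-out cross-validation with per-split panel re-selection
#'
#' The honest cross-validation design: for each of the `n` samples, the other
#' `n - 1` samples are used to select PCAIM panels *from scratch* and to fit
#' the PCA, and the held-out sample's coordinates are predicted from each
#' panel. With `reuse_panels = TRUE` the panels are instead selected once on
#' the full cohort and reused across splits — the optimistic design that
#' measures how well fixed panels summarise the cohort, not true
#' cross-validated accuracy (the held-out sample then influenced marker
#' choice; interpret accordingly).
#'
#' @inheritParams loocv_split
#' @param reuse_panels Select panels once on the full cohort (optimistic)
#'   instead of per split (default `FALSE`).
#' @param panels Optional list of fixed panels ([snp_panel()]s or SNP id
#'   vectors) to evaluate as-is (no selection at all) — e.g. random baseline
#'   panels; overrides `sizes` and `reuse_panels`.
#' @param progress Print a progress message every `progress` splits (0 = off).
#' @return An object of class `loocv_result`: list with `predictions` (one
#'   row per sample per panel size; columns `sample_id`, `panel_size`,
#'   `pred_latitude`, `pred_longitude`), `report` (an [error_summary()]
#'   tibble with a `panel_size` column), and `params`.
#' @export
loocv <- function(g, geo, sizes = c(500L, 800L, 1000L), pool_size = 5000L,
                  r2_threshold = 0.8, k = 2L, k_neighbors = 10L,
                  weight_power = 0, scale_freq = FALSE,
                  reuse_panels = FALSE, panels = NULL, progress = 0L) {
  geo <- geo_table(geo)
  if (!all(g$sample_ids %in% geo$sample_id)) {
    abort("every sample needs a coordinate record for LOOCV.")
  }
  shared_panels <- NULL
  if (!is.null(panels)) {
    shared_panels <- lapply(panels, function(p) {
      if (inherits(p, "snp_panel")) return(p)
      ids <- as.character(p)
      mi <- match(ids, g$snp_meta$snp_id)
      if (anyNA(mi)) abort("fixed panel contains SNPs absent from the cohort.")
      snp_panel(tibble(rank = seq_along(ids), snp_id = ids,
                       chrom = g$snp_meta$chrom[mi], pos = g$snp_meta$pos[mi],
                       score = NA_real_),
                pool_size = length(ids), target_size = length(ids),
                r2_threshold = 1, k = k)
    })
  } else if (reuse_panels) {
    shared_panels <- build_panels(g, sizes = sizes, pool_size = pool_size,
                                  r2_threshold = r2_threshold, k = k,
                                  scale_freq = scale_freq)
  }
  n <- length(g$sample_ids)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- tryCatch(
      loocv_split(g, geo, g$sample_ids[i], sizes = sizes,
                  pool_size = pool_size, r2_threshold = r2_threshold, k = k,
                  k_neighbors = k_neighbors, weight_power = weight_power,
                  scale_freq = scale_freq, panels = shared_panels),
      error = function(e) abort(sprintf("LOOCV split %d ('%s') failed: %s",
                                        i, g$sample_ids[i],
                                        conditionMessage(e)))
    )
    preds[[i]] <- sp$predictions
    if (progress > 0 && i %% progress == 0) {
      inform(sprintf("loocv: %d / %d splits done", i, n))
    }
  }
  predictions <- bind_rows(preds)
  out <- structure(
    list(predictions = predictions,
         report = error_summary(predictions, geo),
         params = list(sizes = sizes, pool_size = pool_size,
                       r2_threshold = r2_threshold, k = k,
                       k_neighbors = k_neighbors,
                       weight_power = weight_power,
                       scale_freq = scale_freq,
                       reuse_panels = reuse_panels, n_samples = n)),
    class = "loocv_result")
  out
}

#' @export
print.loocv_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("<loocv_result> %d samples, panel sizes %s%s\n",
              p$n_samples, paste(p$sizes, collapse = "/"),
              if (p$reuse_panels) " (panels reused across splits)" else ""))
  print(x$report[x$report$population == "(overall)", ])
  invisible(x)
}

#' External hold-out validation of a fixed panel
#'
#' Trains on one cohort and predicts an external test cohort from a panel
#' selected on the training cohort (the reference-panel-to-new-samples
#' design). Test samples missing more than `max_test_missing` of the panel's
#' SNPs are excluded up front. When no ground-truth coordinates exist for the
#' test cohort, predictions made from *all* available shared SNPs serve as
#' the reference ("all-SNP ground truth").
#'
#' @param train_g,train_geo Training cohort and coordinates.
#' @param test_g External test cohort.
#' @param panel A [snp_panel()].
#' @param test_truth Optional [geo_table()] for the test samples; when `NULL`
#'   the all-SNP predictions are used as truth.
#' @param max_test_missing Per-sample missingness bound on the panel SNPs
#'   (default 0.10).
#' @param k_pcs,k_neighbors,weight_power,harmonize,scale_freq Passed through
#'   to [predict_from_panel()].
#' @return A list: `predictions`, `truth` (tibble of reference coordinates
#'   used), `report` (an [error_summary()]), `errors` (per-sample error
#'   tibble for histograms), `excluded` (ids dropped by the missingness
#'   rule).
#' @export
holdout_validate <- function(train_g, train_geo, test_g, panel,
                             test_truth = NULL, max_test_missing = 0.10,
                             k_pcs = 2L, k_neighbors = 10L, weight_power = 0,
                             harmonize = TRUE, scale_freq = FALSE) {
  snp_ids <- if (inherits(panel, "snp_panel")) panel$snp_id else as.character(panel)
  on_panel <- intersect(snp_ids, test_g$snp_meta$snp_id)
  if (length(on_panel) == 0) abort("no panel SNPs present in test data.")
  miss <- rowMeans(is.na(subset_genotypes(test_g, snps = on_panel)$values))
  excluded <- test_g$sample_ids[miss > max_test_missing]
  if (length(excluded) > 0) {
    inform(sprintf(
      "holdout_validate: excluded %d test sample(s) with > %.0f%% panel missingness.",
      length(excluded), 100 * max_test_missing))
  }
  keep <- setdiff(test_g$sample_ids, excluded)
  if (length(keep) == 0) abort("no test samples survive the missingness filter.")
  test_g <- subset_genotypes(test_g, samples = keep)

  preds <- predict_from_panel(train_g, train_geo, test_g, panel,
                              k_pcs = k_pcs, k_neighbors = k_neighbors,
                              weight_power = weight_power,
                              harmonize = harmonize, scale_freq = scale_freq)
  if (is.null(test_truth)) {
    all_snp <- intersect(train_g$snp_meta$snp_id, test_g$snp_meta$snp_id)
    ref <- predict_from_panel(train_g, train_geo, test_g, all_snp,
                              k_pcs = k_pcs, k_neighbors = k_neighbors,
                              weight_power = weight_power,
                              harmonize = harmonize, scale_freq = scale_freq)
    truth <- geo_table(tibble(sample_id = ref$sample_id,
                              population = ref$sample_id,
                              latitude = ref$pred_latitude,
                              longitude = ref$pred_longitude))
    truth_for_report <- tibble(sample_id = ref$sample_id,
                               population = "(external)",
                               latitude = ref$pred_latitude,
                               longitude = ref$pred_longitude)
  } else {
    truth <- geo_table(test_truth)
    truth_for_report <- truth
  }
  gi <- match(preds$sample_id, truth$sample_id)
  per_sample <- dplyr::bind_cols(
    tibble(sample_id = preds$sample_id),
    coordinate_error(preds$pred_latitude, preds$pred_longitude,
                     truth$latitude[gi], truth$longitude[gi]))
  # per-sample reference points need not share population-level coordinates,
  # so the aggregate report groups all external samples together
  rep_truth <- tibble(sample_id = per_sample$sample_id,
                      population = truth_for_report$population[
                        match(per_sample$sample_id, truth_for_report$sample_id)],
                      lat_error = per_sample$lat_error,
                      lon_error = per_sample$lon_error)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  report <- rep_truth |>
    group_by(.data$population) |>
    summarise(n_samples = n(),
              mean_lat_error = mean(.data$lat_error),
              sd_lat_error = sd_pop(.data$lat_error),
              mean_lon_error = mean(.data$lon_error),
              sd_lon_error = sd_pop(.data$lon_error),
              .groups = "drop") |>
    arrange(.data$population)
  class(report) <- c("error_report", class(report))
  list(predictions = preds, truth = truth, report = report,
       errors = per_sample, excluded = excluded)
}
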
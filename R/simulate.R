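#' Simulation configuration for spatially structured genotype cohorts
#'
#' Describes a cohort of demes placed at geographic coordinates, a minority
#' of SNPs whose allele frequencies follow linear latitudinal/longitudinal
#' clines, a majority of spatially uninformative SNPs with Balding–Nichols
#' style drift, and uniform random missingness. The defaults describe the
#' reference study condition used throughout the package's validation: a
#' 5 x 5 deme grid with 40 samples per deme and 2,000 clinal among 20,000
#' SNPs.
#'
#' @param grid Tibble of demes: columns `deme`, `latitude`, `longitude`,
#'   `n_samples` (default [deme_grid()]).
#' @param n_clinal_snps,n_noise_snps SNP counts (defaults 2000 and 18000).
#' @param cline_strength Maximum allele-frequency range a cline spans across
#'   the grid (default 0.4); per-SNP spans are drawn uniformly between half
#'   and all of it.
#' @param base_freq_range Interval the baseline allele frequencies are drawn
#'   from, within \[0.05, 0.95\] (default c(0.2, 0.8)).
#' @param drift Balding–Nichols dispersion (Fst-like) of per-deme
#'   frequencies around each noise SNP's mean (default 0.01).
#' @param missing_rate Fraction of genotype calls masked at random
#'   (default 0.01).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid = deme_grid(), n_clinal_snps = 2000L,
                       n_noise_snps = 18000L, cline_strength = 0.4,
                       base_freq_range = c(0.2, 0.8), drift = 0.01,
                       missing_rate = 0.01, seed = 1L) {
  grid <- as_tibble(grid)
  need <- c("deme", "latitude", "longitude", "n_samples")
  if (nrow(grid) == 0 || !all(need %in% names(grid))) {
    abort("grid must be a non-empty tibble with deme, latitude, longitude, n_samples.")
  }
  if (any(grid$n_samples < 1)) abort("every deme needs n_samples >= 1.")
  if (base_freq_range[1] < 0.05 || base_freq_range[2] > 0.95 ||
      base_freq_range[1] > base_freq_range[2]) {
    abort("base_freq_range must be an interval within [0.05, 0.95].")
  }
  stopifnot(cline_strength >= 0, missing_rate >= 0, missing_rate < 1,
            drift >= 0, n_clinal_snps >= 0, n_noise_snps >= 0,
            n_clinal_snps + n_noise_snps >= 1)
  structure(list(grid = grid, n_clinal_snps = as.integer(n_clinal_snps),
                 n_noise_snps = as.integer(n_noise_snps),
                 cline_strength = cline_strength,
                 base_freq_range = base_freq_range, drift = drift,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Rectangular deme grid at European-scale coordinates
#'
#' @param n_lat,n_lon Grid dimensions (default 5 x 5).
#' @param lat_range,lon_range Coordinate spans, decimal degrees (defaults
#'   38–54 N and -5–23 E, a continental-European extent).
#' @param n_per_deme Samples per deme (default 40, the minimum population
#'   size the pipeline's cohort filter targets).
#' @return A grid tibble for [sim_config()].
#' @export
deme_grid <- function(n_lat = 5L, n_lon = 5L, lat_range = c(38, 54),
                      lon_range = c(-5, 23), n_per_deme = 40L) {
  lats <- seq(lat_range[1], lat_range[2], length.out = n_lat)
  lons <- seq(lon_range[1], lon_range[2], length.out = n_lon)
  gg <- expand.grid(latitude = lats, longitude = lons)
  tibble(deme = sprintf("deme_%02d", seq_len(nrow(gg))),
         latitude = gg$latitude, longitude = gg$longitude,
         n_samples = as.integer(n_per_deme))
}

#' Cohort preset shaped like the 11-population European reference sample
#'
#' Eleven demes at approximate European capital coordinates with the
#' published per-population sample counts (1,200 samples in total, largest
#' deme 219), and ~20,000 SNPs.
#'
#' @param seed Seed stored in the config (default 1).
#' @return A [sim_config()].
#' @export
europe_like_preset <- function(seed = 1L) {
  grid <- tibble(
    deme = c("Belgium", "France", "Germany", "Ireland", "Italy", "Portugal",
             "Serbia", "Spain", "SwissFrench", "SwissGerman", "UK"),
    latitude = c(50.85, 48.86, 52.52, 53.35, 41.90, 38.72,
                 44.79, 40.42, 46.20, 47.38, 51.51),
    longitude = c(4.35, 2.35, 13.41, -6.26, 12.50, -9.14,
                  20.45, -3.70, 6.14, 8.54, -0.13),
    n_samples = c(43L, 89L, 71L, 61L, 219L, 128L, 44L, 136L, 125L, 84L, 200L)
  )
  sim_config(grid = grid, n_clinal_snps = 2000L, n_noise_snps = 18000L,
             seed = seed)
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a spatially structured genotype cohort
#'
#' Clinal SNPs get per-deme allele frequencies
#' `p_d = clip(p0 + s_lat (lat_d - mean lat) + s_lon (lon_d - mean lon),
#' 0.01, 0.99)`, with the slope direction drawn uniformly on the circle and
#' scaled so the frequency spans a draw between `cline_strength / 2` and
#' `cline_strength` across the grid. Noise SNPs share one baseline frequency
#' with small Balding–Nichols per-deme drift. Genotypes are two independent
#' allele copies (`Binomial(2, p_d)`); calls are masked uniformly at the
#' missing rate. Every member of a deme carries the deme's coordinates as
#' ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genotypes` ([genotype_matrix()]), `geo` ([geo_table()]),
#'   `truth` (tibble of clinal SNP ids with `lat_slope`, `lon_slope` in
#'   frequency per degree, plus the per-deme frequency matrix as attribute
#'   `deme_freqs`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  grid <- cfg$grid
  n_demes <- nrow(grid)
  n <- sum(grid$n_samples)
  p_cl <- cfg$n_clinal_snps
  p_ns <- cfg$n_noise_snps
  p_all <- p_cl + p_ns

  latc <- grid$latitude - mean(grid$latitude)
  lonc <- grid$longitude - mean(grid$longitude)

  # per-deme frequencies: demes x SNPs
  freqs <- matrix(0, n_demes, p_all)
  lat_slope <- lon_slope <- rep(NA_real_, p_cl)
  if (p_cl > 0) {
    p0 <- runif(p_cl, cfg$base_freq_range[1], cfg$base_freq_range[2])
    theta <- runif(p_cl, 0, 2 * pi)
    span <- runif(p_cl, 0.5, 1) * cfg$cline_strength
    for (j in seq_len(p_cl)) {
      f <- cos(theta[j]) * latc + sin(theta[j]) * lonc
      rng <- diff(range(f))
      sc <- if (rng > 0) span[j] / rng else 0
      lat_slope[j] <- cos(theta[j]) * sc
      lon_slope[j] <- sin(theta[j]) * sc
      freqs[, j] <- pmin(pmax(p0[j] + f * sc, 0.01), 0.99)
    }
  }
  if (p_ns > 0) {
    q0 <- runif(p_ns, cfg$base_freq_range[1], cfg$base_freq_range[2])
    if (cfg$drift > 0) {
      a <- q0 * (1 - cfg$drift) / cfg$drift
      b <- (1 - q0) * (1 - cfg$drift) / cfg$drift
      for (d in seq_len(n_demes)) {
        freqs[d, p_cl + seq_len(p_ns)] <- pmin(pmax(rbeta(p_ns, a, b), 0.01), 0.99)
      }
    } else {
      freqs[, p_cl + seq_len(p_ns)] <- matrix(q0, n_demes, p_ns, byrow = TRUE)
    }
  }

  snp_ids <- c(if (p_cl > 0) sprintf("cl%05d", seq_len(p_cl)),
               if (p_ns > 0) sprintf("ns%05d", seq_len(p_ns)))
  al <- random_alleles(p_all)
  meta <- tibble(snp_id = snp_ids,
                 chrom = as.character(rep_len(1:22, p_all)),
                 pos = as.integer(seq_len(p_all) * 1000L),
                 ref_allele = al$ref, alt_allele = al$alt)

  deme_of <- rep(seq_len(n_demes), grid$n_samples)
  sample_ids <- sprintf("%s_s%03d", grid$deme[deme_of],
                        unlist(lapply(grid$n_samples, seq_len)))
  gmat <- matrix(NA_integer_, n, p_all)
  for (d in seq_len(n_demes)) {
    rows <- which(deme_of == d)
    gmat[rows, ] <- matrix(
      rbinom(length(rows) * p_all, 2L, rep(freqs[d, ], each = length(rows))),
      length(rows), p_all)
  }
  if (cfg$missing_rate > 0) {
    mask <- runif(length(gmat)) < cfg$missing_rate
    gmat[mask] <- NA_integer_
  }

  geno <- genotype_matrix(gmat, meta, sample_ids)
  geo <- geo_table(tibble(sample_id = sample_ids,
                          population = grid$deme[deme_of],
                          latitude = grid$latitude[deme_of],
                          longitude = grid$longitude[deme_of]))
  truth <- tibble(snp_id = if (p_cl > 0) snp_ids[seq_len(p_cl)] else character(0),
                  lat_slope = lat_slope, lon_slope = lon_slope)
  attr(truth, "deme_freqs") <-
    matrix(freqs, n_demes, p_all,
           dimnames = list(grid$deme, snp_ids))
  list(genotypes = geno, geo = geo, truth = truth)
}
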
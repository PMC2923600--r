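#' Genotype matrix container
#'
#' Bundles an integer samples x SNPs matrix of allele counts (0, 1, 2, or `NA`
#' for a missing call) with per-SNP metadata and sample identifiers. This is
#' the raw substrate every downstream step (filtering, encoding, PCA, panel
#' selection) consumes.
#'
#' @param values Integer matrix, samples in rows, SNPs in columns. Entries must
#'   be 0, 1, 2 or `NA`.
#' @param snp_meta Data frame with one row per SNP: columns `snp_id`, `chrom`,
#'   `pos` (1-based), and optionally `ref_allele`, `alt_allele`.
#' @param sample_ids Character vector of unique sample identifiers, one per row
#'   of `values`.
#'
#' @return An object of class `genotype_matrix`: a list with elements `values`
#'   (dimnames set to sample and SNP ids), `snp_meta` (tibble) and
#'   `sample_ids`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   values = rbind(c(0L, 2L), c(1L, NA), c(2L, 0L)),
#'   snp_meta = data.frame(snp_id = c("rs1", "rs2"), chrom = c("1", "2"),
#'                         pos = c(100L, 200L)),
#'   sample_ids = c("s1", "s2", "s3")
#' )
#' g
genotype_matrix <- function(values, snp_meta, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  snp_meta <- as_tibble(snp_meta)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snp_meta))) {
    abort("`snp_meta` must have columns snp_id, chrom, pos.")
  }
  if (!"ref_allele" %in% names(snp_meta)) snp_meta$ref_allele <- NA_character_
  if (!"alt_allele" %in% names(snp_meta)) snp_meta$alt_allele <- NA_character_
  snp_meta$snp_id <- as.character(snp_meta$snp_id)
  snp_meta$chrom <- as.character(snp_meta$chrom)
  snp_meta$pos <- as.integer(snp_meta$pos)
  sample_ids <- as.character(sample_ids)
  g <- structure(
    list(values = values, snp_meta = snp_meta, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
}

validate_genotype_matrix <- function(g) {
  v <- g$values
  if (nrow(g$snp_meta) != ncol(v)) {
    abort(sprintf("snp_meta has %d rows but the matrix has %d SNP columns.",
                  nrow(g$snp_meta), ncol(v)))
  }
  if (length(g$sample_ids) != nrow(v)) {
    abort(sprintf("%d sample ids for %d matrix rows.",
                  length(g$sample_ids), nrow(v)))
  }
  if (anyDuplicated(g$snp_meta$snp_id)) {
    abort(paste0("duplicate SNP id(s): ",
                 paste(unique(g$snp_meta$snp_id[duplicated(g$snp_meta$snp_id)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(g$sample_ids)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(g$sample_ids[duplicated(g$sample_ids)]),
                       collapse = ", ")))
  }
  bad <- !is.na(v) & !(v %in% 0:2)
  if (any(bad)) {
    abort(sprintf("%d genotype entries are not 0, 1, 2 or NA.", sum(bad)))
  }
  if (any(!is.na(g$snp_meta$pos) & g$snp_meta$pos < 1L)) {
    abort("SNP positions must be 1-based (>= 1).")
  }
  dimnames(g$values) <- list(g$sample_ids, g$snp_meta$snp_id)
  g
}

# Fast path for internal use on already-validated components (subsetting a
# valid object cannot introduce bad entries; id uniqueness is preserved).
new_genotype_matrix <- function(values, snp_meta, sample_ids) {
  dimnames(values) <- list(sample_ids, snp_meta$snp_id)
  structure(list(values = values, snp_meta = snp_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g A [genotype_matrix()].
#' @param samples Sample ids (or logical/integer index over rows) to keep.
#' @param snps SNP ids (or logical/integer index over columns) to keep. Order
#'   of the result follows the order of this argument.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  ri <- seq_len(nrow(g$values))
  ci <- seq_len(ncol(g$values))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, g$sample_ids) else ri[samples]
    if (anyNA(ri)) abort("unknown sample id(s) in `samples`.")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, g$snp_meta$snp_id) else ci[snps]
    if (anyNA(ci)) abort("unknown SNP id(s) in `snps`.")
  }
  if (anyDuplicated(ri) || anyDuplicated(ci)) {
    abort("subset indices must be unique.")
  }
  new_genotype_matrix(g$values[ri, ci, drop = FALSE],
                      g$snp_meta[ci, , drop = FALSE],
                      g$sample_ids[ri])
}

#' Sample coordinate table
#'
#' Validates a sample-to-coordinates table: one row per sample with its
#' population label and the population's ground-truth latitude/longitude in
#' decimal degrees (the capital-city convention: all members of a population
#' carry identical coordinates).
#'
#' @param x Data frame with columns `sample_id`, `population`, `latitude`,
#'   `longitude`.
#' @return A tibble with the four columns, types normalised.
#' @export
geo_table <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "population", "latitude", "longitude")
  if (!all(need %in% names(x))) {
    abort(paste0("geo table needs columns: ", paste(need, collapse = ", ")))
  }
  x <- x[need]
  x$sample_id <- as.character(x$sample_id)
  x$population <- as.character(x$population)
  x$latitude <- as.numeric(x$latitude)
  x$longitude <- as.numeric(x$longitude)
  if (anyDuplicated(x$sample_id)) abort("duplicate sample ids in geo table.")
  if (any(x$latitude < -90 | x$latitude > 90, na.rm = TRUE)) {
    abort("latitudes must lie in [-90, 90].")
  }
  if (any(x$longitude < -180 | x$longitude >= 180, na.rm = TRUE)) {
    abort("longitudes must lie in [-180, 180).")
  }
  chk <- dplyr::distinct(x, .data$population, .data$latitude, .data$longitude)
  if (anyDuplicated(chk$population)) {
    abort("all samples of one population must share identical coordinates.")
  }
  x
}
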
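#' Read genotypes from VCF or a plain allele-count table
#'
#' Two input formats are supported. `"vcf"` parses a VCF 4.x file (gzip is
#' transparent) with diploid GT fields; multi-allelic records and
#' non-autosomal chromosomes are skipped with a message, and `./.` genotypes
#' become missing entries. `"tsv"` reads a header-bearing table of 0/1/2/NA
#' allele counts: first column sample id, remaining columns one per SNP with
#' the SNP id in the header.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param snp_meta For `"tsv"` input only: optional data frame with `snp_id`,
#'   `chrom`, `pos` (and optionally alleles) for the table's SNPs. When
#'   absent, placeholder metadata is generated.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           snp_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         tsv = read_genotypes_tsv(path, snp_meta))
}

autosome_chroms <- function() c(as.character(1:22), paste0("chr", 1:22))

read_genotypes_vcf <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path,
                                      conditionMessage(e)))
  )
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) abort(sprintf("VCF '%s' contains no variant records.", path))
  multi <- grepl(",", fx$ALT %||% "")
  nonauto <- !(fx$CHROM %in% autosome_chroms())
  keep <- !multi & !nonauto
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    inform(sprintf(
      "read_genotypes: skipped %d record(s) (%d multi-allelic, %d non-autosomal).",
      n_skip, sum(multi), sum(nonauto & !multi)))
  }
  if (!any(keep)) abort("no biallelic autosomal records left after filtering.")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fx <- fx[keep, , drop = FALSE]
  # count ALT allele copies; any missing allele call makes the genotype missing
  counts <- apply(gt, c(1, 2), gt_to_count)
  ids <- fx$ID
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fx$CHROM[blank], ":", fx$POS[blank])
  meta <- tibble(snp_id = ids, chrom = fx$CHROM, pos = as.integer(fx$POS),
                 ref_allele = fx$REF, alt_allele = fx$ALT)
  genotype_matrix(t(counts), meta, colnames(gt))
}

gt_to_count <- function(x) {
  if (is.na(x) || x == "." || x == "./." || x == ".|.") return(NA_integer_)
  al <- strsplit(x, "[/|]")[[1]]
  if (length(al) != 2 || any(al == ".")) return(NA_integer_)
  sum(al == "1")
}

read_genotypes_tsv <- function(path, snp_meta = NULL) {
  tb <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_integer(),
      sample_id = readr::col_character())),
    error = function(e) abort(sprintf("malformed tsv '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (!"sample_id" %in% names(tb)) names(tb)[1] <- "sample_id"
  ids <- tb$sample_id
  m <- as.matrix(tb[setdiff(names(tb), "sample_id")])
  if (is.null(snp_meta)) {
    snp_meta <- tibble(snp_id = colnames(m), chrom = "1",
                       pos = seq_len(ncol(m)))
  }
  genotype_matrix(m, snp_meta, ids)
}

#' Read a sample coordinate table from tsv
#'
#' Expects columns `sample_id`, `population`, `latitude`, `longitude`.
#'
#' @param path Path to a tab-separated file.
#' @return A validated [geo_table()] tibble.
#' @export
read_geo_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  geo_table(readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double())))
}

#' Write a genotype matrix as a plain tsv allele-count table
#'
#' Inverse of `read_genotypes(format = "tsv")`: first column `sample_id`,
#' then one 0/1/2/NA column per SNP.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  tb <- as_tibble(g$values, .name_repair = "minimal")
  tb <- dplyr::bind_cols(tibble(sample_id = g$sample_ids), tb)
  readr::write_tsv(tb, path)
  invisible(path)
}

panel_prov_fields <- c("pool_size", "target_size", "r2_threshold", "k")

#' Write / read a SNP panel file
#'
#' Panels are serialized as tab-separated text with columns `rank`, `snp_id`,
#' `chrom`, `pos`, `score`, preceded by `#`-prefixed header lines recording the
#' selection parameters (pool size, target size, r-squared threshold, number
#' of components). `read_panel(write_panel(p))` reproduces `p` exactly.
#'
#' @param panel A [snp_panel()].
#' @param path File path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns a
#'   [snp_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  prov <- attr(panel, "provenance")
  hdr <- sprintf("# %s: %s", panel_prov_fields,
                 vapply(panel_prov_fields,
                        function(f) format(prov[[f]], digits = 17),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("rank", "snp_id", "chrom", "pos", "score"),
                   collapse = "\t"), con)
  if (nrow(panel) > 0) {
    body <- sprintf("%d\t%s\t%s\t%s\t%s", panel$rank, panel$snp_id,
                    panel$chrom,
                    ifelse(is.na(panel$pos), "NA", as.character(panel$pos)),
                    format(panel$score, digits = 17, trim = TRUE,
                           scientific = FALSE))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  prov <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2 && kv[1] %in% panel_prov_fields) {
      prov[[kv[1]]] <- as.numeric(kv[2])
    }
  }
  if (!all(panel_prov_fields %in% names(prov))) {
    abort(sprintf("panel file '%s' is missing provenance header line(s).", path))
  }
  body <- lines[!grepl("^#", lines)]
  cols <- strsplit(body[1], "\t")[[1]]
  if (!identical(cols, c("rank", "snp_id", "chrom", "pos", "score"))) {
    abort(sprintf("unknown panel columns in '%s': %s", path,
                  paste(cols, collapse = ", ")))
  }
  tb <- readr::read_tsv(I(paste0(paste(body, collapse = "\n"), "\n")),
                        col_types = readr::cols(
                          rank = readr::col_integer(),
                          snp_id = readr::col_character(),
                          chrom = readr::col_character(),
                          pos = readr::col_integer(),
                          score = readr::col_double()))
  snp_panel(tb, pool_size = as.integer(prov$pool_size),
            target_size = as.integer(prov$target_size),
            r2_threshold = prov$r2_threshold, k = as.integer(prov$k))
}
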
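#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF input must contain complete diploid GT calls; the counted allele (the
#' one whose homozygote is coded 2) is ALT. Dosage TSV input has one row per
#' individual: an `id` column followed by one 0/1/2 column per locus.
#' Missingness is rejected with the offending record named; no imputation is
#' performed.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @return Integer genotype matrix (individuals x loci) with sample and
#'   variant ids as dimnames, sample order as in the file.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "vcf") read_vcf_genotypes(path) else read_dosage_tsv(path)
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids)) {
    fx <- vcfR::getFIX(v)
    ids <- paste(fx[, "CHROM"], fx[, "POS"], sep = "_")
  }
  samples <- colnames(gt)
  miss <- which(is.na(gt) | gt %in% c(".", "./.", ".|."), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    abort(sprintf(
      "Missing genotype at variant %s, sample %s; inputs must be complete.",
      ids[miss[1, 1]], samples[miss[1, 2]]
    ))
  }
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  n_alleles <- lengths(alleles)
  if (any(n_alleles != 2L)) {
    bad <- which(n_alleles != 2L, arr.ind = FALSE)[1]
    idx <- arrayInd(bad, dim(gt))
    abort(sprintf(
      "Non-diploid genotype at variant %s, sample %s.",
      ids[idx[1, 1]], samples[idx[1, 2]]
    ))
  }
  counts <- vapply(alleles, function(a) sum(a != "0"), numeric(1))
  X <- matrix(as.integer(counts), nrow = nrow(gt), ncol = ncol(gt))
  X <- t(X)
  dimnames(X) <- list(samples, ids)
  check_genotypes(X)
  X
}

read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 2L) abort("Dosage TSV must have an id column plus at least one locus.")
  ids <- as.character(tab[[1]])
  X <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing dosage at locus %s, individual %s.",
      colnames(X)[idx[2]], ids[idx[1]]
    ))
  }
  if (!all(X %in% c(0, 1, 2))) {
    abort("Dosage values must be 0, 1 or 2.")
  }
  storage.mode(X) <- "integer"
  rownames(X) <- ids
  X
}

#' Write a genotype matrix as dosage TSV or VCF
#'
#' The dosage format round-trips bit-identically through [read_genotypes()].
#' The VCF output is a minimal VCFv4.2 with one biallelic record per locus
#' (placeholder chromosome/positions, REF=A, ALT=B, GT only); the counted
#' allele is written as ALT, so reading the file back reproduces the matrix.
#'
#' @param X Genotype matrix (individuals x loci, values 0/1/2).
#' @param path Output path.
#' @param format `"dosage"` or `"vcf"`.
#' @param header_lines Optional comment lines (written with a leading `#` for
#'   dosage TSV, ignored for VCF).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(X, path, format = c("dosage", "vcf"),
                            header_lines = NULL) {
  check_genotypes(X)
  format <- match.arg(format)
  ids <- rownames(X) %||% sprintf("ind%04d", seq_len(nrow(X)))
  vids <- colnames(X) %||% sprintf("snp%04d", seq_len(ncol(X)))
  if (format == "dosage") {
    tab <- tibble::as_tibble(as.data.frame(X))
    names(tab) <- vids
    tab <- dplyr::bind_cols(tibble::tibble(id = ids), tab)
    if (!is.null(header_lines)) {
      writeLines(paste0("# ", header_lines), path)
      readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
    } else {
      readr::write_tsv(tab, path, progress = FALSE)
    }
  } else {
    gt_codes <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_along(vids), function(j) {
      paste(
        c(
          "1", as.character(j), vids[j], "A", "B", ".", ".", ".", "GT",
          gt_codes[X[, j] + 1L]
        ),
        collapse = "\t"
      )
    }, character(1))
    writeLines(
      c(
        "##fileformat=VCFv4.2",
        "##source=aseshrink",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", ids), collapse = "\t"),
        body
      ),
      path
    )
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a TSV with columns `id` and `phenotype`; a `weight` column is
#' optional and defaults to 1 with a warning. When `genotypes` is supplied
#' the table is aligned to the genotype sample ids; genotyped individuals
#' without a phenotype are dropped with a message, and a complete id mismatch
#' is an error.
#'
#' @param path File path.
#' @param genotypes Optional genotype matrix to align against.
#' @return A tibble with columns `id`, `phenotype`, `weight`.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("id", "phenotype") %in% names(tab))) {
    abort("Phenotype TSV must have columns `id` and `phenotype`.")
  }
  if (!"weight" %in% names(tab)) {
    warn("No `weight` column found; defaulting all weights to 1.")
    tab$weight <- 1
  }
  if (any(!is.finite(tab$weight)) || any(tab$weight <= 0)) {
    abort("All phenotype weights must be strictly positive.")
  }
  tab <- tibble::as_tibble(tab[, c("id", "phenotype", "weight")])
  tab$id <- as.character(tab$id)
  if (!is.null(genotypes)) {
    ids <- rownames(genotypes)
    common <- intersect(ids, tab$id)
    if (length(common) == 0L) {
      abort("No overlap between phenotype ids and genotype sample ids.")
    }
    dropped <- setdiff(ids, tab$id)
    if (length(dropped) > 0L) {
      inform(sprintf("%d genotyped individuals have no phenotype and were dropped.", length(dropped)))
    }
    tab <- tab[match(intersect(ids, tab$id), tab$id), , drop = FALSE]
  }
  tab
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble (`id`, `phenotype`, `weight`).
#' @param header_lines Optional `#`-prefixed comment lines.
#' @export
write_phenotypes <- function(pheno, path, header_lines = NULL) {
  tab <- tibble::as_tibble(pheno[, c("id", "phenotype", "weight")])
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}
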
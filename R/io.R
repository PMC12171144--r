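#' Read and write the tabular pipeline formats
#'
#' Pedigree TSV: columns `animal`, `sire`, `dam` (0 or NA = unknown parent),
#' optionally `sex`, `generation`. Phenotype TSV: `animal`, `y`, `cg`,
#' `age`, optionally `eg`, `level`. Dosage TSV: `animal` column then one
#' 0/1/2 column per marker (NA = missing); the marker map travels in a
#' separate TSV with `chrom`, `pos`, `id`. Malformed rows are reported with
#' line numbers.
#'
#' @param path file path.
#' @return the typed structure for each reader.
#' @name ssgxe_io
NULL

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname ssgxe_io
#' @export
read_pedigree <- function(path) {
  df <- read_tsv_checked(path, c("animal", "sire", "dam"))
  bad <- which(is.na(df$animal))
  if (length(bad))
    stop(sprintf("%s: missing animal id at data line(s) %s", path,
                 paste(bad, collapse = ",")), call. = FALSE)
  check_pedigree(df)
}

#' @rdname ssgxe_io
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ssgxe_io
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, c("animal", "y", "cg", "age"))
  bad <- which(!is.finite(df$y) | !is.finite(df$age))
  if (length(bad))
    stop(sprintf("%s: non-finite y/age at data line(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ",")), call. = FALSE)
  df
}

#' @rdname ssgxe_io
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from dosage TSV, VCF, or PLINK .raw
#'
#' VCF: the GT field is converted to the ALT-allele dosage; `./.` becomes
#' missing. PLINK `.raw` dialect: the six leading columns (FID IID PAT MAT
#' SEX PHENOTYPE) are followed by one counted-allele dosage column per
#' marker. For formats without positional information a `map` data.frame
#' (`chrom`, `pos`, `id`) can be supplied; otherwise markers are laid on one
#' pseudo-chromosome.
#'
#' @param path genotype file.
#' @param format "auto" (by extension), "tsv", "vcf" or "raw".
#' @param map_path companion map TSV for the dosage-TSV format.
#' @param map explicit map data.frame overriding any file.
#' @return a `genotype_set`.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf", "raw"),
                           map_path = NULL, map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else if (grepl("\\.raw$", path)) "raw" else "tsv"
  }
  if (format == "vcf") {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    dos <- apply(gt, c(1, 2), function(x) {
      if (x %in% c(".", "./.", ".|.")) return(NA_integer_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
    dos <- t(dos)  # animals x markers
    rr <- SummarizedExperiment::rowRanges(vcf)
    vmap <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                       pos = BiocGenerics::start(rr),
                       id = names(rr))
    return(new_genotype_set(rownames(dos), vmap, dos))
  }
  if (format == "raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    miss <- setdiff(lead, names(df))
    if (length(miss))
      stop("not a PLINK .raw file: missing ", paste(miss, collapse = ", "),
           call. = FALSE)
    dos <- as.matrix(df[, setdiff(names(df), lead), drop = FALSE])
    ids <- as.character(df$IID)
    snp_ids <- sub("_[ACGT0-9]+$", "", colnames(dos))
    m <- if (!is.null(map)) map else
      data.frame(chrom = 1L, pos = seq_len(ncol(dos)), id = snp_ids)
    rownames(dos) <- ids
    return(new_genotype_set(ids, m, dos))
  }
  df <- read_tsv_checked(path, "animal")
  dos <- as.matrix(df[, setdiff(names(df), "animal"), drop = FALSE])
  rownames(dos) <- as.character(df$animal)
  if (is.null(map)) {
    map <- if (!is.null(map_path))
      read_tsv_checked(map_path, c("chrom", "pos", "id"))
    else data.frame(chrom = 1L, pos = seq_len(ncol(dos)),
                    id = colnames(dos))
  }
  new_genotype_set(as.character(df$animal), map, dos)
}

#' @rdname ssgxe_io
#' @param g a `genotype_set`.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(animal = g$animal_ids, g$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map_path <- sub("(\\.tsv)?$", ".map.tsv", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map.tsv")
  utils::write.table(g$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, map_path))
}

#' Write genotypes as a minimal VCF
#'
#' Unphased GT records with the counted allele as ALT; missing dosage
#' becomes `./.`.
#'
#' @param g a `genotype_set`.
#' @param path output path (plain-text .vcf).
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", as.character(g$animal_ids)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$id[j], "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene/feature intervals from BED or GFF3
#'
#' BED input is 0-based half-open; GFF3 is 1-based closed. Both are
#' converted to the internal 0-based half-open convention, so a GFF3
#' feature `1..100` equals a BED feature `0..100`.
#'
#' @param path interval file (.bed, .gff/.gff3).
#' @param format override the extension-based detection.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF")
  md <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(md)) md$name
  else if ("Name" %in% names(md)) md$Name
  else if ("ID" %in% names(md)) md$ID
  else paste0("feature", seq_along(gr))
  # GRanges is 1-based closed; internal convention is 0-based half-open
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             name = as.character(nm))
}

#' Write a symmetric matrix in coordinate-format text
#'
#' @param M dense or sparse matrix.
#' @param path output path; columns `i`, `j`, `x` for the lower triangle.
#' @export
write_matrix_coord <- function(M, path) {
  M <- methods::as(methods::as(Matrix::Matrix(M), "generalMatrix"),
                   "TsparseMatrix")
  keep <- M@i >= M@j
  df <- data.frame(i = M@i[keep] + 1L, j = M@j[keep] + 1L, x = M@x[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load / save a run configuration (YAML or JSON)
#'
#' @param path configuration file (.yaml/.yml or .json).
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg
}

#' @rdname read_config
#' @param cfg named list.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}
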
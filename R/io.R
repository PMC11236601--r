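## Plain-text readers and writers for the pipeline's interchange formats.

#' Write a dosage matrix as CSV
#'
#' Rows are individuals, columns markers; missing dosages are empty cells.
#'
#' @param dosage individuals x markers matrix.
#' @param path output file.
#' @export
write_dosage_csv <- function(dosage, path) {
  df <- data.frame(id = rownames(dosage), as.data.frame(dosage),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dosage matrix from CSV (as written by \code{write_dosage_csv})
#' @param path input file.
#' @return individuals x markers integer matrix with NA missing.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write inbred genotypes as a minimal VCF
#'
#' Emits biallelic records with a GT field; dosage 0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, missing -> ./. Chromosome and position come from the map when
#' supplied, else marker index placeholders.
#'
#' @param dosage individuals x markers matrix.
#' @param path output .vcf file.
#' @param map optional \code{genetic_map} (cM rounded to an integer
#'   pseudo-position).
#' @export
write_vcf <- function(dosage, path, map = NULL) {
  markers <- colnames(dosage)
  if (!is.null(map)) {
    i <- match(markers, map$marker)
    chrom <- map$chrom[i]; pos <- round(map$cM[i] * 1e4) + 1
  } else {
    chrom <- rep(1L, length(markers)); pos <- seq_along(markers)
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(dosage)), collapse = "\t"))
  body <- vapply(seq_along(markers), function(j) {
    gt <- gt_code[as.character(dosage[, j])]
    gt[is.na(gt)] <- "./."
    paste(c(chrom[j], pos[j], markers[j], "A", "B", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read biallelic genotypes from a VCF into a dosage matrix
#'
#' Uses \pkg{vcfR}; the dosage counts ALT alleles in the GT field.
#'
#' @param path .vcf or .vcf.gz file.
#' @return individuals x markers integer matrix with NA missing.
#' @export
read_vcf_dosage <- function(path) {
  stop_if(!requireNamespace("vcfR", quietly = TRUE),
          "reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == ".")) NA_integer_
      else sum(al != "0")
    }, integer(1))
  }
  d <- apply(gt, 2, alt_count)
  rownames(d) <- rownames(gt)
  t(d)  # individuals x markers
}

#' Write a genetic map as CSV
#' @param map a \code{genetic_map}.
#' @param path output file.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map)[, c("marker", "chrom", "cM")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a genetic map from CSV
#' @param path file with columns marker, chrom, cM.
#' @return a \code{genetic_map}, sorted within chromosome.
#' @export
read_map_csv <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "cM") %in% names(map)))
  map <- map[order(map$chrom, map$cM), ]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}
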
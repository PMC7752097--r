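#' Write a genotype matrix as VCF
#'
#' Minimal VCFv4.2 writer for integer-coded genotypes (GT field only;
#' alleles are reported as A/T placeholders since the simulator does not
#' model sequence content).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$plants$id), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gm$geno))) {
    g <- gm$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c(gm$markers$chrom[j], gm$markers$pos[j],
                       paste0("m", j), "A", "T", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Parses GT fields of a biallelic VCF into the 0/1/2 dosage coding.
#' Plant metadata must be supplied separately.
#'
#' @param path VCF file.
#' @param plants Optional plant metadata data.frame (default: ids only).
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, plants = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  fields <- strsplit(body, "\t")
  chrom <- vapply(fields, `[`, "", 1)
  pos <- as.numeric(vapply(fields, `[`, "", 2))
  gt <- t(vapply(fields, function(f) {
    g <- sub(":.*", "", f[-(1:9)])
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }, integer(length(ids))))
  if (is.null(plants)) plants <- data.frame(id = ids)
  ord <- order(chrom, pos)
  genotype_matrix(t(gt)[, ord, drop = FALSE],
                  data.frame(chrom = chrom, pos = pos)[ord, ], plants)
}

#' Write gene models as GFF3
#'
#' @param annotation data.frame with gene, chrom, start, end.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(annotation$chrom, "invlocus", "gene",
                   annotation$start, annotation$end, ".", "+", ".",
                   paste0("ID=", annotation$gene), sep = "\t"), con)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED uses 0-based half-open coordinates; input intervals are 1-based
#' inclusive.
#'
#' @param intervals data.frame with chrom, start, end and optionally name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  writeLines(paste(intervals$chrom, intervals$start - 1, intervals$end,
                   nm, sep = "\t"), path)
  invisible(path)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth Truth list from a simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
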
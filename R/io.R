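#' Read a multi-record FASTA file
#'
#' @param path FASTA file (wrapped lines allowed).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a population VCF into a record set
#'
#' Parses CHROM/POS/REF/ALT/QUAL and the per-sample GT, GQ and DP fields of
#' a VCF 4.x file (gzip-aware, via vcfR). Absent GQ or DP FORMAT fields
#' yield all-`NA` matrices with a warning.
#'
#' @param path VCF file.
#' @return A list of class `vcf_records`: `chrom`, `pos`, `ref` (character),
#'   `alt` (list of character vectors, one per site), `qual` (numeric),
#'   `samples`, and site x sample matrices `gt` (genotype strings like
#'   `"0/1"`, `NA` when missing), `gq`, `dp` (numeric).
#' @export
read_population_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  fmt <- c("GQ", "DP")
  num <- lapply(fmt, function(f) {
    m <- tryCatch(vcfR::extract.gt(v, element = f, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("FORMAT field ", f, " absent; treated as missing")
      m <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    }
    m
  })
  recs <- list(chrom = unname(fix[, "CHROM"]),
               pos = as.integer(fix[, "POS"]),
               ref = unname(fix[, "REF"]),
               alt = strsplit(unname(fix[, "ALT"]), ",", fixed = TRUE),
               qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
               samples = colnames(gt),
               gt = gt, gq = num[[1L]], dp = num[[2L]])
  class(recs) <- "vcf_records"
  recs
}

#' @export
print.vcf_records <- function(x, ...) {
  cat("VCF record set:", length(x$pos), "sites x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Number of sites in a record set
#' @param records a `vcf_records` object.
#' @export
n_sites <- function(records) length(records$pos)

# subset a vcf_records object by site index
subset_records <- function(records, i) {
  out <- records
  out$chrom <- records$chrom[i]
  out$pos <- records$pos[i]
  out$ref <- records$ref[i]
  out$alt <- records$alt[i]
  out$qual <- records$qual[i]
  out$gt <- records$gt[i, , drop = FALSE]
  out$gq <- records$gq[i, , drop = FALSE]
  out$dp <- records$dp[i, , drop = FALSE]
  out
}

#' Read an accession-to-population grouping file
#'
#' Two-column TSV (accession, population), no header required; a header
#' line is tolerated if its first field is `accession`.
#'
#' @param path TSV file.
#' @return Named character vector mapping accession id to population.
#' @export
read_grouping <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (tolower(g[1L, 1L]) == "accession") g <- g[-1L, , drop = FALSE]
  stats::setNames(as.character(g[[2L]]), as.character(g[[1L]]))
}

#' Write an accession-to-population grouping file
#' @param grouping named character vector (names are accession ids).
#' @param path output TSV.
#' @export
write_grouping <- function(grouping, path) {
  utils::write.table(data.frame(accession = names(grouping),
                                population = unname(grouping)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
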
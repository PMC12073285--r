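#' Codominant diploid genotype matrix
#'
#' Container for accession x locus diploid calls with integer allele labels
#' (fragment sizes in bp). Missing calls are `NA` in both allele slots.
#'
#' @param a1,a2 integer matrices (accessions x loci) holding the two allele
#'   labels of every call; a call must be missing (`NA`) in both or neither.
#' @param accession_ids,locus_ids unique row and column identifiers; taken
#'   from dimnames when omitted.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, accession_ids = rownames(a1),
                            locus_ids = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)))
  if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(nrow(a1)))
  if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(ncol(a1)))
  stopifnot(!anyDuplicated(accession_ids), !anyDuplicated(locus_ids))
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls: a1 and a2 must be missing together")
  mode(a1) <- "integer"; mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(accession_ids, locus_ids)
  structure(list(a1 = a1, a2 = a2), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype matrix:", nrow(x$a1), "accessions x", ncol(x$a1), "loci;",
      sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Accession and locus identifiers of a genotype matrix
#' @param matrix a `genotype_matrix`.
#' @export
accessions <- function(matrix) rownames(matrix$a1)

#' @rdname accessions
#' @export
loci <- function(matrix) colnames(matrix$a1)

#' Extract the two allele vectors of one locus
#' @param matrix a `genotype_matrix`.
#' @param locus_id locus identifier.
#' @return List with integer vectors `a1`, `a2` (named by accession).
#' @export
genotype_calls <- function(matrix, locus_id) {
  if (!locus_id %in% colnames(matrix$a1))
    stop("locus ", locus_id, " not present")
  list(a1 = matrix$a1[, locus_id], a2 = matrix$a2[, locus_id])
}

#' Subset a genotype matrix
#' @param matrix a `genotype_matrix`.
#' @param accession_ids,locus_ids identifiers to keep (default: all).
#' @export
subset_genotypes <- function(matrix, accession_ids = accessions(matrix),
                             locus_ids = loci(matrix)) {
  genotype_matrix(matrix$a1[accession_ids, locus_ids, drop = FALSE],
                  matrix$a2[accession_ids, locus_ids, drop = FALSE])
}

#' Allele frequencies at a locus
#'
#' @param matrix a `genotype_matrix`.
#' @param locus_id locus identifier.
#' @return Named numeric vector p over allele labels (sorted ascending);
#'   sums to 1. Errors when every call is missing.
#' @export
allele_frequencies <- function(matrix, locus_id) {
  g <- genotype_calls(matrix, locus_id)
  alleles <- c(g$a1, g$a2)
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L) stop("all calls missing at locus ", locus_id)
  tab <- table(alleles)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p[order(as.integer(names(p)))]
}

#' Fixation index from heterozygosities
#'
#' F = (He - Ho) / He; defined as 0 when He = 0 (monomorphic locus).
#'
#' @param ho observed heterozygosity.
#' @param he expected heterozygosity.
#' @export
#' @examples
#' fixation_index(0.671, 0.599)  # heterozygote excess, F < 0
fixation_index <- function(ho, he) ifelse(he == 0, 0, (he - ho) / he)

#' Polymorphism information content from allele frequencies
#'
#' Botstein's PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2, the form
#' computed by the Cervus software for codominant loci.
#'
#' @param p allele frequency vector.
#' @export
pic_from_freqs <- function(p) {
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Per-locus diversity statistics
#'
#' Computes the standard codominant diversity bundle at one locus: number of
#' genotyped accessions N, observed alleles Na, effective alleles
#' Ne = 1/sum(p^2), Shannon's information index I = -sum(p ln p), observed
#' heterozygosity Ho, Nei's expected heterozygosity He = 1 - sum(p^2)
#' (optionally the unbiased 2N/(2N-1) variant), fixation index
#' F = (He - Ho)/He, and Botstein/Cervus PIC with its low/moderate/high
#' class.
#'
#' @param matrix a `genotype_matrix`.
#' @param locus_id locus identifier.
#' @param unbiased_he use the unbiased small-sample He correction
#'   (GenAlEx's default He column is the biased Nei form, so default FALSE).
#' @return One-row data frame: locus_id, N, Na, Ne, I, Ho, He, F, PIC,
#'   pic_class.
#' @export
#' @examples
#' m <- genotype_matrix(matrix(c(100L, 100L, 100L, 102L), 4, 1),
#'                      matrix(c(100L, 100L, 102L, 102L), 4, 1))
#' locus_stats(m, "locus1")
locus_stats <- function(matrix, locus_id, unbiased_he = FALSE) {
  g <- genotype_calls(matrix, locus_id)
  ok <- !is.na(g$a1)
  n <- sum(ok)
  if (n == 0L) stop("all calls missing at locus ", locus_id)
  p <- allele_frequencies(matrix, locus_id)
  s2 <- sum(p^2)
  he <- 1 - s2
  if (unbiased_he) he <- he * (2 * n) / (2 * n - 1)
  ho <- mean(g$a1[ok] != g$a2[ok])
  pic <- pic_from_freqs(p)
  data.frame(locus_id = locus_id, N = n, Na = length(p), Ne = 1 / s2,
             I = -sum(p * log(p)), Ho = ho, He = he,
             F = fixation_index(ho, he), PIC = pic,
             pic_class = classify_pic(max(0, min(1, pic))),
             stringsAsFactors = FALSE)
}

#' Classify a PIC value
#'
#' Bands: low (PIC < 0.25), moderate (0.25 <= PIC < 0.50),
#' high (PIC >= 0.50).
#'
#' @param pic value in \[0, 1\].
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
classify_pic <- function(pic) {
  if (is.na(pic) || pic < 0 || pic > 1) stop("PIC must be in [0, 1]")
  if (pic < 0.25) "low" else if (pic < 0.50) "moderate" else "high"
}

#' Panel-level diversity summary
#'
#' Per-locus [locus_stats()] for every locus plus an unweighted mean row and
#' the total allele count over loci.
#'
#' @param matrix a `genotype_matrix`.
#' @param unbiased_he passed to [locus_stats()].
#' @return A list of class `panel_summary`: `stats` (per-locus data frame),
#'   `means` (named numeric vector over N, Na, Ne, I, Ho, He, F, PIC), and
#'   `total_alleles` (sum of Na).
#' @export
panel_summary <- function(matrix, unbiased_he = FALSE) {
  stats <- do.call(rbind, lapply(loci(matrix), function(l)
    locus_stats(matrix, l, unbiased_he = unbiased_he)))
  summarize_panel_table(stats)
}

#' Summarise a per-locus statistics table
#'
#' Mean row (unweighted over loci) and total allele count for an existing
#' per-locus statistics table with columns among N, Na, Ne, I, Ho, He, F,
#' PIC. Useful for published tables as well as [panel_summary()] output.
#'
#' @param stats data frame with a `locus_id` column plus numeric statistic
#'   columns.
#' @return A `panel_summary` list (see [panel_summary()]).
#' @export
summarize_panel_table <- function(stats) {
  cols <- intersect(c("N", "Na", "Ne", "I", "Ho", "He", "F", "PIC"),
                    names(stats))
  means <- vapply(stats[cols], mean, numeric(1L))
  structure(list(stats = stats, means = means,
                 total_alleles = if ("Na" %in% cols) sum(stats$Na) else NA),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, digits = 3, ...) {
  df <- x$stats
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("Mean:", paste(sprintf("%s=%.3f", names(x$means), x$means),
                     collapse = " "), "\n")
  if (!is.na(x$total_alleles))
    cat("Total alleles:", x$total_alleles, "\n")
  invisible(x)
}

#' Screen markers on allele count and PIC
#'
#' Keeps loci with at least `min_na` observed alleles and PIC strictly
#' greater than `min_pic`.
#'
#' @param stats per-locus statistics data frame (from [panel_summary()]).
#' @param min_na minimum observed allele count (inclusive).
#' @param min_pic PIC threshold (strict).
#' @return Character vector of selected locus ids.
#' @export
screen_markers <- function(stats, min_na = 3, min_pic = 0.30) {
  stats$locus_id[stats$Na >= min_na & stats$PIC > min_pic]
}

#' Read a GenAlEx-style codominant genotype CSV
#'
#' Layout: a header row `accession[,population],L1,L1,L2,L2,...` with two
#' columns per locus, one data row per accession; `0` encodes a missing
#' allele. An optional `population` second column is returned as the
#' grouping.
#'
#' @param path CSV file.
#' @return A list: `matrix` (a [genotype_matrix()]) and `grouping` (named
#'   vector, or NULL when the file has no population column).
#' @export
read_genalex_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  has_pop <- tolower(names(raw)[2L]) %in% c("pop", "population")
  first_locus <- if (has_pop) 3L else 2L
  ids <- as.character(raw[[1L]])
  grouping <- if (has_pop) stats::setNames(as.character(raw[[2L]]), ids)
              else NULL
  lc <- names(raw)[first_locus:ncol(raw)]
  if (length(lc) %% 2L != 0L) stop("odd number of allele columns")
  locus_ids <- lc[seq(1L, length(lc), by = 2L)]
  vals <- as.matrix(raw[, first_locus:ncol(raw), drop = FALSE])
  mode(vals) <- "integer"
  vals[vals == 0L] <- NA_integer_
  a1 <- vals[, seq(1L, ncol(vals), by = 2L), drop = FALSE]
  a2 <- vals[, seq(2L, ncol(vals), by = 2L), drop = FALSE]
  # a call is missing only when both alleles are 0
  half <- is.na(a1) != is.na(a2)
  if (any(half)) {
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
    warning(sum(half), " half-missing calls set fully missing")
  }
  list(matrix = genotype_matrix(a1, a2, ids, locus_ids), grouping = grouping)
}

#' Write a genotype matrix as GenAlEx-style CSV
#'
#' @param matrix a `genotype_matrix`.
#' @param path output CSV.
#' @param grouping optional named accession-to-population vector, written as
#'   a `population` column.
#' @export
write_genalex_csv <- function(matrix, path, grouping = NULL) {
  a1 <- matrix$a1; a2 <- matrix$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  k <- ncol(a1)
  out <- matrix(0L, nrow(a1), 2L * k)
  out[, seq(1L, 2L * k, by = 2L)] <- a1
  out[, seq(2L, 2L * k, by = 2L)] <- a2
  colnames(out) <- rep(colnames(a1), each = 2L)
  df <- data.frame(accession = rownames(a1), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(grouping))
    df$population <- unname(grouping[rownames(a1)])
  df <- cbind(df, as.data.frame(out, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-locus statistics table to TSV
#'
#' Column order: locus_id, N, Na, Ne, I, Ho, He, F, PIC, pic_class.
#'
#' @param summary a `panel_summary` object.
#' @param path output file.
#' @export
write_stats_table <- function(summary, path) {
  utils::write.table(summary$stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
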
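#' Binary fingerprint matrix from genotypes
#'
#' One column per (locus, allele); a cell is 1 when the accession carries
#' that allele (so a heterozygote sets two bits at its locus, a homozygote
#' one). Missing loci leave all that locus's cells 0 and are recorded in a
#' missing mask.
#'
#' @param matrix a `genotype_matrix`.
#' @return A list of class `fingerprint_matrix`: `binary` (accessions x
#'   allele-columns 0/1 matrix, columns named `"locus:allele"`), `columns`
#'   (data frame locus_id/allele), `missing` (accessions x loci logical
#'   mask), `profiles` (per-accession profile key, missing loci encoded
#'   distinctly).
#' @export
binarize <- function(matrix) {
  acc <- accessions(matrix)
  cols <- list(); blocks <- list()
  for (l in loci(matrix)) {
    g <- genotype_calls(matrix, l)
    alleles <- sort(unique(c(g$a1, g$a2)))
    alleles <- alleles[!is.na(alleles)]
    b <- base::matrix(0L, length(acc), length(alleles),
                      dimnames = list(acc, paste0(l, ":", alleles)))
    ok <- !is.na(g$a1)
    for (j in seq_along(alleles))
      b[ok, j] <- as.integer(g$a1[ok] == alleles[j] |
                             g$a2[ok] == alleles[j])
    blocks[[l]] <- b
    cols[[l]] <- data.frame(locus_id = l, allele = alleles,
                            stringsAsFactors = FALSE)
  }
  binary <- do.call(cbind, blocks)
  miss <- is.na(matrix$a1)
  # profile keys: per-locus bit strings, a fully missing locus rendered as
  # "?" marks so it cannot collide with an all-zero observed pattern
  offsets <- cumsum(c(0L, vapply(blocks, ncol, integer(1L))))
  profiles <- vapply(seq_along(acc), function(i) {
    parts <- character(length(blocks))
    for (li in seq_along(blocks)) {
      rng <- (offsets[li] + 1L):offsets[li + 1L]
      parts[li] <- if (miss[i, li]) strrep("?", length(rng))
                   else paste(binary[i, rng], collapse = "")
    }
    paste(parts, collapse = "|")
  }, character(1L))
  structure(list(binary = binary,
                 columns = do.call(rbind, c(cols, make.row.names = FALSE)),
                 missing = miss, profiles = stats::setNames(profiles, acc)),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("fingerprint matrix:", nrow(x$binary), "accessions x",
      ncol(x$binary), "allele columns\n")
  invisible(x)
}

#' Discrimination rate of a fingerprint panel
#'
#' Groups accessions sharing an identical fingerprint profile and reports
#' the fraction unambiguously distinguished: every member of a group of two
#' or more counts as ambiguous, so the rate is
#' `100 * (n - sum of sizes of groups >= 2) / n`. With
#' `treat_missing = "strict"` (default) a missing locus is part of the
#' profile and distinguishes; with `"ignore"` profiles that agree wherever
#' both are observed are linked (transitively) into one group.
#'
#' @param fp a [binarize()] result.
#' @param treat_missing `"strict"` or `"ignore"`.
#' @return A list of class `discrimination_report`: `n_accessions`,
#'   `groups` (list of accession-id vectors, size >= 2 only),
#'   `n_unambiguous`, `rate` (percent, 2 dp).
#' @export
discrimination <- function(fp, treat_missing = c("strict", "ignore")) {
  treat_missing <- match.arg(treat_missing)
  acc <- rownames(fp$binary)
  n <- length(acc)
  if (n < 2L) stop("need at least two accessions")
  if (treat_missing == "strict") {
    sp <- split(acc, fp$profiles)
  } else {
    # wildcard match on missing loci; transitive closure via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    miss <- fp$missing
    offsets <- cumsum(c(0L, as.integer(table(factor(
      fp$columns$locus_id, levels = unique(fp$columns$locus_id))))))
    nl <- ncol(miss)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      same <- TRUE
      for (li in seq_len(nl)) {
        if (miss[i, li] || miss[j, li]) next
        rng <- (offsets[li] + 1L):offsets[li + 1L]
        if (any(fp$binary[i, rng] != fp$binary[j, rng])) {
          same <- FALSE; break
        }
      }
      if (same) parent[find(j)] <- find(i)
    }
    comp <- vapply(seq_len(n), find, integer(1L))
    sp <- split(acc, comp)
  }
  groups <- sp[vapply(sp, length, integer(1L)) >= 2L]
  names(groups) <- NULL
  n_amb <- sum(vapply(groups, length, integer(1L)))
  rate <- round(100 * (n - n_amb) / n, 2)
  structure(list(n_accessions = n, groups = groups,
                 n_unambiguous = n - n_amb, rate = rate),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("discrimination:", x$n_unambiguous, "of", x$n_accessions,
      sprintf("accessions unambiguous (%.2f%%)\n", x$rate))
  for (g in x$groups)
    cat("  shared profile:", paste(g, collapse = ", "), "\n")
  invisible(x)
}

#' Write a fingerprint matrix to CSV
#'
#' Accessions x allele columns, header `locus:allele`.
#'
#' @param fp a [binarize()] result.
#' @param path output CSV.
#' @export
write_fingerprint_csv <- function(fp, path) {
  utils::write.csv(as.data.frame(fp$binary), path, quote = FALSE)
  invisible(path)
}

#' Write a discrimination report as JSON
#' @param report a [discrimination()] result.
#' @param path output file.
#' @export
write_discrimination_json <- function(report, path) {
  jsonlite::write_json(list(n_accessions = report$n_accessions,
                            n_unambiguous = report$n_unambiguous,
                            rate_percent = report$rate,
                            ambiguous_groups = report$groups),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
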
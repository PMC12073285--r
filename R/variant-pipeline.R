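#' Variant quality-control thresholds
#'
#' Site- and call-level thresholds for filtering population variants before
#' SSR marker selection: site QUAL > `min_qual`, per-call GQ > `min_gq` and
#' DP within `dp_range` (inclusive; failing calls are set missing), then a
#' site-level allele-frequency/missingness rule. Under `maf_mode = "lt"`
#' (default) a site is kept when its minor allele frequency is below
#' `maf_bound` *or* its post-masking missing rate is at most
#' `max_missing_rate` — the literal low-frequency-prioritising disjunction.
#' Under the conventional `maf_mode = "ge"` a site is kept when MAF is at
#' least `maf_bound` *and* the missing rate is at most `max_missing_rate`.
#'
#' @param min_qual minimum site QUAL (strict).
#' @param min_gq minimum per-call genotype quality (strict).
#' @param dp_range inclusive per-call depth bounds.
#' @param maf_bound minor-allele-frequency bound.
#' @param max_missing_rate maximum fraction of missing calls per site.
#' @param maf_mode `"lt"` or `"ge"`, see Details above.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_qual = 40, min_gq = 40, dp_range = c(5, 100),
                          maf_bound = 0.05, max_missing_rate = 0.05,
                          maf_mode = c("lt", "ge")) {
  maf_mode <- match.arg(maf_mode)
  stopifnot(dp_range[1L] <= dp_range[2L],
            maf_bound >= 0, maf_bound <= 1,
            max_missing_rate >= 0, max_missing_rate <= 1)
  structure(list(min_qual = min_qual, min_gq = min_gq, dp_range = dp_range,
                 maf_bound = maf_bound, max_missing_rate = max_missing_rate,
                 maf_mode = maf_mode),
            class = "qc_thresholds")
}

#' Keep only long insertion/deletion variants
#'
#' Retains sites where at least one ALT allele differs from REF by more than
#' `min_len_diff` nucleotides in length. SNPs and short InDels are dropped.
#' Malformed alleles (non-DNA characters, `.` placeholders, symbolic
#' alleles) trigger a per-record warning and the record is skipped; the
#' number skipped is reported in the `n_malformed` attribute.
#'
#' @param records a `vcf_records` object.
#' @param min_len_diff strict length-difference threshold in nt (default 10,
#'   i.e. keep |len(alt) - len(ref)| > 10).
#' @return The filtered `vcf_records`, with attribute `n_malformed`.
#' @export
extract_long_indels <- function(records, min_len_diff = 10L) {
  ok_allele <- function(a) length(a) > 0L && !any(grepl("[^ACGTNacgtn]", a))
  malformed <- 0L
  keep <- logical(n_sites(records))
  for (i in seq_along(keep)) {
    ref <- records$ref[i]
    alts <- records$alt[[i]]
    if (!ok_allele(ref) || !ok_allele(alts)) {
      malformed <- malformed + 1L
      warning("malformed alleles at ", records$chrom[i], ":",
              records$pos[i], "; record skipped")
      next
    }
    keep[i] <- any(abs(nchar(alts) - nchar(ref)) > min_len_diff)
  }
  out <- subset_records(records, which(keep))
  attr(out, "n_malformed") <- malformed
  out
}

# per-site allele frequencies from genotype strings ("0/1", "0|1", NA)
.site_allele_freqs <- function(gt_row) {
  alleles <- unlist(strsplit(gt_row[!is.na(gt_row)], "[/|]"))
  alleles <- alleles[alleles != "."]
  if (length(alleles) == 0L) return(numeric(0L))
  tab <- table(alleles)
  as.numeric(tab) / sum(tab)
}

# minor allele frequency: frequency of the second most common allele
# (0 when monomorphic)
.site_maf <- function(gt_row) {
  p <- sort(.site_allele_freqs(gt_row), decreasing = TRUE)
  if (length(p) < 2L) 0 else p[2L]
}

#' Apply variant quality control
#'
#' Calls failing GQ (strict) or DP (inclusive bounds) are set missing first;
#' site-level missing rate and MAF are then computed on the masked
#' genotypes, and a site passes when `QUAL > min_qual` and the
#' MAF/missing-rate rule of [qc_thresholds()] holds.
#'
#' @param records a `vcf_records` object.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with `records` (passing sites, with masked GT), `tally`
#'   (named integer vector of per-rule site rejections plus masked-call
#'   counts `calls_masked_gq` / `calls_masked_dp`), and `site_stats`
#'   (per-input-site data frame of qual, maf, missing rate and pass flag).
#' @export
apply_qc <- function(records, thresholds = qc_thresholds()) {
  gt <- records$gt
  gq <- records$gq
  dp <- records$dp
  fail_gq <- !is.na(gt) & !is.na(gq) & gq <= thresholds$min_gq
  fail_dp <- !is.na(gt) & !is.na(dp) &
    (dp < thresholds$dp_range[1L] | dp > thresholds$dp_range[2L])
  gt[fail_gq | fail_dp] <- NA_character_

  ns <- n_sites(records)
  miss <- numeric(ns)
  maf <- numeric(ns)
  for (i in seq_len(ns)) {
    row <- gt[i, ]
    miss[i] <- mean(is.na(row) | row %in% c("./.", ".|.", "."))
    maf[i] <- .site_maf(row)
  }
  qual_ok <- !is.na(records$qual) & records$qual > thresholds$min_qual
  rate_ok <- if (thresholds$maf_mode == "lt") {
    (maf < thresholds$maf_bound) | (miss <= thresholds$max_missing_rate)
  } else {
    (maf >= thresholds$maf_bound) & (miss <= thresholds$max_missing_rate)
  }
  pass <- qual_ok & rate_ok
  tally <- c(qual = sum(!qual_ok),
             maf_missing = sum(qual_ok & !rate_ok),
             calls_masked_gq = sum(fail_gq),
             calls_masked_dp = sum(fail_dp & !fail_gq))
  out <- subset_records(records, which(pass))
  out$gt <- gt[pass, , drop = FALSE]
  list(records = out, tally = tally,
       site_stats = data.frame(chrom = records$chrom, pos = records$pos,
                               qual = records$qual, maf = maf,
                               missing_rate = miss, pass = pass,
                               stringsAsFactors = FALSE))
}

#' Mine SSRs from long InDel alleles
#'
#' Runs [find_ssrs()] on the inserted (ALT longer than REF) or deleted (REF
#' longer) allele sequence of every ALT whose length difference from REF
#' exceeds `min_len_diff`; each hit becomes a locus candidate annotated with
#' the source site.
#'
#' @param records long-InDel `vcf_records` (see [extract_long_indels()]).
#' @param criteria a [repeat_criteria()] object.
#' @param min_len_diff same threshold as in [extract_long_indels()].
#' @return Data frame of candidates: `chrom`, `pos`, `locus_id`
#'   (`"chrom_pos"`), `allele` (ALT index), plus the [find_ssrs()] hit
#'   columns.
#' @export
mine_variant_ssrs <- function(records, criteria = repeat_criteria(),
                              min_len_diff = 10L) {
  out <- list()
  for (i in seq_len(n_sites(records))) {
    ref <- toupper(records$ref[i])
    alts <- toupper(records$alt[[i]])
    for (j in seq_along(alts)) {
      if (abs(nchar(alts[j]) - nchar(ref)) <= min_len_diff) next
      allele_seq <- if (nchar(alts[j]) > nchar(ref)) alts[j] else ref
      hits <- find_ssrs(allele_seq, criteria,
                        seq_id = paste0(records$chrom[i], ":",
                                        records$pos[i], ":alt", j))
      if (nrow(hits) == 0L) next
      hits$chrom <- records$chrom[i]
      hits$pos <- records$pos[i]
      hits$locus_id <- paste(records$chrom[i], records$pos[i], sep = "_")
      hits$allele <- j
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      locus_id = character(), allele = integer(),
                      seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical_label = character(), repeat_count = integer(),
                      motif_len = integer(), compound = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, lapply(out, as.data.frame))
  rownames(res) <- NULL
  res[, c("chrom", "pos", "locus_id", "allele", "seq_id", "start", "end",
          "motif", "canonical_label", "repeat_count", "motif_len",
          "compound")]
}

#' Collapse SSR candidates to genomic loci
#'
#' One locus per (chrom, pos); `n_supporting_sequences` counts the collapsed
#' candidates. When candidates at one site disagree on the motif, the
#' majority motif is kept and the conflict logged as a warning.
#'
#' @param candidates output of [mine_variant_ssrs()].
#' @return Data frame of class `ssr_loci`: `locus_id`, `chrom`, `pos`,
#'   `motif`, `canonical_label`, `motif_len`, `n_supporting_sequences`, and
#'   flags `mononucleotide`, `compound`.
#' @export
collapse_to_loci <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(structure(data.frame(locus_id = character(), chrom = character(),
                                pos = integer(), motif = character(),
                                canonical_label = character(),
                                motif_len = integer(),
                                n_supporting_sequences = integer(),
                                mononucleotide = logical(),
                                compound = logical(),
                                stringsAsFactors = FALSE),
                     class = c("ssr_loci", "data.frame")))
  sp <- split(candidates, candidates$locus_id)
  rows <- lapply(sp, function(d) {
    tab <- sort(table(d$motif), decreasing = TRUE)
    motif <- names(tab)[1L]
    if (length(tab) > 1L)
      warning("conflicting motifs at ", d$locus_id[1L], "; keeping ", motif)
    data.frame(locus_id = d$locus_id[1L], chrom = d$chrom[1L],
               pos = d$pos[1L], motif = motif,
               canonical_label = canonical_motif(motif),
               motif_len = nchar(motif),
               n_supporting_sequences = nrow(d),
               mononucleotide = nchar(motif) == 1L,
               compound = any(d$compound),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  class(loci) <- c("ssr_loci", "data.frame")
  loci
}

#' Drop mononucleotide and compound loci
#'
#' Removes loci flagged mononucleotide, loci whose mined tract was compound,
#' and loci lying within `max_gap` bp of another locus on the same sequence
#' (which makes both compound). Input order is preserved.
#'
#' @param loci an `ssr_loci` data frame.
#' @param max_gap adjacency threshold in bp (default 100).
#' @return The filtered `ssr_loci`.
#' @export
filter_locus_classes <- function(loci, max_gap = 100L) {
  if (nrow(loci) == 0L) return(loci)
  near <- logical(nrow(loci))
  for (ch in unique(loci$chrom)) {
    i <- which(loci$chrom == ch)
    if (length(i) < 2L) next
    o <- i[order(loci$pos[i])]
    d <- diff(loci$pos[o])
    adj <- d <= max_gap
    near[o] <- near[o] | c(adj, FALSE) | c(FALSE, adj)
  }
  out <- loci[!loci$mononucleotide & !loci$compound & !near, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssr_loci", "data.frame")
  out
}

#' Ranked genotype frequencies at a locus
#'
#' Counts unordered diploid genotypes over the non-missing accessions of a
#' [genotype_matrix()] and returns frequencies in non-increasing order.
#'
#' @param matrix a `genotype_matrix`.
#' @param locus_id locus to summarise.
#' @return A list of class `genotype_freqs`: `locus_id`, `n_genotyped`,
#'   `genotypes` (labels `"a/b"`, a <= b), `freq` (non-increasing, sums
#'   to 1).
#' @export
genotype_frequencies <- function(matrix, locus_id) {
  g <- genotype_calls(matrix, locus_id)
  ok <- !is.na(g$a1) & !is.na(g$a2)
  if (!any(ok)) stop("all calls missing at locus ", locus_id)
  lab <- paste(pmin(g$a1[ok], g$a2[ok]), pmax(g$a1[ok], g$a2[ok]), sep = "/")
  tab <- sort(table(lab), decreasing = TRUE)
  structure(list(locus_id = locus_id, n_genotyped = sum(ok),
                 genotypes = names(tab),
                 freq = as.numeric(tab) / sum(tab)),
            class = "genotype_freqs")
}

#' Keep loci with a secondary common genotype
#'
#' A locus is retained when its second-ranked genotype frequency is at least
#' `min_secondary`; the `has_secondary_genotype` flag is recorded on the
#' result. Loci with a single observed genotype are always dropped.
#'
#' @param loci an `ssr_loci` data frame.
#' @param summaries list of [genotype_frequencies()] results, one per locus
#'   (named by locus_id, or in locus order).
#' @param min_secondary minimum frequency of the second-most-common
#'   genotype.
#' @return The filtered `ssr_loci` with a `has_secondary_genotype` column.
#' @export
select_candidates <- function(loci, summaries, min_secondary = 0.05) {
  if (is.null(names(summaries)))
    names(summaries) <- vapply(summaries, `[[`, character(1L), "locus_id")
  sec <- vapply(loci$locus_id, function(id) {
    s <- summaries[[id]]
    if (is.null(s) || length(s$freq) < 2L) 0 else s$freq[2L]
  }, numeric(1L))
  loci$has_secondary_genotype <- sec >= min_secondary
  out <- loci[loci$has_secondary_genotype, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssr_loci", "data.frame")
  out
}

#' Write an SSR locus table to TSV
#' @param loci an `ssr_loci` data frame.
#' @param path output file.
#' @export
write_ssr_loci <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
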
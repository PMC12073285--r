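# build a minimal vcf_records object in memory
mk_records <- function(chrom, pos, ref, alt, qual, gt, gq = NULL, dp = NULL) {
  ns <- length(pos)
  k <- ncol(gt)
  if (is.null(gq)) gq <- matrix(99, ns, k)
  if (is.null(dp)) dp <- matrix(30, ns, k)
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alt = alt, qual = qual,
                 samples = paste0("S", seq_len(k)),
                 gt = gt, gq = gq, dp = dp),
            class = "vcf_records")
}

test_that("long-InDel extraction keeps only strict >10 nt length changes", {
  gt <- matrix("0/1", 3, 2)
  r <- mk_records(rep("sc1", 3), c(100, 200, 300),
                  ref = c("A", "A", "A"),
                  alt = list(paste0("A", strrep("TA", 6)),   # +12
                             paste0("A", strrep("TA", 5)),   # +10, dropped
                             "G"),                           # SNP
                  qual = c(90, 90, 90), gt = gt)
  out <- extract_long_indels(r)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$pos, 100L)
  # deletions count symmetrically
  r2 <- mk_records("sc1", 100, ref = paste0("A", strrep("CT", 7)),
                   alt = list("A"), qual = 90, gt = matrix("0/0", 1, 2))
  expect_equal(n_sites(extract_long_indels(r2)), 1L)
  # malformed allele: warned and skipped
  r3 <- mk_records("sc1", 5, ref = "<DEL>", alt = list("A"), qual = 90,
                   gt = matrix("0/0", 1, 2))
  expect_warning(out3 <- extract_long_indels(r3), "malformed")
  expect_equal(n_sites(out3), 0L)
  expect_equal(attr(out3, "n_malformed"), 1L)
})

test_that("QC masks calls on GQ/DP then filters sites on QUAL and MAF/missing", {
  # QUAL strictly > 40
  gt <- matrix("0/1", 2, 4)
  r <- mk_records(rep("sc1", 2), c(1, 2), c("A", "A"),
                  list("T", "T"), qual = c(39.9, 40.5), gt = gt)
  res <- apply_qc(r)
  expect_equal(n_sites(res$records), 1L)
  expect_equal(res$tally[["qual"]], 1L)
  # DP bounds inclusive: 5 retained, 4 masked (masking precedes site rates)
  gt <- matrix(c("0/0", "0/1", "1/1", "0/1"), 1, 4)
  dp <- matrix(c(5, 4, 100, 101), 1, 4)
  r <- mk_records("sc1", 1, "A", list("T"), qual = 90, gt = gt, dp = dp)
  res <- apply_qc(r, qc_thresholds(max_missing_rate = 0.6))
  expect_equal(res$tally[["calls_masked_dp"]], 2L)
  expect_equal(res$site_stats$missing_rate, 0.5)
  expect_equal(sum(is.na(res$records$gt)), 2L)
  expect_false(is.na(res$records$gt[1, 1]))  # DP 5 kept
  # GQ strictly > 40: GQ 40 masked
  gq <- matrix(c(41, 40, 99, 99), 1, 4)
  r <- mk_records("sc1", 1, "A", list("T"), qual = 90, gt = gt, gq = gq)
  res <- apply_qc(r)
  expect_equal(res$tally[["calls_masked_gq"]], 1L)
})

test_that("literal MAF-or-missing disjunction matches the worked case", {
  # 60 samples, 4 missing (6.7%), MAF 0.3: fails both disjuncts under "lt"
  gt <- matrix("0/0", 1, 60)
  gt[1, 1:18] <- "0/1"  # 36 non-missing after masking -> compute below
  gt[1, 57:60] <- "./."
  r <- mk_records("sc1", 1, "A", list("T"), qual = 90, gt = gt)
  st <- apply_qc(r)$site_stats
  expect_gt(st$maf, 0.05)
  expect_gt(st$missing_rate, 0.05)
  expect_false(st$pass)
  res_ge <- apply_qc(r, qc_thresholds(maf_mode = "ge"))
  expect_false(res_ge$site_stats$pass)   # missing still too high
  # same genotypes, no missing: the "lt" disjunction keeps it (missing
  # rate disjunct holds), as does the conventional "ge" conjunction
  gt2 <- gt; gt2[1, 57:60] <- "0/0"
  r2 <- mk_records("sc1", 1, "A", list("T"), qual = 90, gt = gt2)
  expect_true(apply_qc(r2)$site_stats$pass)
  expect_true(apply_qc(r2, qc_thresholds(maf_mode = "ge"))$site_stats$pass)
  # rejection tallies account for every dropped site
  both <- mk_records(rep("sc1", 3), 1:3, c("A", "A", "A"),
                     list("T", "T", "T"), qual = c(10, 90, 90),
                     gt = rbind(gt, gt, gt2))
  res <- apply_qc(both)
  expect_equal(res$tally[["qual"]], 1L)
  expect_equal(res$tally[["maf_missing"]], 1L)
  expect_equal(sum(res$tally[c("qual", "maf_missing")]),
               n_sites(both) - n_sites(res$records))
})

test_that("variant SSR mining annotates hits with their source site", {
  r <- mk_records("Scaffold_1", 500, "A",
                  list(c(paste0("A", strrep("AT", 6)), "T")),
                  qual = 90, gt = matrix("0/1", 1, 2))
  cand <- mine_variant_ssrs(r)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$locus_id, "Scaffold_1_500")
  expect_equal(cand$motif, "AT")
  # two repeat-bearing alts at one site both contribute candidates
  r2 <- mk_records("sc1", 9, paste0("A", strrep("GA", 8)),
                   list(c("A", paste0("A", strrep("GA", 16)))),
                   qual = 90, gt = matrix("0/1", 1, 2))
  cand2 <- mine_variant_ssrs(r2)
  expect_equal(nrow(cand2), 2L)
  expect_equal(unique(cand2$locus_id), "sc1_9")
  loci <- collapse_to_loci(cand2)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_supporting_sequences, 2L)
  # allele with no qualifying repeat yields nothing
  r3 <- mk_records("sc1", 1, "A",
                   list(paste0("A", "GGCTTCAGTCCGGATTCAAGGCCTGACGGT")),
                   qual = 90, gt = matrix("0/1", 1, 2))
  expect_equal(nrow(mine_variant_ssrs(r3)), 0L)
})

test_that("locus collapse keys on chrom_pos and majority motif wins", {
  cand <- data.frame(
    chrom = c("sc1", "sc1", "sc1", "sc2"), pos = c(10L, 10L, 10L, 10L),
    locus_id = c("sc1_10", "sc1_10", "sc1_10", "sc2_10"),
    allele = 1:4, seq_id = "x", start = 1L, end = 12L,
    motif = c("AT", "AT", "TA", "CTT"),
    canonical_label = "", repeat_count = 6L,
    motif_len = c(2L, 2L, 2L, 3L), compound = FALSE,
    stringsAsFactors = FALSE)
  expect_warning(loci <- collapse_to_loci(cand), "conflicting")
  expect_equal(nrow(loci), 2L)
  l1 <- loci[loci$locus_id == "sc1_10", ]
  expect_equal(l1$motif, "AT")
  expect_equal(l1$n_supporting_sequences, 3L)
})

test_that("class filter drops mono, compound and adjacent loci", {
  loci <- data.frame(
    locus_id = paste0("sc1_", c(100, 5000, 5040, 9000, 12000)),
    chrom = "sc1", pos = c(100L, 5000L, 5040L, 9000L, 12000L),
    motif = c("A", "AT", "GA", "CTT", "AT"),
    canonical_label = "", motif_len = c(1L, 2L, 2L, 3L, 2L),
    n_supporting_sequences = 1L,
    mononucleotide = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    compound = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  class(loci) <- c("ssr_loci", "data.frame")
  out <- filter_locus_classes(loci)
  # mono dropped; 5000/5040 dropped as 40 bp apart; compound dropped
  expect_equal(out$locus_id, "sc1_9000")
})

test_that("genotype frequencies are ranked and candidate selection applies", {
  m <- gm_from_calls(list(c(100L, 100L, 100L, 102L),
                          c(100L, 100L, 102L, 102L)))
  gf <- genotype_frequencies(m, "locus1")
  expect_equal(gf$freq, c(0.5, 0.25, 0.25))
  expect_equal(sum(gf$freq), 1)
  expect_true(all(diff(gf$freq) <= 0))
  # monomorphic -> single frequency 1, locus excluded
  mono <- gm_from_calls(list(rep(100L, 4), rep(100L, 4)))
  expect_equal(genotype_frequencies(mono, "locus1")$freq, 1)
  loci <- data.frame(locus_id = "locus1", chrom = "c", pos = 1L,
                     motif = "AT", canonical_label = "", motif_len = 2L,
                     n_supporting_sequences = 1L, mononucleotide = FALSE,
                     compound = FALSE, stringsAsFactors = FALSE)
  class(loci) <- c("ssr_loci", "data.frame")
  expect_equal(nrow(select_candidates(loci,
                                      list(genotype_frequencies(mono,
                                                                "locus1")))),
               0L)
  expect_equal(nrow(select_candidates(loci,
                                      list(genotype_frequencies(m,
                                                                "locus1")))),
               1L)
  # a 0.97/0.03 split fails the default 0.05 secondary threshold
  rare <- gm_from_calls(list(c(rep(100L, 97), rep(102L, 3)),
                             c(rep(100L, 97), rep(102L, 3))))
  expect_equal(nrow(select_candidates(loci,
                                      list(genotype_frequencies(rare,
                                                                "locus1")))),
               0L)
  # all-missing locus errors
  mm <- genotype_matrix(matrix(NA_integer_, 3, 1), matrix(NA_integer_, 3, 1))
  expect_error(genotype_frequencies(mm, "locus1"), "missing")
})
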
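# Dirichlet draw via gamma variates; alpha > 0
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

.BASES <- c("A", "C", "G", "T")

# replace [a, b] of a character vector with fresh random bases
.rand_bases <- function(n) sample(.BASES, n, replace = TRUE)

#' Simulate a reference with planted SSR tracts
#'
#' Generates scaffolds of random, SSR-free background sequence (detected
#' tracts in the background are re-randomised until none remain) and plants
#' perfect repeat tracts at recorded coordinates, with breaker bases at the
#' tract boundaries so planted repeats are exactly maximal. Positions are
#' spaced at least `min_spacing` bp apart (and away from scaffold ends), so
#' planted tracts are non-compound by construction.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length scaffold length in bp.
#' @param n_ssrs_per_scaffold planted tracts per scaffold.
#' @param motif_pool motifs sampled for planting.
#' @param count_range repeat-count range sampled per tract (counts at or
#'   above the detection minimum for the motif length; pass counts below it
#'   to plant sub-threshold tracts).
#' @param min_spacing minimum distance between planted tract starts, bp.
#' @param criteria [repeat_criteria()] used for background cleaning.
#' @param seed integer seed; fixes the output exactly.
#' @return A list of class `sim_reference`: `sequences` (named character
#'   vector) and `truth` (data frame seq_id, start, end, motif,
#'   repeat_count, motif_len).
#' @export
simulate_reference <- function(n_scaffolds = 2L, scaffold_length = 10000L,
                               n_ssrs_per_scaffold = 5L,
                               motif_pool = c("AT", "TA", "AG", "CA",
                                              "TAT", "AAT", "CTT", "ATG",
                                              "ATAC", "TATG"),
                               count_range = c(6L, 15L),
                               min_spacing = 400L,
                               criteria = repeat_criteria(),
                               seed = 1L) {
  set.seed(seed)
  need <- n_ssrs_per_scaffold * min_spacing + 2L * min_spacing
  if (n_ssrs_per_scaffold > 0L && scaffold_length < need)
    stop("scaffold too short to pack ", n_ssrs_per_scaffold,
         " tracts at spacing ", min_spacing)
  seqs <- character(n_scaffolds)
  truth <- list()
  for (sc in seq_len(n_scaffolds)) {
    sid <- paste0("Scaffold_", sc)
    s <- .rand_bases(scaffold_length)
    # scrub spontaneous background repeats
    for (iter in 1:50) {
      hits <- find_ssrs(paste(s, collapse = ""), criteria, seq_id = sid)
      if (nrow(hits) == 0L) break
      for (h in seq_len(nrow(hits))) {
        a <- max(1L, hits$start[h] - 2L)
        b <- min(scaffold_length, hits$end[h] + 2L)
        s[a:b] <- .rand_bases(b - a + 1L)
      }
    }
    if (n_ssrs_per_scaffold > 0L) {
      slots <- seq(from = min_spacing,
                   by = (scaffold_length - 2L * min_spacing) %/%
                        max(1L, n_ssrs_per_scaffold),
                   length.out = n_ssrs_per_scaffold)
      starts <- slots + sample.int(50L, n_ssrs_per_scaffold, replace = TRUE)
      for (t in seq_len(n_ssrs_per_scaffold)) {
        motif <- sample(motif_pool, 1L)
        m <- nchar(motif)
        count <- sample(count_range[1L]:count_range[2L], 1L)
        a <- starts[t]
        b <- a + m * count - 1L
        tract <- strsplit(strrep(motif, count), "", fixed = TRUE)[[1L]]
        s[a:b] <- tract
        # breaker bases: differ from the periodic continuation on each side
        s[a - 1L] <- sample(setdiff(.BASES, tract[m]), 1L)
        s[b + 1L] <- sample(setdiff(.BASES, tract[1L]), 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = sid, start = a, end = b, motif = motif,
          repeat_count = count, motif_len = m, stringsAsFactors = FALSE)
      }
    }
    seqs[sc] <- paste(s, collapse = "")
    names(seqs)[sc] <- sid
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(seq_id = character(), start = integer(),
                           end = integer(), motif = character(),
                           repeat_count = integer(), motif_len = integer())
  structure(list(sequences = seqs, truth = truth), class = "sim_reference")
}

#' Simulate a population VCF at planted SSR loci
#'
#' Emits one InDel site per planted tract of a [simulate_reference()]
#' result: REF is the anchor base plus the reference tract, ALT alleles are
#' repeat-count expansions or contractions whose length differences exceed
#' the long-InDel threshold (unless `short_allele_fraction` plants some
#' below it). Per-sample genotypes are drawn under Hardy-Weinberg from
#' Balding-Nichols subpopulation allele frequencies; QUAL, GQ and DP are
#' drawn so that known fractions of sites/calls violate the default QC
#' thresholds, and all planted outcomes are recorded in the truth table.
#'
#' @param reference a `sim_reference` object.
#' @param n_accessions samples in the VCF.
#' @param n_subpops subpopulations.
#' @param divergence Balding-Nichols divergence parameter in \[0, 1).
#' @param n_alts ALT alleles per site.
#' @param qual_fail_rate fraction of sites with QUAL below 40.
#' @param gq_fail_rate,dp_fail_rate fraction of calls with GQ at or below
#'   40 / DP outside 5-100.
#' @param missing_rate fraction of calls written as `./.`.
#' @param short_allele_fraction fraction of sites whose alt length
#'   differences are all 10 nt or less (so they are dropped by the
#'   long-InDel rule).
#' @param seed integer seed.
#' @return A list of class `sim_vcf`: `site_truth` (per-site locus_id,
#'   coordinates, motif, qual, flags qual_pass and long_indel),
#'   `genotype_truth` (accession x site allele-index matrices `a1`, `a2`;
#'   NA where written missing), `subpop` (accession assignment), `vcf_lines`
#'   (character vector, written by [write_sim_vcf()]).
#' @export
simulate_population_vcf <- function(reference, n_accessions = 60L,
                                    n_subpops = 3L, divergence = 0.07,
                                    n_alts = 2L, qual_fail_rate = 0.2,
                                    gq_fail_rate = 0.02,
                                    dp_fail_rate = 0.02,
                                    missing_rate = 0.01,
                                    short_allele_fraction = 0,
                                    seed = 1L) {
  set.seed(seed)
  truth <- reference$truth
  ns <- nrow(truth)
  if (ns == 0L) stop("reference has no planted tracts")
  acc <- sprintf("ACC%03d", seq_len(n_accessions))
  subpop <- stats::setNames(
    paste0("P", rep_len(seq_len(n_subpops), n_accessions)), acc)
  qual_fail <- stats::runif(ns) < qual_fail_rate
  short_site <- stats::runif(ns) < short_allele_fraction
  site_rows <- list()
  a1 <- base::matrix(NA_integer_, n_accessions, ns,
                     dimnames = list(acc, NULL))
  a2 <- a1
  lines <- character(ns)
  for (i in seq_len(ns)) {
    m <- truth$motif_len[i]
    count <- truth$repeat_count[i]
    sid <- truth$seq_id[i]
    anchor_pos <- truth$start[i] - 1L
    anchor <- substr(reference$sequences[[sid]], anchor_pos, anchor_pos)
    ref_allele <- paste0(anchor, strrep(truth$motif[i], count))
    # unit deltas: > 10 nt length difference unless a short site is planted
    need_units <- (10L %/% m) + 1L
    deltas <- if (short_site[i]) seq_len(min(n_alts, max(1L, 10L %/% m)))
              else need_units + (seq_len(n_alts) - 1L) * need_units
    alt_counts <- count + deltas
    alts <- paste0(anchor, strrep(truth$motif[i], alt_counts))
    k <- 1L + length(alts)
    anc <- .rdirichlet(rep(1, k))
    pop_freq <- lapply(seq_len(n_subpops), function(pp) {
      if (divergence <= 0) anc
      else .rdirichlet(anc * (1 - divergence) / divergence)
    })
    names(pop_freq) <- paste0("P", seq_len(n_subpops))
    g1 <- g2 <- integer(n_accessions)
    for (j in seq_len(n_accessions)) {
      p <- pop_freq[[subpop[j]]]
      g1[j] <- sample.int(k, 1L, prob = p) - 1L
      g2[j] <- sample.int(k, 1L, prob = p) - 1L
    }
    miss <- stats::runif(n_accessions) < missing_rate
    gq <- round(stats::runif(n_accessions, 60, 99))
    gq_bad <- stats::runif(n_accessions) < gq_fail_rate
    gq[gq_bad] <- round(stats::runif(sum(gq_bad), 5, 40))
    dp <- round(stats::runif(n_accessions, 10, 60))
    dp_bad <- stats::runif(n_accessions) < dp_fail_rate
    dp[dp_bad] <- ifelse(stats::runif(sum(dp_bad)) < 0.5,
                         round(stats::runif(sum(dp_bad), 0, 4)),
                         round(stats::runif(sum(dp_bad), 101, 200)))
    qual <- if (qual_fail[i]) round(stats::runif(1, 10, 39.5), 1)
            else round(stats::runif(1, 60, 999), 1)
    gt <- ifelse(miss, "./.", paste0(pmin(g1, g2), "/", pmax(g1, g2)))
    a1[!miss, i] <- pmin(g1, g2)[!miss]
    a2[!miss, i] <- pmax(g1, g2)[!miss]
    sample_f <- paste(gt, gq, dp, sep = ":")
    lines[i] <- paste(c(sid, anchor_pos, ".", ref_allele,
                        paste(alts, collapse = ","), qual, "PASS", ".",
                        "GT:GQ:DP", sample_f), collapse = "\t")
    site_rows[[i]] <- data.frame(
      locus_id = paste(sid, anchor_pos, sep = "_"), chrom = sid,
      pos = anchor_pos, motif = truth$motif[i], qual = qual,
      qual_pass = !qual_fail[i], long_indel = !short_site[i],
      stringsAsFactors = FALSE)
  }
  site_truth <- do.call(rbind, site_rows)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", acc), collapse = "\t"))
  structure(list(site_truth = site_truth,
                 genotype_truth = list(a1 = a1, a2 = a2),
                 subpop = subpop,
                 vcf_lines = c(header, lines)),
            class = "sim_vcf")
}

#' Write a simulated VCF to disk
#' @param sim a `sim_vcf` object.
#' @param path output file (plain text VCF).
#' @export
write_sim_vcf <- function(sim, path) {
  writeLines(sim$vcf_lines, path)
  invisible(path)
}

#' Simulate a diploid genotype matrix under Balding-Nichols divergence
#'
#' Ancestral allele frequencies are Dirichlet(1,...,1); subpopulation
#' frequencies follow the Balding-Nichols model with the given divergence
#' parameter (expected Fst); genotypes are drawn under Hardy-Weinberg
#' within subpopulations and masked missing at the given rate. Allele
#' labels are fragment sizes: `base_size + motif_len * (allele index - 1)`,
#' mapping 1:1 to simulated repeat counts.
#'
#' @param n_accessions accessions (rows).
#' @param n_loci loci (columns).
#' @param n_subpops subpopulations (balanced assignment).
#' @param divergence Balding-Nichols parameter in \[0, 1).
#' @param allele_range inclusive range of allele counts per locus.
#' @param missing_rate fraction of calls masked missing.
#' @param motif_len repeat-unit length used for fragment-size spacing.
#' @param seed integer seed.
#' @return A list of class `sim_genotypes`: `matrix` (a
#'   [genotype_matrix()]), `grouping` (named accession-to-subpop vector),
#'   `truth` (ancestral and per-subpop allele frequencies per locus).
#' @export
simulate_genotype_matrix <- function(n_accessions = 149L, n_loci = 20L,
                                     n_subpops = 3L, divergence = 0.07,
                                     allele_range = c(3L, 12L),
                                     missing_rate = 0.01, motif_len = 3L,
                                     seed = 1L) {
  set.seed(seed)
  stopifnot(n_subpops >= 1L, divergence >= 0, divergence < 1)
  acc <- sprintf("CX%03d", seq_len(n_accessions))
  grouping <- stats::setNames(
    paste0("P", rep_len(seq_len(n_subpops), n_accessions)), acc)
  locus_ids <- sprintf("SSR%02d", seq_len(n_loci))
  a1 <- base::matrix(NA_integer_, n_accessions, n_loci,
                     dimnames = list(acc, locus_ids))
  a2 <- a1
  truth <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    k <- sample(allele_range[1L]:allele_range[2L], 1L)
    base_size <- sample(100:280, 1L)
    labels <- base_size + motif_len * (seq_len(k) - 1L)
    anc <- .rdirichlet(rep(1, k))
    pop_freq <- lapply(seq_len(n_subpops), function(pp) {
      if (divergence <= 0) anc
      else .rdirichlet(anc * (1 - divergence) / divergence)
    })
    names(pop_freq) <- paste0("P", seq_len(n_subpops))
    for (j in seq_len(n_accessions)) {
      p <- pop_freq[[grouping[j]]]
      a1[j, l] <- labels[sample.int(k, 1L, prob = p)]
      a2[j, l] <- labels[sample.int(k, 1L, prob = p)]
    }
    truth[[l]] <- list(locus_id = locus_ids[l], labels = labels,
                       ancestral = anc, subpop_freqs = pop_freq)
  }
  if (missing_rate > 0) {
    mask <- base::matrix(stats::runif(n_accessions * n_loci) < missing_rate,
                         n_accessions, n_loci)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  names(truth) <- locus_ids
  structure(list(matrix = genotype_matrix(a1, a2, acc, locus_ids),
                 grouping = grouping, truth = truth),
            class = "sim_genotypes")
}

#' Simulate replicate log-likelihood tables with a planted knee
#'
#' Mean log-likelihood rises steeply up to the planted number of clusters
#' and almost flattens beyond it, with small replicate noise, so the Evanno
#' second-difference statistic peaks at the planted K.
#'
#' @param k_range consecutive K values covered.
#' @param true_k planted knee (interior to `k_range`).
#' @param n_reps replicates per K.
#' @param rise,tail mean log-likelihood gain per K before / after the knee.
#' @param noise_sd replicate standard deviation.
#' @param seed integer seed.
#' @return Data frame with columns `K`, `rep`, `logL`.
#' @export
simulate_structure_runs <- function(k_range = 1:8, true_k = 3L,
                                    n_reps = 10L, rise = 400, tail = 15,
                                    noise_sd = 8, seed = 1L) {
  set.seed(seed)
  stopifnot(true_k > min(k_range), true_k < max(k_range))
  mean_l <- -5000 + rise * pmin(k_range, true_k) +
    tail * pmax(0, k_range - true_k)
  out <- do.call(rbind, lapply(seq_along(k_range), function(i) {
    data.frame(K = k_range[i], rep = seq_len(n_reps),
               logL = stats::rnorm(n_reps, mean_l[i], noise_sd))
  }))
  rownames(out) <- NULL
  out
}
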
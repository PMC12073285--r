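#' Primer design parameters
#'
#' Design window for SSR flanking primers: melting temperatures 57-61 degC
#' (optimum 60, pair difference at most 5), lengths 18-27 bp (optimum 20),
#' GC 20-80%, product 100-300 bp spanning the repeat tract, 150 bp flanks.
#' The post-design filter additionally rejects primers with a homopolymer
#' run of `max_homopolymer + 1` or longer and primers whose GC falls outside
#' `reject_gc_outside` ("extreme GC"; stricter than the design window so the
#' filter is non-vacuous).
#'
#' @param tm_min,tm_opt,tm_max melting temperature window, degC.
#' @param max_pair_tm_diff maximum Tm difference within a pair, degC.
#' @param len_range,len_opt primer length window and optimum, bp.
#' @param gc_range design GC window, percent.
#' @param product_range PCR product size window, bp.
#' @param flank flank length extracted either side of the tract, bp.
#' @param max_homopolymer longest tolerated single-base run in a primer.
#' @param reject_gc_outside filter-stage GC band, percent.
#' @param pairs_per_locus ranked pairs returned per locus.
#' @return An object of class `primer_params`.
#' @export
primer_params <- function(tm_min = 57.0, tm_opt = 60.0, tm_max = 61.0,
                          max_pair_tm_diff = 5.0,
                          len_range = c(18L, 27L), len_opt = 20L,
                          gc_range = c(20, 80),
                          product_range = c(100L, 300L),
                          flank = 150L, max_homopolymer = 3L,
                          reject_gc_outside = c(40, 60),
                          pairs_per_locus = 3L) {
  stopifnot(tm_min <= tm_opt, tm_opt <= tm_max,
            len_range[1L] <= len_range[2L],
            gc_range[1L] <= gc_range[2L],
            product_range[1L] <= product_range[2L], flank >= 0)
  structure(list(tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
                 max_pair_tm_diff = max_pair_tm_diff,
                 len_range = as.integer(len_range),
                 len_opt = as.integer(len_opt),
                 gc_range = gc_range,
                 product_range = as.integer(product_range),
                 flank = as.integer(flank),
                 max_homopolymer = as.integer(max_homopolymer),
                 reject_gc_outside = reject_gc_outside,
                 pairs_per_locus = as.integer(pairs_per_locus)),
            class = "primer_params")
}

#' Extract the template around an SSR tract
#'
#' Returns the tract extended by `flank` bp on both sides, truncated at the
#' sequence ends, together with the tract's offset inside the template.
#'
#' @param reference named character vector of sequences (or
#'   `DNAStringSet`).
#' @param seq_id sequence holding the tract.
#' @param tract_start,tract_end 1-based inclusive tract coordinates.
#' @param flank flank length in bp.
#' @return List: `template` (string), `template_start` (position of the
#'   template's first base on the source sequence), `tract_offset`
#'   (1-based start of the tract within the template), `tract_len`.
#' @export
extract_flanks <- function(reference, seq_id, tract_start, tract_end,
                           flank = 150L) {
  if (inherits(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  if (!seq_id %in% names(reference)) stop("sequence ", seq_id, " not found")
  seq <- reference[[seq_id]]
  a <- max(1L, tract_start - flank)
  b <- min(nchar(seq), tract_end + flank)
  list(template = substr(seq, a, b), template_start = a,
       tract_offset = tract_start - a + 1L,
       tract_len = tract_end - tract_start + 1L)
}

#' GC content of a sequence, in percent
#' @param seq non-empty DNA string.
#' @export
#' @examples
#' gc_content("ATGC")  # 50
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  100 * sum(s %in% c("G", "C")) / length(s)
}

# SantaLucia (1998) unified nearest-neighbor parameters, 5'->3' stacks.
# dh kcal/mol, ds cal/(mol K)
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Primer melting temperature
#'
#' Nearest-neighbor Tm under the SantaLucia (1998) unified parameter set
#' with terminal AT/GC initiation corrections, a monovalent-equivalent salt
#' entropy correction `0.368 (N-1) ln[Na_eq]` where
#' `Na_eq = Na + 120 sqrt(Mg)` (concentrations in mM), and the standard
#' `R ln(CT/4)` concentration term for non-self-complementary duplexes.
#' Defaults emulate a PCR buffer: 50 mM monovalent cation, 1.5 mM free
#' Mg2+, 250 nM total primer. The Wallace rule 2(A+T)+4(G+C) is available
#' as `method = "wallace"`.
#'
#' @param seq primer sequence, length >= 8.
#' @param method `"nn"` (default) or `"wallace"`.
#' @param na,mg monovalent and divalent cation concentrations, mM.
#' @param conc total primer concentration, nM.
#' @return Tm in degC.
#' @export
melting_temperature <- function(seq, method = c("nn", "wallace"),
                                na = 50, mg = 1.5, conc = 250) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (nchar(seq) < 8L) stop("sequence too short for a Tm estimate")
  if (grepl("[^ACGT]", seq)) stop("sequence must be over A, C, G, T")
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (method == "wallace")
    return(2 * sum(s %in% c("A", "T")) + 4 * sum(s %in% c("G", "C")))
  n <- length(s)
  stacks <- paste0(s[-n], s[-1L])
  dh <- sum(.NN_DH[stacks])
  ds <- sum(.NN_DS[stacks])
  # initiation with terminal A/T or G/C ends
  for (b in s[c(1L, n)]) {
    if (b %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else                    { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  na_eq <- (na + 120 * sqrt(mg)) / 1000      # molar
  ds <- ds + 0.368 * (n - 1) * log(na_eq)
  r <- 1.987                                  # cal/(mol K)
  ct <- conc * 1e-9
  dh * 1000 / (ds + r * log(ct / 4)) - 273.15
}

.homopolymer_max <- function(seq) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

# penalty used to rank primer pairs; weights are fixed, documented constants
.pair_penalty <- function(len_f, len_r, tm_f, tm_r, gc_f, gc_r, params) {
  abs(len_f - params$len_opt) + abs(len_r - params$len_opt) +
    abs(tm_f - params$tm_opt) + abs(tm_r - params$tm_opt) +
    0.1 * (abs(gc_f - 50) + abs(gc_r - 50)) +
    abs(tm_f - tm_r)
}

# all single-primer candidates on one strand of the template:
# start/end template coordinates plus length, Tm, GC
.candidate_windows <- function(template, starts, params, tm_method) {
  out <- list()
  for (a in starts) {
    for (len in params$len_range[1L]:params$len_range[2L]) {
      b <- a + len - 1L
      if (b > nchar(template)) break
      p <- substr(template, a, b)
      if (grepl("N", p, fixed = TRUE)) next
      gc <- gc_content(p)
      if (gc < params$gc_range[1L] || gc > params$gc_range[2L]) next
      tm <- melting_temperature(p, method = tm_method)
      if (tm < params$tm_min || tm > params$tm_max) next
      out[[length(out) + 1L]] <- list(start = a, end = b, len = len,
                                      tm = tm, gc = gc)
    }
  }
  out
}

#' Enumerate ranked primer pairs for a template
#'
#' Scans every forward window ending before the repeat tract and every
#' reverse window starting after it, keeps windows satisfying the
#' length/Tm/GC constraints of [primer_params()], forms all pairs whose
#' product (forward start to reverse end) lies within `product_range` and
#' whose Tm difference is at most `max_pair_tm_diff`, ranks pairs by a
#' fixed penalty (distance from optimal length and Tm, distance of GC from
#' 50%, Tm imbalance) and returns the best `pairs_per_locus`. Enumeration
#' is deterministic.
#'
#' @param template template string from [extract_flanks()].
#' @param tract_offset,tract_len tract position within the template.
#' @param params a [primer_params()] object.
#' @param locus_id recorded on each returned pair.
#' @param tm_method passed to [melting_temperature()].
#' @return A data frame of class `primer_pairs` (possibly 0 rows, with a
#'   `reason` attribute when empty): locus_id, forward, reverse (5'->3' on
#'   the opposite strand), f_start, f_end, r_start, r_end (template
#'   coordinates), len_f, len_r, tm_f, tm_r, gc_f, gc_r, product_size,
#'   score.
#' @export
enumerate_primer_pairs <- function(template, tract_offset, tract_len,
                                   params = primer_params(),
                                   locus_id = "locus", tm_method = "nn") {
  empty <- function(reason) {
    d <- data.frame(locus_id = character(), forward = character(),
                    reverse = character(), f_start = integer(),
                    f_end = integer(), r_start = integer(),
                    r_end = integer(), len_f = integer(), len_r = integer(),
                    tm_f = numeric(), tm_r = numeric(), gc_f = numeric(),
                    gc_r = numeric(), product_size = integer(),
                    score = numeric(), stringsAsFactors = FALSE)
    attr(d, "reason") <- reason
    class(d) <- c("primer_pairs", "data.frame")
    d
  }
  tlen <- nchar(template)
  tract_end <- tract_offset + tract_len - 1L
  if (tlen < params$product_range[1L]) return(empty("template_too_short"))
  # forward primers must end before the tract, reverse start after it
  f_starts <- seq_len(max(0L, tract_offset - params$len_range[1L]))
  fwd <- .candidate_windows(template, f_starts, params, tm_method)
  fwd <- Filter(function(w) w$end < tract_offset, fwd)
  r_starts <- seq.int(tract_end + 1L, tlen)
  r_starts <- r_starts[r_starts + params$len_range[1L] - 1L <= tlen]
  rev <- if (length(r_starts)) .candidate_windows(template, r_starts, params,
                                                  tm_method) else list()
  if (length(fwd) == 0L || length(rev) == 0L)
    return(empty("no_feasible_primer"))
  fd <- do.call(rbind, lapply(fwd, as.data.frame))
  rd <- do.call(rbind, lapply(rev, as.data.frame))
  grid <- expand.grid(fi = seq_len(nrow(fd)), ri = seq_len(nrow(rd)))
  f <- fd[grid$fi, ]; r <- rd[grid$ri, ]
  size <- r$end - f$start + 1L
  ok <- size >= params$product_range[1L] & size <= params$product_range[2L] &
    abs(f$tm - r$tm) <= params$max_pair_tm_diff
  if (!any(ok)) return(empty("no_feasible_pair"))
  f <- f[ok, ]; r <- r[ok, ]; size <- size[ok]
  pairs <- data.frame(
    locus_id = locus_id,
    f_start = f$start, f_end = f$end, r_start = r$start, r_end = r$end,
    len_f = f$len, len_r = r$len, tm_f = f$tm, tm_r = r$tm,
    gc_f = f$gc, gc_r = r$gc, product_size = size,
    score = .pair_penalty(f$len, r$len, f$tm, r$tm, f$gc, r$gc, params),
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$score, pairs$f_start, pairs$r_start), ,
                 drop = FALSE]
  pairs <- utils::head(pairs, params$pairs_per_locus)
  rownames(pairs) <- NULL
  pairs$forward <- substring(template, pairs$f_start, pairs$f_end)
  pairs$reverse <- vapply(substring(template, pairs$r_start, pairs$r_end),
                          revcomp, character(1L), USE.NAMES = FALSE)
  pairs <- pairs[, c("locus_id", "forward", "reverse", "f_start", "f_end",
                     "r_start", "r_end", "len_f", "len_r", "tm_f", "tm_r",
                     "gc_f", "gc_r", "product_size", "score")]
  class(pairs) <- c("primer_pairs", "data.frame")
  pairs
}

#' Filter primer pairs by post-design rejection rules
#'
#' Rejects pairs with a short target fragment (product below the
#' `product_range` floor), a homopolymer run longer than `max_homopolymer`
#' in either primer (i.e. >= 4 consecutive identical bases under the
#' default), or either primer's GC outside `reject_gc_outside` ("extreme
#' GC"). Optionally also rejects primers containing >= 3 tandem copies of a
#' dinucleotide motif.
#'
#' @param pairs a `primer_pairs` data frame.
#' @param params a [primer_params()] object.
#' @param reject_di_repeats also reject >= 3 tandem dinucleotide copies.
#' @return List: `accepted` (filtered `primer_pairs`) and `tally` (named
#'   integer vector of per-rule rejections; a pair counts once, under its
#'   first failing rule: short_product, homopolymer, extreme_gc,
#'   di_repeat).
#' @export
filter_primer_pairs <- function(pairs, params = primer_params(),
                                reject_di_repeats = FALSE) {
  rules <- c("short_product", "homopolymer", "extreme_gc", "di_repeat")
  tally <- stats::setNames(integer(4L), rules)
  if (nrow(pairs) == 0L) return(list(accepted = pairs, tally = tally))
  di_hit <- function(p) grepl("([ACGT][ACGT])\\1\\1", p)
  fail <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    f <- pairs$forward[i]; r <- pairs$reverse[i]
    if (pairs$product_size[i] < params$product_range[1L])
      fail[i] <- "short_product"
    else if (max(.homopolymer_max(f), .homopolymer_max(r)) >
             params$max_homopolymer)
      fail[i] <- "homopolymer"
    else if (min(pairs$gc_f[i], pairs$gc_r[i]) < params$reject_gc_outside[1L] ||
             max(pairs$gc_f[i], pairs$gc_r[i]) > params$reject_gc_outside[2L])
      fail[i] <- "extreme_gc"
    else if (reject_di_repeats && (di_hit(f) || di_hit(r)))
      fail[i] <- "di_repeat"
  }
  for (rl in rules) tally[rl] <- sum(fail == rl)
  accepted <- pairs[fail == "", , drop = FALSE]
  rownames(accepted) <- NULL
  class(accepted) <- c("primer_pairs", "data.frame")
  list(accepted = accepted, tally = tally)
}

#' Design primers for a set of SSR loci
#'
#' Convenience wrapper: [extract_flanks()], [enumerate_primer_pairs()] and
#' [filter_primer_pairs()] for every locus, using the tract coordinates in
#' `loci` (columns `seq_id`/`chrom`, `start`, `end`).
#'
#' @param reference named sequence vector.
#' @param loci data frame with tract coordinates (`ssr_hits`-like; columns
#'   seq_id, start, end and optionally locus_id).
#' @param params a [primer_params()] object.
#' @param tm_method passed to [melting_temperature()].
#' @return A `primer_pairs` data frame over all loci.
#' @export
design_primers <- function(reference, loci, params = primer_params(),
                           tm_method = "nn") {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    sid <- if ("seq_id" %in% names(loci)) loci$seq_id[i] else loci$chrom[i]
    lid <- if ("locus_id" %in% names(loci)) loci$locus_id[i]
           else paste(sid, loci$start[i], sep = "_")
    fl <- extract_flanks(reference, sid, loci$start[i], loci$end[i],
                         params$flank)
    pairs <- enumerate_primer_pairs(fl$template, fl$tract_offset,
                                    fl$tract_len, params, locus_id = lid,
                                    tm_method = tm_method)
    out[[length(out) + 1L]] <- filter_primer_pairs(pairs, params)$accepted
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("primer_pairs", "data.frame")
  res
}

#' Write a primer table to TSV
#' @param pairs a `primer_pairs` data frame.
#' @param path output file.
#' @export
write_primer_table <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
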
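# Independent brute-force SSR scanner: tests every (start, motif_len)
# anchor exhaustively with literal substring comparisons. Shares no code
# with find_ssrs (which works on periodicity run-lengths).
oracle_find_ssrs <- function(sequence, criteria = repeat_criteria()) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(s)
  rep_of_shorter <- function(motif) {
    m <- nchar(motif)
    for (d in seq_len(max(0L, m - 1L)))
      if (m %% d == 0L && strrep(substr(motif, 1L, d), m / d) == motif)
        return(TRUE)
    FALSE
  }
  rows <- list()
  for (m in 1:6) {
    for (a in seq_len(max(0L, n - m * criteria$min_repeats[m] + 1L))) {
      motif <- paste(s[a:(a + m - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (rep_of_shorter(motif)) next
      # anchor must be the left edge of the periodic region
      if (a > 1L && s[a - 1L] != "N" && s[a - 1L] == s[a - 1L + m]) next
      k <- 0L
      b <- a
      while (b + m - 1L <= n &&
             paste(s[b:(b + m - 1L)], collapse = "") == motif) {
        k <- k + 1L
        b <- b + m
      }
      if (k < criteria$min_repeats[m]) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = a + m * k - 1L, motif = motif,
        repeat_count = k, motif_len = m, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeat_count = integer(),
                      motif_len = integer(), compound = logical()))
  h <- do.call(rbind, rows)
  h <- h[order(h$start, h$motif_len), , drop = FALSE]
  # independent pairwise compound flagging
  comp <- logical(nrow(h))
  if (nrow(h) > 1L) {
    for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
      if (i == j) next
      gap <- max(h$start[i], h$start[j]) - min(h$end[i], h$end[j]) - 1L
      if (gap <= criteria$max_compound_gap) comp[i] <- TRUE
    }
  }
  h$compound <- comp
  rownames(h) <- NULL
  h
}

# random repeat-rich test sequence: spacers interleaved with planted
# tandem repeats of random motif and count (above and below thresholds)
random_repeat_rich_seq <- function(len = 1000L, n_repeats = 6L) {
  bases <- c("A", "C", "G", "T")
  parts <- character(0L)
  total <- 0L
  for (i in seq_len(n_repeats)) {
    sp <- paste(sample(bases, sample(20:80, 1L), replace = TRUE),
                collapse = "")
    m <- sample(1:6, 1L)
    motif <- paste(sample(bases, m, replace = TRUE), collapse = "")
    k <- sample(2:14, 1L)
    parts <- c(parts, sp, strrep(motif, k))
  }
  out <- paste(parts, collapse = "")
  if (nchar(out) < len)
    out <- paste0(out, paste(sample(bases, len - nchar(out),
                                    replace = TRUE), collapse = ""))
  substr(out, 1L, len)
}

hit_key <- function(h) {
  if (nrow(h) == 0L) return(character())
  paste(h$start, h$end, h$motif, h$repeat_count, h$motif_len, h$compound,
        sep = "|")
}

panel_stats_path <- function() {
  system.file("extdata", "asinensis_panel_stats.tsv", package = "ssrkit")
}

# matrix with hand-specified calls: list of per-locus list(a1 vector, a2
# vector)
gm_from_calls <- function(...) {
  calls <- list(...)
  a1 <- do.call(cbind, lapply(calls, `[[`, 1L))
  a2 <- do.call(cbind, lapply(calls, `[[`, 2L))
  genotype_matrix(a1, a2)
}
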
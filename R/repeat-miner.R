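#' MISA-compatible repeat detection criteria
#'
#' Minimum number of repeat units required, per motif length, for a tandem
#' repeat tract to be reported, plus the maximum gap between neighbouring
#' tracts below which both are flagged as compound. Defaults are the standard
#' MISA settings used for genome-wide SSR surveys: 10 units for
#' mononucleotide motifs and 6/5/5/5/5 for di- through hexanucleotide motifs,
#' with a 100 bp compound gap.
#'
#' @param min_repeats integer vector of length 6; minimum repeat-unit counts
#'   for motif lengths 1..6.
#' @param max_compound_gap maximum distance in bp between adjacent tracts for
#'   them to be flagged compound.
#' @return An object of class `repeat_criteria`.
#' @export
#' @examples
#' repeat_criteria()
repeat_criteria <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                            max_compound_gap = 100L) {
  min_repeats <- as.integer(min_repeats)
  stopifnot(length(min_repeats) == 6L, all(min_repeats >= 1L),
            max_compound_gap >= 0)
  structure(list(min_repeats = min_repeats,
                 max_compound_gap = as.integer(max_compound_gap)),
            class = "repeat_criteria")
}

#' @export
print.repeat_criteria <- function(x, ...) {
  cat("SSR detection criteria\n")
  cat("  min repeat units (motif length 1-6):",
      paste(x$min_repeats, collapse = ", "), "\n")
  cat("  compound gap: <=", x$max_compound_gap, "bp\n")
  invisible(x)
}

# TRUE if motif is a whole-number tandem repetition of a shorter unit
# (e.g. "ATAT" of "AT"); such motifs are never reported as their own class.
.is_rep_of_shorter <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(FALSE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        strrep(substr(motif, 1L, d), m %/% d) == motif) return(TRUE)
  }
  FALSE
}

.check_dna <- function(sequence) {
  if (grepl("[^ACGTNacgtn]", sequence))
    stop("sequence contains characters other than A, C, G, T, N")
}

#' Find perfect SSR tracts in a DNA sequence
#'
#' Scans a nucleotide sequence for maximal perfect tandem repeats of motif
#' length 1-6 under MISA-compatible minimum-repeat criteria. For a
#' periodic region admitting several motif-length interpretations the
#' shortest motif is reported (so `(AT)6`, never `(ATAT)3`); `N` never
#' participates in a repeat. Tracts whose distance to an adjacent tract is
#' at most `criteria$max_compound_gap` are flagged compound.
#'
#' @param sequence a single DNA string over `A,C,G,T,N` (case-insensitive).
#' @param criteria a [repeat_criteria()] object.
#' @param seq_id sequence identifier recorded with each hit.
#' @return A data frame of class `ssr_hits`, one row per tract, sorted by
#'   start, with columns `seq_id`, `start`, `end` (1-based inclusive),
#'   `motif`, `canonical_label`, `repeat_count`, `motif_len`, `compound`.
#' @export
#' @examples
#' find_ssrs("CCGTACACACACACACGGTT")
find_ssrs <- function(sequence, criteria = repeat_criteria(), seq_id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .check_dna(sequence)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(s)
  ok <- s != "N"
  out <- list()
  for (m in 1:6) {
    minrep <- criteria$min_repeats[m]
    if (n < m * minrep) next
    # eq[j] is TRUE when position j matches position j+m (both non-N);
    # a run of r TRUEs starting at j is a maximal m-periodic region [j, j+r+m-1]
    idx <- seq_len(n - m)
    eq <- (s[idx] == s[idx + m]) & ok[idx] & ok[idx + m]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]
      len <- r$lengths[k] + m            # region length in bp
      count <- len %/% m
      if (count < minrep) next
      motif <- paste(s[a:(a + m - 1L)], collapse = "")
      if (.is_rep_of_shorter(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, start = a, end = a + m * count - 1L,
        motif = motif, repeat_count = count, motif_len = m,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    hits <- data.frame(seq_id = character(), start = integer(),
                       end = integer(), motif = character(),
                       canonical_label = character(),
                       repeat_count = integer(), motif_len = integer(),
                       compound = logical(), stringsAsFactors = FALSE)
    class(hits) <- c("ssr_hits", "data.frame")
    return(hits)
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$motif_len), , drop = FALSE]
  hits$canonical_label <- vapply(hits$motif, canonical_motif, character(1L))
  hits$compound <- flag_compound(hits$start, hits$end,
                                 criteria$max_compound_gap)
  rownames(hits) <- NULL
  hits <- hits[, c("seq_id", "start", "end", "motif", "canonical_label",
                   "repeat_count", "motif_len", "compound")]
  class(hits) <- c("ssr_hits", "data.frame")
  hits
}

# compound flag for tracts sorted by start: TRUE when the gap to the previous
# or next tract (next start - this end - 1) is <= max_gap; overlap counts too
flag_compound <- function(start, end, max_gap) {
  k <- length(start)
  if (k < 2L) return(rep(FALSE, k))
  gap <- start[-1L] - end[-k] - 1L
  near <- gap <= max_gap
  c(near, FALSE) | c(FALSE, near)
}

#' Find SSRs across a set of sequences
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`.
#' @inheritParams find_ssrs
#' @return A single `ssr_hits` data frame over all sequences.
#' @export
find_ssrs_set <- function(sequences, criteria = repeat_criteria()) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  res <- mapply(find_ssrs, sequences, seq_id = ids,
                MoreArgs = list(criteria = criteria), SIMPLIFY = FALSE)
  hits <- do.call(rbind, res)
  rownames(hits) <- NULL
  class(hits) <- c("ssr_hits", "data.frame")
  hits
}

#' Canonical motif label
#'
#' Pairs a motif with its reverse complement, rendered `"observed/revcomp"`
#' (e.g. `"TAT/ATA"`). Only strand complementarity is collapsed; rotations
#' of a motif remain distinct classes, so `"AT/AT"` and `"TA/TA"` are
#' different labels. With `collapse = TRUE` the pair is instead reported
#' under its lexicographically smaller member, which merges a motif and its
#' reverse complement into one programmatic group.
#'
#' @param motif DNA motif of length 1-6.
#' @param collapse order the pair lexicographically instead of
#'   observed-first.
#' @return The canonical label, a single string.
#' @export
#' @examples
#' canonical_motif("TAT")   # "TAT/ATA"
#' canonical_motif("AT")    # "AT/AT"
canonical_motif <- function(motif, collapse = FALSE) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- toupper(motif)
  if (nchar(motif) < 1L || nchar(motif) > 6L || grepl("[^ACGT]", motif))
    stop("motif must be 1-6 bases over A, C, G, T")
  rc <- revcomp(motif)
  if (collapse && rc < motif) paste(rc, motif, sep = "/")
  else paste(motif, rc, sep = "/")
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string over `A,C,G,T,N`.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Summarise SSR hits by repeat class and motif
#'
#' Tabulates hits by motif-length class (mono- .. hexanucleotide) and by
#' canonical motif label, with within-class relative frequencies.
#'
#' @param hits an `ssr_hits` data frame (or any data frame with
#'   `motif_len` and `canonical_label` columns).
#' @return A list of class `motif_summary` with elements `total`,
#'   `by_class` (class, count, percent of total), `by_motif` (class, label,
#'   count, percent within class), and `types_per_class` (distinct labels
#'   per class).
#' @export
summarize_motifs <- function(hits) {
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  total <- nrow(hits)
  if (total == 0L) {
    return(structure(list(
      total = 0L,
      by_class = data.frame(class = classes, count = 0L, percent = NA_real_),
      by_motif = data.frame(class = character(), label = character(),
                            count = integer(), percent = numeric()),
      types_per_class = stats::setNames(integer(6L), classes)),
      class = "motif_summary"))
  }
  cls <- factor(classes[hits$motif_len], levels = classes)
  cc <- as.integer(table(cls))
  by_class <- data.frame(class = classes, count = cc,
                         percent = round(100 * cc / total, 2))
  tab <- as.data.frame(table(class = cls, label = hits$canonical_label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3L] <- "count"
  cls_tot <- by_class$count[match(tab$class, by_class$class)]
  tab$percent <- round(100 * tab$count / cls_tot, 2)
  tab <- tab[order(match(tab$class, classes), -tab$count, tab$label), ]
  rownames(tab) <- NULL
  tpc <- vapply(classes, function(cl) length(unique(tab$label[tab$class == cl])),
                integer(1L))
  structure(list(total = total, by_class = by_class, by_motif = tab,
                 types_per_class = tpc),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("SSR motif summary:", x$total, "hits\n")
  print(x$by_class, row.names = FALSE)
  cat("distinct motif types per class:",
      paste(x$types_per_class, collapse = "/"), "\n")
  invisible(x)
}

#' Write an SSR hit table to TSV
#'
#' Columns: seq_id, start, end, motif, canonical_label, repeat_count, class,
#' compound.
#'
#' @param hits an `ssr_hits` data frame.
#' @param path output file.
#' @export
write_ssr_hits <- function(hits, path) {
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  out <- data.frame(seq_id = hits$seq_id, start = hits$start, end = hits$end,
                    motif = hits$motif, canonical_label = hits$canonical_label,
                    repeat_count = hits$repeat_count,
                    class = classes[hits$motif_len],
                    compound = hits$compound, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
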
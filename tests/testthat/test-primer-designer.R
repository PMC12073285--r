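# balanced-composition template with a central tri repeat, guaranteed
# feasible for the default design window
make_template <- function(seed = 5, flank = 180L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  left <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  right <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  tract <- strrep("CTT", 8)
  list(template = paste0(left, tract, right),
       tract_offset = flank + 1L, tract_len = nchar(tract))
}

test_that("flank extraction handles interior tracts, ends and flank 0", {
  ref <- c(sc = strrep("ACGT", 250))   # 1 kb
  fl <- extract_flanks(ref, "sc", 201, 220, flank = 150)
  expect_equal(fl$template_start, 51L)
  expect_equal(nchar(fl$template), 320L)
  expect_equal(fl$tract_offset, 151L)
  # truncation at the left end
  fl2 <- extract_flanks(ref, "sc", 20, 40, flank = 150)
  expect_equal(fl2$template_start, 1L)
  expect_equal(fl2$tract_offset, 20L)
  # flank 0 returns the tract itself
  fl3 <- extract_flanks(ref, "sc", 201, 220, flank = 0)
  expect_equal(nchar(fl3$template), 20L)
  expect_error(extract_flanks(ref, "nope", 1, 10), "not found")
})

test_that("GC content is a plain percentage", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGGCCC"), 100)
  expect_error(gc_content(""), "empty")
})

test_that("Wallace-rule Tm is 2(A+T) + 4(G+C)", {
  p <- paste0(strrep("AT", 5), strrep("GC", 5))     # 10 AT + 10 GC
  expect_equal(melting_temperature(p, method = "wallace"), 60)
  expect_equal(melting_temperature(paste0(strrep("A", 10), strrep("T", 8)),
                                   method = "wallace"), 36)
  expect_error(melting_temperature("ACGTACG"), "short")
})

test_that("nearest-neighbor Tm matches an independent published calculator", {
  # reference values from Biopython MeltingTemp.Tm_NN (SantaLucia 1998
  # unified table, entropy salt correction at the same monovalent
  # equivalent, CT/4 = 62.5 nM), computed independently and frozen
  frozen <- c(
    "AAACGGAACGTGCTAATGCT" = 61.669,
    "CCACACGTGATTTCTGGATG" = 59.956,
    "TATTAGTGGGTGAATCGGGC" = 60.314,
    "GGGCAAACGGTATAATCATCA" = 59.204,
    "GACATAAGGGGCCATGAGTG" = 61.255,
    "AAGCCTAGCCTTTTTGGTGG" = 61.632,
    "CAAAACCAAATTCACTTGAAAGC" = 58.874,
    "CCACCAGCACAAGTGGTATG" = 62.030,
    "GGAGAGGGTTGAGGTAGGGT" = 63.304,
    "CGGTGTTTGAGATTGTGGAA" = 59.452)
  for (p in names(frozen))
    expect_lt(abs(melting_temperature(p) - frozen[[p]]), 1)
  # Tm is strand-symmetric (duplex property)
  expect_equal(melting_temperature("AAACGGAACGTGCTAATGCT"),
               melting_temperature(revcomp("AAACGGAACGTGCTAATGCT")))
})

test_that("primer enumeration returns valid, deterministic ranked pairs", {
  tp <- make_template()
  pairs <- enumerate_primer_pairs(tp$template, tp$tract_offset,
                                  tp$tract_len, locus_id = "L1")
  params <- primer_params()
  expect_gt(nrow(pairs), 0)
  expect_lte(nrow(pairs), params$pairs_per_locus)
  # every pair satisfies the contract
  tract_end <- tp$tract_offset + tp$tract_len - 1L
  expect_true(all(pairs$f_end < tp$tract_offset))
  expect_true(all(pairs$r_start > tract_end))        # product spans tract
  expect_true(all(pairs$product_size >= params$product_range[1]))
  expect_true(all(pairs$product_size <= params$product_range[2]))
  expect_true(all(abs(pairs$tm_f - pairs$tm_r) <= params$max_pair_tm_diff))
  expect_true(all(pairs$tm_f >= params$tm_min & pairs$tm_f <= params$tm_max))
  expect_equal(pairs$product_size, pairs$r_end - pairs$f_start + 1L)
  # reverse primer is the reverse complement of its template window
  expect_equal(pairs$reverse[1],
               revcomp(substr(tp$template, pairs$r_start[1], pairs$r_end[1])))
  # deterministic
  again <- enumerate_primer_pairs(tp$template, tp$tract_offset,
                                  tp$tract_len, locus_id = "L1")
  expect_identical(pairs, again)
  # too-short template: empty with a reason
  short <- enumerate_primer_pairs(substr(tp$template, 1, 80), 40, 10)
  expect_equal(nrow(short), 0)
  expect_equal(attr(short, "reason"), "template_too_short")
})

test_that("primer filter rejects runs, short products and extreme GC", {
  base <- data.frame(locus_id = "L", forward = "ACGCAGTCGATCGATGCTGA",
                     reverse = "TGCATGCGATCGCATCGTAC",
                     f_start = 1L, f_end = 20L, r_start = 150L, r_end = 169L,
                     len_f = 20L, len_r = 20L, tm_f = 60, tm_r = 60,
                     gc_f = 55, gc_r = 55, product_size = 169L, score = 1,
                     stringsAsFactors = FALSE)
  hp <- base; hp$forward <- "ACGCAGTCGAAAATGCTGAC"          # AAAA run
  sp <- base; sp$product_size <- 90L                        # short product
  xg <- base; xg$gc_f <- 30                                 # extreme GC
  pairs <- rbind(base, hp, sp, xg)
  class(pairs) <- c("primer_pairs", "data.frame")
  res <- filter_primer_pairs(pairs)
  expect_equal(nrow(res$accepted), 1L)
  expect_equal(res$tally[["homopolymer"]], 1L)
  expect_equal(res$tally[["short_product"]], 1L)
  expect_equal(res$tally[["extreme_gc"]], 1L)
  expect_equal(nrow(res$accepted) + sum(res$tally), nrow(pairs))
  # optional dinucleotide-repeat rule
  di <- base; di$reverse <- "TGCATGAGAGAGCATCGTAC"          # (AG)3
  res2 <- filter_primer_pairs(rbind(base, di), reject_di_repeats = TRUE)
  expect_equal(res2$tally[["di_repeat"]], 1L)
})

test_that("design_primers spans tracts end to end on a synthetic scaffold", {
  set.seed(9)
  ref <- simulate_reference(n_scaffolds = 1, scaffold_length = 5000,
                            n_ssrs_per_scaffold = 3, seed = 31)
  hits <- find_ssrs_set(ref$sequences)
  pairs <- design_primers(ref$sequences, hits)
  expect_gt(nrow(pairs), 0)
  # each accepted product contains its tract
  for (i in seq_len(nrow(pairs))) {
    tr <- hits[paste(hits$seq_id, hits$start, sep = "_") ==
               pairs$locus_id[i], ]
    fl <- extract_flanks(ref$sequences, tr$seq_id, tr$start, tr$end)
    expect_lte(pairs$f_end[i], fl$tract_offset - 1L)
    expect_gte(pairs$r_start[i], fl$tract_offset + fl$tract_len)
  }
})
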
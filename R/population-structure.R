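#' Per-population allele frequencies
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping named accession-to-population vector covering the
#'   matrix's accessions.
#' @return Named list (one element per population) of lists of per-locus
#'   allele-frequency vectors, each over the union of allele labels seen at
#'   that locus across the whole matrix (zeros for absent alleles).
#' @export
population_allele_freqs <- function(matrix, grouping) {
  grouping <- grouping[accessions(matrix)]
  if (anyNA(grouping)) stop("grouping missing for some accessions")
  pops <- sort(unique(grouping))
  all_alleles <- lapply(loci(matrix), function(l)
    names(allele_frequencies(matrix, l)))
  names(all_alleles) <- loci(matrix)
  out <- lapply(pops, function(pp) {
    sub <- subset_genotypes(matrix, accessions(matrix)[grouping == pp])
    fr <- lapply(loci(matrix), function(l) {
      p <- stats::setNames(numeric(length(all_alleles[[l]])),
                           all_alleles[[l]])
      obs <- tryCatch(allele_frequencies(sub, l), error = function(e) NULL)
      if (!is.null(obs)) p[names(obs)] <- obs
      p
    })
    names(fr) <- loci(matrix)
    fr
  })
  names(out) <- pops
  out
}

#' Nei's (1972) standard genetic distance
#'
#' D = -ln(Jxy / sqrt(Jx Jy)) with Jxy, Jx, Jy summed over loci and
#' alleles. Identical frequency sets give D = 0; when the normalized
#' identity is 0 (no shared alleles anywhere) the distance is infinite and
#' reported as `cap` with attribute `capped = TRUE`.
#'
#' @param freqs_a,freqs_b lists of per-locus allele-frequency vectors over
#'   matching loci and allele labels (as produced by
#'   [population_allele_freqs()]).
#' @param cap value reported for an infinite distance (default `Inf`; pass
#'   a finite cap for tree building).
#' @return The distance (non-negative scalar), possibly with attribute
#'   `capped`.
#' @export
nei_distance <- function(freqs_a, freqs_b, cap = Inf) {
  stopifnot(length(freqs_a) == length(freqs_b))
  jxy <- jx <- jy <- 0
  for (l in seq_along(freqs_a)) {
    p <- freqs_a[[l]]; q <- freqs_b[[l]]
    stopifnot(length(p) == length(q))
    jxy <- jxy + sum(p * q)
    jx <- jx + sum(p^2)
    jy <- jy + sum(q^2)
  }
  ident <- jxy / sqrt(jx * jy)
  if (ident <= 0) return(structure(cap, capped = TRUE))
  max(0, -log(min(1, ident)))
}

#' Nei distance matrix between populations or accessions
#'
#' With a `grouping`, distances between populations; without, every
#' accession is its own unit (frequencies 0/0.5/1), giving an
#' accession-level matrix for clustering.
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping optional named accession-to-population vector.
#' @param cap finite substitute for infinite distances (default 10).
#' @return Symmetric matrix with zero diagonal, labelled by population or
#'   accession.
#' @export
nei_distance_matrix <- function(matrix, grouping = NULL, cap = 10) {
  if (is.null(grouping))
    grouping <- stats::setNames(accessions(matrix), accessions(matrix))
  fr <- population_allele_freqs(matrix, grouping)
  n <- length(fr)
  d <- matrix(0, n, n, dimnames = list(names(fr), names(fr)))
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- as.numeric(nei_distance(fr[[i]], fr[[j]],
                                                    cap = cap))
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration; node height equals half the merge
#' distance, so the tree is ultrametric. Implemented via
#' `stats::hclust(method = "average")` and converted with
#' `ape::as.phylo`, which emits exactly those branch lengths.
#'
#' @param dist symmetric distance matrix (zero diagonal) or `dist` object.
#' @return A list of class `upgma_tree`: `phylo` (an `ape::phylo`) and
#'   `newick` (Newick string with branch lengths).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick
upgma <- function(dist) {
  if (!inherits(dist, "dist")) {
    dist <- as.matrix(dist)
    if (anyNA(dist)) stop("distance matrix contains NA")
    if (any(!is.finite(dist))) stop("distance matrix contains Inf")
    if (max(abs(dist - t(dist))) > 1e-12) stop("matrix not symmetric")
    dist <- stats::as.dist(dist)
  }
  if (anyNA(dist)) stop("distance matrix contains NA")
  if (attr(dist, "Size") < 2L) stop("need at least two units")
  hc <- stats::hclust(dist, method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(phylo = phy, newick = ape::write.tree(phy)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$phylo$tip.label), "tips\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#' @param tree an `upgma_tree` or `phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "upgma_tree")) tree$phylo else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

# one-hot allele-indicator rows for the 2N gene copies at the loci of a
# matrix; list with per-locus indicator matrices (2N x alleles) and a mask
# of which copies are observed
.allele_indicators <- function(matrix) {
  lapply(loci(matrix), function(l) {
    g <- genotype_calls(matrix, l)
    alleles <- sort(unique(c(g$a1, g$a2)))
    alleles <- alleles[!is.na(alleles)]
    n <- length(g$a1)
    x <- base::matrix(NA_real_, 2L * n, length(alleles))
    ok <- !is.na(g$a1)
    x[seq_len(n)[ok], ] <- outer(g$a1[ok], alleles, `==`) + 0
    x[n + seq_len(n)[ok], ] <- outer(g$a2[ok], alleles, `==`) + 0
    list(x = x, ok = ok)
  })
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level AMOVA for codominant diploid data: among populations, among
#' individuals within populations, within individuals. Sums of squares are
#' Euclidean deviations of per-gene-copy allele indicator vectors in a
#' nested ANOVA (equivalent to the squared-distance formulation), summed
#' over loci; at each locus only individuals genotyped there contribute.
#' Degrees of freedom are k-1, N-k and N; variance components come from
#' the expected mean squares with the unequal-size coefficient
#' n_c = (N - sum(n_p^2)/N)/(k-1); negative components are truncated to 0
#' by default (raw values retained). Percentages use the truncated
#' components.
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping named accession-to-population vector; at least two
#'   populations with at least two individuals each.
#' @param truncate truncate negative variance components at zero.
#' @return An object of class `amova`: data frame `table` with rows
#'   among_populations / among_individuals / within_individuals / total and
#'   columns df, SS, MS, sigma2, percent; plus `sigma2_raw` and `n_c`.
#' @export
amova <- function(matrix, grouping, truncate = TRUE) {
  grouping <- grouping[accessions(matrix)]
  if (anyNA(grouping)) stop("grouping missing for some accessions")
  pops <- sort(unique(grouping))
  k <- length(pops)
  n_p <- as.integer(table(factor(grouping, levels = pops)))
  if (k < 2L) stop("need at least two populations")
  if (any(n_p < 2L)) stop("every population needs at least two individuals")
  n <- nrow(matrix$a1)
  ind <- .allele_indicators(matrix)
  pop_of <- factor(grouping, levels = pops)
  ss_ap <- ss_ai <- ss_wi <- 0
  for (li in seq_along(ind)) {
    x <- ind[[li]]$x
    ok <- ind[[li]]$ok              # individuals genotyped at this locus
    ids <- which(ok)
    if (length(ids) < 2L) next
    rows <- c(ids, n + ids)         # the 2 copies of each genotyped ind.
    xo <- x[rows, , drop = FALSE]
    ind_f <- factor(rep(ids, 2L))
    pop_f <- pop_of[rep(ids, 2L)]
    grand <- colMeans(xo)
    ind_mean <- vapply(seq_len(ncol(xo)),
                       function(cc) tapply(xo[, cc], ind_f, mean),
                       numeric(nlevels(ind_f)))
    ind_mean <- base::matrix(ind_mean, nrow = nlevels(ind_f),
                             dimnames = list(levels(ind_f), NULL))
    pop_mean <- vapply(seq_len(ncol(xo)),
                       function(cc) tapply(xo[, cc], pop_f, mean),
                       numeric(nlevels(pop_f)))
    pop_mean <- base::matrix(pop_mean, nrow = nlevels(pop_f),
                             dimnames = list(levels(pop_f), NULL))
    # within individuals: copies about their individual's mean
    dev_wi <- xo - ind_mean[as.character(ind_f), , drop = FALSE]
    ss_wi <- ss_wi + sum(dev_wi^2)
    # among individuals: individual means about their population mean
    ind_pop <- pop_of[ids]
    dev_ai <- ind_mean - pop_mean[as.character(ind_pop), , drop = FALSE]
    ss_ai <- ss_ai + 2 * sum(dev_ai^2)
    # among populations: population means about the grand mean
    cnt <- table(ind_pop)
    cnt <- cnt[cnt > 0L]
    dev_ap <- sweep(pop_mean[names(cnt), , drop = FALSE], 2L, grand)
    ss_ap <- ss_ap + sum(2 * as.numeric(cnt) * rowSums(dev_ap^2))
  }
  df <- c(k - 1L, n - k, n)
  ms <- c(ss_ap, ss_ai, ss_wi) / df
  n_c <- (n - sum(n_p^2) / n) / (k - 1L)
  s2_wi <- ms[3L]
  s2_ai <- (ms[2L] - s2_wi) / 2
  s2_ap <- (ms[1L] - ms[2L]) / (2 * n_c)
  raw <- c(among_populations = s2_ap, among_individuals = s2_ai,
           within_individuals = s2_wi)
  s2 <- if (truncate) pmax(raw, 0) else raw
  pct <- 100 * s2 / sum(s2)
  tab <- data.frame(
    source = c("among_populations", "among_individuals",
               "within_individuals", "total"),
    df = c(df, sum(df)),
    SS = c(ss_ap, ss_ai, ss_wi, ss_ap + ss_ai + ss_wi),
    MS = c(ms, NA),
    sigma2 = c(s2, sum(s2)),
    percent = c(pct, 100),
    stringsAsFactors = FALSE)
  structure(list(table = tab, sigma2_raw = raw, n_c = n_c),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$SS <- round(tab$SS, digits); tab$MS <- round(tab$MS, digits)
  tab$sigma2 <- round(tab$sigma2, digits)
  tab$percent <- round(tab$percent)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Variance-component percentages
#'
#' Shares of the total, in percent, for a vector of (non-negative) variance
#' components — e.g. among-population / among-individual /
#' within-individual AMOVA components.
#'
#' @param sigma2 numeric vector of variance components.
#' @return Percentages summing to 100.
#' @export
variance_percentages <- function(sigma2) 100 * sigma2 / sum(sigma2)

#' Write an AMOVA table to TSV
#' @param x an `amova` object.
#' @param path output file.
#' @export
write_amova <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise Fst between populations
#'
#' For each population pair, Fst = sigma2_among / sigma2_total from a
#' two-level AMOVA (among populations / within populations) on the pair's
#' gene copies, clipped to \[0, 1\]. This is the AMOVA-based (GenAlEx-style)
#' estimator, recorded in the `estimator` attribute.
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping named accession-to-population vector.
#' @return Symmetric Fst matrix with zero diagonal and attribute
#'   `estimator = "amova"`.
#' @export
pairwise_fst <- function(matrix, grouping) {
  grouping <- grouping[accessions(matrix)]
  pops <- sort(unique(grouping))
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  fst <- base::matrix(0, k, k, dimnames = list(pops, pops))
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    ids <- accessions(matrix)[grouping %in% c(pops[i], pops[j])]
    sub <- subset_genotypes(matrix, ids)
    fst[i, j] <- fst[j, i] <- .fst_two_level(sub, grouping[ids])
  }
  attr(fst, "estimator") <- "amova"
  fst
}

# two-level AMOVA Fst on gene copies: among populations / within populations
.fst_two_level <- function(matrix, grouping) {
  pops <- sort(unique(grouping))
  pop_of <- factor(grouping[accessions(matrix)], levels = pops)
  n <- nrow(matrix$a1)
  ind <- .allele_indicators(matrix)
  ss_ap <- ss_wp <- 0
  c_ap <- c_wp <- 0     # copy counts for df, accumulated per locus
  for (li in seq_along(ind)) {
    x <- ind[[li]]$x
    ok <- ind[[li]]$ok
    ids <- which(ok)
    if (length(ids) < 2L) next
    rows <- c(ids, n + ids)
    xo <- x[rows, , drop = FALSE]
    pop_f <- pop_of[rep(ids, 2L)]
    if (length(unique(pop_f)) < 2L) next
    grand <- colMeans(xo)
    pop_mean <- vapply(seq_len(ncol(xo)),
                       function(cc) tapply(xo[, cc], pop_f, mean),
                       numeric(nlevels(pop_f)))
    pop_mean <- base::matrix(pop_mean, nrow = nlevels(pop_f),
                             dimnames = list(levels(pop_f), NULL))
    cnt <- table(pop_f)
    cnt <- cnt[cnt > 0L]
    dev_ap <- sweep(pop_mean[names(cnt), , drop = FALSE], 2L, grand)
    ss_ap <- ss_ap + sum(as.numeric(cnt) * rowSums(dev_ap^2))
    dev_wp <- xo - pop_mean[as.character(pop_f), , drop = FALSE]
    ss_wp <- ss_wp + sum(dev_wp^2)
  }
  # df on full design: copies = 2N, k pops
  k <- length(pops)
  copies <- 2L * n
  n_cop <- 2L * as.integer(table(pop_of))
  df_ap <- k - 1L
  df_wp <- copies - k
  ms_ap <- ss_ap / df_ap
  ms_wp <- ss_wp / df_wp
  n_c <- (copies - sum(n_cop^2) / copies) / (k - 1L)
  s2_wp <- ms_wp
  s2_ap <- (ms_ap - ms_wp) / n_c
  if (s2_ap <= 0) return(0)
  min(1, s2_ap / (s2_ap + s2_wp))
}

#' Write an Fst matrix as a lower-triangle TSV
#' @param fst symmetric Fst matrix.
#' @param path output file.
#' @export
write_fst <- function(fst, path) {
  m <- round(fst, 3)
  m[upper.tri(m)] <- NA
  utils::write.table(cbind(population = rownames(m), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Per-population diversity summary
#'
#' [locus_stats()] computed within each population and averaged over loci
#' (so `N` is the mean per-locus genotyped sample size and may be
#' non-integer), with an overall mean row.
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping named accession-to-population vector.
#' @return Data frame with one row per population plus a `Mean` row;
#'   columns population, N, Na, Ne, I, Ho, He, F.
#' @export
grouped_diversity <- function(matrix, grouping) {
  grouping <- grouping[accessions(matrix)]
  pops <- sort(unique(grouping))
  rows <- lapply(pops, function(pp) {
    sub <- subset_genotypes(matrix, accessions(matrix)[grouping == pp])
    ps <- panel_summary(sub)
    data.frame(population = pp, t(ps$means[c("N", "Na", "Ne", "I", "Ho",
                                             "He", "F")]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(population = "Mean",
                         t(colMeans(out[, -1L, drop = FALSE])),
                         stringsAsFactors = FALSE)
  rbind(out, mean_row)
}

#' Evanno delta-K from replicate log-likelihoods
#'
#' Post-processing of admixture-model runs: for each interior K,
#' deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)), with
#' the sample (n-1) standard deviation over replicates. The optimal K is
#' the argmax of deltaK over interior K with positive sd; interior K with
#' sd = 0 are flagged undefined and excluded.
#'
#' @param runs data frame with columns `K` and `logL`, one row per
#'   replicate run; at least three consecutive K values with at least two
#'   replicates each.
#' @return A list of class `delta_k`: `table` (K, n_reps, mean_logL, sd,
#'   delta_k) and `optimal_k`.
#' @export
#' @examples
#' runs <- data.frame(K = rep(1:4, each = 3),
#'                    logL = c(-1000, -1000, -1000, -510, -500, -490,
#'                             -400, -400, -400, -390, -390, -390))
#' evanno_delta_k(runs)$optimal_k
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "logL") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("need at least three K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  mean_l <- vapply(ks, function(k) mean(runs$logL[runs$K == k]), numeric(1L))
  sd_l <- vapply(ks, function(k) stats::sd(runs$logL[runs$K == k]),
                 numeric(1L))
  n_reps <- vapply(ks, function(k) sum(runs$K == k), integer(1L))
  if (any(n_reps < 2L)) stop("need at least two replicates per K")
  dk <- rep(NA_real_, length(ks))
  interior <- 2:(length(ks) - 1L)
  for (i in interior) {
    if (is.na(sd_l[i]) || sd_l[i] <= 0) next  # undefined, excluded
    dk[i] <- abs(mean_l[i + 1L] - 2 * mean_l[i] + mean_l[i - 1L]) / sd_l[i]
  }
  if (all(is.na(dk))) stop("delta-K undefined at every interior K")
  structure(list(table = data.frame(K = ks, n_reps = n_reps,
                                    mean_logL = mean_l, sd = sd_l,
                                    delta_k = dk),
                 optimal_k = ks[which.max(dk)]),
            class = "delta_k")
}

#' @export
print.delta_k <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("optimal K:", x$optimal_k, "\n")
  invisible(x)
}

#' Write a delta-K table to TSV
#' @param x a `delta_k` object.
#' @param path output file.
#' @export
write_delta_k <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
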
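test_that("Nei distance matches closed forms and is symmetric", {
  # one locus, p = (1, 0) vs q = (0.5, 0.5): identity 1/sqrt(2)
  fa <- list(c(1, 0)); fb <- list(c(0.5, 0.5))
  expect_equal(nei_distance(fa, fb), -log(1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(nei_distance(fa, fb), 0.3466, tolerance = 1e-4)
  expect_equal(nei_distance(fa, fa), 0)
  expect_equal(nei_distance(fa, fb), nei_distance(fb, fa))
  # disjoint fixed alleles: infinite identity-zero case is flagged
  d <- nei_distance(list(c(1, 0)), list(c(0, 1)), cap = 10)
  expect_equal(as.numeric(d), 10)
  expect_true(attr(d, "capped"))
  # zero iff identical on simulated frequency sets
  set.seed(4)
  sim <- simulate_genotype_matrix(n_accessions = 30, n_loci = 6,
                                  n_subpops = 2, divergence = 0.1,
                                  missing_rate = 0, seed = 21)
  fr <- population_allele_freqs(sim$matrix, sim$grouping)
  expect_gt(nei_distance(fr[[1]], fr[[2]]), 0)
})

test_that("UPGMA reproduces the hand-computed 3-taxon tree", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  # A,B merge at height 1; C joins at height 3
  expect_true(grepl("(A:1,B:1)", tr$newick, fixed = TRUE) ||
              grepl("(B:1,A:1)", tr$newick, fixed = TRUE))
  expect_true(grepl("C:3", tr$newick, fixed = TRUE))
  expect_true(grepl("):2", tr$newick, fixed = TRUE))
  # two taxa: a cherry with equal branch lengths d/2
  d2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_true(grepl("X:2.5", upgma(d2)$newick, fixed = TRUE))
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("UPGMA trees are ultrametric and label-permutation invariant", {
  set.seed(10)
  sim <- simulate_genotype_matrix(n_accessions = 20, n_loci = 8,
                                  n_subpops = 2, divergence = 0.15,
                                  missing_rate = 0, seed = 13)
  dm <- nei_distance_matrix(sim$matrix)
  tr <- upgma(dm)
  depth <- ape::node.depth.edgelength(tr$phylo)
  tips <- depth[seq_along(tr$phylo$tip.label)]
  expect_lt(max(tips) - min(tips), 1e-9)
  # permuting labels gives the same tree topology and heights
  perm <- sample(rownames(dm))
  tr2 <- upgma(dm[perm, perm])
  expect_equal(sort(ape::cophenetic.phylo(tr$phylo)[rownames(dm), rownames(dm)]
                    [lower.tri(diag(nrow(dm)))]),
               sort(ape::cophenetic.phylo(tr2$phylo)[rownames(dm), rownames(dm)]
                    [lower.tri(diag(nrow(dm)))]))
  # independent cross-check against phangorn's UPGMA heights
  skip_if_not_installed("phangorn")
  ph <- phangorn::upgma(stats::as.dist(dm))
  expect_equal(sort(ape::cophenetic.phylo(tr$phylo)[rownames(dm), rownames(dm)]
                    [lower.tri(diag(nrow(dm)))]),
               sort(ape::cophenetic.phylo(ph)[rownames(dm), rownames(dm)]
                    [lower.tri(diag(nrow(dm)))]),
               tolerance = 1e-9)
})

test_that("AMOVA degrees of freedom, percents and panmixia behave", {
  sim <- simulate_genotype_matrix(n_accessions = 149, n_loci = 10,
                                  n_subpops = 3, divergence = 0.07,
                                  missing_rate = 0, seed = 40)
  am <- amova(sim$matrix, sim$grouping)
  tab <- am$table
  k <- 3; n <- 149
  expect_equal(tab$df[1:3], c(k - 1, n - k, n))
  expect_equal(tab$df[4], 2 * n - 1)
  expect_equal(sum(tab$percent[1:3]), 100, tolerance = 1e-9)
  expect_true(all(tab$sigma2[1:3] >= 0))
  # a panmictic population split arbitrarily shows ~no among-pop variance
  pan <- simulate_genotype_matrix(n_accessions = 500, n_loci = 12,
                                  n_subpops = 1, divergence = 0,
                                  missing_rate = 0, seed = 55)
  fake <- stats::setNames(rep(c("A", "B"), length.out = 500),
                          accessions(pan$matrix))
  am0 <- amova(pan$matrix, fake)
  expect_lt(am0$table$percent[1], 2)
  expect_error(amova(sim$matrix,
                     stats::setNames(c("A", rep("B", 148)),
                                     accessions(sim$matrix))),
               "at least two individuals")
})

test_that("printed variance components yield the published within share", {
  pct <- variance_percentages(c(0.636, 0.290, 4.930))
  expect_equal(round(pct[3]), 84)
  expect_equal(sum(pct), 100)
})

test_that("pairwise Fst is a valid matrix and recovers divergence", {
  sim <- simulate_genotype_matrix(n_accessions = 400, n_loci = 50,
                                  n_subpops = 2, divergence = 0.10,
                                  missing_rate = 0, seed = 90)
  fst <- pairwise_fst(sim$matrix, sim$grouping)
  expect_equal(fst, t(fst))
  expect_equal(unname(diag(fst)), rep(0, 2))
  expect_true(all(fst >= 0 & fst <= 1))
  expect_lt(abs(fst[1, 2] - 0.10), 0.03)
  expect_equal(attr(fst, "estimator"), "amova")
  # monotone in the divergence parameter
  est <- vapply(c(0.02, 0.05, 0.15), function(th) {
    s <- simulate_genotype_matrix(n_accessions = 200, n_loci = 30,
                                  n_subpops = 2, divergence = th,
                                  missing_rate = 0, seed = 91)
    pairwise_fst(s$matrix, s$grouping)[1, 2]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  # identical allele pools: Fst 0
  pan <- simulate_genotype_matrix(n_accessions = 300, n_loci = 20,
                                  n_subpops = 1, divergence = 0,
                                  missing_rate = 0, seed = 92)
  fake <- stats::setNames(rep(c("A", "B"), length.out = 300),
                          accessions(pan$matrix))
  expect_lt(pairwise_fst(pan$matrix, fake)[1, 2], 0.02)
})

test_that("per-cluster diversity averages match the panel on one group", {
  sim <- simulate_genotype_matrix(n_accessions = 40, n_loci = 6,
                                  n_subpops = 1, divergence = 0,
                                  missing_rate = 0.05, seed = 17)
  one <- stats::setNames(rep("ALL", 40), accessions(sim$matrix))
  gd <- grouped_diversity(sim$matrix, one)
  ps <- panel_summary(sim$matrix)
  expect_equal(gd$He[1], unname(ps$means["He"]))
  expect_equal(gd$N[1], unname(ps$means["N"]))   # mean per-locus N
  expect_true(all(gd$Ho >= 0 & gd$Ho <= 1))
  # published cluster Shannon indices average to 0.975
  expect_equal(round(mean(c(0.934, 1.141, 0.851)), 3), 0.975)
})

test_that("Evanno delta-K matches direct formula and finds planted knees", {
  # means (-1000, -500, -400, -390) with sd 10 at K = 2 gives deltaK = 40
  runs <- data.frame(K = rep(1:4, each = 2),
                     logL = c(-1000, -1000, -510, -490, -400, -400,
                              -390, -390))
  dk <- evanno_delta_k(runs)
  sd2 <- stats::sd(c(-510, -490))
  expect_equal(dk$table$delta_k[2], abs(-400 + 1000 - 2 * 500) / sd2)
  expect_equal(dk$table$delta_k[2] * sd2 / 10, 40)  # at sd 10
  expect_equal(dk$optimal_k, 2L)
  # perfectly linear means: second difference 0 everywhere
  lin <- data.frame(K = rep(1:4, each = 2),
                    logL = rep(c(-400, -300, -200, -100), each = 2) +
                      rep(c(-1, 1), 4))
  expect_equal(max(evanno_delta_k(lin)$table$delta_k, na.rm = TRUE), 0)
  # zero-sd interior K is excluded from the argmax
  z <- data.frame(K = rep(1:4, each = 2),
                  logL = c(-1000, -1000, -500, -500, -400, -390, -390, -380))
  expect_true(is.na(evanno_delta_k(z)$table$delta_k[2]))
  # planted knees are recovered across many random tables
  hitrate <- mean(vapply(1:100, function(i) {
    tk <- sample(2:6, 1)
    runs <- simulate_structure_runs(k_range = 1:8, true_k = tk, seed = i)
    evanno_delta_k(runs)$optimal_k == tk
  }, logical(1)))
  expect_equal(hitrate, 1)
})
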
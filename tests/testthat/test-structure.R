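test_that("allele-sharing distance matches the brute-force matcher", {
  g <- tibble::tibble(
    accession = rep(c("X", "Y"), each = 3),
    marker = rep(c("M1", "M2", "M3"), 2),
    genotype = c("A/A", "A/G", "C/T", "A/A", "A/G", "C/T"))
  expect_equal(as.matrix(dist_allele_sharing(g))["X", "Y"], 0)

  g$genotype <- c("A/A", "C/C", "G/G", "T/T", "A/A", "C/C")
  expect_equal(as.matrix(dist_allele_sharing(g))["X", "Y"], 1)

  set.seed(41)
  panel <- sim_panel(12, seed = 42)
  sim <- sim_genotypes(panel, n_neutral = 20, n_ht = 0, missing_rate = 0.1,
                       seed = 43)
  d <- as.matrix(dist_allele_sharing(sim))
  wide <- split(sim$genotype, sim$accession)
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    a <- panel$accession[pair[1]]
    b <- panel$accession[pair[2]]
    expect_equal(d[a, b], share_brute(wide[[a]], wide[[b]]))
  }
})

test_that("Nei distance is zero for identical profiles and infinite for
           fixed alternatives", {
  g <- tibble::tibble(
    accession = rep(c("a1", "a2", "b1", "b2"), each = 2),
    marker = rep(c("M1", "M2"), 4),
    genotype = c("A/G", "C/C", "A/G", "C/C", "A/G", "C/C", "A/G", "C/C"))
  grp <- data.frame(accession = c("a1", "a2", "b1", "b2"),
                    group = c("X", "X", "Y", "Y"))
  expect_equal(as.matrix(dist_nei(g, grp))["X", "Y"], 0)

  g2 <- g
  g2$genotype <- c("A/A", "C/C", "A/A", "C/C", "G/G", "T/T", "G/G", "T/T")
  expect_warning(dn <- dist_nei(g2, grp), "infinite")
  expect_true(is.infinite(as.matrix(dn)["X", "Y"]))

  # direct frequency-product oracle on a simulated two-group panel
  panel <- sim_panel(40, seed = 44)
  sim <- sim_genotypes(panel, n_neutral = 15, n_ht = 0, missing_rate = 0,
                       seed = 45)
  dn2 <- as.matrix(dist_nei(sim, data.frame(accession = panel$accession,
                                            group = panel$subpop)))
  freqs <- function(sub) {
    f <- allele_freqs(sim[sim$accession %in% sub, ])
    stats::setNames(f$freq, paste(f$marker, f$allele))
  }
  fa <- freqs(panel$accession[panel$subpop == "A"])
  fb <- freqs(panel$accession[panel$subpop == "B"])
  keys <- union(names(fa), names(fb))
  xa <- stats::setNames(rep(0, length(keys)), keys); xa[names(fa)] <- fa
  xb <- stats::setNames(rep(0, length(keys)), keys); xb[names(fb)] <- fb
  manual <- -log(sum(xa * xb) / sqrt(sum(xa^2) * sum(xb^2)))
  expect_equal(dn2["A", "B"], manual, tolerance = 1e-12)
})

test_that("UPGMA reproduces hand agglomeration and is ultrametric", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(as.dist(d))
  expect_equal(sort(attr(tree, "heights")), c(1, 3))
  coph <- as.matrix(cophenetic(tree))[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)

  # root-to-leaf depths identical (ultrametric) on random matrices, and the
  # cophenetic matrix equals an independent UPGMA (hclust average linkage)
  for (s in 1:5) {
    set.seed(50 + s)
    n <- sample(4:7, 1)
    x <- matrix(runif(n * 3), n)
    rownames(x) <- letters[1:n]
    dd <- dist(x)
    tree2 <- upgma(dd)
    depths <- ape::node.depth.edgelength(tree2)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
    ref <- cophenetic(stats::hclust(dd, method = "average"))
    expect_equal(as.matrix(cophenetic(tree2))[labels(dd), labels(dd)],
                 as.matrix(ref)[labels(dd), labels(dd)], tolerance = 1e-9)
  }
})

test_that("UPGMA ties break deterministically and permutation only relabels", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  t1 <- upgma(as.dist(d))
  # equal distances: first join must be the smallest label pair (A, B)
  first <- ape::extract.clade(t1, ape::getMRCA(t1, c("A", "B")))
  expect_setequal(first$tip.label, c("A", "B"))
  expect_identical(ape::write.tree(t1), ape::write.tree(upgma(as.dist(d))))

  set.seed(60)
  x <- matrix(runif(18), 6)
  rownames(x) <- paste0("t", 1:6)
  dd <- as.matrix(dist(x))
  perm <- sample(6)
  t_orig <- upgma(as.dist(dd))
  t_perm <- upgma(as.dist(dd[perm, perm]))
  lab <- rownames(dd)
  expect_equal(as.matrix(cophenetic(t_perm))[lab, lab],
               as.matrix(cophenetic(t_orig))[lab, lab], tolerance = 1e-9)
  expect_error(upgma(as.dist(matrix(NA_real_, 2, 2))), "complete")
})

test_that("PCoA recovers configurations from Euclidean distances", {
  # two points at distance 2: one positive eigenvalue, coordinates +-1
  d2 <- as.dist(matrix(c(0, 2, 2, 0), 2, dimnames = list(c("p", "q"), NULL)))
  pc2 <- pcoa_analysis(d2)
  expect_equal(sum(pc2$eigenvalues > 1e-9), 1)
  expect_equal(pc2$eigenvalues[1], 2)
  expect_equal(sort(pc2$points$Axis1), c(-1, 1))

  # collinear points: a single positive axis carries 100%
  line <- dist(matrix(c(0, 1, 2.5, 4), 4))
  pcl <- pcoa_analysis(line)
  expect_equal(length(pcl$contribution), 1)
  expect_equal(pcl$contribution, 100)

  # reconstruction oracle: distances from 3-D points are reproduced
  set.seed(70)
  x <- matrix(rnorm(36), 12, 3)
  dx <- dist(x)
  pc <- pcoa_analysis(dx)
  rec <- dist(as.matrix(pc$points[, -1]))
  expect_lt(max(abs(rec - dx)), 1e-8)
  expect_equal(sum(pc$eigenvalues), sum(dx^2) / 12, tolerance = 1e-8)

  degen <- pcoa_analysis(matrix(0, 3, 3))
  expect_true(degen$degenerate)
})

test_that("admixture sampler matches the analytic single-population
           likelihood at K = 1", {
  panel <- sim_panel(40, seed = 80)
  g <- sim_genotypes(panel, n_neutral = 15, n_ht = 0, missing_rate = 0.05,
                     seed = 81)
  fit <- structure_gibbs(g, K = 1, burnin = 300, reps = 1500, seed = 82)
  expect_true(all(fit$Q$Cluster1 == 1))
  # analytic plug-in log-likelihood under pooled frequencies
  f <- allele_freqs(g)
  counts <- f$count
  ll <- sum(counts * log(f$freq))
  expect_equal(fit$mean_lnl, ll, tolerance = 0.02 * abs(ll))
  expect_gt(fit$L_est, ll * 1.05) # within a few percent, allowing MC noise
})

test_that("admixture sampler is deterministic and keeps Q rows normalized", {
  panel <- sim_panel(25, seed = 83)
  g <- sim_genotypes(panel, n_neutral = 10, n_ht = 0, seed = 84)
  f1 <- structure_gibbs(g, K = 3, burnin = 50, reps = 100, seed = 85)
  f2 <- structure_gibbs(g, K = 3, burnin = 50, reps = 100, seed = 85)
  expect_identical(f1$lnl_trace, f2$lnl_trace)
  expect_identical(f1$Q, f2$Q)
  qsum <- rowSums(as.matrix(f1$Q[, -1]))
  expect_true(all(abs(qsum - 1) < 1e-9))
  expect_error(structure_gibbs(g, K = 30, seed = 1), "exceed")
})

test_that("admixture at K = 2 recovers planted subpopulations", {
  panel <- sim_panel(120, seed = 86)
  g <- sim_genotypes(panel, n_neutral = 40, n_ht = 0, fst = 0.15,
                     missing_rate = 0, seed = 87)
  fit <- structure_gibbs(g, K = 2, burnin = 1000, reps = 3000,
                         marker_set = "NEUTRAL", seed = 88)
  asg <- assign_subpopulations(fit, meta = panel[, c("accession", "subpop")])
  tab <- table(asg$cluster, asg$subpop)
  acc <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / sum(tab)
  expect_gte(acc, 0.9)
})

test_that("Evanno table reproduces hand arithmetic and flags degenerate
           profiles", {
  mk <- function(K, L) {
    structure(list(K = K, L_est = L, Q = NULL, lnl_trace = numeric(0),
                   mean_lnl = L, n = 10, m = 5, seed = NULL),
              class = "structure_fit")
  }
  # three runs per K with spread {-5, 0, +5}: sd exactly 5
  fits <- unlist(lapply(list(c(1, -1000), c(2, -700), c(3, -690), c(4, -688)),
                        function(kl) {
                          lapply(c(-5, 0, 5), function(e) mk(kl[1], kl[2] + e))
                        }), recursive = FALSE)
  ev <- evanno_delta_k(fits)
  expect_equal(ev$delta_K[ev$K == 2], 58)
  expect_equal(ev$delta_K[ev$K == 3], 1.6)
  expect_equal(optimal_k(ev), 2)

  # linear mean likelihood: all second differences zero, no peak
  lin <- unlist(lapply(1:4, function(k) {
    lapply(c(-5, 0, 5), function(e) mk(k, -1000 + 100 * k + e))
  }), recursive = FALSE)
  expect_warning(evl <- evanno_delta_k(lin), "ambiguous")
  expect_true(attr(evl, "ambiguous"))
  expect_true(is.na(optimal_k(evl)))

  # zero spread at one K leaves delta-K undefined there
  zs <- c(fits[1:3], list(mk(2, -700), mk(2, -700), mk(2, -700)),
          fits[7:12])
  expect_warning(evz <- evanno_delta_k(zs), "zero likelihood spread")
  expect_true(is.na(evz$delta_K[evz$K == 2]))
  expect_error(evanno_delta_k(fits[1:6]), ">= 3 K")
})

test_that("subpopulation assignment uses argmax with admixture flagging", {
  fit <- structure(list(
    Q = tibble::tibble(accession = c("a", "b", "c"),
                       Cluster1 = c(0.9, 0.5, 0.2),
                       Cluster2 = c(0.1, 0.5, 0.8)),
    K = 2L, n = 3, m = 1, lnl_trace = 0, mean_lnl = 0, L_est = 0,
    seed = NULL), class = "structure_fit")
  asg <- assign_subpopulations(fit)
  expect_equal(asg$cluster, c("Cluster1", "Cluster1", "Cluster2"))
  expect_equal(asg$admixed, c(FALSE, FALSE, FALSE))
  asg2 <- assign_subpopulations(fit, threshold = 0.6)
  expect_equal(asg2$admixed, c(FALSE, TRUE, FALSE))
  # cross-tab totals equal panel size
  meta <- tibble::tibble(accession = c("a", "b", "c"),
                         sowing_type = c("SS", "WS", "WS"))
  comp <- subpop_composition(assign_subpopulations(fit, meta = meta),
                             "sowing_type")
  expect_equal(sum(comp$n), 3)
  expect_true(all(abs(tapply(comp$pct, comp$cluster, sum) - 100) < 1e-9))
})
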
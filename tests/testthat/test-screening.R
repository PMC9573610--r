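test_that("field survival rate pools replicates over seeds sown", {
  expect_equal(field_survival_rate(c(6, 6, 6), 10), 60)
  expect_equal(field_survival_rate(0, 10), 0)
  expect_equal(field_survival_rate(c(10, 10, 10), 10), 100)
  expect_equal(field_survival_rate(c(3, 6), 10), 45)
  expect_error(field_survival_rate(integer(0)), "no replicate")
  expect_error(field_survival_rate(11, 10), "exceed")
})

test_that("grain filling rate divides hundred-grain weight by filling days", {
  expect_equal(grain_filling_rate(30, "2018-05-01", "2018-05-31"), 1)
  expect_equal(grain_filling_rate(0, "2018-05-01", "2018-05-31"), 0)
  # calendar-day subtraction oracle
  expect_equal(grain_filling_rate(24, "2018-05-01", "2018-05-25"),
               24 / as.numeric(as.Date("2018-05-25") - as.Date("2018-05-01")))
  expect_equal(grain_filling_rate(24, "2018-05-01", "2018-05-25"), 1)
  expect_error(grain_filling_rate(30, "2018-05-31", "2018-05-01"), "positive")
})

test_that("mean grain weight averages replicates of up to five plants", {
  expect_equal(mean_grain_weight(rep(10, 5)), 10)
  expect_equal(mean_grain_weight(list(5, 15)), 10)
  # only the first five plants of a replicate are weighed
  expect_equal(mean_grain_weight(c(1, 1, 1, 1, 1, 100)), 1)
  # direct two-level mean oracle
  set.seed(42)
  reps <- list(runif(5, 10, 40), runif(3, 10, 40), runif(5, 10, 40))
  expect_equal(mean_grain_weight(reps),
               mean(vapply(reps, function(w) mean(w[1:min(5, length(w))]),
                           numeric(1))))
  expect_true(is.na(mean_grain_weight(list(numeric(0)))))
})

test_that("loss rates follow the relative-weight formula with clamping", {
  expect_equal(loss_rates(50, 45, 42), tibble::tibble(LR1 = 10, LR2 = 16))
  expect_equal(loss_rates(50, 50, 50), tibble::tibble(LR1 = 0, LR2 = 0))
  # late-sowing gain clamps to zero loss; total loss clamps at 100
  expect_equal(loss_rates(40, 44, 2), tibble::tibble(LR1 = 0, LR2 = 95))
  expect_equal(loss_rates(10, -5, 0)$LR1, 100)
  expect_true(all(is.na(loss_rates(0, 1, 1))))
})

test_that("classification reproduces the printed nine-level standard", {
  expect_equal(classify_level(10, 15), 1L)
  expect_equal(classify_level(50, 30), 4L)
  expect_equal(classify_level(85, 95), 9L)
  expect_true(is.na(classify_level(20, 70))) # |diff| = 50 > 40: excluded
  # boundary semantics: bands closed above, ties go to the lower band
  expect_equal(classify_level(20, 20), 1L)
  expect_equal(classify_level(20.0001, 20), 2L)
  expect_equal(classify_level(40, 40), 3L)
  expect_error(classify_level(120, 10), "\\[0, 100\\]")
})

test_that("band-sum classification agrees with the literal rule transcription
           on an exhaustive grid", {
  grid <- expand.grid(lr1 = seq(0, 100, by = 0.5), lr2 = seq(0, 100, by = 0.5))
  got <- classify_level(grid$lr1, grid$lr2)
  lit <- mapply(level_literal, grid$lr1, grid$lr2)
  excluded <- vapply(lit, identical, logical(1), "EXCLUDED")
  expect_true(all(is.na(got[excluded])))
  covered <- !excluded & !is.na(lit)
  expect_true(all(got[covered] == as.numeric(lit[covered])))
  # the printed rules leave a narrow non-excluded sliver (band indices two
  # apart, loss difference <= 40) that the band sum fills continuously
  gap <- !excluded & is.na(lit)
  expect_true(all(!is.na(got[gap])))
  expect_true(all(abs(grid$lr1[gap] - grid$lr2[gap]) <= 40))
})

test_that("classification is symmetric and monotone", {
  set.seed(7)
  lr1 <- runif(300, 0, 100)
  lr2 <- runif(300, 0, 100)
  expect_identical(classify_level(lr1, lr2), classify_level(lr2, lr1))
  # raising either loss rate never lowers the level (non-excluded pairs)
  base <- classify_level(lr1, lr2)
  for (d in c(5, 20)) {
    up <- classify_level(pmin(lr1 + d, 100), lr2)
    keep <- !is.na(base) & !is.na(up)
    expect_true(all(up[keep] >= base[keep]))
  }
})

test_that("levels map to HT / INTERMEDIATE / HS categories", {
  expect_equal(categorize_level(c(1, 2, 3)), rep("HT", 3))
  expect_equal(categorize_level(c(4, 5, 6)), rep("INTERMEDIATE", 3))
  expect_equal(categorize_level(c(7, 8, 9)), rep("HS", 3))
  expect_true(is.na(categorize_level(NA_integer_)))
  expect_error(categorize_level(10), "1..9")
})

test_that("screen_round scores accessions and ledgers exclusions", {
  # identical weights across stages: everyone level 1, no HS
  tr <- trial_from_weights(rep(30, 6), rep(30, 6), rep(30, 6))
  res <- screen_round(tr)
  expect_s3_class(res, "pea_screening")
  expect_true(all(res$level == 1))
  s <- round_summary(res)
  expect_equal(s$n_hs, 0)
  expect_equal(s$n_ht, 6)
  expect_equal(sum(s$level_counts$n), s$n_classified)

  # single accession: one result, histogram mass 1
  res1 <- screen_round(trial_from_weights(30, 24, 15))
  expect_equal(nrow(res1), 1)
  expect_equal(res1$level, classify_level(20, 50))
  expect_equal(sum(round_summary(res1)$level_counts$n), 1)

  # exclusion ledger: missing stage and LR divergence
  tr2 <- dplyr::bind_rows(
    make_trial("X1", "NS", list(30)), make_trial("X1", "LS1", list(30)),
    trial_from_weights(50, 45, 15, ids = "X2"))
  res2 <- screen_round(tr2)
  expect_equal(res2$exclusion_reason[res2$accession == "X1"],
               "MISSING_LATE_STAGE")
  expect_equal(res2$exclusion_reason[res2$accession == "X2"], "LR_DIFF_GT_40")
  expect_true(all(is.na(res2$level)))
  expect_error(screen_round(tr2[0, ]), "empty")
})

test_that("screening recovers planted tolerance classes", {
  panel <- sim_panel(200, prop_ht = 0.5, seed = 11)
  trial <- sim_trial(panel, effect = 60, noise_sd = 5, seed = 12)
  res <- screen_round(trial)
  truth <- attr(trial, "truth")
  j <- dplyr::inner_join(tibble::as_tibble(res), truth, by = "accession")
  expect_gt(mean(j$level[j$latent_class == "HT"] %in% 1:3, na.rm = TRUE), 0.9)
  expect_gt(mean(j$level[j$latent_class == "HS"] %in% 7:9, na.rm = TRUE), 0.9)
})

test_that("iterative screening carries forward extremes and tracks consistency", {
  # deterministic weights, three identical rounds
  w_ns <- c(50, 50, 50, 50)
  w_ls1 <- c(45, 30, 20, 8)   # LR1: 10, 40, 60, 84
  w_ls2 <- c(40, 25, 12, 4)   # LR2: 20, 50, 76, 92
  rounds <- replicate(3, trial_from_weights(w_ns, w_ls1, w_ls2),
                      simplify = FALSE)
  s <- screen_iterative(rounds)
  r1 <- s$results[[1]]
  expect_equal(s$extreme_ht, r1$accession[r1$category == "HT"])
  expect_equal(s$extreme_hs, r1$accession[r1$category == "HS"])
  expect_setequal(s$consistent$accession, c(s$extreme_ht, s$extreme_hs))

  # category flip between rounds drops the accession from the consistency set
  flip <- rounds
  flip[[3]] <- trial_from_weights(50, 8, 4, ids = "G001") |>
    dplyr::bind_rows(trial_from_weights(rep(50, 3), w_ls1[-1], w_ls2[-1],
                                        ids = sprintf("G%03d", 2:4)))
  s2 <- screen_iterative(flip)
  expect_false("G001" %in% s2$consistent$accession)

  # disjoint rounds are rejected
  expect_error(screen_iterative(list(
    trial_from_weights(50, 40, 30, ids = "A"),
    trial_from_weights(50, 40, 30, ids = "B"))), "share no accessions")
})

test_that("consistency set sits inside the union of final extremes on
           synthetic three-round runs", {
  panel <- sim_panel(80, seed = 21)
  rounds <- list()
  current <- panel
  for (r in 1:3) {
    rounds[[r]] <- sim_trial(current, round = r, seed = 30 + r)
    res <- screen_round(rounds[[r]])
    keep <- res$accession[!is.na(res$category) & res$category != "INTERMEDIATE"]
    current <- panel[panel$accession %in% keep, ]
  }
  s <- screen_iterative(rounds)
  # set-algebra oracle on the per-round category tables
  cats <- lapply(s$results, function(r) {
    stats::setNames(r$category, r$accession)
  })
  in_all <- Reduce(intersect, lapply(cats, names))
  manual <- Filter(function(a) {
    vals <- unlist(lapply(cats, function(x) x[a]))
    vals <- vals[!is.na(vals)]
    length(vals) > 0 && length(unique(vals)) == 1 && unique(vals) %in% c("HT", "HS")
  }, unique(unlist(lapply(cats, names))))
  expect_setequal(s$consistent$accession, manual)
  expect_true(all(s$consistent$accession %in% c(s$extreme_ht, s$extreme_hs)))
})

test_that("KS statistic matches a brute-force ECDF scan and flags degenerate
           input", {
  x <- c(2, 3, 3, 5, 8)
  got <- ks_normality(x)
  expect_equal(got$statistic, ks_stat_brute(x), tolerance = 1e-12)
  expect_false(got$degenerate)
  deg <- ks_normality(rep(4, 6))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_error(ks_normality(c(1, 2)), ">= 5")
})

test_that("GFR ANOVA matches the closed-form F for two balanced groups", {
  # two groups, equal within-group variance, known means
  g1 <- c(1.0, 1.2, 0.8, 1.1, 0.9)
  g2 <- g1 + 0.5
  res <- screen_round(trial_from_weights(rep(50, 10), rep(45, 10), rep(40, 10)))
  res$category <- rep(c("HT", "HS"), each = 5)
  res$GFR_NS <- c(g1, g2)
  res$GFR_LS1 <- c(g1, g2)
  res$GFR_LS2 <- c(g1, g2)
  out <- compare_gfr(res)
  n <- 5
  ssb <- n * sum((c(mean(g1), mean(g2)) - mean(c(g1, g2)))^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_manual <- (ssb / 1) / (ssw / 8)
  expect_equal(out$statistic, rep(f_manual, 3), tolerance = 1e-12)
  # identical groups: F = 0
  res$GFR_NS <- rep(g1, 2)
  expect_equal(compare_gfr(res)$statistic[out$stage == "NS"][1], 0)
  # single observation per group: error
  res2 <- res[c(1, 6), ]
  class(res2) <- class(res)
  expect_error(compare_gfr(res2), ">= 2")
})
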
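# Independent oracles used across tests. These re-derive expected values by
# direct transcription or brute force, never by calling the code under test.

# Literal transcription of the nine printed level rules. Returns NA where no
# rule applies (the printed rules cover band-index differences <= 1 only) and
# "EXCLUDED" where the loss rates differ by more than 40 points.
level_literal <- function(lr1, lr2) {
  if (abs(lr1 - lr2) > 40) return("EXCLUDED")
  between <- function(x, lo, hi) x > lo & x <= hi
  b0 <- function(x) x >= 0 & x <= 20
  if (b0(lr1) && b0(lr2)) return(1)
  if ((b0(lr1) && between(lr2, 20, 40)) ||
      (between(lr1, 20, 40) && b0(lr2))) return(2)
  if (between(lr1, 20, 40) && between(lr2, 20, 40)) return(3)
  if ((between(lr1, 20, 40) && between(lr2, 40, 60)) ||
      (between(lr1, 40, 60) && between(lr2, 20, 40))) return(4)
  if (between(lr1, 40, 60) && between(lr2, 40, 60)) return(5)
  if ((between(lr1, 40, 60) && between(lr2, 60, 80)) ||
      (between(lr1, 60, 80) && between(lr2, 40, 60))) return(6)
  if (between(lr1, 60, 80) && between(lr2, 60, 80)) return(7)
  if ((between(lr1, 60, 80) && between(lr2, 80, 100)) ||
      (between(lr1, 80, 100) && between(lr2, 60, 80))) return(8)
  if (between(lr1, 80, 100) && between(lr2, 80, 100)) return(9)
  NA
}

# Brute-force diversity indices from a vector of "A/G" genotype calls.
diversity_brute <- function(genotypes) {
  genotypes <- genotypes[!is.na(genotypes) & genotypes != "./."]
  alleles <- unlist(strsplit(genotypes, "/", fixed = TRUE))
  p <- as.numeric(table(alleles)) / length(alleles)
  gd <- 1 - sum(p^2)
  pic <- gd
  k <- length(p)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) pic <- pic - 2 * p[i]^2 * p[j]^2
  }
  het <- vapply(strsplit(genotypes, "/", fixed = TRUE),
                function(a) a[1] != a[2], logical(1))
  list(gd = gd, pic = pic, maf = max(p), na = k, he = mean(het),
       ng = length(unique(genotypes)))
}

# Brute-force one-sample KS statistic against N(mean, sd): sup over the
# ECDF jump points of both one-sided deviations.
ks_stat_brute <- function(x) {
  x <- sort(x)
  n <- length(x)
  f <- pnorm(x, mean(x), sd(x))
  max(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n))
}

# Brute-force longest substring of `a` whose reverse complement occurs in `b`.
rc_brute <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, NULL)[[1]]]), collapse = "")
}

cross_run_brute <- function(a, b) {
  best <- 0
  na <- nchar(a)
  for (len in seq_len(na)) {
    for (start in 1:(na - len + 1)) {
      sub <- substr(a, start, start + len - 1)
      if (grepl(rc_brute(sub), b, fixed = TRUE)) best <- max(best, len)
    }
  }
  best
}

self_run_brute <- function(a) cross_run_brute(a, a)

# Brute-force allele-sharing distance between two "A/G" genotype vectors.
share_brute <- function(g1, g2) {
  shared <- 0L
  compared <- 0L
  for (k in seq_along(g1)) {
    if (g1[k] == "./." || g2[k] == "./.") next
    compared <- compared + 1L
    a <- strsplit(g1[k], "/", fixed = TRUE)[[1]]
    b <- strsplit(g2[k], "/", fixed = TRUE)[[1]]
    for (al in unique(c(a, b))) {
      shared <- shared + min(sum(a == al), sum(b == al))
    }
  }
  1 - shared / (2 * compared)
}

# Minimal hand-built trial tibble: one accession/stage/replicate per row.
make_trial <- function(accession, stage, weights, replicate = 1,
                       survivors = 10, sown = 10, round = 1,
                       flowering = as.Date("2018-05-01"),
                       maturity = as.Date("2018-05-31"), hgw = 30) {
  tibble::tibble(accession = accession, round = round, stage = stage,
                 replicate = replicate, sown = sown, survivors = survivors,
                 plant_weights = lapply(weights, identity),
                 flowering_date = flowering, maturity_date = maturity,
                 hundred_grain_weight = hgw)
}

# Trial where every accession has deterministic stage weights (one replicate).
trial_from_weights <- function(w_ns, w_ls1, w_ls2, ids = NULL) {
  n <- length(w_ns)
  ids <- ids %||% sprintf("G%03d", seq_len(n))
  dplyr::bind_rows(
    make_trial(ids, "NS", as.list(w_ns)),
    make_trial(ids, "LS1", as.list(w_ls1)),
    make_trial(ids, "LS2", as.list(w_ls2))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
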
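# convert a long genotype tibble into paired allele-index matrices
# (alleles coded 1..k per marker, alphabetical; NA = missing call)
geno_to_indices <- function(geno, marker_set = NULL) {
  assert_columns(geno, c("accession", "marker", "genotype"), "geno")
  if (!is.null(marker_set) && "marker_set" %in% names(geno)) {
    geno <- geno[geno$marker_set %in% marker_set, ]
  }
  if (nrow(geno) == 0) abort("no genotype calls selected")
  acc <- unique(geno$accession)
  markers <- unique(geno$marker)
  al <- split_alleles(geno$genotype)
  al[is_missing_call(geno$genotype), ] <- NA_character_
  i <- match(geno$accession, acc)
  j <- match(geno$marker, markers)
  a1 <- matrix(NA_integer_, length(acc), length(markers),
               dimnames = list(acc, markers))
  a2 <- a1
  alphabets <- lapply(split(c(al[, 1], al[, 2]), rep(markers[j], 2)),
                      function(x) sort(unique(x[!is.na(x)])))
  alphabets <- alphabets[markers]
  k1 <- unlist(Map(function(a, mk) match(a, alphabets[[mk]]), al[, 1],
                   markers[j]), use.names = FALSE)
  k2 <- unlist(Map(function(a, mk) match(a, alphabets[[mk]]), al[, 2],
                   markers[j]), use.names = FALSE)
  a1[cbind(i, j)] <- pmin(k1, k2)
  a2[cbind(i, j)] <- pmax(k1, k2)
  list(a1 = a1, a2 = a2,
       n_alleles = vapply(alphabets, length, integer(1)),
       alphabets = alphabets)
}

#' Allele-sharing distance between accessions
#'
#' Individual-level genetic distance `d(i, j) = 1 - shared / (2 * m)`, where
#' `shared` counts the alleles the two genotypes have in common (multiset
#' intersection, 0-2 per marker) and `m` is the number of markers with
#' non-missing calls in both accessions (pairwise-complete). Pairs with no
#' comparable marker get `NA` with a warning.
#'
#' @param geno Long genotype tibble (`accession`, `marker`, `genotype`).
#' @param marker_set Optional marker-set filter (e.g. "NEUTRAL").
#' @return A `dist` object labelled by accession.
#' @examples
#' g <- sim_genotypes(sim_panel(10, seed = 1), n_neutral = 8, n_ht = 0, seed = 2)
#' dist_allele_sharing(g)
#' @export
dist_allele_sharing <- function(geno, marker_set = NULL) {
  ix <- geno_to_indices(geno, marker_set)
  if (nrow(ix$a1) < 2) abort("need >= 2 accessions")
  d <- .allele_share_dist(ix$a1, ix$a2)
  dimnames(d) <- list(rownames(ix$a1), rownames(ix$a1))
  if (anyNA(d[upper.tri(d)])) {
    warn("some accession pairs share no comparable markers; distances NA")
  }
  as.dist(d)
}

#' Nei's (1972) standard genetic distance between groups
#'
#' From per-group allele frequencies: with gene identities
#' `J_X = sum_l sum_a x_a^2`, `J_Y` likewise and
#' `J_XY = sum_l sum_a x_a y_a` summed over shared loci,
#' `D = -ln(J_XY / sqrt(J_X * J_Y))`. Groups fixed for different alleles at
#' some locus can give `J_XY = 0`, i.e. infinite distance, which is flagged
#' with a warning.
#'
#' @param geno Long genotype tibble.
#' @param groups Either a character vector of group labels aligned with the
#'   distinct accessions of `geno`, or a data frame with columns `accession`
#'   and `group`.
#' @param marker_set Optional marker-set filter.
#' @return A `dist` object over groups.
#' @export
dist_nei <- function(geno, groups, marker_set = NULL) {
  if (!is.null(marker_set) && "marker_set" %in% names(geno)) {
    geno <- geno[geno$marker_set %in% marker_set, ]
  }
  acc <- unique(geno$accession)
  if (is.data.frame(groups)) {
    assert_columns(groups, c("accession", "group"), "groups")
    grp <- groups$group[match(acc, groups$accession)]
  } else {
    if (length(groups) != length(acc)) {
      abort("`groups` must match the number of distinct accessions")
    }
    grp <- groups
  }
  labels <- sort(unique(grp[!is.na(grp)]))
  if (length(labels) < 2) abort("need >= 2 groups")
  geno$group <- grp[match(geno$accession, acc)]
  freqs <- geno |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ allele_freqs(.x)) |>
    dplyr::ungroup()

  d <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  inf_flag <- FALSE
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j <= i) next
      fx <- freqs[freqs$group == labels[i], ]
      fy <- freqs[freqs$group == labels[j], ]
      shared <- intersect(unique(fx$marker), unique(fy$marker))
      fx <- fx[fx$marker %in% shared, ]
      fy <- fy[fy$marker %in% shared, ]
      jx <- sum(fx$freq^2)
      jy <- sum(fy$freq^2)
      joined <- dplyr::inner_join(fx, fy, by = c("marker", "allele"))
      jxy <- sum(joined$freq.x * joined$freq.y)
      if (jxy == 0) {
        inf_flag <- TRUE
        d[i, j] <- d[j, i] <- Inf
      } else {
        d[i, j] <- d[j, i] <- -log(jxy / sqrt(jx * jy))
      }
    }
  }
  if (inf_flag) warn("some group pairs share no alleles: infinite Nei distance")
  as.dist(d)
}

#' UPGMA tree from a distance matrix
#'
#' Agglomerates with unweighted pair-group average linkage (cluster-size
#' weighted distance updates), producing an ultrametric rooted tree. Ties in
#' the minimum distance are broken deterministically by the smallest pair of
#' leaf labels, so output is reproducible and invariant (up to relabelling)
#' under input permutation.
#'
#' @param d A `dist` object or symmetric matrix; must be complete.
#' @return An [ape::as.phylo] tree (class `phylo`) with branch lengths;
#'   serialize with [ape::write.tree()].
#' @examples
#' d <- as.dist(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'                     dimnames = list(c("A", "B", "C"), NULL)))
#' upgma(d)
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (anyNA(dm)) abort("UPGMA needs a complete distance matrix")
  n <- nrow(dm)
  if (n < 2) abort("need >= 2 taxa")
  labels <- rownames(dm) %||% as.character(seq_len(n))

  # per active cluster: newick fragment, size, height, smallest leaf index
  nwk <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  min_leaf <- seq_len(n)
  join_heights <- numeric(0)
  dcur <- dm

  while (length(nwk) > 1) {
    k <- length(nwk)
    best <- NULL
    best_d <- Inf
    best_tie <- c(Inf, Inf)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- dcur[i, j]
        tie <- sort(c(min_leaf[i], min_leaf[j]))
        better <- dij < best_d - 1e-15 ||
          (dij <= best_d + 1e-15 &&
             (tie[1] < best_tie[1] ||
                (tie[1] == best_tie[1] && tie[2] < best_tie[2])))
        if (better) {
          best <- c(i, j); best_d <- dij; best_tie <- tie
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    join_heights <- c(join_heights, h)
    merged <- sprintf("(%s:%.12g,%s:%.12g)",
                      nwk[i], h - height[i], nwk[j], h - height[j])
    others <- setdiff(seq_len(k), c(i, j))
    # size-weighted average linkage update
    newd <- (size[i] * dcur[i, others] + size[j] * dcur[j, others]) /
      (size[i] + size[j])
    dcur <- rbind(cbind(dcur[others, others, drop = FALSE], newd),
                  c(newd, 0))
    nwk <- c(nwk[others], merged)
    size <- c(size[others], size[i] + size[j])
    height <- c(height[others], h)
    min_leaf <- c(min_leaf[others], min(min_leaf[i], min_leaf[j]))
  }

  tree <- ape::read.tree(text = paste0(nwk, ";"))
  attr(tree, "heights") <- sort(join_heights)
  tree
}

#' Principal coordinate analysis of a genetic distance matrix
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axis contribution rates are each positive eigenvalue as a
#' percentage of the positive-eigenvalue total.
#'
#' @param d A `dist` object or symmetric matrix.
#' @return An object of class `pea_pcoa`: list with `points` (tibble:
#'   `accession`, `Axis1`, `Axis2`, ...), `eigenvalues` (all, descending),
#'   `contribution` (percent per retained axis), `degenerate` (TRUE for an
#'   all-zero input, where rates are undefined).
#' @examples
#' g <- sim_genotypes(sim_panel(12, seed = 1), n_neutral = 10, n_ht = 0, seed = 2)
#' pcoa_analysis(dist_allele_sharing(g))
#' @export
pcoa_analysis <- function(d) {
  dm <- as.matrix(d)
  if (anyNA(dm)) abort("PCoA needs a complete distance matrix")
  n <- nrow(dm)
  labels <- rownames(dm) %||% as.character(seq_len(n))
  # Gower double centering: B = (I - J/n) (-d^2/2) (I - J/n)
  B <- -0.5 * dm^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-12 & eig$values > 0
  if (!any(pos)) {
    return(structure(list(
      points = tibble::tibble(accession = labels),
      eigenvalues = eig$values, contribution = numeric(0),
      degenerate = TRUE), class = "pea_pcoa"))
  }
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(accession = labels),
                              tibble::as_tibble(coords)),
    eigenvalues = eig$values,
    contribution = eig$values[pos] / sum(eig$values[pos]) * 100,
    degenerate = FALSE
  ), class = "pea_pcoa")
}

#' @export
print.pea_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$points), length(x$contribution)))
  if (length(x$contribution) > 0) {
    k <- min(3, length(x$contribution))
    cat(sprintf("First %d axes explain %.1f%%\n", k,
                sum(x$contribution[seq_len(k)])))
  }
  invisible(x)
}

#' @export
tidy.pea_pcoa <- function(x, ...) x$points

#' @export
glance.pea_pcoa <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$points),
    n_positive = length(x$contribution),
    contrib_axis1 = x$contribution[1] %||% NA_real_,
    contrib_first3 = sum(head(x$contribution, 3)))
}

#' Admixture-model Gibbs sampler (STRUCTURE-style clustering)
#'
#' Bayesian clustering of accessions into `K` ancestral clusters under the
#' admixture model with uncorrelated allele frequencies: per-allele-copy
#' cluster origins, cluster allele frequencies with a `Dirichlet(lambda)`
#' prior and per-accession admixture proportions with a `Dirichlet(alpha)`
#' prior are Gibbs-sampled; missing calls are skipped. The admixture
#' concentration `alpha` is fixed (no Metropolis update). The run-level
#' likelihood estimate is `mean(lnL) - var(lnL)/2` over the post-burn-in
#' trace (the deviance-style estimator used for delta-K model selection).
#'
#' Clusters are reported in canonical order (by the first accession whose
#' membership exceeds 0.5) so runs are comparable despite label switching.
#'
#' @param geno Long genotype tibble.
#' @param K Number of clusters (>= 1).
#' @param burnin,reps Burn-in sweeps and recorded sweeps. The defaults
#'   (2000/8000) are desk-scale; 10000/100000 mirrors the conventional
#'   field-scale setting.
#' @param alpha,lambda Dirichlet concentrations for admixture proportions and
#'   allele frequencies.
#' @param marker_set Optional marker-set filter.
#' @param seed Integer seed; same seed and inputs give identical traces.
#' @return Object of class `structure_fit`: `Q` (tibble `accession`,
#'   `Cluster1..K`), `lnl_trace`, `L_est`, `mean_lnl`, `K`, `n`, `m`,
#'   `seed`.
#' @examples
#' g <- sim_genotypes(sim_panel(20, seed = 1), n_neutral = 10, n_ht = 0, seed = 2)
#' fit <- structure_gibbs(g, K = 2, burnin = 100, reps = 200, seed = 3)
#' @export
structure_gibbs <- function(geno, K, burnin = 2000, reps = 8000,
                            alpha = 1, lambda = 1, marker_set = NULL,
                            seed = NULL) {
  stopifnot(K >= 1, reps >= 1, burnin >= 0)
  ix <- geno_to_indices(geno, marker_set)
  n <- nrow(ix$a1)
  if (K > n) abort("K cannot exceed the number of accessions")
  out <- with_seed(seed,
                   .admixture_gibbs(ix$a1, ix$a2, ix$n_alleles, as.integer(K),
                                    as.integer(burnin), as.integer(reps),
                                    alpha, lambda))
  Q <- out$Q
  Q <- Q / rowSums(Q)
  # canonical cluster order: by first accession reaching majority membership
  first_major <- apply(Q, 2, function(q) {
    w <- which(q > 0.5)
    if (length(w) == 0) Inf else w[1]
  })
  ord <- order(first_major, seq_len(K))
  Q <- Q[, ord, drop = FALSE]
  colnames(Q) <- paste0("Cluster", seq_len(K))
  lnl <- out$lnl
  structure(list(
    Q = dplyr::bind_cols(tibble::tibble(accession = rownames(ix$a1)),
                         tibble::as_tibble(Q)),
    lnl_trace = lnl,
    L_est = mean(lnl) - var(lnl) / 2,
    mean_lnl = mean(lnl),
    K = as.integer(K), n = n, m = ncol(ix$a1), seed = seed
  ), class = "structure_fit")
}

#' @export
print.structure_fit <- function(x, ...) {
  cat(sprintf("Admixture fit: K = %d, %d accessions x %d markers\n",
              x$K, x$n, x$m))
  cat(sprintf("L_est = %.1f (mean lnL %.1f over %d sweeps)\n",
              x$L_est, x$mean_lnl, length(x$lnl_trace)))
  invisible(x)
}

#' @export
tidy.structure_fit <- function(x, ...) {
  tidyr::pivot_longer(x$Q, -"accession", names_to = "cluster",
                      values_to = "q")
}

#' @export
glance.structure_fit <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, m = x$m, L_est = x$L_est,
                 mean_lnl = x$mean_lnl, n_sweeps = length(x$lnl_trace))
}

#' Evanno delta-K table and optimal cluster number
#'
#' From replicate admixture runs over a contiguous range of `K`:
#' `L(K)` = mean run likelihood estimate, `L'(K) = L(K) - L(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and `delta_K = |L''(K)| / sd(L_est at K)`.
#' The optimal `K` maximizes `delta_K` over interior values. A zero
#' likelihood spread at some `K` leaves `delta_K` undefined there; an
#' all-zero second difference is flagged as ambiguous.
#'
#' @param fits List of `structure_fit` objects covering >= 3 contiguous `K`
#'   values with >= 2 runs each.
#' @return Tibble of class `evanno_table` with per-K rows: `K`, `n_runs`,
#'   `mean_L`, `sd_L`, `L1` (first difference), `L2_abs`, `delta_K`.
#'   Attributes: `optimal_K`, `ambiguous`.
#' @export
evanno_delta_k <- function(fits) {
  stopifnot(is.list(fits), length(fits) > 0)
  est <- dplyr::bind_rows(lapply(fits, function(f) {
    stopifnot(inherits(f, "structure_fit"))
    tibble::tibble(K = f$K, L_est = f$L_est)
  }))
  tab <- est |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(n_runs = dplyr::n(), mean_L = mean(.data$L_est),
                     sd_L = sd(.data$L_est), .groups = "drop") |>
    dplyr::arrange(.data$K)
  ks <- tab$K
  if (length(ks) < 3) abort("need >= 3 K values for delta-K")
  if (any(diff(ks) != 1)) abort("K values must be contiguous")
  if (any(tab$n_runs < 2)) abort("need >= 2 runs per K")
  tab$L1 <- c(NA, diff(tab$mean_L))
  tab$L2_abs <- c(NA, abs(diff(tab$L1[-1])), NA)
  tab$delta_K <- tab$L2_abs / tab$sd_L
  zero_sd <- !is.na(tab$L2_abs) & tab$sd_L == 0
  if (any(zero_sd)) {
    warn("zero likelihood spread at some K; delta-K undefined there")
    tab$delta_K[zero_sd] <- NA_real_
  }
  interior <- which(!is.na(tab$delta_K))
  ambiguous <- length(interior) == 0 ||
    all(tab$delta_K[interior] == 0)
  optimal <- if (ambiguous) NA_integer_ else {
    tab$K[interior[which.max(tab$delta_K[interior])]]
  }
  if (ambiguous) warn("delta-K has no peak; optimal K ambiguous")
  out <- tab
  class(out) <- c("evanno_table", class(out))
  attr(out, "optimal_K") <- optimal
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Optimal K from an Evanno table
#' @param x An `evanno_table` from [evanno_delta_k()].
#' @return Integer optimal K (`NA` if ambiguous).
#' @export
optimal_k <- function(x) {
  stopifnot(inherits(x, "evanno_table"))
  attr(x, "optimal_K")
}

#' @export
glance.evanno_table <- function(x, ...) {
  tibble::tibble(optimal_K = attr(x, "optimal_K"),
                 ambiguous = attr(x, "ambiguous"),
                 max_delta_K = suppressWarnings(max(x$delta_K, na.rm = TRUE)))
}

#' Assign accessions to subpopulations from admixture proportions
#'
#' Each accession goes to its largest-membership cluster (ties to the lowest
#' cluster index); accessions whose largest membership is below `threshold`
#' are flagged admixed. Joining panel metadata enables composition
#' cross-tabulations.
#'
#' @param fit A `structure_fit`.
#' @param meta Optional tibble with `accession` plus grouping columns
#'   (e.g. `sowing_type`, `origin`, or a screening `category`) to join.
#' @param threshold Membership below which an assignment is flagged admixed.
#' @return Tibble: `accession`, `cluster` (e.g. "Cluster1"), `max_q`,
#'   `admixed`, plus any joined metadata columns.
#' @export
assign_subpopulations <- function(fit, meta = NULL, threshold = 0.5) {
  stopifnot(inherits(fit, "structure_fit"))
  qm <- as.matrix(fit$Q[, -1, drop = FALSE])
  idx <- max.col(qm, ties.method = "first")
  out <- tibble::tibble(
    accession = fit$Q$accession,
    cluster = colnames(qm)[idx],
    max_q = qm[cbind(seq_len(nrow(qm)), idx)],
    admixed = qm[cbind(seq_len(nrow(qm)), idx)] < threshold
  )
  if (!is.null(meta)) {
    assert_columns(meta, "accession", "meta")
    out <- dplyr::left_join(out, meta, by = "accession")
  }
  out
}

#' Subpopulation composition cross-tabulation
#'
#' Counts and percentages of a metadata grouping within each assigned
#' subpopulation.
#'
#' @param assignments Output of [assign_subpopulations()] (with metadata
#'   joined).
#' @param by Name of the metadata column to tabulate.
#' @return Tibble: `cluster`, the grouping column, `n`, `pct` (percent within
#'   cluster).
#' @export
subpop_composition <- function(assignments, by) {
  assert_columns(assignments, c("cluster", by), "assignments")
  assignments |>
    dplyr::count(.data$cluster, dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(pct = .data$n / sum(.data$n) * 100) |>
    dplyr::ungroup()
}
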
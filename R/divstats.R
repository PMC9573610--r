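# split "A/G" genotype strings into a two-column allele matrix
split_alleles <- function(genotype) {
  parts <- stringr::str_split_fixed(genotype, stringr::fixed("/"), 2)
  parts[parts == "." | parts == ""] <- NA_character_
  parts
}

is_missing_call <- function(genotype) {
  is.na(genotype) | genotype == "./." | genotype == "."
}

#' Allele frequencies per marker
#'
#' Counts both allele copies of all non-missing genotype calls and
#' normalizes. Missing calls contribute nothing; no imputation.
#'
#' @param geno Long genotype tibble with columns `accession`, `marker`,
#'   `genotype` (e.g. from [sim_genotypes()]).
#' @return Tibble with columns `marker`, `allele`, `count`, `freq`. Markers
#'   with no non-missing call are absent (see [marker_stats()] for flags).
#' @examples
#' g <- sim_genotypes(sim_panel(20, seed = 1), n_neutral = 3, n_ht = 0, seed = 2)
#' allele_freqs(g)
#' @export
allele_freqs <- function(geno) {
  assert_columns(geno, c("marker", "genotype"), "geno")
  ok <- !is_missing_call(geno$genotype)
  al <- split_alleles(geno$genotype[ok])
  tibble::tibble(marker = rep(geno$marker[ok], 2),
                 allele = c(al[, 1], al[, 2])) |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$marker, .data$allele, name = "count") |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

# diversity indices from one marker's allele-frequency vector
diversity_from_freqs <- function(p) {
  gd <- 1 - sum(p^2)
  # Botstein PIC: 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2
  pic <- gd
  if (length(p) > 1) {
    for (i in seq_len(length(p) - 1)) {
      for (j in (i + 1):length(p)) pic <- pic - 2 * p[i]^2 * p[j]^2
    }
  }
  c(gd = gd, pic = pic)
}

#' Per-marker diversity statistics
#'
#' For every marker: number of distinct observed genotypes (`NG`), distinct
#' alleles (`Na`), major allele frequency (`MAF`), gene diversity
#' (`GD = 1 - sum p^2`), observed heterozygosity (`He`, the fraction of
#' heterozygous non-missing calls -- low in a selfing crop), a bias-corrected
#' expected heterozygosity (`He_exp = n/(n-1) * GD` over n non-missing
#' calls), Botstein's polymorphic information content (`PIC`), and the
#' informativeness class. All formulas are k-allele general.
#'
#' @inheritParams allele_freqs
#' @return Tibble with one row per marker: `marker` (plus `marker_set` if
#'   present in `geno`), `n_calls`, `NG`, `Na`, `MAF`, `GD`, `He`, `He_exp`,
#'   `PIC`, `info_class`, `all_missing`. Markers with only missing calls
#'   carry `NA` statistics and `all_missing = TRUE`.
#' @examples
#' g <- sim_genotypes(sim_panel(40, seed = 1), n_neutral = 5, n_ht = 0, seed = 2)
#' marker_stats(g)
#' @export
marker_stats <- function(geno) {
  assert_columns(geno, c("accession", "marker", "genotype"), "geno")
  has_set <- "marker_set" %in% names(geno)
  geno |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(d, key) {
      set <- if (has_set) d$marker_set[1] else NA_character_
      ok <- !is_missing_call(d$genotype)
      n <- sum(ok)
      if (n == 0) {
        return(tibble::tibble(
          marker_set = set, n_calls = 0L, NG = NA_integer_, Na = NA_integer_,
          MAF = NA_real_, GD = NA_real_, He = NA_real_, He_exp = NA_real_,
          PIC = NA_real_, all_missing = TRUE))
      }
      al <- split_alleles(d$genotype[ok])
      # normalize genotype representation to an unordered pair
      gt <- paste(pmin(al[, 1], al[, 2]), pmax(al[, 1], al[, 2]), sep = "/")
      p <- table(c(al[, 1], al[, 2]))
      p <- as.numeric(p / sum(p))
      div <- diversity_from_freqs(p)
      tibble::tibble(
        marker_set = set, n_calls = n,
        NG = dplyr::n_distinct(gt),
        Na = length(p),
        MAF = max(p),
        GD = div[["gd"]],
        He = mean(al[, 1] != al[, 2]),
        He_exp = if (n > 1) n / (n - 1) * div[["gd"]] else NA_real_,
        PIC = div[["pic"]],
        all_missing = FALSE)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(info_class = classify_informativeness(.data$PIC),
                  .after = "PIC")
}

#' Marker informativeness class from PIC
#'
#' Highly informative markers have `PIC >= 0.5`, moderately informative
#' `0.25 <= PIC < 0.5`, slightly informative `PIC < 0.25`.
#'
#' @param pic Numeric PIC values in `[0, 1]` (`NA` allowed).
#' @return Character vector: "HIGH", "MODERATE", "SLIGHT", or `NA`.
#' @examples
#' classify_informativeness(c(0.5, 0.25, 0.2499))
#' @export
classify_informativeness <- function(pic) {
  if (any(!is.na(pic) & (pic < 0 | pic > 1))) abort("PIC must lie in [0, 1]")
  dplyr::case_when(
    is.na(pic) ~ NA_character_,
    pic >= 0.5 ~ "HIGH",
    pic >= 0.25 ~ "MODERATE",
    TRUE ~ "SLIGHT"
  )
}

#' Panel-level diversity summary
#'
#' Summarizes per-marker statistics into the conventional marker-panel table:
#' marker count, total distinct genotypes and alleles, unweighted means of
#' MAF, GD, He and PIC, and informativeness-class counts -- one row per
#' marker set.
#'
#' @param stats Per-marker tibble from [marker_stats()].
#' @param marker_set Optional filter: keep only this marker set.
#' @return Tibble with one row per marker set.
#' @export
panel_summary <- function(stats, marker_set = NULL) {
  assert_columns(stats, c("marker", "NG", "Na", "MAF", "GD", "He", "PIC"),
                 "stats")
  if (!is.null(marker_set)) {
    keep_set <- marker_set
    stats <- stats[!is.na(stats$marker_set) &
                     stats$marker_set %in% keep_set, ]
  }
  if ("all_missing" %in% names(stats)) stats <- stats[!stats$all_missing, ]
  if (nrow(stats) == 0) abort("no markers left after filtering")
  grp <- if ("marker_set" %in% names(stats)) "marker_set" else character(0)
  stats |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      total_NG = sum(.data$NG),
      total_Na = sum(.data$Na),
      mean_MAF = mean(.data$MAF),
      mean_GD = mean(.data$GD),
      mean_He = mean(.data$He),
      mean_PIC = mean(.data$PIC),
      n_high = sum(.data$info_class == "HIGH"),
      n_moderate = sum(.data$info_class == "MODERATE"),
      n_slight = sum(.data$info_class == "SLIGHT"),
      .groups = "drop"
    )
}
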
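#' Field survival rate
#'
#' Percentage of sown seeds surviving to maturity, pooled over replicates:
#' `sum(survivors) / (sown * n_reps) * 100`. With one replicate this reduces
#' to the plain survivor fraction; with three it averages the replicate rows.
#'
#' @param survivors Integer vector of surviving plant counts, one per
#'   replicate.
#' @param sown Seeds sown per replicate row (default 10).
#' @return Survival rate in percent.
#' @examples
#' field_survival_rate(c(6, 6, 6)) # 60
#' @export
field_survival_rate <- function(survivors, sown = 10) {
  if (length(survivors) == 0) abort("no replicate survivor counts supplied")
  if (anyNA(survivors) || any(survivors < 0)) {
    abort("survivor counts must be non-negative and non-missing")
  }
  if (any(survivors > sown)) abort("survivors cannot exceed seeds sown")
  sum(survivors) / (sown * length(survivors)) * 100
}

#' Grain filling rate
#'
#' Hundred-grain weight divided by the calendar days from first flowering to
#' maturity, in grams per day.
#'
#' @param hundred_grain_weight Hundred-grain weight, grams.
#' @param flowering_date,maturity_date Calendar dates (Date or ISO strings).
#' @return Grain filling rate, g/day (vectorized).
#' @examples
#' grain_filling_rate(24, "2018-05-01", "2018-05-25") # 1
#' @export
grain_filling_rate <- function(hundred_grain_weight, flowering_date,
                               maturity_date) {
  dur <- as.numeric(as.Date(maturity_date) - as.Date(flowering_date))
  if (any(!is.na(dur) & dur <= 0)) {
    abort("grain-filling duration must be positive (maturity after flowering)")
  }
  hundred_grain_weight / dur
}

#' Average grain weight per plant
#'
#' Mean of up to `max_plants` per-plant grain weights within each replicate,
#' averaged over replicates. Five mature plants per accession are weighed by
#' default; replicates with no surviving measured plants are dropped, and an
#' accession with none anywhere is unscoreable (`NA`).
#'
#' @param plant_weights A numeric vector (one replicate) or list of numeric
#'   vectors (one per replicate), grams.
#' @param max_plants Plants used per replicate.
#' @return Mean grain weight per plant, grams, or `NA` if no weights exist.
#' @examples
#' mean_grain_weight(list(c(5, 5), c(15, 15))) # 10
#' @export
mean_grain_weight <- function(plant_weights, max_plants = 5) {
  if (is.numeric(plant_weights)) plant_weights <- list(plant_weights)
  per_rep <- vapply(plant_weights, function(w) {
    w <- w[!is.na(w)]
    if (length(w) == 0) return(NA_real_)
    mean(head(w, max_plants))
  }, numeric(1))
  if (all(is.na(per_rep))) return(NA_real_)
  mean(per_rep, na.rm = TRUE)
}

#' Grain-weight loss rates under late sowing
#'
#' `LR1 = (1 - W_LS1 / W_NS) * 100` and `LR2 = (1 - W_LS2 / W_NS) * 100`,
#' clamped to `[0, 100]`: a late-sown yield *gain* (negative loss) is treated
#' as zero loss, since the classification standard's domain starts at no loss.
#'
#' @param w_ns,w_ls1,w_ls2 Average grain weight per plant (grams) at normal
#'   sowing and the two late-sowing stages. Vectorized.
#' @return Tibble with columns `LR1` and `LR2` (percent); `NA` where
#'   `w_ns` is missing or non-positive (unscoreable).
#' @examples
#' loss_rates(50, 45, 42) # 10, 16
#' @export
loss_rates <- function(w_ns, w_ls1, w_ls2) {
  bad <- is.na(w_ns) | w_ns <= 0
  lr <- function(w_ls) {
    x <- (1 - w_ls / w_ns) * 100
    x <- pmin(100, pmax(0, x))
    x[bad] <- NA_real_
    x
  }
  tibble::tibble(LR1 = lr(w_ls1), LR2 = lr(w_ls2))
}

# 20-point band index of a loss rate: [0,20] -> 0, (20,40] -> 1, ...
lr_band <- function(x) findInterval(x, c(20, 40, 60, 80), left.open = TRUE)

#' Nine-level heat-tolerance classification
#'
#' Assigns the tolerance level from the two loss rates. The printed standard
#' partitions each loss rate into five 20-point bands (closed below at 0,
#' then left-open: `[0,20]`, `(20,40]`, ...); the level is the band-index sum
#' plus one, which reproduces the printed nine rules exactly on their domain
#' and extends them continuously to the narrow non-excluded region where the
#' two band indices differ by two. Accessions whose loss rates differ by more
#' than 40 points are excluded (`NA`) as affected by systematic error.
#'
#' @param lr1,lr2 Loss rates in percent, each in `[0, 100]`. Vectorized.
#' @return Integer vector of levels 1-9; `NA` where excluded or where either
#'   input is `NA`.
#' @examples
#' classify_level(10, 15) # 1
#' classify_level(50, 30) # 4
#' classify_level(20, 70) # NA (excluded)
#' @export
classify_level <- function(lr1, lr2) {
  ok <- !is.na(lr1) & !is.na(lr2)
  if (any(ok & (lr1 < 0 | lr1 > 100 | lr2 < 0 | lr2 > 100))) {
    abort("loss rates must lie in [0, 100]; clamp with loss_rates() first")
  }
  level <- lr_band(lr1) + lr_band(lr2) + 1L
  level[!ok | abs(lr1 - lr2) > 40] <- NA_integer_
  as.integer(level)
}

#' Heat-tolerance category from level
#'
#' Levels 1-3 are heat-tolerant (HT), 7-9 heat-sensitive (HS), 4-6
#' intermediate.
#'
#' @param level Integer levels 1-9 (`NA` allowed for excluded accessions).
#' @return Character vector: "HT", "INTERMEDIATE", "HS", or `NA`.
#' @examples
#' categorize_level(c(1, 5, 9))
#' @export
categorize_level <- function(level) {
  if (any(!is.na(level) & !(level %in% 1:9))) {
    abort("levels must be integers in 1..9")
  }
  dplyr::case_when(
    is.na(level) ~ NA_character_,
    level <= 3 ~ "HT",
    level >= 7 ~ "HS",
    TRUE ~ "INTERMEDIATE"
  )
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests per-accession tolerance levels against a normal distribution with
#' the sample mean and standard deviation, reporting the KS statistic and the
#' plain asymptotic two-sided p-value (no small-sample or
#' estimated-parameter correction), matching the classical SPSS-style output.
#' Note the estimated parameters make the test conservative, and heavy
#' discreteness (many ties at few levels) makes it reject for large samples;
#' it is meant as a coarse sanity check of the level histogram's shape.
#'
#' @param levels Integer vector of per-accession levels (1-9), `NA` dropped.
#' @return One-row tibble: `n`, `statistic` (D), `p_value`, `degenerate`
#'   (TRUE when the sample variance is zero and the test is undefined).
#' @examples
#' ks_normality(c(1, 2, 3, 3, 4, 5, 5, 6, 7))
#' @export
ks_normality <- function(levels) {
  x <- levels[!is.na(levels)]
  if (length(x) < 5) abort("need >= 5 classified accessions for the KS check")
  if (sd(x) == 0) {
    return(tibble::tibble(n = length(x), statistic = NA_real_,
                          p_value = NA_real_, degenerate = TRUE))
  }
  kt <- suppressWarnings(
    ks.test(x, "pnorm", mean = mean(x), sd = sd(x), exact = FALSE))
  tibble::tibble(n = length(x), statistic = unname(kt$statistic),
                 p_value = kt$p.value, degenerate = FALSE)
}

#' Screen one round of a heat-tolerance trial
#'
#' Aggregates a round's trial records per accession: average grain weight per
#' plant at each sowing stage, field survival rate and grain filling rate per
#' stage, loss rates LR1/LR2, nine-level classification with the 40-point
#' exclusion rule, and HT/INTERMEDIATE/HS category. Accessions that cannot be
#' scored (missing stage, no surviving weighed plants at normal sowing) are
#' kept with an `exclusion_reason`.
#'
#' @param trial Trial tibble as produced by [sim_trial()] or
#'   [read_trial_table()].
#' @param max_plants Plants per replicate used for grain weighing.
#' @return A tibble of class `pea_screening`, one row per accession, with
#'   columns `accession`, `W_NS`, `W_LS1`, `W_LS2`, `LR1`, `LR2`, `level`,
#'   `category`, `exclusion_reason`, and per-stage `FSR_*` (percent) and
#'   `GFR_*` (g/day). Use [round_summary()] / [glance()] for the level
#'   histogram, KS check and HT/HS counts.
#' @examples
#' res <- screen_round(sim_trial(sim_panel(20, seed = 1), seed = 2))
#' round_summary(res)
#' @export
screen_round <- function(trial, max_plants = 5) {
  assert_columns(trial, c("accession", "stage", "replicate", "sown",
                          "survivors", "plant_weights"), "trial")
  if (nrow(trial) == 0) abort("empty trial dataset")
  if (!all(trial$stage %in% c("NS", "LS1", "LS2"))) {
    abort("stage must be one of NS, LS1, LS2")
  }
  if (is.character(trial$plant_weights)) {
    trial$plant_weights <- parse_weights(trial$plant_weights)
  }
  has_gfr <- all(c("hundred_grain_weight", "flowering_date",
                   "maturity_date") %in% names(trial))

  per_stage <- trial |>
    dplyr::group_by(.data$accession, .data$stage) |>
    dplyr::summarise(
      W = mean_grain_weight(.data$plant_weights, max_plants = max_plants),
      FSR = field_survival_rate(.data$survivors, sown = .data$sown[1]),
      GFR = if (has_gfr) {
        mean(grain_filling_rate(.data$hundred_grain_weight,
                                .data$flowering_date, .data$maturity_date))
      } else NA_real_,
      .groups = "drop"
    )

  wide <- per_stage |>
    tidyr::pivot_wider(names_from = "stage",
                       values_from = c("W", "FSR", "GFR"),
                       names_sep = "_")
  for (col in c(t(outer(c("W", "FSR", "GFR"), c("NS", "LS1", "LS2"),
                        paste, sep = "_")))) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  res <- wide |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        is.na(.data$W_NS) ~ "NO_NS_WEIGHTS",
        .data$W_NS <= 0 ~ "NONPOSITIVE_W_NS",
        is.na(.data$W_LS1) | is.na(.data$W_LS2) ~ "MISSING_LATE_STAGE",
        TRUE ~ NA_character_
      )
    )
  lrs <- loss_rates(res$W_NS, res$W_LS1, res$W_LS2)
  res$LR1 <- ifelse(is.na(res$exclusion_reason), lrs$LR1, NA_real_)
  res$LR2 <- ifelse(is.na(res$exclusion_reason), lrs$LR2, NA_real_)
  res$level <- classify_level(res$LR1, res$LR2)
  res$exclusion_reason[is.na(res$exclusion_reason) & is.na(res$level) &
                         !is.na(res$LR1) & !is.na(res$LR2)] <- "LR_DIFF_GT_40"
  res$category <- categorize_level(res$level)

  out <- res |>
    dplyr::select("accession", "W_NS", "W_LS1", "W_LS2", "LR1", "LR2",
                  "level", "category", "exclusion_reason",
                  dplyr::starts_with("FSR_"), dplyr::starts_with("GFR_"))
  class(out) <- c("pea_screening", class(out))
  out
}

#' Round-level summary of a screening
#'
#' Level histogram, Kolmogorov-Smirnov normality check on per-accession
#' levels, HT/HS counts and the exclusion tally for one screened round.
#'
#' @param results A `pea_screening` tibble from [screen_round()].
#' @return A list of class `pea_round_summary`: `level_counts` (tibble),
#'   `ks` (tibble from [ks_normality()], or NULL if < 5 classified),
#'   `n_classified`, `n_ht`, `n_hs`, `n_excluded`.
#' @export
round_summary <- function(results) {
  stopifnot(inherits(results, "pea_screening"))
  lv <- results$level[!is.na(results$level)]
  level_counts <- tibble::tibble(level = 1:9) |>
    dplyr::left_join(dplyr::count(tibble::tibble(level = lv), .data$level),
                     by = "level") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  structure(list(
    level_counts = level_counts,
    ks = if (length(lv) >= 5) ks_normality(lv) else NULL,
    n_classified = length(lv),
    n_ht = sum(results$category == "HT", na.rm = TRUE),
    n_hs = sum(results$category == "HS", na.rm = TRUE),
    n_excluded = sum(!is.na(results$exclusion_reason))
  ), class = "pea_round_summary")
}

#' @export
print.pea_round_summary <- function(x, ...) {
  cat(sprintf("Screened round: %d classified (%d HT, %d HS, %d excluded)\n",
              x$n_classified, x$n_ht, x$n_hs, x$n_excluded))
  cat("Level counts:", paste(x$level_counts$n, collapse = " "), "\n")
  if (!is.null(x$ks)) {
    cat(sprintf("KS normality: D = %.3f, p = %.3f\n",
                x$ks$statistic, x$ks$p_value))
  }
  invisible(x)
}

#' Iterative multi-round heat-tolerance screening
#'
#' Screens each round and follows the selection logic of the field design:
#' the HT and HS accessions of round *r* are the candidates for round *r+1*;
#' the final round's HT and HS sets are the extremely heat-tolerant and
#' extremely heat-sensitive accessions; and the consistency set contains the
#' accessions assigned the same extreme category (HT or HS) in every round in
#' which they were classified.
#'
#' @param rounds A list of trial tibbles, one per round, in order.
#' @param max_plants Plants per replicate used for grain weighing.
#' @return A list of class `pea_screening_series`: `results` (list of
#'   `pea_screening` tibbles), `summaries` (list of round summaries),
#'   `extreme_ht`, `extreme_hs` (accession ids from the final round),
#'   `consistent` (tibble: accession, category, n_rounds).
#' @examples
#' panel <- sim_panel(30, seed = 1)
#' r1 <- sim_trial(panel, round = 1, seed = 2)
#' s <- screen_iterative(list(r1))
#' @export
screen_iterative <- function(rounds, max_plants = 5) {
  stopifnot(is.list(rounds), length(rounds) >= 1)
  ids <- lapply(rounds, function(r) unique(r$accession))
  for (r in seq_along(rounds)[-1]) {
    if (length(intersect(ids[[r]], ids[[r - 1]])) == 0) {
      abort(sprintf("rounds %d and %d share no accessions", r - 1, r))
    }
  }
  results <- lapply(rounds, screen_round, max_plants = max_plants)
  summaries <- lapply(results, round_summary)

  last <- results[[length(results)]]
  extreme_ht <- last$accession[!is.na(last$category) & last$category == "HT"]
  extreme_hs <- last$accession[!is.na(last$category) & last$category == "HS"]

  cats <- dplyr::bind_rows(lapply(seq_along(results), function(r) {
    dplyr::mutate(results[[r]][, c("accession", "category")],
                  round = r)
  })) |>
    dplyr::filter(!is.na(.data$category))
  consistent <- cats |>
    dplyr::filter(.data$category %in% c("HT", "HS")) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(same = dplyr::n_distinct(.data$category) == 1,
                     n_rounds = dplyr::n(),
                     category = .data$category[1],
                     .groups = "drop")
  # drop accessions ever classified outside the extremes or inconsistent
  ever_mid <- unique(cats$accession[cats$category == "INTERMEDIATE"])
  consistent <- consistent |>
    dplyr::filter(.data$same, !(.data$accession %in% ever_mid)) |>
    dplyr::select("accession", "category", "n_rounds")

  structure(list(results = results, summaries = summaries,
                 extreme_ht = extreme_ht, extreme_hs = extreme_hs,
                 consistent = consistent),
            class = "pea_screening_series")
}

#' @export
print.pea_screening_series <- function(x, ...) {
  cat(sprintf("Iterative screening over %d round(s)\n", length(x$results)))
  cat(sprintf("Extremely HT: %d, extremely HS: %d, consistent: %d\n",
              length(x$extreme_ht), length(x$extreme_hs), nrow(x$consistent)))
  invisible(x)
}

#' Compare grain filling rates between tolerance categories
#'
#' One-way analysis of variance of per-accession grain filling rate between
#' HT and HS accessions (intermediates dropped by default), separately for
#' each sowing stage.
#'
#' @param results A `pea_screening` tibble with `GFR_*` columns.
#' @param include_intermediate Keep INTERMEDIATE as a third group?
#' @return Tibble with one row per stage: `stage`, `df_between`, `df_within`,
#'   `statistic` (F), `p_value`, and per-group means.
#' @export
compare_gfr <- function(results, include_intermediate = FALSE) {
  stopifnot(inherits(results, "pea_screening"))
  long <- results |>
    dplyr::filter(!is.na(.data$category)) |>
    tidyr::pivot_longer(dplyr::starts_with("GFR_"), names_to = "stage",
                        names_prefix = "GFR_", values_to = "gfr") |>
    dplyr::filter(!is.na(.data$gfr))
  if (!include_intermediate) {
    long <- dplyr::filter(long, .data$category %in% c("HT", "HS"))
  }
  long |>
    dplyr::group_by(.data$stage) |>
    dplyr::group_modify(function(d, key) {
      sizes <- table(d$category)
      sizes <- sizes[sizes > 0]
      if (length(sizes) < 2 || any(sizes < 2)) {
        abort(sprintf(
          "stage %s: ANOVA needs >= 2 groups with >= 2 accessions each",
          key$stage))
      }
      fit <- anova(lm(gfr ~ category, data = d))
      means <- tapply(d$gfr, d$category, mean)
      tibble::tibble(
        df_between = fit$Df[1], df_within = fit$Df[2],
        statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
        mean_ht = unname(means["HT"]), mean_hs = unname(means["HS"]))
    }) |>
    dplyr::ungroup()
}

#' @export
glance.pea_screening <- function(x, ...) {
  s <- round_summary(x)
  tibble::tibble(
    n = nrow(x), n_classified = s$n_classified, n_ht = s$n_ht,
    n_hs = s$n_hs, n_excluded = s$n_excluded,
    ks_statistic = if (is.null(s$ks)) NA_real_ else s$ks$statistic,
    ks_p = if (is.null(s$ks)) NA_real_ else s$ks$p_value
  )
}

#' @export
tidy.pea_screening_series <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$results), function(r) {
    dplyr::mutate(tibble::as_tibble(x$results[[r]]), round = r,
                  .before = 1)
  }))
}

#' @export
glance.pea_screening_series <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$results), function(r) {
    dplyr::mutate(glance(x$results[[r]]), round = r, .before = 1)
  }))
}
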
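#' Simulate a daily mean-temperature series for one growing season
#'
#' Generates daily mean temperatures from 1 March to 31 July of one year: a
#' linear seasonal warming trend plus an optional sinusoidal bump and Gaussian
#' day-to-day noise. The positive default trend makes any late-sowing growth
#' window warmer, in expectation, than the matching normal-sowing window
#' shifted 15 days earlier -- the property the late-sowing heat treatment
#' relies on.
#'
#' @param year Calendar year of the season.
#' @param t_start Mean temperature (deg C) on 1 March.
#' @param trend Linear warming rate, deg C per day.
#' @param amplitude Amplitude (deg C) of a half-period sine bump over the
#'   season; 0 disables it.
#' @param noise_sd Standard deviation (deg C) of iid daily noise.
#' @param from,to Optional span override (ISO dates); `to` must be after
#'   `from`.
#' @param seed Integer seed; same seed gives a bit-identical series.
#' @return A tibble with columns `date` (Date) and `t_mean` (deg C).
#' @examples
#' sim_temperatures(2017, seed = 1)
#' @export
sim_temperatures <- function(year = 2017, t_start = 8, trend = 0.12,
                             amplitude = 0, noise_sd = 1.5,
                             from = NULL, to = NULL, seed = NULL) {
  from <- as.Date(from %||% sprintf("%d-03-01", year))
  to <- as.Date(to %||% sprintf("%d-07-31", year))
  if (!is.finite(as.numeric(to - from)) || to <= from) {
    abort("temperature span must be positive: `to` must be after `from`")
  }
  dates <- seq(from, to, by = "day")
  d <- as.numeric(dates - from)
  with_seed(seed, {
    t_mean <- t_start + trend * d +
      amplitude * sin(pi * d / max(d)) +
      rnorm(length(d), 0, noise_sd)
    tibble::tibble(date = dates, t_mean = t_mean)
  })
}

#' Simulate a germplasm panel with latent heat-tolerance classes
#'
#' Creates the accession metadata the trial and genotype generators consume:
#' sowing-date type (spring- vs winter-sowing), a coarse geographic origin
#' correlated with sowing type, a latent binary heat-tolerance class (HT/HS)
#' driving grain-weight loss under late sowing, and a latent genetic
#' subpopulation correlated with sowing type (the structure that neutral
#' markers differentiate).
#'
#' @param n_accessions Number of accessions (>= 2).
#' @param prop_ss Proportion of spring-sowing (SS) accessions.
#' @param prop_ht Proportion of latent heat-tolerant (HT) accessions.
#' @param seed Integer seed.
#' @return Tibble with columns `accession`, `sowing_type` (SS/WS), `origin`,
#'   `latent_class` (HT/HS), `subpop` (A/B).
#' @examples
#' sim_panel(20, seed = 1)
#' @export
sim_panel <- function(n_accessions = 200, prop_ss = 0.56, prop_ht = 0.5,
                      seed = NULL) {
  stopifnot(n_accessions >= 2, prop_ss >= 0, prop_ss <= 1,
            prop_ht >= 0, prop_ht <= 1)
  with_seed(seed, {
    sowing <- ifelse(runif(n_accessions) < prop_ss, "SS", "WS")
    # origin mix differs by sowing type: SS accessions are mostly northern,
    # WS mostly southern, mirroring the production geography of the crop
    origin <- vapply(sowing, function(s) {
      p <- if (s == "SS") c(0.72, 0.06, 0.17, 0.05) else c(0.15, 0.68, 0.12, 0.05)
      sample(c("North China", "South China", "Foreign", "Unknown"), 1, prob = p)
    }, character(1))
    latent <- ifelse(runif(n_accessions) < prop_ht, "HT", "HS")
    # genetic subpopulation correlated with sowing type, not identical to it
    p_a <- ifelse(sowing == "SS", 0.75, 0.22)
    subpop <- ifelse(runif(n_accessions) < p_a, "A", "B")
    tibble::tibble(
      accession = sprintf("G%04d", seq_len(n_accessions)),
      sowing_type = sowing,
      origin = origin,
      latent_class = latent,
      subpop = subpop
    )
  })
}

#' Simulate one round of a three-stage heat-tolerance field trial
#'
#' Emulates the sowing-date design: every accession is sown at a normal stage
#' (NS, 1 March) and two late stages (LS1, 16 March; LS2, 31 March) that push
#' reproductive growth into heat. Normal-sowing grain weight per plant is
#' log-normal; late-sowing weights are the NS weight scaled by a stage- and
#' class-dependent loss. The latent HS class loses `effect` percentage points
#' more grain weight than HT at both late stages, and loss increases from LS1
#' to LS2. Survival out of `sown` seeds decreases NS -> LS1 -> LS2. Losses
#' falling outside [0, 100] are truncated and counted (see attribute
#' `n_truncated`).
#'
#' @param panel Panel tibble from [sim_panel()] (needs `accession`,
#'   `latent_class`).
#' @param round Screening round number (1, 2 or 3). Round 1 defaults to one
#'   replicate per stage (completely randomized design); rounds 2-3 to three
#'   (randomized block design).
#' @param reps_per_stage Replicates per sowing stage; default depends on
#'   `round`.
#' @param effect Mean loss-rate separation (percentage points) between latent
#'   HS and HT classes. Stage base losses scale with it: HT accessions lose
#'   `effect * stage_frac` percent, HS `effect * (stage_frac + 1)`.
#' @param noise_sd Accession-by-stage loss noise, percentage points.
#' @param stage_frac Stage base-loss fractions for LS1/LS2 (of `effect`).
#' @param median_w Median NS grain weight per plant, grams.
#' @param sdlog_w Log-scale sd of accession NS grain weight.
#' @param plant_cv Plant-to-plant log-scale sd of measured grain weights
#'   within an accession; 0 makes plants within an accession identical.
#' @param n_plants Mature plants sampled per replicate for grain weighing.
#' @param sown Seeds sown per row.
#' @param survival Named survival probabilities per stage (NS, LS1, LS2);
#'   defaults follow the field survival rates observed in the first screening
#'   season (61.8/47.4/28.5 percent).
#' @param year Calendar year used for sowing dates; defaults to
#'   `2016 + round`.
#' @param seed Integer seed.
#' @return Tibble of trial records with columns `accession`, `round`, `stage`,
#'   `replicate`, `sown`, `survivors`, `plant_weights` (list-column of grams),
#'   `flowering_date`, `maturity_date`, `hundred_grain_weight`. Attributes:
#'   `truth` (the panel, including latent classes) and `n_truncated`.
#' @examples
#' trial <- sim_trial(sim_panel(10, seed = 1), seed = 2)
#' @export
sim_trial <- function(panel, round = 1,
                      reps_per_stage = if (round == 1) 1L else 3L,
                      effect = 60, noise_sd = 5,
                      stage_frac = c(LS1 = 0.25, LS2 = 1 / 3),
                      median_w = 25, sdlog_w = 0.6, plant_cv = 0.1,
                      n_plants = 5, sown = 10,
                      survival = c(NS = 0.618, LS1 = 0.474, LS2 = 0.285),
                      year = 2016 + round, seed = NULL) {
  assert_columns(panel, c("accession", "latent_class"), "panel")
  stopifnot(round %in% 1:3, reps_per_stage >= 1)
  n <- nrow(panel)
  stages <- c("NS", "LS1", "LS2")
  sow_dates <- as.Date(sprintf("%d-03-01", year)) + c(NS = 0, LS1 = 15, LS2 = 30)
  # growth periods shorten with later sowing (heat accelerates phenology)
  flower_days <- c(NS = 60, LS1 = 55, LS2 = 50)
  fill_days <- c(NS = 35, LS1 = 30, LS2 = 26)

  with_seed(seed, {
    w0 <- rlnorm(n, log(median_w), sdlog_w) # accession NS weight, grams
    hgw0 <- rlnorm(n, log(22), 0.15)        # accession hundred-grain weight
    n_trunc <- 0L
    rows <- vector("list", n * 3L)
    idx <- 0L
    for (i in seq_len(n)) {
      cls <- panel$latent_class[i]
      for (s in stages) {
        loss <- if (s == "NS") 0 else {
          raw <- effect * (stage_frac[[s]] + as.numeric(cls == "HS")) +
            rnorm(1, 0, noise_sd)
          if (raw < 0 || raw > 100) n_trunc <- n_trunc + 1L
          min(100, max(0, raw))
        }
        mean_w <- w0[i] * (1 - loss / 100)
        flower <- sow_dates[[s]] + max(20L, round(flower_days[[s]] + rnorm(1, 0, 3)))
        mature <- flower + max(5L, round(fill_days[[s]] + rnorm(1, 0, 3)))
        hgw <- max(0.5, hgw0[i] * (1 - 0.6 * loss / 100) * exp(rnorm(1, 0, 0.05)))
        for (r in seq_len(reps_per_stage)) {
          surv <- rbinom(1, sown, survival[[s]])
          n_meas <- min(n_plants, surv)
          w <- if (n_meas > 0 && mean_w > 0) {
            if (plant_cv > 0) {
              rlnorm(n_meas, log(mean_w) - plant_cv^2 / 2, plant_cv)
            } else rep(mean_w, n_meas)
          } else numeric(0)
          idx <- idx + 1L
          rows[[idx]] <- tibble::tibble(
            accession = panel$accession[i], round = as.integer(round),
            stage = s, replicate = r, sown = as.integer(sown),
            survivors = surv, plant_weights = list(w),
            flowering_date = flower, maturity_date = mature,
            hundred_grain_weight = hgw
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    if (n_trunc > 0) {
      warn(sprintf("%d loss value(s) fell outside [0, 100] and were truncated",
                   n_trunc))
    }
    attr(out, "truth") <- panel
    attr(out, "n_truncated") <- n_trunc
    out
  })
}

#' Simulate SNP genotypes with planted population structure
#'
#' Draws two marker sets over the panel: neutral markers whose allele
#' frequencies differentiate the latent genetic subpopulations (column
#' `subpop`), and heat-tolerance-related markers differentiated by the latent
#' tolerance class instead. Per-group allele frequencies follow the
#' Balding-Nichols construction: around an ancestral frequency vector with
#' dispersion controlled by `fst`. Genotypes are drawn under within-group
#' random mating; a fraction of markers is tri-allelic; calls go missing at
#' `missing_rate`.
#'
#' @param panel Panel tibble with `accession`, `subpop`, `latent_class`.
#' @param n_neutral,n_ht Numbers of neutral and heat-tolerance-related
#'   markers.
#' @param fst Differentiation parameter in (0, 1).
#' @param missing_rate Fraction of calls set to missing, in [0, 1).
#' @param prop_triallelic Fraction of markers carrying a third allele.
#' @param seed Integer seed.
#' @return Long tibble with columns `accession`, `marker`, `marker_set`
#'   (NEUTRAL / HT_RELATED) and `genotype` ("A/G" style, alleles sorted;
#'   missing = "./."). Attribute `freqs`: the per-group allele frequencies the
#'   genotypes were drawn from.
#' @examples
#' g <- sim_genotypes(sim_panel(30, seed = 1), n_neutral = 5, n_ht = 2, seed = 2)
#' @export
sim_genotypes <- function(panel, n_neutral = 46, n_ht = 20, fst = 0.15,
                          missing_rate = 0.02, prop_triallelic = 0.05,
                          seed = NULL) {
  assert_columns(panel, c("accession", "subpop", "latent_class"), "panel")
  stopifnot(fst > 0, fst < 1, missing_rate >= 0, missing_rate < 1)
  sets <- c(rep("NEUTRAL", n_neutral), rep("HT_RELATED", n_ht))
  group_col <- c(NEUTRAL = "subpop", HT_RELATED = "latent_class")
  for (set in unique(sets)) {
    if (length(unique(panel[[group_col[[set]]]])) < 2) {
      abort(sprintf(
        "fst-differentiated %s markers need >= 2 groups in panel column `%s`",
        set, group_col[[set]]))
    }
  }
  n_mark <- length(sets)
  if (n_mark == 0) abort("no markers requested")
  marker_ids <- sprintf("M%03d", seq_len(n_mark))

  with_seed(seed, {
    freq_rows <- list()
    geno <- matrix(NA_character_, nrow(panel), n_mark,
                   dimnames = list(panel$accession, marker_ids))
    bn <- (1 - fst) / fst # Balding-Nichols concentration
    for (j in seq_len(n_mark)) {
      k_all <- if (runif(1) < prop_triallelic) 3L else 2L
      alleles <- sort(sample(c("A", "C", "G", "T"), k_all))
      # ancestral frequencies, kept away from fixation
      anc <- runif(k_all, 0.15, 0.85)
      anc <- anc / sum(anc)
      groups <- panel[[group_col[[sets[j]]]]]
      for (g in unique(groups)) {
        p <- rgamma_dirichlet(anc * bn)
        freq_rows[[length(freq_rows) + 1L]] <- tibble::tibble(
          marker = marker_ids[j], marker_set = sets[j], group = g,
          allele = alleles, freq = p)
        rows <- which(groups == g)
        a1 <- sample(alleles, length(rows), TRUE, prob = p)
        a2 <- sample(alleles, length(rows), TRUE, prob = p)
        geno[rows, j] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
      }
    }
    if (missing_rate > 0) {
      miss <- runif(length(geno)) < missing_rate
      geno[miss] <- "./."
    }
    out <- tibble::tibble(
      accession = rep(panel$accession, times = n_mark),
      marker = rep(marker_ids, each = nrow(panel)),
      marker_set = rep(sets, each = nrow(panel)),
      genotype = as.vector(geno)
    )
    attr(out, "freqs") <- dplyr::bind_rows(freq_rows)
    out
  })
}

# Dirichlet draw via normalized gammas
rgamma_dirichlet <- function(shape) {
  x <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(x) == 0) x <- shape # degenerate fallback for tiny shapes
  x / sum(x)
}
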
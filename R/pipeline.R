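#' Default pipeline configuration
#'
#' A nested list mirroring the YAML schema accepted by [run_pipeline()]:
#' `seed` (mandatory), `panel` (n_accessions, prop_ss, prop_ht), `trial`
#' (effect, noise_sd, rounds), `genotypes` (n_neutral, n_ht, fst,
#' missing_rate), `structure` (marker_sets, k_range, runs_per_k, burnin,
#' reps) and `temperatures`. Values are desk-scale defaults; override any
#' subset via the `config` argument or YAML file.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = NULL,
    temperatures = list(year = 2017, t_start = 8, trend = 0.12,
                        noise_sd = 1.5),
    panel = list(n_accessions = 120, prop_ss = 0.56, prop_ht = 0.5),
    trial = list(effect = 60, noise_sd = 5, rounds = 3),
    genotypes = list(n_neutral = 46, n_ht = 20, fst = 0.15,
                     missing_rate = 0.02),
    structure = list(marker_sets = c("NEUTRAL", "HT_RELATED"),
                     k_range = 1:4, runs_per_k = 3,
                     burnin = 1000, reps = 4000)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full screening-and-structure pipeline on synthetic data
#'
#' Orchestrates every stage end to end: simulate a season's temperatures and
#' a germplasm panel; run the multi-round heat-tolerance trial with
#' carry-forward of HT/HS accessions between rounds; classify each round;
#' genotype the accessions retained after round 1 with both marker sets;
#' compute per-marker diversity statistics and the panel summary; and, per
#' marker set, run the admixture sampler over a K range with replicate runs,
#' select K by the Evanno criterion, and cross-tabulate subpopulation
#' composition. All randomness derives from the single mandatory seed, so a
#' rerun with the same configuration is reproducible.
#'
#' @param config Named list (see [default_pipeline_config()]) or path to a
#'   YAML file with the same structure. `config$seed` is mandatory.
#' @param out_dir Optional directory: every stage output is written there as
#'   a delimited table (plus Newick trees and a markdown report).
#' @return A list of class `pea_run_report` with elements `config`,
#'   `provenance`, `screening` (a `pea_screening_series`), `marker_stats`,
#'   `panel_summary`, `structure` (per marker set: evanno table, optimal K,
#'   best-K fit, assignments, composition cross-tabs), `upgma` (per marker
#'   set Newick string), `pcoa` (per marker set `pea_pcoa`).
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(seed = 1, panel = list(n_accessions = 24),
#'                          genotypes = list(n_neutral = 8, n_ht = 4),
#'                          structure = list(k_range = 1:3, runs_per_k = 2,
#'                                           burnin = 100, reps = 300)))
#' }
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$seed)) abort("pipeline config must set a seed")
  seed <- as.integer(cfg$seed)

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_tsv <- function(x, name) {
    if (!is.null(out_dir)) readr::write_tsv(x, file.path(out_dir, name))
  }

  # --- temperatures -------------------------------------------------------
  tp <- cfg$temperatures
  temps <- sim_temperatures(year = tp$year, t_start = tp$t_start,
                            trend = tp$trend, noise_sd = tp$noise_sd,
                            seed = child_seed(seed, 1))
  save_tsv(temps, "temperatures.tsv")

  # --- panel and iterative trial -----------------------------------------
  panel <- sim_panel(cfg$panel$n_accessions, prop_ss = cfg$panel$prop_ss,
                     prop_ht = cfg$panel$prop_ht,
                     seed = child_seed(seed, 2))
  rounds <- list()
  current <- panel
  n_rounds <- cfg$trial$rounds
  for (r in seq_len(n_rounds)) {
    tr <- sim_trial(current, round = r, effect = cfg$trial$effect,
                    noise_sd = cfg$trial$noise_sd,
                    seed = child_seed(seed, 10 + r))
    rounds[[r]] <- tr
    if (!is.null(out_dir)) {
      write_trial_table(tr, file.path(out_dir, sprintf("trial_round%d.tsv", r)))
    }
    res_r <- screen_round(tr)
    keep <- res_r$accession[!is.na(res_r$category) &
                              res_r$category %in% c("HT", "HS")]
    if (r < n_rounds) {
      if (length(keep) < 2) {
        warn(sprintf("round %d kept %d extreme accession(s); stopping early",
                     r, length(keep)))
        n_rounds <- r
        break
      }
      current <- panel[panel$accession %in% keep, ]
    }
  }
  screening <- screen_iterative(rounds)
  for (r in seq_along(screening$results)) {
    save_tsv(tibble::as_tibble(screening$results[[r]]),
             sprintf("screening_round%d.tsv", r))
  }

  # --- genotypes on the accessions retained after round 1 ----------------
  r1 <- screening$results[[1]]
  kept1 <- r1$accession[!is.na(r1$category) & r1$category %in% c("HT", "HS")]
  geno_panel <- panel[panel$accession %in% kept1, ]
  gcfg <- cfg$genotypes
  geno <- sim_genotypes(geno_panel, n_neutral = gcfg$n_neutral,
                        n_ht = gcfg$n_ht, fst = gcfg$fst,
                        missing_rate = gcfg$missing_rate,
                        seed = child_seed(seed, 20))
  if (!is.null(out_dir)) {
    write_genotype_table(geno, file.path(out_dir, "genotypes.tsv"),
                         file.path(out_dir, "marker_sets.tsv"))
  }

  mstats <- marker_stats(geno)
  psummary <- panel_summary(mstats)
  save_tsv(mstats, "marker_stats.tsv")
  save_tsv(psummary, "panel_summary.tsv")

  # metadata for cross-tabs: sowing type, origin and round-1 category
  meta <- dplyr::left_join(geno_panel,
                           r1[, c("accession", "category")],
                           by = "accession")

  scfg <- cfg$structure
  structure_out <- list()
  upgma_out <- list()
  pcoa_out <- list()
  for (set in scfg$marker_sets) {
    d <- dist_allele_sharing(geno, marker_set = set)
    tree <- upgma(d)
    upgma_out[[set]] <- ape::write.tree(tree)
    if (!is.null(out_dir)) {
      ape::write.tree(tree, file.path(out_dir, sprintf("upgma_%s.nwk", set)))
    }
    pc <- pcoa_analysis(d)
    pcoa_out[[set]] <- pc
    save_tsv(pc$points, sprintf("pcoa_%s.tsv", set))

    fits <- list()
    for (k in scfg$k_range) {
      for (run in seq_len(scfg$runs_per_k)) {
        fits[[length(fits) + 1L]] <-
          structure_gibbs(geno, K = k, burnin = scfg$burnin,
                          reps = scfg$reps, marker_set = set,
                          seed = child_seed(seed, 1000 +
                                              1009 * match(set, scfg$marker_sets) +
                                              31 * k + run))
      }
    }
    ev <- evanno_delta_k(fits)
    best_k <- optimal_k(ev)
    kfits <- Filter(function(f) f$K == best_k, fits)
    best <- kfits[[which.max(vapply(kfits, function(f) f$L_est, numeric(1)))]]
    assignments <- assign_subpopulations(best, meta = meta)
    comp <- list(
      sowing_type = subpop_composition(assignments, "sowing_type"),
      category = subpop_composition(
        dplyr::filter(assignments, !is.na(.data$category)), "category"))
    structure_out[[set]] <- list(evanno = ev, optimal_K = best_k,
                                 fit = best, assignments = assignments,
                                 composition = comp)
    save_tsv(tibble::as_tibble(ev), sprintf("evanno_%s.tsv", set))
    save_tsv(best$Q, sprintf("structure_Q_%s_K%d.tsv", set, best_k))
    save_tsv(assignments, sprintf("subpops_%s.tsv", set))
  }

  report <- structure(list(
    config = cfg,
    provenance = list(seed = seed, config_hash = rlang::hash(cfg),
                      package_version = as.character(
                        utils::packageVersion("peaheat")),
                      r_version = R.version.string),
    temperatures = temps,
    screening = screening,
    marker_stats = mstats,
    panel_summary = psummary,
    structure = structure_out,
    upgma = upgma_out,
    pcoa = pcoa_out
  ), class = "pea_run_report")
  if (!is.null(out_dir)) {
    writeLines(format_report(report), file.path(out_dir, "report.md"))
    yaml::write_yaml(cfg, file.path(out_dir, "config_used.yaml"))
  }
  report
}

#' Render a pipeline report as markdown
#'
#' Human-readable summary of a [run_pipeline()] result: per-round level
#' histograms, HT/HS counts and KS checks, the diversity panel table, the
#' Evanno-selected K and subpopulation composition per marker set. Sections
#' whose stage is absent are marked absent rather than dropped.
#'
#' @param report A `pea_run_report`.
#' @return Character vector of markdown lines (also used by the `print`
#'   method and written as `report.md` by [run_pipeline()]).
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "pea_run_report"))
  lines <- c("# Heat-tolerance screening pipeline report", "",
             sprintf("- seed: %d", report$provenance$seed),
             sprintf("- config hash: %s", report$provenance$config_hash),
             sprintf("- package: peaheat %s", report$provenance$package_version),
             "")
  if (!is.null(report$screening)) {
    lines <- c(lines, "## Screening rounds", "")
    for (r in seq_along(report$screening$results)) {
      s <- report$screening$summaries[[r]]
      lines <- c(lines, sprintf("### Round %d", r),
                 sprintf("- classified: %d (HT %d, HS %d, excluded %d)",
                         s$n_classified, s$n_ht, s$n_hs, s$n_excluded),
                 sprintf("- level counts 1-9: %s",
                         paste(s$level_counts$n, collapse = " ")))
      if (!is.null(s$ks)) {
        lines <- c(lines, sprintf("- KS normality: D = %.3f, p = %.3f",
                                  s$ks$statistic, s$ks$p_value))
      }
      lines <- c(lines, "")
    }
    lines <- c(lines,
               sprintf("- extremely HT: %d, extremely HS: %d, consistent: %d",
                       length(report$screening$extreme_ht),
                       length(report$screening$extreme_hs),
                       nrow(report$screening$consistent)), "")
  } else {
    lines <- c(lines, "## Screening rounds", "", "(absent)", "")
  }
  if (!is.null(report$panel_summary)) {
    ps <- report$panel_summary
    lines <- c(lines, "## Marker diversity", "")
    for (i in seq_len(nrow(ps))) {
      lines <- c(lines, sprintf(
        paste0("- %s: %d markers, total NG %d, total Na %d, mean MAF %.3f, ",
               "mean GD %.3f, mean He %.3f, mean PIC %.3f ",
               "(%d high / %d moderate / %d slight)"),
        ps$marker_set[i] %||% "ALL", ps$n_markers[i], ps$total_NG[i],
        ps$total_Na[i], ps$mean_MAF[i], ps$mean_GD[i], ps$mean_He[i],
        ps$mean_PIC[i], ps$n_high[i], ps$n_moderate[i], ps$n_slight[i]))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "## Marker diversity", "", "(absent)", "")
  }
  lines <- c(lines, "## Population structure", "")
  if (length(report$structure) == 0) {
    lines <- c(lines, "(absent)", "")
  }
  for (set in names(report$structure)) {
    st <- report$structure[[set]]
    lines <- c(lines, sprintf("### %s markers", set),
               sprintf("- Evanno-optimal K: %d", st$optimal_K),
               sprintf("- PCoA first-3-axis contribution: %.1f%%",
                       sum(head(report$pcoa[[set]]$contribution, 3))))
    for (by in names(st$composition)) {
      tab <- st$composition[[by]]
      for (cl in unique(tab$cluster)) {
        sub <- tab[tab$cluster == cl, ]
        lines <- c(lines, sprintf(
          "- %s by %s: %s", cl, by,
          paste(sprintf("%s %d (%.1f%%)", sub[[by]], sub$n, sub$pct),
                collapse = ", ")))
      }
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.pea_run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
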
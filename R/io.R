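# semicolon-joined gram strings <-> numeric list-column
parse_weights <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

join_weights <- function(x) {
  vapply(x, function(w) paste(format(w, digits = 10, trim = TRUE),
                              collapse = ";"),
         character(1))
}

#' Write / read a trial-phenotype table
#'
#' Tab-delimited table with one row per accession, round, sowing stage and
#' replicate; per-plant grain weights are semicolon-joined grams.
#'
#' @param trial Trial tibble (see [sim_trial()]).
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the trial tibble with `plant_weights`
#'   restored as a list-column.
#' @export
write_trial_table <- function(trial, path) {
  out <- trial
  if (is.list(out$plant_weights)) {
    out$plant_weights <- join_weights(out$plant_weights)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           plant_weights = readr::col_character()))
  assert_columns(out, c("accession", "round", "stage", "replicate", "sown",
                        "survivors", "plant_weights"), "trial table")
  out$plant_weights <- parse_weights(out$plant_weights)
  out
}

#' Write / read a genotype matrix
#'
#' The tabular format is wide -- rows are accessions, columns markers, cells
#' allele pairs like `A/G` with missing calls `./.` -- with an optional
#' side-car marker-set table (`marker`, `marker_set`). The minimal VCF export
#' writes one record per marker with a GT field only.
#'
#' @param geno Long genotype tibble (see [sim_genotypes()]).
#' @param path Output path.
#' @param markers_path Optional path for the marker-set table (written only
#'   if `geno` has a `marker_set` column); on read, joined back if supplied.
#' @return Writers return `path` invisibly; `read_genotype_table()` returns
#'   the long genotype tibble.
#' @export
write_genotype_table <- function(geno, path, markers_path = NULL) {
  assert_columns(geno, c("accession", "marker", "genotype"), "geno")
  wide <- geno |>
    dplyr::select("accession", "marker", "genotype") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "genotype")
  readr::write_tsv(wide, path)
  if (!is.null(markers_path) && "marker_set" %in% names(geno)) {
    readr::write_tsv(dplyr::distinct(geno[, c("marker", "marker_set")]),
                     markers_path)
  }
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path, markers_path = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(wide, "accession", "genotype table")
  out <- tidyr::pivot_longer(wide, -"accession", names_to = "marker",
                             values_to = "genotype")
  if (!is.null(markers_path)) {
    sets <- readr::read_tsv(markers_path, show_col_types = FALSE)
    assert_columns(sets, c("marker", "marker_set"), "marker-set table")
    out <- dplyr::left_join(out, sets, by = "marker")
  }
  out
}

#' @rdname write_genotype_table
#' @export
write_genotype_vcf <- function(geno, path) {
  assert_columns(geno, c("accession", "marker", "genotype"), "geno")
  ix <- geno_to_indices(geno)
  acc <- rownames(ix$a1)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", acc), collapse = "\t"))
  body <- vapply(seq_along(ix$n_alleles), function(j) {
    alleles <- ix$alphabets[[j]]
    ref <- alleles[1]
    alt <- if (length(alleles) > 1) {
      paste(alleles[-1], collapse = ",")
    } else "."
    gt <- ifelse(is.na(ix$a1[, j]), "./.",
                 paste(ix$a1[, j] - 1, ix$a2[, j] - 1, sep = "/"))
    paste(c("1", j, colnames(ix$a1)[j], ref, alt, ".", ".", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
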
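check_sequence <- function(seq, allow_empty = FALSE) {
  seq <- toupper(seq)
  if (!allow_empty && any(nchar(seq) == 0)) abort("empty primer sequence")
  if (any(grepl("[^ACGT]", seq))) {
    abort("primer sequences may only contain A, C, G, T")
  }
  seq
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(seq, NULL), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

#' GC content of a primer
#'
#' @param seq Primer sequence(s), A/C/G/T only.
#' @return GC percentage, vectorized.
#' @examples
#' gc_content("ACGT") # 50
#' @export
gc_content <- function(seq) {
  seq <- check_sequence(seq)
  vapply(strsplit(seq, NULL),
         function(x) mean(x %in% c("G", "C")) * 100, numeric(1))
}

#' Primer melting temperature
#'
#' For primers of at least 14 nt, the basic GC formula
#' `Tm = 64.9 + 41 * (GC - 16.4) / length`; below 14 nt the Wallace rule
#' `2(A+T) + 4(G+C)`. Both are parameter-free approximations adequate for
#' design-rule screening, not thermodynamic predictions.
#'
#' @param seq Primer sequence(s).
#' @return Tm in deg C, vectorized, with attribute `method` ("gc" or
#'   "wallace" per sequence).
#' @examples
#' melting_temp(strrep("AC", 10)) # 20-mer, 10 GC
#' @export
melting_temp <- function(seq) {
  seq <- check_sequence(seq)
  len <- nchar(seq)
  gc_n <- round(gc_content(seq) * len / 100)
  tm <- ifelse(len >= 14,
               64.9 + 41 * (gc_n - 16.4) / len,
               2 * (len - gc_n) + 4 * gc_n)
  attr(tm, "method") <- ifelse(len >= 14, "gc", "wallace")
  tm
}

#' Longest self-complementary run within a primer
#'
#' Length of the longest substring whose reverse complement also occurs in
#' the same sequence (exhaustive scan). A hairpin- or self-dimer-prone primer
#' has a long such run; a run of 0 means not even a single base can pair.
#'
#' @param seq A single primer sequence.
#' @return Integer run length.
#' @examples
#' max_self_complementarity("ACGT")   # 4 (self-reverse-complementary)
#' max_self_complementarity("AAAAAA") # 0 (no T present)
#' @export
max_self_complementarity <- function(seq) {
  seq <- check_sequence(seq)
  stopifnot(length(seq) == 1)
  n <- nchar(seq)
  for (len in n:1) {
    for (start in 1:(n - len + 1)) {
      sub <- substr(seq, start, start + len - 1)
      if (grepl(revcomp(sub), seq, fixed = TRUE)) return(len)
    }
  }
  0L
}

#' Longest complementary run between two primers
#'
#' Longest substring of `a` whose reverse complement occurs in `b`
#' (equivalently, the longest perfectly annealing duplex between the two),
#' plus the length of the complementary overlap at the two 3' ends (the
#' longest 3'-terminal suffix of `a` that is the reverse complement of the
#' 3'-terminal suffix of `b`), which is the extension-prone configuration.
#'
#' @param a,b Primer sequences.
#' @return Tibble with `max_run` and `three_prime_run`.
#' @examples
#' cross_complementarity("AAAA", "TTTT")
#' @export
cross_complementarity <- function(a, b) {
  a <- check_sequence(a); b <- check_sequence(b)
  stopifnot(length(a) == 1, length(b) == 1)
  na <- nchar(a)
  max_run <- 0L
  for (len in na:1) {
    hit <- FALSE
    for (start in 1:(na - len + 1)) {
      sub <- substr(a, start, start + len - 1)
      if (grepl(revcomp(sub), b, fixed = TRUE)) { hit <- TRUE; break }
    }
    if (hit) { max_run <- len; break }
  }
  three <- 0L
  lim <- min(na, nchar(b))
  for (len in seq_len(lim)) {
    sa <- substr(a, na - len + 1, na)
    sb <- substr(b, nchar(b) - len + 1, nchar(b))
    if (sa == revcomp(sb)) three <- len
  }
  tibble::tibble(max_run = max_run, three_prime_run = three)
}

primer_rule <- function(rule, value, status) {
  tibble::tibble(rule = rule, value = value, status = status)
}

#' Validate primers against SNaPshot design rules
#'
#' Applies the printed design constraints per primer role. Peripheral
#' (locus-amplification) primers: length 15-30 nt, effective (tailed) length
#' <= 38 nt, GC 40-60%, Tm 58-60 deg C, bounded self-complementarity,
#' cross-complementarity with partner primers <= 4 nt, and no 3'-terminal
#' complementary overlap. Extension (single-base extension) primers: pre-tail
#' length 15-30 nt, GC 40-60%, Tm 58-60 deg C (both pre-tail), tailed length
#' >= 36 nt, and tailed length differing by 4-6 nt from primers at adjacent
#' loci (a warning only, since length spacing is a multiplexing convention,
#' not a hard constraint).
#'
#' Self-complementary runs of at least `self_warn` nt warn and of at least
#' `self_fail` nt fail (the printed rule is qualitative; thresholds are
#' configurable).
#'
#' @param primers Tibble with columns `name`, `sequence`, `role`
#'   (PERIPHERAL_F / PERIPHERAL_R / EXTENSION) and optionally `tail`
#'   (extension primers only).
#' @param self_warn,self_fail Self-complementarity warning / failure
#'   thresholds (nt).
#' @param cross_max Maximum allowed inter-primer complementary run (nt).
#' @param three_prime_max Maximum tolerated 3'-end complementary overlap
#'   (nt).
#' @param neighbor_lengths Optional numeric vector of tailed lengths of
#'   extension primers at adjacent loci.
#' @return Tibble of class `primer_report`: one row per primer and rule with
#'   `name`, `role`, `rule`, `value`, `status` (pass/warn/fail). Overall
#'   verdicts via [glance()]: pass iff no rule fails.
#' @export
validate_primers <- function(primers, self_warn = 4, self_fail = 6,
                             cross_max = 4, three_prime_max = 2,
                             neighbor_lengths = NULL) {
  assert_columns(primers, c("name", "sequence", "role"), "primers")
  if (!all(primers$role %in% c("PERIPHERAL_F", "PERIPHERAL_R", "EXTENSION"))) {
    abort("role must be PERIPHERAL_F, PERIPHERAL_R or EXTENSION")
  }
  if (!"tail" %in% names(primers)) primers$tail <- ""
  primers$tail[is.na(primers$tail)] <- ""
  if (any(primers$tail != "" & primers$role != "EXTENSION")) {
    abort("only extension primers may carry a tail")
  }
  primers$sequence <- check_sequence(primers$sequence)
  primers$tail <- toupper(primers$tail)

  rows <- lapply(seq_len(nrow(primers)), function(i) {
    p <- primers[i, ]
    len <- nchar(p$sequence)
    tailed <- nchar(p$tail) + len
    gc <- gc_content(p$sequence)
    tm <- as.numeric(melting_temp(p$sequence))
    selfc <- max_self_complementarity(p$sequence)
    st <- function(ok) ifelse(ok, "pass", "fail")
    out <- dplyr::bind_rows(
      primer_rule("length_15_30", len, st(len >= 15 && len <= 30)),
      primer_rule("gc_40_60", gc, st(gc >= 40 && gc <= 60)),
      primer_rule("tm_58_60", tm, st(tm >= 58 && tm <= 60)),
      primer_rule("self_complementarity", selfc,
                  if (selfc >= self_fail) "fail"
                  else if (selfc >= self_warn) "warn" else "pass")
    )
    if (p$role == "EXTENSION") {
      out <- dplyr::bind_rows(
        out,
        primer_rule("tailed_length_ge_36", tailed, st(tailed >= 36)))
      if (!is.null(neighbor_lengths) && length(neighbor_lengths) > 0) {
        gaps <- abs(tailed - neighbor_lengths)
        ok <- all(gaps >= 4 & gaps <= 6)
        out <- dplyr::bind_rows(
          out,
          primer_rule("adjacent_spacing_4_6", min(gaps),
                      ifelse(ok, "pass", "warn")))
      }
    } else {
      out <- dplyr::bind_rows(
        out,
        primer_rule("effective_length_le_38", tailed, st(tailed <= 38)))
      partners <- primers$sequence[-i][primers$role[-i] != "EXTENSION"]
      if (length(partners) > 0) {
        cc <- dplyr::bind_rows(
          lapply(partners, cross_complementarity, a = p$sequence))
        out <- dplyr::bind_rows(
          out,
          primer_rule("cross_complementarity_le_4", max(cc$max_run),
                      st(max(cc$max_run) <= cross_max)),
          primer_rule("three_prime_overlap", max(cc$three_prime_run),
                      st(max(cc$three_prime_run) <= three_prime_max)))
      }
    }
    dplyr::mutate(out, name = p$name, role = p$role, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("primer_report", class(out))
  out
}

#' @export
glance.primer_report <- function(x, ...) {
  x |>
    dplyr::group_by(.data$name, .data$role) |>
    dplyr::summarise(n_fail = sum(.data$status == "fail"),
                     n_warn = sum(.data$status == "warn"),
                     overall = ifelse(sum(.data$status == "fail") == 0,
                                      "pass", "fail"),
                     .groups = "drop")
}

#' Read primers from a delimited table or FASTA
#'
#' Delimited input needs columns `name`, `sequence`, `role`, optional
#' `tail`. FASTA input encodes the role (and optional `tail=SEQ`) in the
#' record description, e.g. `>P1 EXTENSION tail=TTTT`.
#'
#' @param path File path (`.fa`/`.fasta` treated as FASTA).
#' @param delim Field delimiter for tabular input.
#' @return Primer tibble suitable for [validate_primers()].
#' @export
read_primers <- function(path, delim = "\t") {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    heads <- grep("^>", lines)
    if (length(heads) == 0) abort("no FASTA records found")
    ends <- c(heads[-1] - 1, length(lines))
    recs <- lapply(seq_along(heads), function(k) {
      desc <- sub("^>", "", lines[heads[k]])
      parts <- strsplit(desc, "\\s+")[[1]]
      tail <- sub("^tail=", "", grep("^tail=", parts, value = TRUE))
      seqs <- paste(lines[(heads[k] + 1):ends[k]], collapse = "")
      tibble::tibble(
        name = parts[1],
        sequence = gsub("\\s", "", seqs),
        role = if (length(parts) > 1) parts[2] else "PERIPHERAL_F",
        tail = if (length(tail) > 0) tail else "")
    })
    dplyr::bind_rows(recs)
  } else {
    out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
    assert_columns(out, c("name", "sequence", "role"), "primer table")
    out
  }
}
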
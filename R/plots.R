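#' Plot the tolerance-level histogram of a screened round
#'
#' @param object A `pea_screening` tibble from [screen_round()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pea_screening <- function(object, ...) {
  counts <- round_summary(object)$level_counts
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$level), y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Heat-tolerance level", y = "Accessions",
                  title = "Level distribution") +
    ggplot2::theme_minimal()
}

#' Plot the Evanno delta-K profile
#'
#' @param object An `evanno_table` from [evanno_delta_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evanno_table <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dplyr::filter(dat, !is.na(.data$delta_K)),
                  ggplot2::aes(x = .data$K, y = .data$delta_K)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K),
                  title = "Evanno delta-K") +
    ggplot2::theme_minimal()
}

#' Plot the first two PCoA axes
#'
#' @param object A `pea_pcoa` from [pcoa_analysis()].
#' @param colour Optional vector (aligned with samples) to colour points by,
#'   e.g. subpopulation assignments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pea_pcoa <- function(object, colour = NULL, ...) {
  pts <- object$points
  if (!all(c("Axis1", "Axis2") %in% names(pts))) {
    abort("PCoA has fewer than two positive axes; nothing to plot")
  }
  if (!is.null(colour)) pts$colour <- colour
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, object$contribution[i])
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(x = lab(1), y = lab(2), title = "PCoA") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Plot admixture proportions as a stacked bar chart
#'
#' Accessions are ordered by their dominant cluster and membership, the
#' conventional presentation of admixture results.
#'
#' @param object A `structure_fit` from [structure_gibbs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_fit <- function(object, ...) {
  q <- tidy(object)
  ord <- assign_subpopulations(object) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$max_q))
  q$accession <- factor(q$accession, levels = ord$accession)
  ggplot2::ggplot(q, ggplot2::aes(x = .data$accession, y = .data$q,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Admixture proportion", fill = NULL,
                  title = sprintf("Admixture proportions (K = %d)", object$K)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
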
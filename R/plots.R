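#' Plot the per-base minor allele frequency profile of an assay
#'
#' The classic consensus-pileup diagnostic: MAF (in %) at each base of the
#' amplicon, flat near zero away from true variants after family consensus.
#'
#' @param pileup A [consensus_pileup()].
#' @param highlight Optional positions (e.g. panel mutation offsets) drawn
#'   in a different colour.
#' @return A ggplot object.
#' @export
plot_maf_profile <- function(pileup, highlight = integer()) {
  stopifnot(inherits(pileup, "consensus_pileup"))
  df <- tibble::as_tibble(pileup)
  df$maf_pct <- 100 * df$maf
  df$target <- df$pos %in% highlight
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$maf_pct,
                                   fill = .data$target)) +
    ggplot2::geom_col(width = 0.8, show.legend = any(df$target)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                               name = NULL,
                               labels = c(`FALSE` = "background", `TRUE` = "target")) +
    ggplot2::labs(x = "position in amplicon (bp)",
                  y = "minor allele frequency (%)",
                  title = df$assay_id[[1L]]) +
    ggplot2::theme_minimal()
}

#' Plot a patient's monitoring timeline
#'
#' Plasma draws along the treatment axis, coloured by ctDNA status, with
#' clinical events as vertical markers.
#'
#' @param timeline A [build_timeline()] object.
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline) {
  stopifnot(inherits(timeline, "patient_timeline"))
  s <- timeline$samples
  s$status <- ifelse(is.na(s$positive), "not evaluable",
                     ifelse(s$positive, "ctDNA positive", "ctDNA negative"))
  ev <- tibble::as_tibble(timeline$events)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$day, y = 0)) +
    ggplot2::geom_vline(data = ev, ggplot2::aes(xintercept = .data$day),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_text(data = ev, ggplot2::aes(x = .data$day, y = 0.6,
                                               label = .data$event),
                       angle = 90, hjust = 1, size = 2.8, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 3) +
    ggplot2::scale_colour_manual(values = c(
      "ctDNA positive" = "firebrick", "ctDNA negative" = "steelblue",
      "not evaluable" = "grey70"), name = NULL) +
    ggplot2::scale_y_continuous(limits = c(-0.5, 1), breaks = NULL) +
    ggplot2::labs(x = "days from treatment", y = NULL,
                  title = paste("patient", timeline$patient_id)) +
    ggplot2::theme_minimal()
}
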
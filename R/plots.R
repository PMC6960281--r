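#' Plot PAM site density along a contig
#'
#' Histogram of PAM occurrences by genomic position, filled by strand.
#'
#' @param sites Tibble from [scan_pams()].
#' @param binwidth Bin width in bp (default 1000).
#' @return A ggplot object.
#' @export
plot_pam_density <- function(sites, binwidth = 1000) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$pam_start,
                                      fill = .data$strand)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$contig), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = "PAM sites per bin",
                  fill = "strand") +
    ggplot2::theme_minimal()
}

#' Plot candidate positions relative to the TSS
#'
#' Distribution of `tss_offset` for designed candidates, split by
#' targeting class and seed uniqueness; the dashed line marks the TSS.
#'
#' @param design Tibble from [design_guides()].
#' @return A ggplot object.
#' @export
plot_tss_offsets <- function(design) {
  ggplot2::ggplot(design, ggplot2::aes(x = .data$tss_offset,
                                       fill = .data$unique)) +
    ggplot2::geom_histogram(binwidth = 5, position = "stack") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(.data$system),
                        ggplot2::vars(.data$targeting_class)) +
    ggplot2::labs(x = "offset from TSS (transcript axis, bp)",
                  y = "candidates", fill = "unique seed") +
    ggplot2::theme_minimal()
}

#' Plot a targetability report
#'
#' @param report Tibble from [summarize_targetability()].
#' @return A ggplot object.
#' @export
plot_targetability <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$systems,
                                       y = .data$fraction_targetable)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$fraction_targetable)), vjust = -0.4) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "targetable units (%)",
                  title = sprintf("Targetability (%s level)",
                                  unique(report$unit))) +
    ggplot2::theme_minimal()
}

#' Plot fragment coverage over a region
#'
#' @param coverage A [fragment_coverage()] result.
#' @param contig Contig id (default: first).
#' @param from,to Region bounds (default: whole contig).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, contig = NULL, from = 1, to = NULL) {
  contig <- contig %||% names(coverage$coverage)[1]
  v <- coverage_vector(coverage, contig)
  to <- to %||% length(v)
  df <- tibble(pos = seq(from, to), depth = v[seq(from, to)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = sprintf("%s position (bp)", contig),
                  y = "fractional fragment coverage") +
    ggplot2::theme_minimal()
}
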
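#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a search result into its contig table
#'
#' One row per candidate contig with scores, significance and verification
#' status.
#'
#' @param x An `saa_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.saa_result <- function(x, ...) {
  select(x$contigs, -dplyr::any_of("reads"))
}

#' One-row summary of a search result
#'
#' @param x An `saa_result`.
#' @param ... Unused.
#' @return A one-row tibble: family, contig and recruited-read counts.
#' @export
glance.saa_result <- function(x, ...) {
  tibble(n_families = nrow(x$families),
         n_contigs = nrow(x$contigs),
         n_verified = sum(x$contigs$verified),
         n_reads_recruited = nrow(x$assignments),
         total_reads = x$total_reads)
}

#' Plot contig lengths and scores of a search result
#'
#' Contig length against banded alignment score, coloured by verification
#' status and faceted by family.
#'
#' @param object An `saa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saa_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length, y = .data$score,
                                    colour = .data$verified)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "contig length (aa)", y = "banded score (bits)",
                  colour = "verified") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of per-family RPKM abundances
#'
#' @param result An `saa_result`.
#' @return A ggplot.
#' @export
plot_abundance <- function(result) {
  ggplot2::ggplot(result$families,
                  ggplot2::aes(x = stats::reorder(.data$family, -.data$rpkm),
                               y = .data$rpkm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "RPKM") +
    ggplot2::theme_minimal()
}
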
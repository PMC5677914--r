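#' Plot cohort relative coverage with copy-number bands
#'
#' Samples ordered by mean relative coverage, one point per sample,
#' shaded horizontal bands marking the classification intervals — the
#' standard way to eyeball a cohort's CYP2D6 copy-number structure.
#'
#' @param cnv_calls A `pgx_cnv_calls` tibble.
#' @param bands Band configuration used for shading.
#' @return A ggplot object.
#' @export
plot_coverage <- function(cnv_calls, bands = default_cnv_bands()) {
  df <- as_tibble(cnv_calls) |>
    arrange(.data$mean_rel_cov) |>
    mutate(rank = row_number(),
           class = ifelse(.data$conclusive,
                          paste0("CN ", .data$copy_number),
                          "inconclusive"))
  band_df <- bands$bands |>
    mutate(label = paste0("CN ", .data$copy_number))
  ggplot(df, aes(x = .data$rank, y = .data$mean_rel_cov)) +
    geom_rect(data = band_df,
              aes(xmin = -Inf, xmax = Inf, ymin = .data$lower,
                  ymax = .data$upper),
              inherit.aes = FALSE, fill = "grey85", alpha = 0.6) +
    geom_point(aes(colour = .data$class), size = 1.2) +
    labs(x = "sample (ordered by coverage)",
         y = "mean relative coverage (1 = two copies)",
         colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.pgx_cnv_calls <- function(object, ...) plot_coverage(object, ...)

#' Plot per-locus missingness by platform
#'
#' Number of samples without a usable call (missing or quality-failed)
#' at each panel locus, faceted by platform.
#'
#' @param calls A genotype tibble.
#' @param panel A `pgx_panel` (for locus order).
#' @return A ggplot object.
#' @export
plot_missingness <- function(calls, panel = load_panel()) {
  panel_tbl <- as_tibble(panel) |> arrange(.data$chrom, .data$pos)
  df <- calls |>
    group_by(.data$platform, .data$rsid, .data$gene) |>
    summarise(n_no_call = sum(.data$status != "pass"), .groups = "drop") |>
    mutate(rsid = factor(.data$rsid, levels = panel_tbl$rsid))
  ggplot(df, aes(x = .data$rsid, y = .data$n_no_call,
                 fill = .data$gene == "CYP2D6")) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~platform, ncol = 1) +
    scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    labs(x = NULL, y = "samples without a passing call") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 5))
}

#' Plot the actionability category breakdown
#'
#' @param actionability Output of [categorize_samples()].
#' @return A ggplot object.
#' @export
plot_actionability <- function(actionability) {
  df <- actionability |>
    count(.data$category) |>
    mutate(category = factor(.data$category, levels = 1:3,
                             labels = c("1: no variant of interest",
                                        "2: dosing benefit",
                                        "3: serious-risk variant")))
  ggplot(df, aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = .data$n), vjust = -0.4, size = 3) +
    labs(x = NULL, y = "samples") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
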
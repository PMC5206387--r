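# ggplot2 visualizations: survival step curves, a protein-domain lollipop
# of variant loci, and matched-pair expression dotplots.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_segment
#'   geom_line geom_hline labs theme_minimal scale_y_continuous facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1),
                  tibble(time = object$time, surv = object$surv))
  ggplot(df, aes(x = .data$time, y = .data$surv)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Years", y = "Transplant-free survival") +
    theme_minimal()
}

#' Plot the two-group survival comparison of a report
#'
#' @param object A [survival_report()].
#' @param ... Unused.
#' @return A ggplot with one step curve per group and the test p-value in
#'   the subtitle.
#' @export
autoplot.survival_report <- function(object, ...) {
  df <- purrr::imap(object$curves, function(curve, g) {
    bind_rows(tibble(time = 0, surv = 1),
              tibble(time = curve$time, surv = curve$surv)) %>%
      mutate(group = g)
  }) %>% bind_rows()
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Years", y = "Transplant-free survival",
         subtitle = sprintf("Gehan-Breslow p = %.3g", object$test$p_value)) +
    theme_minimal()
}

#' Lollipop plot of variant loci along the protein
#'
#' Distinct variants positioned by residue number, with domain boundaries
#' marked, in the style of a protein variant map.
#'
#' @param variants Annotated variant tibble (needs `residue_number`,
#'   `variant_name`, `domain_assigned`).
#' @param boundaries Domain boundaries, as in [classify_domain()].
#' @return A ggplot.
#' @export
plot_variant_domains <- function(variants,
                                 boundaries = default_domain_boundaries()) {
  pts <- variants %>% distinct(.data$variant_name, .keep_all = TRUE)
  ggplot(pts, aes(x = .data$residue_number, y = 1,
                  colour = .data$domain_assigned)) +
    geom_segment(aes(xend = .data$residue_number, y = 0, yend = 1)) +
    geom_point(size = 2) +
    geom_segment(data = boundaries,
                 aes(x = .data$start, xend = .data$end, y = 0, yend = 0,
                     colour = .data$domain),
                 linewidth = 2, inherit.aes = FALSE) +
    labs(x = "Residue", y = NULL, colour = "Domain") +
    theme_minimal()
}

#' Paired expression dotplot for one gene
#'
#' @param expr Expression tibble.
#' @param pairs Matched-pair tibble.
#' @param gene Gene to plot.
#' @return A ggplot with one line per pair connecting WT to MUT expression.
#' @export
plot_paired_expression <- function(expr, pairs, gene) {
  row <- expr[expr$gene == gene, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("gene '", gene, "' not found"))
  df <- bind_rows(
    tibble(pair = pairs$pair_id, genotype = "WT",
           value = as.numeric(row[, pairs$wt_sample])),
    tibble(pair = pairs$pair_id, genotype = "MUT",
           value = as.numeric(row[, pairs$mut_sample]))
  ) %>% mutate(genotype = factor(.data$genotype, levels = c("WT", "MUT")))
  ggplot(df, aes(x = .data$genotype, y = .data$value, group = .data$pair)) +
    geom_line(alpha = 0.5) +
    geom_point() +
    labs(x = NULL, y = "Expression (TPM)", title = gene) +
    theme_minimal()
}
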